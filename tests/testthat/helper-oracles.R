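# Independent oracles and small generators shared across tests.

rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Smith-Waterman oracle: Biostrings' local pairwiseAlignment under the same
# scoring scheme (match +1, mismatch -1; a gap of length L costs 2 + (L-1),
# i.e. gapOpening = 1, gapExtension = 1 in Biostrings' parametrisation).
sw_oracle_score <- function(q, r) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    q, r, type = "local", substitutionMatrix = mat,
    gapOpening = 1, gapExtension = 1))
}

# query = mutated substring of a random reference (point mutations and an
# occasional short indel), guaranteeing shared seeds
mutated_instance <- function(rlen = 1500, qspan = c(80, 300), mut = 0.03) {
  r <- rdna(rlen)
  a <- sample(1:(rlen - qspan[2] - 5), 1)
  b <- a + sample(qspan[1]:qspan[2], 1)
  q <- substr(r, a, b)
  qv <- strsplit(q, "")[[1]]
  nm <- max(1, stats::rpois(1, mut * length(qv)))
  pos <- sample(seq_along(qv), min(nm, length(qv)))
  qv[pos] <- vapply(qv[pos], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  q <- paste(qv, collapse = "")
  if (stats::runif(1) < 0.5) {
    ip <- sample(10:(nchar(q) - 10), 1)
    q <- paste0(substr(q, 1, ip), rdna(sample(1:3, 1)),
                substr(q, ip + 1, nchar(q)))
  }
  list(q = q, r = r)
}

# a clean synthetic subalignment row (all-match cigar); minus-strand rows
# carry oriented-query coordinates relative to a query of length qlen, as
# the aligner produces them
mk_sub <- function(qstart, qend, rstart, origin = "genome", ref_id = "ref",
                   strand = "+", score = qend - qstart, query_id = "q",
                   cigar = NULL, qlen = 6000L) {
  len <- qend - qstart
  if (is.null(cigar)) cigar <- paste0(len, "M")
  if (strand == "+") {
    qo <- c(qstart, qend)
  } else {
    qo <- c(qlen - qend, qlen - qstart)
  }
  data.frame(query_id = query_id, qstart = as.integer(qstart),
             qend = as.integer(qend), ref_id = ref_id,
             rstart = as.integer(rstart), rend = as.integer(rstart + len),
             origin = origin, strand = strand, score = as.integer(score),
             cigar = cigar, qo_start = as.integer(qo[1]),
             qo_end = as.integer(qo[2]), stringsAsFactors = FALSE)
}

# Exhaustive composition oracle for clean, query-disjoint subalignments:
# every subset whose consecutive pairs (ordered by query start) respect the
# rules is a composite.  Independent of the package's chain enumeration.
compose_oracle <- function(subs, max_gap = 200) {
  n <- nrow(subs)
  res <- list()
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    idx <- idx[order(subs$qstart[idx])]
    ok <- TRUE
    if (length(idx) > 1) {
      for (k in 1:(length(idx) - 1)) {
        a <- subs[idx[k], ]; b <- subs[idx[k + 1], ]
        if (a$qend > b$qstart) { ok <- FALSE; break }
        if (a$origin == "genome" && b$origin == "genome") {
          if (a$ref_id != b$ref_id || a$strand != b$strand) { ok <- FALSE; break }
          rgap <- if (a$strand == "+") b$rstart - a$rend else a$rstart - b$rend
          if (rgap < 0 || rgap > max_gap) { ok <- FALSE; break }
        }
      }
    }
    if (ok)
      res[[length(res) + 1L]] <- list(
        ids = paste(sort(idx), collapse = ","),
        score = sum(subs$score[idx]))
  }
  res
}

# brute-force annotation oracle: plain interval scan
annotate_oracle <- function(reference_id, tgn, features, vicinity = 100000) {
  t0 <- tgn - 1
  f <- features[features$reference_id == reference_id, , drop = FALSE]
  g <- f[f$category == "gene", , drop = FALSE]
  hit <- g[g$start <= t0 & g$end > t0, , drop = FALSE]
  hit_gene <- if (nrow(hit)) paste(hit$name[order(hit$start)], collapse = "/") else ""
  up <- g[g$end <= t0 & t0 - g$end <= vicinity, , drop = FALSE]
  upstream <- if (nrow(up)) up$name[which.max(up$end)] else ""
  dn <- g[g$start > t0 & g$start - t0 <= vicinity, , drop = FALSE]
  downstream <- if (nrow(dn)) dn$name[which.min(dn$start)] else ""
  list(hit_gene = hit_gene, upstream_gene = upstream,
       downstream_gene = downstream)
}

# per-position frequency oracle for the IUPAC consensus
consensus_oracle <- function(seqs, threshold) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T",
             AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
             CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N")
  mat <- do.call(rbind, strsplit(seqs, ""))
  vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]; col <- col[col != "N"]
    if (!length(col)) return("N")
    fr <- 100 * table(factor(col, levels = c("A", "C", "G", "T"))) / length(col)
    sel <- sort(names(fr)[fr >= threshold])
    if (!length(sel)) "N" else iupac[[paste(sel, collapse = "")]]
  }, character(1))
}
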