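#' @name subalignments
#' @title Subalignment tables
#' @description
#' A subalignment is one locally aligned query/reference segment.  The
#' aligner returns them as data.frames with columns:
#' `query_id`; `qstart`,`qend` (0-based half-open, in original query
#' coordinates); `ref_id`; `rstart`,`rend` (0-based half-open, plus strand);
#' `origin` (`"genome"` = blue, `"transposon"` = red); `strand`; `score`;
#' `cigar` (run-length M/X/I/D, I consumes query, D consumes reference); and
#' `qo_start`,`qo_end` (the interval in oriented-query coordinates that the
#' cigar walks, ascending together with the reference).  For plus-strand
#' subalignments the oriented and original intervals coincide.
NULL

parse_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MXID]", cigar))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cigar))
    stop("malformed cigar: ", cigar)
  data.frame(len = as.integer(sub("[MXID]$", "", toks)),
             op = sub("^[0-9]+", "", toks), stringsAsFactors = FALSE)
}

expand_cigar <- function(cigar) {
  runs <- parse_cigar(cigar)
  rep(runs$op, runs$len)
}

encode_cigar <- function(ops) {
  if (!length(ops)) return("")
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Recompute an alignment score from its cigar
#'
#' Sums match/mismatch columns and charges affine gap costs per I/D run
#' (first column `gap_open`, each further column `gap_extend`).  Every
#' subalignment returned by the aligner reproduces its `score` exactly under
#' this recomputation.
#'
#' @param cigar Run-length M/X/I/D string.
#' @param params [nt_params()] carrying the scoring scheme.
#' @return Integer score.
#' @export
rescore_cigar <- function(cigar, params = nt_params()) {
  runs <- parse_cigar(cigar)
  s <- 0L
  for (i in seq_len(nrow(runs))) {
    n <- runs$len[i]
    s <- s + switch(runs$op[i],
                    M = n * params$match,
                    X = n * params$mismatch,
                    I = ,
                    D = params$gap_open + (n - 1L) * params$gap_extend)
  }
  as.integer(s)
}

#' Extend a seed hit into a scored local subalignment
#'
#' Runs a banded affine-gap local alignment (Gotoh) around the seed
#' diagonal.  The explored reference window is capped at 2x the query length
#' around the seed for `"short"` interval extension and 8x for `"long"`.
#'
#' @param query Query DNA string (already oriented; use the reverse
#'   complement for minus-strand seeds).
#' @param reference Reference DNA string (plus strand).
#' @param qpos,rpos 0-based seed anchor offsets in `query` / `reference`.
#' @param params [nt_params()] (scoring scheme, band width).
#' @param extension `"short"` or `"long"` window cap.
#' @return One-row subalignment data.frame (without `query_id`/`origin`
#'   bookkeeping), or `NULL` when no positive-scoring alignment exists in
#'   the window.
#' @export
extend_seed <- function(query, reference, qpos, rpos, params = nt_params(),
                        extension = params$interval_extension) {
  mult <- if (identical(extension, "long")) 8L else 2L
  window <- mult * nchar(query)
  res <- banded_extend_cpp(toupper(query), toupper(reference),
                           as.integer(qpos), as.integer(rpos),
                           params$match, params$mismatch,
                           params$gap_open, params$gap_extend,
                           as.integer(window), params$band)
  if (res$score <= 0) return(NULL)
  data.frame(qstart = res$qstart, qend = res$qend,
             rstart = res$rstart, rend = res$rend,
             score = res$score, cigar = res$cigar,
             stringsAsFactors = FALSE)
}

# Cluster seed hits of one (ref, strand): single-linkage on the diagonal
# (offset difference <= diag_band), then split clusters whose members are
# further apart on the reference than the extension window.  One
# representative (median by reference position) is extended per cluster.
cluster_seeds <- function(qo, rpos, diag_band, max_span) {
  diag <- rpos - qo
  o <- order(diag, rpos)
  qo <- qo[o]; rpos <- rpos[o]; diag <- diag[o]
  grp <- cumsum(c(1L, diff(diag) > diag_band))
  reps <- list()
  for (g in split(seq_along(grp), grp)) {
    ro <- g[order(rpos[g])]
    sub_grp <- cumsum(c(1L, diff(rpos[ro]) > max_span))
    for (h in split(ro, sub_grp)) {
      mid <- h[ceiling(length(h) / 2)]
      reps[[length(reps) + 1L]] <- c(qo = qo[mid], rpos = rpos[mid])
    }
  }
  do.call(rbind, reps)
}

empty_subalignments <- function() {
  data.frame(query_id = character(), qstart = integer(), qend = integer(),
             ref_id = character(), rstart = integer(), rend = integer(),
             origin = character(), strand = character(), score = integer(),
             cigar = character(), qo_start = integer(), qo_end = integer(),
             stringsAsFactors = FALSE)
}

align_against_db <- function(query_id, query, db, index, params) {
  L <- nchar(query)
  hits <- lookup_seeds(index, query)
  if (!nrow(hits)) return(empty_subalignments())
  rcq <- NULL
  out <- list()
  for (strand in unique(hits$strand)) {
    hs <- hits[hits$strand == strand, , drop = FALSE]
    if (strand == "-") {
      if (is.null(rcq)) rcq <- revcomp(query)
      oriented <- rcq
      qo <- L - index$k - hs$qpos   # back to oriented coordinates
    } else {
      oriented <- query
      qo <- hs$qpos
    }
    mult <- if (identical(params$interval_extension, "long")) 8L else 2L
    for (rid in unique(hs$ref_id)) {
      sel <- hs$ref_id == rid
      reps <- cluster_seeds(qo[sel], hs$rpos[sel],
                            diag_band = 16L, max_span = mult * L)
      refseq <- db$seqs[[rid]]
      for (i in seq_len(nrow(reps))) {
        ext <- extend_seed(oriented, refseq, reps[i, "qo"], reps[i, "rpos"],
                           params)
        if (is.null(ext)) next
        if (strand == "-") {
          qstart <- L - ext$qend; qend <- L - ext$qstart
        } else {
          qstart <- ext$qstart; qend <- ext$qend
        }
        out[[length(out) + 1L]] <- data.frame(
          query_id = query_id, qstart = qstart, qend = qend,
          ref_id = rid, rstart = ext$rstart, rend = ext$rend,
          origin = db$role, strand = strand, score = ext$score,
          cigar = ext$cigar, qo_start = ext$qstart, qo_end = ext$qend,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_subalignments())
  do.call(rbind, out)
}

# Deterministic subalignment ordering: score desc, then reference id,
# reference start, strand, query start.
order_subs <- function(subs) {
  subs[order(-subs$score, subs$ref_id, subs$rstart, subs$strand, subs$qstart), ,
       drop = FALSE]
}

#' Align a query against the genome and transposon databases
#'
#' Seeds from both databases are extended and deduplicated.  Exact duplicate
#' (query, reference) interval pairs keep the best-scoring extension, and a
#' subalignment whose query interval is properly contained in that of
#' another subalignment scoring at least as high is suppressed: once a best
#' alignment covers a query range, no shorter alignment inside that range is
#' reported.
#'
#' @param query_rec One-row record data.frame (`id`, `seq`) or a named list.
#' @param gd Genome [reference_db()] (may be `NULL`).
#' @param td Transposon [reference_db()] (may be `NULL`).
#' @param params [nt_params()].
#' @param gd_index,td_index Optional prebuilt [build_index()] objects; built
#'   on the fly (at `params$nucleus_size`) when missing.
#' @return A subalignment data.frame (see [subalignments]).
#' @export
align_query <- function(query_rec, gd = NULL, td = NULL, params = nt_params(),
                        gd_index = NULL, td_index = NULL) {
  query <- toupper(query_rec$seq[1])
  query_id <- query_rec$id[1]
  if (nchar(query) < params$nucleus_size)
    stop("query ", query_id, " is shorter than the nucleus size (",
         params$nucleus_size, ")")
  if (nchar(query) > 15000)
    warning("query ", query_id, " longer than 15,000 nt; alignment may be slow")
  subs <- empty_subalignments()
  if (!is.null(gd)) {
    if (is.null(gd_index)) gd_index <- build_index(gd, params$nucleus_size)
    subs <- rbind(subs, align_against_db(query_id, query, gd, gd_index, params))
  }
  if (!is.null(td)) {
    if (is.null(td_index)) td_index <- build_index(td, params$nucleus_size)
    subs <- rbind(subs, align_against_db(query_id, query, td, td_index, params))
  }
  if (!nrow(subs)) return(subs)
  subs <- order_subs(subs)
  key <- paste(subs$ref_id, subs$strand, subs$qstart, subs$qend,
               subs$rstart, subs$rend, subs$origin)
  subs <- subs[!duplicated(key), , drop = FALSE]
  # no-shorter-alignments rule: when a best alignment covers (nearly) the
  # whole query, alignments properly nested in its query range are dropped
  n <- nrow(subs)
  qlen <- nchar(query)
  covering <- which(subs$qend - subs$qstart >= 0.9 * qlen)
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in covering) {
      if (i == j || drop[j]) next
      if (subs$qstart[j] <= subs$qstart[i] && subs$qend[j] >= subs$qend[i] &&
          (subs$qend[j] - subs$qstart[j]) > (subs$qend[i] - subs$qstart[i]) &&
          subs$score[j] >= subs$score[i]) {
        drop[i] <- TRUE
        break
      }
    }
  }
  subs <- subs[!drop, , drop = FALSE]
  rownames(subs) <- NULL
  subs
}
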