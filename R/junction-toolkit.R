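#' Crop the terminal queries (Q5'/Q3') of a transposon
#'
#' The first `crop_len` nucleotides of the transposon become Q5' and the
#' last `crop_len` become Q3'.  The default of 60 comfortably contains the
#' terminal inverted repeats of class II transposons (31 bp for P-element,
#' 12 bp for hobo) plus enough internal sequence to tell the two ends apart
#' in either insertion orientation.  Ids are suffixed `_TIR5` / `_TIR3`,
#' the header convention the junction-extraction step relies on.
#'
#' @param nt One-row record data.frame (or list with `id`, `seq`).
#' @param crop_len Crop length; the transposon must be at least twice as
#'   long.
#' @return Two-row record data.frame (Q5' then Q3').
#' @export
crop_terminal_queries <- function(nt, crop_len = 60L) {
  id <- nt$id[1]; seq <- toupper(nt$seq[1])
  n <- nchar(seq)
  if (n < 2L * crop_len)
    stop("transposon ", id, " (", n, " nt) shorter than twice the crop length")
  seq_records(id = paste0(id, c("_TIR5", "_TIR3")),
              seq = c(substr(seq, 1L, crop_len),
                      substr(seq, n - crop_len + 1L, n)))
}

clip_window <- function(lo, hi, len) {
  c(max(1L, lo), min(len, hi), lo < 1L || hi > len)
}

#' Extract junction queries (JQs) from contigs around terminal-crop hits
#'
#' For every Q5' hit an upstream genomic flank is collected and for every
#' Q3' hit a downstream flank, irrespective of insertion orientation:
#' minus-strand windows are reverse-complemented so each JQ reads
#' flank + Q5' region (side 5') or Q3' region + flank (side 3') in
#' transposon-forward coordinates.  Hits are paired per contig by the
#' expected crop-to-crop distance; when only one terminus of a remnant
#' survives, the partner JQ is built by a three-part join: the surviving
#' crop region, a window as long as the transposon, and `tail` further
#' nucleotides beyond it.  When a contig end truncates a window the JQ is
#' emitted anyway with `alert = TRUE` and an `ALERT` string in its
#' description.
#'
#' @param contigs Record data.frame of the contigs.
#' @param hits data.frame with columns `contig`, `side` (`"5'"`/`"3'"`),
#'   `coordinate` (1-based start of the crop-length match on the contig) and
#'   `strand` (`"+"`/`"-"`), as produced by [run_wf1()].
#' @param flank Flanking length collected next to each crop (default 3000,
#'   giving ~3060-nt JQs with the default crop).
#' @param nt_len Length of the transposon reference (used for pairing and
#'   the single-TIR join).
#' @param tail Extra nucleotides beyond the transposon-length window in the
#'   single-TIR join.
#' @param crop_len Terminal crop length used in the scan.
#' @param pair_slack Tolerance (nt) on the expected crop-to-crop distance
#'   when pairing 5' and 3' hits.
#' @return Record data.frame with extra columns `side`, `source_contig`,
#'   `alert`.
#' @export
extract_junction_queries <- function(contigs, hits, flank = 3000L, nt_len,
                                     tail = 2000L, crop_len = 60L,
                                     pair_slack = 500L) {
  stopifnot(all(c("contig", "side", "coordinate", "strand") %in% names(hits)))
  seqs <- contigs$seq
  names(seqs) <- contigs$id
  out <- list()
  emit <- function(contig_id, side, lo, hi, rc, joined) {
    len <- nchar(seqs[[contig_id]])
    w <- clip_window(lo, hi, len)
    alert <- as.logical(w[3])
    s <- substr(seqs[[contig_id]], w[1], w[2])
    if (rc) s <- revcomp(s)
    n_prev <- sum(vapply(out, function(x) x$source_contig == contig_id &&
                           x$side == side, logical(1)))
    tag <- if (side == "5'") "JQ5" else "JQ3"
    desc <- paste0(if (joined) "single-TIR join; " else "",
                   if (alert) "ALERT terminal remnant near contig end" else "")
    out[[length(out) + 1L]] <<- list(
      id = paste0(contig_id, "_", tag, "_", n_prev + 1L),
      desc = trimws(desc), seq = s, side = side,
      source_contig = contig_id, alert = alert)
  }

  for (cid in unique(hits$contig)) {
    if (!cid %in% names(seqs)) stop("hit references unknown contig ", cid)
    len <- nchar(seqs[[cid]])
    h <- hits[hits$contig == cid, , drop = FALSE]
    if (any(h$coordinate < 1L | h$coordinate + crop_len - 1L > len))
      stop("hit coordinate outside contig ", cid)
    h5 <- h[h$side == "5'", , drop = FALSE]
    h3 <- h[h$side == "3'", , drop = FALSE]
    used3 <- rep(FALSE, nrow(h3))
    paired5 <- rep(FALSE, nrow(h5))
    expected <- nt_len - crop_len
    for (i in seq_len(nrow(h5))) {
      delta <- if (nrow(h3)) {
        ifelse(h3$strand == h5$strand[i],
               ifelse(h5$strand[i] == "+",
                      h3$coordinate - h5$coordinate[i],
                      h5$coordinate[i] - h3$coordinate),
               NA_real_)
      } else numeric(0)
      ok <- which(!used3 & !is.na(delta) & abs(delta - expected) <= pair_slack)
      if (length(ok)) {
        j <- ok[which.min(abs(delta[ok] - expected))]
        used3[j] <- TRUE
        paired5[i] <- TRUE
      }
    }
    for (i in seq_len(nrow(h5))) {
      s <- h5$coordinate[i]
      if (h5$strand[i] == "+")
        emit(cid, "5'", s - flank, s + crop_len - 1L, FALSE, FALSE)
      else
        emit(cid, "5'", s, s + crop_len - 1L + flank, TRUE, FALSE)
      if (!paired5[i]) {  # 3' TIR lost: three-part join for the partner JQ3'
        if (h5$strand[i] == "+")
          emit(cid, "3'", s, s + crop_len + nt_len + tail - 1L, FALSE, TRUE)
        else
          emit(cid, "3'", s - nt_len - tail, s + crop_len - 1L, TRUE, TRUE)
      }
    }
    for (j in seq_len(nrow(h3))) {
      s <- h3$coordinate[j]
      if (h3$strand[j] == "+")
        emit(cid, "3'", s, s + crop_len - 1L + flank, FALSE, FALSE)
      else
        emit(cid, "3'", s - flank, s + crop_len - 1L, TRUE, FALSE)
      if (!used3[j]) {  # 5' TIR lost: join for the partner JQ5'
        if (h3$strand[j] == "+")
          emit(cid, "5'", s - nt_len - tail, s + crop_len - 1L, FALSE, TRUE)
        else
          emit(cid, "5'", s, s + crop_len + nt_len + tail - 1L, TRUE, TRUE)
      }
    }
  }
  if (!length(out))
    return(cbind(seq_records(character(0), character(0))[0, ],
                 data.frame(side = character(0), source_contig = character(0),
                            alert = logical(0))))
  df <- do.call(rbind, lapply(out, function(x)
    data.frame(x, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}

#' Flanking sequence centered on a reference coordinate
#'
#' Two local subsequences of `half_len` nucleotides around the coordinate
#' are joined into one contiguous sequence of `2 * half_len` nucleotides;
#' the coordinate itself falls in the right-hand half.  With the default
#' `half_len = 8` the output has the length of a P-element/hobo TSD window;
#' `half_len = 20` yields the 40-nt flanks convenient for motif work.
#'
#' @param gd Genome [reference_db()].
#' @param reference_id Reference name.
#' @param coordinate 1-based coordinate of interest.
#' @param half_len Half-window length (>= 1).
#' @return One-row record data.frame, FASTA-ready.
#' @export
flanking_at_coordinate <- function(gd, reference_id, coordinate,
                                   half_len = 8L) {
  stopifnot(half_len >= 1)
  refseq <- gd$seqs[[reference_id]]
  if (is.null(refseq)) stop("unknown reference ", reference_id)
  lo <- coordinate - half_len
  hi <- coordinate + half_len - 1L
  if (lo < 1L || hi > nchar(refseq))
    stop("ALERT: window around coordinate ", coordinate,
         " truncated by the end of ", reference_id)
  seq_records(id = paste0(reference_id, "_", coordinate, "_flank"),
              seq = substr(refseq, lo, hi))
}

#' IUPAC consensus of equal-length sequences
#'
#' Per position, every nucleotide whose frequency among non-N letters is at
#' least `threshold` percent enters the set mapped to an IUPAC ambiguity
#' symbol (A/C/G/T; 2-fold R/Y/S/W/K/M; 3-fold B/D/H/V; 4-fold N).  At a
#' threshold of 100 the sequences must be identical at every position, or
#' an error is raised; below that, a position where no nucleotide reaches
#' the threshold is reported as N with a warning.
#'
#' @param seqs Character vector (>= 2) of equal-length DNA strings.
#' @param threshold Inclusion threshold in percent (inclusive: "at least").
#' @return A list of class `consensus_result` with `consensus`, `threshold`
#'   and `n_sequences`.
#' @export
#' @examples
#' compute_consensus(c("ACGT", "ACGA", "ACGA", "ACGA"), threshold = 20)
compute_consensus <- function(seqs, threshold = 20) {
  seqs <- toupper(seqs)
  if (length(seqs) < 2) stop("need at least 2 sequences for a consensus")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("sequences have unequal lengths: ", paste(unique(lens), collapse = ", "))
  mat <- do.call(rbind, strsplit(seqs, ""))
  cons <- character(ncol(mat))
  warned <- FALSE
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col != "N"]
    if (!length(col)) { cons[j] <- "N"; warned <- TRUE; next }
    freq <- 100 * table(factor(col, levels = c("A", "C", "G", "T"))) / length(col)
    sel <- names(freq)[freq >= threshold]
    if (!length(sel)) {
      if (threshold >= 100)
        stop("sequences are not identical at position ", j,
             "; no consensus at a 100% threshold")
      cons[j] <- "N"; warned <- TRUE
    } else {
      cons[j] <- as.character(
        Biostrings::mergeIUPACLetters(paste(sel, collapse = "")))
    }
  }
  if (warned)
    warning("position(s) with no nucleotide at >= ", threshold,
            "% reported as N")
  structure(list(consensus = paste(cons, collapse = ""),
                 threshold = threshold, n_sequences = length(seqs)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result>", x$consensus, "(", x$n_sequences, "sequences,",
      paste0(x$threshold, "% threshold )\n"))
  invisible(x)
}
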