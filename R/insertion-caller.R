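#' Call an insertion (TGN, orientation, side) from a junction composite
#'
#' The terminal genomic nucleotide (TGN) is the first genome-derived ("blue")
#' nucleotide adjacent, on the query, to a transposon-derived ("red")
#' nucleotide at the junction border; it is reported as a 1-based coordinate
#' on the genome reference.  Orientation is 1 (plus) when the genome and
#' transposon parts align on concordant strands and 2 (minus) otherwise.
#' The side records which transposon terminus forms the junction: 5' when
#' the red part sits closer to the start of the transposon reference, 3'
#' otherwise.
#'
#' @param comp A junction composite (see [composites]).
#' @param gd Genome [reference_db()] (used for bounds checking).
#' @param params [nt_params()].
#' @param td Optional transposon [reference_db()]; when given, the side call
#'   uses the true transposon length (otherwise the red part's own span).
#' @param junction_tol Maximum query gap between the two parts of the
#'   junction.
#' @return A list of class `insertion_call` with elements `transposon`,
#'   `reference_id`, `tgn`, `orientation`, `side`, `tsd` (`NA` until
#'   [extract_tsd()] is run), `tsd_direction` (+1: the duplicated motif
#'   starts at the TGN; -1: it ends at the TGN), `score`, `source_query`.
#' @export
call_insertion <- function(comp, gd, params = nt_params(), td = NULL,
                           junction_tol = 10L) {
  parts <- comp$parts
  if (!any(parts$origin == "genome"))
    stop("composite has no genome part; insertion not callable")
  if (comp$classification != "junction")
    stop("insertion calls require a junction composite")
  blue <- red <- NULL
  blue_is_left <- NA
  for (i in seq_len(nrow(parts) - 1L)) {
    a <- parts[i, ]; b <- parts[i + 1L, ]
    if (b$qstart - a$qend > junction_tol) next
    if (a$origin == "genome" && b$origin == "transposon") {
      blue <- a; red <- b; blue_is_left <- TRUE; break
    }
    if (a$origin == "transposon" && b$origin == "genome") {
      blue <- b; red <- a; blue_is_left <- FALSE; break
    }
  }
  if (is.null(blue))
    stop("no genome-transposon junction with abutting parts in composite")

  # TGN: genome-part endpoint facing the transposon part on the query
  at_right_end <- xor(blue_is_left, blue$strand == "-")
  tgn <- if (at_right_end) blue$rend else blue$rstart + 1L
  tsd_direction <- if (at_right_end) -1L else +1L

  ref_len <- nchar(gd$seqs[[blue$ref_id]])
  if (is.null(ref_len) || length(ref_len) == 0)
    stop("reference ", blue$ref_id, " not present in the genome database")
  if (tgn < 1L || tgn > ref_len)
    stop("TGN ", tgn, " outside reference ", blue$ref_id)

  nt_len <- if (!is.null(td) && red$ref_id %in% names(td$seqs))
    nchar(td$seqs[[red$ref_id]]) else red$rend
  side <- if (red$rstart <= nt_len - red$rend) "5'" else "3'"

  structure(list(
    transposon = red$ref_id,
    reference_id = blue$ref_id,
    tgn = as.integer(tgn),
    orientation = if (blue$strand == red$strand) 1L else 2L,
    side = side,
    tsd = NA_character_,
    tsd_direction = tsd_direction,
    score = comp$total_score,
    source_query = parts$query_id[1]
  ), class = "insertion_call")
}

#' @export
print.insertion_call <- function(x, ...) {
  cat(sprintf("<insertion_call> %s @ %s:%d (orientation %d, side %s, score %d)\n",
              x$transposon, x$reference_id, x$tgn, x$orientation, x$side,
              x$score))
  invisible(x)
}

#' Extract the target site duplication at an insertion call
#'
#' Returns the `length` genomic nucleotides adjacent to the junction on the
#' genomic side — the copy of the duplicated motif that sits next to the
#' transposon.  Depending on the junction geometry the motif either ends at
#' the TGN or starts at it (`tsd_direction` of the call).
#'
#' @param call An [call_insertion()] result.
#' @param gd Genome [reference_db()].
#' @param length TSD length in bp (default 8).
#' @return The TSD as a DNA string of exactly `length` characters.
#' @export
extract_tsd <- function(call, gd, length = 8L) {
  stopifnot(inherits(call, "insertion_call"), length >= 1)
  refseq <- gd$seqs[[call$reference_id]]
  if (call$tsd_direction < 0) {
    start <- call$tgn - length + 1L; end <- call$tgn
  } else {
    start <- call$tgn; end <- call$tgn + length - 1L
  }
  if (start < 1L || end > nchar(refseq))
    stop("ALERT: TSD window [", start, ",", end, "] truncated by the end of ",
         call$reference_id)
  substr(refseq, start, end)
}
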