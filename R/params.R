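#' Runtime parameters for alignment, composition and reporting
#'
#' Bundles every tunable of the mapping heuristic.  Defaults follow the
#' recommended desktop settings for mapping class II transposons.
#'
#' @param nucleus_size Seed (k-mer) length of the alignment heuristic.
#'   Values below 10 are rarely useful and trigger a warning downstream.
#' @param picking_depth Number of distinct, equally scoring reference
#'   placements reported per query span.  With the default 1, once a query
#'   span is covered by an alignment against one reference subsequence, no
#'   other identical-scoring placement is reported.
#' @param number_of_results Maximum number of composite results kept per
#'   query after ranking by score.
#' @param interval_extension `"short"` caps the explored reference window at
#'   2x the query length around a seed, `"long"` at 8x.
#' @param bonus If `TRUE`, a junction composite whose transposon part carries
#'   an almost intact terminal inverted repeat (TIR) at the border receives a
#'   +500 score bonus, prioritising insertion candidates.
#' @param max_genomic_gap Largest reference-coordinate gap (nucleotides)
#'   across which two genome-origin subalignments are still merged into one
#'   final alignment.
#' @param tsd_flank_length Length (bp) of the TSD / flanking sequence
#'   extracted around junctions or coordinates; 8 matches the TSD of
#'   P-element and hobo in *D. melanogaster*.
#' @param consensus_threshold Minimum per-position nucleotide frequency, in
#'   percent, for a base to enter the IUPAC consensus symbol.
#' @param min_report_score Minimum subalignment score retained when scanning
#'   contigs with 60-nt terminal crops (WF1 filtering).
#' @param match,mismatch,gap_open,gap_extend Scoring scheme of the local
#'   aligner.  The defaults make a perfect 60-nt query score 60.
#' @param band Half-width, in diagonals, of the banded extension around a
#'   seed.
#'
#' @return A list of class `nt_params`.
#' @export
#' @examples
#' p <- nt_params(nucleus_size = 12)
#' p$max_genomic_gap
nt_params <- function(nucleus_size = 20,
                      picking_depth = 1,
                      number_of_results = 10,
                      interval_extension = c("short", "long"),
                      bonus = FALSE,
                      max_genomic_gap = 200,
                      tsd_flank_length = 8,
                      consensus_threshold = 20,
                      min_report_score = 40,
                      match = 1L, mismatch = -1L,
                      gap_open = -2L, gap_extend = -1L,
                      band = 32L) {
  interval_extension <- match.arg(interval_extension)
  stopifnot(nucleus_size >= 1, picking_depth >= 1, number_of_results >= 1,
            max_genomic_gap >= 0, tsd_flank_length >= 1,
            consensus_threshold > 0, band >= 1)
  if (!(match > 0 && mismatch < 0 && gap_open <= mismatch && gap_extend <= 0))
    stop("scoring scheme must satisfy match > 0 > mismatch and gaps <= mismatch")
  structure(list(
    nucleus_size = as.integer(nucleus_size),
    picking_depth = as.integer(picking_depth),
    number_of_results = as.integer(number_of_results),
    interval_extension = interval_extension,
    bonus = isTRUE(bonus),
    max_genomic_gap = as.integer(max_genomic_gap),
    tsd_flank_length = as.integer(tsd_flank_length),
    consensus_threshold = as.numeric(consensus_threshold),
    min_report_score = as.integer(min_report_score),
    match = as.integer(match), mismatch = as.integer(mismatch),
    gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
    band = as.integer(band)
  ), class = "nt_params")
}

#' Workflow presets
#'
#' `wf1_params()` configures the contig-scanning step (WF1): short interval
#' extension, picking depth 1, nucleus size 20, up to 1000 results, bonus
#' off.  `wf2_params()` configures junction-query mapping against the
#' canonical reference (WF2): short extension, picking depth 1, nucleus size
#' 30, 2 results, bonus on.
#'
#' @param ... Overrides forwarded to [nt_params()].
#' @return An `nt_params` object.
#' @export
wf1_params <- function(...) {
  args <- list(nucleus_size = 20, picking_depth = 1, number_of_results = 1000,
               interval_extension = "short", bonus = FALSE)
  do.call(nt_params, utils::modifyList(args, list(...)))
}

#' @rdname wf1_params
#' @export
wf2_params <- function(...) {
  args <- list(nucleus_size = 30, picking_depth = 1, number_of_results = 2,
               interval_extension = "short", bonus = TRUE)
  do.call(nt_params, utils::modifyList(args, list(...)))
}
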