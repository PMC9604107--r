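# per-original-query-position alignment columns of one part (M/X only)
walk_cigar_query <- function(part) {
  runs <- parse_cigar(part$cigar)
  qo <- integer(0); op <- character(0)
  q <- part$qo_start
  for (i in seq_len(nrow(runs))) {
    if (runs$op[i] %in% c("M", "X")) {
      qo <- c(qo, q:(q + runs$len[i] - 1L))
      op <- c(op, rep(runs$op[i], runs$len[i]))
      q <- q + runs$len[i]
    } else if (runs$op[i] == "I") {
      q <- q + runs$len[i]
    }
  }
  if (part$strand == "-") {
    L <- part$qstart + part$qo_end  # original query length
    qo <- L - 1L - qo
  }
  data.frame(qpos = qo, op = op, stringsAsFactors = FALSE)
}

# does the alignment cover query interval [lo, hi) almost intact?
covers_query_interval <- function(part, lo, hi, coverage_min = 0.9,
                                  identity_min = 0.9) {
  prof <- walk_cigar_query(part)
  inside <- prof$qpos >= lo & prof$qpos < hi
  aligned <- sum(inside)
  if (aligned == 0) return(FALSE)
  matches <- sum(inside & prof$op == "M")
  aligned / (hi - lo) >= coverage_min && matches / aligned >= identity_min
}

#' WF1: scan contigs with terminal crops and extract junction queries
#'
#' The transposon's Q5'/Q3' terminal crops are aligned against the contigs
#' (the ARG is the only reference loaded, as the genome database).  Hits are
#' kept when they score at least `params$min_report_score` and carry the
#' complete TIR (the TIR portion of the crop aligned at >= 90% coverage and
#' identity); picking depth and result-count limits apply per crop query.
#' Junction queries are then extracted around the surviving hits.
#'
#' @param arg Record data.frame of ARG contigs (or a genome
#'   [reference_db()]).
#' @param nt One-row transposon record.
#' @param tir5_len,tir3_len TIR lengths at the two termini (nt).
#' @param params [nt_params()]; see [wf1_params()] for the standard preset.
#'   For exhaustive discovery of identical-scoring remnants set
#'   `picking_depth` high (e.g. 10000).
#' @param crop_len Terminal crop length.
#' @param flank,tail,pair_slack Passed to [extract_junction_queries()].
#' @return list with `hits` (contig, side, coordinate, strand, score),
#'   `jqs` (junction-query records) and `crops` (the Q5'/Q3' records).
#' @export
run_wf1 <- function(arg, nt, tir5_len = 12L, tir3_len = tir5_len,
                    params = wf1_params(), crop_len = 60L, flank = 3000L,
                    tail = 2000L, pair_slack = 500L) {
  gd <- if (inherits(arg, "reference_db")) arg else reference_db(arg, "genome")
  arg_records <- seq_records(names(gd$seqs), unname(gd$seqs))
  crops <- crop_terminal_queries(nt, crop_len)
  gd_index <- build_index(gd, params$nucleus_size)
  hits <- list()
  for (i in 1:2) {
    side <- if (i == 1) "5'" else "3'"
    tir_iv <- if (i == 1) c(0L, tir5_len) else c(crop_len - tir3_len, crop_len)
    subs <- align_query(crops[i, ], gd = gd, params = params,
                        gd_index = gd_index)
    if (!nrow(subs)) next
    subs <- subs[subs$score >= params$min_report_score, , drop = FALSE]
    if (!nrow(subs)) next
    ok <- vapply(seq_len(nrow(subs)), function(r)
      covers_query_interval(subs[r, ], tir_iv[1], tir_iv[2]), logical(1))
    subs <- subs[ok, , drop = FALSE]
    if (!nrow(subs)) next
    ctx <- list(query = crops$seq[i],
                seqs = stats::setNames(as.list(gd$seqs),
                                       paste0("genome:", names(gd$seqs))))
    comps <- compose_alignments(subs, params, context = ctx)
    comps <- pick_placements(comps, params)
    for (comp in comps) {
      p <- comp$parts[which.max(comp$parts$score), ]
      hits[[length(hits) + 1L]] <- data.frame(
        contig = p$ref_id, side = side,
        coordinate = p$rstart - p$qo_start + 1L,
        strand = p$strand, score = comp$total_score,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(contig = character(), side = character(),
               coordinate = integer(), strand = character(),
               score = integer(), stringsAsFactors = FALSE)
  jqs <- extract_junction_queries(arg_records, hits, flank = flank,
                                  nt_len = nchar(nt$seq[1]), tail = tail,
                                  crop_len = crop_len,
                                  pair_slack = pair_slack)
  list(hits = hits, jqs = jqs, crops = crops)
}

#' WF2: map junction queries against the canonical reference and call insertions
#'
#' Each JQ is aligned against the CRG (genome database) plus the transposon
#' database, subalignments are composed, the insertion-candidate bonus is
#' applied (when enabled), results are re-ranked and the picking-depth rule
#' applied.  The best composite per JQ becomes one result row: a junction
#' composite yields a TGN, orientation and TSD; an all-genomic best result
#' (insertion also present in the CRG) yields a genomic row without TGN.
#'
#' @param jqs Junction-query record data.frame ([extract_junction_queries()]
#'   output or any records).
#' @param crg Canonical reference records or a genome [reference_db()].
#' @param td Transposon records or a transposon [reference_db()].
#' @param tir_features Feature data.frame with the TIR5/TIR3 intervals of
#'   the transposons (for the bonus).
#' @param params [nt_params()]; see [wf2_params()] for the standard preset.
#' @param features Optional gene/NT feature data.frame on the CRG for
#'   annotation of calls.
#' @return list with `results` (one row per JQ; see [empty_results()], plus
#'   an `overlapping_nts` column), `calls` (named list of
#'   [call_insertion()] objects for junction rows) and `composites` (named
#'   list of the retained composites per JQ).
#' @export
run_wf2 <- function(jqs, crg, td, tir_features = NULL, params = wf2_params(),
                    features = NULL) {
  gd <- if (inherits(crg, "reference_db")) crg else reference_db(crg, "genome")
  tdb <- if (inherits(td, "reference_db")) td else reference_db(td, "transposon")
  gd_index <- build_index(gd, params$nucleus_size)
  td_index <- build_index(tdb, params$nucleus_size)
  ref_seqs <- c(stats::setNames(as.list(gd$seqs),
                                paste0("genome:", names(gd$seqs))),
                stats::setNames(as.list(tdb$seqs),
                                paste0("transposon:", names(tdb$seqs))))
  rows <- list()
  calls <- list()
  kept <- list()
  wide <- nt_params_clone(params, number_of_results = max(
    params$number_of_results, 50L))
  for (i in seq_len(nrow(jqs))) {
    jq <- jqs[i, ]
    if (nchar(jq$seq) < params$nucleus_size) {
      warning("junction query ", jq$id, " shorter than the nucleus size; skipped")
      next
    }
    subs <- align_query(jq, gd = gd, td = tdb, params = params,
                        gd_index = gd_index, td_index = td_index)
    comps <- compose_alignments(subs, wide,
                                context = list(query = jq$seq,
                                               seqs = ref_seqs))
    comps <- lapply(comps, apply_bonus, td = tdb,
                    tir_features = tir_features, params = params)
    comps <- rank_composites(comps)
    comps <- comps[seq_len(min(length(comps), params$number_of_results))]
    comps <- pick_placements(comps, params)
    kept[[jq$id]] <- comps
    if (!length(comps)) {
      rows[[length(rows) + 1L]] <- result_row(jq$id, classification = "")
      next
    }
    top <- comps[[1]]
    if (top$classification == "junction") {
      call <- call_insertion(top, gd, params, td = tdb)
      call$tsd <- tryCatch(
        extract_tsd(call, gd, params$tsd_flank_length),
        error = function(e) NA_character_)
      ann <- annotate_call(call, features)
      # nested landscape: further transposons present among the parts
      others <- setdiff(
        unique(top$parts$ref_id[top$parts$origin == "transposon"]),
        call$transposon)
      ann$overlapping_nts <- paste(
        setdiff(unique(c(strsplit(ann$overlapping_nts, "/")[[1]], others)), ""),
        collapse = "/")
      calls[[jq$id]] <- call
      rows[[length(rows) + 1L]] <- result_row(
        jq$id, transposon = call$transposon,
        reference_id = call$reference_id, tgn = call$tgn,
        orientation = as.character(call$orientation),
        score = top$total_score, hit_gene = ann$hit_gene,
        upstream_gene = ann$upstream_gene,
        downstream_gene = ann$downstream_gene,
        tsd = if (is.na(call$tsd)) "" else call$tsd,
        classification = "junction",
        overlapping_nts = ann$overlapping_nts)
    } else {
      rows[[length(rows) + 1L]] <- result_row(
        jq$id, reference_id = top$parts$ref_id[1],
        score = top$total_score,
        classification = top$classification)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    cbind(empty_results(), data.frame(overlapping_nts = character()))
  list(results = results, calls = calls, composites = kept)
}

#' Build one row of the results table
#'
#' Convenience constructor with the canonical column order (see
#' [empty_results()]).
#'
#' @param query_id,transposon,reference_id,tgn,orientation,score,hit_gene,upstream_gene,downstream_gene,tsd,classification,overlapping_nts Field values.
#' @return One-row data.frame.
#' @export
result_row <- function(query_id, transposon = "", reference_id = "",
                       tgn = NA_integer_, orientation = "unknown",
                       score = NA_integer_, hit_gene = "",
                       upstream_gene = "", downstream_gene = "", tsd = "",
                       classification = "genomic", overlapping_nts = "") {
  data.frame(query_id = query_id, transposon = transposon,
             reference_id = reference_id, tgn_coordinate = tgn,
             orientation = orientation, score = score, hit_gene = hit_gene,
             upstream_gene = upstream_gene, downstream_gene = downstream_gene,
             tsd = tsd, classification = classification,
             overlapping_nts = overlapping_nts, stringsAsFactors = FALSE)
}

nt_params_clone <- function(params, ...) {
  args <- unclass(params)
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(nt_params, args)
}
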