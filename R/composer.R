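#' @name composites
#' @title Composite alignments
#' @description
#' A composite alignment is an ordered set of subalignments (by query
#' position) forming one final result.  It is represented as a list with
#' elements `parts` (subalignment data.frame, possibly junction-trimmed),
#' `total_score`, `bonus_applied`, `classification` (`"genomic"` when all
#' parts are genome-origin, `"transposon_internal"` when all are
#' transposon-origin, `"junction"` when mixed) and `placement_rank`.
NULL

# ---- junction-overlap trimming -------------------------------------------
#
# Local alignment endpoints wander past the true junction whenever the few
# bases beyond it happen to extend the score (endpoint wander of
# Smith-Waterman).  Two parts that belong to the same final result may
# therefore overlap by a handful of query bases.  Such overlaps are resolved
# by trimming before the pair rules are checked:
#   * genome vs transposon pair: the genome part is trimmed.  At a true
#     junction the transposon part sits at a terminus of the transposon
#     reference and cannot wander outward, so the transposon boundary
#     defines the junction (and hence the TGN).
#   * same-origin pair: the query-left part is trimmed at its right end.
# Overlaps wider than the band half-width are treated as genuinely
# conflicting alignments and the pair is not composed.

count_trim <- function(ops, e) {
  # how many columns to drop to remove e query-consuming columns,
  # plus any then-dangling reference-only (D) columns
  q <- 0L; n <- 0L
  for (i in seq_along(ops)) {
    n <- i
    if (ops[i] != "D") q <- q + 1L
    if (q == e) break
  }
  if (q < e) return(NA_integer_)
  while (n < length(ops) && ops[n + 1L] == "D") n <- n + 1L
  n
}

retag_part <- function(part, ops, params) {
  part$cigar <- encode_cigar(ops)
  part$score <- rescore_cigar(part$cigar, params)
  part
}

trim_part_right <- function(part, e, params) {
  ops <- expand_cigar(part$cigar)
  if (part$strand == "+") {
    n <- count_trim(rev(ops), e)
    if (is.na(n) || n >= length(ops)) return(NULL)
    removed <- ops[(length(ops) - n + 1L):length(ops)]
    ops <- ops[seq_len(length(ops) - n)]
    part$rend <- part$rend - sum(removed != "I")
    part$qo_end <- part$qo_end - e
  } else {
    n <- count_trim(ops, e)
    if (is.na(n) || n >= length(ops)) return(NULL)
    removed <- ops[seq_len(n)]
    ops <- ops[-seq_len(n)]
    part$rstart <- part$rstart + sum(removed != "I")
    part$qo_start <- part$qo_start + e
  }
  part$qend <- part$qend - e
  part <- retag_part(part, ops, params)
  if (part$score <= 0) return(NULL)
  part
}

trim_part_left <- function(part, e, params) {
  ops <- expand_cigar(part$cigar)
  if (part$strand == "+") {
    n <- count_trim(ops, e)
    if (is.na(n) || n >= length(ops)) return(NULL)
    removed <- ops[seq_len(n)]
    ops <- ops[-seq_len(n)]
    part$rstart <- part$rstart + sum(removed != "I")
    part$qo_start <- part$qo_start + e
  } else {
    n <- count_trim(rev(ops), e)
    if (is.na(n) || n >= length(ops)) return(NULL)
    removed <- ops[(length(ops) - n + 1L):length(ops)]
    ops <- ops[seq_len(length(ops) - n)]
    part$rend <- part$rend - sum(removed != "I")
    part$qo_end <- part$qo_end - e
  }
  part$qstart <- part$qstart + e
  part <- retag_part(part, ops, params)
  if (part$score <= 0) return(NULL)
  part
}

# diagonal (refpos - oriented query pos) at the middle aligned column of a
# part; robust to endpoint wander, unlike the raw interval endpoints
part_mid_diag <- function(part) {
  runs <- parse_cigar(part$cigar)
  aligned <- sum(runs$len[runs$op %in% c("M", "X")])
  target <- ceiling(aligned / 2)
  q <- part$qo_start; r <- part$rstart; seen <- 0L
  for (i in seq_len(nrow(runs))) {
    len <- runs$len[i]; op <- runs$op[i]
    if (op %in% c("M", "X")) {
      if (seen + len >= target) {
        step <- target - seen
        return((r + step - 1L) - (q + step - 1L))
      }
      seen <- seen + len; q <- q + len; r <- r + len
    } else if (op == "I") q <- q + len
    else r <- r + len
  }
  part$rstart - part$qo_start
}

# score of a part after trimming 0..emax query columns from one end
# (mirrors trim_part_right/left, including the dangling-D strip);
# -Inf marks unattainable trims
removal_scores <- function(part, emax, params, from_right) {
  ops <- expand_cigar(part$cigar)
  # original-right end corresponds to the cigar end on "+" and the cigar
  # front on "-" (the cigar walks the oriented query)
  at_cigar_end <- (part$strand == "+") == from_right
  if (!at_cigar_end) ops <- rev(ops)
  n <- length(ops)
  v <- rep(-Inf, emax + 1L)
  S <- rescore_cigar(part$cigar, params)
  mx_left <- sum(ops %in% c("M", "X"))
  refund_at <- function(i) {
    # contiguous D columns at the new end (positions i, i-1, ...)
    k <- 0L
    while (i - k >= 1L && ops[i - k] == "D") k <- k + 1L
    if (k == 0L) 0L else params$gap_open + (k - 1L) * params$gap_extend
  }
  rec <- function(s) if (s > 0) s else -Inf  # trims to <= 0 are infeasible
  if (mx_left > 0L) v[1] <- rec(S - refund_at(n))
  q_removed <- 0L
  i <- n
  while (i >= 1L && q_removed < emax) {
    op <- ops[i]
    if (op %in% c("M", "X")) {
      S <- S - if (op == "M") params$match else params$mismatch
      mx_left <- mx_left - 1L
      q_removed <- q_removed + 1L
    } else {
      # outermost column of a gap run: extension unless it is the last one
      run_last <- i == 1L || ops[i - 1L] != op
      S <- S - if (run_last) params$gap_open else params$gap_extend
      if (op == "I") q_removed <- q_removed + 1L
    }
    i <- i - 1L
    if (op %in% c("M", "X", "I") && mx_left > 0L)
      v[q_removed + 1L] <- rec(S - refund_at(i))
  }
  v
}

# Resolve a candidate consecutive pair (a query-left, b query-right).
# Returns list(a=, b=) with trimmed parts, or NULL when the pair cannot be
# composed.  Rules:
#   (a) two genome-origin parts merge only on the same reference and strand,
#       collinearly, with genomic distance >= 0 and <= max_genomic_gap;
#   (b) any pair involving a transposon-origin part composes freely.
# Query overlaps (endpoint wander of the local aligner) are resolved by the
# split point that maximizes the summed trimmed score; among ties the
# transposon part of a junction pair keeps its columns (at a true junction
# it is anchored at a transposon terminus), otherwise the query-left part
# is trimmed.  Overlaps spanning most of either part mark genuinely
# conflicting alignments and are not composed.  The genomic distance
# between two blue parts is measured from their mid-part diagonals plus the
# unaligned query gap, which keeps the rule exact even when endpoints
# wander.
join_pair <- function(a, b, params, context = NULL) {
  e <- a$qend - b$qstart
  if (e > 0) {
    if (e >= 0.8 * min(a$qend - a$qstart, b$qend - b$qstart)) return(NULL)
    va <- removal_scores(a, e, params, from_right = TRUE)
    vb <- removal_scores(b, e, params, from_right = FALSE)
    tot <- va + rev(vb)   # tot[i] = trim a by i-1, b by e-(i-1)
    if (!any(is.finite(tot))) return(NULL)
    prefer_intact_b <- a$origin == "genome" && b$origin == "transposon"
    best <- if (prefer_intact_b) max(which(tot == max(tot)))
            else if (a$origin == "transposon" && b$origin == "genome")
              min(which(tot == max(tot)))
            else max(which(tot == max(tot)))
    e_a <- best - 1L
    e_b <- e - e_a
    if (e_a > 0L) {
      a <- trim_part_right(a, e_a, params)
      if (!is.null(a) && !is.null(context)) a <- reoptimize_part(a, params, context)
    }
    if (e_b > 0L) {
      b <- trim_part_left(b, e_b, params)
      if (!is.null(b) && !is.null(context)) b <- reoptimize_part(b, params, context)
    }
    if (is.null(a) || is.null(b)) return(NULL)
    if (a$qend > b$qstart) return(NULL)
  }
  if (a$origin == "genome" && b$origin == "genome") {
    if (a$ref_id != b$ref_id || a$strand != b$strand) return(NULL)
    qgap <- b$qstart - a$qend
    dd <- part_mid_diag(b) - part_mid_diag(a)
    rgap <- if (a$strand == "+") dd + qgap else -dd + qgap
    if (rgap < 0 || rgap > params$max_genomic_gap) return(NULL)
  }
  list(a = a, b = b)
}

# Re-optimize a trimmed part: the optimal alignment of a query subinterval
# need not be the prefix/suffix of the whole part's optimal path, so after a
# junction trim the part is re-aligned (banded, within its own query
# interval and a padded reference window) when sequence context is known.
reoptimize_part <- function(part, params, context) {
  key <- paste0(part$origin, ":", part$ref_id)
  refseq <- context$seqs[[key]]
  if (is.null(refseq)) return(part)
  L <- nchar(context$query)
  oq <- if (part$strand == "-") {
    if (is.null(context$rc_query)) revcomp(context$query) else context$rc_query
  } else context$query
  sq <- substr(oq, part$qo_start + 1L, part$qo_end)
  pad <- 2L * params$band
  wlo <- max(0L, part$rstart - pad)
  whi <- min(nchar(refseq), part$rend + pad)
  rwin <- substr(refseq, wlo + 1L, whi)
  res <- banded_extend_cpp(sq, rwin, 0L, part$rstart - wlo,
                           params$match, params$mismatch,
                           params$gap_open, params$gap_extend,
                           as.integer(2L * nchar(sq) + pad), params$band)
  if (res$score <= part$score) return(part)
  part$qo_start <- part$qo_start + res$qstart
  part$qo_end <- part$qo_start + (res$qend - res$qstart)
  part$rstart <- wlo + res$rstart
  part$rend <- wlo + res$rend
  if (part$strand == "-") {
    part$qstart <- L - part$qo_end
    part$qend <- L - part$qo_start
  } else {
    part$qstart <- part$qo_start
    part$qend <- part$qo_end
  }
  part$score <- res$score
  part$cigar <- res$cigar
  part
}

classify_parts <- function(parts) {
  orig <- unique(parts$origin)
  if (length(orig) > 1) "junction"
  else if (orig == "genome") "genomic"
  else "transposon_internal"
}

new_composite <- function(parts) {
  list(parts = parts, total_score = as.integer(sum(parts$score)),
       bonus_applied = FALSE, classification = classify_parts(parts),
       placement_rank = NA_integer_)
}

#' Compose subalignments into ranked final alignments
#'
#' Enumerates every rule-respecting ordered subset of the subalignments of
#' one query: parts are ordered by query position and must not overlap on
#' the query (small junction overlaps are resolved by trimming, see
#' Details in [composites]); two genome-origin ("blue") parts merge only
#' when they sit collinearly on the same reference with a reference gap
#' between 0 and `params$max_genomic_gap`; pairs involving a
#' transposon-origin ("red") part compose without overlap or gap
#' restrictions, which is what permits junction, self-insertion and
#' internally deleted transposon results.  Composites are ranked by total
#' score (ties: fewer parts, then reference id, then leftmost reference
#' start) and truncated to `params$number_of_results`.
#'
#' @param subs Subalignment data.frame from [align_query()] (single query).
#' @param params [nt_params()].
#' @param max_composites Safety cap on the enumeration.
#' @param context Optional sequence context: a list with `query` (the query
#'   string) and `seqs` (reference sequences named `"<origin>:<ref_id>"`).
#'   When given, a part trimmed at a junction is re-aligned within its
#'   trimmed query interval, so every part is the optimal alignment of its
#'   own subinterval (the optimum of a whole query need not contain the
#'   optimum of a prefix).  The workflows supply this automatically.
#' @return List of composites (see [composites]).
#' @export
compose_alignments <- function(subs, params = nt_params(),
                               max_composites = 20000L, context = NULL) {
  if (!is.null(context) && is.null(context$rc_query))
    context$rc_query <- revcomp(context$query)
  if (!nrow(subs)) return(list())
  if (length(unique(subs$query_id)) > 1)
    stop("compose_alignments expects subalignments of a single query")
  o <- order(subs$qstart, subs$qend, subs$ref_id, subs$rstart, subs$strand)
  subs <- subs[o, , drop = FALSE]
  n <- nrow(subs)
  composites <- list()
  overflow <- FALSE

  extend_chain <- function(parts, last_idx) {
    if (length(composites) >= max_composites) { overflow <<- TRUE; return() }
    composites[[length(composites) + 1L]] <<- new_composite(
      do.call(rbind, parts))
    if (last_idx >= n) return()
    last <- parts[[length(parts)]]
    for (j in (last_idx + 1L):n) {
      joined <- join_pair(last, subs[j, , drop = FALSE], params, context)
      if (is.null(joined)) next
      new_parts <- parts
      new_parts[[length(new_parts)]] <- joined$a
      new_parts[[length(new_parts) + 1L]] <- joined$b
      extend_chain(new_parts, j)
      if (overflow) return()
    }
  }
  for (i in seq_len(n)) {
    extend_chain(list(subs[i, , drop = FALSE]), i)
    if (overflow) break
  }
  if (overflow)
    warning("composite enumeration truncated at ", max_composites,
            " candidates")
  composites <- rank_composites(composites)
  composites[seq_len(min(length(composites), params$number_of_results))]
}

rank_composites <- function(composites) {
  if (!length(composites)) return(composites)
  score <- vapply(composites, `[[`, integer(1), "total_score")
  nparts <- vapply(composites, function(c) nrow(c$parts), integer(1))
  ref1 <- vapply(composites, function(c) c$parts$ref_id[1], character(1))
  rmin <- vapply(composites, function(c) min(c$parts$rstart), integer(1))
  q1 <- vapply(composites, function(c) min(c$parts$qstart), integer(1))
  composites[order(-score, nparts, ref1, rmin, q1)]
}

# per-reference-position alignment columns of one part (M/X only)
walk_cigar_ref <- function(part) {
  runs <- parse_cigar(part$cigar)
  refpos <- integer(0); op <- character(0)
  r <- part$rstart
  for (i in seq_len(nrow(runs))) {
    if (runs$op[i] %in% c("M", "X")) {
      refpos <- c(refpos, r:(r + runs$len[i] - 1L))
      op <- c(op, rep(runs$op[i], runs$len[i]))
      r <- r + runs$len[i]
    } else if (runs$op[i] == "D") {
      r <- r + runs$len[i]
    }
  }
  data.frame(refpos = refpos, op = op, stringsAsFactors = FALSE)
}

#' Apply the insertion-candidate score bonus
#'
#' A junction composite whose transposon part abuts a genome part at the
#' query junction and whose border-adjacent terminal segment carries an
#' almost intact annotated TIR (coverage and identity both at least 90%
#' over the TIR interval) receives a one-time +500 score bonus.  A no-op
#' when the bonus option is off or the composite is not a junction.
#'
#' @param comp A composite (see [composites]).
#' @param td Transposon [reference_db()] (unused directly; kept for the
#'   module contract and future per-NT options).
#' @param tir_features Feature data.frame from [annotate_transposon()]
#'   holding `TIR5`/`TIR3` intervals of the transposon(s).
#' @param params [nt_params()]; the bonus fires only when `params$bonus`.
#' @param identity_min,coverage_min "Almost intact" thresholds.
#' @param junction_tol Maximum query gap (nt) between the two parts for them
#'   to count as abutting, and maximum distance between the border reference
#'   endpoint and the TIR interval.
#' @return The composite, with `total_score` increased by 500 and
#'   `bonus_applied = TRUE` when the conditions hold.
#' @export
apply_bonus <- function(comp, td = NULL, tir_features = NULL,
                        params = nt_params(), identity_min = 0.9,
                        coverage_min = 0.9, junction_tol = 10L) {
  if (!params$bonus || comp$classification != "junction" ||
      comp$bonus_applied || is.null(tir_features) || !nrow(tir_features))
    return(comp)
  parts <- comp$parts
  tirs <- tir_features[tir_features$category %in% c("TIR5", "TIR3"), ,
                       drop = FALSE]
  if (!nrow(tirs)) return(comp)
  for (i in seq_len(nrow(parts) - 1L)) {
    a <- parts[i, ]; b <- parts[i + 1L, ]
    is_junction <- xor(a$origin == "transposon", b$origin == "transposon")
    if (!is_junction) next
    if (b$qstart - a$qend > junction_tol) next
    red_is_left <- a$origin == "transposon"
    red <- if (red_is_left) a else b
    # reference endpoint of the transposon part facing the junction
    facing_right <- xor(red_is_left, red$strand == "-")
    border_ref <- if (facing_right) red$rend - 1L else red$rstart
    cand <- tirs[tirs$reference_id == red$ref_id, , drop = FALSE]
    for (t in seq_len(nrow(cand))) {
      ts <- cand$start[t]; te <- cand$end[t]
      if (border_ref < ts - junction_tol || border_ref >= te + junction_tol)
        next
      prof <- walk_cigar_ref(red)
      inside <- prof$refpos >= ts & prof$refpos < te
      aligned <- sum(inside)
      if (aligned == 0) next
      matches <- sum(inside & prof$op == "M")
      if (aligned / (te - ts) >= coverage_min &&
          matches / aligned >= identity_min) {
        comp$total_score <- comp$total_score + 500L
        comp$bonus_applied <- TRUE
        return(comp)
      }
    }
  }
  comp
}

#' Limit equal-scoring placements per query span (picking depth)
#'
#' Among equal-scoring composites covering the same query span, at most
#' `params$picking_depth` distinct reference placements are kept: once a
#' query span is covered by an alignment against one reference subsequence,
#' further identical-scoring placements at other coordinates are dropped.
#' Surviving composites get a `placement_rank` within their group.
#'
#' @param composites Ranked list of composites.
#' @param params [nt_params()].
#' @return Filtered list, global rank order preserved.
#' @export
pick_placements <- function(composites, params = nt_params()) {
  if (!length(composites)) return(composites)
  keys <- vapply(composites, function(c)
    paste(c$total_score, min(c$parts$qstart), max(c$parts$qend)),
    character(1))
  seen <- new.env(parent = emptyenv())
  keep <- logical(length(composites))
  for (i in seq_along(composites)) {
    sig <- paste(composites[[i]]$parts$ref_id,
                 composites[[i]]$parts$rstart,
                 composites[[i]]$parts$strand, collapse = ";")
    got <- if (is.null(seen[[keys[i]]])) character(0) else seen[[keys[i]]]
    if (sig %in% got) {
      pos <- match(sig, got)
      keep[i] <- pos <= params$picking_depth
    } else {
      got <- c(got, sig)
      seen[[keys[i]]] <- got
      keep[i] <- length(got) <= params$picking_depth
    }
    if (keep[i])
      composites[[i]]$placement_rank <- match(sig, seen[[keys[i]]])
  }
  composites[keep]
}
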