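#' Feature tables
#'
#' Annotation features are data.frames with columns `reference_id`, `name`,
#' `category` (`gene`, `transposon`, `TIR5`, `TIR3`, `exon`, `UTR`,
#' `other`), `start`, `end` and `strand`.  Intervals are 0-based,
#' end-exclusive: **the annotation line referring to the first nucleotide of
#' a sequence starts at coordinate 0** (a 1-based interval 1..31 becomes
#' 0..31).  GFF3 input (1-based, end-inclusive) is converted on read.
#'
#' @param reference_id,name,category,start,end,strand Column vectors.
#' @return A validated feature data.frame.
#' @export
feature_table <- function(reference_id = character(), name = character(),
                          category = character(), start = integer(),
                          end = integer(), strand = "+") {
  cats <- c("gene", "transposon", "TIR5", "TIR3", "exon", "UTR", "other")
  category <- as.character(category)
  if (length(category) && !all(category %in% cats))
    stop("unknown feature category: ",
         paste(setdiff(category, cats), collapse = ", "))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(end <= start))
    stop("features need 0 <= start < end")
  data.frame(reference_id = as.character(reference_id),
             name = as.character(name), category = category,
             start = start, end = end,
             strand = rep_len(as.character(strand), length(start)),
             stringsAsFactors = FALSE)
}

#' Read annotation features from GFF3
#'
#' Uses `rtracklayer` for parsing; 1-based inclusive GFF coordinates are
#' converted to the package's 0-based end-exclusive convention.  The feature
#' name is taken from the `Name`, `ID` or `gene_id` attribute (first
#' available); GFF types `gene`/`pseudogene` map to category `gene`,
#' types containing "transpos" to `transposon`, `exon` to `exon`,
#' UTR types to `UTR`, anything else to `other`.
#'
#' @param path GFF3 file.
#' @return Feature data.frame (see [feature_table()]).
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  nm <- rep(NA_character_, length(gr))
  for (attr in c("Name", "ID", "gene_id")) {
    if (attr %in% names(md)) {
      v <- as.character(md[[attr]])
      nm <- ifelse(is.na(nm) & !is.na(v), v, nm)
    }
  }
  nm[is.na(nm)] <- paste0("feature_", seq_len(sum(is.na(nm))))
  type <- tolower(as.character(md$type))
  category <- rep("other", length(gr))
  category[type %in% c("gene", "pseudogene")] <- "gene"
  category[grepl("transpos", type)] <- "transposon"
  category[type == "exon"] <- "exon"
  category[grepl("utr", type)] <- "UTR"
  feature_table(reference_id = as.character(GenomicRanges::seqnames(gr)),
                name = nm, category = category,
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr),
                strand = as.character(GenomicRanges::strand(gr)))
}

#' Read annotation features from the minimal 5/6-column TSV
#'
#' Columns: reference_id, start, end, name, category, (optional) strand.
#' Coordinates are 0-based, end-exclusive — the first nucleotide of a
#' sequence is coordinate 0.
#'
#' @param path TSV file (no header).
#' @return Feature data.frame.
#' @export
read_features_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 5) stop("TE-annotation TSV needs at least 5 columns")
  feature_table(reference_id = df[[1]], start = df[[2]], end = df[[3]],
                name = df[[4]], category = df[[5]],
                strand = if (ncol(df) >= 6) df[[6]] else "+")
}

#' Annotate an insertion call with the local gene landscape
#'
#' Reports the hit gene(s) whose interval contains the TGN (overlapping
#' genes are joined with "/"), the nearest non-overlapping upstream and
#' downstream genes within `vicinity` nucleotides, and any
#' transposon-category features containing the TGN (the nested-insertion
#' landscape).
#'
#' @param call An [call_insertion()] result (or any list with
#'   `reference_id` and 1-based `tgn`).
#' @param features Feature data.frame.
#' @param vicinity Search radius for flanking genes (bp).
#' @return list with `hit_gene`, `upstream_gene`, `downstream_gene`,
#'   `overlapping_nts` (character; empty strings when absent).
#' @export
annotate_call <- function(call, features, vicinity = 100000L) {
  empty <- list(hit_gene = "", upstream_gene = "", downstream_gene = "",
                overlapping_nts = "")
  if (is.null(features) || !nrow(features)) return(empty)
  f <- features[features$reference_id == call$reference_id, , drop = FALSE]
  if (!nrow(f)) return(empty)
  t0 <- call$tgn - 1L  # 0-based position of the TGN
  genes <- f[f$category == "gene", , drop = FALSE]
  hit <- upstream <- downstream <- ""
  if (nrow(genes)) {
    ir <- IRanges::IRanges(start = genes$start + 1L, end = genes$end)
    ov <- IRanges::overlapsAny(ir, IRanges::IRanges(t0 + 1L, t0 + 1L))
    if (any(ov)) {
      hg <- genes[ov, , drop = FALSE]
      hit <- paste(hg$name[order(hg$start)], collapse = "/")
    }
    up <- genes[!ov & genes$end <= t0, , drop = FALSE]
    if (nrow(up)) {
      up <- up[t0 - up$end <= vicinity, , drop = FALSE]
      if (nrow(up)) upstream <- up$name[which.max(up$end)]
    }
    dn <- genes[!ov & genes$start > t0, , drop = FALSE]
    if (nrow(dn)) {
      dn <- dn[dn$start - t0 <= vicinity, , drop = FALSE]
      if (nrow(dn)) downstream <- dn$name[which.min(dn$start)]
    }
  }
  nts <- f[f$category == "transposon" & f$start <= t0 & f$end > t0, ,
           drop = FALSE]
  list(hit_gene = hit, upstream_gene = upstream, downstream_gene = downstream,
       overlapping_nts = paste(nts$name, collapse = "/"))
}

#' Annotate a transposon record with its TIRs and extra features
#'
#' Intervals are supplied in the 0-based, end-exclusive convention (a
#' 31-bp TIR starting at the first nucleotide is `c(0, 31)`).  The TIR5 and
#' TIR3 features produced here are what the insertion-candidate bonus
#' ([apply_bonus()]) consumes.
#'
#' @param nt One-row record data.frame (or list with `id`, `seq`).
#' @param tir5,tir3 Integer vectors `c(start, end)`, 0-based end-exclusive.
#' @param extra Optional feature data.frame with additional annotations on
#'   the transposon (exons, UTRs, ...).
#' @return Feature data.frame.
#' @export
annotate_transposon <- function(nt, tir5, tir3, extra = NULL) {
  id <- nt$id[1]; len <- nchar(nt$seq[1])
  chk <- function(iv, label) {
    if (length(iv) != 2 || iv[1] < 0 || iv[2] <= iv[1] || iv[2] > len)
      stop(label, " interval [", paste(iv, collapse = ","),
           ") outside transposon bounds [0,", len, ")")
  }
  chk(tir5, "TIR5"); chk(tir3, "TIR3")
  feats <- feature_table(
    reference_id = c(id, id), name = c("TIR5", "TIR3"),
    category = c("TIR5", "TIR3"),
    start = c(tir5[1], tir3[1]), end = c(tir5[2], tir3[2]))
  if (!is.null(extra) && nrow(extra)) {
    bad <- extra$start < 0 | extra$end > len
    if (any(bad)) stop("extra feature interval outside transposon bounds")
    feats <- rbind(feats, extra)
  }
  feats
}
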