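#' Sequence record tables
#'
#' Sequences are passed around as plain data frames with columns `id`,
#' `desc` and `seq` (uppercase DNA over A/C/G/T/N).  `seq_records()` builds
#' and validates such a table; letters outside the alphabet (including IUPAC
#' ambiguity codes in input files) are normalized to `N` and counted in a
#' message.
#'
#' @param id Character vector of record identifiers (non-empty, unique).
#' @param seq Character vector of sequences.
#' @param desc Optional descriptions (FASTA header remainder).
#' @return A data.frame with columns `id`, `desc`, `seq`.
#' @export
seq_records <- function(id, seq, desc = "") {
  id <- as.character(id); seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (any(!nzchar(id))) stop("record ids must be non-empty")
  dup <- unique(id[duplicated(id)])
  if (length(dup)) stop("duplicate record id(s): ", paste(dup, collapse = ", "))
  if (any(!nzchar(seq))) stop("empty sequence for record(s): ",
                              paste(id[!nzchar(seq)], collapse = ", "))
  n_bad <- sum(vapply(gregexpr("[^ACGTN]", seq), function(m)
    if (m[1] == -1L) 0L else length(m), integer(1)))
  if (n_bad > 0) {
    seq <- gsub("[^ACGTN]", "N", seq)
    message("normalized ", n_bad, " non-ACGTN letter(s) to N")
  }
  data.frame(id = id, desc = rep_len(as.character(desc), length(id)),
             seq = seq, stringsAsFactors = FALSE)
}

#' Read a (multi-)FASTA file
#'
#' Order is preserved; sequences are uppercased; non-ACGTN letters are
#' normalized to `N`.  Duplicate ids and empty files are errors.
#'
#' @param path Path to a FASTA file.
#' @return A record data.frame as produced by [seq_records()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA format error: no records in ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_records(id, as.character(set), desc)
}

#' Write records to FASTA
#'
#' @param records Record data.frame ([seq_records()]).
#' @param path Output path.
#' @param width Line width for sequence folding.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  desc <- if ("desc" %in% names(records)) records$desc else ""
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Convert a multi-FASTA of contigs to headerless RAW files
#'
#' Every header must begin with `contig_<number>` (after the `>`); one file
#' `<id>.raw` per record is written to `outdir`, containing the bare
#' sequence with no header and no line breaks.
#'
#' @param path Multi-FASTA input.
#' @param outdir Output directory (created if missing).
#' @return Character vector of written file paths.
#' @export
fasta_to_raw <- function(path, outdir) {
  recs <- read_fasta(path)
  bad <- !grepl("^contig_[0-9]+$", recs$id)
  if (any(bad))
    stop("header does not follow the contig_<number> convention: \">",
         recs$id[which(bad)[1]], "\"")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  out <- file.path(outdir, paste0(recs$id, ".raw"))
  for (i in seq_len(nrow(recs))) cat(recs$seq[i], file = out[i], sep = "")
  out
}

#' Columns of the exported results table, in order.
#' @keywords internal
result_columns <- function() {
  c("query_id", "transposon", "reference_id", "tgn_coordinate", "orientation",
    "score", "hit_gene", "upstream_gene", "downstream_gene", "tsd",
    "classification")
}

#' An empty results table with the canonical column order.
#' @return A zero-row data.frame with the result columns.
#' @export
empty_results <- function() {
  df <- data.frame(query_id = character(), transposon = character(),
                   reference_id = character(), tgn_coordinate = integer(),
                   orientation = character(), score = integer(),
                   hit_gene = character(), upstream_gene = character(),
                   downstream_gene = character(), tsd = character(),
                   classification = character(), stringsAsFactors = FALSE)
  df[, result_columns()]
}

#' Export mapping/annotation results as CSV
#'
#' Writes an RFC-4180 CSV (UTF-8, comma separator, character fields quoted)
#' with a fixed, deterministic column order: query_id, transposon,
#' reference_id, tgn_coordinate, orientation, score, hit_gene,
#' upstream_gene, downstream_gene, tsd, classification.
#'
#' @param rows Results data.frame (see [empty_results()] for the schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_results_csv <- function(rows, path) {
  cols <- result_columns()
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols))
    stop("results table lacks column(s): ", paste(missing_cols, collapse = ", "))
  utils::write.csv(rows[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a plain-text coordinate list
#'
#' One 1-based coordinate per line; blank lines are skipped.  The target
#' reference is supplied separately (the file carries coordinates only).
#'
#' @param path Text file with one integer coordinate per line.
#' @param reference_id Reference (chromosome/contig) the coordinates refer to.
#' @return data.frame with columns `reference_id`, `coordinate`.
#' @export
read_coordinate_list <- function(path, reference_id) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  vals <- suppressWarnings(as.integer(trimws(lines[keep])))
  bad <- which(is.na(vals) | trimws(lines[keep]) != as.character(vals))
  if (length(bad))
    stop("cannot parse coordinate at line ", keep[bad[1]], ": \"",
         trimws(lines[keep[bad[1]]]), "\"")
  data.frame(reference_id = rep(reference_id, length(vals)),
             coordinate = vals, stringsAsFactors = FALSE)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
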