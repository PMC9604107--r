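#' Reference databases (genome database GD / transposon database TD)
#'
#' A reference database holds named sequences with a role: `"genome"` (its
#' subalignments are the "blue" parts) or `"transposon"` ("red" parts).  The
#' same sequence may be loaded in both databases.
#'
#' @param records Record data.frame ([seq_records()] / [read_fasta()]).
#' @param role `"genome"` or `"transposon"`.
#' @return An object of class `reference_db`.
#' @export
#' @examples
#' gd <- reference_db(seq_records("chr1", "ACGTACGT"), "genome")
reference_db <- function(records, role = c("genome", "transposon")) {
  role <- match.arg(role)
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  records <- seq_records(records$id, records$seq,
                         if ("desc" %in% names(records)) records$desc else "")
  seqs <- records$seq
  names(seqs) <- records$id
  structure(list(seqs = seqs, role = role), class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("<reference_db> role:", x$role, "-", length(x$seqs), "sequence(s),",
      sum(nchar(x$seqs)), "nt total\n")
  invisible(x)
}

kmerize <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Build a k-mer seed index over a reference database
#'
#' Every k-mer occurrence of every entry is recorded exactly once per
#' (reference, offset) on the plus strand; reverse-complement matching is
#' obtained at lookup time by querying both orientations of the query
#' (see [lookup_seeds()]).  The seed length k is the "nucleus size" of the
#' alignment heuristic; values below 10 are allowed but warned about, as
#' they flood downstream steps with spurious partial alignments.
#'
#' @param db A [reference_db()].
#' @param k Seed length (nucleus size), `k >= 4`.
#' @return An object of class `seed_index`.
#' @export
build_index <- function(db, k) {
  stopifnot(inherits(db, "reference_db"))
  k <- as.integer(k)
  if (k < 4) stop("nucleus size must be >= 4")
  if (k < 10) warning("nucleus size ", k, " is below the minimal effective value 10")
  min_len <- min(nchar(db$seqs))
  if (k > min_len)
    stop("nucleus size ", k, " exceeds the shortest reference (", min_len, " nt)")
  ref_ids <- character(0); offs <- integer(0); kms <- character(0)
  for (id in names(db$seqs)) {
    km <- kmerize(db$seqs[[id]], k)
    kms <- c(kms, km)
    offs <- c(offs, seq_along(km) - 1L)
    ref_ids <- c(ref_ids, rep(id, length(km)))
  }
  keys <- unique(kms)
  postings <- split(seq_along(kms), factor(kms, levels = keys))
  structure(list(k = k, role = db$role, keys = keys, postings = postings,
                 ref = ref_ids, off = offs),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("<seed_index> k =", x$k, "-", length(x$ref), "postings over",
      length(x$keys), "distinct k-mers (role:", paste0(x$role, ")\n"))
  invisible(x)
}

lookup_one_strand <- function(index, oriented_query) {
  k <- index$k
  qk <- kmerize(oriented_query, k)
  if (!length(qk)) return(NULL)
  m <- match(qk, index$keys)
  hit_q <- which(!is.na(m))
  if (!length(hit_q)) return(NULL)
  posting_idx <- index$postings[m[hit_q]]
  counts <- lengths(posting_idx)
  flat <- unlist(posting_idx, use.names = FALSE)
  data.frame(qpos = rep(hit_q - 1L, counts),
             ref_id = index$ref[flat],
             rpos = index$off[flat],
             stringsAsFactors = FALSE)
}

#' Exact seed matches between a query and an indexed database
#'
#' Both strands are searched: the plus strand directly, the minus strand by
#' matching the reverse complement of the query against the plus-strand
#' index.  Query offsets are reported in the coordinates of the original
#' query for both strands.
#'
#' @param index A [build_index()] result.
#' @param query A DNA string with `nchar(query) >= k`.
#' @return data.frame with columns `qpos`, `ref_id`, `rpos` (0-based) and
#'   `strand` (`"+"`/`"-"`); zero rows when nothing matches.
#' @export
lookup_seeds <- function(index, query) {
  query <- toupper(query)
  k <- index$k
  if (nchar(query) < k) stop("query shorter than nucleus size ", k)
  plus <- lookup_one_strand(index, query)
  if (!is.null(plus)) plus$strand <- "+"
  rcq <- revcomp(query)
  minus <- lookup_one_strand(index, rcq)
  if (!is.null(minus)) {
    # convert offsets in the reverse-complemented query back to original coords
    minus$qpos <- nchar(query) - k - minus$qpos
    minus$strand <- "-"
  }
  out <- rbind(plus, minus)
  if (is.null(out))
    out <- data.frame(qpos = integer(), ref_id = character(),
                      rpos = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  out
}
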