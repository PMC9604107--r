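#' Generate a random genome sequence
#'
#' Reproducible for a fixed seed; base composition follows the requested GC
#' content.
#'
#' @param length Sequence length (>= 1).
#' @param gc GC content in `[0, 1]`.
#' @param seed Integer seed.
#' @param id Record id.
#' @return One-row record data.frame.
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1L, id = "chr1") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  set.seed(seed)
  seq_records(id, random_dna(length, gc))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Generate a random class II transposon with terminal inverted repeats
#'
#' The last `tir_len` nucleotides are the reverse complement of the first
#' `tir_len` (a perfect TIR pair).
#'
#' @param length Transposon length.
#' @param tir_len TIR length (12 mimics hobo, 31 P-element).
#' @param seed Integer seed.
#' @param id Record id.
#' @return list with `record` (one-row record data.frame), `tir5` and `tir3`
#'   (0-based end-exclusive intervals) and `features`
#'   (see [annotate_transposon()]).
#' @export
generate_transposon <- function(length, tir_len = 12L, seed = 1L, id = "NT1") {
  stopifnot(length >= 4 * tir_len)
  set.seed(seed)
  body <- random_dna(length)
  tir <- substr(body, 1L, tir_len)
  seq <- paste0(substr(body, 1L, length - tir_len), revcomp(tir))
  rec <- seq_records(id, seq)
  tir5 <- c(0L, tir_len)
  tir3 <- c(length - tir_len, length)
  list(record = rec, tir5 = tir5, tir3 = tir3,
       features = annotate_transposon(rec, tir5, tir3))
}

# Apply n point mutations to a transposon copy, at fixed interior offsets of
# both terminal crop regions (outside the TIRs, preserving long exact runs
# so seeding still works).  Bases are rotated A->C->G->T->A.
mutate_copy <- function(nt_seq, n, tir_len = 12L, crop_len = 60L) {
  if (n <= 0) return(nt_seq)
  len <- nchar(nt_seq)
  off <- tir_len + 2L + 3L * seq_len(n)
  stopifnot(max(off) <= crop_len - 2L)
  pos <- c(off, len - off + 1L)
  rot <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  for (p in pos)
    substr(nt_seq, p, p) <- rot[[substr(nt_seq, p, p)]]
  nt_seq
}

#' Plant a transposon insertion with a target site duplication
#'
#' The duplicated motif is copied from the genomic sequence at the site (as
#' transposition does): with `tsd = genome[c - tsd_len + 1 .. c]`, the contig
#' becomes `genome[1..c] + NT(oriented, possibly truncated) + tsd +
#' genome[c+1..]`, i.e. one TSD copy is the pre-existing genomic sequence
#' and contig length = genome + remnant + tsd_len.  The truth record carries
#' the TGN expected for each junction side: for orientation 1 the 5'
#' junction sits at `c` and the 3' junction at `c - tsd_len + 1`; for
#' orientation 2 the sides swap.
#'
#' @param genome One-row record data.frame (the reference the coordinate
#'   refers to).
#' @param nt One-row transposon record.
#' @param coordinate 1-based genomic coordinate of the last genomic base
#'   before the insertion; must leave room for the TSD
#'   (`coordinate > tsd_len`).
#' @param tsd_len TSD length (bp).
#' @param orientation 1 (plus) or 2 (minus, the remnant is
#'   reverse-complemented).
#' @param remnant_type `"full"`, `"single_tir_5"` (3' portion including the
#'   3' TIR lost), `"single_tir_3"` (5' portion lost), or `"nested"`
#'   (bookkeeping label; nesting itself is done by planting into an already
#'   planted contig).
#' @param contig_id Id of the produced contig.
#' @param copy_mutations Number of point mutations applied to this copy
#'   (divergence of the remnant from the canonical reference).
#' @param tir_len,crop_len Geometry used to place copy mutations.
#' @return list with `contig` (record data.frame) and `truth` (one-row
#'   data.frame: contig_id, transposon, coordinate, orientation, tsd,
#'   remnant_type, tgn5, tgn3, copy_mutations).
#' @export
plant_insertion <- function(genome, nt, coordinate, tsd_len = 8L,
                            orientation = 1L, remnant_type = "full",
                            contig_id = paste0(genome$id[1], "_contig"),
                            copy_mutations = 0L, tir_len = 12L,
                            crop_len = 60L) {
  g <- genome$seq[1]
  len <- nchar(g)
  if (coordinate <= tsd_len || coordinate >= len)
    stop("insertion coordinate ", coordinate, " out of range for a ",
         tsd_len, "-bp TSD in a ", len, "-nt reference")
  nt_seq <- mutate_copy(nt$seq[1], copy_mutations, tir_len, crop_len)
  m <- nchar(nt_seq)
  remnant <- switch(remnant_type,
    full = , nested = nt_seq,
    single_tir_5 = substr(nt_seq, 1L, floor(0.6 * m)),
    single_tir_3 = substr(nt_seq, m - floor(0.6 * m) + 1L, m),
    stop("unknown remnant_type: ", remnant_type))
  oriented <- if (orientation == 2L) revcomp(remnant) else remnant
  tsd <- substr(g, coordinate - tsd_len + 1L, coordinate)
  contig_seq <- paste0(substr(g, 1L, coordinate), oriented, tsd,
                       substr(g, coordinate + 1L, len))
  tgn_left <- coordinate                 # junction at the left of the remnant
  tgn_right <- coordinate - tsd_len + 1L # junction at the right (TSD copy)
  truth <- data.frame(
    contig_id = contig_id, transposon = nt$id[1],
    coordinate = as.integer(coordinate), orientation = as.integer(orientation),
    tsd = tsd, remnant_type = remnant_type,
    tgn5 = if (orientation == 1L) tgn_left else tgn_right,
    tgn3 = if (orientation == 1L) tgn_right else tgn_left,
    copy_mutations = as.integer(copy_mutations),
    stringsAsFactors = FALSE)
  list(contig = seq_records(contig_id, contig_seq), truth = truth)
}

#' Build a full synthetic case study (CRG, ARG contigs, TD, truth table)
#'
#' Emulates a resequencing project: a canonical reference genome (CRG) of
#' `n_contigs` chromosomes, an alternative reference genome (ARG) of as many
#' contigs, and a mixture of events of the transposon under study
#' (`nt_id`): insertions private to the ARG (expected junction results with
#' a TGN), insertions shared by ARG and CRG (expected all-genomic best
#' results, no TGN), a single-TIR remnant (3' TIR lost), and one insertion
#' nested inside a remnant of a second, longer transposon (`host_id`)
#' private to the ARG.  Each planted copy carries a distinct number of point
#' mutations, the divergence real remnants accumulate.  Gene features are
#' placed around a subset of sites so annotation is exercised, including one
#' pair of overlapping genes.
#'
#' @param seed Integer seed; fixtures are byte-reproducible from
#'   `(parameters, seed)`.
#' @param n_contigs Number of chromosomes/contigs (>= 8).
#' @param contig_len_range Range the chromosome lengths are drawn from.
#' @param nt_len,host_len Lengths of the scanned and host transposons.
#' @param tir_len TIR length of the scanned transposon.
#' @param tsd_len TSD length.
#' @param n_private,n_shared Number of private / shared full insertions.
#' @return list with `crg`, `arg` (record data.frames), `td`, `nt`
#'   (the scanned transposon record), `tir_features`, `gene_features`,
#'   `truth` (one row per event of the scanned transposon; column `shared`
#'   marks insertions present in the CRG), `tsd_len`, `tir_len`.
#' @export
make_case_study <- function(seed = 1L, n_contigs = 10L,
                            contig_len_range = c(50000L, 200000L),
                            nt_len = 2000L, host_len = 4000L, tir_len = 12L,
                            tsd_len = 8L, n_private = 4L, n_shared = 2L) {
  stopifnot(n_contigs >= n_private + n_shared + 2L)
  set.seed(seed)
  lens <- as.integer(round(runif(n_contigs, contig_len_range[1],
                                 contig_len_range[2])))
  segs <- vapply(lens, random_dna, character(1))
  nt <- generate_transposon(nt_len, tir_len = tir_len,
                            seed = seed + 1000L, id = "NTA")
  host <- generate_transposon(host_len, tir_len = 20L,
                              seed = seed + 2000L, id = "NTB")
  set.seed(seed + 1L)  # generate_transposon reseeds; restore event stream

  crg_ids <- paste0("chr", seq_len(n_contigs))
  arg_ids <- paste0("contig_", seq_len(n_contigs))
  crg_seqs <- segs
  arg_seqs <- segs

  # event layout: one event per contig
  kinds <- c(rep("private", n_private), rep("shared", n_shared),
             "single_tir_5", "nested",
             rep("none", n_contigs - n_private - n_shared - 2L))
  truth <- list()
  mut_counter <- 0L
  margin <- 3100L + nt_len + 2000L  # room for flanks and single-TIR joins
  for (i in seq_len(n_contigs)) {
    kind <- kinds[i]
    if (kind == "none") next
    L <- lens[i]
    coord <- as.integer(round(runif(1, margin, L - margin)))
    ori <- if (runif(1) < 0.5) 1L else 2L
    mut <- mut_counter %% 6L
    mut_counter <- mut_counter + 1L
    base <- seq_records(crg_ids[i], segs[i])
    if (kind == "nested") {
      # host remnant (private to the ARG), then the scanned NT inside it
      ph <- plant_insertion(base, host$record, coord, tsd_len = tsd_len,
                            orientation = 1L, contig_id = arg_ids[i],
                            copy_mutations = 0L)
      inner <- as.integer(coord + 1200L)  # inside the host remnant
      pa <- plant_insertion(seq_records(crg_ids[i], ph$contig$seq),
                            nt$record, inner, tsd_len = tsd_len,
                            orientation = 1L, remnant_type = "nested",
                            contig_id = arg_ids[i], copy_mutations = mut,
                            tir_len = tir_len)
      arg_seqs[i] <- pa$contig$seq
      tr <- pa$truth
      # the genome-adjacent junctions of the compound event are those of the
      # host remnant at `coord` in CRG space
      tr$tgn5 <- coord
      tr$tgn3 <- coord - tsd_len + 1L
      tr$tsd <- substr(segs[i], coord - tsd_len + 1L, coord)
      tr$shared <- FALSE
      tr$host <- host$record$id
      truth[[length(truth) + 1L]] <- tr
      next
    }
    rtype <- if (kind == "single_tir_5") "single_tir_5" else "full"
    p <- plant_insertion(base, nt$record, coord, tsd_len = tsd_len,
                         orientation = ori, remnant_type = rtype,
                         contig_id = arg_ids[i], copy_mutations = mut,
                         tir_len = tir_len)
    arg_seqs[i] <- p$contig$seq
    if (kind == "shared") crg_seqs[i] <- p$contig$seq
    tr <- p$truth
    tr$shared <- kind == "shared"
    tr$host <- ""
    truth[[length(truth) + 1L]] <- tr
  }
  truth <- do.call(rbind, truth)

  # gene features on the CRG: a gene containing each private site, a pair of
  # overlapping genes at the first one, and flanking genes
  gene_rows <- list()
  priv <- truth[!truth$shared & truth$remnant_type == "full", , drop = FALSE]
  for (i in seq_len(nrow(priv))) {
    chr <- paste0("chr", sub("contig_", "", priv$contig_id[i]))
    c0 <- priv$coordinate[i] - 1L
    gene_rows[[length(gene_rows) + 1L]] <- feature_table(
      reference_id = chr, name = paste0("gene", i, "A"), category = "gene",
      start = c0 - 400L, end = c0 + 600L)
    if (i == 1L)
      gene_rows[[length(gene_rows) + 1L]] <- feature_table(
        reference_id = chr, name = paste0("gene", i, "B"), category = "gene",
        start = c0 - 100L, end = c0 + 900L)
    gene_rows[[length(gene_rows) + 1L]] <- feature_table(
      reference_id = chr, name = paste0("gene", i, "_up"), category = "gene",
      start = max(0L, c0 - 5000L), end = c0 - 3000L)
    gene_rows[[length(gene_rows) + 1L]] <- feature_table(
      reference_id = chr, name = paste0("gene", i, "_dn"), category = "gene",
      start = c0 + 3000L, end = c0 + 5000L)
  }
  gene_features <- if (length(gene_rows)) do.call(rbind, gene_rows)
                   else feature_table()

  list(crg = seq_records(crg_ids, crg_seqs),
       arg = seq_records(arg_ids, arg_seqs),
       td = seq_records(c(nt$record$id, host$record$id),
                        c(nt$record$seq, host$record$seq)),
       nt = nt$record,
       tir_features = rbind(nt$features, host$features),
       gene_features = gene_features,
       truth = truth, tsd_len = tsd_len, tir_len = tir_len,
       nt_len = nt_len)
}
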