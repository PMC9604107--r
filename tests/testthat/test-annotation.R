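mk_call <- function(reference_id, tgn) list(reference_id = reference_id,
                                            tgn = as.integer(tgn))

test_that("hit genes, overlapping genes and flanking genes are reported", {
  feats <- feature_table(
    reference_id = rep("2L", 4),
    name = c("Lamp1", "CG13175", "CG33964", "far_gene"),
    category = "gene",
    start = c(1000L, 5000L, 5400L, 9000L),
    end = c(2000L, 5600L, 6200L, 9500L))

  inside <- annotate_call(mk_call("2L", 1500), feats)
  expect_equal(inside$hit_gene, "Lamp1")
  expect_equal(inside$downstream_gene, "CG13175")

  overlapped <- annotate_call(mk_call("2L", 5500), feats)
  expect_equal(overlapped$hit_gene, "CG13175/CG33964")

  desert <- annotate_call(mk_call("2L", 7000), feats)
  expect_equal(desert$hit_gene, "")
  expect_equal(desert$upstream_gene, "CG33964")
  expect_equal(desert$downstream_gene, "far_gene")

  other_chr <- annotate_call(mk_call("3R", 1500), feats)
  expect_equal(other_chr$hit_gene, "")
})

test_that("annotation agrees with a brute-force interval scan", {
  set.seed(50)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    starts <- sort(sample(0:50000, n))
    feats <- feature_table(reference_id = "chr", name = paste0("g", 1:n),
                           category = "gene", start = starts,
                           end = starts + sample(200:5000, n, TRUE))
    tgn <- sample(1:50000, 1)
    got <- annotate_call(mk_call("chr", tgn), feats)
    orc <- annotate_oracle("chr", tgn, feats)
    expect_equal(got[c("hit_gene", "upstream_gene", "downstream_gene")], orc)
    # flanking genes never contain the TGN
    for (nm in c(got$upstream_gene, got$downstream_gene)) {
      if (!nzchar(nm)) next
      f <- feats[feats$name == nm, ]
      expect_false(f$start <= tgn - 1 && f$end > tgn - 1)
    }
  }
})

test_that("transposon-category features containing the TGN are reported as landscape", {
  feats <- rbind(
    feature_table("chr", "accord", "transposon", 100L, 7500L),
    feature_table("chr", "Cyp6g1-like", "gene", 8000L, 9000L))
  got <- annotate_call(mk_call("chr", 5000), feats)
  expect_equal(got$overlapping_nts, "accord")
})

test_that("transposon annotation uses the zero-based convention for TIR intervals", {
  set.seed(51)
  p_el <- seq_records("P_element", rdna(2907))
  feats <- annotate_transposon(p_el, tir5 = c(0, 31), tir3 = c(2876, 2907))
  expect_equal(feats$end[1] - feats$start[1], 31L)   # 31-bp TIR from 1..31
  expect_equal(feats$category, c("TIR5", "TIR3"))

  hobo <- seq_records("hobo", rdna(3000))
  hfeats <- annotate_transposon(hobo, tir5 = c(0, 12), tir3 = c(2988, 3000))
  expect_equal(hfeats$end[1] - hfeats$start[1], 12L)

  expect_error(annotate_transposon(p_el, tir5 = c(0, 31), tir3 = c(2900, 2950)),
               "outside transposon bounds")
})

test_that("the 5-column TSV reader keeps zero-based coordinates as written", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("P_element\t0\t31\tTIR5\tTIR5", f)
  feats <- read_features_tsv(f)
  expect_equal(feats$start, 0L)
  expect_equal(feats$end, 31L)
})

test_that("GFF3 input converts 1-based inclusive intervals to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("2L", "src", "gene", "1001", "2000", ".", "+", ".",
                     "ID=gene1;Name=Lamp1", sep = "\t"),
               paste("2L", "src", "transposable_element", "3001", "4000", ".",
                     "+", ".", "ID=te1;Name=hobo", sep = "\t")), f)
  feats <- read_features_gff3(f)
  expect_equal(feats$start, c(1000L, 3000L))
  expect_equal(feats$end, c(2000L, 4000L))
  expect_equal(feats$category, c("gene", "transposon"))
  expect_equal(feats$name, c("Lamp1", "hobo"))
})
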