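test_that("WF1 emits one JQ pair per planted remnant and filters by score and TIR", {
  g1 <- generate_genome(30000, seed = 60, id = "s1")
  g2 <- generate_genome(30000, seed = 61, id = "s2")
  g3 <- generate_genome(30000, seed = 62, id = "s3")
  nt <- generate_transposon(2000, tir_len = 12, seed = 63, id = "NT1")
  contigs <- rbind(
    plant_insertion(g1, nt$record, 12000, contig_id = "contig_1",
                    copy_mutations = 0)$contig,
    plant_insertion(g2, nt$record, 15000, contig_id = "contig_2",
                    copy_mutations = 1, orientation = 2)$contig,
    plant_insertion(g3, nt$record, 18000, contig_id = "contig_3",
                    copy_mutations = 2)$contig)
  wf1 <- run_wf1(contigs, nt$record, tir5_len = 12,
                 params = wf1_params(picking_depth = 10000))
  expect_equal(sum(wf1$jqs$side == "5'"), 3)
  expect_equal(sum(wf1$jqs$side == "3'"), 3)
  expect_true(all(wf1$hits$score >= 40))
  expect_setequal(unique(wf1$hits$contig), paste0("contig_", 1:3))
})

test_that("WF1 on contigs without the transposon yields empty outputs", {
  g <- generate_genome(20000, seed = 64, id = "contig_1")
  nt <- generate_transposon(2000, tir_len = 12, seed = 65, id = "NT1")
  wf1 <- run_wf1(g, nt$record, tir5_len = 12)
  expect_equal(nrow(wf1$hits), 0)
  expect_equal(nrow(wf1$jqs), 0)
})

test_that("the full WF1 -> WF2 pipeline resolves a mixed case study exactly", {
  cs <- make_case_study(seed = 77, n_contigs = 8,
                        contig_len_range = c(20000, 26000))
  wf1 <- run_wf1(cs$arg, cs$nt, tir5_len = cs$tir_len,
                 params = wf1_params(picking_depth = 10000))
  wf2 <- run_wf2(wf1$jqs, cs$crg, cs$td, tir_features = cs$tir_features,
                 params = wf2_params(tsd_flank_length = cs$tsd_len),
                 features = cs$gene_features)
  res <- wf2$results
  for (i in seq_len(nrow(cs$truth))) {
    tr <- cs$truth[i, ]
    rows <- res[grepl(paste0("^", tr$contig_id, "_"), res$query_id), ]
    expect_gte(nrow(rows), 1)
    if (tr$shared) {
      expect_true(all(rows$classification == "genomic"))
      expect_true(all(is.na(rows$tgn_coordinate)))
      next
    }
    exact <- rows$classification == "junction" &
      rows$tgn_coordinate %in% c(tr$tgn5, tr$tgn3) & rows$tsd == tr$tsd
    expect_true(any(exact))
    if (tr$remnant_type == "full") {
      expect_setequal(rows$tgn_coordinate, c(tr$tgn5, tr$tgn3))
      expect_true(all(rows$tsd == tr$tsd))
      expect_true(all(rows$orientation == as.character(tr$orientation)))
    }
    if (tr$remnant_type == "nested") {
      expect_true(all(rows$transposon == tr$host))
      expect_true(any(grepl(cs$nt$id, rows$overlapping_nts)))
    }
  }
  # annotation: first private insertion sits in engineered overlapping genes
  priv1 <- cs$truth[!cs$truth$shared & cs$truth$remnant_type == "full", ][1, ]
  rows1 <- res[grepl(paste0("^", priv1$contig_id, "_"), res$query_id), ]
  expect_true(all(grepl("/", rows1$hit_gene)))
})

test_that("WF2 skips queries shorter than the nucleus size with a warning", {
  g <- generate_genome(20000, seed = 66)
  nt <- generate_transposon(2000, seed = 67, id = "NT1")
  jqs <- data.frame(id = "tiny", desc = "", seq = "ACGTACGT",
                    stringsAsFactors = FALSE)
  expect_warning(out <- run_wf2(jqs, g, seq_records(nt$record$id, nt$record$seq)),
                 "skipped")
  expect_equal(nrow(out$results), 0)
})

test_that("workflow presets reproduce the recommended parameter sets", {
  w1 <- wf1_params()
  expect_equal(w1$interval_extension, "short")
  expect_equal(w1$picking_depth, 1L)
  expect_equal(w1$nucleus_size, 20L)
  expect_equal(w1$number_of_results, 1000L)
  expect_false(w1$bonus)
  w2 <- wf2_params()
  expect_equal(w2$interval_extension, "short")
  expect_equal(w2$picking_depth, 1L)
  expect_equal(w2$nucleus_size, 30L)
  expect_equal(w2$number_of_results, 2L)
  expect_true(w2$bonus)
  # the deep-picking preset used for LTR elements is accepted
  expect_equal(wf1_params(picking_depth = 10000)$picking_depth, 10000L)
})
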