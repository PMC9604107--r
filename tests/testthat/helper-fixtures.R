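# Run the full WF1 -> WF2 pipeline on one planted-insertion fixture and
# return the truth row together with the mapping results.
plant_and_map <- function(seed, glen = 50000, nt_len = 2000, tir_len = 12,
                          tsd_len = 8, orientation = 1, shared = FALSE,
                          remnant_type = "full") {
  g <- generate_genome(glen, seed = seed, id = "chr1")
  nt <- generate_transposon(nt_len, tir_len = tir_len, seed = seed + 5000,
                            id = "NT1")
  set.seed(seed + 10000)
  margin <- 3100 + nt_len + 2100
  coord <- sample(margin:(glen - margin), 1)
  p <- plant_insertion(g, nt$record, coord, tsd_len = tsd_len,
                       orientation = orientation,
                       remnant_type = remnant_type, contig_id = "contig_1",
                       tir_len = tir_len)
  crg <- if (shared) seq_records("chr1", p$contig$seq) else g
  wf1 <- run_wf1(p$contig, nt$record, tir5_len = tir_len,
                 params = wf1_params(picking_depth = 10000))
  wf2 <- run_wf2(wf1$jqs, crg,
                 seq_records(nt$record$id, nt$record$seq),
                 tir_features = nt$features,
                 params = wf2_params(tsd_flank_length = tsd_len))
  list(truth = p$truth, results = wf2$results, calls = wf2$calls,
       wf1 = wf1, genome = g)
}
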