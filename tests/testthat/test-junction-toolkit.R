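test_that("terminal crops take the transposon ends verbatim with TIR5/TIR3 ids", {
  set.seed(40)
  nt <- seq_records("P_element", rdna(2907))
  crops <- crop_terminal_queries(nt, 60)
  expect_equal(crops$id, c("P_element_TIR5", "P_element_TIR3"))
  expect_equal(crops$seq[1], substr(nt$seq, 1, 60))
  expect_equal(crops$seq[2], substr(nt$seq, 2848, 2907))
  expect_error(crop_terminal_queries(seq_records("s", rdna(100)), 60),
               "twice the crop length")
})

test_that("junction queries collect flank + crop windows of the expected size", {
  set.seed(41)
  contig <- seq_records("c1", rdna(12000))
  hits <- data.frame(contig = "c1", side = c("5'", "3'"),
                     coordinate = c(5001L, 6941L), strand = "+",
                     stringsAsFactors = FALSE)
  jqs <- extract_junction_queries(contig, hits, flank = 3000, nt_len = 2000,
                                  crop_len = 60)
  expect_equal(nrow(jqs), 2)
  expect_equal(nchar(jqs$seq), c(3060L, 3060L))
  expect_false(any(jqs$alert))
  # JQ5' ends with the crop region; JQ3' begins with it
  expect_equal(substr(jqs$seq[jqs$side == "5'"], 3001, 3060),
               substr(contig$seq, 5001, 5060))
  expect_equal(substr(jqs$seq[jqs$side == "3'"], 1, 60),
               substr(contig$seq, 6941, 7000))
})

test_that("minus-strand windows are reverse-complemented into canonical JQs", {
  set.seed(42)
  contig <- seq_records("c1", rdna(12000))
  hits <- data.frame(contig = "c1", side = c("5'", "3'"),
                     coordinate = c(6941L, 5001L), strand = "-",
                     stringsAsFactors = FALSE)
  jqs <- extract_junction_queries(contig, hits, flank = 3000, nt_len = 2000,
                                  crop_len = 60)
  expect_equal(substr(jqs$seq[jqs$side == "5'"], 3001, 3060),
               revcomp(substr(contig$seq, 6941, 7000)))
  expect_equal(nchar(jqs$seq), c(3060L, 3060L))
})

test_that("remnants near a contig end emit truncated JQs flagged with ALERT", {
  set.seed(43)
  contig <- seq_records("c1", rdna(3000))
  hits <- data.frame(contig = "c1", side = c("5'", "3'"),
                     coordinate = c(501L, 2441L), strand = "+",
                     stringsAsFactors = FALSE)
  jqs <- extract_junction_queries(contig, hits, flank = 3000, nt_len = 2000,
                                  crop_len = 60)
  expect_true(all(jqs$alert))
  expect_true(all(grepl("ALERT", jqs$desc)))
  expect_equal(nchar(jqs$seq[jqs$side == "5'"], ), 560L)  # clipped at start
})

test_that("an unpaired terminus triggers the three-part single-TIR join", {
  set.seed(44)
  contig <- seq_records("c1", rdna(12000))
  hits <- data.frame(contig = "c1", side = "5'", coordinate = 5001L,
                     strand = "+", stringsAsFactors = FALSE)
  jqs <- extract_junction_queries(contig, hits, flank = 3000, nt_len = 2907,
                                  tail = 2000, crop_len = 60)
  join <- jqs[jqs$side == "3'", ]
  expect_equal(nrow(join), 1)
  expect_equal(nchar(join$seq), 60L + 2907L + 2000L)
  expect_match(join$desc, "single-TIR join")
})

test_that("hits outside the contig are rejected", {
  contig <- seq_records("c1", "ACGTACGTACGT")
  hits <- data.frame(contig = "c1", side = "5'", coordinate = 100L,
                     strand = "+", stringsAsFactors = FALSE)
  expect_error(extract_junction_queries(contig, hits, flank = 10, nt_len = 5,
                                        crop_len = 4), "outside contig")
})

test_that("flanking sequences are centered with the coordinate in the right half", {
  gd <- reference_db(seq_records("r", "AAACCCGGGTTT"), "genome")
  expect_equal(flanking_at_coordinate(gd, "r", 7, half_len = 3)$seq, "CCCGGG")
  set.seed(45)
  gd2 <- reference_db(seq_records("chr", rdna(200)), "genome")
  expect_equal(nchar(flanking_at_coordinate(gd2, "chr", 100, 20)$seq), 40L)
  expect_equal(nchar(flanking_at_coordinate(gd2, "chr", 100)$seq), 16L)
  expect_error(flanking_at_coordinate(gd2, "chr", 5, 8), "ALERT")
  expect_error(flanking_at_coordinate(gd2, "chr", 198, 8), "ALERT")
})

test_that("IUPAC consensus maps per-position frequency sets to ambiguity codes", {
  got <- compute_consensus(c("ACGT", "ACGA", "ACGA", "ACGA"), threshold = 20)
  expect_equal(got$consensus, "ACGW")
  expect_equal(got$n_sequences, 4L)

  same <- compute_consensus(rep("GTCTAGAC", 5), threshold = 100)
  expect_equal(same$consensus, "GTCTAGAC")
  expect_error(compute_consensus(c("AAAA", "AAAT"), threshold = 100),
               "identical")

  mixed <- compute_consensus(c("AAAA", "CAAA", "GAAA", "TAAA"), threshold = 20)
  expect_equal(substr(mixed$consensus, 1, 1), "N")  # 4-fold position

  expect_error(compute_consensus(c("AC", "ACG"), 20), "unequal")
  expect_error(compute_consensus("AC", 20), "at least 2")
})

test_that("consensus matches the frequency oracle on random inputs", {
  set.seed(46)
  for (rep in 1:10) {
    n <- sample(4:12, 1); len <- sample(5:15, 1)
    seqs <- vapply(seq_len(n), function(i) rdna(len), character(1))
    for (thr in c(10, 20, 34, 60)) {
      got <- suppressWarnings(compute_consensus(seqs, thr))
      expect_equal(strsplit(got$consensus, "")[[1]], consensus_oracle(seqs, thr))
    }
  }
})

test_that("raising the threshold never increases positional degeneracy", {
  degeneracy <- c(A = 1, C = 1, G = 1, T = 1, R = 2, Y = 2, S = 2, W = 2,
                  K = 2, M = 2, B = 3, D = 3, H = 3, V = 3, N = 4)
  set.seed(47)
  for (rep in 1:8) {
    seqs <- vapply(1:10, function(i) rdna(12), character(1))
    prev <- NULL
    # with 10 sequences the top base reaches >= 30%, so every position keeps
    # a non-empty selection set at these thresholds
    for (thr in c(10, 20, 30)) {
      cons <- compute_consensus(seqs, thr)$consensus
      d <- degeneracy[strsplit(cons, "")[[1]]]
      if (!is.null(prev)) expect_true(all(d <= prev))
      prev <- d
    }
  }
})
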