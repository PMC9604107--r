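p <- nt_params(number_of_results = 1000)

test_that("genome pairs merge up to the maximal genomic distance and split beyond", {
  for (gap in c(0, 150, 200)) {
    subs <- rbind(mk_sub(0, 1000, 0), mk_sub(1000, 2000, 1000 + gap))
    comps <- compose_alignments(subs, p)
    expect_equal(nrow(comps[[1]]$parts), 2)
    expect_equal(comps[[1]]$total_score, 2000L)
  }
  subs <- rbind(mk_sub(0, 1000, 0), mk_sub(1000, 2000, 1201))
  comps <- compose_alignments(subs, p)
  expect_true(all(vapply(comps, function(cc) nrow(cc$parts), integer(1)) == 1))
})

test_that("genome pairs with overlapping genomic coordinates are never merged", {
  subs <- rbind(mk_sub(0, 1000, 0), mk_sub(1000, 2000, 995))  # 5 nt overlap
  comps <- compose_alignments(subs, p)
  expect_true(all(vapply(comps, function(cc) nrow(cc$parts), integer(1)) == 1))
})

test_that("junction pairs compose without gap restrictions and scores add", {
  subs <- rbind(mk_sub(0, 3000, 50000, origin = "genome", ref_id = "chr1"),
                mk_sub(3000, 3060, 0, origin = "transposon", ref_id = "NT"))
  comps <- compose_alignments(subs, p)
  top <- comps[[1]]
  expect_equal(top$classification, "junction")
  expect_equal(top$total_score, 3060L)
  expect_equal(nrow(top$parts), 2)
})

test_that("transposon parts sharing reference coordinates still compose (self-insertion)", {
  subs <- rbind(mk_sub(0, 500, 100, origin = "transposon", ref_id = "NT"),
                mk_sub(500, 900, 100, origin = "transposon", ref_id = "NT"))
  comps <- compose_alignments(subs, p)
  expect_equal(nrow(comps[[1]]$parts), 2)
  expect_equal(comps[[1]]$classification, "transposon_internal")
})

test_that("compose equals exhaustive subset enumeration on small instances", {
  set.seed(20)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    qb <- sort(sample(seq(0, 5000, by = 10), 2 * n))
    subs <- do.call(rbind, lapply(seq_len(n), function(i) {
      mk_sub(qb[2 * i - 1], qb[2 * i],
             rstart = sample(c(qb[2 * i - 1] + sample(-300:300, 1),
                               sample(0:10000, 1)), 1),
             origin = sample(c("genome", "transposon"), 1, prob = c(.7, .3)),
             ref_id = sample(c("r1", "r2"), 1),
             strand = sample(c("+", "-"), 1, prob = c(.8, .2)))
    }))
    subs$rstart <- pmax(subs$rstart, 0L)
    subs$rend <- subs$rstart + (subs$qend - subs$qstart)
    got <- compose_alignments(subs, p)
    # recover original row index of each part
    key <- paste(subs$qstart, subs$qend, subs$rstart, subs$origin)
    got_sets <- vapply(got, function(cc)
      paste(sort(match(paste(cc$parts$qstart, cc$parts$qend, cc$parts$rstart,
                             cc$parts$origin), key)), collapse = ","),
      character(1))
    got_scores <- vapply(got, `[[`, integer(1), "total_score")
    orc <- compose_oracle(subs, max_gap = p$max_genomic_gap)
    orc_sets <- vapply(orc, `[[`, character(1), "ids")
    orc_scores <- vapply(orc, function(x) x$score, numeric(1))
    expect_setequal(paste(got_sets, got_scores),
                    paste(orc_sets, orc_scores))
    expect_true(all(diff(got_scores) <= 0))  # ranked by score
    # conservation: total equals the sum of part scores
    for (cc in got)
      expect_equal(cc$total_score, sum(cc$parts$score))
  }
})

test_that("no output composite violates the genome-genome pair rules", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    qb <- sort(sample(seq(0, 3000, by = 5), 2 * n))
    subs <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_sub(qb[2 * i - 1], qb[2 * i], sample(0:4000, 1))))
    for (cc in compose_alignments(subs, p)) {
      parts <- cc$parts
      if (nrow(parts) < 2) next
      for (k in 1:(nrow(parts) - 1)) {
        a <- parts[k, ]; b <- parts[k + 1, ]
        expect_lte(a$qend, b$qstart)
        if (a$origin == "genome" && b$origin == "genome") {
          rgap <- if (a$strand == "+") b$rstart - a$rend else a$rstart - b$rend
          expect_gte(rgap, 0)
          expect_lte(rgap, p$max_genomic_gap)
        }
      }
    }
  }
})

test_that("query-overlapping junction parts are trimmed so the transposon terminus defines the border", {
  # blue wandered 3 columns into the transposon crop region
  blue <- mk_sub(0, 3003, 46997, origin = "genome")
  red <- mk_sub(3000, 3060, 0, origin = "transposon", ref_id = "NT")
  comps <- compose_alignments(rbind(blue, red), p)
  top <- comps[[1]]
  expect_equal(top$classification, "junction")
  expect_equal(nrow(top$parts), 2)
  bluep <- top$parts[top$parts$origin == "genome", ]
  expect_equal(bluep$qend, 3000L)       # trimmed back to the red boundary
  expect_equal(bluep$rend, 49997L)      # reference end retreats with it
  expect_equal(top$total_score, 3000L + 60L)
})

test_that("overlaps spanning most of a part mark conflicting alignments and do not compose", {
  blue <- mk_sub(0, 3060, 0, origin = "genome")          # full cover
  red <- mk_sub(3000, 3060, 0, origin = "transposon", ref_id = "NT")
  comps <- compose_alignments(rbind(blue, red), p)
  expect_true(all(vapply(comps, function(cc) nrow(cc$parts), integer(1)) == 1))
})

test_that("the insertion-candidate bonus adds exactly 500 for an intact border TIR", {
  tir <- annotate_transposon(list(id = "NT", seq = rdna(2907)),
                             tir5 = c(0, 31), tir3 = c(2876, 2907))
  subs <- rbind(mk_sub(0, 3000, 10000, origin = "genome"),
                mk_sub(3000, 3060, 0, origin = "transposon", ref_id = "NT"))
  comp <- compose_alignments(subs, p)[[1]]
  on <- apply_bonus(comp, tir_features = tir, params = nt_params(bonus = TRUE))
  off <- apply_bonus(comp, tir_features = tir, params = nt_params(bonus = FALSE))
  expect_equal(on$total_score - comp$total_score, 500L)
  expect_true(on$bonus_applied)
  expect_equal(off$total_score, comp$total_score)
  expect_false(off$bonus_applied)
  # applying twice never double-counts
  expect_equal(apply_bonus(on, tir_features = tir,
                           params = nt_params(bonus = TRUE))$total_score,
               on$total_score)
})

test_that("a mostly deleted TIR at the border earns no bonus", {
  tir <- annotate_transposon(list(id = "NT", seq = rdna(2907)),
                             tir5 = c(0, 31), tir3 = c(2876, 2907))
  # transposon part starts 16 nt into the TIR: barely 48% of it aligned
  subs <- rbind(mk_sub(0, 3000, 10000, origin = "genome"),
                mk_sub(3000, 3044, 16, origin = "transposon", ref_id = "NT"))
  comp <- compose_alignments(subs, p)[[1]]
  res <- apply_bonus(comp, tir_features = tir, params = nt_params(bonus = TRUE))
  expect_false(res$bonus_applied)
})

test_that("picking depth limits identical-scoring placements per query span", {
  subs <- rbind(mk_sub(0, 300, 5000), mk_sub(0, 300, 25300))
  comps <- compose_alignments(subs, p)
  expect_length(pick_placements(comps, nt_params(picking_depth = 1)), 1)
  expect_length(pick_placements(comps, nt_params(picking_depth = 2)), 2)
  expect_length(pick_placements(comps, nt_params(picking_depth = 10000)), 2)
  kept <- pick_placements(comps, nt_params(picking_depth = 2))
  expect_equal(vapply(kept, `[[`, integer(1), "placement_rank"), c(1L, 2L))
})
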