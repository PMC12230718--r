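# Independent penalty-sum oracle: recompute the score directly from the
# defect record and the default penalty magnitudes.
oracle_score <- function(core, fold, canonical = c("1", "2", "19")) {
  d <- core$defects
  8 - 1.5 * length(d$mismatch_pairs) - 1.5 * length(d$stem_bulges) -
    0.5 * length(d$wobble_pairs) -
    (!core$family %in% canonical) * 1.0 -
    switch(d$n7_n25, watson_crick = 0, wobble = 1.5, mismatch = 3.0) -
    2.5 * (1 - fold$concordance) -
    (fold$delta_g >= 0) * 2.0
}

test_that("scores equal the independent sum-of-penalties oracle", {
  set.seed(501)
  cfg <- penalty_config()
  reg <- ire_motifs()
  for (rep in 1:25) {
    fx <- build_core(sample(reg$motif_id, 1),
                     mismatches = sample(0:1, 1),
                     stem_bulges = sample(0:1, 1),
                     n7_n25 = sample(c("pair", "wobble", "mismatch"), 1),
                     seed = NULL)
    cands <- scan_sequence(fx$seq)
    fold <- make_fold(concordance = sample(0:6, 1) / 6,
                      delta_g = sample(c(-8, -2, 0), 1))
    for (core in cands) {
      s <- score_candidate(core, fold, cfg)
      expect_equal(s$score, oracle_score(core, fold), tolerance = 1e-12)
    }
  }
})

test_that("the perfect canonical candidate scores the full 8", {
  fx <- build_core("1", lower_stem = 6, seed = 11)
  core <- Filter(function(c) irescan:::n_defects(c) == 0,
                 scan_sequence(fx$seq))[[1]]
  s <- score_candidate(core, fold_window(fx$seq, core, engine = "vienna"))
  expect_equal(s$score, 8)
  expect_equal(s$category, "High")
  expect_length(s$penalties, 0)
})

test_that("anchor arithmetic: closing-pair and stem defects, fold held fixed", {
  core <- scan_sequence("GCGUUCGCAGUGCCGAACC")[[1]]
  fold1 <- make_fold(concordance = 1, delta_g = -5)
  mut <- core
  mut$defects$n7_n25 <- "mismatch"
  expect_equal(score_candidate(mut, fold1)$score, 5.0)   # 8 - 3.0
  mm <- core
  mm$defects$mismatch_pairs <- 1L
  s <- score_candidate(mm, fold1)
  expect_equal(s$score, 6.5)                              # 8 - 1.5
  expect_equal(s$category, "High-medium")
})

test_that("category thresholds step where declared", {
  cfg <- penalty_config()
  expect_equal(categorize(8, cfg), "High")
  expect_equal(categorize(7, cfg), "High")
  expect_equal(categorize(6.99, cfg), "High-medium")
  expect_equal(categorize(5.0, cfg), "Medium")
  expect_equal(categorize(3.5, cfg), "Medium-low")
  expect_equal(categorize(1.5, cfg), "Low")
  expect_equal(categorize(0, cfg), "Very-low")
  expect_equal(categorize(-2, cfg), "Very-low")
  # pooled tiers merge pairwise and monotonically
  tiers <- unname(irescan:::POOLED_TIER[irescan:::CATEGORY_LEVELS])
  expect_equal(tiers, c("high", "high", "medium", "medium", "low", "low"))
})

test_that("adding any defect never increases the score", {
  core <- scan_sequence("GCGUUCGCAGUGCCGAACC")[[1]]
  fold <- make_fold()
  base <- score_candidate(core, fold)$score
  worsen <- list(
    function(c) { c$defects$mismatch_pairs <- 1L; c },
    function(c) { c$defects$wobble_pairs <- 1L; c },
    function(c) { c$defects$stem_bulges <- 10L; c },
    function(c) { c$defects$n7_n25 <- "wobble"; c },
    function(c) { c$defects$n7_n25 <- "mismatch"; c })
  for (w in worsen) {
    expect_lte(score_candidate(w(core), fold)$score, base)
  }
  # discordance and non-negative energy also only subtract
  expect_lte(score_candidate(core, make_fold(concordance = 0.5))$score, base)
  expect_lte(score_candidate(core, make_fold(delta_g = 0))$score, base)
})

test_that("a closing-pair mutation outranks a stem mismatch in category loss", {
  # whole-pipeline comparison on otherwise identical fixtures
  cat_rank <- function(cat) match(cat, irescan:::CATEGORY_LEVELS)
  run <- function(n7_n25, mismatches) {
    fx <- build_core("1", mismatches = mismatches, n7_n25 = n7_n25,
                     seed = 77)
    res <- find_ires(setNames(fx$seq, "x"), engine = "builtin")
    res$predictions
  }
  perfect <- run("pair", 0)
  closing <- run("mismatch", 0)
  stem <- run("pair", 1)
  expect_equal(perfect$category, "High")
  drop_closing <- cat_rank(closing$category) - cat_rank(perfect$category)
  drop_stem <- cat_rank(stem$category) - cat_rank(perfect$category)
  expect_gte(drop_closing, 2)
  expect_gt(drop_closing, drop_stem)
})

test_that("site winners prefer score, then registry row, then fewer defects", {
  core1 <- scan_sequence("GCGUUCGCAGUGCCGAACC")[[1]]
  core20 <- core1; core20$row <- 21L; core20$motif_id <- "20"
  s_hi <- score_candidate(core1, make_fold())
  s_lo <- score_candidate(core20, make_fold(concordance = 0.5))
  expect_equal(pick_site_winner(list(s_lo, s_hi))$core$motif_id, "1")
  s_tie <- score_candidate(core20, make_fold())
  expect_equal(pick_site_winner(list(s_tie, s_hi))$core$motif_id, "1")
  expect_equal(pick_site_winner(list(s_tie))$core$motif_id, "20")
  defective <- core1; defective$defects$wobble_pairs <- 1L
  s_def <- score_candidate(defective, make_fold())
  s_def$score <- s_hi$score  # force a full tie apart from defect count
  expect_equal(irescan:::n_defects(pick_site_winner(list(s_def, s_hi))$core), 0)
})

test_that("quality bars clamp to their declared ranges", {
  cfg <- penalty_config()
  core <- scan_sequence("GCGUUCGCAGUGCCGAACC")[[1]]
  top <- summarize_quality(score_candidate(core, make_fold(delta_g = -11.7)), cfg)
  expect_equal(top$score_bar, 1)
  expect_equal(top$energy_bar, 11.7 / 15)
  worst <- summarize_quality(score_candidate(core, make_fold(concordance = 0,
                                                             delta_g = 0)), cfg)
  expect_equal(worst$energy_bar, 0)
  low <- score_candidate(core, make_fold())
  low$score <- cfg$bar_min
  expect_equal(summarize_quality(low, cfg)$score_bar, 0)
  low$score <- cfg$bar_min - 100
  expect_equal(summarize_quality(low, cfg)$score_bar, 0)
})

test_that("scoring configuration is validated and overridable", {
  expect_error(penalty_config(n7_n25_mismatch = 1.0),
               "must exceed stem_mismatch")
  expect_error(penalty_config(stem_mismatch = -1), "non-negative")
  expect_error(penalty_config(nonsense = 2), "unknown scoring config key")
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("stem_mismatch: 2.0", "n7_n25_mismatch: 4.0"), tmp)
  cfg <- penalty_config(tmp)
  expect_equal(cfg$stem_mismatch, 2.0)
  expect_equal(cfg$n7_n25_mismatch, 4.0)
  expect_false(identical(cfg$hash, penalty_config()$hash))
  expect_identical(penalty_config()$hash, penalty_config()$hash)
})
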