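# Comparison building, the three feature statistics, model adequacy and the
# bootstrapped selection procedure.

make_meta <- function(n_part = 2, n_days = 3, post_day = TRUE,
                      types = c("fasting", "FMV", "post_breakfast",
                                "post_lunch", "post_dinner")) {
  rows <- expand.grid(participant = sprintf("P%02d", seq_len(n_part)),
                      day = seq_len(n_days), sample_type = types,
                      stringsAsFactors = FALSE)
  if (post_day) {
    rows <- rbind(rows, expand.grid(
      participant = sprintf("P%02d", seq_len(n_part)),
      day = n_days + 1L, sample_type = c("fasting", "FMV"),
      stringsAsFactors = FALSE))
  }
  rows$preday_condition <- "standardized"
  rows$sample_id <- sprintf("%s_d%d_%s", rows$participant, rows$day,
                            rows$sample_type)
  rows
}

test_that("a full 3-day schedule yields 9 meal pairs with dinner extras", {
  pairs <- build_comparisons(make_meta())
  expect_length(pairs, 9)
  dinners <- Filter(function(p) p$meal == "dinner", pairs)
  expect_length(dinners, 3)
  for (p in dinners) {
    if (p$day < 3) {
      expect_length(p$extra_baseline, 4)  # 2 participants x fasting + FMV
      expect_false(p$extra_baseline_missing)
    }
  }
  # day-3 dinner: next day exists here (post-day), so extras present; drop
  # the post-day rows to exercise the boundary case
  pairs2 <- build_comparisons(make_meta(post_day = FALSE))
  d3 <- Filter(function(p) p$meal == "dinner" && p$day == 3, pairs2)[[1]]
  expect_length(d3$extra_baseline, 0)
  expect_true(d3$extra_baseline_missing)
})

test_that("baseline-free and postprandial-free metadata degrade loudly", {
  only_fasting <- make_meta(types = "fasting", post_day = FALSE)
  expect_warning(pairs <- build_comparisons(only_fasting), "no baseline")
  expect_length(pairs, 0)

  no_base <- make_meta(types = c("post_breakfast"), post_day = FALSE)
  w <- capture_warnings(build_comparisons(no_base))
  expect_match(w, "no baseline|no .* pairs", all = TRUE)
  expect_length(w, 4)  # one per day plus the no-pairs summary
})

test_that("feature AUC matches brute-force pairwise counting", {
  expect_equal(feature_auc(c(1, 2, 3, 4, 5, 6),
                           rep(c(FALSE, TRUE), each = 3)), 1)
  expect_equal(feature_auc(c(1, 2, 3, 2, 3, 4),
                           rep(c(FALSE, TRUE), each = 3)), 7 / 9)
  expect_equal(feature_auc(c(1, 2, 3, 1, 2, 3),
                           rep(c(FALSE, TRUE), each = 3)), 0.5)
  expect_equal(feature_auc(rep(5, 8), rep(c(FALSE, TRUE), each = 4)), 0.5)

  set.seed(17)
  for (i in 1:200) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    v <- c(sample(1:6, n1, replace = TRUE) + 0.5 * rbinom(n1, 1, 0.5),
           sample(1:6, n2, replace = TRUE))
    lab <- rep(c(FALSE, TRUE), c(n1, n2))
    a <- brute_auc(v[!lab], v[lab])
    expect_equal(feature_auc(v, lab, direction_agnostic = FALSE), a,
                 tolerance = 1e-12)
    expect_equal(feature_auc(v, lab), max(a, 1 - a), tolerance = 1e-12)
    # vectorized column version agrees with the scalar one
    expect_equal(unname(urimark:::.col_auc(cbind(x = v), lab,
                                           direction_agnostic = FALSE)),
                 a, tolerance = 1e-12)
  }
})

test_that("t-test matches stats::t.test and handles degenerate input", {
  expect_equal(as.numeric(feature_ttest(c(1, 2, 3, 1, 2, 3),
                                        rep(c(FALSE, TRUE), each = 3))), 1)
  p <- feature_ttest(c(0, 0, 0, 0, 1, 1, 1, 1),
                     rep(c(FALSE, TRUE), each = 4))
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "degenerate"))

  set.seed(23)
  for (i in 1:50) {
    x <- rnorm(6); y <- rnorm(7, 0.5)
    ours <- feature_ttest(c(x, y), rep(c(FALSE, TRUE), c(6, 7)))
    ref <- t.test(y, x, var.equal = TRUE)$p.value
    expect_equal(as.numeric(ours), ref, tolerance = 1e-12)
  }
})

test_that("tier assignment follows the threshold bands", {
  expect_equal(assign_tier(0.0025, 0.01, 0.92), "discriminatory")
  expect_equal(assign_tier(0.0015, 0.03, 0.85), "putative")
  expect_equal(assign_tier(0.0005, 0.001, 0.99), "none")
  # high importance but AUC below the discriminatory cut stays putative
  expect_equal(assign_tier(0.01, 0.01, 0.85), "putative")
  # discriminatory requires all three conditions
  expect_equal(assign_tier(0.0025, 0.2, 0.95), "putative")
  expect_equal(assign_tier(0.0025, 0.01, 0.89), "putative")
  # vectorized and pure
  st <- c(0.003, 0.0015, 0)
  expect_equal(assign_tier(st, c(0.01, 0.2, 0.9), c(0.95, 0.85, 0.5)),
               c("discriminatory", "putative", "none"))
  expect_identical(assign_tier(st, c(0.01, 0.2, 0.9), c(0.95, 0.85, 0.5)),
                   assign_tier(st, c(0.01, 0.2, 0.9), c(0.95, 0.85, 0.5)))
})

test_that("a perfectly separable model is adequate with margin near 1", {
  X <- cbind(f1 = rep(c(0, 1), each = 6), f2 = rep(c(0, 1), each = 6))
  y <- factor(rep(c("baseline", "post"), each = 6))
  ass <- rf_fit_and_assess(X, y, rf_config(ntree = 500), seed = 1)
  expect_gt(ass$margin, 0.8)
  expect_equal(ass$auc, 1)
  expect_true(ass$adequate)
  expect_error(rf_fit_and_assess(X, factor(rep("a", 12))), "2 classes")
})

test_that("pure-noise models hover at chance and are mostly inadequate", {
  set.seed(31)
  margins <- numeric(20); aucs <- numeric(20); adequate <- logical(20)
  for (i in 1:20) {
    X <- matrix(rnorm(16 * 150), 16)
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    y <- factor(rep(c("baseline", "post"), each = 8))
    ass <- rf_fit_and_assess(X, y, rf_config(ntree = 300),
                             seed = sample.int(1e6, 1))
    margins[i] <- ass$margin; aucs[i] <- ass$auc
    adequate[i] <- ass$adequate
  }
  expect_lt(abs(mean(margins)), 0.1)
  expect_gte(mean(aucs), 0.3)
  expect_lte(mean(aucs), 0.7)
  expect_gte(mean(!adequate), 0.9)
})

test_that("bootstrap selection recovers spikes, is deterministic, errors on
          tiny classes", {
  sim <- simulate_fingerprint_matrix(n_per_class = 10, n_background = 300,
                                     n_spiked = 3, fold_change = 4,
                                     seed = 5)
  fs <- bootstrap_select(sim$X, sim$y, bootstrap_config(n_boot = 30),
                         rf_config(ntree = 500), seed = 8)
  st <- fs$stats
  expect_true(all(st$tier[st$bin %in% sim$spiked] != "none"))
  expect_lte(mean(st$tier[!(st$bin %in% sim$spiked)] != "none"), 0.01)
  expect_true(all(st$auc >= 0.5 & st$auc <= 1))
  expect_true(all(st$selection_fraction >= 0 & st$selection_fraction <= 1))

  fs2 <- bootstrap_select(sim$X, sim$y, bootstrap_config(n_boot = 30),
                          rf_config(ntree = 500), seed = 8)
  expect_identical(fs$stats, fs2$stats)

  expect_error(bootstrap_select(sim$X[c(1, 2, 11, 12), ],
                                sim$y[c(1, 2, 11, 12)]),
               ">= 3 samples")
})

test_that("spiked-bin AUC never falls as the effect size grows", {
  aucs <- vapply(c(2, 4, 8), function(fc) {
    sim <- simulate_fingerprint_matrix(n_per_class = 8, n_background = 100,
                                       n_spiked = 2, fold_change = fc,
                                       seed = 77)  # paired seeds
    fs <- bootstrap_select(sim$X, sim$y, bootstrap_config(n_boot = 20),
                           rf_config(ntree = 300), seed = 4)
    mean(fs$stats$auc[fs$stats$bin %in% sim$spiked])
  }, numeric(1))
  expect_true(all(diff(aucs) >= -1e-9))
})

test_that("ranger importance ranking agrees with randomForest on spikes", {
  skip_if_not_installed("randomForest")
  sim <- simulate_fingerprint_matrix(n_per_class = 10, n_background = 150,
                                     n_spiked = 5, fold_change = 6,
                                     seed = 13)
  fs <- bootstrap_select(sim$X, sim$y, bootstrap_config(n_boot = 20),
                         rf_config(ntree = 500), seed = 2)
  set.seed(3)
  rf <- randomForest::randomForest(sim$X, sim$y, ntree = 1000,
                                   importance = TRUE)
  imp_rf <- rf$importance[, "MeanDecreaseAccuracy"]
  top_rf <- names(sort(imp_rf, decreasing = TRUE))[1:5]
  top_ours <- fs$stats$bin[order(-fs$stats$importance)][1:5]
  expect_setequal(top_rf, sim$spiked)
  expect_setequal(top_ours, sim$spiked)
})
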