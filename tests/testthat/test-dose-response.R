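# Portion classification, FMV summaries, extreme-portion testing, Spearman
# validation and assay censoring.

test_that("portion classes follow the 0.5x/1.5x medium rule", {
  expect_equal(classify_portion(208, 125), "large")   # > 187.5
  expect_equal(classify_portion(31, 125), "small")    # < 62.5
  expect_equal(classify_portion(0, 125), "none")
  # medium band inclusive on both edges
  expect_equal(classify_portion(62.5, 125), "medium")
  expect_equal(classify_portion(187.5, 125), "medium")
  expect_error(classify_portion(-1, 125), ">= 0")
})

test_that("bundled grape menu portions reproduce their printed classes", {
  menu <- read.csv(system.file("extdata", "grape_portions.csv",
                               package = "urimark"),
                   stringsAsFactors = FALSE)
  got <- mapply(classify_portion, menu$grams, menu$medium_g)
  expect_equal(unname(got), menu$portion_class)
})

test_that("FMV summaries give mean, SE and n per group", {
  s <- summarize_fmv(c(10, 10, 10), rep("a", 3))
  expect_equal(s$mean, 10); expect_equal(s$se, 0); expect_equal(s$n, 3L)

  s <- summarize_fmv(c(8, 10, 12), rep("a", 3))
  expect_equal(s$mean, 10)
  expect_equal(s$se, 2 / sqrt(3), tolerance = 1e-9)  # 1.1547

  s <- summarize_fmv(c(5, 8, 10, 12), c("solo", "a", "a", "a"))
  expect_true(is.na(s$se[s$group == "solo"]))
  expect_equal(s$mean[s$group == "solo"], 5)
})

test_that("extreme-portion t-test is symmetric with degenerate rules", {
  r <- extreme_portion_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p, 1, tolerance = 1e-12)

  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 7)
  r1 <- extreme_portion_test(a, b)
  r2 <- extreme_portion_test(b, a)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, t.test(b, a, var.equal = TRUE)$p.value,
               tolerance = 1e-12)

  r <- extreme_portion_test(c(0, 0), c(1, 1))
  expect_equal(r$p, 0); expect_true(r$degenerate)
  expect_error(extreme_portion_test(1, c(1, 2)), ">= 2")
})

test_that("none-vs-large groups separate in a dosed simulation", {
  # linear dose-response with effect ~5x the noise sd: detected at P < 0.01
  # in nearly all seeds
  hits <- 0
  for (s in 1:50) {
    d <- simulate_dose_response(doses_g = c(0, 250), n_per_level = 15,
                                noise_sdlog = 0.25, seed = s)
    r <- extreme_portion_test(
      d$concentration[d$portion_class == "none"],
      d$concentration[d$portion_class == "large"])
    if (r$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
})

test_that("Spearman correlation handles ranks, ties and degeneracy", {
  r <- portion_correlation(c(1, 2, 3, 4), c(2, 4, 5, 9))
  expect_equal(r$rho, 1)
  r <- portion_correlation(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r$rho, -1)
  r <- portion_correlation(rep(2, 5), rnorm(5))
  expect_true(is.na(r$rho))
  expect_error(portion_correlation(1:2, 1:2), ">= 3")
  # portion classes are ordered none < small < medium < large
  r <- portion_correlation(c("none", "small", "medium", "large"),
                           c(1, 2, 3, 4))
  expect_equal(r$rho, 1)
  expect_error(portion_correlation(c("none", "tiny", "large"), 1:3),
               "unknown portion class")
})

test_that("Spearman rho is invariant to monotone transforms", {
  set.seed(41)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.5)
  base <- portion_correlation(x, y)$rho
  expect_equal(portion_correlation(exp(x), y)$rho, base, tolerance = 1e-12)
  expect_equal(portion_correlation(x, y^3 + 5 * y)$rho, base,
               tolerance = 1e-12)
  expect_equal(portion_correlation(rank(x), exp(y))$rho, base,
               tolerance = 1e-12)
})

test_that("quantification censoring applies the LOD/2 rule", {
  r <- censor_quantification(0.1, lod = 0.5, loq = 1.0)
  expect_equal(r$value, 0.25)
  expect_equal(r$flag, "below_LOD")
  r <- censor_quantification(0.7, 0.5, 1.0)
  expect_equal(r$value, 0.7)
  expect_equal(r$flag, "below_LOQ")
  r <- censor_quantification(2.0, 0.5, 1.0)
  expect_equal(r$value, 2.0)
  expect_equal(r$flag, "ok")
  r <- censor_quantification(c(0.1, 0.7, 2), 0.5, 1)
  expect_equal(r$flag, c("below_LOD", "below_LOQ", "ok"))
  expect_error(censor_quantification(-1, 0.5, 1), "negative")
  expect_error(censor_quantification(1, 2, 1))
})

test_that("dose-response table links exposure to the next-day FMV", {
  cfg <- study_config(n_participants = 3, seed = 19)
  b <- generate_study(cfg, render = FALSE)
  fmv <- b$metadata$sample_id[b$metadata$sample_type == "FMV"]
  conc <- stats::setNames(
    b$truth$true_concentrations[fmv, "Tartaric acid"], fmv)
  tab <- dose_response_table(b$exposure, b$metadata, conc, "grape", 125)
  # day 1: 200 g wine -> large; day 2: 31 + 43 = 74 g -> medium; day 3: none
  expect_equal(unique(tab$portion_class[tab$day == 1]), "large")
  expect_equal(unique(tab$portion_class[tab$day == 2]), "medium")
  expect_equal(unique(tab$portion_class[tab$day == 3]), "none")
  # next-day linkage: day-1 row uses the day-2 FMV
  expect_true(all(grepl("_d2_FMV", tab$fmv_sample[tab$day == 1])))
  # amounts are conc x volume where volume is recorded
  i <- which(!is.na(tab$amount_ug))[1]
  vol <- b$metadata$volume_ml[b$metadata$sample_id == tab$fmv_sample[i]]
  expect_equal(tab$amount_ug[i], tab$concentration[i] * vol)
})

test_that("volume-independent dilution leaves the dose signal intact", {
  # with volumes independent of dose, adjusted and unadjusted analyses
  # agree in the sign of the correlation
  set.seed(61)
  d <- simulate_dose_response(seed = 61)
  vol <- rlnorm(nrow(d), log(250), 0.3)  # independent of dose
  rho_raw <- portion_correlation(d$portion_class, d$concentration)$rho
  rho_adj <- portion_correlation(d$portion_class,
                                 d$concentration * vol)$rho
  expect_equal(sign(rho_raw), sign(rho_adj))
  expect_gt(rho_raw, 0)
})
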