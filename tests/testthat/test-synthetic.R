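# The generator defines the study conditions every downstream stage is
# tested under: excretion kinetics, dilution/SG coupling, spectra.

test_that("excretion kernel is normalized, single-peaked, halflife-true", {
  tt <- seq(0.1, 48, 0.1)
  for (tp in c(2, 6, 10)) {
    for (hl in c(2, 4, 8)) {
      g <- excretion_kernel(tt, tp, hl)
      expect_equal(max(g), 1, tolerance = 1e-6)
      expect_equal(tt[which.max(g)], tp, tolerance = 0.05)
      expect_equal(excretion_kernel(tp + hl, tp, hl), 0.5, tolerance = 1e-9)
      expect_true(all(g >= 0))
    }
  }
  expect_equal(excretion_kernel(c(-1, 0), 6, 4), c(0, 0))
})

test_that("tartaric-like kinetics peak inside the 4-8 h window", {
  kin <- demo_panel()[[1]]  # grape marker, t_peak 6 h, halflife 4 h
  grid <- seq(0, 24, 0.1)
  conc <- simulate_excretion(data.frame(time_h = 0, grams = 200), kin, grid)
  t_max <- grid[which.max(conc)]
  expect_gte(t_max, 4)
  expect_lte(t_max, 8)
})

test_that("excretion is baseline without events and linear in grams", {
  kin <- demo_panel()[[1]]
  st <- seq(0, 48, 1)
  none <- simulate_excretion(data.frame(time_h = numeric(0),
                                        grams = numeric(0)), kin, st)
  expect_equal(none, rep(kin$baseline_level, length(st)))

  one <- simulate_excretion(data.frame(time_h = 5, grams = 100), kin, st)
  two <- simulate_excretion(data.frame(time_h = 5, grams = 200), kin, st)
  expect_equal(two - kin$baseline_level, 2 * (one - kin$baseline_level),
               tolerance = 1e-12)

  expect_error(simulate_excretion(data.frame(time_h = 5, grams = -1),
                                  kin, st), "negative grams")
  expect_error(simulate_excretion(data.frame(time_h = 5, grams = 1),
                                  kin, c(3, 1)), "sorted")
})

test_that("above-baseline FMV response is monotone in dose", {
  kin <- demo_panel()[[1]]
  fmv <- 36  # 07:00 on the following day, dinner day 1 at 19:00
  doses <- c(0, 10, 50, 125, 200, 400)
  conc <- vapply(doses, function(g)
    simulate_excretion(data.frame(day = 1, meal_slot = "dinner", grams = g),
                       kin, fmv), numeric(1))
  expect_true(all(diff(conc) >= 0))
})

test_that("menu validation names the offending row", {
  cfg <- study_config(seed = 1)
  bad_slot <- data.frame(day = 1, meal_slot = "brunch", food = "x",
                         grams = 10)
  expect_error(generate_study(cfg, menu = bad_slot, render = FALSE),
               "row 1 .*unknown meal slot 'brunch'")
  bad_day <- data.frame(day = c(1, 9), meal_slot = "dinner", food = "x",
                        grams = 10)
  expect_error(generate_study(cfg, menu = bad_day, render = FALSE),
               "row 2 .*unknown day 9")
})

test_that("study generation is deterministic under a fixed seed", {
  cfg <- study_config(n_participants = 2, n_days = 3, seed = 7)
  b1 <- generate_study(cfg, render = FALSE)
  b2 <- generate_study(cfg, render = FALSE)
  expect_identical(b1$metadata, b2$metadata)
  expect_identical(b1$truth, b2$truth)

  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  generate_study(cfg, dir = d1, render = FALSE, force = TRUE)
  generate_study(cfg, dir = d2, render = FALSE, force = TRUE)
  for (f in c("metadata.csv", "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a grape-free menu leaves the grape marker at baseline", {
  cfg <- study_config(n_participants = 2, seed = 3)
  menu <- data.frame(day = 1, meal_slot = "lunch", food = "bread",
                     food_group = "wholegrain", grams = 80)
  b <- generate_study(cfg, menu = menu, render = FALSE)
  kin <- demo_panel()[[1]]
  expect_equal(unname(b$truth$true_concentrations[, "Tartaric acid"]),
               rep(kin$baseline_level, nrow(b$metadata)))
})

test_that("next-day FMV reflects the previous day's grape exposure", {
  # wine at dinner day 1, smaller grape doses day 2, nothing on day 3:
  # the FMV after the wine day must exceed the FMV after the no-grape day
  # for every participant
  cfg <- study_config(n_participants = 4, n_days = 3, seed = 11)
  b <- generate_study(cfg, menu = grape_menu(), render = FALSE)
  md <- b$metadata
  conc <- b$truth$true_concentrations[, "Tartaric acid"]
  for (p in unique(md$participant)) {
    fmv_after_wine <- conc[md$participant == p & md$day == 2 &
                             md$sample_type == "FMV"]
    fmv_after_none <- conc[md$participant == p & md$day == 4 &
                             md$sample_type == "FMV"]
    expect_gt(fmv_after_wine, fmv_after_none)
  }
})

test_that("every day carries baseline and postprandial samples", {
  b <- generate_study(study_config(seed = 2), render = FALSE)
  md <- b$metadata
  for (d in 1:3) {
    types <- md$sample_type[md$day == d]
    expect_true(any(types %in% c("fasting", "FMV")))
    expect_true(any(grepl("^post_", types)))
  }
})

test_that("excreted amount is independent of the dilution factor", {
  # hydration dilutes the concentration but raises the voided volume:
  # conc/d * (vol*d) is constant
  true_conc <- 12; base_vol <- 150
  amounts <- vapply(c(1, 3), function(d)
    volume_adjust(true_conc / d, base_vol * d), numeric(1))
  expect_equal(amounts[1], amounts[2], tolerance = 1e-9)
})

test_that("rendered spectra carry adducts, satellites and the TIC profile", {
  caffeine <- biomarker_kinetics("Caffeine", formula = "C8H10N4O2",
                                 adducts = "[M+H]+", food_group = "coffee")
  cfg <- study_config(seed = 5, noise_sdlog = 0, background_bins = 0)
  ss <- render_spectrum(c(Caffeine = 10), list(caffeine), "positive",
                        config = cfg)
  pk <- ss$scans[[cfg$apex_scan]]
  # main peak at the protonated m/z, satellite one 13C shift up
  expect_equal(unname(pk[1, "mz"]), 195.08765, tolerance = 1e-5)
  expect_equal(unname(pk[2, "mz"] - pk[1, "mz"]), 1.003355,
               tolerance = 1e-9)
  expect_equal(unname(pk[2, "intensity"] / pk[1, "intensity"]), 0.011 * 8,
               tolerance = 1e-9)
  # TIC apex where configured
  expect_equal(which.max(ss$tic), cfg$apex_scan)
})

test_that("zero concentration and zero baseline contribute no peaks", {
  kin <- biomarker_kinetics("X", neutral_monoisotopic_mass = 200,
                            adducts = "[M+H]+", baseline_level = 0)
  cfg <- study_config(seed = 5, noise_sdlog = 0, background_bins = 0)
  ss <- render_spectrum(c(X = 0), list(kin), "positive", config = cfg)
  expect_true(all(vapply(ss$scans, nrow, integer(1)) == 0))
})

test_that("out-of-range adducts are omitted and recorded", {
  # TMAO's [2M+H]+ dimer sits at 151.14; its [M+H]+ monomer at 76.08 is in
  # range, but a 50 Da metabolite's [M+H]+ is below the positive range
  tiny <- biomarker_kinetics("Tiny", neutral_monoisotopic_mass = 50,
                             adducts = "[M+H]+", baseline_level = 1)
  cfg <- study_config(seed = 5, noise_sdlog = 0, background_bins = 0)
  ss <- render_spectrum(c(Tiny = 5), list(tiny), "positive", config = cfg)
  expect_true(all(vapply(ss$scans, nrow, integer(1)) == 0))
  expect_equal(ss$omitted$adduct, "[M+H]+")
  expect_match(ss$omitted$reason, "outside")
})

test_that("noisy TIC apex stays within 2 scans of the configured apex", {
  cfg <- study_config(seed = 9, noise_sdlog = 0.1, background_bins = 50,
                      n_scans = 60, apex_scan = 25)
  kin <- demo_panel()[[1]]
  bg <- make_background(50, "negative")
  set.seed(42)
  for (i in 1:5) {
    ss <- render_spectrum(c("Tartaric acid" = 10), list(kin), "negative",
                          background = bg, config = cfg)
    expect_lte(abs(which.max(ss$tic) - 25), 2)
  }
})

test_that("bundles refuse to overwrite without force", {
  d <- file.path(tempdir(), "bundle_force")
  dir.create(d, showWarnings = FALSE)
  writeLines("x", file.path(d, "existing.txt"))
  expect_error(generate_study(study_config(seed = 1), dir = d,
                              render = FALSE), "not empty")
  unlink(d, recursive = TRUE)
})
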