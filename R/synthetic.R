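# Synthetic free-living food-intervention study generator.
#
# Emulates the data layout of a multi-participant, multi-day spot-urine
# intervention: a sample-metadata table with specific-gravity triplicates and
# volumes, a menu/exposure log, a ground-truth marker panel with dose- and
# time-dependent excretion, and per-sample flow-infusion spectra (both
# ionization modes) written as centroided mzML.

# Clock-time conventions (hours). Meals at conventional UK times; spot urine
# samples 2-3 h after each meal; FMV/fasting early the following morning.
.SLOT_TIMES <- c(breakfast = 8, lunch = 13, afternoon_snack = 16, dinner = 19)
.SAMPLE_TIMES <- c(FMV = 7, fasting = 7.5, post_breakfast = 10.5,
                   post_lunch = 15.5, post_dinner = 21.5)
.BASELINE_TYPES <- c("fasting", "FMV")
.POST_TYPES <- c("post_breakfast", "post_lunch", "post_dinner")

.MODE_RANGES <- list(positive = c(55, 1000), negative = c(63, 1000))

#' Configuration of a synthetic intervention study
#'
#' @param n_participants Number of participants (>= 2).
#' @param n_days Number of menu-plan days (default 3).
#' @param seed Integer master seed; the whole study is deterministic given it.
#' @param dilution_meanlog,dilution_sdlog Log-normal parameters of the
#'   per-sample hydration (dilution) factor. The defaults place typical
#'   specific gravity in the 1.011-1.037 range via `SG = 1 + 0.030/dilution`.
#' @param participant_sdlog Log-normal sd of the per-participant excretion
#'   multiplier (inter-individual variability in marker excretion).
#' @param noise_sdlog Multiplicative log-normal technical noise per peak per
#'   scan.
#' @param background_bins Number of background metabolome signals per
#'   ionization mode, drawn once per study and held fixed across samples.
#' @param n_scans,apex_scan,profile_sd Infusion profile: number of scans per
#'   run, index of the configured apex, and Gaussian width (in scans) of the
#'   total-ion-current profile.
#' @param response_factor Instrument response (intensity units per ug/mL).
#' @param mass_error_ppm_sd Per-signal calibration error (ppm, drawn once per
#'   study) applied to theoretical m/z values.
#' @param preday_conditions Pre-day evening-meal conditions recycled across
#'   participants (default alternates the standardized meal with a
#'   low-polyphenol meal of the participant's choosing; give a single value
#'   for an unstratified study).
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_participants = 2, n_days = 3, seed = 1,
                         dilution_meanlog = log(1.5), dilution_sdlog = 0.3,
                         participant_sdlog = 0.25, noise_sdlog = 0.1,
                         background_bins = 2000, n_scans = 60,
                         apex_scan = 30, profile_sd = 8,
                         response_factor = 1e4, mass_error_ppm_sd = 1.5,
                         preday_conditions = c("standardized",
                                               "low_polyphenol")) {
  stopifnot(n_participants >= 2, n_days >= 1, n_scans >= 3,
            apex_scan >= 1, apex_scan <= n_scans, profile_sd > 0,
            dilution_sdlog >= 0, noise_sdlog >= 0, background_bins >= 0)
  structure(list(
    n_participants = as.integer(n_participants),
    n_days = as.integer(n_days),
    meal_slots = names(.SLOT_TIMES),
    sample_schedule = names(.SAMPLE_TIMES),
    slot_times = .SLOT_TIMES,
    sample_times = .SAMPLE_TIMES,
    seed = as.integer(seed),
    dilution_meanlog = dilution_meanlog, dilution_sdlog = dilution_sdlog,
    participant_sdlog = participant_sdlog, noise_sdlog = noise_sdlog,
    background_bins = as.integer(background_bins),
    n_scans = as.integer(n_scans), apex_scan = as.integer(apex_scan),
    profile_sd = profile_sd, response_factor = response_factor,
    mass_error_ppm_sd = mass_error_ppm_sd,
    preday_conditions = preday_conditions
  ), class = "study_config")
}

#' Excretion kinetics of one urinary dietary biomarker
#'
#' The above-baseline urine concentration after a single exposure follows a
#' normalized gamma-shaped kernel peaking at `t_peak` and decaying on the
#' scale of `elimination_halflife` (see [excretion_kernel()]); the response is
#' linear in grams consumed with slope `dose_coefficient`.
#'
#' @param metabolite_name Metabolite name (should match the reference panel
#'   for annotation to close the loop).
#' @param formula Elemental formula; used for the neutral monoisotopic mass
#'   and the 13C satellite abundance. Either `formula` or
#'   `neutral_monoisotopic_mass` must be given.
#' @param neutral_monoisotopic_mass Neutral monoisotopic mass (Da).
#' @param adducts Character vector of adduct rule names under which the
#'   metabolite ionizes (see [adduct_rules()]).
#' @param food_group Food group whose exposure drives this marker (matched
#'   against the menu's `food_group`).
#' @param dose_coefficient Peak above-baseline concentration (ug/mL at
#'   reference hydration) per gram of food consumed. The default, with the
#'   default kinetics, puts the next-morning FMV concentration after a 200 g
#'   evening exposure near 10 ug/mL.
#' @param t_peak Time to peak excretion after exposure (h). Default 6, so a
#'   single exposure peaks inside the 4-8 h window typical of grape-derived
#'   tartaric acid.
#' @param elimination_halflife Post-peak decay half-life (h).
#' @param baseline_level Baseline urine concentration (ug/mL) without
#'   exposure.
#' @return Object of class `biomarker_kinetics`.
#' @export
biomarker_kinetics <- function(metabolite_name, formula = NULL,
                               neutral_monoisotopic_mass = NULL,
                               adducts = "[M-H]-", food_group = "grape",
                               dose_coefficient = 0.2, t_peak = 6,
                               elimination_halflife = 4,
                               baseline_level = 0.5) {
  if (is.null(neutral_monoisotopic_mass)) {
    if (is.null(formula)) stop("give either formula or neutral_monoisotopic_mass")
    neutral_monoisotopic_mass <- monoisotopic_mass(formula)
  }
  stopifnot(t_peak > 0, elimination_halflife > 0, dose_coefficient >= 0,
            baseline_level >= 0, neutral_monoisotopic_mass > 0)
  structure(list(
    metabolite_name = metabolite_name, formula = formula,
    neutral_monoisotopic_mass = neutral_monoisotopic_mass,
    adducts = adducts, food_group = food_group,
    dose_coefficient = dose_coefficient, t_peak = t_peak,
    elimination_halflife = elimination_halflife,
    baseline_level = baseline_level
  ), class = "biomarker_kinetics")
}

#' Demonstration kinetics panel
#'
#' Two-marker panel: tartaric acid as a grape/wine exposure marker with peak
#' excretion at 6 h, and caffeine as a coffee marker with a faster peak.
#'
#' @return List of [biomarker_kinetics()] objects.
#' @export
demo_panel <- function() {
  list(
    biomarker_kinetics("Tartaric acid", formula = "C4H6O6",
                       adducts = c("[M-H]-", "[M-H]- 13C", "[M+Na-2H]-"),
                       food_group = "grape", dose_coefficient = 0.2,
                       t_peak = 6, elimination_halflife = 4,
                       baseline_level = 0.5),
    biomarker_kinetics("Caffeine", formula = "C8H10N4O2",
                       adducts = "[M+H]+", food_group = "coffee",
                       dose_coefficient = 0.05, t_peak = 2,
                       elimination_halflife = 5, baseline_level = 0.2)
  )
}

#' Demonstration grape menu
#'
#' Three-day exposure log patterned on a realistic menu plan: a large glass
#' of red wine at dinner on day 1, a small grape-containing smoothie at
#' breakfast plus a medium raisin snack at dinner on day 2, and no grape
#' products on day 3.
#'
#' @return Data frame of exposure events (`day`, `meal_slot`, `food`,
#'   `food_group`, `grams`).
#' @export
grape_menu <- function() {
  data.frame(
    day = c(1L, 2L, 2L),
    meal_slot = c("dinner", "breakfast", "dinner"),
    food = c("red wine", "red berry smoothie (10% grape)", "raisins"),
    food_group = "grape",
    grams = c(200, 31, 43),
    stringsAsFactors = FALSE
  )
}

#' Normalized single-peak excretion kernel
#'
#' Gamma-shaped kernel `g(t) = (t/t_peak)^k * exp(k * (1 - t/t_peak))` for
#' `t > 0` (0 otherwise), normalized so `g(t_peak) = 1`.  The shape
#' parameter `k` is chosen so that the kernel falls to one half of its peak
#' value `halflife` hours after the peak:
#' `k = log(2) / (x - log(1 + x))` with `x = halflife / t_peak`.
#'
#' @param t Time since exposure (h); vectorized.
#' @param t_peak Time of peak excretion (h).
#' @param halflife Post-peak half-life (h).
#' @return Kernel values in `[0, 1]`.
#' @export
excretion_kernel <- function(t, t_peak, halflife) {
  stopifnot(t_peak > 0, halflife > 0)
  x <- halflife / t_peak
  k <- log(2) / (x - log1p(x))
  g <- numeric(length(t))
  pos <- t > 0
  u <- t[pos] / t_peak
  g[pos] <- exp(k * (log(u) + 1 - u))
  g
}

.event_times <- function(events, slot_times) {
  if ("time_h" %in% names(events)) return(events$time_h)
  if (!all(c("day", "meal_slot") %in% names(events))) {
    stop("events need either a time_h column or day + meal_slot columns")
  }
  bad <- !(events$meal_slot %in% names(slot_times))
  if (any(bad)) {
    stop("menu row ", which(bad)[1], " references unknown meal slot '",
         events$meal_slot[which(bad)[1]], "'")
  }
  (events$day - 1) * 24 + unname(slot_times[events$meal_slot])
}

#' Simulate a marker's urine concentration series
#'
#' Concentration at time `t` is `baseline_level` plus, for every exposure
#' event, `dose_coefficient * grams * g(t - t_event)` with `g` the
#' [excretion_kernel()].  Concentrations are at reference hydration
#' (pre-dilution); the response is linear in grams by construction.
#'
#' @param events Data frame of exposure events with `grams` and either
#'   `time_h` or (`day`, `meal_slot`).
#' @param kinetics A [biomarker_kinetics()] object.
#' @param sample_times Sorted vector of absolute times (h) at which urine is
#'   sampled.
#' @param slot_times Named meal-slot clock times; default the package's
#'   convention (breakfast 08:00, lunch 13:00, snack 16:00, dinner 19:00).
#' @return Numeric vector of concentrations (ug/mL), one per sample time.
#' @export
simulate_excretion <- function(events, kinetics, sample_times,
                               slot_times = .SLOT_TIMES) {
  stopifnot(inherits(kinetics, "biomarker_kinetics"))
  if (is.unsorted(sample_times)) stop("sample_times must be sorted")
  if (nrow(events) == 0) {
    return(rep(kinetics$baseline_level, length(sample_times)))
  }
  if (any(events$grams < 0)) stop("negative grams in exposure events")
  tev <- .event_times(events, slot_times)
  conc <- vapply(sample_times, function(t) {
    kinetics$baseline_level + sum(
      kinetics$dose_coefficient * events$grams *
        excretion_kernel(t - tev, kinetics$t_peak, kinetics$elimination_halflife)
    )
  }, numeric(1))
  pmax(conc, 0)
}

#' Draw a background metabolome for one ionization mode
#'
#' Background signal identities (m/z positions) and base intensities are
#' drawn once per study and held fixed across samples; per-sample variation
#' is multiplicative log-normal noise applied at render time.
#'
#' @param n_bins Number of background signals.
#' @param mode `"positive"` or `"negative"`.
#' @param intensity_meanlog,intensity_sdlog Log-normal parameters of base
#'   intensities.
#' @return Data frame with columns `mz`, `base_intensity`.
#' @export
make_background <- function(n_bins, mode = c("positive", "negative"),
                            intensity_meanlog = log(2e4),
                            intensity_sdlog = 1.5) {
  mode <- match.arg(mode)
  rng <- .MODE_RANGES[[mode]]
  if (n_bins == 0) {
    return(data.frame(mz = numeric(0), base_intensity = numeric(0)))
  }
  mz <- sort(stats::runif(n_bins, rng[1] + 0.5, rng[2] - 0.5))
  data.frame(mz = mz,
             base_intensity = stats::rlnorm(n_bins, intensity_meanlog,
                                            intensity_sdlog))
}

.marker_peaks <- function(true_concentrations, panel, mode, dilution_factor,
                          response_factor, mass_errors = NULL) {
  rng <- .MODE_RANGES[[mode]]
  peaks <- list(); omitted <- list()
  for (kin in panel) {
    conc <- true_concentrations[[kin$metabolite_name]]
    if (is.null(conc) || is.na(conc)) conc <- 0
    obs <- conc / dilution_factor
    ncarbon <- if (!is.null(kin$formula)) carbon_count(kin$formula) else 0L
    rules <- .adduct_rule_table()
    for (ad in kin$adducts) {
      if (grepl("13C", ad, fixed = TRUE)) next  # satellites added automatically
      charge <- rules$charge[match(ad, rules$name)]
      if ((mode == "positive") != (charge > 0)) next  # wrong polarity
      mz <- theoretical_mz(kin$neutral_monoisotopic_mass, ad)
      key <- paste(kin$metabolite_name, ad)
      if (!is.null(mass_errors) && key %in% names(mass_errors)) {
        mz <- mz * (1 + mass_errors[[key]] * 1e-6)
      }
      mult <- rules$multiplicity[match(ad, rules$name)]
      if (mz < rng[1] || mz > rng[2]) {
        omitted[[length(omitted) + 1]] <- data.frame(
          metabolite = kin$metabolite_name, adduct = ad, mz = mz, mode = mode,
          reason = "outside mode m/z range", stringsAsFactors = FALSE)
        next
      }
      if (obs <= 0) next
      base_int <- obs * response_factor
      peaks[[length(peaks) + 1]] <- data.frame(
        metabolite = kin$metabolite_name, adduct = ad,
        mz = mz, intensity = base_int, stringsAsFactors = FALSE)
      # M+1 13C satellite, ~1.1% per carbon in the ion
      sat_int <- base_int * 0.011 * ncarbon * mult
      sat_mz <- mz + mass_constants()[["c13_shift"]]
      if (sat_int > 0 && sat_mz >= rng[1] && sat_mz <= rng[2]) {
        peaks[[length(peaks) + 1]] <- data.frame(
          metabolite = kin$metabolite_name, adduct = paste(ad, "13C"),
          mz = sat_mz, intensity = sat_int, stringsAsFactors = FALSE)
      }
    }
  }
  list(peaks = if (length(peaks)) do.call(rbind, peaks) else NULL,
       omitted = if (length(omitted)) do.call(rbind, omitted) else NULL)
}

#' Render a flow-infusion scan set for one sample
#'
#' Produces ~`n_scans` centroided scans whose total ion current follows a
#' Gaussian infusion profile centered at `apex_scan`.  Each panel metabolite
#' contributes peaks at the m/z of its configured adducts plus an M+1 13C
#' satellite (abundance ~1.1% per carbon); intensities scale with the
#' sample's observed concentration (`true concentration / dilution_factor`)
#' times the instrument response.  Background signals are taken from a fixed
#' per-study background table.  Adducts falling outside the mode's m/z range
#' are omitted and reported in the result.
#'
#' @param true_concentrations Named numeric vector (metabolite -> ug/mL at
#'   reference hydration).
#' @param panel List of [biomarker_kinetics()].
#' @param mode `"positive"` (m/z 55-1000) or `"negative"` (m/z 63-1000).
#' @param dilution_factor Hydration dilution factor of this sample.
#' @param background Data frame from [make_background()] (same mode), or NULL.
#' @param config A [study_config()] supplying scan count, apex, profile
#'   width, noise and response factor.
#' @param mass_errors Optional named vector of per-signal calibration errors
#'   (ppm), keyed `"<metabolite> <adduct>"`.
#' @param seed Optional seed for the per-scan noise.
#' @return Object of class `scan_set`: list of centroided scans (m/z,
#'   intensity matrices), per-scan TIC, the configured apex, mode, and the
#'   omitted-adduct table.
#' @export
render_spectrum <- function(true_concentrations, panel,
                            mode = c("positive", "negative"),
                            dilution_factor = 1, background = NULL,
                            config = study_config(), mass_errors = NULL,
                            seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  mk <- .marker_peaks(true_concentrations, panel, mode, dilution_factor,
                      config$response_factor, mass_errors)
  # background metabolites are urine-borne too, so they dilute alongside
  # the markers
  mz <- c(if (!is.null(mk$peaks)) mk$peaks$mz, background$mz)
  base_int <- c(if (!is.null(mk$peaks)) mk$peaks$intensity,
                background$base_intensity / dilution_factor)
  if (is.null(mz)) {
    mz <- numeric(0)
    base_int <- numeric(0)
  }
  ord <- order(mz)
  mz <- mz[ord]; base_int <- base_int[ord]
  s <- seq_len(config$n_scans)
  profile <- exp(-(s - config$apex_scan)^2 / (2 * config$profile_sd^2))
  scans <- lapply(s, function(i) {
    if (length(mz) == 0) {
      return(matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("mz", "intensity"))))
    }
    noise <- if (config$noise_sdlog > 0) {
      stats::rlnorm(length(mz), 0, config$noise_sdlog)
    } else rep(1, length(mz))
    cbind(mz = mz, intensity = base_int * profile[i] * noise)
  })
  structure(list(
    scans = scans,
    tic = vapply(scans, function(p) sum(p[, "intensity"]), numeric(1)),
    mode = mode, mz_range = .MODE_RANGES[[mode]],
    apex_scan = config$apex_scan,
    omitted = mk$omitted
  ), class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  cat("<scan_set> ", length(x$scans), " scans, ", x$mode, " mode, m/z ",
      x$mz_range[1], "-", x$mz_range[2], ", TIC apex at scan ",
      which.max(x$tic), "\n", sep = "")
  invisible(x)
}

#' Write a scan set to a centroided mzML file
#'
#' Standard-conformant mzML via the proteowizard backend; a round-trip read
#' with [read_mzml()] returns the same peak lists within float tolerance.
#'
#' @param scans A `scan_set` from [render_spectrum()].
#' @param path Output file path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(scans, path) {
  stopifnot(inherits(scans, "scan_set"))
  n <- length(scans$scans)
  if (n == 0) stop("no spectra to write")
  pks <- lapply(scans$scans, function(p) {
    storage.mode(p) <- "double"
    p
  })
  counts <- vapply(pks, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = if (scans$mode == "positive") 1L else 0L,
    peaksCount = counts,
    totIonCurrent = scans$tic,
    retentionTime = as.numeric(seq_len(n)),
    basePeakMZ = vapply(pks, function(p)
      if (nrow(p)) p[which.max(p[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pks, function(p)
      if (nrow(p)) max(p[, 2]) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pks, function(p) if (nrow(p)) min(p[, 1]) else 0, numeric(1)),
    highMZ = vapply(pks, function(p) if (nrow(p)) max(p[, 1]) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = scans$mz_range[1],
    scanWindowUpperLimit = scans$mz_range[2],
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

.sample_schedule <- function(n_days) {
  # full schedule on menu days; FMV + fasting on the post-day
  rows <- do.call(rbind, lapply(seq_len(n_days), function(d) {
    data.frame(day = d, sample_type = names(.SAMPLE_TIMES),
               stringsAsFactors = FALSE)
  }))
  rbind(rows, data.frame(day = n_days + 1L,
                         sample_type = c("FMV", "fasting"),
                         stringsAsFactors = FALSE))
}

.validate_menu <- function(menu, config) {
  need <- c("day", "meal_slot", "grams")
  if (!all(need %in% names(menu))) {
    stop("menu must have columns: ", paste(need, collapse = ", "))
  }
  bad_day <- !(menu$day %in% seq_len(config$n_days))
  if (any(bad_day)) {
    stop("menu row ", which(bad_day)[1], " references unknown day ",
         menu$day[which(bad_day)[1]])
  }
  bad_slot <- !(menu$meal_slot %in% config$meal_slots)
  if (any(bad_slot)) {
    stop("menu row ", which(bad_slot)[1], " references unknown meal slot '",
         menu$meal_slot[which(bad_slot)[1]], "'")
  }
  if (any(menu$grams < 0)) {
    stop("menu row ", which(menu$grams < 0)[1], " has negative grams")
  }
  if (is.null(menu$food_group)) menu$food_group <- menu$food
  menu
}

#' Generate a complete synthetic intervention study
#'
#' Builds sample metadata (one row per collected spot-urine sample: fasting,
#' FMV and three postprandial samples per menu day, plus the post-day FMV and
#' fasting samples), the exposure log, the ground truth (true concentrations,
#' dilution factors, spiked bins with their metabolite/adduct identity, and
#' adducts omitted as out of range), and optionally per-sample mzML spectra
#' in both ionization modes.  Deterministic given `config$seed`.
#'
#' @param config A [study_config()].
#' @param panel List of [biomarker_kinetics()]; non-empty.
#' @param menu Exposure log data frame (`day`, `meal_slot`, `food`, `grams`,
#'   optional `food_group`), applied to every participant.
#' @param dir Output directory; if non-NULL, writes `metadata.csv`,
#'   `exposure.csv`, `ground_truth.json`, `config.json` and (if `render`)
#'   `mzml/<sample>_<mode>.mzML` files.
#' @param render Render and keep spectra? If FALSE only metadata and ground
#'   truth are produced.
#' @param force Overwrite a non-empty `dir`.
#' @return Object of class `study_bundle` with elements `metadata`,
#'   `exposure`, `truth` (true concentration matrix, dilution factors,
#'   spiked-bin table, omitted adducts), `background`, `spectra` (list of
#'   `scan_set` per sample and mode, if rendered in memory), `paths`, and the
#'   `config` and `panel` used.
#' @export
generate_study <- function(config = study_config(), panel = demo_panel(),
                           menu = grape_menu(), dir = NULL, render = TRUE,
                           force = FALSE) {
  stopifnot(inherits(config, "study_config"), length(panel) >= 1)
  menu <- .validate_menu(menu, config)
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
      stop("output directory '", dir, "' is not empty; use force = TRUE")
    }
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  }
  set.seed(config$seed)

  participants <- sprintf("P%02d", seq_len(config$n_participants))
  preday <- rep(config$preday_conditions,
                length.out = config$n_participants)
  sched <- .sample_schedule(config$n_days)

  meta <- do.call(rbind, lapply(seq_along(participants), function(i) {
    m <- sched
    m$participant <- participants[i]
    m$preday_condition <- preday[i]
    m
  }))
  meta$collection_time_h <- (meta$day - 1) * 24 +
    unname(.SAMPLE_TIMES[meta$sample_type])
  meta$sample_id <- sprintf("%s_d%d_%s", meta$participant, meta$day,
                            meta$sample_type)
  meta <- meta[order(meta$participant, meta$collection_time_h), ]
  rownames(meta) <- NULL
  n_samp <- nrow(meta)

  # hydration: dilution factor, SG triplicate, volume coupled to dilution so
  # that the excreted amount (conc x volume) is hydration-independent
  dil <- stats::rlnorm(n_samp, config$dilution_meanlog, config$dilution_sdlog)
  sg_true <- pmin(pmax(1 + 0.030 / dil, 1.001), 1.059)
  sg_trip <- t(vapply(sg_true, function(s)
    round(s + stats::rnorm(3, 0, 3e-4), 4), numeric(3)))
  base_vol <- ifelse(meta$sample_type == "FMV",
                     stats::rlnorm(n_samp, log(250), 0.3),
                     stats::rlnorm(n_samp, log(120), 0.4))
  meta$volume_ml <- round(base_vol * dil, 1)
  meta$sg1 <- sg_trip[, 1]; meta$sg2 <- sg_trip[, 2]; meta$sg3 <- sg_trip[, 3]
  meta$temperature_c <- round(stats::rnorm(n_samp, 20, 1), 1)

  # participant-level excretion multipliers (inter-individual variability)
  pmult <- stats::rlnorm(config$n_participants, 0, config$participant_sdlog)
  names(pmult) <- participants

  # true concentration matrix: samples x metabolites, reference hydration
  truth_conc <- matrix(0, n_samp, length(panel),
                       dimnames = list(meta$sample_id,
                                       vapply(panel, `[[`, "",
                                              "metabolite_name")))
  for (kin in panel) {
    ev <- menu[menu$food_group == kin$food_group, , drop = FALSE]
    for (p in participants) {
      rows <- which(meta$participant == p)
      conc <- simulate_excretion(ev, kin, meta$collection_time_h[rows],
                                 config$slot_times)
      above <- (conc - kin$baseline_level) * pmult[[p]]
      truth_conc[rows, kin$metabolite_name] <- kin$baseline_level + above
    }
  }

  # per-signal calibration error, fixed across the study
  keys <- unlist(lapply(panel, function(kin)
    paste(kin$metabolite_name,
          kin$adducts[!grepl("13C", kin$adducts, fixed = TRUE)])))
  mass_errors <- stats::rnorm(length(keys), 0, config$mass_error_ppm_sd)
  names(mass_errors) <- keys

  background <- list(
    positive = make_background(config$background_bins, "positive"),
    negative = make_background(config$background_bins, "negative")
  )

  # spiked-bin table: where each marker adduct lands after 0.01 amu binning
  spiked <- list(); omitted <- list()
  for (kin in panel) {
    for (ad in kin$adducts) {
      base_ad <- sub(" 13C$", "", ad)
      mz <- theoretical_mz(kin$neutral_monoisotopic_mass, ad)
      key <- paste(kin$metabolite_name, base_ad)
      if (key %in% names(mass_errors)) mz <- mz * (1 + mass_errors[[key]] * 1e-6)
      mode <- if (grepl("\\+( 13C)?$", ad)) "positive" else "negative"
      rng <- .MODE_RANGES[[mode]]
      if (mz < rng[1] || mz > rng[2]) {
        omitted[[length(omitted) + 1]] <- data.frame(
          metabolite = kin$metabolite_name, adduct = ad, mz = mz, mode = mode,
          reason = "outside mode m/z range", stringsAsFactors = FALSE)
        next
      }
      idx <- floor((mz - rng[1]) / 0.01)
      spiked[[length(spiked) + 1]] <- data.frame(
        mode = mode, bin_index = idx,
        bin = sprintf("%s_%.2f", substr(mode, 1, 3), rng[1] + idx / 100),
        mz = mz, metabolite = kin$metabolite_name, adduct = ad,
        stringsAsFactors = FALSE)
    }
  }
  truth <- list(
    true_concentrations = truth_conc,
    dilution_factor = stats::setNames(dil, meta$sample_id),
    participant_multiplier = pmult,
    mass_errors_ppm = mass_errors,
    spiked_bins = do.call(rbind, spiked),
    omitted_adducts = if (length(omitted)) do.call(rbind, omitted) else NULL
  )

  spectra <- NULL
  paths <- list(dir = dir)
  if (render) {
    spectra <- vector("list", n_samp)
    names(spectra) <- meta$sample_id
    if (!is.null(dir)) dir.create(file.path(dir, "mzml"), showWarnings = FALSE)
    for (i in seq_len(n_samp)) {
      per_mode <- list()
      for (mode in c("positive", "negative")) {
        ss <- render_spectrum(stats::setNames(truth_conc[i, ],
                                              colnames(truth_conc)),
                              panel, mode = mode,
                              dilution_factor = dil[i],
                              background = background[[mode]],
                              config = config, mass_errors = mass_errors)
        if (!is.null(dir)) {
          write_mzml(ss, file.path(dir, "mzml",
                                   sprintf("%s_%s.mzML", meta$sample_id[i],
                                           mode)))
        }
        per_mode[[mode]] <- ss
      }
      spectra[[i]] <- per_mode
    }
    if (!is.null(dir)) {
      paths$mzml <- file.path(dir, "mzml",
                              sprintf("%s_%s.mzML",
                                      rep(meta$sample_id, each = 2),
                                      c("positive", "negative")))
    }
  }

  meta <- meta[, c("sample_id", "participant", "day", "sample_type",
                   "preday_condition", "collection_time_h", "volume_ml",
                   "sg1", "sg2", "sg3", "temperature_c")]
  exposure <- menu
  if (!is.null(dir)) {
    utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
    utils::write.csv(exposure, file.path(dir, "exposure.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(true_concentrations = as.data.frame(truth_conc),
           sample_id = meta$sample_id,
           dilution_factor = unname(truth$dilution_factor),
           participant_multiplier = truth$participant_multiplier,
           mass_errors_ppm = as.list(truth$mass_errors_ppm),
           spiked_bins = truth$spiked_bins,
           omitted_adducts = truth$omitted_adducts),
      file.path(dir, "ground_truth.json"),
      digits = NA, auto_unbox = TRUE, pretty = TRUE)
    cfg <- config
    class(cfg) <- NULL
    jsonlite::write_json(cfg, file.path(dir, "config.json"), digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(lapply(panel, unclass),
                         file.path(dir, "panel.json"), digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
    paths$metadata <- file.path(dir, "metadata.csv")
    paths$exposure <- file.path(dir, "exposure.csv")
    paths$ground_truth <- file.path(dir, "ground_truth.json")
  }

  structure(list(metadata = meta, exposure = exposure, truth = truth,
                 background = background, spectra = spectra, paths = paths,
                 config = config, panel = panel),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("<study_bundle> ", length(unique(x$metadata$participant)),
      " participants, ", max(x$metadata$day) - 1, " menu days, ",
      nrow(x$metadata), " samples, ", ncol(x$truth$true_concentrations),
      " ground-truth markers\n", sep = "")
  if (!is.null(x$paths$dir)) cat("  written to ", x$paths$dir, "\n", sep = "")
  invisible(x)
}

#' Simulate a spiked two-class fingerprint matrix directly
#'
#' Fast path for feature-selection simulations: draws a background of
#' log-normal bin intensities shared by both classes, multiplies a chosen set
#' of spiked bins by `fold_change` in the postprandial class, and applies
#' per-sample multiplicative log-normal noise.  This is the same intensity
#' model the spectrum renderer uses, skipping the mzML round trip.
#'
#' @param n_per_class Samples per class.
#' @param n_background Number of background bins.
#' @param n_spiked Number of spiked (truly discriminatory) bins.
#' @param fold_change Multiplicative effect in the postprandial class.
#' @param noise_sdlog Per-sample log-normal noise sd.
#' @param base_meanlog,base_sdlog Log-normal parameters of bin base
#'   intensities.
#' @param seed Seed.
#' @return List with `X` (samples x bins), `y` (factor baseline/postprandial)
#'   and `spiked` (spiked column names).
#' @export
simulate_fingerprint_matrix <- function(n_per_class = 10, n_background = 2000,
                                        n_spiked = 5, fold_change = 4,
                                        noise_sdlog = 0.3,
                                        base_meanlog = 10, base_sdlog = 1.5,
                                        seed = 1) {
  set.seed(seed)
  p <- n_background + n_spiked
  n <- 2 * n_per_class
  base <- stats::rlnorm(p, base_meanlog, base_sdlog)
  X <- matrix(stats::rlnorm(n * p, 0, noise_sdlog), n, p) *
    rep(base, each = n)
  spike_cols <- sort(sample.int(p, n_spiked))
  post <- (n_per_class + 1):n
  X[post, spike_cols] <- X[post, spike_cols] * fold_change
  colnames(X) <- sprintf("bin%04d", seq_len(p))
  y <- factor(rep(c("baseline", "postprandial"), each = n_per_class),
              levels = c("baseline", "postprandial"))
  rownames(X) <- paste0("S", seq_len(n))
  list(X = X, y = y, spiked = colnames(X)[spike_cols])
}
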