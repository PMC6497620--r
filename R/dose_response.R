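# Dose-response validation of candidate biomarkers: portion-size
# classification against a food-portion reference, next-day FMV
# concentration summaries, extreme-portion t-tests, and Spearman rank
# correlation of portion size with concentration.

#' Classify a daily food intake into portion-size classes
#'
#' A "large" portion exceeds 1.5x the reference medium portion and a
#' "small" portion is below 0.5x it; the medium band is inclusive on both
#' edges; zero grams is "none".
#'
#' @param grams Grams consumed (vectorized, >= 0).
#' @param medium_g Reference medium portion in grams (> 0).
#' @param large_factor,small_factor Multipliers defining the class
#'   boundaries (defaults 1.5 and 0.5).
#' @return Character vector in `{none, small, medium, large}`.
#' @export
#' @examples
#' classify_portion(208, 125)  # large
#' classify_portion(31, 125)   # small
classify_portion <- function(grams, medium_g, large_factor = 1.5,
                             small_factor = 0.5) {
  stopifnot(medium_g > 0)
  if (any(grams < 0)) stop("grams must be >= 0")
  out <- rep("medium", length(grams))
  out[grams > large_factor * medium_g] <- "large"
  out[grams < small_factor * medium_g] <- "small"
  out[grams == 0] <- "none"
  out
}

#' Mean and standard error of FMV concentrations per group
#'
#' @param values Concentrations (ug/mL).
#' @param groups Grouping vector (e.g. day or exposure class).
#' @return Data frame `group`, `mean`, `se`, `n`; the SE of a single-record
#'   group is reported as `NA`. Empty groups are dropped with a warning.
#' @export
summarize_fmv <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values)
  if (any(!keep)) warning(sum(!keep), " record(s) with missing value skipped")
  values <- values[keep]; groups <- groups[keep]
  if (length(values) == 0) {
    warning("no records to summarize")
    return(data.frame(group = character(0), mean = numeric(0),
                      se = numeric(0), n = integer(0)))
  }
  g <- factor(groups)
  n <- as.integer(table(g))
  data.frame(
    group = levels(g),
    mean = as.numeric(tapply(values, g, mean)),
    se = as.numeric(tapply(values, g, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)),
    n = n, stringsAsFactors = FALSE
  )
}

#' Compare concentrations after the lowest and highest portion sizes
#'
#' Two-sided Student's (pooled-variance) t-test of the mean FMV
#' concentration after the highest versus lowest consumed portion class.
#'
#' @param low,high Concentration vectors for the lowest- and
#'   highest-portion groups (>= 2 each).
#' @return List `t`, `p`, `df`, plus `degenerate` flag for zero-variance
#'   input (P = 1 for identical groups, P = 0 for separated constant
#'   groups).
#' @export
extreme_portion_test <- function(low, high) {
  if (length(low) < 2 || length(high) < 2) {
    stop("need >= 2 observations per group")
  }
  n1 <- length(low); n2 <- length(high)
  sp2 <- ((n1 - 1) * stats::var(low) + (n2 - 1) * stats::var(high)) /
    (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  dm <- mean(high) - mean(low)
  if (se == 0) {
    degen <- abs(dm) >= .Machine$double.eps^0.5
    return(list(t = if (degen) Inf * sign(dm) else 0,
                p = if (degen) 0 else 1,
                df = n1 + n2 - 2, degenerate = degen))
  }
  tt <- dm / se
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = n1 + n2 - 2),
       df = n1 + n2 - 2, degenerate = FALSE)
}

#' Spearman rank correlation of portion size with concentration
#'
#' Midrank-tied Spearman correlation with the t-approximation P-value.
#' Portion classes are converted to their natural order
#' none < small < medium < large when a character/factor vector is given.
#'
#' @param portion Portion classes (character/ordered factor) or grams.
#' @param concentration Biomarker concentrations.
#' @return List `rho`, `p`, `n`. A constant input vector makes the
#'   correlation undefined: both are returned as `NA`.
#' @export
portion_correlation <- function(portion, concentration) {
  if (is.character(portion) || is.factor(portion)) {
    lv <- c("none", "small", "medium", "large")
    if (!all(as.character(portion) %in% lv)) {
      stop("unknown portion class; expected ", paste(lv, collapse = ", "))
    }
    portion <- as.integer(factor(as.character(portion), levels = lv))
  }
  keep <- !is.na(portion) & !is.na(concentration)
  x <- portion[keep]; ycc <- concentration[keep]
  if (length(x) < 3) stop("need >= 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(ycc)) < 2) {
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, ycc, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Censor a quantified concentration at the assay detection limits
#'
#' Below the limit of detection the value is substituted by LOD/2 (a common
#' convention for left-censored assay data) and flagged `below_LOD`; between
#' LOD and LOQ the measured value is kept but flagged `below_LOQ`.
#'
#' @param concentration Measured concentration(s), >= 0.
#' @param lod,loq Limits of detection and quantification (LOD <= LOQ).
#' @return Data frame `value`, `flag` (`below_LOD`, `below_LOQ` or `ok`).
#' @export
censor_quantification <- function(concentration, lod, loq) {
  stopifnot(lod <= loq)
  if (any(concentration < 0)) stop("negative concentration")
  value <- concentration
  flag <- rep("ok", length(concentration))
  below_lod <- concentration < lod
  value[below_lod] <- lod / 2
  flag[below_lod] <- "below_LOD"
  flag[!below_lod & concentration < loq] <- "below_LOQ"
  data.frame(value = value, flag = flag, stringsAsFactors = FALSE)
}

#' Build the dose-response table for one food group and marker
#'
#' Sums each participant-day's exposure to the food group across meals,
#' classifies the daily total into a portion class, and links it to the FMV
#' sample collected the following day (its marker concentration and,
#' where the voided volume is available, the volume-adjusted excreted
#' amount).
#'
#' @param exposure Exposure log (`day`, `grams`, optional `food_group`).
#' @param metadata Study metadata with FMV rows (`sample_id`, `participant`,
#'   `day`, `sample_type`, `volume_ml`).
#' @param concentrations Named vector: FMV `sample_id` -> concentration
#'   (ug/mL).
#' @param food_group Food group to tabulate.
#' @param medium_g Reference medium portion (grams).
#' @return Data frame (`participant`, `day`, `grams`, `portion_class`,
#'   `fmv_sample`, `concentration`, `amount_ug`).
#' @export
dose_response_table <- function(exposure, metadata, concentrations,
                                food_group, medium_g) {
  if (is.null(exposure$food_group)) exposure$food_group <- exposure$food
  ev <- exposure[exposure$food_group == food_group, , drop = FALSE]
  participants <- unique(metadata$participant)
  fmv_days <- metadata$day[metadata$sample_type == "FMV"]
  all_days <- sort(unique(metadata$day))
  days <- all_days[(all_days + 1) %in% fmv_days]  # days with a next-day FMV
  rows <- list()
  for (p in participants) {
    for (d in days) {
      g <- sum(ev$grams[ev$day == d])
      fmv <- metadata$sample_id[metadata$participant == p &
                                  metadata$day == d + 1 &
                                  metadata$sample_type == "FMV"]
      if (length(fmv) == 0) next
      conc <- unname(concentrations[fmv[1]])
      vol <- metadata$volume_ml[metadata$sample_id == fmv[1]]
      amount <- if (!is.na(vol) && !is.null(conc) && !is.na(conc)) {
        conc * vol
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        participant = p, day = d, grams = g,
        portion_class = classify_portion(g, medium_g),
        fmv_sample = fmv[1],
        concentration = if (is.null(conc)) NA_real_ else conc,
        amount_ug = amount, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a next-morning FMV dose-response experiment
#'
#' Each participant consumes a fixed dose at dinner; the marker
#' concentration in the next morning's FMV urine follows the excretion
#' kinetics with multiplicative log-normal inter-individual noise.
#'
#' @param doses_g Dose levels (grams); each is given to `n_per_level`
#'   participants.
#' @param n_per_level Participants per dose level.
#' @param kinetics A [biomarker_kinetics()].
#' @param noise_sdlog Log-normal sd of the inter-individual multiplier.
#' @param medium_g Reference medium portion for the portion class.
#' @param seed Seed.
#' @return Data frame `grams`, `portion_class`, `concentration`.
#' @export
simulate_dose_response <- function(doses_g = c(0, 50, 125, 250),
                                   n_per_level = 10,
                                   kinetics = demo_panel()[[1]],
                                   noise_sdlog = 0.25, medium_g = 125,
                                   seed = 1) {
  set.seed(seed)
  grams <- rep(doses_g, each = n_per_level)
  # dinner at 19:00, FMV at 07:00 the next morning
  fmv_lag <- 12
  above <- kinetics$dose_coefficient * grams *
    excretion_kernel(fmv_lag, kinetics$t_peak, kinetics$elimination_halflife)
  conc <- (kinetics$baseline_level + above) *
    stats::rlnorm(length(grams), 0, noise_sdlog)
  data.frame(grams = grams,
             portion_class = classify_portion(grams, medium_g),
             concentration = conc, stringsAsFactors = FALSE)
}
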