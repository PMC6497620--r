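# Accurate-mass annotation of selected m/z bins against a metabolite
# reference using adduct / neutral-loss rules at ppm tolerance, plus MSI
# (Metabolomics Standards Initiative) evidence-level assignment.

.adduct_rule_table <- function() {
  k <- mass_constants()
  rules <- rbind(
    data.frame(name = "[M+H]+",       multiplicity = 1, delta = k[["proton"]],                    charge = 1L),
    data.frame(name = "[M-H]-",       multiplicity = 1, delta = -k[["proton"]],                   charge = -1L),
    data.frame(name = "[M+Na]+",      multiplicity = 1, delta = k[["na_minus_h"]] + k[["proton"]], charge = 1L),
    data.frame(name = "[M+K]+",       multiplicity = 1, delta = k[["k_minus_h"]] + k[["proton"]],  charge = 1L),
    data.frame(name = "[2M+H]+",      multiplicity = 2, delta = k[["proton"]],                    charge = 1L),
    data.frame(name = "[M+Na-2H]-",   multiplicity = 1, delta = k[["na_minus_h"]] - k[["proton"]], charge = -1L),
    data.frame(name = "[M-SULP-H]-",  multiplicity = 1, delta = -k[["so3_loss"]] - k[["proton"]],  charge = -1L)
  )
  # 13C isotopologue satellites of the singly charged base rules
  sat <- rules[rules$multiplicity == 1, ]
  sat$name <- paste0(sat$name, " 13C")
  sat$delta <- sat$delta + k[["c13_shift"]]
  rbind(rules, sat)
}

#' Adduct and neutral-loss rules known to the annotator
#'
#' Returns the bundled rule set covering the ionization products observed for
#' the package's dietary-biomarker panel: protonated/deprotonated species,
#' sodium and potassium adducts, the proton-bound dimer, the sodiated
#' deprotonated species, the SO3 (sulfate) neutral loss, and the 13C (M+1)
#' satellite of each singly charged rule.  Theoretical m/z for a rule is
#' `multiplicity * M + delta` for a singly charged ion of neutral mass `M`.
#'
#' @return Data frame with columns `name`, `multiplicity`, `delta`, `charge`.
#' @export
#' @examples
#' adduct_rules()
adduct_rules <- function() {
  rules <- .adduct_rule_table()
  rownames(rules) <- NULL
  rules
}

#' Theoretical m/z of an ionization product
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (positive scalar or
#'   vector).
#' @param rule Adduct rule name, e.g. `"[M+H]+"`; see [adduct_rules()].
#' @return Theoretical m/z (same length as `neutral_mass`).
#' @export
#' @examples
#' theoretical_mz(194.08038, "[M+H]+")  # caffeine -> 195.08765
theoretical_mz <- function(neutral_mass, rule) {
  stopifnot(is.numeric(neutral_mass), all(neutral_mass > 0))
  rules <- .adduct_rule_table()
  i <- match(rule, rules$name)
  if (is.na(i)) {
    stop("unknown adduct rule '", rule, "'; available rules: ",
         paste(rules$name, collapse = ", "))
  }
  rules$multiplicity[i] * neutral_mass + rules$delta[i]
}

#' Load the bundled dietary-biomarker reference panel
#'
#' The panel lists previously reported urinary food-intake biomarkers (rye
#' bread, coffee, sweetened cereal, oily fish, broccoli, grapes/wine, almonds
#' and related foods) with elemental formulas, the ionization products under
#' which each has been observed, and the evidence class backing its identity.
#'
#' @param path Optional path to an alternative reference CSV with columns
#'   `name, formula, food_group, adducts, msi_evidence` (adducts separated by
#'   `;`).
#' @return Data frame with one row per metabolite; `monoisotopic_mass` is
#'   computed from the formula on load.
#' @export
reference_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "biomarker_reference.csv", package = "urimark")
  }
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "food_group", "adducts", "msi_evidence")
  if (!all(need %in% names(ref))) {
    stop("reference table must have columns: ", paste(need, collapse = ", "))
  }
  ref$monoisotopic_mass <- vapply(ref$formula, monoisotopic_mass, numeric(1))
  ref
}

#' Annotate selected bins by accurate mass
#'
#' Matches m/z bins against all (metabolite, adduct-rule) pairs of a reference
#' table.  When an accurate (un-binned) m/z is supplied for a bin, a hit
#' requires the theoretical m/z to lie within `tolerance_ppm` of it and the
#' ppm error is reported against that accurate mass.  When only the bin label
#' is available the match criterion is the theoretical m/z falling inside the
#' 0.01 amu bin interval widened by the ppm tolerance, and the ppm error is
#' reported against the bin center (which can exceed the tolerance, since a
#' 0.01 amu bin is wider than 5 ppm below ~1000 m/z).  Mode-tagged bin
#' labels (`pos_`/`neg_`) restrict matches to rules of that polarity.
#'
#' @param bins Data frame with columns `bin` (label), `mz_lower` (bin lower
#'   edge) and optionally `observed_mz` (accurate mass of the dominant peak in
#'   the bin, taken from the un-binned data).
#' @param reference Reference table as returned by [reference_panel()].
#' @param tolerance_ppm Mass tolerance in ppm, in the 1-5 ppm window the
#'   first-pass profile supports. Default 5.
#' @param bin_width Bin width in amu (default 0.01).
#' @return Data frame of annotation hits (`bin`, `observed_mz`, `metabolite`,
#'   `adduct`, `theoretical_mz`, `ppm_error`, `msi_level`, `ambiguous`),
#'   sorted within bin by absolute ppm error.  Bins without a hit appear once
#'   with `metabolite = NA`.
#' @export
annotate_bins <- function(bins, reference, tolerance_ppm = 5, bin_width = 0.01) {
  stopifnot(is.data.frame(bins), all(c("bin", "mz_lower") %in% names(bins)))
  if (!is.numeric(tolerance_ppm) || tolerance_ppm <= 0) {
    stop("tolerance_ppm must be a positive number")
  }
  if (!is.data.frame(reference) || nrow(reference) == 0) {
    stop("empty reference table")
  }
  if (is.null(reference$monoisotopic_mass)) {
    reference$monoisotopic_mass <-
      vapply(reference$formula, monoisotopic_mass, numeric(1))
  }
  # expand reference into (metabolite, rule, theoretical m/z) rows
  rule_tab <- .adduct_rule_table()
  expand <- do.call(rbind, lapply(seq_len(nrow(reference)), function(i) {
    rules <- trimws(strsplit(reference$adducts[i], ";")[[1]])
    data.frame(
      metabolite = reference$name[i],
      adduct = rules,
      theoretical_mz = vapply(rules, function(r)
        theoretical_mz(reference$monoisotopic_mass[i], r), numeric(1)),
      charge = rule_tab$charge[match(rules, rule_tab$name)],
      msi_evidence = reference$msi_evidence[i],
      stringsAsFactors = FALSE
    )
  }))

  out <- lapply(seq_len(nrow(bins)), function(i) {
    lo <- bins$mz_lower[i]
    hi <- lo + bin_width
    obs <- if ("observed_mz" %in% names(bins)) bins$observed_mz[i] else NA_real_
    # mode-tagged bin labels restrict matches to the right polarity
    mode_ok <- if (grepl("^pos_", bins$bin[i])) {
      expand$charge > 0
    } else if (grepl("^neg_", bins$bin[i])) {
      expand$charge < 0
    } else rep(TRUE, nrow(expand))
    if (!is.na(obs)) {
      ppm <- (obs - expand$theoretical_mz) / expand$theoretical_mz * 1e6
      hit <- abs(ppm) <= tolerance_ppm & mode_ok
    } else {
      tol_da <- expand$theoretical_mz * tolerance_ppm * 1e-6
      hit <- expand$theoretical_mz >= lo - tol_da &
        expand$theoretical_mz < hi + tol_da & mode_ok
      center <- lo + bin_width / 2
      ppm <- (center - expand$theoretical_mz) / expand$theoretical_mz * 1e6
    }
    if (!any(hit)) {
      return(data.frame(
        bin = bins$bin[i], observed_mz = obs, metabolite = NA_character_,
        adduct = NA_character_, theoretical_mz = NA_real_,
        ppm_error = NA_real_,
        msi_level = NA_integer_, ambiguous = FALSE, stringsAsFactors = FALSE
      ))
    }
    h <- expand[hit, , drop = FALSE]
    h <- h[order(abs(ppm[hit])), , drop = FALSE]
    data.frame(
      bin = bins$bin[i], observed_mz = obs, metabolite = h$metabolite,
      adduct = h$adduct, theoretical_mz = h$theoretical_mz,
      ppm_error = ppm[hit][order(abs(ppm[hit]))],
      msi_level = vapply(h$msi_evidence, function(e)
        assign_msi_level(evidence = e), integer(1)),
      ambiguous = length(unique(h$metabolite)) > 1,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign a Metabolomics Standards Initiative identification level
#'
#' Level 1 requires a match (mass, MSn fragmentation and retention time)
#' against an authentic chemical standard run under the same conditions;
#' level 2 a match against public or commercial spectral libraries without a
#' standard; level 3 identifies a compound class only.
#'
#' @param has_standard_match,has_spectral_library_match,class_only Logical
#'   evidence flags; exactly one must be `TRUE`.
#' @param evidence Alternatively, a single string `"standard"`, `"library"`
#'   or `"class"`.
#' @return Integer MSI level (1, 2 or 3).
#' @export
#' @examples
#' assign_msi_level(has_standard_match = TRUE)
#' assign_msi_level(evidence = "library")
assign_msi_level <- function(has_standard_match = FALSE,
                             has_spectral_library_match = FALSE,
                             class_only = FALSE,
                             evidence = NULL) {
  if (!is.null(evidence)) {
    stopifnot(is.character(evidence), length(evidence) == 1L)
    has_standard_match <- evidence == "standard"
    has_spectral_library_match <- evidence == "library"
    class_only <- evidence == "class"
    if (!any(has_standard_match, has_spectral_library_match, class_only)) {
      stop("unknown evidence profile '", evidence,
           "'; expected 'standard', 'library' or 'class'")
    }
  }
  flags <- c(has_standard_match, has_spectral_library_match, class_only)
  if (sum(flags) != 1L) {
    stop("contradictory evidence flags: exactly one of has_standard_match, ",
         "has_spectral_library_match, class_only must be TRUE")
  }
  which(flags)[1]
}
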