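# Pipeline orchestration: simulate a study bundle to disk and run the
# chained normalize -> fingerprint -> discover -> annotate -> dose-response
# analysis with reproducible configuration and a per-stage summary.

#' Simulate a study bundle to disk
#'
#' Thin wrapper around [generate_study()] that always writes the bundle
#' (metadata, exposure log, ground truth, config snapshot and mzML spectra)
#' to a directory.
#'
#' @param dir Output directory.
#' @param config,panel,menu See [generate_study()].
#' @param force Overwrite a non-empty directory.
#' @return The `study_bundle`, invisibly.
#' @export
simulate_study <- function(dir, config = study_config(),
                           panel = demo_panel(), menu = grape_menu(),
                           force = FALSE) {
  if (missing(dir) || is.null(dir)) stop("an output directory is required")
  invisible(generate_study(config, panel, menu, dir = dir, render = TRUE,
                           force = force))
}

#' Run the full discovery and validation pipeline on a study bundle
#'
#' Stages: SG normalization of the fingerprint, fingerprinting of the mzML
#' runs (apex window, 0.01 amu binning, mode concatenation), bootstrapped
#' RF/AUC/t-test feature selection per baseline-vs-postprandial comparison,
#' accurate-mass annotation of tiered bins, and the dose-response table per
#' panel food group.  All tabular outputs are written as TSV into
#' `out_dir`, together with a summary JSON of per-stage counts and a config
#' snapshot.
#'
#' @param bundle A `study_bundle` (from [simulate_study()] /
#'   [generate_study()]) or the path of a bundle directory.
#' @param out_dir Output directory for reports (default
#'   `<bundle dir>/results`).
#' @param fp_config A [fingerprint_config()].
#' @param boot,rf,thr Discovery configuration ([bootstrap_config()],
#'   [rf_config()], [selection_thresholds()]).
#' @param reference Annotation reference table (default the bundled panel).
#' @param tolerance_ppm Annotation mass tolerance (ppm).
#' @param target_sg Normalization target specific gravity.
#' @param seed Master seed for the discovery stage.
#' @param skip_annotation Skip the annotation stage.
#' @return List of class `pipeline_result`: `fingerprint`, `normalization`,
#'   `discovery`, `annotation`, `dose_response`, `summary`.
#' @export
run_pipeline <- function(bundle, out_dir = NULL,
                         fp_config = fingerprint_config(),
                         boot = bootstrap_config(), rf = rf_config(),
                         thr = selection_thresholds(),
                         reference = reference_panel(),
                         tolerance_ppm = 5, target_sg = 1.010, seed = 1,
                         skip_annotation = FALSE) {
  if (is.character(bundle)) bundle <- read_study_bundle(bundle)
  stopifnot(inherits(bundle, "study_bundle"))
  if (is.null(out_dir) && !is.null(bundle$paths$dir)) {
    out_dir <- file.path(bundle$paths$dir, "results")
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  summary <- list()

  stage <- "normalize"
  res <- tryCatch({
    norm_records <- normalize_samples(bundle$metadata, target_sg)
    summary$normalize <- list(n_samples = nrow(norm_records),
                              n_qc_flagged = sum(norm_records$qc_flag))

    stage <- "fingerprint"
    fps <- fingerprint_study(bundle, fp_config)
    fp <- normalize_fingerprint(fps$combined, norm_records)
    attr(fp, "bin_mz") <- attr(fps$combined, "bin_mz")
    summary$fingerprint <- list(n_samples = nrow(fp), n_bins = ncol(fp))

    stage <- "discover"
    disc <- run_discovery(fp, bundle$metadata, boot, rf, thr, seed = seed)
    tiered <- unique(unlist(lapply(disc, function(d)
      d$stats$bin[d$stats$tier != "none"])))
    summary$discover <- list(
      n_comparisons = length(disc),
      n_adequate = sum(vapply(disc, function(d)
        d$adequacy$adequate, logical(1))),
      n_tiered_bins = length(tiered))

    ann <- NULL
    if (!skip_annotation) {
      stage <- "annotate"
      if (length(tiered)) {
        bmz <- attr(fp, "bin_mz")
        bins <- data.frame(
          bin = tiered,
          mz_lower = as.numeric(sub("^(pos|neg)_", "", tiered)),
          observed_mz = unname(bmz[tiered]),
          stringsAsFactors = FALSE)
        ann <- annotate_bins(bins, reference, tolerance_ppm)
        summary$annotate <- list(
          n_bins = length(tiered),
          n_annotated = length(unique(ann$bin[!is.na(ann$metabolite)])))
      } else {
        summary$annotate <- list(n_bins = 0L, n_annotated = 0L)
      }
    }

    stage <- "dose_response"
    dr <- list()
    fmv_ids <- bundle$metadata$sample_id[bundle$metadata$sample_type == "FMV"]
    portions <- utils::read.csv(system.file("extdata",
                                            "portion_reference.csv",
                                            package = "urimark"),
                                stringsAsFactors = FALSE)
    for (kin in bundle$panel) {
      conc <- bundle$truth$true_concentrations[fmv_ids, kin$metabolite_name]
      medium <- portions$medium_g[match(kin$food_group, portions$food)]
      if (is.na(medium)) medium <- 100
      tab <- dose_response_table(bundle$exposure, bundle$metadata,
                                 stats::setNames(conc, fmv_ids),
                                 kin$food_group, medium)
      stats <- if (!is.null(tab) && length(unique(tab$portion_class)) > 1) {
        portion_correlation(tab$portion_class, tab$concentration)
      } else list(rho = NA_real_, p = NA_real_, n = 0L)
      dr[[kin$metabolite_name]] <- list(table = tab, spearman = stats)
    }
    summary$dose_response <- list(n_markers = length(dr))

    list(fingerprint = fp, normalization = norm_records, discovery = disc,
         annotation = ann, dose_response = dr)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    utils::write.table(res$normalization,
                       file.path(out_dir, "normalization.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (lab in names(res$discovery)) {
      utils::write.table(res$discovery[[lab]]$stats,
                         file.path(out_dir, paste0("features_", lab, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(res$annotation)) {
      utils::write.table(res$annotation,
                         file.path(out_dir, "annotation.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    for (m in names(res$dose_response)) {
      tab <- res$dose_response[[m]]$table
      if (!is.null(tab)) {
        utils::write.table(tab,
                           file.path(out_dir, paste0(
                             "dose_response_",
                             gsub("[^A-Za-z0-9]+", "_", m), ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(c(res, list(summary = summary, out_dir = out_dir)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>\n")
  cat("  normalize:    ", s$normalize$n_samples, " samples (",
      s$normalize$n_qc_flagged, " QC-flagged)\n", sep = "")
  cat("  fingerprint:  ", s$fingerprint$n_samples, " x ",
      s$fingerprint$n_bins, " bins\n", sep = "")
  cat("  discover:     ", s$discover$n_comparisons, " comparisons, ",
      s$discover$n_tiered_bins, " tiered bins\n", sep = "")
  if (!is.null(s$annotate)) {
    cat("  annotate:     ", s$annotate$n_annotated, "/", s$annotate$n_bins,
        " tiered bins annotated\n", sep = "")
  }
  cat("  dose-response:", s$dose_response$n_markers, "markers\n")
  invisible(x)
}

#' Read a study bundle written by [simulate_study()]
#'
#' Restores metadata, exposure log and ground truth from disk; spectra stay
#' on disk and are read lazily by [fingerprint_study()].
#'
#' @param dir Bundle directory.
#' @return A `study_bundle` (without in-memory spectra).
#' @export
read_study_bundle <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("not a study bundle: ", dir)
  metadata <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  exposure <- utils::read.csv(file.path(dir, "exposure.csv"),
                              stringsAsFactors = FALSE)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  config <- do.call(study_config, cfgl[c(
    "n_participants", "n_days", "seed", "dilution_meanlog",
    "dilution_sdlog", "participant_sdlog", "noise_sdlog",
    "background_bins", "n_scans", "apex_scan", "profile_sd",
    "response_factor", "mass_error_ppm_sd", "preday_conditions")])
  truth_conc <- as.matrix(gt$true_concentrations)
  rownames(truth_conc) <- gt$sample_id
  truth <- list(
    true_concentrations = truth_conc,
    dilution_factor = stats::setNames(gt$dilution_factor, gt$sample_id),
    participant_multiplier = gt$participant_multiplier,
    mass_errors_ppm = unlist(gt$mass_errors_ppm),
    spiked_bins = gt$spiked_bins,
    omitted_adducts = gt$omitted_adducts
  )
  panel_raw <- jsonlite::read_json(file.path(dir, "panel.json"),
                                   simplifyVector = TRUE)
  panel <- lapply(seq_len(nrow(panel_raw)), function(i) {
    biomarker_kinetics(
      metabolite_name = panel_raw$metabolite_name[i],
      formula = panel_raw$formula[i],
      adducts = panel_raw$adducts[[i]],
      food_group = panel_raw$food_group[i],
      dose_coefficient = panel_raw$dose_coefficient[i],
      t_peak = panel_raw$t_peak[i],
      elimination_halflife = panel_raw$elimination_halflife[i],
      baseline_level = panel_raw$baseline_level[i])
  })
  structure(list(metadata = metadata, exposure = exposure, truth = truth,
                 background = NULL, spectra = NULL,
                 paths = list(dir = dir), config = config,
                 panel = panel),
            class = "study_bundle")
}
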