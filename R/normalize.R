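# Specific-gravity (refractive index) normalization of spot urine samples.
#
# Urine dilution varies with fluid intake; normalizing every sample to a
# common specific gravity before analysis puts all spectra in a comparable
# dynamic range.  The SG excess (SG - 1) is taken as proportional to total
# solute, the standard urinomics convention, so the urine volume pipetted
# into a fixed 500 uL make-up volume scales as
# (target_sg - 1) / (mean_sg - 1).

#' Average a specific-gravity triplicate
#'
#' @param triplicate Numeric vector of 3 refractometer SG readings, each in
#'   `[1.000, 1.060]`.
#' @param max_spread Maximum tolerated max-min disagreement before the QC
#'   flag is raised (default 0.002).
#' @return List with `mean_sg` and logical `flag` (reading disagreement).
#' @export
#' @examples
#' average_sg(c(1.010, 1.012, 1.014))  # flagged, spread 0.004
average_sg <- function(triplicate, max_spread = 0.002) {
  stopifnot(is.numeric(triplicate), length(triplicate) == 3)
  if (any(triplicate < 1.000 | triplicate > 1.060)) {
    stop("SG reading outside the physically plausible range [1.000, 1.060]: ",
         paste(format(triplicate), collapse = ", "))
  }
  list(mean_sg = mean(triplicate),
       flag = (max(triplicate) - min(triplicate)) > max_spread)
}

#' Urine and water volumes for SG normalization
#'
#' Samples more concentrated than the target are diluted
#' (`urine = makeup * (target_sg - 1) / (mean_sg - 1)`); samples already at
#' or below the target SG are used neat (no up-concentration step exists in
#' the protocol), giving a dilution factor of 1.
#'
#' @param mean_sg Mean specific gravity of the sample.
#' @param target_sg Reference SG all samples are brought to (default 1.010).
#' @param makeup_ul Total extraction volume in uL (default 500).
#' @return List (`normalization_record`): `mean_sg`, `target_sg`,
#'   `urine_volume_ul`, `water_volume_ul`, `dilution_factor`.  Urine + water
#'   always sum to `makeup_ul`; the factor is >= 1.
#' @export
#' @examples
#' dilution_volumes(1.020, 1.010)  # 250 uL urine + 250 uL water, factor 2
dilution_volumes <- function(mean_sg, target_sg = 1.010, makeup_ul = 500) {
  stopifnot(mean_sg >= 1.000, target_sg > 1.000, makeup_ul > 0)
  if (mean_sg == 1.000) {
    stop("mean SG 1.000 with target ", target_sg,
         ": pure-water sample cannot be normalized")
  }
  urine <- if (mean_sg > target_sg) {
    makeup_ul * (target_sg - 1) / (mean_sg - 1)
  } else {
    makeup_ul
  }
  structure(list(mean_sg = mean_sg, target_sg = target_sg,
                 urine_volume_ul = urine,
                 water_volume_ul = makeup_ul - urine,
                 dilution_factor = makeup_ul / urine),
            class = "normalization_record")
}

#' Convert a concentration to an excreted amount
#'
#' @param concentration Concentration in ug/mL.
#' @param total_volume_ml Total voided volume in mL; if missing (`NA`), the
#'   adjustment is skipped with a warning (spot-sample volumes are not always
#'   recorded successfully) and `NA` returned.
#' @return Excreted amount in ug.
#' @export
volume_adjust <- function(concentration, total_volume_ml) {
  stopifnot(is.numeric(concentration))
  out <- concentration * total_volume_ml
  if (anyNA(total_volume_ml)) {
    warning("missing urine volume; volume adjustment skipped for ",
            sum(is.na(total_volume_ml)), " sample(s)")
  }
  if (any(!is.na(total_volume_ml) & total_volume_ml <= 0)) {
    stop("total_volume_ml must be positive")
  }
  out
}

#' Build normalization records for a study metadata table
#'
#' @param metadata Data frame with columns `sample_id`, `sg1`, `sg2`, `sg3`.
#' @param target_sg Reference SG (default 1.010).
#' @param makeup_ul Make-up volume in uL (default 500).
#' @return Data frame: `sample_id`, `mean_sg`, `urine_volume_ul`,
#'   `water_volume_ul`, `dilution_factor`, `qc_flag`.
#' @export
normalize_samples <- function(metadata, target_sg = 1.010, makeup_ul = 500) {
  stopifnot(all(c("sample_id", "sg1", "sg2", "sg3") %in% names(metadata)))
  recs <- lapply(seq_len(nrow(metadata)), function(i) {
    avg <- average_sg(c(metadata$sg1[i], metadata$sg2[i], metadata$sg3[i]))
    rec <- dilution_volumes(avg$mean_sg, target_sg, makeup_ul)
    data.frame(sample_id = metadata$sample_id[i], mean_sg = avg$mean_sg,
               urine_volume_ul = rec$urine_volume_ul,
               water_volume_ul = rec$water_volume_ul,
               dilution_factor = rec$dilution_factor,
               qc_flag = avg$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Apply SG normalization to a fingerprint matrix
#'
#' Divides each sample's binned intensities by its normalization dilution
#' factor, the in-silico equivalent of pipetting
#' `makeup * (target_sg - 1)/(mean_sg - 1)` uL of urine into the fixed
#' make-up volume before acquisition (the instrument response is linear in
#' concentration).
#'
#' @param fingerprint Samples x bins matrix with sample ids as row names.
#' @param records Data frame from [normalize_samples()].
#' @return Normalized matrix of the same shape.
#' @export
normalize_fingerprint <- function(fingerprint, records) {
  i <- match(rownames(fingerprint), records$sample_id)
  if (anyNA(i)) {
    stop("no normalization record for sample(s): ",
         paste(rownames(fingerprint)[is.na(i)], collapse = ", "))
  }
  fingerprint / records$dilution_factor[i]
}
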