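# Conversion of centroided mzML flow-infusion runs into an aligned
# samples x 0.01-amu-bin fingerprint matrix per ionization mode.

#' Fingerprinting configuration
#'
#' @param bin_width Bin width in amu (default 0.01).
#' @param mz_range_positive,mz_range_negative Acquisition m/z ranges per
#'   ionization mode (defaults 55-1000 and 63-1000).
#' @param apex_window_scans Scans kept on each side of the infusion apex
#'   (default 5, an 11-scan window).
#' @return Object of class `fingerprint_config`.
#' @export
fingerprint_config <- function(bin_width = 0.01,
                               mz_range_positive = c(55, 1000),
                               mz_range_negative = c(63, 1000),
                               apex_window_scans = 5) {
  stopifnot(bin_width > 0,
            mz_range_positive[1] < mz_range_positive[2],
            mz_range_negative[1] < mz_range_negative[2],
            apex_window_scans >= 0)
  structure(list(bin_width = bin_width,
                 mz_range_positive = mz_range_positive,
                 mz_range_negative = mz_range_negative,
                 apex_window_scans = as.integer(apex_window_scans)),
            class = "fingerprint_config")
}

.mode_range <- function(config, mode) {
  switch(mode, positive = config$mz_range_positive,
         negative = config$mz_range_negative,
         stop("unknown ionization mode '", mode, "'"))
}

#' Read a centroided mzML file
#'
#' @param path Path to an mzML file of centroided MS1 scans.
#' @return Object of class `scan_set`: ordered peak lists, per-scan TIC,
#'   and the ionization mode if recorded.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0) stop("no spectra in ", path)
  not_centroided <- which(!is.na(hdr$centroided) & !hdr$centroided)
  if (length(not_centroided)) {
    stop("profile-mode (non-centroided) data in ", path, ", scan ",
         not_centroided[1], "; centroid before fingerprinting")
  }
  pk <- mzR::peaks(handle)
  if (nrow(hdr) == 1) pk <- list(pk)
  scans <- lapply(pk, function(p) {
    colnames(p) <- c("mz", "intensity")
    p
  })
  mode <- if (!is.null(hdr$polarity) && all(hdr$polarity == 1)) {
    "positive"
  } else if (!is.null(hdr$polarity) && all(hdr$polarity == 0)) {
    "negative"
  } else NA_character_
  structure(list(scans = scans,
                 tic = vapply(scans, function(p)
                   sum(p[, "intensity"]), numeric(1)),
                 mode = mode, mz_range = NULL, apex_scan = NA_integer_,
                 omitted = NULL),
            class = "scan_set")
}

#' Locate the apex of the infusion profile
#'
#' The apex is the argmax of the 3-scan moving average of the total ion
#' current (earliest scan on ties); the selected window is the apex plus and
#' minus `apex_window_scans`, clipped to the run.
#'
#' @param scans A `scan_set`.
#' @param apex_window_scans Half-width of the scan window (default 5).
#' @return List with `apex` (scan index) and `window` (integer vector of
#'   selected scan indices).
#' @export
find_apex <- function(scans, apex_window_scans = 5) {
  stopifnot(inherits(scans, "scan_set"))
  tic <- scans$tic
  if (length(tic) < 3) stop("need at least 3 scans to locate the apex")
  if (all(tic == 0)) stop("all-zero total ion current; cannot locate apex")
  smoothed <- as.numeric(stats::filter(tic, rep(1 / 3, 3), sides = 2))
  smoothed[is.na(smoothed)] <- -Inf  # run edges never beat an interior apex
  apex <- which.max(smoothed)
  # a raw-TIC plateau straddling the smoothed apex is resolved to its
  # earliest scan (tie-break rule)
  cand <- which(tic == max(tic))
  cand <- cand[abs(cand - apex) <= 1]
  if (length(cand)) apex <- min(cand)
  window <- max(1, apex - apex_window_scans):
    min(length(tic), apex + apex_window_scans)
  list(apex = apex, window = window)
}

#' Bin the scans of an apex window into a fingerprint row
#'
#' Every peak with m/z inside the mode's range is assigned to the half-open
#' bin `[lower, lower + bin_width)` with index
#' `floor((mz - range_lower) / bin_width)`; intensities are summed within a
#' bin across all window scans, then divided by the number of scans, so that
#' windows of different widths stay comparable.  Out-of-range peaks are
#' dropped and counted.
#'
#' @param scans A `scan_set`.
#' @param config A [fingerprint_config()].
#' @param mode `"positive"` or `"negative"`.
#' @param window Integer vector of scan indices to aggregate (default: all
#'   scans).
#' @return Named numeric vector of per-scan mean bin intensities; names are
#'   bin labels `<pos|neg>_<lower edge>`.  Attributes: `dropped` (number of
#'   out-of-range peaks), `bin_mz` (intensity-weighted mean accurate m/z per
#'   bin, for annotation against the un-binned data).
#' @export
bin_scans <- function(scans, config = fingerprint_config(),
                      mode = c("positive", "negative"),
                      window = seq_along(scans$scans)) {
  mode <- match.arg(mode)
  stopifnot(inherits(scans, "scan_set"), length(window) > 0)
  rng <- .mode_range(config, mode)
  all_peaks <- do.call(rbind, scans$scans[window])
  if (is.null(all_peaks) || nrow(all_peaks) == 0) {
    out <- numeric(0)
    attr(out, "dropped") <- 0L
    attr(out, "bin_mz") <- numeric(0)
    return(out)
  }
  mz <- all_peaks[, "mz"]; int <- all_peaks[, "intensity"]
  keep <- mz >= rng[1] & mz <= rng[2]
  dropped <- sum(!keep)
  mz <- mz[keep]; int <- int[keep]
  idx <- floor((mz - rng[1]) / config$bin_width)
  f <- factor(idx)
  sums <- tapply(int, f, sum) / length(window)
  wmz <- tapply(int * mz, f, sum) / (tapply(int, f, sum))
  uidx <- as.integer(levels(f))
  labels <- sprintf("%s_%.2f", substr(mode, 1, 3),
                    rng[1] + uidx * config$bin_width)
  out <- as.numeric(sums)
  names(out) <- labels
  attr(out, "dropped") <- dropped
  attr(out, "bin_mz") <- stats::setNames(as.numeric(wmz), labels)
  out
}

#' Assemble fingerprint rows into a matrix
#'
#' Columns are the union of bins observed in any sample (sorted); a bin
#' absent from a sample contributes 0.  Row order follows the input order.
#'
#' @param rows Named list of fingerprint rows (from [bin_scans()]), one per
#'   sample; list names are sample ids.
#' @return Samples x bins numeric matrix with a `bin_mz` attribute giving,
#'   per bin, the intensity-weighted accurate m/z pooled across samples.
#' @export
assemble_matrix <- function(rows) {
  stopifnot(is.list(rows), length(rows) > 0, !is.null(names(rows)))
  if (anyDuplicated(names(rows))) {
    stop("duplicate sample id: ",
         names(rows)[anyDuplicated(names(rows))])
  }
  bins <- sort(unique(unlist(lapply(rows, names))))
  X <- matrix(0, length(rows), length(bins),
              dimnames = list(names(rows), bins))
  for (i in seq_along(rows)) {
    X[i, names(rows[[i]])] <- as.numeric(rows[[i]])
  }
  # pool accurate m/z across samples, weighting by each sample's intensity
  num <- stats::setNames(numeric(length(bins)), bins)
  den <- stats::setNames(numeric(length(bins)), bins)
  for (r in rows) {
    bmz <- attr(r, "bin_mz")
    if (is.null(bmz)) next
    num[names(bmz)] <- num[names(bmz)] + bmz * as.numeric(r)
    den[names(bmz)] <- den[names(bmz)] + as.numeric(r)
  }
  attr(X, "bin_mz") <- ifelse(den > 0, num / den, NA_real_)
  X
}

#' Fingerprint a set of mzML files
#'
#' Reads each file, locates the infusion apex, bins the apex window and
#' assembles the aligned matrix, one matrix per ionization mode, column
#' labels mode-tagged so the modes can be concatenated for feature
#' selection.
#'
#' @param files Named character vector of mzML paths (names = sample ids).
#' @param mode `"positive"` or `"negative"`.
#' @param config A [fingerprint_config()].
#' @return Matrix as from [assemble_matrix()], with a `provenance`
#'   attribute (config, per-sample apex index and dropped-peak count).
#' @export
fingerprint_files <- function(files, mode = c("positive", "negative"),
                              config = fingerprint_config()) {
  mode <- match.arg(mode)
  stopifnot(length(files) > 0, !is.null(names(files)))
  rows <- list(); apexes <- integer(length(files)); dropped <- integer(length(files))
  for (i in seq_along(files)) {
    ss <- read_mzml(files[[i]])
    ap <- find_apex(ss, config$apex_window_scans)
    row <- bin_scans(ss, config, mode, ap$window)
    apexes[i] <- ap$apex
    dropped[i] <- attr(row, "dropped")
    rows[[names(files)[i]]] <- row
  }
  X <- assemble_matrix(rows)
  attr(X, "provenance") <- list(config = config,
                                apex = stats::setNames(apexes, names(files)),
                                dropped = stats::setNames(dropped, names(files)))
  X
}

#' Fingerprint both modes of a rendered or on-disk study bundle
#'
#' @param bundle A `study_bundle` from [generate_study()].  Uses in-memory
#'   spectra when present, otherwise reads the bundle's mzML files.
#' @param config A [fingerprint_config()].
#' @return List with per-mode matrices (`positive`, `negative`) and
#'   `combined` (modes concatenated column-wise).
#' @export
fingerprint_study <- function(bundle, config = fingerprint_config()) {
  stopifnot(inherits(bundle, "study_bundle"))
  per_mode <- list()
  for (mode in c("positive", "negative")) {
    if (!is.null(bundle$spectra)) {
      rows <- lapply(bundle$spectra, function(sp) {
        ap <- find_apex(sp[[mode]], config$apex_window_scans)
        bin_scans(sp[[mode]], config, mode, ap$window)
      })
      per_mode[[mode]] <- assemble_matrix(rows)
    } else {
      files <- file.path(bundle$paths$dir, "mzml",
                         sprintf("%s_%s.mzML", bundle$metadata$sample_id, mode))
      names(files) <- bundle$metadata$sample_id
      per_mode[[mode]] <- fingerprint_files(files, mode, config)
    }
  }
  combined <- cbind(per_mode$positive, per_mode$negative)
  attr(combined, "bin_mz") <- c(attr(per_mode$positive, "bin_mz"),
                                attr(per_mode$negative, "bin_mz"))
  c(per_mode, list(combined = combined))
}
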