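# Independent brute-force oracles used to pin down the vectorized
# implementations.

# AUC by explicit pairwise counting, ties one half
brute_auc <- function(baseline, post) {
  wins <- 0
  for (p in post) {
    for (b in baseline) {
      if (p > b) wins <- wins + 1
      else if (p == b) wins <- wins + 0.5
    }
  }
  wins / (length(baseline) * length(post))
}

# binning by naive per-peak dictionary accumulation
brute_bin <- function(scans, lower, upper, bin_width = 0.01) {
  acc <- new.env()
  n_scans <- length(scans)
  for (sc in scans) {
    for (i in seq_len(nrow(sc))) {
      mz <- sc[i, 1]; int <- sc[i, 2]
      if (mz < lower || mz > upper) next
      key <- as.character(floor((mz - lower) / bin_width))
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + int
    }
  }
  keys <- ls(acc)
  idx <- as.integer(keys)
  vals <- vapply(keys, function(k) acc[[k]], numeric(1)) / n_scans
  ord <- order(idx)
  list(index = idx[ord], value = unname(vals[ord]))
}

# random centroided scan list for binning tests
random_scans <- function(n_scans, n_peaks, mz_min = 50, mz_max = 1010) {
  scans <- lapply(seq_len(n_scans), function(i) {
    cbind(mz = stats::runif(n_peaks, mz_min, mz_max),
          intensity = stats::rexp(n_peaks, 1e-4))
  })
  structure(list(scans = scans,
                 tic = vapply(scans, function(p) sum(p[, 2]), numeric(1)),
                 mode = NA_character_, mz_range = NULL,
                 apex_scan = NA_integer_, omitted = NULL),
            class = "scan_set")
}

# scan_set with a prescribed TIC shape (single peak at each scan, fixed m/z)
tic_scan_set <- function(tic) {
  scans <- lapply(tic, function(ti)
    cbind(mz = 100, intensity = ti))
  structure(list(scans = scans, tic = tic, mode = NA_character_,
                 mz_range = NULL, apex_scan = NA_integer_, omitted = NULL),
            class = "scan_set")
}
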