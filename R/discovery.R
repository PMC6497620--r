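# Day-structured baseline vs postprandial comparisons and the bootstrapped
# random-forest / AUC / t-test feature-selection procedure with model
# adequacy gates and tiered candidate calling.
#
# For each experimental day, the fasting and FMV samples form the baseline
# against each of that day's postprandial samples (post-breakfast, -lunch,
# -dinner); the post-dinner sample is additionally compared against the
# following day's fasting and FMV to catch longer-duration markers.

#' Random-forest configuration
#'
#' @param ntree Number of trees (default 1000).
#' @param mtry Variables tried at each split; `NULL` (default) means
#'   `floor(sqrt(p))`, resolved at fit time.
#' @return Object of class `rf_config`.
#' @export
rf_config <- function(ntree = 1000, mtry = NULL) {
  stopifnot(ntree >= 1, is.null(mtry) || mtry >= 1)
  structure(list(ntree = as.integer(ntree), mtry = mtry),
            class = "rf_config")
}

#' Bootstrap resampling configuration
#'
#' @param n_boot Number of bootstraps (default 100).
#' @param train_fraction Fraction of each class used for training
#'   (default 2/3; the remaining 1/3 is the test set).
#' @return Object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 100, train_fraction = 2 / 3) {
  stopifnot(n_boot >= 1, train_fraction > 0, train_fraction < 1)
  structure(list(n_boot = as.integer(n_boot),
                 train_fraction = train_fraction),
            class = "bootstrap_config")
}

#' Feature-selection and model-adequacy thresholds
#'
#' Discriminatory signals require importance score > 0.002, P < 0.05 and
#' AUC >= 0.9; the putative band (worth investigating further) requires
#' importance > 0.001 and AUC > 0.8.  A classification model is deemed
#' adequate if its margin exceeds 0.2 and its AUC exceeds 0.8.
#'
#' @param is_discriminatory,is_putative_low Importance-score thresholds.
#' @param p_max Maximum t-test P-value for the discriminatory tier.
#' @param auc_discriminatory,auc_putative_low AUC thresholds.
#' @param margin_adequate,auc_adequate Model-adequacy gates.
#' @return Object of class `selection_thresholds`.
#' @export
selection_thresholds <- function(is_discriminatory = 0.002,
                                 is_putative_low = 0.001,
                                 p_max = 0.05,
                                 auc_discriminatory = 0.9,
                                 auc_putative_low = 0.8,
                                 margin_adequate = 0.2,
                                 auc_adequate = 0.8) {
  stopifnot(is_putative_low < is_discriminatory,
            auc_putative_low < auc_discriminatory)
  structure(list(is_discriminatory = is_discriminatory,
                 is_putative_low = is_putative_low, p_max = p_max,
                 auc_discriminatory = auc_discriminatory,
                 auc_putative_low = auc_putative_low,
                 margin_adequate = margin_adequate,
                 auc_adequate = auc_adequate),
            class = "selection_thresholds")
}

#' Build baseline vs postprandial comparison pairs from metadata
#'
#' One pair per (day, postprandial meal), built separately within each
#' pre-day condition stratum when more than one is present.  Post-dinner
#' pairs carry the following day's fasting and FMV sample ids as
#' `extra_baseline` (for the additional longer-duration comparison); the
#' last day's pair has an empty, flagged `extra_baseline`.
#'
#' @param metadata Data frame with `sample_id`, `day`, `sample_type`,
#'   `preday_condition`.
#' @return List of `comparison_pair` objects (`label`, `day`, `meal`,
#'   `stratum`, `baseline`, `postprandial`, `extra_baseline`,
#'   `extra_baseline_missing`).
#' @export
build_comparisons <- function(metadata) {
  stopifnot(all(c("sample_id", "day", "sample_type") %in% names(metadata)))
  strata <- if (!is.null(metadata$preday_condition)) {
    unique(metadata$preday_condition)
  } else "all"
  pairs <- list()
  for (s in strata) {
    md <- if (identical(strata, "all")) metadata else
      metadata[metadata$preday_condition == s, , drop = FALSE]
    days <- sort(unique(md$day[md$sample_type %in% .POST_TYPES]))
    for (d in days) {
      baseline <- md$sample_id[md$day == d & md$sample_type %in% .BASELINE_TYPES]
      if (length(baseline) == 0) {
        warning("day ", d, if (length(strata) > 1) paste0(" (", s, ")"),
                ": no baseline samples; comparisons skipped")
        next
      }
      for (meal in c("breakfast", "lunch", "dinner")) {
        post <- md$sample_id[md$day == d &
                               md$sample_type == paste0("post_", meal)]
        if (length(post) == 0) next
        extra <- character(0); extra_missing <- FALSE
        if (meal == "dinner") {
          extra <- md$sample_id[md$day == d + 1 &
                                  md$sample_type %in% .BASELINE_TYPES]
          extra_missing <- length(extra) == 0
        }
        label <- sprintf("day%d_%s", d, meal)
        if (length(strata) > 1) label <- paste0(label, "_", s)
        pairs[[label]] <- structure(
          list(label = label, day = d, meal = meal, stratum = s,
               baseline = baseline, postprandial = post,
               extra_baseline = extra,
               extra_baseline_missing = extra_missing),
          class = "comparison_pair")
      }
    }
  }
  if (length(pairs) == 0) {
    warning("no baseline/postprandial comparison pairs could be built")
  }
  pairs
}

#' Rank-based AUC of a single feature
#'
#' Mann-Whitney formulation: the probability that a postprandial value
#' exceeds a baseline value, ties counted one half.  By default the AUC is
#' made direction-agnostic (`max(a, 1 - a)`), since a marker may rise or
#' fall postprandially.
#'
#' @param values Numeric vector.
#' @param labels Two-level factor or logical (`TRUE`/second level =
#'   postprandial).
#' @param direction_agnostic Report `max(a, 1 - a)`? Default TRUE.
#' @return AUC in `[0, 1]` (`[0.5, 1]` when direction-agnostic). Constant
#'   values give 0.5.
#' @export
#' @examples
#' feature_auc(c(1, 2, 3, 2, 3, 4), rep(c(FALSE, TRUE), each = 3))  # 7/9
feature_auc <- function(values, labels, direction_agnostic = TRUE) {
  post <- .as_post(labels)
  n1 <- sum(!post); n2 <- sum(post)
  if (n1 == 0 || n2 == 0) stop("both classes must be present")
  r <- rank(values)
  a <- (sum(r[post]) - n2 * (n2 + 1) / 2) / (n1 * n2)
  if (direction_agnostic) max(a, 1 - a) else a
}

.as_post <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly 2 levels")
  f == levels(f)[2]
}

# column-wise direction-agnostic AUC for a samples x features matrix;
# pairwise-counting formulation (ties one half), vectorized over features
.col_auc <- function(X, post, direction_agnostic = TRUE) {
  B <- X[!post, , drop = FALSE]
  P <- X[post, , drop = FALSE]
  n1 <- nrow(B); n2 <- nrow(P)
  wins <- numeric(ncol(X))
  for (i in seq_len(n2)) {
    for (k in seq_len(n1)) {
      d <- P[i, ] - B[k, ]
      wins <- wins + (d > 0) + 0.5 * (d == 0)
    }
  }
  a <- wins / (n1 * n2)
  if (direction_agnostic) pmax(a, 1 - a) else a
}

#' Two-sided Student's t-test P-value for a single feature
#'
#' Pooled-variance (classical Student) test.  Degenerate inputs follow the
#' convention: zero pooled variance with equal means gives P = 1; zero
#' variance with unequal means is a perfectly separated degenerate case and
#' gives P = 0 with a `degenerate` attribute.
#'
#' @param values Numeric vector.
#' @param labels Two-level labels (second level = postprandial).
#' @return P-value, with attribute `degenerate` (logical).
#' @export
feature_ttest <- function(values, labels) {
  post <- .as_post(labels)
  x <- values[!post]; y <- values[post]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 samples per class")
  p <- .col_ttest(cbind(values), post)
  out <- as.numeric(p)
  attr(out, "degenerate") <- attr(p, "degenerate")[1]
  out
}

# column-wise pooled-variance two-sided t-test
.col_ttest <- function(X, post) {
  n1 <- sum(!post); n2 <- sum(post)
  B <- X[!post, , drop = FALSE]
  P <- X[post, , drop = FALSE]
  m1 <- colMeans(B)
  m2 <- colMeans(P)
  v1 <- (colSums(B^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(P^2) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)  # guard float cancellation
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  dm <- m2 - m1
  p <- numeric(ncol(X)); degen <- rep(FALSE, ncol(X))
  zero_var <- se <= 1e-12 * pmax(abs(m1) + abs(m2), 1)
  eq <- zero_var & abs(dm) < .Machine$double.eps^0.5
  ne <- zero_var & !eq
  p[eq] <- 1
  p[ne] <- 0
  degen[ne] <- TRUE
  ok <- !zero_var
  if (any(ok)) {
    tt <- dm[ok] / se[ok]
    p[ok] <- 2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
  }
  attr(p, "degenerate") <- degen
  p
}

# out-of-bag per-sample vote fraction for the second class level
.oob_votes <- function(fit, X) {
  pred <- stats::predict(fit, X,
                         predict.all = TRUE, num.threads = 1)$predictions
  inbag <- simplify2array(fit$inbag.counts)  # n x ntree
  oob <- inbag == 0
  votes2 <- rowSums((pred == 2L) & oob)
  counts <- rowSums(oob)
  ifelse(counts > 0, votes2 / counts, NA_real_)
}

#' Fit a random-forest classifier and assess its adequacy
#'
#' Fits a supervised random forest (ntree trees, `mtry = floor(sqrt(p))` by
#' default) and evaluates it by its classification margin and AUC, using
#' out-of-bag votes when no test set is supplied.  The margin is the mean
#' over samples of the vote fraction for the true class minus the best
#' competing class; permutation importance is the mean decrease in accuracy
#' over out-of-bag predictions (unscaled).  The model is deemed adequate if
#' margin > 0.2 and AUC > 0.8.
#'
#' @param X Samples x features matrix (column names required).
#' @param y Two-level factor (second level = postprandial).
#' @param rf An [rf_config()].
#' @param thr A [selection_thresholds()] (adequacy gates).
#' @param seed Seed passed to the forest.
#' @param newdata,newy Optional held-out test set; if given, margin and AUC
#'   are computed from test-set votes instead of out-of-bag votes.
#' @return Object of class `rf_assessment`: `margin`, `auc`, `adequate`,
#'   `importance` (named vector), `fit`.
#' @export
rf_fit_and_assess <- function(X, y, rf = rf_config(),
                              thr = selection_thresholds(), seed = 1,
                              newdata = NULL, newy = NULL) {
  y <- factor(y)
  if (nlevels(y) < 2 || min(table(y)) < 2) {
    stop("need at least 2 samples in each of 2 classes")
  }
  mtry <- if (is.null(rf$mtry)) max(1, floor(sqrt(ncol(X)))) else
    min(rf$mtry, ncol(X))
  fit <- ranger::ranger(x = X, y = y,
                        num.trees = rf$ntree, mtry = mtry,
                        importance = "permutation",
                        scale.permutation.importance = FALSE,
                        keep.inbag = is.null(newdata),
                        num.threads = 1, seed = seed)
  if (is.null(newdata)) {
    votes2 <- .oob_votes(fit, X)
    truth <- y
  } else {
    pred <- stats::predict(fit, newdata,
                           predict.all = TRUE, num.threads = 1)$predictions
    votes2 <- rowMeans(pred == 2L)
    truth <- factor(newy, levels = levels(y))
  }
  post <- truth == levels(y)[2]
  vote_true <- ifelse(post, votes2, 1 - votes2)
  margin <- mean(2 * vote_true - 1, na.rm = TRUE)
  auc <- feature_auc(votes2, post, direction_agnostic = FALSE)
  imp <- fit$variable.importance
  # trees that happen to draw every sample in-bag have no OOB error and
  # poison the importance of the features they used; drop those values
  imp[is.nan(imp)] <- NA_real_
  structure(list(margin = margin, auc = auc,
                 adequate = margin > thr$margin_adequate &&
                   auc > thr$auc_adequate,
                 importance = imp, fit = fit),
            class = "rf_assessment")
}

#' @export
print.rf_assessment <- function(x, ...) {
  cat(sprintf("<rf_assessment> margin %.3f, AUC %.3f -> %s\n", x$margin,
              x$auc, if (x$adequate) "adequate" else "inadequate"))
  invisible(x)
}

#' Assign selection tiers from aggregated feature statistics
#'
#' `discriminatory` requires importance > 0.002, P < 0.05 and AUC >= 0.9;
#' otherwise `putative` requires importance > 0.001 and AUC > 0.8 (the
#' lower-threshold band worth investigating further); everything else is
#' `none`.  A pure function of its inputs; vectorized.
#'
#' @param importance,p,auc Aggregated per-feature statistics.
#' @param thr A [selection_thresholds()].
#' @return Character vector of tiers.
#' @export
#' @examples
#' assign_tier(0.0025, 0.01, 0.92)  # discriminatory
#' assign_tier(0.0015, 0.03, 0.85)  # putative
assign_tier <- function(importance, p, auc, thr = selection_thresholds()) {
  known <- !is.na(importance) & !is.na(p) & !is.na(auc)
  disc <- known & importance > thr$is_discriminatory & p < thr$p_max &
    auc >= thr$auc_discriminatory
  put <- known & !disc & importance > thr$is_putative_low &
    auc > thr$auc_putative_low
  out <- rep("none", length(importance))
  out[put] <- "putative"
  out[disc] <- "discriminatory"
  out
}

#' Bootstrapped random-forest / AUC / t-test feature selection
#'
#' Runs `n_boot` stratified 2/3-1/3 train/test resamples.  Each bootstrap
#' fits a random forest on the training split (permutation importance =
#' out-of-bag mean decrease in accuracy), evaluates model margin and AUC on
#' the test split, and computes the per-feature AUC and Student's t-test on
#' the test samples.  Per-feature statistics are aggregated as means across
#' bootstraps and tiered with [assign_tier()]; the model-level adequacy gate
#' uses the mean margin and mean AUC.
#'
#' @param X Samples x bins intensity matrix (column names required).
#' @param y Two-level labels, baseline first level, postprandial second.
#' @param boot A [bootstrap_config()].
#' @param rf An [rf_config()].
#' @param thr A [selection_thresholds()].
#' @param seed Master seed; per-bootstrap seeds are derived from it, so
#'   results are reproducible.
#' @param p_on_test Compute t-test P-values on each bootstrap's test split
#'   (default) rather than once on the full data.  Splits too small to test
#'   (< 2 per class) automatically fall back to full-data P-values.
#' @return Object of class `feature_selection`: `stats` (data frame with
#'   `bin`, `importance`, `auc`, `p`, `selection_fraction`, `tier`),
#'   `adequacy` (mean margin/AUC, adequate flag, per-bootstrap vectors),
#'   and the configurations used.
#' @export
bootstrap_select <- function(X, y, boot = bootstrap_config(),
                             rf = rf_config(), thr = selection_thresholds(),
                             seed = 1, p_on_test = TRUE) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly 2 classes")
  if (nrow(X) != length(y)) stop("X and y are not aligned")
  cls <- lapply(levels(y), function(l) which(y == l))
  n_cls <- lengths(cls)
  if (any(n_cls < 3)) {
    stop("each class needs >= 3 samples for a stratified 2/3-1/3 split ",
         "(got ", paste(n_cls, collapse = ", "), ")")
  }
  n_train <- pmax(2, round(boot$train_fraction * n_cls))
  n_train <- pmin(n_train, n_cls - 1)  # keep at least one test sample
  p <- ncol(X)
  post_all <- y == levels(y)[2]

  set.seed(seed)
  imp_sum <- imp_n <- auc_sum <- p_sum <- sel_sum <- numeric(p)
  margins <- aucs <- numeric(boot$n_boot)
  p_full <- .col_ttest(X, post_all)
  for (b in seq_len(boot$n_boot)) {
    tr <- unlist(lapply(seq_along(cls), function(k)
      sample(cls[[k]], n_train[k])))
    te <- setdiff(seq_len(nrow(X)), tr)
    ass <- rf_fit_and_assess(X[tr, , drop = FALSE], y[tr], rf, thr,
                             seed = sample.int(2147483646L, 1),
                             newdata = X[te, , drop = FALSE], newy = y[te])
    margins[b] <- ass$margin
    aucs[b] <- ass$auc
    imp_b <- ass$importance[colnames(X)]
    auc_b <- .col_auc(X[te, , drop = FALSE], post_all[te])
    te_counts <- table(y[te])
    p_b <- if (p_on_test && all(te_counts >= 2)) {
      as.numeric(.col_ttest(X[te, , drop = FALSE], post_all[te]))
    } else {
      as.numeric(p_full)
    }
    ok <- !is.na(imp_b)
    imp_sum[ok] <- imp_sum[ok] + imp_b[ok]
    imp_n <- imp_n + ok
    auc_sum <- auc_sum + auc_b
    p_sum <- p_sum + p_b
    sel_sum <- sel_sum + (ok & imp_b > thr$is_putative_low &
                            auc_b > thr$auc_putative_low)
  }
  stats <- data.frame(
    bin = colnames(X),
    importance = ifelse(imp_n > 0, imp_sum / imp_n, NA_real_),
    auc = auc_sum / boot$n_boot,
    p = p_sum / boot$n_boot,
    selection_fraction = sel_sum / boot$n_boot,
    stringsAsFactors = FALSE
  )
  stats$tier <- assign_tier(stats$importance, stats$p, stats$auc, thr)
  rownames(stats) <- NULL
  structure(list(
    stats = stats,
    adequacy = list(margin = mean(margins), auc = mean(aucs),
                    adequate = mean(margins) > thr$margin_adequate &&
                      mean(aucs) > thr$auc_adequate,
                    margins = margins, aucs = aucs),
    config = list(boot = boot, rf = rf, thresholds = thr, seed = seed)
  ), class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  tab <- table(factor(x$stats$tier,
                      levels = c("discriminatory", "putative", "none")))
  cat(sprintf(paste0("<feature_selection> %d bins: %d discriminatory, ",
                     "%d putative | model margin %.3f, AUC %.3f (%s)\n"),
              nrow(x$stats), tab[["discriminatory"]], tab[["putative"]],
              x$adequacy$margin, x$adequacy$auc,
              if (x$adequacy$adequate) "adequate" else "inadequate"))
  invisible(x)
}

#' @export
summary.feature_selection <- function(object, n = 10, ...) {
  print(object)
  sel <- object$stats[object$stats$tier != "none", , drop = FALSE]
  sel <- sel[order(-sel$importance), , drop = FALSE]
  if (nrow(sel)) {
    cat("Top tiered bins:\n")
    print(utils::head(sel, n), row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' Run feature selection over all comparison pairs of a study
#'
#' @param fingerprint Combined samples x bins matrix (both modes).
#' @param metadata Study metadata (see [build_comparisons()]).
#' @param boot,rf,thr,seed As in [bootstrap_select()].
#' @param include_extra Run the additional post-dinner vs next-day baseline
#'   comparisons where next-day samples exist (default TRUE).
#' @return Named list of `feature_selection` objects, one per comparison
#'   (extra comparisons suffixed `_nextday`).
#' @export
run_discovery <- function(fingerprint, metadata, boot = bootstrap_config(),
                          rf = rf_config(), thr = selection_thresholds(),
                          seed = 1, include_extra = TRUE) {
  pairs <- build_comparisons(metadata)
  out <- list()
  for (pair in pairs) {
    sets <- list(c(baseline = list(pair$baseline),
                   post = list(pair$postprandial)))
    names(sets) <- pair$label
    if (include_extra && length(pair$extra_baseline)) {
      sets[[paste0(pair$label, "_nextday")]] <-
        c(baseline = list(pair$extra_baseline),
          post = list(pair$postprandial))
    }
    for (lab in names(sets)) {
      ids <- c(sets[[lab]]$baseline, sets[[lab]]$post)
      missing <- setdiff(ids, rownames(fingerprint))
      if (length(missing)) {
        warning(lab, ": samples missing from fingerprint (",
                paste(missing, collapse = ", "), "); skipped")
        next
      }
      ycmp <- factor(rep(c("baseline", "postprandial"),
                         c(length(sets[[lab]]$baseline),
                           length(sets[[lab]]$post))),
                     levels = c("baseline", "postprandial"))
      res <- try(bootstrap_select(fingerprint[ids, , drop = FALSE], ycmp,
                                  boot, rf, thr, seed = seed), silent = TRUE)
      if (inherits(res, "try-error")) {
        warning(lab, ": ", attr(res, "condition")$message, "; skipped")
        next
      }
      out[[lab]] <- res
    }
  }
  out
}
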