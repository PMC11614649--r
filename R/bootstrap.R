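#' Bootstrap bias in percent
#'
#' Prediction error of a bootstrap distribution relative to the original
#' point estimate: `(median - estimate) * 100 / estimate`.
#'
#' @param estimate Original point estimate (nonzero).
#' @param bootstrap_median Median of the bootstrap estimates.
#' @return Bias in percent.
#' @export
bias_percent <- function(estimate, bootstrap_median) {
  if (any(estimate == 0)) stop("estimate must be nonzero")
  (bootstrap_median - estimate) * 100 / estimate
}

#' Empirical percentile interval
#'
#' Linear interpolation between order statistics (the default quantile
#' definition), e.g. the 5th-95th interval reported as a 90% bootstrap
#' confidence interval.
#'
#' @param samples Numeric vector (nonempty).
#' @param lower_pct,upper_pct Percentiles in \[0, 100\].
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
percentile_interval <- function(samples, lower_pct = 5, upper_pct = 95) {
  if (length(samples) == 0) stop("empty sample list")
  stopifnot(lower_pct <= upper_pct)
  unname(stats::quantile(samples, c(lower_pct, upper_pct) / 100, type = 7))
}

#' Nonparametric bootstrap of a fitted population model
#'
#' Resamples *subjects* (with their full event histories) with replacement
#' to the original subject count, refits the model on each replicate, and
#' summarises the converged replicates per parameter with the bootstrap
#' median, the 5th-95th percentile interval and the relative bias
#' [bias_percent()]. Non-converged replicates are excluded from the
#' summaries and counted.
#'
#' @param ds The original [tdm_dataset()].
#' @param fit The original `ppk_fit` (supplies point estimates, the model
#'   structure and warm initial values for the refits).
#' @param n_reps Number of bootstrap replicates (default 1000; tests use
#'   100-200 for desk-scale runtime).
#' @param seed Integer seed making the resampling reproducible.
#' @param resample_indices Optional list of integer vectors (subject indices
#'   per replicate) overriding random resampling, e.g. a forced identity
#'   resample.
#' @param fit_args Extra arguments for [fit_model()].
#' @return An object of class `bootstrap_summary`: `table` (one row per
#'   parameter: estimate, median, ci_lower, ci_upper, bias_percent),
#'   `replicates` (matrix of converged replicate estimates), `indices`,
#'   `n_requested`, `n_converged`, `seed`.
#' @export
bootstrap_model <- function(ds, fit, n_reps = 1000, seed = NULL,
                            resample_indices = NULL,
                            fit_args = list(se = FALSE)) {
  stopifnot(inherits(ds, "tdm_dataset"), inherits(fit, "ppk_fit"),
            n_reps >= 1)
  ids <- unique(ds$ID)
  n <- length(ids)
  if (is.null(resample_indices)) {
    resample_indices <- with_seed(seed, {
      lapply(seq_len(n_reps), function(r) sample.int(n, n, replace = TRUE))
    })
  } else {
    n_reps <- length(resample_indices)
  }
  sub_rows <- split(seq_len(nrow(ds)), factor(ds$ID, levels = ids))
  est_names <- names(coef(fit))
  reps <- matrix(NA_real_, n_reps, length(est_names),
                 dimnames = list(NULL, est_names))
  converged <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    idx <- resample_indices[[r]]
    pieces <- lapply(seq_along(idx), function(j) {
      piece <- ds[sub_rows[[idx[j]]], , drop = FALSE]
      piece$ID <- sprintf("B%05d", j)  # duplicated subjects stay distinct
      piece
    })
    bds <- tdm_dataset(do.call(rbind, pieces), validate = FALSE)
    bfit <- tryCatch(
      do.call(fit_model, c(list(ds = bds, init = fit$model), fit_args)),
      error = function(e) NULL)
    if (!is.null(bfit) && bfit$converged) {
      reps[r, ] <- coef(bfit)[est_names]
      converged[r] <- TRUE
    }
  }
  if (!any(converged)) stop("no bootstrap replicate converged")
  good <- reps[converged, , drop = FALSE]
  est <- coef(fit)[est_names]
  tab <- data.frame(
    parameter = est_names,
    estimate = unname(est),
    median = apply(good, 2, stats::median),
    ci_lower = apply(good, 2, function(x) percentile_interval(x)[1]),
    ci_upper = apply(good, 2, function(x) percentile_interval(x)[2]),
    stringsAsFactors = FALSE)
  tab$bias_percent <- bias_percent(tab$estimate, tab$median)
  rownames(tab) <- NULL
  structure(list(table = tab, replicates = good,
                 indices = resample_indices,
                 n_requested = n_reps, n_converged = sum(converged),
                 seed = seed),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("<bootstrap_summary> ", x$n_converged, "/", x$n_requested,
      " replicates converged\n", sep = "")
  tab <- x$table
  for (col in c("estimate", "median", "ci_lower", "ci_upper", "bias_percent")) {
    tab[[col]] <- signif(tab[[col]], 4)
  }
  print(tab, row.names = FALSE)
  invisible(x)
}
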