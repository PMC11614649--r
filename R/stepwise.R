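#' Candidate covariate for stepwise selection
#'
#' Binary flags enter linearly (`TV * (1 + p Z)`); continuous covariates as a
#' power of the covariate centred at its population median
#' (`TV * (Z/Z_m)^p`).
#'
#' @param covariate Covariate column name (e.g. `"FLU"`, `"AGE"`).
#' @param target `"cl"` or `"v"`.
#' @param kind `"linear"` or `"power"`.
#' @return An object of class `covariate_candidate`.
#' @export
covariate_candidate <- function(covariate, target = "cl",
                                kind = c("linear", "power")) {
  kind <- match.arg(kind)
  target <- match.arg(target, c("cl", "v"))
  structure(list(covariate = covariate, target = target, kind = kind),
            class = "covariate_candidate")
}

#' Stepwise selection thresholds
#'
#' Forward inclusion requires the objective function to drop by more than
#' `include_threshold` (default 3.84, chi-square 1 df at p < 0.05); backward
#' elimination removes a covariate unless its deletion raises the objective
#' by more than `exclude_threshold` (default 6.63, p < 0.01).
#'
#' @param include_threshold,exclude_threshold Positive OFV-change thresholds
#'   with `exclude_threshold > include_threshold`.
#' @return An object of class `stepwise_config`.
#' @export
stepwise_config <- function(include_threshold = 3.84,
                            exclude_threshold = 6.63) {
  stopifnot(include_threshold > 0, exclude_threshold > include_threshold)
  structure(list(include_threshold = include_threshold,
                 exclude_threshold = exclude_threshold),
            class = "stepwise_config")
}

# build the covariate_effect for a candidate at its null value
candidate_effect <- function(cand, ds) {
  if (cand$kind == "linear") {
    covariate_effect(cand$target, cand$covariate, "linear", 0)
  } else {
    sub1 <- ds[!duplicated(ds$ID), , drop = FALSE]
    ref <- stats::median(sub1[[cand$covariate]])
    if (!is.finite(ref) || ref <= 0) {
      stop("cannot centre power covariate ", cand$covariate,
           " at a nonpositive median")
    }
    covariate_effect(cand$target, cand$covariate, "power", 0, reference = ref)
  }
}

cand_label <- function(cand) {
  paste0(cand$covariate, "->", toupper(cand$target), " (", cand$kind, ")")
}

#' Stepwise covariate model building
#'
#' Forward pass: among the remaining candidates, refit with each added in
#' turn and include the one yielding the largest OFV decrease, provided the
#' decrease exceeds the inclusion threshold; repeat until no candidate
#' qualifies. Ties within 1e-6 go to the earlier-declared candidate.
#' Backward pass: covariates added in the forward pass are deleted one at a
#' time; a covariate is removed (least-damaging first) unless its deletion
#' increases the OFV by more than the exclusion threshold. Candidate fits
#' that fail are skipped and logged in the trace.
#'
#' @param ds A [tdm_dataset()].
#' @param base A [population_model()] giving the base structure and initial
#'   values (typically allometric weight scaling only).
#' @param candidates List of [covariate_candidate()] objects.
#' @param cfg A [stepwise_config()].
#' @param fit_args Extra arguments passed to [fit_model()] (e.g. `control`).
#' @return List with `fit` (final `ppk_fit`), `model` (its
#'   [population_model()]) and `trace` (a data frame recording every tested
#'   model's OFV and the decision taken).
#' @export
stepwise_covariate_search <- function(ds, base, candidates,
                                      cfg = stepwise_config(),
                                      fit_args = list(se = FALSE)) {
  stopifnot(inherits(cfg, "stepwise_config"))
  trace <- list()
  log_row <- function(phase, label, ofv, delta, decision) {
    trace[[length(trace) + 1]] <<- data.frame(
      phase = phase, candidate = label, ofv = ofv, delta_ofv = delta,
      decision = decision, stringsAsFactors = FALSE)
  }
  do_fit <- function(model) {
    do.call(fit_model, c(list(ds = ds, init = model), fit_args))
  }
  current_fit <- do_fit(base)
  log_row("base", "(base)", current_fit$ofv, NA, "start")
  remaining <- candidates
  added <- list()  # candidate + effect index bookkeeping

  # forward inclusion
  repeat {
    if (length(remaining) == 0) break
    deltas <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (k in seq_along(remaining)) {
      cand <- remaining[[k]]
      model_k <- current_fit$model
      model_k$covariates <- c(model_k$covariates,
                              list(candidate_effect(cand, ds)))
      fit_k <- tryCatch(do_fit(model_k), error = function(e) NULL)
      if (is.null(fit_k) || !is.finite(fit_k$ofv)) {
        log_row("forward", cand_label(cand), NA, NA, "fit failed, skipped")
        next
      }
      fits[[k]] <- fit_k
      deltas[k] <- current_fit$ofv - fit_k$ofv
      log_row("forward", cand_label(cand), fit_k$ofv, deltas[k], "tested")
    }
    if (all(is.na(deltas))) break
    best_delta <- max(deltas, na.rm = TRUE)
    if (!(best_delta > cfg$include_threshold)) break
    # first candidate within 1e-6 of the best wins (declaration order)
    k_star <- which(!is.na(deltas) & deltas >= best_delta - 1e-6)[1]
    cand <- remaining[[k_star]]
    current_fit <- fits[[k_star]]
    added[[length(added) + 1]] <- cand
    log_row("forward", cand_label(cand), current_fit$ofv, deltas[k_star],
            "included")
    remaining <- remaining[-k_star]
  }

  # backward elimination over forward-added covariates
  repeat {
    if (length(added) == 0) break
    increases <- rep(NA_real_, length(added))
    fits <- vector("list", length(added))
    for (k in seq_along(added)) {
      cand <- added[[k]]
      model_k <- current_fit$model
      drop_idx <- which(vapply(model_k$covariates, function(ce) {
        ce$covariate == cand$covariate && ce$target == cand$target &&
          ce$kind == cand$kind
      }, logical(1)))[1]
      model_k$covariates <- model_k$covariates[-drop_idx]
      fit_k <- tryCatch(do_fit(model_k), error = function(e) NULL)
      if (is.null(fit_k) || !is.finite(fit_k$ofv)) {
        log_row("backward", cand_label(cand), NA, NA, "fit failed, kept")
        next
      }
      fits[[k]] <- fit_k
      increases[k] <- fit_k$ofv - current_fit$ofv
      log_row("backward", cand_label(cand), fit_k$ofv, increases[k], "tested")
    }
    if (all(is.na(increases))) break
    min_inc <- min(increases, na.rm = TRUE)
    if (min_inc > cfg$exclude_threshold) break
    k_star <- which(!is.na(increases) & increases <= min_inc + 1e-6)[1]
    cand <- added[[k_star]]
    current_fit <- fits[[k_star]]
    log_row("backward", cand_label(cand), current_fit$ofv, increases[k_star],
            "removed")
    added <- added[-k_star]
  }

  list(fit = current_fit, model = current_fit$model,
       selected = vapply(added, cand_label, character(1)),
       trace = do.call(rbind, trace))
}
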