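# prediction helper: structural prediction for every observation of ds at
# either typical (eta = 0) or individual (eta = eta_hat) clearance
predict_all <- function(pd, m, eta) {
  typ <- typical_from_covariates(m, pd$covs)
  out <- vector("list", length(pd$subjects))
  for (i in seq_along(pd$subjects)) {
    out[[i]] <- .predict_subject_cpp(pd$subjects[[i]],
                                     typ$cl[i] * exp(eta[i]), typ$v[i], m$ka)
  }
  out
}

#' Goodness-of-fit prediction table
#'
#' One row per observation with the population prediction PRED (eta = 0),
#' the individual prediction IPRED (at the conditional mode), and the
#' individual weighted residual `iWRES = (DV - IPRED) / g(IPRED)` where `g`
#' is the combined residual-error standard deviation. These are the
#' quantities behind the classic observed-vs-predicted and residual
#' diagnostic panels.
#'
#' @param fit A converged `ppk_fit`.
#' @param ds The [tdm_dataset()] the model was fitted to (or any dataset
#'   whose subjects all appear in the fit).
#' @return Data frame with columns `subject_id`, `time`, `dv`, `pred`,
#'   `ipred`, `iwres`.
#' @export
gof_predictions <- function(fit, ds) {
  stopifnot(inherits(fit, "ppk_fit"))
  if (!fit$converged) stop("fit did not converge")
  pd <- prepare_foce_data(ds)
  missing <- setdiff(pd$ids, names(fit$eta_hat))
  if (length(missing) > 0) {
    stop("subject(s) not in fit: ", paste(missing, collapse = ", "))
  }
  eta <- fit$eta_hat[pd$ids]
  m <- fit$model
  pred <- predict_all(pd, m, rep(0, length(pd$ids)))
  ipred <- predict_all(pd, m, eta)
  rows <- lapply(seq_along(pd$ids), function(i) {
    data.frame(subject_id = pd$ids[i],
               time = NA_real_,
               dv = pd$subjects[[i]]$d,
               pred = pred[[i]],
               ipred = ipred[[i]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # absolute observation times straight from the dataset (same ordering:
  # subjects in first-appearance order, time-sorted within subject)
  obs <- ds[ds$EVID == 0, , drop = FALSE]
  out$time <- obs$TIME[order(match(obs$ID, pd$ids))]
  out$iwres <- (out$dv - out$ipred) / sqrt(residual_variance(out$ipred, m))
  rownames(out) <- NULL
  out
}

#' First-order weighted residuals (WRES)
#'
#' Per subject, the population residual vector `r = DV - PRED` decorrelated
#' by the inverse Cholesky factor of the first-order approximated marginal
#' covariance `G omega2 G' + diag(g2(PRED))`, where `G` is the
#' finite-difference gradient of the predictions with respect to eta at
#' eta = 0. This is the classic NONMEM WRES (not CWRES).
#'
#' @param fit A converged `ppk_fit`.
#' @param ds The [tdm_dataset()].
#' @return Data frame with columns `subject_id`, `time`, `wres`.
#' @export
wres_fo <- function(fit, ds) {
  stopifnot(inherits(fit, "ppk_fit"))
  if (!fit$converged) stop("fit did not converge")
  pd <- prepare_foce_data(ds)
  m <- fit$model
  typ <- typical_from_covariates(m, pd$covs)
  h <- 1e-4
  rows <- lapply(seq_along(pd$ids), function(i) {
    s <- pd$subjects[[i]]
    f0 <- .predict_subject_cpp(s, typ$cl[i], typ$v[i], m$ka)
    fp <- .predict_subject_cpp(s, typ$cl[i] * exp(h), typ$v[i], m$ka)
    fm <- .predict_subject_cpp(s, typ$cl[i] * exp(-h), typ$v[i], m$ka)
    G <- (fp - fm) / (2 * h)
    V <- m$omega2_cl * tcrossprod(G) + diag(residual_variance(f0, m),
                                            nrow = length(f0))
    L <- tryCatch(chol(V), error = function(e) {
      stop("marginal covariance not positive definite for subject ",
           pd$ids[i])
    })
    wres <- backsolve(L, s$d - f0, transpose = TRUE)
    data.frame(subject_id = pd$ids[i], time = rep(NA_real_, length(f0)),
               wres = wres, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  obs <- ds[ds$EVID == 0, , drop = FALSE]
  out$time <- obs$TIME[order(match(obs$ID, pd$ids))]
  rownames(out) <- NULL
  out
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets under the fitted model with the
#' original design (doses, observation times, covariates): per replicate a
#' fresh eta per subject and combined residual error per observation. For
#' each time bin it reports the observed 5th/50th/95th percentiles and, for
#' each of those percentiles, the 2.5%/50%/97.5% band across the simulated
#' replicates. Deterministic given `seed`; empty bins are dropped with a
#' warning.
#'
#' @param fit A converged `ppk_fit`.
#' @param ds The [tdm_dataset()].
#' @param n_sim Number of simulated replicate datasets (>= 1).
#' @param bins Number of quantile-based time bins (default 8), or an
#'   explicit vector of bin edges covering all observation times.
#' @param seed Integer seed.
#' @param band_level Coverage of the across-replicate band around each
#'   simulated percentile (default 0.95).
#' @return An object of class `vpc_result` with elements `bins` (a data
#'   frame, one row per bin), `n_sim`, `seed`.
#' @export
vpc <- function(fit, ds, n_sim = 200, bins = 8, seed = NULL,
                band_level = 0.95) {
  stopifnot(band_level > 0, band_level < 1)
  stopifnot(inherits(fit, "ppk_fit"), n_sim >= 1)
  if (!fit$converged) stop("fit did not converge")
  pd <- prepare_foce_data(ds)
  m <- fit$model
  typ <- typical_from_covariates(m, pd$covs)
  obs <- ds[ds$EVID == 0, , drop = FALSE]
  obs <- obs[order(match(obs$ID, pd$ids)), , drop = FALSE]
  times <- obs$TIME
  dv <- obs$DV
  n_obs_per <- vapply(pd$subjects, function(s) length(s$d), integer(1))

  if (length(bins) == 1) {
    probs <- seq(0, 1, length.out = bins + 1)
    edges <- unique(stats::quantile(times, probs, type = 7))
  } else {
    edges <- sort(unique(bins))
    if (min(times) < min(edges) || max(times) > max(edges)) {
      stop("bin edges do not cover all observation times")
    }
  }
  bin_of <- cut(times, edges, include.lowest = TRUE, labels = FALSE)

  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(r) {
      eta <- stats::rnorm(length(pd$ids), 0, sqrt(m$omega2_cl))
      f <- unlist(predict_all(pd, m, eta), use.names = FALSE)
      eps1 <- stats::rnorm(length(f), 0, sqrt(m$sigma2_prop))
      eps2 <- stats::rnorm(length(f), 0, sqrt(m$sigma2_add))
      f + f * eps1 + eps2
    }, numeric(length(dv)))
  })

  pcts <- c(5, 50, 95) / 100
  rows <- list()
  for (b in sort(unique(bin_of))) {
    sel <- bin_of == b
    if (!any(sel)) next
    obs_q <- stats::quantile(dv[sel], pcts, type = 7)
    sim_q <- apply(sims[sel, , drop = FALSE], 2, stats::quantile,
                   probs = pcts, type = 7)  # 3 x n_sim
    band <- apply(sim_q, 1, stats::quantile,
                  probs = c((1 - band_level) / 2, 0.5,
                            1 - (1 - band_level) / 2),
                  type = 7)  # 3 x 3
    rows[[length(rows) + 1]] <- data.frame(
      bin = b, t_lo = edges[b], t_hi = edges[b + 1],
      t_mid = stats::median(times[sel]), n_obs = sum(sel),
      obs_p5 = obs_q[1], obs_p50 = obs_q[2], obs_p95 = obs_q[3],
      sim_p5_lo = band[1, 1], sim_p5_mid = band[2, 1], sim_p5_hi = band[3, 1],
      sim_p50_lo = band[1, 2], sim_p50_mid = band[2, 2], sim_p50_hi = band[3, 2],
      sim_p95_lo = band[1, 3], sim_p95_mid = band[2, 3], sim_p95_hi = band[3, 3])
  }
  if (length(rows) < length(edges) - 1) {
    warning("empty time bin(s) dropped")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(bins = out, n_sim = n_sim, seed = seed),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat("<vpc_result>", nrow(x$bins), "bins,", x$n_sim, "simulations\n")
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Write diagnostic tables to CSV
#'
#' @param fit A converged `ppk_fit`.
#' @param ds The [tdm_dataset()].
#' @param dir Output directory (created if needed).
#' @param n_sim,bins,seed Passed to [vpc()].
#' @return Invisibly, the paths written (`gof.csv`, `wres.csv`, `vpc.csv`).
#' @export
write_diagnostics <- function(fit, ds, dir, n_sim = 200, bins = 8,
                              seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gof <- gof_predictions(fit, ds)
  gof$wres <- wres_fo(fit, ds)$wres
  v <- vpc(fit, ds, n_sim = n_sim, bins = bins, seed = seed)
  paths <- file.path(dir, c("gof.csv", "vpc.csv"))
  utils::write.csv(gof, paths[1], row.names = FALSE)
  utils::write.csv(v$bins, paths[2], row.names = FALSE)
  invisible(paths)
}
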