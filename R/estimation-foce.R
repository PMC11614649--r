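#' @useDynLib quetipk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Columns that are event bookkeeping, not subject-level covariates
.event_cols <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV")

# Flatten a tdm_dataset into per-subject structures for the FOCE engine:
# observed concentrations, dose amounts, and the obs x dose matrix of
# elapsed times (negative where the dose falls after the observation).
# Also returns one covariate row per subject.
prepare_foce_data <- function(ds) {
  stopifnot(inherits(ds, "tdm_dataset"))
  ids <- unique(ds$ID)
  subjects <- vector("list", length(ids))
  cov_cols <- setdiff(names(ds)[vapply(ds, is.numeric, logical(1))],
                      .event_cols)
  covs <- as.data.frame(matrix(NA_real_, length(ids), length(cov_cols),
                               dimnames = list(NULL, cov_cols)))
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    sub <- ds[ds$ID == ids[i], , drop = FALSE]
    obs <- sub[sub$EVID == 0, , drop = FALSE]
    dose <- sub[sub$EVID == 1, , drop = FALSE]
    keep[i] <- nrow(obs) > 0
    subjects[[i]] <- list(
      d = obs$DV,
      amt = dose$AMT,
      dt = outer(obs$TIME, dose$TIME, `-`)
    )
    covs[i, ] <- as.numeric(sub[1, cov_cols])
  }
  list(subjects = subjects[keep], covs = covs[keep, , drop = FALSE],
       ids = ids[keep])
}

#' Conditional individual objective for one subject
#'
#' The -2 log joint density (constant `n log(2pi)` omitted) of one subject's
#' observations and random effect:
#' `sum_j [ (d_j - f_j(eta))^2 / g2_j(eta) + log g2_j(eta) ] +
#'  eta^2 / omega2 + log(omega2)`,
#' where `f` is the structural prediction at the individual clearance
#' `CL_typ exp(eta)` and `g2` the combined residual variance evaluated at the
#' individual prediction (the "interaction" in FOCE-I).
#'
#' @param sub A `tdm_dataset` containing exactly one subject.
#' @param m A [population_model()].
#' @param eta Random-effect value on log CL/F.
#' @return The scalar objective value.
#' @export
individual_objective <- function(sub, m, eta) {
  stopifnot(inherits(m, "population_model"))
  pd <- prepare_foce_data(sub)
  if (length(pd$subjects) != 1) stop("sub must contain exactly one subject with observations")
  typ <- typical_from_covariates(m, pd$covs)
  s <- pd$subjects[[1]]
  f <- .predict_subject_cpp(s, typ$cl[1] * exp(eta), typ$v[1], m$ka)
  g2 <- residual_variance(f, m)
  val <- sum((s$d - f)^2 / g2 + log(g2))
  if (m$omega2_cl > 0) {
    val <- val + eta^2 / m$omega2_cl + log(m$omega2_cl)
  } else if (eta != 0) {
    stop("omega2_cl is zero but a nonzero eta was requested")
  }
  val
}

#' Conditional modes of the random effects
#'
#' For every subject with at least one observation, minimises
#' [individual_objective()] over eta (safeguarded Newton iteration with a
#' grid + golden-section fallback).
#'
#' @param ds A [tdm_dataset()].
#' @param m A [population_model()].
#' @return Named numeric vector of modes, one per subject, with attribute
#'   `converged` (logical vector; non-converged subjects are flagged, not
#'   raised).
#' @export
conditional_modes <- function(ds, m) {
  pd <- prepare_foce_data(ds)
  typ <- typical_from_covariates(m, pd$covs)
  res <- .foce_eval_cpp(pd$subjects, typ$cl, typ$v, m$ka, m$omega2_cl,
                        m$sigma2_prop, m$sigma2_add,
                        rep(0, length(pd$subjects)))
  out <- stats::setNames(res$eta_hat, pd$ids)
  attr(out, "converged") <- stats::setNames(res$converged, pd$ids)
  out
}

#' FOCE-I objective function value
#'
#' Sum over subjects of the Laplace-type approximation of -2 log marginal
#' likelihood at the conditional mode eta_hat_i, using the exact curvature
#' of the conditional objective at the mode (with a Gauss-Newton fallback
#' when that curvature is not positive) and omitting the `n log(2pi)`
#' constant (NONMEM convention, so chi-square difference thresholds apply
#' unchanged). Residual variances are evaluated at the individual
#' predictions (interaction). At `omega2 = 0` this reduces exactly to the
#' -2 log-likelihood of the fixed-effects heteroscedastic model.
#'
#' @param ds A [tdm_dataset()].
#' @param m A [population_model()].
#' @return Scalar OFV with attributes `eta_hat`, `contributions` and
#'   `converged`.
#' @export
foce_ofv <- function(ds, m) {
  pd <- prepare_foce_data(ds)
  typ <- typical_from_covariates(m, pd$covs)
  res <- .foce_eval_cpp(pd$subjects, typ$cl, typ$v, m$ka, m$omega2_cl,
                        m$sigma2_prop, m$sigma2_add,
                        rep(0, length(pd$subjects)))
  structure(res$ofv,
            eta_hat = stats::setNames(res$eta_hat, pd$ids),
            contributions = stats::setNames(res$contrib, pd$ids),
            converged = all(res$converged))
}

# ---- parameter packing ------------------------------------------------------

# Estimated parameters and their transforms:
#   theta_cl, theta_v, omega2_cl, sigma2_prop, sigma2_add : log scale
#   linear covariate coefficient p (> -1)                 : log(1 + p)
#   power covariate exponent                              : identity
par_spec <- function(m, fix = character()) {
  spec <- list(
    list(name = "theta_cl", type = "log"),
    list(name = "theta_v", type = "log")
  )
  for (k in seq_along(m$covariates)) {
    ce <- m$covariates[[k]]
    if (isTRUE(ce$fixed)) next
    spec[[length(spec) + 1]] <- list(
      name = paste0("theta_", ce$covariate,
                    if (ce$target != "cl") paste0("_", ce$target) else ""),
      type = if (ce$kind == "linear") "log1p" else "identity",
      cov_index = k)
  }
  spec <- c(spec, list(
    list(name = "omega2_cl", type = "log"),
    list(name = "sigma2_prop", type = "log"),
    list(name = "sigma2_add", type = "log")
  ))
  spec[!vapply(spec, function(s) s$name %in% fix, logical(1))]
}

par_get <- function(m, s) {
  if (!is.null(s$cov_index)) m$covariates[[s$cov_index]]$value else m[[s$name]]
}

par_set <- function(m, s, value) {
  if (!is.null(s$cov_index)) m$covariates[[s$cov_index]]$value <- value
  else m[[s$name]] <- value
  m
}

pack_par <- function(m, spec) {
  vapply(spec, function(s) {
    x <- par_get(m, s)
    switch(s$type, log = log(x), log1p = log(1 + x), identity = x)
  }, numeric(1))
}

unpack_par <- function(par, spec, m) {
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    x <- switch(s$type, log = exp(par[i]), log1p = expm1(par[i]),
                identity = par[i])
    m <- par_set(m, s, x)
  }
  m
}

natural_par <- function(m, spec) {
  stats::setNames(vapply(spec, function(s) par_get(m, s), numeric(1)),
                  vapply(spec, function(s) s$name, character(1)))
}

# central finite-difference Hessian with relative steps
fd_hessian <- function(fn, x, rel_step = 1e-3) {
  n <- length(x)
  h <- pmax(abs(x) * rel_step, 1e-6)
  H <- matrix(NA_real_, n, n)
  f0 <- fn(x)
  for (i in seq_len(n)) {
    ei <- replace(numeric(n), i, h[i])
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
    if (i < n) for (j in seq((i + 1), n)) {
      ej <- replace(numeric(n), j, h[j])
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Fit a population model to a TDM dataset by FOCE-I
#'
#' Maximises the approximate marginal likelihood (minimises [foce_ofv()])
#' over the fixed effects, covariate coefficients and variance components.
#' Ka is always held fixed. Positive parameters are optimised on the log
#' scale; linear covariate coefficients on `log(1 + p)` so they stay above
#' -1. The outer optimiser is a quasi-Newton method (`nlminb`); inner
#' conditional modes are warm-started between objective evaluations.
#' Fitting is deterministic given data and initial values.
#'
#' @param ds A [tdm_dataset()].
#' @param init A [population_model()] providing initial values and the
#'   covariate structure to estimate.
#' @param fix Character vector of parameter names to hold fixed at their
#'   initial values (e.g. `"sigma2_add"`).
#' @param se Compute relative standard errors from a finite-difference
#'   Hessian at the optimum (skipped during bootstrap refits for speed).
#'   If the Hessian is not positive definite the SEs are reported as `NA`
#'   with a warning, never fabricated.
#' @param control Passed to [stats::nlminb()] (`iter.max`, `eval.max`,
#'   `rel.tol` etc.).
#' @return An object of class `ppk_fit`: `model` (the estimates as a
#'   [population_model()]), `ofv`, `se_percent`, `eta_hat`, `converged`,
#'   `boundary`, `trace` (data frame of objective evaluations), `message`.
#' @export
fit_model <- function(ds, init = population_model(), fix = character(),
                      se = TRUE, control = list()) {
  stopifnot(inherits(ds, "tdm_dataset"), inherits(init, "population_model"))
  pd <- prepare_foce_data(ds)
  n_sub <- length(pd$subjects)
  spec <- par_spec(init, fix = fix)
  start <- pack_par(init, spec)
  eta_warm <- rep(0, n_sub)
  trace <- new.env(parent = emptyenv())
  trace$ofv <- numeric(0)
  inner_ok <- TRUE

  # pre-extract covariate columns once; the objective then works on plain
  # numeric vectors (data-frame indexing is too slow for the hot loop)
  cov_cols <- lapply(init$covariates, function(ce) {
    z <- pd$covs[[ce$covariate]]
    if (is.null(z)) stop("covariate column ", ce$covariate,
                         " absent from data")
    z
  })
  typical_fast <- function(m) {
    cl <- rep.int(m$theta_cl, n_sub)
    v <- rep.int(m$theta_v, n_sub)
    for (k in seq_along(m$covariates)) {
      ce <- m$covariates[[k]]
      mult <- if (ce$kind == "linear") 1 + ce$value * cov_cols[[k]]
              else (cov_cols[[k]] / ce$reference)^ce$value
      if (ce$target == "cl") cl <- cl * mult else v <- v * mult
    }
    if (any(cl <= 0) || any(v <= 0)) return(NULL)
    list(cl = cl, v = v)
  }

  objective <- function(par) {
    m <- unpack_par(par, spec, init)
    typ <- typical_fast(m)
    if (is.null(typ)) return(1e12)
    res <- .foce_eval_cpp(pd$subjects, typ$cl, typ$v, m$ka, m$omega2_cl,
                          m$sigma2_prop, m$sigma2_add, eta_warm)
    if (!is.finite(res$ofv)) return(1e12)
    eta_warm <<- res$eta_hat
    if (!all(res$converged)) inner_ok <<- FALSE
    trace$ofv <- c(trace$ofv, res$ofv)
    res$ofv
  }

  f0 <- objective(start)
  if (!is.finite(f0) || f0 >= 1e12) {
    stop("non-finite objective at initial values")
  }
  ctl <- utils::modifyList(list(iter.max = 400, eval.max = 2000,
                                rel.tol = 1e-9), control)
  bound <- 30
  opt <- stats::nlminb(start, objective, lower = -bound, upper = bound,
                       control = ctl)
  # convergence contract: relative OFV change < 1e-6 and parameter change
  # < 1e-4 at a restart from the optimum. When nlminb already reports clean
  # relative convergence the restart is skipped; otherwise (e.g. "false
  # convergence" triggered by the ~1e-8 finite-difference jitter of the
  # Laplace curvature) the fixed-point property is verified explicitly.
  if (opt$convergence == 0 ||
      grepl("relative convergence|X-convergence", opt$message)) {
    fixed_point <- TRUE
  } else {
    opt2 <- stats::nlminb(opt$par, objective, lower = -bound, upper = bound,
                          control = ctl)
    fixed_point <-
      abs(opt$objective - opt2$objective) <
        1e-6 * max(1, abs(opt$objective)) &&
      max(abs(opt$par - opt2$par)) < 1e-4
    if (opt2$objective <= opt$objective) opt <- opt2
  }
  m_hat <- unpack_par(opt$par, spec, init)
  typ <- typical_from_covariates(m_hat, pd$covs)
  final <- .foce_eval_cpp(pd$subjects, typ$cl, typ$v, m_hat$ka,
                          m_hat$omega2_cl, m_hat$sigma2_prop,
                          m_hat$sigma2_add, eta_warm)
  boundary <- any(abs(opt$par) > bound - 1e-6)
  converged <- fixed_point && all(final$converged) && !boundary

  se_percent <- rep(NA_real_, length(spec))
  names(se_percent) <- vapply(spec, function(s) s$name, character(1))
  if (se) {
    est_nat <- natural_par(m_hat, spec)
    obj_nat <- function(x) {
      m <- m_hat
      for (i in seq_along(spec)) m <- par_set(m, spec[[i]], x[i])
      typ <- tryCatch(typical_from_covariates(m, pd$covs),
                      error = function(e) NULL)
      if (is.null(typ)) return(NA_real_)
      r <- .foce_eval_cpp(pd$subjects, typ$cl, typ$v, m$ka, m$omega2_cl,
                          m$sigma2_prop, m$sigma2_add, final$eta_hat)
      r$ofv
    }
    H <- tryCatch(fd_hessian(obj_nat, est_nat), error = function(e) NULL)
    ok <- FALSE
    if (!is.null(H) && all(is.finite(H))) {
      # work on the relative scale (x / |estimate|): the natural-scale
      # Hessian is legitimately ill-conditioned when parameters differ by
      # orders of magnitude, and SE%% is the relative-scale quantity anyway
      a <- abs(est_nat)
      Hs <- H * tcrossprod(a)
      ev <- eigen(Hs, symmetric = TRUE, only.values = TRUE)$values
      if (all(ev > 1e-10 * max(abs(ev)))) {
        cov <- tryCatch(2 * solve(Hs),  # OFV = -2 logLik: Cov = 2 H^{-1}
                        error = function(e) NULL)
        if (!is.null(cov) && all(is.finite(diag(cov))) &&
            all(diag(cov) > 0)) {
          se_percent[] <- 100 * sqrt(diag(cov))
          ok <- TRUE
        }
      }
    }
    if (!ok) warning("Hessian not positive definite; SEs reported as NA")
  }

  structure(list(
    model = m_hat,
    ofv = final$ofv,
    se_percent = se_percent,
    eta_hat = stats::setNames(final$eta_hat, pd$ids),
    converged = converged,
    boundary = boundary,
    trace = data.frame(eval = seq_along(trace$ofv), ofv = trace$ofv),
    message = opt$message,
    n_subjects = n_sub,
    n_observations = sum(vapply(pd$subjects, function(s) length(s$d),
                                numeric(1))),
    fix = fix
  ), class = "ppk_fit")
}

#' Estimates of a fitted model as a named vector
#' @param object A `ppk_fit`.
#' @param ... Unused.
#' @return Named numeric vector of the estimated parameters (natural scale).
#' @export
coef.ppk_fit <- function(object, ...) {
  natural_par(object$model, par_spec(object$model, fix = object$fix))
}

#' Parameter table of a fitted model
#'
#' One row per model parameter in the conventional report layout
#' (Estimate, SE%), including the fixed Ka.
#'
#' @param fit A `ppk_fit`.
#' @return A data frame with columns `parameter`, `estimate`, `se_percent`,
#'   `fixed`.
#' @export
fit_parameter_table <- function(fit) {
  stopifnot(inherits(fit, "ppk_fit"))
  est <- coef(fit)
  out <- data.frame(parameter = c(names(est), "ka"),
                    estimate = c(unname(est), fit$model$ka),
                    se_percent = c(unname(fit$se_percent[names(est)]), NA),
                    fixed = c(rep(FALSE, length(est)), TRUE),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.ppk_fit <- function(x, ...) {
  cat("<ppk_fit> OFV =", format(x$ofv, digits = 10),
      if (x$converged) "(converged)" else "(NOT converged)",
      if (x$boundary) "[boundary]" else "", "\n")
  tab <- fit_parameter_table(x)
  tab$estimate <- signif(tab$estimate, 6)
  tab$se_percent <- signif(tab$se_percent, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialize a fit to JSON
#' @param fit A `ppk_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "ppk_fit"))
  payload <- list(
    model = model_to_list(fit$model),
    parameters = as.list(coef(fit)),
    ka_fixed = fit$model$ka,
    se_percent = as.list(fit$se_percent),
    ofv = fit$ofv,
    converged = fit$converged,
    boundary = fit$boundary,
    eta_hat = as.list(fit$eta_hat),
    n_subjects = fit$n_subjects,
    n_observations = fit$n_observations
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Reload a fit written by [write_fit_json()]
#'
#' Reconstructs a `ppk_fit` carrying the estimates, conditional modes and
#' OFV (the optimisation trace is not persisted), sufficient for the
#' diagnostics and simulation stages of a file-based pipeline.
#'
#' @param path Path to the JSON file.
#' @return A `ppk_fit`.
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  model <- model_from_list(x$model)
  structure(list(
    model = model,
    ofv = x$ofv,
    se_percent = vapply(x$se_percent, function(v)
      if (is.null(v)) NA_real_ else as.numeric(v), numeric(1)),
    eta_hat = vapply(x$eta_hat, as.numeric, numeric(1)),
    converged = isTRUE(x$converged),
    boundary = isTRUE(x$boundary),
    trace = data.frame(eval = integer(0), ofv = numeric(0)),
    message = "restored from JSON",
    n_subjects = x$n_subjects,
    n_observations = x$n_observations,
    fix = character(0)
  ), class = "ppk_fit")
}
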