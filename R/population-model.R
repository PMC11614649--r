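#' Covariate effect on a structural parameter
#'
#' Three functional forms are supported, matching standard population-PK
#' covariate modelling:
#' \describe{
#'   \item{`allometric`}{power scaling by body weight referenced to 70 kg,
#'     with a *fixed* exponent (0.75 on CL/F, 1 on V/F).}
#'   \item{`power`}{`TV * (Z / reference)^p` for a continuous covariate
#'     centred at its population median; exponent `p` estimated.}
#'   \item{`linear`}{`TV * (1 + p * Z)` for a categorical covariate
#'     (e.g. a binary comedication flag); coefficient `p` estimated.}
#' }
#'
#' @param target `"cl"` or `"v"`.
#' @param covariate Column name of the covariate (e.g. `"WT"`, `"FLU"`).
#' @param kind One of `"allometric"`, `"power"`, `"linear"`.
#' @param value Exponent (allometric/power) or coefficient (linear).
#' @param reference Reference value for power forms (70 kg for allometric).
#' @param fixed If `TRUE` the value is never estimated (always `TRUE` for
#'   allometric weight scaling).
#' @return An object of class `covariate_effect`.
#' @export
covariate_effect <- function(target, covariate, kind, value,
                             reference = NULL, fixed = (kind == "allometric")) {
  target <- match.arg(target, c("cl", "v"))
  kind <- match.arg(kind, c("allometric", "power", "linear"))
  if (kind %in% c("allometric", "power")) {
    if (is.null(reference) || reference <= 0) {
      stop("power-form covariate effects need a positive reference value")
    }
  }
  if (kind == "allometric") {
    ok <- (target == "cl" && value == 0.75) || (target == "v" && value == 1)
    if (!ok) stop("allometric exponent must be 0.75 for CL/F and 1 for V/F")
  }
  structure(list(target = target, covariate = covariate, kind = kind,
                 value = value, reference = reference, fixed = fixed),
            class = "covariate_effect")
}

#' Population pharmacokinetic model
#'
#' Fixed effects, covariate structure and variance components of the
#' nonlinear mixed-effects model for quetiapine:
#' \itemize{
#'   \item typical CL/F `theta_cl` (L/h) and V/F `theta_v` (L) at 70 kg
#'     without comedication, with fixed allometric weight scaling
#'     (exponent 0.75 on CL/F, 1 on V/F);
#'   \item fractional clearance changes `theta_flu`, `theta_dul` for
#'     fluvoxamine and duloxetine coadministration, entering as
#'     `(1 + theta * flag)`;
#'   \item Ka fixed at 1.46/h (not estimated);
#'   \item one log-normal random effect on CL/F with variance `omega2_cl`
#'     (individual CL/F = typical CL/F * exp(eta));
#'   \item combined residual error `D = F + F*eps1 + eps2` with proportional
#'     variance `sigma2_prop` and additive variance `sigma2_add` (ng/mL)^2,
#'     i.e. Var(D|F) = sigma2_prop * F^2 + sigma2_add.
#' }
#'
#' Defaults are the final-model estimates of the quetiapine TDM analysis
#' (CL/F 118 L/h, V/F 2460 L, theta_FLU -0.536, theta_DUL -0.537,
#' omega2 0.333, sigma2 0.267 / 29.917). `omega2_cl`, `sigma2_prop` and
#' `sigma2_add` are interpreted as variances (the NONMEM OMEGA/SIGMA
#' convention); pass `variability_scale = "sd"` to supply them as standard
#' deviations instead, in which case they are squared on entry.
#'
#' @param theta_cl,theta_v,ka Typical CL/F (L/h), V/F (L) and fixed Ka (1/h).
#' @param theta_flu,theta_dul Fractional-change coefficients for the
#'   fluvoxamine and duloxetine flags (must each exceed -1 so clearance stays
#'   positive). Ignored when `covariates` is supplied explicitly.
#' @param omega2_cl Between-subject variance of eta on CL/F.
#' @param sigma2_prop,sigma2_add Proportional and additive residual variances.
#' @param covariates Optional list of [covariate_effect()] objects replacing
#'   the default structure (allometric WT on both parameters, linear FLU and
#'   DUL on CL/F).
#' @param variability_scale `"variance"` (default) or `"sd"`.
#' @return An object of class `population_model`.
#' @export
population_model <- function(theta_cl = 118, theta_v = 2460, ka = 1.46,
                             theta_flu = -0.536, theta_dul = -0.537,
                             omega2_cl = 0.333, sigma2_prop = 0.267,
                             sigma2_add = 29.917, covariates = NULL,
                             variability_scale = c("variance", "sd")) {
  variability_scale <- match.arg(variability_scale)
  stopifnot(theta_cl > 0, theta_v > 0, ka > 0,
            omega2_cl >= 0, sigma2_prop >= 0, sigma2_add >= 0)
  if (variability_scale == "sd") {
    omega2_cl <- omega2_cl^2
    sigma2_prop <- sigma2_prop^2
    sigma2_add <- sigma2_add^2
  }
  if (is.null(covariates)) {
    stopifnot(1 + theta_flu > 0, 1 + theta_dul > 0)
    covariates <- list(
      covariate_effect("cl", "WT", "allometric", 0.75, reference = 70),
      covariate_effect("v", "WT", "allometric", 1, reference = 70),
      covariate_effect("cl", "FLU", "linear", theta_flu),
      covariate_effect("cl", "DUL", "linear", theta_dul)
    )
  }
  for (ce in covariates) {
    if (ce$kind == "linear" && 1 + ce$value <= 0) {
      stop("linear covariate coefficient on ", ce$covariate,
           " must exceed -1")
    }
  }
  structure(list(theta_cl = theta_cl, theta_v = theta_v, ka = ka,
                 omega2_cl = omega2_cl, sigma2_prop = sigma2_prop,
                 sigma2_add = sigma2_add, covariates = covariates),
            class = "population_model")
}

# coefficient of a named linear effect, or NULL
linear_coefficient <- function(m, covariate, target = "cl") {
  for (ce in m$covariates) {
    if (ce$kind == "linear" && ce$covariate == covariate &&
        ce$target == target) {
      return(ce$value)
    }
  }
  NULL
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model>\n")
  cat(sprintf("  theta: CL/F = %.6g L/h, V/F = %.6g L, Ka = %.4g /h (fixed)\n",
              x$theta_cl, x$theta_v, x$ka))
  for (ce in x$covariates) {
    cat(sprintf("  covariate: %s on %s [%s] value = %.6g%s\n",
                ce$covariate, toupper(ce$target), ce$kind, ce$value,
                if (!is.null(ce$reference))
                  sprintf(", ref = %.4g", ce$reference) else ""))
  }
  cat(sprintf("  omega2(CL/F) = %.6g, sigma2_prop = %.6g, sigma2_add = %.6g\n",
              x$omega2_cl, x$sigma2_prop, x$sigma2_add))
  invisible(x)
}

# Multiplier contributed by one covariate effect for covariate values z
effect_multiplier <- function(ce, z) {
  switch(ce$kind,
         allometric = ,
         power = (z / ce$reference)^ce$value,
         linear = 1 + ce$value * z)
}

# Vectorised typical parameters from a data frame of covariate values
# (one row per subject). Returns data.frame(cl, v, ka).
typical_from_covariates <- function(m, covs) {
  n <- nrow(covs)
  cl <- rep(m$theta_cl, n)
  v <- rep(m$theta_v, n)
  for (ce in m$covariates) {
    if (!ce$covariate %in% names(covs)) {
      stop("covariate column ", ce$covariate, " absent from data")
    }
    mult <- effect_multiplier(ce, covs[[ce$covariate]])
    if (ce$target == "cl") cl <- cl * mult else v <- v * mult
  }
  if (any(cl <= 0) || any(v <= 0)) {
    stop("covariate structure yields nonpositive CL/F or V/F")
  }
  data.frame(cl = cl, v = v, ka = rep(m$ka, n))
}

#' Typical (population-predicted) PK parameters for one subject
#'
#' Applies the covariate model at eta = 0:
#' `CL/F = theta_cl (WT/70)^0.75 (1 + theta_FLU FLU)(1 + theta_DUL DUL)`,
#' `V/F = theta_v (WT/70)`, `Ka` fixed.
#'
#' @param weight Body weight in kg, > 0.
#' @param flu,dul Binary comedication flags (0/1).
#' @param m A [population_model()].
#' @return A [pk_parameters()] object.
#' @export
typical_parameters <- function(weight, flu = 0, dul = 0, m = population_model()) {
  stopifnot(inherits(m, "population_model"))
  if (any(weight <= 0)) stop("weight must be positive")
  stopifnot(all(flu %in% c(0, 1)), all(dul %in% c(0, 1)))
  covs <- data.frame(WT = weight, FLU = flu, DUL = dul)
  typ <- typical_from_covariates(m, covs)
  pk_parameters(typ$cl, typ$v, typ$ka)
}

#' Individual PK parameters from typical values and a random effect
#'
#' The single random effect acts multiplicatively on CL/F,
#' `CL/F_i = CL/F_typ * exp(eta)`; V/F and Ka carry no between-subject
#' variability.
#'
#' @param typ Typical [pk_parameters()].
#' @param eta_cl Subject-level deviation on log CL/F.
#' @return A [pk_parameters()] object.
#' @export
individual_parameters <- function(typ, eta_cl) {
  stopifnot(inherits(typ, "pk_parameters"), is.finite(eta_cl))
  pk_parameters(typ$cl * exp(eta_cl), typ$v, typ$ka)
}

#' Residual error variance at a predicted concentration
#'
#' Combined proportional + additive model: for predicted concentration `F`,
#' `Var(D | F) = sigma2_prop F^2 + sigma2_add` (ng/mL)^2.
#'
#' @param f_pred Predicted concentration(s), ng/mL, >= 0.
#' @param m A [population_model()] (or any list with `sigma2_prop`,
#'   `sigma2_add`).
#' @return Variance(s) in (ng/mL)^2.
#' @export
residual_variance <- function(f_pred, m) {
  stopifnot(all(f_pred >= 0))
  m$sigma2_prop * f_pred^2 + m$sigma2_add
}

# plain-list representation (JSON-friendly) and its inverse
model_to_list <- function(m) {
  list(theta_cl = m$theta_cl, theta_v = m$theta_v, ka = m$ka,
       omega2_cl = m$omega2_cl, sigma2_prop = m$sigma2_prop,
       sigma2_add = m$sigma2_add,
       covariates = lapply(m$covariates, function(ce) {
         list(target = ce$target, covariate = ce$covariate, kind = ce$kind,
              value = ce$value, reference = ce$reference, fixed = ce$fixed)
       }))
}

model_from_list <- function(x) {
  covs <- lapply(x$covariates, function(ce) {
    covariate_effect(ce$target, ce$covariate, ce$kind, ce$value,
                     reference = ce$reference,
                     fixed = isTRUE(ce$fixed))
  })
  population_model(theta_cl = x$theta_cl, theta_v = x$theta_v, ka = x$ka,
                   omega2_cl = x$omega2_cl, sigma2_prop = x$sigma2_prop,
                   sigma2_add = x$sigma2_add,
                   covariates = if (length(covs)) covs else NULL)
}

#' Write a model specification to a key-value config file
#'
#' Flat YAML-style `key: value` lines; covariate effects are one line each.
#'
#' @param m A [population_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model_config <- function(m, path) {
  stopifnot(inherits(m, "population_model"))
  num <- function(x) format(x, digits = 15, scientific = FALSE)
  lines <- c(
    paste0("theta_cl: ", num(m$theta_cl)),
    paste0("theta_v: ", num(m$theta_v)),
    paste0("ka: ", num(m$ka)),
    paste0("omega2_cl: ", num(m$omega2_cl)),
    paste0("sigma2_prop: ", num(m$sigma2_prop)),
    paste0("sigma2_add: ", num(m$sigma2_add)),
    vapply(m$covariates, function(ce) {
      paste0("covariate: target=", ce$target, " name=", ce$covariate,
             " kind=", ce$kind, " value=", num(ce$value),
             if (!is.null(ce$reference)) paste0(" reference=", num(ce$reference))
             else "")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a model specification written by [write_model_config()]
#'
#' @param path Path to the config file.
#' @return A [population_model()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  getnum <- function(key) as.numeric(vals[keys == key][1])
  covs <- lapply(vals[keys == "covariate"], function(v) {
    fields <- strsplit(strsplit(v, "\\s+")[[1]], "=")
    fl <- stats::setNames(vapply(fields, `[`, character(1), 2),
                          vapply(fields, `[`, character(1), 1))
    covariate_effect(fl[["target"]], fl[["name"]], fl[["kind"]],
                     as.numeric(fl[["value"]]),
                     reference = if ("reference" %in% names(fl))
                       as.numeric(fl[["reference"]]) else NULL)
  })
  population_model(theta_cl = getnum("theta_cl"), theta_v = getnum("theta_v"),
                   ka = getnum("ka"), omega2_cl = getnum("omega2_cl"),
                   sigma2_prop = getnum("sigma2_prop"),
                   sigma2_add = getnum("sigma2_add"),
                   covariates = if (length(covs)) covs else NULL)
}
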