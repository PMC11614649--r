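#' Individual pharmacokinetic parameters
#'
#' One-compartment model with first-order absorption, parameterised by
#' apparent oral clearance CL/F (L/h), apparent volume of distribution V/F
#' (L) and absorption rate constant Ka (1/h). Bioavailability F is absorbed
#' into the apparent parameters; no separate F exists anywhere in the
#' package. The elimination rate constant ke = cl/v is derived.
#'
#' @param cl Apparent clearance CL/F in L/h, > 0.
#' @param v Apparent volume V/F in L, > 0.
#' @param ka Absorption rate constant in 1/h, > 0 (default 1.46, the
#'   literature value at which it is fixed throughout).
#' @return An object of class `pk_parameters`.
#' @export
pk_parameters <- function(cl, v, ka = 1.46) {
  stopifnot(is.numeric(cl), is.numeric(v), is.numeric(ka),
            cl > 0, v > 0, ka > 0)
  structure(list(cl = cl, v = v, ka = ka, ke = cl / v),
            class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf("<pk_parameters> CL/F = %.4g L/h, V/F = %.4g L, Ka = %.4g /h (ke = %.4g /h)\n",
              x$cl, x$v, x$ka, x$ke))
  invisible(x)
}

# Core single-dose profile in ng/mL for an oral dose in mg.
# Internal computation is mg/L; the factor 1000 to ng/mL is applied here and
# nowhere else in the package (unit contract).
#
# Near the ka = ke degeneracy the general expression is 0/0; for
# |ka - ke|/ka < 1e-8 the analytic limit dose/v * ka * t * exp(-ka t) is used.
conc_profile <- function(dose, cl, v, ka, t) {
  ke <- cl / v
  if (abs(ka - ke) / ka < 1e-8) {
    mgL <- (dose / v) * ka * t * exp(-ka * t)
  } else {
    mgL <- (dose / v) * (ka / (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
  }
  1000 * mgL
}

#' Concentration after a single oral dose
#'
#' Closed-form concentration of the one-compartment first-order-absorption
#' model, `C(t) = 1000 (dose/V) Ka/(Ka-ke) (exp(-ke t) - exp(-Ka t))` ng/mL,
#' with the analytic limit used when Ka and ke coincide.
#'
#' @param dose Dose in mg.
#' @param p A [pk_parameters()] object.
#' @param t Time(s) since the dose, hours, >= 0. Vectorised.
#' @return Concentration(s) in ng/mL; 0 at `t = 0`.
#' @export
conc_single_dose <- function(dose, p, t) {
  stopifnot(inherits(p, "pk_parameters"))
  if (any(t < 0)) stop("negative time")
  conc_profile(dose, p$cl, p$v, p$ka, t)
}

#' Multiple-dose regimen
#'
#' @param dose mg per administration (scalar, or one value per dose).
#' @param interval Dosing interval tau in hours, > 0.
#' @param n_doses Number of administrations, >= 1.
#' @return An object of class `pk_regimen`.
#' @export
pk_regimen <- function(dose, interval, n_doses) {
  stopifnot(all(dose >= 0), interval > 0, n_doses >= 1)
  dose <- rep_len(dose, n_doses)
  structure(list(dose = dose, interval = interval, n_doses = as.integer(n_doses)),
            class = "pk_regimen")
}

#' Concentration under repeated dosing (linear superposition)
#'
#' Sum of [conc_single_dose()] contributions from every administration at or
#' before `t`; doses are given at times `0, tau, 2 tau, ...`.
#'
#' @param regimen A [pk_regimen()].
#' @param p A [pk_parameters()] object.
#' @param t Time(s) since the first dose, hours. Vectorised.
#' @return Concentration(s) in ng/mL.
#' @export
conc_multi_dose <- function(regimen, p, t) {
  stopifnot(inherits(regimen, "pk_regimen"), inherits(p, "pk_parameters"))
  if (any(t < 0)) stop("negative time")
  dose_times <- (seq_len(regimen$n_doses) - 1) * regimen$interval
  out <- numeric(length(t))
  for (k in seq_along(dose_times)) {
    el <- t - dose_times[k]
    on <- el >= 0
    if (any(on)) {
      out[on] <- out[on] + conc_single_dose(regimen$dose[k], p, el[on])
    }
  }
  out
}

#' Steady-state concentration within a dosing interval
#'
#' Closed form for the limit of [conc_multi_dose()] as the number of doses
#' grows:
#' `C_ss(t) = 1000 (dose/V) Ka/(Ka-ke) [exp(-ke t)/(1-exp(-ke tau)) -
#'  exp(-Ka t)/(1-exp(-Ka tau))]`.
#' Because drug enters the gut (not plasma) at dose time, the profile is
#' continuous across doses and `C_ss(0)` is the trough.
#'
#' @param dose mg per administration.
#' @param tau Dosing interval in hours.
#' @param p A [pk_parameters()] object.
#' @param t_in_interval Time(s) since the last dose, in `[0, tau)`. Vectorised.
#' @return Concentration(s) in ng/mL, strictly positive.
#' @export
conc_steady_state <- function(dose, tau, p, t_in_interval) {
  stopifnot(inherits(p, "pk_parameters"), tau > 0)
  if (any(t_in_interval < 0) || any(t_in_interval >= tau)) {
    stop("t_in_interval outside [0, tau)")
  }
  ke <- p$ke
  ka <- p$ka
  t <- t_in_interval
  if (abs(ka - ke) / ka < 1e-8) {
    # ka -> ke limit: summing (dose/v) ka s exp(-ka s) over s = t + n tau gives
    # (dose/v) ka exp(-ka t) [ t/(1-E) + tau E/(1-E)^2 ] with E = exp(-ka tau)
    E <- exp(-ka * tau)
    mgL <- (dose / p$v) * ka * exp(-ka * t) * (t / (1 - E) + tau * E / (1 - E)^2)
  } else {
    mgL <- (dose / p$v) * (ka / (ka - ke)) *
      (exp(-ke * t) / (1 - exp(-ke * tau)) -
         exp(-ka * t) / (1 - exp(-ka * tau)))
  }
  1000 * mgL
}
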