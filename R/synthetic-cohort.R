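#' Configuration of a synthetic TDM cohort
#'
#' The defaults emulate the source cohort the analysis pipeline expects:
#' 96 schizophrenic patients contributing ~154 sparse quetiapine
#' concentrations (each subject 1 or 2 samples, mean 154/96), body weight
#' Normal(70.88, 16.84) kg truncated to the 40-120 kg simulation span,
#' fluvoxamine and duloxetine flags each present in 2/96 subjects, and the
#' final-model parameters as generating truth. Prevalences and design
#' richness are configurable upward for power in recovery tests.
#'
#' Demographic columns with *no* effect in the generative model (`AGE`,
#' `SEX`, `ALB`, `CRE`, drawn at the reported cohort means/SDs) are included
#' so covariate selection has true-negative candidates.
#'
#' @param n_subjects Number of subjects.
#' @param n_obs_min,n_obs_max,n_obs_mean Observations per subject: an
#'   integer drawn between min and max with the given mean.
#' @param weight_mean,weight_sd,weight_range Truncated-normal weight model
#'   (kg).
#' @param flu_prevalence,dul_prevalence Bernoulli probabilities of the
#'   comedication flags.
#' @param daily_dose Maintenance dose in mg/day (split every `interval` h).
#' @param interval Dosing interval in hours.
#' @param n_doses Number of administrations before the sampling window (14
#'   q12h doses = 7 days, comfortably past steady state for a ~14 h
#'   half-life).
#' @param sampling `"trough"` (samples at the end of the final dosing
#'   intervals, TDM practice), `"uniform"` (uniform within those intervals,
#'   which also covers the absorption phase), or `"mixed"` (first sample
#'   uniform within the first dosing interval, the rest as `"uniform"`;
#'   first-dose sampling is what makes V/F identifiable from two points per
#'   subject).
#' @param truth Generating [population_model()].
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 96, n_obs_min = 1, n_obs_max = 2,
                          n_obs_mean = 154 / 96,
                          weight_mean = 70.88, weight_sd = 16.84,
                          weight_range = c(40, 120),
                          flu_prevalence = 2 / 96, dul_prevalence = 2 / 96,
                          daily_dose = 600, interval = 12, n_doses = 14,
                          sampling = c("trough", "uniform", "mixed"),
                          truth = population_model(), seed = NULL) {
  sampling <- match.arg(sampling)
  stopifnot(n_subjects >= 1,
            n_obs_min >= 1, n_obs_max >= n_obs_min,
            n_obs_mean >= n_obs_min, n_obs_mean <= n_obs_max,
            weight_range[1] < weight_range[2], weight_range[1] > 0,
            flu_prevalence >= 0, flu_prevalence <= 1,
            dul_prevalence >= 0, dul_prevalence <= 1,
            daily_dose > 0, interval > 0, n_doses >= 1,
            n_obs_max <= n_doses,
            inherits(truth, "population_model"))
  structure(as.list(environment()), class = "cohort_config")
}

rtrunc_norm <- function(n, mean, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Generate a synthetic TDM cohort
#'
#' Per subject: draw weight, comedication flags and demographic columns;
#' draw `eta ~ N(0, omega2)` and form individual parameters through the
#' covariate model; lay down the dosing history; sample observation times
#' per the sampling policy; and observe `D = F + F eps1 + eps2` with the
#' combined residual-error model. Negative simulated concentrations are
#' handled by redrawing `eps2` (truncated additive noise, avoiding a point
#' mass at zero); the number of redraws is recorded in the `n_redrawn`
#' attribute. Fully reproducible from the config seed.
#'
#' @param cfg A [cohort_config()].
#' @return A [tdm_dataset()] with attributes `config`, `eta` (the true
#'   random effects) and `n_redrawn`.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  m <- cfg$truth
  with_seed(cfg$seed, {
    n <- cfg$n_subjects
    wt <- rtrunc_norm(n, cfg$weight_mean, cfg$weight_sd, cfg$weight_range)
    flu <- stats::rbinom(n, 1, cfg$flu_prevalence)
    dul <- stats::rbinom(n, 1, cfg$dul_prevalence)
    age <- rtrunc_norm(n, 43.53, 14.17, c(18, 90))
    sex <- stats::rbinom(n, 1, 44 / 96)
    alb <- rtrunc_norm(n, 41.39, 3.27, c(25, 60))
    cre <- rtrunc_norm(n, 63.64, 15.19, c(20, 150))
    span <- cfg$n_obs_max - cfg$n_obs_min
    n_obs <- cfg$n_obs_min +
      if (span > 0) stats::rbinom(n, span, (cfg$n_obs_mean - cfg$n_obs_min) / span)
      else rep(0L, n)
    eta <- stats::rnorm(n, 0, sqrt(m$omega2_cl))
    typ <- typical_from_covariates(m, data.frame(WT = wt, FLU = flu, DUL = dul))
    dose_amt <- cfg$daily_dose * cfg$interval / 24
    dose_times <- (seq_len(cfg$n_doses) - 1) * cfg$interval
    reg <- pk_regimen(dose_amt, cfg$interval, cfg$n_doses)
    n_redrawn <- 0L
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      k <- n_obs[i]
      if (cfg$sampling == "mixed" && k >= 2) {
        # one absorption-phase sample after the first dose, rest at steady
        # state in the final intervals
        k_ss <- k - 1
        int_lo <- (cfg$n_doses - k_ss + seq_len(k_ss) - 1) * cfg$interval
        t_obs <- c(stats::runif(1, 0, cfg$interval),
                   sort(int_lo + stats::runif(k_ss, 0, cfg$interval)))
      } else {
        # observations fall in the last k dosing intervals
        int_lo <- (cfg$n_doses - k + seq_len(k) - 1) * cfg$interval
        t_obs <- if (cfg$sampling == "trough") int_lo + cfg$interval
                 else sort(int_lo + stats::runif(k, 0, cfg$interval))
      }
      p_i <- individual_parameters(
        pk_parameters(typ$cl[i], typ$v[i], typ$ka[i]), eta[i])
      f <- conc_multi_dose(reg, p_i, t_obs)
      eps1 <- stats::rnorm(k, 0, sqrt(m$sigma2_prop))
      d <- f + f * eps1 + stats::rnorm(k, 0, sqrt(m$sigma2_add))
      # negative observations: redraw the residual pair (eps1, eps2) -- with
      # a proportional-error SD ~0.5, 1 + eps1 < 0 happens and no additive
      # redraw alone could rescue such a draw
      while (any(d < 0)) {
        bad <- d < 0
        n_redrawn <- n_redrawn + sum(bad)
        d[bad] <- f[bad] * (1 + stats::rnorm(sum(bad), 0, sqrt(m$sigma2_prop))) +
          stats::rnorm(sum(bad), 0, sqrt(m$sigma2_add))
      }
      id <- sprintf("S%03d", i)
      rows[[i]] <- data.frame(
        ID = id,
        TIME = c(dose_times, t_obs),
        AMT = c(rep(dose_amt, cfg$n_doses), rep(NA_real_, k)),
        DV = c(rep(NA_real_, cfg$n_doses), d),
        EVID = c(rep(1, cfg$n_doses), rep(0, k)),
        WT = wt[i], FLU = flu[i], DUL = dul[i],
        AGE = age[i], SEX = sex[i], ALB = alb[i], CRE = cre[i],
        stringsAsFactors = FALSE)
    }
    ds <- tdm_dataset(do.call(rbind, rows), validate = TRUE)
    attr(ds, "config") <- cfg
    attr(ds, "eta") <- eta
    attr(ds, "n_redrawn") <- n_redrawn
    ds
  })
}

#' Family of datasets for parameter-recovery studies
#'
#' Builds a deterministic list of synthetic cohorts spanning sparse to rich
#' sampling designs and low to high comedication prevalence, for use by
#' estimation tests.
#'
#' @param truth Generating [population_model()].
#' @param scenarios List of lists; each may override `n_subjects`,
#'   `n_obs_min`/`n_obs_max`/`n_obs_mean` (or the shorthand `n_obs` for a
#'   fixed count), `flu_prevalence`, `dul_prevalence`, `sampling` and must
#'   supply a `seed`. A `name` element labels the dataset.
#' @return Named list of [tdm_dataset()] objects.
#' @export
generate_recovery_suite <- function(truth = population_model(),
                                    scenarios = default_recovery_scenarios()) {
  out <- list()
  for (sc in scenarios) {
    sc <- as.list(sc)
    name <- sc$name %||% paste0("scenario", length(out) + 1)
    sc$name <- NULL
    if (!is.null(sc$n_obs)) {
      sc$n_obs_min <- sc$n_obs_max <- sc$n_obs_mean <- sc$n_obs
      sc$n_obs <- NULL
    }
    cfg <- do.call(cohort_config, c(sc, list(truth = truth)))
    out[[name]] <- generate_cohort(cfg)
  }
  out
}

#' Default recovery scenarios (sparse and rich, low and high prevalence)
#' @return A list of scenario lists for [generate_recovery_suite()].
#' @export
default_recovery_scenarios <- function() {
  list(
    list(name = "sparse_default", n_subjects = 96, seed = 101),
    list(name = "sparse_boosted", n_subjects = 96, flu_prevalence = 0.25,
         dul_prevalence = 0.25, sampling = "uniform", seed = 102),
    list(name = "rich", n_subjects = 96, n_obs = 8, flu_prevalence = 0.25,
         dul_prevalence = 0.25, sampling = "uniform", seed = 103)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
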