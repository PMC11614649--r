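# Independent oracles and small fixture builders (all fixtures are built in
# code; nothing is read from disk).

# Matrix-exponential solution of the two-compartment linear ODE system
#   dA_gut/dt = -ka A_gut ; dA_c/dt = ka A_gut - ke A_c
# with bolus additions to the gut at the dose times. Exact to machine
# precision; independent of the package's closed-form path.
ode_conc_oracle <- function(dose_times, dose_amts, cl, v, ka, t) {
  M <- matrix(c(-ka, ka, 0, -cl / v), 2, 2)
  vapply(t, function(tt) {
    st <- c(0, 0)
    prev <- 0
    for (k in seq_along(dose_times)) {
      td <- dose_times[k]
      if (td > tt) break
      st <- as.vector(Matrix::expm(M * (td - prev)) %*% st)
      st[1] <- st[1] + dose_amts[k]
      prev <- td
    }
    st <- as.vector(Matrix::expm(M * (tt - prev)) %*% st)
    1000 * st[2] / v
  }, numeric(1))
}

# final-model values (the package defaults) as a shorthand
final_model <- function(...) population_model(...)

# minimal two-subject event table: 1 dose + 2 observations each
tiny_event_df <- function() {
  data.frame(
    ID = rep(c("A", "B"), each = 3),
    TIME = c(0, 2, 6, 0, 3, 8),
    AMT = c(300, NA, NA, 400, NA, NA),
    DV = c(NA, 150, 120, NA, 180, 140),
    EVID = c(1, 0, 0, 1, 0, 0),
    WT = rep(c(70, 85), each = 3),
    FLU = rep(c(0, 1), each = 3),
    DUL = 0,
    stringsAsFactors = FALSE
  )
}

# noise-free cohort at a given truth (all etas and residuals zero)
noiseless_cohort <- function(n = 6, truth = population_model(),
                             sampling = "trough", seed = 7) {
  tr <- truth
  tr$omega2_cl <- 0
  tr$sigma2_prop <- 0
  tr$sigma2_add <- 0
  generate_cohort(cohort_config(
    n_subjects = n, n_obs_min = 2, n_obs_max = 2, n_obs_mean = 2,
    flu_prevalence = 0, dul_prevalence = 0, sampling = sampling,
    truth = tr, seed = seed))
}

# standard fit initials away from the truth (shared across tests so no
# test tunes its own starting point)
generic_init <- function(covariates = NULL) {
  population_model(theta_cl = 60, theta_v = 1500, theta_flu = -0.2,
                   theta_dul = -0.2, omega2_cl = 0.2, sigma2_prop = 0.1,
                   sigma2_add = 10, covariates = covariates)
}

# base model with allometric weight scaling only (no DDI covariates)
base_model_no_ddi <- function(theta_cl = 60, theta_v = 1500,
                              omega2_cl = 0.2, sigma2_prop = 0.1,
                              sigma2_add = 10) {
  population_model(
    theta_cl = theta_cl, theta_v = theta_v, omega2_cl = omega2_cl,
    sigma2_prop = sigma2_prop, sigma2_add = sigma2_add,
    covariates = list(
      covariate_effect("cl", "WT", "allometric", 0.75, reference = 70),
      covariate_effect("v", "WT", "allometric", 1, reference = 70)))
}

# fabricate a ppk_fit at known parameters/modes (for diagnostics tests that
# need a "fit" at the truth without running the optimiser)
fit_at <- function(model, ds) {
  modes <- conditional_modes(ds, model)
  structure(list(model = model, ofv = as.numeric(foce_ofv(ds, model)),
                 se_percent = NULL, eta_hat = modes, converged = TRUE,
                 boundary = FALSE, trace = NULL, message = "constructed",
                 n_subjects = n_subjects(ds),
                 n_observations = n_observations(ds), fix = character(0)),
            class = "ppk_fit")
}
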