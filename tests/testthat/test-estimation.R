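# shared small fixture: one subject, 14 doses q12h, manual observations
one_subject_ds <- function(dv, t_obs, wt = 70, n_doses = 14, amt = 300) {
  k <- length(dv)
  tdm_dataset(data.frame(
    ID = "S1",
    TIME = c((0:(n_doses - 1)) * 12, t_obs),
    AMT = c(rep(amt, n_doses), rep(NA, k)),
    DV = c(rep(NA, n_doses), dv),
    EVID = c(rep(1, n_doses), rep(0, k)),
    WT = wt, FLU = 0, DUL = 0, stringsAsFactors = FALSE))
}

pred_R <- function(ds, m, eta = 0) {
  # R-side prediction path, independent of the C++ engine
  sub1 <- ds[!duplicated(ds$ID), , drop = FALSE]
  out <- numeric(0)
  for (id in unique(ds$ID)) {
    sub <- ds[ds$ID == id, , drop = FALSE]
    typ <- typical_parameters(sub$WT[1], sub$FLU[1], sub$DUL[1], m)
    p <- individual_parameters(typ, eta)
    dose <- sub[sub$EVID == 1, ]
    obs <- sub[sub$EVID == 0, ]
    f <- vapply(obs$TIME, function(tt) {
      el <- tt - dose$TIME
      sum(vapply(which(el >= 0), function(k)
        conc_single_dose(dose$AMT[k], p, el[k]), numeric(1)))
    }, numeric(1))
    out <- c(out, f)
  }
  out
}

test_that("individual objective matches the -2 log joint density", {
  m <- population_model(sigma2_prop = 0, sigma2_add = 4, omega2_cl = 0.333)
  # zero residual leaves only the ln-variance term (eta prior dropped)
  t_obs <- 168
  f <- pred_R(one_subject_ds(1, t_obs), m)
  ds0 <- one_subject_ds(f, t_obs)
  expect_equal(individual_objective(ds0, m, 0) - log(m$omega2_cl), log(4))

  # doubling the residual with fixed g2 adds 3 (d-f)^2 / g2
  r <- 5
  v1 <- individual_objective(one_subject_ds(f + r, t_obs), m, 0)
  v2 <- individual_objective(one_subject_ds(f + 2 * r, t_obs), m, 0)
  expect_equal(v2 - v1, 3 * r^2 / 4, tolerance = 1e-10)

  # full Gaussian density oracle on a random small case
  set.seed(42)
  mm <- final_model()
  dv <- c(180, 140)
  tt <- c(157, 168)
  eta <- 0.31
  ds <- one_subject_ds(dv, tt)
  f_eta <- pred_R(ds, mm, eta)
  g2 <- residual_variance(f_eta, mm)
  dens <- sum(stats::dnorm(dv, f_eta, sqrt(g2), log = TRUE)) +
    stats::dnorm(eta, 0, sqrt(mm$omega2_cl), log = TRUE)
  expect_equal(individual_objective(ds, mm, eta),
               -2 * dens - (length(dv) + 1) * log(2 * pi),
               tolerance = 1e-8)
})

test_that("conditional modes recover the generating eta", {
  # additive-only error: noise-free data at eta = 0 gives a mode at 0
  m_add <- population_model(sigma2_prop = 0, sigma2_add = 25,
                            omega2_cl = 0.333)
  f <- pred_R(one_subject_ds(c(1, 1), c(157, 168)), m_add)
  ds0 <- one_subject_ds(f, c(157, 168))
  expect_lt(abs(conditional_modes(ds0, m_add)[["S1"]]), 1e-4)

  # rich design, tiny residual: mode near the generating eta = 0.5
  m_tiny <- population_model(sigma2_prop = 1e-6, sigma2_add = 0.01,
                             omega2_cl = 0.333)
  tt <- 156 + c(0.5, 1, 2, 4, 6, 8, 10, 12)
  f5 <- pred_R(one_subject_ds(rep(1, 8), tt), m_tiny, eta = 0.5)
  ds5 <- one_subject_ds(f5, tt)
  mode5 <- conditional_modes(ds5, m_tiny)[["S1"]]
  expect_gt(mode5, 0.45)
  expect_lt(mode5, 0.55)

  # brute-force grid oracle on a noisy subject
  mm <- final_model()
  set.seed(7)
  dsn <- one_subject_ds(f * exp(stats::rnorm(2, 0, 0.4)), c(157, 168))
  grid <- seq(-3, 3, by = 1e-3)
  lvals <- vapply(grid, function(e) individual_objective(dsn, mm, e),
                  numeric(1))
  expect_equal(conditional_modes(dsn, mm)[["S1"]], grid[which.min(lvals)],
               tolerance = 1.5e-3)
})

test_that("OFV reduces to the fixed-effects -2LL as omega2 -> 0", {
  ds <- generate_cohort(cohort_config(n_subjects = 10, seed = 55,
                                      sampling = "uniform"))
  m0 <- final_model()
  m0$omega2_cl <- 0
  f0 <- pred_R(ds, m0)
  obs <- ds[ds$EVID == 0, ]
  g2 <- residual_variance(f0, m0)
  closed <- sum((obs$DV - f0)^2 / g2 + log(g2))
  expect_equal(as.numeric(foce_ofv(ds, m0)), closed, tolerance = 1e-6)
  # and equals the sum of per-subject conditional objectives at eta = 0
  per_sub <- vapply(unique(ds$ID), function(id)
    individual_objective(tdm_dataset(ds[ds$ID == id, ], validate = FALSE),
                         m0, 0), numeric(1))
  expect_equal(as.numeric(foce_ofv(ds, m0)), sum(per_sub), tolerance = 1e-8)
})

test_that("OFV is additive over duplicated rows and order-invariant", {
  ds <- generate_cohort(cohort_config(n_subjects = 6, seed = 21))
  m0 <- final_model()
  m0$omega2_cl <- 0  # eta-fixed limit
  base <- as.numeric(foce_ofv(ds, m0))
  obs_rows <- which(ds$EVID == 0)
  dup <- tdm_dataset(rbind(as.data.frame(ds),
                           as.data.frame(ds)[obs_rows[1], ]),
                     validate = FALSE)
  extra <- as.numeric(foce_ofv(dup, m0)) - base
  f0 <- pred_R(ds, m0)
  g2 <- residual_variance(f0[1], m0)
  expect_equal(extra, (ds$DV[obs_rows[1]] - f0[1])^2 / g2 + log(g2),
               tolerance = 1e-8)

  m <- final_model()
  rev_ds <- tdm_dataset(do.call(rbind, lapply(rev(unique(ds$ID)), function(id)
    as.data.frame(ds[ds$ID == id, ]))), validate = FALSE)
  expect_equal(as.numeric(foce_ofv(rev_ds, m)), as.numeric(foce_ofv(ds, m)),
               tolerance = 1e-10)
})

test_that("fitting is a fixed point and flags degenerate problems", {
  ds <- generate_cohort(cohort_config(
    n_subjects = 30, n_obs_min = 2, n_obs_max = 2, n_obs_mean = 2,
    flu_prevalence = 0.25, dul_prevalence = 0.25, sampling = "mixed",
    seed = 314))
  fit <- fit_model(ds, init = generic_init(), se = FALSE)
  expect_true(fit$converged)
  refit <- fit_model(ds, init = fit$model, se = FALSE)
  expect_lt(abs(refit$ofv - fit$ofv), 1e-6 * max(1, abs(fit$ofv)))

  # one subject, flat data: boundary / non-convergence, never silence
  flat <- one_subject_ds(c(150, 150), c(157, 168))
  flat_fit <- suppressWarnings(
    fit_model(flat, init = generic_init(), se = TRUE))
  expect_true(!flat_fit$converged || flat_fit$boundary ||
                any(is.na(flat_fit$se_percent)))

  # initialization error contract
  bad_init <- generic_init()
  bad_init$sigma2_add <- 0
  bad_init$sigma2_prop <- 0
  expect_error(fit_model(ds, init = bad_init), "initial values")
})
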