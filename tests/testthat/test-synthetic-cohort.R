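test_that("noise-free limit reproduces the structural predictions", {
  ds <- noiseless_cohort(n = 5, seed = 23)
  cfg <- attr(ds, "config")
  reg <- pk_regimen(cfg$daily_dose * cfg$interval / 24, cfg$interval,
                    cfg$n_doses)
  for (id in unique(ds$ID)) {
    sub <- ds[ds$ID == id, ]
    obs <- sub[sub$EVID == 0, ]
    p <- typical_parameters(sub$WT[1], sub$FLU[1], sub$DUL[1], cfg$truth)
    expect_equal(obs$DV, conc_multi_dose(reg, p, obs$TIME), tolerance = 1e-10)
  }
})

test_that("default cohort matches the emulated study dimensions", {
  ds <- generate_cohort(cohort_config(seed = 24))
  expect_identical(n_subjects(ds), 96L)
  expect_gte(n_observations(ds), 96L)
  expect_lte(n_observations(ds), 192L)
  expect_identical(nrow(validate_tdm(ds)), 0L)
  # covariates present for the stepwise search
  expect_true(all(c("AGE", "SEX", "ALB", "CRE") %in% names(ds)))
})

test_that("weights follow the truncated normal and eta has variance omega2", {
  # analytic truncated-normal mean as oracle (the raw mean 70.88 shifts to
  # ~72.1 after truncation to [40, 120])
  a <- (40 - 70.88) / 16.84
  b <- (120 - 70.88) / 16.84
  mean_trunc <- 70.88 + 16.84 * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
  ds <- generate_cohort(cohort_config(n_subjects = 4000, n_obs_min = 1,
                                      n_obs_max = 1, n_obs_mean = 1,
                                      n_doses = 2, seed = 25))
  wts <- ds$WT[!duplicated(ds$ID)]
  expect_lt(abs(mean(wts) - mean_trunc), 1)
  expect_true(all(wts >= 40 & wts <= 120))

  ds2 <- generate_cohort(cohort_config(n_subjects = 5000, n_obs_min = 1,
                                       n_obs_max = 1, n_obs_mean = 1,
                                       n_doses = 2, weight_sd = 1e-9,
                                       weight_mean = 70, seed = 26))
  expect_lt(abs(stats::var(attr(ds2, "eta")) / 0.333 - 1), 0.05)
})

test_that("comedication flags follow the configured prevalence", {
  counts <- vapply(1:20, function(s) {
    ds <- generate_cohort(cohort_config(n_subjects = 96, n_obs_min = 1,
                                        n_obs_max = 1, n_obs_mean = 1,
                                        n_doses = 2, seed = 400 + s))
    sum(ds$FLU[!duplicated(ds$ID)])
  }, numeric(1))
  # pooled count ~ Binomial(1920, 2/96): mean 40, sd ~6.2
  expect_gt(sum(counts), 40 - 20)
  expect_lt(sum(counts), 40 + 20)
})

test_that("generation is seed-deterministic and validates under all policies", {
  for (pol in c("trough", "uniform", "mixed")) {
    cfg <- cohort_config(n_subjects = 15, sampling = pol, seed = 27,
                         n_obs_min = 2, n_obs_max = 2, n_obs_mean = 2)
    d1 <- generate_cohort(cfg)
    d2 <- generate_cohort(cfg)
    expect_identical(as.data.frame(d1), as.data.frame(d2))
    expect_identical(nrow(validate_tdm(d1)), 0L)
  }
})

test_that("recovery suite is deterministic and spans sparse to rich designs", {
  s1 <- generate_recovery_suite()
  s2 <- generate_recovery_suite()
  expect_identical(names(s1), c("sparse_default", "sparse_boosted", "rich"))
  expect_identical(as.data.frame(s1$rich), as.data.frame(s2$rich))
  expect_identical(n_subjects(s1$sparse_default), 96L)
  # the rich design carries 8 observations per subject
  expect_identical(n_observations(s1$rich), 96L * 8L)
  # the sparse default mirrors the default cohort dimensions
  expect_lte(n_observations(s1$sparse_default), 192L)
})

test_that("rich designs recover the volume better than sparse ones", {
  # at equal subject count the typical-clearance error is floored by the
  # realized mean of the subject-level etas (omega/sqrt(96) ~ 6%), so design
  # richness shows up in the sampling-time-sensitive parameter V/F
  scenarios <- c(
    lapply(1:3, function(k) list(name = paste0("sp", k), n_subjects = 96,
                                 flu_prevalence = 0.25, dul_prevalence = 0.25,
                                 sampling = "uniform", seed = 200 + k)),
    lapply(1:3, function(k) list(name = paste0("ri", k), n_subjects = 96,
                                 n_obs = 8,
                                 flu_prevalence = 0.25, dul_prevalence = 0.25,
                                 sampling = "uniform", seed = 300 + k)))
  suite <- generate_recovery_suite(scenarios = scenarios)
  err <- vapply(suite, function(ds) {
    fit <- fit_model(ds, init = generic_init(), se = FALSE)
    abs(coef(fit)[["theta_v"]] - 2460) / 2460
  }, numeric(1))
  expect_lt(stats::median(err[c("ri1", "ri2", "ri3")]),
            stats::median(err[c("sp1", "sp2", "sp3")]))
})
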