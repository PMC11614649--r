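test_that("attainment and exceedance are exact fractions", {
  expect_equal(attainment_probability(c(150, 200, 499), c(100, 500)), 1)
  expect_equal(attainment_probability(c(50, 150, 600), c(100, 500)), 1 / 3)
  expect_equal(exceedance_probability(c(400, 501), 500), 0.5)
  expect_equal(exceedance_probability(c(100, 200), 500), 0)
  expect_error(attainment_probability(numeric(0)), "empty")
  expect_error(exceedance_probability(numeric(0)), "empty")
  # counting oracle + partition identity on random samples
  set.seed(303)
  x <- stats::runif(1e4, 0, 800)
  n_in <- 0; n_up <- 0
  for (xi in x) {
    if (xi > 500) n_up <- n_up + 1
    else if (xi >= 100) n_in <- n_in + 1
  }
  expect_equal(attainment_probability(x, c(100, 500)), n_in / 1e4)
  expect_equal(exceedance_probability(x, 500), n_up / 1e4)
  below <- mean(x < 100)
  expect_equal(attainment_probability(x, c(100, 500)) +
                 exceedance_probability(x, 500) + below, 1)
})

test_that("degenerate population gives all-or-nothing attainment", {
  m <- final_model()
  m$omega2_cl <- 0
  des <- simulation_design(weights = c(60, 100), doses = c(1, 12),
                           n_virtual = 50, conditions = "none", seed = 1)
  pta <- simulate_virtual_patients(m, des)
  expect_true(all(pta$grid$p_target %in% c(0, 1)))
  expect_true(all(pta$grid$p_target + pta$grid$p_exceed +
                    pta$grid$p_below == 1))
})

test_that("nonpositive doses are skipped with a warning", {
  des <- simulation_design(weights = 70, doses = c(0, 12), n_virtual = 10,
                           conditions = "none", seed = 2)
  expect_warning(pta <- simulate_virtual_patients(final_model(), des),
                 "skipped")
  expect_identical(unique(pta$grid$dose), 12)
})

test_that("Monte Carlo attainment matches the closed-form eta integral", {
  m <- final_model()
  des <- simulation_design(weights = 70, doses = 12, n_virtual = 1000,
                           conditions = "none", seed = 33)
  pta <- simulate_virtual_patients(m, des)
  # trough is strictly decreasing in eta, so P(100 <= C <= 500) is a normal
  # probability between the eta solutions of C = upper and C = lower
  typ <- typical_parameters(70, 0, 0, m)
  trough <- function(eta) {
    conc_steady_state(12 * 70 / 2, 12,
                      pk_parameters(typ$cl * exp(eta), typ$v, typ$ka), 0)
  }
  sd_eta <- sqrt(m$omega2_cl)
  eta_at <- function(target)
    stats::uniroot(function(e) trough(e) - target, c(-8, 8),
                   tol = 1e-12)$root
  p_exact <- stats::pnorm(eta_at(100), 0, sd_eta) -
    stats::pnorm(eta_at(500), 0, sd_eta)
  se <- sqrt(p_exact * (1 - p_exact) / 1000)
  expect_lt(abs(pta$grid$p_target - p_exact), 3 * se)
})

test_that("exceedance is monotone in dose and DDI ordering holds", {
  m <- final_model()
  des <- simulation_design(n_virtual = 300, seed = 44)
  pta <- simulate_virtual_patients(m, des)
  g <- pta$grid
  for (cond in unique(g$condition)) {
    for (w in unique(g$weight)) {
      cell <- g[g$condition == cond & g$weight == w, ]
      expect_true(all(diff(cell$p_exceed[order(cell$dose)]) >= 0))
    }
  }
  # mean simulated concentration: both > flu ~ dul > none (clearance
  # fractions 0.2148 < 0.463 ~ 0.464 < 1)
  mean_conc <- function(cond)
    mean(pta$samples[[sprintf("%s_w80_d12", cond)]])
  expect_gt(mean_conc("both"), mean_conc("flu"))
  expect_gt(mean_conc("both"), mean_conc("dul"))
  expect_gt(mean_conc("flu"), mean_conc("none"))
  expect_gt(mean_conc("dul"), mean_conc("none"))
  expect_lt(abs(mean_conc("flu") / mean_conc("dul") - 1), 0.15)
})

test_that("identical design and seed reproduce the PTA bit for bit", {
  m <- final_model()
  des <- simulation_design(weights = c(40, 80), doses = c(4, 12),
                           n_virtual = 200, seed = 55)
  p1 <- simulate_virtual_patients(m, des)
  p2 <- simulate_virtual_patients(m, des)
  expect_identical(p1$grid, p2$grid)
  expect_identical(p1$samples, p2$samples)
})

test_that("dose recommendation picks the argmax, breaks ties low, merges ranges", {
  fake_grid <- expand.grid(condition = "none",
                           weight = c(40, 60, 80, 100, 120),
                           dose = c(4, 8, 12, 16),
                           stringsAsFactors = FALSE)
  # 40 kg favours 16; heavier groups favour 12
  fake_grid$p_target <- with(fake_grid, ifelse(
    weight == 40,
    c(`4` = 0.50, `8` = 0.80, `12` = 0.90, `16` = 0.94)[as.character(dose)],
    c(`4` = 0.55, `8` = 0.85, `12` = 0.95, `16` = 0.90)[as.character(dose)]))
  fake_grid$p_exceed <- 0.01
  pta <- structure(list(grid = fake_grid, samples = list(), design = NULL),
                   class = "pta_result")
  rec <- recommend_doses(pta)
  expect_identical(nrow(rec), 2L)
  expect_equal(rec$dose, c(16, 12))
  expect_equal(rec$weight_lo, c(40, 60))
  expect_equal(rec$weight_hi, c(60, 120))
  expect_identical(rec$weight_hi_closed, c(FALSE, TRUE))

  # tie within tolerance goes to the lower dose
  tie <- fake_grid[fake_grid$weight == 40, ]
  tie$p_target <- c(0.90, 0.938, 0.936, 0.94)[match(tie$dose, c(4, 8, 12, 16))]
  pta2 <- structure(list(grid = tie, samples = list(), design = NULL),
                    class = "pta_result")
  expect_equal(recommend_doses(pta2, tie_tol = 0.005)$dose, 8)
})
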