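ddi_flags <- function(condition) {
  switch(condition,
         none = c(flu = 0, dul = 0),
         flu = c(flu = 1, dul = 0),
         dul = c(flu = 0, dul = 1),
         both = c(flu = 1, dul = 1),
         stop("unknown DDI condition: ", condition))
}

#' Design of a Monte Carlo dose-finding simulation
#'
#' Defaults mirror the published simulation layout: 1,000 virtual patients
#' per cell over five weight groups (40-120 kg), eight daily-dose groups
#' (1-28 mg/kg/day), four comedication conditions, and the 100-500 ng/mL
#' therapeutic window. The dosing interval, evaluated concentration metric
#' and residual-error inclusion are not pinned down by the published design,
#' so all three are explicit switches; the default policy is the total daily
#' dose split every 12 h (immediate-release practice), evaluated at the
#' steady-state trough, with between-subject variability on and residual
#' error off.
#'
#' @param weights Weight grid in kg.
#' @param doses Dose grid in mg/kg/day.
#' @param n_virtual Virtual patients per (weight, dose, condition) cell.
#' @param conditions Subset of `c("none", "flu", "dul", "both")`.
#' @param window Therapeutic window `c(lower, upper)` in ng/mL.
#' @param interval Dosing interval tau in hours (the daily dose is split
#'   into `24 / interval` administrations).
#' @param metric `"trough"` (steady-state trough), `"cavg"` (steady-state
#'   average over the interval, `1000 * dose / (CL * tau)`), or `"cmax"`
#'   (steady-state peak, located numerically).
#' @param include_residual Add combined residual error to each virtual
#'   patient's evaluated concentration.
#' @param seed Integer seed.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(weights = c(40, 60, 80, 100, 120),
                              doses = c(1, 4, 8, 12, 16, 20, 24, 28),
                              n_virtual = 1000,
                              conditions = c("none", "flu", "dul", "both"),
                              window = c(100, 500), interval = 12,
                              metric = c("trough", "cavg", "cmax"),
                              include_residual = FALSE, seed = NULL) {
  metric <- match.arg(metric)
  conditions <- match.arg(conditions, c("none", "flu", "dul", "both"),
                          several.ok = TRUE)
  stopifnot(length(weights) > 0, all(weights > 0),
            length(doses) > 0, n_virtual >= 1,
            length(window) == 2, window[1] < window[2],
            interval > 0, 24 %% interval == 0)
  structure(list(weights = weights, doses = doses, n_virtual = n_virtual,
                 conditions = conditions, window = window,
                 interval = interval, metric = metric,
                 include_residual = include_residual, seed = seed),
            class = "simulation_design")
}

# steady-state metric for vectors of individual parameters (shared v, ka)
ss_metric <- function(dose_mg, tau, cl, v, ka, metric) {
  if (metric == "cavg") return(1000 * dose_mg / (cl * tau))
  if (metric == "trough") {
    # trough = concentration at dose time (profile continuous across doses);
    # vectorised over individual clearances
    ke <- cl / v
    degen <- abs(ka - ke) / ka < 1e-8
    out <- 1000 * (dose_mg / v) * (ka / (ka - ke)) *
      (1 / (1 - exp(-ke * tau)) - 1 / (1 - exp(-ka * tau)))
    if (any(degen)) {
      E <- exp(-ka * tau)
      out[degen] <- 1000 * (dose_mg / v) * ka * tau * E / (1 - E)^2
    }
    return(out)
  }
  # cmax: maximise over the interval per subject
  vapply(seq_along(cl), function(i) {
    p <- pk_parameters(cl[i], v, ka)
    stats::optimize(function(t) conc_steady_state(dose_mg, tau, p, t),
                    c(0, tau * (1 - 1e-9)), maximum = TRUE,
                    tol = 1e-6)$objective
  }, numeric(1))
}

#' Simulate virtual patients and tally target attainment
#'
#' For every (weight, dose, condition) cell: draw `n_virtual` random effects
#' `eta ~ N(0, omega2)`, form individual CL/F through the covariate model,
#' evaluate the steady-state concentration under the design's regimen
#' policy, optionally perturb with combined residual error, and tally the
#' fractions inside the window (attainment), above its upper limit
#' (exceedance) and below its lower limit. Reproducible given the design
#' seed. Nonpositive doses are skipped with a warning.
#'
#' @param m A [population_model()] with final-model values.
#' @param design A [simulation_design()].
#' @return An object of class `pta_result`: `grid` (data frame with one row
#'   per cell: `condition`, `weight`, `dose`, `p_target`, `p_exceed`,
#'   `p_below`), `samples` (named list of simulated concentration vectors),
#'   `design`.
#' @export
simulate_virtual_patients <- function(m = population_model(),
                                      design = simulation_design()) {
  stopifnot(inherits(m, "population_model"),
            inherits(design, "simulation_design"))
  doses <- design$doses
  if (any(doses <= 0)) {
    warning("nonpositive dose(s) skipped")
    doses <- doses[doses > 0]
  }
  n_admin <- 24 / design$interval
  rows <- list()
  samples <- list()
  with_seed(design$seed, {
    for (cond in design$conditions) {
      fl <- ddi_flags(cond)
      for (w in design$weights) {
        typ <- typical_parameters(w, fl["flu"], fl["dul"], m)
        eta <- stats::rnorm(design$n_virtual, 0, sqrt(m$omega2_cl))
        for (dpd in doses) {
          dose_mg <- dpd * w / n_admin
          cl_i <- typ$cl * exp(eta)
          conc <- ss_metric(dose_mg, design$interval, cl_i, typ$v, typ$ka,
                            design$metric)
          if (design$include_residual) {
            eps1 <- stats::rnorm(length(conc), 0, sqrt(m$sigma2_prop))
            eps2 <- stats::rnorm(length(conc), 0, sqrt(m$sigma2_add))
            conc <- conc + conc * eps1 + eps2
          }
          key <- sprintf("%s_w%g_d%g", cond, w, dpd)
          samples[[key]] <- conc
          rows[[length(rows) + 1]] <- data.frame(
            condition = cond, weight = w, dose = dpd,
            p_target = attainment_probability(conc, design$window),
            p_exceed = exceedance_probability(conc, design$window[2]),
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  grid <- do.call(rbind, rows)
  grid$p_below <- 1 - grid$p_target - grid$p_exceed
  rownames(grid) <- NULL
  structure(list(grid = grid, samples = samples, design = design),
            class = "pta_result")
}

#' Probability of target attainment
#'
#' Fraction of simulated concentrations inside the closed therapeutic
#' window.
#'
#' @param sample Nonempty numeric vector of concentrations, ng/mL.
#' @param window `c(lower, upper)` in ng/mL.
#' @return Fraction in \[0, 1\].
#' @export
attainment_probability <- function(sample, window = c(100, 500)) {
  if (length(sample) == 0) stop("empty sample")
  mean(sample >= window[1] & sample <= window[2])
}

#' Probability of exceeding the window's upper limit
#'
#' The safety measure: fraction of simulated concentrations strictly above
#' `upper`.
#'
#' @param sample Nonempty numeric vector of concentrations, ng/mL.
#' @param upper Upper limit in ng/mL.
#' @return Fraction in \[0, 1\].
#' @export
exceedance_probability <- function(sample, upper = 500) {
  if (length(sample) == 0) stop("empty sample")
  mean(sample > upper)
}

#' Initial-dose recommendation table
#'
#' Per condition and weight, selects the dose maximising the attainment
#' probability; doses whose attainment lies within `tie_tol` of the best are
#' treated as tied and the lowest such dose is recommended. Contiguous
#' weights sharing a recommended dose are merged into ranges (closed on the
#' last group, right-open before a dose change), with the span of attainment
#' and exceedance probabilities across the merged weights.
#'
#' @param pta A `pta_result` covering the full design grid.
#' @param tie_tol Attainment tolerance for ties (absolute fraction,
#'   default 0.005 = 0.5 percentage points).
#' @return An object of class `recommendation_table` (a data frame): one row
#'   per condition and merged weight range with the recommended dose and the
#'   attainment/exceedance ranges in percent.
#' @export
recommend_doses <- function(pta, tie_tol = 0.005) {
  stopifnot(inherits(pta, "pta_result"))
  grid <- pta$grid
  per_weight <- list()
  for (cond in unique(grid$condition)) {
    for (w in sort(unique(grid$weight))) {
      cell <- grid[grid$condition == cond & grid$weight == w, , drop = FALSE]
      cell <- cell[order(cell$dose), , drop = FALSE]
      best <- max(cell$p_target)
      pick <- cell[cell$p_target >= best - tie_tol, , drop = FALSE][1, ]
      per_weight[[length(per_weight) + 1]] <- data.frame(
        condition = cond, weight = w, dose = pick$dose,
        p_target = pick$p_target, p_exceed = pick$p_exceed,
        stringsAsFactors = FALSE)
    }
  }
  pw <- do.call(rbind, per_weight)
  out <- list()
  for (cond in unique(pw$condition)) {
    sub <- pw[pw$condition == cond, , drop = FALSE]
    sub <- sub[order(sub$weight), , drop = FALSE]
    run_start <- 1
    for (i in seq_len(nrow(sub))) {
      last_of_run <- i == nrow(sub) || sub$dose[i + 1] != sub$dose[run_start]
      if (!last_of_run) next
      rng <- run_start:i
      closed <- i == nrow(sub)  # right-open until the dose changes
      out[[length(out) + 1]] <- data.frame(
        condition = cond,
        weight_lo = sub$weight[run_start],
        weight_hi = if (closed) sub$weight[i] else sub$weight[i + 1],
        weight_hi_closed = closed,
        dose = sub$dose[run_start],
        p_target_lo = 100 * min(sub$p_target[rng]),
        p_target_hi = 100 * max(sub$p_target[rng]),
        p_exceed_lo = 100 * min(sub$p_exceed[rng]),
        p_exceed_hi = 100 * max(sub$p_exceed[rng]),
        stringsAsFactors = FALSE)
      run_start <- i + 1
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("recommendation_table", "data.frame")
  tab
}

#' @export
print.recommendation_table <- function(x, ...) {
  cat("<recommendation_table>\n")
  df <- as.data.frame(x)
  df$weight_range <- sprintf("[%g-%g%s", df$weight_lo, df$weight_hi,
                             ifelse(df$weight_hi_closed, "]", ")"))
  df$attainment <- sprintf("%.1f-%.1f%%", df$p_target_lo, df$p_target_hi)
  df$exceedance <- sprintf("%.1f-%.1f%%", df$p_exceed_lo, df$p_exceed_hi)
  print(df[, c("condition", "weight_range", "dose", "attainment",
               "exceedance")], row.names = FALSE)
  invisible(x)
}

#' Write the PTA grid and recommendation table to CSV
#' @param pta A `pta_result`.
#' @param grid_path,table_path Output paths (either may be `NULL` to skip).
#' @param tie_tol Passed to [recommend_doses()].
#' @return Invisibly, the recommendation table.
#' @export
write_pta <- function(pta, grid_path = NULL, table_path = NULL,
                      tie_tol = 0.005) {
  if (!is.null(grid_path)) {
    utils::write.csv(pta$grid, grid_path, row.names = FALSE)
  }
  rec <- recommend_doses(pta, tie_tol = tie_tol)
  if (!is.null(table_path)) {
    utils::write.csv(as.data.frame(rec), table_path, row.names = FALSE)
  }
  invisible(rec)
}
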