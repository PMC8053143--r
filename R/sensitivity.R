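run_pair <- function(start_age, n, seed, params, life_table) {
  seq_arm <- run_cohort(strategy("sequential"), start_age, n, seed,
                        params, life_table)
  mono <- run_cohort(strategy("alendronate_mono"), start_age, n, seed,
                     params, life_table)
  compare_strategies(seq_arm, mono, params$econ)
}

#' Base-case results table
#'
#' Runs both strategies at each starting age with common random numbers and
#' tabulates discounted lifetime cost, QALYs and the ICER of sequential
#' teriparatide/alendronate versus alendronate monotherapy, mirroring the
#' layout of the published base-case table.
#'
#' @param ages Starting ages (default 70, 75, 80).
#' @param n Women per cohort.
#' @param seed Integer seed (shared across arms and ages).
#' @param params A `cea_params` object.
#' @param life_table A `life_table` object.
#' @return Data frame with one row per age and strategy: discounted cost by
#'   sector and in total (yen and USD), QALYs, and the ICER on the
#'   intervention rows.
#' @export
base_case_table <- function(ages = c(70, 75, 80), n = 10000, seed = 1,
                            params = default_parameters(),
                            life_table = make_synthetic_life_table()) {
  rows <- list()
  for (age in ages) {
    mono <- run_cohort(strategy("alendronate_mono"), age, n, seed,
                       params, life_table)
    seq_arm <- run_cohort(strategy("sequential"), age, n, seed,
                          params, life_table)
    cmp <- compare_strategies(seq_arm, mono, params$econ)
    for (r in list(list(coh = mono, icer = NA_real_),
                   list(coh = seq_arm, icer = cmp$icer))) {
      coh <- r$coh
      total <- perspective_cost(coh, params$econ$perspective)
      rows[[length(rows) + 1]] <- data.frame(
        age = age, strategy = coh$strategy,
        cost_healthcare_yen = coh$mean_cost_healthcare,
        cost_ltc_yen = coh$mean_cost_ltc,
        cost_yen = total,
        cost_usd = yen_to_usd(total, params$econ$yen_per_usd),
        qaly = coh$mean_qaly,
        icer_yen_per_qaly = r$icer,
        icer_usd_per_qaly = yen_to_usd(r$icer, params$econ$yen_per_usd)
      )
    }
  }
  do.call(rbind, rows)
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the base-case comparison with one parameter set to the lower and
#' upper bound of its published range, everything else fixed, using common
#' random numbers across arms and bounds.
#'
#' @param param_id Identifier of a parameter with a deterministic range (see
#'   `param_ids(with_dsa_range = TRUE)`).
#' @param ages Starting ages.
#' @param n Women per cohort.
#' @param seed Integer seed.
#' @param params A `cea_params` object.
#' @param life_table A `life_table` object.
#' @return A `sweep_result` data frame with one row per age and bound:
#'   `age`, `param`, `bound`, `value`, `delta_cost`, `delta_qaly`,
#'   `icer_yen_per_qaly` and one `ce_at_*` flag per threshold.
#' @export
one_way_dsa <- function(param_id, ages = c(70, 75, 80), n = 10000, seed = 1,
                        params = default_parameters(),
                        life_table = make_synthetic_life_table()) {
  reg <- param_registry()
  if (!param_id %in% names(reg) || !is.finite(reg[[param_id]]$dsa_lo))
    stop(sprintf(
      "parameter '%s' has no deterministic sensitivity range; valid ids: %s",
      param_id, paste(param_ids(with_dsa_range = TRUE), collapse = ", ")))
  ent <- reg[[param_id]]
  grid <- c(lo = ent$dsa_lo, hi = ent$dsa_hi)
  rows <- list()
  for (age in ages) {
    for (b in names(grid)) {
      p <- set_param(params, param_id, grid[[b]])
      cmp <- run_pair(age, n, seed, p, life_table)
      rows[[length(rows) + 1]] <- sweep_row(age, param_id, b, grid[[b]], cmp,
                                            params$econ)
    }
  }
  structure(do.call(rbind, rows), class = c("sweep_result", "data.frame"))
}

sweep_row <- function(age, param, bound, value, cmp, econ) {
  row <- data.frame(age = age, param = param, bound = bound, value = value,
                    delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
                    icer_yen_per_qaly = cmp$icer)
  for (i in seq_along(econ$wtp_thresholds))
    row[[sprintf("ce_at_%s", format(econ$wtp_thresholds[i],
                                    scientific = FALSE, trim = TRUE))]] <-
      cmp$cost_effective_at[[i]]
  row
}

#' Teriparatide price sweep
#'
#' Decreases the annual teriparatide cost in 5% increments from 0% to 100%
#' discount and recomputes the ICER at each grid point with common random
#' numbers, reporting for each age and willingness-to-pay threshold the
#' smallest discount at which sequential therapy becomes cost-effective.
#'
#' @param ages Starting ages.
#' @param n Women per cohort.
#' @param seed Integer seed.
#' @param params A `cea_params` object.
#' @param life_table A `life_table` object.
#' @return List with `grid` (a `sweep_result` data frame over discounts) and
#'   `thresholds` (data frame: age, WTP, smallest cost-effective discount or
#'   `NA`).
#' @export
price_sweep <- function(ages = c(70, 75, 80), n = 10000, seed = 1,
                        params = default_parameters(),
                        life_table = make_synthetic_life_table()) {
  discounts <- seq(0, 1, by = 0.05)
  base_cost <- params$drugs$teriparatide$annual_drug_cost
  rows <- list()
  for (age in ages) {
    for (d in discounts) {
      p <- set_param(params, "teriparatide.annual_drug_cost",
                     base_cost * (1 - d))
      cmp <- run_pair(age, n, seed, p, life_table)
      rows[[length(rows) + 1]] <-
        sweep_row(age, "teriparatide.price_discount", "grid", d, cmp,
                  params$econ)
    }
  }
  grid <- structure(do.call(rbind, rows),
                    class = c("sweep_result", "data.frame"))
  thr <- list()
  wtp <- params$econ$wtp_thresholds
  for (age in ages) {
    for (i in seq_along(wtp)) {
      colname <- sprintf("ce_at_%s", format(wtp[i], scientific = FALSE,
                                            trim = TRUE))
      sub <- grid[grid$age == age, ]
      ok <- sub$value[sub[[colname]]]
      thr[[length(thr) + 1]] <- data.frame(
        age = age, wtp = wtp[i],
        threshold_discount = if (length(ok)) min(ok) else NA_real_)
    }
  }
  list(grid = grid, thresholds = do.call(rbind, thr))
}

#' Joint fracture-incidence sweep
#'
#' Scales the hip and vertebral incidence-rate tables jointly from 50% to
#' 150% of base case in 10% steps and recomputes the ICER at each factor
#' with common random numbers.
#'
#' @inheritParams price_sweep
#' @return A `sweep_result` data frame over scaling factors.
#' @export
incidence_sweep <- function(ages = c(70, 75, 80), n = 10000, seed = 1,
                            params = default_parameters(),
                            life_table = make_synthetic_life_table()) {
  factors <- seq(0.5, 1.5, by = 0.1)
  rows <- list()
  for (age in ages) {
    for (f in factors) {
      p <- set_param(params, "epi.hip_incidence_scale",
                     params$epi$hip_incidence_scale * f)
      p <- set_param(p, "epi.vert_incidence_scale",
                     params$epi$vert_incidence_scale * f)
      cmp <- run_pair(age, n, seed, p, life_table)
      rows[[length(rows) + 1]] <-
        sweep_row(age, "incidence_scale", "grid", f, cmp, params$econ)
    }
  }
  structure(do.call(rbind, rows), class = c("sweep_result", "data.frame"))
}

#' Scenario analyses
#'
#' Two pre-specified structural scenarios: `"teriparatide_offset_3y"` extends
#' the teriparatide offset period to 3 years after the 2-year treatment;
#' `"vert_excess_mortality"` applies the same excess mortality to clinical
#' vertebral fractures as to hip fractures (attributable fraction 0.25 with
#' the hip relative hazards).
#'
#' @param name Scenario name.
#' @param ages Starting ages.
#' @param n Women per cohort.
#' @param seed Integer seed.
#' @param params A `cea_params` object.
#' @param life_table A `life_table` object.
#' @return A base-case table (see [base_case_table()]) under the scenario.
#' @export
scenario <- function(name = c("teriparatide_offset_3y",
                              "vert_excess_mortality"),
                     ages = c(70, 75, 80), n = 10000, seed = 1,
                     params = default_parameters(),
                     life_table = make_synthetic_life_table()) {
  name <- match.arg(name)
  p <- scenario_params(name, params)
  base_case_table(ages, n, seed, p, life_table)
}

#' Parameter set under a named scenario
#'
#' @inheritParams scenario
#' @return The modified `cea_params` object.
#' @export
scenario_params <- function(name = c("teriparatide_offset_3y",
                                     "vert_excess_mortality"),
                            params = default_parameters()) {
  name <- match.arg(name)
  switch(name,
    teriparatide_offset_3y =
      set_param(params, "teriparatide.offset_years", 3),
    vert_excess_mortality =
      set_param(params, "mort.attributable_vert", 0.25)
  )
}

#' Probabilistic sensitivity analysis
#'
#' For each simulation, one value of every distributed parameter is drawn
#' (beta and gamma distributions fitted to published 95% CIs, triangular
#' distributions on published ranges, grouped multipliers for the cost and
#' utility blocks, a single discount rate applied to costs and QALYs), and a
#' cohort of `n_trials` women per strategy is run with common random numbers.
#' The cost-effectiveness acceptability curve value at a willingness-to-pay
#' is the fraction of simulations in which sequential therapy has positive
#' incremental net monetary benefit.
#'
#' @param ages Starting ages.
#' @param n_sims Number of parameter draws (outer loop).
#' @param n_trials Women per cohort per simulation (inner loop).
#' @param seed Integer seed.
#' @param params A `cea_params` object.
#' @param life_table A `life_table` object.
#' @param wtp Willingness-to-pay grid for the acceptability curve; defaults
#'   to the two thresholds in `params$econ`.
#' @param specs Optional named list of [dist_spec()] objects overriding the
#'   registry distributions (a point-mass list degenerates the PSA to the
#'   deterministic comparison).
#' @return A `psa_result` object: `draws` (data frame of per-simulation
#'   incremental cost and QALYs per age) and `ceac` (data frame of
#'   acceptability fractions per age and WTP).
#' @export
run_psa <- function(ages = c(70, 75, 80), n_sims = 200, n_trials = 10000,
                    seed = 1, params = default_parameters(),
                    life_table = make_synthetic_life_table(),
                    wtp = NULL, specs = NULL) {
  stopifnot(n_sims >= 1, n_trials >= 1)
  if (is.null(wtp)) wtp <- params$econ$wtp_thresholds
  if (is.null(specs)) {
    reg <- param_registry()
    reg <- reg[vapply(reg, function(x) !is.null(x$psa), TRUE)]
    specs <- lapply(reg, `[[`, "psa")
  }
  set.seed(seed)
  draws <- matrix(NA_real_, n_sims, length(specs),
                  dimnames = list(NULL, names(specs)))
  for (j in seq_along(specs)) draws[, j] <- sample_parameter(specs[[j]], n_sims)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
  rows <- list()
  for (s in seq_len(n_sims)) {
    p <- params
    for (id in colnames(draws)) p <- set_param(p, id, draws[s, id])
    for (age in ages) {
      cmp <- run_pair(age, n_trials, sim_seeds[s], p, life_table)
      rows[[length(rows) + 1]] <- data.frame(
        sim = s, age = age,
        delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly)
    }
  }
  draws_df <- do.call(rbind, rows)
  ceac <- do.call(rbind, lapply(ages, function(age) {
    sub <- draws_df[draws_df$age == age, ]
    do.call(rbind, lapply(wtp, function(w) data.frame(
      age = age, wtp = w,
      p_cost_effective = mean(w * sub$delta_qaly - sub$delta_cost > 0))))
  }))
  structure(list(draws = draws_df, parameter_draws = as.data.frame(draws),
                 ceac = ceac, n_sims = n_sims, n_trials = n_trials,
                 seed = seed, sim_seeds = sim_seeds),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d simulations x %s trials (seed %d)\n", x$n_sims,
              format(x$n_trials, big.mark = ","), x$seed))
  print(x$ceac, row.names = FALSE)
  invisible(x)
}
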