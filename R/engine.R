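baseline_utility <- function(age, params) {
  u <- params$util
  idx <- findInterval(age, u$age_lo)
  if (any(idx == 0))
    stop(sprintf("age %s below the first utility band (%d)",
                 paste(age[idx == 0], collapse = ", "), u$age_lo[1]))
  pmin(1, u$baseline[idx] * u$utility_scale)
}

#' QALY weight for one cycle
#'
#' Baseline age-band EQ-5D utility multiplied by the applicable fracture
#' disutility multipliers: the first-year multiplier in the cycle of a
#' fracture, the beyond-first-year multiplier in every later cycle, lifelong.
#' Hip and vertebral multipliers combine multiplicatively when both histories
#' exist. A cycle in which the woman dies contributes zero utility.
#'
#' All arguments are vectorised over individuals.
#'
#' @param age Age at the cycle.
#' @param hip_now,vert_now Logical: fracture of that type in this cycle.
#' @param prior_hip,prior_vert Logical: fracture of that type in an earlier
#'   cycle.
#' @param died_now Logical: death in this cycle.
#' @param params A `cea_params` object.
#' @return QALY weights in `[0, 1]`.
#' @export
#' @examples
#' cycle_utility(72, FALSE, FALSE, FALSE, FALSE, FALSE)  # 0.810
cycle_utility <- function(age, hip_now, vert_now, prior_hip, prior_vert,
                          died_now, params = default_parameters()) {
  u <- params$util
  fh <- ifelse(hip_now, u$du_hip_year1, ifelse(prior_hip, u$du_hip_later, 1))
  fv <- ifelse(vert_now, u$du_vert_year1,
               ifelse(prior_vert, u$du_vert_later, 1))
  ifelse(died_now, 0, baseline_utility(age, params) * fh * fv)
}

#' Costs booked in one cycle
#'
#' Healthcare-sector costs: for a persisting on-treatment year, the annual
#' drug cost scaled by adherence, the yearly prescription charge, four
#' physician visits (the drug's first visit at the first-visit fee, all
#' others at the subsequent fee), two blood tests, and a DXA scan at the end
#' of overall treatment years 2, 5 and 10; for a woman discontinuing within
#' the first year of a drug, a 3-month drug supply (one prescription fill,
#' one quarter of the annual cost) and one visit; for a later-year
#' discontinuer, one visit only. Fracture treatment costs are booked in the
#' fracture cycle: hip 1,726,000 yen, first in-model clinical vertebral
#' 420,000 yen, subsequent vertebral 842,000 yen.
#'
#' Long-term-care (non-healthcare sector) costs: 876,000 yen per year in the
#' post-hip state, else 213,000 yen per year in the post-vertebral state,
#' with half the annual amount in the cycle of the state-defining (first)
#' fracture. When both states exist only the hip amount is charged.
#'
#' In a death cycle only the fracture treatment cost and long-term-care cost
#' are booked; treatment-related costs are not.
#'
#' All arguments are vectorised over individuals.
#'
#' @param status Character: `"none"`, `"persist"` or `"discontinue"`.
#' @param drug Drug name for on-treatment individuals (`NA` otherwise).
#' @param phase_year 1-based year within the drug's phase.
#' @param overall_year 1-based year within the whole treatment program.
#' @param hip_now,vert_now Logical: fracture of that type this cycle.
#' @param first_hip,first_vert Logical: first in-model fracture of that type.
#' @param post_hip,post_vert Logical: in the post-fracture state at cycle end
#'   (including a fracture this cycle).
#' @param died_now Logical: death this cycle.
#' @param params A `cea_params` object.
#' @return Data frame with columns `drug_cost`, `visit_cost`, `test_cost`,
#'   `fracture_medical_cost`, `ltc_cost` (undiscounted yen).
#' @export
cycle_costs <- function(status, drug, phase_year, overall_year,
                        hip_now, vert_now, first_hip, first_vert,
                        post_hip, post_vert, died_now,
                        params = default_parameters()) {
  n <- length(status)
  drug_cost <- visit_cost <- test_cost <- fx_cost <- ltc_cost <- numeric(n)
  cs <- params$costs
  for (dn in names(params$drugs)) {
    d <- params$drugs[[dn]]
    sel <- !died_now & status == "persist" & !is.na(drug) & drug == dn
    if (any(sel)) {
      y <- phase_year[sel]
      drug_cost[sel] <- d$annual_drug_cost * adherence(dn, y, params) +
        d$prescription_charge
      visit_cost[sel] <- ifelse(y == 1,
                                d$first_visit_cost + 3 * d$subsequent_visit_cost,
                                4 * d$subsequent_visit_cost)
      test_cost[sel] <- 2 * cs$blood_test_cost +
        ifelse(overall_year[sel] %in% c(2, 5, 10), cs$dxa_cost, 0)
    }
    sel <- !died_now & status == "discontinue" & !is.na(drug) & drug == dn
    if (any(sel)) {
      y <- phase_year[sel]
      drug_cost[sel] <- ifelse(y == 1, d$annual_drug_cost / 4, 0)
      visit_cost[sel] <- ifelse(y == 1, d$first_visit_cost,
                                d$subsequent_visit_cost)
    }
  }
  fx_cost[hip_now] <- cs$hip_medical_cost * cs$fracture_medical_scale
  fx_cost[vert_now] <- ifelse(first_vert[vert_now],
                              cs$vert_first_medical_cost,
                              cs$vert_subsequent_medical_cost) *
    cs$fracture_medical_scale
  hip_state <- post_hip
  vert_only <- !post_hip & post_vert
  ltc_cost[hip_state] <- cs$ltc_post_hip * cs$ltc_scale *
    ifelse(first_hip[hip_state], 0.5, 1)
  ltc_cost[vert_only] <- cs$ltc_post_vert * cs$ltc_scale *
    ifelse(first_vert[vert_only], 0.5, 1)
  data.frame(drug_cost = drug_cost, visit_cost = visit_cost,
             test_cost = test_cost, fracture_medical_cost = fx_cost,
             ltc_cost = ltc_cost)
}

# One cohort, advanced cycle by cycle with vectorised state. Four uniform
# deviates per woman are drawn every cycle whether or not she is still alive,
# so that runs with the same seed are aligned draw-for-draw across
# strategies and sweep points (common random numbers).
run_engine <- function(strategy, start_age, n, seed, params, life_table,
                       keep_ledger = FALSE) {
  stopifnot(inherits(strategy, "cea_strategy"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  horizon <- params$econ$horizon_age
  n_cycles <- horizon - start_age
  stopifnot(n_cycles >= 1)
  phases <- strategy$phases
  K <- length(phases)
  # per-phase schedules
  sched <- lapply(seq_len(K), function(k) {
    d <- phases[[k]]$drug; L <- phases[[k]]$years
    yrs <- seq_len(L)
    full_off <- if (is.na(params$drugs[[d]]$offset_years)) L
                else params$drugs[[d]]$offset_years
    list(drug = d, years = L,
         cont = annual_continuation_prob(d, yrs, params),
         adh = adherence(d, yrs, params),
         mhip = effective_rr(d, "hip", yrs, params),
         mvert = effective_rr(d, "vertebral", yrs, params),
         full_offset = full_off,
         year_offset = if (k == 1) 0 else
           sum(vapply(phases[seq_len(k - 1)], `[[`, 0, "years")))
  })
  ages <- start_age + seq_len(n_cycles) - 1
  qx <- life_table_qx(life_table, ages)
  haz <- -log(1 - pmin(qx, 1 - 1e-12))
  hip_rate <- band_rate(params$epi$hip_rates, ages) * 1e-5 *
    params$epi$rr_prior_vf_hip * params$epi$hip_incidence_scale
  vert_rate <- band_rate(params$epi$vert_rates, ages) * 1e-5 *
    params$epi$rr_prior_vf_vert * params$epi$vert_incidence_scale
  base_u <- baseline_utility(ages, params)
  dfc <- (1 + params$econ$discount_cost)^-(seq_len(n_cycles) - 1)
  dfq <- (1 + params$econ$discount_qaly)^-(seq_len(n_cycles) - 1)
  mort <- params$mort
  max_hip <- params$epi$max_hip_fractures

  alive <- rep(TRUE, n)
  ph <- rep(if (K > 0) 1L else 0L, n)   # 0 = not on a treatment phase
  py <- rep(1L, n)
  in_off <- rep(FALSE, n)
  off_len <- rr0h <- rr0v <- numeric(n)
  yo <- integer(n)
  nh <- nv <- integer(n)
  ysh <- rep(NA_integer_, n)            # years since last hip (0 = this cycle)
  ysv <- rep(NA_integer_, n)
  cost_hc <- cost_ltc <- qaly <- numeric(n)
  cycles_lived <- integer(n)
  if (keep_ledger) {
    ledger <- list()
    comp <- c("drug_cost", "visit_cost", "test_cost",
              "fracture_medical_cost", "ltc_cost", "utility")
    for (cm in comp) ledger[[cm]] <- matrix(0, n, n_cycles)
  }

  for (t in seq_len(n_cycles)) {
    u_cont <- stats::runif(n); u_hip <- stats::runif(n)
    u_vert <- stats::runif(n); u_death <- stats::runif(n)
    if (!any(alive)) next
    a <- alive
    status <- rep("none", n)
    mh <- rep(1, n); mv <- rep(1, n)
    for (k in seq_len(K)) {
      on <- a & ph == k
      if (!any(on)) next
      y <- py[on]
      persist <- on
      persist[on] <- u_cont[on] < sched[[k]]$cont[y]
      status[persist] <- "persist"
      status[on & !persist] <- "discontinue"
      mh[persist] <- sched[[k]]$mhip[py[persist]]
      mv[persist] <- sched[[k]]$mvert[py[persist]]
    }
    # offset phase: risk returns linearly to untreated levels
    off <- a & in_off
    if (any(off)) {
      yo[off] <- yo[off] + 1L
      active <- off & yo < off_len
      if (any(active)) {
        fr <- yo[active] / off_len[active]
        mh[active] <- rr0h[active] + (1 - rr0h[active]) * fr
        mv[active] <- rr0v[active] + (1 - rr0v[active]) * fr
      }
      done <- off & yo >= off_len
      in_off[done] <- FALSE
    }
    # fracture events (hip takes precedence; at most one per cycle)
    p_hip <- 1 - exp(-hip_rate[t] * mh)
    hip_now <- a & nh < max_hip & u_hip < p_hip
    p_vert <- 1 - exp(-vert_rate[t] * mv)
    vert_now <- a & !hip_now & u_vert < p_vert
    first_hip <- hip_now & nh == 0L
    first_vert <- vert_now & nv == 0L
    nh2 <- nh + hip_now
    nv2 <- nv + vert_now
    ysh2 <- ifelse(hip_now, 0L, ysh)
    ysv2 <- ifelse(vert_now, 0L, ysv)
    # death with excess post-fracture hazard
    m_mort <- mortality_multiplier(ysh2, ysv2, mort)
    p_death <- 1 - exp(-haz[t] * m_mort)
    die <- a & u_death < p_death
    # utility
    u_cycle <- cycle_utility(ages[t], hip_now[a], vert_now[a], nh[a] > 0,
                             nv[a] > 0, die[a], params)
    qaly[a] <- qaly[a] + u_cycle * dfq[t]
    # costs
    drug_vec <- rep(NA_character_, n)
    oy <- integer(n)
    for (k in seq_len(K)) {
      on <- a & ph == k
      drug_vec[on] <- sched[[k]]$drug
      oy[on] <- sched[[k]]$year_offset + py[on]
    }
    cc <- cycle_costs(status[a], drug_vec[a], py[a], oy[a],
                      hip_now[a], vert_now[a], first_hip[a], first_vert[a],
                      nh2[a] > 0, nv2[a] > 0, die[a], params)
    hc <- cc$drug_cost + cc$visit_cost + cc$test_cost +
      cc$fracture_medical_cost
    cost_hc[a] <- cost_hc[a] + hc * dfc[t]
    cost_ltc[a] <- cost_ltc[a] + cc$ltc_cost * dfc[t]
    if (keep_ledger) {
      for (cm in c("drug_cost", "visit_cost", "test_cost",
                   "fracture_medical_cost", "ltc_cost"))
        ledger[[cm]][a, t] <- cc[[cm]]
      ledger$utility[a, t] <- u_cycle
    }
    cycles_lived[a] <- t
    # state transitions
    nh <- nh2; nv <- nv2
    ysh <- ifelse(is.na(ysh2), NA_integer_, ysh2 + 1L)
    ysv <- ifelse(is.na(ysv2), NA_integer_, ysv2 + 1L)
    pers <- a & status == "persist"
    py[pers] <- py[pers] + 1L
    for (k in seq_len(K)) {
      compl <- pers & ph == k & py > sched[[k]]$years
      if (any(compl)) {
        if (k < K) {
          ph[compl] <- k + 1L
          py[compl] <- 1L
        } else {
          L <- sched[[k]]$years
          ph[compl] <- 0L
          in_off[compl] <- TRUE
          yo[compl] <- 0L
          off_len[compl] <- sched[[k]]$full_offset
          rr0h[compl] <- sched[[k]]$mhip[L]
          rr0v[compl] <- sched[[k]]$mvert[L]
        }
      }
      disc <- a & status == "discontinue" & ph == k
      if (any(disc)) {
        taken <- py[disc] - 1L
        ph[disc] <- 0L
        in_off[disc] <- TRUE
        yo[disc] <- 0L
        off_len[disc] <- sched[[k]]$full_offset * taken / sched[[k]]$years
        rr0h[disc] <- ifelse(taken >= 1L, sched[[k]]$mhip[pmax(taken, 1L)], 1)
        rr0v[disc] <- ifelse(taken >= 1L, sched[[k]]$mvert[pmax(taken, 1L)], 1)
      }
    }
    alive <- a & !die
  }

  out <- list(
    strategy = strategy$name, start_age = start_age, n = n, seed = seed,
    cost_hc = cost_hc, cost_ltc = cost_ltc, qaly = qaly,
    ever_hip = nh > 0, ever_vert = nv > 0, n_hip = nh, n_vert = nv,
    dead = !alive, cycles_lived = cycles_lived
  )
  if (keep_ledger) out$ledger <- ledger
  out
}

#' Simulate one individual trajectory
#'
#' Runs a single woman through the model cycle by cycle, from the starting
#' age until death or age 105, and returns her per-cycle ledger: undiscounted
#' costs by component and the cycle QALY weight. Each cycle samples, in
#' order, treatment continuation, the effective relative-risk multipliers
#' (treatment or offset phase), fracture, then death.
#'
#' @param strategy A [strategy()] object.
#' @param start_age Starting age (the analysis uses 70, 75, 80; other ages
#'   are allowed with a warning).
#' @param params A `cea_params` object.
#' @param life_table A `life_table` object.
#' @param seed Integer seed.
#' @return Data frame with one row per lived cycle: `cycle_index` (0-based),
#'   `age`, `drug_cost`, `visit_cost`, `test_cost`, `fracture_medical_cost`,
#'   `ltc_cost`, `utility`.
#' @export
simulate_individual <- function(strategy, start_age, params =
                                  default_parameters(),
                                life_table = make_synthetic_life_table(),
                                seed = NULL) {
  if (!start_age %in% c(70, 75, 80))
    warning("starting ages of the analysis are 70, 75 and 80")
  res <- run_engine(strategy, start_age, 1L, seed, params, life_table,
                    keep_ledger = TRUE)
  k <- res$cycles_lived
  if (k == 0) k <- 1
  data.frame(
    cycle_index = seq_len(k) - 1L,
    age = start_age + seq_len(k) - 1L,
    drug_cost = res$ledger$drug_cost[1, seq_len(k)],
    visit_cost = res$ledger$visit_cost[1, seq_len(k)],
    test_cost = res$ledger$test_cost[1, seq_len(k)],
    fracture_medical_cost = res$ledger$fracture_medical_cost[1, seq_len(k)],
    ltc_cost = res$ledger$ltc_cost[1, seq_len(k)],
    utility = res$ledger$utility[1, seq_len(k)]
  )
}

#' Run a cohort through the microsimulation
#'
#' Simulates `n` independent women one at a time under the given strategy and
#' aggregates discounted mean costs by payer sector, mean QALYs, their
#' standard errors, and lifetime event probabilities. Results are reproducible
#' bit-for-bit for a given `(seed, n, params)`.
#'
#' @param strategy A [strategy()] object.
#' @param start_age Starting age.
#' @param n Number of simulated women.
#' @param seed Integer seed.
#' @param params A `cea_params` object.
#' @param life_table A `life_table` object.
#' @param keep_individuals If `TRUE`, per-individual discounted cost and QALY
#'   vectors are kept in the result (used for paired comparisons).
#' @return A `cohort_result` object.
#' @export
run_cohort <- function(strategy, start_age, n, seed,
                       params = default_parameters(),
                       life_table = make_synthetic_life_table(),
                       keep_individuals = FALSE) {
  res <- run_engine(strategy, start_age, n, seed, params, life_table)
  total <- res$cost_hc + res$cost_ltc
  out <- structure(list(
    strategy = res$strategy, start_age = start_age, n = n, seed = seed,
    mean_cost_healthcare = mean(res$cost_hc),
    mean_cost_ltc = mean(res$cost_ltc),
    mean_qaly = mean(res$qaly),
    se_cost = stats::sd(total) / sqrt(n),
    se_qaly = stats::sd(res$qaly) / sqrt(n),
    lifetime_p_hip = mean(res$ever_hip),
    lifetime_p_vert = mean(res$ever_vert),
    mean_n_hip = mean(res$n_hip),
    mean_n_vert = mean(res$n_vert),
    p_dead_by_105 = mean(res$dead)
  ), class = "cohort_result")
  if (keep_individuals) {
    out$cost_hc <- res$cost_hc
    out$cost_ltc <- res$cost_ltc
    out$qaly <- res$qaly
  }
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("Cohort: %s, start age %d, n = %s\n", x$strategy, x$start_age,
              format(x$n, big.mark = ",")))
  cat(sprintf("  discounted cost: healthcare %s + LTC %s yen\n",
              format(round(x$mean_cost_healthcare), big.mark = ","),
              format(round(x$mean_cost_ltc), big.mark = ",")))
  cat(sprintf("  discounted QALY: %.3f (se %.4f)\n", x$mean_qaly, x$se_qaly))
  cat(sprintf("  lifetime P(hip) %.3f, P(vert) %.3f, P(dead by 105) %.4f\n",
              x$lifetime_p_hip, x$lifetime_p_vert, x$p_dead_by_105))
  invisible(x)
}

#' No-intervention validation run
#'
#' Runs the no-intervention arm and reports the probability of death by age
#' 105 and the lifetime probabilities of at least one hip and at least one
#' clinical vertebral fracture, the quantities used to check the model's
#' natural-history behaviour.
#'
#' @param start_age Starting age.
#' @param n Number of simulated women.
#' @param seed Integer seed.
#' @param params A `cea_params` object.
#' @param life_table A `life_table` object.
#' @return List with `start_age`, `n`, `p_dead_by_105`, `lifetime_p_hip`,
#'   `lifetime_p_vert`.
#' @export
validate_no_intervention <- function(start_age, n, seed,
                                     params = default_parameters(),
                                     life_table =
                                       make_synthetic_life_table()) {
  res <- run_cohort(strategy("no_intervention"), start_age, n, seed,
                    params, life_table)
  list(start_age = start_age, n = n,
       p_dead_by_105 = res$p_dead_by_105,
       lifetime_p_hip = res$lifetime_p_hip,
       lifetime_p_vert = res$lifetime_p_vert)
}
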