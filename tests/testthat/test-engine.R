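zero_incidence_params <- function() {
  p <- default_parameters()
  p$epi$hip_rates$rate[] <- 0
  p$epi$vert_rates$rate[] <- 0
  p
}

test_that("cycle utility combines age-band baseline and fracture
           multipliers", {
  expect_equal(cycle_utility(72, FALSE, FALSE, FALSE, FALSE, FALSE), 0.810)
  expect_equal(cycle_utility(72, TRUE, FALSE, FALSE, FALSE, FALSE),
               0.810 * 0.776)
  expect_equal(cycle_utility(86, FALSE, FALSE, TRUE, TRUE, FALSE),
               0.684 * 0.855 * 0.868)
  # first-year multiplier in the fracture cycle even with prior history
  expect_equal(cycle_utility(86, TRUE, FALSE, TRUE, FALSE, FALSE),
               0.684 * 0.776)
  # death cycle contributes nothing
  expect_equal(cycle_utility(72, TRUE, FALSE, FALSE, FALSE, TRUE), 0)
  # utility multiplier from the PSA block is capped at 1
  p <- set_param(default_parameters(), "util.utility_scale", 1.3)
  expect_equal(cycle_utility(72, FALSE, FALSE, FALSE, FALSE, FALSE, p),
               min(1, 0.810 * 1.3))
})

test_that("cycle costs follow the resource-use rules", {
  # persisting first teriparatide year: adherence-scaled drug cost,
  # prescription charge, first + 3 subsequent visits, 2 blood tests
  cc <- cycle_costs("persist", "teriparatide", 1, 1, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, FALSE)
  expect_equal(cc$drug_cost, 333400 * 0.702 + 1100)
  expect_equal(cc$visit_cost, 18300 + 3 * 9400)
  expect_equal(cc$test_cost, 2 * 2900)
  expect_equal(cc$fracture_medical_cost, 0)
  expect_equal(cc$ltc_cost, 0)
  # DXA at the end of overall treatment years 2, 5 and 10
  cc2 <- cycle_costs("persist", "teriparatide", 2, 2, FALSE, FALSE, FALSE,
                     FALSE, FALSE, FALSE, FALSE)
  expect_equal(cc2$test_cost, 2 * 2900 + 4500)
  cc5 <- cycle_costs("persist", "alendronate", 3, 5, FALSE, FALSE, FALSE,
                     FALSE, FALSE, FALSE, FALSE)
  expect_equal(cc5$test_cost, 2 * 2900 + 4500)
  # first-year discontinuation: one 3-month fill and one first visit
  cd <- cycle_costs("discontinue", "alendronate", 1, 1, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, FALSE)
  expect_equal(cd$drug_cost, 8700 / 4)
  expect_equal(cd$visit_cost, 3600)
  expect_equal(cd$test_cost, 0)
  # later-year discontinuation: one subsequent visit, no drug cost
  cd2 <- cycle_costs("discontinue", "alendronate", 4, 4, FALSE, FALSE, FALSE,
                     FALSE, FALSE, FALSE, FALSE)
  expect_equal(cd2$drug_cost, 0)
  expect_equal(cd2$visit_cost, 1900)
  # first hip fracture cycle: treatment cost plus half-year long-term care
  cf <- cycle_costs("none", NA, 1, 1, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                    FALSE)
  expect_equal(cf$fracture_medical_cost, 1726000)
  expect_equal(cf$ltc_cost, 876000 / 2)
  # established post-hip state dominates post-vertebral for long-term care
  cl <- cycle_costs("none", NA, 1, 1, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                    FALSE)
  expect_equal(cl$ltc_cost, 876000)
  cv <- cycle_costs("none", NA, 1, 1, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE,
                    FALSE)
  expect_equal(cv$fracture_medical_cost, 842000)  # subsequent vertebral
  expect_equal(cv$ltc_cost, 213000)
  # off treatment, never fractured: nothing is charged
  c0 <- cycle_costs("none", NA, 1, 1, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE)
  expect_true(all(unlist(c0) == 0))
  # death cycle books fracture and long-term-care costs only
  cdth <- cycle_costs("persist", "teriparatide", 1, 1, TRUE, FALSE, TRUE,
                      FALSE, TRUE, FALSE, TRUE)
  expect_equal(cdth$drug_cost, 0)
  expect_equal(cdth$visit_cost, 0)
  expect_equal(cdth$fracture_medical_cost, 1726000)
  expect_equal(cdth$ltc_cost, 876000 / 2)
})

test_that("cohort runs are reproducible bit-for-bit under a fixed seed", {
  lt <- make_synthetic_life_table()
  a <- run_cohort(strategy("sequential"), 75, 2000, 99, life_table = lt)
  b <- run_cohort(strategy("sequential"), 75, 2000, 99, life_table = lt)
  expect_identical(a, b)
})

test_that("with no fractures the mean QALY equals the discounted life-table
           annuity", {
  p <- zero_incidence_params()
  lt <- make_synthetic_life_table()
  coh <- run_cohort(strategy("no_intervention"), 70, 50000, 3, p, lt)
  ages <- 70:104
  qx <- life_table_qx(lt, ages)
  surv <- cumprod(1 - qx)                    # P(alive through cycle t)
  u <- c(0.810, 0.771, 0.769, 0.684)[findInterval(ages, c(70, 75, 80, 85))]
  annuity <- sum(u * surv * 1.02^-(seq_along(ages) - 1))
  expect_lt(abs(coh$mean_qaly - annuity), 3 * coh$se_qaly)
  expect_equal(coh$lifetime_p_hip, 0)
  expect_equal(coh$lifetime_p_vert, 0)
  expect_equal(coh$mean_cost_healthcare, 0)
  expect_equal(coh$mean_cost_ltc, 0)
})

test_that("alendronate monotherapy never books teriparatide costs", {
  # zeroing the teriparatide price must not change the arm at all
  p0 <- set_param(default_parameters(), "teriparatide.annual_drug_cost", 0)
  lt <- make_synthetic_life_table()
  a <- run_cohort(strategy("alendronate_mono"), 75, 3000, 5, life_table = lt)
  b <- run_cohort(strategy("alendronate_mono"), 75, 3000, 5, p0,
                  life_table = lt)
  expect_equal(a$mean_cost_healthcare, b$mean_cost_healthcare)
  expect_equal(a$mean_qaly, b$mean_qaly)
})

test_that("sector accumulators agree with the per-cycle ledger and
           utilities never exceed baseline", {
  lt <- make_synthetic_life_table()
  res <- osteocea:::run_engine(strategy("sequential"), 70, 500, 17,
                               default_parameters(), lt, keep_ledger = TRUE)
  n_cycles <- ncol(res$ledger$drug_cost)
  dfc <- 1.02^-(seq_len(n_cycles) - 1)
  hc <- (res$ledger$drug_cost + res$ledger$visit_cost + res$ledger$test_cost +
           res$ledger$fracture_medical_cost) %*% dfc
  ltc <- res$ledger$ltc_cost %*% dfc
  q <- res$ledger$utility %*% dfc
  expect_equal(as.numeric(hc), res$cost_hc)
  expect_equal(as.numeric(ltc), res$cost_ltc)
  expect_equal(as.numeric(q), res$qaly)
  base_u <- c(0.810, 0.771, 0.769, 0.684)[
    findInterval(70:104, c(70, 75, 80, 85))]
  expect_true(all(res$ledger$utility <=
                    matrix(base_u, 500, n_cycles, byrow = TRUE) + 1e-12))
})

test_that("raising incidence rates raises mean fracture counts", {
  lt <- make_synthetic_life_table()
  base <- run_cohort(strategy("no_intervention"), 70, 20000, 21,
                     make_fixture_cohort_params(1), lt)
  high <- run_cohort(strategy("no_intervention"), 70, 20000, 21,
                     make_fixture_cohort_params(1.5), lt)
  expect_gte(high$mean_n_hip + high$mean_n_vert,
             base$mean_n_hip + base$mean_n_vert)
  expect_gte(high$lifetime_p_vert, base$lifetime_p_vert)
})

test_that("an immediate death leaves a one-cycle ledger", {
  lt <- flat_life_table(1 - 1e-15)
  led <- suppressWarnings(
    simulate_individual(strategy("sequential"), 71, life_table = lt,
                        seed = 2))
  expect_equal(nrow(led), 1)
  expect_equal(led$utility, 0)
  expect_warning(simulate_individual(strategy("sequential"), 71,
                                     life_table = lt, seed = 2),
                 "70, 75 and 80")
})

test_that("zeroed incidence gives zero lifetime fracture probabilities in
           the validation report", {
  v <- validate_no_intervention(75, 2000, 4, zero_incidence_params())
  expect_equal(v$lifetime_p_hip, 0)
  expect_equal(v$lifetime_p_vert, 0)
  expect_gt(v$p_dead_by_105, 0.99)
})
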