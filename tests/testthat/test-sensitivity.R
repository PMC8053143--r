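lt_test <- make_synthetic_life_table()

test_that("identity grid points reproduce the base case bit-for-bit", {
  n <- 1500; seed <- 8
  base <- osteocea:::run_pair(80, n, seed, default_parameters(), lt_test)
  ps <- price_sweep(ages = 80, n = n, seed = seed, life_table = lt_test)
  row0 <- ps$grid[ps$grid$value == 0, ]
  expect_identical(row0$icer_yen_per_qaly, base$icer)
  expect_identical(row0$delta_cost, base$delta_cost)
  isw <- incidence_sweep(ages = 80, n = n, seed = seed,
                         life_table = lt_test)
  row1 <- isw[isw$value == 1, ]
  expect_identical(row1$icer_yen_per_qaly, base$icer)
  expect_identical(row1$delta_qaly, base$delta_qaly)
})

test_that("one-way analysis honours the published ranges and errors on
           parameters without one", {
  expect_error(one_way_dsa("mort.rh_hip_year1", ages = 80, n = 100, seed = 1),
               "no deterministic sensitivity range")
  expect_error(one_way_dsa("nope", ages = 80, n = 100, seed = 1),
               "valid ids")
  res <- one_way_dsa("teriparatide.rr_vert", ages = 80, n = 1500, seed = 8,
                     life_table = lt_test)
  expect_equal(nrow(res), 2)
  expect_equal(sort(res$value), c(0.16, 0.32))
  # a more efficacious teriparatide (lower RR) gives the better ICER
  expect_lt(res$icer_yen_per_qaly[res$value == 0.16],
            res$icer_yen_per_qaly[res$value == 0.32])
  # setting a bound equal to the base reproduces the base case exactly
  reg <- param_registry()
  base <- osteocea:::run_pair(80, 1500, 8, default_parameters(), lt_test)
  same <- osteocea:::run_pair(
    80, 1500, 8, set_param(default_parameters(), "teriparatide.rr_vert",
                           0.23), lt_test)
  expect_identical(same$icer, base$icer)
  # adherence bounds are first-year values carried to later years as ratios
  ent <- reg[["alendronate.adherence_scale"]]
  p_hi <- set_param(default_parameters(), "alendronate.adherence_scale",
                    ent$dsa_hi)
  expect_equal(adherence("alendronate", 1, p_hi), 0.8)
  expect_equal(adherence("alendronate", 7, p_hi), 0.609 * 0.8 / 0.706)
})

test_that("teriparatide price discounts span 0-100% in 5% steps and zero
           price empties the drug cost", {
  ps <- price_sweep(ages = 80, n = 800, seed = 3, life_table = lt_test)
  expect_equal(sort(unique(ps$grid$value)), seq(0, 1, by = 0.05))
  expect_equal(nrow(ps$thresholds), 2)
  # free teriparatide can only help: ICER at 100% discount below 0% discount
  expect_lt(ps$grid$icer_yen_per_qaly[ps$grid$value == 1],
            ps$grid$icer_yen_per_qaly[ps$grid$value == 0])
  # any threshold found must lie on the grid
  thr <- ps$thresholds$threshold_discount
  expect_true(all(is.na(thr) | thr %in% seq(0, 1, by = 0.05)))
  # a 100% discount removes teriparatide drug costs from the ledger
  p0 <- set_param(default_parameters(), "teriparatide.annual_drug_cost", 0)
  led <- simulate_individual(strategy("sequential"), 80, p0, lt_test,
                             seed = 12)
  expect_lt(max(led$drug_cost), 8700 * 1 + 1700 + 1)  # alendronate only
})

test_that("ICER does not increase with fracture incidence under common
           random numbers", {
  isw <- incidence_sweep(ages = 80, n = 4000, seed = 13,
                         life_table = lt_test)
  icers <- isw$icer_yen_per_qaly[order(isw$value)]
  # a strongly decreasing trend, allowing per-step Monte-Carlo wiggle
  expect_lt(cor(seq_along(icers), icers, method = "spearman"), -0.7)
  expect_lt(icers[length(icers)], icers[1])
})

test_that("scenario analyses modify only their target parameters", {
  expect_error(scenario("bogus", ages = 80, n = 100, seed = 1))
  p3 <- scenario_params("teriparatide_offset_3y")
  expect_equal(p3$drugs$teriparatide$offset_years, 3)
  expect_equal(p3$mort$attributable_vert, 0)
  pv <- scenario_params("vert_excess_mortality")
  expect_equal(pv$mort$attributable_vert, 0.25)
  expect_equal(pv$drugs$teriparatide$offset_years, 2)
  # with vertebral incidence zeroed the mortality scenario equals the base
  p0 <- default_parameters()
  p0$epi$vert_rates$rate[] <- 0
  pv0 <- scenario_params("vert_excess_mortality", p0)
  a <- run_cohort(strategy("sequential"), 80, 2000, 6, p0, lt_test)
  b <- run_cohort(strategy("sequential"), 80, 2000, 6, pv0, lt_test)
  expect_identical(a$mean_qaly, b$mean_qaly)
  expect_identical(a$mean_cost_healthcare, b$mean_cost_healthcare)
})

test_that("a longer teriparatide offset weakly improves the sequential
           arm's incremental QALYs under paired seeds", {
  n <- 6000; seed <- 23
  base <- run_cohort(strategy("sequential"), 80, n, seed,
                     default_parameters(), lt_test, keep_individuals = TRUE)
  long <- run_cohort(strategy("sequential"), 80, n, seed,
                     scenario_params("teriparatide_offset_3y"), lt_test,
                     keep_individuals = TRUE)
  d <- long$qaly - base$qaly
  se <- sd(d) / sqrt(n)
  expect_gte(mean(d), -3 * se)
})

test_that("degenerate PSA reproduces the deterministic comparison with a
           0/1 acceptability curve", {
  reg <- param_registry()
  ids <- param_ids(with_psa = TRUE)
  point <- lapply(ids, function(id) {
    base <- if (id == "econ.discount") 0.02 else reg[[id]]$psa$base
    dist_spec("fixed", base = base)
  })
  names(point) <- ids
  psa <- run_psa(ages = 80, n_sims = 3, n_trials = 1200, seed = 5,
                 life_table = lt_test, specs = point)
  expect_true(all(psa$ceac$p_cost_effective %in% c(0, 1)))
  # and it matches the deterministic comparison run at the same seeds
  cmp1 <- osteocea:::run_pair(80, 1200, psa$sim_seeds[1],
                              default_parameters(), lt_test)
  w <- psa$ceac$wtp[1]
  det <- as.numeric(w * cmp1$delta_qaly - cmp1$delta_cost > 0)
  got <- psa$draws[psa$draws$sim == 1, ]
  expect_equal(as.numeric(w * got$delta_qaly - got$delta_cost > 0), det)
})

test_that("acceptability is non-decreasing in willingness-to-pay", {
  psa <- run_psa(ages = c(75, 80), n_sims = 12, n_trials = 600, seed = 9,
                 life_table = lt_test,
                 wtp = c(1e6, 3e6, 5e6, 8e6, 1e7, 2e7))
  for (age in c(75, 80)) {
    sub <- psa$ceac[psa$ceac$age == age, ]
    sub <- sub[order(sub$wtp), ]
    expect_true(all(diff(sub$p_cost_effective) >= 0))
  }
  expect_equal(nrow(psa$draws), 2 * 12)
})
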