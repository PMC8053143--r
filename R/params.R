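#' Base-case model parameters
#'
#' Builds the full parameter set of the cost-effectiveness model: drug efficacy
#' (trial relative risks versus placebo), adherence and persistence schedules,
#' drug and monitoring costs, age-band fracture incidence rates, relative risks
#' associated with a prior vertebral fracture, post-hip excess-mortality
#' parameters, EQ-5D baseline utilities with fracture disutility multipliers,
#' fracture treatment and long-term-care costs, and economic settings
#' (2% annual discounting, willingness-to-pay thresholds of 5 and 10 million
#' yen per QALY, lifetime horizon to age 105, yen-to-dollar rate of 105).
#'
#' All values are 2020 Japanese yen. The function is pure: repeated calls
#' return identical objects.
#'
#' @return An object of class `cea_params`, a named list with components
#'   `drugs`, `epi`, `mort`, `util`, `costs` and `econ`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$drugs$teriparatide$rr_vert   # 0.23
#' p$costs$hip_medical_cost       # 1726000
default_parameters <- function() {
  drugs <- list(
    teriparatide = list(
      name = "teriparatide",
      rr_hip = 0.35,
      rr_vert = 0.23,
      duration_years = 2,
      offset_years = 2,                    # 3 in the scenario analysis
      adherence_years = c(1, 2),
      adherence_rates = c(0.702, 0.678),
      persistence_years = c(1, 2),
      persistence_cum = c(0.680, 0.516),
      annual_drug_cost = 333400,
      prescription_charge = 1100,
      first_visit_cost = 18300,
      subsequent_visit_cost = 9400,
      adherence_scale = 1,
      persistence_scale = 1
    ),
    alendronate = list(
      name = "alendronate",
      rr_hip = 0.64,
      rr_vert = 0.50,
      duration_years = 10,                 # 8 when sequenced after teriparatide
      offset_years = NA_real_,             # offset equals the treatment duration
      adherence_years = c(1, 5),
      adherence_rates = c(0.706, 0.609),   # linear decline years 1-5, flat after
      persistence_years = c(1, 7),
      persistence_cum = c(0.55, 0.10),     # geometric interpolation, flat year 8+
      annual_drug_cost = 8700,
      prescription_charge = 1700,
      first_visit_cost = 3600,
      subsequent_visit_cost = 1900,
      adherence_scale = 1,
      persistence_scale = 1
    )
  )
  epi <- list(
    hip_rates = data.frame(
      age_lo = c(70, 75, 80, 85, 90, 95, 100),
      rate = c(158.1, 362.2, 851.1, 1580.2, 2466.0, 2961.7, 2471.0)
    ),
    vert_rates = data.frame(
      age_lo = c(70, 75, 80, 85, 90, 95, 100),
      rate = c(514, 1106, 2034, 2331, 3638, 4369, 3645)
    ),
    rr_prior_vf_hip = 2.3,
    rr_prior_vf_vert = 4.4,
    max_hip_fractures = 2L,
    hip_incidence_scale = 1,
    vert_incidence_scale = 1
  )
  mort <- list(
    rh_hip_year1 = 2.87,
    rh_hip_later = 1.73,
    attributable_hip = 0.25,
    attributable_vert = 0                  # 0.25 in the scenario analysis
  )
  util <- list(
    age_lo = c(65, 70, 75, 80, 85),
    baseline = c(0.862, 0.810, 0.771, 0.769, 0.684),
    du_hip_year1 = 0.776,
    du_hip_later = 0.855,
    du_vert_year1 = 0.724,
    du_vert_later = 0.868,
    utility_scale = 1
  )
  costs <- list(
    hip_medical_cost = 1726000,
    vert_first_medical_cost = 420000,
    vert_subsequent_medical_cost = 842000,
    ltc_post_hip = 876000,
    ltc_post_vert = 213000,
    blood_test_cost = 2900,
    dxa_cost = 4500,
    fracture_medical_scale = 1,
    ltc_scale = 1
  )
  econ <- list(
    discount_cost = 0.02,
    discount_qaly = 0.02,
    wtp_thresholds = c(5e6, 1e7),
    yen_per_usd = 105,
    horizon_age = 105,
    perspective = "healthcare_plus_ltc"
  )
  params <- structure(
    list(drugs = drugs, epi = epi, mort = mort, util = util,
         costs = costs, econ = econ),
    class = "cea_params"
  )
  validate_params(params)
  params
}

#' Validate a parameter set
#'
#' Checks the structural invariants of a `cea_params` object: treatment
#' relative risks in (0, 1], prior-fracture relative risks and mortality
#' relative hazards at least 1, non-negative costs and rates, probabilities in
#' range, and a horizon beyond the simulated starting ages.
#'
#' @param params A `cea_params` object.
#' @return `params`, invisibly; errors on violation.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "cea_params"))
  for (d in params$drugs) {
    if (!(d$rr_hip > 0 && d$rr_hip <= 1 && d$rr_vert > 0 && d$rr_vert <= 1))
      stop("treatment relative risks must lie in (0, 1]")
    adh <- pmin(1, d$adherence_rates * d$adherence_scale)
    if (any(adh <= 0) || any(adh > 1))
      stop("adherence rates must lie in (0, 1]")
    if (any(diff(d$persistence_cum) > 0) ||
        any(d$persistence_cum < 0) || any(d$persistence_cum > 1))
      stop("cumulative persistence must be non-increasing and in [0, 1]")
    cost_fields <- c("annual_drug_cost", "prescription_charge",
                     "first_visit_cost", "subsequent_visit_cost")
    if (any(unlist(d[cost_fields]) < 0)) stop("drug costs must be non-negative")
  }
  if (any(params$epi$hip_rates$rate < 0) || any(params$epi$vert_rates$rate < 0))
    stop("incidence rates must be non-negative")
  if (params$epi$rr_prior_vf_hip < 1 || params$epi$rr_prior_vf_vert < 1)
    stop("prior-fracture relative risks must be >= 1")
  if (params$mort$rh_hip_year1 < 1 || params$mort$rh_hip_later < 1)
    stop("mortality relative hazards must be >= 1")
  if (params$mort$attributable_hip < 0 || params$mort$attributable_hip > 1 ||
      params$mort$attributable_vert < 0 || params$mort$attributable_vert > 1)
    stop("attributable fractions must lie in [0, 1]")
  if (any(params$util$baseline <= 0) || any(params$util$baseline > 1))
    stop("baseline utilities must lie in (0, 1]")
  if (any(unlist(params$costs) < 0)) stop("costs must be non-negative")
  ec <- params$econ
  if (ec$discount_cost < 0 || ec$discount_cost > 0.10 ||
      ec$discount_qaly < 0 || ec$discount_qaly > 0.10)
    stop("discount rates must lie in [0, 0.10]")
  if (ec$horizon_age <= 70) stop("horizon age must exceed the starting ages")
  invisible(params)
}

#' @export
print.cea_params <- function(x, ...) {
  cat("Cost-effectiveness model parameters (cea_params)\n")
  cat(sprintf("  drugs: %s\n", paste(names(x$drugs), collapse = ", ")))
  cat(sprintf("  teriparatide RR hip/vert: %.2f / %.2f; annual cost %s yen\n",
              x$drugs$teriparatide$rr_hip, x$drugs$teriparatide$rr_vert,
              format(x$drugs$teriparatide$annual_drug_cost, big.mark = ",")))
  cat(sprintf("  alendronate  RR hip/vert: %.2f / %.2f; annual cost %s yen\n",
              x$drugs$alendronate$rr_hip, x$drugs$alendronate$rr_vert,
              format(x$drugs$alendronate$annual_drug_cost, big.mark = ",")))
  cat(sprintf("  discounting %.0f%%/yr, WTP %s yen/QALY, horizon age %d\n",
              100 * x$econ$discount_cost,
              paste(format(x$econ$wtp_thresholds, big.mark = ",",
                           scientific = FALSE), collapse = " / "),
              x$econ$horizon_age))
  invisible(x)
}

# ---- probability distributions for sensitivity analysis ---------------------

#' Fit a beta distribution to a printed 95% confidence interval
#'
#' Finds shape parameters such that the 2.5% and 97.5% quantiles of the beta
#' distribution equal `lo` and `hi`. Used to turn the published confidence
#' intervals of efficacy relative risks and disutility multipliers into
#' sampling distributions for probabilistic sensitivity analysis.
#'
#' @param lo,hi The 2.5% and 97.5% quantiles; must satisfy `0 < lo < hi < 1`.
#' @param tol Relative tolerance on the recovered quantiles (default 1e-6).
#' @return Named numeric vector `c(shape1, shape2)`.
#' @export
#' @examples
#' sh <- fit_beta_from_ci(0.16, 0.32)
#' stats::qbeta(c(0.025, 0.975), sh[1], sh[2])
fit_beta_from_ci <- function(lo, hi, tol = 1e-6) {
  if (!(lo > 0 && hi < 1 && lo < hi))
    stop("beta CI bounds must satisfy 0 < lo < hi < 1")
  m <- (lo + hi) / 2
  s <- (hi - lo) / (2 * stats::qnorm(0.975))
  k <- m * (1 - m) / s^2 - 1
  if (!is.finite(k) || k <= 0) k <- 2
  start <- log(c(m * k, (1 - m) * k))
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    (stats::qbeta(0.025, a, b) - lo)^2 + (stats::qbeta(0.975, a, b) - hi)^2
  }
  fit <- stats::optim(start, obj, control = list(reltol = 1e-16, maxit = 5000))
  fit <- stats::optim(fit$par, obj, control = list(reltol = 1e-16, maxit = 5000))
  sh <- exp(fit$par)
  q <- stats::qbeta(c(0.025, 0.975), sh[1], sh[2])
  if (abs(q[1] - lo) / lo > tol || abs(q[2] - hi) / hi > tol)
    stop(sprintf("beta CI fit did not converge for (%g, %g)", lo, hi))
  c(shape1 = sh[1], shape2 = sh[2])
}

#' Fit a gamma distribution to a printed 95% confidence interval
#'
#' Finds shape and rate such that the 2.5% and 97.5% gamma quantiles equal
#' `lo` and `hi`. Used for relative risks and relative hazards above 1
#' (prior-fracture fracture risks, post-hip mortality hazards).
#'
#' @param lo,hi The 2.5% and 97.5% quantiles; must satisfy `0 < lo < hi`.
#' @param tol Relative tolerance on the recovered quantiles (default 1e-6).
#' @return Named numeric vector `c(shape, rate)`.
#' @export
fit_gamma_from_ci <- function(lo, hi, tol = 1e-6) {
  if (!(lo > 0 && lo < hi))
    stop("gamma CI bounds must satisfy 0 < lo < hi")
  m <- (lo + hi) / 2
  s <- (hi - lo) / (2 * stats::qnorm(0.975))
  start <- log(c(m^2 / s^2, m / s^2))
  obj <- function(p) {
    a <- exp(p[1]); r <- exp(p[2])
    (stats::qgamma(0.025, a, rate = r) - lo)^2 +
      (stats::qgamma(0.975, a, rate = r) - hi)^2
  }
  fit <- stats::optim(start, obj, control = list(reltol = 1e-16, maxit = 5000))
  fit <- stats::optim(fit$par, obj, control = list(reltol = 1e-16, maxit = 5000))
  pr <- exp(fit$par)
  q <- stats::qgamma(c(0.025, 0.975), pr[1], rate = pr[2])
  if (abs(q[1] - lo) / lo > tol || abs(q[2] - hi) / hi > tol)
    stop(sprintf("gamma CI fit did not converge for (%g, %g)", lo, hi))
  c(shape = pr[1], rate = pr[2])
}

#' Construct a distribution specification
#'
#' @param kind One of `"fixed"`, `"triangular"`, `"beta_from_ci"`,
#'   `"gamma_from_ci"`.
#' @param base Base (and, for triangular, modal) value.
#' @param lo,hi Range bounds: triangular support, or the 95% CI for the
#'   beta/gamma fits. Ignored for `"fixed"`.
#' @return A `dist_spec` object.
#' @export
dist_spec <- function(kind = c("fixed", "triangular", "beta_from_ci",
                               "gamma_from_ci"),
                      base, lo = NA_real_, hi = NA_real_) {
  kind <- match.arg(kind)
  if (kind != "fixed") {
    if (!(lo <= base && base <= hi)) stop("need lo <= base <= hi")
    if (kind == "beta_from_ci" && !(lo > 0 && hi < 1))
      stop("beta_from_ci requires 0 < lo < hi < 1")
    if (kind == "gamma_from_ci" && !(lo > 0))
      stop("gamma_from_ci requires 0 < lo < hi")
  }
  structure(list(kind = kind, base = base, lo = lo, hi = hi),
            class = "dist_spec")
}

#' Triangular random deviates
#'
#' @param n Number of draws.
#' @param lo,mode,hi Support bounds and mode.
#' @return Numeric vector of length `n` in `[lo, hi]`.
#' @export
rtriangular <- function(n, lo, mode, hi) {
  stopifnot(lo <= mode, mode <= hi)
  if (lo == hi) return(rep(lo, n))
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(u < fc,
         lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

#' Draw one value from a distribution specification
#'
#' @param spec A `dist_spec` object.
#' @param n Number of draws (default 1).
#' @return Numeric vector of draws; `"fixed"` always returns `base`.
#' @export
sample_parameter <- function(spec, n = 1) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$kind,
    fixed = rep(spec$base, n),
    triangular = rtriangular(n, spec$lo, spec$base, spec$hi),
    beta_from_ci = {
      sh <- fit_beta_from_ci(spec$lo, spec$hi)
      stats::rbeta(n, sh[1], sh[2])
    },
    gamma_from_ci = {
      pr <- fit_gamma_from_ci(spec$lo, spec$hi)
      stats::rgamma(n, pr[1], rate = pr[2])
    }
  )
}

# ---- parameter registry -----------------------------------------------------

#' Registry of addressable model parameters
#'
#' Every parameter with a deterministic-sensitivity range or a probabilistic
#' distribution is addressable by a stable identifier (for example
#' `"teriparatide.rr_vert"`). Adherence and persistence ranges are expressed
#' as multiplicative scales on the base schedules, following the convention
#' that the first-year bound-to-base ratio carries over to later years
#' (schedule values are capped at 1). Fracture medical costs and long-term-care
#' costs vary as two grouped multipliers, matching the single printed range
#' that spans each cost block; baseline utilities vary as one multiplier.
#' `econ.discount` sets the cost and QALY discount rates jointly.
#'
#' @return A data-frame-like list of registry entries, each with `id`, `path`
#'   (list path into a `cea_params` object), `dsa_lo`/`dsa_hi` (NA when the
#'   parameter has no one-way range) and `psa` (a [dist_spec()] or NULL).
#' @export
param_registry <- function() {
  tri <- function(base, lo, hi) dist_spec("triangular", base, lo, hi)
  beta <- function(base, lo, hi) dist_spec("beta_from_ci", base, lo, hi)
  gam <- function(base, lo, hi) dist_spec("gamma_from_ci", base, lo, hi)
  e <- function(id, path, dsa_lo = NA_real_, dsa_hi = NA_real_, psa = NULL)
    list(id = id, path = path, dsa_lo = dsa_lo, dsa_hi = dsa_hi, psa = psa)
  # adherence scale bounds from Table ranges applied as ratios to the base
  t_ad <- c(0.6, 0.8) / 0.702
  a_ad <- c(0.62, 0.8) / 0.706
  entries <- list(
    e("teriparatide.rr_hip", c("drugs", "teriparatide", "rr_hip"),
      0.15, 0.73, beta(0.35, 0.15, 0.73)),
    e("teriparatide.rr_vert", c("drugs", "teriparatide", "rr_vert"),
      0.16, 0.32, beta(0.23, 0.16, 0.32)),
    e("alendronate.rr_hip", c("drugs", "alendronate", "rr_hip"),
      0.45, 0.88, beta(0.64, 0.45, 0.88)),
    e("alendronate.rr_vert", c("drugs", "alendronate", "rr_vert"),
      0.40, 0.64, beta(0.50, 0.40, 0.64)),
    e("teriparatide.adherence_scale",
      c("drugs", "teriparatide", "adherence_scale"),
      t_ad[1], t_ad[2], tri(1, t_ad[1], t_ad[2])),
    e("alendronate.adherence_scale",
      c("drugs", "alendronate", "adherence_scale"),
      a_ad[1], a_ad[2], tri(1, a_ad[1], a_ad[2])),
    e("teriparatide.persistence_scale",
      c("drugs", "teriparatide", "persistence_scale"),
      0.85, 1.15, tri(1, 0.85, 1.15)),
    e("alendronate.persistence_scale",
      c("drugs", "alendronate", "persistence_scale"),
      0.85, 1.15, tri(1, 0.85, 1.15)),
    e("teriparatide.annual_drug_cost",
      c("drugs", "teriparatide", "annual_drug_cost")),
    e("teriparatide.offset_years", c("drugs", "teriparatide", "offset_years")),
    e("epi.hip_incidence_scale", c("epi", "hip_incidence_scale"),
      0.5, 1.5, tri(1, 0.9, 1.1)),
    e("epi.vert_incidence_scale", c("epi", "vert_incidence_scale"),
      0.5, 1.5, tri(1, 0.75, 1.25)),
    e("epi.rr_prior_vf_hip", c("epi", "rr_prior_vf_hip"),
      psa = gam(2.3, 2.0, 2.8)),
    e("epi.rr_prior_vf_vert", c("epi", "rr_prior_vf_vert"),
      psa = gam(4.4, 3.6, 5.4)),
    e("mort.rh_hip_year1", c("mort", "rh_hip_year1"),
      psa = gam(2.87, 2.52, 3.27)),
    e("mort.rh_hip_later", c("mort", "rh_hip_later"),
      psa = gam(1.73, 1.56, 1.90)),
    e("mort.attributable_hip", c("mort", "attributable_hip"),
      psa = tri(0.25, 0, 0.5)),
    e("mort.attributable_vert", c("mort", "attributable_vert")),
    e("costs.fracture_medical_scale", c("costs", "fracture_medical_scale"),
      0.5, 1.5, tri(1, 0.5, 1.5)),
    e("costs.ltc_scale", c("costs", "ltc_scale"),
      0.5, 1.5, tri(1, 0.5, 1.5)),
    e("util.utility_scale", c("util", "utility_scale"),
      psa = tri(1, 0.85, 1.15)),
    e("util.du_hip_year1", c("util", "du_hip_year1"),
      psa = beta(0.776, 0.720, 0.844)),
    e("util.du_hip_later", c("util", "du_hip_later"),
      psa = beta(0.855, 0.800, 0.909)),
    e("util.du_vert_year1", c("util", "du_vert_year1"),
      psa = beta(0.724, 0.667, 0.779)),
    e("util.du_vert_later", c("util", "du_vert_later"),
      psa = beta(0.868, 0.827, 0.922)),
    e("econ.discount", c("econ", "discount"), psa = tri(0.02, 0, 0.04))
  )
  names(entries) <- vapply(entries, `[[`, "", "id")
  entries
}

#' Parameter identifiers
#'
#' @param with_dsa_range If `TRUE`, only identifiers with a one-way
#'   deterministic-sensitivity range.
#' @param with_psa If `TRUE`, only identifiers with a probabilistic
#'   distribution.
#' @return Character vector of identifiers accepted by [set_param()].
#' @export
param_ids <- function(with_dsa_range = FALSE, with_psa = FALSE) {
  reg <- param_registry()
  ids <- names(reg)
  if (with_dsa_range)
    ids <- ids[vapply(reg, function(x) is.finite(x$dsa_lo), TRUE)]
  if (with_psa)
    ids <- ids[vapply(reg, function(x) !is.null(x$psa), TRUE)]
  ids
}

#' Read a parameter by identifier
#'
#' @param params A `cea_params` object.
#' @param id A registry identifier (see [param_ids()]).
#' @return The current value (for `econ.discount`, the cost discount rate).
#' @export
get_param <- function(params, id) {
  reg <- param_registry()
  if (!id %in% names(reg))
    stop(sprintf("unknown parameter id '%s'; valid ids: %s",
                 id, paste(names(reg), collapse = ", ")))
  if (id == "econ.discount") return(params$econ$discount_cost)
  params[[reg[[id]]$path]]
}

#' Set a parameter by identifier
#'
#' @param params A `cea_params` object.
#' @param id A registry identifier (see [param_ids()]).
#' @param value New value. `econ.discount` sets both cost and QALY discount
#'   rates.
#' @return The modified `cea_params` object.
#' @export
set_param <- function(params, id, value) {
  reg <- param_registry()
  if (!id %in% names(reg))
    stop(sprintf("unknown parameter id '%s'; valid ids: %s",
                 id, paste(names(reg), collapse = ", ")))
  if (id == "econ.discount") {
    params$econ$discount_cost <- value
    params$econ$discount_qaly <- value
  } else {
    params[[reg[[id]]$path]] <- value
  }
  params
}

#' Apply parameter overrides from a list or a YAML/JSON file
#'
#' @param params A `cea_params` object.
#' @param overrides Either a named list of `id = value` pairs or the path of a
#'   YAML or JSON file containing one. Unknown identifiers are an error.
#' @return The modified `cea_params` object.
#' @export
apply_overrides <- function(params, overrides) {
  if (is.character(overrides) && length(overrides) == 1) {
    overrides <- if (grepl("\\.json$", overrides, ignore.case = TRUE))
      jsonlite::fromJSON(overrides)
    else
      yaml::read_yaml(overrides)
  }
  if (length(overrides) == 0) return(params)
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    stop("overrides must be a named list of parameter id = value")
  for (id in names(overrides))
    params <- set_param(params, id, overrides[[id]])
  validate_params(params)
  params
}
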