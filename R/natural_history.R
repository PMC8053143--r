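band_rate <- function(table, age) {
  idx <- findInterval(age, table$age_lo)
  if (any(idx == 0))
    stop(sprintf("age %s below the first incidence band (%d)",
                 paste(age[idx == 0], collapse = ", "), table$age_lo[1]))
  table$rate[idx]
}

#' Annual fracture probability
#'
#' Converts the age-band incidence rate (per 100,000 person-years, without
#' intervention) into a per-cycle probability via the rate-to-risk transform
#' `1 - exp(-r)`, after multiplying the rate by the prior-vertebral-fracture
#' relative risk (the whole cohort has a prior vertebral fracture), the
#' current treatment relative-risk multiplier, and any incidence scaling.
#' Returns 0 for hip fractures once the two-hip-fracture maximum is reached.
#'
#' @param fracture_type `"hip"` or `"vertebral"`.
#' @param age Age in years (vectorised); must be covered by the bands.
#' @param treatment_multiplier Effective relative-risk multiplier in `(0, 1]`.
#' @param n_hip Number of hip fractures already sustained.
#' @param params A `cea_params` object.
#' @return Fracture probabilities in `[0, 1)`.
#' @export
#' @examples
#' annual_fracture_prob("hip", 82)  # 1 - exp(-851.1e-5 * 2.3)
annual_fracture_prob <- function(fracture_type = c("hip", "vertebral"), age,
                                 treatment_multiplier = 1, n_hip = 0,
                                 params = default_parameters()) {
  fracture_type <- match.arg(fracture_type)
  epi <- params$epi
  if (fracture_type == "hip") {
    r <- band_rate(epi$hip_rates, age) * 1e-5 * epi$rr_prior_vf_hip *
      epi$hip_incidence_scale * treatment_multiplier
    p <- 1 - exp(-r)
    p[n_hip >= epi$max_hip_fractures] <- 0
    p
  } else {
    r <- band_rate(epi$vert_rates, age) * 1e-5 * epi$rr_prior_vf_vert *
      epi$vert_incidence_scale * treatment_multiplier
    1 - exp(-r)
  }
}

#' Annual death probability
#'
#' Converts the life-table annual death probability at the given age to a
#' hazard, applies the post-fracture excess-mortality multiplier
#' `1 + attributable_fraction * (relative_hazard - 1)`, and converts back to
#' a probability. The relative hazard after a hip fracture is 2.87 during the
#' fracture year itself (`years_since_hip = 0`) and 1.73 from the following
#' year onward, lifelong; the attributable fraction (base 0.25) reflects that
#' comorbidities, not the fracture, drive most of the observed excess
#' mortality. The vertebral analogue is active only in the excess
#' vertebral-mortality scenario (`attributable_vert > 0`), where the hip
#' relative hazards are applied to vertebral fracture history.
#'
#' @param age Age in years (vectorised).
#' @param life_table A `life_table` object.
#' @param years_since_hip Whole years since the most recent hip fracture
#'   (0 = this cycle); `NA` if never fractured.
#' @param years_since_vert As above for clinical vertebral fracture.
#' @param params A `cea_params` object.
#' @return Death probabilities in `(0, 1]`.
#' @export
annual_death_prob <- function(age, life_table, years_since_hip = NA,
                              years_since_vert = NA,
                              params = default_parameters()) {
  qx <- life_table_qx(life_table, age)
  h <- -log(1 - pmin(qx, 1 - 1e-12))
  m <- mortality_multiplier(years_since_hip, years_since_vert, params$mort)
  1 - exp(-h * m)
}

# excess-mortality hazard multiplier from fracture history (vectorised)
mortality_multiplier <- function(years_since_hip, years_since_vert, mort) {
  rh_hip <- ifelse(is.na(years_since_hip), 1,
                   ifelse(years_since_hip == 0, mort$rh_hip_year1,
                          mort$rh_hip_later))
  m <- 1 + mort$attributable_hip * (rh_hip - 1)
  if (mort$attributable_vert > 0) {
    rh_vert <- ifelse(is.na(years_since_vert), 1,
                      ifelse(years_since_vert == 0, mort$rh_hip_year1,
                             mort$rh_hip_later))
    m <- m * (1 + mort$attributable_vert * (rh_vert - 1))
  }
  m
}

#' Sample one cycle's events for one woman
#'
#' At most one fracture can occur per cycle; hip fracture takes precedence
#' over vertebral fracture (the vertebral draw is made only if no hip
#' fracture occurred), and death is sampled after the fracture so that the
#' within-a-year excess hazard applies in the fracture cycle itself.
#'
#' @param state List with elements `age`, `n_hip`, `n_vert`,
#'   `years_since_hip`, `years_since_vert` (years since last fracture, `NA`
#'   if none).
#' @param probs List with elements `hip`, `vert` (fracture probabilities
#'   already reflecting treatment) — death is computed here from `life_table`.
#' @param life_table A `life_table` object.
#' @param params A `cea_params` object.
#' @return List with logical `hip`, `vert`, `death` and the updated `state`.
#' @export
sample_cycle_events <- function(state, probs, life_table,
                                params = default_parameters()) {
  hip <- state$n_hip < params$epi$max_hip_fractures &&
    stats::runif(1) < probs$hip
  vert <- !hip && stats::runif(1) < probs$vert
  if (hip) {
    state$n_hip <- state$n_hip + 1L
    state$years_since_hip <- 0L
  }
  if (vert) {
    state$n_vert <- state$n_vert + 1L
    state$years_since_vert <- 0L
  }
  p_death <- annual_death_prob(state$age, life_table, state$years_since_hip,
                               state$years_since_vert, params)
  death <- stats::runif(1) < p_death
  state$alive <- !death
  state$age <- state$age + 1L
  if (!is.na(state$years_since_hip))
    state$years_since_hip <- state$years_since_hip + 1L
  if (!is.na(state$years_since_vert))
    state$years_since_vert <- state$years_since_vert + 1L
  list(hip = hip, vert = vert, death = death, state = state)
}
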