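#' Treatment strategies
#'
#' A strategy is an ordered list of treatment phases, each a drug taken for a
#' fixed number of years (if the woman persists). The three strategies of the
#' analysis are sequential teriparatide/alendronate (2 years of daily
#' teriparatide followed by 8 years of weekly alendronate), alendronate
#' monotherapy (10 years), and no intervention.
#'
#' In the sequential strategy a woman who completes teriparatide starts the
#' alendronate adherence and persistence schedules at their year-1 values; a
#' woman who discontinues teriparatide does not start alendronate and instead
#' enters the teriparatide offset phase.
#'
#' @param name One of `"sequential"`, `"alendronate_mono"`,
#'   `"no_intervention"`.
#' @return A `cea_strategy` object.
#' @export
#' @examples
#' strategy("sequential")
strategy <- function(name = c("sequential", "alendronate_mono",
                              "no_intervention")) {
  name <- match.arg(name)
  phases <- switch(name,
    sequential = list(list(drug = "teriparatide", years = 2),
                      list(drug = "alendronate", years = 8)),
    alendronate_mono = list(list(drug = "alendronate", years = 10)),
    no_intervention = list()
  )
  structure(list(name = name, phases = phases), class = "cea_strategy")
}

#' @export
print.cea_strategy <- function(x, ...) {
  if (length(x$phases) == 0) {
    cat(sprintf("Strategy '%s': no treatment\n", x$name))
  } else {
    ph <- vapply(x$phases, function(p) sprintf("%s %dy", p$drug, p$years), "")
    cat(sprintf("Strategy '%s': %s\n", x$name, paste(ph, collapse = " -> ")))
  }
  invisible(x)
}

drug_params <- function(params, drug) {
  d <- params$drugs[[drug]]
  if (is.null(d)) stop(sprintf("unknown drug '%s'", drug))
  d
}

# Base (unscaled) annual continuation probabilities implied by the printed
# cumulative persistence anchors. Alendronate: 55% at year 1 falling to 10% at
# year 7 with a constant annual continuation ratio (geometric interpolation),
# then no dropout through year 10. Teriparatide: 68.0% at year 1, 51.6% at
# year 2.
base_annual_continuation <- function(d, years) {
  y1 <- d$persistence_cum[1]
  if (d$name == "alendronate") {
    ratio <- (d$persistence_cum[2] / y1)^(1 / (d$persistence_years[2] - 1))
    p <- c(y1, rep(ratio, d$persistence_years[2] - 1),
           rep(1, max(0, years - d$persistence_years[2])))
  } else {
    p <- c(y1, d$persistence_cum[2] / y1, rep(1, max(0, years - 2)))
  }
  p[seq_len(years)]
}

#' Cumulative persistence with a drug
#'
#' Probability of still being on the drug at the end of the given treatment
#' year. Deterministic-sensitivity scaling (`persistence_scale`) applies to
#' the annual continuation probabilities, capped at 1, and the cumulative
#' curve is rebuilt as their running product.
#'
#' @param drug `"teriparatide"` or `"alendronate"`.
#' @param year Treatment year within the drug's phase (1-based); vectorised.
#' @param params A `cea_params` object.
#' @return Cumulative persistence probabilities in `[0, 1]`.
#' @export
#' @examples
#' cumulative_persistence("alendronate", 1:10)
cumulative_persistence <- function(drug, year, params = default_parameters()) {
  stopifnot(all(year >= 1))
  d <- drug_params(params, drug)
  ann <- pmin(1, base_annual_continuation(d, max(year)) * d$persistence_scale)
  cumprod(ann)[year]
}

#' Annual continuation probability
#'
#' Per-cycle probability of persisting through treatment year `year` given
#' persistence through year `year - 1`; the ratio `S(year)/S(year-1)` of the
#' cumulative persistence curve, with `S(0) = 1`.
#'
#' @inheritParams cumulative_persistence
#' @return Probabilities in `(0, 1]`.
#' @export
annual_continuation_prob <- function(drug, year,
                                     params = default_parameters()) {
  stopifnot(all(year >= 1))
  d <- drug_params(params, drug)
  pmin(1, base_annual_continuation(d, max(year)) * d$persistence_scale)[year]
}

#' Adherence rate while on a drug
#'
#' Fraction of prescribed doses taken during a treatment year by a persisting
#' woman. Alendronate declines linearly from 70.6% (year 1) to 60.9%
#' (year 5) and stays flat from year 6 onward; teriparatide is 70.2% in year
#' 1 and 67.8% in year 2. Sensitivity scaling multiplies the schedule,
#' capped at 1.
#'
#' @inheritParams cumulative_persistence
#' @return Adherence rates in `(0, 1]`.
#' @export
adherence <- function(drug, year, params = default_parameters()) {
  stopifnot(all(year >= 1))
  d <- drug_params(params, drug)
  y1 <- d$adherence_years[1]; y2 <- d$adherence_years[2]
  a1 <- d$adherence_rates[1]; a2 <- d$adherence_rates[2]
  yr <- pmin(pmax(year, y1), y2)
  base <- a1 + (a2 - a1) * (yr - y1) / (y2 - y1)
  pmin(1, base * d$adherence_scale)
}

#' Effective relative risk on treatment
#'
#' Community effectiveness of a drug in a given treatment year, assuming a
#' linear relationship between relative risk reduction and adherence:
#' `1 - adherence * (1 - trial RR)`. Applies only to women who persist to the
#' end of the cycle; non-persisting women receive no protection that cycle.
#'
#' @param drug `"teriparatide"` or `"alendronate"`.
#' @param fracture_type `"hip"` or `"vertebral"`.
#' @param year Treatment year within the drug's phase (1-based); vectorised.
#' @param params A `cea_params` object.
#' @return Relative-risk multipliers in `(0, 1]`.
#' @export
#' @examples
#' effective_rr("teriparatide", "vertebral", 1)  # 1 - 0.702 * (1 - 0.23)
effective_rr <- function(drug, fracture_type = c("hip", "vertebral"), year,
                         params = default_parameters()) {
  fracture_type <- match.arg(fracture_type)
  d <- drug_params(params, drug)
  rr <- if (fracture_type == "hip") d$rr_hip else d$rr_vert
  1 - adherence(drug, year, params) * (1 - rr)
}

#' Offset-phase state after stopping a drug
#'
#' Captures when and how a woman left treatment: the drug, the number of
#' completed years on it, the planned phase duration, and the full offset
#' length for completers. For early discontinuers the offset length is scaled
#' down in proportion to time on treatment.
#'
#' @param drug `"teriparatide"` or `"alendronate"`.
#' @param years_taken Completed years on the drug at stopping.
#' @param phase_duration Planned years of the treatment phase.
#' @param params A `cea_params` object (supplies the teriparatide offset
#'   length; the alendronate offset equals its phase duration).
#' @return An `offset_state` list with elements `drug`, `years_taken`,
#'   `offset_length`, `rr_hip_at_stop`, `rr_vert_at_stop`.
#' @export
offset_state <- function(drug, years_taken, phase_duration,
                         params = default_parameters()) {
  d <- drug_params(params, drug)
  full_offset <- if (is.na(d$offset_years)) phase_duration else d$offset_years
  structure(list(
    drug = drug,
    years_taken = years_taken,
    offset_length = full_offset * years_taken / phase_duration,
    rr_hip_at_stop = if (years_taken >= 1)
      effective_rr(drug, "hip", years_taken, params) else 1,
    rr_vert_at_stop = if (years_taken >= 1)
      effective_rr(drug, "vertebral", years_taken, params) else 1
  ), class = "offset_state")
}

#' Relative risk during the offset phase
#'
#' After stopping therapy, fracture risk returns linearly to the untreated
#' level over the offset length: the multiplier interpolates from the last
#' on-treatment effective relative risk to 1 as `years_since_stop` runs from
#' 0 to `offset_length`, and is exactly 1 once `years_since_stop >=
#' offset_length`.
#'
#' @param state An [offset_state()] object.
#' @param fracture_type `"hip"` or `"vertebral"`.
#' @param years_since_stop Whole years since stopping (>= 1); vectorised.
#' @return Relative-risk multipliers in `(0, 1]`, non-decreasing in
#'   `years_since_stop`.
#' @export
offset_rr <- function(state, fracture_type = c("hip", "vertebral"),
                      years_since_stop) {
  fracture_type <- match.arg(fracture_type)
  stopifnot(all(years_since_stop >= 1))
  rr0 <- if (fracture_type == "hip") state$rr_hip_at_stop
         else state$rr_vert_at_stop
  if (state$offset_length <= 0) return(rep(1, length(years_since_stop)))
  frac <- pmin(1, years_since_stop / state$offset_length)
  rr0 + (1 - rr0) * frac
}
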