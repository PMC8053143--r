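perspective_cost <- function(result, perspective) {
  switch(perspective,
         healthcare_plus_ltc = result$mean_cost_healthcare +
           result$mean_cost_ltc,
         healthcare_only = result$mean_cost_healthcare,
         stop(sprintf("unknown perspective '%s'", perspective)))
}

#' Incremental cost-effectiveness comparison
#'
#' Compares an intervention cohort against a comparator cohort run at the
#' same starting age: incremental cost (perspective-appropriate sum of
#' sectors), incremental QALYs, the ICER when both increments are positive,
#' and dominance labels otherwise (`"dominant"` when cheaper and more
#' effective, `"dominated"` when costlier and not more effective, including
#' the infinite-ICER case of extra cost with zero QALY gain).
#'
#' @param intervention,comparator `cohort_result` objects from [run_cohort()]
#'   at the same starting age.
#' @param econ Economic settings (`params$econ`); supplies the perspective,
#'   willingness-to-pay thresholds and exchange rate.
#' @return A `comparison_result` object with `delta_cost` (yen),
#'   `delta_qaly`, `icer` (yen/QALY, or `Inf`/`-Inf` in dominance cases),
#'   `dominance` (`"dominant"`, `"dominated"` or `NA`), `icer_usd` and
#'   `cost_effective_at`, a named logical vector over the thresholds.
#' @export
compare_strategies <- function(intervention, comparator,
                               econ = default_parameters()$econ) {
  stopifnot(inherits(intervention, "cohort_result"),
            inherits(comparator, "cohort_result"))
  if (intervention$start_age != comparator$start_age)
    stop("cohorts must share the same starting age")
  dc <- perspective_cost(intervention, econ$perspective) -
    perspective_cost(comparator, econ$perspective)
  dq <- intervention$mean_qaly - comparator$mean_qaly
  dominance <- NA_character_
  if (dc > 0 && dq > 0) {
    icer <- dc / dq
  } else if (dc <= 0 && dq >= 0) {
    dominance <- "dominant"
    icer <- -Inf
  } else if (dc >= 0 && dq <= 0) {
    dominance <- "dominated"
    icer <- Inf
  } else {
    # cheaper and less effective: south-west quadrant, report the ratio
    icer <- dc / dq
    dominance <- "sw_quadrant"
  }
  wtp <- econ$wtp_thresholds
  ce <- if (identical(dominance, "dominant")) rep(TRUE, length(wtp))
        else if (identical(dominance, "dominated")) rep(FALSE, length(wtp))
        else if (identical(dominance, "sw_quadrant")) wtp * dq - dc >= 0
        else icer <= wtp
  names(ce) <- format(wtp, scientific = FALSE, trim = TRUE)
  structure(list(
    start_age = intervention$start_age,
    perspective = econ$perspective,
    delta_cost = dc, delta_qaly = dq,
    icer = icer, dominance = dominance,
    icer_usd = icer / econ$yen_per_usd,
    cost_effective_at = ce
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Incremental comparison (age %d, %s)\n", x$start_age,
              x$perspective))
  cat(sprintf("  delta cost: %s yen; delta QALY: %.4f\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly))
  if (!is.na(x$dominance) && x$dominance %in% c("dominant", "dominated")) {
    cat(sprintf("  %s\n", x$dominance))
  } else {
    cat(sprintf("  ICER: %s yen/QALY (%s $/QALY)\n",
                format(round(x$icer), big.mark = ","),
                format(round(x$icer_usd), big.mark = ",")))
  }
  for (w in names(x$cost_effective_at))
    cat(sprintf("  cost-effective at WTP %s: %s\n", w,
                x$cost_effective_at[[w]]))
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * mean QALYs - perspective cost` for one cohort. For a two-strategy
#' comparison, the intervention has the higher net monetary benefit at a
#' willingness-to-pay exactly when [compare_strategies()] classifies it as
#' cost-effective at that threshold.
#'
#' @param result A `cohort_result` object.
#' @param wtp Willingness-to-pay threshold (yen/QALY, >= 0); vectorised.
#' @param econ Economic settings (supplies the perspective).
#' @return Net monetary benefit in yen.
#' @export
net_monetary_benefit <- function(result, wtp,
                                 econ = default_parameters()$econ) {
  stopifnot(all(wtp >= 0))
  wtp * result$mean_qaly - perspective_cost(result, econ$perspective)
}

#' Convert yen to US dollars
#'
#' @param yen Amount in yen.
#' @param yen_per_usd Exchange rate (the analysis uses 105).
#' @return Amount in US dollars.
#' @export
yen_to_usd <- function(yen, yen_per_usd = 105) yen / yen_per_usd
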