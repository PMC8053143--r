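# Brute-force expected-value oracle for a 2-cycle horizon.
#
# Exhaustively enumerates the event tree (treatment continuation x fracture x
# death over two annual cycles) for a single-drug treatment phase and returns
# the exact expected discounted healthcare cost, long-term-care cost and
# QALYs. Written as independent scalar arithmetic over the printed parameter
# values; it deliberately does not call the simulation engine.

oracle_two_cycles <- function(drug = c("teriparatide", "alendronate", "none"),
                              start_age = 70,
                              params = default_parameters()) {
  drug <- match.arg(drug)
  cs <- params$costs
  ut <- params$util
  mt <- params$mort
  lt <- make_synthetic_life_table()

  if (drug == "none") {
    dr <- NULL
  } else {
    d <- params$drugs[[drug]]
    # schedule values by direct arithmetic on the printed anchors
    if (drug == "teriparatide") {
      cont <- c(0.68, 0.516 / 0.68)
      adh <- c(0.702, 0.678)
    } else {
      cont <- c(0.55, (0.10 / 0.55)^(1 / 6))
      adh <- c(0.706, 0.706 + (0.609 - 0.706) / 4)
    }
    dr <- list(
      cont = cont, adh = adh,
      mh = 1 - adh * (1 - d$rr_hip),
      mv = 1 - adh * (1 - d$rr_vert),
      annual = d$annual_drug_cost, rx = d$prescription_charge,
      fv = d$first_visit_cost, sv = d$subsequent_visit_cost
    )
  }

  band <- function(tab, age) tab$rate[findInterval(age, tab$age_lo)]
  p_frac <- function(type, age, mult) {
    rr <- if (type == "hip") params$epi$rr_prior_vf_hip
          else params$epi$rr_prior_vf_vert
    tab <- if (type == "hip") params$epi$hip_rates else params$epi$vert_rates
    1 - exp(-band(tab, age) * 1e-5 * rr * mult)
  }
  p_die <- function(age, hip_now, hip_prior) {
    qx <- lt$qx[match(age, lt$age)]
    rh <- if (hip_now) mt$rh_hip_year1 else if (hip_prior) mt$rh_hip_later
          else 1
    m <- 1 + mt$attributable_hip * (rh - 1)
    1 - exp(log(1 - qx) * m)
  }
  base_u <- function(age) ut$baseline[findInterval(age, ut$age_lo)]

  exp_cost_hc <- exp_cost_ltc <- exp_qaly <- 0
  df_c <- function(t) (1 + params$econ$discount_cost)^-t
  df_q <- function(t) (1 + params$econ$discount_qaly)^-t

  # status: "persist", "discontinue", "none"; returns treatment HC cost
  treat_cost <- function(status, year) {
    if (is.null(dr) || status == "none") return(0)
    if (status == "persist") {
      visits <- if (year == 1) dr$fv + 3 * dr$sv else 4 * dr$sv
      dxa <- if (year == 2) cs$dxa_cost else 0
      dr$annual * dr$adh[year] + dr$rx + visits + 2 * cs$blood_test_cost + dxa
    } else {
      if (year == 1) dr$annual / 4 + dr$fv else dr$sv
    }
  }

  status_branches <- function(year, prev_persisted) {
    if (is.null(dr) || !prev_persisted) return(list(list(p = 1, s = "none")))
    list(list(p = dr$cont[year], s = "persist"),
         list(p = 1 - dr$cont[year], s = "discontinue"))
  }

  for (s1 in status_branches(1, TRUE)) {
    mh1 <- if (s1$s == "persist") dr$mh[1] else 1
    mv1 <- if (s1$s == "persist") dr$mv[1] else 1
    ph1 <- p_frac("hip", start_age, mh1)
    pv1 <- p_frac("vertebral", start_age, mv1)
    for (ev1 in list(list(p = ph1, hip = TRUE, vert = FALSE),
                     list(p = (1 - ph1) * pv1, hip = FALSE, vert = TRUE),
                     list(p = (1 - ph1) * (1 - pv1), hip = FALSE,
                          vert = FALSE))) {
      pd1 <- p_die(start_age, ev1$hip, FALSE)
      for (death1 in c(TRUE, FALSE)) {
        p1 <- s1$p * ev1$p * (if (death1) pd1 else 1 - pd1)
        if (p1 == 0) next
        # cycle-1 accounting
        u1 <- if (death1) 0 else
          base_u(start_age) * (if (ev1$hip) ut$du_hip_year1 else 1) *
            (if (ev1$vert) ut$du_vert_year1 else 1)
        hc1 <- (if (death1) 0 else treat_cost(s1$s, 1)) +
          (if (ev1$hip) cs$hip_medical_cost else 0) +
          (if (ev1$vert) cs$vert_first_medical_cost else 0)
        ltc1 <- if (ev1$hip) cs$ltc_post_hip / 2
                else if (ev1$vert) cs$ltc_post_vert / 2 else 0
        exp_qaly <- exp_qaly + p1 * u1 * df_q(0)
        exp_cost_hc <- exp_cost_hc + p1 * hc1 * df_c(0)
        exp_cost_ltc <- exp_cost_ltc + p1 * ltc1 * df_c(0)
        if (death1) next
        # cycle 2
        age2 <- start_age + 1
        for (s2 in status_branches(2, s1$s == "persist")) {
          mh2 <- if (s2$s == "persist") dr$mh[2] else 1
          mv2 <- if (s2$s == "persist") dr$mv[2] else 1
          ph2 <- p_frac("hip", age2, mh2)   # n_hip <= 1, still below the cap
          pv2 <- p_frac("vertebral", age2, mv2)
          for (ev2 in list(list(p = ph2, hip = TRUE, vert = FALSE),
                           list(p = (1 - ph2) * pv2, hip = FALSE,
                                vert = TRUE),
                           list(p = (1 - ph2) * (1 - pv2), hip = FALSE,
                                vert = FALSE))) {
            pd2 <- p_die(age2, ev2$hip, ev1$hip)
            for (death2 in c(TRUE, FALSE)) {
              p2 <- p1 * s2$p * ev2$p * (if (death2) pd2 else 1 - pd2)
              if (p2 == 0) next
              fh <- if (ev2$hip) ut$du_hip_year1
                    else if (ev1$hip) ut$du_hip_later else 1
              fv <- if (ev2$vert) ut$du_vert_year1
                    else if (ev1$vert) ut$du_vert_later else 1
              u2 <- if (death2) 0 else base_u(age2) * fh * fv
              fx2 <- (if (ev2$hip) cs$hip_medical_cost else 0) +
                (if (ev2$vert) {
                  if (ev1$vert) cs$vert_subsequent_medical_cost
                  else cs$vert_first_medical_cost
                } else 0)
              hc2 <- (if (death2) 0 else treat_cost(s2$s, 2)) + fx2
              post_hip <- ev1$hip || ev2$hip
              post_vert <- ev1$vert || ev2$vert
              ltc2 <- if (post_hip) {
                cs$ltc_post_hip * (if (ev2$hip && !ev1$hip) 0.5 else 1)
              } else if (post_vert) {
                cs$ltc_post_vert * (if (ev2$vert && !ev1$vert) 0.5 else 1)
              } else 0
              exp_qaly <- exp_qaly + p2 * u2 * df_q(1)
              exp_cost_hc <- exp_cost_hc + p2 * hc2 * df_c(1)
              exp_cost_ltc <- exp_cost_ltc + p2 * ltc2 * df_c(1)
            }
          }
        }
      }
    }
  }
  list(cost_hc = exp_cost_hc, cost_ltc = exp_cost_ltc, qaly = exp_qaly)
}

# life table with constant death probability at every age (test fixture)
flat_life_table <- function(qx, from = 60, to = 105) {
  structure(data.frame(age = from:to, qx = qx),
            class = c("life_table", "data.frame"))
}
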