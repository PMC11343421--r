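# Outcome accrual.
#
# State-based quantities (life-years, state utilities, disease-management and
# drug cost) use half-cycle-corrected occupancy: the mean of cycle-start and
# cycle-end occupancy, approximating mid-cycle transitions. Event-based
# quantities (hHF, AEs, death costs and the associated utility losses) apply
# in full in the cycle they occur, discounted at that cycle. One hHF event
# costs a full 0.335 QALYs (decrement held for twelve months); one AE event
# costs |disutility|/12 QALYs (decrement held one month).

#' Accrue costs, life-years and QALYs over a cohort trace
#'
#' @param trace a `cohort_trace` from [run_cohort()].
#' @param p the `model_parameters` bundle the trace was run under.
#' @return object of class `outcome_summary` with `discounted` and
#'   `undiscounted` blocks (LY and QALY totals and per-state splits, QALY
#'   losses due to hHF and AEs, cost categories), cumulative expected event
#'   counts, event rates per 100 person-years, alive person-years, and mean
#'   undiscounted years on treatment.
#' @export
accrue_outcomes <- function(trace, p) {
  occ <- trace$occupancy
  n <- trace$n_cycles
  ev <- trace$events
  ec <- p$economics
  arm <- trace$arm

  occ_start <- occ[1:n, , drop = FALSE]
  occ_end <- occ[2:(n + 1), , drop = FALSE]
  occ_mid <- if (isTRUE(ec$half_cycle_correction)) {
    (occ_start + occ_end) / 2
  } else {
    occ_start
  }

  # occupancy collapsed over treatment status, by alive state
  state_mid <- occ_mid[, 1:4, drop = FALSE] + occ_mid[, 5:8, drop = FALSE]
  colnames(state_mid) <- ALIVE_STATES
  alive_mid <- rowSums(state_mid)
  on_mid <- rowSums(occ_mid[, 1:4, drop = FALSE])

  cyc <- seq_len(n) - 1
  df_b <- discount_factor(ec$annual_discount_rate_benefit, cyc)
  df_c <- discount_factor(ec$annual_discount_rate_cost, cyc)

  ae <- p$adverse_events[p$adverse_events$include, , drop = FALSE]
  ae_cols <- if (nrow(ae)) paste0("ae_", ae$event) else character()
  ae_ev <- as.matrix(ev[, ae_cols, drop = FALSE])

  u <- p$utilities$state_utility[ALIVE_STATES]
  hhf_qaly_per_event <- p$utilities$hhf_disutility *
    p$utilities$hhf_disutility_duration / 12
  ae_qaly_per_event <- ae$disutility * ae$duration_months / 12

  cs <- p$costs
  drug_on <- cs$monthly_drug_cost[["EPG_SOC"]]
  drug_off <- cs$monthly_drug_cost[["SOC"]]

  block <- function(dfb, dfc) {
    ly_state <- colSums(state_mid * dfb) / 12
    qaly_state <- (t(state_mid) %*% dfb)[, 1] * u / 12
    qaly_loss_hhf <- sum(ev$hhf * dfb) * hhf_qaly_per_event
    qaly_loss_ae <- if (nrow(ae)) {
      sum((t(ae_ev) %*% dfb)[, 1] * ae_qaly_per_event)
    } else 0

    cost_drug <- sum((on_mid * drug_on + (alive_mid - on_mid) * drug_off) * dfc)
    cost_hhf <- sum(ev$hhf * dfc) * cs$hhf_cost
    cost_cv_death <- sum(ev$cv_deaths * dfc) * cs$cv_death_cost
    cost_noncv_death <- sum(ev$noncv_deaths * dfc) * cs$noncv_death_cost
    cost_ae_by_event <- if (nrow(ae)) {
      x <- (t(ae_ev) %*% dfc)[, 1] * ae$unit_cost
      names(x) <- ae$event
      x
    } else numeric()
    cost_mgmt_state <- (t(state_mid) %*% dfc)[, 1] * cs$monthly_disease_mgmt_cost
    names(cost_mgmt_state) <- ALIVE_STATES

    cost_event <- cost_hhf + cost_cv_death + cost_noncv_death
    cost_ae <- sum(cost_ae_by_event)
    cost_mgmt <- sum(cost_mgmt_state)
    list(
      ly = list(total = sum(ly_state), by_state = ly_state),
      qaly = list(total = sum(qaly_state) + qaly_loss_hhf + qaly_loss_ae,
                  by_state = qaly_state,
                  loss_hhf = qaly_loss_hhf, loss_ae = qaly_loss_ae),
      cost = list(total = cost_drug + cost_event + cost_ae + cost_mgmt,
                  drug = cost_drug, hhf = cost_hhf,
                  cv_death = cost_cv_death, noncv_death = cost_noncv_death,
                  ae = cost_ae, ae_by_event = cost_ae_by_event,
                  disease_mgmt = cost_mgmt,
                  disease_mgmt_by_state = cost_mgmt_state)
    )
  }

  undiscounted <- block(rep(1, n), rep(1, n))
  discounted <- block(df_b, df_c)

  person_years <- sum(alive_mid) / 12
  totals <- c(hhf = sum(ev$hhf), cv_death = sum(ev$cv_deaths),
              noncv_death = sum(ev$noncv_deaths),
              discontinuation = sum(ev$discontinuations))
  ae_totals <- if (nrow(ae)) colSums(ae_ev) else numeric()
  if (nrow(ae)) names(ae_totals) <- ae$event
  rates <- c(100 * totals[c("hhf", "cv_death", "noncv_death")] / person_years,
             ae_aggregate = unname(100 * sum(ae_totals) / person_years),
             100 * ae_totals / person_years)

  structure(list(
    arm = arm,
    discounted = discounted,
    undiscounted = undiscounted,
    events_total = c(totals, ae_totals),
    event_rates_per_100py = rates,
    person_years = person_years,
    years_on_treatment = mean_time_on_treatment(trace),
    n_cycles = n
  ), class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  d <- x$discounted
  cat(sprintf("<outcome_summary> arm %s (%d cycles)\n", x$arm, x$n_cycles))
  cat(sprintf("  discounted: LY %.3f, QALY %.3f, total cost RM %s\n",
              d$ly$total, d$qaly$total,
              format(round_report(d$cost$total), big.mark = ",")))
  cat(sprintf("  event rates /100 PY: hHF %.2f, CV death %.2f, non-CV death %.2f\n",
              x$event_rates_per_100py[["hhf"]],
              x$event_rates_per_100py[["cv_death"]],
              x$event_rates_per_100py[["noncv_death"]]))
  if (x$arm == "EPG_SOC") {
    cat(sprintf("  mean time on treatment: %.2f years\n", x$years_on_treatment))
  }
  invisible(x)
}

#' Run both arms and summarise
#'
#' Convenience wrapper: runs the cohort for both arms under one bundle and
#' returns the per-arm outcome summaries plus the incremental result.
#'
#' @param p a validated `model_parameters` bundle.
#' @param horizon optional horizon override (months).
#' @return list with `epg_soc`, `soc` (`outcome_summary`) and `incremental`
#'   (`incremental_result`).
#' @export
run_base_case <- function(p, horizon = NULL) {
  tr_e <- run_cohort(p, "EPG_SOC", horizon = horizon)
  tr_s <- run_cohort(p, "SOC", horizon = horizon)
  a <- accrue_outcomes(tr_e, p)
  b <- accrue_outcomes(tr_s, p)
  list(epg_soc = a, soc = b, incremental = incremental(a, b))
}

#' Export an outcome summary as JSON
#'
#' @param x an `outcome_summary` (or any list-like result).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  json <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}
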