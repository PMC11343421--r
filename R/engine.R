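# Cohort propagation.
#
# The cohort lives on (alive state x on/off treatment) compartments plus two
# absorbing dead states. Within each monthly cycle events happen in a fixed
# order: (1) CV death, then blended non-CV death applied to the CV survivors;
# (2) treatment discontinuation (intervention arm, on-treatment compartments
# only), moving mass to the matching off-treatment compartment; (3) health
# state transitions among survivors using the period- and treatment-status-
# appropriate matrix (off-treatment patients use SoC matrices); (4) expected
# transient events (hHF, AEs) accrue on the post-death end-of-cycle alive
# occupancy. This ordering means deaths cannot occur from a state the patient
# left mid-cycle and transient events accrue to survivors.

resolve_horizon <- function(p, horizon = NULL) {
  ec <- p$economics
  h <- horizon %||% ec$horizon
  start <- ec$starting_age
  if (identical(h, "lifetime")) {
    h <- ceiling((ec$max_age - start) * 12)
  }
  h <- as.integer(h)
  # life-table coverage limits how far the engine can look up background
  # mortality; clamp the horizon (with a warning) rather than fail mid-run
  max_lt_age <- min(tapply(p$life_table$table$age, p$life_table$table$sex, max))
  h_max <- floor((max_lt_age + 1 - start) * 12)
  if (h > h_max) {
    warning(sprintf("horizon clamped from %d to %d cycles (life table ends at age %d)",
                    h, h_max, max_lt_age), call. = FALSE)
    h <- h_max
  }
  h
}

# Precompute, for every cycle and compartment, the per-cycle probabilities of
# CV death, blended non-CV death and discontinuation, plus the constant
# monthly hHF and AE rates. Vectorised over cycles: this is what makes a
# 1,000-iteration PSA affordable in plain R.
precompute_cycle_inputs <- function(p, arm, n_cycles) {
  t0 <- seq_len(n_cycles) - 1      # cycle start times in months
  ages <- p$economics$starting_age + t0 / 12
  comp_state <- rep(ALIVE_STATES, 2)
  comp_trt <- rep(c(1, 0), each = 4)
  if (arm == "SOC") comp_trt <- rep(0, 8)

  p_cv <- p_ncv <- p_disc <- matrix(0, n_cycles, 8,
                                    dimnames = list(NULL, COMPARTMENTS[1:8]))
  p_lt <- noncv_lifetable_probability(p$life_table, pmin(ages, max(p$life_table$table$age)))
  for (k in 1:8) {
    ctx <- hazard_context(elapsed_time = t0, cycle_length = p$economics$cycle_length,
                          treatment = comp_trt[k], state = comp_state[k])
    p_cv[, k] <- cycle_event_probability(p$survival$cv_death, ctx)
    p_trial_ncv <- trial_noncv_probability(p$survival$all_cause_death,
                                           p$survival$cv_death, ctx, warn = FALSE)
    p_ncv[, k] <- blended_noncv_probability(p_trial_ncv, p_lt)
    if (arm == "EPG_SOC" && comp_trt[k] == 1) {
      dctx <- hazard_context(elapsed_time = t0,
                             cycle_length = p$economics$cycle_length,
                             treatment = 1, state = comp_state[k])
      p_disc[, k] <- cycle_event_probability(p$survival$discontinuation, dctx)
    }
  }

  hhf_rate <- event_rate(p$hhf, comp_state, comp_trt)
  ae <- p$adverse_events[p$adverse_events$include, , drop = FALSE]
  # on-treatment compartments experience intervention-arm AE rates, everyone
  # else the SoC rates
  ae_rates <- if (nrow(ae)) {
    sapply(seq_len(nrow(ae)), function(i)
      ifelse(comp_trt == 1, ae$rate_epg[i], ae$rate_soc[i]))
  } else {
    matrix(0, 8, 0)
  }
  if (nrow(ae)) colnames(ae_rates) <- ae$event

  periods <- transition_period(p$transitions, t0)
  m_on <- p$transitions$matrices[["EPG_SOC"]]
  m_off <- p$transitions$matrices[["SOC"]]

  list(p_cv = p_cv, p_ncv = p_ncv, p_disc = p_disc, hhf_rate = hhf_rate,
       ae = ae, ae_rates = ae_rates, periods = periods, m_on = m_on,
       m_off = m_off, ages = ages)
}

#' Run the cohort model for one treatment arm
#'
#' Propagates the cohort (starting 25 percent in each KCCQ-CSS quartile, all
#' on treatment in the intervention arm) cycle by cycle until the horizon,
#' age `max_age`, or total alive occupancy below `1e-6`, whichever comes
#' first. Off-treatment patients in the intervention arm immediately adopt
#' SoC transition matrices, event risks, utilities and drug cost.
#'
#' @param p a validated `model_parameters` bundle.
#' @param arm `"EPG_SOC"` (intervention) or `"SOC"` (comparator).
#' @param horizon optional override of the configured horizon (months).
#' @return an object of class `cohort_trace`: `occupancy` is a
#'   `(cycles+1) x 10` matrix over compartments, `events` a per-cycle
#'   data.frame of expected event counts (hHF, deaths by cause,
#'   discontinuations, each adverse event).
#' @export
run_cohort <- function(p, arm = c("EPG_SOC", "SOC"), horizon = NULL) {
  arm <- match.arg(arm)
  n <- resolve_horizon(p, horizon)
  inp <- precompute_cycle_inputs(p, arm, n)

  occ <- matrix(0, n + 1, 10, dimnames = list(NULL, COMPARTMENTS))
  init <- rep(0, 10)
  if (arm == "EPG_SOC") init[1:4] <- 0.25 else init[5:8] <- 0.25
  occ[1, ] <- init

  ev_names <- c("hhf", "cv_deaths", "noncv_deaths", "discontinuations")
  events <- matrix(0, n, length(ev_names) + ncol(inp$ae_rates),
                   dimnames = list(NULL, c(ev_names,
                                           if (ncol(inp$ae_rates))
                                             paste0("ae_", colnames(inp$ae_rates)))))
  n_eff <- n
  for (t in seq_len(n)) {
    v <- occ[t, 1:8]
    d_cv <- v * inp$p_cv[t, ]
    surv1 <- v - d_cv
    d_ncv <- surv1 * inp$p_ncv[t, ]
    alive <- surv1 - d_ncv

    disc <- alive[1:4] * inp$p_disc[t, 1:4]
    alive_on <- alive[1:4] - disc
    alive_off <- alive[5:8] + disc

    per <- inp$periods[t]
    new_on <- as.numeric(alive_on %*% inp$m_on[[per]])
    new_off <- as.numeric(alive_off %*% inp$m_off[[per]])
    end_alive <- c(new_on, new_off)

    occ[t + 1, 1:8] <- end_alive
    occ[t + 1, 9] <- occ[t, 9] + sum(d_cv)
    occ[t + 1, 10] <- occ[t, 10] + sum(d_ncv)

    events[t, "hhf"] <- sum(end_alive * inp$hhf_rate)
    events[t, "cv_deaths"] <- sum(d_cv)
    events[t, "noncv_deaths"] <- sum(d_ncv)
    events[t, "discontinuations"] <- sum(disc)
    if (ncol(inp$ae_rates)) {
      events[t, -(1:4)] <- as.numeric(end_alive %*% inp$ae_rates)
    }

    if (sum(end_alive) < 1e-6) {
      n_eff <- t
      break
    }
  }
  occ <- occ[seq_len(n_eff + 1), , drop = FALSE]
  events <- as.data.frame(events[seq_len(n_eff), , drop = FALSE])
  events <- cbind(cycle = seq_len(n_eff) - 1L, events,
                  age = inp$ages[seq_len(n_eff)])

  structure(list(occupancy = occ, events = events, arm = arm,
                 n_cycles = n_eff, starting_age = p$economics$starting_age,
                 cycle_length = p$economics$cycle_length),
            class = "cohort_trace")
}

#' Expected hHF events for a given occupancy
#'
#' Cohort expectation of the Poisson hospitalisation process:
#' `sum_state occupancy * exp(intercept + beta_trt * on_treatment +
#' beta_state)`. Events beyond the first in a cycle are counted (no
#' per-patient cap).
#'
#' @param rate_model an [event_rate_model()].
#' @param occupancy named numeric over alive states.
#' @param on_treatment 0/1 treatment status of that occupancy.
#' @return expected events per cycle (>= 0).
#' @export
expected_hhf_events <- function(rate_model, occupancy, on_treatment = 0) {
  states <- names(occupancy) %||% ALIVE_STATES[seq_along(occupancy)]
  sum(occupancy * event_rate(rate_model, states, on_treatment))
}

#' Discount factor at a monthly cycle index
#'
#' `(1 + rate)^(-cycle/12)`; cycle 0 has factor 1.
#'
#' @param annual_rate annual discount rate (>= 0).
#' @param cycle cycle index (months); vectorised.
#' @return discount factor(s).
#' @export
discount_factor <- function(annual_rate, cycle) {
  stopifnot(annual_rate >= 0, all(cycle >= 0))
  (1 + annual_rate)^(-cycle / 12)
}

#' Mean undiscounted time on treatment
#'
#' Sum over cycles of (half-cycle-corrected) on-treatment occupancy, in
#' years. Defined as 0 for a comparator-arm trace.
#'
#' @param trace a `cohort_trace`.
#' @return years on treatment.
#' @export
mean_time_on_treatment <- function(trace) {
  if (trace$arm != "EPG_SOC") return(0)
  occ <- trace$occupancy
  n <- trace$n_cycles
  on_mass <- rowSums(occ[, 1:4, drop = FALSE])
  sum((on_mass[1:n] + on_mass[2:(n + 1)]) / 2) / 12
}
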