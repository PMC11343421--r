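# Individual-level validation oracle.
#
# Simulates the same decision problem patient by patient with sampled (not
# expected) deaths, discontinuations, state transitions and event counts,
# using the exported per-cycle probability primitives directly. The cohort
# engine's deterministic trace must agree with the microsimulation's mean
# occupancy and accrued outcomes within Monte Carlo error; this validates the
# cohort propagation and accrual independently of the matrix algebra.

#' Microsimulate the cohort patient by patient
#'
#' @param p a validated `model_parameters` bundle.
#' @param arm `"EPG_SOC"` or `"SOC"`.
#' @param n_patients number of simulated walkers.
#' @param horizon number of monthly cycles to simulate.
#' @param seed integer seed.
#' @return an object of class `cohort_trace` (mean occupancy and mean event
#'   counts per cycle across walkers, same layout as [run_cohort()]), with
#'   `n_patients` recorded for Monte Carlo error computation.
#' @export
microsimulate_cohort <- function(p, arm = c("EPG_SOC", "SOC"),
                                 n_patients = 10000L, horizon = 60L,
                                 seed = 1L) {
  arm <- match.arg(arm)
  n_cycles <- resolve_horizon(p, horizon)
  ec <- p$economics
  t0 <- seq_len(n_cycles) - 1
  ages <- ec$starting_age + t0 / 12

  comp_state <- rep(ALIVE_STATES, 2)
  comp_trt <- rep(c(1, 0), each = 4)
  if (arm == "SOC") comp_trt <- rep(0, 8)

  # per-cycle probabilities per compartment, from the exported primitives
  p_cv <- p_ncv <- p_disc <- matrix(0, n_cycles, 8)
  p_lt <- noncv_lifetable_probability(
    p$life_table, pmin(ages, max(p$life_table$table$age)))
  for (k in 1:8) {
    ctx <- hazard_context(t0, ec$cycle_length, comp_trt[k], comp_state[k])
    p_cv[, k] <- cycle_event_probability(p$survival$cv_death, ctx)
    p_ncv[, k] <- blended_noncv_probability(
      trial_noncv_probability(p$survival$all_cause_death, p$survival$cv_death,
                              ctx, warn = FALSE), p_lt)
    if (arm == "EPG_SOC" && comp_trt[k] == 1) {
      p_disc[, k] <- cycle_event_probability(p$survival$discontinuation, ctx)
    }
  }
  hhf_rate <- event_rate(p$hhf, comp_state, comp_trt)
  ae <- p$adverse_events[p$adverse_events$include, , drop = FALSE]

  cum_rows <- function(m) {
    t(apply(m, 1, cumsum))
  }
  mats_on <- lapply(p$transitions$matrices[["EPG_SOC"]], cum_rows)
  mats_off <- lapply(p$transitions$matrices[["SOC"]], cum_rows)
  periods <- transition_period(p$transitions, t0)

  with_seed(seed, {
    n <- as.integer(n_patients)
    state <- rep_len(1:4, n)          # 25% per quartile at entry
    on_trt <- rep(arm == "EPG_SOC", n)
    status <- rep(1L, n)              # 1 alive, 2 dead CV, 3 dead non-CV

    occ <- matrix(0, n_cycles + 1, 10, dimnames = list(NULL, COMPARTMENTS))
    ev_names <- c("hhf", "cv_deaths", "noncv_deaths", "discontinuations")
    events <- matrix(0, n_cycles, length(ev_names) + nrow(ae),
                     dimnames = list(NULL, c(ev_names,
                                             if (nrow(ae)) paste0("ae_", ae$event))))
    tally <- function(row) {
      for (k in 1:8) {
        occ[row, k] <<- sum(status == 1L & state == ((k - 1) %% 4 + 1) &
                              on_trt == (k <= 4)) / n
      }
      occ[row, 9] <<- sum(status == 2L) / n
      occ[row, 10] <<- sum(status == 3L) / n
    }
    tally(1)

    comp_of <- function(alive_idx) {
      state[alive_idx] + ifelse(on_trt[alive_idx], 0L, 4L)
    }

    for (t in seq_len(n_cycles)) {
      alive_idx <- which(status == 1L)
      if (!length(alive_idx)) {
        occ[(t + 1):(n_cycles + 1), ] <- matrix(occ[t, ],
                                                nrow = n_cycles - t + 1,
                                                ncol = 10, byrow = TRUE)
        break
      }
      k <- comp_of(alive_idx)
      u <- stats::runif(length(alive_idx))
      die_cv <- u < p_cv[t, k]
      u2 <- stats::runif(length(alive_idx))
      die_ncv <- !die_cv & (u2 < p_ncv[t, k])
      status[alive_idx[die_cv]] <- 2L
      status[alive_idx[die_ncv]] <- 3L
      events[t, "cv_deaths"] <- sum(die_cv) / n
      events[t, "noncv_deaths"] <- sum(die_ncv) / n

      surv_idx <- alive_idx[!die_cv & !die_ncv]
      if (length(surv_idx)) {
        k_s <- comp_of(surv_idx)
        on_idx <- surv_idx[on_trt[surv_idx]]
        if (length(on_idx)) {
          disc <- stats::runif(length(on_idx)) <
            p_disc[t, state[on_idx]]
          on_trt[on_idx[disc]] <- FALSE
          events[t, "discontinuations"] <- sum(disc) / n
        }
        # transitions: treatment status after discontinuation decides the
        # matrix; select on a snapshot so nobody transitions twice per cycle
        per <- periods[t]
        state_snap <- state
        for (grp_on in c(TRUE, FALSE)) {
          mset <- if (grp_on) mats_on[[per]] else mats_off[[per]]
          for (s in 1:4) {
            idx <- surv_idx[state_snap[surv_idx] == s &
                              on_trt[surv_idx] == grp_on]
            if (!length(idx)) next
            r <- stats::runif(length(idx))
            cm <- mset[s, ]
            state[idx] <- 1L + findInterval(r, cm[1:3], left.open = FALSE)
          }
        }
        # transient events on end-of-cycle states
        k_end <- comp_of(surv_idx)
        events[t, "hhf"] <- sum(stats::rpois(length(surv_idx),
                                             hhf_rate[k_end])) / n
        if (nrow(ae)) {
          for (j in seq_len(nrow(ae))) {
            rate <- ifelse(on_trt[surv_idx], ae$rate_epg[j], ae$rate_soc[j])
            events[t, 4L + j] <- sum(stats::rpois(length(surv_idx), rate)) / n
          }
        }
      }
      tally(t + 1)
    }

    events <- as.data.frame(events)
    events <- cbind(cycle = t0, events, age = ages)
    structure(list(occupancy = occ, events = events, arm = arm,
                   n_cycles = n_cycles, starting_age = ec$starting_age,
                   cycle_length = ec$cycle_length, n_patients = n),
              class = "cohort_trace")
  })
}
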