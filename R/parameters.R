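#' Canonical health-state definitions
#'
#' The model's four alive states are the KCCQ-CSS quartiles observed at
#' baseline in the source trial population: Q1 (0 to <55.73), Q2 (55.73 to
#' <73.96), Q3 (73.96 to <88.02) and Q4 (88.02 to 100). Lower scores mean
#' worse symptoms and function. Death is split into cardiovascular and
#' non-cardiovascular causes.
#'
#' @return a data.frame with columns `state_id`, `kccq_lower`, `kccq_upper`.
#' @export
health_state_definitions <- function() {
  data.frame(
    state_id = ALIVE_STATES,
    kccq_lower = KCCQ_BOUNDS[1:4],
    kccq_upper = KCCQ_BOUNDS[2:5],
    stringsAsFactors = FALSE
  )
}

#' Transition schedule between alive states
#'
#' Monthly transition probabilities between KCCQ-CSS quartiles vary over three
#' periods (months 1-3, months 4-8, months 9+), treatment-specific, and are
#' conditional on surviving the cycle. The months 9+ matrices apply unchanged
#' until the end of the horizon.
#'
#' @param matrices named list `list(EPG_SOC = list(m1_3 = M, m4_8 = M,
#'   m9plus = M), SOC = ...)` of 4x4 row-stochastic matrices with rows/columns
#'   ordered Q1..Q4.
#' @param period_breaks integer cycle (month) indices where the matrix set
#'   changes; default `c(3, 8)`.
#' @return an object of class `transition_schedule`.
#' @export
transition_schedule <- function(matrices, period_breaks = c(3L, 8L)) {
  for (arm in ARMS) {
    if (is.null(matrices[[arm]])) {
      stop(sprintf("transition matrices missing for arm '%s'", arm), call. = FALSE)
    }
    for (per in MATRIX_PERIODS) {
      m <- matrices[[arm]][[per]]
      if (is.null(m)) {
        stop(sprintf("transition matrix missing for arm '%s', period '%s'", arm, per),
             call. = FALSE)
      }
      m <- as.matrix(m)
      if (!all(dim(m) == c(4L, 4L))) {
        stop(sprintf(
          "transition matrix for arm '%s', period '%s' has dimension %dx%d, expected 4x4",
          arm, per, nrow(m), ncol(m)), call. = FALSE)
      }
      dimnames(m) <- list(ALIVE_STATES, ALIVE_STATES)
      matrices[[arm]][[per]] <- m
    }
  }
  structure(list(period_breaks = as.integer(period_breaks),
                 matrices = matrices[ARMS]),
            class = "transition_schedule")
}

# Map a 0-based cycle index to the matrix period label.
# Cycle t spans month t+1, so cycles 0-2 are months 1-3, cycles 3-7 months
# 4-8, cycles 8+ months 9 onwards.
transition_period <- function(schedule, cycle) {
  br <- schedule$period_breaks
  ifelse(cycle < br[1], MATRIX_PERIODS[1],
         ifelse(cycle < br[2], MATRIX_PERIODS[2], MATRIX_PERIODS[3]))
}

#' Parametric time-to-event specification
#'
#' Holds one fitted survival process: distribution family, regression
#' coefficients and ancillary parameters. Time unit is months. Two coefficient
#' conventions are used, matching common survival-regression output so
#' externally fitted coefficients can be transcribed verbatim:
#' accelerated-failure-time (AFT, linear predictor on the log-time location)
#' for `weibull`, `lognormal`, `loglogistic` and `gengamma`; proportional
#' hazards (PH, linear predictor on the log hazard) for `exponential` and
#' `gompertz`.
#'
#' Covariates are the treatment indicator and indicators for alive states Q1,
#' Q2, Q3 relative to the declared reference state (default Q4, best health).
#'
#' @param family one of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`, `"gompertz"`, `"gengamma"`.
#' @param coefs named numeric vector with elements among `intercept`,
#'   `treatment`, `Q1`, `Q2`, `Q3` (missing covariate coefficients are 0).
#' @param ancillary named list: `sigma` (>0) for AFT families, `Q` for the
#'   generalised gamma, `shape` for the Gompertz.
#' @param ref_state reference alive state for the state indicators.
#' @return object of class `survival_spec`.
#' @export
survival_spec <- function(family, coefs, ancillary = list(), ref_state = "Q4") {
  families <- c("exponential", "weibull", "lognormal", "loglogistic",
                "gompertz", "gengamma")
  if (!family %in% families) {
    stop(sprintf("unsupported survival family '%s'", family), call. = FALSE)
  }
  allowed <- c("intercept", "treatment", setdiff(ALIVE_STATES, ref_state))
  bad <- setdiff(names(coefs), allowed)
  if (length(bad)) {
    stop(sprintf("undeclared covariate coefficient(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  scale <- if (family %in% c("exponential", "gompertz")) "ph" else "aft"
  structure(list(family = family, coefs = coefs, ancillary = ancillary,
                 ref_state = ref_state, scale = scale, time_unit = "months"),
            class = "survival_spec")
}

#' Poisson log-rate model for a recurrent event
#'
#' Monthly event rate is `exp(intercept + treatment_coef * on_treatment +
#' state_coef[state])`, with the reference state contributing 0. Used for the
#' heart-failure hospitalisation process.
#'
#' @param intercept log monthly rate in the reference state, off treatment.
#' @param treatment_coef log rate ratio for active treatment.
#' @param state_coefs named numeric (`Q1`,`Q2`,`Q3` when `ref_state = "Q4"`).
#' @param ref_state reference alive state.
#' @return object of class `event_rate_model`.
#' @export
event_rate_model <- function(intercept, treatment_coef = 0,
                             state_coefs = c(Q1 = 0, Q2 = 0, Q3 = 0),
                             ref_state = "Q4") {
  structure(list(intercept = intercept, treatment_coef = treatment_coef,
                 state_coefs = state_coefs, ref_state = ref_state),
            class = "event_rate_model")
}

#' Monthly event rate by state and treatment status
#'
#' @param model an [event_rate_model()].
#' @param state alive state(s).
#' @param on_treatment 0/1 indicator(s).
#' @return monthly rate(s).
#' @export
event_rate <- function(model, state, on_treatment) {
  sc <- ifelse(state == model$ref_state, 0, model$state_coefs[state])
  exp(model$intercept + model$treatment_coef * on_treatment + unname(sc))
}

#' Adverse-event profile
#'
#' One row per treatment-emergent adverse event with monthly incidence rate
#' per arm, utility decrement (held for one month), and unit management cost.
#' Ketoacidosis has a trial event rate below 1 per 100 patient-years and is
#' excluded by default (`include = FALSE`); a scenario flag turns it on.
#'
#' @param table data.frame with columns `event`, `rate_epg`, `rate_soc`
#'   (monthly rates), `disutility` (<= 0), `duration_months`, `unit_cost`,
#'   `include` (logical).
#' @return object of class `adverse_event_profile` (a data.frame).
#' @export
adverse_event_profile <- function(table) {
  needed <- c("event", "rate_epg", "rate_soc", "disutility",
              "duration_months", "unit_cost", "include")
  miss <- setdiff(needed, names(table))
  if (length(miss)) {
    stop(sprintf("adverse event table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  table <- as.data.frame(table)[, needed]
  class(table) <- c("adverse_event_profile", "data.frame")
  table
}

#' Cost inputs (2022 Malaysian ringgit)
#'
#' @param monthly_drug_cost named numeric `c(EPG_SOC = , SOC = )`: monthly
#'   acquisition cost of the full regimen per arm; off-treatment patients in
#'   the intervention arm pay the SoC cost.
#' @param hhf_cost cost per heart-failure admission.
#' @param cv_death_cost cost per cardiovascular death event.
#' @param noncv_death_cost cost per non-cardiovascular death (0 by assumption).
#' @param monthly_disease_mgmt_cost monthly outpatient disease-management cost
#'   per alive patient (equal across states).
#' @param currency_year costing year tag.
#' @return object of class `cost_set`.
#' @export
cost_set <- function(monthly_drug_cost = c(EPG_SOC = 212, SOC = 101),
                     hhf_cost = 5276, cv_death_cost = 2573,
                     noncv_death_cost = 0, monthly_disease_mgmt_cost = 28,
                     currency_year = 2022L) {
  structure(list(monthly_drug_cost = monthly_drug_cost,
                 hhf_cost = hhf_cost, cv_death_cost = cv_death_cost,
                 noncv_death_cost = noncv_death_cost,
                 monthly_disease_mgmt_cost = monthly_disease_mgmt_cost,
                 currency_year = as.integer(currency_year)),
            class = "cost_set")
}

#' Utility inputs
#'
#' State utilities by KCCQ-CSS quartile plus one-off event decrements: the
#' hospitalisation decrement is held for twelve months (one full QALY-scale
#' decrement of 0.335 per event), adverse-event decrements for one month.
#'
#' @param state_utility named numeric over Q1..Q4, in `[0,1]`.
#' @param hhf_disutility utility decrement per hospitalisation (<= 0).
#' @param hhf_disutility_duration months the decrement persists.
#' @return object of class `utility_model`.
#' @export
utility_model <- function(state_utility = c(Q1 = 0.613, Q2 = 0.707,
                                            Q3 = 0.778, Q4 = 0.832),
                          hhf_disutility = -0.335,
                          hhf_disutility_duration = 12) {
  structure(list(state_utility = state_utility,
                 hhf_disutility = hhf_disutility,
                 hhf_disutility_duration = hhf_disutility_duration),
            class = "utility_model")
}

#' Economic configuration
#'
#' @param annual_discount_rate_cost annual discount rate for costs (0.03).
#' @param annual_discount_rate_benefit annual discount rate for LYs/QALYs.
#' @param cet cost-effectiveness threshold, RM per QALY gained (47,439 =
#'   Malaysian GDP per capita, 2021).
#' @param cycle_length cycle length in months (1).
#' @param horizon number of monthly cycles, or `"lifetime"`.
#' @param starting_age cohort starting age in years (base case 64.6).
#' @param half_cycle_correction logical; average cycle-start and cycle-end
#'   occupancy for state-based accruals.
#' @param max_age age at which a lifetime horizon terminates (100).
#' @return object of class `economic_config`.
#' @export
economic_config <- function(annual_discount_rate_cost = 0.03,
                            annual_discount_rate_benefit = 0.03,
                            cet = 47439, cycle_length = 1,
                            horizon = "lifetime", starting_age = 64.6,
                            half_cycle_correction = TRUE, max_age = 100) {
  structure(list(annual_discount_rate_cost = annual_discount_rate_cost,
                 annual_discount_rate_benefit = annual_discount_rate_benefit,
                 cet = cet, cycle_length = cycle_length, horizon = horizon,
                 starting_age = starting_age,
                 half_cycle_correction = half_cycle_correction,
                 max_age = max_age),
            class = "economic_config")
}

#' General-population life table with cardiovascular death share
#'
#' @param table data.frame with columns `age`, `sex` (`"male"`/`"female"`),
#'   `annual_qx` (annual all-cause death probability) and `cv_share`
#'   (proportion of deaths from circulatory causes, ICD-10 I00-I99).
#' @param sex_mix named numeric `c(male = , female = )` summing to 1,
#'   the sex distribution of the modelled cohort.
#' @return object of class `life_table`.
#' @export
life_table <- function(table, sex_mix = c(male = 0.55, female = 0.45)) {
  needed <- c("age", "sex", "annual_qx", "cv_share")
  miss <- setdiff(needed, names(table))
  if (length(miss)) {
    stop(sprintf("life table missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(table = as.data.frame(table)[, needed], sex_mix = sex_mix),
            class = "life_table")
}

#' Treatment-effect metadata
#'
#' The base-case effects live inside the event-rate and survival
#' specifications; this component records the bounds and subgroup overrides
#' used by sensitivity and subgroup analyses.
#'
#' @param hr_hhf_dsa_bounds low/high rate-ratio bounds for hospitalisation
#'   (upper 95 percent CI bound 0.83 per the source analysis).
#' @param subgroups named list of `list(hr_cv = , hr_hhf = )` overrides; the
#'   defaults carry the diabetes-status subgroups (T2D: CV 1.01, hHF 0.78;
#'   non-T2D: CV 0.83, hHF 0.77).
#' @return object of class `treatment_effect`.
#' @export
treatment_effect <- function(hr_hhf_dsa_bounds = c(low = 0.60, high = 0.83),
                             subgroups = list(
                               t2d = list(hr_cv = 1.01, hr_hhf = 0.78),
                               non_t2d = list(hr_cv = 0.83, hr_hhf = 0.77))) {
  structure(list(hr_hhf_dsa_bounds = hr_hhf_dsa_bounds, subgroups = subgroups),
            class = "treatment_effect")
}

#' Phenotype-pooling specification
#'
#' Deterministic pooling weights (local phenotype prevalence: 67 percent
#' reduced EF, 33 percent EF>40) and the probabilistic resampling counts
#' (670 + 330 = 1,000 iterations).
#'
#' @param weight_hfref,weight_ef40 pooling weights, must sum to 1.
#' @param psa_resample_counts named integer `c(hfref = 670, ef40 = 330)`.
#' @return object of class `combine_spec`.
#' @export
combine_spec <- function(weight_hfref = 0.67, weight_ef40 = 0.33,
                         psa_resample_counts = c(hfref = 670L, ef40 = 330L)) {
  structure(list(weight_hfref = weight_hfref, weight_ef40 = weight_ef40,
                 psa_resample_counts = psa_resample_counts,
                 psa_total = sum(psa_resample_counts)),
            class = "combine_spec")
}

#' Assemble a full model parameter bundle
#'
#' @param transitions a [transition_schedule()].
#' @param survival named list with `cv_death`, `all_cause_death` and
#'   `discontinuation` [survival_spec()] objects.
#' @param hhf an [event_rate_model()] for heart-failure hospitalisation.
#' @param adverse_events an [adverse_event_profile()].
#' @param costs a [cost_set()].
#' @param utilities a [utility_model()].
#' @param economics an [economic_config()].
#' @param life_table a [life_table()].
#' @param treatment_effect a [treatment_effect()].
#' @param combine a [combine_spec()].
#' @param states health-state definitions (canonical by default).
#' @return object of class `model_parameters`.
#' @export
model_parameters <- function(transitions, survival, hhf, adverse_events,
                             costs = cost_set(), utilities = utility_model(),
                             economics = economic_config(), life_table,
                             treatment_effect = hfcea::treatment_effect(),
                             combine = combine_spec(),
                             states = health_state_definitions()) {
  need <- c("cv_death", "all_cause_death", "discontinuation")
  miss <- setdiff(need, names(survival))
  if (length(miss)) {
    stop(sprintf("survival specifications missing: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(states = states, transitions = transitions,
                 survival = survival, hhf = hhf,
                 adverse_events = adverse_events, costs = costs,
                 utilities = utilities, economics = economics,
                 life_table = life_table, treatment_effect = treatment_effect,
                 combine = combine),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  cat(sprintf("  alive states: %s (KCCQ-CSS quartiles)\n",
              paste(ALIVE_STATES, collapse = ", ")))
  cat(sprintf("  starting age: %.1f y; horizon: %s; discount: %.1f%%/%.1f%% (cost/benefit)\n",
              x$economics$starting_age, as.character(x$economics$horizon),
              100 * x$economics$annual_discount_rate_cost,
              100 * x$economics$annual_discount_rate_benefit))
  cat(sprintf("  survival: CV death %s, all-cause %s, discontinuation %s\n",
              x$survival$cv_death$family, x$survival$all_cause_death$family,
              x$survival$discontinuation$family))
  cat(sprintf("  adverse events: %d modelled (%d included)\n",
              nrow(x$adverse_events), sum(x$adverse_events$include)))
  invisible(x)
}
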