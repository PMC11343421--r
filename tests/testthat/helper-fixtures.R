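# Shared fixtures. Bundles are cached per test run: the packaged base-case
# config is the calibrated synthetic world; toy_bundle() is an uncalibrated
# but valid bundle for structural tests; degenerate_bundle() builds closed-
# form-checkable worlds (identity transitions, constant hazards, zero
# background mortality).

.fixture_cache <- new.env(parent = emptyenv())

fixture_config <- function() {
  system.file("extdata", "basecase", "config.json", package = "hfcea")
}

calibrated_bundle <- function() {
  if (is.null(.fixture_cache$cal)) {
    .fixture_cache$cal <- load_parameters(fixture_config())
  }
  .fixture_cache$cal
}

toy_bundle <- function() {
  if (is.null(.fixture_cache$toy)) {
    .fixture_cache$toy <- generate_bundle(synthetic_spec(seed = 7L))
  }
  .fixture_cache$toy
}

flat_life_table <- function(min_age = 50, max_age = 200, qx = 0,
                            cv_share = 0.3) {
  ages <- min_age:max_age
  tab <- rbind(
    data.frame(age = ages, sex = "male", annual_qx = qx, cv_share = cv_share),
    data.frame(age = ages, sex = "female", annual_qx = qx, cv_share = cv_share)
  )
  life_table(tab, sex_mix = c(male = 0.5, female = 0.5))
}

near_zero_hazard <- function() {
  survival_spec("exponential", coefs = c(intercept = -30))
}

const_hazard_spec <- function(monthly_prob) {
  if (monthly_prob <= 0) return(near_zero_hazard())
  survival_spec("exponential", coefs = c(intercept = log(-log(1 - monthly_prob))))
}

QSTATES <- c("Q1", "Q2", "Q3", "Q4")

identity_matrices <- function() {
  m <- diag(4)
  dimnames(m) <- list(QSTATES, QSTATES)
  per <- list(m1_3 = m, m4_8 = m, m9plus = m)
  list(EPG_SOC = per, SOC = per)
}

# A world where every quantity has a closed form: identity transitions, a
# constant monthly death probability (CV cause only), optional constant
# discontinuation, no background mortality, no transient events, no
# discounting.
degenerate_bundle <- function(monthly_death_prob = 0, disc_prob = 0,
                              horizon = 12, max_age = 200,
                              half_cycle_correction = FALSE,
                              hhf_intercept = -30) {
  death <- const_hazard_spec(monthly_death_prob)
  ae <- adverse_event_profile(data.frame(
    event = "uti", rate_epg = 0, rate_soc = 0, disutility = -0.04,
    duration_months = 1, unit_cost = 213, include = FALSE))
  model_parameters(
    transitions = transition_schedule(identity_matrices()),
    survival = list(cv_death = death, all_cause_death = death,
                    discontinuation = const_hazard_spec(disc_prob)),
    hhf = event_rate_model(intercept = hhf_intercept),
    adverse_events = ae,
    costs = cost_set(),
    utilities = utility_model(),
    economics = economic_config(annual_discount_rate_cost = 0,
                                annual_discount_rate_benefit = 0,
                                horizon = horizon,
                                half_cycle_correction = half_cycle_correction,
                                max_age = max_age),
    life_table = flat_life_table(max_age = max_age)
  )
}

# Intervention arm made clinically identical to the comparator: same
# matrices, null treatment effects, equal adverse-event rates. Only the drug
# price differs while on treatment.
null_effect_bundle <- function(base = toy_bundle()) {
  p <- base
  p$transitions$matrices$EPG_SOC <- p$transitions$matrices$SOC
  p$hhf$treatment_coef <- 0
  p$survival$cv_death$coefs["treatment"] <- 0
  p$survival$all_cause_death$coefs["treatment"] <- 0
  p$adverse_events$rate_epg <- p$adverse_events$rate_soc
  p
}

make_psa_frame <- function(dc, dq, base_cost = 10000, base_qaly = 4) {
  data.frame(iteration = seq_along(dc),
             cost_epg_soc = base_cost + dc, ly_epg_soc = base_qaly + dq,
             qaly_epg_soc = base_qaly + dq,
             cost_soc = base_cost, ly_soc = base_qaly, qaly_soc = base_qaly)
}
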