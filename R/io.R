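# Configuration reading/writing.
#
# The bundle is stored as one structured JSON config. Bulky tabular pieces
# (transition matrices, life table, adverse-event table) may either be inline
# or reference delimited-text files (comma-separated, header row, UTF-8, "."
# decimal) relative to the config's directory. write_parameters() always
# emits the canonical fully-inline form, so write(load(x)) is byte-stable.

PARAM_SECTIONS <- c("schema", "states", "transitions", "survival", "hhf",
                    "adverse_events", "costs", "utilities", "economics",
                    "life_table", "treatment_effect", "combine")

SECTION_KEYS <- list(
  transitions = c("period_breaks", "matrices"),
  survival = c("cv_death", "all_cause_death", "discontinuation"),
  hhf = c("intercept", "treatment_coef", "state_coefs", "ref_state"),
  costs = c("monthly_drug_cost", "hhf_cost", "cv_death_cost",
            "noncv_death_cost", "monthly_disease_mgmt_cost", "currency_year"),
  utilities = c("state_utility", "hhf_disutility", "hhf_disutility_duration"),
  economics = c("annual_discount_rate_cost", "annual_discount_rate_benefit",
                "cet", "cycle_length", "horizon", "starting_age",
                "half_cycle_correction", "max_age"),
  life_table = c("table", "sex_mix"),
  treatment_effect = c("hr_hhf_dsa_bounds", "subgroups"),
  combine = c("weight_hfref", "weight_ef40", "psa_resample_counts", "psa_total")
)

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop(sprintf("configuration error: unknown key(s) %s",
                 paste(sprintf("'%s.%s'", where, unknown), collapse = ", ")),
         call. = FALSE)
  }
}

require_section <- function(cfg, name) {
  if (is.null(cfg[[name]])) {
    stop(sprintf("configuration error: missing section '%s'", name),
         call. = FALSE)
  }
  cfg[[name]]
}

read_table_ref <- function(x, dir, what) {
  if (is.character(x) && length(x) == 1L) {
    path <- file.path(dir, x)
    if (!file.exists(path)) {
      stop(sprintf("configuration error: %s file '%s' not found", what, path),
           call. = FALSE)
    }
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
}

load_matrices <- function(mx, dir) {
  if (is.character(mx) && length(mx) == 1L) {
    long <- read_table_ref(mx, dir, "transition matrix")
    need <- c("arm", "period", "from", ALIVE_STATES)
    miss <- setdiff(need, names(long))
    if (length(miss)) {
      stop(sprintf("transition matrix file missing column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    out <- list()
    for (arm in unique(long$arm)) {
      for (per in unique(long$period[long$arm == arm])) {
        sub <- long[long$arm == arm & long$period == per, ]
        m <- as.matrix(sub[match(ALIVE_STATES, sub$from), ALIVE_STATES])
        out[[arm]][[per]] <- m
      }
    }
    out
  } else {
    lapply(mx, function(arm_set) lapply(arm_set, function(m) {
      m <- as.matrix(m)
      if (!all(dim(m) == c(4L, 4L))) {
        stop(sprintf("transition matrix has dimension %dx%d, expected 4x4",
                     nrow(m), ncol(m)), call. = FALSE)
      }
      m
    }))
  }
}

as_survival_spec <- function(x, where) {
  check_keys(x, c("family", "coefs", "ancillary", "ref_state"), where)
  survival_spec(family = x$family,
                coefs = unlist(x$coefs),
                ancillary = as.list(x$ancillary),
                ref_state = x$ref_state %||% "Q4")
}

#' Load a model parameter bundle from a structured config
#'
#' Reads a JSON config (optionally referencing delimited-text tables for the
#' transition matrices, adverse-event table and life table), constructs every
#' domain type, and validates the result. Unknown keys are rejected with
#' their paths; missing sections raise a configuration error naming the
#' section.
#'
#' @param path path to the JSON configuration file.
#' @param validate stop on validation violations (default `TRUE`).
#' @return a validated `model_parameters` bundle.
#' @export
load_parameters <- function(path, validate = TRUE) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file '%s' not found", path), call. = FALSE)
  }
  dir <- dirname(path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  check_keys(cfg, PARAM_SECTIONS, "<root>")

  for (sec in setdiff(PARAM_SECTIONS, c("schema", "states"))) require_section(cfg, sec)
  for (sec in names(SECTION_KEYS)) check_keys(cfg[[sec]], SECTION_KEYS[[sec]], sec)

  tr <- cfg$transitions
  transitions <- transition_schedule(load_matrices(tr$matrices, dir),
                                     period_breaks = tr$period_breaks %||% c(3L, 8L))

  survival <- list(
    cv_death = as_survival_spec(cfg$survival$cv_death, "survival.cv_death"),
    all_cause_death = as_survival_spec(cfg$survival$all_cause_death,
                                       "survival.all_cause_death"),
    discontinuation = as_survival_spec(cfg$survival$discontinuation,
                                       "survival.discontinuation")
  )

  hhf <- event_rate_model(intercept = cfg$hhf$intercept,
                          treatment_coef = cfg$hhf$treatment_coef %||% 0,
                          state_coefs = unlist(cfg$hhf$state_coefs),
                          ref_state = cfg$hhf$ref_state %||% "Q4")

  ae <- adverse_event_profile(read_table_ref(cfg$adverse_events, dir,
                                             "adverse event"))

  costs <- cost_set(monthly_drug_cost = unlist(cfg$costs$monthly_drug_cost),
                    hhf_cost = cfg$costs$hhf_cost,
                    cv_death_cost = cfg$costs$cv_death_cost,
                    noncv_death_cost = cfg$costs$noncv_death_cost,
                    monthly_disease_mgmt_cost = cfg$costs$monthly_disease_mgmt_cost,
                    currency_year = cfg$costs$currency_year)

  utilities <- utility_model(state_utility = unlist(cfg$utilities$state_utility),
                             hhf_disutility = cfg$utilities$hhf_disutility,
                             hhf_disutility_duration = cfg$utilities$hhf_disutility_duration)

  economics <- economic_config(
    annual_discount_rate_cost = cfg$economics$annual_discount_rate_cost,
    annual_discount_rate_benefit = cfg$economics$annual_discount_rate_benefit,
    cet = cfg$economics$cet, cycle_length = cfg$economics$cycle_length,
    horizon = cfg$economics$horizon, starting_age = cfg$economics$starting_age,
    half_cycle_correction = cfg$economics$half_cycle_correction,
    max_age = cfg$economics$max_age)

  lt <- life_table(read_table_ref(cfg$life_table$table, dir, "life table"),
                   sex_mix = unlist(cfg$life_table$sex_mix))

  te <- treatment_effect(
    hr_hhf_dsa_bounds = unlist(cfg$treatment_effect$hr_hhf_dsa_bounds),
    subgroups = lapply(cfg$treatment_effect$subgroups, as.list))

  cb <- combine_spec(weight_hfref = cfg$combine$weight_hfref,
                     weight_ef40 = cfg$combine$weight_ef40,
                     psa_resample_counts = unlist(cfg$combine$psa_resample_counts))

  p <- model_parameters(transitions = transitions, survival = survival,
                        hhf = hhf, adverse_events = ae, costs = costs,
                        utilities = utilities, economics = economics,
                        life_table = lt, treatment_effect = te, combine = cb)
  if (validate) assert_valid(p)
  p
}

spec_to_list <- function(sp) {
  list(family = sp$family, coefs = as.list(sp$coefs),
       ancillary = sp$ancillary, ref_state = sp$ref_state)
}

#' Write a model parameter bundle as canonical JSON
#'
#' By default all tables are inlined; key order and number formatting are
#' deterministic, so writing the same bundle twice produces byte-identical
#' files and every numeric survives a round trip unchanged (full precision,
#' no rounding). With `table_files = TRUE` the transition matrices, life
#' table and adverse-event table are written as separate delimited-text
#' files next to the config, which references them by name.
#'
#' @param p a `model_parameters` bundle.
#' @param path output file path.
#' @param table_files write bulky tables as sibling CSV files.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path, table_files = FALSE) {
  if (table_files) {
    dir <- dirname(path)
    long <- do.call(rbind, lapply(ARMS, function(arm)
      do.call(rbind, lapply(MATRIX_PERIODS, function(per) {
        m <- p$transitions$matrices[[arm]][[per]]
        cbind(data.frame(arm = arm, period = per, from = ALIVE_STATES),
              as.data.frame(m))
      }))))
    utils::write.csv(long, file.path(dir, "transitions.csv"), row.names = FALSE)
    utils::write.csv(p$life_table$table, file.path(dir, "life_table.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(p$adverse_events),
                     file.path(dir, "adverse_events.csv"), row.names = FALSE)
  }
  cfg <- list(
    schema = "hfcea/parameters/v1",
    transitions = list(
      period_breaks = p$transitions$period_breaks,
      matrices = if (table_files) "transitions.csv" else
        lapply(p$transitions$matrices, function(arm_set)
          lapply(arm_set, function(m) unname(as.matrix(m))))
    ),
    survival = lapply(p$survival, spec_to_list),
    hhf = list(intercept = p$hhf$intercept,
               treatment_coef = p$hhf$treatment_coef,
               state_coefs = as.list(p$hhf$state_coefs),
               ref_state = p$hhf$ref_state),
    adverse_events = if (table_files) "adverse_events.csv" else
      as.data.frame(p$adverse_events),
    costs = list(monthly_drug_cost = as.list(p$costs$monthly_drug_cost),
                 hhf_cost = p$costs$hhf_cost,
                 cv_death_cost = p$costs$cv_death_cost,
                 noncv_death_cost = p$costs$noncv_death_cost,
                 monthly_disease_mgmt_cost = p$costs$monthly_disease_mgmt_cost,
                 currency_year = p$costs$currency_year),
    utilities = list(state_utility = as.list(p$utilities$state_utility),
                     hhf_disutility = p$utilities$hhf_disutility,
                     hhf_disutility_duration = p$utilities$hhf_disutility_duration),
    economics = p$economics[c("annual_discount_rate_cost",
                              "annual_discount_rate_benefit", "cet",
                              "cycle_length", "horizon", "starting_age",
                              "half_cycle_correction", "max_age")],
    life_table = list(table = if (table_files) "life_table.csv" else
                        p$life_table$table,
                      sex_mix = as.list(p$life_table$sex_mix)),
    treatment_effect = list(hr_hhf_dsa_bounds = as.list(p$treatment_effect$hr_hhf_dsa_bounds),
                            subgroups = p$treatment_effect$subgroups),
    combine = list(weight_hfref = p$combine$weight_hfref,
                   weight_ef40 = p$combine$weight_ef40,
                   psa_resample_counts = as.list(p$combine$psa_resample_counts),
                   psa_total = p$combine$psa_total)
  )
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Export a trace as delimited text
#'
#' One row per cycle boundary for occupancy, merged with per-cycle event
#' expectations (events of cycle `t` span months `t` to `t+1`).
#'
#' @param trace a `cohort_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  occ <- as.data.frame(trace$occupancy)
  occ$cycle <- seq_len(nrow(occ)) - 1L
  ev <- trace$events
  out <- merge(occ, ev, by = "cycle", all.x = TRUE, sort = TRUE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
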