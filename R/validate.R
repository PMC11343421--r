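violation <- function(field, rule, message) {
  data.frame(field = field, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a model parameter bundle
#'
#' Checks every structural invariant the engine relies on and returns a
#' report; an empty report means the bundle is valid. Each violation names
#' the offending field and the rule it breaks.
#'
#' @param p a `model_parameters` bundle.
#' @return a data.frame of class `validation_report` with columns `field`,
#'   `rule`, `message`; zero rows iff valid.
#' @export
validate_parameters <- function(p) {
  v <- list()
  add <- function(field, rule, message) {
    v[[length(v) + 1L]] <<- violation(field, rule, message)
  }

  # health states: canonical contiguous quartile bounds, exactly four alive
  st <- p$states
  if (!identical(st$state_id, ALIVE_STATES)) {
    add("states.state_id", "alive states",
        "exactly four alive states Q1..Q4 required")
  } else {
    if (max(abs(st$kccq_lower - KCCQ_BOUNDS[1:4])) > 1e-9 ||
        max(abs(st$kccq_upper - KCCQ_BOUNDS[2:5])) > 1e-9) {
      add("states.kccq_bounds", "quartile bounds",
          "bounds must be 0/55.73/73.96/88.02/100, contiguous and non-overlapping")
    }
  }

  # transition matrices: 4x4, entries in [0,1], rows sum to 1
  for (arm in ARMS) {
    for (per in MATRIX_PERIODS) {
      m <- p$transitions$matrices[[arm]][[per]]
      fld <- sprintf("transitions.matrices.%s.%s", arm, per)
      if (is.null(m) || !all(dim(m) == c(4, 4))) {
        add(fld, "dimension", "4x4 matrix over alive states required")
        next
      }
      if (any(is.na(m))) {
        add(fld, "missing values", "matrix contains missing entries")
        next
      }
      if (any(m < 0 | m > 1)) {
        add(fld, "entry range", "all entries must lie in [0,1]")
      }
      rs <- rowSums(m)
      if (any(abs(rs - 1) > 1e-9)) {
        bad <- which(abs(rs - 1) > 1e-9)
        add(fld, "row sum != 1",
            sprintf("row(s) %s sum to %s",
                    paste(ALIVE_STATES[bad], collapse = ","),
                    paste(signif(rs[bad], 8), collapse = ",")))
      }
    }
  }

  # survival specs
  for (nm in c("cv_death", "all_cause_death", "discontinuation")) {
    sp <- p$survival[[nm]]
    fld <- paste0("survival.", nm)
    if (!inherits(sp, "survival_spec")) {
      add(fld, "type", "survival_spec required")
      next
    }
    if (sp$scale == "aft") {
      sg <- sp$ancillary$sigma
      if (is.null(sg) || !(sg > 0)) {
        add(paste0(fld, ".ancillary.sigma"), "positivity",
            "AFT families require sigma > 0")
      }
    }
    if (sp$family == "gengamma" && is.null(sp$ancillary$Q)) {
      add(paste0(fld, ".ancillary.Q"), "required parameter",
          "generalised gamma requires shape parameter Q")
    }
    if (!("intercept" %in% names(sp$coefs)) || !is.finite(sp$coefs["intercept"])) {
      add(paste0(fld, ".coefs.intercept"), "finite", "finite intercept required")
    }
  }

  # hHF rate model: finite non-negative rate for every state/arm combination
  rates <- outer(ALIVE_STATES, c(0, 1),
                 function(s, trt) event_rate(p$hhf, s, trt))
  if (any(!is.finite(rates)) || any(rates < 0)) {
    add("hhf", "rate finite and >= 0",
        "exp(linear predictor) must be finite and non-negative for all combinations")
  }

  # adverse events
  ae <- p$adverse_events
  if (any(ae$rate_epg < 0) || any(ae$rate_soc < 0)) {
    add("adverse_events.rates", "non-negative", "monthly AE rates must be >= 0")
  }
  if (any(ae$disutility > 0)) {
    add("adverse_events.disutility", "sign", "disutilities must be <= 0")
  }
  if (any(ae$unit_cost < 0)) {
    add("adverse_events.unit_cost", "non-negative", "AE costs must be >= 0")
  }

  # costs
  cs <- p$costs
  costs_num <- c(cs$monthly_drug_cost, cs$hhf_cost, cs$cv_death_cost,
                 cs$noncv_death_cost, cs$monthly_disease_mgmt_cost)
  if (any(costs_num < 0)) add("costs", "non-negative", "all costs must be >= 0")
  if (!identical(as.integer(cs$currency_year), 2022L)) {
    add("costs.currency_year", "currency year", "costs must carry year tag 2022")
  }

  # utilities: in [0,1], strictly increasing Q1 -> Q4
  u <- p$utilities$state_utility[ALIVE_STATES]
  if (any(is.na(u)) || any(u < 0 | u > 1)) {
    add("utilities.state_utility", "range", "state utilities must lie in [0,1]")
  } else if (any(diff(u) <= 0)) {
    add("utilities.state_utility", "monotonicity",
        "state utilities must be strictly increasing Q1 -> Q4")
  }
  if (p$utilities$hhf_disutility > 0) {
    add("utilities.hhf_disutility", "sign", "disutilities must be <= 0")
  }

  # economics
  ec <- p$economics
  if (ec$annual_discount_rate_cost < 0 || ec$annual_discount_rate_benefit < 0) {
    add("economics.discount", "non-negative", "discount rates must be >= 0")
  }
  if (!(identical(ec$horizon, "lifetime") ||
        (is.numeric(ec$horizon) && ec$horizon > 0))) {
    add("economics.horizon", "positivity", "horizon must be > 0 or 'lifetime'")
  }
  if (ec$max_age <= ec$starting_age) {
    add("economics.max_age", "ordering", "max_age must exceed starting_age")
  }

  # life table
  lt <- p$life_table
  tab <- lt$table
  if (any(tab$annual_qx < 0 | tab$annual_qx > 1)) {
    add("life_table.annual_qx", "range", "annual probabilities must lie in [0,1]")
  }
  if (any(tab$cv_share < 0 | tab$cv_share > 1)) {
    add("life_table.cv_share", "range", "CV death share must lie in [0,1]")
  }
  if (abs(sum(lt$sex_mix) - 1) > 1e-9) {
    add("life_table.sex_mix", "sum to 1", "sex mix must sum to 1")
  }
  for (s in names(lt$sex_mix)) {
    ages <- sort(tab$age[tab$sex == s])
    span <- floor(ec$starting_age):floor(ec$max_age)
    if (!all(span %in% ages)) {
      add("life_table.age", "coverage",
          sprintf("life table (%s) must cover ages %d-%d", s,
                  min(span), max(span)))
    }
  }

  # pooling weights
  cb <- p$combine
  if (abs(cb$weight_hfref + cb$weight_ef40 - 1) > 1e-9) {
    add("combine.weights", "sum to 1", "phenotype weights must sum to 1")
  }
  if (sum(cb$psa_resample_counts) != cb$psa_total) {
    add("combine.psa_resample_counts", "sum",
        "resample counts must sum to psa_total")
  }

  # treatment effect ratios
  te <- p$treatment_effect
  ratios <- c(te$hr_hhf_dsa_bounds,
              unlist(lapply(te$subgroups, function(g) c(g$hr_cv, g$hr_hhf))))
  if (any(ratios <= 0)) {
    add("treatment_effect", "positivity", "hazard/rate ratios must be > 0")
  }

  out <- if (length(v)) do.call(rbind, v) else
    data.frame(field = character(), rule = character(), message = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Stop if a parameter bundle is invalid
#'
#' @param p a `model_parameters` bundle.
#' @return `p`, invisibly, when valid.
#' @export
assert_valid <- function(p) {
  rep <- validate_parameters(p)
  if (nrow(rep) > 0) {
    stop(sprintf("invalid model parameters:\n%s",
                 paste(sprintf("- %s [%s]: %s", rep$field, rep$rule, rep$message),
                       collapse = "\n")), call. = FALSE)
  }
  invisible(p)
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<validation_report> no violations\n")
  } else {
    cat(sprintf("<validation_report> %d violation(s)\n", nrow(x)))
    print.data.frame(x)
  }
  invisible(x)
}
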