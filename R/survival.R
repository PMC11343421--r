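#' Cyclic hazard context
#'
#' Covariate and timing information for converting a parametric survival
#' process into a per-cycle conditional event probability. The alive-state
#' indicator at the start of a cycle selects the hazard for the whole cycle
#' (piecewise-constant covariate approximation: a cohort model cannot track
#' within-cycle state switching).
#'
#' @param elapsed_time months since model entry (cycle start).
#' @param cycle_length cycle length in months.
#' @param treatment 0/1 active-treatment indicator.
#' @param state alive state (`"Q1"`..`"Q4"`).
#' @param current_age age in years at cycle start (optional, informational).
#' @return object of class `hazard_context`.
#' @export
hazard_context <- function(elapsed_time, cycle_length = 1, treatment = 0,
                           state = "Q4", current_age = NA_real_) {
  stopifnot(all(elapsed_time >= 0), cycle_length > 0)
  structure(list(elapsed_time = elapsed_time, cycle_length = cycle_length,
                 treatment = treatment, state = state,
                 current_age = current_age),
            class = "hazard_context")
}

spec_linear_predictor <- function(spec, treatment = 0, state = spec$ref_state) {
  lp <- unname(spec$coefs["intercept"])
  if (is.na(lp)) stop("survival_spec has no intercept", call. = FALSE)
  tc <- spec$coefs["treatment"]
  if (!is.na(tc)) lp <- lp + unname(tc) * treatment
  if (state != spec$ref_state) {
    sc <- spec$coefs[state]
    if (!is.na(sc)) lp <- lp + unname(sc)
  }
  lp
}

# Survivor function for each supported family. `lp` is the linear predictor:
# log-time location (AFT families) or log hazard (PH families). Vectorised
# over t.
surv_eval <- function(family, t, lp, anc) {
  t <- pmax(t, 0)
  out <- switch(
    family,
    exponential = exp(-exp(lp) * t),
    gompertz = {
      g <- anc$shape %||% 0
      if (abs(g) < 1e-12) {
        exp(-exp(lp) * t)
      } else {
        exp(-exp(lp) / g * (exp(g * t) - 1))
      }
    },
    weibull = exp(-(t / exp(lp))^(1 / anc$sigma)),
    lognormal = ifelse(t <= 0, 1,
                       stats::pnorm((log(t) - lp) / anc$sigma,
                                    lower.tail = FALSE)),
    loglogistic = 1 / (1 + (t / exp(lp))^(1 / anc$sigma)),
    gengamma = {
      q <- anc$Q
      s <- anc$sigma
      if (abs(q) < 1e-8) {
        ifelse(t <= 0, 1,
               stats::pnorm((log(t) - lp) / s, lower.tail = FALSE))
      } else {
        w <- (log(pmax(t, .Machine$double.xmin)) - lp) / s
        u <- exp(q * w) / q^2
        a <- 1 / q^2
        if (q > 0) {
          ifelse(t <= 0, 1, stats::pgamma(u, a, lower.tail = FALSE))
        } else {
          ifelse(t <= 0, 1, stats::pgamma(u, a, lower.tail = TRUE))
        }
      }
    },
    stop(sprintf("unsupported survival family '%s'", family), call. = FALSE)
  )
  pmin(pmax(out, 0), 1)
}

#' Survivor function of a parametric time-to-event specification
#'
#' Evaluates `S(t)` under the family's canonical parameterisation: AFT
#' location-scale for Weibull/lognormal/log-logistic/generalised gamma
#' (covariates shift the log-time location), proportional hazards for
#' exponential/Gompertz (covariates shift the log hazard). `S(0) = 1` and `S`
#' is non-increasing in `t` for every family.
#'
#' @param spec a [survival_spec()].
#' @param t time(s) in months, `>= 0`; vectorised.
#' @param treatment 0/1 indicator.
#' @param state alive-state covariate value.
#' @return survival probabilit(y/ies) in `[0,1]`.
#' @export
survival_probability <- function(spec, t, treatment = 0, state = spec$ref_state) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  lp <- spec_linear_predictor(spec, treatment, state)
  surv_eval(spec$family, t, lp, spec$ancillary)
}

#' Per-cycle conditional event probability
#'
#' The probability that the event occurs during the cycle given it has not
#' occurred by the cycle start: `1 - S(t + delta) / S(t)` with the context's
#' covariates held fixed over the cycle.
#'
#' @param spec a [survival_spec()].
#' @param ctx a [hazard_context()]; `elapsed_time` may be a vector.
#' @return probabilit(y/ies) in `[0,1]`.
#' @export
cycle_event_probability <- function(spec, ctx) {
  t0 <- ctx$elapsed_time
  s0 <- survival_probability(spec, t0, ctx$treatment, ctx$state)
  if (any(s0 <= 0)) {
    stop("survival function is zero at cycle start (degenerate support)",
         call. = FALSE)
  }
  s1 <- survival_probability(spec, t0 + ctx$cycle_length, ctx$treatment, ctx$state)
  pmin(pmax(1 - s1 / s0, 0), 1)
}

#' Monthly non-cardiovascular death probability from a life table
#'
#' The sex-mix-weighted annual non-CV probability is the all-cause annual
#' probability times one minus the CV share of deaths; it is converted to a
#' monthly probability as `1 - (1 - p)^(1/12)`. Ages are looked up by integer
#' floor.
#'
#' @param lt a [life_table()].
#' @param age age in years (scalar or vector).
#' @param sex_mix optional override of the table's cohort sex mix.
#' @return monthly probabilit(y/ies).
#' @export
noncv_lifetable_probability <- function(lt, age, sex_mix = lt$sex_mix) {
  tab <- lt$table
  a <- floor(age)
  rng <- range(tab$age)
  if (any(a < rng[1] | a > rng[2])) {
    stop(sprintf("age %s outside life-table range [%d, %d]",
                 paste(unique(a[a < rng[1] | a > rng[2]]), collapse = ", "),
                 rng[1], rng[2]), call. = FALSE)
  }
  annual <- rep(0, length(a))
  for (s in names(sex_mix)) {
    sub <- tab[tab$sex == s, ]
    idx <- match(a, sub$age)
    annual <- annual + sex_mix[[s]] * sub$annual_qx[idx] * (1 - sub$cv_share[idx])
  }
  1 - (1 - annual)^(1 / 12)
}

#' Blend trial-based and life-table non-CV mortality
#'
#' In any cycle the risk of non-CV death for the heart-failure cohort must be
#' at least as high as in the age- and sex-matched general population, so the
#' larger of the two estimates is used.
#'
#' @param trial_based,lifetable_based monthly probabilities in `[0,1]`.
#' @return elementwise maximum.
#' @export
blended_noncv_probability <- function(trial_based, lifetable_based) {
  stopifnot(all(trial_based >= 0 & trial_based <= 1),
            all(lifetable_based >= 0 & lifetable_based <= 1))
  pmax(trial_based, lifetable_based)
}

#' Trial-based non-CV death probability by subtraction
#'
#' Per-cycle non-CV probability is the difference between the all-cause and
#' CV parametric risk equations, floored at zero: extrapolated curves can
#' cross, in which case the difference is clipped (and a warning emitted).
#'
#' @param all_cause_spec,cv_spec [survival_spec()] objects.
#' @param ctx a [hazard_context()].
#' @param warn emit a warning when the CV probability exceeds the all-cause
#'   probability.
#' @return monthly probabilit(y/ies), never negative.
#' @export
trial_noncv_probability <- function(all_cause_spec, cv_spec, ctx, warn = TRUE) {
  p_ac <- cycle_event_probability(all_cause_spec, ctx)
  p_cv <- cycle_event_probability(cv_spec, ctx)
  d <- p_ac - p_cv
  if (warn && any(d < -1e-12)) {
    warning("CV death probability exceeds all-cause probability; non-CV risk clipped at 0",
            call. = FALSE)
  }
  pmax(d, 0)
}
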