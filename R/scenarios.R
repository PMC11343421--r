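# Scenario catalogue mirroring the published scenario/subgroup analyses
# (alternative discount rates, horizons, starting age, survival-family swaps,
# no discontinuation, ketoacidosis inclusion, removal of the CV survival
# benefit, diabetes-status subgroups). Procurement-price scenarios are not
# reproducible (prices undisclosed) and are not included.

#' Refit a survival specification under an alternative family
#'
#' Alternative-family coefficient sets are not available, so family-swap
#' scenarios refit the target family to the base specification's survivor
#' curve: least squares on log S over a monthly grid at the reference
#' covariate pattern (off treatment, reference state). Covariate effects are
#' carried over: copied directly between AFT families, converted to log
#' hazard-ratio scale (`-beta/sigma`, exact for a Weibull base) for PH
#' targets.
#'
#' @param spec the base [survival_spec()].
#' @param family target family.
#' @param t_grid months at which the curves are matched.
#' @return a [survival_spec()] of the target family.
#' @export
refit_survival_family <- function(spec, family,
                                  t_grid = c(3, 6, 12, 24, 36, 48, 60, 84, 120)) {
  if (family == spec$family) return(spec)
  s_target <- survival_probability(spec, t_grid)
  # crude median for initialisation
  t50 <- if (min(s_target) < 0.5) {
    t_grid[which.min(abs(s_target - 0.5))]
  } else {
    max(t_grid) * 2
  }
  obj <- function(par) {
    anc <- switch(family,
                  exponential = list(),
                  gompertz = list(shape = par[2]),
                  gengamma = list(sigma = exp(par[2]), Q = par[3]),
                  list(sigma = exp(par[2])))
    s <- surv_eval(family, t_grid, par[1], anc)
    sum((log(pmax(s, 1e-12)) - log(pmax(s_target, 1e-12)))^2)
  }
  init <- switch(family,
                 exponential = log(-log(max(s_target[t_grid == 12], 0.5)) / 12),
                 gompertz = c(log(-log(max(s_target[t_grid == 12], 0.5)) / 12), 0.001),
                 gengamma = c(log(t50), 0, 1),
                 c(log(t50), 0))
  fit <- if (length(init) == 1) {
    stats::optim(init, obj, method = "Brent", lower = init - 8, upper = init + 8)
  } else {
    stats::optim(init, obj, control = list(maxit = 2000, reltol = 1e-12))
  }
  par <- fit$par
  anc <- switch(family,
                exponential = list(),
                gompertz = list(shape = par[2]),
                gengamma = list(sigma = exp(par[2]), Q = par[3]),
                list(sigma = exp(par[2])))
  new_scale <- if (family %in% c("exponential", "gompertz")) "ph" else "aft"
  covs <- spec$coefs[setdiff(names(spec$coefs), "intercept")]
  if (length(covs)) {
    if (spec$scale == "aft" && new_scale == "ph") {
      covs <- -covs / spec$ancillary$sigma
    } else if (spec$scale == "ph" && new_scale == "aft") {
      covs <- -covs * (anc$sigma %||% 1)
    }
  }
  survival_spec(family, coefs = c(intercept = unname(par[1]), covs),
                ancillary = anc, ref_state = spec$ref_state)
}

zero_hazard_spec <- function(ref_state = "Q4") {
  survival_spec("exponential", coefs = c(intercept = -30), ref_state = ref_state)
}

swap_family <- function(process, family) {
  function(p) {
    p$survival[[process]] <- refit_survival_family(p$survival[[process]], family)
    if (process == "cv_death") {
      p$survival$all_cause_death <-
        refit_survival_family(p$survival$all_cause_death, family)
    }
    p
  }
}

subgroup_override <- function(p, hr_cv, hr_hhf) {
  # subgroups share the base transition matrices; only the treatment effects
  # on CV death and hospitalisation differ
  p <- set_treatment_ratio(p, hr_cv, "cv_death")
  p <- set_treatment_ratio(p, hr_hhf, "hhf")
  p
}

#' Default scenario catalogue
#'
#' Mirrors the published scenario set: starting age 71.9, horizons of 5 and
#' 10 years, discount rates 0 and 5 percent, the five alternative mortality
#' and discontinuation extrapolation families, no treatment discontinuation,
#' ketoacidosis included, no CV survival benefit, and the diabetes-status
#' subgroups.
#'
#' @param p a `model_parameters` bundle (for subgroup hazard ratios).
#' @return list of [scenario_spec()] objects.
#' @export
scenario_default_specs <- function(p) {
  alt <- c("lognormal", "loglogistic", "exponential", "gengamma", "gompertz")
  alt_disc <- c("weibull", "lognormal", "loglogistic", "exponential", "gompertz")
  sg <- p$treatment_effect$subgroups
  c(
    list(
      scenario_spec("starting age 71.9 years",
                    list(economics.starting_age = 71.9)),
      scenario_spec("time horizon 5 years", list(economics.horizon = 60)),
      scenario_spec("time horizon 10 years", list(economics.horizon = 120)),
      scenario_spec("discount rate 0%",
                    list(economics.annual_discount_rate_cost = 0,
                         economics.annual_discount_rate_benefit = 0)),
      scenario_spec("discount rate 5%",
                    list(economics.annual_discount_rate_cost = 0.05,
                         economics.annual_discount_rate_benefit = 0.05))
    ),
    lapply(alt, function(fam)
      scenario_spec(sprintf("mortality extrapolation: %s", fam),
                    swap_family("cv_death", fam))),
    lapply(alt_disc, function(fam)
      scenario_spec(sprintf("discontinuation extrapolation: %s", fam),
                    swap_family("discontinuation", fam))),
    list(
      scenario_spec("no treatment discontinuation", function(q) {
        q$survival$discontinuation <- zero_hazard_spec()
        q
      }),
      scenario_spec("ketoacidosis included", function(q) {
        q$adverse_events$include[q$adverse_events$event == "ketoacidosis"] <- TRUE
        q
      }),
      scenario_spec("no CV death benefit",
                    function(q) set_treatment_ratio(q, 1, "cv_death")),
      scenario_spec("T2D subgroup", function(q)
        subgroup_override(q, sg$t2d$hr_cv, sg$t2d$hr_hhf)),
      scenario_spec("non-T2D subgroup", function(q)
        subgroup_override(q, sg$non_t2d$hr_cv, sg$non_t2d$hr_hhf))
    )
  )
}
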