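# Deterministic, probabilistic and scenario sensitivity analysis.

run_icer <- function(p, horizon = NULL) {
  res <- run_base_case(p, horizon = horizon)
  res$incremental
}

#' One-way sensitivity specification
#'
#' @param path dotted parameter path (see [param_set()]), or a label when an
#'   `apply` function is supplied.
#' @param low,high values on the parameter's natural scale (`low <= high`).
#' @param label display label.
#' @param note provenance note (e.g. "95% CI bound", "+/-20%").
#' @param apply optional `function(params, value)` for overrides that are not
#'   a plain path assignment (e.g. hazard ratios mapped into coefficients).
#' @return object of class `dsa_spec`.
#' @export
dsa_spec <- function(path, low, high, label = path, note = "", apply = NULL) {
  if (is.numeric(low) && is.numeric(high) && low > high) {
    stop("dsa_spec: low must be <= high on the natural scale", call. = FALSE)
  }
  structure(list(path = path, low = low, high = high, label = label,
                 note = note, apply = apply),
            class = "dsa_spec")
}

apply_override <- function(p, spec, value) {
  if (is.function(spec$apply)) spec$apply(p, value) else param_set(p, spec$path, value)
}

#' Apply a hazard/rate ratio to a treatment coefficient
#'
#' Maps a ratio onto the treatment coefficient of the hospitalisation model
#' (log rate ratio directly) or of an AFT/PH mortality specification (AFT:
#' `beta = -log(hr) * sigma`, exact for the Weibull; PH: `beta = log(hr)`).
#'
#' @param p a `model_parameters` bundle.
#' @param hr the ratio (> 0).
#' @param process `"hhf"` or `"cv_death"`.
#' @return modified bundle.
#' @export
set_treatment_ratio <- function(p, hr, process = c("hhf", "cv_death")) {
  process <- match.arg(process)
  stopifnot(hr > 0)
  if (process == "hhf") {
    p$hhf$treatment_coef <- log(hr)
  } else {
    sp <- p$survival$cv_death
    p$survival$cv_death$coefs["treatment"] <-
      if (sp$scale == "aft") -log(hr) * sp$ancillary$sigma else log(hr)
  }
  p
}

#' Default one-way sensitivity specifications
#'
#' Printed confidence-interval bounds are used where available (upper 95
#' percent bound 0.83 for the hospitalisation rate ratio; removal of the CV
#' survival benefit, ratio 1); other inputs vary by +/-20 percent (costs)
#' or +/-10 percent (utilities), overridable.
#'
#' @param p a `model_parameters` bundle.
#' @return list of [dsa_spec()] objects.
#' @export
dsa_default_specs <- function(p) {
  pct <- function(path, frac, note) {
    base <- param_get(p, path)
    dsa_spec(path, base * (1 - frac), base * (1 + frac), note = note)
  }
  hr_hhf_base <- exp(p$hhf$treatment_coef)
  sp <- p$survival$cv_death
  hr_cv_base <- if (sp$scale == "aft") {
    exp(-coef_or_zero(sp$coefs, "treatment") / sp$ancillary$sigma)
  } else {
    exp(coef_or_zero(sp$coefs, "treatment"))
  }
  bounds <- p$treatment_effect$hr_hhf_dsa_bounds
  list(
    dsa_spec("treatment_effect_hhf", bounds[["low"]], bounds[["high"]],
             label = "hHF rate ratio (95% CI)", note = "95% CI bounds",
             apply = function(q, v) set_treatment_ratio(q, v, "hhf")),
    dsa_spec("treatment_effect_cv_death", unname(hr_cv_base), 1,
             label = "CV death HR (base to no effect)", note = "HR -> 1",
             apply = function(q, v) set_treatment_ratio(q, v, "cv_death")),
    pct("costs.monthly_drug_cost.EPG_SOC", 0.20, "+/-20%"),
    pct("costs.hhf_cost", 0.20, "+/-20%"),
    pct("costs.cv_death_cost", 0.20, "+/-20%"),
    pct("costs.monthly_disease_mgmt_cost", 0.20, "+/-20%"),
    dsa_spec("utilities.hhf_disutility",
             p$utilities$hhf_disutility * 1.2, p$utilities$hhf_disutility * 0.8,
             label = "hHF disutility", note = "+/-20%"),
    dsa_spec("utility_q1", p$utilities$state_utility[["Q1"]] * 0.9,
             min(p$utilities$state_utility[["Q1"]] * 1.1,
                 p$utilities$state_utility[["Q2"]] - 1e-6),
             label = "Q1 state utility", note = "+/-10%, capped below Q2",
             apply = function(q, v) {
               q$utilities$state_utility[["Q1"]] <- v
               q
             })
  )
}

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' Runs the model at each specification's low and high value with everything
#' else at base, reports the resulting ICERs sorted by bar width, and flags
#' rows whose interval crosses the cost-effectiveness threshold. A row whose
#' override produces invalid parameters is marked failed and the run
#' continues.
#'
#' @param p a validated `model_parameters` base bundle.
#' @param specs list of [dsa_spec()] (default [dsa_default_specs()]).
#' @return data.frame of class `dsa_table`: one row per spec with `icer_low`,
#'   `icer_high`, `width`, `crosses_cet`, `failed`; the base-case ICER and
#'   threshold are attached as attributes.
#' @export
run_dsa <- function(p, specs = dsa_default_specs(p)) {
  base <- run_icer(p)
  cet <- p$economics$cet
  one_side <- function(spec, value) {
    tryCatch({
      q <- apply_override(p, spec, value)
      assert_valid(q)
      inc <- run_icer(q)
      list(icer = inc$icer_per_qaly, tag = inc$tag, failed = FALSE)
    }, error = function(e) list(icer = NA_real_, tag = "failed", failed = TRUE))
  }
  rows <- lapply(specs, function(sp) {
    lo <- one_side(sp, sp$low)
    hi <- one_side(sp, sp$high)
    data.frame(parameter = sp$label, low = as.numeric(sp$low),
               high = as.numeric(sp$high),
               icer_low = lo$icer, icer_high = hi$icer,
               tag_low = lo$tag, tag_high = hi$tag,
               failed = lo$failed || hi$failed,
               note = sp$note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$width <- abs(out$icer_high - out$icer_low)
  out$crosses_cet <- !out$failed & !is.na(out$width) &
    (pmin(out$icer_low, out$icer_high) <= cet) &
    (pmax(out$icer_low, out$icer_high) > cet)
  out <- out[order(ifelse(is.na(out$width), -Inf, out$width), decreasing = TRUE), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer_per_qaly
  attr(out, "cet") <- cet
  class(out) <- c("dsa_table", "data.frame")
  out
}

#' Probabilistic distribution specification
#'
#' @param path dotted parameter path (or label, with `apply`).
#' @param family `"beta"`, `"gamma"`, `"lognormal"`, `"normal"`,
#'   `"dirichlet_row"` or `"fixed"`.
#' @param mean,se moment parameters from which the hyperparameters are
#'   derived (`beta`/`gamma`/`normal`); `lognormal` takes `mean` (the ratio)
#'   and `ci` (95 percent interval on the ratio scale).
#' @param ci length-2 interval for `lognormal`.
#' @param conc concentration multiplier for `dirichlet_row`.
#' @param apply optional `function(params, value)` override setter.
#' @return object of class `psa_dist_spec`.
#' @export
psa_dist_spec <- function(path, family, mean = NULL, se = NULL, ci = NULL,
                          conc = 100, apply = NULL) {
  structure(list(path = path, family = family, mean = mean, se = se, ci = ci,
                 conc = conc, apply = apply),
            class = "psa_dist_spec")
}

draw_one <- function(spec, base_value) {
  switch(spec$family,
    fixed = base_value,
    beta = {
      m <- spec$mean; s <- spec$se %||% (0.1 * abs(m))
      sgn <- if (m < 0) -1 else 1
      m <- abs(m)
      v <- s^2
      if (v >= m * (1 - m)) v <- 0.9 * m * (1 - m)
      k <- m * (1 - m) / v - 1
      sgn * stats::rbeta(1, m * k, (1 - m) * k)
    },
    gamma = {
      m <- spec$mean; s <- spec$se %||% (0.2 * m)
      if (m == 0) return(0)
      shape <- (m / s)^2
      stats::rgamma(1, shape = shape, rate = shape / m)
    },
    normal = stats::rnorm(1, spec$mean, spec$se),
    lognormal = {
      sdlog <- log(spec$ci[2] / spec$ci[1]) / (2 * stats::qnorm(0.975))
      stats::rlnorm(1, log(spec$mean), sdlog)
    },
    stop(sprintf("unsupported PSA distribution family '%s'", spec$family),
         call. = FALSE)
  )
}

#' Default probabilistic distributions
#'
#' Standard cost-utility practice in the absence of published uncertainty
#' tables: beta for utilities and disutility magnitudes (moment-matched, SE
#' 10 percent of the mean), gamma for event and management costs (SE 20
#' percent of the mean), lognormal for the treatment hazard/rate ratios
#' (spread from the printed composite 95 percent interval 0.69-0.90), and
#' Dirichlet rows for the transition matrices (concentration 100 times the
#' base row). Drug acquisition prices are treated as known and held fixed.
#'
#' @param p a `model_parameters` bundle.
#' @return list of [psa_dist_spec()] objects.
#' @export
psa_default_distributions <- function(p) {
  specs <- list()
  for (s in ALIVE_STATES) {
    specs[[length(specs) + 1L]] <- psa_dist_spec(
      sprintf("utilities.state_utility.%s", s), "beta",
      mean = p$utilities$state_utility[[s]])
  }
  specs[[length(specs) + 1L]] <- psa_dist_spec(
    "utilities.hhf_disutility", "beta", mean = p$utilities$hhf_disutility)
  for (path in c("costs.hhf_cost", "costs.cv_death_cost",
                 "costs.monthly_disease_mgmt_cost")) {
    specs[[length(specs) + 1L]] <- psa_dist_spec(path, "gamma",
                                                 mean = param_get(p, path))
  }
  ci_spread <- c(0.69, 0.90)
  hr_hhf <- exp(p$hhf$treatment_coef)
  specs[[length(specs) + 1L]] <- psa_dist_spec(
    "hr_hhf", "lognormal", mean = hr_hhf,
    ci = hr_hhf * ci_spread / sqrt(prod(ci_spread)),
    apply = function(q, v) set_treatment_ratio(q, v, "hhf"))
  sp <- p$survival$cv_death
  hr_cv <- if (sp$scale == "aft") {
    exp(-coef_or_zero(sp$coefs, "treatment") / sp$ancillary$sigma)
  } else {
    exp(coef_or_zero(sp$coefs, "treatment"))
  }
  specs[[length(specs) + 1L]] <- psa_dist_spec(
    "hr_cv_death", "lognormal", mean = unname(hr_cv),
    ci = unname(hr_cv) * ci_spread / sqrt(prod(ci_spread)),
    apply = function(q, v) set_treatment_ratio(q, v, "cv_death"))
  specs[[length(specs) + 1L]] <- psa_dist_spec(
    "transitions", "dirichlet_row", conc = 100)
  specs
}

draw_valid <- function(spec, base_value, max_retries = 100L) {
  for (i in seq_len(max_retries + 1L)) {
    v <- draw_one(spec, base_value)
    ok <- is.finite(v) &&
      !(spec$family == "gamma" && v < 0) &&
      !(spec$family == "beta" && (abs(v) > 1)) &&
      !(spec$family == "lognormal" && v <= 0)
    if (ok) return(list(value = v, retries = i - 1L))
  }
  stop(sprintf("PSA draw for '%s' failed after %d retries", spec$path,
               max_retries), call. = FALSE)
}

sample_bundle <- function(p, dists) {
  retries <- 0L
  drawn <- list()
  for (spec in dists) {
    if (spec$family == "dirichlet_row") {
      for (arm in ARMS) {
        for (per in MATRIX_PERIODS) {
          m <- p$transitions$matrices[[arm]][[per]]
          for (i in 1:4) {
            g <- stats::rgamma(4, shape = spec$conc * pmax(m[i, ], 1e-9))
            m[i, ] <- g / sum(g)
          }
          p$transitions$matrices[[arm]][[per]] <- m
        }
      }
      next
    }
    base_value <- if (is.null(spec$apply)) param_get(p, spec$path) else NA_real_
    d <- draw_valid(spec, base_value)
    retries <- retries + d$retries
    drawn[[spec$path]] <- d$value
    p <- if (is.null(spec$apply)) {
      param_set(p, spec$path, d$value)
    } else {
      spec$apply(p, d$value)
    }
  }
  list(params = p, draws = drawn, retries = retries)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation: each iteration samples all parameters jointly from
#' their distributions, runs both arms, and records total discounted cost,
#' LYs and QALYs per arm. Reproducible under the seed; invalid draws are
#' redrawn (hard error after 100 retries for one parameter). PSA draws relax
#' the base-case requirement that state utilities be strictly ordered
#' (independent draws may cross); hard constraints (signs, ranges,
#' row-stochasticity) always hold by construction or redraw.
#'
#' @param p a validated `model_parameters` bundle.
#' @param dists list of [psa_dist_spec()] (default
#'   [psa_default_distributions()]).
#' @param n number of iterations (>= 1).
#' @param seed integer seed.
#' @return `psa_samples` data.frame: `iteration`, per-arm `cost_*`, `ly_*`,
#'   `qaly_*`; per-iteration draws and the distribution manifest are
#'   attached as attributes `draws` and `manifest`.
#' @export
run_psa <- function(p, dists = psa_default_distributions(p), n = 1000L,
                    seed = 1L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    rows <- vector("list", n)
    draw_log <- vector("list", n)
    total_retries <- 0L
    for (it in seq_len(n)) {
      sb <- sample_bundle(p, dists)
      total_retries <- total_retries + sb$retries
      res <- run_base_case(sb$params)
      rows[[it]] <- data.frame(
        iteration = it,
        cost_epg_soc = res$epg_soc$discounted$cost$total,
        ly_epg_soc = res$epg_soc$discounted$ly$total,
        qaly_epg_soc = res$epg_soc$discounted$qaly$total,
        cost_soc = res$soc$discounted$cost$total,
        ly_soc = res$soc$discounted$ly$total,
        qaly_soc = res$soc$discounted$qaly$total)
      draw_log[[it]] <- sb$draws
    }
    out <- do.call(rbind, rows)
    attr(out, "seed") <- seed
    attr(out, "retries") <- total_retries
    attr(out, "draws") <- draw_log
    attr(out, "manifest") <- lapply(dists, function(d)
      d[c("path", "family", "mean", "se", "ci", "conc")])
    class(out) <- c("psa_samples", "data.frame")
    out
  })
}

#' Scenario specification
#'
#' @param name scenario label.
#' @param overrides either a named list of `path = value` overrides or a
#'   `function(params) -> params`.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, overrides) {
  structure(list(name = name, overrides = overrides), class = "scenario_spec")
}

apply_scenario <- function(p, spec) {
  ov <- spec$overrides
  if (is.function(ov)) return(ov(p))
  for (path in names(ov)) p <- param_set(p, path, ov[[path]])
  p
}

#' Run scenario and subgroup analyses
#'
#' One row per scenario with its ICER and the percentage change from the
#' base-case ICER; the base case is always the first row. A scenario whose
#' overrides produce invalid parameters is marked failed and the run
#' continues. The base bundle is never modified.
#'
#' @param p a validated `model_parameters` base bundle.
#' @param specs list of [scenario_spec()] objects (possibly empty).
#' @return data.frame with `scenario`, `delta_cost`, `delta_qaly`, `icer`,
#'   `pct_change`, `failed`.
#' @export
run_scenarios <- function(p, specs = list()) {
  base <- run_icer(p)
  base_icer <- base$icer_per_qaly
  rows <- list(data.frame(scenario = "base case",
                          delta_cost = base$delta_cost,
                          delta_qaly = base$delta_qaly,
                          icer = base_icer, pct_change = 0, failed = FALSE,
                          stringsAsFactors = FALSE))
  for (sp in specs) {
    rows[[length(rows) + 1L]] <- tryCatch({
      q <- apply_scenario(p, sp)
      assert_valid(q)
      inc <- run_icer(q)
      data.frame(scenario = sp$name, delta_cost = inc$delta_cost,
                 delta_qaly = inc$delta_qaly, icer = inc$icer_per_qaly,
                 pct_change = round_report(100 * (inc$icer_per_qaly / base_icer - 1)),
                 failed = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(scenario = sp$name, delta_cost = NA_real_,
                 delta_qaly = NA_real_, icer = NA_real_, pct_change = NA_real_,
                 failed = TRUE, stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
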