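#' Incremental cost-effectiveness result
#'
#' Deltas are intervention minus comparator on the discounted scale. The ICER
#' is reported only when the QALY (or LY) delta is non-zero; otherwise a
#' dominance tag applies: cheaper and more effective is `dominant`, costlier
#' and no more effective is `dominated`.
#'
#' @param a intervention `outcome_summary` (or a list with `cost`, `ly`,
#'   `qaly` scalars).
#' @param b comparator, same type as `a`.
#' @return object of class `incremental_result` with `delta_cost`,
#'   `delta_ly`, `delta_qaly`, `icer_per_qaly`, `icer_per_ly`, and `tag`.
#' @export
incremental <- function(a, b) {
  pick <- function(x) {
    if (inherits(x, "outcome_summary")) {
      list(cost = x$discounted$cost$total, ly = x$discounted$ly$total,
           qaly = x$discounted$qaly$total)
    } else {
      x
    }
  }
  a <- pick(a); b <- pick(b)
  dc <- a$cost - b$cost
  dl <- a$ly - b$ly
  dq <- a$qaly - b$qaly

  tag <- if (dq > 0 && dc <= 0) "dominant"
    else if (dq <= 0 && dc > 0) "dominated"
    else "ratio"
  ratio <- function(delta_eff) {
    if (tag != "ratio" || delta_eff == 0) NA_real_ else dc / delta_eff
  }
  structure(list(delta_cost = dc, delta_ly = dl, delta_qaly = dq,
                 icer_per_qaly = ratio(dq), icer_per_ly = ratio(dl),
                 tag = tag),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat("<incremental_result>\n")
  cat(sprintf("  delta cost RM %.0f | delta LY %.4f | delta QALY %.4f\n",
              x$delta_cost, x$delta_ly, x$delta_qaly))
  if (x$tag == "ratio") {
    cat(sprintf("  ICER: RM %.0f per QALY gained (RM %.0f per LY)\n",
                x$icer_per_qaly, x$icer_per_ly))
  } else {
    cat(sprintf("  %s\n", x$tag))
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `threshold * delta_QALY - delta_cost`; positive iff the ICER lies below
#' the threshold (for a positive QALY gain).
#'
#' @param delta_cost incremental cost.
#' @param delta_qaly incremental QALYs.
#' @param threshold willingness-to-pay per QALY (>= 0).
#' @return net monetary benefit in currency units.
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, threshold) {
  stopifnot(all(threshold >= 0))
  threshold * delta_qaly - delta_cost
}

psa_deltas <- function(samples) {
  list(dc = samples$cost_epg_soc - samples$cost_soc,
       dq = samples$qaly_epg_soc - samples$qaly_soc,
       dl = samples$ly_epg_soc - samples$ly_soc)
}

#' Cost-effectiveness acceptability curve
#'
#' At each threshold, the fraction of PSA iterations in which the
#' intervention has strictly positive net monetary benefit; ties go to the
#' comparator, so the two arms' probabilities always sum to one.
#'
#' @param samples a `psa_samples` data.frame (see [run_psa()]): one row per
#'   iteration with per-arm `cost_*`, `ly_*`, `qaly_*` columns.
#' @param thresholds numeric vector of willingness-to-pay values.
#' @return data.frame with `threshold`, `prob_epg_soc`, `prob_soc`.
#' @export
ceac <- function(samples, thresholds) {
  if (nrow(samples) == 0) stop("empty PSA sample set", call. = FALSE)
  d <- psa_deltas(samples)
  prob <- vapply(thresholds, function(l)
    mean(net_monetary_benefit(d$dc, d$dq, l) > 0), numeric(1))
  data.frame(threshold = thresholds, prob_epg_soc = prob, prob_soc = 1 - prob)
}

#' Probabilistic mean ICER and interval summaries
#'
#' The mean ICER is the ratio of mean incremental cost to mean incremental
#' QALYs across iterations (not the mean of per-iteration ratios); with a
#' degenerate PSA this reproduces the deterministic ICER. Intervals are
#' 2.5/97.5 percentiles of the deltas.
#'
#' @param samples a `psa_samples` data.frame.
#' @return list with `mean_delta_cost`, `mean_delta_qaly`, `mean_icer`,
#'   `ci_delta_cost`, `ci_delta_qaly`, dominance tallies and `n`.
#' @export
psa_mean_icer <- function(samples) {
  if (nrow(samples) == 0) stop("empty PSA sample set", call. = FALSE)
  d <- psa_deltas(samples)
  mdc <- mean(d$dc)
  mdq <- mean(d$dq)
  list(
    mean_delta_cost = mdc,
    mean_delta_qaly = mdq,
    mean_icer = if (mdq == 0) NA_real_ else mdc / mdq,
    ci_delta_cost = stats::quantile(d$dc, c(0.025, 0.975), names = FALSE),
    ci_delta_qaly = stats::quantile(d$dq, c(0.025, 0.975), names = FALSE),
    n_dominant = sum(d$dq > 0 & d$dc <= 0),
    n_dominated = sum(d$dq <= 0 & d$dc > 0),
    n = nrow(samples)
  )
}

#' Pool deterministic phenotype results
#'
#' Pooled incremental cost and QALYs are prevalence-weighted means of the
#' phenotype-specific results (weights 0.67 reduced EF / 0.33 EF>40 by
#' default); the pooled ICER is the ratio of the pooled deltas, computed at
#' full precision.
#'
#' @param r_hfref,r_ef40 `incremental_result` objects.
#' @param spec a [combine_spec()].
#' @return an `incremental_result` for the overall population.
#' @export
combine_phenotypes_deterministic <- function(r_hfref, r_ef40,
                                             spec = combine_spec()) {
  w1 <- spec$weight_hfref
  w2 <- spec$weight_ef40
  stopifnot(abs(w1 + w2 - 1) < 1e-9)
  a <- list(cost = w1 * r_hfref$delta_cost + w2 * r_ef40$delta_cost,
            ly = w1 * r_hfref$delta_ly + w2 * r_ef40$delta_ly,
            qaly = w1 * r_hfref$delta_qaly + w2 * r_ef40$delta_qaly)
  incremental(a, list(cost = 0, ly = 0, qaly = 0))
}

#' Pool PSA iterations across phenotypes
#'
#' Draws the configured numbers of iterations (670 reduced EF, 330 EF>40 by
#' default) uniformly at random without replacement from each phenotype's
#' PSA pool and concatenates them into a single pooled sample set,
#' reproducible under the seed.
#'
#' @param samples_hfref,samples_ef40 `psa_samples` data.frames.
#' @param spec a [combine_spec()].
#' @param seed integer seed.
#' @return pooled `psa_samples` data.frame with fresh iteration ids and a
#'   `phenotype` column recording provenance.
#' @export
combine_phenotypes_psa <- function(samples_hfref, samples_ef40,
                                   spec = combine_spec(), seed = 1L) {
  counts <- spec$psa_resample_counts
  if (nrow(samples_hfref) < counts[["hfref"]]) {
    stop(sprintf("reduced-EF pool has %d iterations, need %d",
                 nrow(samples_hfref), counts[["hfref"]]), call. = FALSE)
  }
  if (nrow(samples_ef40) < counts[["ef40"]]) {
    stop(sprintf("EF>40 pool has %d iterations, need %d",
                 nrow(samples_ef40), counts[["ef40"]]), call. = FALSE)
  }
  cols <- c("cost_epg_soc", "ly_epg_soc", "qaly_epg_soc",
            "cost_soc", "ly_soc", "qaly_soc")
  with_seed(seed, {
    i1 <- sample.int(nrow(samples_hfref), counts[["hfref"]], replace = FALSE)
    i2 <- sample.int(nrow(samples_ef40), counts[["ef40"]], replace = FALSE)
    out <- rbind(
      cbind(samples_hfref[i1, cols, drop = FALSE], phenotype = "hfref"),
      cbind(samples_ef40[i2, cols, drop = FALSE], phenotype = "ef40")
    )
    out <- cbind(iteration = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    attr(out, "seed") <- seed
    class(out) <- c("psa_samples", "data.frame")
    out
  })
}
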