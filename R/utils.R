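#' @keywords internal
"_PACKAGE"

# Alive health states (KCCQ-CSS quartiles, Q4 = best health) and the canonical
# quartile bounds on the 0-100 score scale.
ALIVE_STATES <- c("Q1", "Q2", "Q3", "Q4")
KCCQ_BOUNDS <- c(0, 55.73, 73.96, 88.02, 100)
ARMS <- c("EPG_SOC", "SOC")
MATRIX_PERIODS <- c("m1_3", "m4_8", "m9plus")
COMPARTMENTS <- c(paste0(ALIVE_STATES, "_on"), paste0(ALIVE_STATES, "_off"),
                  "dead_cv", "dead_noncv")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the previous global RNG state so
#' that no hidden randomness leaks between calls.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Get or set a value inside a parameter bundle by dotted path
#'
#' Paths address nested list components, e.g.
#' `"costs.hhf_cost"` or `"economics.starting_age"`. Used by the sensitivity
#' analysis machinery so parameter variations can be declared as data.
#'
#' @param x a nested list (typically a `model_parameters` bundle).
#' @param path character scalar, components separated by `.`.
#' @param value replacement value.
#' @return `param_get` returns the addressed value; `param_set` the modified
#'   object.
#' @export
param_get <- function(x, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  for (k in keys) {
    if (!(k %in% names(x))) {
      stop(sprintf("unknown parameter path '%s' (no component '%s')", path, k),
           call. = FALSE)
    }
    x <- x[[k]]
  }
  x
}

#' @rdname param_get
#' @export
param_set <- function(x, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  set_rec <- function(x, keys) {
    if (length(keys) == 0L) return(value)
    k <- keys[[1]]
    if (!(k %in% names(x))) {
      stop(sprintf("unknown parameter path '%s' (no component '%s')", path, k),
           call. = FALSE)
    }
    x[[k]] <- set_rec(x[[k]], keys[-1])
    x
  }
  set_rec(x, keys)
}

coef_or_zero <- function(coefs, name) {
  if (name %in% names(coefs)) coefs[[name]] else 0
}

# round-half-up to match the reporting convention of published tables
round_report <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
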