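#' Derive a stage-specific seed from a master seed
#'
#' All randomness in the package flows from a single master seed; each
#' stochastic stage derives its own sub-stream seed from the master seed and
#' a stage tag, so that adding or reordering stages never perturbs the
#' random numbers of unrelated stages.
#'
#' @param seed Master integer seed.
#' @param tag Character stage tag (e.g. `"landuse_t0"`).
#' @return An integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 1000000007
  as.integer(((abs(seed) %% 65521) * 32749 + h) %% 2147483647)
}

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library code never disturbs user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Clamp values to [lo, hi]; warn once with a count when clamping negative
# physical quantities (per-layer bookkeeping for the ES equations).
clamp <- function(x, lo = -Inf, hi = Inf, warn_label = NULL) {
  n_bad <- sum(x < lo | x > hi, na.rm = TRUE)
  if (n_bad > 0 && !is.null(warn_label)) {
    warning(sprintf("%s: %d value(s) clamped to [%s, %s]",
                    warn_label, n_bad, format(lo), format(hi)), call. = FALSE)
  }
  pmin(pmax(x, lo), hi)
}

# min-max rescale to [0, 1]; constant input maps to 0 (with optional warning)
minmax <- function(x, warn_label = NULL) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[2] - r[1] < .Machine$double.eps * max(1, abs(r[2]))) {
    if (!is.null(warn_label)) {
      warning(sprintf("%s: constant values, rescaled to 0", warn_label),
              call. = FALSE)
    }
    return(ifelse(is.na(x), NA_real_, 0))
  }
  (x - r[1]) / (r[2] - r[1])
}
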