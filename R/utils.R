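# Shared numeric helpers. Percentiles everywhere in the package use the
# same linear-interpolation definition (R quantile type 7) so the null
# threshold, hub cutoff and baseline estimator are mutually consistent.

percentile <- function(x, p) {
  stopifnot(length(x) > 0, p >= 0, p <= 100)
  as.numeric(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}

#' Derive independent per-stage seeds from one master seed
#'
#' All randomness in the package flows from a single integer seed. Each
#' pipeline stage (layout, ground truth, noise, surrogates, ...) receives its
#' own sub-seed drawn deterministically from the master seed, so changing the
#' number of draws in one stage never perturbs another stage's stream.
#'
#' @param seed master integer seed.
#' @param labels character vector naming the stages.
#' @return named integer vector of sub-seeds (all below 2^31).
#' @export
derive_seeds <- function(seed, labels) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max, length(labels))
  names(s) <- labels
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
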