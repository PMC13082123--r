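#' Linear-shift surrogate of a trace
#'
#' Rotates a series by a fixed number of frames, wrapping the tail back to
#' the start. Length, mean, variance, value multiset and autocorrelation
#' structure are preserved exactly; only the alignment to other traces is
#' destroyed, which is the surrogate property the significance null needs.
#'
#' @param x numeric series.
#' @param shift_frames integer shift, `0 <= shift_frames < length(x)`.
#' @param mode `"circular"` (default) wraps the series; `"truncate"` returns
#'   only the overlapping tail (`x[(shift+1):n]`), discarding the rest —
#'   a literal non-wrapping shift kept for comparison.
#' @return shifted series; for `"circular"`, `y[t] = x[((t - shift - 1) mod
#'   n) + 1]`.
#' @export
linear_shift <- function(x, shift_frames, mode = c("circular", "truncate")) {
  mode <- match.arg(mode)
  n <- length(x)
  shift_frames <- as.integer(shift_frames)
  if (shift_frames < 0 || shift_frames >= n)
    stop("shift_frames must be in [0, n)")
  if (shift_frames == 0) return(x)
  if (mode == "circular") {
    c(x[(n - shift_frames + 1):n], x[1:(n - shift_frames)])
  } else {
    x[(shift_frames + 1):n]
  }
}

#' Build the linear-shift null model
#'
#' For each gate-passing pair and each surrogate draw, one trace of the pair
#' is circularly shifted by a uniformly drawn offset of more than
#' `dt_min_s` (default 5 min), the maximum lagged correlation is recomputed
#' on the identical lag grid, and all surrogate `r_max` values are pooled.
#' The significance threshold is a percentile (default 95th) of this pooled
#' null distribution.
#'
#' Shift offsets are drawn per pair and per surrogate, uniformly over the
#' integer frames in `(dt_min_s * frame_rate, n_frames)`.
#'
#' @param dff a `dff_trace` (the same one the pairs were computed from).
#' @param pairs a `pair_stats` data.frame from [all_pairs()]; only rows with
#'   `verdict == "pass"` are used.
#' @param n_surrogates surrogate draws per pair (default 20).
#' @param dt_min_s minimum shift in seconds (default 300 = 5 min); the
#'   recording must be longer than this.
#' @param percentile percentile of the pooled null defining the threshold.
#' @param seed integer seed; the null is fully reproducible given it.
#' @param shift_mode passed to [linear_shift()].
#' @return object of class `null_model`: list with `surrogate_r`,
#'   `threshold_r0`, `n_surrogates_per_pair`, `percentile`, `seed`,
#'   `n_pairs`, `n_pooled`, `shift_frames_range`.
#' @export
build_null <- function(dff, pairs, n_surrogates = 20, dt_min_s = 300,
                       percentile = 95, seed = 1,
                       shift_mode = c("circular", "truncate")) {
  stopifnot(inherits(dff, "dff_trace"))
  shift_mode <- match.arg(shift_mode)
  pass <- as.data.frame(pairs)[pairs$verdict == "pass", , drop = FALSE]
  if (nrow(pass) == 0) stop("no gate-passing pairs; cannot build a null model")
  fr <- dff$frame_rate
  n <- nrow(dff$dff)
  if (dff$duration <= dt_min_s)
    stop(sprintf(
      "recording (%.1f s) too short for the linear-shift null (needs > %g s)",
      dff$duration, dt_min_s))
  smin <- as.integer(floor(dt_min_s * fr)) + 1L
  smax <- n - 1L
  if (smin > smax) stop("no admissible shift offsets for this recording")
  max_lag <- attr(pairs, "max_lag_frames") %||%
    as.integer(ceiling(fr * 100 / 4))
  max_lag <- min(max_lag, n - 3L)
  L <- stats::nextn(n + max_lag)

  set.seed(as.integer(seed))
  shifts <- matrix(sample(seq.int(smin, smax), nrow(pass) * n_surrogates,
                          replace = TRUE),
                   nrow = nrow(pass))
  cache_a <- list()
  surrogate_r <- rep(NA_real_, nrow(pass) * n_surrogates)
  k <- 0L
  for (p in seq_len(nrow(pass))) {
    a <- pass$cell_a[p]; b <- pass$cell_b[p]
    ja <- match(a, dff$cell_ids); jb <- match(b, dff$cell_ids)
    if (is.null(cache_a[[a]])) cache_a[[a]] <- .lag_cache(dff$dff[, ja], L)
    ca <- cache_a[[a]]
    y <- dff$dff[, jb]
    for (s in seq_len(n_surrogates)) {
      ys <- linear_shift(y, shifts[p, s], mode = shift_mode)
      if (shift_mode == "truncate") {
        m <- length(ys)
        if (m < max_lag + 3) next
        xs <- dff$dff[1:m, ja]
        Ls <- stats::nextn(m + max_lag)
        lr <- .lagged_r(.lag_cache(xs, Ls), .lag_cache(ys, Ls), Ls, max_lag)
      } else {
        lr <- .lagged_r(ca, .lag_cache(ys, L), L, max_lag)
      }
      k <- k + 1L
      surrogate_r[k] <- .best_lag(lr$lags, lr$r)$r_max
    }
  }
  surrogate_r <- surrogate_r[seq_len(k)]
  surrogate_r <- surrogate_r[!is.na(surrogate_r)]
  if (!length(surrogate_r)) stop("all surrogate correlations undefined")
  structure(
    list(surrogate_r = surrogate_r,
         threshold_r0 = percentile(surrogate_r, percentile),
         n_surrogates_per_pair = n_surrogates,
         percentile = percentile, seed = seed, n_pairs = nrow(pass),
         n_pooled = length(surrogate_r),
         shift_frames_range = c(smin, smax), shift_mode = shift_mode),
    class = "null_model"
  )
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf(
    "<null_model> %d pairs x %d surrogates (%d pooled); r0 = %.4f (%gth pct)\n",
    x$n_pairs, x$n_surrogates_per_pair, x$n_pooled, x$threshold_r0,
    x$percentile))
  invisible(x)
}

#' Significance threshold from a null model
#'
#' The stated percentile of the pooled surrogate connectivity strengths,
#' using the linear-interpolation percentile definition (R type 7) shared
#' across the package.
#'
#' @param null a `null_model`.
#' @param percentile percentile in (0, 100); default 95.
#' @return the threshold r0.
#' @export
significance_threshold <- function(null, percentile = 95) {
  stopifnot(inherits(null, "null_model"))
  if (!length(null$surrogate_r)) stop("empty null distribution")
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)")
  percentile(null$surrogate_r, percentile)
}

#' Write the null-model summary
#'
#' @param null a `null_model`.
#' @param path output JSON path.
#' @param dump_csv optional path for the full surrogate r distribution.
#' @return invisibly, `null`.
#' @export
write_null_json <- function(null, path, dump_csv = NULL) {
  stopifnot(inherits(null, "null_model"))
  jsonlite::write_json(
    list(percentile = null$percentile, threshold_r0 = null$threshold_r0,
         n_pairs = null$n_pairs,
         n_surrogates_per_pair = null$n_surrogates_per_pair,
         seed = null$seed, n_pooled = null$n_pooled),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(dump_csv))
    utils::write.csv(data.frame(surrogate_r = null$surrogate_r), dump_csv,
                     row.names = FALSE)
  invisible(null)
}
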