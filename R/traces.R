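#' Construct a trace matrix
#'
#' Container for raw single-cell fluorescence time series: a frames x cells
#' matrix of intensities (arbitrary units) plus the sampling rate.
#'
#' @param values numeric matrix, frames x cells, no missing values.
#' @param frame_rate sampling rate in Hz.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   the matrix column names.
#' @return an object of class `trace_matrix` with fields `values`,
#'   `frame_rate`, `cell_ids` and `duration` (seconds).
#' @export
trace_matrix <- function(values, frame_rate, cell_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  if (nrow(values) < 2) stop("trace matrix needs at least 2 frames")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0)
    stop("frame_rate must be a single positive number")
  if (anyNA(values) || any(!is.finite(values)))
    stop("trace matrix contains missing or non-finite values")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (length(cell_ids) != ncol(values))
    stop("cell_ids length must match the number of columns")
  colnames(values) <- cell_ids
  structure(
    list(values = values, frame_rate = frame_rate, cell_ids = cell_ids,
         duration = nrow(values) / frame_rate),
    class = "trace_matrix"
  )
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d frames x %d cells @ %g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$frame_rate, x$duration))
  invisible(x)
}

#' Read a trace CSV
#'
#' Expects a header row, a first column `time_s`, and one column per cell.
#' The frame rate is inferred from the median spacing of `time_s`; if
#' `frame_rate` is supplied it is cross-checked and a mismatch above 1%
#' is an error.
#'
#' @param path CSV file path.
#' @param frame_rate optional expected frame rate (Hz) to validate against.
#' @return a [trace_matrix()].
#' @export
read_traces_csv <- function(path, frame_rate = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s")
    stop("trace CSV must have 'time_s' as its first column")
  if (ncol(df) < 2) stop("trace CSV has no cell columns")
  tt <- df[["time_s"]]
  dt <- diff(tt)
  if (any(dt <= 0)) stop("time_s must be strictly increasing")
  fr <- 1 / stats::median(dt)
  if (max(abs(dt - stats::median(dt))) > 0.01 * stats::median(dt))
    stop("time_s spacing is not uniform (>1% deviation)")
  if (!is.null(frame_rate) && abs(fr - frame_rate) / frame_rate > 0.01)
    stop(sprintf("inferred frame rate %.4g Hz differs from configured %.4g Hz by >1%%",
                 fr, frame_rate))
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(vals)) stop("trace CSV contains missing values")
  trace_matrix(vals, frame_rate = fr, cell_ids = names(df)[-1])
}

#' Read an ROI centroid CSV
#'
#' Columns `cell_id`, `x`, `y` with coordinates in micrometres.
#'
#' @param path CSV file path.
#' @return data.frame with character `cell_id` and numeric `x`, `y`.
#' @export
read_rois_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("ROI CSV must have columns cell_id, x, y")
  df$cell_id <- as.character(df$cell_id)
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id in ROI table")
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("ROI coordinates must be finite")
  df[need]
}

# Rolling percentile on a coarse anchor grid (every window/4 frames) with
# linear interpolation between anchors; full-window quantiles at every frame
# would be O(n * window) for no practical gain at baseline-drift timescales.
rolling_percentile <- function(x, q, window) {
  n <- length(x)
  half <- max(1L, floor(window / 2))
  step <- max(1L, floor(window / 4))
  anchors <- unique(c(seq(1L, n, by = step), n))
  vals <- vapply(anchors, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    percentile(x[lo:hi], q * 100)
  }, numeric(1))
  if (length(anchors) == 1) return(rep(vals, n))
  stats::approx(anchors, vals, xout = seq_len(n), rule = 2)$y
}

#' Normalize raw fluorescence to dF/F
#'
#' \eqn{\Delta F/F = (F - F_0)/F_0} per cell, with the basal fluorescence
#' \eqn{F_0} estimated as a low percentile of the trace. The percentile is
#' taken on a running-median smoothed copy (default 1 s window) so frame
#' noise does not bias the baseline low; dF/F itself is computed from the
#' unsmoothed trace. An optional background trace is subtracted before
#' baseline estimation.
#'
#' Cells whose estimated \eqn{F_0} is not strictly positive (e.g. an
#' all-zero trace) are flagged invalid with a warning; their dF/F is set to
#' `NA` and they are excluded from all downstream analysis.
#'
#' @param raw a [trace_matrix()].
#' @param method baseline estimator: `"global"` (single percentile per cell)
#'   or `"rolling"` (windowed percentile for drifting baselines).
#' @param q baseline percentile as a fraction (default 0.2 = 20th percentile).
#' @param window_s rolling window in seconds (only for `method = "rolling"`).
#' @param smooth_s running-median pre-smoothing window in seconds used for
#'   baseline estimation only; 0 disables smoothing.
#' @param background optional numeric vector (one value per frame) subtracted
#'   from every cell before baseline estimation.
#' @return an object of class `dff_trace`: list with `dff` (frames x cells,
#'   `NA` for invalid cells), `f0` (per cell), `valid` (logical per cell),
#'   plus `frame_rate`, `cell_ids`, `duration`.
#' @export
compute_dff <- function(raw, method = c("global", "rolling"), q = 0.2,
                        window_s = 30, smooth_s = 1, background = NULL) {
  stopifnot(inherits(raw, "trace_matrix"))
  method <- match.arg(method)
  stopifnot(q > 0, q < 1)
  vals <- raw$values
  n <- nrow(vals)
  if (!is.null(background)) {
    stopifnot(length(background) == n)
    vals <- vals - background
  }
  fr <- raw$frame_rate
  k <- max(1L, as.integer(round(smooth_s * fr)))
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, if (n %% 2 == 0) n - 1L else n)

  dff <- matrix(NA_real_, n, ncol(vals), dimnames = dimnames(vals))
  f0 <- numeric(ncol(vals))
  valid <- rep(TRUE, ncol(vals))
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    xs <- if (k > 1) stats::runmed(x, k, endrule = "median") else x
    base <- if (method == "global") {
      rep(percentile(xs, q * 100), n)
    } else {
      rolling_percentile(xs, q, window = as.integer(round(window_s * fr)))
    }
    if (any(base <= 0) || all(x == 0)) {
      valid[j] <- FALSE
      f0[j] <- NA_real_
      next
    }
    f0[j] <- base[1]
    dff[, j] <- (x - base) / base
  }
  if (any(!valid))
    warning(sprintf("%d cell(s) flagged invalid (non-positive baseline): %s",
                    sum(!valid), paste(raw$cell_ids[!valid], collapse = ", ")))
  structure(
    list(dff = dff, f0 = f0, valid = valid, frame_rate = fr,
         cell_ids = raw$cell_ids, duration = raw$duration,
         baseline_method = method),
    class = "dff_trace"
  )
}

# Prominence of local maxima: height minus the higher of the two deepest
# valleys separating the peak from the nearest taller sample on each side
# (trace edge counts as a bound when no taller sample exists).
peak_prominence <- function(x, idx) {
  vapply(idx, function(p) {
    h <- x[p]
    left <- if (p > 1) x[seq_len(p - 1)] else numeric(0)
    hi <- which(left > h)
    lmin <- if (length(left) == 0) h else min(left[seq(
      from = if (length(hi)) max(hi) else 1L, to = length(left))])
    right <- if (p < length(x)) x[(p + 1):length(x)] else numeric(0)
    hi2 <- which(right > h)
    rmin <- if (length(right) == 0) h else min(right[seq_len(
      if (length(hi2)) min(hi2) else length(right))])
    h - max(lmin, rmin)
  }, numeric(1))
}

# centered moving average with exact partial windows at the edges
movavg <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  h <- w %/% 2
  cs <- c(0, cumsum(x))
  lo <- pmax(0L, seq_len(n) - h - 1L)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

detect_peaks_one <- function(x, frame_rate, k, min_separation_s, smooth_s) {
  n <- length(x)
  if (n < 3 || anyNA(x)) return(list(idx = integer(0), prom = numeric(0)))
  # noise scale from the unsmoothed first difference; detection runs on a
  # lightly smoothed copy so 40 Hz frame noise cannot masquerade as peaks
  sigma <- stats::mad(diff(x)) / sqrt(2)
  xs <- movavg(x, max(1L, as.integer(round(smooth_s * frame_rate))))
  cand <- which(diff(sign(diff(xs))) == -2) + 1L
  if (!length(cand)) return(list(idx = integer(0), prom = numeric(0)))
  # cheap upper bound on prominence (prefix/suffix minima) prunes the noise
  # candidates before the exact per-peak scan
  pre_min <- cummin(c(Inf, xs[-n]))
  suf_min <- rev(cummin(c(Inf, rev(xs)[-n])))
  bound <- xs[cand] - pmax(pre_min[cand], suf_min[cand])
  cand <- cand[bound >= k * sigma & bound > 0]
  if (!length(cand)) return(list(idx = integer(0), prom = numeric(0)))
  prom <- peak_prominence(xs, cand)
  keep <- prom >= k * sigma & prom > 0
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(list(idx = integer(0), prom = numeric(0)))
  x <- xs
  # enforce refractory separation, keeping the most prominent peak first
  min_sep <- max(1L, as.integer(round(min_separation_s * frame_rate)))
  ord <- order(-prom, -x[cand], cand)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(cand[i] - kept) >= min_sep))
      kept <- c(kept, cand[i])
  }
  o <- order(kept)
  list(idx = kept[o], prom = prom[match(kept[o], cand)])
}

#' Detect calcium peaks and gate active cells
#'
#' Local maxima of dF/F whose prominence exceeds `k` times a robust per-cell
#' noise scale, with a refractory minimum separation. The noise scale is
#' 1.4826 x the median absolute deviation of the first-differenced trace
#' divided by sqrt(2) (the first difference whitens slow transients so the
#' MAD reflects frame noise). A cell is "active" when it has at least
#' `active_min_peaks` peaks.
#'
#' Detection runs on a lightly smoothed copy of the trace (centered moving
#' average, default 0.25 s — shorter than a calcium transient but long
#' enough to suppress single-frame noise excursions); the noise scale is
#' always estimated from the unsmoothed trace, so the `k * sigma` threshold
#' keeps its physical meaning of k times the frame noise.
#'
#' @param dff a `dff_trace` from [compute_dff()].
#' @param k prominence multiplier (default 3).
#' @param min_separation_s minimum inter-peak separation in seconds.
#' @param smooth_s detection smoothing window in seconds (0 disables).
#' @param active_min_peaks activity gate (default 4 peaks).
#' @return an object of class `peak_set`: list with `peak_times` (list of
#'   numeric vectors, seconds), `peak_count`, `is_active`, `prominences`,
#'   plus `frame_rate`, `duration`, `cell_ids`, and the gate used.
#' @export
detect_peaks <- function(dff, k = 3, min_separation_s = 1, smooth_s = 0.25,
                         active_min_peaks = 4) {
  stopifnot(inherits(dff, "dff_trace"), k >= 0, min_separation_s >= 0)
  fr <- dff$frame_rate
  m <- ncol(dff$dff)
  peak_times <- vector("list", m)
  prominences <- vector("list", m)
  names(peak_times) <- names(prominences) <- dff$cell_ids
  for (j in seq_len(m)) {
    x <- dff$dff[, j]
    if (!dff$valid[j] || anyNA(x)) {
      peak_times[[j]] <- numeric(0); prominences[[j]] <- numeric(0)
      next
    }
    pk <- detect_peaks_one(x, fr, k, min_separation_s, smooth_s)
    peak_times[[j]] <- (pk$idx - 1) / fr
    prominences[[j]] <- pk$prom
  }
  cnt <- lengths(peak_times)
  structure(
    list(peak_times = peak_times, peak_count = cnt,
         is_active = cnt >= active_min_peaks, prominences = prominences,
         frame_rate = fr, duration = dff$duration, cell_ids = dff$cell_ids,
         active_min_peaks = active_min_peaks),
    class = "peak_set"
  )
}

#' Build a peak set directly from known event times
#'
#' Useful for classifying simulated ground-truth trains or externally
#' detected events without re-running detection.
#'
#' @param peak_times named list of per-cell peak times (seconds, ascending).
#' @param duration recording duration in seconds.
#' @param frame_rate sampling rate in Hz (metadata only).
#' @param active_min_peaks activity gate (default 4).
#' @return a `peak_set`.
#' @export
peak_set <- function(peak_times, duration, frame_rate = NA_real_,
                     active_min_peaks = 4) {
  stopifnot(is.list(peak_times), duration > 0)
  peak_times <- lapply(peak_times, function(t) sort(as.numeric(t)))
  bad <- vapply(peak_times, function(t) length(t) &&
                  (min(t) < 0 || max(t) > duration), logical(1))
  if (any(bad)) stop("peak times outside [0, duration]")
  cnt <- lengths(peak_times)
  structure(
    list(peak_times = peak_times, peak_count = cnt,
         is_active = cnt >= active_min_peaks,
         prominences = lapply(cnt, function(k) rep(NA_real_, k)),
         frame_rate = frame_rate, duration = duration,
         cell_ids = names(peak_times) %||% as.character(seq_along(peak_times)),
         active_min_peaks = active_min_peaks),
    class = "peak_set"
  )
}

#' Population calcium event rate
#'
#' Peaks per minute per 100 cells: total peak count divided by the duration
#' in minutes and by the population size in units of 100 cells.
#'
#' @param peaks a `peak_set` (or a numeric vector of per-cell peak counts).
#' @param duration_s recording duration in seconds.
#' @param n_cells number of cells in the population.
#' @return event rate in peaks / min / 100 cells.
#' @export
event_rate <- function(peaks, duration_s = NULL, n_cells = NULL) {
  if (inherits(peaks, "peak_set")) {
    duration_s <- duration_s %||% peaks$duration
    n_cells <- n_cells %||% length(peaks$peak_count)
    total <- sum(peaks$peak_count)
  } else {
    total <- sum(peaks)
  }
  if (is.null(duration_s) || duration_s <= 0) stop("duration must be positive")
  if (is.null(n_cells) || n_cells < 1) stop("empty cell population")
  total / (duration_s / 60) / (n_cells / 100)
}

#' Write peak and activity tables
#'
#' @param peaks a `peak_set`.
#' @param peaks_path output CSV for per-peak rows
#'   (`cell_id, peak_time_s, prominence`).
#' @param activity_path output CSV for the per-cell activity summary
#'   (`cell_id, n_peaks, is_active`).
#' @return invisibly, the activity data.frame.
#' @export
write_peaks_csv <- function(peaks, peaks_path, activity_path) {
  stopifnot(inherits(peaks, "peak_set"))
  rows <- do.call(rbind, lapply(seq_along(peaks$peak_times), function(j) {
    t <- peaks$peak_times[[j]]
    if (!length(t)) return(NULL)
    data.frame(cell_id = peaks$cell_ids[j], peak_time_s = t,
               prominence = peaks$prominences[[j]])
  }))
  if (is.null(rows))
    rows <- data.frame(cell_id = character(0), peak_time_s = numeric(0),
                       prominence = numeric(0))
  utils::write.csv(rows, peaks_path, row.names = FALSE)
  act <- data.frame(cell_id = peaks$cell_ids, n_peaks = peaks$peak_count,
                    is_active = peaks$is_active)
  utils::write.csv(act, activity_path, row.names = FALSE)
  invisible(act)
}
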