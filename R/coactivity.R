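# Lagged Pearson correlation between trace pairs.
#
# For each integer frame lag tau in [-max_lag, +max_lag], the correlation is
# computed on the overlapping segments only (no zero padding), each lag
# normalized by its own overlap means and variances: padding would bias r
# toward zero at large lags. The per-lag cross products are obtained for all
# lags at once by FFT; means and variances come from prefix sums, so the
# whole lag grid costs O(n log n) per pair.

.lag_cache <- function(x, L) {
  list(X = stats::fft(c(x, numeric(L - length(x)))),
       c1 = cumsum(x), c2 = cumsum(x^2), n = length(x))
}

.lagged_r <- function(ca, cb, L, max_lag) {
  n <- ca$n
  cc <- Re(stats::fft(Conj(ca$X) * cb$X, inverse = TRUE)) / L
  lags <- seq.int(-max_lag, max_lag)
  sxy <- cc[ifelse(lags >= 0, lags + 1L, L + lags + 1L)]
  m <- n - abs(lags)
  Sx <- Sy <- Sxx <- Syy <- numeric(length(lags))
  pos <- which(lags >= 0)
  k <- lags[pos]
  Sx[pos] <- ca$c1[n - k]
  Sxx[pos] <- ca$c2[n - k]
  head_y <- ifelse(k > 0, cb$c1[pmax(k, 1L)], 0)
  head_y2 <- ifelse(k > 0, cb$c2[pmax(k, 1L)], 0)
  Sy[pos] <- cb$c1[n] - head_y
  Syy[pos] <- cb$c2[n] - head_y2
  neg <- which(lags < 0)
  j <- -lags[neg]
  Sx[neg] <- ca$c1[n] - ca$c1[j]
  Sxx[neg] <- ca$c2[n] - ca$c2[j]
  Sy[neg] <- cb$c1[n - j]
  Syy[neg] <- cb$c2[n - j]

  num <- m * sxy - Sx * Sy
  vx <- m * Sxx - Sx^2
  vy <- m * Syy - Sy^2
  # a segment is treated as zero-variance (r undefined at that lag) when its
  # centered sum of squares is indistinguishable from cancellation noise
  ok <- vx > 1e-8 * m * Sxx & vy > 1e-8 * m * Syy
  r <- rep(NA_real_, length(lags))
  r[ok] <- pmin(1, pmax(-1, num[ok] / sqrt(vx[ok] * vy[ok])))
  list(lags = lags, r = r, n_overlap = m)
}

.best_lag <- function(lags, r) {
  if (all(is.na(r))) return(list(r_max = NA_real_, best_lag = NA_integer_))
  mx <- max(r, na.rm = TRUE)
  cand <- which(!is.na(r) & r == mx)
  # ties broken toward the smallest |tau|, then toward negative tau
  best <- cand[order(abs(lags[cand]), lags[cand])][1]
  list(r_max = mx, best_lag = lags[best])
}

#' Time-lagged Pearson correlation of two traces
#'
#' Correlation strength between two dF/F series across integer frame lags
#' in `[-max_lag_frames, +max_lag_frames]`. A positive best lag means the
#' second series trails the first (events in `y` occur later than in `x`).
#' The maximum across lags is the pair's connectivity strength.
#'
#' Lags at which either overlapping segment has zero variance are undefined
#' (`NA`) and skipped; if every lag is undefined, `r_max` is `NA` and the
#' pair is treated downstream as excluded for inactivity.
#'
#' @param x,y numeric vectors of equal length (dF/F series).
#' @param max_lag_frames maximum lag in frames; must leave at least 3
#'   overlapping samples (`max_lag_frames <= length(x) - 3`).
#' @return list with `lags` (frames), `r` (correlation per lag), `r_max`,
#'   `best_lag_frames`, and `n_overlap` (samples per lag).
#' @export
lagged_correlation <- function(x, y, max_lag_frames) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  max_lag_frames <- as.integer(max_lag_frames)
  if (max_lag_frames < 0 || max_lag_frames > n - 3)
    stop("max_lag_frames must be in [0, n - 3]")
  L <- stats::nextn(n + max_lag_frames)
  out <- .lagged_r(.lag_cache(x, L), .lag_cache(y, L), L, max_lag_frames)
  b <- .best_lag(out$lags, out$r)
  list(lags = out$lags, r = out$r, r_max = b$r_max,
       best_lag_frames = b$best_lag, n_overlap = out$n_overlap)
}

#' Implied signal propagation speed
#'
#' Distance divided by the absolute lag at maximal correlation. A zero lag
#' (synchronous pair) has no defined propagation speed and returns `NA`,
#' which the speed gate treats as outside the admissible window.
#'
#' @param distance_um Euclidean centroid distance in micrometres (>= 0).
#' @param best_lag_s lag at maximal correlation in seconds.
#' @return speed in micrometres per second (`NA` for zero lag). Vectorized.
#' @export
propagation_speed <- function(distance_um, best_lag_s) {
  if (any(distance_um < 0, na.rm = TRUE)) stop("distance must be non-negative")
  ifelse(is.na(best_lag_s) | best_lag_s == 0, NA_real_,
         distance_um / abs(best_lag_s))
}

#' Physiological pair-exclusion filter
#'
#' Applies the exclusion rules for non-physiological cell pairs, in order:
#' \enumerate{
#'   \item distance — intercellular distance above `d_max_um`;
#'   \item speed — implied propagation speed outside
#'     `[v_min_um_s, v_max_um_s]` (closed interval), including the undefined
#'     zero-lag case (a synchronous pair is "faster than measurable" and is
#'     admitted only when the window is unbounded above);
#'   \item inactivity — either cell below `active_min_peaks` peaks.
#' }
#' Pairs whose correlation is undefined at every lag (`r_max` is `NA`) are
#' excluded as inactive regardless of the speed column, since no lag or
#' speed exists for them.
#'
#' @param pairs data.frame with columns `distance_um`, `speed_um_s`,
#'   `best_lag_s`, `r_max`, and (if `peaks` is not given) `n_peaks_a`,
#'   `n_peaks_b`.
#' @param peaks optional `peak_set` used to look up per-cell peak counts via
#'   `cell_a` / `cell_b` columns.
#' @param d_max_um,v_min_um_s,v_max_um_s,active_min_peaks gate parameters.
#' @return `pairs` with `verdict` (`"pass"`/`"excluded"`) and `reason`
#'   (`NA`, `"distance"`, `"speed"`, `"inactivity"`) columns replaced.
#' @export
pair_filter <- function(pairs, peaks = NULL, d_max_um = 100,
                        v_min_um_s = 4, v_max_um_s = 25,
                        active_min_peaks = 4) {
  stopifnot(is.data.frame(pairs))
  if (!is.null(peaks)) {
    cnt <- stats::setNames(peaks$peak_count, peaks$cell_ids)
    pairs$n_peaks_a <- unname(cnt[as.character(pairs$cell_a)])
    pairs$n_peaks_b <- unname(cnt[as.character(pairs$cell_b)])
  }
  n <- nrow(pairs)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (pairs$distance_um[i] > d_max_um) {
      reason[i] <- "distance"
    } else if (!is.null(pairs$r_max) && is.na(pairs$r_max[i])) {
      reason[i] <- "inactivity"
    } else if (if (is.na(pairs$speed_um_s[i])) {
      # zero-lag sentinel: "faster than measurable" — outside any bounded
      # window, admissible only when the window is unbounded above
      is.finite(v_max_um_s)
    } else {
      pairs$speed_um_s[i] < v_min_um_s || pairs$speed_um_s[i] > v_max_um_s
    }) {
      reason[i] <- "speed"
    } else if (pairs$n_peaks_a[i] < active_min_peaks ||
               pairs$n_peaks_b[i] < active_min_peaks) {
      reason[i] <- "inactivity"
    }
  }
  pairs$verdict <- ifelse(is.na(reason), "pass", "excluded")
  pairs$reason <- reason
  pairs
}

#' Pairwise co-activity statistics over all active cell pairs
#'
#' Computes, for every unordered pair of active cells, the Euclidean
#' centroid distance, the maximum time-lagged Pearson correlation
#' (connectivity strength), the lag at the maximum, the implied propagation
#' speed, and the physiological filter verdict. Inactive or invalid cells
#' are never paired.
#'
#' The default lag window is derived from the gates themselves:
#' `max_lag_s = d_max_um / v_min_um_s` (25 s at the defaults), the smallest
#' window guaranteed to contain every admissible propagation delay.
#'
#' @param dff a `dff_trace`.
#' @param rois ROI table (`cell_id`, `x`, `y` in micrometres) covering every
#'   cell in `dff`.
#' @param peaks a `peak_set` on the same cells.
#' @param d_max_um,v_min_um_s,v_max_um_s,active_min_peaks gate parameters.
#' @param max_lag_s lag window override in seconds (default derived).
#' @param skip_distant if `TRUE` (default), pairs already failing the
#'   distance gate are recorded without computing their correlation.
#' @return data.frame of class `pair_stats` with columns `cell_a`, `cell_b`,
#'   `distance_um`, `r_max`, `best_lag_s`, `speed_um_s`, `n_peaks_a`,
#'   `n_peaks_b`, `verdict`, `reason`; attributes carry `frame_rate`,
#'   `n_frames`, `max_lag_frames` and `active_cells`.
#' @export
all_pairs <- function(dff, rois, peaks, d_max_um = 100, v_min_um_s = 4,
                      v_max_um_s = 25, active_min_peaks = 4,
                      max_lag_s = NULL, skip_distant = TRUE) {
  stopifnot(inherits(dff, "dff_trace"), inherits(peaks, "peak_set"))
  missing_roi <- setdiff(dff$cell_ids, rois$cell_id)
  if (length(missing_roi))
    stop("cell id(s) missing from ROI table: ",
         paste(missing_roi, collapse = ", "))
  fr <- dff$frame_rate
  n <- nrow(dff$dff)
  active <- which(peaks$peak_count >= active_min_peaks & dff$valid)
  empty <- data.frame(cell_a = character(0), cell_b = character(0),
                      distance_um = numeric(0), r_max = numeric(0),
                      best_lag_s = numeric(0), speed_um_s = numeric(0),
                      n_peaks_a = integer(0), n_peaks_b = integer(0),
                      verdict = character(0), reason = character(0))
  max_lag <- if (is.null(max_lag_s)) {
    as.integer(ceiling(fr * d_max_um / v_min_um_s))
  } else {
    as.integer(ceiling(fr * max_lag_s))
  }
  max_lag <- min(max_lag, n - 3L)
  if (length(active) < 2) {
    warning("fewer than 2 active cells; no pairs computed")
    res <- empty
  } else {
    ids <- dff$cell_ids[active]
    xy <- rois[match(ids, rois$cell_id), c("x", "y")]
    L <- stats::nextn(n + max_lag)
    caches <- vector("list", length(active))
    get_cache <- function(i) {
      if (is.null(caches[[i]]))
        caches[[i]] <<- .lag_cache(dff$dff[, active[i]], L)
      caches[[i]]
    }
    cmb <- utils::combn(length(active), 2)
    np <- ncol(cmb)
    out <- list(cell_a = character(np), cell_b = character(np),
                distance_um = numeric(np), r_max = rep(NA_real_, np),
                best_lag_s = rep(NA_real_, np),
                speed_um_s = rep(NA_real_, np),
                n_peaks_a = integer(np), n_peaks_b = integer(np))
    for (p in seq_len(np)) {
      i <- cmb[1, p]; j <- cmb[2, p]
      # canonical unordered order: cell_a < cell_b by id
      if (ids[i] > ids[j]) { tmp <- i; i <- j; j <- tmp }
      d <- sqrt((xy$x[i] - xy$x[j])^2 + (xy$y[i] - xy$y[j])^2)
      out$cell_a[p] <- ids[i]; out$cell_b[p] <- ids[j]
      out$distance_um[p] <- d
      out$n_peaks_a[p] <- peaks$peak_count[[match(ids[i], peaks$cell_ids)]]
      out$n_peaks_b[p] <- peaks$peak_count[[match(ids[j], peaks$cell_ids)]]
      if (skip_distant && d > d_max_um) next
      lr <- .lagged_r(get_cache(i), get_cache(j), L, max_lag)
      b <- .best_lag(lr$lags, lr$r)
      out$r_max[p] <- b$r_max
      if (!is.na(b$r_max)) {
        out$best_lag_s[p] <- b$best_lag / fr
        out$speed_um_s[p] <- propagation_speed(d, out$best_lag_s[p])
      }
    }
    res <- as.data.frame(out, stringsAsFactors = FALSE)
    res <- pair_filter(res, d_max_um = d_max_um, v_min_um_s = v_min_um_s,
                       v_max_um_s = v_max_um_s,
                       active_min_peaks = active_min_peaks)
  }
  attr(res, "frame_rate") <- fr
  attr(res, "n_frames") <- n
  attr(res, "max_lag_frames") <- max_lag
  attr(res, "active_cells") <- dff$cell_ids[active]
  class(res) <- c("pair_stats", "data.frame")
  res
}

#' Write the pair statistics table
#'
#' @param pairs a `pair_stats` data.frame.
#' @param path output CSV path.
#' @return invisibly, `pairs`.
#' @export
write_pairs_csv <- function(pairs, path) {
  cols <- c("cell_a", "cell_b", "distance_um", "r_max", "best_lag_s",
            "speed_um_s", "verdict", "reason")
  utils::write.csv(as.data.frame(pairs)[, cols], path, row.names = FALSE)
  invisible(pairs)
}
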