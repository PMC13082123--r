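# Independent oracles and small fixture builders shared across tests.

# Brute-force per-lag Pearson correlation: an O(n * lags) loop over cor()
# on explicitly subset overlap segments. Deliberately naive and independent
# of the package's FFT + prefix-sum implementation.
naive_lagged_r <- function(x, y, max_lag) {
  n <- length(x)
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      xs <- x[1:(n - k)]; ys <- y[(1 + k):n]
    } else {
      xs <- x[(1 - k):n]; ys <- y[1:(n + k)]
    }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)
  }, numeric(1))
  ok <- which(!is.na(r))
  if (!length(ok)) return(list(lags = lags, r = r, r_max = NA, best_lag = NA))
  mx <- max(r[ok])
  cand <- ok[r[ok] == mx]
  best <- cand[order(abs(lags[cand]), lags[cand])][1]
  list(lags = lags, r = r, r_max = mx, best_lag = lags[best])
}

# sort-and-interpolate percentile, written out independently of quantile()
percentile_oracle <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p / 100 + 1
  lo <- floor(h)
  if (lo >= length(xs)) return(xs[length(xs)])
  xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
}

# A dff_trace built directly from a matrix (bypassing baseline estimation),
# for tests that start from known dF/F signals.
make_dff <- function(mat, frame_rate, cell_ids = NULL) {
  mat <- as.matrix(mat)
  ids <- if (!is.null(cell_ids)) cell_ids else colnames(mat)
  if (is.null(ids)) ids <- paste0("c", seq_len(ncol(mat)))
  colnames(mat) <- ids
  structure(
    list(dff = mat, f0 = rep(1, ncol(mat)), valid = rep(TRUE, ncol(mat)),
         frame_rate = frame_rate, cell_ids = ids,
         duration = nrow(mat) / frame_rate, baseline_method = "direct"),
    class = "dff_trace")
}

# minimal passing pair_stats table for null-model tests
make_pass_pairs <- function(cell_a, cell_b, max_lag_frames, n_frames,
                            frame_rate) {
  df <- data.frame(cell_a = cell_a, cell_b = cell_b,
                   distance_um = 50, r_max = 0.5, best_lag_s = 1,
                   speed_um_s = 10, n_peaks_a = 10L, n_peaks_b = 10L,
                   verdict = "pass", reason = NA_character_)
  attr(df, "frame_rate") <- frame_rate
  attr(df, "n_frames") <- n_frames
  attr(df, "max_lag_frames") <- max_lag_frames
  attr(df, "active_cells") <- unique(c(cell_a, cell_b))
  class(df) <- c("pair_stats", "data.frame")
  df
}

# single calcium-like transient (fast rise, slow decay), peak height `amp`
transient_bump <- function(n, at, amp, frame_rate, rise = 0.05, decay = 0.5) {
  t <- (seq_len(n) - 1) / frame_rate - at
  t_star <- log(decay / rise) / (1 / rise - 1 / decay)
  norm <- exp(-t_star / decay) - exp(-t_star / rise)
  out <- numeric(n)
  pos <- t >= 0
  out[pos] <- amp * (exp(-t[pos] / decay) - exp(-t[pos] / rise)) / norm
  out
}

# synthetic screen plate: one readout, given condition values plus controls
toy_plate <- function(values, conditions, controls, readout = "atp_intensity",
                      plate_id = "P1") {
  data.frame(
    plate_id = plate_id,
    well_id = sprintf("W%02d", seq_len(length(values) + length(controls))),
    condition = c(conditions, rep("NEGCTRL", length(controls))),
    readout = readout,
    value = c(values, controls),
    is_negative_control = c(rep(FALSE, length(values)),
                            rep(TRUE, length(controls))))
}
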