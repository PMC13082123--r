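test_that("dF/F normalization matches hand-computed baselines", {
  # constant trace: F equals F0 everywhere, so dF/F is identically zero
  const <- trace_matrix(matrix(50, 100, 1), frame_rate = 10)
  d <- compute_dff(const, smooth_s = 0)
  expect_equal(unname(d$dff[, 1]), rep(0, 100))
  expect_equal(unname(d$f0), 50)

  # 20th percentile of (100, 100, 200, 100) is 100 -> dff = (0, 0, 1, 0)
  tm <- trace_matrix(matrix(c(100, 100, 200, 100), 4, 1), frame_rate = 1)
  d2 <- compute_dff(tm, q = 0.2, smooth_s = 0)
  expect_equal(unname(d2$dff[, 1]), c(0, 0, 1, 0))
})

test_that("dF/F is invariant to multiplicative rescaling of the raw trace", {
  set.seed(11)
  raw <- matrix(100 + 30 * abs(sin(1:400 / 15)) + rnorm(400 * 3, sd = 2),
                400, 3)
  tm <- trace_matrix(raw, frame_rate = 20)
  tm_scaled <- trace_matrix(7.3 * raw, frame_rate = 20)
  for (method in c("global", "rolling")) {
    a <- compute_dff(tm, method = method)
    b <- compute_dff(tm_scaled, method = method)
    expect_equal(a$dff, b$dff, tolerance = 1e-12)
  }
})

test_that("non-positive baselines flag the cell invalid and exclude it", {
  raw <- cbind(ok = 100 + transient_bump(200, 5, 50, 10),
               dead = rep(0, 200))
  tm <- trace_matrix(raw, frame_rate = 10)
  expect_warning(d <- compute_dff(tm), "invalid")
  expect_false(d$valid[2])
  expect_true(d$valid[1])
  expect_true(all(is.na(d$dff[, 2])))
  pk <- detect_peaks(d)
  expect_identical(unname(pk$peak_count[2]), 0L)
  expect_false(pk$is_active[2])
})

test_that("recovered transient amplitudes track the injected kernel", {
  cfg <- sim_config(n_cells = 3, n_sources = 0, n_edges = 0,
                    bg_rate_per_min = 3, duration_s = 300, frame_rate = 20,
                    seed = 21)
  f <- simulate_field(cfg)
  d <- compute_dff(f$traces)
  fr <- cfg$frame_rate
  ratios <- unlist(lapply(seq_along(f$traces$cell_ids), function(j) {
    sapply(f$truth$event_times[[j]], function(te) {
      win <- max(1, round(te * fr) - 5):min(nrow(d$dff), round(te * fr) + 10)
      injected <- max(f$noiseless_dff[win, j])
      if (injected < 0.9 * cfg$kernel_amplitude) return(NA) # overlapping events
      # read the recovered trace at the frame of the true kernel maximum, so
      # the comparison is not inflated by taking a max over noisy frames
      peak_frame <- win[which.max(f$noiseless_dff[win, j])]
      d$dff[peak_frame, j] / injected
    })
  }))
  expect_lt(abs(mean(ratios, na.rm = TRUE) - 1), 0.1)
})

test_that("peak detection applies the prominence and four-peak activity rules", {
  fr <- 20; n <- 2400  # 120 s at 20 Hz
  set.seed(3)
  noise <- rnorm(n, sd = 0.05)
  flat <- make_dff(matrix(0, n, 1), fr)
  pk0 <- detect_peaks(flat)
  expect_identical(unname(pk0$peak_count[1]), 0L)
  expect_false(pk0$is_active[1])

  # four well-separated transients of amplitude 10 x the noise scale
  at4 <- c(20, 50, 80, 110)
  x4 <- Reduce(`+`, lapply(at4, function(a) transient_bump(n, a, 0.5, fr))) + noise
  pk4 <- detect_peaks(make_dff(cbind(x4), fr))
  expect_identical(unname(pk4$peak_count[1]), 4L)
  expect_true(pk4$is_active[1])
  expect_equal(pk4$peak_times[[1]], at4, tolerance = 0.5)

  x3 <- Reduce(`+`, lapply(at4[1:3], function(a) transient_bump(n, a, 0.5, fr))) + noise
  pk3 <- detect_peaks(make_dff(cbind(x3), fr))
  expect_identical(unname(pk3$peak_count[1]), 3L)
  expect_false(pk3$is_active[1])
})

test_that("peak count is non-increasing in the prominence multiplier", {
  fr <- 10; n <- 6000
  set.seed(5)
  at <- sort(runif(12, 5, 590))
  x <- Reduce(`+`, lapply(at, function(a)
    transient_bump(n, a, runif(1, 0.2, 1), fr))) + rnorm(n, sd = 0.05)
  d <- make_dff(cbind(x), fr)
  counts <- sapply(c(0.5, 1, 2, 3, 5, 10), function(k)
    detect_peaks(d, k = k)$peak_count[1])
  expect_true(all(diff(counts) <= 0))
})

test_that("detected counts track injected Poisson event counts at high SNR", {
  cfg <- sim_config(n_cells = 15, n_sources = 0, n_edges = 0,
                    bg_rate_per_min = 3, frame_rate = 20, seed = 31)
  f <- simulate_field(cfg)
  d <- compute_dff(f$traces)
  pk <- detect_peaks(d)
  injected <- sum(lengths(f$truth$event_times))
  detected <- sum(pk$peak_count)
  expect_lt(abs(detected - injected) / injected, 0.10)
})

test_that("activity gating is monotone in peak count", {
  base <- list(a = c(10, 20, 30), b = c(10, 20, 30, 40), c = numeric(0))
  ps <- peak_set(base, duration = 60)
  expect_false(ps$is_active[["a"]])
  expect_true(ps$is_active[["b"]])
  # adding one peak to every cell can only turn cells active, never inactive
  more <- peak_set(lapply(base, function(t) c(t, 55)), duration = 60)
  expect_true(all(more$is_active >= ps$is_active))
})

test_that("event rate is peaks per minute per 100 cells", {
  expect_equal(event_rate(rep(0.5, 100), duration_s = 600, n_cells = 100), 5)
  expect_equal(event_rate(25, duration_s = 300, n_cells = 50), 10)
  expect_equal(event_rate(0, duration_s = 600, n_cells = 80), 0)
  expect_error(event_rate(5, duration_s = 600, n_cells = 0), "empty")

  set.seed(7)
  for (i in 1:20) {
    total <- rpois(1, 50); dur <- runif(1, 60, 1200); nc <- sample(10:500, 1)
    expect_equal(event_rate(total, dur, nc), total / (dur / 60) / (nc / 100))
    expect_equal(event_rate(2 * total, dur, nc), 2 * event_rate(total, dur, nc))
    expect_equal(event_rate(total, 2 * dur, nc), event_rate(total, dur, nc) / 2)
    expect_equal(event_rate(total, dur, 2 * nc), event_rate(total, dur, nc) / 2)
  }
})

test_that("trace CSV round-trips and validates the frame rate", {
  cfg <- sim_config(n_cells = 4, duration_s = 30, frame_rate = 10,
                    n_sources = 2, n_edges = 0, seed = 41)
  f <- simulate_field(cfg)
  dir <- withr::local_tempdir()
  write_dataset(f, dir)
  tr <- read_traces_csv(file.path(dir, "traces.csv"))
  expect_equal(tr$frame_rate, 10, tolerance = 1e-6)
  expect_equal(tr$values, f$traces$values, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(tr$cell_ids, f$traces$cell_ids)
  expect_error(read_traces_csv(file.path(dir, "traces.csv"),
                               frame_rate = 10.5), "differs")
  rois <- read_rois_csv(file.path(dir, "rois.csv"))
  expect_identical(rois$cell_id, f$rois$cell_id)
})
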