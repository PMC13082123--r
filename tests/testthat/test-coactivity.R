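test_that("lagged correlation recovers identity and constructed delays", {
  set.seed(1)
  x <- transient_bump(400, 10, 1, 10) + rnorm(400, sd = 1e-4)
  self <- lagged_correlation(x, x, 50)
  expect_equal(self$r_max, 1, tolerance = 1e-12)
  expect_identical(self$best_lag_frames, 0L)

  y <- c(rep(0, 5), x[1:395])  # x delayed by exactly 5 frames
  del <- lagged_correlation(x, y, 50)
  expect_identical(del$best_lag_frames, 5L)
  expect_gt(del$r_max, 0.99)
})

test_that("per-lag correlations equal the brute-force Pearson oracle", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(200:800, 1)
    max_lag <- sample(10:60, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- lagged_correlation(x, y, max_lag)
    oracle <- naive_lagged_r(x, y, max_lag)
    expect_lt(max(abs(mine$r - oracle$r)), 1e-12)
    expect_equal(mine$r_max, oracle$r_max, tolerance = 1e-12)
    expect_identical(as.integer(mine$best_lag_frames),
                     as.integer(oracle$best_lag))
  }
})

test_that("lag symmetry: r_xy(tau) = r_yx(-tau)", {
  set.seed(9)
  x <- rnorm(500); y <- rnorm(500)
  fwd <- lagged_correlation(x, y, 40)
  rev_ <- lagged_correlation(y, x, 40)
  expect_equal(fwd$r, rev(rev_$r), tolerance = 1e-12)
})

test_that("zero-variance segments give undefined correlations", {
  x <- rep(1, 100)
  y <- rnorm(100)
  out <- lagged_correlation(x, y, 10)
  expect_true(all(is.na(out$r)))
  expect_true(is.na(out$r_max))
  expect_error(lagged_correlation(rnorm(10), rnorm(10), 8), "max_lag")
})

test_that("propagation speed is distance over |lag| with zero-lag sentinel", {
  expect_equal(propagation_speed(50, 5), 10)
  expect_equal(propagation_speed(100, 4), 25)
  expect_equal(propagation_speed(50, -5), 10)  # sign of the lag is irrelevant
  expect_true(is.na(propagation_speed(50, 0)))
  expect_error(propagation_speed(-1, 5), "non-negative")
})

test_that("pair filter applies distance, speed and activity gates in order", {
  row <- function(d, v, lag, r, na_, nb_) {
    data.frame(cell_a = "a", cell_b = "b", distance_um = d, speed_um_s = v,
               best_lag_s = lag, r_max = r, n_peaks_a = na_, n_peaks_b = nb_)
  }
  # distance wins even when speed would also fail
  both <- pair_filter(row(120, 30, 2, 0.5, 10, 10))
  expect_identical(both$reason, "distance")
  sp <- pair_filter(row(50, 30, 2, 0.5, 10, 10))
  expect_identical(sp$reason, "speed")
  # speed precedes the activity check
  sp2 <- pair_filter(row(50, 30, 2, 0.5, 3, 10))
  expect_identical(sp2$reason, "speed")
  inact <- pair_filter(row(50, 10, 5, 0.5, 3, 10))
  expect_identical(inact$reason, "inactivity")
  ok <- pair_filter(row(50, 10, 5, 0.5, 10, 10))
  expect_identical(ok$verdict, "pass")
  # closed speed window: both boundaries are kept
  expect_identical(pair_filter(row(50, 4, 12.5, 0.5, 5, 5))$verdict, "pass")
  expect_identical(pair_filter(row(50, 25, 2, 0.5, 5, 5))$verdict, "pass")
})

test_that("pair filter is idempotent and monotone in the speed window", {
  set.seed(13)
  tab <- data.frame(
    cell_a = "a", cell_b = "b",
    distance_um = runif(60, 0, 150),
    best_lag_s = sample(c(0, runif(10, 0.5, 30)), 60, replace = TRUE),
    r_max = runif(60), n_peaks_a = sample(0:10, 60, TRUE),
    n_peaks_b = sample(0:10, 60, TRUE))
  tab$speed_um_s <- propagation_speed(tab$distance_um, tab$best_lag_s)
  once <- pair_filter(tab)
  twice <- pair_filter(once)
  expect_identical(once$verdict, twice$verdict)
  expect_identical(once$reason, twice$reason)
  wide <- pair_filter(tab, v_min_um_s = 4, v_max_um_s = 25)
  narrow <- pair_filter(tab, v_min_um_s = 6, v_max_um_s = 20)
  expect_true(all(which(narrow$verdict == "pass") %in%
                  which(wide$verdict == "pass")))
})

test_that("all_pairs enumerates active pairs and derives the lag window", {
  fr <- 10; n <- 1200
  set.seed(17)
  mk <- function(events) {
    Reduce(`+`, lapply(events, function(a) transient_bump(n, a, 1, fr))) +
      rnorm(n, sd = 0.02)
  }
  mat <- cbind(a = mk(c(10, 30, 50, 70, 90)),
               b = mk(c(12, 32, 52, 72, 92)),
               c = mk(c(20, 45, 60, 85, 105)),
               d = rnorm(n, sd = 0.02))  # inactive
  dff <- make_dff(mat, fr)
  rois <- data.frame(cell_id = c("a", "b", "c", "d"),
                     x = c(0, 30, 60, 90), y = 0)
  pk <- detect_peaks(dff)
  expect_identical(sum(pk$is_active), 3L)
  pr <- all_pairs(dff, rois, pk)
  expect_identical(nrow(pr), 3L)  # C(3,2)
  expect_equal(attr(pr, "max_lag_frames"),
               min(ceiling(fr * 100 / 4), n - 3))
  expect_true(all(pr$cell_a < pr$cell_b))
  # a-b: 2 s delay over 30 um -> 15 um/s, inside the window
  ab <- pr[pr$cell_a == "a" & pr$cell_b == "b", ]
  expect_equal(ab$best_lag_s, 2, tolerance = 0.2)
  expect_identical(ab$verdict, "pass")

  # fewer than two active cells: empty result with a warning
  dff1 <- make_dff(mat[, c("a", "d")], fr)
  pk1 <- detect_peaks(dff1)
  expect_warning(e <- all_pairs(dff1, rois, pk1), "fewer than 2")
  expect_identical(nrow(e), 0L)

  # skipping distant pairs must not change any verdict
  pr_full <- all_pairs(dff, rois, pk, skip_distant = FALSE)
  expect_identical(pr$verdict, pr_full$verdict)
  expect_identical(pr$reason, pr_full$reason)
})

test_that("all_pairs rejects traces whose cells are missing from the ROI table", {
  dff <- make_dff(matrix(rnorm(200), 100, 2), 10, cell_ids = c("a", "zz"))
  pk <- peak_set(list(a = c(1, 2, 3, 4, 5), zz = c(1, 2, 3, 4, 5)),
                 duration = 10)
  rois <- data.frame(cell_id = "a", x = 0, y = 0)
  expect_error(all_pairs(dff, rois, pk), "zz")
})
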