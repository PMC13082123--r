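test_that("layout respects the field and the minimum separation", {
  cfg2 <- sim_config(n_cells = 2, n_sources = 0, n_edges = 0, seed = 1)
  l2 <- generate_layout(cfg2)
  expect_identical(nrow(l2), 2L)
  expect_gte(sqrt(sum((l2[1, c("x", "y")] - l2[2, c("x", "y")])^2)), 10)

  cfg <- sim_config(n_cells = 50, field_um = 400, seed = 5)
  l <- generate_layout(cfg)
  d <- as.matrix(dist(l[, c("x", "y")]))
  expect_true(all(d[upper.tri(d)] >= cfg$min_separation_um))
  expect_true(all(l$x >= 0 & l$x <= 400 & l$y >= 0 & l$y <= 400))
  expect_identical(generate_layout(cfg), l)  # seeded determinism

  packed <- sim_config(n_cells = 50, field_um = 20, seed = 1)
  expect_error(generate_layout(packed), "could not place")
})

test_that("ground truth wires in-range couplings with consistent delays", {
  cfg <- sim_config(n_cells = 40, field_um = 350, n_sources = 8,
                    n_edges = 8, seed = 11)
  rois <- generate_layout(cfg)
  tr <- generate_truth(rois, cfg)
  ed <- tr$true_edges
  expect_identical(nrow(ed), 8L)
  expect_true(all(ed$distance_um <= cfg$coupling_d_max_um))
  expect_true(all(ed$speed_um_s >= 4 & ed$speed_um_s <= 25))
  expect_equal(ed$delay_s, ed$distance_um / ed$speed_um_s)
  expect_true(all(ed$source %in% tr$source_cells))
  expect_false(any(ed$receiver %in% tr$source_cells))
  # all event times inside the recording
  expect_true(all(unlist(tr$event_times) >= 0))
  expect_true(all(unlist(tr$event_times) <= cfg$duration_s))
  # an example delay: 60 um at 12 um/s is 5 s
  expect_equal(60 / 12, 5)
})

test_that("perfect-fidelity, zero-jitter propagation copies the source train", {
  cfg <- sim_config(n_cells = 20, field_um = 200, n_sources = 3, n_edges = 3,
                    edge_fidelity = 1, source_jitter_frac = 0, seed = 13)
  rois <- generate_layout(cfg)
  tr <- generate_truth(rois, cfg)
  for (e in seq_len(nrow(tr$true_edges))) {
    src <- tr$true_edges$source[e]; rec <- tr$true_edges$receiver[e]
    expected <- tr$event_components[[src]]$source + tr$true_edges$delay_s[e]
    expected <- expected[expected <= cfg$duration_s]
    got <- tr$event_components[[rec]]$propagated
    expect_true(all(expected %in% got))
  }
})

test_that("rendering produces baseline-anchored fluorescence with kernel peaks", {
  cfg0 <- sim_config(n_cells = 3, n_sources = 0, n_edges = 0,
                     bg_rate_per_min = 0, noise_sigma = 0, duration_s = 30,
                     frame_rate = 20, seed = 17)
  f0 <- simulate_field(cfg0)
  expect_true(all(f0$traces$values == cfg0$baseline_f0))

  # single event, zero noise: dF/F recovers the kernel amplitude within 2%
  cfg1 <- sim_config(n_cells = 2, n_sources = 0, n_edges = 0,
                     bg_rate_per_min = 0, noise_sigma = 0, duration_s = 60,
                     frame_rate = 40, kernel_amplitude = 1, seed = 19)
  rois <- generate_layout(cfg1)
  truth <- generate_truth(rois, cfg1)
  truth$event_times[[1]] <- 20.0137  # deliberately off the frame grid
  rend <- render_fluorescence(truth, cfg1)
  d <- compute_dff(rend$traces)
  expect_lt(abs(max(d$dff[, 1]) - 1), 0.02)
})

test_that("the dataset is a pure function of the configuration", {
  cfg <- sim_config(n_cells = 8, duration_s = 20, frame_rate = 20,
                    n_sources = 2, n_edges = 2, field_um = 150, seed = 23)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(simulate_field(cfg), d1)
  write_dataset(simulate_field(cfg), d2)
  for (fn in c("traces.csv", "rois.csv", "truth_edges.csv", "events.csv",
               "manifest.json")) {
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)), label = fn)
  }
  mf <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_identical(mf$seed, 23L)
})

test_that("noiseless lagged correlation recovers injected delays to one frame", {
  cfg <- sim_config(n_cells = 30, field_um = 250, n_sources = 6, n_edges = 6,
                    noise_sigma = 0, duration_s = 300, frame_rate = 20,
                    edge_fidelity = 1, seed = 29)
  f <- simulate_field(cfg, noise = FALSE)
  max_lag <- as.integer(ceiling(cfg$frame_rate * 25))
  for (e in seq_len(nrow(f$truth$true_edges))) {
    ed <- f$truth$true_edges[e, ]
    x <- f$noiseless_dff[, ed$source]
    y <- f$noiseless_dff[, ed$receiver]
    lr <- lagged_correlation(x, y, max_lag)
    expect_lt(abs(lr$best_lag_frames / cfg$frame_rate - ed$delay_s),
              1 / cfg$frame_rate + 1e-9)
  }
})

test_that("couplings faster than the gate are rejected by the pipeline", {
  cfg <- sim_config(n_cells = 25, field_um = 220, n_sources = 5, n_edges = 5,
                    speed_range_um_s = c(30, 40), seed = 31)
  f <- simulate_field(cfg)
  rep <- run_analyze(f$traces, f$rois, seed = 31, truth = f$truth)
  expect_identical(rep$truth_scoring$tp, 0L)
})

test_that("removing the periodic sources silences the coupling graph", {
  cfg <- sim_config(n_cells = 20, field_um = 200, n_sources = 4, n_edges = 4,
                    seed = 37)
  f <- simulate_field(cfg)
  ab <- remove_sources(f$truth)
  expect_identical(nrow(ab$true_edges), 0L)
  expect_identical(ab$source_cells, character(0))
  for (id in names(ab$event_times)) {
    expect_identical(ab$event_times[[id]],
                     f$truth$event_components[[id]]$background)
  }
})
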