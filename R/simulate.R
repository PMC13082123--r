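#' Simulation configuration
#'
#' Parameters of the synthetic calcium recording generator. Defaults mirror
#' the recording conditions the pipeline targets: a 10-min recording at
#' 40 Hz of ~50 cells in a 400 µm square field, a subpopulation of
#' autonomously rhythmic source cells, event propagation along a known
#' coupling graph at physiological speeds, fast-GCaMP transient kinetics,
#' and additive Gaussian frame noise.
#'
#' @param n_cells number of cells (>= 2).
#' @param field_um side of the square field, micrometres.
#' @param frame_rate sampling rate, Hz.
#' @param duration_s recording length, seconds.
#' @param n_sources number of periodic (pacemaker) source cells.
#' @param source_period_s nominal source period, seconds; each source draws
#'   its intrinsic period uniformly within ±20% of this, so unrelated
#'   sources are not artificially phase-locked.
#' @param source_jitter_frac s.d. of inter-event jitter as a fraction of the
#'   period (default 0.05).
#' @param n_edges number of true couplings (source -> follower).
#' @param coupling_d_max_um maximum coupling distance (default 100 µm, the
#'   physiological gate).
#' @param speed_range_um_s propagation speed range for the couplings.
#' @param edge_fidelity probability a source event propagates across an
#'   edge.
#' @param kernel_rise_s,kernel_decay_s,kernel_amplitude transient kernel:
#'   difference of exponentials normalized to peak `kernel_amplitude`
#'   (dF/F units); defaults mimic fast GCaMP6f kinetics.
#' @param noise_sigma additive Gaussian noise s.d. in dF/F units.
#' @param baseline_f0 basal fluorescence level (arbitrary units).
#' @param bg_rate_per_min Poisson background event rate per non-source cell.
#' @param min_separation_um minimum centroid separation in the layout.
#' @param bleach_frac optional linear bleaching: fractional baseline loss
#'   over the whole recording (0 disables).
#' @param seed master integer seed; the entire dataset is a pure function
#'   of this configuration.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 50, field_um = 400, frame_rate = 40,
                       duration_s = 600, n_sources = 10,
                       source_period_s = 30, source_jitter_frac = 0.05,
                       n_edges = 10, coupling_d_max_um = 100,
                       speed_range_um_s = c(4, 25), edge_fidelity = 0.9,
                       kernel_rise_s = 0.05, kernel_decay_s = 0.5,
                       kernel_amplitude = 1, noise_sigma = 0.1,
                       baseline_f0 = 100, bg_rate_per_min = 0.2,
                       min_separation_um = 10, bleach_frac = 0, seed = 1) {
  cfg <- list(n_cells = n_cells, field_um = field_um,
              frame_rate = frame_rate, duration_s = duration_s,
              n_sources = n_sources, source_period_s = source_period_s,
              source_jitter_frac = source_jitter_frac, n_edges = n_edges,
              coupling_d_max_um = coupling_d_max_um,
              speed_range_um_s = speed_range_um_s,
              edge_fidelity = edge_fidelity, kernel_rise_s = kernel_rise_s,
              kernel_decay_s = kernel_decay_s,
              kernel_amplitude = kernel_amplitude,
              noise_sigma = noise_sigma, baseline_f0 = baseline_f0,
              bg_rate_per_min = bg_rate_per_min,
              min_separation_um = min_separation_um,
              bleach_frac = bleach_frac, seed = seed)
  stopifnot(n_cells >= 2, field_um > 0, frame_rate > 0, duration_s > 0,
            n_sources >= 0, n_sources <= n_cells, source_period_s > 0,
            source_jitter_frac >= 0, n_edges >= 0,
            length(speed_range_um_s) == 2,
            speed_range_um_s[1] > 0,
            speed_range_um_s[2] >= speed_range_um_s[1],
            edge_fidelity >= 0, edge_fidelity <= 1,
            kernel_rise_s > 0, kernel_decay_s > kernel_rise_s,
            kernel_amplitude > 0, noise_sigma >= 0, baseline_f0 > 0,
            bg_rate_per_min >= 0, bleach_frac >= 0, bleach_frac < 1)
  structure(cfg, class = "sim_config")
}

#' Random cell layout
#'
#' Uniform centroids in the square field with a minimum pairwise separation
#' (rejection sampling); errors if the packing is infeasible after bounded
#' retries.
#'
#' @param cfg a [sim_config()].
#' @return ROI data.frame (`cell_id`, `x`, `y` in micrometres).
#' @export
generate_layout <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seeds(cfg$seed, c("layout", "truth", "noise"))[["layout"]])
  xs <- ys <- numeric(cfg$n_cells)
  for (i in seq_len(cfg$n_cells)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      px <- stats::runif(1, 0, cfg$field_um)
      py <- stats::runif(1, 0, cfg$field_um)
      if (i == 1 || all(sqrt((xs[seq_len(i - 1)] - px)^2 +
                             (ys[seq_len(i - 1)] - py)^2) >=
                        cfg$min_separation_um)) {
        xs[i] <- px; ys[i] <- py; placed <- TRUE; break
      }
    }
    if (!placed)
      stop(sprintf(
        "could not place %d cells at %g um separation in a %g um field",
        cfg$n_cells, cfg$min_separation_um, cfg$field_um))
  }
  data.frame(cell_id = sprintf("cell_%03d", seq_len(cfg$n_cells)),
             x = xs, y = ys)
}

# one jittered quasi-periodic event train over [0, duration]
.periodic_train <- function(period, jitter_frac, duration) {
  t <- stats::runif(1, 0, period)
  out <- numeric(0)
  while (t <= duration) {
    out <- c(out, t)
    step <- period * (1 + jitter_frac * stats::rnorm(1))
    t <- t + max(step, 0.2 * period)
  }
  out
}

#' Ground-truth architecture: sources, couplings and event trains
#'
#' Selects `n_sources` rhythmic pacemaker cells, wires `n_edges` couplings
#' from sources to non-source followers within the coupling distance
#' (assigned round-robin so pacemakers spread their followers — the
#' hub-and-spoke architecture the analysis is designed to detect), assigns
#' each edge a propagation speed and the implied delay, propagates source
#' events along edges with probability `edge_fidelity`, and gives every
#' non-source cell an independent Poisson background train.
#'
#' @param rois layout from [generate_layout()].
#' @param cfg the [sim_config()].
#' @return object of class `ground_truth`: list with `true_edges`
#'   (data.frame `cell_a, cell_b, source, receiver, distance_um,
#'   speed_um_s, delay_s`), `source_cells`, `source_periods`,
#'   `event_times` (per-cell sorted), `event_components` (per-cell list of
#'   `source`/`propagated`/`background` event times), `duration`.
#' @export
generate_truth <- function(rois, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seeds(cfg$seed, c("layout", "truth", "noise"))[["truth"]])
  ids <- rois$cell_id
  n <- length(ids)
  sources <- if (cfg$n_sources > 0) sort(sample(ids, cfg$n_sources)) else character(0)

  comp <- stats::setNames(
    lapply(ids, function(i) list(source = numeric(0), propagated = numeric(0),
                                 background = numeric(0))), ids)
  periods <- stats::setNames(
    cfg$source_period_s * stats::runif(length(sources), 0.8, 1.2), sources)
  for (s in sources)
    comp[[s]]$source <- .periodic_train(periods[[s]], cfg$source_jitter_frac,
                                        cfg$duration_s)

  # couplings: round-robin over shuffled sources, each picking a random
  # in-range non-source follower not already coupled to that source
  edges <- NULL
  if (cfg$n_edges > 0) {
    if (!length(sources)) stop("n_edges > 0 requires at least one source")
    dmat <- as.matrix(stats::dist(rois[, c("x", "y")]))
    dimnames(dmat) <- list(ids, ids)
    avail <- lapply(sources, function(s) {
      cand <- setdiff(ids[dmat[s, ] <= cfg$coupling_d_max_um], c(s, sources))
      sample(cand, length(cand))
    })
    names(avail) <- sources
    order_s <- rep(sample(sources), length.out = 10 * cfg$n_edges)
    picked <- list()
    for (s in order_s) {
      if (length(picked) >= cfg$n_edges) break
      if (!length(avail[[s]])) next
      r <- avail[[s]][1]
      avail[[s]] <- avail[[s]][-1]
      key <- paste(sort(c(s, r)), collapse = "|")
      if (!is.null(picked[[key]])) next
      picked[[key]] <- c(s, r)
    }
    if (length(picked) < cfg$n_edges)
      stop("not enough in-range source-follower pairs for n_edges couplings")
    sp <- stats::runif(length(picked), cfg$speed_range_um_s[1],
                       cfg$speed_range_um_s[2])
    src <- vapply(picked, `[`, character(1), 1)
    rec <- vapply(picked, `[`, character(1), 2)
    d <- dmat[cbind(src, rec)]
    edges <- data.frame(
      cell_a = pmin(src, rec), cell_b = pmax(src, rec),
      source = src, receiver = rec,
      distance_um = as.numeric(d), speed_um_s = sp,
      delay_s = as.numeric(d) / sp, row.names = NULL)
    for (e in seq_len(nrow(edges))) {
      ev <- comp[[edges$source[e]]]$source
      keep <- stats::runif(length(ev)) < cfg$edge_fidelity
      arr <- ev[keep] + edges$delay_s[e]
      arr <- arr[arr <= cfg$duration_s]
      comp[[edges$receiver[e]]]$propagated <-
        sort(c(comp[[edges$receiver[e]]]$propagated, arr))
    }
  }
  if (is.null(edges))
    edges <- data.frame(cell_a = character(0), cell_b = character(0),
                        source = character(0), receiver = character(0),
                        distance_um = numeric(0), speed_um_s = numeric(0),
                        delay_s = numeric(0))

  for (i in setdiff(ids, sources)) {
    nbg <- stats::rpois(1, cfg$bg_rate_per_min * cfg$duration_s / 60)
    comp[[i]]$background <- sort(stats::runif(nbg, 0, cfg$duration_s))
  }
  event_times <- lapply(comp, function(z)
    sort(c(z$source, z$propagated, z$background)))
  structure(
    list(true_edges = edges, source_cells = sources,
         source_periods = periods, event_times = event_times,
         event_components = comp, duration = cfg$duration_s),
    class = "ground_truth"
  )
}

#' Remove the periodic source cells from a ground truth
#'
#' The computational analogue of ablating the rhythmic pacemaker
#' subpopulation: source trains and all propagated events are deleted, so
#' every cell keeps only its independent background events and the coupling
#' graph carries no signal.
#'
#' @param truth a `ground_truth`.
#' @return a `ground_truth` with empty `true_edges` and background-only
#'   event trains; ablated sources listed in `ablated_sources`.
#' @export
remove_sources <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  comp <- lapply(truth$event_components, function(z)
    list(source = numeric(0), propagated = numeric(0),
         background = z$background))
  truth$ablated_sources <- truth$source_cells
  truth$source_cells <- character(0)
  truth$source_periods <- truth$source_periods[0]
  truth$true_edges <- truth$true_edges[0, , drop = FALSE]
  truth$event_components <- comp
  truth$event_times <- lapply(comp, function(z) z$background)
  truth
}

# difference-of-exponentials transient, normalized to peak `amplitude`
calcium_kernel <- function(dt, rise_s, decay_s, amplitude) {
  t_star <- log(decay_s / rise_s) / (1 / rise_s - 1 / decay_s)
  norm <- exp(-t_star / decay_s) - exp(-t_star / rise_s)
  out <- numeric(length(dt))
  pos <- dt >= 0
  out[pos] <- amplitude * (exp(-dt[pos] / decay_s) - exp(-dt[pos] / rise_s)) / norm
  out
}

#' Render fluorescence traces from a ground truth
#'
#' Per cell, the noiseless dF/F is the sum of transient kernels at the
#' (continuous-time) event times, evaluated on the frame grid; raw
#' fluorescence is `baseline_f0 * (1 + dF/F)` plus Gaussian noise of s.d.
#' `noise_sigma * baseline_f0` (and an optional linear bleach of the
#' baseline).
#'
#' @param truth a `ground_truth`.
#' @param cfg the [sim_config()].
#' @param noise include additive noise (default `TRUE`); `FALSE` renders
#'   the noiseless recording.
#' @return list with `traces` (a [trace_matrix()]) and `noiseless_dff`
#'   (frames x cells matrix).
#' @export
render_fluorescence <- function(truth, cfg, noise = TRUE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  set.seed(derive_seeds(cfg$seed, c("layout", "truth", "noise"))[["noise"]])
  fr <- cfg$frame_rate
  n <- as.integer(round(cfg$duration_s * fr))
  times <- (seq_len(n) - 1) / fr
  ids <- names(truth$event_times)
  tail_s <- 10 * cfg$kernel_decay_s
  dff <- matrix(0, n, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    for (te in truth$event_times[[j]]) {
      i0 <- max(1L, as.integer(floor(te * fr)) + 1L)
      i1 <- min(n, as.integer(ceiling((te + tail_s) * fr)) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      dff[idx, j] <- dff[idx, j] +
        calcium_kernel(times[idx] - te, cfg$kernel_rise_s,
                       cfg$kernel_decay_s, cfg$kernel_amplitude)
    }
  }
  base <- cfg$baseline_f0 *
    (1 - cfg$bleach_frac * (seq_len(n) - 1) / max(1, n - 1))
  raw <- base * (1 + dff)
  if (noise && cfg$noise_sigma > 0)
    raw <- raw + matrix(stats::rnorm(n * length(ids),
                                     sd = cfg$noise_sigma * cfg$baseline_f0),
                        n, length(ids))
  list(traces = trace_matrix(raw, frame_rate = fr, cell_ids = ids),
       noiseless_dff = dff)
}

#' Simulate a complete recording field
#'
#' Layout, ground truth and rendered fluorescence in one call; the entire
#' dataset is a deterministic function of the configuration (including its
#' seed).
#'
#' @param cfg a [sim_config()].
#' @param noise include frame noise (default `TRUE`).
#' @return list of class `sim_field` with `cfg`, `rois`, `truth`, `traces`
#'   and `noiseless_dff`.
#' @export
simulate_field <- function(cfg = sim_config(), noise = TRUE) {
  rois <- generate_layout(cfg)
  truth <- generate_truth(rois, cfg)
  rend <- render_fluorescence(truth, cfg, noise = noise)
  structure(list(cfg = cfg, rois = rois, truth = truth,
                 traces = rend$traces, noiseless_dff = rend$noiseless_dff),
            class = "sim_field")
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `traces.csv` (`time_s` + one column per cell), `rois.csv`,
#' `truth_edges.csv`, `events.csv` (`cell_id, event_time_s`) and
#' `manifest.json` embedding the full configuration and seed.
#'
#' @param field a `sim_field` from [simulate_field()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, the vector of written file paths.
#' @export
write_dataset <- function(field, out_dir) {
  stopifnot(inherits(field, "sim_field"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  tr <- field$traces
  n <- nrow(tr$values)
  df <- data.frame(time_s = (seq_len(n) - 1) / tr$frame_rate,
                   tr$values, check.names = FALSE)
  paths <- file.path(out_dir, c("traces.csv", "rois.csv", "truth_edges.csv",
                                "events.csv", "manifest.json"))
  utils::write.csv(df, paths[1], row.names = FALSE)
  utils::write.csv(field$rois, paths[2], row.names = FALSE)
  utils::write.csv(field$truth$true_edges, paths[3], row.names = FALSE)
  ev <- field$truth$event_times
  evdf <- data.frame(
    cell_id = rep(names(ev), lengths(ev)),
    event_time_s = unlist(ev, use.names = FALSE))
  utils::write.csv(evdf, paths[4], row.names = FALSE)
  jsonlite::write_json(unclass(field$cfg), paths[5], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
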