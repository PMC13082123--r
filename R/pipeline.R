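#' Analysis configuration with physiological defaults
#'
#' Every parameter defaults to the value the method prescribes where one
#' exists: 100 µm distance gate, 4–25 µm/s speed window, 4-peak activity
#' gate, 95th-percentile null threshold, 5-min minimum surrogate shift and
#' top-5% hub rule. The `preset = "synchrony_1s"` variant replaces the
#' velocity gating with a ±1 s near-synchrony lag window (an alternative
#' edge definition used for event-synchrony readings of co-activity); it is
#' exposed as a preset rather than merged with the velocity rule.
#'
#' @param baseline_method,baseline_q,baseline_window_s,smooth_s see
#'   [compute_dff()].
#' @param peak_k,peak_min_separation_s,peak_smooth_s see [detect_peaks()].
#' @param active_min_peaks activity gate (peaks per recording).
#' @param d_max_um,v_min_um_s,v_max_um_s physiological pair gates.
#' @param max_lag_s lag window override (`NULL` = derived from the gates).
#' @param n_surrogates,dt_min_s,percentile,shift_mode null-model parameters.
#' @param hub_top_frac,periodic_min_peaks,periodic_cv_max network
#'   classification parameters.
#' @param preset `"velocity"` (default) or `"synchrony_1s"`.
#' @return a named list of class `analysis_config`.
#' @export
analysis_config <- function(baseline_method = "global", baseline_q = 0.2,
                            baseline_window_s = 30, smooth_s = 1,
                            peak_k = 3, peak_min_separation_s = 1,
                            peak_smooth_s = 0.25,
                            active_min_peaks = 4, d_max_um = 100,
                            v_min_um_s = 4, v_max_um_s = 25,
                            max_lag_s = NULL, n_surrogates = 20,
                            dt_min_s = 300, percentile = 95,
                            shift_mode = "circular", hub_top_frac = 0.05,
                            periodic_min_peaks = 4, periodic_cv_max = 0.3,
                            preset = c("velocity", "synchrony_1s")) {
  preset <- match.arg(preset)
  cfg <- as.list(environment())
  if (preset == "synchrony_1s") {
    # near-synchrony edges: any lag within +/-1 s counts, no speed window
    cfg$max_lag_s <- 1
    cfg$v_min_um_s <- 0
    cfg$v_max_um_s <- Inf
  }
  structure(cfg, class = "analysis_config")
}

gates_of <- function(cfg) {
  cfg[c("d_max_um", "v_min_um_s", "v_max_um_s", "active_min_peaks",
        "percentile")]
}

#' Run the full co-activity analysis pipeline
#'
#' Traces → dF/F → peak detection → pairwise lagged correlation with
#' physiological gating → linear-shift null threshold → network metrics.
#' With an output directory, every intermediate table is written
#' (`activity.csv`, `peaks.csv`, `pairs.csv`, `edges.csv`, `nodes.csv`,
#' `null.json`, `report.json`). Identical inputs, configuration and seed
#' produce identical outputs.
#'
#' @param traces a [trace_matrix()] (or path to a trace CSV).
#' @param rois ROI data.frame (or path to an ROI CSV) covering every cell.
#' @param config an [analysis_config()].
#' @param seed integer seed for the surrogate null.
#' @param out_dir optional output directory for artifact files.
#' @param truth optional `ground_truth`; when supplied, the report gains
#'   edge-recovery precision/recall/F1 against the true coupling graph.
#' @return object of class `run_report`: a list with provenance (seed,
#'   config), per-stage counts, the significance threshold, the network
#'   summary, the population event rate, and (optionally) truth scoring.
#'   The fitted objects are attached in `$objects`.
#' @export
run_analyze <- function(traces, rois, config = analysis_config(), seed = 1,
                        out_dir = NULL, truth = NULL) {
  if (is.character(traces)) traces <- read_traces_csv(traces)
  if (is.character(rois)) rois <- read_rois_csv(rois)
  stopifnot(inherits(traces, "trace_matrix"), inherits(config, "analysis_config"))
  missing_roi <- setdiff(traces$cell_ids, rois$cell_id)
  if (length(missing_roi))
    stop_stage("input", "cell id(s) missing from ROI table: ",
               paste(missing_roi, collapse = ", "))

  dff <- compute_dff(traces, method = config$baseline_method,
                     q = config$baseline_q,
                     window_s = config$baseline_window_s,
                     smooth_s = config$smooth_s)
  peaks <- detect_peaks(dff, k = config$peak_k,
                        min_separation_s = config$peak_min_separation_s,
                        smooth_s = config$peak_smooth_s,
                        active_min_peaks = config$active_min_peaks)
  rate <- event_rate(peaks)
  n_active <- sum(peaks$is_active & dff$valid)

  pairs <- withCallingHandlers(
    all_pairs(dff, rois, peaks, d_max_um = config$d_max_um,
              v_min_um_s = config$v_min_um_s, v_max_um_s = config$v_max_um_s,
              active_min_peaks = config$active_min_peaks,
              max_lag_s = config$max_lag_s),
    warning = function(w) invokeRestart("muffleWarning"))

  null <- NULL
  r0 <- NA_real_
  if (any(pairs$verdict == "pass")) {
    null <- build_null(dff, pairs, n_surrogates = config$n_surrogates,
                       dt_min_s = config$dt_min_s,
                       percentile = config$percentile, seed = seed,
                       shift_mode = config$shift_mode)
    r0 <- null$threshold_r0
  }

  net <- NULL
  net_summary <- list(n_active = n_active, n_edges = 0L,
                      communicating_pct = 0, n_hubs = 0L, n_periodic = 0L,
                      mean_degree = 0, mean_edge_r = 0, mean_edge_speed = 0)
  if (n_active > 0) {
    net <- build_network(pairs, r0, rois, peaks,
                         hub_top_frac = config$hub_top_frac,
                         periodic_min_peaks = config$periodic_min_peaks,
                         periodic_cv_max = config$periodic_cv_max)
    net_summary <- summary(net)
  }

  excl <- table(factor(pairs$reason,
                       levels = c("distance", "speed", "inactivity")))
  report <- list(
    seed = seed,
    config = unclass(config),
    counts = list(
      n_cells = length(traces$cell_ids),
      n_valid = sum(dff$valid),
      n_active = n_active,
      n_pairs = nrow(pairs),
      n_excluded_distance = as.integer(excl[["distance"]]),
      n_excluded_speed = as.integer(excl[["speed"]]),
      n_excluded_inactivity = as.integer(excl[["inactivity"]]),
      n_pass = sum(pairs$verdict == "pass")),
    threshold_r0 = r0,
    event_rate_per_min_per_100 = rate,
    network = net_summary)
  if (!is.null(truth)) {
    pred <- if (is.null(net)) pairs[0, c("cell_a", "cell_b")] else
      net$edges[, c("cell_a", "cell_b")]
    report$truth_scoring <- score_edges(pred, truth$true_edges)
  }
  report <- structure(report, class = "run_report")
  objects <- list(dff = dff, peaks = peaks, pairs = pairs, null = null,
                  network = net)
  report$objects <- objects

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_peaks_csv(peaks, file.path(out_dir, "peaks.csv"),
                    file.path(out_dir, "activity.csv"))
    write_pairs_csv(pairs, file.path(out_dir, "pairs.csv"))
    if (!is.null(null)) write_null_json(null, file.path(out_dir, "null.json"))
    if (!is.null(net))
      write_network_csv(net, file.path(out_dir, "edges.csv"),
                        file.path(out_dir, "nodes.csv"))
    jsonlite::write_json(unclass(report[setdiff(names(report), "objects")]),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run_report> %d cells (%d active); %d pairs (%d pass); r0 = %s; %d edges; %.1f%% communicating\n",
    x$counts$n_cells, x$counts$n_active, x$counts$n_pairs, x$counts$n_pass,
    ifelse(is.na(x$threshold_r0), "NA", sprintf("%.3f", x$threshold_r0)),
    x$network$n_edges, x$network$communicating_pct))
  invisible(x)
}

#' Score a recovered edge set against the true coupling graph
#'
#' @param predicted data.frame with `cell_a`, `cell_b` (unordered pairs).
#' @param true_edges data.frame with `cell_a`, `cell_b`.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`
#'   (`f1 = 2TP / (2TP + FP + FN)`; `NA` when both sets are empty).
#' @export
score_edges <- function(predicted, true_edges) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  pk <- if (nrow(predicted)) key(predicted$cell_a, predicted$cell_b) else character(0)
  tk <- if (nrow(true_edges)) key(true_edges$cell_a, true_edges$cell_b) else character(0)
  tp <- length(intersect(pk, tk))
  fp <- length(setdiff(pk, tk))
  fn <- length(setdiff(tk, pk))
  denom <- 2 * tp + fp + fn
  list(tp = tp, fp = fp, fn = fn,
       precision = if (length(pk)) tp / length(pk) else NA_real_,
       recall = if (length(tk)) tp / length(tk) else NA_real_,
       f1 = if (denom > 0) 2 * tp / denom else NA_real_)
}

#' Contrast two analysis reports
#'
#' Side-by-side differences of the quantities typically compared between
#' conditions (e.g. control vs knockdown): communicating-cell percentage,
#' hub and periodic-cell counts, event rate, edge count and threshold. A
#' warning is recorded (and raised) when the two runs used different gates
#' or thresholds and are therefore not directly comparable.
#'
#' @param report_a,report_b two `run_report` objects.
#' @return data.frame `metric, value_a, value_b, delta` (delta = b - a),
#'   with any compatibility warnings in `attr(, "warnings")`.
#' @export
run_compare <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "run_report"), inherits(report_b, "run_report"))
  warn <- character(0)
  ga <- gates_of(report_a$config); gb <- gates_of(report_b$config)
  if (!isTRUE(all.equal(ga, gb))) {
    warn <- c(warn, "reports were produced with different gate parameters")
  }
  metrics <- c(communicating_pct = "network.communicating_pct",
               n_hubs = "network.n_hubs", n_periodic = "network.n_periodic",
               event_rate_per_min_per_100 = "event_rate_per_min_per_100",
               n_edges = "network.n_edges", threshold_r0 = "threshold_r0")
  pull <- function(rep, path) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    v <- rep
    for (p in parts) v <- v[[p]]
    as.numeric(v)
  }
  va <- vapply(metrics, pull, numeric(1), rep = report_a)
  vb <- vapply(metrics, pull, numeric(1), rep = report_b)
  out <- data.frame(metric = names(metrics), value_a = unname(va),
                    value_b = unname(vb), delta = unname(vb - va))
  if (length(warn)) {
    attr(out, "warnings") <- warn
    warning(paste(warn, collapse = "; "))
  }
  out
}
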