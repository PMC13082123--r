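#' Build the co-activity network
#'
#' Undirected simple graph over all active cells (isolates included). An
#' edge connects a pair iff it passed the physiological gates and its
#' connectivity strength reaches the significance threshold
#' (`r_max >= r0`). Edge weight is `r_max`; topology metrics are computed on
#' the unweighted graph.
#'
#' @param pairs a `pair_stats` data.frame from [all_pairs()].
#' @param r0 significance threshold (from [significance_threshold()]); `NA`
#'   yields a graph with no edges.
#' @param rois ROI table with `cell_id`, `x`, `y`.
#' @param peaks a `peak_set`, used for per-node peak counts and the
#'   periodic-cell classification.
#' @param hub_top_frac fraction of the degree distribution defining hubs
#'   (default 0.05 = top 5%).
#' @param periodic_min_peaks,periodic_cv_max parameters of
#'   [classify_periodic()].
#' @return object of class `coactivity_network`: list with `graph`
#'   (an igraph object), `nodes` (data.frame `cell_id, x, y, degree, is_hub,
#'   is_periodic, n_peaks`), `edges` (data.frame `cell_a, cell_b, r_max,
#'   best_lag_s, speed_um_s`), `threshold_r0`, `communicating_pct`.
#' @export
build_network <- function(pairs, r0, rois, peaks, hub_top_frac = 0.05,
                          periodic_min_peaks = 4, periodic_cv_max = 0.3) {
  stopifnot(is.data.frame(pairs))
  nodes_id <- attr(pairs, "active_cells")
  if (is.null(nodes_id))
    nodes_id <- sort(unique(c(pairs$cell_a, pairs$cell_b)))
  if (!length(nodes_id)) stop("network has zero nodes (no active cells)")
  pr <- as.data.frame(pairs)
  keep <- pr$verdict == "pass" & !is.na(pr$r_max) &
    !is.na(r0) & pr$r_max >= r0
  edges <- pr[keep, c("cell_a", "cell_b", "r_max", "best_lag_s",
                      "speed_um_s"), drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("cell_a", "cell_b")], directed = FALSE,
    vertices = data.frame(name = nodes_id))
  if (nrow(edges)) igraph::E(g)$weight <- edges$r_max
  deg <- igraph::degree(g)
  is_hub <- find_hubs(deg, top_frac = hub_top_frac)
  periodic_all <- classify_periodic(peaks, min_peaks = periodic_min_peaks,
                                    cv_max = periodic_cv_max)
  idx <- match(nodes_id, peaks$cell_ids)
  nodes <- data.frame(
    cell_id = nodes_id,
    x = rois$x[match(nodes_id, rois$cell_id)],
    y = rois$y[match(nodes_id, rois$cell_id)],
    degree = as.integer(deg),
    is_hub = is_hub,
    is_periodic = unname(periodic_all[idx]),
    n_peaks = unname(peaks$peak_count[idx]))
  rownames(nodes) <- NULL
  structure(
    list(graph = g, nodes = nodes, edges = edges, threshold_r0 = r0,
         communicating_pct = 100 * mean(nodes$degree >= 1)),
    class = "coactivity_network"
  )
}

#' @export
print.coactivity_network <- function(x, ...) {
  cat(sprintf(
    "<coactivity_network> %d nodes, %d edges; %.1f%% communicating; %d hub(s), %d periodic\n",
    nrow(x$nodes), nrow(x$edges), x$communicating_pct,
    sum(x$nodes$is_hub), sum(x$nodes$is_periodic)))
  invisible(x)
}

#' Percentage of communicating cells
#'
#' Cells with at least one significant co-activity edge (degree >= 1), as a
#' percentage of all active cells in the network.
#'
#' @param net a `coactivity_network`.
#' @return percentage in [0, 100].
#' @export
communicating_fraction <- function(net) {
  stopifnot(inherits(net, "coactivity_network"))
  if (nrow(net$nodes) == 0) stop("network has zero nodes")
  100 * mean(net$nodes$degree >= 1)
}

#' Flag network hubs
#'
#' Nodes whose degree reaches the `(1 - top_frac)` quantile of the degree
#' sequence (linear-interpolation percentile, ties at the cutoff included).
#' Isolated nodes are never hubs, so a graph with no edges has none.
#'
#' @param degree integer vector of node degrees.
#' @param top_frac top fraction of the degree distribution (default 0.05).
#' @return logical vector of hub flags.
#' @export
find_hubs <- function(degree, top_frac = 0.05) {
  stopifnot(length(degree) >= 1, top_frac > 0, top_frac < 1)
  cutoff <- percentile(degree, 100 * (1 - top_frac))
  degree >= cutoff & degree >= 1
}

#' Classify periodic (rhythmic) cells
#'
#' A cell is periodic when it has at least `min_peaks` calcium peaks and the
#' coefficient of variation of its inter-peak intervals is at most `cv_max`.
#' The CV uses the population (n) standard deviation of the intervals.
#' Cells with fewer than 2 peaks have no defined intervals and are never
#' periodic.
#'
#' @param peaks a `peak_set`.
#' @param min_peaks minimum peak count (default 4).
#' @param cv_max maximum inter-peak-interval CV (default 0.3).
#' @return named logical vector, one flag per cell.
#' @export
classify_periodic <- function(peaks, min_peaks = 4, cv_max = 0.3) {
  stopifnot(inherits(peaks, "peak_set"))
  out <- vapply(seq_along(peaks$peak_times), function(j) {
    t <- peaks$peak_times[[j]]
    if (length(t) < max(2, min_peaks)) return(FALSE)
    iv <- diff(t)
    m <- mean(iv)
    if (m <= 0) return(FALSE)
    cv <- sqrt(mean((iv - m)^2)) / m
    cv <= cv_max
  }, logical(1))
  names(out) <- peaks$cell_ids
  out
}

#' Summary metrics of a co-activity network
#'
#' @param object a `coactivity_network`.
#' @param ... unused.
#' @return list with `n_active`, `n_edges`, `communicating_pct`, `n_hubs`,
#'   `n_periodic`, `mean_degree`, `mean_edge_r`, `mean_edge_speed` (the two
#'   edge means are 0 for an empty edge set).
#' @export
summary.coactivity_network <- function(object, ...) {
  net <- object
  ne <- nrow(net$edges)
  list(
    n_active = nrow(net$nodes),
    n_edges = ne,
    communicating_pct = net$communicating_pct,
    n_hubs = sum(net$nodes$is_hub),
    n_periodic = sum(net$nodes$is_periodic),
    mean_degree = mean(net$nodes$degree),
    mean_edge_r = if (ne) mean(net$edges$r_max) else 0,
    mean_edge_speed = if (ne) mean(net$edges$speed_um_s, na.rm = TRUE) else 0
  )
}

#' Write network tables
#'
#' @param net a `coactivity_network`.
#' @param edges_path edge-list CSV (`cell_a, cell_b, r_max, best_lag_s,
#'   speed_um_s`).
#' @param nodes_path node table CSV (`cell_id, x, y, degree, is_hub,
#'   is_periodic, n_peaks`).
#' @return invisibly, `net`.
#' @export
write_network_csv <- function(net, edges_path, nodes_path) {
  stopifnot(inherits(net, "coactivity_network"))
  utils::write.csv(net$edges, edges_path, row.names = FALSE)
  utils::write.csv(net$nodes, nodes_path, row.names = FALSE)
  invisible(net)
}

#' Diagnostic plot of the spatially embedded network
#'
#' Nodes at their centroid coordinates; periodic cells green, hubs red,
#' edges drawn between significantly co-active pairs.
#'
#' @param x a `coactivity_network`.
#' @param ... passed to `plot.default`.
#' @export
plot.coactivity_network <- function(x, ...) {
  nd <- x$nodes
  plot(nd$x, nd$y, asp = 1, pch = 16,
       col = ifelse(nd$is_hub, "red3",
                    ifelse(nd$is_periodic, "forestgreen", "grey40")),
       xlab = "x (µm)", ylab = "y (µm)", ...)
  if (nrow(x$edges)) {
    ia <- match(x$edges$cell_a, nd$cell_id)
    ib <- match(x$edges$cell_b, nd$cell_id)
    segments(nd$x[ia], nd$y[ia], nd$x[ib], nd$y[ib],
             col = grDevices::adjustcolor("purple3", 0.5))
  }
  invisible(x)
}
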