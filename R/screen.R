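#' Plate Z-scores against negative controls
#'
#' Per plate and readout, `z = (X - mu) / s.d.`, where `mu` is the mean of
#' the negative-control wells and `s.d.` is the sample (n-1) standard
#' deviation of all wells on the plate — the convention used for
#' triple-readout RNAi screens scoring nascent-protein puncta, ATP
#' intensity and tumour-microtube length. The score is invariant under
#' affine rescaling of a plate, and a well equal to the negative-control
#' mean scores exactly 0.
#'
#' `formula = "mad"` substitutes the median of the controls for `mu` and
#' the MAD of the population for `s.d.` (a fully robust variant).
#'
#' @param plate data.frame with columns `plate_id`, `well_id`, `condition`,
#'   `readout`, `value`, `is_negative_control`.
#' @param formula `"paper"` (mean/sd, default) or `"mad"` (median/MAD).
#' @return `plate` with a `z` column added.
#' @export
robust_z <- function(plate, formula = c("paper", "mad")) {
  formula <- match.arg(formula)
  need <- c("plate_id", "well_id", "condition", "readout", "value",
            "is_negative_control")
  if (!all(need %in% names(plate)))
    stop("plate table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(plate$value))) stop("plate values must be finite")
  plate$z <- NA_real_
  for (key in split(seq_len(nrow(plate)),
                    list(plate$plate_id, plate$readout), drop = TRUE)) {
    idx <- key
    neg <- plate$value[idx][plate$is_negative_control[idx]]
    if (length(neg) < 2)
      stop("each plate/readout needs at least 2 negative-control wells")
    mu <- if (formula == "paper") mean(neg) else stats::median(neg)
    s <- if (formula == "paper") stats::sd(plate$value[idx])
         else stats::mad(plate$value[idx])
    if (!is.finite(s) || s == 0)
      stop("degenerate plate: zero population spread for plate ",
           plate$plate_id[idx][1], " readout ", plate$readout[idx][1])
    plate$z[idx] <- (plate$value[idx] - mu) / s
  }
  plate
}

#' Rank screen conditions across readouts
#'
#' Aggregates per-condition Z-scores across the available readouts (default
#' the mean) after applying a sign alignment so that loss-of-function moves
#' every readout in the negative direction, then ranks ascending — the
#' strongest loss-of-function hit first. Ties are broken lexicographically
#' by condition name. Conditions missing a readout are aggregated over the
#' remaining ones and flagged.
#'
#' @param ztab a Z-scored table from [robust_z()] (negative-control wells
#'   are excluded from ranking).
#' @param aggregate `"mean"` (default), `"min"` or `"max"` across readouts.
#' @param sign_map named numeric vector of +1/-1 per readout aligning the
#'   loss-of-function direction; readouts absent from the map keep +1.
#' @return data.frame `condition, score, n_readouts, complete, rank`,
#'   ordered by rank.
#' @export
rank_hits <- function(ztab, aggregate = c("mean", "min", "max"),
                      sign_map = NULL) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("condition", "readout", "z") %in% names(ztab)))
  dat <- ztab[!ztab$is_negative_control, , drop = FALSE]
  if (!is.null(sign_map)) {
    sgn <- sign_map[dat$readout]
    sgn[is.na(sgn)] <- 1
    dat$z <- dat$z * as.numeric(sgn)
  }
  n_readouts_total <- length(unique(ztab$readout))
  agg_fun <- switch(aggregate, mean = mean, min = min, max = max)
  per_cond <- lapply(split(dat, dat$condition), function(d) {
    per_readout <- tapply(d$z, d$readout, mean)
    data.frame(condition = d$condition[1],
               score = agg_fun(per_readout),
               n_readouts = length(per_readout),
               complete = length(per_readout) == n_readouts_total)
  })
  out <- do.call(rbind, per_cond)
  out <- out[order(out$score, out$condition), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify a protrusion as a tumour microtube
#'
#' Morphometric gate: a protrusion is a TM iff its length strictly exceeds
#' 10 µm and its calibre lies in the closed interval [0.5, 2.5] µm.
#'
#' @param length_um protrusion length(s), micrometres (> 0).
#' @param calibre_um protrusion calibre(s), micrometres (> 0).
#' @return logical vector: `TRUE` for TM.
#' @export
classify_protrusion <- function(length_um, calibre_um) {
  if (any(length_um <= 0) || any(calibre_um <= 0))
    stop("length and calibre must be positive")
  length_um > 10 & calibre_um >= 0.5 & calibre_um <= 2.5
}

#' EdU proliferation index
#'
#' Percentage of EdU-labelled cells among all (DAPI-counted) cells.
#'
#' @param edu_pos EdU-positive cell count.
#' @param total_dapi total cell count (> 0).
#' @return percentage in [0, 100].
#' @export
edu_index <- function(edu_pos, total_dapi) {
  if (any(total_dapi <= 0)) stop("total cell count must be positive")
  if (any(edu_pos < 0) || any(edu_pos > total_dapi))
    stop("EdU-positive count must be between 0 and the total count")
  100 * edu_pos / total_dapi
}
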