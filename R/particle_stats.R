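#' Spherical volume from a projected area
#'
#' Microtissues are assumed spherical: a projected area `A` gives radius
#' `sqrt(A / pi)` and predicted volume `(4/3) * pi * radius^3`.
#'
#' @param area Projected area in mm^2 (vectorized, all > 0).
#' @return Volume in mm^3.
#' @examples
#' projected_volume(pi)  # unit radius: 4 pi / 3
#' @export
projected_volume <- function(area) {
  if (length(area) == 0 || any(!is.finite(area)) || any(area <= 0)) {
    stop("area must be positive and finite", call. = FALSE)
  }
  r <- sqrt(area / pi)
  (4 / 3) * pi * r^3
}

#' Particle size distribution of microtissue volumes
#'
#' Volumes are sorted ascending and a cumulative weight is attached to each
#' (volume weighting: cumulative volume fraction; number weighting: count
#' fraction). The distribution cutoffs D10/D50/D90 are read off the
#' cumulative curve with linear interpolation between adjacent sorted points
#' using type-7-style plotting positions `u_i = (C_i - w_i) / (C_n - w_n)`
#' (for equal weights this reduces to `(i - 1)/(n - 1)`, i.e.
#' `stats::quantile(type = 7)`). The span `(D90 - D10) / D50` describes the
#' distribution width.
#'
#' @param volumes Vector of per-microtissue volumes in mm^3 (>= 1 positive
#'   value).
#' @param weighting `"volume"` (cumulative volume; the usual Dv convention)
#'   or `"number"` (cumulative count).
#' @return A list of class `particle_distribution`: sorted `volumes`,
#'   `mean_volume`, `D10`, `D50`, `D90`, `span`, `weighting`, `n`.
#' @export
particle_distribution <- function(volumes, weighting = c("volume", "number")) {
  weighting <- match.arg(weighting)
  if (length(volumes) == 0 || any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("volumes must be a non-empty vector of positive values",
         call. = FALSE)
  }
  v <- sort(volumes)
  d <- weighted_percentiles(v, c(0.10, 0.50, 0.90), weighting)
  out <- list(volumes = v, mean_volume = mean(v),
              D10 = d[1], D50 = d[2], D90 = d[3],
              span = (d[3] - d[1]) / d[2],
              weighting = weighting, n = length(v))
  class(out) <- "particle_distribution"
  out
}

# Percentiles of sorted v at probabilities q under type-7-style plotting
# positions of the cumulative weight curve.
#' @noRd
weighted_percentiles <- function(v, q, weighting) {
  n <- length(v)
  if (n == 1) return(rep(v, length(q)))
  w <- if (weighting == "volume") v else rep(1, n)
  cw <- cumsum(w)
  denom <- cw[n] - w[n]
  if (denom <= 0) return(rep(v[n], length(q)))
  u <- (cw - w) / denom
  vapply(q, function(p) {
    p <- clamp(p, 0, 1)
    approx(u, v, xout = p, ties = "ordered")$y
  }, numeric(1))
}

#' @export
print.particle_distribution <- function(x, ...) {
  cat(sprintf(
    "particle_distribution (%s-weighted, n = %d): mean %.4f mm^3 | D10 %.4f, D50 %.4f, D90 %.4f, span %.4f\n",
    x$weighting, x$n, x$mean_volume, x$D10, x$D50, x$D90, x$span))
  invisible(x)
}

#' Predicted tissue volume per culture well
#'
#' Per-well yield: the theoretical microwell count times the mean volume per
#' microtissue, corrected for the fraction of empty microwells.
#'
#' @param microwells_per_well Theoretical number of microwells in the well.
#' @param mean_volume Mean microtissue volume in mm^3.
#' @param pct_empty Percentage of empty microwells, in `[0, 100]`.
#' @return Predicted tissue volume in mm^3.
#' @examples
#' predicted_tissue_volume(300, 0.0093, 29.23)
#' @export
predicted_tissue_volume <- function(microwells_per_well, mean_volume,
                                    pct_empty) {
  if (any(pct_empty < 0 | pct_empty > 100)) {
    stop("pct_empty must lie in [0, 100]", call. = FALSE)
  }
  microwells_per_well * mean_volume * (100 - pct_empty) / 100
}

#' Summary-table row for one (platform, day) dataset
#'
#' Pools object tables of one platform x timepoint combination, converts
#' projected areas to spherical volumes and produces the standard summary
#' columns: identified microtissues, microwell count, empty/filled
#' percentages, mean volume, D10/D50/D90, span and predicted tissue volume.
#'
#' @param objects A `microtissue_objects` data frame (areas in um^2), or a
#'   concatenation of several.
#' @param pct_empty Percentage of empty microwells for the same dataset.
#' @param layout A `plate_layout` (supplies the theoretical microwell count).
#' @param weighting Percentile weighting, see [particle_distribution()].
#' @return One-row data frame with columns `microtissues_identified`,
#'   `microwells_per_well`, `pct_empty`, `pct_filled`,
#'   `volume_per_microtissue`, `D10`, `D50`, `D90`, `span`,
#'   `predicted_tissue_volume`.
#' @export
particle_summary <- function(objects, pct_empty, layout,
                             weighting = "volume") {
  stopifnot(inherits(layout, "plate_layout"))
  vols <- projected_volume(objects$area_um2 / 1e6)  # um^2 -> mm^2
  pd <- particle_distribution(vols, weighting)
  data.frame(
    microtissues_identified = nrow(objects),
    microwells_per_well = layout$microwells_per_well,
    pct_empty = pct_empty,
    pct_filled = 100 - pct_empty,
    volume_per_microtissue = pd$mean_volume,
    D10 = pd$D10, D50 = pd$D50, D90 = pd$D90, span = pd$span,
    predicted_tissue_volume = predicted_tissue_volume(
      layout$microwells_per_well, pd$mean_volume, pct_empty))
}
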