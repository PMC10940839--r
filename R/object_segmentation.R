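#' Threshold a probability map by Otsu's criterion
#'
#' The global threshold is chosen by Otsu's criterion on a 256-bin histogram
#' of the map; pixels at or above the threshold are foreground.
#'
#' @param map Numeric matrix of per-pixel probabilities in `[0, 1]`.
#' @return 0/1 integer matrix with attribute `threshold`.
#' @export
threshold_map <- function(map) {
  if (!is.matrix(map) || !is.numeric(map)) {
    stop("map must be a numeric matrix", call. = FALSE)
  }
  rng <- range(map)
  if (diff(rng) < 1e-12) {
    stop("degenerate input: map is constant, no threshold exists",
         call. = FALSE)
  }
  th <- EBImage::otsu(as_image(map), range = c(0, 1), levels = 256)
  mask <- matrix(as.integer(map >= th), nrow(map), ncol(map))
  attr(mask, "threshold") <- th
  mask
}

#' Declump touching objects by distance-transform watershed
#'
#' Splits connected foreground into individual objects: the Euclidean
#' distance transform of the mask is smoothed (`sigma_d`) and flooded by a
#' watershed whose maxima detection uses a neighbourhood of radius
#' `d_min / 2`, so seed candidates closer than `d_min` merge. Every
#' foreground pixel carries exactly one label (1..N); ridge assignment
#' follows the deterministic flooding order of the watershed.
#'
#' @param mask 0/1 matrix.
#' @param sigma_d Smoothing scale of the distance transform, in pixels.
#' @param d_min Minimum separation between object seeds, in pixels
#'   (typically half the expected object diameter).
#' @return Integer label matrix (0 = background, labels 1..N).
#' @export
declump <- function(mask, sigma_d = 2, d_min = 10) {
  if (!is_binary_mask(mask)) stop("mask must be binary", call. = FALSE)
  if (sum(mask) == 0) {
    return(matrix(0L, nrow(mask), ncol(mask)))
  }
  dm <- EBImage::distmap(as_image(mask))
  dms <- EBImage::gblur(dm, sigma = sigma_d) * mask
  ws <- EBImage::watershed(dms, tolerance = 1,
                           ext = max(1L, as.integer(round(d_min / 2))))
  labels <- matrix(as.integer(EBImage::imageData(ws)), nrow(mask), ncol(mask))
  labels
}

#' Morphometric filter criteria
#'
#' Bounds for removing small or irregular objects by equivalent diameter,
#' eccentricity, compactness and area. The stage mirrors object
#' identification in high-content pipelines: survivors keep their labels.
#'
#' @param min_diameter,max_diameter Equivalent-diameter bounds in um.
#' @param max_eccentricity Maximum eccentricity in `[0, 1)`.
#' @param max_compactness Maximum compactness (`perimeter^2 / (4 pi area)`,
#'   1 for a disc).
#' @param min_area,max_area Area bounds in um^2; default implied by the
#'   diameter bounds.
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(min_diameter, max_diameter,
                            max_eccentricity = 0.95, max_compactness = 2.0,
                            min_area = NULL, max_area = NULL) {
  min_area <- min_area %||% (pi * (min_diameter / 2)^2)
  max_area <- max_area %||% (pi * (max_diameter / 2)^2)
  ok <- min_diameter > 0 && max_diameter > min_diameter &&
    min_area > 0 && max_area > min_area &&
    max_eccentricity > 0 && max_compactness >= 1
  if (!ok) {
    stop("invalid filter criteria: every min must be positive and below its max",
         call. = FALSE)
  }
  structure(list(min_diameter = min_diameter, max_diameter = max_diameter,
                 max_eccentricity = max_eccentricity,
                 max_compactness = max_compactness,
                 min_area = min_area, max_area = max_area),
            class = "filter_criteria")
}

#' Default filter criteria for a layout
#'
#' Diameter bounds 0.25-1.2 times the layout's expected microtissue
#' diameter, eccentricity at most 0.95, compactness at most 2.
#'
#' @param layout A `plate_layout`.
#' @return A [filter_criteria()] object.
#' @export
default_filter_criteria <- function(layout) {
  filter_criteria(min_diameter = 0.25 * layout$expected_diameter,
                  max_diameter = 1.2 * layout$expected_diameter)
}

#' Measure morphometric features of labelled objects
#'
#' For each label: area (pixel count times `pixel_size^2`), unweighted
#' centroid, equivalent diameter `2 sqrt(area / pi)`, eccentricity from the
#' second central moments, perimeter as the length of the traced outer
#' contour polygon (floored at the equivalent-circle circumference, which
#' only binds for objects a few pixels across), compactness
#' `perimeter^2 / (4 pi area)` and form factor `4 pi area / perimeter^2`.
#'
#' @param labels Integer label matrix from [declump()].
#' @param pixel_size um per pixel.
#' @return Data frame of class `microtissue_objects`: `object_id`, `n_px`,
#'   0-based pixel centroid `x_px`, `y_px`, physical centroid `x_um`,
#'   `y_um`, `area_um2`, `diameter_um`, `perimeter_um`, `eccentricity`,
#'   `compactness`, `form_factor`.
#' @export
measure_objects <- function(labels, pixel_size = 1) {
  stopifnot(is.matrix(labels))
  ids <- sort(unique(labels[labels > 0]))
  empty <- data.frame(object_id = integer(0), n_px = integer(0),
                      x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), diameter_um = numeric(0),
                      perimeter_um = numeric(0), eccentricity = numeric(0),
                      compactness = numeric(0), form_factor = numeric(0))
  if (length(ids) == 0) {
    class(empty) <- c("microtissue_objects", "data.frame")
    return(empty)
  }
  contours <- EBImage::ocontour(as_image(labels))
  res <- lapply(ids, function(id) {
    idx <- which(labels == id, arr.ind = TRUE)
    n_px <- nrow(idx)
    # 0-based pixel coordinates: x = column, y = row
    xs <- idx[, 2] - 1
    ys <- idx[, 1] - 1
    cx <- mean(xs); cy <- mean(ys)
    mu20 <- mean((xs - cx)^2); mu02 <- mean((ys - cy)^2)
    mu11 <- mean((xs - cx) * (ys - cy))
    tr2 <- (mu20 + mu02) / 2
    disc <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
    l1 <- tr2 + disc; l2 <- max(tr2 - disc, 0)
    ecc <- if (l1 <= 0) 0 else sqrt(1 - l2 / l1)
    ring <- contours[[as.character(id)]]
    per_px <- if (is.null(ring) || nrow(ring) < 2) 0 else {
      nxt <- rbind(ring[-1, , drop = FALSE], ring[1, , drop = FALSE])
      sum(sqrt(rowSums((ring - nxt)^2)))
    }
    per_px <- max(per_px, 2 * sqrt(pi * n_px))
    area <- n_px * pixel_size^2
    per <- per_px * pixel_size
    data.frame(object_id = id, n_px = n_px,
               x_px = cx, y_px = cy,
               x_um = cx * pixel_size, y_um = cy * pixel_size,
               area_um2 = area,
               diameter_um = 2 * sqrt(area / pi),
               perimeter_um = per,
               eccentricity = ecc,
               compactness = per^2 / (4 * pi * area),
               form_factor = 4 * pi * area / per^2)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("microtissue_objects", "data.frame")
  out
}

#' Remove objects failing morphometric criteria
#'
#' Objects failing any criterion are erased from the label image; survivors
#' keep their labels, so the operation is idempotent. A per-object report of
#' pass/fail reasons is attached as attribute `"report"`.
#'
#' @param labels Integer label matrix.
#' @param criteria A [filter_criteria()] object.
#' @param pixel_size um per pixel.
#' @return Filtered label matrix with attribute `report`.
#' @export
filter_objects <- function(labels, criteria, pixel_size = 1) {
  stopifnot(inherits(criteria, "filter_criteria"))
  feats <- measure_objects(labels, pixel_size)
  if (nrow(feats) == 0) {
    attr(labels, "report") <- data.frame(object_id = integer(0),
                                         pass = logical(0),
                                         reasons = character(0))
    return(labels)
  }
  reasons <- vapply(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    r <- c(
      if (f$diameter_um < criteria$min_diameter) "diameter_below_min",
      if (f$diameter_um > criteria$max_diameter) "diameter_above_max",
      if (f$area_um2 < criteria$min_area) "area_below_min",
      if (f$area_um2 > criteria$max_area) "area_above_max",
      if (f$eccentricity > criteria$max_eccentricity) "eccentricity_above_max",
      if (f$compactness > criteria$max_compactness) "compactness_above_max")
    paste(r, collapse = ";")
  }, character(1))
  pass <- reasons == ""
  drop_ids <- feats$object_id[!pass]
  out <- labels
  if (length(drop_ids) > 0) out[out %in% drop_ids] <- 0L
  attr(out, "report") <- data.frame(object_id = feats$object_id,
                                    pass = pass, reasons = reasons)
  out
}
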