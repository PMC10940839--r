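#' Fill parameters for synthetic well renders
#'
#' @param empty_fraction Probability that a microwell holds no microtissue.
#' @param mean_diameter Mean microtissue equivalent diameter in um; defaults
#'   to the layout's expected diameter (150 um for A400, 250 um for A800,
#'   consistent with per-microtissue volumes around 0.0015-0.009 mm^3).
#' @param diameter_cv Coefficient of variation of the diameter; draws are
#'   truncated at +/- 2 SD (microwell self-assembly yields a narrow per-well
#'   size spread).
#' @param eccentricity_max Maximum ellipse eccentricity (draws are uniform
#'   on `[0, eccentricity_max]`).
#' @param escaped_count Number of displaced ("escaped") microtissues placed
#'   between microwells, on grid-line intersections.
#' @return A validated list of class `fill_params`.
#' @export
fill_params <- function(empty_fraction = 0.1, mean_diameter = NULL,
                        diameter_cv = 0.10, eccentricity_max = 0.6,
                        escaped_count = 0) {
  if (empty_fraction < 0 || empty_fraction > 1) {
    stop("empty_fraction must be in [0, 1]", call. = FALSE)
  }
  if (diameter_cv < 0 || eccentricity_max < 0 || eccentricity_max >= 1) {
    stop("diameter_cv must be >= 0 and eccentricity_max in [0, 1)",
         call. = FALSE)
  }
  structure(list(empty_fraction = empty_fraction,
                 mean_diameter = mean_diameter,
                 diameter_cv = diameter_cv,
                 eccentricity_max = eccentricity_max,
                 escaped_count = as.integer(escaped_count)),
            class = "fill_params")
}

#' Optical parameters for synthetic well renders
#'
#' Brightfield appearance model: bright background, darker microtissues,
#' darkest microwell boundary grid, on a 0..1 intensity scale.
#'
#' @param background_level,tissue_level,boundary_level Mean intensities.
#' @param noise_sd SD of additive Gaussian pixel noise.
#' @param illumination_gradient Relative amplitude of a linear horizontal
#'   illumination ramp (multiplicative, `1 +/- gradient/2` across the image).
#' @param texture_sd SD of extra intensity texture inside microtissues.
#' @return A validated list of class `optics_params`.
#' @export
optics_params <- function(background_level = 0.82, tissue_level = 0.45,
                          boundary_level = 0.15, noise_sd = 0.02,
                          illumination_gradient = 0.08, texture_sd = 0.05) {
  lv <- c(background_level, tissue_level, boundary_level)
  if (any(lv < 0 | lv > 1)) {
    stop("intensity levels must lie in [0, 1]", call. = FALSE)
  }
  structure(list(background_level = background_level,
                 tissue_level = tissue_level,
                 boundary_level = boundary_level,
                 noise_sd = noise_sd,
                 illumination_gradient = illumination_gradient,
                 texture_sd = texture_sd),
            class = "optics_params")
}

# Pixel centres along x (columns) and y (rows) in um, 0-based convention.
#' @noRd
pixel_axes_um <- function(layout) {
  d <- layout_image_dim(layout)
  list(y = (seq_len(d[1]) - 1) * layout$pixel_size,
       x = (seq_len(d[2]) - 1) * layout$pixel_size)
}

# Binary boundary-grid mask for a layout (1 = grid line).
#' @noRd
boundary_grid_mask <- function(layout) {
  ax <- pixel_axes_um(layout)
  p <- layout$microwell_pitch
  hw <- layout$boundary_width / 2
  vx <- layout$margin + (0:layout$grid_cols) * p
  hy <- layout$margin + (0:layout$grid_rows) * p
  near_v <- vapply(ax$x, function(x) min(abs(x - vx)) < hw, logical(1))
  near_h <- vapply(ax$y, function(y) min(abs(y - hy)) < hw, logical(1))
  in_x <- ax$x >= layout$margin - hw & ax$x <= layout$margin + layout$grid_cols * p + hw
  in_y <- ax$y >= layout$margin - hw & ax$y <= layout$margin + layout$grid_rows * p + hw
  m <- outer(in_y, near_v & in_x) | outer(near_h & in_y, in_x)
  storage.mode(m) <- "integer"
  m
}

# Pixel set (linear indices) of a rotated ellipse; centre and axes in um.
#' @noRd
ellipse_pixels <- function(layout, cx, cy, a, b, theta) {
  ps <- layout$pixel_size
  d <- layout_image_dim(layout)
  rmax <- max(a, b)
  rows <- max(1, floor((cy - rmax) / ps)):min(d[1], ceiling((cy + rmax) / ps) + 1)
  cols <- max(1, floor((cx - rmax) / ps)):min(d[2], ceiling((cx + rmax) / ps) + 1)
  dx <- outer(rep(1, length(rows)), (cols - 1) * ps - cx)
  dy <- outer((rows - 1) * ps - cy, rep(1, length(cols)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0) return(integer(0))
  (cols[idx[, 2]] - 1) * d[1] + rows[idx[, 1]]
}

# Semi-axes (um) of an ellipse with equivalent diameter deq and eccentricity e.
#' @noRd
ellipse_axes <- function(deq, e) {
  r <- deq / 2
  a <- r / (1 - e^2)^0.25
  c(a = a, b = r * (1 - e^2)^0.25)
}

#' Render a synthetic brightfield well image with ground truth
#'
#' Draws the microwell boundary grid, one textured elliptical microtissue per
#' occupied microwell (jittered off-centre) and, optionally, escaped
#' microtissues on grid-line intersections; applies an illumination ramp and
#' additive noise. Identical arguments and seed give bit-identical output.
#'
#' Random draw order (so oracles can replay it): (1) one `runif` per
#' microwell in row-major order, compared against `empty_fraction`, decides
#' emptiness; (2) per occupied microwell, in order: diameter (`rnorm`,
#' truncated at +/- 2 SD), eccentricity, orientation, x-jitter, y-jitter;
#' (3) escaped-object placement; (4) texture and image noise.
#'
#' @param layout A [make_layout()] / [make_tile_layout()] layout.
#' @param fill A [fill_params()] object.
#' @param optics An [optics_params()] object.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return A list of class `ground_truth` with elements `image` (numeric
#'   matrix in `[0, 1]`, rows = y), `tissue_mask`, `boundary_mask` (0/1
#'   integer matrices), `occupancy` (data frame: `well_id`, `row`, `col`,
#'   `status`, `object_id`), `objects` (catalog: `id`, `x_um`, `y_um`,
#'   `x_px`, `y_px`, `diameter_um`, `eccentricity`, `housed`, `well_id`),
#'   plus `layout` and `seed`.
#' @export
render_well_image <- function(layout, fill = fill_params(),
                              optics = optics_params(), seed = 1) {
  stopifnot(inherits(layout, "plate_layout"))
  if (!inherits(fill, "fill_params")) fill <- do.call(fill_params, fill)
  if (!inherits(optics, "optics_params")) optics <- do.call(optics_params, optics)
  mean_d <- fill$mean_diameter %||% layout$expected_diameter
  if (mean_d >= layout$microwell_pitch) {
    stop("mean_diameter must be smaller than the microwell pitch",
         call. = FALSE)
  }
  with_seed(seed, {
    render_well_image_impl(layout, fill, optics, mean_d, seed)
  })
}

#' @noRd
render_well_image_impl <- function(layout, fill, optics, mean_d, seed) {
  d <- layout_image_dim(layout)
  ps <- layout$pixel_size
  centers <- microwell_centers(layout)
  n <- nrow(centers)
  p <- layout$microwell_pitch
  interior_half <- p / 2 - layout$boundary_width / 2

  # draw 1: emptiness, row-major well order
  empty <- runif(n) < fill$empty_fraction

  tissue <- matrix(0L, d[1], d[2])
  catalog <- list()
  occ_obj <- rep(NA_integer_, n)
  obj_id <- 0L
  for (w in seq_len(n)) {
    if (empty[w]) next
    deq <- rnorm(1, mean_d, fill$diameter_cv * mean_d)
    deq <- clamp(deq, mean_d * (1 - 2 * fill$diameter_cv),
                 mean_d * (1 + 2 * fill$diameter_cv))
    ecc <- runif(1, 0, fill$eccentricity_max)
    theta <- runif(1, 0, pi)
    ab <- ellipse_axes(deq, ecc)
    amax <- interior_half - 2 * ps
    if (ab["a"] > amax) ab <- ab * (amax / ab["a"])
    slack <- max(interior_half - ab["a"] - ps, 0)
    jx <- runif(1, -1, 1) * slack
    jy <- runif(1, -1, 1) * slack
    cx <- centers$x_um[w] + jx
    cy <- centers$y_um[w] + jy
    px <- ellipse_pixels(layout, cx, cy, ab["a"], ab["b"], theta)
    if (length(px) == 0) next
    tissue[px] <- 1L
    obj_id <- obj_id + 1L
    occ_obj[w] <- obj_id
    catalog[[obj_id]] <- data.frame(
      id = obj_id,
      x_um = mean((ceiling(px / d[1]) - 1) * ps),
      y_um = mean(((px - 1) %% d[1]) * ps),
      diameter_um = 2 * sqrt(length(px) / pi) * ps,
      eccentricity = ecc, housed = TRUE, well_id = w)
  }

  # escaped objects on interior grid intersections
  if (fill$escaped_count > 0) {
    ix <- layout$margin + seq_len(max(layout$grid_cols - 1, 1)) * p
    iy <- layout$margin + seq_len(max(layout$grid_rows - 1, 1)) * p
    inter <- expand.grid(x = ix, y = iy)
    for (k in seq_len(fill$escaped_count)) {
      shrink <- 1
      for (try in 1:100) {
        if (try > 30) shrink <- 0.7
        i <- sample.int(nrow(inter), 1)
        cx <- inter$x[i] + runif(1, -1, 1) * p / 6
        cy <- inter$y[i] + runif(1, -1, 1) * p / 6
        deq <- clamp(rnorm(1, mean_d, fill$diameter_cv * mean_d),
                     mean_d * (1 - 2 * fill$diameter_cv),
                     mean_d * (1 + 2 * fill$diameter_cv)) * shrink
        ecc <- runif(1, 0, fill$eccentricity_max)
        theta <- runif(1, 0, pi)
        ab <- ellipse_axes(deq, ecc)
        px <- ellipse_pixels(layout, cx, cy, ab["a"], ab["b"], theta)
        if (length(px) > 0 && !any(tissue[px] == 1L)) {
          tissue[px] <- 1L
          obj_id <- obj_id + 1L
          catalog[[obj_id]] <- data.frame(
            id = obj_id,
            x_um = mean((ceiling(px / d[1]) - 1) * ps),
            y_um = mean(((px - 1) %% d[1]) * ps),
            diameter_um = 2 * sqrt(length(px) / pi) * ps,
            eccentricity = ecc, housed = FALSE, well_id = NA_integer_)
          break
        }
      }
    }
  }

  boundary <- boundary_grid_mask(layout)

  img <- matrix(optics$background_level, d[1], d[2])
  img[boundary == 1L] <- optics$boundary_level
  tpx <- which(tissue == 1L)
  img[tpx] <- optics$tissue_level +
    rnorm(length(tpx), 0, optics$texture_sd)
  if (optics$illumination_gradient != 0) {
    ramp <- 1 + optics$illumination_gradient *
      ((seq_len(d[2]) - 1) / max(d[2] - 1, 1) - 0.5)
    img <- sweep(img, 2, ramp, `*`)
  }
  if (optics$noise_sd > 0) {
    img <- img + rnorm(length(img), 0, optics$noise_sd)
  }
  img <- clamp(img, 0, 1)

  objects <- if (obj_id > 0) do.call(rbind, catalog) else
    data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
               diameter_um = numeric(0), eccentricity = numeric(0),
               housed = logical(0), well_id = integer(0))
  objects$x_px <- objects$x_um / ps
  objects$y_px <- objects$y_um / ps

  status <- ifelse(empty, "empty", "single")
  status[!empty & is.na(occ_obj)] <- "empty"  # degenerate: ellipse off-frame
  occupancy <- data.frame(well_id = centers$well_id, row = centers$row,
                          col = centers$col, status = status,
                          object_id = occ_obj)
  structure(list(image = img, tissue_mask = tissue, boundary_mask = boundary,
                 occupancy = occupancy, objects = objects, layout = layout,
                 seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  tab <- table(factor(x$occupancy$status, c("empty", "single", "multi")))
  cat(sprintf(
    "ground_truth '%s': %d microwells (%d empty, %d single, %d multi), %d objects, seed %s\n",
    x$layout$platform_name, nrow(x$occupancy), tab["empty"], tab["single"],
    tab["multi"], nrow(x$objects), format(x$seed)))
  invisible(x)
}

#' Quadrant-style sparse pixel labels from ground truth
#'
#' Emulates interactive sparse annotation: the well array is divided into
#' four quadrants and, for a few microwells per quadrant, pixels inside the
#' microwell block are labelled as foreground (the target structure) or
#' background. All other pixels stay unlabelled.
#'
#' @param truth A `ground_truth` from [render_well_image()].
#' @param target `"tissue"` (microtissue vs background) or `"boundary"`
#'   (microwell grid vs background).
#' @param wells_per_quadrant Number of labelled microwells per quadrant.
#' @param max_px_per_class Per-well cap on labelled pixels per class.
#' @param seed Integer seed for well and pixel subsampling.
#' @return Integer matrix, same shape as the image: 0 = unlabelled,
#'   1 = foreground, 2 = background.
#' @export
sparse_labels_from_truth <- function(truth, target = c("tissue", "boundary"),
                                     wells_per_quadrant = 6,
                                     max_px_per_class = 250, seed = 1) {
  target <- match.arg(target)
  layout <- truth$layout
  centers <- microwell_centers(layout)
  fg_mask <- if (target == "tissue") truth$tissue_mask else truth$boundary_mask
  d <- dim(fg_mask)
  ps <- layout$pixel_size
  p <- layout$microwell_pitch
  bw <- layout$boundary_width

  quad <- 1L + (centers$row > layout$grid_rows / 2) +
    2L * (centers$col > layout$grid_cols / 2)
  labels <- matrix(0L, d[1], d[2])
  with_seed(seed, {
    for (q in 1:4) {
      ids <- centers$well_id[quad == q]
      if (length(ids) == 0) next
      take <- if (length(ids) <= wells_per_quadrant) ids else
        sample(ids, wells_per_quadrant)
      for (w in take) {
        rows <- clamp(round((centers$y_um[w] + c(-1, 1) * (p / 2 + bw)) / ps),
                      1, d[1])
        cols <- clamp(round((centers$x_um[w] + c(-1, 1) * (p / 2 + bw)) / ps),
                      1, d[2])
        block <- matrix(FALSE, d[1], d[2])
        block[rows[1]:rows[2], cols[1]:cols[2]] <- TRUE
        fg <- which(block & fg_mask == 1L)
        bg <- which(block & fg_mask == 0L)
        if (length(fg) > max_px_per_class) fg <- sample(fg, max_px_per_class)
        if (length(bg) > max_px_per_class) bg <- sample(bg, max_px_per_class)
        labels[fg] <- 1L
        labels[bg] <- 2L
      }
    }
  })
  labels
}

#' Displacement model for media-change-driven microtissue escape
#'
#' At every media change, each still-housed microtissue escapes its microwell
#' with probability
#' `p = clamp(base_escape_prob * (1 + aspiration_coeff * aspiration) *
#' (1 + dispension_coeff * dispension), 0, 1)`. Escape is irreversible.
#' The functional form is a phenomenological stand-in for the observed
#' cumulative displacement over repeated media changes; its coefficients are
#' free parameters, not calibrated values.
#'
#' @param base_escape_prob Escape probability per media change at zero speeds.
#' @param aspiration_coeff,dispension_coeff Dimensionless multipliers per
#'   unit speed (uL/s).
#' @param media_change_days Days on which half-medium changes occur
#'   (default days 3, 7, 10, 14 and 17 of the differentiation protocol).
#' @return A list of class `displacement_model`.
#' @export
displacement_model <- function(base_escape_prob = 0.02,
                               aspiration_coeff = 0,
                               dispension_coeff = 0,
                               media_change_days = c(3, 7, 10, 14, 17)) {
  if (base_escape_prob < 0 || base_escape_prob > 1) {
    stop("base_escape_prob must be in [0, 1]", call. = FALSE)
  }
  structure(list(base_escape_prob = base_escape_prob,
                 aspiration_coeff = aspiration_coeff,
                 dispension_coeff = dispension_coeff,
                 media_change_days = media_change_days),
            class = "displacement_model")
}

#' @noRd
escape_probability <- function(model, aspiration, dispension) {
  clamp(model$base_escape_prob *
          (1 + model$aspiration_coeff * aspiration) *
          (1 + model$dispension_coeff * dispension), 0, 1)
}

#' Simulate a longitudinal occupancy series under media changes
#'
#' Starting from an initial occupancy, applies the [displacement_model()]
#' escape rule at every media change preceding each requested timepoint.
#' Escaped objects are moved to between-well positions (grid intersections);
#' the per-well empty count is non-decreasing over time.
#'
#' Random draw order: (1) one `runif` per microwell (initial emptiness);
#' (2) per media change day, in ascending order, one `runif` per microwell
#' (escape test; draws for already-empty wells are made and discarded so the
#' stream is replayable); (3) escape placement jitter.
#'
#' @param layout A `plate_layout`.
#' @param model A [displacement_model()].
#' @param aspiration,dispension Liquid-handling speeds in uL/s (>= 0).
#' @param timepoints Ascending vector of observation days.
#' @param seed Integer seed.
#' @param initial_empty_fraction Emptiness probability at day 0.
#' @param fill,optics Rendering parameters, used when `render = TRUE`.
#' @param render If `TRUE`, each timepoint also carries a rendered image and
#'   masks (object sizes are drawn once and kept across days).
#' @return A list with one element per timepoint: `list(day, truth)` where
#'   `truth` is a `ground_truth` (masks/image `NULL` unless `render = TRUE`).
#' @export
simulate_series <- function(layout, model = displacement_model(),
                            aspiration = 100, dispension = 100,
                            timepoints = c(7, 14, 21), seed = 1,
                            initial_empty_fraction = 0.05,
                            fill = fill_params(), optics = optics_params(),
                            render = FALSE) {
  stopifnot(inherits(layout, "plate_layout"),
            inherits(model, "displacement_model"))
  if (aspiration < 0 || dispension < 0) {
    stop("speeds must be >= 0", call. = FALSE)
  }
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must be sorted in strictly ascending order",
         call. = FALSE)
  }
  p_esc <- escape_probability(model, aspiration, dispension)
  centers <- microwell_centers(layout)
  n <- nrow(centers)
  pitch <- layout$microwell_pitch

  with_seed(seed, {
    empty <- runif(n) < initial_empty_fraction
    housed <- !empty
    escaped_pos <- data.frame(well_id = integer(0), x_um = numeric(0),
                              y_um = numeric(0))
    ix <- layout$margin + seq_len(max(layout$grid_cols - 1, 1)) * pitch
    iy <- layout$margin + seq_len(max(layout$grid_rows - 1, 1)) * pitch

    out <- vector("list", length(timepoints))
    prev <- 0
    for (ti in seq_along(timepoints)) {
      day <- timepoints[ti]
      changes <- model$media_change_days[model$media_change_days > prev &
                                           model$media_change_days <= day]
      for (ch in changes) {
        esc <- runif(n) < p_esc
        newly <- which(housed & esc)
        if (length(newly) > 0) {
          housed[newly] <- FALSE
          escaped_pos <- rbind(escaped_pos, data.frame(
            well_id = newly,
            x_um = sample(ix, length(newly), replace = TRUE) +
              runif(length(newly), -1, 1) * pitch / 6,
            y_um = sample(iy, length(newly), replace = TRUE) +
              runif(length(newly), -1, 1) * pitch / 6))
        }
      }
      prev <- day
      status <- ifelse(housed, "single", "empty")
      occupancy <- data.frame(well_id = centers$well_id, row = centers$row,
                              col = centers$col, status = status,
                              object_id = ifelse(housed, centers$well_id,
                                                 NA_integer_))
      nh <- sum(housed)
      ne <- nrow(escaped_pos)
      objects <- rbind(
        data.frame(id = centers$well_id[housed],
                   x_um = centers$x_um[housed], y_um = centers$y_um[housed],
                   diameter_um = rep(NA_real_, nh),
                   eccentricity = rep(NA_real_, nh),
                   housed = rep(TRUE, nh),
                   well_id = centers$well_id[housed]),
        data.frame(id = n + seq_len(ne),
                   x_um = escaped_pos$x_um, y_um = escaped_pos$y_um,
                   diameter_um = rep(NA_real_, ne),
                   eccentricity = rep(NA_real_, ne),
                   housed = rep(FALSE, ne),
                   well_id = rep(NA_integer_, ne)))
      objects$x_px <- objects$x_um / layout$pixel_size
      objects$y_px <- objects$y_um / layout$pixel_size
      truth <- structure(
        list(image = NULL, tissue_mask = NULL, boundary_mask = NULL,
             occupancy = occupancy, objects = objects, layout = layout,
             seed = seed),
        class = "ground_truth")
      out[[ti]] <- list(day = day, truth = truth)
    }
    if (render) {
      out <- render_series(out, layout, fill, optics)
    }
    out
  })
}

# Rasterize the object catalogs of an occupancy series (shared sizes drawn
# from the fill distribution at the current RNG position).
#' @noRd
render_series <- function(series, layout, fill, optics) {
  mean_d <- fill$mean_diameter %||% layout$expected_diameter
  all_ids <- sort(unique(unlist(lapply(series, function(s) s$truth$objects$id))))
  sizes <- clamp(rnorm(length(all_ids), mean_d, fill$diameter_cv * mean_d),
                 mean_d * (1 - 2 * fill$diameter_cv),
                 mean_d * (1 + 2 * fill$diameter_cv))
  names(sizes) <- all_ids
  boundary <- boundary_grid_mask(layout)
  d <- layout_image_dim(layout)
  for (ti in seq_along(series)) {
    obj <- series[[ti]]$truth$objects
    tissue <- matrix(0L, d[1], d[2])
    for (k in seq_len(nrow(obj))) {
      r <- sizes[as.character(obj$id[k])] / 2
      px <- ellipse_pixels(layout, obj$x_um[k], obj$y_um[k], r, r, 0)
      tissue[px] <- 1L
      obj$diameter_um[k] <- 2 * sqrt(length(px) / pi) * layout$pixel_size
      obj$eccentricity[k] <- 0
    }
    img <- matrix(optics$background_level, d[1], d[2])
    img[boundary == 1L] <- optics$boundary_level
    tpx <- which(tissue == 1L)
    img[tpx] <- optics$tissue_level + rnorm(length(tpx), 0, optics$texture_sd)
    img <- clamp(img + rnorm(length(img), 0, optics$noise_sd), 0, 1)
    series[[ti]]$truth$objects <- obj
    series[[ti]]$truth$tissue_mask <- tissue
    series[[ti]]$truth$boundary_mask <- boundary
    series[[ti]]$truth$image <- img
  }
  series
}
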