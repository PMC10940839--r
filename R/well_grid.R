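#' Point-in-polygon test (ray casting, boundary inclusive)
#'
#' Points exactly on a polygon edge or vertex count as inside ("within the
#' boundary points" is read inclusively).
#'
#' @param x,y Point coordinates (vectors of equal length).
#' @param poly Two-column matrix of polygon vertices `(x, y)`; the ring is
#'   closed implicitly.
#' @param eps Tolerance for the on-boundary test.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, poly, eps = 1e-9) {
  stopifnot(is.matrix(poly), ncol(poly) == 2)
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  jj <- c(n, seq_len(n - 1))
  vapply(seq_along(x), function(i) {
    xi <- x[i]; yi <- y[i]
    # on-boundary: distance from point to any segment within eps
    dx <- px[jj] - px; dy <- py[jj] - py
    len2 <- dx^2 + dy^2
    t <- ifelse(len2 > 0, ((xi - px) * dx + (yi - py) * dy) / len2, 0)
    t <- clamp(t, 0, 1)
    d2 <- (px + t * dx - xi)^2 + (py + t * dy - yi)^2
    if (any(d2 <= eps^2)) return(TRUE)
    # ray casting towards +x
    crosses <- ((py > yi) != (py[jj] > yi)) &
      (xi < px + (yi - py) * (px[jj] - px) / (py[jj] - py))
    sum(crosses) %% 2L == 1L
  }, logical(1))
}

#' Extract microwell polygons from a boundary probability map
#'
#' Thresholds the boundary map (Otsu), closes small gaps in the grid lines
#' (morphological closing with a disc of the boundary width), labels the
#' interior connected components, keeps components of plausible microwell
#' area (`[0.4, 1.3] x pitch^2`) whose bounding box fits a grid cell, and
#' snaps the survivors onto the ideal square lattice fitted to their
#' centroids by least squares. Lattice snapping makes the microwell count
#' robust to locally broken boundary pixels; it can be disabled.
#'
#' @param boundary_map Boundary-class probability map (numeric matrix), or a
#'   binary boundary mask.
#' @param layout A `plate_layout` (supplies pitch, pixel size and boundary
#'   width).
#' @param snap If `FALSE`, components are returned without lattice snapping.
#' @param impute_missing If `TRUE` (default), lattice sites inside the
#'   detected index range that lost their component (typically two
#'   interiors merged across a locally missed boundary segment) are
#'   restored with the ideal interior square of the fitted lattice.
#' @return A list of class `microwell_cells`: `cells` (data frame:
#'   `microwell_id`, `row`, `col`, centre `x_px`, `y_px`, `area_px`,
#'   `imputed`) and `polygons` (list of closed `(x, y)` pixel-coordinate
#'   rings, one per cell), plus the `layout`.
#' @export
extract_microwells <- function(boundary_map, layout, snap = TRUE,
                               impute_missing = TRUE) {
  stopifnot(inherits(layout, "plate_layout"))
  mask <- if (is_binary_mask(boundary_map)) boundary_map else
    threshold_map(boundary_map)
  ps <- layout$pixel_size
  pitch_px <- layout$microwell_pitch / ps
  bw_px <- max(1L, as.integer(round(layout$boundary_width / ps)))
  brush <- EBImage::makeBrush(2L * bw_px + 1L, shape = "disc")
  closed <- EBImage::closing(as_image(mask), brush)
  interior <- 1 - EBImage::imageData(closed)
  lab <- EBImage::bwlabel(as_image(interior))
  labm <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))

  nlab <- max(labm)
  if (nlab == 0) stop("microwell detection failed: no interior components",
                      call. = FALSE)
  idx <- which(labm > 0, arr.ind = TRUE)
  id <- labm[labm > 0]
  area <- tabulate(id, nlab)
  cx <- rowsum(as.numeric(idx[, 2] - 1), id)[, 1] / area[sort(unique(id))]
  cy <- rowsum(as.numeric(idx[, 1] - 1), id)[, 1] / area[sort(unique(id))]
  bbw <- tapply(idx[, 2], id, function(v) diff(range(v)) + 1)
  bbh <- tapply(idx[, 1], id, function(v) diff(range(v)) + 1)

  keep <- which(area >= 0.4 * pitch_px^2 & area <= 1.3 * pitch_px^2 &
                  bbw <= 1.35 * pitch_px & bbh <= 1.35 * pitch_px)
  if (length(keep) < 4) {
    stop("microwell detection failed: fewer than 4 candidate microwells",
         call. = FALSE)
  }
  cx <- cx[keep]; cy <- cy[keep]; area_k <- area[keep]

  if (snap) {
    fit_axis <- function(v) {
      k <- round((v - min(v)) / pitch_px)
      co <- coef(lm(v ~ k))
      idx <- as.integer(round((v - co[1]) / co[2]))
      # origin of the 1-based index frame: centre of index 1
      list(step = co[2], origin1 = unname(co[1] + co[2] * min(idx)),
           idx1 = idx - min(idx) + 1L)
    }
    fx <- fit_axis(cx); fy <- fit_axis(cy)
    col_i <- fx$idx1
    row_i <- fy$idx1
    # one component per lattice site: keep the largest on collision
    site <- paste(row_i, col_i)
    ord <- order(-area_k)
    first <- ord[!duplicated(site[ord])]
    sel <- sort(first)
  } else {
    sel <- order(cy, cx)
    row_i <- rep(NA_integer_, length(sel)); col_i <- row_i
  }

  contours <- EBImage::ocontour(as_image(labm))
  polygons <- lapply(seq_along(sel), function(m) {
    k <- sel[m]
    ring <- contours[[as.character(keep[k])]]
    cbind(x = ring[, 2], y = ring[, 1])  # ocontour returns (row, col), 0-based
  })
  cells <- data.frame(
    microwell_id = seq_along(sel),
    row = if (snap) row_i[sel] else seq_along(sel),
    col = if (snap) col_i[sel] else rep(1L, length(sel)),
    x_px = cx[sel], y_px = cy[sel], area_px = area_k[sel],
    imputed = FALSE)

  # Lattice sites inside the detected index range with no surviving
  # component (e.g. a locally missed boundary segment merged two interiors):
  # impute their polygon from the fitted lattice as the ideal interior
  # square, provided it lies fully inside the image.
  if (snap && impute_missing) {
    have <- paste(cells$row, cells$col)
    half <- (pitch_px - bw_px) / 2 - 1
    d <- dim(mask)
    for (r in seq(min(cells$row), max(cells$row))) {
      for (cc in seq(min(cells$col), max(cells$col))) {
        if (paste(r, cc) %in% have) next
        x0 <- fx$origin1 + fx$step * (cc - 1)
        y0 <- fy$origin1 + fy$step * (r - 1)
        if (x0 - half < 0 || x0 + half > d[2] - 1 ||
            y0 - half < 0 || y0 + half > d[1] - 1) next
        polygons[[length(polygons) + 1L]] <- cbind(
          x = c(x0 - half, x0 + half, x0 + half, x0 - half),
          y = c(y0 - half, y0 - half, y0 + half, y0 + half))
        cells <- rbind(cells, data.frame(
          microwell_id = nrow(cells) + 1L, row = r, col = cc,
          x_px = x0, y_px = y0, area_px = (2 * half)^2, imputed = TRUE))
      }
    }
    ord <- order(cells$row, cells$col)
    polygons <- polygons[ord]
    cells <- cells[ord, , drop = FALSE]
    cells$microwell_id <- seq_len(nrow(cells))
    rownames(cells) <- NULL
  }
  structure(list(cells = cells, polygons = polygons, layout = layout),
            class = "microwell_cells")
}

#' @export
print.microwell_cells <- function(x, ...) {
  cat(sprintf("microwell_cells: %d microwells (%s)\n",
              nrow(x$cells), x$layout$platform_name))
  invisible(x)
}

#' Assign microtissue centroids to microwells and call occupancy
#'
#' Each object's centroid is tested against the microwell polygons
#' (point-in-polygon, boundary counts as inside). An object inside two
#' polygons signals a grid-extraction failure and raises an error. Objects
#' in no polygon are counted as unassigned ("floating between wells").
#' A microwell is empty iff it holds no centroid; wells holding more than
#' one microtissue count as filled.
#'
#' @param cells A [extract_microwells()] result.
#' @param objects A `microtissue_objects` data frame (needs `object_id`,
#'   `x_px`, `y_px`).
#' @return A list of class `occupancy_table`: per-cell statuses (`cells`:
#'   `microwell_id`, `row`, `col`, `status`, `n_occupants`), the assignment
#'   map (`assignments`: `object_id`, `microwell_id`), and summary counts
#'   `n_microwells`, `n_empty`, `n_single`, `n_multi`, `pct_empty`,
#'   `pct_filled`, `n_unassigned`.
#' @export
assign_occupancy <- function(cells, objects) {
  stopifnot(inherits(cells, "microwell_cells"))
  n_cells <- nrow(cells$cells)
  n_obj <- nrow(objects)
  bbox <- t(vapply(cells$polygons, function(p)
    c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2])), numeric(4)))
  assigned <- rep(NA_integer_, n_obj)
  occupants <- vector("list", n_cells)
  for (i in seq_len(n_obj)) {
    x <- objects$x_px[i]; y <- objects$y_px[i]
    cand <- which(x >= bbox[, 1] & x <= bbox[, 2] &
                    y >= bbox[, 3] & y <= bbox[, 4])
    hit <- cand[vapply(cand, function(k)
      point_in_polygon(x, y, cells$polygons[[k]]), logical(1))]
    if (length(hit) > 1) {
      stop("object centroid falls inside two microwell polygons; ",
           "grid extraction produced overlapping cells", call. = FALSE)
    }
    if (length(hit) == 1) {
      assigned[i] <- hit
      occupants[[hit]] <- c(occupants[[hit]], objects$object_id[i])
    }
  }
  n_occ <- lengths(occupants)
  status <- ifelse(n_occ == 0, "empty", ifelse(n_occ == 1, "single", "multi"))
  n_empty <- sum(n_occ == 0)
  n_single <- sum(n_occ == 1)
  n_multi <- sum(n_occ > 1)
  out <- list(
    cells = data.frame(microwell_id = cells$cells$microwell_id,
                       row = cells$cells$row, col = cells$cells$col,
                       status = status, n_occupants = n_occ),
    assignments = data.frame(
      object_id = if (n_obj) objects$object_id else integer(0),
      microwell_id = if (n_obj) cells$cells$microwell_id[assigned] else integer(0)),
    n_microwells = n_cells,
    n_empty = n_empty, n_single = n_single, n_multi = n_multi,
    pct_empty = 100 * n_empty / n_cells,
    pct_filled = 100 * (n_cells - n_empty) / n_cells,
    n_unassigned = sum(is.na(assigned)))
  class(out) <- "occupancy_table"
  out
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat(sprintf(
    "occupancy_table: %d microwells | empty %d (%.2f%%), single %d, multi %d | %d unassigned objects\n",
    x$n_microwells, x$n_empty, x$pct_empty, x$n_single, x$n_multi,
    x$n_unassigned))
  invisible(x)
}

#' Digitalize a plate: long-format per-microwell occupancy over time
#'
#' Combines per-well, per-day occupancy tables of one multi-well plate into
#' a single long table (one row per microwell per observation) suitable for
#' plate-heatmap rendering and well tracking over time.
#'
#' @param tables List of `occupancy_table` objects.
#' @param plate_well Character vector of culture-well identifiers, parallel
#'   to `tables`.
#' @param day Numeric vector of observation days, parallel to `tables`.
#' @return Data frame with columns `plate_well`, `day`, `microwell_row`,
#'   `microwell_col`, `status`.
#' @export
digitalize_plate <- function(tables, plate_well, day) {
  stopifnot(length(tables) == length(plate_well),
            length(tables) == length(day))
  if (anyDuplicated(paste(plate_well, day))) {
    stop("duplicate (plate_well, day) keys", call. = FALSE)
  }
  if (length(tables) == 0) {
    return(data.frame(plate_well = character(0), day = numeric(0),
                      microwell_row = integer(0), microwell_col = integer(0),
                      status = character(0)))
  }
  out <- lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    stopifnot(inherits(tb, "occupancy_table"))
    data.frame(plate_well = plate_well[i], day = day[i],
               microwell_row = tb$cells$row, microwell_col = tb$cells$col,
               status = tb$cells$status)
  })
  do.call(rbind, out)
}

#' Plate-map overview figure
#'
#' Renders one day of a digitalized plate as a per-microwell occupancy map
#' (one facet per culture well), mirroring plate-digitalization overviews.
#' Requires ggplot2.
#'
#' @param digitalized Output of [digitalize_plate()].
#' @param day Day to render (default: first day present).
#' @return A ggplot object.
#' @export
plot_plate_map <- function(digitalized, day = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plate-map rendering", call. = FALSE)
  }
  day <- day %||% digitalized$day[1]
  df <- digitalized[digitalized$day == day, , drop = FALSE]
  df$occupied <- df$status != "empty"
  ggplot2::ggplot(df, ggplot2::aes(x = microwell_col, y = microwell_row,
                                   fill = occupied)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~plate_well) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "#f0f0f0")) +
    ggplot2::labs(title = sprintf("Plate occupancy, day %s", day),
                  x = "microwell column", y = "microwell row",
                  fill = "occupied") +
    ggplot2::theme_minimal()
}

#' Export microwell polygons as GeoJSON
#'
#' Pixel-coordinate polygons, one feature per microwell with property
#' `microwell_id`.
#'
#' @param cells A `microwell_cells` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
microwells_as_geojson <- function(cells, path) {
  stopifnot(inherits(cells, "microwell_cells"))
  features <- lapply(seq_along(cells$polygons), function(i) {
    ring <- cells$polygons[[i]]
    ring <- rbind(ring, ring[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(microwell_id = cells$cells$microwell_id[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) unname(ring[j, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
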