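#' Microwell plate layouts
#'
#' A `plate_layout` describes the geometry of the microwell array inside one
#' culture well: pitch, grid dimensions, pixel scale and boundary-line width.
#' Two presets mirror the commercial platforms used for microtissue
#' self-assembly: `"A400"` (1200 microwells, 400 um square pitch, ~250 cells
#' per microtissue) and `"A800"` (300 microwells, 800 um square pitch,
#' ~1000 cells per microtissue). Arrays are rectangular (A400: 30 x 40,
#' A800: 15 x 20), so exactly `microwells_per_well` lattice sites fall
#' inside the well footprint.
#'
#' Pixel coordinates are 0-based `(x, y)` = (column, row), origin top-left;
#' physical coordinates in micrometres are `pixel * pixel_size`.
#'
#' @param platform_name `"A400"` or `"A800"`.
#' @param pixel_size Image scale in um per pixel (> 0). 8 um/px is the
#'   working scale for full-well overview renders; 2 um/px for
#'   1600 um x 1600 um field-of-view tiles.
#' @return An object of class `plate_layout`.
#' @examples
#' make_layout("A800", pixel_size = 8)
#' @export
make_layout <- function(platform_name, pixel_size = 8) {
  presets <- list(
    A400 = list(pitch = 400, n = 1200, rows = 30, cols = 40,
                expected_diameter = 150),
    A800 = list(pitch = 800, n = 300, rows = 15, cols = 20,
                expected_diameter = 250)
  )
  if (!is.character(platform_name) || length(platform_name) != 1L ||
      !platform_name %in% names(presets)) {
    stop("unknown platform name: ", paste(platform_name, collapse = ", "),
         " (available: ", paste(names(presets), collapse = ", "), ")",
         call. = FALSE)
  }
  p <- presets[[platform_name]]
  new_plate_layout(
    platform_name = platform_name,
    microwell_pitch = p$pitch,
    grid_rows = p$rows,
    grid_cols = p$cols,
    pixel_size = pixel_size,
    margin = p$pitch / 2,
    expected_diameter = p$expected_diameter
  )
}

#' Field-of-view tile layout
#'
#' A small rectangular sub-array matching a microscope field of view
#' (default 2 um/px, zero margin so a 1600 um x 1600 um tile holds a
#' 4 x 4 A400 or 2 x 2 A800 block).
#'
#' @inheritParams make_layout
#' @param grid_rows,grid_cols Number of microwell rows/columns in the tile.
#' @param margin Border around the array in um.
#' @return A `plate_layout`.
#' @export
make_tile_layout <- function(platform_name, pixel_size = 2,
                             grid_rows = NULL, grid_cols = NULL, margin = 0) {
  full <- make_layout(platform_name, pixel_size = pixel_size)
  defaults <- switch(platform_name, A400 = c(4L, 4L), A800 = c(2L, 2L))
  grid_rows <- grid_rows %||% defaults[1]
  grid_cols <- grid_cols %||% defaults[2]
  new_plate_layout(
    platform_name = paste0(platform_name, "-tile"),
    microwell_pitch = full$microwell_pitch,
    grid_rows = as.integer(grid_rows),
    grid_cols = as.integer(grid_cols),
    pixel_size = pixel_size,
    margin = margin,
    expected_diameter = full$expected_diameter
  )
}

#' @noRd
new_plate_layout <- function(platform_name, microwell_pitch, grid_rows,
                             grid_cols, pixel_size, margin,
                             expected_diameter, boundary_width = 40) {
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be > 0", call. = FALSE)
  }
  width_um <- grid_cols * microwell_pitch + 2 * margin
  height_um <- grid_rows * microwell_pitch + 2 * margin
  layout <- list(
    platform_name = platform_name,
    microwell_pitch = microwell_pitch,
    microwells_per_well = as.integer(grid_rows * grid_cols),
    grid_rows = as.integer(grid_rows),
    grid_cols = as.integer(grid_cols),
    well_mask_shape = list(shape = "rectangle",
                           width_um = width_um, height_um = height_um),
    pixel_size = pixel_size,
    boundary_width = boundary_width,
    margin = margin,
    expected_diameter = expected_diameter
  )
  class(layout) <- "plate_layout"
  layout
}

#' @export
print.plate_layout <- function(x, ...) {
  dims <- layout_image_dim(x)
  cat(sprintf(
    "plate_layout '%s': %d microwells (%d x %d grid), pitch %g um, %g um/px, image %d x %d px\n",
    x$platform_name, x$microwells_per_well, x$grid_rows, x$grid_cols,
    x$microwell_pitch, x$pixel_size, dims[1], dims[2]))
  invisible(x)
}

#' Image dimensions implied by a layout
#'
#' @param layout A `plate_layout`.
#' @return Integer vector `c(nrow, ncol)` in pixels.
#' @export
layout_image_dim <- function(layout) {
  c(round(layout$well_mask_shape$height_um / layout$pixel_size),
    round(layout$well_mask_shape$width_um / layout$pixel_size))
}

#' Microwell lattice centres
#'
#' @param layout A `plate_layout`.
#' @return A data frame with one row per microwell, in row-major order:
#'   `well_id`, `row`, `col`, centre coordinates `x_um`, `y_um` and the
#'   same in 0-based pixels `x_px`, `y_px`.
#' @export
microwell_centers <- function(layout) {
  g <- expand.grid(col = seq_len(layout$grid_cols),
                   row = seq_len(layout$grid_rows))
  g <- g[order(g$row, g$col), , drop = FALSE]
  x_um <- layout$margin + (g$col - 0.5) * layout$microwell_pitch
  y_um <- layout$margin + (g$row - 0.5) * layout$microwell_pitch
  data.frame(
    well_id = seq_len(nrow(g)),
    row = g$row, col = g$col,
    x_um = x_um, y_um = y_um,
    x_px = x_um / layout$pixel_size,
    y_px = y_um / layout$pixel_size,
    row.names = NULL
  )
}

#' Cells per microtissue for a seeding density
#'
#' Cells seeded into a culture well distribute over the microwells, so each
#' microtissue self-assembles from roughly `cells_seeded / microwells`
#' cells (e.g. 300 000 cells over 1200 microwells gives 250 cells per
#' microtissue on the A400 platform, and 1000 on the A800).
#'
#' @param cells_seeded Number of cells seeded per culture well.
#' @param layout A `plate_layout` (or a plain microwell count).
#' @return Cells per microtissue.
#' @export
cells_per_microtissue <- function(cells_seeded, layout) {
  n <- if (inherits(layout, "plate_layout")) layout$microwells_per_well
       else as.numeric(layout)
  if (cells_seeded <= 0 || n <= 0) {
    stop("cells_seeded and microwell count must be positive", call. = FALSE)
  }
  cells_seeded / n
}
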