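test_that("grid extraction recovers the exact microwell counts from clean masks", {
  for (pf in c("A800", "A400")) {
    layout <- make_layout(pf, pixel_size = 8)
    truth <- render_well_image(layout, fill_params(empty_fraction = 1),
                               seed = 1)
    cells <- extract_microwells(truth$boundary_mask, layout)
    expect_equal(nrow(cells$cells), layout$microwells_per_well)
    expect_equal(anyDuplicated(cells$cells[, c("row", "col")]), 0L)
  }
})

test_that("lattice snapping survives randomly deleted boundary pixels", {
  layout <- make_layout("A800", pixel_size = 8)
  truth <- render_well_image(layout, fill_params(empty_fraction = 1), seed = 1)
  broken <- truth$boundary_mask
  on_px <- which(broken == 1L)
  set.seed(42)
  broken[sample(on_px, length(on_px) %/% 10)] <- 0L
  cells <- extract_microwells(broken, layout)
  expect_equal(nrow(cells$cells), layout$microwells_per_well)
})

test_that("too few candidates raise a detection error", {
  layout <- tile_layout()
  blank <- matrix(0L, 100, 100); blank[1, 1] <- 1L
  expect_error(extract_microwells(blank, layout), "detection failed")
})

test_that("points on a polygon edge count as inside", {
  sq <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  expect_true(point_in_polygon(5, 0, sq))
  expect_true(point_in_polygon(10, 10, sq))
  expect_true(point_in_polygon(5, 5, sq))
  expect_false(point_in_polygon(10.01, 5, sq))
  expect_false(point_in_polygon(-1, -1, sq))
})

test_that("ray casting agrees with an independent point-in-polygon oracle", {
  set.seed(13)
  ang <- sort(runif(7, 0, 2 * pi))
  poly <- cbind(x = 5 + 4 * cos(ang), y = 5 + 4 * sin(ang))
  x <- runif(200, 0, 10); y <- runif(200, 0, 10)
  got <- point_in_polygon(x, y, poly)
  ref <- mgcv::in.out(rbind(poly, poly[1, ]), cbind(x, y))
  expect_equal(got, as.logical(ref))
})

test_that("occupancy assignment equals the exhaustive all-pairs evaluation", {
  grid <- square_grid(10, 10)  # axis-aligned squares: the oracle is trivial
  set.seed(7)
  objects <- data.frame(object_id = 1:50,
                        x_px = runif(50, 0, 210), y_px = runif(50, 0, 210))
  occ <- assign_occupancy(grid, objects)
  # brute force over all (object, cell) pairs with interval arithmetic
  truth_assign <- rep(NA_integer_, 50)
  for (i in 1:50) for (k in seq_along(grid$polygons)) {
    p <- grid$polygons[[k]]
    if (objects$x_px[i] >= min(p[, 1]) && objects$x_px[i] <= max(p[, 1]) &&
        objects$y_px[i] >= min(p[, 2]) && objects$y_px[i] <= max(p[, 2])) {
      truth_assign[i] <- k
    }
  }
  expect_equal(occ$assignments$microwell_id, truth_assign)
  n_occ <- tabulate(truth_assign, 100)
  expect_equal(occ$n_empty, sum(n_occ == 0))
  expect_equal(occ$n_single, sum(n_occ == 1))
  expect_equal(occ$n_multi, sum(n_occ > 1))
  expect_equal(occ$n_unassigned, sum(is.na(truth_assign)))
  # partition property and the percentage identities
  expect_equal(occ$n_empty + occ$n_single + occ$n_multi, occ$n_microwells)
  expect_equal(occ$pct_empty + occ$pct_filled, 100, tolerance = 1e-9)
  expect_equal(occ$pct_empty, 100 * occ$n_empty / occ$n_microwells)
  expect_equal(sum(!is.na(occ$assignments$microwell_id)) + occ$n_unassigned,
               nrow(objects))
})

test_that("no objects means all empty; one per cell means none empty", {
  grid <- square_grid(4, 4)
  none <- assign_occupancy(grid, data.frame(object_id = integer(0),
                                            x_px = numeric(0),
                                            y_px = numeric(0)))
  expect_equal(none$pct_empty, 100)
  centers <- data.frame(object_id = seq_len(16),
                        x_px = grid$cells$x_px, y_px = grid$cells$y_px)
  all_full <- assign_occupancy(grid, centers)
  expect_equal(all_full$pct_empty, 0)
  expect_equal(all_full$n_single, 16)
})

test_that("occupancy is invariant to a common integer translation", {
  layout <- make_tile_layout("A400", pixel_size = 4, grid_rows = 3,
                             grid_cols = 3, margin = 200)
  truth <- render_well_image(layout, fill_params(empty_fraction = 0.3),
                             seed = 21)
  shift <- 7
  shifted_mask <- matrix(0L, nrow(truth$boundary_mask) + shift,
                         ncol(truth$boundary_mask) + shift)
  shifted_mask[(shift + 1):(shift + nrow(truth$boundary_mask)),
               (shift + 1):(shift + ncol(truth$boundary_mask))] <-
    truth$boundary_mask
  objects <- data.frame(object_id = truth$objects$id,
                        x_px = truth$objects$x_px,
                        y_px = truth$objects$y_px)
  occ1 <- assign_occupancy(extract_microwells(truth$boundary_mask, layout),
                           objects)
  objects2 <- transform(objects, x_px = x_px + shift, y_px = y_px + shift)
  occ2 <- assign_occupancy(extract_microwells(shifted_mask, layout), objects2)
  expect_equal(occ1$cells$status[order(occ1$cells$row, occ1$cells$col)],
               occ2$cells$status[order(occ2$cells$row, occ2$cells$col)])
  expect_equal(occ1$pct_empty, occ2$pct_empty)
})

test_that("plate digitalization emits one row per microwell per observation", {
  grid <- square_grid(5, 4)
  occ <- assign_occupancy(grid, data.frame(object_id = integer(0),
                                           x_px = numeric(0),
                                           y_px = numeric(0)))
  one <- digitalize_plate(list(occ), "W01", 7)
  expect_equal(nrow(one), 20)
  expect_named(one, c("plate_well", "day", "microwell_row", "microwell_col",
                      "status"))
  # 24 wells x 3 days of a 300-microwell platform: 21600 rows
  tables <- rep(list(occ), 24 * 3)
  wells <- rep(sprintf("W%02d", 1:24), each = 3)
  days <- rep(c(7, 14, 21), times = 24)
  many <- digitalize_plate(tables, wells, days)
  expect_equal(nrow(many), 24 * 3 * 20)
  expect_error(digitalize_plate(list(occ, occ), c("W01", "W01"), c(7, 7)),
               "duplicate")
  empty <- digitalize_plate(list(), character(0), numeric(0))
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("plate_well", "day", "microwell_row",
                        "microwell_col", "status"))
})

test_that("microwell polygons export as valid GeoJSON", {
  grid <- square_grid(2, 2)
  path <- withr::local_tempfile(fileext = ".geojson")
  microwells_as_geojson(grid, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 4)
  expect_equal(gj$features[[1]]$properties$microwell_id, 1)
})
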