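test_that("rendering is deterministic and occupancy is conserved", {
  layout <- tile_layout()
  a <- render_well_image(layout, fill_params(empty_fraction = 0.3,
                                             escaped_count = 2), seed = 11)
  b <- render_well_image(layout, fill_params(empty_fraction = 0.3,
                                             escaped_count = 2), seed = 11)
  expect_identical(a$image, b$image)
  expect_identical(a$tissue_mask, b$tissue_mask)
  expect_identical(a$occupancy, b$occupancy)
  tab <- table(factor(a$occupancy$status, c("empty", "single", "multi")))
  expect_equal(sum(tab), layout$microwells_per_well)
  c_ <- render_well_image(layout, fill_params(empty_fraction = 0.3,
                                              escaped_count = 2), seed = 12)
  expect_false(identical(a$image, c_$image))
})

test_that("empty_fraction extremes force all-single and all-empty wells", {
  layout <- make_tile_layout("A800", pixel_size = 8, grid_rows = 3,
                             grid_cols = 3, margin = 400)
  full <- render_well_image(layout, fill_params(empty_fraction = 0,
                                                escaped_count = 0), seed = 1)
  expect_true(all(full$occupancy$status == "single"))
  expect_equal(nrow(full$objects), layout$microwells_per_well)
  none <- render_well_image(layout, fill_params(empty_fraction = 1,
                                                escaped_count = 0), seed = 1)
  expect_true(all(none$occupancy$status == "empty"))
  expect_equal(sum(none$tissue_mask), 0)
})

test_that("per-well emptiness replays the documented Bernoulli draws", {
  layout <- make_layout("A400", pixel_size = 8)
  truth <- render_well_image(layout, fill_params(empty_fraction = 0.1),
                             seed = 7)
  set.seed(7)
  expected_empty <- runif(layout$microwells_per_well) < 0.1
  expect_equal(truth$occupancy$status == "empty", unname(expected_empty))
})

test_that("catalog centroids lie on tissue and escaped objects sit between wells", {
  truth <- tile_truth()
  layout <- truth$layout
  for (i in seq_len(nrow(truth$objects))) {
    r <- round(truth$objects$y_px[i]) + 1
    c <- round(truth$objects$x_px[i]) + 1
    expect_equal(truth$tissue_mask[r, c], 1L)
  }
  esc <- truth$objects[!truth$objects$housed, , drop = FALSE]
  expect_gte(nrow(esc), 1)
  # escaped centroids are near a grid line, not inside a microwell interior
  p <- layout$microwell_pitch
  off_x <- abs((esc$x_um - layout$margin) %% p - p / 2)
  off_y <- abs((esc$y_um - layout$margin) %% p - p / 2)
  expect_true(all(pmin(p / 2 - off_x, p / 2 - off_y) <= p / 6 + 1e-9))
})

test_that("geometry and parameter validation reject impossible renders", {
  layout <- tile_layout()
  expect_error(render_well_image(layout,
                                 fill_params(mean_diameter = 500)),
               "pitch")
  expect_error(fill_params(empty_fraction = 1.5), "empty_fraction")
})

test_that("quadrant sparse labels are consistent with ground truth", {
  truth <- tile_truth()
  for (target in c("tissue", "boundary")) {
    lab <- sparse_labels_from_truth(truth, target, seed = 5)
    mask <- if (target == "tissue") truth$tissue_mask else truth$boundary_mask
    expect_true(all(mask[lab == 1L] == 1L))
    expect_true(all(mask[lab == 2L] == 0L))
    expect_gt(sum(lab == 1L), 50)
    expect_gt(sum(lab == 2L), 50)
  }
})

test_that("series emptiness follows the closed-form Bernoulli compounding", {
  layout <- make_layout("A400", pixel_size = 8)
  model <- displacement_model(base_escape_prob = 0.01,
                              aspiration_coeff = 0, dispension_coeff = 0)
  series <- simulate_series(layout, model, timepoints = c(21), seed = 3,
                            initial_empty_fraction = 0)
  # five media changes at p = 0.01 each
  frac <- mean(series[[1]]$truth$occupancy$status == "empty")
  p_exp <- 1 - 0.99^5
  se <- sqrt(p_exp * (1 - p_exp) / layout$microwells_per_well)
  expect_lt(abs(frac - p_exp), 3 * se)
})

test_that("series extremes: zero escape keeps occupancy, certain escape empties all", {
  layout <- make_tile_layout("A800", pixel_size = 8, grid_rows = 4,
                             grid_cols = 4, margin = 400)
  still <- simulate_series(layout, displacement_model(base_escape_prob = 0),
                           timepoints = c(7, 14, 21), seed = 2,
                           initial_empty_fraction = 0.2)
  fracs <- vapply(still, function(s)
    mean(s$truth$occupancy$status == "empty"), numeric(1))
  expect_equal(fracs, rep(fracs[1], 3))
  gone <- simulate_series(layout, displacement_model(base_escape_prob = 1),
                          timepoints = c(7), seed = 2,
                          initial_empty_fraction = 0)
  expect_true(all(gone[[1]]$truth$occupancy$status == "empty"))
})

test_that("series are monotone in time and stochastically monotone in escape rate", {
  layout <- make_layout("A800", pixel_size = 8)
  lo <- hi <- numeric(100)
  for (s in 1:100) {
    ser <- simulate_series(layout, displacement_model(0.02),
                           timepoints = c(7, 14, 21), seed = s,
                           initial_empty_fraction = 0.05)
    empties <- vapply(ser, function(x)
      sum(x$truth$occupancy$status == "empty"), numeric(1))
    expect_true(all(diff(empties) >= 0))
    lo[s] <- empties[3]
    hi[s] <- sum(simulate_series(layout, displacement_model(0.05),
                                 timepoints = c(21), seed = s,
                                 initial_empty_fraction = 0.05
    )[[1]]$truth$occupancy$status == "empty")
  }
  expect_gt(mean(hi), mean(lo))
})

test_that("unsorted timepoints and invalid speeds are rejected", {
  layout <- tile_layout()
  expect_error(simulate_series(layout, timepoints = c(14, 7)), "sorted")
  expect_error(simulate_series(layout, aspiration = -1), "speeds")
})

test_that("rendered series carry masks consistent with their catalogs", {
  layout <- make_tile_layout("A800", pixel_size = 8, grid_rows = 3,
                             grid_cols = 3, margin = 400)
  ser <- simulate_series(layout, displacement_model(0.3),
                         timepoints = c(7, 14), seed = 9,
                         initial_empty_fraction = 0, render = TRUE)
  for (s in ser) {
    expect_false(is.null(s$truth$image))
    expect_equal(dim(s$truth$tissue_mask), layout_image_dim(layout))
    for (i in seq_len(nrow(s$truth$objects))) {
      r <- round(s$truth$objects$y_px[i]) + 1
      c <- round(s$truth$objects$x_px[i]) + 1
      expect_equal(s$truth$tissue_mask[r, c], 1L)
    }
  }
})
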