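test_that("Otsu thresholding separates bimodal maps and rejects constants", {
  m <- matrix(0.1, 50, 50)
  m[20:30, 20:30] <- 0.9
  mask <- threshold_map(m)
  expect_equal(mask == 1L, m == 0.9)
  expect_error(threshold_map(matrix(0.5, 10, 10)), "degenerate")
})

test_that("Otsu's threshold is near-optimal in Dice on a real probability map", {
  truth <- tile_truth()
  map <- tile_tissue_map()
  mask <- threshold_map(map)
  d_otsu <- dice(mask, truth$tissue_mask)
  sweep <- vapply(seq(0.05, 0.95, by = 0.005), function(t)
    dice(map >= t, truth$tissue_mask), numeric(1))
  expect_gte(d_otsu, max(sweep) - 0.05)
})

test_that("declumping preserves pixels and leaves disjoint objects intact", {
  expect_equal(max(declump(matrix(0L, 40, 40))), 0)
  m <- matrix(0L, 80, 80)
  m[10:25, 10:25] <- 1L
  m[50:70, 50:70] <- 1L
  lab <- declump(m, d_min = 10)
  expect_equal(sort(unique(as.vector(lab[lab > 0]))), c(1L, 2L))
  expect_equal((lab > 0) * 1L, m, ignore_attr = TRUE)  # label conservation
  expect_equal(length(unique(lab[m == 1L & lab > 0])), 2)
  # each square keeps its pixel set
  expect_equal(length(unique(as.vector(lab[10:25, 10:25]))), 1)
  expect_equal(length(unique(as.vector(lab[50:70, 50:70]))), 1)
})

test_that("two overlapping discs split within 2 px of the analytic bisector", {
  n <- 100
  msk <- matrix(0L, n, n)
  for (r in 1:n) for (c in 1:n) {
    if ((r - 50)^2 + (c - 35)^2 <= 400 ||
        (r - 50)^2 + (c - 65)^2 <= 400) msk[r, c] <- 1L
  }
  lab <- declump(msk, d_min = 20)
  expect_equal(max(lab), 2)
  expect_equal(sum(lab > 0), sum(msk))
  left_lab <- lab[50, 35]
  right_lab <- lab[50, 65]
  expect_true(left_lab != right_lab)
  for (r in 40:60) {
    cols_l <- which(lab[r, ] == left_lab)
    cols_r <- which(lab[r, ] == right_lab)
    if (length(cols_l) && length(cols_r)) {
      # centres are equidistant from col 50: the ridge is the bisector
      expect_lte(abs(max(cols_l) - 50), 2)
      expect_lte(abs(min(cols_r) - 50), 2)
    }
  }
})

test_that("morphometrics match closed-form disc and ellipse geometry", {
  n <- 121
  disc <- matrix(0L, n, n)
  for (r in 1:n) for (c in 1:n)
    if ((r - 61)^2 + (c - 61)^2 <= 50^2) disc[r, c] <- 1L
  f <- measure_objects(disc, pixel_size = 1)
  expect_equal(f$area_um2, pi * 50^2, tolerance = 0.02)
  expect_lt(f$eccentricity, 0.1)
  expect_gt(f$form_factor, 0.9)
  expect_lte(f$form_factor, 1 + 1e-9)
  expect_gte(f$compactness, 1 - 1e-9)
  expect_equal(f$diameter_um, 2 * sqrt(f$area_um2 / pi))

  ell <- matrix(0L, 250, 250)
  for (r in 1:250) for (c in 1:250)
    if (((r - 125) / 20)^2 + ((c - 125) / 100)^2 <= 1) ell[r, c] <- 1L
  fe <- measure_objects(ell, pixel_size = 1)
  expect_equal(fe$eccentricity, sqrt(1 - 1 / 25), tolerance = 0.02)

  single <- matrix(0L, 9, 9); single[3, 7] <- 1L
  fs <- measure_objects(single, pixel_size = 2)
  expect_equal(fs$x_px, 6)  # 0-based column
  expect_equal(fs$y_px, 2)  # 0-based row
  expect_equal(fs$area_um2, 4)
})

test_that("measurements are exactly scale-equivariant in pixel size", {
  lab <- (tile_tissue_map() >= 0.5) * 1L
  lab <- declump(lab, d_min = 10)
  f1 <- measure_objects(lab, pixel_size = 2)
  f2 <- measure_objects(lab, pixel_size = 4)
  expect_equal(f2$diameter_um, 2 * f1$diameter_um)
  expect_equal(f2$area_um2, 4 * f1$area_um2)
  expect_equal(f2$eccentricity, f1$eccentricity)
  expect_equal(f2$compactness, f1$compactness)
})

test_that("object filtering applies each rule and is idempotent", {
  layout <- tile_layout()
  truth <- tile_truth()
  mask <- threshold_map(tile_tissue_map())
  lab <- declump(mask, d_min = 0.5 * layout$expected_diameter / 4)

  permissive <- filter_criteria(1e-3, 1e6, max_eccentricity = 0.9999,
                                max_compactness = 1e6)
  expect_equal(filter_objects(lab, permissive, 4), lab, ignore_attr = TRUE)

  # a 2-px speck is removed under a 100 um minimum diameter at 2 um/px
  speck <- matrix(0L, 30, 30); speck[5, 5:6] <- 1L
  out <- filter_objects(speck, filter_criteria(100, 400), pixel_size = 2)
  expect_equal(sum(out), 0)
  expect_match(attr(out, "report")$reasons, "diameter_below_min")

  # survivor set equals the brute-force rule on measured diameters
  crit <- default_filter_criteria(layout)
  feats <- measure_objects(lab, 4)
  keep_ids <- feats$object_id[
    feats$diameter_um >= crit$min_diameter &
      feats$diameter_um <= crit$max_diameter &
      feats$area_um2 >= crit$min_area & feats$area_um2 <= crit$max_area &
      feats$eccentricity <= crit$max_eccentricity &
      feats$compactness <= crit$max_compactness]
  filtered <- filter_objects(lab, crit, 4)
  expect_setequal(unique(filtered[filtered > 0]), keep_ids)
  # idempotence, with survivors keeping identity
  again <- filter_objects(filtered, crit, 4)
  expect_equal(as.vector(again), as.vector(filtered))

  expect_error(filter_criteria(200, 100), "criteria")
})

test_that("segmentation recovers the catalog objects on the synthetic tile", {
  truth <- tile_truth()
  seg <- segment_well(truth$image, tile_tissue_classifier(), truth$layout)
  n_true <- nrow(truth$objects)
  expect_lte(abs(nrow(seg$objects) - n_true), ceiling(0.05 * n_true))
  # matched centroid error below a quarter of the mean diameter
  mean_d_px <- mean(truth$objects$diameter_um) / truth$layout$pixel_size
  for (i in seq_len(nrow(seg$objects))) {
    d <- sqrt((truth$objects$x_px - seg$objects$x_px[i])^2 +
                (truth$objects$y_px - seg$objects$y_px[i])^2)
    expect_lt(min(d), 0.25 * mean_d_px)
  }
})
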