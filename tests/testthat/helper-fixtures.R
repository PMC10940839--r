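# Shared fixtures, built once per test run and cached in-session.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# Small A400 field-of-view tile (4 x 4 microwells, 400 x 400 px at 4 um/px)
tile_layout <- function() make_tile_layout("A400", pixel_size = 4)

tile_truth <- function() cached("tile_truth", {
  render_well_image(tile_layout(),
                    fill_params(empty_fraction = 0.2, escaped_count = 1),
                    seed = 3)
})

tile_tissue_classifier <- function() cached("tile_tissue_classifier", {
  truth <- tile_truth()
  labels <- sparse_labels_from_truth(truth, "tissue", seed = 3)
  train_pixel_classifier(truth$image, labels, seed = 1)
})

tile_boundary_classifier <- function() cached("tile_boundary_classifier", {
  truth <- tile_truth()
  labels <- sparse_labels_from_truth(truth, "boundary", seed = 4)
  train_pixel_classifier(truth$image, labels, seed = 1)
})

tile_tissue_map <- function() cached("tile_tissue_map", {
  predict_probability(tile_tissue_classifier(), tile_truth()$image)
})

# Dense random labels straight from the ground-truth mask (for data-budget
# experiments, unlike the quadrant-style sparse labelling).
dense_labels_from_truth <- function(truth, n_per_class, seed) {
  mask <- truth$tissue_mask
  fg <- which(mask == 1L)
  bg <- which(mask == 0L)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  set.seed(seed)
  labels[sample(fg, min(n_per_class, length(fg)))] <- 1L
  labels[sample(bg, min(n_per_class, length(bg)))] <- 2L
  labels
}

# Full-well classifiers at 8 um/px, shared by the end-to-end checks.
well_classifiers <- function() cached("well_classifiers", {
  train_well_classifiers(c("A400", "A800"), seed = 1, pixel_size = 8)
})

# Axis-aligned square microwell grid built by hand (for occupancy oracles).
square_grid <- function(n_rows, n_cols, pitch = 20, origin = 5) {
  polys <- list()
  cells <- data.frame()
  id <- 0
  for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
    id <- id + 1
    x0 <- origin + (c - 1) * pitch
    y0 <- origin + (r - 1) * pitch
    polys[[id]] <- cbind(x = c(x0, x0 + pitch - 2, x0 + pitch - 2, x0),
                         y = c(y0, y0, y0 + pitch - 2, y0 + pitch - 2))
    cells <- rbind(cells, data.frame(microwell_id = id, row = r, col = c,
                                     x_px = x0 + pitch / 2,
                                     y_px = y0 + pitch / 2,
                                     area_px = (pitch - 2)^2))
  }
  structure(list(cells = cells, polygons = polys,
                 layout = make_tile_layout("A400", pixel_size = 4)),
            class = "microwell_cells")
}
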