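#' Dice overlap coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks are defined to agree
#' perfectly (Dice 1), so degenerate cases do not poison averages.
#'
#' @param mask_a,mask_b Binary matrices of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) {
    stop("masks must have identical shapes", call. = FALSE)
  }
  a <- mask_a > 0
  b <- mask_b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Empty-microwell identification accuracy
#'
#' Compares per-microwell binary calls (empty vs occupied) between a
#' predicted occupancy table and the ground truth, matched on the
#' (row, col) lattice position. Overall binary agreement is the primary
#' figure; recall of the empty class is also reported since "correctly
#' identified empty microwells" admits both readings.
#'
#' @param predicted An `occupancy_table` (or data frame with `row`, `col`,
#'   `status`).
#' @param truth A `ground_truth` (or its `occupancy` data frame).
#' @return A list of class `occupancy_accuracy`: `accuracy`, `empty_recall`,
#'   `n_microwells`, and the 2x2 `confusion` table.
#' @export
empty_well_accuracy <- function(predicted, truth) {
  pred <- if (inherits(predicted, "occupancy_table")) predicted$cells
          else predicted
  tru <- if (inherits(truth, "ground_truth")) truth$occupancy else truth
  m <- merge(pred[, c("row", "col", "status")],
             tru[, c("row", "col", "status")],
             by = c("row", "col"), suffixes = c("_pred", "_true"))
  if (nrow(m) != nrow(pred) || nrow(m) != nrow(tru)) {
    stop("microwell lattices do not match between prediction and truth",
         call. = FALSE)
  }
  pe <- m$status_pred == "empty"
  te <- m$status_true == "empty"
  confusion <- table(predicted = factor(ifelse(pe, "empty", "occupied"),
                                        c("empty", "occupied")),
                     truth = factor(ifelse(te, "empty", "occupied"),
                                    c("empty", "occupied")))
  out <- list(accuracy = mean(pe == te),
              empty_recall = if (any(te)) mean(pe[te]) else NA_real_,
              n_microwells = nrow(m),
              confusion = confusion)
  class(out) <- "occupancy_accuracy"
  out
}

#' @export
print.occupancy_accuracy <- function(x, ...) {
  cat(sprintf(
    "occupancy_accuracy: %.3f overall agreement (empty recall %.3f) over %d microwells\n",
    x$accuracy, x$empty_recall, x$n_microwells))
  invisible(x)
}

#' End-to-end segmentation validation on synthetic tiles
#'
#' Generates field-of-view tiles with paired ground truth, trains the
#' microtissue pixel classifier on quadrant-style sparse labels from the
#' training tiles, segments the held-out tiles (Otsu thresholding, watershed
#' declumping, morphometric filtering) and scores pixel-level Dice against
#' the known masks.
#'
#' @param platforms Platforms to include.
#' @param n_train,n_validation Tiles per platform in each split.
#' @param seed Integer seed driving tile generation and training.
#' @param pixel_size Tile scale in um/px.
#' @param n_trees Trees of the pixel classifier.
#' @return A list of class `validation_report`: `dice` (mean validation
#'   Dice), `dice_train`, per-image table `per_image`, `n_images`, `split`.
#' @export
run_segmentation_validation <- function(platforms = c("A400", "A800"),
                                        n_train = 5, n_validation = 5,
                                        seed = 1, pixel_size = 2,
                                        n_trees = 100) {
  per_image <- list()
  for (pf in platforms) {
    layout <- make_tile_layout(pf, pixel_size = pixel_size)
    fill <- fill_params(empty_fraction = 0.1, escaped_count = 0)
    seeds_train <- seed + seq_len(n_train)
    seeds_val <- seed + 1000 + seq_len(n_validation)
    train <- lapply(seeds_train, function(s)
      render_well_image(layout, fill, seed = s))
    labels <- lapply(seq_along(train), function(i)
      sparse_labels_from_truth(train[[i]], "tissue",
                               wells_per_quadrant = 6,
                               seed = seeds_train[i]))
    clf <- train_pixel_classifier(lapply(train, `[[`, "image"), labels,
                                  n_trees = n_trees, seed = seed)
    score <- function(truth, split) {
      seg <- segment_well(truth$image, clf, layout)
      data.frame(platform = pf, split = split, seed = truth$seed,
                 dice = dice(seg$labels > 0, truth$tissue_mask))
    }
    per_image <- c(per_image,
                   lapply(train, score, split = "train"),
                   lapply(lapply(seeds_val, function(s)
                     render_well_image(layout, fill, seed = s)),
                     score, split = "validation"))
  }
  tab <- do.call(rbind, per_image)
  out <- list(dice = mean(tab$dice[tab$split == "validation"]),
              dice_train = mean(tab$dice[tab$split == "train"]),
              per_image = tab,
              n_images = nrow(tab),
              split = "validation")
  class(out) <- "validation_report"
  out
}

#' End-to-end occupancy validation on synthetic wells
#'
#' Renders full synthetic wells (mixed platforms, varying emptiness,
#' escaped objects present), runs the whole pipeline — pixel classification
#' for tissue and boundary, segmentation, grid extraction with lattice
#' snapping, centroid-in-polygon assignment — and scores per-microwell
#' empty/occupied calls against the generator ground truth.
#'
#' @param n_wells Number of wells (split over the platforms).
#' @param platforms Platforms to mix.
#' @param seed Integer seed.
#' @param pixel_size Render scale in um/px.
#' @param empty_range Range of per-well empty fractions.
#' @param escaped_count Escaped objects per well.
#' @param n_trees Trees of the pixel classifiers.
#' @param classifiers Optional pre-trained classifiers, a list
#'   `list(A400 = list(tissue = , boundary = ), ...)`; trained from one
#'   seeded training well per platform when omitted.
#' @return A list of class `validation_report`: `accuracy` (pooled
#'   per-microwell agreement), `empty_recall`, `per_well` table,
#'   `n_microwells`, `n_images`.
#' @export
run_occupancy_validation <- function(n_wells = 10,
                                     platforms = c("A400", "A800"),
                                     seed = 1, pixel_size = 8,
                                     empty_range = c(0.05, 0.30),
                                     escaped_count = 5, n_trees = 100,
                                     classifiers = NULL) {
  classifiers <- classifiers %||% train_well_classifiers(
    platforms, seed = seed, pixel_size = pixel_size, n_trees = n_trees)
  pf_seq <- rep(platforms, length.out = n_wells)
  fractions <- seq(empty_range[1], empty_range[2], length.out = n_wells)
  per_well <- vector("list", n_wells)
  n_match <- 0; n_total <- 0
  for (i in seq_len(n_wells)) {
    pf <- pf_seq[i]
    layout <- make_layout(pf, pixel_size = pixel_size)
    truth <- render_well_image(
      layout, fill_params(empty_fraction = fractions[i],
                          escaped_count = escaped_count),
      seed = seed + 100 + i)
    res <- analyze_well_image(truth$image, classifiers[[pf]]$tissue,
                              classifiers[[pf]]$boundary, layout)
    acc <- empty_well_accuracy(res$occupancy, truth)
    n_match <- n_match + acc$accuracy * acc$n_microwells
    n_total <- n_total + acc$n_microwells
    per_well[[i]] <- data.frame(platform = pf, seed = seed + 100 + i,
                                empty_fraction = fractions[i],
                                accuracy = acc$accuracy,
                                empty_recall = acc$empty_recall,
                                n_microwells = acc$n_microwells)
  }
  tab <- do.call(rbind, per_well)
  out <- list(accuracy = n_match / n_total,
              empty_recall = mean(tab$empty_recall, na.rm = TRUE),
              per_well = tab, n_microwells = n_total, n_images = n_wells)
  class(out) <- "validation_report"
  out
}

#' Train tissue and boundary classifiers from seeded training wells
#'
#' One full-well render per platform provides quadrant-style sparse labels
#' for both classification tasks.
#'
#' @inheritParams run_occupancy_validation
#' @return Nested list: `classifiers[[platform]]$tissue` / `$boundary`.
#' @export
train_well_classifiers <- function(platforms = c("A400", "A800"), seed = 1,
                                   pixel_size = 8, n_trees = 100,
                                   escaped_count = 3) {
  out <- list()
  for (pf in platforms) {
    layout <- make_layout(pf, pixel_size = pixel_size)
    truth <- render_well_image(
      layout, fill_params(empty_fraction = 0.15,
                          escaped_count = escaped_count),
      seed = seed)
    lab_t <- sparse_labels_from_truth(truth, "tissue",
                                      wells_per_quadrant = 8, seed = seed)
    lab_b <- sparse_labels_from_truth(truth, "boundary",
                                      wells_per_quadrant = 8, seed = seed + 1)
    out[[pf]] <- list(
      tissue = train_pixel_classifier(truth$image, lab_t,
                                      n_trees = n_trees, seed = seed),
      boundary = train_pixel_classifier(truth$image, lab_b,
                                        n_trees = n_trees, seed = seed))
  }
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (!is.null(x$dice)) {
    cat(sprintf("validation_report: mean Dice %.3f (train %.3f) over %d images\n",
                x$dice, x$dice_train, x$n_images))
  }
  if (!is.null(x$accuracy)) {
    cat(sprintf("validation_report: occupancy accuracy %.3f over %d microwells in %d wells\n",
                x$accuracy, x$n_microwells, x$n_images))
  }
  invisible(x)
}
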