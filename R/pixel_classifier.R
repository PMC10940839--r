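#' Train a random-forest pixel classifier
#'
#' Trains a random forest (default 100 trees) on the filter-bank features of
#' sparsely labelled pixels, for a two-class segmentation task (foreground
#' vs background). Two independent classifiers with the same filter bank are
#' typically trained per experiment: one for microtissues, one for microwell
#' boundaries.
#'
#' @param images A single image matrix or a list of image matrices.
#' @param labels Matching label matrix/matrices: 0 = unlabelled,
#'   1 = foreground, 2 = background (see [sparse_labels_from_truth()]).
#' @param spec A [filter_bank_spec()].
#' @param n_trees Number of trees (>= 1; default 100).
#' @param seed Integer seed; training is reproducible.
#' @return An object of class `pixel_classifier`.
#' @export
train_pixel_classifier <- function(images, labels,
                                   spec = filter_bank_spec(),
                                   n_trees = 100, seed = 1) {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(labels)) labels <- list(labels)
  stopifnot(length(images) == length(labels))
  if (!is.numeric(n_trees) || n_trees < 1) {
    stop("n_trees must be >= 1", call. = FALSE)
  }
  xs <- list(); ys <- list()
  for (i in seq_along(images)) {
    if (!all(dim(images[[i]]) == dim(labels[[i]]))) {
      stop("labels must have the same shape as their image", call. = FALSE)
    }
    idx <- which(labels[[i]] != 0L)
    if (length(idx) == 0) next
    bank <- compute_filter_bank(images[[i]], spec)
    xs[[length(xs) + 1L]] <- bank[idx, , drop = FALSE]
    ys[[length(ys) + 1L]] <- labels[[i]][idx]
  }
  X <- do.call(rbind, xs)
  y <- unlist(ys)
  if (is.null(X) || length(unique(y)) < 2) {
    stop("training labels must contain both classes", call. = FALSE)
  }
  yf <- factor(c("foreground", "background")[y],
               levels = c("foreground", "background"))
  forest <- with_seed(seed, {
    randomForest::randomForest(x = X, y = yf, ntree = as.integer(n_trees))
  })
  structure(list(forest = forest, spec = spec,
                 n_trees = as.integer(n_trees), seed = seed,
                 n_train = length(y),
                 feature_names = colnames(X)),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "pixel_classifier: %d trees, %d features x %d scales, %d training pixels, seed %s\n",
    x$n_trees, length(x$spec$features), length(x$spec$sigmas), x$n_train,
    format(x$seed)))
  invisible(x)
}

# Foreground vote fraction for a feature matrix, via the compiled forest
# traversal. Identical to predict(forest, type = "prob")[, "foreground"]
# (asserted in the test suite); reads the forest arrays directly to avoid
# predict()'s per-call marshalling on multi-megapixel inputs.
#' @noRd
forest_prob_foreground <- function(forest, X) {
  fr <- forest$forest
  nclass <- length(forest$classes)
  ntree <- fr$ntree
  nrnodes <- fr$nrnodes
  treemap <- fr$treemap  # nrnodes x 2 x ntree
  ld <- as.integer(treemap[, 1, ])
  rd <- as.integer(treemap[, 2, ])
  votes <- .forest_votes_cpp(X, ld, rd,
                             matrix(as.integer(fr$nodestatus), nrnodes, ntree),
                             matrix(as.integer(fr$bestvar), nrnodes, ntree),
                             matrix(as.numeric(fr$xbestsplit), nrnodes, ntree),
                             matrix(as.integer(fr$nodepred), nrnodes, ntree),
                             nclass)
  votes[, match("foreground", forest$classes)]
}

#' @noRd
predict_prob_from_bank <- function(classifier, bank) {
  d <- attr(bank, "image_dim")
  p <- forest_prob_foreground(classifier$forest,
                              bank[, classifier$feature_names, drop = FALSE])
  matrix(p, d[1], d[2])
}

#' Predict a per-pixel foreground probability map
#'
#' Applies a trained [train_pixel_classifier()] model to an image. The
#' returned map holds the foreground probability per pixel; the background
#' probability is its complement (the two sum to one by construction).
#'
#' @param classifier A `pixel_classifier`.
#' @param image Numeric image matrix (same modality/scale as training).
#' @return Numeric matrix in `[0, 1]`, same shape as `image`, with
#'   attribute `classifier_seed`.
#' @export
predict_probability <- function(classifier, image) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  bank <- compute_filter_bank(image, classifier$spec)
  map <- predict_prob_from_bank(classifier, bank)
  attr(map, "classifier_seed") <- classifier$seed
  map
}

#' Persist / restore a pixel classifier
#'
#' The classifier is written as a single portable file embedding the filter
#' bank specification and training seed.
#'
#' @param classifier A `pixel_classifier`.
#' @param path File path.
#' @return `load_pixel_classifier()` returns the `pixel_classifier`.
#' @export
save_pixel_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_pixel_classifier
#' @export
load_pixel_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "pixel_classifier")) {
    stop("file does not contain a pixel_classifier", call. = FALSE)
  }
  obj
}
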