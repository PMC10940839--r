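#' Filter bank specification
#'
#' The pixel classifier works on a multi-scale filter bank ("all image
#' filters"): six feature families, each computed at every smoothing scale.
#' Default scales span sub-pixel texture to object-scale structure at
#' working resolutions of 2-8 um/px.
#'
#' @param sigmas Strictly increasing Gaussian scales in pixels (all > 0).
#' @param features Subset of `"gaussian"`, `"gradient_magnitude"`,
#'   `"laplacian"`, `"difference_of_gaussians"`, `"hessian_eigenvalue"`
#'   (largest-magnitude eigenvalue of the Hessian) and
#'   `"structure_tensor_eigenvalue"` (largest eigenvalue of the structure
#'   tensor).
#' @return A list of class `filter_bank_spec`.
#' @export
filter_bank_spec <- function(sigmas = c(0.7, 1.0, 1.6, 3.5, 5.0),
                             features = c("gaussian", "gradient_magnitude",
                                          "laplacian",
                                          "difference_of_gaussians",
                                          "hessian_eigenvalue",
                                          "structure_tensor_eigenvalue")) {
  all_features <- c("gaussian", "gradient_magnitude", "laplacian",
                    "difference_of_gaussians", "hessian_eigenvalue",
                    "structure_tensor_eigenvalue")
  if (length(sigmas) == 0) {
    stop("at least one sigma is required", call. = FALSE)
  }
  if (any(sigmas <= 0) || is.unsorted(sigmas, strictly = TRUE)) {
    stop("sigmas must be strictly increasing and > 0", call. = FALSE)
  }
  features <- match.arg(features, all_features, several.ok = TRUE)
  if (length(features) == 0) stop("feature list is empty", call. = FALSE)
  structure(list(sigmas = sigmas, features = features),
            class = "filter_bank_spec")
}

# Sampled Gaussian kernel and its first/second derivatives; radius 3.5 sigma.
# The Gaussian is normalized to unit sum. The first derivative is odd, so it
# sums to zero exactly; the sampled second derivative does not, so its DC
# component is removed to make the response to constant images exactly zero.
#' @noRd
gauss_kernels <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  s <- sum(g)
  d2g <- (x^2 / sigma^4 - 1 / sigma^2) * g / s
  list(g = g / s,
       dg = (-x / sigma^2) * g / s,
       d2g = d2g - sum(d2g) / length(d2g))
}

#' @noRd
sepconv <- function(img, k_row, k_col) {
  .sepconv2_cpp(img, k_row, k_col)
}

#' Compute a multi-scale filter bank for one image
#'
#' One feature plane per (feature, sigma) pair; filters are separable
#' Gaussian-derivative convolutions with reflected borders, so planes are
#' translation-equivariant away from the border. The difference of Gaussians
#' uses scales `(sigma, 1.6 sigma)`; the structure tensor smooths the
#' gradient outer product at the same sigma.
#'
#' @param image Single-channel numeric matrix with finite values.
#' @param spec A [filter_bank_spec()].
#' @return Numeric matrix with one row per pixel (column-major pixel order)
#'   and one named column per feature plane, with attribute `image_dim`.
#' @export
compute_filter_bank <- function(image, spec = filter_bank_spec()) {
  stopifnot(inherits(spec, "filter_bank_spec"))
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(image))) {
    stop("image must be finite-valued", call. = FALSE)
  }
  nplane <- length(spec$sigmas) * length(spec$features)
  out <- matrix(NA_real_, length(image), nplane)
  cn <- character(nplane)
  j <- 0L
  for (s in spec$sigmas) {
    k <- gauss_kernels(s)
    f <- spec$features
    g <- if (any(c("gaussian", "difference_of_gaussians") %in% f))
      sepconv(image, k$g, k$g) else NULL
    need_grad <- any(c("gradient_magnitude",
                       "structure_tensor_eigenvalue") %in% f)
    if (need_grad) {
      gx <- sepconv(image, k$g, k$dg)
      gy <- sepconv(image, k$dg, k$g)
    }
    need_hess <- any(c("laplacian", "hessian_eigenvalue") %in% f)
    if (need_hess) {
      gxx <- sepconv(image, k$g, k$d2g)
      gyy <- sepconv(image, k$d2g, k$g)
    }
    for (feat in f) {
      plane <- switch(
        feat,
        gaussian = g,
        gradient_magnitude = sqrt(gx^2 + gy^2),
        laplacian = gxx + gyy,
        difference_of_gaussians = {
          k2 <- gauss_kernels(1.6 * s)
          g - sepconv(image, k2$g, k2$g)
        },
        hessian_eigenvalue = {
          gxy <- sepconv(image, k$dg, k$dg)
          tr2 <- (gxx + gyy) / 2
          disc <- sqrt(((gxx - gyy) / 2)^2 + gxy^2)
          l1 <- tr2 + disc
          l2 <- tr2 - disc
          ifelse(abs(l1) >= abs(l2), l1, l2)
        },
        structure_tensor_eigenvalue = {
          jxx <- sepconv(gx * gx, k$g, k$g)
          jyy <- sepconv(gy * gy, k$g, k$g)
          jxy <- sepconv(gx * gy, k$g, k$g)
          (jxx + jyy) / 2 + sqrt(((jxx - jyy) / 2)^2 + jxy^2)
        })
      j <- j + 1L
      out[, j] <- plane
      cn[j] <- sprintf("%s_s%g", feat, s)
    }
  }
  colnames(out) <- cn
  attr(out, "image_dim") <- dim(image)
  out
}

#' Extract one feature plane from a filter bank as a matrix
#'
#' @param bank Output of [compute_filter_bank()].
#' @param name Column name of the plane.
#' @return Numeric matrix with the original image dimensions.
#' @export
filter_plane <- function(bank, name) {
  d <- attr(bank, "image_dim")
  matrix(bank[, name], d[1], d[2])
}
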