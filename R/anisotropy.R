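# Fibre anisotropy from the gradient nematic (structure) tensor within a
# region of interest, following the published FibrilTool protocol: the local
# fibril direction at each pixel is perpendicular to the intensity gradient;
# directions are averaged as a second-rank tensor so that antipodal angles
# reinforce rather than cancel, and the eigenvalue gap of the unit-trace
# tensor is the anisotropy score (0 = isotropic, 1 = perfectly aligned).

# Central-difference gradients with replicated (reflective) borders.
image_gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- (img[, c(2:nc, nc), drop = FALSE] -
           img[, c(1, 1:(nc - 1)), drop = FALSE]) / 2
  gy <- (img[c(2:nr, nr), , drop = FALSE] -
           img[c(1, 1:(nr - 1)), , drop = FALSE]) / 2
  list(gx = gx, gy = gy)
}

#' Averaged nematic tensor of fibril orientations in a region
#'
#' For each masked pixel the fibril direction is taken perpendicular to the
#' finite-difference intensity gradient, and its outer product is accumulated
#' with weight equal to the squared gradient magnitude; pixels whose gradient
#' magnitude falls below `1e-6` times the image intensity range carry no
#' orientation information and are skipped. The accumulated tensor is
#' normalised to unit trace.
#'
#' @param image 2D intensity matrix.
#' @param mask Logical matrix, same shape, with at least 16 pixels; defaults
#'   to the whole image.
#' @param smooth_sigma Optional Gaussian pre-smoothing s.d. in px (0 = none,
#'   the protocol default).
#' @return A list of class `nematic_tensor`: `nxx`, `nyy`, `nxy` (unit-trace
#'   components), `n_pixels` (pixels contributing), `defined` (`FALSE` when
#'   no gradient exceeded the floor, in which case the tensor is isotropic by
#'   convention).
#' @export
nematic_tensor <- function(image, mask = NULL, smooth_sigma = 0) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  mask <- validate_mask(mask, min_pixels = 16L)
  stopifnot(all(dim(mask) == dim(image)))
  if (smooth_sigma > 0) image <- gaussian_blur(image, smooth_sigma)
  g <- image_gradients(image)
  rng <- diff(range(image))
  floor_mag <- 1e-6 * rng
  w <- g$gx^2 + g$gy^2
  use <- mask & (sqrt(w) >= floor_mag) & (w > 0)
  if (!any(use)) {
    return(structure(list(nxx = 0.5, nyy = 0.5, nxy = 0, n_pixels = 0L,
                          defined = FALSE), class = "nematic_tensor"))
  }
  gx <- g$gx[use]; gy <- g$gy[use]
  # fibril direction u = (-gy, gx)/|g|; outer product weighted by |g|^2
  # gives the closed form below
  sxx <- sum(gy^2)
  syy <- sum(gx^2)
  sxy <- sum(-gx * gy)
  tr <- sxx + syy
  structure(list(nxx = sxx / tr, nyy = syy / tr, nxy = sxy / tr,
                 n_pixels = sum(use), defined = TRUE),
            class = "nematic_tensor")
}

#' Anisotropy score from a nematic tensor
#'
#' The eigenvalue gap `lambda1 - lambda2` of the unit-trace tensor, equal to
#' `2 * sqrt(((nxx - nyy)/2)^2 + nxy^2)`, together with the principal
#' orientation (the eigenvector of the larger eigenvalue, an axial angle in
#' `[0, pi)`).
#'
#' @param tensor A [nematic_tensor()].
#' @return A list of class `anisotropy_score`: `value` in `[0, 1]`,
#'   `mean_orientation` (radians, `NA` when undefined), `n_pixels`,
#'   `defined`.
#' @export
anisotropy_score <- function(tensor) {
  stopifnot(inherits(tensor, "nematic_tensor"))
  if (!tensor$defined) {
    return(structure(list(value = 0, mean_orientation = NA_real_,
                          n_pixels = tensor$n_pixels, defined = FALSE),
                     class = "anisotropy_score"))
  }
  d <- (tensor$nxx - tensor$nyy) / 2
  value <- 2 * sqrt(d^2 + tensor$nxy^2)
  ang <- 0.5 * atan2(2 * tensor$nxy, tensor$nxx - tensor$nyy)
  structure(list(value = min(1, value), mean_orientation = ang %% pi,
                 n_pixels = tensor$n_pixels, defined = TRUE),
            class = "anisotropy_score")
}

#' Fibre anisotropy of an image region
#'
#' @inheritParams nematic_tensor
#' @return An `anisotropy_score` (see [anisotropy_score()]).
#' @export
fibre_anisotropy <- function(image, mask = NULL, smooth_sigma = 0) {
  anisotropy_score(nematic_tensor(image, mask, smooth_sigma))
}

#' @export
print.anisotropy_score <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("Anisotropy %.3f, orientation %.1f deg (%d px)\n",
                x$value, x$mean_orientation * 180 / pi, x$n_pixels))
  } else {
    cat("Anisotropy undefined (no in-mask gradients); value 0\n")
  }
  invisible(x)
}

# Separable Gaussian blur with replicated borders (optional pre-filter).
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  conv1 <- function(m) {
    # along rows (first margin), replicated edges
    p <- m[pad_idx(nrow(m)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * p[j:(j + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}
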