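# Chromatin condensation parameter (CCP): Sobel edge density inside the
# nucleus mask. Edges are binarised at a threshold relative to the in-mask
# maximum gradient magnitude, which makes the parameter invariant to affine
# intensity rescaling, and the count is divided by the nuclear pixel area so
# that differently sized nuclei are comparable.

# 3x3 convolution via shifted sums, replicated (reflective) borders.
conv3x3 <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- list(c(1, 1:(nr - 1)), seq_len(nr), c(2:nr, nr))
  ci <- list(c(1, 1:(nc - 1)), seq_len(nc), c(2:nc, nc))
  out <- matrix(0, nr, nc)
  for (i in 1:3) for (j in 1:3) {
    if (kernel[i, j] != 0) {
      out <- out + kernel[i, j] * img[ri[[i]], ci[[j]], drop = FALSE]
    }
  }
  out
}

#' Sobel gradient magnitude
#'
#' Standard 3x3 Sobel pair with replicated borders.
#'
#' @param image 2D intensity matrix.
#' @return Matrix of `sqrt(Sx^2 + Sy^2)`.
#' @export
sobel_magnitude <- function(image) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  sx <- conv3x3(image, kx)
  sy <- conv3x3(image, t(kx))
  sqrt(sx^2 + sy^2)
}

# 1-px 8-neighbourhood erosion of a logical mask.
erode1 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  # border-padding with FALSE so the image border always erodes
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- matrix(TRUE, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    out <- out & p[(1L + di):(nr + di), (1L + dj):(nc + dj)]
  }
  out
}

#' Sobel edge map inside a nucleus region
#'
#' A pixel is an edge when it lies inside the mask (excluding a 1 px rim, so
#' the nuclear outline itself never counts as chromatin texture) and its
#' Sobel gradient magnitude reaches `threshold` times the in-mask maximum
#' magnitude. A constant in-mask intensity yields no edges.
#'
#' @param image 2D intensity matrix (nucleus channel, projected).
#' @param mask Logical nucleus mask.
#' @param threshold Fraction of the in-mask maximum gradient magnitude, in
#'   `(0, 1]` (default 0.15).
#' @return Logical edge map, same shape as `image`.
#' @export
sobel_edges <- function(image, mask, threshold = 0.15) {
  mask <- validate_mask(mask)
  stopifnot(all(dim(mask) == dim(image)),
            threshold > 0, threshold <= 1)
  mag <- sobel_magnitude(image)
  inner <- erode1(mask)
  maxmag <- max(mag[mask])
  # numerical floor: cancellation in the convolution leaves O(1e-16)
  # residue on flat regions, which must not register as structure
  eps <- 1e-9 * max(abs(image), 1e-12)
  if (maxmag <= eps) return(matrix(FALSE, nrow(image), ncol(image)))
  inner & (mag >= threshold * maxmag) & (mag > eps)
}

#' Chromatin condensation parameter of a nucleus
#'
#' Ratio of Sobel edge pixels to total nuclear pixel area.
#'
#' @inheritParams sobel_edges
#' @return A list of class `ccp_value`: `value` in `[0, 1]`, `edge_pixels`,
#'   `area_pixels`, `threshold`.
#' @export
ccp <- function(image, mask, threshold = 0.15) {
  mask <- validate_mask(mask)
  edges <- sobel_edges(image, mask, threshold)
  area <- sum(mask)
  structure(list(value = sum(edges) / area,
                 edge_pixels = sum(edges), area_pixels = area,
                 threshold = threshold),
            class = "ccp_value")
}

#' @export
print.ccp_value <- function(x, ...) {
  cat(sprintf("CCP %.4f (%d edge px / %d nucleus px, threshold %.2f)\n",
              x$value, x$edge_pixels, x$area_pixels, x$threshold))
  invisible(x)
}
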