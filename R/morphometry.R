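# Projection and mask-based morphometrics: area and the width/length
# eccentricity ratio.

#' Maximum-intensity projection of a Z-stack
#'
#' Per-pixel maximum over the slices of a `rows x cols x slices` array; a 2D
#' image passes through unchanged. Idempotent and invariant under slice
#' permutation.
#'
#' @param stack 2D matrix or 3D array of intensities.
#' @return A 2D matrix.
#' @export
project_max <- function(stack) {
  d <- dim(stack)
  if (is.null(d) || length(d) < 2L) stop("not an image", call. = FALSE)
  if (length(d) == 2L) return(stack)
  if (d[3] == 0L) stop("empty stack", call. = FALSE)
  out <- stack[, , 1]
  for (k in seq_len(d[3])[-1]) out <- pmax(out, stack[, , k])
  out
}

validate_mask <- function(mask, min_pixels = 1L) {
  stopifnot(is.matrix(mask))
  if (!is.logical(mask)) mask <- mask > 0.5
  n <- sum(mask)
  if (n < min_pixels) {
    stop(sprintf("mask has %d pixels; >= %d required", n, min_pixels),
         call. = FALSE)
  }
  mask
}

#' Region area from a binary mask
#'
#' @param mask Logical matrix (the region of interest).
#' @param pixel_size Pixel edge length in um/px.
#' @return List with `area_px` (pixel count) and `area_um2`.
#' @export
region_area <- function(mask, pixel_size = 1) {
  mask <- validate_mask(mask)
  stopifnot(pixel_size > 0)
  n <- sum(mask)
  list(area_px = n, area_um2 = n * pixel_size^2)
}

#' Width/length eccentricity ratio of a region
#'
#' The ratio of minor to major axis length of the moment-equivalent ellipse
#' (second central moments of the pixel coordinates). Values near 1 indicate
#' a round region; values towards 0 an elongated one.
#'
#' Note this is the width-over-length convention used in cell-shape work,
#' **not** the standard ellipse eccentricity `sqrt(1 - b^2/a^2)` (which is 0
#' for a circle). The two conventions run in opposite directions.
#'
#' @param mask Logical matrix with at least 5 pixels.
#' @return List with `ratio` in `(0, 1]`, `major_px`, `minor_px` (full axis
#'   lengths of the equivalent ellipse), `orientation` (radians in
#'   `[0, pi)`), and `centroid` (`c(row, col)`, pixel centres).
#' @export
eccentricity_ratio <- function(mask) {
  mask <- validate_mask(mask, min_pixels = 5L)
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  my <- mean(y); mx <- mean(x)
  # second central moments of the pixel-centre point set
  mu20 <- mean((x - mx)^2)
  mu02 <- mean((y - my)^2)
  mu11 <- mean((x - mx) * (y - my))
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l2 <= 1e-12) stop("degenerate (collinear) mask", call. = FALSE)
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  list(ratio = sqrt(l2 / l1),
       major_px = 4 * sqrt(l1), minor_px = 4 * sqrt(l2),
       orientation = ang %% pi,
       centroid = c(row = my, col = mx))
}

#' Morphometrics of one region
#'
#' Convenience wrapper returning area and eccentricity together.
#'
#' @inheritParams region_area
#' @return Tibble with one row: `area_px`, `area_um2`, `eccentricity`,
#'   `centroid_row`, `centroid_col`.
#' @export
morphometrics <- function(mask, pixel_size = 1) {
  ar <- region_area(mask, pixel_size)
  ec <- eccentricity_ratio(mask)
  tibble::tibble(area_px = ar$area_px, area_um2 = ar$area_um2,
                 eccentricity = ec$ratio,
                 centroid_row = ec$centroid[["row"]],
                 centroid_col = ec$centroid[["col"]])
}

#' Heuristic segmentation fallback
#'
#' Otsu threshold, largest connected component, hole fill. Intended for real
#' micrographs where no ground-truth mask exists; synthetic data should use
#' the generator's mask. Treat the result as a heuristic, not a measurement.
#'
#' @param image 2D intensity matrix on `[0, 1]`.
#' @return Logical mask.
#' @export
segment_otsu <- function(image) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("segment_otsu requires the EBImage package", call. = FALSE)
  }
  thr <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  bw <- image > thr
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  tab <- tabulate(as.integer(lab[lab > 0]))
  if (length(tab) == 0L) stop("no foreground found", call. = FALSE)
  keep <- which.max(tab)
  filled <- EBImage::fillHull(EBImage::Image((lab == keep) * 1))
  matrix(as.logical(filled > 0.5), nrow(image), ncol(image))
}
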