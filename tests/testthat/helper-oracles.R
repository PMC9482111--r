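# Independent brute-force oracles and fixture builders. These deliberately
# share no code with the package internals they check.

# Naive nematic tensor: explicit double loop, central differences with
# replicated borders, squared-magnitude weighting, 1e-6*range floor.
naive_nematic <- function(img, mask = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  floor_mag <- 1e-6 * (max(img) - min(img))
  sxx <- syy <- sxy <- 0
  n_used <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      jp <- min(j + 1L, nc); jm <- max(j - 1L, 1L)
      ip <- min(i + 1L, nr); im <- max(i - 1L, 1L)
      gx <- (img[i, jp] - img[i, jm]) / 2
      gy <- (img[ip, j] - img[im, j]) / 2
      mag <- sqrt(gx^2 + gy^2)
      if (mag < floor_mag || mag == 0) next
      # fibril direction perpendicular to gradient, weight |g|^2
      ux <- -gy / mag; uy <- gx / mag
      w <- mag^2
      sxx <- sxx + w * ux * ux
      syy <- syy + w * uy * uy
      sxy <- sxy + w * ux * uy
      n_used <- n_used + 1L
    }
  }
  tr <- sxx + syy
  if (tr == 0) return(list(nxx = 0.5, nyy = 0.5, nxy = 0, n_pixels = 0L))
  list(nxx = sxx / tr, nyy = syy / tr, nxy = sxy / tr, n_pixels = n_used)
}

# Naive 3x3 Sobel magnitude, replicated borders, explicit loops.
naive_sobel <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      sx <- 0; sy <- 0
      for (di in -1:1) {
        for (dj in -1:1) {
          ii <- min(max(i + di, 1L), nr)
          jj <- min(max(j + dj, 1L), nc)
          sx <- sx + kx[di + 2, dj + 2] * img[ii, jj]
          sy <- sy + ky[di + 2, dj + 2] * img[ii, jj]
        }
      }
      out[i, j] <- sqrt(sx^2 + sy^2)
    }
  }
  out
}

# Sinusoidal stripe pattern with wavefronts perpendicular to `angle`, i.e.
# the stripes (the fibril-like ridges) run along `angle`.
stripe_image <- function(n, angle, period = 8) {
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)
  0.5 + 0.5 * sin(2 * pi * (x * cos(angle + pi / 2) +
                              y * sin(angle + pi / 2)) / period)
}

# Filled ellipse mask rotated by `angle`, built from the analytic inequality.
rotated_ellipse_mask <- function(n, a, b, angle) {
  cx <- n / 2 + 0.5; cy <- n / 2 + 0.5
  x <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  y <- matrix(seq_len(n), n, n) - cy
  u <- x * cos(angle) + y * sin(angle)
  v <- -x * sin(angle) + y * cos(angle)
  (u^2 / a^2 + v^2 / b^2) <= 1
}

# Small-scale study configuration used across tests; exercises the default
# effect template at reduced canvas and replication.
test_config <- function(n_cells = 4, n_nuclei = 4, ...) {
  study_config(
    n_cells = n_cells, n_nuclei = n_nuclei,
    canvas = c(128, 128), nucleus_canvas = c(96, 96),
    cell = cell_phantom(semi_major = 45, semi_minor = 32, n_fibres = 60,
                        fibre_width = 2, noise_sd = 0.02),
    nucleus = nucleus_phantom(semi_major = 26, semi_minor = 19,
                              focus_radius = 3, noise_sd = 0.02),
    ...)
}

# Pull one pairwise comparison row from a compare_study() table.
pairwise_row <- function(cc, metric, timepoint, a, b) {
  cc[cc$metric == metric & cc$timepoint == timepoint &
       ((cc$group_a == a & cc$group_b == b) |
          (cc$group_a == b & cc$group_b == a)), ]
}
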