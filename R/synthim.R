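# Seeded generator of ground-truthed synthetic fluorescence micrographs:
# elliptical cells carrying oriented fibre texture (cytoskeleton channel) and
# nuclei carrying punctate heterochromatin foci (DNA channel), arranged in a
# 3-group x 3-timepoint loading design.

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` degenerates to the uniform
#' distribution on `[0, 2*pi)`; `kappa = Inf` returns `mu` exactly.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration parameter (>= 0).
#' @return Angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  if (is.infinite(kappa)) return(rep(mu %% (2 * pi), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    nk <- sum(keep)
    if (nk > 0) {
      u3 <- stats::runif(nk)
      theta <- sign(u3 - 0.5) * acos(f[keep]) + mu
      out[(got + 1):(got + nk)] <- theta
      got <- got + nk
    }
  }
  out %% (2 * pi)
}

#' Sample axial fibre orientations
#'
#' Fibres have no polarity, so orientations live on `[0, pi)`. Sampling uses
#' the doubled-angle device: `theta = vonMises(2*mu, kappa) / 2`.
#'
#' @inheritParams rvonmises
#' @param mu Mean orientation in radians (axial, period `pi`).
#' @return Orientations in `[0, pi)`.
#' @export
raxial <- function(n, mu, kappa) {
  (rvonmises(n, 2 * mu, kappa) / 2) %% pi
}

#' Phantom parameter records
#'
#' `cell_phantom()` parameterises an elliptical cell whose cytoskeleton
#' channel carries straight fibre segments with von Mises-distributed axial
#' orientations; `nucleus_phantom()` parameterises an elliptical nucleus with
#' bright heterochromatin foci over a uniform euchromatin background.
#' Lengths are in pixels, intensities on `[0, 1]`.
#'
#' @param semi_major,semi_minor Ellipse semi-axes in px (`semi_minor <=
#'   semi_major`).
#' @param n_fibres Number of fibre segments.
#' @param orientation_kappa von Mises concentration of fibre orientations
#'   (0 = isotropic; `Inf` = perfectly parallel).
#' @param mean_orientation Mean fibre orientation in radians.
#' @param fibre_width Full width of the Gaussian fibre profile in px.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units; the image is clipped back to `[0, 1]`).
#' @return A parameter list of class `cell_phantom` / `nucleus_phantom`.
#' @export
cell_phantom <- function(semi_major = 180, semi_minor = 120, n_fibres = 140,
                         orientation_kappa = 1, mean_orientation = 0,
                         fibre_width = 3, noise_sd = 0.02) {
  stopifnot(semi_major > 0, semi_minor > 0, semi_minor <= semi_major,
            n_fibres >= 0, orientation_kappa >= 0, fibre_width > 0,
            noise_sd >= 0)
  structure(list(semi_major = semi_major, semi_minor = semi_minor,
                 n_fibres = n_fibres, orientation_kappa = orientation_kappa,
                 mean_orientation = mean_orientation,
                 fibre_width = fibre_width, noise_sd = noise_sd),
            class = "cell_phantom")
}

#' @rdname cell_phantom
#' @param n_foci Number of heterochromatin foci.
#' @param focus_radius Focus disc radius in px.
#' @param focus_contrast Focus brightness as a fraction above the nuclear
#'   background (>= 0).
#' @export
nucleus_phantom <- function(semi_major = 60, semi_minor = 45, n_foci = 8,
                            focus_radius = 5, focus_contrast = 0.8,
                            noise_sd = 0.02) {
  stopifnot(semi_major > 0, semi_minor > 0, semi_minor <= semi_major,
            n_foci >= 0, focus_radius > 0, focus_contrast >= 0, noise_sd >= 0)
  structure(list(semi_major = semi_major, semi_minor = semi_minor,
                 n_foci = n_foci, focus_radius = focus_radius,
                 focus_contrast = focus_contrast, noise_sd = noise_sd),
            class = "nucleus_phantom")
}

# Filled ellipse mask on an nr x nc canvas, pixel-centre convention.
ellipse_mask <- function(nr, nc, cy, cx, a, b) {
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  y <- matrix(seq_len(nr), nr, nc)
  ((x - cx)^2 / a^2 + (y - cy)^2 / b^2) <= 1
}

# Uniform points inside an axis-aligned ellipse centred at (cy, cx).
runif_ellipse <- function(n, cy, cx, a, b) {
  u <- sqrt(stats::runif(n))
  t <- stats::runif(n, 0, 2 * pi)
  cbind(y = cy + u * b * sin(t), x = cx + u * a * cos(t))
}

# Additively splat one line segment with a Gaussian cross-profile into `acc`.
splat_segment <- function(acc, y0, x0, theta, len, sigma) {
  nr <- nrow(acc); nc <- ncol(acc)
  dx <- cos(theta); dy <- sin(theta)
  x1 <- x0 - dx * len / 2; y1 <- y0 - dy * len / 2
  x2 <- x0 + dx * len / 2; y2 <- y0 + dy * len / 2
  pad <- ceiling(2.5 * sigma) + 1
  xr <- max(1L, floor(min(x1, x2) - pad)):min(nc, ceiling(max(x1, x2) + pad))
  yr <- max(1L, floor(min(y1, y2) - pad)):min(nr, ceiling(max(y1, y2) + pad))
  if (length(xr) == 0L || length(yr) == 0L) return(acc)
  px <- matrix(xr, length(yr), length(xr), byrow = TRUE)
  py <- matrix(yr, length(yr), length(xr))
  # point-to-segment distance
  vx <- x2 - x1; vy <- y2 - y1
  l2 <- vx^2 + vy^2
  tt <- if (l2 == 0) 0 else pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / l2))
  d2 <- (px - (x1 + tt * vx))^2 + (py - (y1 + tt * vy))^2
  acc[yr, xr] <- acc[yr, xr] + exp(-d2 / (2 * sigma^2))
  acc
}

#' Render a synthetic cytoskeleton-channel cell image
#'
#' Draws an elliptical cell whose interior carries `n_fibres` straight,
#' Gaussian-profile fibre segments with orientations sampled from an axial
#' von Mises distribution, clips the texture to the cell mask, soft-saturates
#' overlapping fibres and adds clipped Gaussian noise. Deterministic for a
#' given `(params, seed, canvas)`.
#'
#' @param params A [cell_phantom()].
#' @param seed Integer seed.
#' @param canvas Canvas size `c(rows, cols)` in px (default 512 x 512).
#' @param pixel_size_um Pixel size recorded in the result (um/px).
#' @return A list with `image` (matrix in `[0, 1]`), `mask` (logical matrix),
#'   `orientations` (the sampled fibre angles), `pixel_size_um`,
#'   `channel_role`.
#' @export
render_cell <- function(params, seed, canvas = c(512, 512),
                        pixel_size_um = 0.1) {
  stopifnot(inherits(params, "cell_phantom"), length(canvas) == 2L)
  nr <- canvas[1]; nc <- canvas[2]
  if (2 * params$semi_major > min(nr, nc)) {
    stop("cell phantom larger than canvas", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    cy <- nr / 2 + 0.5; cx <- nc / 2 + 0.5
    x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    y <- matrix(seq_len(nr), nr, nc)
    rho <- sqrt((x - cx)^2 / params$semi_major^2 +
                  (y - cy)^2 / params$semi_minor^2)
    mask <- rho <= 1
    # intensity tapers to zero just OUTSIDE the mask so the cell outline
    # contributes no sharp gradient inside the analysis region
    win <- pmin(pmax((1.12 - rho) / 0.12, 0), 1)
    acc <- matrix(0, nr, nc)
    if (params$n_fibres > 0) {
      th <- raxial(params$n_fibres, params$mean_orientation,
                   params$orientation_kappa)
      ctr <- runif_ellipse(params$n_fibres, cy, cx,
                           0.9 * params$semi_major, 0.9 * params$semi_minor)
      # stress fibres span the cell; few end caps land inside the mask
      len <- stats::runif(params$n_fibres, 1.2, 2.0) * params$semi_major
      sigma <- params$fibre_width / 2
      for (i in seq_len(params$n_fibres)) {
        acc <- splat_segment(acc, ctr[i, "y"], ctr[i, "x"], th[i],
                             len[i], sigma)
      }
    } else {
      th <- numeric(0)
    }
    img <- win * (0.08 + 0.9 * (1 - exp(-acc)))
    if (params$noise_sd > 0) {
      img <- img + stats::rnorm(nr * nc, 0, params$noise_sd)
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = mask, orientations = th,
         pixel_size_um = pixel_size_um, channel_role = "cytoskeleton")
  })
}

#' Render a synthetic DNA-channel nucleus image
#'
#' Draws an elliptical nucleus with uniform euchromatin background and
#' `n_foci` bright anti-aliased heterochromatin discs at `focus_contrast`
#' above background, plus clipped Gaussian noise. Deterministic for a given
#' `(params, seed, canvas)`.
#'
#' @param params A [nucleus_phantom()].
#' @inheritParams render_cell
#' @return As [render_cell()], with `foci` (centre coordinates) instead of
#'   `orientations` and `channel_role = "nucleus"`.
#' @export
render_nucleus <- function(params, seed, canvas = c(512, 512),
                           pixel_size_um = 0.1) {
  stopifnot(inherits(params, "nucleus_phantom"), length(canvas) == 2L)
  nr <- canvas[1]; nc <- canvas[2]
  if (2 * params$semi_major > min(nr, nc)) {
    stop("nucleus phantom larger than canvas", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    cy <- nr / 2 + 0.5; cx <- nc / 2 + 0.5
    mask <- ellipse_mask(nr, nc, cy, cx, params$semi_major, params$semi_minor)
    bg <- 0.45
    prof <- matrix(0, nr, nc)
    ctr <- if (params$n_foci > 0) {
      runif_ellipse(params$n_foci, cy, cx,
                    0.85 * params$semi_major, 0.85 * params$semi_minor)
    } else {
      matrix(numeric(0), 0, 2, dimnames = list(NULL, c("y", "x")))
    }
    if (params$n_foci > 0) {
      x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      y <- matrix(seq_len(nr), nr, nc)
      for (i in seq_len(params$n_foci)) {
        d <- sqrt((x - ctr[i, "x"])^2 + (y - ctr[i, "y"])^2)
        # 1 px anti-aliased rim; overlapping foci merge by max, not sum
        prof <- pmax(prof, pmin(1, pmax(0, params$focus_radius + 0.5 - d)))
      }
    }
    img <- bg * (1 + params$focus_contrast * prof) * mask
    if (params$noise_sd > 0) {
      img <- img + stats::rnorm(nr * nc, 0, params$noise_sd)
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = mask, foci = ctr,
         pixel_size_um = pixel_size_um, channel_role = "nucleus")
  })
}

#' Study design configuration for the synthetic generator
#'
#' Encodes the loading experiment the generator emulates: three groups
#' (unloaded control, physiological strain, pathological strain) crossed with
#' three post-cessation fixation timepoints (1 h, 6 h, 24 h). Group effects
#' enter through two per-(group, timepoint) tables: `kappa_table` sets the
#' fibre orientation concentration of the cell channel (driving measured
#' anisotropy) and `foci_table` sets the heterochromatin focus count of the
#' nucleus channel (driving the measured chromatin condensation parameter).
#'
#' The default tables encode the experiment's qualitative time-course:
#' a strong but transient fibre-alignment response to physiological strain
#' (peaking at 1 h, decayed by 24 h), a delayed alignment response to
#' pathological strain (near-basal at 1 h and 6 h, high at 24 h), and
#' chromatin condensation that is mildly and transiently elevated after
#' physiological strain but strongly elevated at 1 h and 6 h after
#' pathological strain, decaying towards (while remaining above) baseline by
#' 24 h.
#'
#' @param n_per_cell Images per (group, timepoint) cell of the design
#'   (default 10; must be >= 2). Used for both channels unless overridden.
#' @param n_cells,n_nuclei Per-channel replication. Real acquisitions
#'   typically yield roughly twice as many measurable nuclei as whole cells
#'   (every DAPI nucleus is scored, not only the cells selected for
#'   cytoskeletal imaging), so the two counts are configurable separately.
#' @param canvas Canvas size in px for cell images.
#' @param nucleus_canvas Canvas for nucleus images (defaults to `canvas`;
#'   nuclei are much smaller than cells and are usually cropped tighter).
#' @param pixel_size_um Pixel size metadata (um/px).
#' @param bit_depth TIFF bit depth, 8 or 16.
#' @param z_slices 1 for single-plane TIFFs, or a slice count (e.g. 8) to
#'   emit Z-stacks whose maximum-intensity projection equals the single-plane
#'   render.
#' @param cell,nucleus Baseline phantom parameter lists ([cell_phantom()],
#'   [nucleus_phantom()]); per-image geometry is jittered by `geom_jitter`.
#' @param geom_jitter Relative s.d. of per-image semi-axis jitter.
#' @param kappa_table,foci_table 3 x 3 numeric matrices (rows: unloaded,
#'   physiological, pathological; columns: 1h, 6h, 24h).
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_per_cell = 10,
                         n_cells = n_per_cell,
                         n_nuclei = n_per_cell,
                         canvas = c(512, 512),
                         nucleus_canvas = canvas,
                         pixel_size_um = 0.1,
                         bit_depth = 16,
                         z_slices = 1,
                         cell = cell_phantom(),
                         nucleus = nucleus_phantom(),
                         geom_jitter = 0.08,
                         kappa_table = NULL,
                         foci_table = NULL) {
  groups <- c("unloaded", "physiological", "pathological")
  timepoints <- c("1h", "6h", "24h")
  if (is.null(kappa_table)) {
    kappa_table <- rbind(unloaded      = c(0.5, 0.5, 0.5),
                         physiological = c(4.0, 2.0, 0.6),
                         pathological  = c(0.5, 0.7, 3.0))
  }
  if (is.null(foci_table)) {
    foci_table <- rbind(unloaded      = c(8, 8, 8),
                        physiological = c(10, 8, 8),
                        pathological  = c(28, 26, 10))
  }
  colnames(kappa_table) <- colnames(foci_table) <- timepoints
  stopifnot(n_cells >= 2, n_nuclei >= 2, bit_depth %in% c(8, 16),
            z_slices >= 1,
            all(dim(kappa_table) == c(3, 3)), all(dim(foci_table) == c(3, 3)))
  structure(list(groups = groups, timepoints = timepoints,
                 n_cells = n_cells, n_nuclei = n_nuclei, canvas = canvas,
                 nucleus_canvas = nucleus_canvas,
                 pixel_size_um = pixel_size_um, bit_depth = bit_depth,
                 z_slices = z_slices, cell = cell, nucleus = nucleus,
                 geom_jitter = geom_jitter, kappa_table = kappa_table,
                 foci_table = foci_table),
            class = "study_config")
}

# Expand a single-plane image into a z_slices stack whose per-pixel maximum
# reproduces the plane (triangular slice weighting peaking at the mid slice).
as_zstack <- function(img, z_slices) {
  if (z_slices == 1L) return(img)
  w <- 1 - abs(seq_len(z_slices) - (z_slices + 1) / 2) / z_slices
  w <- w / max(w)
  array(vapply(w, function(wi) img * wi, img), c(dim(img), z_slices))
}

#' Generate a full synthetic loading study
#'
#' Renders one cell image and one nucleus image per design row (group x
#' timepoint x replicate), assigns wells and plates cyclically, and returns
#' the design table together with the per-image generator ground truth.
#' Byte-identical outputs are produced for identical `(config, seed)`.
#'
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @param out_dir If non-`NULL`, TIFF images/masks plus `design.csv` and
#'   `truth.csv` are written there; otherwise images stay in memory.
#' @return A list with `design` (tibble: image_id, group, timepoint, well,
#'   plate, channel), `truth` (tibble of generator parameters per image), and
#'   `images` (named list of render results; `NULL` fields for the written
#'   case are retained so downstream code never re-reads what it has).
#' @export
generate_study <- function(config = study_config(), seed = 1, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  seed <- as.integer(seed)
  grid <- expand.grid(rep = seq_len(max(config$n_cells, config$n_nuclei)),
                      timepoint = config$timepoints,
                      group = config$groups,
                      stringsAsFactors = FALSE)
  design <- list(); truth <- list(); images <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid$group[i]; tp <- grid$timepoint[i]; rep_i <- grid$rep[i]
    well <- sprintf("w%d", ((rep_i - 1L) %% 3L) + 1L)
    plate <- sprintf("p%d", (((rep_i - 1L) %/% 3L) %% 3L) + 1L)
    base_id <- sprintf("%s_%s_r%02d", g, tp, rep_i)
    # derived per-image seeds; kept well below .Machine$integer.max
    seed_i <- (seed + i * 7919L) %% 2100000000L
    kappa <- config$kappa_table[g, tp]
    nfoci <- config$foci_table[g, tp]
    jit <- withr::with_seed(seed_i, {
      list(cell = stats::rnorm(2, 1, config$geom_jitter),
           nuc = stats::rnorm(2, 1, config$geom_jitter),
           ori = stats::runif(1, 0, pi))
    })
    if (rep_i <= config$n_cells) {
      cp <- config$cell
      a <- cp$semi_major * max(0.7, jit$cell[1])
      b <- min(cp$semi_minor * max(0.7, jit$cell[2]), a)
      cellp <- cell_phantom(semi_major = a, semi_minor = b,
                            n_fibres = cp$n_fibres, orientation_kappa = kappa,
                            mean_orientation = jit$ori,
                            fibre_width = cp$fibre_width,
                            noise_sd = cp$noise_sd)
      id <- paste0(base_id, "_cell")
      images[[id]] <- render_cell(cellp, seed_i + 1L, config$canvas,
                                  config$pixel_size_um)
      design[[id]] <- tibble::tibble(image_id = id, group = g,
                                     timepoint = tp, well = well,
                                     plate = plate, channel = "cytoskeleton")
      truth[[id]] <- tibble::tibble(
        image_id = id, group = g, timepoint = tp, channel = "cytoskeleton",
        semi_major = cellp$semi_major, semi_minor = cellp$semi_minor,
        orientation_kappa = kappa,
        mean_orientation = cellp$mean_orientation,
        n_fibres = cp$n_fibres, n_foci = NA_integer_,
        noise_sd = cp$noise_sd)
    }
    if (rep_i <= config$n_nuclei) {
      np <- config$nucleus
      an <- np$semi_major * max(0.7, jit$nuc[1])
      bn <- min(np$semi_minor * max(0.7, jit$nuc[2]), an)
      nucp <- nucleus_phantom(semi_major = an, semi_minor = bn,
                              n_foci = nfoci,
                              focus_radius = np$focus_radius,
                              focus_contrast = np$focus_contrast,
                              noise_sd = np$noise_sd)
      id <- paste0(base_id, "_nuc")
      images[[id]] <- render_nucleus(nucp, seed_i + 2L,
                                     config$nucleus_canvas,
                                     config$pixel_size_um)
      design[[id]] <- tibble::tibble(image_id = id, group = g,
                                     timepoint = tp, well = well,
                                     plate = plate, channel = "nucleus")
      truth[[id]] <- tibble::tibble(
        image_id = id, group = g, timepoint = tp, channel = "nucleus",
        semi_major = nucp$semi_major, semi_minor = nucp$semi_minor,
        orientation_kappa = NA_real_, mean_orientation = NA_real_,
        n_fibres = NA_integer_, n_foci = nfoci,
        noise_sd = np$noise_sd)
    }
  }
  nm <- names(images)
  design <- do.call(rbind, design)
  truth <- do.call(rbind, truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in nm) {
      img <- as_zstack(images[[id]]$image, config$z_slices)
      write_micrograph(img, file.path(out_dir, paste0(id, ".tif")),
                       bits = config$bit_depth)
      write_micrograph(images[[id]]$mask * 1,
                       file.path(out_dir, paste0(id, "_mask.tif")), bits = 8)
    }
    utils::write.csv(design, file.path(out_dir, "design.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  list(design = design, truth = truth, images = images)
}
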