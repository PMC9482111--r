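# End-to-end orchestration: simulate (or load) -> project -> measure
# (morphometry, anisotropy, CCP) -> gated statistics, with a manifest
# recording config, seed, row counts and output checksums.

#' Measure one projected image
#'
#' Applies the metrics appropriate to the channel role: area and
#' eccentricity for both channels, fibre anisotropy for the cytoskeleton
#' channel, CCP for the nucleus channel.
#'
#' @param image 2D matrix or 3D stack (projected internally).
#' @param mask Logical region mask.
#' @param channel `"cytoskeleton"` or `"nucleus"`.
#' @param pixel_size_um Pixel size in um/px.
#' @param ccp_threshold Relative Sobel threshold for [ccp()].
#' @return Tibble with columns `metric`, `value`.
#' @export
measure_image <- function(image, mask, channel = c("cytoskeleton", "nucleus"),
                          pixel_size_um = 0.1, ccp_threshold = 0.15) {
  channel <- match.arg(channel)
  img <- project_max(image)
  m <- morphometrics(mask, pixel_size_um)
  out <- tibble::tibble(
    metric = c("area_um2", "area_px", "eccentricity"),
    value = c(m$area_um2, m$area_px, m$eccentricity))
  if (channel == "cytoskeleton") {
    a <- fibre_anisotropy(img, mask)
    out <- rbind(out, tibble::tibble(metric = "anisotropy", value = a$value))
  } else {
    cv <- ccp(img, mask, ccp_threshold)
    out <- rbind(out, tibble::tibble(metric = "ccp", value = cv$value))
  }
  out
}

#' Measure every image of a generated or loaded study
#'
#' @param study A list as returned by [generate_study()] (`design` +
#'   `images`), or by [load_study()].
#' @inheritParams measure_image
#' @return Tidy tibble: image_id, group, timepoint, well, plate, channel,
#'   metric, value. Images whose measurement fails are skipped with a
#'   warning and reported in the `skipped` attribute.
#' @export
measure_study <- function(study, ccp_threshold = 0.15) {
  design <- study$design
  rows <- vector("list", nrow(design))
  skipped <- character(0)
  for (i in seq_len(nrow(design))) {
    id <- design$image_id[i]
    rec <- study$images[[id]]
    res <- tryCatch(
      measure_image(rec$image, rec$mask, design$channel[i],
                    rec$pixel_size_um, ccp_threshold),
      error = function(e) {
        warning(sprintf("skipping %s: %s", id, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) {
      skipped <- c(skipped, id)
      next
    }
    rows[[i]] <- cbind(design[i, ], res)
  }
  out <- do.call(rbind, rows)
  out <- tibble::as_tibble(out)
  attr(out, "skipped") <- skipped
  out
}

#' Load a study written by [generate_study()] from disk
#'
#' Reads `design.csv` and the image/mask TIFF pairs; multi-page TIFFs come
#' back as stacks and are projected at measurement time.
#'
#' @param dir Directory containing `design.csv` and the TIFFs.
#' @param pixel_size_um Pixel size metadata to attach (um/px).
#' @return A list with `design` and `images`, as [generate_study()].
#' @export
load_study <- function(dir, pixel_size_um = 0.1) {
  design <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "design.csv"), stringsAsFactors = FALSE))
  images <- list()
  for (i in seq_len(nrow(design))) {
    id <- design$image_id[i]
    img_path <- file.path(dir, paste0(id, ".tif"))
    mask_path <- file.path(dir, paste0(id, "_mask.tif"))
    if (!file.exists(img_path) || !file.exists(mask_path)) {
      warning(sprintf("missing files for %s; row will be skipped", id),
              call. = FALSE)
      images[[id]] <- NULL
      next
    }
    images[[id]] <- list(image = read_micrograph(img_path),
                         mask = read_mask(mask_path),
                         pixel_size_um = pixel_size_um,
                         channel_role = design$channel[i])
  }
  list(design = design, images = images)
}

#' Compare groups for every (metric, timepoint) family
#'
#' @param measurements Tidy measurement tibble from [measure_study()].
#' @param metrics Metrics to test (default: anisotropy, ccp, area_um2,
#'   eccentricity, intersected with what is present).
#' @inheritParams compare_groups
#' @return A list: `comparisons` (tibble, one row per pairwise comparison
#'   with omnibus columns repeated) and `objects` (named list of
#'   `group_comparison` results, keyed `metric@timepoint`).
#' @export
compare_study <- function(measurements, metrics = NULL, alpha = 0.05,
                          alpha_gate = 0.05) {
  if (is.null(metrics)) {
    metrics <- intersect(c("anisotropy", "ccp", "area_um2", "eccentricity"),
                         unique(measurements$metric))
  }
  objects <- list()
  rows <- list()
  for (met in metrics) {
    for (tp in unique(measurements$timepoint)) {
      sub <- measurements[measurements$metric == met &
                            measurements$timepoint == tp, ]
      if (nrow(sub) == 0L) next
      cmp <- compare_groups(sub$value, sub$group, alpha = alpha,
                            alpha_gate = alpha_gate)
      key <- paste0(met, "@", tp)
      objects[[key]] <- cmp
      rows[[key]] <- cbind(tibble::tibble(metric = met, timepoint = tp,
                                          gate = cmp$gate,
                                          omnibus_stat = cmp$omnibus_stat,
                                          omnibus_p = cmp$omnibus_p),
                           cmp$pairwise)
    }
  }
  list(comparisons = tibble::as_tibble(do.call(rbind, rows)),
       objects = objects)
}

# Default bovine ocular loading context reported in run manifests.
default_strain_report <- function() {
  geom <- ocular_geometry(radius = 16.2e-3, wall_thickness = 1.6e-3)
  bands <- lapply(c(physiological = 27, pathological = 60), function(iop) {
    b <- strain_band(loading_regimen(mmhg_to_pascal(iop), 1e6, 7e6), geom)
    sig_lo <- if (iop == 27) 2 else 1  # printed precision per regimen
    list(iop_mmhg = iop, iop_kpa = format_kpa(mmhg_to_pascal(iop)),
         stress_pa = b$stress_pa,
         strain_min_pct = format_percent(b$strain_min, sig_lo),
         strain_max_pct = format_percent(b$strain_max, sig_lo),
         frequency_hz = b$frequency_hz)
  })
  bands
}

#' Run the full synthetic-study pipeline
#'
#' Generates (or loads) a study, measures every image, runs the gated group
#' comparisons per (metric, timepoint) family, and assembles a manifest.
#' Identical `(config, seed)` reproduce identical outputs.
#'
#' @param config A [study_config()], used when `input_dir` is `NULL`.
#' @param seed Integer seed for the generator.
#' @param input_dir Optional directory with a previously written study
#'   (design.csv + TIFFs); overrides simulation.
#' @param out_dir Optional output directory; when given, the study TIFFs (in
#'   simulate mode), `measurements.csv`, `comparisons.csv` and
#'   `manifest.json`-compatible list are written there.
#' @param ccp_threshold Relative Sobel threshold.
#' @return A list of class `study_run`: `measurements`, `comparisons`,
#'   `manifest`, `truth` (simulate mode only).
#' @export
run_pipeline <- function(config = study_config(), seed = 1,
                         input_dir = NULL, out_dir = NULL,
                         ccp_threshold = 0.15) {
  warnings_seen <- character(0)
  wh <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  study <- withCallingHandlers({
    if (is.null(input_dir)) {
      generate_study(config, seed,
                     out_dir = if (is.null(out_dir)) NULL else
                       file.path(out_dir, "images"))
    } else {
      load_study(input_dir)
    }
  }, warning = wh)
  measurements <- withCallingHandlers(
    measure_study(study, ccp_threshold = ccp_threshold), warning = wh)
  comparisons <- withCallingHandlers(
    compare_study(measurements), warning = wh)
  manifest <- list(
    package_version = as.character(utils::packageVersion("scleromech")),
    seed = seed,
    config_hash = rlang::hash(config),
    ccp_threshold = ccp_threshold,
    n_images = length(study$images),
    n_measurement_rows = nrow(measurements),
    n_comparison_families = length(comparisons$objects),
    n_skipped = length(attr(measurements, "skipped")),
    skipped = attr(measurements, "skipped"),
    warnings = warnings_seen,
    strain_context = default_strain_report())
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    mpath <- file.path(out_dir, "measurements.csv")
    cpath <- file.path(out_dir, "comparisons.csv")
    utils::write.csv(measurements, mpath, row.names = FALSE)
    utils::write.csv(comparisons$comparisons, cpath, row.names = FALSE)
    files <- c(mpath, cpath,
               list.files(file.path(out_dir, "images"), full.names = TRUE))
    files <- files[file.exists(files)]
    manifest$checksums <- as.list(tools::md5sum(files))
  }
  structure(list(measurements = measurements,
                 comparisons = comparisons$comparisons,
                 comparison_objects = comparisons$objects,
                 manifest = manifest,
                 truth = study$truth),
            class = "study_run")
}

#' @export
print.study_run <- function(x, ...) {
  cat(sprintf("Study run: %d images, %d measurement rows, %d families\n",
              x$manifest$n_images, x$manifest$n_measurement_rows,
              x$manifest$n_comparison_families))
  sig <- x$comparisons[x$comparisons$significant, ]
  cat(sprintf("%d significant pairwise comparisons at alpha = 0.05\n",
              nrow(sig)))
  invisible(x)
}
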