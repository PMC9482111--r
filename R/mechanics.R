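# Young-Laplace thin-sphere mechanics: IOP -> in-wall hoop stress -> cyclic
# tensile strain band over a Young's modulus range.

# 1 mmHg in Pa (conventional definition, 13.5951 g/cm3 * 9.80665 m/s2 * 1 mm)
MMHG_TO_PA <- 133.322

#' Convert pressure from mmHg to pascal
#'
#' Intraocular pressure is conventionally reported in mmHg; the Laplace-law
#' stress calculation works in SI units.
#'
#' @param p_mmhg Pressure in mmHg (scalar or vector, non-negative).
#' @return Pressure in Pa.
#' @examples
#' mmhg_to_pascal(27)   # healthy baseline IOP
#' mmhg_to_pascal(60)   # elevated, glaucomatous IOP
#' @seealso [pascal_to_mmhg()], [hoop_stress()]
#' @export
mmhg_to_pascal <- function(p_mmhg) {
  stopifnot(is.numeric(p_mmhg), all(is.finite(p_mmhg)))
  if (any(p_mmhg < 0)) {
    stop("pressure in mmHg must be non-negative", call. = FALSE)
  }
  p_mmhg * MMHG_TO_PA
}

#' @rdname mmhg_to_pascal
#' @param p_pa Pressure in Pa (non-negative).
#' @export
pascal_to_mmhg <- function(p_pa) {
  stopifnot(is.numeric(p_pa), all(is.finite(p_pa)))
  if (any(p_pa < 0)) {
    stop("pressure in Pa must be non-negative", call. = FALSE)
  }
  p_pa / MMHG_TO_PA
}

#' Ocular globe geometry for the thin-sphere stress model
#'
#' @param radius Globe radius in metres.
#' @param wall_thickness Eye tunic (scleral wall) thickness in metres; must be
#'   positive and smaller than the radius for the thin-wall model to apply.
#' @return An object of class `ocular_geometry`.
#' @examples
#' ocular_geometry(radius = 16.2e-3, wall_thickness = 1.6e-3)  # bovine eye
#' @export
ocular_geometry <- function(radius, wall_thickness) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius),
            is.numeric(wall_thickness), length(wall_thickness) == 1L,
            is.finite(wall_thickness))
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (wall_thickness <= 0) stop("wall_thickness must be positive", call. = FALSE)
  if (wall_thickness >= radius) {
    stop("wall_thickness must be smaller than radius", call. = FALSE)
  }
  structure(list(radius = radius, wall_thickness = wall_thickness),
            class = "ocular_geometry")
}

#' @export
print.ocular_geometry <- function(x, ...) {
  cat(sprintf("Ocular geometry: r = %.3g mm, t = %.3g mm\n",
              x$radius * 1e3, x$wall_thickness * 1e3))
  invisible(x)
}

#' Cyclic loading regimen
#'
#' Bundles the intraocular pressure driving the load with the scleral Young's
#' modulus range used to translate stress into strain, and the cyclic waveform
#' metadata (frequency, duration). The waveform itself is applied by loading
#' hardware and is recorded here as metadata only; no time-domain simulation
#' is performed.
#'
#' @param iop Intraocular pressure in Pa.
#' @param modulus_low,modulus_high Lower/upper Young's modulus in Pa
#'   (`0 < modulus_low <= modulus_high`). The range captures the
#'   strain-stiffening of collagenous tissue: the compliant endpoint maps to
#'   the largest strain, the stiff endpoint to the smallest.
#' @param frequency Loading frequency in Hz (default 1, the ocular pulse).
#' @param duration Loading duration in seconds (default 3600).
#' @return An object of class `loading_regimen`.
#' @examples
#' loading_regimen(iop = mmhg_to_pascal(27),
#'                 modulus_low = 1e6, modulus_high = 7e6)
#' @export
loading_regimen <- function(iop, modulus_low, modulus_high,
                            frequency = 1, duration = 3600) {
  stopifnot(is.numeric(iop), length(iop) == 1L, is.finite(iop),
            is.numeric(modulus_low), length(modulus_low) == 1L,
            is.numeric(modulus_high), length(modulus_high) == 1L)
  if (iop < 0) stop("iop must be non-negative", call. = FALSE)
  if (modulus_low <= 0) stop("modulus_low must be positive", call. = FALSE)
  if (modulus_high < modulus_low) {
    stop("modulus_high must be >= modulus_low", call. = FALSE)
  }
  if (frequency <= 0) stop("frequency must be positive", call. = FALSE)
  structure(list(iop = iop, modulus_low = modulus_low,
                 modulus_high = modulus_high, frequency = frequency,
                 duration = duration),
            class = "loading_regimen")
}

#' In-wall hoop stress of a pressurised thin-walled sphere
#'
#' Young-Laplace law for a thin spherical shell: `sigma = p * r / (2 * t)`,
#' the circumferential stress carried by the wall of a sphere of radius `r`
#' and wall thickness `t` under internal pressure `p`.
#'
#' @param p Internal pressure in Pa (non-negative).
#' @param geom An [ocular_geometry()].
#' @return Hoop stress in Pa.
#' @examples
#' geom <- ocular_geometry(16.2e-3, 1.6e-3)
#' hoop_stress(mmhg_to_pascal(27), geom)
#' @export
hoop_stress <- function(p, geom) {
  stopifnot(inherits(geom, "ocular_geometry"), is.numeric(p),
            all(is.finite(p)))
  if (any(p < 0)) stop("pressure must be non-negative", call. = FALSE)
  p * geom$radius / (2 * geom$wall_thickness)
}

#' Cyclic tensile strain band from a loading regimen
#'
#' Divides the Laplace hoop stress by the two Young's modulus endpoints. The
#' stiff endpoint gives the lower strain bound, the compliant endpoint the
#' upper bound, so `strain_min <= strain_max` always.
#'
#' @param regimen A [loading_regimen()].
#' @param geom An [ocular_geometry()].
#' @return A list with `stress_pa`, `strain_min`, `strain_max` (strains as
#'   dimensionless fractions), `frequency_hz`.
#' @examples
#' geom <- ocular_geometry(16.2e-3, 1.6e-3)
#' reg <- loading_regimen(mmhg_to_pascal(27), 1e6, 7e6)
#' band <- strain_band(reg, geom)
#' format_percent(c(band$strain_min, band$strain_max))
#' @export
strain_band <- function(regimen, geom) {
  stopifnot(inherits(regimen, "loading_regimen"))
  sigma <- hoop_stress(regimen$iop, geom)
  list(stress_pa = sigma,
       strain_min = sigma / regimen$modulus_high,
       strain_max = sigma / regimen$modulus_low,
       frequency_hz = regimen$frequency)
}

#' Report a strain fraction in percent at a fixed number of significant figures
#'
#' @param x Strain as a dimensionless fraction.
#' @param sig Significant figures (default 2, the reporting convention for the
#'   physiological band; the pathological band is conventionally printed at 1).
#' @return Numeric percent value rounded to `sig` significant figures.
#' @export
format_percent <- function(x, sig = 2) {
  signif(100 * x, sig)
}

#' @rdname format_percent
#' @param p_pa Pressure in Pa.
#' @return `format_kpa`: pressure in kPa at `sig` significant figures.
#' @export
format_kpa <- function(p_pa, sig = 2) {
  signif(p_pa / 1000, sig)
}
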