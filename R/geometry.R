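#' Tumor cell count from diameter
#'
#' Converts a tumor diameter to a cell count using the thin-disc geometry:
#' a circular tumor patch three cell layers deep (cell length ~10 um) at
#' tissue density `1e6` cells per cubic millimetre, i.e.
#' `cells = pi (d/2)^2 h density`.
#'
#' @param diameter_mm tumor diameter \[mm\], `>= 0` (vectorized).
#' @param depth_mm tumor depth \[mm\]; default `3e-2` (3 layers x 10 um).
#' @param density_cells_mm3 cells per mm^3; default `1e6`.
#' @return Cell count.
#' @examples
#' cells_from_diameter(15)    # "small"  tumor, ~5.3e6 cells
#' cells_from_diameter(20.6)  # "medium" tumor, ~1e7 cells
#' @export
cells_from_diameter <- function(diameter_mm, depth_mm = 3e-2,
                                density_cells_mm3 = 1e6) {
  if (any(diameter_mm < 0)) stop("diameter must be >= 0")
  cells_from_radius(diameter_mm / 2, depth_mm, density_cells_mm3)
}

#' Tumor cell count from radius
#'
#' Radius form of [cells_from_diameter()].
#'
#' @param radius_mm tumor radius \[mm\], `>= 0` (vectorized).
#' @inheritParams cells_from_diameter
#' @return Cell count.
#' @export
cells_from_radius <- function(radius_mm, depth_mm = 3e-2,
                              density_cells_mm3 = 1e6) {
  if (any(radius_mm < 0)) stop("radius must be >= 0")
  pi * radius_mm^2 * depth_mm * density_cells_mm3
}

#' Tumor diameter from cell count
#'
#' Inverse of [cells_from_diameter()]:
#' `d = 2 sqrt(cells / (pi h density))`.
#'
#' @param cells cell count, `>= 0` (vectorized).
#' @inheritParams cells_from_diameter
#' @return Diameter \[mm\].
#' @export
diameter_from_cells <- function(cells, depth_mm = 3e-2,
                                density_cells_mm3 = 1e6) {
  if (any(cells < 0)) stop("cells must be >= 0")
  2 * sqrt(cells / (pi * depth_mm * density_cells_mm3))
}

#' Intravesical dose to molar amount
#'
#' Converts an instilled dose in mg over a carrier volume to micromolar:
#' `(dose_mg / volume_ml) / mw`, expressed in umol/L.  The standard MMC
#' protocol (40 mg in 50 ml, molecular weight 334 g/mol) gives ~2,395 uM.
#'
#' @param dose_mg instilled drug mass \[mg\].
#' @param volume_ml carrier volume \[ml\]; default 50.
#' @param mw molecular weight \[g/mol\]; default 334 (MMC).
#' @return Drug amount \[uM\].
#' @export
dose_to_molar <- function(dose_mg, volume_ml = 50, mw = 334) {
  if (any(dose_mg < 0)) stop("dose must be >= 0")
  if (volume_ml <= 0 || mw <= 0) stop("volume and mw must be > 0")
  # mg/ml = g/L; /(g/mol) = mol/L; *1e6 = umol/L
  (dose_mg / volume_ml) / mw * 1e6
}

#' Molar dose to continuous instillation rate
#'
#' Spreads a single molar dose over a treatment course:
#' `m = m0 / tau`.
#'
#' @param m0 drug amount \[uM\].
#' @param tau course length \[days\]; default 365.
#' @return Instillation rate \[uM/day\].
#' @export
molar_to_rate <- function(m0, tau = 365) {
  if (any(m0 < 0)) stop("m0 must be >= 0")
  if (tau <= 0) stop("tau must be > 0")
  m0 / tau
}

#' Instillation rate back to a course dose in mg
#'
#' Inverts the full chain mg -> uM -> uM/day: a rate `m` sustained for
#' `tau` days corresponds to `m * tau` uM, i.e.
#' `m * tau * mw * volume / 1e6` mg.
#'
#' @param m instillation rate \[uM/day\].
#' @param tau course length \[days\]; default 365.
#' @param volume_ml carrier volume \[ml\]; default 50.
#' @param mw molecular weight \[g/mol\]; default 334.
#' @return Dose \[mg\] per course.
#' @export
rate_to_course_mg <- function(m, tau = 365, volume_ml = 50, mw = 334) {
  if (any(m < 0)) stop("m must be >= 0")
  if (tau <= 0 || volume_ml <= 0 || mw <= 0)
    stop("tau, volume and mw must be > 0")
  m * tau * mw * volume_ml / 1e6
}

#' Drug half-life in minutes
#'
#' Exponential-decay half-life `ln(2)/mu1`, converted from days to
#' minutes.  The published MMC washout rate 21.05/day gives 47.4 minutes.
#'
#' @param mu1 first-order washout rate \[1/day\].
#' @return Half-life \[minutes\].
#' @export
half_life_minutes <- function(mu1) {
  if (any(mu1 <= 0)) stop("mu1 must be > 0")
  log(2) / mu1 * 1440
}
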