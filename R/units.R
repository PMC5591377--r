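# Physical constants and unit conversions shared by all modules.
#
# Internal convention: concentrations in umol L^-1, radii in cm, diffusion
# coefficients in cm^2 per unit time (seconds for transient work, hours for
# steady-state algebra), volumetric rates in umol cm^-3 h^-1.  All user-facing
# I/O stays in the field units (um depth, umol L^-1, nmol h^-1, mm^3).

ATOMIC_MASS_C <- 12.011
ATOMIC_MASS_N <- 14.007

# Printed anchors for O2 diffusion in 3.5% saline water.
.D_ANCHORS <- list(t = c(24, 27), d = c(2.175e-5, 2.3535e-5))

.check_range <- function(x, name, lo, hi) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    stop(sprintf("`%s` must be within [%g, %g]", name, lo, hi), call. = FALSE)
  }
  invisible(x)
}

#' Molecular diffusion coefficient of O2 in saline water
#'
#' Linear interpolation (and extrapolation within the valid temperature range)
#' through the two anchor values for 3.5% saline water: 2.175e-5 cm^2 s^-1 at
#' 24 degC and 2.3535e-5 cm^2 s^-1 at 27 degC.
#'
#' @param temperature_c Water temperature, degrees Celsius, in \[0, 40\].
#' @return Diffusion coefficient in cm^2 s^-1.
#' @examples
#' diffusion_coefficient(24)
#' diffusion_coefficient(25.5)
#' @export
diffusion_coefficient <- function(temperature_c) {
  .check_range(temperature_c, "temperature_c", 0, 40)
  slope <- diff(.D_ANCHORS$d) / diff(.D_ANCHORS$t)
  .D_ANCHORS$d[1] + slope * (temperature_c - .D_ANCHORS$t[1])
}

#' Air-saturation O2 concentration of saline water
#'
#' Oxygen solubility at equilibrium with water-saturated air at 1 atm, from
#' the Garcia and Gordon (1992) refit of the Benson and Krause data
#' (umol kg^-1 coefficients).  The value is reported per litre under a
#' freshwater-density approximation (difference < 3% over the salinity range
#' handled here); pass an explicit `c_sat` to [medium_properties()] to
#' override it wherever a measured bulk concentration is available.
#'
#' @param temperature_c Temperature, degrees Celsius, in \[0, 40\].
#' @param salinity Practical salinity, in \[0, 40\].
#' @return Air-saturation O2 concentration, umol L^-1.
#' @references Garcia, H.E. and Gordon, L.I. (1992) Oxygen solubility in
#'   seawater: better fitting equations. Limnol. Oceanogr. 37, 1307-1312.
#' @examples
#' air_saturation(24, 35)
#' air_saturation(24, 3.5)
#' @export
air_saturation <- function(temperature_c, salinity) {
  .check_range(temperature_c, "temperature_c", 0, 40)
  .check_range(salinity, "salinity", 0, 40)
  ts <- log((298.15 - temperature_c) / (273.15 + temperature_c))
  a <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  b <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  c0 <- -2.75915e-7
  lnc <- a[1] + ts * (a[2] + ts * (a[3] + ts * (a[4] + ts * (a[5] + ts * a[6])))) +
    salinity * (b[1] + ts * (b[2] + ts * (b[3] + ts * b[4]))) +
    c0 * salinity^2
  exp(lnc)
}

#' Properties of the bathing medium
#'
#' Bundles temperature, salinity, the O2 diffusion coefficient `d_w` and the
#' ambient (bulk) O2 concentration `c_sat` used as the far-field boundary
#' value.  Both coefficients default to published parameterizations
#' ([diffusion_coefficient()], [air_saturation()]) but can be overridden with
#' measured values.
#'
#' @param temperature_c Temperature, degC, in \[0, 40\]. Default 24.
#' @param salinity Practical salinity, in \[0, 40\]. Default 35
#'   (the diffusion anchors are for 3.5% saline water).
#' @param d_w O2 diffusion coefficient in water, cm^2 s^-1. Default from
#'   [diffusion_coefficient()].
#' @param c_sat Ambient/bulk O2 concentration, umol L^-1. Default from
#'   [air_saturation()].
#' @return An object of class `medium_properties`.
#' @examples
#' medium_properties()
#' medium_properties(27, 3.5)
#' @export
medium_properties <- function(temperature_c = 24, salinity = 35,
                              d_w = NULL, c_sat = NULL) {
  .check_range(temperature_c, "temperature_c", 0, 40)
  .check_range(salinity, "salinity", 0, 40)
  if (is.null(d_w)) d_w <- diffusion_coefficient(temperature_c)
  if (is.null(c_sat)) c_sat <- air_saturation(temperature_c, salinity)
  if (d_w <= 0) stop("`d_w` must be positive", call. = FALSE)
  if (c_sat <= 0) stop("`c_sat` must be positive", call. = FALSE)
  structure(
    list(temperature_c = temperature_c, salinity = salinity,
         d_w = d_w, c_sat = c_sat),
    class = "medium_properties"
  )
}

#' @export
print.medium_properties <- function(x, ...) {
  cat("Medium: ", x$temperature_c, " degC, S = ", x$salinity,
      ", D_w = ", format(x$d_w, digits = 5), " cm2/s, C_sat = ",
      round(x$c_sat, 1), " umol/L\n", sep = "")
  invisible(x)
}

#' Aggregate model parameters
#'
#' Dimensionless and geometric parameters of the aggregate oxygen model:
#' `theta`, the ratio of apparent O2 diffusivity inside the gel-like aggregate
#' to that in free water (default 0.95); `pq`, the photosynthetic quotient in
#' mol O2 released per mol C fixed (default 1.2); `dbl_um`, the diffusive
#' boundary-layer thickness in um, with `Inf` meaning a stagnant infinite
#' medium; and `anoxia_umol_l`, the concentration below which the core is
#' called anoxic (default 1 umol L^-1).
#'
#' @param theta Apparent diffusivity ratio, in (0, 1\]. Default 0.95.
#' @param pq Photosynthetic quotient, > 0. Default 1.2.
#' @param dbl_um Diffusive boundary-layer thickness, um; `Inf` (default)
#'   selects the stagnant infinite-medium external solution.
#' @param anoxia_umol_l Anoxia threshold, umol L^-1, >= 0. Default 1.
#' @return An object of class `model_params`.
#' @export
model_params <- function(theta = 0.95, pq = 1.2, dbl_um = Inf,
                         anoxia_umol_l = 1) {
  if (!is.numeric(theta) || theta <= 0 || theta > 1) {
    stop("`theta` must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(pq) || pq <= 0) stop("`pq` must be positive", call. = FALSE)
  if (!is.numeric(dbl_um) || is.na(dbl_um) || dbl_um <= 0) {
    stop("`dbl_um` must be positive (Inf for stagnant medium)", call. = FALSE)
  }
  if (!is.numeric(anoxia_umol_l) || anoxia_umol_l < 0) {
    stop("`anoxia_umol_l` must be >= 0", call. = FALSE)
  }
  structure(
    list(theta = theta, pq = pq, dbl_um = dbl_um,
         anoxia_umol_l = anoxia_umol_l),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model: theta = ", x$theta, ", PQ = ", x$pq, ", DBL = ",
      if (is.finite(x$dbl_um)) paste0(x$dbl_um, " um") else "stagnant (Inf)",
      ", anoxia < ", x$anoxia_umol_l, " umol/L\n", sep = "")
  invisible(x)
}

#' Convert a per-aggregate rate to a volumetric rate
#'
#' `1 nmol mm^-3 h^-1 = 1 umol cm^-3 h^-1`, so the conversion is a plain
#' ratio.  [volumetric_to_per_aggregate()] is the exact inverse.
#'
#' @param rate_nmol_h Per-aggregate rate, nmol h^-1.
#' @param volume_mm3 Aggregate volume, mm^3, > 0.
#' @return Volumetric rate, umol cm^-3 h^-1.
#' @examples
#' per_aggregate_to_volumetric(19, 2.8) # dark respiration, ~6.8
#' @export
per_aggregate_to_volumetric <- function(rate_nmol_h, volume_mm3) {
  if (any(volume_mm3 <= 0)) stop("`volume_mm3` must be positive", call. = FALSE)
  rate_nmol_h / volume_mm3
}

#' @rdname per_aggregate_to_volumetric
#' @param rate_umol_cm3_h Volumetric rate, umol cm^-3 h^-1.
#' @export
volumetric_to_per_aggregate <- function(rate_umol_cm3_h, volume_mm3) {
  if (any(volume_mm3 <= 0)) stop("`volume_mm3` must be positive", call. = FALSE)
  rate_umol_cm3_h * volume_mm3
}

#' Read a medium/model configuration file
#'
#' YAML file with a `medium` section (`temperature_c`, `salinity`, optional
#' `d_w_cm2_s`, `c_sat_umol_l`) and a `model` section (`theta`, `pq`,
#' `dbl_um`, `anoxia_umol_l`); missing keys fall back to the defaults of
#' [medium_properties()] and [model_params()].
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `medium` and `model`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  med <- cfg$medium %||% list()
  mod <- cfg$model %||% list()
  medium <- medium_properties(
    temperature_c = med$temperature_c %||% 24,
    salinity = med$salinity %||% 35,
    d_w = med$d_w_cm2_s,
    c_sat = med$c_sat_umol_l
  )
  model <- model_params(
    theta = mod$theta %||% 0.95,
    pq = mod$pq %||% 1.2,
    dbl_um = mod$dbl_um %||% Inf,
    anoxia_umol_l = mod$anoxia_umol_l %||% 1
  )
  list(medium = medium, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
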