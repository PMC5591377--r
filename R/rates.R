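# Estimators turning microsensor data into aggregate rates: whole-aggregate
# fluxes from depth profiles, gross photosynthesis, light-dark shift rates,
# carbon fixation, and the assembled rate table.

#' Whole-aggregate O2 flux from a depth microprofile
#'
#' Estimates the total O2 exchange rate of a spherical aggregate from the
#' concentration field in the water above it.  Sign convention: efflux
#' (net production) positive, uptake (dark respiration) negative.
#'
#' Two estimators are provided.  The default `"radial"` estimator maps
#' heights above the aggregate surface to radial distance
#' `r = R + (surface_depth - depth)` (the profile is assumed to pass through
#' the aggregate centre) and fits the steady spherical far field
#' `C = C_inf + k/r` by least squares over the external window; the total
#' flux is `4 pi D_w k`.  The `"planar"` estimator applies Fick's first law
#' to the linear diffusive-boundary-layer gradient, `J = -D_w dC/dz`, fitted
#' over the window closest to the surface, scaled by the sphere surface
#' `pi ESD^2`.
#'
#' @param profile [radial_profile()].
#' @param geometry [aggregate_geometry()].
#' @param medium [medium_properties()].
#' @param method `"radial"` (default) or `"planar"`.
#' @param window_um External fit window as heights above the aggregate
#'   surface, um. Default `c(50, 1000 * esd_mm)`: points at least 50 um off
#'   the surface (sensor-contact artefacts) and within one ESD.
#' @param conf_level Confidence level for the flux interval (default 0.95).
#' @return Object of class `aggregate_flux`: `flux_nmol_h`, `se_nmol_h`,
#'   `ci_nmol_h` (2-vector), `method`, `n_points`, and the `lm` fit.
#' @examples
#' spec <- berry_scenario(noise_sd = 0)
#' prof <- generate_profile(spec, light_ue = 0)
#' whole_aggregate_flux(prof, spec$geometry, spec$medium)
#' @export
whole_aggregate_flux <- function(profile, geometry, medium,
                                 method = c("radial", "planar"),
                                 window_um = NULL, conf_level = 0.95) {
  stopifnot(inherits(profile, "radial_profile"),
            inherits(geometry, "aggregate_geometry"),
            inherits(medium, "medium_properties"))
  method <- match.arg(method)
  if (is.null(window_um)) window_um <- c(50, 1000 * geometry$esd_mm)
  height_um <- profile$surface_depth_um - profile$data$depth_um
  sel <- height_um >= window_um[1] & height_um <= window_um[2]
  if (sum(sel) < 4) {
    stop("need at least 4 external points in the fit window (have ",
         sum(sel), ")", call. = FALSE)
  }
  o2 <- profile$data$o2_umol_l[sel]
  if (stats::sd(o2) == 0 && diff(range(o2)) == 0 && all(o2 == o2[1])) {
    # perfectly flat external profile: no gradient, no flux
    return(structure(list(flux_nmol_h = 0, se_nmol_h = 0,
                          ci_nmol_h = c(0, 0), method = method,
                          n_points = sum(sel), fit = NULL),
                     class = "aggregate_flux"))
  }
  d_h <- medium$d_w * 3600  # cm2/h
  if (method == "radial") {
    r_cm <- geometry$radius_cm + height_um[sel] * 1e-4
    fit <- stats::lm(o2 ~ I(1 / r_cm))
    k <- stats::coef(fit)[[2]]                    # umol/L * cm
    # noise-free synthetic profiles fit perfectly; the SE is then 0
    se_k <- suppressWarnings(summary(fit))$coefficients[2, 2]
    scale <- 4 * pi * d_h                         # -> nmol/h
    flux <- scale * k
    se <- scale * se_k
    tq <- stats::qt(1 - (1 - conf_level) / 2, stats::df.residual(fit))
  } else {
    z_cm <- profile$data$depth_um[sel] * 1e-4
    fit <- stats::lm(o2 ~ z_cm)
    slope <- stats::coef(fit)[[2]]                # umol/L per cm, depthward
    se_s <- suppressWarnings(summary(fit))$coefficients[2, 2]
    area_cm2 <- geometry$surface_mm2 * 1e-2
    scale <- d_h * area_cm2                       # -> nmol/h
    flux <- scale * slope   # O2 rising toward the surface depth = efflux
    se <- scale * se_s
    tq <- stats::qt(1 - (1 - conf_level) / 2, stats::df.residual(fit))
  }
  structure(
    list(flux_nmol_h = flux, se_nmol_h = se,
         ci_nmol_h = flux + c(-1, 1) * tq * se, method = method,
         n_points = sum(sel), fit = fit),
    class = "aggregate_flux"
  )
}

#' @export
print.aggregate_flux <- function(x, ...) {
  cat("Whole-aggregate O2 flux (", x$method, " fit, n = ", x$n_points,
      "): ", round(x$flux_nmol_h, 2), " nmol/h  [",
      round(x$ci_nmol_h[1], 2), ", ", round(x$ci_nmol_h[2], 2), "]\n",
      sep = "")
  invisible(x)
}

#' Gross photosynthesis from net photosynthesis and dark respiration
#'
#' Gross O2 production approximated as the measured net efflux in the light
#' plus the magnitude of dark respiration (respiration in light assumed equal
#' to that in darkness).  The same arithmetic applies to per-aggregate
#' (nmol h^-1) and volumetric (umol cm^-3 h^-1) inputs.
#'
#' @param net Net photosynthesis (production positive).
#' @param dark_respiration Dark respiration magnitude, >= 0.
#' @return Gross photosynthesis, same units as the inputs.
#' @examples
#' gross_photosynthesis(13, 19)
#' @export
gross_photosynthesis <- function(net, dark_respiration) {
  if (any(dark_respiration < 0)) {
    stop("`dark_respiration` is a magnitude and must be >= 0", call. = FALSE)
  }
  net + dark_respiration
}

#' Volumetric gross photosynthesis by the light-dark shift technique
#'
#' The initial rate of O2 decline at a sensor point immediately after
#' darkening equals the local gross photosynthesis that was running an
#' instant before: respiration continues unchanged while production stops,
#' and over the first seconds the diffusive field has not yet relaxed.  The
#' slope is fitted by least squares over `window_s` after `dark_onset_s` and
#' converted from umol L^-1 s^-1 to umol cm^-3 h^-1 (factor 3.6).  Longer
#' windows are biased low as diffusion starts to resupply the point.
#'
#' @param trace [o2_trace()] sampled at >= 1 Hz.
#' @param dark_onset_s Darkening time, s. Default: the trace metadata.
#' @param window_s Fit window relative to `dark_onset_s`, s. Default
#'   `c(2, 12)`: the first ~2 s are discarded (sensor 90% response < 1 s plus
#'   switch transients).
#' @return Local volumetric gross photosynthesis, umol cm^-3 h^-1.
#' @export
light_dark_shift_rate <- function(trace, dark_onset_s = NULL,
                                  window_s = c(2, 12)) {
  stopifnot(inherits(trace, "o2_trace"))
  if (is.null(dark_onset_s)) dark_onset_s <- trace$dark_onset_s
  if (is.null(dark_onset_s) || is.na(dark_onset_s)) {
    stop("no dark onset given or recorded in the trace", call. = FALSE)
  }
  t0 <- dark_onset_s + window_s[1]
  t1 <- dark_onset_s + window_s[2]
  sel <- trace$data$time_s >= t0 & trace$data$time_s <= t1
  if (sum(sel) < 3) {
    stop("fit window [", t0, ", ", t1, "] s holds fewer than 3 samples",
         call. = FALSE)
  }
  fit <- stats::lm(o2_umol_l ~ time_s, data = trace$data[sel, ])
  slope <- stats::coef(fit)[[2]]       # umol/L/s
  -slope * 3.6                         # umol/cm3/h
}

#' Carbon fixation from gross O2 production
#'
#' Converts gross photosynthetic O2 production to carbon fixation through
#' the photosynthetic quotient: `C = gross_O2 / PQ * 12.011` (ng C h^-1 from
#' nmol O2 h^-1).
#'
#' @param gross_o2_nmol_h Gross O2 production, nmol h^-1, >= 0.
#' @param pq Photosynthetic quotient, mol O2 per mol C, > 0 (default 1.2).
#' @return Carbon fixation, ng C h^-1.
#' @examples
#' carbon_fixation(32, 1.2)
#' @export
carbon_fixation <- function(gross_o2_nmol_h, pq = 1.2) {
  if (any(gross_o2_nmol_h < 0)) stop("gross O2 must be >= 0", call. = FALSE)
  if (any(pq <= 0)) stop("`pq` must be positive", call. = FALSE)
  gross_o2_nmol_h / pq * ATOMIC_MASS_C
}

#' Ratio of dark respiration to gross photosynthesis
#'
#' @param dark_respiration Dark respiration magnitude.
#' @param gross Gross photosynthesis, > 0, same units.
#' @return Dimensionless ratio.
#' @examples
#' resp_to_gross_ratio(19, 50)
#' @export
resp_to_gross_ratio <- function(dark_respiration, gross) {
  if (any(gross <= 0)) stop("`gross` must be positive", call. = FALSE)
  dark_respiration / gross
}

#' Assemble the per-aggregate and volumetric rate table
#'
#' The computational counterpart of a classic aggregate O2 budget table: one
#' dark row (dark respiration) and one row per light level with net and
#' gross photosynthesis, their volumetric equivalents, the light-dark shift
#' volumetric gross rate where a trace is available, and carbon fixation.
#' All arithmetic is carried at full precision; rounding happens only in the
#' print method (integers for per-aggregate rates, Table-style decimals for
#' volumetric rates).
#'
#' @param dark_profile Dark [radial_profile()] (required for gross rates;
#'   without it the table is returned partial with a warning).
#' @param light_profiles List of lighted [radial_profile()]s, each with a
#'   `light_ue` metadata value.
#' @param geometry [aggregate_geometry()].
#' @param medium [medium_properties()].
#' @param model [model_params()] (supplies PQ).
#' @param shift_traces Optional named list of [o2_trace()]s, names = light
#'   level in uE m^-2 s^-1.
#' @param method Flux estimator passed to [whole_aggregate_flux()].
#' @return Object of class `rate_table`: a data.frame with columns
#'   `light_ue`, `dark_resp_nmol_h`, `vol_dark_resp_umol_cm3_h`,
#'   `net_nmol_h`, `vol_net_umol_cm3_h`, `gross_nmol_h`,
#'   `vol_gross_umol_cm3_h`, `ld_shift_vol_gross_umol_cm3_h`,
#'   `carbon_fix_ng_h`.
#' @export
build_rate_table <- function(dark_profile = NULL, light_profiles = list(),
                             geometry, medium, model = model_params(),
                             shift_traces = NULL, method = "radial") {
  v <- geometry$volume_mm3
  dark <- NA_real_
  if (!is.null(dark_profile)) {
    dark <- -whole_aggregate_flux(dark_profile, geometry, medium,
                                  method = method)$flux_nmol_h
  } else {
    warning("no dark profile: gross rates cannot be computed, table partial",
            call. = FALSE)
  }
  rows <- list(data.frame(
    light_ue = 0, dark_resp_nmol_h = dark,
    vol_dark_resp_umol_cm3_h = per_aggregate_to_volumetric(dark, v),
    net_nmol_h = NA_real_, vol_net_umol_cm3_h = NA_real_,
    gross_nmol_h = NA_real_, vol_gross_umol_cm3_h = NA_real_,
    ld_shift_vol_gross_umol_cm3_h = NA_real_, carbon_fix_ng_h = NA_real_))
  for (p in light_profiles) {
    net <- whole_aggregate_flux(p, geometry, medium,
                                method = method)$flux_nmol_h
    gross <- if (is.na(dark)) NA_real_ else gross_photosynthesis(net, dark)
    shift <- NA_real_
    if (!is.null(shift_traces) && !is.na(p$light_ue)) {
      tr <- shift_traces[[as.character(p$light_ue)]]
      if (!is.null(tr)) shift <- light_dark_shift_rate(tr)
    }
    rows[[length(rows) + 1]] <- data.frame(
      light_ue = p$light_ue, dark_resp_nmol_h = NA_real_,
      vol_dark_resp_umol_cm3_h = NA_real_,
      net_nmol_h = net,
      vol_net_umol_cm3_h = per_aggregate_to_volumetric(net, v),
      gross_nmol_h = gross,
      vol_gross_umol_cm3_h = per_aggregate_to_volumetric(gross, v),
      ld_shift_vol_gross_umol_cm3_h = shift,
      carbon_fix_ng_h = if (is.na(gross)) NA_real_ else
        carbon_fixation(gross, model$pq))
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$light_ue)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("rate_table", "data.frame")
  tab
}

#' @export
print.rate_table <- function(x, ...) {
  disp <- data.frame(
    `light uE` = x$light_ue,
    `dark resp` = round(x$dark_resp_nmol_h),
    `vol dark` = round(x$vol_dark_resp_umol_cm3_h, 1),
    `net phot` = round(x$net_nmol_h),
    `vol net` = round(x$vol_net_umol_cm3_h, 1),
    `gross phot` = round(x$gross_nmol_h),
    `vol gross` = round(x$vol_gross_umol_cm3_h, 1),
    `L-D shift` = round(x$ld_shift_vol_gross_umol_cm3_h, 1),
    `C fix ng/h` = round(x$carbon_fix_ng_h),
    check.names = FALSE)
  cat("Aggregate O2 rate table (per-aggregate nmol/h, volumetric",
      "umol/cm3/h):\n")
  print(disp, row.names = FALSE)
  invisible(x)
}
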