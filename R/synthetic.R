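# Synthetic microsensor data: every input the estimators consume, generated
# from the forward models with additive Gaussian sensor noise.  All
# randomness is controlled by the scenario seed, so files are reproducible
# byte for byte.

#' Scenario specification for the synthetic-data generator
#'
#' Bundles the forward-model configuration that a set of synthetic
#' measurements is drawn from: geometry, medium, model parameters, the true
#' volumetric rates at each light level, the acquisition grid (depth step,
#' trace sampling rate, sensor position), and the noise level and seed.
#'
#' @param geometry [aggregate_geometry()].
#' @param medium [medium_properties()].
#' @param model [model_params()].
#' @param dark_resp_umol_cm3_h True volumetric dark respiration magnitude.
#' @param net_umol_cm3_h Named numeric vector of true net volumetric
#'   production per light level, names = uE m^-2 s^-1.
#' @param step_um Depth-profile grid step, um (default 50, the sensor tip
#'   diameter).
#' @param surface_depth_um Depth of the aggregate surface below the water
#'   surface, um (default 2000).
#' @param hz Trace sampling rate, s^-1 (default 1).
#' @param noise_sd Sensor noise s.d., umol L^-1 (default 2).
#' @param seed Integer seed fixing all randomness (default 1).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(geometry, medium, model = model_params(),
                          dark_resp_umol_cm3_h, net_umol_cm3_h,
                          step_um = 50, surface_depth_um = 2000, hz = 1,
                          noise_sd = 2, seed = 1) {
  stopifnot(step_um > 0, hz > 0, noise_sd >= 0, dark_resp_umol_cm3_h >= 0)
  if (is.null(names(net_umol_cm3_h)) && length(net_umol_cm3_h) > 0) {
    stop("`net_umol_cm3_h` must be named by light level", call. = FALSE)
  }
  structure(
    list(geometry = geometry, medium = medium, model = model,
         dark_resp_umol_cm3_h = dark_resp_umol_cm3_h,
         net_umol_cm3_h = net_umol_cm3_h, step_um = step_um,
         surface_depth_um = surface_depth_um, hz = hz,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' The green berry study scenario
#'
#' Preset reproducing the conditions of the green berry aggregate study:
#' ESD 1.7 mm with working volume 2.8 mm^3, 24 degC / salinity 35 medium,
#' theta 0.95, PQ 1.2, true volumetric dark respiration 6.8 umol cm^-3 h^-1
#' and net production 4.8 (170 uE) and 11 (320 uE) umol cm^-3 h^-1, 50 um
#' depth steps, 1 Hz traces, 2 umol L^-1 sensor noise.
#'
#' @param noise_sd Sensor noise s.d., umol L^-1 (default 2).
#' @param seed Integer seed (default 1).
#' @return A [scenario_spec()].
#' @export
berry_scenario <- function(noise_sd = 2, seed = 1) {
  scenario_spec(
    geometry = aggregate_geometry(1.7, volume_mm3 = 2.8),
    medium = medium_properties(24, 35),
    model = model_params(theta = 0.95, pq = 1.2),
    dark_resp_umol_cm3_h = 6.8,
    net_umol_cm3_h = c("170" = 4.8, "320" = 11),
    noise_sd = noise_sd, seed = seed
  )
}

.scenario_q <- function(spec, light_ue) {
  if (light_ue == 0) return(-spec$dark_resp_umol_cm3_h)
  q <- spec$net_umol_cm3_h[[as.character(light_ue)]]
  if (is.null(q)) {
    stop("scenario has no net rate for light level ", light_ue, call. = FALSE)
  }
  q
}

#' Generate a synthetic steady-state depth microprofile
#'
#' Samples the analytic steady-state O2 field along a vertical line through
#' the aggregate centre (from the water surface to the bottom of the
#' aggregate) on the scenario's depth grid, adds i.i.d. Gaussian sensor
#' noise, and optionally writes the profile CSV.  Deterministic for a fixed
#' scenario seed; each light level uses an independent, seed-derived stream.
#'
#' @param spec [scenario_spec()].
#' @param light_ue Light level, uE m^-2 s^-1; 0 generates the dark
#'   (respiration) profile.
#' @param path Optional output CSV path.
#' @return The [radial_profile()] (invisibly the path is also written).
#' @export
generate_profile <- function(spec, light_ue, path = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  q <- .scenario_q(spec, light_ue)
  esd_um <- spec$geometry$esd_mm * 1000
  center_um <- spec$surface_depth_um + esd_um / 2
  depth <- seq(0, spec$surface_depth_um + esd_um, by = spec$step_um)
  r_cm <- abs(depth - center_um) * 1e-4
  o2 <- pmax(.steady_o2(r_cm, spec$geometry, q, spec$medium, spec$model), 0)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed + round(light_ue))
    o2 <- pmax(o2 + stats::rnorm(length(o2), sd = spec$noise_sd), 0)
  }
  prof <- radial_profile(depth, o2, surface_depth_um = spec$surface_depth_um,
                         light_ue = light_ue,
                         temperature_c = spec$medium$temperature_c,
                         salinity = spec$medium$salinity)
  if (!is.null(path)) write_profile(prof, path)
  prof
}

#' Generate a synthetic light-dark shift trace
#'
#' Runs the transient solver under a piecewise light schedule (initialized at
#' the analytic steady state of the first interval), records the centre-cell
#' concentration at the scenario sampling rate, adds Gaussian sensor noise,
#' and optionally writes the trace CSV.  The recorded dark onset is the first
#' scheduled dark interval.
#'
#' @param spec [scenario_spec()].
#' @param schedule [light_schedule()]; sources in umol cm^-3 h^-1.
#' @param path Optional output CSV path.
#' @param ... Passed to [simulate_transient()] (grid resolution etc.).
#' @return The [o2_trace()].
#' @export
generate_ld_trace <- function(spec, schedule, path = NULL, ...) {
  stopifnot(inherits(spec, "scenario_spec"))
  sim <- simulate_transient(spec$geometry, spec$medium, spec$model, schedule,
                            initial = "steady", dt_out_s = 1 / spec$hz, ...)
  o2 <- sim$trace$o2_umol_l
  if (spec$noise_sd > 0) {
    set.seed(spec$seed + 104729L)
    o2 <- pmax(o2 + stats::rnorm(length(o2), sd = spec$noise_sd), 0)
  }
  tr <- o2_trace(sim$trace$time_s, o2, dark_onset_s = sim$dark_onset_s)
  if (!is.null(path)) write_trace(tr, path)
  tr
}

#' Generate a synthetic acetylene-reduction incubation table
#'
#' Ethylene amounts are drawn as
#' `true_rate * dry_mass * dark_hours * (1 + rel_noise * N(0,1))`, emulating
#' GC-quantified totals from bottles incubated on a light/dark cycle with
#' fixation confined to the dark hours.
#'
#' @param n_bottles Number of bottles.
#' @param true_rate_nmol_mg_h True fixation-phase rate, nmol mg^-1 h^-1.
#' @param dry_mass_mg Dry mass per bottle, mg (recycled to `n_bottles`).
#' @param span_h Incubation span, h (default 48).
#' @param dark_h_per_day Dark hours per day (default 10).
#' @param rel_noise Relative noise s.d. (default 0.05).
#' @param seed Integer seed (default 1).
#' @param path Optional output CSV path.
#' @return A data.frame with the [read_incubation()] columns.
#' @export
generate_incubation_table <- function(n_bottles, true_rate_nmol_mg_h,
                                      dry_mass_mg, span_h = 48,
                                      dark_h_per_day = 10, rel_noise = 0.05,
                                      seed = 1, path = NULL) {
  stopifnot(n_bottles >= 1, true_rate_nmol_mg_h >= 0, all(dry_mass_mg > 0),
            rel_noise >= 0)
  mass <- rep_len(dry_mass_mg, n_bottles)
  dark_h <- active_hours(span_h, dark_h_per_day)
  set.seed(as.integer(seed))
  eth <- true_rate_nmol_mg_h * mass * dark_h *
    (1 + rel_noise * stats::rnorm(n_bottles))
  df <- data.frame(bottle_id = sprintf("B%02d", seq_len(n_bottles)),
                   ethylene_nmol = pmax(eth, 0), span_h = span_h,
                   dark_h_per_day = dark_h_per_day, dry_mass_mg = mass)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
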