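# Time-dependent radial diffusion-reaction solver for light-dark shift
# experiments.  Conservative finite volumes on spherical shells (the r = 0
# singularity is handled by a symmetry cell with zero inner-face area),
# method of lines in time via deSolve.  Time unit: seconds.

#' Piecewise-constant light schedule
#'
#' @param t_start_s,t_end_s Interval bounds, s.  Must be contiguous and
#'   increasing.
#' @param q_umol_cm3_h Uniform volumetric source inside the aggregate during
#'   each interval, umol cm^-3 h^-1 (production positive).
#' @return A data.frame usable as `schedule` in [simulate_transient()].
#' @export
light_schedule <- function(t_start_s, t_end_s, q_umol_cm3_h) {
  stopifnot(length(t_start_s) == length(t_end_s),
            length(t_end_s) == length(q_umol_cm3_h))
  if (any(t_end_s <= t_start_s)) stop("empty schedule interval", call. = FALSE)
  if (length(t_start_s) > 1 &&
      any(abs(t_start_s[-1] - t_end_s[-length(t_end_s)]) > 1e-9)) {
    stop("schedule intervals must be contiguous", call. = FALSE)
  }
  data.frame(t_start_s = t_start_s, t_end_s = t_end_s,
             q_umol_cm3_h = q_umol_cm3_h)
}

# Spherical-shell grid: uniform cells inside the aggregate, power-stretched
# cells outside up to R + l_cm.
.make_grid <- function(R, l_cm, n_inside, n_outside, stretch = 1.6) {
  f_in <- seq(0, R, length.out = n_inside + 1)
  f_out <- R + l_cm * (seq(0, 1, length.out = n_outside + 1))^stretch
  faces <- c(f_in, f_out[-1])
  centers <- (faces[-1] + faces[-length(faces)]) / 2
  list(faces = faces, centers = centers,
       areas = 4 * pi * faces^2,
       volumes = 4 * pi / 3 * diff(faces^3),
       inside = centers < R)
}

#' Simulate the transient O2 field of an aggregate
#'
#' Solves `dC/dt = (1/r^2) d/dr(r^2 D dC/dr) + q(r, t)` with `D = theta D_w`
#' inside the aggregate and `D_w` outside, a symmetry condition at `r = 0`
#' and, by default, a far-field Dirichlet condition `C = C_inf` at
#' `r = R + l_cm`.  The source is the uniform in-aggregate rate given by the
#' schedule; where a cell is at zero O2, a consuming source is switched off
#' (no consumption of absent oxygen) and intermediate negatives are clipped.
#'
#' @param geometry [aggregate_geometry()].
#' @param medium [medium_properties()].
#' @param model [model_params()]; a finite `dbl_um` sets the domain size
#'   `l_cm` unless overridden.
#' @param schedule Data.frame from [light_schedule()].
#' @param initial `"ambient"` (uniform `c_sat`), `"steady"` (analytic steady
#'   state for the first scheduled source), a single number (uniform inside
#'   the aggregate, `c_sat` outside), or a numeric vector over the grid
#'   centres.
#' @param l_cm Water-layer thickness beyond the aggregate surface, cm.
#'   Default: the model's DBL if finite, else `10 R`.
#' @param n_inside,n_outside Finite-volume cells inside/outside (defaults 60
#'   and 90).
#' @param dt_out_s Output sampling interval, s (default 1, the microsensor
#'   logging rate).
#' @param boundary `"dirichlet"` (far field held at `c_sat`) or
#'   `"reflecting"` (closed outer boundary, for mass-balance checks).
#' @param rtol,atol Integrator tolerances (defaults 1e-6 and 1e-3 umol L^-1).
#' @param src_eps O2 level (umol L^-1) below which a consuming source ramps
#'   linearly to zero (default 0.5, below the anoxia threshold); regularizes
#'   the no-consumption-of-absent-O2 cutoff.
#' @return Object of class `transient_trace`: data.frame `trace` (`time_s`,
#'   `o2_umol_l` at the centre cell), full field matrix `field`
#'   (time x cells), grid vectors, and the inputs.
#' @examples
#' geom <- aggregate_geometry(1.7, volume_mm3 = 2.8)
#' sched <- light_schedule(0, 300, -6.8)
#' tr <- simulate_transient(geom, medium_properties(), model_params(), sched,
#'                          initial = 520, n_inside = 25, n_outside = 40)
#' time_to_anoxia(tr)
#' @export
simulate_transient <- function(geometry, medium, model = model_params(),
                               schedule, initial = "ambient", l_cm = NULL,
                               n_inside = 60, n_outside = 90, dt_out_s = 1,
                               boundary = c("dirichlet", "reflecting"),
                               rtol = 1e-6, atol = 1e-3, src_eps = 0.5) {
  stopifnot(inherits(geometry, "aggregate_geometry"),
            inherits(medium, "medium_properties"),
            inherits(model, "model_params"),
            is.data.frame(schedule))
  boundary <- match.arg(boundary)
  R <- geometry$radius_cm
  if (is.null(l_cm)) {
    l_cm <- if (is.finite(model$dbl_um)) model$dbl_um * 1e-4 else 10 * R
  }
  g <- .make_grid(R, l_cm, n_inside, n_outside)
  nc <- length(g$centers)
  d_cell <- ifelse(g$inside, model$theta * medium$d_w, medium$d_w)  # cm2/s
  # harmonic-mean interface diffusivity on interior faces
  d_face <- 2 * d_cell[-1] * d_cell[-nc] / (d_cell[-1] + d_cell[-nc])
  dx_face <- diff(g$centers)
  a_face <- g$areas[2:nc]          # faces between cells
  a_bnd <- g$areas[nc + 1]
  dx_bnd <- g$faces[nc + 1] - g$centers[nc]
  vol_frac <- sum(g$volumes[g$inside])  # cm3 actually reacting
  # source scaling: schedule q is per aggregate volume (geometry$volume_mm3);
  # distribute the implied total over the discretized inside cells so the
  # total source matches q * V exactly.
  src_scale <- (geometry$volume_mm3 * 1e-3) / vol_frac

  c_inf <- medium$c_sat
  y0 <- .initial_state(initial, g, geometry, medium, model, schedule)

  rhs <- function(t, y, parms) {
    q_l_s <- parms$q_l_s
    flux <- d_face * a_face * (y[-1] - y[-nc]) / dx_face  # inward-positive
    dy <- numeric(nc)
    dy[1] <- flux[1] / g$volumes[1]
    dy[2:(nc - 1)] <- (flux[2:(nc - 1)] - flux[1:(nc - 2)]) /
      g$volumes[2:(nc - 1)]
    bflux <- if (boundary == "dirichlet") {
      medium$d_w * a_bnd * (c_inf - y[nc]) / dx_bnd
    } else 0
    dy[nc] <- (bflux - flux[nc - 1]) / g$volumes[nc]
    src <- ifelse(g$inside, q_l_s, 0)
    # no consumption of absent O2: consuming sources ramp linearly to zero
    # below `src_eps` umol/L (first-order limitation regularizing the C = 0
    # cutoff for the stiff integrator)
    neg <- src < 0
    src[neg] <- src[neg] * pmin(pmax(y[neg] / parms$src_eps, 0), 1)
    list(dy + src)
  }

  out_t <- numeric(0)
  out_y <- NULL
  y <- y0
  for (i in seq_len(nrow(schedule))) {
    q_l_s <- schedule$q_umol_cm3_h[i] * 1000 / 3600 * src_scale  # umol/L/s
    times <- unique(c(seq(schedule$t_start_s[i], schedule$t_end_s[i],
                          by = dt_out_s), schedule$t_end_s[i]))
    sol <- deSolve::ode.1D(y = y, times = times, func = rhs,
                           parms = list(q_l_s = q_l_s, src_eps = src_eps),
                           nspec = 1, dimens = nc, method = "lsoda",
                           rtol = rtol, atol = atol, maxsteps = 20000)
    if (attr(sol, "istate")[1] < 0) {
      stop("transient solver failed to converge in schedule interval ", i,
           call. = FALSE)
    }
    keep <- if (i < nrow(schedule)) -nrow(sol) else TRUE
    block <- sol[keep, , drop = FALSE]
    out_t <- c(out_t, block[, 1])
    out_y <- rbind(out_y, block[, -1, drop = FALSE])
    y <- sol[nrow(sol), -1]
  }
  out_y[out_y < 0] <- 0
  structure(
    list(trace = data.frame(time_s = out_t, o2_umol_l = out_y[, 1]),
         field = out_y, time_s = out_t, radius_cm = g$centers,
         inside = g$inside, volumes_cm3 = g$volumes, schedule = schedule,
         geometry = geometry, medium = medium, model = model,
         boundary = boundary, dark_onset_s = .first_dark_onset(schedule)),
    class = "transient_trace"
  )
}

.initial_state <- function(initial, g, geometry, medium, model, schedule) {
  nc <- length(g$centers)
  if (is.character(initial)) {
    if (initial == "ambient") return(rep(medium$c_sat, nc))
    if (initial == "steady") {
      return(pmax(.steady_o2(g$centers, geometry,
                             schedule$q_umol_cm3_h[1], medium, model), 0))
    }
    stop("unknown `initial`: ", initial, call. = FALSE)
  }
  if (is.numeric(initial) && length(initial) == 1) {
    return(ifelse(g$inside, initial, medium$c_sat))
  }
  if (is.numeric(initial) && length(initial) == nc) return(initial)
  stop("`initial` must be \"ambient\", \"steady\", a scalar, or a grid vector",
       call. = FALSE)
}

.first_dark_onset <- function(schedule) {
  dark <- which(schedule$q_umol_cm3_h < 0)
  if (length(dark) == 0) NA_real_ else schedule$t_start_s[dark[1]]
}

#' @export
print.transient_trace <- function(x, ...) {
  cat("Transient O2 trace: ", nrow(x$trace), " samples over ",
      round(max(x$time_s) - min(x$time_s)), " s, centre now ",
      round(x$trace$o2_umol_l[nrow(x$trace)], 1), " umol/L\n", sep = "")
  invisible(x)
}

#' Time to core anoxia
#'
#' First time at which the centre concentration crosses below `threshold`
#' (linear interpolation between samples), counted from `from_s`.
#'
#' @param trace A `transient_trace` (or anything with `time_s` and a centre
#'   `o2_umol_l` column in `$trace`).
#' @param threshold_umol_l Anoxia threshold, umol L^-1. Default: the model's
#'   `anoxia_umol_l` if available, else 1.
#' @param from_s Reference time, s. Default: the first dark onset in the
#'   schedule if present, else the trace start.
#' @return Minutes to the first crossing; `Inf` if the trace never crosses
#'   ("never").
#' @export
time_to_anoxia <- function(trace, threshold_umol_l = NULL, from_s = NULL) {
  tt <- trace$trace$time_s
  o2 <- trace$trace$o2_umol_l
  if (is.null(threshold_umol_l)) {
    threshold_umol_l <- if (!is.null(trace$model)) trace$model$anoxia_umol_l else 1
  }
  if (is.null(from_s)) {
    from_s <- if (!is.null(trace$dark_onset_s) && !is.na(trace$dark_onset_s)) {
      trace$dark_onset_s
    } else tt[1]
  }
  keep <- tt >= from_s
  tt <- tt[keep]; o2 <- o2[keep]
  below <- which(o2 < threshold_umol_l)
  if (length(below) == 0) return(Inf)
  i <- below[1]
  if (i == 1) return(0)
  t_cross <- tt[i - 1] + (threshold_umol_l - o2[i - 1]) /
    (o2[i] - o2[i - 1]) * (tt[i] - tt[i - 1])
  (t_cross - from_s) / 60
}

#' Total dissolved O2 in the simulated domain
#'
#' Volume integral of the field at each output time; used for mass-balance
#' checks with a reflecting outer boundary.
#'
#' @param trace A `transient_trace`.
#' @return Numeric vector, nmol O2 per time point.
#' @export
total_o2 <- function(trace) {
  stopifnot(inherits(trace, "transient_trace"))
  as.numeric(trace$field %*% trace$volumes_cm3)  # umol/L * cm3 = nmol
}
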