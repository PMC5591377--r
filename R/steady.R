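# Closed-form O2 field for a uniformly reacting sphere in a diffusive medium.
#
# Inside (r <= R):      C(r) = C_R + q/(6 theta D) (R^2 - r^2)
# Outside, stagnant:    C(r) = C_inf + Q_tot / (4 pi D r)
# Outside, finite DBL:  C(r) = C_inf + Q_tot/(4 pi D) (1/r - 1/(R + dbl)),
#                       C = C_inf beyond R + dbl
# with Q_tot = q * V the total reaction (production positive) and
# C_R the surface concentration from the external solution at r = R.
# Working units: C umol/L, q umol cm^-3 h^-1 (= 1000 umol L^-1 h^-1),
# D cm^2 h^-1, r cm; then Q_tot in these units is numerically nmol h^-1.

.steady_parts <- function(geometry, q_umol_cm3_h, medium, model) {
  R <- geometry$radius_cm
  d_h <- medium$d_w * 3600            # cm^2/h
  q_l <- q_umol_cm3_h * 1000          # umol L^-1 h^-1
  q_tot <- q_umol_cm3_h * geometry$volume_mm3  # nmol h^-1 (numerically)
  dbl_cm <- model$dbl_um * 1e-4
  r_out <- if (is.finite(dbl_cm)) R + dbl_cm else Inf
  inv_out <- if (is.finite(r_out)) 1 / r_out else 0
  c_r <- medium$c_sat + q_tot / (4 * pi * d_h) * (1 / R - inv_out)
  list(R = R, d_h = d_h, q_l = q_l, q_tot = q_tot, r_out = r_out,
       inv_out = inv_out, c_r = c_r, theta = model$theta)
}

.steady_o2 <- function(r_cm, geometry, q_umol_cm3_h, medium, model) {
  p <- .steady_parts(geometry, q_umol_cm3_h, medium, model)
  inside <- r_cm <= p$R
  out <- numeric(length(r_cm))
  out[inside] <- p$c_r +
    p$q_l / (6 * p$theta * p$d_h) * (p$R^2 - r_cm[inside]^2)
  re <- pmin(pmax(r_cm[!inside], p$R), p$r_out)
  out[!inside] <- medium$c_sat +
    p$q_tot / (4 * pi * p$d_h) * (1 / re - p$inv_out)
  out
}

#' Steady-state O2 field of a uniformly reacting aggregate
#'
#' Analytic solution for a sphere with uniform volumetric reaction rate `q`
#' (net production positive, respiration negative) embedded in either a
#' stagnant infinite medium or a medium with a finite diffusive boundary
#' layer (`dbl_um` in [model_params()]).  Concentrations that would fall
#' below zero (respiration stronger than [critical_respiration()]) are
#' truncated at zero and flagged, never returned negative.
#'
#' The total source feeding the external field is `q * volume_mm3`, so a
#' geometry whose volume was set independently of the ESD reproduces reported
#' per-aggregate totals exactly; with the default (sphere) volume the internal
#' and external fluxes match identically at the surface.
#'
#' @param geometry [aggregate_geometry()].
#' @param q_umol_cm3_h Uniform volumetric reaction rate, umol cm^-3 h^-1;
#'   production positive.
#' @param medium [medium_properties()].
#' @param model [model_params()].
#' @param r_max_cm Outer radius of the returned grid, cm.  Default: `R + dbl`
#'   for a finite boundary layer, else `4 R`.
#' @param n Number of grid points (default 500).
#' @return Object of class `radial_solution`: data.frame `profile`
#'   (`radius_cm`, `o2_umol_l`), logical `core_anoxic`, and the inputs.
#' @examples
#' geom <- aggregate_geometry(1.7)
#' med <- medium_properties()
#' sol <- solve_steady(geom, -6.8, med)
#' core_concentration(sol)
#' @export
solve_steady <- function(geometry, q_umol_cm3_h, medium,
                         model = model_params(), r_max_cm = NULL, n = 500) {
  stopifnot(inherits(geometry, "aggregate_geometry"),
            inherits(medium, "medium_properties"),
            inherits(model, "model_params"))
  R <- geometry$radius_cm
  if (is.null(r_max_cm)) {
    r_max_cm <- if (is.finite(model$dbl_um)) R + model$dbl_um * 1e-4 else 4 * R
  }
  r <- seq(0, r_max_cm, length.out = n)
  o2 <- .steady_o2(r, geometry, q_umol_cm3_h, medium, model)
  anoxic <- any(o2 < 0)
  if (anoxic) {
    o2 <- pmax(o2, 0)
    warning("core anoxic under stated q: profile truncated at 0 umol/L",
            call. = FALSE)
  }
  structure(
    list(profile = data.frame(radius_cm = r, o2_umol_l = o2),
         core_anoxic = anoxic, q_umol_cm3_h = q_umol_cm3_h,
         geometry = geometry, medium = medium, model = model),
    class = "radial_solution"
  )
}

#' @export
print.radial_solution <- function(x, ...) {
  cat("Radial O2 solution: q = ", x$q_umol_cm3_h, " umol/cm3/h, core = ",
      round(core_concentration(x), 1), " umol/L, surface = ",
      round(surface_concentration(x), 1), " umol/L",
      if (x$core_anoxic) " [core anoxic]" else "", "\n", sep = "")
  invisible(x)
}

#' Core and surface concentrations of a steady solution
#'
#' @param solution A `radial_solution` from [solve_steady()].
#' @return Concentration at the aggregate centre (resp. surface), umol L^-1.
#' @export
core_concentration <- function(solution) {
  stopifnot(inherits(solution, "radial_solution"))
  max(0, .steady_o2(0, solution$geometry, solution$q_umol_cm3_h,
                    solution$medium, solution$model))
}

#' @rdname core_concentration
#' @export
surface_concentration <- function(solution) {
  stopifnot(inherits(solution, "radial_solution"))
  max(0, .steady_o2(solution$geometry$radius_cm, solution$geometry,
                    solution$q_umol_cm3_h, solution$medium, solution$model))
}

#' Critical respiration rate for core anoxia (diffusion limitation)
#'
#' The uniform volumetric respiration at which diffusive O2 supply from the
#' surrounding water just fails to keep the aggregate core oxic, i.e. the
#' rate at which the steady-state centre concentration reaches zero:
#'
#' `Q_crit = C_inf / (R^2/(6 theta D) + V/(4 pi D) (1/R - 1/(R + dbl)))`
#'
#' with the stagnant infinite-medium limit
#' `Q_crit = C_inf / (R^2 (1/(3 D) + 1/(6 theta D)))` as `dbl -> Inf`.
#' Respiration above this threshold makes the core anoxic regardless of the
#' ambient concentration gradient.
#'
#' @inheritParams solve_steady
#' @return Critical respiration magnitude, umol cm^-3 h^-1.
#' @examples
#' critical_respiration(aggregate_geometry(1.7), medium_properties())
#' @export
critical_respiration <- function(geometry, medium, model = model_params()) {
  stopifnot(inherits(geometry, "aggregate_geometry"),
            inherits(medium, "medium_properties"),
            inherits(model, "model_params"))
  R <- geometry$radius_cm
  d_h <- medium$d_w * 3600
  dbl_cm <- model$dbl_um * 1e-4
  inv_out <- if (is.finite(dbl_cm)) 1 / (R + dbl_cm) else 0
  v_cm3 <- geometry$volume_mm3 * 1e-3
  resistance <- R^2 / (6 * model$theta * d_h) +
    v_cm3 / (4 * pi * d_h) * (1 / R - inv_out)   # h * L/cm3-ish; C in umol/L
  medium$c_sat / resistance / 1000
}
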