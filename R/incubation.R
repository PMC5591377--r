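# Acetylene-reduction (nitrogenase) rates and elemental C:N arithmetic.

#' Hours of diazotrophic activity within an incubation span
#'
#' Nitrogen fixation in unicellular cyanobacteria is typically confined to
#' one phase of the photoperiod (the dark hours, when nitrogenase is shielded
#' from photosynthetic O2).  Given the incubation span and the photoperiod,
#' this returns the hours during which fixation is assumed active.  The span
#' is taken to start at light onset; partial final cycles contribute the
#' completed dark (or light) hours plus any partial overlap.
#'
#' @param span_h Incubation duration, h, > 0.
#' @param dark_h_per_day Dark hours per 24 h cycle (default 10, a 14 h
#'   light / 10 h dark photoperiod).
#' @param active_phase One of `"dark_only"` (default), `"light_only"`,
#'   `"continuous"`.
#' @return Active hours within the span.
#' @examples
#' active_hours(48)                 # 2 days -> 20 dark hours
#' @export
active_hours <- function(span_h, dark_h_per_day = 10,
                         active_phase = c("dark_only", "light_only",
                                          "continuous")) {
  active_phase <- match.arg(active_phase)
  if (any(span_h <= 0)) stop("`span_h` must be positive", call. = FALSE)
  if (any(dark_h_per_day < 0 | dark_h_per_day > 24)) {
    stop("`dark_h_per_day` must be in [0, 24]", call. = FALSE)
  }
  if (active_phase == "continuous") return(span_h)
  light_h <- 24 - dark_h_per_day
  cycles <- floor(span_h / 24)
  rem <- span_h - 24 * cycles
  if (active_phase == "dark_only") {
    cycles * dark_h_per_day + pmax(0, rem - light_h)
  } else {
    cycles * light_h + pmin(rem, light_h)
  }
}

#' Acetylene reduction rate per unit dry mass
#'
#' Converts the total ethylene produced during an incubation into a
#' nitrogenase activity rate, normalized to aggregate dry mass and to the
#' hours during which fixation is assumed active (by default only the dark
#' hours of the photoperiod).
#'
#' @param ethylene_nmol Total ethylene produced, nmol, >= 0.
#' @param span_h Incubation duration, h.
#' @param dry_mass_mg Aggregate dry mass, mg, > 0.
#' @param dark_h_per_day Dark hours per 24 h cycle (default 10).
#' @param active_phase See [active_hours()]; default `"dark_only"`.
#' @return Rate, nmol C2H4 mg^-1 h^-1.
#' @examples
#' acetylene_reduction_rate(1100, 48, 5)  # -> 11
#' @export
acetylene_reduction_rate <- function(ethylene_nmol, span_h, dry_mass_mg,
                                     dark_h_per_day = 10,
                                     active_phase = "dark_only") {
  if (any(ethylene_nmol < 0)) stop("`ethylene_nmol` must be >= 0", call. = FALSE)
  if (any(dry_mass_mg <= 0)) stop("`dry_mass_mg` must be positive", call. = FALSE)
  act <- active_hours(span_h, dark_h_per_day, active_phase)
  if (any(act <= 0)) {
    stop("no active hours in the incubation span", call. = FALSE)
  }
  ethylene_nmol / (dry_mass_mg * act)
}

#' Molar carbon-to-nitrogen ratio from elemental masses
#'
#' @param carbon_ug Carbon mass, ug (any mass unit, shared with nitrogen).
#' @param nitrogen_ug Nitrogen mass, same unit, > 0.
#' @return Molar C:N ratio: `(C/12.011) / (N/14.007)`.
#' @examples
#' cn_molar_ratio(85.2, 14.0)
#' @export
cn_molar_ratio <- function(carbon_ug, nitrogen_ug) {
  if (any(carbon_ug < 0)) stop("`carbon_ug` must be >= 0", call. = FALSE)
  if (any(nitrogen_ug <= 0)) stop("`nitrogen_ug` must be positive", call. = FALSE)
  (carbon_ug / ATOMIC_MASS_C) / (nitrogen_ug / ATOMIC_MASS_N)
}

#' Read an incubation bottle table from CSV
#'
#' Columns `bottle_id`, `ethylene_nmol`, `span_h`, `dark_h_per_day`,
#' `dry_mass_mg`; adds the computed `rate_nmol_mg_h` column (dark-only
#' convention).
#'
#' @param path CSV path.
#' @return A data.frame, one row per bottle.
#' @export
read_incubation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bottle_id", "ethylene_nmol", "span_h", "dark_h_per_day",
            "dry_mass_mg")
  if (!all(need %in% names(df))) {
    stop("incubation CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$rate_nmol_mg_h <- acetylene_reduction_rate(
    df$ethylene_nmol, df$span_h, df$dry_mass_mg, df$dark_h_per_day)
  df
}
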