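# Microsensor profile and trace I/O.
#
# Profile CSV: comment header lines "# surface_depth_um=", "# light_uE=",
# "# temperature_c=", "# salinity="; then columns depth_um, o2_umol_l.
# Trace CSV: "# dark_onset_s="; then columns time_s, o2_umol_l.

.read_meta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  list(meta = meta, n_header = length(hdr))
}

.read_body <- function(path, n_header, cols) {
  df <- utils::read.csv(path, skip = n_header, stringsAsFactors = FALSE)
  if (!all(cols %in% names(df))) {
    stop(sprintf("%s: expected columns %s", path, paste(cols, collapse = ", ")),
         call. = FALSE)
  }
  for (cl in cols) {
    vals <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(vals) & !is.na(df[[cl]]) | is.na(df[[cl]]))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value in column '%s', data row %d",
                   path, cl, bad[1]), call. = FALSE)
    }
    df[[cl]] <- vals
  }
  df[, cols]
}

#' Read an O2 depth microprofile
#'
#' Parses a microsensor depth profile CSV (depth in um from the water
#' surface, positive downward; O2 in umol L^-1) with its metadata header.
#' Validation is strict: depth must be strictly increasing, O2 non-negative,
#' the aggregate surface depth must lie inside the profiled depth range, and
#' malformed rows are reported with their row number.
#'
#' @param path CSV path.
#' @return Object of class `radial_profile` with `data` (columns `depth_um`,
#'   `o2_umol_l`), `surface_depth_um`, `light_ue`, `temperature_c`,
#'   `salinity`.
#' @export
read_profile <- function(path) {
  m <- .read_meta(path)
  if (is.null(m$meta$surface_depth_um)) {
    stop(path, ": missing '# surface_depth_um=' metadata", call. = FALSE)
  }
  df <- .read_body(path, m$n_header, c("depth_um", "o2_umol_l"))
  radial_profile(df$depth_um, df$o2_umol_l,
                 surface_depth_um = m$meta$surface_depth_um,
                 light_ue = m$meta$light_uE %||% NA_real_,
                 temperature_c = m$meta$temperature_c %||% NA_real_,
                 salinity = m$meta$salinity %||% NA_real_)
}

#' Construct a depth microprofile object
#'
#' @param depth_um Depths, um from the water surface, strictly increasing.
#' @param o2_umol_l O2 concentrations, umol L^-1, non-negative.
#' @param surface_depth_um Depth of the aggregate surface, um.
#' @param light_ue Light level, uE m^-2 s^-1 (0 = dark).
#' @param temperature_c,salinity Measurement conditions (optional).
#' @return Object of class `radial_profile`.
#' @export
radial_profile <- function(depth_um, o2_umol_l, surface_depth_um,
                           light_ue = NA_real_, temperature_c = NA_real_,
                           salinity = NA_real_) {
  if (length(depth_um) != length(o2_umol_l)) {
    stop("depth and O2 vectors differ in length", call. = FALSE)
  }
  if (any(diff(depth_um) <= 0)) {
    stop("depth must be strictly increasing (row ",
         which(diff(depth_um) <= 0)[1] + 1, ")", call. = FALSE)
  }
  if (any(o2_umol_l < 0)) {
    stop("negative O2 at row ", which(o2_umol_l < 0)[1], call. = FALSE)
  }
  if (surface_depth_um < min(depth_um) || surface_depth_um > max(depth_um)) {
    stop("aggregate surface depth outside the profiled range", call. = FALSE)
  }
  structure(
    list(data = data.frame(depth_um = depth_um, o2_umol_l = o2_umol_l),
         surface_depth_um = surface_depth_um, light_ue = light_ue,
         temperature_c = temperature_c, salinity = salinity),
    class = "radial_profile"
  )
}

#' @export
print.radial_profile <- function(x, ...) {
  cat("O2 depth profile: ", nrow(x$data), " points, surface at ",
      x$surface_depth_um, " um, light ",
      if (is.na(x$light_ue)) "?" else x$light_ue, " uE/m2/s\n", sep = "")
  invisible(x)
}

#' Write a depth microprofile to CSV
#'
#' Inverse of [read_profile()]; metadata goes into `#` header lines.
#'
#' @param profile A `radial_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "radial_profile"))
  hdr <- c(sprintf("# surface_depth_um=%.10g", profile$surface_depth_um),
           if (!is.na(profile$light_ue))
             sprintf("# light_uE=%.10g", profile$light_ue),
           if (!is.na(profile$temperature_c))
             sprintf("# temperature_c=%.10g", profile$temperature_c),
           if (!is.na(profile$salinity))
             sprintf("# salinity=%.10g", profile$salinity))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(profile$data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an O2 point time series (light-dark shift recording)
#'
#' @param path CSV path with `# dark_onset_s=` metadata and columns
#'   `time_s`, `o2_umol_l`.
#' @return Object of class `o2_trace` with `data` and `dark_onset_s`.
#' @export
read_trace <- function(path) {
  m <- .read_meta(path)
  df <- .read_body(path, m$n_header, c("time_s", "o2_umol_l"))
  if (any(diff(df$time_s) <= 0)) {
    stop(path, ": time must be strictly increasing", call. = FALSE)
  }
  o2_trace(df$time_s, df$o2_umol_l,
           dark_onset_s = m$meta$dark_onset_s %||% NA_real_)
}

#' Construct an O2 point time-series object
#'
#' @param time_s Sample times, s, strictly increasing.
#' @param o2_umol_l O2 at the sensor tip, umol L^-1.
#' @param dark_onset_s Time at which the light was switched off, s.
#' @return Object of class `o2_trace`.
#' @export
o2_trace <- function(time_s, o2_umol_l, dark_onset_s = NA_real_) {
  structure(
    list(data = data.frame(time_s = time_s, o2_umol_l = o2_umol_l),
         dark_onset_s = dark_onset_s),
    class = "o2_trace"
  )
}

#' Write an O2 time series to CSV
#'
#' @param trace An `o2_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "o2_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(trace$dark_onset_s)) {
    writeLines(sprintf("# dark_onset_s=%.10g", trace$dark_onset_s), con)
  }
  utils::write.csv(trace$data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
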