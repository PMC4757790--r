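#' Construct an emission spectrum
#'
#' The atom of all processing: one emission spectrum on a wavelength grid
#' with its excitation and integration-time metadata. Raw spectra are in
#' detector counts; calibrated spectra (see [calibrate()]) are in counts
#' per millisecond.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param intensity Numeric vector of the same length as `wavelength_nm`.
#'   Counts (raw) or counts per ms (calibrated). May be negative after
#'   calibration: the difference spectrum is legitimately negative near
#'   the protoporphyrin IX bands, so nothing is clipped.
#' @param excitation_nm Excitation wavelength: 407, 425, or `NA` for a
#'   dark spectrum.
#' @param integration_time_ms Integration time in ms, must be positive.
#' @param calibrated Logical; `TRUE` once dark-subtracted and normalised
#'   to 1 ms.
#' @return An object of class `znpp_spectrum`.
#' @examples
#' s <- spectrum_new(500:750, rexp(251), excitation_nm = 425)
#' @export
spectrum_new <- function(wavelength_nm, intensity, excitation_nm = NA_real_,
                         integration_time_ms = 200, calibrated = FALSE) {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) < 2L)
    stop("a spectrum needs at least two wavelengths", call. = FALSE)
  if (any(!is.finite(wavelength_nm)) || any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be finite and strictly increasing", call. = FALSE)
  if (length(intensity) != length(wavelength_nm))
    stop("intensity length (", length(intensity),
         ") does not match grid length (", length(wavelength_nm), ")",
         call. = FALSE)
  if (!is.na(excitation_nm) && !excitation_nm %in% c(407, 425))
    stop("excitation_nm must be 407, 425 or NA (dark)", call. = FALSE)
  if (!is.finite(integration_time_ms) || integration_time_ms <= 0)
    stop("integration_time_ms must be positive", call. = FALSE)
  structure(
    list(wavelength_nm = wavelength_nm,
         intensity = intensity,
         excitation_nm = as.numeric(excitation_nm),
         integration_time_ms = as.numeric(integration_time_ms),
         calibrated = isTRUE(calibrated)),
    class = "znpp_spectrum")
}

#' @export
print.znpp_spectrum <- function(x, ...) {
  exc <- if (is.na(x$excitation_nm)) "dark" else paste0(x$excitation_nm, " nm")
  cat(sprintf("<znpp_spectrum> %d points, %.0f-%.0f nm, excitation %s, %g ms, %s\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), exc, x$integration_time_ms,
              if (x$calibrated) "calibrated (counts/ms)" else "raw (counts)"))
  invisible(x)
}

#' The default common wavelength grid
#'
#' All cycle spectra are interpolated onto a uniform 1-nm grid from 500 to
#' 750 nm on load. The band arithmetic of the method (normalisation over
#' 520-525 nm, fitting over 560-750 nm, index bands at 562/576/593 nm)
#' presumes a shared grid, and 1 nm resolves the narrowest spectral
#' features involved (roughly 10-nm haemoglobin dips).
#'
#' @param from,to,by Grid limits and spacing in nm.
#' @return Numeric wavelength vector.
#' @export
common_grid <- function(from = 500, to = 750, by = 1) {
  if (by <= 0 || by > 2) stop("grid spacing must be in (0, 2] nm", call. = FALSE)
  seq(from, to, by = by)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; wavelengths outside the source range are held at
#' the nearest endpoint value (rule 2), which only matters for reference
#' curves supplied on a narrower grid.
#'
#' @param spec A `znpp_spectrum`.
#' @param grid Target wavelength vector (strictly increasing).
#' @return A `znpp_spectrum` on `grid`.
#' @export
resample_spectrum <- function(spec, grid = common_grid()) {
  stopifnot(inherits(spec, "znpp_spectrum"))
  y <- stats::approx(spec$wavelength_nm, spec$intensity, xout = grid,
                     rule = 2)$y
  spectrum_new(grid, y, spec$excitation_nm, spec$integration_time_ms,
               spec$calibrated)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavelength_nm) == length(b$wavelength_nm) &&
    all(abs(a$wavelength_nm - b$wavelength_nm) <=
          tol * pmax(1, abs(a$wavelength_nm)))
}

#' Calibrate a raw spectrum
#'
#' Subtracts the paired dark spectrum and divides by the integration time,
#' normalising to counts per millisecond. Negative values are kept.
#'
#' @param raw Raw `znpp_spectrum` (counts).
#' @param dark Dark `znpp_spectrum` acquired with the same grid and
#'   integration time.
#' @return Calibrated `znpp_spectrum` in counts per ms.
#' @examples
#' g <- common_grid()
#' dark <- spectrum_new(g, rep(40, length(g)), NA, 200)
#' raw  <- spectrum_new(g, 40 + 200 * exp(-(g - 600)^2 / 1e4), 425, 200)
#' cal  <- calibrate(raw, dark)
#' @export
calibrate <- function(raw, dark) {
  stopifnot(inherits(raw, "znpp_spectrum"), inherits(dark, "znpp_spectrum"))
  if (raw$calibrated)
    stop("spectrum is already calibrated", call. = FALSE)
  if (!same_grid(raw, dark))
    stop("raw and dark spectra are not on the same wavelength grid",
         call. = FALSE)
  if (abs(raw$integration_time_ms - dark$integration_time_ms) > 1e-9)
    stop("raw and dark integration times differ", call. = FALSE)
  spectrum_new(raw$wavelength_nm,
               (raw$intensity - dark$intensity) / raw$integration_time_ms,
               raw$excitation_nm, raw$integration_time_ms, calibrated = TRUE)
}

#' Construct a measurement cycle
#'
#' One acquisition cycle of the clinical protocol: a 425-nm-excited
#' spectrum, a 407-nm-excited spectrum and a dark spectrum, all sharing
#' one wavelength grid and integration time.
#'
#' @param f425,f407,dark `znpp_spectrum` objects with excitation tags
#'   425, 407 and `NA` respectively.
#' @return An object of class `znpp_cycle`.
#' @export
measurement_cycle <- function(f425, f407, dark) {
  for (s in list(f425, f407, dark)) stopifnot(inherits(s, "znpp_spectrum"))
  if (!identical(f425$excitation_nm, 425) || !identical(f407$excitation_nm, 407))
    stop("cycle spectra must be tagged excitation 425 and 407 nm", call. = FALSE)
  if (!is.na(dark$excitation_nm))
    stop("dark spectrum must have excitation NA", call. = FALSE)
  if (!same_grid(f425, f407) || !same_grid(f425, dark))
    stop("cycle spectra must share one wavelength grid", call. = FALSE)
  structure(list(f425 = f425, f407 = f407, dark = dark), class = "znpp_cycle")
}

#' Calibrate a whole measurement cycle
#'
#' @param cycle A `znpp_cycle` with raw spectra.
#' @return A `znpp_cycle` whose `f425` and `f407` are calibrated; the dark
#'   spectrum is retained unchanged.
#' @export
calibrate_cycle <- function(cycle) {
  stopifnot(inherits(cycle, "znpp_cycle"))
  if (cycle$f425$calibrated && cycle$f407$calibrated) return(cycle)
  structure(list(f425 = calibrate(cycle$f425, cycle$dark),
                 f407 = calibrate(cycle$f407, cycle$dark),
                 dark = cycle$dark),
            class = "znpp_cycle")
}

#' Construct a measurement session
#'
#' A session mirrors the clinical acquisition: one subject, several tissue
#' sites, ten measurement cycles per site, each site carrying a validity
#' flag (set by the examiner) and the blood absorption index observed when
#' the site was accepted. A complete study session has 10 valid sites of
#' 10 cycles each, i.e. 100 usable cycles. Invalid sites are retained in
#' the object but excluded from quantitation.
#'
#' @param subject_id Opaque subject label.
#' @param sites List of site records; each a list with elements `cycles`
#'   (list of `znpp_cycle`), `valid` (logical) and
#'   `blood_index_at_start` (numeric, may be `NA`).
#' @return An object of class `znpp_session`.
#' @export
session_new <- function(subject_id, sites) {
  stopifnot(is.list(sites))
  sites <- lapply(sites, function(s) {
    stopifnot(is.list(s$cycles))
    for (cy in s$cycles) stopifnot(inherits(cy, "znpp_cycle"))
    list(cycles = s$cycles,
         valid = isTRUE(s$valid),
         blood_index_at_start =
           if (is.null(s$blood_index_at_start)) NA_real_
           else as.numeric(s$blood_index_at_start),
         n_cycle_warning = length(s$cycles) != 10L)
  })
  structure(list(subject_id = as.character(subject_id), sites = sites),
            class = "znpp_session")
}

#' @export
print.znpp_session <- function(x, ...) {
  nv <- sum(vapply(x$sites, function(s) s$valid, logical(1)))
  nc <- sum(vapply(x$sites, function(s) length(s$cycles), integer(1)))
  cat(sprintf("<znpp_session> subject %s: %d sites (%d valid), %d cycles\n",
              x$subject_id, length(x$sites), nv, nc))
  invisible(x)
}

#' Pool calibrated cycles from the valid sites of a session
#'
#' Returns every measurement cycle belonging to a site flagged valid,
#' calibrated and resampled onto the common grid. An empty list is a
#' legitimate result (all sites invalid); quantitation refuses it
#' downstream.
#'
#' @param session A `znpp_session`.
#' @param grid Common wavelength grid for resampling.
#' @return List of calibrated `znpp_cycle` objects.
#' @export
pool_valid_cycles <- function(session, grid = common_grid()) {
  stopifnot(inherits(session, "znpp_session"))
  out <- list()
  for (site in session$sites) {
    if (!site$valid) next
    for (cy in site$cycles) {
      cal <- calibrate_cycle(cy)
      out[[length(out) + 1L]] <- structure(
        list(f425 = resample_spectrum(cal$f425, grid),
             f407 = resample_spectrum(cal$f407, grid),
             dark = resample_spectrum(cal$dark, grid)),
        class = "znpp_cycle")
    }
  }
  out
}
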