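#' Write a spectrum to delimited text
#'
#' Two tab-separated columns (`wavelength_nm`, `intensity`) preceded by
#' commented `key=value` metadata lines, including a row count so that
#' silently truncated files are rejected on read. Values are written with
#' 17 significant digits so the write/read round trip is exact to well
#' below 1e-9 relative.
#'
#' @param spec A `znpp_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "znpp_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# excitation_nm=%s",
            if (is.na(spec$excitation_nm)) "dark" else
              format(spec$excitation_nm)),
    sprintf("# integration_time_ms=%s",
            format(spec$integration_time_ms, digits = 17)),
    sprintf("# calibrated=%s", if (spec$calibrated) "true" else "false"),
    sprintf("# rows=%d", length(spec$wavelength_nm)),
    "wavelength_nm\tintensity"), con)
  writeLines(sprintf("%s\t%s",
                     formatC(spec$wavelength_nm, digits = 17, format = "g"),
                     formatC(spec$intensity, digits = 17, format = "g")), con)
  invisible(path)
}

#' Read a spectrum from delimited text
#'
#' Counterpart of [write_spectrum()]. Parse errors name the offending
#' line; non-monotone wavelength grids and row counts disagreeing with
#' the `# rows=` header are rejected.
#'
#' @param path Input file path.
#' @return A `znpp_spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  meta <- lines[is_meta]
  kv <- list()
  for (i in seq_along(meta)) {
    m <- regmatches(meta[i], regexec("^#\\s*([A-Za-z_]+)=(.*)$", meta[i]))[[1]]
    if (length(m) != 3L)
      stop("cannot parse metadata line ", which(is_meta)[i], ": '", meta[i],
           "'", call. = FALSE)
    kv[[m[2]]] <- trimws(m[3])
  }
  for (key in c("excitation_nm", "integration_time_ms", "rows"))
    if (is.null(kv[[key]]))
      stop("missing required metadata '", key, "' in header of ", path,
           call. = FALSE)
  body <- lines[!is_meta]
  if (length(body) && grepl("^wavelength_nm", body[1])) body <- body[-1]
  body <- body[nzchar(body)]
  if (length(body) != as.integer(kv$rows))
    stop("file appears truncated: header declares ", kv$rows,
         " rows but ", length(body), " data lines found", call. = FALSE)
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad))
    stop("malformed data line ", which(!is_meta)[bad[1] + 1L], call. = FALSE)
  wl <- as.numeric(vapply(parts, `[[`, "", 1L))
  iv <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (any(is.na(wl)) || any(is.na(iv)))
    stop("non-numeric value in data rows of ", path, call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("wavelengths not strictly increasing at data line ",
         which(diff(wl) <= 0)[1] + 1L, call. = FALSE)
  spectrum_new(wl, iv,
               excitation_nm = if (kv$excitation_nm == "dark") NA_real_
                               else as.numeric(kv$excitation_nm),
               integration_time_ms = as.numeric(kv$integration_time_ms),
               calibrated = identical(kv$calibrated, "true"))
}

spectrum_to_list <- function(s) {
  list(excitation_nm = if (is.na(s$excitation_nm)) "dark" else s$excitation_nm,
       integration_time_ms = s$integration_time_ms,
       calibrated = s$calibrated,
       intensity = s$intensity)
}

spectrum_from_list <- function(x, grid) {
  spectrum_new(grid, as.numeric(x$intensity),
               excitation_nm = if (identical(x$excitation_nm, "dark"))
                 NA_real_ else as.numeric(x$excitation_nm),
               integration_time_ms = as.numeric(x$integration_time_ms),
               calibrated = isTRUE(x$calibrated))
}

#' Write a session to a structured-text (JSON) document
#'
#' A session is stored as a single JSON document, schema
#' `"znpp-session/1"`: the shared wavelength grid once at top level,
#' then per-site validity flags, start indices and embedded per-cycle
#' intensity arrays. The document records its cycle count so truncated
#' files are rejected on read. Photodiode remission samples, if present
#' in `session$remission`, are carried through opaquely; they do not
#' enter any calculation.
#'
#' @param session A `znpp_session` whose cycles share one grid.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "znpp_session"))
  grid <- NULL
  sites <- lapply(session$sites, function(site) {
    cycles <- lapply(site$cycles, function(cy) {
      if (is.null(grid)) grid <<- cy$f425$wavelength_nm
      if (!isTRUE(all.equal(grid, cy$f425$wavelength_nm, tolerance = 1e-12)))
        stop("all cycles in a session file must share one wavelength grid",
             call. = FALSE)
      list(f425 = spectrum_to_list(cy$f425),
           f407 = spectrum_to_list(cy$f407),
           dark = spectrum_to_list(cy$dark))
    })
    list(valid = site$valid,
         blood_index_at_start = site$blood_index_at_start,
         cycles = cycles)
  })
  doc <- list(format = "znpp-session/1",
              subject_id = session$subject_id,
              n_cycles = sum(vapply(session$sites,
                                    function(s) length(s$cycles), integer(1))),
              wavelength_nm = grid,
              sites = sites)
  if (!is.null(session$remission)) doc$remission <- session$remission
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' Read a session document
#'
#' Counterpart of [write_session()]. A site holding a number of cycles
#' other than 10 is flagged (`n_cycle_warning`), not rejected.
#'
#' @param path Path to a `znpp-session/1` JSON document.
#' @return A `znpp_session`.
#' @export
read_session <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "znpp-session/1"))
    stop("not a znpp-session/1 document: ", path, call. = FALSE)
  grid <- as.numeric(unlist(doc$wavelength_nm))
  sites <- lapply(doc$sites, function(site) {
    cycles <- lapply(site$cycles, function(cy)
      measurement_cycle(spectrum_from_list(cy$f425, grid),
                        spectrum_from_list(cy$f407, grid),
                        spectrum_from_list(cy$dark, grid)))
    list(cycles = cycles, valid = isTRUE(site$valid),
         blood_index_at_start =
           if (is.null(site$blood_index_at_start)) NA_real_
           else as.numeric(site$blood_index_at_start))
  })
  n_found <- sum(vapply(sites, function(s) length(s$cycles), integer(1)))
  if (!is.null(doc$n_cycles) && n_found != as.integer(doc$n_cycles))
    stop("session file truncated: declares ", doc$n_cycles,
         " cycles, found ", n_found, call. = FALSE)
  out <- session_new(doc$subject_id, sites)
  if (!is.null(doc$remission)) out$remission <- doc$remission
  out
}
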