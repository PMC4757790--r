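#' Default analysis configuration
#'
#' Central place for the tunable constants of the quantitation pipeline.
#'
#' @return Named list: `fit.window_nm` (fitting window, default 560-750),
#'   `norm.window_nm` (normalisation band for the difference spectrum,
#'   520-525), `index.bands_nm` (blood-index band centres 562/576/593),
#'   `index.halfwidth_nm` (band half-width, 3), `index.thresholds`
#'   (red-orange / orange / green zone boundaries, 0.0014/0.0042/0.0070),
#'   `index.mode` (`"three_band"` or `"two_band"`), `sg.window`,
#'   `sg.order` (Savitzky-Golay pre-smoothing), `fit.a_max` (upper bound
#'   of the blood-path search, mm).
#' @export
quantify_config <- function() {
  list(fit.window_nm = c(560, 750),
       norm.window_nm = c(520, 525),
       index.bands_nm = c(562, 576, 593),
       index.halfwidth_nm = 3,
       index.thresholds = c(0.0014, 0.0042, 0.0070),
       index.mode = "three_band",
       sg.window = 9,
       sg.order = 3,
       fit.a_max = 0.05)
}

merge_config <- function(config) {
  base <- quantify_config()
  if (is.null(config)) return(base)
  base[names(config)] <- config
  base
}

band_mean <- function(spec, lo, hi) {
  sel <- spec$wavelength_nm >= lo & spec$wavelength_nm <= hi
  if (!any(sel)) stop("grid does not cover the band [", lo, ", ", hi, "] nm",
                      call. = FALSE)
  mean(spec$intensity[sel])
}

#' Dual-wavelength excitation difference spectrum
#'
#' Normalises the 407-nm-excited spectrum to the 425-nm-excited spectrum
#' over the 520-525 nm band (where capillary blood absorbs both
#' excitations nearly identically) and subtracts. The tissue background,
#' being almost the same at the two excitations, cancels; ZnPP, excited
#' about 78% less efficiently at 407 nm, is largely retained, and PPIX,
#' excited more strongly at 407 nm, contributes negatively.
#'
#' @param f425,f407 Calibrated `znpp_spectrum` objects on one grid
#'   covering 520-750 nm.
#' @param config Optional configuration overriding [quantify_config()].
#' @return An object of class `znpp_diffspec` with `wavelength_nm`,
#'   `values` (counts/ms, may be negative) and the normalisation scalar
#'   `norm_k` applied to the 407 spectrum.
#' @export
difference_spectrum <- function(f425, f407, config = NULL) {
  cfg <- merge_config(config)
  stopifnot(inherits(f425, "znpp_spectrum"), inherits(f407, "znpp_spectrum"))
  if (!f425$calibrated || !f407$calibrated)
    stop("difference spectrum requires calibrated inputs", call. = FALSE)
  if (!same_grid(f425, f407))
    stop("f425 and f407 must share one wavelength grid", call. = FALSE)
  nb <- cfg$norm.window_nm
  m425 <- band_mean(f425, nb[1], nb[2])
  m407 <- band_mean(f407, nb[1], nb[2])
  if (!is.finite(m407) || m407 <= 0)
    stop("degenerate input: nonpositive 407-nm band mean over the ",
         "normalisation window", call. = FALSE)
  k <- m425 / m407
  structure(list(wavelength_nm = f425$wavelength_nm,
                 values = f425$intensity - k * f407$intensity,
                 norm_k = k),
            class = "znpp_diffspec")
}

#' Second derivative on a uniform grid
#'
#' Central second differences `(v[i-1] - 2 v[i] + v[i+1]) / h^2` with the
#' two endpoints dropped. Optional Savitzky-Golay pre-smoothing; second
#' differences amplify shot noise like h^-2, and a 9-point cubic window
#' is small against the ~25-40 nm porphyrin bands.
#'
#' @param values Numeric vector sampled on a uniform grid.
#' @param h Grid spacing (nm).
#' @param sg_window,sg_order Savitzky-Golay window length (odd; 0 or 1
#'   disables smoothing) and polynomial order.
#' @return Numeric vector of length `length(values) - 2`.
#' @export
second_derivative <- function(values, h = 1, sg_window = 0, sg_order = 3) {
  n <- length(values)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (!is.finite(h) || h <= 0) stop("h must be positive", call. = FALSE)
  if (sg_window >= 3)
    values <- signal::sgolayfilt(values, p = sg_order, n = sg_window)
  (values[1:(n - 2)] - 2 * values[2:(n - 1)] + values[3:n]) / h^2
}

check_uniform <- function(wl) {
  h <- diff(wl)
  if (max(h) - min(h) > 1e-9 * max(abs(wl)))
    stop("operation requires a uniform wavelength grid", call. = FALSE)
  h[1]
}

# Curvature operator used by the fit: SG smoothing, central second
# differences, and removal of half a smoothing window at each end where
# the SG endpoint fits are transient.
curvature_op <- function(h, sg_window, sg_order) {
  trim <- if (sg_window >= 3) (sg_window - 1L) / 2L else 0L
  function(v) {
    d2 <- second_derivative(v, h, sg_window, sg_order)
    if (trim > 0) d2 <- d2[(trim + 1L):(length(d2) - trim)]
    d2
  }
}

#' Fit the difference spectrum by second-derivative smoothness
#'
#' Removes the three structured features from a difference spectrum D:
#' the ZnPP emission template (amplitude z), the PPIX emission template
#' (amplitude p, sign free) and the haemoglobin absorption imprint
#' (effective blood path a, mm), by requiring that the remaining
#' background
#' \deqn{B(\lambda) = \frac{D(\lambda) - z F_{ZnPP}(\lambda)
#'       - p F_{PPIX}(\lambda)}{e^{-a \mu_a(\lambda)}}}
#' be smooth over 560-750 nm, i.e. that the integrated squared second
#' derivative of B be minimal. The subject-varying background itself is
#' never modelled - only its lack of sharp curvature is exploited.
#'
#' For fixed a the problem is linear in (z, p), so the implementation
#' profiles them out by exact least squares on the curvature of the
#' basis spectra and searches a on a deterministic bracketed grid
#' followed by golden-section refinement. No random initialisation is
#' involved; results are reproducible to optimizer tolerance.
#'
#' @param diff A `znpp_diffspec` on a uniform grid.
#' @param refs A `znpp_reflib` from [load_reference_library()].
#' @param config Optional configuration overriding [quantify_config()].
#' @return Object of class `znpp_fit`: amplitudes `a` (mm, >= 0), `z`,
#'   `p` (counts/ms at template peak), `residual_background`
#'   (`znpp_spectrum` of B over the fit window), `objective_value`
#'   (sum of squared smoothed second derivative), `converged`.
#' @export
fit_difference_spectrum <- function(diff, refs, config = NULL) {
  cfg <- merge_config(config)
  stopifnot(inherits(diff, "znpp_diffspec"), inherits(refs, "znpp_reflib"))
  h <- check_uniform(diff$wavelength_nm)
  win <- cfg$fit.window_nm
  sel <- diff$wavelength_nm >= win[1] & diff$wavelength_nm <= win[2]
  if (sum(sel) < cfg$sg.window + 4)
    stop("fit window too short on this grid", call. = FALSE)
  wl <- diff$wavelength_nm[sel]
  D <- diff$values[sel]
  Fz <- stats::approx(refs$znpp$grid, refs$znpp$shape, wl, rule = 2)$y
  Fp <- stats::approx(refs$ppix$grid, refs$ppix$shape, wl, rule = 2)$y
  mu <- refs$mu_a_fun(wl)
  L <- curvature_op(h, cfg$sg.window, cfg$sg.order)

  profile <- function(a) {
    E <- exp(-a * mu)
    X <- cbind(L(Fz / E), L(Fp / E))
    y <- L(D / E)
    beta <- stats::lm.fit(X, y)$coefficients
    beta[is.na(beta)] <- 0
    r <- y - X %*% beta
    list(obj = sum(r^2), z = beta[1], p = beta[2])
  }

  a_grid <- seq(0, cfg$fit.a_max, length.out = 51L)
  objs <- vapply(a_grid, function(a) profile(a)$obj, numeric(1))
  i <- which.min(objs)
  lo <- a_grid[max(1L, i - 1L)]
  hi <- a_grid[min(length(a_grid), i + 1L)]
  a_hat <- if (lo < hi)
    stats::optimize(function(a) profile(a)$obj, c(lo, hi), tol = 1e-9)$minimum
  else a_grid[i]
  best <- profile(a_hat)
  if (best$obj > objs[i]) { a_hat <- a_grid[i]; best <- profile(a_hat) }

  B <- (D - best$z * Fz - best$p * Fp) / exp(-a_hat * mu)
  structure(list(a = a_hat, z = unname(best$z), p = unname(best$p),
                 residual_background = spectrum_new(wl, B, NA_real_, 1,
                                                    calibrated = TRUE),
                 objective_value = best$obj,
                 norm_k = diff$norm_k,
                 converged = TRUE),
            class = "znpp_fit")
}

#' @export
print.znpp_fit <- function(x, ...) {
  cat(sprintf(
    "<znpp_fit> a = %.5f mm, z = %.4g, p = %.4g, objective = %.4g\n",
    x$a, x$z, x$p, x$objective_value))
  invisible(x)
}

zone_from_index <- function(index, thresholds) {
  if (index >= thresholds[3]) "green"
  else if (index >= thresholds[2]) "orange"
  else if (index >= thresholds[1]) "red_orange"
  else "red"
}

#' Blood absorption index of a 407-nm-excited spectrum
#'
#' Measures the haemoglobin absorption dip imprinted on the tissue
#' autofluorescence around the 576-nm oxyhaemoglobin peak, used to
#' qualify measurement sites in real time. Three bands centred at 562,
#' 576 and 593 nm (+/- 3 nm) are averaged; the index a >= 0 is the
#' effective haemoglobin path (mm, reported on the 10^-2 scale of the
#' zone thresholds) such that after dividing the spectrum by
#' \eqn{e^{-a \mu_a(\lambda)}} the central band falls on the straight
#' line between the flanking bands, i.e. the dip is exactly removed.
#' Solved by bracketed root finding. A two-band closed-form variant
#' (561/576 equality, `index.mode = "two_band"`) is also provided.
#'
#' The zone is the LED colour shown to the examiner: index >= 0.70e-2
#' green (site acceptable), 0.42e-2 to 0.70e-2 orange, 0.14e-2 to
#' 0.42e-2 red_orange, below 0.14e-2 red. Thresholds are closed on the
#' left of each upper zone (an index of exactly 0.70e-2 is green).
#'
#' @param f407 Calibrated 407-nm-excited `znpp_spectrum`.
#' @param refs A `znpp_reflib`.
#' @param config Optional configuration overriding [quantify_config()].
#' @return Object of class `znpp_blood_index`: `index`, `zone` (one of
#'   `"green"`, `"orange"`, `"red_orange"`, `"red"`), `flat` (`TRUE` when
#'   no absorption dip was found and the index was reported as 0).
#' @export
blood_absorption_index <- function(f407, refs, config = NULL) {
  cfg <- merge_config(config)
  stopifnot(inherits(f407, "znpp_spectrum"), inherits(refs, "znpp_reflib"))
  if (!f407$calibrated)
    stop("blood_absorption_index requires a calibrated spectrum",
         call. = FALSE)
  hw <- cfg$index.halfwidth_nm
  if (identical(cfg$index.mode, "two_band")) {
    bands <- c(561, 576)
    G <- vapply(bands, function(w) band_mean(f407, w - hw, w + hw),
                numeric(1))
    if (any(G <= 0))
      stop("nonpositive band mean; cannot form blood absorption index",
           call. = FALSE)
    mu <- refs$mu_a_fun(bands)
    index <- log(G[2] / G[1]) / (mu[1] - mu[2])
    flat <- FALSE
    if (index < 0) { index <- 0; flat <- TRUE }
  } else {
    bands <- cfg$index.bands_nm
    G <- vapply(bands, function(w) band_mean(f407, w - hw, w + hw),
                numeric(1))
    if (any(G <= 0))
      stop("nonpositive band mean; cannot form blood absorption index",
           call. = FALSE)
    sel <- lapply(bands, function(w)
      f407$wavelength_nm >= w - hw & f407$wavelength_nm <= w + hw)
    mu <- refs$mu_a_fun(f407$wavelength_nm)
    wfrac <- (bands[2] - bands[1]) / (bands[3] - bands[1])
    # divide the whole spectrum by exp(-a mu) first, then average the
    # bands: with the dip removed the central band falls on the chord
    # between the flanks
    gap <- function(a) {
      corr <- f407$intensity * exp(a * mu)
      Gc <- vapply(sel, function(s) mean(corr[s]), numeric(1))
      Gc[2] - ((1 - wfrac) * Gc[1] + wfrac * Gc[3])
    }
    a_max <- 0.05
    flat <- FALSE
    if (gap(0) >= 0) {
      index <- 0; flat <- TRUE
    } else if (gap(a_max) < 0) {
      index <- 0; flat <- TRUE
    } else {
      index <- stats::uniroot(gap, c(0, a_max), tol = 1e-12)$root
    }
  }
  structure(list(index = index,
                 zone = zone_from_index(index, cfg$index.thresholds),
                 flat = flat, bands_nm = bands, band_means = G),
            class = "znpp_blood_index")
}

#' Site acceptance decision
#'
#' A site qualifies for quantitative measurement only when its blood
#' absorption index is in the green zone (>= 0.70e-2, boundary
#' included), where the ratio-metric proportionality between detected
#' ZnPP fluorescence and the ZnPP/haem ratio holds.
#'
#' @param blood_index A `znpp_blood_index`.
#' @return Logical flag.
#' @export
accept_site <- function(blood_index) {
  stopifnot(inherits(blood_index, "znpp_blood_index"))
  identical(blood_index$zone, "green")
}

#' Quantify the ZnPP amplitude of one subject's session
#'
#' Runs the full per-cycle pipeline (calibration, difference spectrum,
#' second-derivative fit) over every cycle from the session's valid
#' sites, then averages the ZnPP amplitudes. A complete study session
#' yields 100 cycles.
#'
#' @param session A `znpp_session`.
#' @param refs A `znpp_reflib`.
#' @param config Optional configuration overriding [quantify_config()].
#' @param scale Proportionality constant from instrument units to umol
#'   ZnPP per mol haem (see [robust_proportional_slope()]); `NA` leaves
#'   `scaled_znpp` unset.
#' @return Object of class `znpp_subject_result`: `mean_z`, `sem_z`
#'   (0 with `sem_degenerate = TRUE` when only one cycle is available),
#'   `n_cycles`, `scaled_znpp`, and a per-cycle data frame `cycles` with
#'   columns `site`, `cycle`, `a`, `z`, `p`, `objective`.
#' @export
quantify_subject <- function(session, refs, config = NULL, scale = NA_real_) {
  stopifnot(inherits(session, "znpp_session"))
  cfg <- merge_config(config)
  grid <- refs$grid
  rows <- list()
  site_no <- 0L
  for (site in session$sites) {
    site_no <- site_no + 1L
    if (!site$valid) next
    cyc_no <- 0L
    for (cy in site$cycles) {
      cyc_no <- cyc_no + 1L
      cal <- calibrate_cycle(cy)
      f425 <- resample_spectrum(cal$f425, grid)
      f407 <- resample_spectrum(cal$f407, grid)
      fit <- fit_difference_spectrum(difference_spectrum(f425, f407, cfg),
                                     refs, cfg)
      rows[[length(rows) + 1L]] <-
        data.frame(site = site_no, cycle = cyc_no, a = fit$a, z = fit$z,
                   p = fit$p, objective = fit$objective_value)
    }
  }
  if (!length(rows))
    stop("session has no valid cycles; nothing to quantify", call. = FALSE)
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  mean_z <- mean(tab$z)
  sem_degenerate <- n < 2L
  sem_z <- if (sem_degenerate) 0 else stats::sd(tab$z) / sqrt(n)
  structure(list(subject_id = session$subject_id,
                 mean_z = mean_z, sem_z = sem_z, n_cycles = n,
                 sem_degenerate = sem_degenerate,
                 scaled_znpp = mean_z * scale,
                 cycles = tab),
            class = "znpp_subject_result")
}

#' @export
print.znpp_subject_result <- function(x, ...) {
  cat(sprintf(
    "<znpp_subject_result> subject %s: mean z = %.3f +/- %.3f (s.e.m., n = %d)%s\n",
    x$subject_id, x$mean_z, x$sem_z, x$n_cycles,
    if (is.na(x$scaled_znpp)) "" else
      sprintf("; %.1f umol/mol haem", x$scaled_znpp)))
  invisible(x)
}

#' Split-half repeatability limits of agreement
#'
#' For each subject, compares the average ZnPP amplitude over the first
#' five tissue sites with that over the last five; the repeatability
#' limit of agreement is 1.96 times the s.d. of these per-subject
#' differences across the cohort.
#'
#' @param site_means Numeric matrix or data frame, one row per subject,
#'   exactly 10 columns of per-site mean amplitudes.
#' @return List with `differences` (per subject), `loa`
#'   (1.96 x s.d.) and `n_subjects`.
#' @export
repeatability_split <- function(site_means) {
  m <- as.matrix(site_means)
  if (ncol(m) != 10L)
    stop("repeatability split requires exactly 10 sites per subject",
         call. = FALSE)
  if (nrow(m) < 2L)
    stop("repeatability split requires at least 2 subjects", call. = FALSE)
  d <- rowMeans(m[, 1:5, drop = FALSE]) - rowMeans(m[, 6:10, drop = FALSE])
  list(differences = d, loa = 1.96 * stats::sd(d), n_subjects = nrow(m))
}
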