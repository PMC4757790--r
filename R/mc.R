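#' Define one tissue layer
#'
#' Optical properties of a plane-parallel layer at the excitation and
#' emission wavelengths, plus its fluorescence parameters. The amount of
#' fluorescence generated at an absorption event is the deposited weight
#' times the fluorophore's contribution to the absorption coefficient
#' times the quantum yield gamma.
#'
#' @param thickness_mm Layer thickness in mm (the last layer of a stack
#'   is typically thick enough to be effectively semi-infinite).
#' @param mu_a_exc,mu_s_exc,g_exc Absorption and scattering coefficients
#'   (mm^-1) and Henyey-Greenstein anisotropy at the excitation
#'   wavelength.
#' @param mu_a_em,mu_s_em,g_em Same at the emission wavelength.
#' @param frac_auto,frac_znpp Contribution of tissue autofluorophores /
#'   ZnPP to the absorption coefficient (default 0.1 for
#'   autofluorescence, 0 for ZnPP).
#' @param gamma Fluorescence quantum yield (default 1).
#' @return A named numeric vector (one row of the layer matrix).
#' @export
tissue_layer <- function(thickness_mm, mu_a_exc, mu_s_exc, g_exc,
                         mu_a_em = mu_a_exc, mu_s_em = mu_s_exc,
                         g_em = g_exc, frac_auto = 0.1, frac_znpp = 0,
                         gamma = 1) {
  vals <- c(thickness_mm = thickness_mm,
            mu_a_exc = mu_a_exc, mu_s_exc = mu_s_exc, g_exc = g_exc,
            mu_a_em = mu_a_em, mu_s_em = mu_s_em, g_em = g_em,
            frac_auto = frac_auto, frac_znpp = frac_znpp, gamma = gamma)
  if (any(!is.finite(vals))) stop("non-finite layer parameter", call. = FALSE)
  if (thickness_mm < 0 || any(vals[c(2, 3, 5, 6)] < 0))
    stop("thickness and optical coefficients must be >= 0", call. = FALSE)
  if (abs(g_exc) >= 1 || abs(g_em) >= 1)
    stop("|g| must be < 1", call. = FALSE)
  if (frac_auto < 0 || frac_auto > 1 || frac_znpp < 0 || frac_znpp > 1)
    stop("fluorophore fractions must be in [0, 1]", call. = FALSE)
  vals
}

#' Assemble a layered tissue model
#'
#' @param layers List of [tissue_layer()] rows, surface first.
#' @param n_tissue Tissue refractive index (default 1.33).
#' @return Object of class `znpp_tissue_model`.
#' @export
tissue_model <- function(layers, n_tissue = 1.33) {
  if (!length(layers)) stop("need at least one layer", call. = FALSE)
  m <- do.call(rbind, layers)
  if (sum(m[, "thickness_mm"]) <= 0)
    stop("layer stack has zero total thickness", call. = FALSE)
  structure(list(layers = m, n_tissue = n_tissue),
            class = "znpp_tissue_model")
}

#' Fibre-optic probe geometry
#'
#' A single excitation/detection fibre in contact with the tissue,
#' embedded in a perfectly reflecting ferrule. Photons are launched
#' uniformly over the fibre face with a cosine-weighted angle inside the
#' acceptance cone; a photon is detected when it exits the tissue within
#' the fibre face at an angle satisfying sin(theta) <= NA / n_tissue.
#' The fibre face is treated as index-matched to the wet mucosa.
#'
#' @param diameter_um Fibre core diameter, micrometres (200-1500).
#' @param numerical_aperture NA in air (default 0.22).
#' @param n_fiber Fibre core refractive index (recorded; not used under
#'   the index-matched contact assumption).
#' @param ferrule_diameter_mm Diameter of the reflecting ferrule annulus.
#' @return Object of class `znpp_fiber_probe`.
#' @export
fiber_probe <- function(diameter_um = 1000, numerical_aperture = 0.22,
                        n_fiber = 1.46, ferrule_diameter_mm = 12) {
  if (diameter_um < 200 || diameter_um > 1500)
    stop("fibre diameter must be in [200, 1500] um", call. = FALSE)
  if (numerical_aperture <= 0 || numerical_aperture >= 1)
    stop("NA must be in (0, 1)", call. = FALSE)
  structure(list(diameter_um = diameter_um,
                 numerical_aperture = numerical_aperture,
                 n_fiber = n_fiber,
                 ferrule_diameter_mm = ferrule_diameter_mm),
            class = "znpp_fiber_probe")
}

mc_call <- function(model, probe, n_photons, seed, fluorescence,
                    spawn_prob, n_depth_bins, depth_max_mm) {
  stopifnot(inherits(model, "znpp_tissue_model"),
            inherits(probe, "znpp_fiber_probe"))
  if (n_photons < 1000)
    stop("n_photons must be at least 1000", call. = FALSE)
  raw <- .mc_run_cpp(model$layers,
                     probe$diameter_um / 2000,     # radius in mm
                     probe$numerical_aperture,
                     model$n_tissue,
                     probe$ferrule_diameter_mm / 2,
                     as.integer(n_photons),
                     as.double(seed),
                     fluorescence,
                     spawn_prob, as.integer(n_depth_bins), depth_max_mm)
  structure(raw, class = "znpp_mc_result")
}

#' Excitation-only Monte Carlo run
#'
#' Propagates excitation photons through the layer stack and returns the
#' normalized weight ledger: detected (back into the fibre), absorbed per
#' layer, escaped through the free surface, transmitted through the
#' bottom, and the net roulette balance. The five ledger entries sum to
#' one exactly (to floating-point rounding) on every run.
#'
#' @param model A [tissue_model()].
#' @param probe A [fiber_probe()].
#' @param n_photons Number of photons (>= 1000).
#' @param seed Integer seed; identical seeds give bit-identical ledgers.
#' @param n_depth_bins,depth_max_mm Optional depth histogram of absorbed
#'   weight (for comparison with Beer-Lambert decay in non-scattering
#'   media).
#' @return Object of class `znpp_mc_result`.
#' @export
run_excitation <- function(model, probe, n_photons = 1e5, seed = 1,
                           n_depth_bins = 0, depth_max_mm = 0) {
  mc_call(model, probe, n_photons, seed, fluorescence = FALSE,
          spawn_prob = 0, n_depth_bins = n_depth_bins,
          depth_max_mm = depth_max_mm)
}

#' Fluorescence Monte Carlo run (weighted direct emission)
#'
#' At every excitation absorption event a fluorescence photon is emitted
#' isotropically with weight deposited x quantum yield, thinned by
#' `spawn_prob` (weight divided by `spawn_prob`, unbiased), and
#' transported at the emission-wavelength optical properties. Detected
#' fluorescence is tallied per source layer and per fluorophore class
#' (tissue autofluorescence vs ZnPP, which fluoresces only in layers
#' with `frac_znpp > 0`), normalized per injected excitation photon.
#'
#' @inheritParams run_excitation
#' @param spawn_prob Fluorescence spawning probability in (0, 1];
#'   1 transports a fluorescence photon at every deposition.
#' @return Object of class `znpp_mc_result` with a `fluorescence`
#'   component.
#' @export
run_fluorescence <- function(model, probe, n_photons = 1e5, seed = 1,
                             spawn_prob = 0.1) {
  if (spawn_prob <= 0 || spawn_prob > 1)
    stop("spawn_prob must be in (0, 1]", call. = FALSE)
  mc_call(model, probe, n_photons, seed, fluorescence = TRUE,
          spawn_prob = spawn_prob, n_depth_bins = 0, depth_max_mm = 0)
}

#' @export
print.znpp_mc_result <- function(x, ...) {
  e <- x$excitation
  cat(sprintf("<znpp_mc_result> %g photons, seed %g\n", x$n_photons, x$seed))
  cat(sprintf("  excitation: detected %.4g, absorbed %.4g, escaped %.4g, transmitted %.4g\n",
              e$detected, sum(e$absorbed_by_layer), e$escaped, e$transmitted))
  if (!is.null(x$fluorescence))
    cat(sprintf("  fluorescence detected: auto %.4g, ZnPP %.4g (per injected photon)\n",
                x$fluorescence$detected[["autofluorescence"]],
                x$fluorescence$detected[["znpp"]]))
  invisible(x)
}

#' Energy-ledger defect of a Monte Carlo run
#'
#' Relative deviation of the weight ledger from exact conservation. The
#' excitation ledger must sum to 1; each fluorescence class ledger must
#' sum to its generated weight.
#'
#' @param result A `znpp_mc_result`.
#' @return Maximum relative defect over the checked ledgers.
#' @export
mc_ledger_defect <- function(result) {
  e <- result$excitation
  defect <- abs(e$detected + sum(e$absorbed_by_layer) + e$escaped +
                  e$transmitted + e$roulette_net - 1)
  if (!is.null(result$fluorescence)) {
    f <- result$fluorescence
    for (cls in c("autofluorescence", "znpp")) {
      gen <- f$generated[[cls]]
      if (gen > 0) {
        tot <- f$detected[[cls]] + f$absorbed[[cls]] + f$escaped[[cls]] +
          f$transmitted[[cls]] + f$roulette_net[[cls]]
        defect <- max(defect, abs(tot - gen) / gen)
      }
    }
  }
  defect
}

#' Point-source emission detection fraction (geometry oracle hook)
#'
#' Transports isotropically emitted photons from an on-axis point at a
#' given depth through vacuum to the fibre face. Used to validate the
#' detection geometry against the closed form
#' `(1 - cos(theta*)) / 2`, `theta* = min(atan(r/depth), asin(NA/n))`.
#'
#' @param depth_mm Source depth below the fibre face.
#' @param probe A [fiber_probe()].
#' @param n_tissue Refractive index used for the NA acceptance.
#' @param n_photons,seed Simulation size and seed.
#' @return Detected fraction.
#' @export
run_point_emission <- function(depth_mm, probe, n_tissue = 1.33,
                               n_photons = 1e6, seed = 1) {
  stopifnot(inherits(probe, "znpp_fiber_probe"))
  .mc_point_emission_cpp(depth_mm, probe$diameter_um / 2000,
                         probe$numerical_aperture, n_tissue,
                         as.integer(n_photons), as.double(seed))
}

#' Blood absorption index from simulated autofluorescence weights
#'
#' Closed-form two-band index: detected autofluorescence at 561 and
#' 576 nm is divided by `exp(-a * mu_a)` with `a` chosen so both
#' corrected weights agree:
#' \deqn{a = \ln(G_{576}/G_{561}) / (\mu_{561} - \mu_{576}).}
#' More blood suppresses 576 nm (the stronger absorption) relative to
#' 561 nm, giving a larger index.
#'
#' @param g561,g576 Detected autofluorescence weights at 561 and 576 nm.
#' @param refs A `znpp_reflib` supplying the whole-blood coefficients
#'   (or pass `mu561`, `mu576` directly).
#' @param mu561,mu576 Whole-blood absorption coefficients (mm^-1).
#' @return The blood absorption index (effective path, mm).
#' @export
simulated_blood_index <- function(g561, g576, refs = NULL,
                                  mu561 = NULL, mu576 = NULL) {
  if (!is.null(refs)) {
    mu561 <- refs$mu_a_fun(561); mu576 <- refs$mu_a_fun(576)
  }
  if (any(c(g561, g576) <= 0))
    stop("autofluorescence weights must be positive", call. = FALSE)
  log(g576 / g561) / (mu561 - mu576)
}

#' Three-layer mucosa model of the measurement geometry
#'
#' Builds the epithelium / superficial stroma / lower stroma stack used
#' throughout the simulations: a fluorophore-free (in ZnPP) epithelium
#' over two blood-perfused stromal layers differing only in blood
#' content. The blood contribution to the absorption coefficients enters
#' through the vessel-packaging correction at the excitation (425 nm)
#' and emission wavelengths; baseline (bloodless) tissue absorption and
#' scattering are configurable defaults chosen at the middle of the
#' physiological range for oral mucosa.
#'
#' @param refs A `znpp_reflib`.
#' @param epithelium_um Epithelium thickness (50-400 um range studied).
#' @param vessel_diameter_um Mean vessel diameter (0 = evenly
#'   distributed erythrocytes).
#' @param blood_fraction,blood_fraction_lower Blood volume fraction of
#'   the superficial / lower stroma.
#' @param emission_nm Emission wavelength for the emission-side optical
#'   properties (561, 576 or 593).
#' @param mu_a_base_exc,mu_a_base_em Bloodless tissue absorption
#'   (mm^-1).
#' @param mu_s_exc,mu_s_em,g Scattering coefficients (mm^-1) and
#'   anisotropy.
#' @param superficial_um,lower_mm Stromal thicknesses.
#' @return A [tissue_model()].
#' @export
default_tissue_model <- function(refs, epithelium_um = 100,
                                 vessel_diameter_um = 24,
                                 blood_fraction = 0.01,
                                 blood_fraction_lower = blood_fraction,
                                 emission_nm = 593,
                                 mu_a_base_exc = 0.1, mu_a_base_em = 0.03,
                                 mu_s_exc = 20, mu_s_em = 15, g = 0.9,
                                 superficial_um = 200, lower_mm = 10) {
  stopifnot(inherits(refs, "znpp_reflib"))
  blood_exc <- function(f) {
    if (f <= 0) return(0)
    corrected_mu_a(refs$mu_a_whole_425, vessel_geometry(vessel_diameter_um, f))
  }
  blood_em <- function(f) {
    if (f <= 0) return(0)
    corrected_mu_a(refs$mu_a_fun(emission_nm),
                   vessel_geometry(vessel_diameter_um, f))
  }
  stroma <- function(thick_mm, f) {
    tissue_layer(thick_mm,
                 mu_a_exc = mu_a_base_exc + blood_exc(f), mu_s_exc = mu_s_exc,
                 g_exc = g,
                 mu_a_em = mu_a_base_em + blood_em(f), mu_s_em = mu_s_em,
                 g_em = g, frac_auto = 0.1, frac_znpp = 0.1, gamma = 1)
  }
  tissue_model(list(
    tissue_layer(epithelium_um / 1000,
                 mu_a_exc = mu_a_base_exc, mu_s_exc = mu_s_exc, g_exc = g,
                 mu_a_em = mu_a_base_em, mu_s_em = mu_s_em, g_em = g,
                 frac_auto = 0.1, frac_znpp = 0, gamma = 1),
    stroma(superficial_um / 1000, blood_fraction),
    stroma(lower_mm, blood_fraction_lower)))
}

#' Sweep Monte Carlo simulations over a configuration grid
#'
#' Runs one fluorescence simulation per grid cell. Vessel diameter
#' enters only through the packaged absorption coefficient applied to
#' the stromal blood contribution.
#'
#' @param refs A `znpp_reflib`.
#' @param grid Data frame with any of the columns `epithelium_um`,
#'   `vessel_diameter_um`, `blood_fraction`, `fiber_diameter_um`,
#'   `emission_nm`; missing columns take the defaults of
#'   [default_tissue_model()] / [fiber_probe()].
#' @param n_photons,seed,spawn_prob Simulation size per cell, base seed
#'   (cell i uses `seed + i - 1`) and spawn thinning.
#' @return `grid` with appended result columns `detected_excitation`,
#'   `detected_autofluorescence`, `detected_znpp`, `ledger_defect`.
#' @export
mc_sweep <- function(refs, grid, n_photons = 1e4, seed = 1,
                     spawn_prob = 0.1) {
  grid <- as.data.frame(grid)
  n <- nrow(grid)
  res <- data.frame(detected_excitation = numeric(n),
                    detected_autofluorescence = numeric(n),
                    detected_znpp = numeric(n),
                    ledger_defect = numeric(n))
  for (i in seq_len(n)) {
    g <- grid[i, , drop = FALSE]
    model <- default_tissue_model(
      refs,
      epithelium_um = g$epithelium_um %||% 100,
      vessel_diameter_um = g$vessel_diameter_um %||% 24,
      blood_fraction = g$blood_fraction %||% 0.01,
      emission_nm = g$emission_nm %||% 593)
    probe <- fiber_probe(diameter_um = g$fiber_diameter_um %||% 1000)
    r <- run_fluorescence(model, probe, n_photons = n_photons,
                          seed = seed + i - 1, spawn_prob = spawn_prob)
    res$detected_excitation[i] <- r$excitation$detected
    res$detected_autofluorescence[i] <-
      r$fluorescence$detected[["autofluorescence"]]
    res$detected_znpp[i] <- r$fluorescence$detected[["znpp"]]
    res$ledger_defect[i] <- mc_ledger_defect(r)
  }
  cbind(grid, res)
}
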