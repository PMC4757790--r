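# Shared fixtures: one reference library per test run, and small
# constructors used across files.

test_refs <- load_reference_library()

# smooth subject-like autofluorescence background on the common grid
smooth_background <- function(grid = test_refs$grid,
                              levels = c(110, 95, 70, 50, 35, 25)) {
  stats::spline(c(500, 550, 600, 650, 700, 750), levels, xout = grid,
                method = "natural")$y
}

# difference spectrum built directly from components (bypassing the
# generator), matching the analysis model: imprinted background plus
# detector-level porphyrin bands
make_diff <- function(background, a = 0, z = 0, p = 0,
                      refs = test_refs) {
  vals <- background * exp(-a * refs$mu_a_blood) +
    z * refs$znpp$shape + p * refs$ppix$shape
  structure(list(wavelength_nm = refs$grid, values = vals, norm_k = 1),
            class = "znpp_diffspec")
}

make_calibrated <- function(values, excitation = 407,
                            grid = test_refs$grid) {
  spectrum_new(grid, values, excitation, 1, calibrated = TRUE)
}

# tiny raw session: n_sites x n_cycles, constant spectra, instant to build
tiny_session <- function(n_sites = 2, n_cycles = 2, valid = NULL,
                         grid = seq(500, 750, by = 2)) {
  dark <- spectrum_new(grid, rep(40, length(grid)), NA, 200)
  f425 <- spectrum_new(grid, 40 + 200 * seq(2, 1, length.out = length(grid)),
                       425, 200)
  f407 <- spectrum_new(grid, 40 + 180 * seq(2, 1, length.out = length(grid)),
                       407, 200)
  cyc <- measurement_cycle(f425, f407, dark)
  if (is.null(valid)) valid <- rep(TRUE, n_sites)
  session_new("tiny", lapply(seq_len(n_sites), function(i)
    list(cycles = rep(list(cyc), n_cycles), valid = valid[i],
         blood_index_at_start = 0.009)))
}
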