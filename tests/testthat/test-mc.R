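# Small-photon-budget Monte Carlo checks. Each run's weight ledger is
# exact by construction (roulette keeps an explicit balance), so
# conservation is asserted tightly; physical comparisons use analytic
# oracles with Monte Carlo standard errors.

simple_model <- function(mu_a = 0.3, mu_s = 10, g = 0.8,
                         mu_a_em = 0.1, mu_s_em = 8,
                         frac_znpp = 0.1) {
  tissue_model(list(
    tissue_layer(0.1, mu_a, mu_s, g, mu_a_em, mu_s_em, g,
                 frac_auto = 0.1, frac_znpp = 0),
    tissue_layer(10, mu_a, mu_s, g, mu_a_em, mu_s_em, g,
                 frac_auto = 0.1, frac_znpp = frac_znpp)))
}

test_that("same seed and inputs give bit-identical ledgers", {
  m <- simple_model()
  p <- fiber_probe()
  r1 <- run_excitation(m, p, 5000, seed = 7)
  r2 <- run_excitation(m, p, 5000, seed = 7)
  expect_identical(r1$excitation, r2$excitation)
  r3 <- run_excitation(m, p, 5000, seed = 8)
  expect_false(identical(r1$excitation, r3$excitation))
})

test_that("energy ledgers are conserved on every run", {
  p <- fiber_probe()
  for (seed in 1:3) {
    r <- run_excitation(simple_model(), p, 5000, seed = seed)
    expect_lt(mc_ledger_defect(r), 1e-6)
  }
  rf <- run_fluorescence(simple_model(), p, 3000, seed = 4,
                         spawn_prob = 0.05)
  expect_lt(mc_ledger_defect(rf), 1e-6)
})

test_that("transparent layers transmit everything launched into them", {
  m <- tissue_model(list(tissue_layer(5, 0, 0, 0, frac_auto = 0)))
  r <- run_excitation(m, fiber_probe(), 5000, seed = 1)
  e <- r$excitation
  expect_equal(e$transmitted + e$escaped, 1, tolerance = 1e-12)
  expect_equal(sum(e$absorbed_by_layer), 0)
  expect_equal(e$transmitted, 1)  # launch cone points into the tissue
})

test_that("a pure absorber reproduces Beer-Lambert depth deposition", {
  mu_a <- 1
  m <- tissue_model(list(tissue_layer(10, mu_a, 0, 0, frac_auto = 0)))
  p <- fiber_probe()
  nbins <- 20; zmax <- 3
  r <- run_excitation(m, p, 1e5, seed = 2, n_depth_bins = nbins,
                      depth_max_mm = zmax)
  expect_equal(r$excitation$detected, 0)
  # oracle: depth density averaged over the NA-limited cosine launch
  # cone, where sin^2(theta) is uniform on [0, (NA/n)^2]
  s2max <- (0.22 / 1.33)^2
  u <- seq(1e-6, 1 - 1e-6, length.out = 2001) * s2max
  cosu <- sqrt(1 - u)
  edges <- seq(0, zmax, length.out = nbins + 1)
  expected <- vapply(seq_len(nbins), function(b) {
    mean(exp(-mu_a * edges[b] / cosu) - exp(-mu_a * edges[b + 1] / cosu))
  }, numeric(1))
  se <- sqrt(expected * (1 - expected) / 1e5)
  dev <- abs(r$depth_profile - expected) / se
  expect_lt(max(dev), 3)
})

test_that("fluorescence behaves linearly and respects source placement", {
  p <- fiber_probe()
  # gamma = 0: no fluorescence at all
  m0 <- tissue_model(list(tissue_layer(5, 0.3, 10, 0.8, frac_auto = 0.1,
                                       gamma = 0)))
  r0 <- run_fluorescence(m0, p, 2000, seed = 3, spawn_prob = 0.1)
  expect_equal(r0$fluorescence$generated[["autofluorescence"]], 0)
  expect_equal(r0$fluorescence$detected[["autofluorescence"]], 0)

  # doubling the ZnPP contribution doubles detected ZnPP fluorescence
  r1 <- run_fluorescence(simple_model(frac_znpp = 0.1), p, 3000,
                         seed = 5, spawn_prob = 0.05)
  r2 <- run_fluorescence(simple_model(frac_znpp = 0.2), p, 3000,
                         seed = 5, spawn_prob = 0.05)
  expect_equal(r2$fluorescence$detected[["znpp"]],
               2 * r1$fluorescence$detected[["znpp"]], tolerance = 1e-9)

  # ZnPP restricted to stroma: nothing attributed to the epithelium
  det <- r1$fluorescence$detected_by_layer
  expect_equal(unname(det[1, "znpp"]), 0)
  expect_gt(det[2, "znpp"], 0)
  expect_gt(det[1, "autofluorescence"], 0)
})

test_that("detection geometry matches the solid-angle closed form", {
  p <- fiber_probe(diameter_um = 1000)
  r_fib <- 0.5; na_t <- 0.22 / 1.33
  for (depth in c(0.2, 1, 3)) {
    frac <- run_point_emission(depth, p, n_photons = 2e5, seed = 6)
    theta_star <- min(atan(r_fib / depth), asin(na_t))
    expected <- (1 - cos(theta_star)) / 2
    se <- sqrt(expected * (1 - expected) / 2e5)
    expect_lt(abs(frac - expected), 3 * se + 1e-12)
  }
})

test_that("larger fibres detect at least as much fluorescence", {
  d200 <- run_fluorescence(simple_model(), fiber_probe(200), 4000,
                           seed = 11, spawn_prob = 0.05)
  d1000 <- run_fluorescence(simple_model(), fiber_probe(1000), 4000,
                            seed = 11, spawn_prob = 0.05)
  expect_gt(d1000$fluorescence$detected[["autofluorescence"]],
            d200$fluorescence$detected[["autofluorescence"]])
})

test_that("simulated blood index inverts the imposed absorption exactly", {
  mu561 <- test_refs$mu_a_fun(561)
  mu576 <- test_refs$mu_a_fun(576)
  expect_equal(simulated_blood_index(0.4, 0.4, test_refs), 0)
  a0 <- 0.007
  g0 <- 0.35
  expect_equal(
    simulated_blood_index(g0 * exp(-a0 * mu561), g0 * exp(-a0 * mu576),
                          test_refs), a0, tolerance = 1e-12)
  expect_error(simulated_blood_index(0, 1, test_refs), "positive")
})

test_that("more stromal blood raises the simulated blood index", {
  p <- fiber_probe()
  index_for <- function(f_blood) {
    g <- vapply(c(561, 576), function(em) {
      m <- default_tissue_model(test_refs, blood_fraction = f_blood,
                                emission_nm = em)
      r <- run_fluorescence(m, p, 4000, seed = 17, spawn_prob = 0.05)
      r$fluorescence$detected[["autofluorescence"]]
    }, numeric(1))
    simulated_blood_index(g[1], g[2], test_refs)
  }
  expect_gt(index_for(0.04), index_for(0.01))
})

test_that("a one-cell sweep equals a direct run with the same seed", {
  grid <- data.frame(epithelium_um = 100, vessel_diameter_um = 24,
                     blood_fraction = 0.01, fiber_diameter_um = 1000)
  sw <- mc_sweep(test_refs, grid, n_photons = 2000, seed = 19,
                 spawn_prob = 0.1)
  direct <- run_fluorescence(default_tissue_model(test_refs),
                             fiber_probe(1000), 2000, seed = 19,
                             spawn_prob = 0.1)
  expect_equal(sw$detected_znpp, direct$fluorescence$detected[["znpp"]])
  expect_equal(sw$detected_excitation, direct$excitation$detected)
  # vessel-diameter cells feed the packaged 425-nm coefficients
  mu <- vapply(c(24, 38, 52), function(d)
    corrected_mu_a(test_refs$mu_a_whole_425, vessel_geometry(d, 0.01)),
    numeric(1))
  expect_equal(mu, c(0.413, 0.263, 0.192), tolerance = 0.002)
})
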