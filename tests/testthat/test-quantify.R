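test_that("difference spectrum normalises, subtracts, and scales", {
  g <- test_refs$grid
  b <- smooth_background()
  f <- make_calibrated(b, 425)
  f2 <- make_calibrated(b, 407)
  d <- difference_spectrum(f, f2)
  expect_equal(d$norm_k, 1)
  expect_true(all(abs(d$values) < 1e-12))

  # invariance under common multiplicative rescaling: k unchanged,
  # values scale linearly
  f425 <- make_calibrated(b + 3 * test_refs$znpp$shape, 425)
  f407 <- make_calibrated(0.9 * b + 0.3 * test_refs$znpp$shape, 407)
  d1 <- difference_spectrum(f425, f407)
  d2 <- difference_spectrum(
    make_calibrated(5 * f425$intensity, 425),
    make_calibrated(5 * f407$intensity, 407))
  expect_equal(d2$norm_k, d1$norm_k, tolerance = 1e-12)
  expect_equal(d2$values, 5 * d1$values, tolerance = 1e-12)

  expect_error(difference_spectrum(
    make_calibrated(-b, 425), make_calibrated(-b, 407)), "degenerate")
  raw <- spectrum_new(g, b, 425, 200)
  expect_error(difference_spectrum(raw, f2), "calibrated")
})

test_that("the difference spectrum retains ~78% of the ZnPP amplitude", {
  gs <- spectrum_gen_spec(noise_sd = 0, background_ratio_sd = 0,
                          ppix_amplitude = 0, blood_path_a = 0, seed = 5)
  cyc <- calibrate_cycle(generate_spectrum_pair(gs, test_refs))
  d <- difference_spectrum(cyc$f425, cyc$f407)
  at593 <- d$values[d$wavelength_nm == 593]
  expect_equal(d$norm_k, 1, tolerance = 1e-9)
  expect_equal(at593, 0.78 * gs$znpp_amplitude, tolerance = 1e-6)
})

test_that("background suppression is exact for identical shapes, >=90% at default", {
  # identical background shapes (flat ratio field): residual exactly zero
  gs0 <- spectrum_gen_spec(noise_sd = 0, background_ratio_sd = 0,
                           znpp_amplitude = 0, ppix_amplitude = 0, seed = 2)
  cyc0 <- calibrate_cycle(generate_spectrum_pair(gs0, test_refs))
  d0 <- difference_spectrum(cyc0$f425, cyc0$f407)
  expect_lt(max(abs(d0$values)), 1e-9)

  # default 5% shape perturbation: suppression at 593 nm stays >= 90%
  # on average (the instrument's observed regime is 93 +/- 2%)
  sup <- vapply(1:20, function(s) {
    gs <- spectrum_gen_spec(noise_sd = 0, znpp_amplitude = 0,
                            ppix_amplitude = 0, seed = s)
    cyc <- calibrate_cycle(generate_spectrum_pair(gs, test_refs))
    d <- difference_spectrum(cyc$f425, cyc$f407)
    i <- which(d$wavelength_nm == 593)
    1 - abs(d$values[i]) / cyc$f425$intensity[i]
  }, numeric(1))
  expect_gte(mean(sup), 0.90)
})

test_that("second derivative matches closed forms on a uniform grid", {
  x <- seq(500, 700, by = 1)
  expect_true(all(abs(second_derivative(3 + 2 * x)) < 1e-9))
  alpha <- 0.05
  expect_equal(second_derivative(alpha * x^2),
               rep(2 * alpha, length(x) - 2), tolerance = 1e-6)
  # sine of period P picks up a factor (2 pi / P)^2, within 1% for
  # P >= 20 nm at 1-nm sampling
  for (P in c(20, 50, 100)) {
    v <- sin(2 * pi * x / P)
    d2 <- second_derivative(v)
    expect_equal(max(abs(d2)), (2 * pi / P)^2, tolerance = 0.01)
  }
  expect_error(second_derivative(c(1, 2)), "3 points")
  expect_error(
    fit_difference_spectrum(
      structure(list(wavelength_nm = c(500, 501, 503, 510),
                     values = rep(1, 4), norm_k = 1),
                class = "znpp_diffspec"), test_refs),
    "uniform")
})

test_that("the fit recovers noiseless generated amplitudes", {
  for (s in c(1, 2)) {
    gs <- spectrum_gen_spec(noise_sd = 0, seed = s)
    cyc <- calibrate_cycle(generate_spectrum_pair(gs, test_refs))
    d <- difference_spectrum(cyc$f425, cyc$f407)
    fit <- fit_difference_spectrum(d, test_refs)
    truth <- expected_diff_amplitude(gs, test_refs, norm_k = d$norm_k)
    expect_equal(fit$z, unname(truth["z"]), tolerance = 0.01)
    expect_equal(fit$p, unname(truth["p"]), tolerance = 0.01)
    expect_equal(fit$a, gs$blood_path_a, tolerance = 0.05)
    expect_true(fit$converged)
  }
})

test_that("a featureless smooth background yields near-zero amplitudes", {
  grid <- test_refs$grid
  cubic <- 30 - 0.05 * (grid - 500) + 2e-4 * (grid - 500)^2 -
    3e-7 * (grid - 500)^3
  fit <- fit_difference_spectrum(make_diff(cubic), test_refs)
  # residual amplitudes are limited by the discrete-grid orthogonality
  # of the smoothed curvature operator, a few 1e-4 of the background
  scale <- max(abs(cubic))
  expect_lt(abs(fit$z) / scale, 5e-4)
  expect_lt(abs(fit$p) / scale, 5e-4)
  expect_lt(fit$a, 1e-4)
})

test_that("fit objective at the optimum does not exceed the truth's", {
  gs <- spectrum_gen_spec(noise_sd = 0, seed = 9)
  cyc <- calibrate_cycle(generate_spectrum_pair(gs, test_refs))
  d <- difference_spectrum(cyc$f425, cyc$f407)
  fit <- fit_difference_spectrum(d, test_refs)
  # evaluate the objective at the generating parameters
  truth <- expected_diff_amplitude(gs, test_refs, norm_k = d$norm_k)
  cfg <- quantify_config()
  sel <- d$wavelength_nm >= 560 & d$wavelength_nm <= 750
  wl <- d$wavelength_nm[sel]
  B_true <- (d$values[sel] - truth["z"] * test_refs$znpp$shape[sel] -
               truth["p"] * test_refs$ppix$shape[sel]) /
    exp(-gs$blood_path_a * test_refs$mu_a_blood[sel])
  d2 <- second_derivative(B_true, 1, cfg$sg.window, cfg$sg.order)
  trim <- (cfg$sg.window - 1) / 2
  obj_truth <- sum(d2[(trim + 1):(length(d2) - trim)]^2)
  expect_lte(fit$objective_value, obj_truth * (1 + 1e-9))
})

test_that("recovered z is linear in the generated amplitude", {
  z0 <- c(0, 2, 4, 6, 8, 10)
  zhat <- vapply(z0, function(z) {
    gs <- spectrum_gen_spec(noise_sd = 0, background_ratio_sd = 0,
                            znpp_amplitude = z, seed = 31)
    cyc <- calibrate_cycle(generate_spectrum_pair(gs, test_refs))
    fit <- fit_difference_spectrum(
      difference_spectrum(cyc$f425, cyc$f407), test_refs)
    fit$z
  }, numeric(1))
  co <- stats::lm(zhat ~ z0)
  expect_gt(summary(co)$r.squared, 0.999)
  # slope relative to the 78% difference-spectrum retention
  expect_equal(unname(coef(co)[2]), 0.78, tolerance = 0.02)
})

test_that("recovered z is stable across the green zone of blood paths", {
  zhat <- vapply(c(0.0072, 0.010, 0.015, 0.020), function(a) {
    gs <- spectrum_gen_spec(noise_sd = 0, blood_path_a = a, seed = 13)
    cyc <- calibrate_cycle(generate_spectrum_pair(gs, test_refs))
    fit <- fit_difference_spectrum(
      difference_spectrum(cyc$f425, cyc$f407), test_refs)
    fit$z
  }, numeric(1))
  expect_lt(diff(range(zhat)) / mean(zhat), 0.05)
})

test_that("blood absorption index inverts an imposed absorption imprint", {
  b <- smooth_background()
  for (a0 in c(0.005, 0.009, 0.02)) {
    f <- make_calibrated(b * exp(-a0 * test_refs$mu_a_blood), 407)
    bi <- blood_absorption_index(f, test_refs)
    expect_equal(bi$index, a0, tolerance = 0.05)
    expect_false(bi$flat)
  }
  # smooth background with no imprint: index 0, flat flag, red zone
  bi0 <- blood_absorption_index(make_calibrated(b, 407), test_refs)
  expect_equal(bi0$index, 0)
  expect_true(bi0$flat)
  expect_equal(bi0$zone, "red")

  # exactly invariant to multiplicative background scaling
  f1 <- make_calibrated(b * exp(-0.009 * test_refs$mu_a_blood), 407)
  f2 <- make_calibrated(7 * f1$intensity, 407)
  expect_equal(blood_absorption_index(f2, test_refs)$index,
               blood_absorption_index(f1, test_refs)$index,
               tolerance = 1e-12)
})

test_that("zone thresholds follow the LED table with closed left bounds", {
  th <- quantify_config()$index.thresholds
  cases <- list(c(0.0050, "orange"),      # between 0.42e-2 and 0.70e-2
                c(0.0070, "green"),       # boundary is green
                c(0.0071, "green"),
                c(0.0042, "orange"),
                c(0.0041, "red_orange"),
                c(0.0014, "red_orange"),
                c(0.0013, "red"),
                c(0, "red"))
  for (cs in cases)
    expect_equal(znppfluor:::zone_from_index(as.numeric(cs[1]), th), cs[2])

  mk <- function(zone) structure(list(index = 0, zone = zone, flat = FALSE),
                                 class = "znpp_blood_index")
  expect_true(accept_site(mk("green")))
  expect_false(accept_site(mk("orange")))
  expect_false(accept_site(mk("red")))
})

test_that("two-band index mode matches its closed form", {
  b <- smooth_background()
  a0 <- 0.007
  # impose the imprint on a *flat* baseline pair of bands as in the
  # simulation context where the two-band form is exact
  mu <- test_refs$mu_a_fun(test_refs$grid)
  f <- make_calibrated(100 * exp(-a0 * mu), 407)
  bi <- blood_absorption_index(f, test_refs,
                               config = list(index.mode = "two_band"))
  expect_equal(bi$index, a0, tolerance = 0.02)
})

test_that("subject quantitation averages cycles and reports s.e.m.", {
  gs <- spectrum_gen_spec(seed = 21)
  ses <- generate_session(gs, test_refs, n_sites = 2, cycles_per_site = 3)
  res <- quantify_subject(ses, test_refs)
  expect_equal(res$n_cycles, 6)
  expect_equal(res$mean_z, mean(res$cycles$z))
  expect_equal(res$sem_z, sd(res$cycles$z) / sqrt(6))
  expect_false(res$sem_degenerate)
  expect_true(is.na(res$scaled_znpp))
  res2 <- quantify_subject(ses, test_refs, scale = 1.28)
  expect_equal(res2$scaled_znpp, 1.28 * res2$mean_z)

  # single valid cycle: mean defined, s.e.m. degenerates to 0 with flag
  ses1 <- generate_session(gs, test_refs, n_sites = 1, cycles_per_site = 1)
  r1 <- quantify_subject(ses1, test_refs)
  expect_equal(r1$n_cycles, 1)
  expect_equal(r1$sem_z, 0)
  expect_true(r1$sem_degenerate)
})

test_that("split-half repeatability matches its closed form", {
  # identical halves: zero limits of agreement
  m <- matrix(rep(1:4, each = 10), nrow = 4, byrow = TRUE)
  expect_equal(repeatability_split(m)$loa, 0)

  # site means mu_s + N(0, sigma_site): LoA ~ 1.96 sigma sqrt(2/5)
  sigma_site <- 2.5
  sim <- withr::with_seed(42, {
    t(replicate(56, 60 + rnorm(10, 0, sigma_site)))
  })
  rs <- repeatability_split(sim)
  expect_equal(rs$loa, 1.96 * sigma_site * sqrt(2 / 5), tolerance = 0.15)

  expect_error(repeatability_split(sim[, 1:8]), "10 sites")
  expect_error(repeatability_split(sim[1, , drop = FALSE]), "2 subjects")
})
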