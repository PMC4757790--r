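test_that("robust zero-offset slope is exact, equivariant, and robust", {
  ref <- c(10, 20, 30, 40, 80)
  expect_equal(robust_proportional_slope(2.5 * ref, ref), 2.5,
               tolerance = 1e-9)
  # scale equivariance
  dev <- 2.5 * ref + c(0.1, -0.2, 0, 0.2, -0.1)
  b <- robust_proportional_slope(dev, ref)
  expect_equal(robust_proportional_slope(3 * dev, ref), 3 * b,
               tolerance = 1e-9)
  expect_error(robust_proportional_slope(1:2, 1:2), "3 complete pairs")
  expect_error(robust_proportional_slope(1:3, rep(0, 3)), "all zero")

  # 10% gross outliers (x10 contamination): robust slope stays within
  # 3% of truth while ordinary least squares is dragged far off
  sim <- withr::with_seed(101, {
    x <- runif(100, 20, 150)
    y <- 2 * x + rnorm(100, 0, 2)
    y[1:10] <- 10 * y[1:10]
    list(x = x, y = y)
  })
  b_rob <- robust_proportional_slope(sim$y, sim$x)
  b_ols <- sum(sim$x * sim$y) / sum(sim$x^2)
  expect_equal(b_rob, 2, tolerance = 0.03)
  expect_gt(abs(b_ols - 2) / 2, 0.03)
})

test_that("tau-scale is consistent, equivariant, and high-breakdown", {
  expect_equal(tau_scale(rep(5, 20)), 0)
  x <- withr::with_seed(7, rnorm(1e5))
  expect_equal(tau_scale(x), 1, tolerance = 0.02)
  # scale equivariance
  expect_equal(tau_scale(-3.5 * x), 3.5 * tau_scale(x), tolerance = 1e-9)
  # 10% gross outliers at +50: the tau-estimate stays bounded near the
  # clean scale (each capped outlier adds rho = c2^2, which at 10%
  # contamination inflates the estimate to ~1.2) while the classical
  # s.d. explodes
  xc <- withr::with_seed(8, {
    y <- rnorm(2000); y[1:200] <- 50; y
  })
  expect_lt(tau_scale(xc), 1.3)
  expect_gt(tau_scale(xc), 1)
  expect_gt(sd(xc), 10)
  expect_error(tau_scale(1), "at least 2")
})

test_that("robust limits of agreement summarise paired differences", {
  # identical methods: zero bias and zero limits
  v <- c(31, 45, 52, 60, 75, 90)
  agr0 <- robust_bland_altman(v, v, n_boot = 0)
  expect_equal(agr0$bias, 0)
  expect_equal(agr0$loa, 0)

  # invariant under common additive shifts of both methods
  d <- withr::with_seed(3, rnorm(56, 0, 9.69))
  ref <- withr::with_seed(4, runif(56, 20, 150))
  a1 <- robust_bland_altman(ref + d, ref, n_boot = 200, seed = 5)
  a2 <- robust_bland_altman(ref + d + 100, ref + 100, n_boot = 200,
                            seed = 5)
  expect_equal(a1$bias, a2$bias, tolerance = 1e-9)
  expect_equal(a1$loa, a2$loa, tolerance = 1e-9)

  # device noise sd 19/1.96 at n = 56: LoA comes out near 19
  expect_equal(a1$loa, 19, tolerance = 0.15)
  expect_true(a1$ci_loa[1] < a1$loa && a1$loa < a1$ci_loa[2])

  # bootstrap determinism
  a3 <- robust_bland_altman(ref + d, ref, n_boot = 200, seed = 5)
  expect_identical(a1$ci_loa, a3$ci_loa)
  expect_identical(a1$ci_bias, a3$ci_bias)
  expect_error(robust_bland_altman(ref + d, ref, n_boot = 10),
               "seed is required")

  # fewer than 5 pairs: point estimates returned, CIs refused
  small <- robust_bland_altman(c(1, 2, 3), c(1.1, 2.2, 2.9),
                               n_boot = 100, seed = 1)
  expect_true(all(is.na(small$ci_loa)))
  expect_false(is.na(small$loa))
})

test_that("the LoA confidence factor follows 1.96 sqrt(3/n)", {
  expect_equal(loa_ci_halfwidth_factor(56), 0.4537, tolerance = 5e-4)
  expect_equal(loa_ci_halfwidth_factor(3), 1.96)
  expect_lt(loa_ci_halfwidth_factor(1e8), 1e-3)
  expect_error(loa_ci_halfwidth_factor(1), "at least 2")
})

test_that("diagnostic metrics are Bayes-consistent across forms", {
  # counts -> rates -> Bayes recomputation agrees to 1e-12
  dm <- diagnostic_metrics_from_counts(tp = 34, fp = 2, fn = 1, tn = 19)
  dm2 <- diagnostic_metrics_from_rates(dm$sensitivity, dm$specificity,
                                       dm$prevalence)
  expect_equal(dm2$ppv, dm$ppv, tolerance = 1e-12)
  expect_equal(dm2$npv, dm$npv, tolerance = 1e-12)

  # the study's printed operating points
  r1 <- diagnostic_metrics_from_rates(0.97, 0.90, 35 / 56)
  expect_equal(round(100 * r1$ppv), 94)
  expect_equal(round(100 * r1$npv), 95)
  r2 <- diagnostic_metrics_from_rates(0.89, 0.90, 35 / 56)
  expect_equal(round(100 * r2$npv), 83)

  r3 <- diagnostic_metrics_from_rates(1, 1, 0.3)
  expect_equal(r3$ppv, 1)
  expect_equal(r3$npv, 1)

  # empty margins are flagged undefined, not silently zero
  dm3 <- diagnostic_metrics_from_counts(tp = 0, fp = 0, fn = 0, tn = 5)
  expect_true("sensitivity" %in% dm3$undefined)
  expect_true(is.na(dm3$sensitivity))
  expect_error(diagnostic_metrics_from_rates(1.2, 0.5, 0.5), "0, 1")
})

test_that("Youden cutpoint equals exhaustive maximisation", {
  brute <- function(scores, labels) {
    # independent oracle: scan every candidate threshold directly
    cand <- sort(unique(c(scores - 1e-9, scores + 1e-9,
                          min(scores) - 1, max(scores) + 1)))
    J <- vapply(cand, function(t) {
      pos <- scores > t
      sum(pos & labels) / sum(labels) +
        sum(!pos & !labels) / sum(!labels) - 1
    }, numeric(1))
    max(J)
  }
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(10:1000, 1)
      labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)
      scores <- round(rnorm(n, ifelse(labels, 1, 0), 1.2), 1)  # with ties
      res <- roc_optimal_cutpoint(scores, labels)
      expect_equal(res$youden, brute(scores, labels), tolerance = 1e-9)
    }
  })

  # perfectly separated classes
  res <- roc_optimal_cutpoint(c(1, 2, 3, 10, 11, 12),
                              c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(res$youden, 1)
  expect_true(res$threshold > 3 && res$threshold < 10)
  expect_error(roc_optimal_cutpoint(1:5, rep(TRUE, 5)), "both classes")
})

test_that("Youden cutpoint agrees with an independent ROC implementation", {
  co <- generate_cohort(cohort_gen_spec(seed = 9))
  labels <- co$hplc_mean > 50
  res <- roc_optimal_cutpoint(co$device_value, labels)
  roc <- pROC::roc(labels, co$device_value, quiet = TRUE,
                   direction = "<")
  best <- pROC::coords(roc, "best", best.method = "youden",
                       transpose = FALSE)
  J_ext <- max(best$sensitivity + best$specificity - 1)
  expect_equal(res$youden, J_ext, tolerance = 1e-9)
})

test_that("iron status classification uses the strict 50 cutoff", {
  cl <- classify_iron_status(c(51, 50, 45, 39, 120))
  expect_equal(cl$status,
               c("deficient", "replete_or_indeterminate",
                 "replete_or_indeterminate", "replete_or_indeterminate",
                 "deficient"))
  expect_equal(cl$indeterminate_zone, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_error(classify_iron_status(NA), "finite")
})
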