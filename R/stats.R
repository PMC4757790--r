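#' Robust zero-offset scaling slope
#'
#' Slope of a straight line through the origin fitted to paired device /
#' reference values by an M-type estimator: starting from the median of
#' the per-pair ratios, iteratively reweighted least squares with Tukey
#' bisquare weights (tuning constant 4.685, residual scale re-estimated
#' by MAD each iteration), at most 50 iterations, relative tolerance
#' 1e-8. Used to convert instrument units to umol ZnPP per mol haem
#' without an additive offset: zero signal must mean zero ZnPP.
#'
#' @param device,reference Paired numeric vectors, length >= 3.
#' @return The scale factor (device units per reference unit).
#' @export
robust_proportional_slope <- function(device, reference) {
  if (length(device) != length(reference) || length(device) < 3)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (all(reference == 0))
    stop("reference values are all zero", call. = FALSE)
  ok <- is.finite(device) & is.finite(reference)
  x <- reference[ok]; y <- device[ok]
  b <- stats::median(y[x != 0] / x[x != 0])
  cc <- 4.685
  for (iter in 1:50) {
    r <- y - b * x
    s <- stats::mad(r, center = 0)
    if (s == 0) break
    u <- r / (cc * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    denom <- sum(w * x^2)
    if (denom == 0) break
    b_new <- sum(w * x * y) / denom
    if (abs(b_new - b) <= 1e-8 * max(1, abs(b))) { b <- b_new; break }
    b <- b_new
  }
  b
}

#' Robust tau-estimate of location and scale
#'
#' The Maronna-Zamar tau-estimator: an initial MAD-type scale
#' (median absolute deviation from the median, without the normal
#' consistency factor), a bisquare-weighted location around the median
#' (tuning c1 = 4.5), and a truncated second-moment scale (tuning
#' c2 = 3) corrected for consistency with the s.d. under normality.
#' High breakdown (50%) and about 80% Gaussian efficiency; this is the
#' dispersion behind the robust limits of agreement.
#'
#' @param x Numeric vector, length >= 2.
#' @param c1,c2 Tuning constants.
#' @return List with `location` and `scale` (`scale` is 0 for constant
#'   input).
#' @export
tau_location_scale <- function(x, c1 = 4.5, c2 = 3.0) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  n <- length(x)
  med <- stats::median(x)
  s0 <- stats::median(abs(x - med))
  if (s0 == 0) return(list(location = med, scale = 0))
  u <- (x - med) / (s0 * c1)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  mu <- sum(w * x) / sum(w)
  t <- (x - mu) / s0
  rho <- pmin(t^2, c2^2)
  # normal consistency: with s0 ~ q*sigma (q = qnorm(3/4)), the truncated
  # second moment has expectation E[min(Z^2, (c2 q)^2)] under N(0,1)
  # (~0.9247 for c2 = 3)
  a <- c2 * stats::qnorm(0.75)
  Es2 <- (2 * stats::pnorm(a) - 1) - 2 * a * stats::dnorm(a) +
    2 * a^2 * (1 - stats::pnorm(a))
  list(location = mu, scale = s0 * sqrt(sum(rho) / (n * Es2)))
}

#' Robust tau-scale (s.d. analogue)
#'
#' @inheritParams tau_location_scale
#' @return The tau-scale estimate (0 for constant input).
#' @export
tau_scale <- function(x, c1 = 4.5, c2 = 3.0) {
  tau_location_scale(x, c1, c2)$scale
}

#' Robust Bland-Altman limits of agreement
#'
#' Differences between two methods on a common scale are summarised by
#' a robust bias (tau-location) and limits of agreement equal to 1.96
#' times the robust tau-scale of the differences, with percentile
#' bootstrap confidence intervals. With fewer than 5 pairs the point
#' estimates are still returned but CIs are refused.
#'
#' @param device,reference Paired values on a common scale (umol ZnPP
#'   per mol haem).
#' @param n_boot Bootstrap resamples (default 2000; 0 skips CIs).
#' @param seed Integer seed, required when CIs are computed.
#' @param conf Confidence level.
#' @return Object of class `znpp_agreement`: `bias`, `loa`, `ci_bias`,
#'   `ci_loa`, `n`, `n_boot`, `seed`.
#' @export
robust_bland_altman <- function(device, reference, n_boot = 2000,
                                seed = NULL, conf = 0.95) {
  if (length(device) != length(reference))
    stop("paired vectors must have equal length", call. = FALSE)
  d <- device - reference
  d <- d[is.finite(d)]
  if (length(d) < 2) stop("need at least 2 paired differences", call. = FALSE)
  ts <- tau_location_scale(d)
  bias <- ts$location
  loa <- 1.96 * ts$scale
  ci_bias <- ci_loa <- c(NA_real_, NA_real_)
  if (n_boot > 0 && length(d) >= 5) {
    if (is.null(seed))
      stop("a seed is required for bootstrap confidence intervals",
           call. = FALSE)
    boot <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        db <- sample(d, replace = TRUE)
        tb <- tau_location_scale(db)
        c(tb$location, 1.96 * tb$scale)
      }, numeric(2))
    })
    alpha <- (1 - conf) / 2
    ci_bias <- unname(stats::quantile(boot[1, ], c(alpha, 1 - alpha)))
    ci_loa <- unname(stats::quantile(boot[2, ], c(alpha, 1 - alpha)))
  }
  structure(list(bias = bias, loa = loa, ci_bias = ci_bias,
                 ci_loa = ci_loa, n = length(d), n_boot = n_boot,
                 seed = seed, differences = d),
            class = "znpp_agreement")
}

#' @export
print.znpp_agreement <- function(x, ...) {
  cat(sprintf("<znpp_agreement> n = %d: bias %.2f, limits of agreement %.2f",
              x$n, x$bias, x$loa))
  if (!any(is.na(x$ci_loa)))
    cat(sprintf(" (95%% CI %.2f-%.2f)", x$ci_loa[1], x$ci_loa[2]))
  cat("\n")
  invisible(x)
}

#' Half-width factor of the limits-of-agreement confidence interval
#'
#' Standard large-sample approximation: the 95% CI of a limit of
#' agreement extends about `1.96 * sqrt(3/n)` times the s.d. of the
#' differences on each side. At the study size n = 56 this is ~0.45 s.
#'
#' @param n Number of paired subjects (>= 2).
#' @return The multiplier of s.
#' @export
loa_ci_halfwidth_factor <- function(n) {
  if (!is.finite(n) || n < 2)
    stop("n must be at least 2", call. = FALSE)
  1.96 * sqrt(3 / n)
}

#' Diagnostic metrics from a contingency table
#'
#' @param tp,fp,fn,tn Nonnegative counts.
#' @return Object of class `znpp_diagnostic`: `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `prevalence`, `counts`. Metrics with
#'   an empty margin are `NA` and flagged in `undefined`.
#' @export
diagnostic_metrics_from_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("empty contingency table", call. = FALSE)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  out <- list(sensitivity = div(tp, tp + fn),
              specificity = div(tn, tn + fp),
              ppv = div(tp, tp + fp),
              npv = div(tn, tn + fn),
              prevalence = (tp + fn) / n,
              counts = counts, threshold = NA_real_)
  out$undefined <- names(which(vapply(out[1:4], is.na, logical(1))))
  structure(out, class = "znpp_diagnostic")
}

#' Diagnostic metrics from rates and prevalence
#'
#' Predictive values by the Bayes identities:
#' \deqn{PPV = \frac{se \cdot \pi}{se \cdot \pi + (1 - sp)(1 - \pi)}
#'   \qquad NPV = \frac{sp (1 - \pi)}{(1 - se) \pi + sp (1 - \pi)}}
#'
#' @param sensitivity,specificity,prevalence Fractions in \[0, 1\].
#' @return Object of class `znpp_diagnostic`.
#' @export
diagnostic_metrics_from_rates <- function(sensitivity, specificity,
                                          prevalence) {
  v <- c(sensitivity, specificity, prevalence)
  if (any(v < 0 | v > 1)) stop("rates must be in [0, 1]", call. = FALSE)
  se <- sensitivity; sp <- specificity; pi <- prevalence
  structure(list(sensitivity = se, specificity = sp,
                 ppv = se * pi / (se * pi + (1 - sp) * (1 - pi)),
                 npv = sp * (1 - pi) / ((1 - se) * pi + sp * (1 - pi)),
                 prevalence = pi, counts = NULL, threshold = NA_real_,
                 undefined = character(0)),
            class = "znpp_diagnostic")
}

#' @export
print.znpp_diagnostic <- function(x, ...) {
  cat(sprintf(
    "<znpp_diagnostic> sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%%s\n",
    100 * x$sensitivity, 100 * x$specificity, 100 * x$ppv, 100 * x$npv,
    if (is.na(x$threshold)) "" else sprintf(" at threshold %g", x$threshold)))
  invisible(x)
}

#' ROC-optimal cutpoint by the Youden index
#'
#' Evaluates every midpoint between adjacent distinct scores (plus
#' open-ended thresholds below and above the data) classifying
#' score > threshold as positive, and returns the threshold maximising
#' Youden's J = sensitivity + specificity - 1. Ties are broken toward
#' higher specificity (the larger threshold).
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Logical or 0/1 vector; `TRUE` = positive (deficient).
#' @return A `znpp_diagnostic` with `threshold` and `youden` set,
#'   computed from the counts at the optimum.
#' @export
roc_optimal_cutpoint <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  s <- sort(unique(scores))
  thr <- c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  np <- sum(labels); nn <- sum(!labels)
  J <- vapply(thr, function(t) {
    pos <- scores > t
    sum(pos & labels) / np + sum(!pos & !labels) / nn - 1
  }, numeric(1))
  # among J ties, the largest threshold = the higher-specificity point
  cand <- which(J >= max(J) - 1e-12)
  best <- list(t = max(thr[cand]), J = max(J))
  pos <- scores > best$t
  out <- diagnostic_metrics_from_counts(tp = sum(pos & labels),
                                        fp = sum(pos & !labels),
                                        fn = sum(!pos & labels),
                                        tn = sum(!pos & !labels))
  out$threshold <- best$t
  out$youden <- best$J
  out
}

#' Classify iron status from a ZnPP/haem ratio
#'
#' Functional iron deficiency is a ZnPP/haem ratio strictly above the
#' cutoff (default 50 umol per mol haem). Values in the 40-50 band are
#' additionally annotated as the indeterminate zone, where elevations do
#' not necessarily indicate iron deficiency.
#'
#' @param znpp_value Numeric ZnPP/haem ratio(s), umol per mol haem.
#' @param cutoff Deficiency cutoff (strict inequality).
#' @param indeterminate_band Lower and upper bound of the indeterminate
#'   annotation band.
#' @return Data frame with columns `value`, `status` (`"deficient"` or
#'   `"replete_or_indeterminate"`), `indeterminate_zone`.
#' @export
classify_iron_status <- function(znpp_value, cutoff = 50,
                                 indeterminate_band = c(40, 50)) {
  if (any(!is.finite(znpp_value)))
    stop("znpp_value must be finite", call. = FALSE)
  status <- ifelse(znpp_value > cutoff, "deficient",
                   "replete_or_indeterminate")
  data.frame(value = znpp_value, status = status,
             indeterminate_zone = status != "deficient" &
               znpp_value >= indeterminate_band[1] &
               znpp_value <= indeterminate_band[2])
}
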