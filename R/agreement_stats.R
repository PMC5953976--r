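#' Paired MTV measurements from two methods or observers
#'
#' @param ids patient identifiers.
#' @param a,b MTV values (cm^3) from side A and side B, congruent with
#'   `ids`; all non-negative, no missing entries, length >= 3.
#' @return An object of class `paired_measurements`.
#' @export
paired_measurements <- function(ids, a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(ids) != length(a))
    stop("`ids`, `a` and `b` must have equal length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(a) || anyNA(b) || any(!is.finite(a)) || any(!is.finite(b)))
    stop("missing or non-finite values are not allowed", call. = FALSE)
  if (any(a < 0) || any(b < 0))
    stop("MTV values must be non-negative", call. = FALSE)
  structure(list(ids = ids, a = a, b = b), class = "paired_measurements")
}

as_pairs <- function(pairs) {
  if (!inherits(pairs, "paired_measurements"))
    stop("expected a `paired_measurements` object", call. = FALSE)
  pairs
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of `values` against a normal law with the sample mean
#' and SD. Because the null parameters are estimated from the data, the
#' plain KS p-value is anticonservative; the Lilliefors-corrected version is
#' therefore the default.
#'
#' @param values numeric vector, n >= 5.
#' @param lilliefors use the Lilliefors correction (default TRUE).
#' @return The p-value.
#' @export
ks_normality <- function(values, lilliefors = TRUE) {
  values <- as.numeric(values)
  if (length(values) < 5L)
    stop("normality check needs at least 5 values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("values are constant; normality test undefined", call. = FALSE)
  if (lilliefors) {
    nortest::lillie.test(values)$p.value
  } else {
    suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values))$p.value
    )
  }
}

#' Cube-root transform
#'
#' The order-preserving transform under which skewed MTV distributions
#' become near-normal, applied before computing the ICC.
#'
#' @param values non-negative numeric vector.
#' @return `values^(1/3)`.
#' @export
cube_root_transform <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values) || any(values < 0))
    stop("cube-root transform requires non-negative values", call. = FALSE)
  values^(1 / 3)
}

#' Consistency intraclass correlation coefficient
#'
#' Two-way mixed-effects, single-rater, consistency ICC (the ICC(3,1)
#' form): `(MSR - MSE) / (MSR + (k-1) MSE)` with `k = 2` raters, where MSR
#' and MSE are the subject and residual mean squares of the two-way ANOVA
#' `value ~ subject + rater`. Consistency ICC ignores a fixed shift between
#' raters. The p-value comes from the F test `MSR/MSE` on
#' `(n-1, (n-1)(k-1))` degrees of freedom.
#'
#' @param pairs a [paired_measurements()].
#' @param transform `"cube_root"` (default, matching the skewed nature of
#'   MTV) or `"none"`.
#' @return List with `icc`, `p`, `transform`, `n`.
#' @export
icc_consistency <- function(pairs, transform = c("cube_root", "none")) {
  pairs <- as_pairs(pairs)
  transform <- match.arg(transform)
  a <- pairs$a; b <- pairs$b
  if (transform == "cube_root") {
    a <- cube_root_transform(a); b <- cube_root_transform(b)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero variance in both measurement lists; ICC undefined", call. = FALSE)
  n <- length(a); k <- 2L
  df <- data.frame(value = c(a, b),
                   subject = factor(rep(seq_len(n), 2L)),
                   rater = factor(rep(c("A", "B"), each = n)))
  # a perfect fit (b == a) is legitimate here: MSE 0 gives ICC 1, p 0
  ms <- suppressWarnings(
    stats::anova(stats::lm(value ~ subject + rater, data = df))[["Mean Sq"]])
  msr <- ms[1L]; mse <- ms[3L]
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  f0 <- msr / mse
  p <- stats::pf(f0, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, p = p, transform = transform, n = n)
}

#' Kendall's tau rank agreement
#'
#' Tie-corrected tau (tau-b) with the asymptotic normal p-value, invariant
#' under any strictly increasing transform of either list (so raw and
#' cube-root MTV give identical tau).
#'
#' @param pairs a [paired_measurements()].
#' @return List with `tau`, `p`, `n`.
#' @export
kendall_tau <- function(pairs) {
  pairs <- as_pairs(pairs)
  if (stats::var(pairs$a) == 0 || stats::var(pairs$b) == 0)
    stop("all-tied measurement list; Kendall's tau undefined", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(pairs$a, pairs$b, method = "kendall", exact = FALSE)
  )
  list(tau = unname(ct$estimate), p = ct$p.value, n = length(pairs$a))
}

#' Non-parametric Bland-Altman analysis
#'
#' Median bias and percentile limits of agreement of the differences
#' `d = a - b` (orientation: side A minus side B, in the order supplied),
#' with quantiles by linear interpolation between order statistics
#' (`type = 7`), pinned so the limits are bit-reproducible. The slope of
#' the least-squares fit of `d` on the pair means is reported to flag a
#' trend of difference with magnitude; it is descriptive, not a test.
#'
#' @param pairs a [paired_measurements()].
#' @param probs lower/upper limit probabilities (default 2.5% and 97.5%).
#' @return List with `median_diff`, `loa_low`, `loa_high`, `trend_slope`,
#'   `differences`, `means`.
#' @export
bland_altman <- function(pairs, probs = c(0.025, 0.975)) {
  pairs <- as_pairs(pairs)
  d <- pairs$a - pairs$b
  m <- (pairs$a + pairs$b) / 2
  q <- unname(stats::quantile(d, probs = probs, type = 7))
  slope <- if (stats::var(m) > 0)
    unname(stats::coef(stats::lm(d ~ m))[2L]) else NA_real_
  list(median_diff = stats::median(d), loa_low = q[1L], loa_high = q[2L],
       trend_slope = slope, differences = d, means = m)
}

#' Full agreement report for one paired comparison
#'
#' Bundles the consistency ICC (on cube-root transformed values by
#' default), Kendall's tau and the non-parametric Bland-Altman summary
#' (on untransformed values) into one record mirroring a method- or
#' observer-comparison table row.
#'
#' @param pairs a [paired_measurements()].
#' @param comparison label for the pair, e.g. `"fixed25 vs pct41"`.
#' @param icc_transform transform used for the ICC.
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(pairs, comparison = "A vs B",
                             icc_transform = c("cube_root", "none")) {
  pairs <- as_pairs(pairs)
  icc <- icc_consistency(pairs, transform = icc_transform)
  tau <- kendall_tau(pairs)
  ba <- bland_altman(pairs)
  structure(list(comparison = comparison, n = length(pairs$a),
                 icc = icc$icc, icc_p = icc$p,
                 icc_transform = icc$transform,
                 tau = tau$tau, tau_p = tau$p,
                 median_diff = ba$median_diff,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 trend_slope = ba$trend_slope),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s (n = %d)\n", x$comparison, x$n))
  cat(sprintf("  ICC (%s): %.4f (p = %.3g)   Kendall tau: %.4f (p = %.3g)\n",
              x$icc_transform, x$icc, x$icc_p, x$tau, x$tau_p))
  cat(sprintf("  Bland-Altman: median diff %.4g, LoA [%.4g, %.4g], trend slope %.3g\n",
              x$median_diff, x$loa_low, x$loa_high, x$trend_slope))
  invisible(x)
}

#' @export
as.data.frame.agreement_report <- function(x, ...) {
  data.frame(comparison = x$comparison, n = x$n, icc = x$icc, icc_p = x$icc_p,
             tau = x$tau, tau_p = x$tau_p, median_diff = x$median_diff,
             loa_low = x$loa_low, loa_high = x$loa_high,
             trend_slope = x$trend_slope, stringsAsFactors = FALSE)
}
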