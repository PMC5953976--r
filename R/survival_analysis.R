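DAYS_PER_YEAR <- 365.25
FIVE_YEARS_DAYS <- 5 * DAYS_PER_YEAR

#' Binary ROC outcome from right-censored follow-up
#'
#' The ROC analysis treats progression as a binary endpoint within a fixed
#' horizon (default 5 years): 1 for an event at or before the horizon, 0 for
#' follow-up beyond the horizon without an event, and `NA` (excluded from
#' the ROC, but kept in KM/Cox) for patients censored before the horizon,
#' whose status at the horizon is unknown.
#'
#' @param time follow-up time in days.
#' @param event event indicator (1 = progressed/died).
#' @param horizon_days horizon in days (default `5 * 365.25`).
#' @return Integer vector of 0/1/NA.
#' @export
roc_outcome <- function(time, event, horizon_days = FIVE_YEARS_DAYS) {
  if (any(time <= 0)) stop("follow-up times must be positive", call. = FALSE)
  out <- ifelse(event == 1 & time <= horizon_days, 1L,
                ifelse(time >= horizon_days, 0L, NA_integer_))
  out
}

#' ROC curve over the observed MTV values
#'
#' Sweeps every unique MTV value as a candidate cut-off, classifying
#' high-risk when `mtv >= t` (inclusive), and reports sensitivity and
#' specificity at each, the trapezoidal AUC, and a 95% confidence interval
#' (DeLong by default, bootstrap optional).
#'
#' @param mtv MTV values (one per patient).
#' @param outcome binary outcome (1 = event); both classes must be present.
#' @param ci_method `"delong"`, `"bootstrap"` or `"none"`.
#' @param conf confidence level (default 0.95).
#' @return An object of class `roc_result` with fields `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `auc_ci`, `optimal_threshold`,
#'   `optimal_sens`, `optimal_spec`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(mtv, outcome, ci_method = c("delong", "bootstrap", "none"),
                      conf = 0.95) {
  ci_method <- match.arg(ci_method)
  keep <- !is.na(mtv) & !is.na(outcome)
  mtv <- as.numeric(mtv[keep]); outcome <- as.integer(outcome[keep])
  if (!all(outcome %in% c(0L, 1L)))
    stop("`outcome` must be binary 0/1", call. = FALSE)
  if (length(unique(outcome)) < 2L)
    stop("both outcome classes must be present (degenerate ROC)", call. = FALSE)
  thr <- sort(unique(mtv))
  sens <- vapply(thr, function(t) mean(mtv[outcome == 1L] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(mtv[outcome == 0L] < t), numeric(1))
  # trapezoid over (FPR, TPR), closing the curve at (0,0) (threshold above max)
  fpr <- c(1 - spec, 0); tpr <- c(sens, 0)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  auc_ci <- c(NA_real_, NA_real_)
  if (ci_method != "none") {
    proc <- pROC::roc(response = outcome, predictor = mtv,
                      levels = c(0L, 1L), direction = "<", quiet = TRUE)
    ci <- pROC::ci.auc(proc, conf.level = conf,
                       method = if (ci_method == "delong") "delong" else "bootstrap")
    auc_ci <- as.numeric(ci[c(1L, 3L)])
  }
  res <- structure(list(thresholds = thr, sensitivity = sens,
                        specificity = spec, auc = auc, auc_ci = auc_ci,
                        n_pos = sum(outcome == 1L), n_neg = sum(outcome == 0L),
                        optimal_threshold = NA_real_, optimal_sens = NA_real_,
                        optimal_spec = NA_real_),
                   class = "roc_result")
  opt <- optimal_cutoff(res)
  res$optimal_threshold <- opt$threshold
  res$optimal_sens <- opt$sens
  res$optimal_spec <- opt$spec
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), %d events / %d non-events\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg))
  cat(sprintf("  optimal cut-off %.4g cm^3 (sens %.3f, spec %.3f)\n",
              x$optimal_threshold, x$optimal_sens, x$optimal_spec))
  invisible(x)
}

#' Optimal ROC cut-off: the point nearest the top-left corner
#'
#' Minimises `(1 - sens)^2 + (1 - spec)^2` over the candidate thresholds;
#' ties are broken deterministically towards the smallest threshold (which
#' favours sensitivity).
#'
#' @param roc a `roc_result`.
#' @return List with `threshold`, `sens`, `spec`, `distance2`.
#' @export
optimal_cutoff <- function(roc) {
  if (!inherits(roc, "roc_result")) stop("expected a `roc_result`", call. = FALSE)
  d2 <- (1 - roc$sensitivity)^2 + (1 - roc$specificity)^2
  i <- which(d2 <= min(d2) + 1e-12)[1L]  # smallest threshold among minimisers
  list(threshold = roc$thresholds[i], sens = roc$sensitivity[i],
       spec = roc$specificity[i], distance2 = d2[i])
}

#' Dichotomise MTV at a cut-off
#'
#' @param mtv MTV values.
#' @param cutoff positive cut-off (cm^3); `mtv >= cutoff` is `"high"`
#'   (inclusive).
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize <- function(mtv, cutoff) {
  if (!is.finite(cutoff) || cutoff <= 0) stop("`cutoff` must be > 0", call. = FALSE)
  factor(ifelse(mtv >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier estimate for one group
#'
#' Product-limit survival curve with the 5-year survival read off at
#' `5 x 365.25` days and the median defined as the first time the curve
#' drops to or below 0.5 (undefined -- `NA` -- if it never does).
#'
#' @param times follow-up times in days (> 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @param group label carried into the result (`"low"`/`"high"`/other).
#' @return An object of class `group_survival` with fields `group`, `n`,
#'   `events`, `surv_5y`, `median_survival`, `km_curve` (a
#'   [survival::survfit] object).
#' @export
km_estimate <- function(times, events, group = NA_character_) {
  if (length(times) < 1L) stop("need at least one subject", call. = FALSE)
  if (any(times <= 0)) stop("follow-up times must be positive", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  s5 <- summary(fit, times = FIVE_YEARS_DAYS, extend = TRUE)$surv
  # median: first time the curve drops to or below 0.5; NA if it never does
  below <- fit$surv <= 0.5 + 1e-12
  med <- if (any(below)) fit$time[which(below)[1L]] else NA_real_
  structure(list(group = group, n = length(times), events = sum(events),
                 surv_5y = s5, median_survival = med, km_curve = fit),
            class = "group_survival")
}

#' @export
print.group_survival <- function(x, ...) {
  cat(sprintf("<group_survival> %s: n = %d, events = %d, 5-y survival %.1f%%, median %s\n",
              x$group, x$n, x$events, 100 * x$surv_5y,
              if (is.na(x$median_survival)) "not reached"
              else sprintf("%.0f d", x$median_survival)))
  invisible(x)
}

#' Log-rank test between two groups
#'
#' @param times_a,events_a follow-up and event indicators, group A.
#' @param times_b,events_b follow-up and event indicators, group B.
#' @return List with `chi2`, `p` (1 df).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) < 1L || length(times_b) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chi2 <- sd$chisq
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Univariate Cox regression on a binary group
#'
#' Partial-likelihood hazard ratio of the second factor level versus the
#' first (high vs low when the covariate comes from [dichotomize()]), with
#' a Wald 95% confidence interval and p-value. Ties are handled by the
#' Breslow approximation by default (Efron available).
#'
#' @param times follow-up times in days.
#' @param events event indicators.
#' @param group two-level factor; both levels must be present and at least
#'   one event observed.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param conf confidence level (default 0.95).
#' @return List with `hr`, `ci_low`, `ci_high`, `p`, `coef`, `se`.
#' @export
cox_univariate <- function(times, events, group, ties = c("breslow", "efron"),
                           conf = 0.95) {
  ties <- match.arg(ties)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("`group` must have exactly two observed levels", call. = FALSE)
  if (sum(events) < 1L)
    stop("at least one event is required", call. = FALSE)
  # separation is diagnosed below from the fitted coefficient, not via warnings
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(times, events) ~ group, ties = ties))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 50)
    stop(sprintf(paste0(
      "Cox partial likelihood is monotone (complete separation of events ",
      "between groups): coef = %.3g, se = %.3g"), beta, se), call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(hr = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
       p = 2 * stats::pnorm(-abs(beta / se)), coef = beta, se = se)
}

#' Full prognostic analysis of one MTV measure
#'
#' Chains the whole biomarker workflow for a single segmentation method:
#' binary 5-year outcome, ROC curve and AUC, top-left-corner optimal
#' cut-off, dichotomisation into low/high MTV, Kaplan-Meier per group with
#' 5-year survival and median, log-rank test and univariate Cox hazard
#' ratio. Patients censored before the horizon are excluded from the ROC
#' only; KM, log-rank and Cox use all patients.
#'
#' @param mtv per-patient MTV values (cm^3).
#' @param time follow-up times (days).
#' @param event event indicators.
#' @param horizon_days ROC outcome horizon (default 5 years).
#' @param cutoff optional fixed cut-off; by default the ROC-optimal one.
#' @param ties Cox tie handling.
#' @return An object of class `mtv_prognosis` bundling `roc`, `cutoff`,
#'   `groups` (factor), `km_low`, `km_high`, `logrank`, `cox`.
#' @export
mtv_prognosis <- function(mtv, time, event, horizon_days = FIVE_YEARS_DAYS,
                          cutoff = NULL, ties = c("breslow", "efron")) {
  stopifnot(length(mtv) == length(time), length(time) == length(event))
  out <- roc_outcome(time, event, horizon_days)
  roc <- roc_curve(mtv, out)
  if (is.null(cutoff)) cutoff <- roc$optimal_threshold
  grp <- dichotomize(mtv, cutoff)
  low <- grp == "low"; high <- grp == "high"
  if (!any(low) || !any(high))
    stop("cut-off does not split the cohort into two groups", call. = FALSE)
  km_low <- km_estimate(time[low], event[low], "low")
  km_high <- km_estimate(time[high], event[high], "high")
  lr <- logrank_test(time[low], event[low], time[high], event[high])
  cox <- cox_univariate(time, event, grp, ties = ties)
  structure(list(roc = roc, cutoff = cutoff, groups = grp,
                 km_low = km_low, km_high = km_high,
                 logrank = lr, cox = cox,
                 n_roc = sum(!is.na(out))),
            class = "mtv_prognosis")
}

#' @export
print.mtv_prognosis <- function(x, ...) {
  cat(sprintf("<mtv_prognosis> AUC %.3f (%.3f-%.3f, n_roc = %d), cut-off %.4g cm^3\n",
              x$roc$auc, x$roc$auc_ci[1], x$roc$auc_ci[2], x$n_roc, x$cutoff))
  cat(sprintf("  low  MTV: n = %d, events = %d, 5-y survival %.1f%%\n",
              x$km_low$n, x$km_low$events, 100 * x$km_low$surv_5y))
  cat(sprintf("  high MTV: n = %d, events = %d, 5-y survival %.1f%%\n",
              x$km_high$n, x$km_high$events, 100 * x$km_high$surv_5y))
  cat(sprintf("  log-rank chi2 = %.2f (p = %.3g); HR %.2f (%.2f-%.2f, p = %.3g)\n",
              x$logrank$chi2, x$logrank$p, x$cox$hr, x$cox$ci_low,
              x$cox$ci_high, x$cox$p))
  invisible(x)
}
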