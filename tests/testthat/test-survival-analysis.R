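test_that("ROC outcome definition handles events, survivors and early censoring", {
  h <- 5 * 365.25
  time <- c(100, 2000, 400, h, 2500)
  event <- c(1, 0, 0, 1, 1)
  out <- roc_outcome(time, event)
  expect_equal(out, c(1L, 0L, NA_integer_, 1L, 0L))
  expect_error(roc_outcome(c(-1, 2), c(1, 0)), "positive")
})

test_that("ROC sweep matches exhaustive 2x2-table enumeration", {
  mtv <- c(5, 10, 20, 40, 80, 160)
  outc <- c(0, 0, 1, 0, 1, 1)
  roc <- roc_curve(mtv, outc, ci_method = "none")
  expect_equal(roc$thresholds, sort(unique(mtv)))
  for (i in seq_along(roc$thresholds)) {
    t <- roc$thresholds[i]
    tp <- sum(mtv >= t & outc == 1); fn <- sum(mtv < t & outc == 1)
    tn <- sum(mtv < t & outc == 0); fp <- sum(mtv >= t & outc == 0)
    expect_equal(roc$sensitivity[i], tp / (tp + fn))
    expect_equal(roc$specificity[i], tn / (tn + fp))
  }
})

test_that("AUC: perfect separation gives 1, independence gives ~0.5, pROC agrees", {
  roc <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1), ci_method = "none")
  expect_equal(roc$auc, 1.0)
  set.seed(22)
  mtv <- rlnorm(400, 5, 1); outc <- rbinom(400, 1, 0.4)
  roc2 <- roc_curve(mtv, outc, ci_method = "none")
  expect_lt(abs(roc2$auc - 0.5), 0.08)
  # independent oracle: pROC AUC on the same data (with ties)
  set.seed(23)
  mtv3 <- sample(1:20, 100, replace = TRUE); outc3 <- rbinom(100, 1, 0.5)
  roc3 <- roc_curve(mtv3, outc3, ci_method = "none")
  p <- pROC::roc(response = outc3, predictor = mtv3, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  expect_equal(roc3$auc, as.numeric(pROC::auc(p)), tolerance = 1e-12)
  expect_error(roc_curve(c(1, 2, 3), c(1, 1, 1)), "degenerate")
})

test_that("AUC is invariant under strictly increasing transforms of MTV", {
  set.seed(24)
  mtv <- rlnorm(200, 6, 1); outc <- rbinom(200, 1, plogis(scale(log(mtv))))
  a1 <- roc_curve(mtv, outc, ci_method = "none")$auc
  a2 <- roc_curve(mtv^(1 / 3), outc, ci_method = "none")$auc
  expect_equal(a1, a2)
})

test_that("optimal cut-off is the exhaustive minimiser of the corner distance", {
  roc <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1), ci_method = "none")
  opt <- optimal_cutoff(roc)
  expect_equal(opt$threshold, 3)
  expect_equal(opt$sens, 1); expect_equal(opt$spec, 1)
  expect_equal(opt$distance2, 0)
  set.seed(25)
  for (rep in 1:50) {
    n <- sample(8:40, 1)
    mtv <- round(rlnorm(n, 5, 1), 1)
    outc <- rbinom(n, 1, 0.5)
    if (length(unique(outc)) < 2) next
    roc <- roc_curve(mtv, outc, ci_method = "none")
    opt <- optimal_cutoff(roc)
    d2 <- (1 - roc$sensitivity)^2 + (1 - roc$specificity)^2
    expect_true(all(opt$distance2 <= d2 + 1e-12))
    # smallest-threshold tie-break
    expect_equal(opt$threshold, min(roc$thresholds[d2 <= min(d2) + 1e-12]))
  }
  # degenerate: all-identical MTV yields the single candidate
  roc1 <- roc_curve(rep(7, 6), c(0, 1, 0, 1, 0, 1), ci_method = "none")
  expect_length(roc1$thresholds, 1)
  expect_equal(optimal_cutoff(roc1)$threshold, 7)
})

test_that("dichotomisation at the cut-off is inclusive for the high group", {
  expect_equal(as.character(dichotomize(c(400, 399.9, 1000), 400)),
               c("high", "low", "high"))
  expect_true(all(dichotomize(c(1, 2), 10) == "low"))
  expect_error(dichotomize(c(1, 2), -5), "> 0")
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  # all events at 1,2,3,4 days: S(2.5) = 0.5
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  s <- summary(km$km_curve, times = 2.5)$surv
  expect_equal(s, 0.5)
  expect_equal(km$median_survival, 2)  # first time S <= 0.5
  # no events: flat curve, median undefined
  km2 <- km_estimate(c(10, 20, 30), c(0, 0, 0))
  expect_equal(km2$surv_5y, 1)
  expect_true(is.na(km2$median_survival))
  # censoring before the first event shrinks the risk set:
  # times 1+ (censored), 2, 3 events: S(2)= 1*(1-1/2)=0.5, S(3)=0
  km3 <- km_estimate(c(1, 2, 3), c(0, 1, 1))
  expect_equal(summary(km3$km_curve, times = c(2, 3))$surv, c(0.5, 0))
  # without censoring KM equals the empirical survival function
  set.seed(26)
  t <- sample(1:50, 30, replace = TRUE)
  km4 <- km_estimate(t, rep(1, 30))
  for (tt in c(5, 17, 33))
    expect_equal(summary(km4$km_curve, times = tt)$surv, mean(t > tt))
})

test_that("log-rank: null behaviour, hand oracle and power under HR 5", {
  set.seed(27)
  t <- rexp(60, 0.01); e <- rbinom(60, 1, 0.7)
  lr <- logrank_test(t, e, t, e)
  expect_lt(lr$chi2, 1e-10)
  expect_gt(lr$p, 0.999)
  # hand-size oracle: A = {1(event), 4(censored)}, B = {2(event), 3(event)}
  # risk sets: t=1: 2A,2B, d=1 -> E_A = 0.5; t=2: 1A,2B, d=1 -> E_A = 1/3;
  # t=3: 1A,1B, d=1 -> E_A = 0.5. O_A = 1, E_A = 4/3.
  # V = sum of hypergeometric variances: t=1: 1*... = 0.25; t=2: 2/9; t=3: 0.25
  lr2 <- logrank_test(c(1, 4), c(1, 0), c(2, 3), c(1, 1))
  OmE <- 1 - (0.5 + 1 / 3 + 0.5)
  V <- 0.25 + 2 / 9 + 0.25
  expect_equal(lr2$chi2, OmE^2 / V, tolerance = 1e-9)
  # power: exponential groups with hazard ratio 5, n = 100/arm
  sig <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    ua <- rexp(100, 0.002); ub <- rexp(100, 0.010)
    logrank_test(pmin(ua, 1000), as.integer(ua <= 1000),
                 pmin(ub, 1000), as.integer(ub <= 1000))$p < 0.001
  }, logical(1))
  expect_gte(mean(sig), 0.95)
})

test_that("Cox partial likelihood matches a hand-coded Breslow oracle", {
  # identical hazards: HR ~ 1, CI covers 1
  set.seed(28)
  t <- rexp(200, 0.01); cens <- runif(200, 50, 300)
  grp <- factor(rep(c("low", "high"), 100), levels = c("low", "high"))
  fit <- cox_univariate(pmin(t, cens), as.integer(t <= cens), grp)
  expect_true(fit$ci_low < 1 && 1 < fit$ci_high)
  expect_lt(abs(log(fit$hr)), 0.5)
  # 4-subject toy, distinct times: maximise the explicit partial likelihood
  tt <- c(1, 2, 3, 4); ee <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  nlpl <- function(beta) {
    risk <- exp(beta * x)
    -sum(vapply(which(ee == 1), function(i)
      beta * x[i] - log(sum(risk[tt >= tt[i]])), numeric(1)))
  }
  beta_hat <- optimize(nlpl, c(-5, 5))$minimum
  fit2 <- cox_univariate(tt, ee, factor(x, levels = c(0, 1)), ties = "breslow")
  expect_equal(fit2$coef, beta_hat, tolerance = 1e-4)
  # complete separation of events is reported, not silently returned
  expect_error(
    cox_univariate(c(1, 2, 3, 100, 101, 102), c(1, 1, 1, 0, 0, 0),
                   factor(c("b", "b", "b", "a", "a", "a"))),
    "monotone")
})

test_that("prognosis wrapper ties the stages together coherently", {
  co <- generate_cohort(cohort_spec(seed = 3))
  fit <- mtv_prognosis(co$mtv_fixed25, co$time_pfs, co$event_pfs)
  expect_s3_class(fit, "mtv_prognosis")
  expect_equal(fit$cutoff, fit$roc$optimal_threshold)
  expect_equal(fit$km_low$n + fit$km_high$n, nrow(co))
  expect_true(fit$cox$hr > 1)
  expect_lt(fit$logrank$p, 0.001)
  # groups consistent with the cut-off
  expect_equal(unname(table(fit$groups)["high"]), sum(co$mtv_fixed25 >= fit$cutoff))
})
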