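test_that("logistic OR on a 2x2 binary predictor equals the cross-product
          ratio exactly", {
  # exposed: 30 case / 10 control; unexposed: 10 case / 30 control
  x <- rep(c(1, 1, 0, 0), c(30, 10, 10, 30))
  y <- rep(c(1, 0, 1, 0), c(30, 10, 10, 30))
  fit <- fit_logistic(cbind(1, exposure = x), y)
  expect_equal(unname(fit$or["exposure"]), 9, tolerance = 1e-6)
  # label swap inverts every OR
  swapped <- fit_logistic(cbind(1, exposure = x), 1 - y)
  expect_equal(unname(swapped$or["exposure"]), 1 / 9, tolerance = 1e-6)
})

test_that("null predictors give OR confidence intervals covering 1", {
  withr::with_seed(5, {
    n <- 2000
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.5)
    fit <- fit_logistic(cbind(1, x = x), y)
    expect_lt(fit$or_ci["x", "lower"], 1)
    expect_gt(fit$or_ci["x", "upper"], 1)
  })
})

test_that("the MLE matches a brute-force likelihood grid on a toy problem", {
  x <- c(-2.1, -1.5, -1, -0.5, -0.2, 0, 0.2, 0.5, 1, 1.4, 1.8, 2.3)
  y <- c(0, 0, 0, 1, 0, 0, 1, 0, 1, 1, 1, 1)
  fit <- fit_logistic(cbind(1, x = x), y)
  loglik <- function(b0, b1) {
    p <- plogis(b0 + b1 * x)
    sum(dbinom(y, 1, p, log = TRUE))
  }
  # coarse-to-fine grid search, independent of the IRLS path
  b0g <- seq(-3, 3, by = 0.1); b1g <- seq(0, 6, by = 0.1)
  ll <- outer(b0g, b1g, Vectorize(loglik))
  best <- which(ll == max(ll), arr.ind = TRUE)
  b0 <- b0g[best[1]]; b1 <- b1g[best[2]]
  for (stepsize in c(0.01, 1e-3, 1e-4, 1e-5)) {
    b0g <- seq(b0 - 10 * stepsize, b0 + 10 * stepsize, by = stepsize)
    b1g <- seq(b1 - 10 * stepsize, b1 + 10 * stepsize, by = stepsize)
    ll <- outer(b0g, b1g, Vectorize(loglik))
    best <- which(ll == max(ll), arr.ind = TRUE)
    b0 <- b0g[best[1]]; b1 <- b1g[best[2]]
  }
  expect_equal(unname(fit$coefficients), c(b0, b1), tolerance = 1e-4)
})

test_that("separation and single-class inputs are flagged, not silent", {
  x <- c(rep(0, 10), rep(1, 10))
  expect_error(fit_logistic(cbind(1, x), x), "separation")
  f <- fit_logistic(cbind(1, x), x, on_separation = "flag")
  expect_true(f$separated)
  expect_error(fit_logistic(cbind(1, x), rep(1, 20)), "single class")
})

test_that("influence pruning removes only genuinely influential points", {
  withr::with_seed(9, {
    n <- 120
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(x))
    clean <- influence_prune(cbind(1, x = x), y)
    expect_length(clean$excluded_ids, 0)
    # plant one extreme-leverage, label-discordant point
    xb <- c(x, 8)
    yb <- c(y, 0)
    pruned <- influence_prune(cbind(1, x = xb), yb,
                              ids = c(sprintf("s%d", 1:n), "planted"))
    expect_true("planted" %in% pruned$excluded_ids)
    # leave-one-out oracle: the planted point moves the slope most
    full <- fit_logistic(cbind(1, x = xb), yb)$coefficients["x"]
    deltas <- vapply(seq_along(yb), function(i) {
      abs(fit_logistic(cbind(1, x = xb[-i]), yb[-i])$coefficients["x"] - full)
    }, 0)
    expect_equal(which.max(deltas), n + 1L)
    # pruning respects the cap
    expect_lte(length(pruned$excluded_ids), floor(0.05 * (n + 1)))
  })
})

test_that("scan grids follow the documented sequences exactly", {
  expect_equal(ironbio:::scan_grid(31, 2, 85), seq(31, 87, by = 2))
  expect_equal(ironbio:::scan_grid(31, 2, 84.5), seq(31, 85, by = 2))
  expect_equal(ironbio:::scan_grid(-1, 0.1, 2.55), seq(-1, 2.6, by = 0.1))
  expect_equal(ironbio:::scan_grid(31, 2, 20), 31)
  g <- ironbio:::scan_grid(-1, 0.1, 3.02)
  expect_equal(diff(g), rep(0.1, length(g) - 1), tolerance = 1e-9)
  expect_gt(g[length(g)], 3.02)
})

test_that("age scan handles empty strata as missing entries and ends at the
          full cohort", {
  co <- quick_cohort(seed = 23)
  zt <- harmonize_cohort(co)
  prof <- scan_age_cutoffs(zt, co, n_resamples = 60)
  expect_s3_class(prof, "scan_profile")
  expect_true(is.na(prof$or[1])) # almost nobody younger than 31
  expect_false(anyNA(prof$or[prof$n >= 30]))
  expect_equal(prof$n[nrow(prof)], sum(!is.na(zt$z_iron)))
  expect_true(all(diff(prof$cutoff) == 2))
  expect_true(all(prof$n_used <= prof$n, na.rm = TRUE))
  # entries below min_n are missing, not errors
  old_only <- zt$age_death >= 31
  expect_silent({
    prof2 <- scan_age_cutoffs(zt[old_only, ], co, n_resamples = 60)
  })
  expect_true(is.na(prof2$or[1]))
})

test_that("cutoff selection equals a brute-force argmax under both rules", {
  withr::with_seed(77, {
    for (i in 1:20) {
      k <- 15
      prof <- data.frame(cutoff = seq(31, by = 2, length.out = k),
                         n = sample(5:80, k, replace = TRUE),
                         or = exp(rnorm(k)),
                         p = runif(k, 0, 0.2))
      prof$ci_low <- prof$or / 2
      prof$ci_high <- prof$or * 2
      ok <- prof$p < 0.05 & prof$n >= 10
      if (!any(ok)) {
        expect_error(select_cutoff(prof), "no scan entry")
        next
      }
      eligible <- prof[ok, ]
      brute_or <- eligible$cutoff[which.max(abs(log(eligible$or)))]
      brute_p <- eligible$cutoff[which.min(eligible$p)]
      expect_equal(select_cutoff(prof, "max_abs_log_or"), brute_or)
      expect_equal(select_cutoff(prof, "min_p"), brute_p)
    }
  })
  # single significant entry is selected; custom rules are honored
  prof <- data.frame(cutoff = c(31, 33, 35), n = c(20, 20, 20),
                     or = c(1.1, 3, 1.2), p = c(0.5, 0.01, 0.6))
  expect_equal(select_cutoff(prof), 33)
  expect_equal(select_cutoff(prof, rule = function(df) max(df$cutoff)), 35)
})

test_that("subcohort contrasts require both groups per stratum", {
  co <- quick_cohort(seed = 29)
  zt <- harmonize_cohort(co)
  expect_error(subcohort_contrast(zt, co, list("age", 10), "iron"),
               "does not contain both")
  cc <- subcohort_contrast(zt, co, list("age", 35), "iron",
                           c("sex", "ancestry", "ph", "pmi"),
                           n_resamples = 80)
  expect_true(is.finite(cc$below$effect$estimate))
  expect_true(is.finite(cc$above$effect$estimate))
  expect_equal(cc$split, list(axis = "age", cutoff = 35))
})

test_that("predicted probabilities are the inverse-logit closed form and
          an intercept-only model predicts prevalence", {
  x <- withr::with_seed(3, rnorm(300))
  y <- withr::with_seed(4, rbinom(300, 1, plogis(-0.5 + x)))
  fit <- fit_logistic(cbind(1, x = x), y)
  grid <- seq(-3, 3, by = 0.5)
  curve <- predicted_probability_curve(fit, grid)
  b <- fit$coefficients
  expect_equal(curve$probability, plogis(b[1] + b[2] * grid),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(curve$probability > 0 & curve$probability < 1))
  expect_true(all(diff(curve$probability) > 0))
  only <- fit_logistic(matrix(1, length(y), 1), y)
  expect_equal(unname(plogis(only$coefficients)), mean(y), tolerance = 1e-8)
})
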