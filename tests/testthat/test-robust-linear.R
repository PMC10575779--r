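test_that("bisquare loss family satisfies its closed forms", {
  for (c in c(1.5476, 3.4437, 4.6851)) {
    at0 <- bisquare(0, c)
    expect_equal(at0$rho, 0)
    expect_equal(at0$psi, 0)
    expect_equal(at0$weight, 1)
    edge <- bisquare(c(-c, c, 2 * c), c)
    expect_equal(edge$rho, rep(c^2 / 6, 3))
    expect_equal(edge$psi, rep(0, 3))
    expect_equal(edge$weight, rep(0, 3))
    expect_equal(bisquare(c / 2, c)$psi, 9 * c / 32, tolerance = 1e-12)
  }
  expect_error(bisquare(1, -2), "c must be > 0")
  # psi continuity and redescent
  u <- seq(-6, 6, by = 0.01)
  psi <- bisquare(u, 2)$psi
  expect_true(all(abs(diff(psi)) < 0.05))
})

test_that("tuning constants reproduce the standard efficiency table", {
  expect_close(bisquare_c_for_efficiency(0.85), 3.4437, 1e-3)
  expect_close(bisquare_c_for_efficiency(0.95), 4.6851, 1e-3)
})

test_that("S-scale is equivariant, consistent, and flags degeneracy", {
  r <- withr::with_seed(1, rnorm(50))
  for (k in c(-3, 0.1, 7)) {
    expect_equal(s_scale(k * r), abs(k) * s_scale(r), tolerance = 1e-6)
  }
  z <- s_scale(rep(0, 10))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  big <- withr::with_seed(2, rnorm(10000, 0, 2))
  expect_close(s_scale(big) / 2, 1, 0.02)
  expect_error(s_scale(1), "n >= 2")
})

test_that("fit_mm interpolates noise-free data exactly", {
  x <- withr::with_seed(3, rnorm(60))
  X <- cbind(1, x)
  fit <- fit_mm(X, 3 + 4 * x)
  expect_equal(unname(fit$coefficients), c(3, 4), tolerance = 1e-10)
  expect_equal(fit$scale, 0)
  expect_true(all(fit$weights == 1))
  expect_true(fit$degenerate)
})

test_that("fit_mm resists gross contamination where OLS fails", {
  withr::with_seed(11, {
    n <- 200
    x <- rnorm(n)
    y <- 2 * x + rnorm(n, 0, 0.5)
    bad <- sample(n, 20)
    y[bad] <- y[bad] + 20
    fit <- fit_mm(cbind(1, x), y)
    ols <- unname(coef(lm(y ~ x))[2])
    expect_lt(abs(fit$coefficients[2] - 2), 0.1)
    expect_gt(abs(ols - 2), 0.3)
    expect_true(fit$converged)
    expect_true(all(fit$weights >= 0 & fit$weights <= 1))
  })
})

test_that("fit_mm agrees with an independent MM implementation on clean
          data", {
  skip_if_not_installed("MASS")
  withr::with_seed(7, {
    n <- 500
    x <- rnorm(n)
    y <- 1 + 2 * x + rnorm(n, 0, 0.5)
    mine <- fit_mm(cbind(1, x), y)
    ref <- MASS::rlm(y ~ x, method = "MM")
    expect_equal(unname(mine$coefficients), unname(coef(ref)),
                 tolerance = 0.01)
  })
})

test_that("fit_mm is regression and scale equivariant and row-order
          invariant", {
  withr::with_seed(21, {
    n <- 120
    x <- rnorm(n)
    y <- 1 + 0.5 * x + rt(n, 3)
    X <- cbind(1, x)
    base <- fit_mm(X, y, seed = 99)
    shifted <- fit_mm(X, y + 10, seed = 99)
    expect_equal(shifted$coefficients[1], base$coefficients[1] + 10,
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(shifted$coefficients[2], base$coefficients[2],
                 tolerance = 1e-6, ignore_attr = TRUE)
    scaled <- fit_mm(cbind(1, 5 * x), y, seed = 99)
    expect_equal(scaled$coefficients[2], base$coefficients[2] / 5,
                 tolerance = 1e-6, ignore_attr = TRUE)
    perm <- withr::with_seed(1, sample(n))
    reordered <- fit_mm(X[perm, ], y[perm])
    expect_equal(unname(reordered$coefficients), unname(base$coefficients),
                 tolerance = 1e-6)
  })
})

test_that("fit_mm rejects degenerate designs by name", {
  x <- rnorm(30)
  X <- cbind(intercept = 1, a = x, b = 2 * x)
  expect_error(fit_mm(X, rnorm(30)), "collinear column\\(s\\): b")
  expect_error(fit_mm(cbind(1, x[1:2]), rnorm(2)), "more observations")
})

test_that("linear vs linear-logarithmic comparison selects the generative
          model", {
  withr::with_seed(31, {
    x <- runif(100, 5, 90)
    y_log <- 1 + 2 * log(x) + rnorm(100, 0, 0.3)
    cmp <- fit_linlog_comparison(x, y_log)
    expect_equal(cmp$selected, "linear-log")
    expect_gt(cmp$ln_term_t, 2)
    y_lin <- 1 + 0.05 * x + rnorm(100, 0, 0.3)
    cmp2 <- fit_linlog_comparison(x, y_lin)
    expect_equal(cmp2$selected, "linear")
  })
  expect_error(fit_linlog_comparison(c(-1, runif(20, 1, 5)), rnorm(21)),
               "x must be > 0")
  expect_error(fit_linlog_comparison(rep(2, 30), rnorm(30)),
               "collinear|rank")
})

test_that("group_difference is antisymmetric under label structure", {
  co <- quick_cohort(seed = 17)
  zt <- harmonize_cohort(co)
  # mirror cohort: identical values, flipped labels -> difference ~ 0
  half <- zt[zt$diagnosis == "control", ]
  mirror <- half
  mirror$diagnosis <- "schizophrenia"
  mirror$subject_id <- paste0(half$subject_id, "m")
  both <- rbind(half, mirror)
  gd <- group_difference(both, "iron")
  expect_lt(abs(gd$effect$estimate), 1e-8)
  # covariate-adjusted difference runs and reports the diagnosis term
  gd2 <- group_difference(zt, "iron", c("age_death", "sex", "ph", "pmi"),
                          co, n_resamples = 100)
  expect_true(is.finite(gd2$effect$estimate))
  expect_lt(gd2$effect$ci_low, gd2$effect$estimate)
  expect_gt(gd2$effect$ci_high, gd2$effect$estimate)
  expect_equal(gd2$effect$t,
               gd2$effect$estimate / gd2$se[["diagnosis"]],
               tolerance = 1e-9)
})

test_that("under heavy corruption the MM slope stays bounded while OLS
          diverges with the corruption magnitude", {
  withr::with_seed(41, {
    n <- 150
    x <- rnorm(n)
    y <- 2 * x + rnorm(n, 0, 0.5)
    bad <- sample(n, 45) # 30% corrupted
    for (mag in c(50, 500)) {
      yb <- y
      yb[bad] <- yb[bad] + mag
      mm <- fit_mm(cbind(1, x), yb)
      ols <- unname(coef(lm(yb ~ x))[2])
      expect_lt(abs(mm$coefficients[2] - 2), 0.5)
    }
    yb <- y; yb[bad] <- yb[bad] + 500
    expect_gt(abs(unname(coef(lm(yb ~ x))[2]) - 2),
              abs(unname(coef(lm(y ~ x))[2]) - 2) + 1)
  })
})
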