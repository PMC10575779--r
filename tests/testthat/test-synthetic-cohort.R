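test_that("default configuration carries the study's demographic conditions", {
  cfg <- default_study_config()
  expect_identical(cfg$n_control, 85L)
  expect_identical(cfg$n_case, 86L)
  expect_equal(cfg$control_age_mean, 54.4)
  expect_equal(cfg$control_age_sd, 14.9)
  expect_equal(cfg$control_age_range, c(17, 85))
  expect_equal(cfg$control_ph_mean, 6.54)
  expect_equal(cfg$control_pmi_mean, 33.1)
  expect_equal(unname(cfg$bank_fractions), c(0.44, 0.21, 0.35))
  expect_equal(cfg$control_smoking_rate, 0.33)
  expect_equal(cfg$case_smoking_rate, 0.74)
  expect_equal(cfg$control_nonnatural_rate, 0.07)
  expect_equal(cfg$case_nonnatural_rate, 0.36)
  expect_equal(cfg$case_iron_mean_shift, 0.58)
  expect_length(validate_config(cfg), 0)
})

test_that("configuration invariants are enforced", {
  bad <- default_study_config()
  bad$bank_fractions <- c("NSW-BTRC" = 0.5, "VBBN" = 0.2, "NIMH-HBCC" = 0.2)
  expect_match(paste(validate_config(bad), collapse = "; "), "sum to 1")
  expect_error(generate_cohort(bad), "invalid synthetic_config")
  bad2 <- default_study_config()
  bad2$case_variance_ratio <- -1
  expect_match(paste(validate_config(bad2), collapse = "; "),
               "case_variance_ratio")
})

test_that("identical configurations generate identical cohorts", {
  a <- generate_cohort(default_study_config(seed = 42))
  b <- generate_cohort(default_study_config(seed = 42))
  expect_identical(a, b)
  c <- generate_cohort(default_study_config(seed = 43))
  expect_false(identical(a$iron, c$iron))
})

test_that("generated cohorts respect structural invariants", {
  cfg <- default_study_config(seed = 9)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), cfg$n_control + cfg$n_case)
  expect_equal(sum(co$diagnosis == "control"), cfg$n_control)
  # ages respect the truncation ranges exactly
  con <- co$diagnosis == "control"
  expect_true(all(co$age_death[con] >= 17 & co$age_death[con] <= 85))
  expect_true(all(co$age_death[!con] >= 17 & co$age_death[!con] <= 84))
  expect_true(all(co$iron > 0))
  # medication data only on cases
  expect_length(validate_cohort(co)$subject_id, 0)
  expect_true(all(is.na(co$ap_mean_daily_dose[con])))
})

test_that("large-sample moments match the configured generative model", {
  cfg <- synthetic_config(n_control = 5000L, n_case = 5000L, seed = 5,
                          missing_rates = c(smoker = 0, alcohol_user = 0,
                                            bmi = 0, copper = 0, zinc = 0,
                                            ferritin = 0))
  co <- generate_cohort(cfg)
  zt <- harmonize_cohort(co)
  con <- !ironbio:::is_case(zt$diagnosis)
  # control z-scores anchored at 0/1 after harmonization
  for (b in unique(zt$bank)) {
    zc <- zt$z_iron[con & zt$bank == b]
    expect_close(mean(zc), 0, 0.05)
    expect_close(sd(zc), 1, 0.05)
  }
  # case/control variance ratio converges to the configured value
  vr <- var(zt$z_iron[!con]) / var(zt$z_iron[con])
  expect_close(vr / cfg$case_variance_ratio, 1, 0.15)
  # planted mean shift on the control-SD scale
  expect_close(mean(zt$z_iron[!con]) - mean(zt$z_iron[con]),
               cfg$case_iron_mean_shift, 0.1)
})

test_that("control iron recovers the configured ln(age) slope (OLS oracle)", {
  flat_scale <- c("NSW-BTRC" = 1, "VBBN" = 1, "NIMH-HBCC" = 1)
  slopes <- vapply(1:50, function(s) {
    co <- generate_cohort(synthetic_config(seed = s,
                                           bank_scale_factors = flat_scale))
    con <- co$diagnosis == "control"
    unname(coef(lm(co$iron[con] ~ log(co$age_death[con])))[2])
  }, 0)
  cfg <- synthetic_config()
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_close(mean(slopes), cfg$control_iron_lnage_slope, 3 * mc_se)
})

test_that("outlier injection is a flagged, seeded, rate-controlled process", {
  co <- quick_cohort(seed = 3)
  expect_identical(inject_outliers(co, 0, 5)$iron, co$iron)
  z0 <- inject_outliers(co, 1, 0, seed = 2)
  expect_equal(z0$iron, co$iron)
  expect_true(all(z0$outlier_injected))
  expect_error(inject_outliers(co, 0.1, -1), "non-negative")
  expect_identical(inject_outliers(co, 0.3, 6, seed = 7),
                   inject_outliers(co, 0.3, 6, seed = 7))
  # flagged counts across seeds stay within the binomial central 99% range
  cfg200 <- synthetic_config(n_control = 100L, n_case = 100L)
  co200 <- generate_cohort(cfg200)
  counts <- vapply(1:40, function(s) {
    sum(inject_outliers(co200, 0.05, 6, seed = s)$outlier_injected)
  }, 0L)
  band <- qbinom(c(0.005, 0.995), 200, 0.05)
  expect_true(all(counts >= band[1] & counts <= band[2]))
  # injected values are genuinely inflated
  z1 <- inject_outliers(co, 1, 6, seed = 1)
  expect_true(all(z1$iron >= co$iron))
  expect_gt(mean(z1$iron - co$iron), 0)
})

test_that("configurations round-trip through flat YAML", {
  cfg <- synthetic_config(seed = 99L, case_iron_mean_shift = 0.7)
  path <- withr::local_tempfile(fileext = ".yml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back, cfg, tolerance = 1e-12)
  expect_identical(generate_cohort(back), generate_cohort(cfg))
  # unknown keys are rejected
  writeLines(c(readLines(path), "bogus_key: 3"), path)
  expect_error(read_config(path), "bogus_key")
})
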