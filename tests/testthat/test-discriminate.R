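test_that("AUC equals the all-pairs statistic on fixtures and edge cases", {
  # printed toy triple: cases {2,3,4}, controls {1,2,3} -> 7/9
  s <- c(2, 3, 4, 1, 2, 3)
  y <- c(1, 1, 1, 0, 0, 0)
  expect_equal(roc_auc(s, y)$auc, 7 / 9, tolerance = 1e-12)
  # perfect separation
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1)
  # exhaustive random fixtures up to n = 50, with ties
  withr::with_seed(12, {
    for (i in 1:25) {
      n <- sample(4:50, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      s <- sample(seq_len(8), n, replace = TRUE) + rnorm(n, 0, 0.01)
      if (i %% 2 == 0) s <- round(s) # heavy ties
      r <- roc_auc(s, y)
      expect_equal(r$auc, auc_pairs(s, y), tolerance = 1e-12)
      # label swap complement
      expect_equal(roc_auc(s, 1 - y)$auc, 1 - r$auc, tolerance = 1e-12)
      # curve is monotone in both coordinates
      expect_true(all(diff(r$points$fpr) >= 0))
      expect_true(all(diff(r$points$tpr) >= 0))
    }
  })
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
  expect_error(roc_auc(rep(2, 6), c(1, 1, 1, 0, 0, 0)), "distinct")
})

test_that("case_low direction mirrors the case_high analysis", {
  withr::with_seed(3, {
    s <- rnorm(60)
    y <- rbinom(60, 1, plogis(-s)) # low scores case-like
    lo <- roc_auc(s, y, direction = "case_low")
    hi <- roc_auc(-s, y, direction = "case_high")
    expect_equal(lo$auc, hi$auc, tolerance = 1e-12)
    oc_lo <- optimal_cutoff(lo)
    oc_hi <- optimal_cutoff(hi)
    expect_equal(oc_lo$cutoff, -oc_hi$cutoff, tolerance = 1e-12)
    expect_equal(oc_lo$sensitivity, oc_hi$sensitivity)
  })
})

test_that("optimal cutoff maximizes Youden J with the documented
          conventions", {
  # perfect separation: J = 1, cutoff at the inter-class midpoint
  r <- roc_auc(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  oc <- optimal_cutoff(r)
  expect_equal(oc$youden_j, 1)
  expect_equal(oc$cutoff, 4)
  expect_equal(oc$accuracy, 1)
  # toy set: equals brute force over all midpoint thresholds
  s <- c(2, 3, 4, 1, 2, 3)
  y <- c(1, 1, 1, 0, 0, 0)
  r2 <- roc_auc(s, y)
  oc2 <- optimal_cutoff(r2)
  thr <- sort(unique(s))
  cand <- c(thr[1] - 1, (thr[-length(thr)] + thr[-1]) / 2)
  j <- vapply(cand, function(ct) {
    mean(s[y == 1] > ct) + mean(s[y == 0] <= ct) - 1
  }, 0)
  expect_equal(oc2$youden_j, max(j), tolerance = 1e-12)
  # direction convention: flagged = above cutoff for a case-high marker
  expect_equal(mean(s[y == 1] > oc2$cutoff), oc2$sensitivity)
  # accuracy identity (TP+TN)/n at the chosen cutoff
  tp <- sum(s > oc2$cutoff & y == 1)
  tn <- sum(s <= oc2$cutoff & y == 0)
  expect_equal(oc2$accuracy, (tp + tn) / length(y))
})

test_that("bias-corrected bootstrap CI is seeded, sane, and collapses when
          degenerate", {
  withr::with_seed(10, {
    s <- c(rnorm(40, 1), rnorm(40))
    y <- rep(c(1, 0), each = 40)
    ci1 <- auc_bootstrap_ci(s, y, B = 400, seed = 5)
    ci2 <- auc_bootstrap_ci(s, y, B = 400, seed = 5)
    expect_identical(ci1, ci2)
    auc <- roc_auc(s, y)$auc
    expect_lt(ci1[1], auc)
    expect_gt(ci1[2], auc)
    expect_true(all(ci1 >= 0 & ci1 <= 1))
  })
  # two-point degenerate scores: all stratified resamples give AUC 1
  sdeg <- c(rep(1, 5), rep(0, 5))
  ydeg <- c(rep(1, 5), rep(0, 5))
  cideg <- auc_bootstrap_ci(sdeg, ydeg, B = 200, seed = 3)
  expect_equal(cideg, c(1, 1))
  expect_error(auc_bootstrap_ci(sdeg, ydeg, B = 50), "B >= 100")
})

test_that("pROC agrees with the rank AUC on random data", {
  skip_if_not_installed("pROC")
  withr::with_seed(14, {
    for (i in 1:5) {
      s <- rnorm(60)
      y <- rbinom(60, 1, 0.5)
      if (length(unique(y)) < 2) next
      mine <- roc_auc(s, y)$auc
      ref <- suppressMessages(as.numeric(pROC::auc(y, s,
                                                   direction = "<")))
      expect_equal(mine, ref, tolerance = 1e-12)
    }
  })
})

test_that("risk flags follow their subcohort domain rules", {
  co <- quick_cohort(seed = 31)
  zt <- harmonize_cohort(co)[1:20, ]
  adj <- list(iron = zt$z_iron, ferritin = zt$z_ferritin,
              ratio = zt$z_ratio)
  cuts <- list(iron = 0.5, ferritin = -0.4, ratio = 0.6)
  fl <- build_risk_flags(zt, adj, age_cutoff = 35, iron_cutoff = 0,
                         cutoffs = cuts)
  # independent rule-by-rule recomputation
  for (i in seq_len(nrow(zt))) {
    young <- !is.na(zt$age_death[i]) && zt$age_death[i] < 35
    lowfe <- !is.na(zt$z_iron[i]) && zt$z_iron[i] < 0
    e1 <- young && !is.na(adj$iron[i]) && adj$iron[i] > 0.5
    e2 <- lowfe && !is.na(adj$ferritin[i]) && adj$ferritin[i] < -0.4
    e3 <- !is.na(adj$ratio[i]) && adj$ratio[i] > 0.6
    if (!(young && is.na(adj$iron[i]))) {
      expect_equal(fl$high_iron_young[i], e1)
    }
    expect_equal(fl$young_domain[i], young)
    if (!(lowfe && is.na(adj$ferritin[i]))) {
      expect_equal(fl$low_ferritin_low_iron[i], e2)
    }
    if (!is.na(adj$ratio[i])) expect_equal(fl$high_ratio[i], e3)
  }
  # an old subject is outside the young-flag domain and never flagged
  old_idx <- which(zt$age_death >= 60)[1]
  expect_false(fl$young_domain[old_idx])
  expect_false(fl$high_iron_young[old_idx])
})

test_that("combined classifier reduces to prevalence with uninformative
          flags and reports consistent fractions", {
  zt <- harmonize_cohort(quick_cohort(seed = 33))
  n <- nrow(zt)
  flags <- data.frame(subject_id = zt$subject_id, diagnosis = zt$diagnosis,
                      high_iron_young = FALSE,
                      low_ferritin_low_iron = FALSE,
                      high_ratio = FALSE, young_domain = FALSE,
                      low_iron_domain = FALSE, complete = TRUE)
  rep0 <- suppressWarnings(combined_classifier(flags))
  prevalence_acc <- max(mean(ironbio:::is_case(zt$diagnosis)),
                        1 - mean(ironbio:::is_case(zt$diagnosis)))
  expect_equal(rep0$accuracy, prevalence_acc, tolerance = 1e-9)
  # informative flags: confusion identities hold
  res <- run_quick_classifier(seed = 33)
  expect_equal(sum(res$confusion), res$n_classified)
  expect_equal(res$accuracy,
               (res$confusion["tp"] + res$confusion["tn"]) /
                 res$n_classified,
               ignore_attr = TRUE)
  expect_equal(res$cases_perturbed + mean(res$predicted[res$labels == 1] == 0),
               1, tolerance = 1e-12)
  expect_true(res$accuracy_ci[1] <= res$accuracy &
                res$accuracy_ci[2] >= res$accuracy)
})

test_that("nested model comparison satisfies likelihood monotonicity", {
  withr::with_seed(40, {
    n <- 300
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(x1))
    full <- fit_logistic(cbind(intercept = 1, x1 = x1, x2 = x2), y)
    reduced <- fit_logistic(cbind(intercept = 1, x1 = x1), y)
    cmp <- compare_nested_models(full, reduced)
    expect_gte(cmp$lr, 0)
    expect_equal(cmp$df, 1)
    self <- compare_nested_models(full, full)
    expect_equal(self$lr, 0)
    expect_equal(self$p_value, 1)
    not_nested <- fit_logistic(cbind(intercept = 1, x3 = rnorm(n)), y)
    expect_error(compare_nested_models(full, not_nested), "not nested")
  })
})

test_that("a pure-noise added predictor yields a chi-square(1) LR statistic", {
  lrs <- vapply(1:200, function(s) {
    withr::with_seed(1000 + s, {
      n <- 150
      x <- rnorm(n)
      z <- rnorm(n)
      y <- rbinom(n, 1, plogis(0.5 * x))
      full <- fit_logistic(cbind(1, x, z), y)
      reduced <- fit_logistic(cbind(1, x), y)
      compare_nested_models(full, reduced)$lr
    })
  }, 0)
  # Kolmogorov distance to chi-square(1) small; mean near 1
  expect_close(mean(lrs), 1, 0.35)
  ks <- suppressWarnings(ks.test(lrs, pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})
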