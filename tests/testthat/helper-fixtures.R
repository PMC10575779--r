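# Shared fixtures built in code.

# Small hand-built three-bank cohort with exactly known values.
tiny_cohort <- function() {
  df <- data.frame(
    subject_id = sprintf("T%02d", 1:18),
    bank = rep(c("NSW-BTRC", "VBBN", "NIMH-HBCC"), each = 6),
    diagnosis = rep(c("control", "control", "control",
                      "schizophrenia", "schizophrenia", "schizophrenia"), 3),
    age_death = rep(c(25, 40, 60, 30, 50, 70), 3),
    sex = rep(c("F", "M"), 9),
    ancestry = rep(c("Caucasian", "Caucasian", "non-Caucasian"), 6),
    ph = 6.5, pmi = 30, death_mode = "natural",
    smoker = NA, alcohol_user = NA, bmi = NA_real_,
    iron = c(10, 12, 14, 15, 16, 17,
             5, 6, 7, 8, 9, 10,
             20, 24, 28, 30, 32, 34),
    copper = 3, zinc = 10,
    ferritin = c(90, 100, 110, 80, 85, 95,
                 45, 50, 55, 40, 42, 47,
                 180, 200, 220, 160, 170, 190),
    ap_mean_daily_dose = NA_real_, ap_lifetime_exposure = NA_real_,
    ap_duration = NA_real_, ap_typicality = NA_character_,
    ap_tox_positive = NA, lithium_tox_positive = NA,
    age_onset = NA_real_,
    stringsAsFactors = FALSE)
  ironbio:::as_cohort(df, provenance = "tiny fixture")
}

# Fast default-condition cohort for pipeline-level tests.
quick_cohort <- function(seed = 1L, ...) {
  generate_cohort(synthetic_config(seed = seed, ...))
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%.6g (expected %.6g +/- %.3g)",
                              object, expected, tol))
}

# Classifier on simple (unadjusted z) markers of a quick cohort.
run_quick_classifier <- function(seed = 1L) {
  co <- quick_cohort(seed = seed)
  zt <- harmonize_cohort(co)
  adj <- list(iron = zt$z_iron, ferritin = zt$z_ferritin,
              ratio = zt$z_ratio)
  fl <- build_risk_flags(zt, adj, age_cutoff = 35, iron_cutoff = 0,
                         cutoffs = list(iron = 0.5, ferritin = -0.5,
                                        ratio = 0.5))
  suppressWarnings(combined_classifier(fl))
}

# All permutations of 1:n (for exhaustive permutation oracles at tiny n).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}

# Brute-force all-pairs AUC: P(case > control) + 0.5 P(tie).
auc_pairs <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  g <- outer(cs, ct, ">")
  t <- outer(cs, ct, "==")
  (sum(g) + 0.5 * sum(t)) / (length(cs) * length(ct))
}

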