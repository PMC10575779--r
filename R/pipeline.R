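# End-to-end orchestration of the analysis stages, mirroring the study
# design: harmonize, estimate robust group differences, scan cutoffs,
# contrast subcohorts, run ROC analyses and the combined classifier.

#' Percent elevation between two group means
#'
#' Raw-scale arithmetic `100 * (case_mean - control_mean) / control_mean`,
#' used for single-bank preliminary comparisons on the measurement scale.
#'
#' @param case_mean,control_mean Group means (same units); `control_mean`
#'   must be nonzero.
#' @return Percent elevation.
#' @export
percent_elevation <- function(case_mean, control_mean) {
  if (any(control_mean == 0)) stop("control_mean must be nonzero")
  100 * (case_mean - control_mean) / control_mean
}

#' Run the full iron-biology case-control analysis
#'
#' Executes the pipeline on a cohort table: control-anchored harmonization;
#' robust (MM-estimator) group differences for iron, ferritin, copper,
#' zinc and the iron-to-ferritin ratio; case/control iron variance
#' comparison; serial age- and iron-cutoff odds-ratio scans with cutoff
#' selection; subcohort contrasts at the selected cutoffs; ROC analyses of
#' adjusted iron (young subcohort), adjusted ferritin (low-iron subcohort,
#' low scores case-like) and adjusted ratio (entire cohort) with
#' bias-corrected bootstrap CIs and Youden-optimal cutoffs; and the
#' combined three-flag classifier.
#'
#' @param cohort A `cohort`.
#' @param efficiency MM-estimator efficiency (default 0.85).
#' @param auc_B Bootstrap replicates for the AUC CIs (default 2000).
#' @param seed Seed for the bootstrap stages.
#' @param scan_args Extra arguments passed to both scans (e.g.
#'   `n_resamples` for the residualization fits).
#' @param age_cutoff,iron_cutoff Optional fixed subcohort boundaries; by
#'   default the scan-selected cutoffs are used (falling back to the
#'   conventional 35 years / 0 SD when no scan entry is selectable).
#' @return A named list with every stage's results.
#' @export
run_iron_pipeline <- function(cohort, efficiency = 0.85, auc_B = 2000L,
                              seed = 1L, scan_args = list(),
                              age_cutoff = NULL, iron_cutoff = NULL) {
  ztable <- harmonize_cohort(cohort)

  effects <- lapply(c(iron = "iron", ferritin = "ferritin",
                      ratio = "ratio", zinc = "zinc", copper = "copper"),
                    function(a) {
                      group_difference(ztable, a, character(0),
                                       efficiency = efficiency)
                    })
  variance <- compare_variance(
    ztable$z_iron[!is_case(ztable$diagnosis)],
    ztable$z_iron[is_case(ztable$diagnosis)])

  age_scan <- do.call(scan_age_cutoffs,
                      c(list(ztable = ztable, cohort = cohort), scan_args))
  iron_scan <- do.call(scan_iron_cutoffs,
                       c(list(ztable = ztable, cohort = cohort), scan_args))
  sel_age <- age_cutoff %||% attr(age_scan, "selected_cutoff")
  if (is.na(sel_age)) sel_age <- 35
  sel_iron <- iron_cutoff %||% attr(iron_scan, "selected_cutoff")
  if (is.na(sel_iron)) sel_iron <- 0

  iron_contrast <- subcohort_contrast(
    ztable, cohort, list("age", sel_age), "iron",
    covariates = c("sex", "ancestry", "ph", "pmi"),
    efficiency = efficiency)
  ferritin_contrast <- subcohort_contrast(
    ztable, cohort, list("iron_z", sel_iron), "ferritin",
    covariates = c("age_death", "sex", "ancestry", "ph", "pmi"),
    efficiency = efficiency)

  # Covariate-adjusted predictors on the analysis subsets used by the ROC
  # panels (iron adjusted without age, since age defines its subcohort).
  idx <- match(ztable$subject_id, cohort$subject_id)
  df <- cohort[idx, , drop = FALSE]
  young <- !is.na(ztable$age_death) & ztable$age_death < sel_age
  low_iron <- !is.na(ztable$z_iron) & ztable$z_iron < sel_iron

  adj_iron_young <- rep(NA_real_, nrow(ztable))
  adj_iron_young[young] <- adjust_analyte(
    ztable$z_iron[young], df[young, , drop = FALSE],
    c("sex", "ancestry", "ph", "pmi"))
  adj_fer_low <- rep(NA_real_, nrow(ztable))
  adj_fer_low[low_iron] <- adjust_analyte(
    ztable$z_ferritin[low_iron], df[low_iron, , drop = FALSE],
    c("age_death", "sex", "ancestry", "ph", "pmi"))
  adj_ratio <- adjust_analyte(ztable$z_ratio, df,
                              c("age_death", "sex", "ancestry", "ph", "pmi"))

  old <- !is.na(ztable$age_death) & ztable$age_death >= sel_age
  adj_iron_old <- rep(NA_real_, nrow(ztable))
  adj_iron_old[old] <- adjust_analyte(
    ztable$z_iron[old], df[old, , drop = FALSE],
    c("sex", "ancestry", "ph", "pmi"))
  high_iron <- !is.na(ztable$z_iron) & ztable$z_iron >= sel_iron
  adj_fer_high <- rep(NA_real_, nrow(ztable))
  adj_fer_high[high_iron] <- adjust_analyte(
    ztable$z_ferritin[high_iron], df[high_iron, , drop = FALSE],
    c("age_death", "sex", "ancestry", "ph", "pmi"))

  dx <- as.numeric(is_case(ztable$diagnosis))
  # per-SD odds ratios of diagnosis within each subcohort
  sub_or <- function(adjusted, sub) {
    sel <- which(sub & !is.na(adjusted))
    fit <- influence_prune(cbind(intercept = 1, predictor = adjusted[sel]),
                           dx[sel], ids = ztable$subject_id[sel])$fit
    list(or = unname(fit$or["predictor"]),
         ci = unname(fit$or_ci["predictor", ]),
         p = unname(fit$p_value["predictor"]), n = length(sel),
         fit = fit)
  }
  or_iron_young <- sub_or(adj_iron_young, young)
  or_iron_old <- sub_or(adj_iron_old, old)
  or_fer_low <- sub_or(adj_fer_low, low_iron)
  or_fer_high <- tryCatch(sub_or(adj_fer_high, high_iron),
                          error = function(e) NULL)
  roc_one <- function(scores, sub, direction, seed_off) {
    r <- roc_auc(scores[sub], dx[sub], direction = direction)
    r$ci <- auc_bootstrap_ci(scores[sub], dx[sub], B = auc_B,
                             seed = seed + seed_off, direction = direction)
    r$optimal <- optimal_cutoff(r)
    r
  }
  roc_iron <- roc_one(adj_iron_young, young & !is.na(adj_iron_young),
                      "case_high", 11L)
  roc_ferritin <- roc_one(adj_fer_low, low_iron & !is.na(adj_fer_low),
                          "case_low", 12L)
  roc_ratio <- roc_one(adj_ratio, !is.na(adj_ratio), "case_high", 13L)

  # Flags use full-cohort adjusted iron/ferritin so every subject's marker
  # is on the same scale as its subcohort-derived cutoff.
  adj_iron_full <- adjust_analyte(ztable$z_iron, df,
                                  c("sex", "ancestry", "ph", "pmi"))
  adj_fer_full <- adjust_analyte(ztable$z_ferritin, df,
                                 c("age_death", "sex", "ancestry", "ph",
                                   "pmi"))
  flags <- build_risk_flags(
    ztable,
    adjusted = list(iron = ifelse(young, adj_iron_young, adj_iron_full),
                    ferritin = ifelse(low_iron, adj_fer_low, adj_fer_full),
                    ratio = adj_ratio),
    age_cutoff = sel_age, iron_cutoff = sel_iron,
    cutoffs = list(iron = roc_iron$optimal$cutoff,
                   ferritin = roc_ferritin$optimal$cutoff,
                   ratio = roc_ratio$optimal$cutoff))
  report <- combined_classifier(flags)

  list(ztable = ztable, effects = effects, variance = variance,
       age_scan = age_scan, iron_scan = iron_scan,
       selected_age_cutoff = sel_age, selected_iron_cutoff = sel_iron,
       iron_contrast = iron_contrast, ferritin_contrast = ferritin_contrast,
       subcohort_or = list(iron_young = or_iron_young,
                           iron_old = or_iron_old,
                           ferritin_low_iron = or_fer_low,
                           ferritin_high_iron = or_fer_high),
       roc = list(iron_young = roc_iron, ferritin_low_iron = roc_ferritin,
                  ratio = roc_ratio),
       flags = flags, classification = report)
}
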