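# ROC analysis with bias-corrected bootstrap CIs, Youden-optimal cutoffs,
# risk-flag construction, and the combined three-predictor classifier.

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation with ties counted 0.5; the
#' curve is enumerated at every threshold between distinct score values.
#' `direction = "case_high"` treats higher scores as case-like (flagged =
#' score above cutoff); `"case_low"` the reverse (scores are negated
#' internally and thresholds mapped back to the original scale).
#'
#' @param scores Numeric predictor values.
#' @param labels Diagnosis indicators (0/1 or logical); both classes
#'   required, with at least two distinct scores.
#' @param direction `"case_high"` (default) or `"case_low"`.
#' @return A `roc_result`: `auc`, `points` (threshold, fpr, tpr),
#'   `n_case`, `n_control`, `direction`, and the score/label data for
#'   bootstrap and cutoff extraction.
#' @export
roc_auc <- function(scores, labels, direction = c("case_high", "case_low")) {
  direction <- match.arg(direction)
  y <- as.numeric(labels)
  keep <- !is.na(scores) & !is.na(y)
  s <- scores[keep]
  y <- y[keep]
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (length(unique(s)) < 2) stop("need at least two distinct scores")
  s_int <- if (direction == "case_low") -s else s
  auc <- auc_rank(s_int, y)
  thr <- sort(unique(s_int))
  cuts <- c(-Inf, (thr[-length(thr)] + thr[-1]) / 2, max(thr))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  pts <- data.frame(
    threshold = if (direction == "case_low") -cuts else cuts,
    fpr = vapply(cuts, function(ct) sum(s_int > ct & y == 0) / n0, 0),
    tpr = vapply(cuts, function(ct) sum(s_int > ct & y == 1) / n1, 0))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  out <- list(auc = auc, points = pts, n_case = n1, n_control = n0,
              direction = direction, scores = s, labels = y)
  class(out) <- "roc_result"
  out
}

# Mann-Whitney AUC (ties 0.5) via midranks.
auc_rank <- function(scores, y) {
  r <- rank(scores)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d cases, %d controls, direction %s)\n",
              x$auc, x$n_case, x$n_control, x$direction))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% bias-corrected bootstrap CI: %.3f to %.3f\n",
                x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' Bias-corrected bootstrap CI for the AUC
#'
#' Stratified bootstrap (resampling within class), bias-corrected (BC)
#' percentile interval: the bias constant `z0` is the normal quantile of
#' the fraction of replicates below the point estimate (ties counted
#' half). Seeded and reproducible; degenerate single-class resamples
#' cannot arise under stratification but are guarded with a retry cap.
#'
#' @param scores,labels As in [roc_auc()].
#' @param B Bootstrap replicates, >= 100 (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @param direction Passed to the AUC computation.
#' @return Length-2 vector `(low, high)`.
#' @export
auc_bootstrap_ci <- function(scores, labels, B = 2000L, level = 0.95,
                             seed = 1L, direction = "case_high") {
  stopifnot(B >= 100)
  y <- as.numeric(labels)
  keep <- !is.na(scores) & !is.na(y)
  s <- scores[keep]
  y <- y[keep]
  if (direction == "case_low") s <- -s
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  hat <- auc_rank(s, y)
  stat <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      for (try in 1:10) {
        i <- c(sample(idx1, length(idx1), replace = TRUE),
               sample(idx0, length(idx0), replace = TRUE))
        yy <- y[i]
        if (length(unique(yy)) == 2) return(auc_rank(s[i], yy))
      }
      NA_real_
    }, 0)
  })
  stat <- stat[!is.na(stat)]
  if (length(unique(stat)) == 1) return(c(stat[1], stat[1]))
  prop <- (sum(stat < hat) + 0.5 * sum(stat == hat)) / length(stat)
  prop <- min(max(prop, 1 / (length(stat) + 1)),
              1 - 1 / (length(stat) + 1))
  z0 <- stats::qnorm(prop)
  alpha <- (1 - level) / 2
  probs <- stats::pnorm(2 * z0 + stats::qnorm(c(alpha, 1 - alpha)))
  unname(stats::quantile(stat, probs))
}

#' Youden-optimal operating cutoff
#'
#' Maximizes Youden's `J = sensitivity + specificity - 1` over all
#' enumerated thresholds; ties break toward higher specificity; the
#' reported threshold is the midpoint between the adjacent distinct scores
#' (on the original score scale).
#'
#' @param roc A `roc_result`.
#' @param criterion `"youden"` (default) or `"accuracy"`.
#' @return List: `cutoff`, `sensitivity`, `specificity`, `accuracy`,
#'   `youden_j`. Flagged (case-like) means score above the cutoff for
#'   `case_high`, below it for `case_low`.
#' @export
optimal_cutoff <- function(roc, criterion = c("youden", "accuracy")) {
  criterion <- match.arg(criterion)
  s <- roc$scores
  y <- roc$labels
  s_int <- if (roc$direction == "case_low") -s else s
  thr <- sort(unique(s_int))
  if (length(thr) < 2) stop("degenerate ROC: all scores identical")
  cuts <- c(thr[1] - 1, (thr[-length(thr)] + thr[-1]) / 2)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  sens <- vapply(cuts, function(ct) sum(s_int > ct & y == 1) / n1, 0)
  spec <- vapply(cuts, function(ct) sum(s_int <= ct & y == 0) / n0, 0)
  acc <- vapply(cuts, function(ct) {
    (sum(s_int > ct & y == 1) + sum(s_int <= ct & y == 0)) / (n1 + n0)
  }, 0)
  score <- if (criterion == "youden") sens + spec - 1 else acc
  best <- which(score == max(score))
  best <- best[which.max(spec[best])]
  cutoff <- cuts[best]
  if (roc$direction == "case_low") cutoff <- -cutoff
  list(cutoff = cutoff, sensitivity = sens[best], specificity = spec[best],
       accuracy = acc[best], youden_j = sens[best] + spec[best] - 1,
       criterion = criterion, direction = roc$direction)
}

#' Per-subject iron-biology risk flags
#'
#' Constructs the three dichotomous high-risk markers:
#' \describe{
#'   \item{high_iron_young}{adjusted iron above its optimal cutoff, defined
#'     on the young subcohort (`age < age_cutoff`);}
#'   \item{low_ferritin_low_iron}{adjusted ferritin below its optimal
#'     cutoff, defined on the low-iron subcohort (`z_iron < iron_cutoff`);}
#'   \item{high_ratio}{adjusted iron-to-ferritin ratio above its optimal
#'     cutoff, defined for the entire cohort.}
#' }
#' Subjects outside a flag's subcohort domain are encoded `FALSE` with the
#' domain recorded in a companion `*_domain` column, so the combined model
#' can use every subject with complete analytes.
#'
#' @param ztable A `zscore_table` (supplies `age_death` and `z_iron`).
#' @param adjusted Named list of covariate-adjusted predictor vectors
#'   (`iron`, `ferritin`, `ratio`) aligned with `ztable` rows.
#' @param age_cutoff Years; young-subcohort boundary (strictly below).
#' @param iron_cutoff Iron SD units; low-iron boundary (strictly below).
#' @param cutoffs Named list of per-marker optimal cutoffs (`iron`,
#'   `ferritin`, `ratio`).
#' @return Data frame: `subject_id`, the three logical flags, the two
#'   domain indicators, and `complete` (all three markers measurable).
#' @export
build_risk_flags <- function(ztable, adjusted, age_cutoff, iron_cutoff,
                             cutoffs) {
  stopifnot(all(c("iron", "ferritin", "ratio") %in% names(adjusted)),
            all(c("iron", "ferritin", "ratio") %in% names(cutoffs)))
  young <- !is.na(ztable$age_death) & ztable$age_death < age_cutoff
  low_iron <- !is.na(ztable$z_iron) & ztable$z_iron < iron_cutoff
  f1 <- young & !is.na(adjusted$iron) & adjusted$iron > cutoffs$iron
  f2 <- low_iron & !is.na(adjusted$ferritin) &
    adjusted$ferritin < cutoffs$ferritin
  f3 <- !is.na(adjusted$ratio) & adjusted$ratio > cutoffs$ratio
  complete <- !is.na(adjusted$iron) & !is.na(adjusted$ferritin) &
    !is.na(adjusted$ratio)
  # inside a flag's domain a missing marker means the flag is unknown
  f1[young & is.na(adjusted$iron)] <- NA
  f2[low_iron & is.na(adjusted$ferritin)] <- NA
  f3[is.na(adjusted$ratio)] <- NA
  data.frame(subject_id = ztable$subject_id,
             diagnosis = ztable$diagnosis,
             high_iron_young = f1,
             low_ferritin_low_iron = f2,
             high_ratio = f3,
             young_domain = young,
             low_iron_domain = low_iron,
             complete = complete & !is.na(f1) & !is.na(f2) & !is.na(f3),
             stringsAsFactors = FALSE)
}

#' Combined three-flag classifier
#'
#' Logistic regression of diagnosis on the three risk flags; the
#' probability cutoff is chosen by Youden's J on the fitted probabilities.
#' Sensitivity, specificity and accuracy carry exact Clopper-Pearson 95%
#' CIs. Also reports the fraction of cases flagged as having perturbed
#' iron biology (predicted case) and of controls flagged intact.
#'
#' @param flags Output of [build_risk_flags()] (rows with `complete ==
#'   FALSE` are dropped and counted).
#' @param labels Optional explicit diagnosis indicators; defaults to the
#'   `diagnosis` column of `flags`.
#' @return A `classification_report`.
#' @export
combined_classifier <- function(flags, labels = NULL) {
  y <- if (is.null(labels)) as.numeric(is_case(flags$diagnosis)) else
    as.numeric(labels)
  keep <- flags$complete & !is.na(y)
  n_dropped <- sum(!keep)
  f <- flags[keep, , drop = FALSE]
  y <- y[keep]
  if (min(sum(y == 0), sum(y == 1)) < 2) {
    stop("need at least 2 subjects per class with complete flags")
  }
  X <- cbind(intercept = 1,
             high_iron_young = as.numeric(f$high_iron_young),
             low_ferritin_low_iron = as.numeric(f$low_ferritin_low_iron),
             high_ratio = as.numeric(f$high_ratio))
  # a flag with no variation cannot enter the model
  keep_col <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                            function(v) length(unique(v)) > 1))
  fit <- fit_logistic(X[, keep_col, drop = FALSE], y,
                      on_separation = "flag")
  if (isTRUE(fit$separated)) {
    warning("combined model shows (quasi-)separation; ",
            "classification uses the saturated fitted probabilities")
  }
  prob <- as.numeric(X[, keep_col, drop = FALSE] %*% fit$coefficients)
  prob <- stats::plogis(prob)
  if (length(unique(prob)) > 1) {
    roc <- roc_auc(prob, y)
    oc <- optimal_cutoff(roc)
    cut <- oc$cutoff
  } else {
    cut <- 0.5
  }
  pred <- as.numeric(prob > cut)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  cp <- function(x, n) as.numeric(stats::binom.test(x, n)$conf.int)
  out <- list(
    fit = fit, probability_cutoff = cut,
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    n_classified = length(y), n_dropped = n_dropped,
    sensitivity = tp / (tp + fn), sensitivity_ci = cp(tp, tp + fn),
    specificity = tn / (tn + fp), specificity_ci = cp(tn, tn + fp),
    accuracy = (tp + tn) / length(y),
    accuracy_ci = cp(tp + tn, length(y)),
    cases_perturbed = mean(pred[y == 1] == 1),
    controls_intact = mean(pred[y == 0] == 0),
    predicted = pred, labels = y)
  class(out) <- "classification_report"
  out
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Combined iron-biology classifier (N = %d classified, %d dropped)\n",
              x$n_classified, x$n_dropped))
  cat(sprintf("  sensitivity %.1f%% [%.1f, %.1f]\n", 100 * x$sensitivity,
              100 * x$sensitivity_ci[1], 100 * x$sensitivity_ci[2]))
  cat(sprintf("  specificity %.1f%% [%.1f, %.1f]\n", 100 * x$specificity,
              100 * x$specificity_ci[1], 100 * x$specificity_ci[2]))
  cat(sprintf("  accuracy    %.1f%% [%.1f, %.1f]\n", 100 * x$accuracy,
              100 * x$accuracy_ci[1], 100 * x$accuracy_ci[2]))
  cat(sprintf("  cases flagged perturbed: %.1f%%; controls intact: %.1f%%\n",
              100 * x$cases_perturbed, 100 * x$controls_intact))
  invisible(x)
}

#' Likelihood-ratio comparison of nested logistic models
#'
#' @param full,reduced `logistic_fit`s on the same observations with the
#'   reduced model's predictors a subset of the full model's.
#' @return List: `lr` (>= 0), `df`, `p_value`, `aic_full`, `aic_reduced`.
#' @export
compare_nested_models <- function(full, reduced) {
  if (!all(reduced$terms %in% full$terms)) {
    stop("models are not nested (reduced terms not a subset)")
  }
  if (full$n_used != reduced$n_used) {
    stop("models were fit on different observation sets")
  }
  df <- length(full$terms) - length(reduced$terms)
  if (df <= 0) df <- 0L
  lr <- max(2 * (full$loglik - reduced$loglik), 0)
  p <- if (df == 0) 1 else stats::pchisq(lr, df, lower.tail = FALSE)
  list(lr = lr, df = df, p_value = p, aic_full = full$aic,
       aic_reduced = reduced$aic)
}
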