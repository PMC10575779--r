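# Logistic diagnosis models with influence-diagnostic exclusion, serial
# age- and iron-cutoff odds-ratio scans, cutoff selection, and subcohort
# contrasts.

#' Maximum-likelihood logistic regression with Wald inference
#'
#' Thin wrapper around [stats::glm()] (binomial family, IRLS/Newton) that
#' reports per-coefficient odds ratios with symmetric Wald 95% CIs on the
#' log-odds scale and flags complete separation instead of returning
#' silently huge coefficients.
#'
#' @param design Numeric predictor matrix including an intercept column.
#' @param labels Diagnosis indicators (0 = control, 1 = case); both classes
#'   must be present.
#' @param separation_bound Absolute log-odds coefficient beyond which the
#'   fit is declared separated (default 15).
#' @param on_separation `"error"` (default) aborts on separation;
#'   `"flag"` keeps the fit (fitted probabilities converge to cell
#'   proportions for saturated binary designs) with `separated = TRUE`.
#' @return A `logistic_fit`: `coefficients`, `se`, `z`, `p_value`, `or`,
#'   `or_ci` (matrix), `loglik`, `n_used`, `excluded_ids`, plus the fitted
#'   probabilities and stored design/labels for diagnostics.
#' @export
fit_logistic <- function(design, labels, separation_bound = 15,
                         on_separation = c("error", "flag")) {
  on_separation <- match.arg(on_separation)
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(labels)
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (qr(X)$rank < ncol(X)) stop("design is rank deficient")
  fit <- suppressWarnings(stats::glm.fit(X, y,
                                         family = stats::binomial()))
  beta <- fit$coefficients
  separated <- !fit$converged || any(abs(beta[-1]) > separation_bound)
  if (separated && on_separation == "error") {
    stop("logistic fit did not converge (possible complete separation)")
  }
  w <- fit$weights
  xtwx <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(xtwx), error = function(e) {
    stop("information matrix is singular")
  })
  se <- sqrt(diag(vcov))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  loglik <- sum(stats::dbinom(y, 1, fit$fitted.values, log = TRUE))
  out <- list(coefficients = beta, se = se, z = z, p_value = p,
              or = exp(beta),
              or_ci = structure(cbind(exp(beta - 1.96 * se),
                                      exp(beta + 1.96 * se)),
                                dimnames = list(names(beta),
                                                c("lower", "upper"))),
              loglik = loglik, aic = -2 * loglik + 2 * length(beta),
              n_used = length(y), excluded_ids = character(0),
              fitted = fit$fitted.values, design = X, labels = y,
              terms = colnames(X), vcov = vcov, separated = separated)
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: n = %d, logLik = %.3f, AIC = %.2f\n",
              x$n_used, x$loglik, x$aic))
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = x$z,
                    p = x$p_value, OR = x$or,
                    or_low = x$or_ci[, "lower"], or_high = x$or_ci[, "upper"])
  print(round(tab, 4))
  if (length(x$excluded_ids) > 0) {
    cat("Influence-pruned observations:",
        paste(x$excluded_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

# Pregibon delta-beta influence per observation of a logistic_fit:
# rsp^2 * h / (1 - h)^2 with standardized Pearson residuals
# rsp = r_pearson / sqrt(1 - h).
pregibon_dbeta <- function(fit) {
  X <- fit$design
  mu <- fit$fitted
  w <- mu * (1 - mu)
  xw <- X * sqrt(w)
  h <- rowSums((xw %*% fit$vcov) * xw)
  h <- pmin(h, 1 - 1e-10)
  r_pearson <- (fit$labels - mu) / sqrt(w)
  dbeta <- r_pearson^2 * h / (1 - h)^2
  list(dbeta = dbeta, leverage = h)
}

#' Influence-pruned logistic fit
#'
#' Fits the model, computes Pregibon-style per-observation coefficient
#' displacement (delta-beta) and leverage, excludes observations whose
#' delta-beta exceeds `threshold` (at most `cap` of the rows, largest
#' first), and refits once on the retained set. No iterative cascade.
#'
#' @param design,labels As in [fit_logistic()].
#' @param ids Optional observation identifiers used to report exclusions.
#' @param threshold Delta-beta exclusion threshold (default 1.0).
#' @param cap Maximum fraction of observations removed (default 0.05).
#' @return List: `fit` (the pruned refit, or the initial fit if nothing was
#'   excluded), `initial_fit`, `excluded_ids`, `dbeta`.
#' @export
influence_prune <- function(design, labels, ids = NULL, threshold = 1,
                            cap = 0.05) {
  X <- as.matrix(design)
  y <- as.numeric(labels)
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (is.null(ids)) ids <- as.character(seq_along(labels))
  ids <- ids[keep]
  initial <- fit_logistic(X, y)
  infl <- pregibon_dbeta(initial)
  cand <- which(infl$dbeta > threshold)
  max_out <- floor(cap * length(y))
  if (length(cand) > max_out) {
    cand <- cand[order(infl$dbeta[cand], decreasing = TRUE)][seq_len(max_out)]
  }
  if (length(cand) == 0) {
    return(list(fit = initial, initial_fit = initial,
                excluded_ids = character(0), dbeta = infl$dbeta))
  }
  y_kept <- y[-cand]
  if (length(unique(y_kept)) < 2) {
    stop("influence pruning would empty a diagnostic class; not applied")
  }
  refit <- tryCatch(fit_logistic(X[-cand, , drop = FALSE], y_kept),
                    error = function(e) NULL)
  if (is.null(refit)) {
    # pruning made the model separable; keep the unpruned fit
    return(list(fit = initial, initial_fit = initial,
                excluded_ids = character(0), dbeta = infl$dbeta))
  }
  refit$excluded_ids <- ids[cand]
  list(fit = refit, initial_fit = initial, excluded_ids = ids[cand],
       dbeta = infl$dbeta)
}

#' Robust covariate adjustment of an analyte
#'
#' Residualizes a z-scored analyte on covariates with [fit_mm()] over the
#' supplied subset and re-standardizes the residuals to SD 1, producing the
#' single "covariate-adjusted analyte (SD units)" predictor used by the
#' cutoff scans and ROC analyses.
#'
#' @param z Analyte z-scores.
#' @param df Data frame (cohort rows aligned with `z`) supplying the
#'   covariates.
#' @param covariates Covariate names (see [group_difference()] for
#'   codings); empty means standardize only.
#' @param standardize Rescale the residuals to SD 1 (default `TRUE`, the
#'   per-1-SD predictor used by scans and ROC); `FALSE` keeps them on the
#'   original z scale (used for adjusted group contrasts).
#' @param ... Passed to [fit_mm()].
#' @return Adjusted values (SD 1 when standardized), `NA` where inputs are
#'   incomplete.
#' @export
adjust_analyte <- function(z, df, covariates, standardize = TRUE, ...) {
  out <- rep(NA_real_, length(z))
  if (length(covariates) == 0) {
    keep <- !is.na(z)
    out[keep] <- if (standardize) z[keep] / stats::sd(z[keep]) else z[keep]
    return(out)
  }
  covm <- covariate_design(df, covariates)
  X <- cbind(intercept = rep(1, length(z)), covm)
  keep <- stats::complete.cases(X, z)
  if (sum(keep) <= ncol(X)) return(out)
  # covariates constant over the analysis subset carry no information
  Xk <- X[keep, , drop = FALSE]
  informative <- c(TRUE, apply(Xk[, -1, drop = FALSE], 2,
                               function(v) stats::sd(v) > 0))
  fit <- fit_mm(Xk[, informative, drop = FALSE], z[keep], ...)
  res <- fit$residuals
  out[keep] <- if (standardize) res / stats::sd(res) else res
  out
}

scan_grid <- function(start, step, max_value) {
  if (!is.finite(max_value) || max_value < start) return(start)
  k <- floor((max_value - start) / step) + 1L
  seq(start, by = step, length.out = k + 1L)
}

# One scan entry: adjusted single-predictor logistic fit (with optional
# influence pruning) on the rows in `sel`; missing entry when the stratum
# is too small or the fit fails.
scan_entry <- function(cutoff, sel, adjusted, diagnosis, ids, min_n,
                       min_per_class, prune, threshold, cap) {
  sel <- sel[!is.na(adjusted[sel])]
  na_row <- data.frame(cutoff = cutoff, n = length(sel),
                       n_used = NA_integer_, or = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                       n_excluded = NA_integer_)
  y <- as.numeric(is_case(diagnosis[sel]))
  if (length(sel) < min_n ||
      min(sum(y == 0), sum(y == 1)) < min_per_class) {
    return(na_row)
  }
  X <- cbind(intercept = 1, predictor = adjusted[sel])
  res <- tryCatch({
    if (prune) {
      influence_prune(X, y, ids = ids[sel], threshold = threshold,
                      cap = cap)$fit
    } else {
      fit_logistic(X, y)
    }
  }, error = function(e) NULL)
  if (is.null(res)) return(na_row)
  data.frame(cutoff = cutoff, n = length(sel), n_used = res$n_used,
             or = unname(res$or["predictor"]),
             ci_low = res$or_ci["predictor", "lower"],
             ci_high = res$or_ci["predictor", "upper"],
             p = unname(res$p_value["predictor"]),
             n_excluded = length(res$excluded_ids))
}

as_scan_profile <- function(rows, axis, step, start, min_n, rule) {
  profile <- do.call(rbind, rows)
  rownames(profile) <- NULL
  class(profile) <- c("scan_profile", "data.frame")
  attr(profile, "axis") <- axis
  attr(profile, "step") <- step
  attr(profile, "start") <- start
  attr(profile, "selected_cutoff") <-
    tryCatch(select_cutoff(profile, rule = rule, min_n = min_n),
             error = function(e) NA_real_)
  attr(profile, "selection_rule") <- rule
  profile
}

#' Serial age-cutoff odds-ratio scan for iron
#'
#' For each age cutoff `a` on the grid `start, start + step, ...` (2-year
#' steps from 31 by default, ending at the first grid point above the
#' oldest subject so the final entry is the full cohort), restricts to
#' subjects who died younger than `a` (strict), covariate-adjusts iron by
#' robust residualization over that subset, fits
#' `diagnosis ~ adjusted iron` with influence pruning, and records the odds
#' ratio of a schizophrenia diagnosis per 1 SD of adjusted iron. Entries
#' with fewer than `min_n` subjects or fewer than `min_per_class` per class
#' are recorded as missing, not errors.
#'
#' @param ztable A `zscore_table` with `z_iron`.
#' @param cohort Matching `cohort` (covariate source).
#' @param covariates Adjustment covariates (default sex, ancestry, pH, PMI;
#'   age is deliberately excluded since age is the scan axis).
#' @param start,step Grid origin and spacing (years).
#' @param min_n,min_per_class Minimum stratum size and per-class count.
#' @param prune Apply influence pruning (default `TRUE`).
#' @param threshold,cap Pruning parameters, see [influence_prune()].
#' @param rule Cutoff selection rule, see [select_cutoff()] (the age scan
#'   defaults to the maximal odds ratio, the iron scan to maximal
#'   significance).
#' @param ... Passed to [fit_mm()] for the residualization.
#' @return A `scan_profile` data frame `(cutoff, n, n_used, or, ci_low,
#'   ci_high, p, n_excluded)` with the selected cutoff in
#'   `attr(, "selected_cutoff")`.
#' @export
scan_age_cutoffs <- function(ztable, cohort,
                             covariates = c("sex", "ancestry", "ph", "pmi"),
                             start = 31, step = 2, min_n = 10,
                             min_per_class = 3, prune = TRUE, threshold = 1,
                             cap = 0.05, rule = "max_abs_log_or", ...) {
  idx <- match(ztable$subject_id, cohort$subject_id)
  df <- cohort[idx, , drop = FALSE]
  age <- ztable$age_death
  cutoffs <- scan_grid(start, step, max(age, na.rm = TRUE))
  rows <- lapply(cutoffs, function(ct) {
    sel <- which(!is.na(age) & age < ct & !is.na(ztable$z_iron))
    adjusted <- rep(NA_real_, length(age))
    if (length(sel) >= min_n) {
      adjusted[sel] <- adjust_analyte(ztable$z_iron[sel],
                                      df[sel, , drop = FALSE],
                                      covariates, ...)
    }
    scan_entry(ct, sel, adjusted, ztable$diagnosis, ztable$subject_id,
               min_n, min_per_class, prune, threshold, cap)
  })
  as_scan_profile(rows, "age", step, start, min_n, rule = rule)
}

#' Serial iron-cutoff odds-ratio scan for ferritin
#'
#' For each iron cutoff `q` on the grid (0.1 SD steps from -1 SD by
#' default, ending above the largest iron z-score), restricts to subjects
#' with harmonized iron below `q`, covariate-adjusts ferritin by robust
#' residualization over that subset, fits `diagnosis ~ adjusted ferritin`
#' with influence pruning, and records the odds ratio per 1 SD of adjusted
#' ferritin.
#'
#' @param ztable A `zscore_table` with `z_iron` and `z_ferritin`.
#' @param cohort Matching `cohort`.
#' @param covariates Adjustment covariates (default age, sex, ancestry, pH,
#'   PMI).
#' @param start,step Grid origin and spacing (iron SD units).
#' @inheritParams scan_age_cutoffs
#' @return A `scan_profile`, as in [scan_age_cutoffs()].
#' @export
scan_iron_cutoffs <- function(ztable, cohort,
                              covariates = c("age_death", "sex", "ancestry",
                                             "ph", "pmi"),
                              start = -1, step = 0.1, min_n = 10,
                              min_per_class = 3, prune = TRUE, threshold = 1,
                              cap = 0.05, rule = "min_p", ...) {
  idx <- match(ztable$subject_id, cohort$subject_id)
  df <- cohort[idx, , drop = FALSE]
  ziron <- ztable$z_iron
  cutoffs <- scan_grid(start, step, max(ziron, na.rm = TRUE))
  rows <- lapply(cutoffs, function(ct) {
    sel <- which(!is.na(ziron) & ziron < ct & !is.na(ztable$z_ferritin))
    adjusted <- rep(NA_real_, length(ziron))
    if (length(sel) >= min_n) {
      adjusted[sel] <- adjust_analyte(ztable$z_ferritin[sel],
                                      df[sel, , drop = FALSE],
                                      covariates, ...)
    }
    scan_entry(ct, sel, adjusted, ztable$diagnosis, ztable$subject_id,
               min_n, min_per_class, prune, threshold, cap)
  })
  as_scan_profile(rows, "iron_z", step, start, min_n, rule = rule)
}

#' Select the operating cutoff from a scan profile
#'
#' Built-in rules, applied to non-missing entries with `p < alpha` and
#' `n >= min_n`:
#' \describe{
#'   \item{`"max_abs_log_or"`}{the cutoff maximizing `|ln OR|` (where the
#'     odds ratio is farthest from 1); used for the age scan, whose
#'     operating age is chosen where the iron odds ratio is maximal;}
#'   \item{`"min_p"`}{the cutoff where the predictor is most significant;
#'     used for the iron scan, whose operating iron level is chosen where
#'     ferritin's significance is maximal.}
#' }
#' Ties break toward the smaller cutoff. A custom `rule` function
#' receiving the profile data frame and returning a cutoff may be supplied
#' instead.
#'
#' @param profile A `scan_profile`.
#' @param rule Rule name or replacement selection function.
#' @param alpha Significance gate (default 0.05).
#' @param min_n Minimum stratum size gate (default 10).
#' @return The selected cutoff value.
#' @export
select_cutoff <- function(profile, rule = c("max_abs_log_or", "min_p"),
                          alpha = 0.05, min_n = 10) {
  if (is.function(rule)) return(rule(as.data.frame(profile)))
  rule <- match.arg(rule)
  df <- as.data.frame(profile)
  ok <- !is.na(df$or) & !is.na(df$p) & df$p < alpha & df$n >= min_n
  if (!any(ok)) {
    stop("no scan entry passes the selection rule; relax alpha or min_n")
  }
  df <- df[ok, , drop = FALSE]
  score <- switch(rule,
                  max_abs_log_or = abs(log(df$or)),
                  min_p = -log(df$p))
  best <- which(score == max(score))
  df$cutoff[best[which.min(df$cutoff[best])]]
}

#' Robust group contrasts within the two sides of a split
#'
#' Splits the cohort at `(axis, cutoff)` (strictly-below vs at-or-above)
#' and, within each side, estimates the covariate-adjusted case-control
#' difference with a robust model of the analyte on diagnosis plus
#' covariates (the diagnosis coefficient is the adjusted contrast, in
#' control-SD z units).
#'
#' @param ztable A `zscore_table`.
#' @param cohort Matching `cohort`.
#' @param split List or vector `(axis, cutoff)`; axis `"age"` splits on age
#'   of death (years), `"iron_z"` on harmonized iron.
#' @param analyte Analyte contrasted (e.g. `"iron"`, `"ferritin"`).
#' @param covariates Covariates adjusted for within each stratum.
#' @param ... Passed to [fit_mm()].
#' @return List with `below` and `above` `robust_fit`s (each carrying an
#'   `effect` in SD units of the adjusted analyte), plus the split used.
#' @export
subcohort_contrast <- function(ztable, cohort, split, analyte,
                               covariates = character(0), ...) {
  axis <- split[[1]]
  cutoff <- as.numeric(split[[2]])
  values <- switch(axis,
                   age = ztable$age_death,
                   iron_z = ztable$z_iron,
                   stop("unknown split axis: ", axis))
  idx <- match(ztable$subject_id, cohort$subject_id)
  df <- cohort[idx, , drop = FALSE]
  zcol <- paste0("z_", analyte)
  sides <- list(below = which(!is.na(values) & values < cutoff),
                above = which(!is.na(values) & values >= cutoff))
  fits <- lapply(names(sides), function(side) {
    sel <- sides[[side]]
    sub_z <- ztable[sel, , drop = FALSE]
    if (length(sel) == 0 || length(unique(sub_z$diagnosis)) < 2) {
      stop("stratum '", side, " ", cutoff,
           "' does not contain both diagnostic groups")
    }
    group_difference(sub_z, analyte, covariates, cohort, ...)
  })
  names(fits) <- names(sides)
  fits$split <- list(axis = axis, cutoff = cutoff)
  fits
}

#' Predicted probability curve from a logistic fit
#'
#' Inverse-logit of the linear predictor over a grid of values of one
#' predictor, holding other predictors (if any) at their sample means.
#'
#' @param fit A `logistic_fit`.
#' @param grid Predictor values.
#' @param predictor Name or index of the scanned predictor column (default
#'   the second design column).
#' @return Data frame `(value, probability)`; probabilities are strictly
#'   monotone in `value` when the scanned coefficient is nonzero.
#' @export
predicted_probability_curve <- function(fit, grid, predictor = 2L) {
  beta <- fit$coefficients
  if (is.character(predictor)) predictor <- match(predictor, names(beta))
  means <- colMeans(fit$design)
  lp0 <- sum(beta[-predictor] * means[-predictor])
  data.frame(value = grid,
             probability = stats::plogis(lp0 + beta[predictor] * grid))
}
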