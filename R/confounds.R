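# Confounder-robustness machinery: propensity-score matching with
# regression adjustment, single-mediator path analysis, and
# medication-association tests.

#' Propensity-score matching with regression adjustment
#'
#' Logistic propensity model `diagnosis ~ covariates`; 1:1 greedy
#' nearest-neighbour matching on the logit propensity without replacement,
#' in seeded random case order, with a caliper expressed in SDs of the
#' logit propensity (0.2 by default). The matched set is then analysed
#' with a covariate-adjusted robust group difference (regression
#' adjustment on top of matching).
#'
#' @param ztable A `zscore_table`.
#' @param cohort Matching `cohort`.
#' @param covariates Covariates entering the propensity model (and the
#'   post-match adjustment).
#' @param analyte Analyte for the post-matching contrast (default
#'   `"iron"`).
#' @param caliper Caliper in logit-propensity SD multiples (default 0.2).
#' @param seed Seed for the case matching order.
#' @param ... Passed to [fit_mm()].
#' @return A `match_result`: `pairs` (case id, control id, distance),
#'   `balance` (per-covariate standardized mean differences pre/post),
#'   `fit` (post-matching `robust_fit` with `effect`), `n_matched`.
#' @export
propensity_match <- function(ztable, cohort,
                             covariates = c("age_death", "sex", "ancestry",
                                            "ph", "pmi"),
                             analyte = "iron", caliper = 0.2, seed = 1L,
                             ...) {
  idx <- match(ztable$subject_id, cohort$subject_id)
  df <- cohort[idx, , drop = FALSE]
  covm <- covariate_design(df, covariates)
  y <- as.numeric(is_case(ztable$diagnosis))
  keep <- stats::complete.cases(covm, y)
  if (length(unique(y[keep])) < 2) stop("both groups must be non-empty")
  X <- cbind(intercept = 1, covm[keep, , drop = FALSE])
  fit_ps <- fit_logistic(X, y[keep])
  lp <- as.numeric(X %*% fit_ps$coefficients) # logit propensity
  ids <- ztable$subject_id[keep]
  yk <- y[keep]
  cal_abs <- caliper * stats::sd(lp)

  case_idx <- which(yk == 1)
  ctrl_idx <- which(yk == 0)
  order_cases <- with_seed(seed, sample(case_idx))
  available <- rep(TRUE, length(ctrl_idx))
  pairs <- list()
  for (ci in order_cases) {
    d <- abs(lp[ctrl_idx] - lp[ci])
    d[!available] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= cal_abs) {
      available[j] <- FALSE
      pairs[[length(pairs) + 1]] <- data.frame(
        case_id = ids[ci], control_id = ids[ctrl_idx[j]],
        distance = d[j], stringsAsFactors = FALSE)
    }
  }
  pre_smd <- vapply(seq_len(ncol(covm)), function(k) {
    smd(covm[keep, k][yk == 1], covm[keep, k][yk == 0])
  }, 0)
  if (length(pairs) == 0) {
    stop("no matches within caliper; pre-matching |SMD|s: ",
         paste(sprintf("%s=%.2f", covariates, abs(pre_smd)),
               collapse = ", "))
  }
  pairs <- do.call(rbind, pairs)
  matched_ids <- c(pairs$case_id, pairs$control_id)
  msel <- match(matched_ids, ids)
  post_smd <- vapply(seq_len(ncol(covm)), function(k) {
    v <- covm[keep, k][msel]
    smd(v[yk[msel] == 1], v[yk[msel] == 0])
  }, 0)
  balance <- data.frame(covariate = covariates, smd_pre = pre_smd,
                        smd_post = post_smd, stringsAsFactors = FALSE)
  sub_z <- ztable[ztable$subject_id %in% matched_ids, , drop = FALSE]
  fit <- group_difference(sub_z, analyte, covariates, cohort, ...)
  out <- list(pairs = pairs, balance = balance, fit = fit,
              n_matched = nrow(pairs), caliper = caliper,
              caliper_abs = cal_abs)
  class(out) <- "match_result"
  out
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Propensity matching: %d pairs (caliper %.2f logit-SD = %.3f)\n",
              x$n_matched, x$caliper, x$caliper_abs))
  print(transform(x$balance, smd_pre = round(smd_pre, 3),
                  smd_post = round(smd_post, 3)), row.names = FALSE)
  cat(sprintf("Post-matching %s effect: %.3f [%.3f, %.3f]\n", x$fit$analyte,
              x$fit$effect$estimate, x$fit$effect$ci_low,
              x$fit$effect$ci_high))
  invisible(x)
}

#' Single-mediator path analysis with a binary outcome
#'
#' Product-of-coefficients mediation: path `a` (exposure to mediator) by
#' robust linear regression, paths `b` (mediator) and `c'` (direct) from a
#' logistic model of the outcome on exposure plus mediator, indirect
#' effect `a * b` with a seeded percentile bootstrap CI. The proportion
#' mediated `ab / (ab + c')` is reported only when the indirect and direct
#' effects share a sign.
#'
#' @param ztable A `zscore_table`.
#' @param cohort Matching `cohort`.
#' @param exposure,mediator Analyte names (z columns used; default iron
#'   exposure, zinc mediator).
#' @param covariates Optional adjustment covariates for both paths.
#' @param B Bootstrap replicates (default 1000); `B = 0` skips the
#'   bootstrap and returns point estimates only.
#' @param seed Integer seed.
#' @param ... Passed to [fit_mm()] (e.g. `n_resamples` to lighten the
#'   bootstrap).
#' @return A `mediation_result`: `a`, `b`, `direct` (c'), `indirect`
#'   (a*b), `indirect_ci`, `proportion_mediated` (or `NA`), `B`, `n`.
#' @export
mediation <- function(ztable, cohort, exposure = "iron", mediator = "zinc",
                      covariates = character(0), B = 1000L, seed = 1L,
                      ...) {
  zx <- ztable[[paste0("z_", exposure)]]
  zm <- ztable[[paste0("z_", mediator)]]
  y <- as.numeric(is_case(ztable$diagnosis))
  covm <- NULL
  if (length(covariates) > 0) {
    idx <- match(ztable$subject_id, cohort$subject_id)
    covm <- covariate_design(cohort[idx, , drop = FALSE], covariates)
  }
  keep <- stats::complete.cases(zx, zm, y, covm)
  zx <- zx[keep]; zm <- zm[keep]; y <- y[keep]
  if (!is.null(covm)) covm <- covm[keep, , drop = FALSE]
  if (stats::sd(zm) == 0) stop("degenerate mediator with zero variance")
  n <- length(zx)

  paths <- function(zx, zm, y, covm) {
    Xa <- cbind(intercept = 1, exposure = zx, covm)
    fa <- fit_mm(Xa, zm, ...)
    Xb <- cbind(intercept = 1, exposure = zx, mediator = zm, covm)
    fb <- fit_logistic(Xb, y)
    c(a = unname(fa$coefficients["exposure"]),
      b = unname(fb$coefficients["mediator"]),
      cprime = unname(fb$coefficients["exposure"]))
  }
  est <- paths(zx, zm, y, covm)
  indirect <- est["a"] * est["b"]
  if (B == 0) {
    out <- list(a = unname(est["a"]), b = unname(est["b"]),
                direct = unname(est["cprime"]),
                indirect = unname(indirect),
                indirect_ci = c(NA_real_, NA_real_),
                proportion_mediated = NA_real_, B = 0L, n = n)
    class(out) <- "mediation_result"
    return(out)
  }
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2) return(NA_real_)
      p <- tryCatch(paths(zx[idx], zm[idx], y[idx],
                          if (is.null(covm)) NULL else
                            covm[idx, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(p)) NA_real_ else p["a"] * p["b"]
    }, 0)
  })
  boot <- boot[!is.na(boot)]
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  pm <- if (sign(indirect) == sign(est["cprime"]) && indirect != 0) {
    unname(indirect / (indirect + est["cprime"]))
  } else {
    NA_real_
  }
  out <- list(a = unname(est["a"]), b = unname(est["b"]),
              direct = unname(est["cprime"]),
              indirect = unname(indirect), indirect_ci = ci,
              proportion_mediated = pm, B = length(boot), n = n)
  class(out) <- "mediation_result"
  out
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation (n = %d, %d bootstrap replicates)\n", x$n, x$B))
  cat(sprintf("  a (exposure->mediator): %.3f\n", x$a))
  cat(sprintf("  b (mediator->outcome, log-odds/SD): %.3f\n", x$b))
  cat(sprintf("  direct c': %.3f\n", x$direct))
  cat(sprintf("  indirect a*b: %.3f [%.3f, %.3f]\n", x$indirect,
              x$indirect_ci[1], x$indirect_ci[2]))
  if (!is.na(x$proportion_mediated)) {
    cat(sprintf("  proportion mediated: %.3f\n", x$proportion_mediated))
  }
  invisible(x)
}

# Two-sided permutation p for a statistic under exposure relabeling; the
# p-value lies on the (k+1)/(B+1) grid.
permutation_p <- function(x, y, stat, n_perm, seed) {
  obs <- stat(x, y)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat(sample(x), y), 0)
  })
  (sum(abs(perm) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
}

#' Medication-association tests on case iron
#'
#' Among schizophrenia cases, tests association of harmonized iron with
#' each antipsychotic exposure: Pearson correlation (Spearman optional)
#' for continuous doses/durations, robust group contrasts for categorical
#' exposures (typicality, toxicology positivity). Each parametric p-value
#' is accompanied by a seeded permutation p-value, and continuous
#' associations are repeated partialling out the adjusters.
#'
#' @param ztable A `zscore_table`.
#' @param cohort Matching `cohort`.
#' @param exposures Exposure columns to test.
#' @param adjusters Adjustment variables for the partial correlations
#'   (default age of onset and treatment duration).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param n_perm Permutation count (default 10000).
#' @param seed Integer seed.
#' @param min_n Minimum measured cases per exposure (default 10).
#' @return Data frame: exposure, type, n, estimate, ci/p columns,
#'   permutation p, adjusted estimate and p (continuous only), status.
#' @export
medication_association <- function(ztable, cohort,
                                   exposures = c("ap_mean_daily_dose",
                                                 "ap_lifetime_exposure",
                                                 "ap_duration",
                                                 "ap_typicality",
                                                 "ap_tox_positive",
                                                 "lithium_tox_positive"),
                                   adjusters = c("age_onset", "ap_duration"),
                                   method = c("pearson", "spearman"),
                                   n_perm = 10000L, seed = 1L, min_n = 10L) {
  method <- match.arg(method)
  idx <- match(ztable$subject_id, cohort$subject_id)
  df <- cohort[idx, , drop = FALSE]
  cases <- is_case(ztable$diagnosis) & !is.na(ztable$z_iron)
  rows <- lapply(exposures, function(ex) {
    v <- df[[ex]][cases]
    z <- ztable$z_iron[cases]
    keep <- !is.na(v)
    base <- data.frame(exposure = ex, type = NA_character_,
                       n = sum(keep), estimate = NA_real_, p = NA_real_,
                       p_perm = NA_real_, estimate_adjusted = NA_real_,
                       p_adjusted = NA_real_, status = "ok",
                       stringsAsFactors = FALSE)
    if (sum(keep) == 0) {
      base$status <- "unavailable"
      return(base)
    }
    if (sum(keep) < min_n) {
      base$status <- "insufficient n"
      return(base)
    }
    vv <- v[keep]; zz <- z[keep]
    if (is.numeric(vv) && length(unique(vv)) > 2) {
      base$type <- "correlation"
      ct <- stats::cor.test(vv, zz, method = method)
      base$estimate <- unname(ct$estimate)
      base$p <- ct$p.value
      base$p_perm <- permutation_p(vv, zz, function(a, b) {
        stats::cor(a, b, method = method)
      }, n_perm, seed + match(ex, exposures))
      adj <- df[adjusters]
      adj <- adj[cases, , drop = FALSE][keep, , drop = FALSE]
      ok <- stats::complete.cases(adj)
      if (sum(ok) >= min_n && all(vapply(adj, is.numeric, TRUE))) {
        am <- as.matrix(adj[ok, , drop = FALSE])
        keep_adj <- apply(am, 2, function(col) stats::sd(col) > 0)
        am <- am[, keep_adj, drop = FALSE]
        if (ncol(am) > 0) {
          rv <- stats::resid(stats::lm(vv[ok] ~ am))
          rz <- stats::resid(stats::lm(zz[ok] ~ am))
          if (stats::sd(rv) > 0 && stats::sd(rz) > 0) {
            cta <- stats::cor.test(rv, rz, method = method)
            base$estimate_adjusted <- unname(cta$estimate)
            base$p_adjusted <- cta$p.value
          }
        }
      }
    } else {
      base$type <- "group contrast"
      g <- if (is.logical(vv)) factor(vv) else factor(vv)
      if (nlevels(droplevels(g)) < 2) {
        base$status <- "constant exposure"
        return(base)
      }
      g <- droplevels(g)
      M <- stats::model.matrix(~g)
      fit <- fit_mm(M, zz)
      base$estimate <- unname(fit$coefficients[2])
      base$p <- fit$p_value[2]
      base$p_perm <- permutation_p(as.numeric(g), zz, function(a, b) {
        mean(b[a == max(a)]) - mean(b[a == min(a)])
      }, n_perm, seed + match(ex, exposures))
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
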