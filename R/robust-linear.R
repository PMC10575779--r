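# MM-estimator robust linear regression: Tukey bisquare loss, S-estimate of
# scale via seeded elemental-set subsampling, efficiency-tuned IRWLS M-step,
# sandwich standard errors. Also linear vs linear-logarithmic model
# comparison and covariate-adjusted robust group differences.

#' Tukey bisquare loss family
#'
#' For `|u| <= c`: `rho = (c^2/6) * (1 - (1 - (u/c)^2)^3)`,
#' `psi = u * (1 - (u/c)^2)^2`, `weight = psi/u` (1 at 0); for `|u| > c`:
#' `rho = c^2/6`, `psi = 0`, `weight = 0`.
#'
#' @param u Standardized residuals (vectorized).
#' @param c Tuning constant, > 0.
#' @return List with components `rho`, `psi`, `weight`.
#' @export
bisquare <- function(u, c) {
  if (c <= 0) stop("tuning constant c must be > 0")
  t2 <- pmin((u / c)^2, 1)
  w <- (1 - t2)^2
  list(rho = (c^2 / 6) * (1 - (1 - t2)^3),
       psi = u * w,
       weight = w)
}

# psi'(u) for the bisquare family (0 beyond c).
bisquare_dpsi <- function(u, c) {
  t2 <- (u / c)^2
  ifelse(t2 <= 1, (1 - t2) * (1 - 5 * t2), 0)
}

.tuning_cache <- new.env(parent = emptyenv())

# Gaussian efficiency of the bisquare M-step at tuning constant c:
# (E psi')^2 / E psi^2, expectations under N(0,1).
bisquare_gauss_efficiency <- function(c) {
  epsi2 <- stats::integrate(function(u) bisquare(u, c)$psi^2 * stats::dnorm(u),
                            -c, c)$value
  edpsi <- stats::integrate(function(u) bisquare_dpsi(u, c) * stats::dnorm(u),
                            -c, c)$value
  edpsi^2 / epsi2
}

# Tuning constant giving consistency at the normal with breakdown point
# bdp: solves E_Phi[rho_c(Z)] = bdp * c^2/6.
bisquare_c_for_breakdown <- function(bdp) {
  stopifnot(bdp > 0.05, bdp <= 0.5)
  key <- sprintf("bdp%.6f", bdp)
  if (!is.null(.tuning_cache[[key]])) return(.tuning_cache[[key]])
  f <- function(c) {
    erho <- stats::integrate(function(u) bisquare(u, c)$rho * stats::dnorm(u),
                             -Inf, Inf)$value
    erho - bdp * c^2 / 6
  }
  .tuning_cache[[key]] <- stats::uniroot(f, c(0.5, 20), tol = 1e-8)$root
  .tuning_cache[[key]]
}

#' Bisquare tuning constant for a target Gaussian efficiency
#'
#' Solves for the tuning constant at which the bisquare M-estimator reaches
#' the requested asymptotic efficiency at the normal model (e.g. 0.85 ->
#' c ~ 3.44, 0.95 -> c ~ 4.69).
#'
#' @param efficiency Target efficiency in (0.5, 0.9999).
#' @return Tuning constant.
#' @export
bisquare_c_for_efficiency <- function(efficiency) {
  stopifnot(efficiency > 0.5, efficiency < 0.9999)
  key <- sprintf("eff%.6f", efficiency)
  if (!is.null(.tuning_cache[[key]])) return(.tuning_cache[[key]])
  .tuning_cache[[key]] <- stats::uniroot(
    function(c) bisquare_gauss_efficiency(c) - efficiency,
    c(1, 20), tol = 1e-8)$root
  .tuning_cache[[key]]
}

#' S-estimate of residual scale
#'
#' Solves `(1/n) sum rho(r_i / sigma) = b` for `sigma` by the standard
#' fixed-point iteration. With the default `c_S = 1.5476` and
#' `b = c_S^2/12` (half the maximum of `rho`) the estimate is consistent
#' at the normal model with a 50% breakdown point, and is scale
#' equivariant: `s_scale(k * r) = |k| * s_scale(r)`.
#'
#' @param residuals Numeric residuals, `n >= 2`.
#' @param c_S S-stage tuning constant.
#' @param b Consistency constant; default `c_S^2 / 12`.
#' @param tol Relative convergence tolerance.
#' @return The scale estimate; 0 with attribute `degenerate = TRUE` when
#'   more than half the residuals are exactly zero.
#' @export
s_scale <- function(residuals, c_S = 1.5476, b = c_S^2 / 12, tol = 1e-10) {
  r <- residuals[!is.na(residuals)]
  n <- length(r)
  if (n < 2) stop("s_scale requires n >= 2")
  if (mean(r == 0) > 0.5) {
    # majority of residuals exactly zero: rho-equation has no positive root
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  s <- stats::median(abs(r)) / 0.6745
  if (s == 0) s <- mean(abs(r))
  r2 <- r * r
  c2 <- c_S^2
  for (i in 1:100) {
    t2 <- pmin.int(r2 / (s * s * c2), 1)
    mean_rho <- (c2 / 6) * (1 - mean((1 - t2)^3))
    s_new <- s * sqrt(mean_rho / b)
    if (abs(s_new - s) <= tol * s) {
      s <- s_new
      break
    }
    s <- s_new
  }
  s
}

# One weighted least-squares step; returns NULL on singular systems.
wls_step <- function(X, y, w) {
  xw <- X * sqrt(w)
  fit <- tryCatch(qr.coef(qr(xw), y * sqrt(w)), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit)) return(NULL)
  fit
}

# IRWLS refinement of an S-candidate: alternate bisquare(c_S) weights at
# the current scale, weighted LS, and scale update.
refine_s_candidate <- function(X, y, beta, c_S, b, steps = 10) {
  r <- y - X %*% beta
  s <- s_scale(r, c_S, b)
  if (s == 0) return(list(beta = beta, scale = 0))
  for (i in seq_len(steps)) {
    w <- bisquare(as.numeric(r) / s, c_S)$weight
    if (sum(w > 0) < ncol(X)) break
    beta_new <- wls_step(X, y, w)
    if (is.null(beta_new)) break
    r <- y - X %*% beta_new
    s_new <- s_scale(r, c_S, b)
    if (s_new == 0) return(list(beta = beta_new, scale = 0))
    done <- abs(s_new - s) < 1e-10 * s &&
      max(abs(beta_new - beta)) < 1e-10 * max(1, max(abs(beta)))
    beta <- beta_new
    s <- s_new
    if (done) break
  }
  list(beta = beta, scale = s)
}

#' MM-estimator robust linear regression
#'
#' Three stages: (1) a high-breakdown S-estimate of coefficients and scale
#' from seeded random elemental-set subsampling with IRWLS refinement of
#' the best candidates; (2) the S-scale is fixed; (3) an IRWLS M-step with
#' bisquare psi at the tuning constant implied by `efficiency`, iterated to
#' coefficient convergence. Robust standard errors use the standard
#' M-estimator sandwich form
#' `Var(beta) = sigma^2 * n/(n-p) * E[psi^2]/E[psi']^2 * (X'X)^{-1}`.
#'
#' The subsampling seed defaults to a symmetric hash of the input data, so
#' repeated calls (in any row order) are deterministic without touching the
#' caller's RNG.
#'
#' @param design Numeric predictor matrix (include an intercept column if
#'   wanted); must have full column rank and `n > p`.
#' @param response Numeric outcome vector.
#' @param efficiency Target Gaussian efficiency of the M-step (default
#'   0.85; 0.95 gives the high-efficiency variant).
#' @param c_S S-stage tuning constant. The default (`NULL`) uses 1.5476
#'   (consistency at the normal with 50% breakdown); in small samples the
#'   breakdown point is capped at the maximum attainable for the design
#'   dimension, `(n - p) / (2n)`, and the constant adjusted accordingly,
#'   which stabilizes the S-search when `n/p` is small.
#' @param n_resamples Number of elemental subsample candidates (default
#'   500).
#' @param max_iter,tol M-step iteration cap and relative coefficient
#'   tolerance.
#' @param seed Subsampling seed; `NULL` derives one from the data.
#' @return A `robust_fit`: coefficients, robust SEs, t statistics (referred
#'   to `n - p` residual df), p-values, 95% CIs, S-scale, final weights,
#'   tuning constants, convergence flag, iteration count, `n_used`.
#' @export
fit_mm <- function(design, response, efficiency = 0.85, c_S = NULL,
                   n_resamples = 500L, max_iter = 500L, tol = 1e-8,
                   seed = NULL) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  y <- as.numeric(response)
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("need more observations than predictors")
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(c_S)) {
    bdp <- min(0.5, (n - p) / (2 * n))
    c_S <- if (bdp >= 0.45) 1.5476 else bisquare_c_for_breakdown(bdp)
  } else {
    bdp <- 0.5
  }
  b_cons <- bdp * c_S^2 / 6
  c_M <- bisquare_c_for_efficiency(efficiency)
  if (is.null(seed)) seed <- data_seed(X, y)

  # --- S stage -------------------------------------------------------
  ols <- qr.coef(qrx, y)
  cand <- with_seed(seed, {
    betas <- vector("list", n_resamples)
    crit <- rep(Inf, n_resamples)
    for (i in seq_len(n_resamples)) {
      idx <- sample.int(n, p)
      beta <- tryCatch(solve(X[idx, , drop = FALSE], y[idx]),
                       error = function(e) NULL)
      if (is.null(beta) || anyNA(beta)) next
      betas[[i]] <- beta
      # cheap robust criterion used to shortlist candidates
      crit[i] <- stats::median(abs(y - X %*% beta))
    }
    betas[order(crit)[seq_len(min(5L, n_resamples))]]
  })
  cand <- Filter(Negate(is.null), cand)
  cand <- c(cand, list(ols))
  best <- NULL
  for (beta in cand) {
    ref <- refine_s_candidate(X, y, beta, c_S, b_cons)
    if (ref$scale == 0) { best <- ref; break }
    if (is.null(best) || ref$scale < best$scale) best <- ref
  }
  sigma <- best$scale
  beta <- best$beta

  if (sigma == 0) {
    # exact fit (noise-free data): coefficients are the interpolating ones
    res <- as.numeric(y - X %*% beta)
    out <- list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
                se = stats::setNames(rep(0, p), colnames(X)),
                t = rep(Inf, p), p_value = rep(0, p),
                ci = structure(cbind(lower = as.numeric(beta),
                                     upper = as.numeric(beta)),
                               dimnames = list(colnames(X),
                                               c("lower", "upper"))),
                scale = 0, weights = rep(1, n), residuals = res,
                fitted = as.numeric(X %*% beta), c_S = c_S, c_M = c_M,
                efficiency = efficiency, converged = TRUE, iterations = 0L,
                n_used = n, df = n - p, degenerate = TRUE)
    class(out) <- "robust_fit"
    return(out)
  }

  # --- M stage (scale fixed) ----------------------------------------
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    u <- as.numeric(y - X %*% beta) / sigma
    w <- bisquare(u, c_M)$weight
    beta_new <- wls_step(X, y, w)
    if (is.null(beta_new)) break
    delta <- max(abs(beta_new - beta)) / max(1, max(abs(beta)))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  res <- as.numeric(y - X %*% beta)
  u <- res / sigma
  fam <- bisquare(u, c_M)
  mean_psi2 <- mean(fam$psi^2)
  mean_dpsi <- mean(bisquare_dpsi(u, c_M))
  xtx_inv <- chol2inv(qr.R(qrx))
  vcov <- sigma^2 * (n / (n - p)) * (mean_psi2 / mean_dpsi^2) * xtx_inv
  se <- sqrt(pmax(diag(vcov), 0))
  tval <- as.numeric(beta) / se
  df <- n - p
  pval <- 2 * stats::pt(-abs(tval), df)
  crit <- stats::qt(0.975, df)
  out <- list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
              se = stats::setNames(se, colnames(X)), t = tval,
              p_value = pval,
              ci = structure(cbind(lower = as.numeric(beta) - crit * se,
                                   upper = as.numeric(beta) + crit * se),
                             dimnames = list(colnames(X),
                                             c("lower", "upper"))),
              scale = sigma, weights = fam$weight, residuals = res,
              fitted = as.numeric(X %*% beta), vcov = vcov,
              c_S = c_S, c_M = c_M, efficiency = efficiency,
              converged = converged, iterations = iter, n_used = n,
              df = df, degenerate = FALSE)
  class(out) <- "robust_fit"
  out
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf(
    "MM-estimator robust fit (efficiency %.2f, c_S = %.4f, c_M = %.4f)\n",
    x$efficiency, x$c_S, x$c_M))
  tab <- data.frame(estimate = x$coefficients, se = x$se, t = x$t,
                    p = x$p_value, ci_low = x$ci[, "lower"],
                    ci_high = x$ci[, "upper"])
  print(round(tab, 4))
  cat(sprintf("Residual S-scale: %.4f on %d df; %s in %d iterations\n",
              x$scale, x$df,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Robust linear vs linear-logarithmic model comparison
#'
#' Fits `y ~ x (+ covariates)` and `y ~ ln(x) (+ covariates)` with
#' [fit_mm()] on identical observations and selects the model with the
#' smaller robust deviance, `sum rho(r_i / sigma*)` at the common scale
#' `sigma* = min` of the two S-scales (both models have the same parameter
#' count, so an AIC-style penalty cancels; ties prefer the linear model).
#'
#' @param x Positive predictor.
#' @param y Outcome.
#' @param covariates Optional numeric covariate matrix.
#' @param efficiency M-step efficiency passed to [fit_mm()].
#' @param ... Further arguments to [fit_mm()].
#' @return A `model_comparison`: both fits, deviance per model, `selected`
#'   (`"linear"` or `"linear-log"`), and the ln-term `t`/`p` from the
#'   linear-logarithmic fit.
#' @export
fit_linlog_comparison <- function(x, y, covariates = NULL,
                                  efficiency = 0.85, ...) {
  keep <- stats::complete.cases(x, y, covariates)
  x <- x[keep]; y <- y[keep]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  }
  if (any(x <= 0)) stop("all x must be > 0 for the ln(x) model")
  if (length(x) < 10) stop("need n >= 10")
  d_lin <- cbind(intercept = rep(1, length(x)), x = x, covariates)
  d_log <- cbind(intercept = rep(1, length(x)), ln_x = log(x), covariates)
  f_lin <- fit_mm(d_lin, y, efficiency = efficiency, ...)
  f_log <- fit_mm(d_log, y, efficiency = efficiency, ...)
  s_common <- min(f_lin$scale, f_log$scale)
  if (s_common == 0) {
    dev <- c(linear = sum(abs(f_lin$residuals)),
             `linear-log` = sum(abs(f_log$residuals)))
  } else {
    dev <- c(linear = sum(bisquare(f_lin$residuals / s_common,
                                   f_lin$c_M)$rho),
             `linear-log` = sum(bisquare(f_log$residuals / s_common,
                                         f_log$c_M)$rho))
  }
  selected <- if (dev["linear-log"] < dev["linear"]) "linear-log" else
    "linear"
  out <- list(linear_fit = f_lin, linlog_fit = f_log, deviance = dev,
              selected = selected,
              ln_term_t = f_log$t[2], ln_term_p = f_log$p_value[2],
              ln_term_df = f_log$df)
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison: linear deviance %.3f vs linear-log %.3f\n",
              x$deviance["linear"], x$deviance["linear-log"]))
  cat(sprintf("Selected: %s; ln-term t(%d) = %.3f, p = %.4g\n", x$selected,
              x$ln_term_df, x$ln_term_t, x$ln_term_p))
  invisible(x)
}

# Numeric design columns for named cohort covariates (reference codings:
# male, Caucasian, natural death are 0).
covariate_design <- function(df, covariates) {
  if (length(covariates) == 0) return(NULL)
  cols <- lapply(covariates, function(cv) {
    switch(cv,
      sex = as.numeric(df$sex == "F"),
      ancestry = as.numeric(df$ancestry == "non-Caucasian"),
      death_mode = as.numeric(df$death_mode == "non-natural"),
      smoker = as.numeric(df$smoker),
      alcohol_user = as.numeric(df$alcohol_user),
      {
        if (!cv %in% names(df)) stop("unknown covariate: ", cv)
        as.numeric(df[[cv]])
      })
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

#' Robust covariate-adjusted group difference
#'
#' Regresses a harmonized analyte z-score on a diagnosis indicator plus the
#' named covariates with [fit_mm()]; the diagnosis coefficient is the
#' case-control difference in control-SD units with a robust 95% CI.
#'
#' @param ztable A `zscore_table` from [harmonize_cohort()].
#' @param analyte Analyte name (`"iron"`, `"ferritin"`, `"copper"`,
#'   `"zinc"`, `"ratio"`).
#' @param covariates Character vector of cohort covariate names (may be
#'   empty).
#' @param cohort The `cohort` the z-table was derived from (supplies
#'   covariate values); may be omitted when `covariates` is empty.
#' @param ... Passed to [fit_mm()].
#' @return A `robust_fit` with an `effect` element for the diagnosis term:
#'   `estimate`, `ci_low`, `ci_high`, `t`, `p`.
#' @export
group_difference <- function(ztable, analyte, covariates = character(0),
                             cohort = NULL, ...) {
  zcol <- paste0("z_", analyte)
  if (!zcol %in% names(ztable)) stop("no column ", zcol, " in z-table")
  z <- ztable[[zcol]]
  dx <- as.numeric(is_case(ztable$diagnosis))
  covm <- NULL
  if (length(covariates) > 0) {
    if (is.null(cohort)) stop("cohort required when covariates are used")
    idx <- match(ztable$subject_id, cohort$subject_id)
    covm <- covariate_design(cohort[idx, , drop = FALSE], covariates)
  }
  X <- cbind(intercept = rep(1, length(z)), diagnosis = dx, covm)
  keep <- stats::complete.cases(X, z)
  if (length(unique(dx[keep])) < 2) {
    stop("one diagnostic group is empty after complete-case filtering")
  }
  Xk <- X[keep, , drop = FALSE]
  # covariates constant over the analysis subset carry no information
  informative <- c(TRUE, TRUE, apply(Xk[, -(1:2), drop = FALSE], 2,
                                     function(v) stats::sd(v) > 0))
  fit <- fit_mm(Xk[, informative, drop = FALSE], z[keep], ...)
  fit$effect <- list(estimate = unname(fit$coefficients["diagnosis"]),
                     ci_low = fit$ci["diagnosis", "lower"],
                     ci_high = fit$ci["diagnosis", "upper"],
                     t = fit$t[2], p = fit$p_value[2])
  fit$analyte <- analyte
  fit$covariates <- covariates
  fit
}
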