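# Protein normalization, control-anchored z-score harmonization across
# banks, iron-to-ferritin ratio, and distributional checks.

#' Protein-normalize a metal concentration
#'
#' Converts a solution concentration from elemental analysis to a
#' protein-normalized tissue level:
#' `metal_conc * dilution_factor / protein_conc` (umol/g protein).
#'
#' @param metal_conc Measured concentration in the analysed solution
#'   (umol/L).
#' @param dilution_factor Unitless dilution applied before measurement
#'   (>= 1).
#' @param protein_conc Protein concentration of the extract (g/L, > 0).
#' @return Protein-normalized level, umol/g protein.
#' @export
protein_normalize <- function(metal_conc, dilution_factor, protein_conc) {
  if (any(protein_conc <= 0)) stop("protein_conc must be > 0")
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1")
  metal_conc * dilution_factor / protein_conc
}

# Per-bank control mean/SD (sample SD, n-1) for one measured variable.
bank_control_scaling <- function(values, bank, diagnosis, label,
                                 min_controls = 3L) {
  out <- lapply(unique(bank), function(b) {
    ctrl <- values[bank == b & !is_case(diagnosis)]
    ctrl <- ctrl[!is.na(ctrl)]
    if (length(ctrl) < min_controls) {
      stop(sprintf("bank %s has fewer than %d controls with measured %s",
                   b, min_controls, label))
    }
    s <- stats::sd(ctrl)
    if (!is.finite(s) || s == 0) {
      stop(sprintf("bank %s has zero control SD for %s", b, label))
    }
    data.frame(bank = b, analyte = label, control_mean = mean(ctrl),
               control_sd = s, n_controls = length(ctrl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

zscore_against <- function(values, bank, scaling) {
  idx <- match(bank, scaling$bank)
  (values - scaling$control_mean[idx]) / scaling$control_sd[idx]
}

#' Control-anchored bank z-scores for one analyte
#'
#' Within each bank, `z = (raw - control mean) / control SD` (sample SD,
#' n-1 denominator), applied to every subject of that bank including cases.
#' This makes banks with different measurement scales commensurable, since
#' any affine rescaling of a bank's raw values cancels.
#'
#' @param cohort A `cohort`; every bank must contain at least 3 controls
#'   with a non-missing value of the analyte.
#' @param analyte One of `"iron"`, `"copper"`, `"zinc"`, `"ferritin"`.
#' @return A `zscore_table` data frame (`subject_id`, `bank`, `diagnosis`,
#'   `age_death`, `z_<analyte>`) with the per-bank scaling constants in
#'   `attr(, "scaling")`.
#' @export
bank_zscores <- function(cohort, analyte) {
  stopifnot(analyte %in% ANALYTES)
  scaling <- bank_control_scaling(cohort[[analyte]], cohort$bank,
                                  cohort$diagnosis, analyte)
  out <- data.frame(subject_id = cohort$subject_id, bank = cohort$bank,
                    diagnosis = cohort$diagnosis,
                    age_death = cohort$age_death, stringsAsFactors = FALSE)
  out[[paste0("z_", analyte)]] <- zscore_against(cohort[[analyte]],
                                                 cohort$bank, scaling)
  class(out) <- c("zscore_table", "data.frame")
  attr(out, "scaling") <- scaling
  out
}

#' Per-subject iron-to-ferritin ratio, bank z-scored
#'
#' The raw ratio `iron / ferritin` is formed within subject first and then
#' z-scored per bank against controls (not a ratio of z-scores, which is
#' undefined near zero). Subjects with missing or non-positive ferritin
#' get a missing ratio.
#'
#' @param cohort A `cohort`.
#' @return Named list: `raw_ratio` (per subject), `z_ratio`, and the
#'   `scaling` table used.
#' @export
iron_ferritin_ratio <- function(cohort) {
  fer <- cohort$ferritin
  fer[!is.na(fer) & fer <= 0] <- NA
  raw <- cohort$iron / fer
  scaling <- bank_control_scaling(raw, cohort$bank, cohort$diagnosis,
                                  "ratio")
  list(raw_ratio = raw,
       z_ratio = zscore_against(raw, cohort$bank, scaling),
       scaling = scaling)
}

#' Harmonize a cohort into a z-score table
#'
#' Applies [bank_zscores()] to each analyte and appends the bank-z-scored
#' iron-to-ferritin ratio.
#'
#' @param cohort A `cohort`.
#' @param analytes Analytes to harmonize (default all four).
#' @param ratio Include the iron-to-ferritin ratio column. Default `TRUE`.
#' @return A `zscore_table` with one `z_*` column per analyte (plus
#'   `z_ratio`), keyed by `subject_id`; per-bank scaling constants in
#'   `attr(, "scaling")`.
#' @export
harmonize_cohort <- function(cohort, analytes = ANALYTES, ratio = TRUE) {
  out <- data.frame(subject_id = cohort$subject_id, bank = cohort$bank,
                    diagnosis = cohort$diagnosis,
                    age_death = cohort$age_death, stringsAsFactors = FALSE)
  scaling <- list()
  for (a in analytes) {
    tab <- bank_zscores(cohort, a)
    out[[paste0("z_", a)]] <- tab[[paste0("z_", a)]]
    scaling[[a]] <- attr(tab, "scaling")
  }
  if (ratio) {
    r <- iron_ferritin_ratio(cohort)
    out$z_ratio <- r$z_ratio
    scaling$ratio <- r$scaling
  }
  class(out) <- c("zscore_table", "data.frame")
  attr(out, "scaling") <- do.call(rbind, scaling)
  out
}

#' Skewness/kurtosis omnibus normality test
#'
#' D'Agostino-Pearson-type omnibus test: the sample skewness and kurtosis
#' are each transformed to approximate standard normal deviates (D'Agostino
#' 1970; Anscombe & Glynn 1983) and combined as `K2 = Z1^2 + Z2^2`, referred
#' to a chi-square distribution with 2 df.
#'
#' @param values Numeric sample, `n >= 8` after removing missing values.
#' @return List: `skewness` (g1), `kurtosis` (g2, non-excess), `z_skew`,
#'   `z_kurt`, `statistic` (K2), `p_value`.
#' @export
test_distribution <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 8) stop("normality test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2

  # skewness (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis (Anscombe & Glynn 1983)
  eg2 <- 3 * (n - 1) / (n + 1)
  vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eg2) / sqrt(vg2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(skewness = g1, kurtosis = g2, z_skew = z1, z_kurt = z2,
       statistic = k2, p_value = stats::pchisq(k2, 2, lower.tail = FALSE),
       n = n)
}

#' Compare group variances
#'
#' Reports the case/control sample-variance ratio together with the
#' two-sided variance-ratio F test and the robust Brown-Forsythe test
#' (Levene with median centring).
#'
#' @param control_values,case_values Numeric samples, each `n >= 3` with
#'   non-zero variance.
#' @return A `variance_comparison` list: `control_variance`,
#'   `case_variance`, `variance_ratio` (case/control), and per-test
#'   statistic and p-value.
#' @export
compare_variance <- function(control_values, case_values) {
  x <- control_values[!is.na(control_values)]
  y <- case_values[!is.na(case_values)]
  if (length(x) < 3 || length(y) < 3) stop("each group requires n >= 3")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) stop("degenerate group with zero variance")
  ft <- stats::var.test(y, x)
  grp <- factor(rep(c("control", "case"), c(length(x), length(y))))
  bf <- car::leveneTest(c(x, y), grp, center = stats::median)
  out <- list(control_variance = vx, case_variance = vy,
              variance_ratio = vy / vx,
              f_statistic = unname(ft$statistic), f_p = ft$p.value,
              bf_statistic = bf$`F value`[1], bf_p = bf$`Pr(>F)`[1],
              tests = c("variance-ratio F", "Brown-Forsythe"))
  class(out) <- "variance_comparison"
  out
}

#' @export
print.variance_comparison <- function(x, ...) {
  cat(sprintf("Variance comparison: case %.3f / control %.3f = ratio %.3f\n",
              x$case_variance, x$control_variance, x$variance_ratio))
  cat(sprintf("  F test:          F = %.3f, p = %.4g\n", x$f_statistic, x$f_p))
  cat(sprintf("  Brown-Forsythe:  F = %.3f, p = %.4g\n", x$bf_statistic,
              x$bf_p))
  invisible(x)
}

#' Write a z-score table to TSV
#'
#' @param ztable A `zscore_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zscores <- function(ztable, path) {
  utils::write.table(as.data.frame(ztable), path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
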