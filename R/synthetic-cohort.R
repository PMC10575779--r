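#' Synthetic multi-bank case-control cohort configuration
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' generator emulates the statistical structure of a three-brain-bank
#' postmortem case-control study of prefrontal trace metals: control iron
#' rises linear-logarithmically with age of death, case iron is age-flat,
#' mean-shifted and over-dispersed; ferritin rises linear-logarithmically
#' with iron and carries a disease offset that is stronger in low-iron
#' cases; zinc and copper are correlated with iron; each bank applies its
#' own multiplicative measurement scale.
#'
#' All analyte parameters are on the raw measurement scale prior to bank
#' scaling: metals in umol/g protein, ferritin in arbitrary western-blot
#' units. Disease offsets expressed in "SD units" refer to the control
#' group's marginal SD of that analyte.
#'
#' @param n_control,n_case Group sizes.
#' @param bank_fractions Named proportions over the three banks; must sum
#'   to 1.
#' @param control_age_mean,control_age_sd,control_age_range Control age-of-
#'   death distribution (truncated normal, years).
#' @param case_age_mean,case_age_sd,case_age_range Case age distribution.
#' @param control_iron_intercept,control_iron_lnage_slope Control iron model
#'   `iron = intercept + slope * ln(age) + noise` (umol/g; slope per
#'   ln-year).
#' @param control_iron_resid_sd Residual SD of control iron about the age
#'   trend (umol/g).
#' @param nsw_control_iron_mean,nsw_case_iron_mean Raw-scale anchor means
#'   (umol/g) from the reference single-bank preliminary comparison; used
#'   for raw-scale percent-elevation arithmetic, not for simulation.
#' @param case_iron_mean_shift Case iron mean shift, in control-SD units.
#' @param case_variance_ratio Case/control iron variance ratio (unitless).
#' @param case_effect_age_max Upper age bound (years) below which the case
#'   iron shift applies; `Inf` (default) plants the shift at all ages.
#'   Cases above the bound follow the control age trend.
#' @param ferritin_intercept,ferritin_lniron_slope,ferritin_resid_sd
#'   Ferritin model `ferritin = intercept + slope * ln(iron) + noise`
#'   (arbitrary units).
#' @param ferritin_sd_total Control marginal ferritin SD (a.u.), used to
#'   convert SD-unit disease offsets to the raw scale.
#' @param case_ferritin_offset Disease offset on ferritin, SD units,
#'   applied to all cases.
#' @param case_ferritin_lowiron_extra Additional ferritin offset (SD units)
#'   for cases whose iron falls below `case_ferritin_lowiron_boundary`.
#' @param case_ferritin_lowiron_boundary Iron boundary (control-SD z units)
#'   for the extra low-iron ferritin offset.
#' @param zinc_mean,zinc_sd,zinc_case_shift,iron_zinc_corr Zinc model
#'   (umol/g; shift in SD units; within-group correlation with iron).
#' @param copper_mean,copper_sd,copper_case_shift,iron_copper_corr Copper
#'   model.
#' @param bank_scale_factors Named multiplicative measurement-scale factors
#'   per bank, applied to all analytes.
#' @param control_female_prop,case_female_prop Sex composition.
#' @param control_caucasian_prop,case_caucasian_prop Ancestry composition.
#' @param control_ph_mean,control_ph_sd,case_ph_mean,case_ph_sd Brain pH.
#' @param control_pmi_mean,control_pmi_sd,case_pmi_mean,case_pmi_sd
#'   Post-mortem interval (hours).
#' @param control_smoking_rate,case_smoking_rate Smoking prevalence.
#' @param control_alcohol_rate,case_alcohol_rate Alcohol-use prevalence.
#' @param control_nonnatural_rate,case_nonnatural_rate Non-natural death
#'   proportion.
#' @param control_bmi_mean,control_bmi_sd,case_bmi_mean,case_bmi_sd BMI.
#' @param medication_availability Proportion of cases with antipsychotic
#'   dose records.
#' @param missing_rates Named per-field missing-completely-at-random rates.
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#'
#' @return An object of class `synthetic_config` (a named list).
#' @seealso [default_study_config()], [generate_cohort()]
#' @export
synthetic_config <- function(n_control = 85L,
                             n_case = 86L,
                             bank_fractions = c("NSW-BTRC" = 0.44,
                                                "VBBN" = 0.21,
                                                "NIMH-HBCC" = 0.35),
                             control_age_mean = 54.4,
                             control_age_sd = 14.9,
                             control_age_range = c(17, 85),
                             case_age_mean = 52.6,
                             case_age_sd = 16.2,
                             case_age_range = c(17, 84),
                             control_iron_intercept = -13.785,
                             control_iron_lnage_slope = 6.703,
                             control_iron_resid_sd = 4.257,
                             nsw_control_iron_mean = 12.7,
                             nsw_case_iron_mean = 16.4,
                             case_iron_mean_shift = 0.58,
                             case_variance_ratio = 2.2,
                             case_effect_age_max = Inf,
                             ferritin_intercept = 43.8,
                             ferritin_lniron_slope = 22.8,
                             ferritin_resid_sd = 28.2,
                             ferritin_sd_total = 30,
                             case_ferritin_offset = -0.35,
                             case_ferritin_lowiron_extra = -0.75,
                             case_ferritin_lowiron_boundary = 0,
                             zinc_mean = 10,
                             zinc_sd = 2,
                             zinc_case_shift = 0.28,
                             iron_zinc_corr = 0.35,
                             copper_mean = 3,
                             copper_sd = 0.8,
                             copper_case_shift = 0,
                             iron_copper_corr = 0.4,
                             bank_scale_factors = c("NSW-BTRC" = 1,
                                                    "VBBN" = 0.65,
                                                    "NIMH-HBCC" = 1.3),
                             control_female_prop = 0.28,
                             case_female_prop = 0.31,
                             control_caucasian_prop = 0.81,
                             case_caucasian_prop = 0.81,
                             control_ph_mean = 6.54, control_ph_sd = 0.29,
                             case_ph_mean = 6.49, case_ph_sd = 0.28,
                             control_pmi_mean = 33.1, control_pmi_sd = 15.3,
                             case_pmi_mean = 36.5, case_pmi_sd = 18.4,
                             control_smoking_rate = 0.33,
                             case_smoking_rate = 0.74,
                             control_alcohol_rate = 0.22,
                             case_alcohol_rate = 0.47,
                             control_nonnatural_rate = 0.07,
                             case_nonnatural_rate = 0.36,
                             control_bmi_mean = 29.3, control_bmi_sd = 6.1,
                             case_bmi_mean = 27.9, case_bmi_sd = 6.2,
                             medication_availability = 0.5,
                             missing_rates = c(smoker = 0.34,
                                               alcohol_user = 0.68,
                                               bmi = 0.5,
                                               copper = 0.2,
                                               zinc = 0.02,
                                               ferritin = 0.01),
                             seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

#' Default study-condition configuration
#'
#' Returns the [synthetic_config()] whose demographic parameters equal the
#' combined-brain-cohort characteristics (85 controls / 86 cases; control
#' age 54.4 +/- 14.9 years on 17-85; pH 6.54 +/- 0.29; PMI 33.1 +/- 15.3 h;
#' bank fractions 0.44/0.21/0.35; smoking 0.33 vs 0.74; non-natural death
#' 0.07 vs 0.36) and whose analyte parameters are calibrated so the planted
#' effects equal the headline combined-cohort effect sizes (iron +0.58 SD
#' with a doubled case variance; marginal ferritin deficit near -0.45 SD,
#' concentrated in low-iron cases).
#'
#' @param seed Integer seed stored in the configuration.
#' @return A `synthetic_config`.
#' @export
default_study_config <- function(seed = 1L) {
  synthetic_config(seed = seed)
}

#' Validate a synthetic configuration
#'
#' @param config A `synthetic_config`.
#' @return Character vector of violated invariants (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(config$n_control >= 0 && config$n_case >= 0,
      "n_control and n_case must be >= 0")
  chk(abs(sum(config$bank_fractions) - 1) < 1e-9,
      "bank_fractions must sum to 1")
  chk(all(config$bank_fractions >= 0 & config$bank_fractions <= 1),
      "bank_fractions must lie in [0, 1]")
  chk(setequal(names(config$bank_fractions), BANKS),
      "bank_fractions must be named by the three banks")
  chk(config$case_variance_ratio > 0, "case_variance_ratio must be > 0")
  for (f in c("control_age_sd", "case_age_sd", "control_iron_resid_sd",
              "ferritin_resid_sd", "ferritin_sd_total", "zinc_sd",
              "copper_sd", "control_ph_sd", "case_ph_sd", "control_pmi_sd",
              "case_pmi_sd", "control_bmi_sd", "case_bmi_sd")) {
    chk(config[[f]] > 0, paste(f, "must be > 0"))
  }
  props <- c("control_female_prop", "case_female_prop",
             "control_caucasian_prop", "case_caucasian_prop",
             "control_smoking_rate", "case_smoking_rate",
             "control_alcohol_rate", "case_alcohol_rate",
             "control_nonnatural_rate", "case_nonnatural_rate",
             "medication_availability")
  for (f in props) {
    chk(config[[f]] >= 0 && config[[f]] <= 1, paste(f, "must lie in [0, 1]"))
  }
  chk(all(config$missing_rates >= 0 & config$missing_rates <= 1),
      "missing_rates must lie in [0, 1]")
  chk(config$control_age_range[1] >= 1 && config$case_age_range[1] >= 1,
      "ages below 1 year are disallowed (ln(age) model)")
  chk(abs(config$iron_zinc_corr) < 1 && abs(config$iron_copper_corr) < 1,
      "iron correlations must lie in (-1, 1)")
  problems
}

# Marginal mean and SD of control iron implied by the configured age
# distribution and the ln(age) trend (quadrature, no simulation).
control_iron_moments <- function(config) {
  mom <- truncnorm_moments(function(a) log(a),
                           config$control_age_mean, config$control_age_sd,
                           config$control_age_range[1],
                           config$control_age_range[2])
  m <- config$control_iron_intercept + config$control_iron_lnage_slope * mom$mean
  v <- config$control_iron_lnage_slope^2 * mom$var + config$control_iron_resid_sd^2
  list(mean = m, sd = sqrt(v))
}

#' Generate a synthetic cohort
#'
#' Draws one cohort under the generative model described in
#' [synthetic_config()]. Identical configurations (including `seed`) give
#' identical cohorts.
#'
#' @param config A valid `synthetic_config`.
#' @return A `cohort` data frame (one row per specimen) in the standard
#'   cohort schema; `attr(, "provenance")` records the generator settings.
#' @export
generate_cohort <- function(config) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop("invalid synthetic_config: ", paste(problems, collapse = "; "))
  }
  n <- config$n_control + config$n_case
  if (n == 0L) {
    return(empty_cohort())
  }
  with_seed(config$seed, {
    diagnosis <- rep(DIAGNOSES, c(config$n_control, config$n_case))
    case <- is_case(diagnosis)

    age <- numeric(n)
    age[!case] <- rtruncnorm(config$n_control, config$control_age_mean,
                             config$control_age_sd,
                             config$control_age_range[1],
                             config$control_age_range[2])
    age[case] <- rtruncnorm(config$n_case, config$case_age_mean,
                            config$case_age_sd,
                            config$case_age_range[1],
                            config$case_age_range[2])

    bank <- sample(names(config$bank_fractions), n, replace = TRUE,
                   prob = config$bank_fractions)

    grp <- function(cfield, sfield) ifelse(case, config[[sfield]],
                                           config[[cfield]])
    sex <- ifelse(stats::runif(n) < grp("control_female_prop",
                                        "case_female_prop"), "F", "M")
    ancestry <- ifelse(stats::runif(n) < grp("control_caucasian_prop",
                                             "case_caucasian_prop"),
                       "Caucasian", "non-Caucasian")
    ph <- pmin(pmax(stats::rnorm(n, grp("control_ph_mean", "case_ph_mean"),
                                 grp("control_ph_sd", "case_ph_sd")),
                    5.05), 7.95)
    pmi <- pmax(stats::rnorm(n, grp("control_pmi_mean", "case_pmi_mean"),
                             grp("control_pmi_sd", "case_pmi_sd")), 1)
    death_mode <- ifelse(stats::runif(n) < grp("control_nonnatural_rate",
                                               "case_nonnatural_rate"),
                         "non-natural", "natural")
    smoker <- stats::runif(n) < grp("control_smoking_rate",
                                    "case_smoking_rate")
    alcohol_user <- stats::runif(n) < grp("control_alcohol_rate",
                                          "case_alcohol_rate")
    bmi <- stats::rnorm(n, grp("control_bmi_mean", "case_bmi_mean"),
                        grp("control_bmi_sd", "case_bmi_sd"))

    # Iron: controls follow the ln(age) trend; cases within the effect-age
    # window are age-flat, shifted and over-dispersed; cases outside the
    # window follow the control trend.
    con_mom <- control_iron_moments(config)
    cond_mean <- config$control_iron_intercept +
      config$control_iron_lnage_slope * log(age)
    cond_sd <- rep(config$control_iron_resid_sd, n)
    shifted <- case & age < config$case_effect_age_max
    cond_mean[shifted] <- con_mom$mean +
      config$case_iron_mean_shift * con_mom$sd
    cond_sd[shifted] <- sqrt(config$case_variance_ratio) * con_mom$sd
    iron_dev <- stats::rnorm(n)
    iron <- pmax(cond_mean + cond_sd * iron_dev, 0.5)

    # Zinc and copper share the standardized iron deviation to induce the
    # configured within-group correlations.
    mix <- function(rho, shift_sd, mean, sd) {
      e <- stats::rnorm(n)
      z <- rho * iron_dev + sqrt(1 - rho^2) * e
      pmax(mean + sd * z + shift_sd * sd * case, 0.1)
    }
    zinc <- mix(config$iron_zinc_corr, config$zinc_case_shift,
                config$zinc_mean, config$zinc_sd)
    copper <- mix(config$iron_copper_corr, config$copper_case_shift,
                  config$copper_mean, config$copper_sd)

    # Ferritin: linear-logarithmic in iron with a two-regime disease offset
    # (stronger for cases whose iron sits below the configured z boundary).
    z_iron0 <- (iron - con_mom$mean) / con_mom$sd
    offset_sd <- config$case_ferritin_offset * case +
      config$case_ferritin_lowiron_extra * case *
        (z_iron0 < config$case_ferritin_lowiron_boundary)
    ferritin <- pmax(config$ferritin_intercept +
                       config$ferritin_lniron_slope * log(iron) +
                       stats::rnorm(n, 0, config$ferritin_resid_sd) +
                       offset_sd * config$ferritin_sd_total, 0.5)

    # Bank measurement scales (multiplicative on all analytes).
    scale <- config$bank_scale_factors[bank]
    iron <- iron * scale
    copper <- copper * scale
    zinc <- zinc * scale
    ferritin <- ferritin * scale

    # Missingness (MCAR) on the configured fields.
    mcar <- function(x, field) {
      r <- config$missing_rates[field]
      if (is.na(r) || r <= 0) return(x)
      x[stats::runif(n) < r] <- NA
      x
    }
    smoker <- mcar(smoker, "smoker")
    alcohol_user <- mcar(alcohol_user, "alcohol_user")
    bmi <- mcar(bmi, "bmi")
    copper <- mcar(copper, "copper")
    zinc <- mcar(zinc, "zinc")
    ferritin <- mcar(ferritin, "ferritin")

    # Antipsychotic records for a configurable subset of cases.
    med_avail <- case & stats::runif(n) < config$medication_availability
    age_onset <- rep(NA_real_, n)
    ap_duration <- rep(NA_real_, n)
    ap_mean_daily_dose <- rep(NA_real_, n)
    ap_lifetime_exposure <- rep(NA_real_, n)
    ap_typicality <- rep(NA_character_, n)
    ap_tox_positive <- rep(NA, n)
    lithium_tox_positive <- rep(NA, n)
    k <- sum(med_avail)
    if (k > 0) {
      onset <- pmin(pmax(stats::rnorm(k, 23, 5), 15), age[med_avail] - 1)
      age_onset[med_avail] <- onset
      dur <- pmax((age[med_avail] - onset) *
                    stats::runif(k, 0.6, 1), 0.5)
      ap_duration[med_avail] <- dur
      dose <- stats::rlnorm(k, log(400), 0.5)
      ap_mean_daily_dose[med_avail] <- dose
      ap_lifetime_exposure[med_avail] <- dose * dur * 365.25 / 1000
      ap_typicality[med_avail] <- sample(c("typical", "atypical", "mixed"),
                                         k, replace = TRUE,
                                         prob = c(0.3, 0.4, 0.3))
      ap_tox_positive[med_avail] <- stats::runif(k) < 0.6
      lithium_tox_positive[med_avail] <- stats::runif(k) < 0.05
    }

    cohort <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      bank = bank,
      diagnosis = diagnosis,
      age_death = age,
      sex = sex,
      ancestry = ancestry,
      ph = ph,
      pmi = pmi,
      death_mode = death_mode,
      smoker = smoker,
      alcohol_user = alcohol_user,
      bmi = bmi,
      iron = iron,
      copper = copper,
      zinc = zinc,
      ferritin = ferritin,
      ap_mean_daily_dose = ap_mean_daily_dose,
      ap_lifetime_exposure = ap_lifetime_exposure,
      ap_duration = ap_duration,
      ap_typicality = ap_typicality,
      ap_tox_positive = ap_tox_positive,
      lithium_tox_positive = lithium_tox_positive,
      age_onset = age_onset,
      stringsAsFactors = FALSE
    )
    as_cohort(cohort, provenance = sprintf("synthetic (seed %d)",
                                           as.integer(config$seed)))
  })
}

#' Inject gross iron outliers into a cohort
#'
#' Independently inflates each record's measured iron by `magnitude`
#' bank-control SDs with probability `rate`, emulating the handful of
#' extreme specimens (several SD above the mean) that motivate robust
#' estimation. Affected records are flagged in an `outlier_injected`
#' provenance column.
#'
#' @param cohort A `cohort`.
#' @param rate Per-record contamination probability in `[0, 1]`.
#' @param magnitude Shift size in bank-control SD units; must be >= 0.
#' @param seed Integer seed.
#' @return The cohort with contaminated iron and an `outlier_injected`
#'   logical column.
#' @export
inject_outliers <- function(cohort, rate, magnitude, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (magnitude < 0) stop("magnitude must be non-negative")
  cohort$outlier_injected <- FALSE
  if (rate == 0 || nrow(cohort) == 0) return(cohort)
  with_seed(seed, {
    hit <- stats::runif(nrow(cohort)) < rate
    for (b in unique(cohort$bank)) {
      ctrl <- cohort$bank == b & !is_case(cohort$diagnosis) &
        !is.na(cohort$iron)
      s <- stats::sd(cohort$iron[ctrl])
      if (!is.finite(s)) s <- stats::sd(cohort$iron[cohort$bank == b],
                                        na.rm = TRUE)
      sel <- hit & cohort$bank == b & !is.na(cohort$iron)
      cohort$iron[sel] <- cohort$iron[sel] + magnitude * s
    }
    cohort$outlier_injected <- hit
    cohort
  })
}

#' Read and write synthetic configurations as flat YAML
#'
#' The configuration serializes as a flat key-value mapping (named vectors
#' become nested keys), so generator settings can be versioned alongside
#' an analysis.
#'
#' @param config A `synthetic_config`.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a validated `synthetic_config`.
#' @export
write_config <- function(config, path) {
  flat <- lapply(unclass(config), function(v) {
    if (!is.null(names(v))) as.list(v) else v
  })
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- synthetic_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (k in names(raw)) {
    v <- raw[[k]]
    if (is.list(v)) v <- unlist(v)
    if (!is.null(names(defaults[[k]]))) v <- v[names(defaults[[k]])]
    cfg[[k]] <- v
  }
  cfg$n_control <- as.integer(cfg$n_control)
  cfg$n_case <- as.integer(cfg$n_case)
  cfg$seed <- as.integer(cfg$seed)
  problems <- validate_config(cfg)
  if (length(problems) > 0) {
    stop("invalid configuration in ", path, ": ",
         paste(problems, collapse = "; "))
  }
  cfg
}
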