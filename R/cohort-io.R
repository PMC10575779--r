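# Cohort table input/output, validation, and demographic summaries.

COHORT_COLUMNS <- c("subject_id", "bank", "diagnosis", "age_death", "sex",
                    "ancestry", "ph", "pmi", "death_mode", "smoker",
                    "alcohol_user", "bmi", "iron", "copper", "zinc",
                    "ferritin", "ap_mean_daily_dose", "ap_lifetime_exposure",
                    "ap_duration", "ap_typicality", "ap_tox_positive",
                    "lithium_tox_positive", "age_onset")
MANDATORY_COLUMNS <- c("subject_id", "bank", "diagnosis", "age_death", "sex",
                       "ancestry", "ph", "pmi", "death_mode")
NUMERIC_COLUMNS <- c("age_death", "ph", "pmi", "bmi", "iron", "copper",
                     "zinc", "ferritin", "ap_mean_daily_dose",
                     "ap_lifetime_exposure", "ap_duration", "age_onset")
BOOLEAN_COLUMNS <- c("smoker", "alcohol_user", "ap_tox_positive",
                     "lithium_tox_positive")

as_cohort <- function(df, provenance = "unspecified") {
  rownames(df) <- NULL
  class(df) <- c("cohort", "data.frame")
  attr(df, "provenance") <- provenance
  df
}

empty_cohort <- function(provenance = "empty") {
  df <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(COHORT_COLUMNS)),
                    COHORT_COLUMNS))
  for (col in NUMERIC_COLUMNS) df[[col]] <- numeric(0)
  for (col in BOOLEAN_COLUMNS) df[[col]] <- logical(0)
  as_cohort(df, provenance)
}

#' Write a cohort table to CSV
#'
#' Comma-separated, UTF-8, `.` decimal separator, mandatory header, empty
#' cell for missing, booleans encoded `yes`/`no`.
#'
#' @param cohort A `cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[, intersect(COHORT_COLUMNS, names(cohort))]
  for (col in intersect(BOOLEAN_COLUMNS, names(out))) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         ifelse(out[[col]], "yes", "no"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate a cohort table
#'
#' Reads the standard cohort CSV schema (header mandatory and matched
#' case-insensitively; extra columns are preserved as metadata). Empty
#' cells become missing values; booleans are decoded from `yes`/`no`.
#'
#' @param path Path to a cohort CSV file.
#' @return A validated `cohort`. Columns beyond the documented schema are
#'   attached as `attr(, "extra_columns")`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(raw), COHORT_COLUMNS)
  if (nrow(raw) == 0L) {
    warning("header-only cohort file: ", path)
    return(empty_cohort(provenance = path))
  }
  df <- data.frame(row = seq_len(nrow(raw)), stringsAsFactors = FALSE)
  for (col in COHORT_COLUMNS) {
    v <- if (col %in% names(raw)) raw[[col]] else NA_character_
    v[!is.na(v) & trimws(v) == ""] <- NA
    df[[col]] <- v
  }
  df$row <- NULL

  decode_enum <- function(col, levels) {
    v <- df[[col]]
    bad <- which(!is.na(v) & !v %in% levels)
    if (length(bad) > 0) {
      stop(sprintf("unknown %s code '%s' at row %d", col, v[bad[1]], bad[1]))
    }
    v
  }
  df$bank <- decode_enum("bank", BANKS)
  df$diagnosis <- decode_enum("diagnosis", DIAGNOSES)
  df$sex <- decode_enum("sex", c("F", "M"))
  df$ancestry <- decode_enum("ancestry", c("Caucasian", "non-Caucasian"))
  df$death_mode <- decode_enum("death_mode", c("natural", "non-natural"))
  df$ap_typicality <- decode_enum("ap_typicality",
                                  c("typical", "atypical", "mixed"))
  for (col in NUMERIC_COLUMNS) {
    suppressWarnings(num <- as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric %s value '%s' at row %d",
                   col, df[[col]][bad[1]], bad[1]))
    }
    df[[col]] <- num
  }
  for (col in BOOLEAN_COLUMNS) {
    v <- tolower(df[[col]])
    bad <- which(!is.na(v) & !v %in% c("yes", "no", "true", "false"))
    if (length(bad) > 0) {
      stop(sprintf("invalid boolean %s value '%s' at row %d",
                   col, df[[col]][bad[1]], bad[1]))
    }
    df[[col]] <- v %in% c("yes", "true") & !is.na(v)
    df[[col]][is.na(v)] <- NA
  }
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  if (length(dup) > 0) {
    stop("duplicate subject_id(s): ", paste(dup, collapse = ", "))
  }
  cohort <- as_cohort(df, provenance = path)
  if (length(extra) > 0) {
    attr(cohort, "extra_columns") <- raw[extra]
  }
  cohort
}

#' Check cohort invariants
#'
#' Violations are reported as data, not raised as errors: unique ids,
#' non-negative analytes, age in (0, 120), pH in (5, 8), PMI >= 0, and
#' medication fields restricted to schizophrenia cases.
#'
#' @param cohort A `cohort`.
#' @return Data frame with columns `subject_id`, `field`, `message`; zero
#'   rows iff the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  v <- list()
  flag <- function(idx, field, message) {
    if (any(idx, na.rm = TRUE)) {
      v[[length(v) + 1]] <<- data.frame(
        subject_id = cohort$subject_id[which(idx)],
        field = field, message = message, stringsAsFactors = FALSE)
    }
  }
  dup <- duplicated(cohort$subject_id)
  flag(dup, "subject_id", "duplicate subject_id")
  for (a in c(ANALYTES, "bmi")) {
    flag(!is.na(cohort[[a]]) & cohort[[a]] < 0, a,
         paste(a, "must be non-negative"))
  }
  flag(!is.na(cohort$age_death) &
         (cohort$age_death <= 0 | cohort$age_death >= 120),
       "age_death", "age_death must lie in (0, 120)")
  flag(!is.na(cohort$ph) & (cohort$ph <= 5 | cohort$ph >= 8),
       "ph", "ph must lie in (5, 8)")
  flag(!is.na(cohort$pmi) & cohort$pmi < 0, "pmi", "pmi must be >= 0")
  med_cols <- c("ap_mean_daily_dose", "ap_lifetime_exposure", "ap_duration",
                "ap_typicality", "ap_tox_positive", "lithium_tox_positive",
                "age_onset")
  for (mc in intersect(med_cols, names(cohort))) {
    flag(!is.na(cohort[[mc]]) & !is_case(cohort$diagnosis), mc,
         "medication fields are defined only for schizophrenia cases")
  }
  if (length(v) == 0) {
    return(data.frame(subject_id = character(0), field = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Group comparison of demographic and tissue-quality variables
#'
#' One row per variable, comparing controls and cases with the classical
#' independent-samples t-test (continuous) or Pearson chi-square test
#' (categorical), missing values excluded pairwise.
#'
#' @param cohort A `cohort` with both diagnostic groups represented.
#' @param welch Use the Welch (unequal-variance) t-test instead of the
#'   pooled-variance Student test. Default `FALSE`.
#' @param correct Apply the Yates continuity correction to chi-square
#'   tests. Default `FALSE` (plain Pearson).
#' @return A `demographics_table` data frame: variable, per-group summary,
#'   test, statistic, df, p-value.
#' @export
summarize_demographics <- function(cohort, welch = FALSE, correct = FALSE) {
  grp <- is_case(cohort$diagnosis)
  if (sum(grp) == 0 || sum(!grp) == 0) {
    stop("both diagnostic groups must be non-empty")
  }
  rows <- list()
  cont <- function(var) {
    x <- cohort[[var]][!grp]; y <- cohort[[var]][grp]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    tt <- stats::t.test(x, y, var.equal = !welch)
    data.frame(
      variable = var,
      control_summary = sprintf("%.2f ± %.2f (n=%d)", mean(x),
                                stats::sd(x), length(x)),
      case_summary = sprintf("%.2f ± %.2f (n=%d)", mean(y),
                             stats::sd(y), length(y)),
      test = if (welch) "Welch t" else "Student t",
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, stringsAsFactors = FALSE)
  }
  cat_summary <- function(tab_col) {
    paste(sprintf("%s:%d (%.2f)", names(tab_col), tab_col,
                  tab_col / sum(tab_col)), collapse = ", ")
  }
  catg <- function(var) {
    v <- cohort[[var]]
    if (is.logical(v)) v <- ifelse(v, "yes", "no")
    keep <- !is.na(v)
    if (sum(keep & !grp) == 0 || sum(keep & grp) == 0) return(NULL)
    tab <- table(factor(ifelse(grp[keep], "case", "control"),
                        c("control", "case")), v[keep])
    if (ncol(tab) < 2) {
      return(data.frame(variable = var,
                        control_summary = cat_summary(tab["control", ,
                                                          drop = TRUE]),
                        case_summary = cat_summary(tab["case", , drop = TRUE]),
                        test = "Pearson chi-square", statistic = 0,
                        df = 0, p_value = 1, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    data.frame(
      variable = var,
      control_summary = cat_summary(tab["control", , drop = TRUE]),
      case_summary = cat_summary(tab["case", , drop = TRUE]),
      test = "Pearson chi-square",
      statistic = unname(ct$statistic), df = unname(ct$parameter),
      p_value = ct$p.value, stringsAsFactors = FALSE)
  }
  for (var in c("bank", "sex", "ancestry", "smoker", "alcohol_user",
                "death_mode")) {
    rows[[var]] <- catg(var)
  }
  for (var in c("age_death", "ph", "pmi", "bmi")) {
    rows[[var]] <- cont(var)
  }
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  class(out) <- c("demographics_table", "data.frame")
  out
}

#' @export
print.demographics_table <- function(x, ...) {
  cat("Demographic and tissue-quality comparison (control vs case)\n")
  df <- as.data.frame(x)
  df$statistic <- round(df$statistic, 2)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d specimens (%d control / %d case), banks: %s\n",
              nrow(x), sum(!is_case(x$diagnosis)), sum(is_case(x$diagnosis)),
              paste(sort(unique(x$bank)), collapse = ", ")))
  cat(sprintf("Provenance: %s\n", attr(x, "provenance") %||% "unspecified"))
  NextMethod()
}
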