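#' @keywords internal
"_PACKAGE"

# Canonical column order of the participant-level trial CSV.
# `hf_event_days` is a semicolon-joined list of event days; missing values
# are empty cells.
TRIAL_COLUMNS <- c(
  "participant_id", "arm", "age", "sex", "height_m", "weight_baseline_kg",
  "bmi", "kccq_baseline", "sixmwd_baseline_m", "crp_baseline_mg_l",
  "ntprobnp_baseline_pg_ml", "nyha", "afib", "cad",
  "weight_week52_kg", "kccq_week52", "sixmwd_week52_m", "crp_week52_mg_l",
  "death_day", "hf_event_days", "observation_days", "on_treatment_at_week52"
)

ARM_LEVELS <- c("placebo", "semaglutide")
BMI_CLASS_LEVELS <- c("I", "II", "III")
WEIGHT_CAT_LEVELS <- c("lt5", "5to10", "10to15", "15to20", "ge20")

#' Assign the obesity class for a BMI
#'
#' Obesity classes follow the half-open convention class I = \[30, 35),
#' class II = \[35, 40), class III = \[40, Inf) kg/m^2, so boundary values
#' such as 35.0 are unambiguous.
#'
#' @param bmi Numeric vector of body-mass indices (kg/m^2), all >= 30.
#' @return Ordered factor with levels `"I" < "II" < "III"`.
#' @examples
#' assign_bmi_class(c(32.6, 35, 43.5))
#' @export
assign_bmi_class <- function(bmi) {
  if (!is.numeric(bmi) || anyNA(bmi)) {
    stop("`bmi` must be numeric with no missing values", call. = FALSE)
  }
  if (any(bmi < 30)) {
    stop("BMI below 30 kg/m^2: not an enrolled obesity-phenotype participant",
         call. = FALSE)
  }
  cls <- cut(bmi, breaks = c(30, 35, 40, Inf), right = FALSE,
             labels = BMI_CLASS_LEVELS)
  factor(cls, levels = BMI_CLASS_LEVELS, ordered = TRUE)
}

#' Percent weight change from baseline to week 52
#'
#' Defined as 100 x (week-52 weight - baseline weight) / baseline weight;
#' negative values are weight loss. A missing week-52 weight propagates as
#' `NA` so the caller decides between imputation and exclusion.
#'
#' @param weight_baseline,weight_week52 Weights in kg (baseline strictly
#'   positive; week 52 positive or `NA`).
#' @return Numeric vector of percent changes.
#' @examples
#' percent_weight_change(100, 90)  # -10
#' @export
percent_weight_change <- function(weight_baseline, weight_week52) {
  if (any(!is.na(weight_baseline) & weight_baseline <= 0) ||
      any(!is.na(weight_week52) & weight_week52 <= 0)) {
    stop("weights must be strictly positive", call. = FALSE)
  }
  100 * (weight_week52 - weight_baseline) / weight_baseline
}

#' Weight-loss category of a percent weight change
#'
#' Maps the percent reduction r = -pct_change to the five ordinal categories
#' <5%, 5-<10%, 10-<15%, 15-<20% and >=20%. Weight gain falls in the "<5%
#' reduction" category; the categories partition the line.
#'
#' @param pct_change Percent weight change (negative = loss); `NA` allowed.
#' @return Ordered factor with levels `lt5 < 5to10 < 10to15 < 15to20 < ge20`.
#' @examples
#' weight_loss_category(c(-4.9, -20, 3))
#' @export
weight_loss_category <- function(pct_change) {
  reduction <- -pct_change
  cls <- cut(pmax(reduction, 0), breaks = c(0, 5, 10, 15, 20, Inf),
             right = FALSE, labels = WEIGHT_CAT_LEVELS)
  factor(cls, levels = WEIGHT_CAT_LEVELS, ordered = TRUE)
}

#' Percentages of a count vector, to one decimal
#'
#' Percentages are rounded to one decimal with the largest-remainder method,
#' so they always sum to exactly 100.0 - the convention behind published
#' trial tables whose percentage columns add up to 100.
#'
#' @param counts Nonnegative integer counts.
#' @return Percentages of `sum(counts)`, one decimal, summing to 100.
#' @examples
#' count_percent(c(33, 51, 54, 50, 58))
#' @export
count_percent <- function(counts) {
  if (sum(counts) <= 0) stop("counts sum to zero", call. = FALSE)
  p10 <- 1000 * counts / sum(counts)  # in tenths of a percent
  fl <- floor(p10)
  need <- 1000 - sum(fl)
  rem <- p10 - fl
  add <- integer(length(counts))
  if (need > 0) {
    add[order(rem, decreasing = TRUE)[seq_len(need)]] <- 1L
  }
  (fl + add) / 10
}

# --- CSV I/O -----------------------------------------------------------------

num_cols <- function() {
  c("age", "height_m", "weight_baseline_kg", "bmi", "kccq_baseline",
    "sixmwd_baseline_m", "crp_baseline_mg_l", "ntprobnp_baseline_pg_ml",
    "weight_week52_kg", "kccq_week52", "sixmwd_week52_m", "crp_week52_mg_l",
    "death_day", "observation_days")
}

#' Read a participant-level trial CSV
#'
#' Expects the canonical header (see [trial_columns()]); missing values are
#' empty cells and `hf_event_days` is a semicolon-joined list of event days.
#' Parse failures (unknown arm label, non-numeric numeric field, duplicate
#' participant id) are errors naming the offending row and column; semantic
#' validation is deferred to [validate_trial()].
#'
#' @param path Path to a CSV file.
#' @return A `trial_data` data frame (one row per participant).
#' @export
read_trial_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[TRIAL_COLUMNS]
  df <- raw
  for (col in num_cols()) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & nzchar(x) & is.na(out))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   x[bad[1]], col, bad[1]), call. = FALSE)
    }
    out[!nzchar(x)] <- NA_real_
    df[[col]] <- out
  }
  bad_arm <- which(!raw$arm %in% ARM_LEVELS)
  if (length(bad_arm)) {
    stop(sprintf("unknown arm label '%s' in row %d", raw$arm[bad_arm[1]],
                 bad_arm[1]), call. = FALSE)
  }
  dup <- which(duplicated(raw$participant_id))
  if (length(dup)) {
    stop(sprintf("duplicate participant_id '%s' in row %d",
                 raw$participant_id[dup[1]], dup[1]), call. = FALSE)
  }
  bad_sex <- which(!raw$sex %in% c("female", "male"))
  if (length(bad_sex)) {
    stop(sprintf("unknown sex '%s' in row %d", raw$sex[bad_sex[1]],
                 bad_sex[1]), call. = FALSE)
  }
  bad_nyha <- which(!raw$nyha %in% c("II", "III", "IV"))
  if (length(bad_nyha)) {
    stop(sprintf("unknown NYHA class '%s' in row %d", raw$nyha[bad_nyha[1]],
                 bad_nyha[1]), call. = FALSE)
  }
  for (col in c("afib", "cad", "on_treatment_at_week52")) {
    x <- raw[[col]]
    bad <- which(nzchar(x) & !x %in% c("TRUE", "FALSE"))
    if (length(bad)) {
      stop(sprintf("non-logical value '%s' in column '%s', row %d",
                   x[bad[1]], col, bad[1]), call. = FALSE)
    }
    df[[col]] <- ifelse(nzchar(x), x == "TRUE", NA)
  }
  df$arm <- factor(df$arm, levels = ARM_LEVELS)
  df$sex <- factor(df$sex, levels = c("female", "male"))
  df$nyha <- factor(df$nyha, levels = c("II", "III", "IV"))
  as_trial_data(df)
}

#' Write a participant-level trial CSV
#'
#' Numeric fields are written with 17 significant digits so that
#' write-then-read round-trips reproduce them bit for bit.
#'
#' @param dataset A `trial_data` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(dataset, path) {
  df <- as.data.frame(dataset)[TRIAL_COLUMNS]
  out <- df
  for (col in num_cols()) {
    x <- df[[col]]
    out[[col]] <- ifelse(is.na(x), "", sprintf("%.17g", x))
  }
  for (col in c("afib", "cad", "on_treatment_at_week52")) {
    x <- df[[col]]
    out[[col]] <- ifelse(is.na(x), "", ifelse(x, "TRUE", "FALSE"))
  }
  for (col in c("arm", "sex", "nyha")) {
    out[[col]] <- as.character(df[[col]])
  }
  out$hf_event_days[is.na(out$hf_event_days)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Canonical trial CSV columns
#' @return Character vector of column names in canonical order.
#' @export
trial_columns <- function() TRIAL_COLUMNS

as_trial_data <- function(df) {
  class(df) <- unique(c("trial_data", class(df)))
  df
}

#' Parse semicolon-joined heart-failure event days
#' @param x Character vector like `"30;200"`; empty or `NA` means no events.
#' @return List of numeric vectors of event days.
#' @export
parse_event_days <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Validate participant-record invariants
#'
#' Checks the record-level invariants: BMI consistent with weight/height
#' (tolerance 1e-6 relative), BMI >= 30, obesity class consistent with BMI,
#' KCCQ-CSS in \[0, 100\], CRP and NTproBNP strictly positive, event days
#' within the observation period, unique ids and both arms non-empty.
#'
#' @param dataset A `trial_data` data frame.
#' @return Data frame of issues (`participant_id`, `field`, `message`);
#'   zero rows when the dataset is valid.
#' @export
validate_trial <- function(dataset) {
  df <- dataset
  issues <- list()
  note <- function(id, field, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      participant_id = id, field = field, message = message,
      stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0) {
    note(NA_character_, "arm", "both arms non-empty: dataset has no records")
    return(do.call(rbind, issues))
  }
  for (a in ARM_LEVELS) {
    if (!any(df$arm == a, na.rm = TRUE)) {
      note(NA_character_, "arm", paste0("both arms non-empty: no ", a, " records"))
    }
  }
  bmi_chk <- df$weight_baseline_kg / df$height_m^2
  bad <- which(abs(bmi_chk - df$bmi) > 1e-6 * pmax(1, abs(df$bmi)))
  for (i in bad) note(df$participant_id[i], "bmi",
                      sprintf("bmi %.4f inconsistent with weight/height^2 = %.4f",
                              df$bmi[i], bmi_chk[i]))
  for (i in which(df$bmi < 30)) note(df$participant_id[i], "bmi", "bmi below 30")
  cls <- tryCatch(assign_bmi_class(pmax(df$bmi, 30)), error = function(e) NULL)
  kccq_bad <- which(!is.na(df$kccq_baseline) &
                      (df$kccq_baseline < 0 | df$kccq_baseline > 100))
  kccq_bad <- c(kccq_bad, which(!is.na(df$kccq_week52) &
                                  (df$kccq_week52 < 0 | df$kccq_week52 > 100)))
  for (i in unique(kccq_bad)) note(df$participant_id[i], "kccq",
                                   "KCCQ-CSS outside [0, 100]")
  for (i in which(!is.na(df$crp_baseline_mg_l) & df$crp_baseline_mg_l <= 0)) {
    note(df$participant_id[i], "crp_baseline_mg_l", "CRP not strictly positive")
  }
  for (i in which(!is.na(df$ntprobnp_baseline_pg_ml) &
                    df$ntprobnp_baseline_pg_ml <= 0)) {
    note(df$participant_id[i], "ntprobnp_baseline_pg_ml",
         "NTproBNP not strictly positive")
  }
  ev <- parse_event_days(df$hf_event_days)
  for (i in seq_len(nrow(df))) {
    if (!is.na(df$death_day[i]) && df$death_day[i] > df$observation_days[i]) {
      note(df$participant_id[i], "death_day", "death after end of observation")
    }
    if (length(ev[[i]]) && any(ev[[i]] > df$observation_days[i])) {
      note(df$participant_id[i], "hf_event_days",
           "HF event after end of observation")
    }
    if (!is.na(df$observation_days[i]) && df$observation_days[i] <= 0) {
      note(df$participant_id[i], "observation_days", "non-positive observation time")
    }
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(participant_id = character(0), field = character(0),
               message = character(0), stringsAsFactors = FALSE)
}

# Week-52 change score on the analysis scale for one endpoint.
# kccq, sixmwd: arithmetic change; crp: change in log CRP; weight: percent
# change from baseline.
endpoint_change <- function(df, endpoint) {
  switch(endpoint,
    kccq   = df$kccq_week52 - df$kccq_baseline,
    sixmwd = df$sixmwd_week52_m - df$sixmwd_baseline_m,
    crp    = log(df$crp_week52_mg_l) - log(df$crp_baseline_mg_l),
    weight = percent_weight_change(df$weight_baseline_kg, df$weight_week52_kg),
    stop("unknown endpoint '", endpoint, "'", call. = FALSE)
  )
}

# Baseline covariate on the analysis scale ("the relevant continuous
# baseline variable").
endpoint_baseline <- function(df, endpoint) {
  switch(endpoint,
    kccq   = df$kccq_baseline,
    sixmwd = df$sixmwd_baseline_m,
    crp    = log(df$crp_baseline_mg_l),
    weight = df$weight_baseline_kg,
    stop("unknown endpoint '", endpoint, "'", call. = FALSE)
  )
}

endpoint_is_log <- function(endpoint) endpoint == "crp"

ENDPOINTS <- c("kccq", "weight", "sixmwd", "crp")
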