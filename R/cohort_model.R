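# Domain types and CSV ingestion for blunt chest trauma cohorts.
#
# A cohort is a plain data.frame, one row per patient, with the columns
# documented in `parse_cohort_csv()`. Radiographic findings are the five
# chest-X-ray variables consumed by the trauma scores.

#' Enumerated levels used by the cohort schema
#'
#' Level sets for the categorical cohort fields: final emergency-department
#' disposition, biological sex, mechanism of injury, and the ordinal
#' pulmonary contusion grade (none, then unilateral/bilateral minor
#' (< 50% lung-field opacity) and unilateral/bilateral major (> 50%)).
#'
#' @name cohort-levels
#' @keywords internal
NULL

disposition_levels <- function() {
  c("discharged", "ward", "icu", "poor_outcome", "death")
}

critical_dispositions <- function() {
  c("icu", "poor_outcome", "death")
}

sex_levels <- function() c("male", "female")

mechanism_levels <- function() {
  c("motor_vehicle_accident", "pedestrian_vehicle_accident",
    "fall_from_height", "assault", "unknown")
}

contusion_levels <- function() {
  c("none", "unilateral_minor", "bilateral_minor",
    "unilateral_major", "bilateral_major")
}

#' Required columns of a cohort CSV
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c("patient_id", "age_years", "sex", "mechanism", "ventilated",
    "disposition", "rib_fracture_count", "bilateral_rib_fractures",
    "contusion_grade", "pneumothorax", "haemothorax")
}

#' Classify final disposition into a critical / non-critical outcome
#'
#' Final disposition is used as an outcome surrogate: death, palliative
#' T-piece ("poor_outcome") and ICU admission are critical; ward admission
#' and discharge are non-critical.
#'
#' @param disposition Character vector of disposition levels
#'   (`discharged`, `ward`, `icu`, `poor_outcome`, `death`).
#' @return Character vector, `"critical"` or `"non_critical"`.
#' @examples
#' classify_outcome(c("icu", "ward", "death"))
#' @export
classify_outcome <- function(disposition) {
  bad <- setdiff(unique(disposition), disposition_levels())
  if (length(bad) > 0 || anyNA(disposition)) {
    stop("unknown disposition level(s): ",
         paste(c(bad, if (anyNA(disposition)) NA), collapse = ", "))
  }
  ifelse(disposition %in% critical_dispositions(), "critical", "non_critical")
}

#' Age band used by the conventional score and the cohort summary
#'
#' Bands are `<45`, `45-65` (both endpoints inclusive) and `>65`.
#'
#' @param age_years Integer vector of ages, all >= 18.
#' @return Character vector of band labels.
#' @export
age_band <- function(age_years) {
  if (anyNA(age_years) || any(age_years < 18)) {
    stop("age_years must be >= 18 and non-missing")
  }
  ifelse(age_years < 45, "<45", ifelse(age_years <= 65, "45-65", ">65"))
}

#' Rib fracture count band
#'
#' Four-band version used by the cohort summary and the SA-CTS rib
#' component: `0`, `1-2`, `3-5` (inclusive), `>5`.
#'
#' @param count Non-negative integer vector of rib fracture counts.
#' @return Character vector of band labels.
#' @export
rib_band <- function(count) {
  if (anyNA(count) || any(count < 0)) stop("rib_fracture_count must be >= 0")
  ifelse(count == 0, "0",
         ifelse(count <= 2, "1-2", ifelse(count <= 5, "3-5", ">5")))
}

# Per-row validation; returns a character reason or NA if the row is valid.
validate_cohort_row <- function(row) {
  as_bool <- function(x) {
    if (is.logical(x)) return(x)
    if (is.na(x)) return(NA)
    x <- tolower(trimws(as.character(x)))
    if (x %in% c("true", "t", "1")) TRUE
    else if (x %in% c("false", "f", "0")) FALSE
    else NA
  }
  problems <- character(0)
  req <- function(field, test, what) {
    val <- row[[field]]
    if (is.null(val) || is.na(val) ||
        (is.character(val) && !nzchar(trimws(val)))) {
      problems <<- c(problems, paste0("missing ", field))
    } else if (!test(val)) {
      problems <<- c(problems, paste0(what, ": ", field, "=", val))
    }
  }
  suppressWarnings({
    age <- as.integer(row$age_years)
    ribs <- as.integer(row$rib_fracture_count)
  })
  vent <- as_bool(row$ventilated)
  bilat <- as_bool(row$bilateral_rib_fractures)
  pneu <- as_bool(row$pneumothorax)
  haemo <- as_bool(row$haemothorax)

  req("patient_id", function(x) nzchar(trimws(as.character(x))), "empty")
  if (is.null(row$age_years) || is.na(row$age_years)) {
    problems <- c(problems, "missing age_years")
  } else if (is.na(age)) {
    problems <- c(problems, paste0("unparseable age_years=", row$age_years))
  } else if (age < 18) {
    problems <- c(problems, paste0("age_years below 18: ", age))
  }
  req("sex", function(x) x %in% sex_levels(), "invalid level")
  req("mechanism", function(x) x %in% mechanism_levels(), "invalid level")
  req("disposition", function(x) x %in% disposition_levels(), "invalid level")
  req("contusion_grade", function(x) x %in% contusion_levels(), "invalid level")
  if (is.null(row$rib_fracture_count) || is.na(row$rib_fracture_count)) {
    problems <- c(problems, "missing rib_fracture_count")
  } else if (is.na(ribs) || ribs < 0) {
    problems <- c(problems,
                  paste0("invalid rib_fracture_count=", row$rib_fracture_count))
  }
  for (f in c("ventilated", "bilateral_rib_fractures", "pneumothorax",
              "haemothorax")) {
    v <- switch(f, ventilated = vent, bilateral_rib_fractures = bilat,
                pneumothorax = pneu, haemothorax = haemo)
    if (is.na(v)) {
      problems <- c(problems,
                    paste0("missing or non-boolean ", f, "=",
                           if (is.null(row[[f]])) "" else row[[f]]))
    }
  }
  if (length(problems) == 0 && isTRUE(bilat) && ribs < 2) {
    problems <- "bilateral_rib_fractures with rib_fracture_count < 2"
  }
  if (length(problems) == 0) NA_character_ else paste(problems, collapse = "; ")
}

#' Read and validate a cohort CSV
#'
#' Reads a comma-separated, UTF-8, headered cohort file (see
#' [cohort_columns()] for the schema; booleans as `true`/`false`, enums as
#' their level names). Rows violating the schema or the domain invariants
#' (age >= 18; bilateral fractures require a count of at least 2; valid
#' enum levels) are rejected with a reason, mirroring the exclusion of
#' incomplete records during data collection. No imputation is performed.
#'
#' @param path Path to the CSV file.
#' @param strict If `TRUE`, any rejected row aborts with an error.
#' @return A list with `records` (validated data.frame with typed columns)
#'   and `rejections` (data.frame with `row` — 1-based data row number —
#'   and `reason`).
#' @export
parse_cohort_csv <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if ("outcome" %in% names(raw)) {
    warning("input column 'outcome' is ignored; ",
            "outcome labels are re-derived from disposition")
  }
  raw[raw == ""] <- NA
  reasons <- vapply(seq_len(nrow(raw)),
                    function(i) validate_cohort_row(as.list(raw[i, ])),
                    character(1))
  bad <- which(!is.na(reasons))
  rejections <- data.frame(row = bad,
                           reason = reasons[bad],
                           stringsAsFactors = FALSE)
  if (strict && nrow(rejections) > 0) {
    stop("strict mode: ", nrow(rejections), " row(s) rejected; first: row ",
         rejections$row[1], " (", rejections$reason[1], ")")
  }
  keep <- raw[is.na(reasons), , drop = FALSE]
  to_bool <- function(x) tolower(trimws(x)) %in% c("true", "t", "1")
  records <- data.frame(
    patient_id = as.character(keep$patient_id),
    age_years = as.integer(keep$age_years),
    sex = as.character(keep$sex),
    mechanism = as.character(keep$mechanism),
    ventilated = to_bool(keep$ventilated),
    disposition = as.character(keep$disposition),
    rib_fracture_count = as.integer(keep$rib_fracture_count),
    bilateral_rib_fractures = to_bool(keep$bilateral_rib_fractures),
    contusion_grade = as.character(keep$contusion_grade),
    pneumothorax = to_bool(keep$pneumothorax),
    haemothorax = to_bool(keep$haemothorax),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  list(records = records, rejections = rejections)
}

#' Write a rejection report
#'
#' @param rejections Rejection data.frame from [parse_cohort_csv()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(rejections, path) {
  utils::write.csv(rejections, path, row.names = FALSE)
  invisible(path)
}

#' Summarise a cohort variable by variable
#'
#' Level counts and percentages (100 * count / N, one decimal) for each
#' cohort variable: sex, age band, mechanism, outcome (with the underlying
#' dispositions), ventilation, rib fracture band, bilaterality, contusion
#' grade, pneumothorax and haemothorax.
#'
#' @param records Validated cohort data.frame (see [parse_cohort_csv()]).
#' @return A data.frame with columns `variable`, `level`, `n`, `pct`.
#' @export
summarize_cohort <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("empty cohort")
  n_total <- nrow(records)
  count_levels <- function(variable, values, levels) {
    n <- vapply(levels, function(l) sum(values == l), integer(1))
    data.frame(variable = variable, level = levels, n = as.integer(n),
               pct = round(100 * n / n_total, 1), stringsAsFactors = FALSE)
  }
  yn <- function(x) ifelse(x, "yes", "no")
  outcome <- classify_outcome(records$disposition)
  out <- rbind(
    count_levels("mechanism", records$mechanism, mechanism_levels()),
    count_levels("sex", records$sex, sex_levels()),
    count_levels("age_band", age_band(records$age_years),
                 c("<45", "45-65", ">65")),
    count_levels("outcome", outcome, c("critical", "non_critical")),
    count_levels("disposition", records$disposition, disposition_levels()),
    count_levels("ventilated", yn(records$ventilated), c("no", "yes")),
    count_levels("rib_fracture_band", rib_band(records$rib_fracture_count),
                 c("0", "1-2", "3-5", ">5")),
    count_levels("bilateral_rib_fractures",
                 yn(records$bilateral_rib_fractures), c("no", "yes")),
    count_levels("contusion_grade", records$contusion_grade,
                 contusion_levels()),
    count_levels("pneumothorax", yn(records$pneumothorax), c("no", "yes")),
    count_levels("haemothorax", yn(records$haemothorax), c("no", "yes"))
  )
  rownames(out) <- NULL
  attr(out, "n_total") <- n_total
  out
}
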