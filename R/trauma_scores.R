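# Additive chest trauma score calculators.
#
# Two schemes plus one variant, all simple sums over per-variable
# components read off a chest X-ray:
#   * C-CTS  — age band + rib fracture band + bilaterality + contusion
#              grade (published range 2-12).
#   * SA-CTS — X-ray only: rib band (zero fractures scores zero) +
#              bilaterality + contusion grade + pneumothorax + haemothorax
#              (range 0-11).
#   * modified SA-CTS — SA-CTS with the age component re-added (1-14).
#
# The original C-CTS component table assigns "< 3" rib fractures a score
# of 1, which read literally includes zero fractures; published worked
# examples are split between that literal reading and one where zero
# fractures score 0. Both conventions are implemented; `table2_literal`
# is the default because it matches the published component table and the
# stated minimum score of 2. See the methods vignette.

#' Construct a radiographic findings object
#'
#' Bundles the five chest-X-ray variables the scores consume. All
#' arguments are vectorised; vectors are recycled to a common length by
#' `data.frame()` rules only when lengths match or are 1.
#'
#' @param rib_fracture_count Non-negative integer count of fractured ribs.
#' @param bilateral_rib_fractures Logical; requires a count of at least 2.
#' @param contusion_grade One of `"none"`, `"unilateral_minor"`,
#'   `"bilateral_minor"`, `"unilateral_major"`, `"bilateral_major"`
#'   (minor/major = under/over 50% lung-field opacity per side).
#' @param pneumothorax,haemothorax Logical presence of pleural injury.
#' @return A data.frame of class `radiographic_findings`.
#' @examples
#' findings(rib_fracture_count = 6, bilateral_rib_fractures = TRUE,
#'          contusion_grade = "bilateral_major", pneumothorax = TRUE)
#' @export
findings <- function(rib_fracture_count = 0L,
                     bilateral_rib_fractures = FALSE,
                     contusion_grade = "none",
                     pneumothorax = FALSE,
                     haemothorax = FALSE) {
  f <- data.frame(rib_fracture_count = as.integer(rib_fracture_count),
                  bilateral_rib_fractures = bilateral_rib_fractures,
                  contusion_grade = contusion_grade,
                  pneumothorax = pneumothorax,
                  haemothorax = haemothorax,
                  stringsAsFactors = FALSE)
  validate_findings(f)
  class(f) <- c("radiographic_findings", class(f))
  f
}

#' Validate radiographic findings
#'
#' Checks the domain invariants: non-negative integer rib count, logical
#' pleural/bilaterality flags, a valid contusion level, and that bilateral
#' fractures imply a count of at least 2.
#'
#' @param f A data.frame or list with the five findings fields.
#' @return `f`, invisibly; errors describe the first violation.
#' @export
validate_findings <- function(f) {
  need <- c("rib_fracture_count", "bilateral_rib_fractures",
            "contusion_grade", "pneumothorax", "haemothorax")
  missing_fields <- setdiff(need, names(f))
  if (length(missing_fields) > 0) {
    stop("findings missing field(s): ", paste(missing_fields, collapse = ", "))
  }
  ribs <- f[["rib_fracture_count"]]
  if (anyNA(ribs) || any(ribs < 0) || any(ribs != round(ribs))) {
    stop("rib_fracture_count must be a non-negative integer")
  }
  for (fl in c("bilateral_rib_fractures", "pneumothorax", "haemothorax")) {
    if (!is.logical(f[[fl]]) || anyNA(f[[fl]])) {
      stop(fl, " must be TRUE/FALSE without missing values")
    }
  }
  bad <- !(f[["contusion_grade"]] %in% contusion_levels())
  if (any(bad)) {
    stop("invalid contusion_grade: ",
         paste(unique(f[["contusion_grade"]][bad]), collapse = ", "))
  }
  if (any(f[["bilateral_rib_fractures"]] & ribs < 2)) {
    stop("bilateral_rib_fractures requires rib_fracture_count >= 2")
  }
  invisible(f)
}

#' Age component of the conventional score
#'
#' `<45` scores 1, `45-65` (inclusive) scores 2, `>65` scores 3.
#'
#' @param age_years Integer vector, all >= 18.
#' @return Integer vector in `{1, 2, 3}`.
#' @export
age_component <- function(age_years) {
  unname(c("<45" = 1L, "45-65" = 2L, ">65" = 3L)[age_band(age_years)])
}

# Rib fracture component. C-CTS table: "< 3" -> 1, "3-5" -> 2, "> 5" -> 3.
# Under zero_scores_zero (and always under SA-CTS) a count of 0 scores 0.
rib_component <- function(count, zero_rib_rule = c("table2_literal",
                                                   "zero_scores_zero")) {
  zero_rib_rule <- match.arg(zero_rib_rule)
  base <- ifelse(count < 3, 1L, ifelse(count <= 5, 2L, 3L))
  if (zero_rib_rule == "zero_scores_zero") base[count == 0] <- 0L
  as.integer(base)
}

contusion_component <- function(grade) {
  unname(c(none = 0L, unilateral_minor = 1L, bilateral_minor = 2L,
           unilateral_major = 3L, bilateral_major = 4L)[grade])
}

score_result <- function(components, scheme) {
  res <- as.data.frame(components, stringsAsFactors = FALSE)
  res$total <- as.integer(rowSums(res))
  res$scheme <- scheme
  class(res) <- c("score_result", class(res))
  res
}

#' Conventional chest trauma score (C-CTS)
#'
#' Additive score over age band, rib fracture band, bilaterality of
#' fractures, and pulmonary contusion grade. Pleural variables are not
#' consumed by this scheme.
#'
#' @param age_years Integer vector of ages (>= 18).
#' @param f Radiographic findings (see [findings()]).
#' @param zero_rib_rule `"table2_literal"` (default; zero fractures fall in
#'   the "< 3" band and score 1, so the total ranges 2-12) or
#'   `"zero_scores_zero"` (zero fractures score 0, as in some published
#'   worked examples).
#' @return A `score_result` data.frame with per-variable components,
#'   `total` and `scheme`.
#' @examples
#' ccts_score(27, findings())                     # total 2
#' ccts_score(56, findings(6, TRUE, "bilateral_major", pneumothorax = TRUE))
#' @export
ccts_score <- function(age_years, f,
                       zero_rib_rule = c("table2_literal",
                                         "zero_scores_zero")) {
  zero_rib_rule <- match.arg(zero_rib_rule)
  validate_findings(f)
  score_result(list(
    age = age_component(age_years),
    rib = rib_component(f$rib_fracture_count, zero_rib_rule),
    bilateral = ifelse(f$bilateral_rib_fractures, 2L, 0L),
    contusion = contusion_component(f$contusion_grade)
  ), scheme = "ccts")
}

#' South African chest trauma score (SA-CTS)
#'
#' X-ray-only additive score: rib fracture band (0 fractures score 0,
#' 1-2 score 1, 3-5 score 2, >5 score 3), bilaterality (2), contusion
#' grade (0-4), pneumothorax (1) and haemothorax (1). Age is not consumed.
#' The total ranges 0-11.
#'
#' @param f Radiographic findings (see [findings()]).
#' @return A `score_result` data.frame.
#' @examples
#' sacts_score(findings())                                   # 0
#' sacts_score(findings(0, FALSE, "bilateral_major", haemothorax = TRUE)) # 5
#' @export
sacts_score <- function(f) {
  validate_findings(f)
  score_result(list(
    rib = rib_component(f$rib_fracture_count, "zero_scores_zero"),
    bilateral = ifelse(f$bilateral_rib_fractures, 2L, 0L),
    contusion = contusion_component(f$contusion_grade),
    pneumothorax = ifelse(f$pneumothorax, 1L, 0L),
    haemothorax = ifelse(f$haemothorax, 1L, 0L)
  ), scheme = "sacts")
}

#' Modified SA-CTS (SA-CTS plus the age component)
#'
#' Sensitivity-analysis variant: the SA-CTS total plus the conventional
#' age component; total ranges 1-14.
#'
#' @inheritParams ccts_score
#' @return A `score_result` data.frame.
#' @export
modified_sacts_score <- function(age_years, f) {
  s <- sacts_score(f)
  res <- score_result(list(
    age = age_component(age_years),
    rib = s$rib, bilateral = s$bilateral, contusion = s$contusion,
    pneumothorax = s$pneumothorax, haemothorax = s$haemothorax
  ), scheme = "modified_sacts")
  res
}

#' Theoretical range of a scoring scheme
#' @param scheme One of `"ccts"`, `"sacts"`, `"modified_sacts"`.
#' @param zero_rib_rule C-CTS zero-rib convention (ignored otherwise).
#' @return Integer vector `c(min, max)`.
#' @export
scheme_range <- function(scheme = c("ccts", "sacts", "modified_sacts"),
                         zero_rib_rule = c("table2_literal",
                                           "zero_scores_zero")) {
  scheme <- match.arg(scheme)
  zero_rib_rule <- match.arg(zero_rib_rule)
  switch(scheme,
         ccts = if (zero_rib_rule == "table2_literal") c(2L, 12L)
                else c(1L, 12L),
         sacts = c(0L, 11L),
         modified_sacts = c(1L, 14L))
}

#' Score every patient in a cohort
#'
#' @param records Validated cohort data.frame (see [parse_cohort_csv()]).
#' @param scheme `"ccts"`, `"sacts"` or `"modified_sacts"`.
#' @param zero_rib_rule C-CTS zero-rib convention; ignored by the SA-CTS,
#'   which always scores zero fractures as zero.
#' @return A `score_result` data.frame, one row per record in input order,
#'   with a leading `patient_id` column.
#' @export
score_cohort <- function(records,
                         scheme = c("ccts", "sacts", "modified_sacts"),
                         zero_rib_rule = c("table2_literal",
                                           "zero_scores_zero")) {
  scheme <- match.arg(scheme)
  zero_rib_rule <- match.arg(zero_rib_rule)
  if (is.null(records) || nrow(records) == 0) stop("empty cohort")
  f <- records[, c("rib_fracture_count", "bilateral_rib_fractures",
                   "contusion_grade", "pneumothorax", "haemothorax")]
  res <- switch(scheme,
                ccts = ccts_score(records$age_years, f, zero_rib_rule),
                sacts = sacts_score(f),
                modified_sacts = modified_sacts_score(records$age_years, f))
  cbind(data.frame(patient_id = records$patient_id,
                   stringsAsFactors = FALSE), res)
}

#' Enumerate every combination of radiographic findings
#'
#' One representative rib count per band (0, 1, 2, 3, 6), crossed with
#' bilaterality (where the count allows it), contusion grade and the two
#' pleural flags. Used for exhaustive score-range checks.
#'
#' @return A findings data.frame covering the full grid.
#' @export
findings_grid <- function() {
  g <- expand.grid(rib_fracture_count = c(0L, 1L, 2L, 3L, 6L),
                   bilateral_rib_fractures = c(FALSE, TRUE),
                   contusion_grade = contusion_levels(),
                   pneumothorax = c(FALSE, TRUE),
                   haemothorax = c(FALSE, TRUE),
                   stringsAsFactors = FALSE)
  g <- g[!(g$bilateral_rib_fractures & g$rib_fracture_count < 2), ]
  rownames(g) <- NULL
  validate_findings(g)
  g
}
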