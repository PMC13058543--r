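# End-to-end orchestration: ingest or simulate a cohort, score it, run
# the association battery and the dichotomised cutpoint analyses, and
# render everything as CSVs plus a plain-text summary.

#' Build an analysis configuration
#'
#' Exactly one of `input_path` (a cohort CSV) or `sim_params` (a
#' `cohort_sim_params` list) must be supplied.
#'
#' @param input_path Path to a cohort CSV.
#' @param sim_params Simulation parameters from [default_sim_params()].
#' @param schemes Scoring schemes to run.
#' @param zero_rib_rule C-CTS zero-rib convention.
#' @param conf_level Confidence level for exact intervals.
#' @param candidate_cutoffs `"auto"` (each scheme's full theoretical
#'   range) or an integer vector.
#' @param strict Abort on any rejected input row.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(input_path = NULL, sim_params = NULL,
                            schemes = c("ccts", "sacts", "modified_sacts"),
                            zero_rib_rule = "table2_literal",
                            conf_level = 0.95,
                            candidate_cutoffs = "auto",
                            strict = FALSE) {
  if (is.null(input_path) == is.null(sim_params)) {
    stop("supply exactly one of input_path or sim_params")
  }
  if (conf_level <= 0 || conf_level >= 1) stop("conf_level must be in (0, 1)")
  schemes <- match.arg(schemes, several.ok = TRUE)
  structure(list(input_path = input_path, sim_params = sim_params,
                 schemes = schemes, zero_rib_rule = zero_rib_rule,
                 conf_level = conf_level,
                 candidate_cutoffs = candidate_cutoffs, strict = strict),
            class = "analysis_config")
}

#' Variable-by-outcome association battery
#'
#' Exact association tests between each cohort variable and the
#' critical/non-critical outcome: 2x2 tables (sex, ventilation,
#' bilaterality, pneumothorax, haemothorax) get the two-sided Fisher p,
#' the conditional-MLE odds ratio and the exact CI; multi-level variables
#' (age band; rib fracture band as <3 / 3-5 / >5; contusion grade) get
#' the r x 2 exact p. No multiplicity correction is applied; each
#' variable is tested at its own raw p, flagged at 0.05.
#'
#' @param records Validated cohort data.frame.
#' @param conf_level Confidence level for exact CIs.
#' @return A data.frame with one row per variable level: counts by
#'   outcome, and `p`, `or`, `ci_low`, `ci_high` on each variable's first
#'   row.
#' @export
association_battery <- function(records, conf_level = 0.95) {
  outcome <- classify_outcome(records$disposition)
  yn <- function(x) factor(ifelse(x, "yes", "no"), levels = c("no", "yes"))
  vars <- list(
    sex = factor(records$sex, levels = sex_levels()),
    ventilation = yn(records$ventilated),
    age_band = factor(age_band(records$age_years),
                      levels = c("<45", "45-65", ">65")),
    rib_band = factor(ifelse(records$rib_fracture_count < 3, "<3",
                             ifelse(records$rib_fracture_count <= 5,
                                    "3-5", ">5")),
                      levels = c("<3", "3-5", ">5")),
    bilateral = yn(records$bilateral_rib_fractures),
    contusion = factor(records$contusion_grade, levels = contusion_levels()),
    pneumothorax = yn(records$pneumothorax),
    haemothorax = yn(records$haemothorax)
  )
  out <- lapply(names(vars), function(v) {
    tab <- table(vars[[v]], factor(outcome,
                                   levels = c("non_critical", "critical")))
    tab <- unclass(tab)[, c("non_critical", "critical"), drop = FALSE]
    res <- data.frame(variable = v, level = rownames(tab),
                      n_non_critical = unname(tab[, "non_critical"]),
                      n_critical = unname(tab[, "critical"]),
                      p = NA_real_, or = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      stringsAsFactors = FALSE)
    # drop empty trailing levels for the test itself, keep them in output
    test_tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(test_tab) == 2) {
      et <- exact_test_2x2(test_tab, conf_level)
      res$p[1] <- et$p_two_sided
      res$or[1] <- et$or_cmle
      res$ci_low[1] <- et$ci_low
      res$ci_high[1] <- et$ci_high
    } else if (nrow(test_tab) > 2) {
      res$p[1] <- fisher_rxc(test_tab)
    }
    res
  })
  out <- do.call(rbind, out)
  out$significant <- ifelse(is.na(out$p), NA, out$p < 0.05)
  rownames(out) <- NULL
  out
}

#' Run the full risk-stratification analysis
#'
#' Loads (or simulates) a cohort, summarises it, runs the association
#' battery, and for each requested scheme computes per-patient scores,
#' the per-score outcome curve, the cutpoint sweep over the candidate
#' cutoffs, and the dichotomised exact test at the selected cutoff. The
#' outcome label is always re-derived from disposition.
#'
#' @param config An [analysis_config()].
#' @return A list of class `reproduction_report`.
#' @export
run_full_analysis <- function(config) {
  if (!inherits(config, "analysis_config")) stop("not an analysis_config")
  rejections <- NULL
  if (!is.null(config$input_path)) {
    parsed <- parse_cohort_csv(config$input_path, strict = config$strict)
    records <- parsed$records
    rejections <- parsed$rejections
    provenance_input <- config$input_path
    seed <- NA_integer_
  } else {
    records <- generate_cohort(config$sim_params)
    provenance_input <- sprintf("simulated (n = %d, seed = %d)",
                                config$sim_params$n, config$sim_params$seed)
    seed <- config$sim_params$seed
  }
  if (nrow(records) == 0) stop("no valid records to analyse")
  outcome <- classify_outcome(records$disposition)
  scheme_results <- lapply(config$schemes, function(sch) {
    scored <- score_cohort(records, sch, config$zero_rib_rule)
    rng <- scheme_range(sch, config$zero_rib_rule)
    cands <- if (identical(config$candidate_cutoffs, "auto")) {
      seq(rng[1], rng[2])
    } else config$candidate_cutoffs
    sweep <- cutpoint_sweep(scored$total, outcome, cands,
                            conf_level = config$conf_level)
    curve <- score_outcome_curve(scored$total, outcome, score_range = rng)
    sel_tab <- dichotomize(scored$total, sweep$selected_cutoff, outcome)
    list(scheme = sch, scores = scored, curve = curve, sweep = sweep,
         selected = exact_test_2x2(sel_tab, config$conf_level),
         selected_cutoff = sweep$selected_cutoff)
  })
  names(scheme_results) <- config$schemes
  structure(list(
    cohort_summary = summarize_cohort(records),
    n = nrow(records),
    rejections = rejections,
    associations = association_battery(records, config$conf_level),
    schemes = scheme_results,
    provenance = list(input = provenance_input, seed = seed,
                      zero_rib_rule = config$zero_rib_rule,
                      conf_level = config$conf_level,
                      n_rejected = if (is.null(rejections)) 0L
                                   else nrow(rejections),
                      package_version =
                        as.character(utils::packageVersion("sacts")),
                      r_version = R.version.string)
  ), class = "reproduction_report")
}

#' Render a report to CSV files plus a text summary
#'
#' Writes the cohort summary, the association battery, one curve CSV and
#' one sweep CSV per scheme, a plain-text summary, and a manifest with
#' MD5 checksums. Numbers are written as computed by the analysis
#' operations; nothing is recomputed here.
#'
#' @param report A `reproduction_report` from [run_full_analysis()].
#' @param outdir Output directory (created if missing).
#' @return The manifest data.frame (`file`, `md5`), invisibly.
#' @export
render_report <- function(report, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) stop("cannot create directory: ", outdir)
  }
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  emit(report$cohort_summary, "cohort_summary.csv")
  emit(report$associations, "associations.csv")
  if (!is.null(report$rejections) && nrow(report$rejections) > 0) {
    emit(report$rejections, "rejected_rows.csv")
  }
  for (sch in names(report$schemes)) {
    sr <- report$schemes[[sch]]
    emit(sr$curve, sprintf("curve_%s.csv", sch))
    emit(sr$sweep$sweep, sprintf("cutpoint_sweep_%s.csv", sch))
  }
  summary_path <- file.path(outdir, "summary.txt")
  lines <- c(
    sprintf("Cohort: %s (N = %d, %d row(s) rejected)",
            report$provenance$input, report$n,
            report$provenance$n_rejected),
    sprintf("Zero-rib convention: %s; confidence level: %g",
            report$provenance$zero_rib_rule, report$provenance$conf_level),
    "",
    "Associations with critical outcome:")
  assoc <- report$associations
  for (v in unique(assoc$variable)) {
    first <- assoc[assoc$variable == v, ][1, ]
    if (is.na(first$p)) next
    line <- sprintf("  %-14s p = %s%s", v, format_p_value(first$p),
                    if (!is.na(first$or))
                      sprintf(", OR %.2f (%.2f-%.2f)", first$or,
                              first$ci_low, first$ci_high) else "")
    lines <- c(lines, line)
  }
  lines <- c(lines, "", "Selected cutoffs (min exact p):")
  for (sch in names(report$schemes)) {
    sr <- report$schemes[[sch]]
    lines <- c(lines, sprintf(
      "  %-15s score >= %d: p = %s, OR %.2f (%.2f-%.2f)",
      sch, sr$selected_cutoff, format_p_value(sr$selected$p_two_sided),
      sr$selected$or_cmle, sr$selected$ci_low, sr$selected$ci_high))
  }
  lines <- c(lines, "",
             sprintf("sacts %s on %s", report$provenance$package_version,
                     report$provenance$r_version))
  writeLines(lines, summary_path)
  files <- c(files, summary_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
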