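#!/usr/bin/env Rscript
# Per-score outcome curves and cutpoint selection on the simulated cohort:
# the analogue of consolidating each score into low/high categories and
# locating the threshold where the critical fraction rises.

library(sacts)

scored <- read.csv("results/scored_cohort.csv", stringsAsFactors = FALSE)
outcome <- classify_outcome(scored$disposition)

for (scheme in c("ccts", "sacts")) {
  totals <- scored[[paste0(scheme, "_total")]]
  rng <- scheme_range(scheme)
  curve <- score_outcome_curve(totals, outcome, score_range = rng)
  write.csv(curve, sprintf("results/curve_%s.csv", scheme), row.names = FALSE)
  sweep <- cutpoint_sweep(totals, outcome, seq(rng[1], rng[2]))
  write.csv(sweep$sweep, sprintf("results/cutpoint_sweep_%s.csv", scheme),
            row.names = FALSE)
  sel <- sweep$sweep[sweep$sweep$cutoff == sweep$selected_cutoff, ]
  cat(sprintf(
    "%s: selected cutoff >= %d (p = %s, OR %.2f, %g%% CI %.2f-%.2f, sens %.2f, spec %.2f)\n",
    toupper(scheme), sweep$selected_cutoff, format_p_value(sel$p), sel$or,
    100 * sweep$conf_level, sel$ci_low, sel$ci_high,
    sel$sensitivity, sel$specificity))
}
cat("Wrote curve and sweep CSVs under results/\n")
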