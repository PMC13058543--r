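#!/usr/bin/env Rscript
# Score the simulated cohort under all three schemes and check the
# published worked examples as a sanity gate before any inference.

library(sacts)

parsed <- parse_cohort_csv("results/cohort.csv", strict = TRUE)
cohort <- parsed$records

scored <- cohort
for (scheme in c("ccts", "sacts", "modified_sacts")) {
  s <- score_cohort(cohort, scheme)
  scored[[paste0(scheme, "_total")]] <- s$total
}
write.csv(scored, "results/scored_cohort.csv", row.names = FALSE)

cat("Score distributions:\n")
print(table(scored$ccts_total))
print(table(scored$sacts_total))

# the published worked examples, recomputed
ex <- worked_examples()
f <- ex[, c("rib_fracture_count", "bilateral_rib_fractures",
            "contusion_grade", "pneumothorax", "haemothorax")]
cc <- vapply(1:4, function(i)
  ccts_score(ex$age_years[i], f[i, ], ex$ccts_convention[i])$total,
  integer(1))
ss <- sacts_score(f)$total
cat(sprintf("Worked examples reproduce: C-CTS %s (published %s), SA-CTS %s (published %s)\n",
            paste(cc, collapse = "/"), paste(ex$ccts_total, collapse = "/"),
            paste(ss, collapse = "/"), paste(ex$sacts_total, collapse = "/")))
cat("Wrote results/scored_cohort.csv\n")
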