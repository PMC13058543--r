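test_that("outcome classification partitions dispositions into two classes", {
  expect_equal(classify_outcome("icu"), "critical")
  expect_equal(classify_outcome("death"), "critical")
  expect_equal(classify_outcome("poor_outcome"), "critical")
  expect_equal(classify_outcome("ward"), "non_critical")
  expect_equal(classify_outcome("discharged"), "non_critical")
  all_levels <- c("discharged", "ward", "icu", "poor_outcome", "death")
  labels <- classify_outcome(all_levels)
  expect_setequal(unique(labels), c("critical", "non_critical"))
  expect_error(classify_outcome("transferred"), "transferred")
  expect_error(classify_outcome(NA_character_), "disposition")
})

test_that("well-formed cohort CSV parses without rejections", {
  records <- make_reference_marginal_cohort()[1:5, ]
  path <- write_cohort_fixture(records)
  parsed <- parse_cohort_csv(path)
  expect_equal(nrow(parsed$records), 5)
  expect_equal(nrow(parsed$rejections), 0)
  expect_identical(parsed$records$age_years, records$age_years)
  expect_identical(parsed$records$bilateral_rib_fractures,
                   records$bilateral_rib_fractures)
})

test_that("invalid rows are rejected with a reason naming the field", {
  records <- make_reference_marginal_cohort()[1:5, ]
  records$disposition[3] <- ""
  path <- write_cohort_fixture(records)
  parsed <- parse_cohort_csv(path)
  expect_equal(nrow(parsed$records), 4)
  expect_equal(parsed$rejections$row, 3)
  expect_match(parsed$rejections$reason, "disposition")
  expect_error(parse_cohort_csv(path, strict = TRUE), "strict")
})

test_that("a 315-row file with 14 malformed rows yields 301 records", {
  base <- make_reference_marginal_cohort()
  extra <- base[1:14, ]
  extra$patient_id <- sprintf("BAD%02d", 1:14)
  # a spread of violations: bad ages, enum typos, under-age, bilateral
  # with too few fractures, non-boolean flags
  extra$age_years[1:3] <- c(17L, 16L, 15L)
  extra$sex[4] <- "unknown_sex"
  extra$disposition[5:6] <- c("home", "")
  extra$contusion_grade[7] <- "severe"
  extra$rib_fracture_count[8] <- -1L
  extra$mechanism[9] <- "bicycle"
  extra$bilateral_rib_fractures[10] <- TRUE
  extra$rib_fracture_count[10] <- 1L
  suppressWarnings(storage.mode(extra$age_years) <- "character")
  extra$age_years[11:12] <- c("abc", "")
  extra$ventilated <- as.character(extra$ventilated)
  extra$ventilated[13:14] <- c("maybe", "")
  base$age_years <- as.character(base$age_years)
  base$ventilated <- as.character(base$ventilated)
  path <- write_cohort_fixture(rbind(base, extra))
  parsed <- parse_cohort_csv(path)
  expect_equal(nrow(parsed$records), 301)
  expect_equal(nrow(parsed$rejections), 14)
})

test_that("missing required columns raise a schema error", {
  records <- make_reference_marginal_cohort()[1:3, ]
  records$haemothorax <- NULL
  path <- write_cohort_fixture(records)
  expect_error(parse_cohort_csv(path), "haemothorax")
})

test_that("an input outcome column is ignored with a warning", {
  records <- make_reference_marginal_cohort()[1:3, ]
  records$outcome <- "non_critical"
  path <- write_cohort_fixture(records)
  expect_warning(parsed <- parse_cohort_csv(path), "re-derived")
  expect_false("outcome" %in% names(parsed$records))
})

test_that("cohort summary reproduces the reference marginal counts", {
  records <- make_reference_marginal_cohort()
  s <- summarize_cohort(records)
  get <- function(var, lev) s[s$variable == var & s$level == lev, ]
  expect_equal(get("sex", "male")$n, 213)
  expect_equal(get("sex", "male")$pct, 70.8)
  expect_equal(get("outcome", "critical")$n, 99)
  # 99/301 = 32.89%, i.e. 32.9 to one decimal under round-to-nearest
  expect_equal(get("outcome", "critical")$pct, 32.9)
  expect_equal(get("rib_fracture_band", "0")$n, 190)
  expect_equal(get("rib_fracture_band", "1-2")$n, 69)
  expect_equal(get("rib_fracture_band", ">5")$pct, 0.3)
  expect_equal(get("haemothorax", "yes")$pct, 37.5)
  expect_equal(get("contusion_grade", "bilateral_major")$pct, 8.6)
  # counts sum to N within every variable
  sums <- tapply(s$n, s$variable, sum)
  expect_true(all(sums == 301))
})

test_that("summary is permutation-invariant and handles edge cohorts", {
  records <- make_reference_marginal_cohort()
  set.seed(7)
  shuffled <- records[sample(nrow(records)), ]
  s1 <- summarize_cohort(records)
  s2 <- summarize_cohort(shuffled)
  expect_equal(s1, s2, ignore_attr = TRUE)
  one <- summarize_cohort(records[42, , drop = FALSE])
  expect_true(all(one$pct %in% c(0, 100)))
  expect_error(summarize_cohort(records[0, ]), "empty")
})

test_that("write -> parse -> summarize round-trips exactly", {
  records <- make_reference_marginal_cohort()
  path <- write_cohort_fixture(records)
  parsed <- parse_cohort_csv(path)
  expect_equal(nrow(parsed$rejections), 0)
  expect_equal(summarize_cohort(parsed$records), summarize_cohort(records),
               ignore_attr = TRUE)
})
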