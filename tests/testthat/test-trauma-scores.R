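test_that("age component follows the published bands", {
  expect_equal(age_component(27), 1L)
  expect_equal(age_component(56), 2L)
  expect_equal(age_component(66), 3L)
  expect_equal(age_component(c(44, 45, 65)), c(1L, 2L, 2L))  # inclusive 45-65
  expect_error(age_component(17), "18")
})

test_that("published worked examples reproduce under their conventions", {
  ex <- worked_examples()
  f <- ex[, c("rib_fracture_count", "bilateral_rib_fractures",
              "contusion_grade", "pneumothorax", "haemothorax")]
  for (i in seq_len(nrow(ex))) {
    cc <- ccts_score(ex$age_years[i], f[i, ], ex$ccts_convention[i])
    expect_equal(cc$total, ex$ccts_total[i],
                 label = sprintf("C-CTS example %s", ex$example[i]))
    ss <- sacts_score(f[i, ])
    expect_equal(ss$total, ex$sacts_total[i],
                 label = sprintf("SA-CTS example %s", ex$example[i]))
  }
  # the zero-rib inconsistency: example a needs the literal convention,
  # b and c need zero_scores_zero; under the opposite convention the
  # totals shift by exactly the rib component
  expect_equal(ccts_score(27, f[1, ], "zero_scores_zero")$total, 1L)
  expect_equal(ccts_score(53, f[2, ], "table2_literal")$total, 4L)
  expect_equal(ccts_score(31, f[3, ], "table2_literal")$total, 6L)
})

test_that("modified SA-CTS adds the age component to the SA-CTS", {
  ex <- worked_examples()
  f <- ex[, c("rib_fracture_count", "bilateral_rib_fractures",
              "contusion_grade", "pneumothorax", "haemothorax")]
  expect_equal(modified_sacts_score(27, f[1, ])$total, 1L)  # 0 + 1
  expect_equal(modified_sacts_score(56, f[4, ])$total, 12L) # 10 + 2
  maximal <- findings(6, TRUE, "bilateral_major", TRUE, TRUE)
  expect_equal(modified_sacts_score(66, maximal)$total, 14L)
})

test_that("score components respect the published boundaries", {
  at_ribs <- function(k, rule = "table2_literal") {
    ccts_score(30, findings(rib_fracture_count = k), rule)$rib
  }
  expect_equal(sapply(c(0, 2, 3, 5, 6), at_ribs), c(1, 1, 2, 2, 3))
  expect_equal(at_ribs(0, "zero_scores_zero"), 0L)
  sac <- function(k) sacts_score(findings(rib_fracture_count = k))$rib
  expect_equal(sapply(c(0, 1, 2, 3, 5, 6, 20), sac), c(0, 1, 1, 2, 2, 3, 3))
})

test_that("findings invariants are enforced", {
  expect_error(findings(rib_fracture_count = -1), "non-negative")
  expect_error(findings(1, TRUE, "none"), "requires")
  expect_error(findings(3, FALSE, "moderate"), "contusion")
  expect_error(sacts_score(data.frame(rib_fracture_count = 1)), "missing")
  # a missing field fails validation rather than scoring 0
  f <- findings(2, FALSE, "none")
  f$pneumothorax <- NA
  expect_error(sacts_score(f), "pneumothorax")
})

test_that("SA-CTS is monotone non-decreasing in every component", {
  grid <- findings_grid()
  base_totals <- sacts_score(grid)$total
  bump <- function(g) sacts_score(g)$total
  more_ribs <- grid
  more_ribs$rib_fracture_count <- grid$rib_fracture_count + 4L
  expect_true(all(bump(more_ribs) >= base_totals))
  with_bilat <- grid
  with_bilat$bilateral_rib_fractures <- TRUE
  with_bilat$rib_fracture_count <- pmax(grid$rib_fracture_count, 2L)
  expect_true(all(bump(with_bilat) >= base_totals))
  grades <- c("none", "unilateral_minor", "bilateral_minor",
              "unilateral_major", "bilateral_major")
  worse_cont <- grid
  worse_cont$contusion_grade <-
    grades[pmin(match(grid$contusion_grade, grades) + 1L, 5L)]
  expect_true(all(bump(worse_cont) >= base_totals))
  for (fl in c("pneumothorax", "haemothorax")) {
    with_fl <- grid
    with_fl[[fl]] <- TRUE
    expect_true(all(bump(with_fl) >= base_totals))
  }
})

test_that("schemes differ only by age, pleural add-ons and the zero-rib rule", {
  grid <- findings_grid()
  sub <- grid[grid$rib_fracture_count >= 1 & !grid$pneumothorax &
                !grid$haemothorax, ]
  for (age in c(27, 56, 80)) {
    expect_equal(sacts_score(sub)$total,
                 ccts_score(age, sub, "table2_literal")$total -
                   age_component(age))
  }
})

test_that("exhaustive enumeration attains exactly the published ranges", {
  grid <- findings_grid()
  expect_setequal(sacts_score(grid)$total, 0:11)
  ccts_totals <- unlist(lapply(c(30, 50, 70), function(a)
    ccts_score(a, grid, "table2_literal")$total))
  expect_setequal(ccts_totals, 2:12)
  mod_totals <- unlist(lapply(c(30, 50, 70), function(a)
    modified_sacts_score(a, grid)$total))
  expect_setequal(mod_totals, 1:14)
})

test_that("cohort scoring is order-preserving, pure and component-consistent", {
  params <- default_sim_params(n = 200, seed = 11)
  coh <- generate_cohort(params)
  s1 <- score_cohort(coh, "sacts")
  s2 <- score_cohort(coh, "sacts")
  expect_identical(s1, s2)
  expect_identical(s1$patient_id, coh$patient_id)
  comp <- s1[, c("rib", "bilateral", "contusion", "pneumothorax",
                 "haemothorax")]
  expect_equal(rowSums(comp), as.numeric(s1$total))
  cc <- score_cohort(coh, "ccts")
  expect_true(all(cc$total >= 2 & cc$total <= 12))
  expect_error(score_cohort(coh[0, ], "sacts"), "empty")
})
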