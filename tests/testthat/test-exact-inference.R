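ref <- study_reference_tables()

test_that("noncentral hypergeometric pmf matches its definition", {
  # psi = 1 is the central hypergeometric distribution
  set.seed(42)
  for (i in 1:20) {
    m <- sample(1:40, 1); n <- sample(1:40, 1)
    k <- sample(1:(m + n), 1)
    sup <- max(0, k - n):min(k, m)
    expect_equal(nchg_pmf(sup, m, n, k, 1), dhyper(sup, m, n, k),
                 tolerance = 1e-12)
    for (psi in c(0.1, 1, 10)) {
      expect_equal(sum(nchg_pmf(sup, m, n, k, psi)), 1, tolerance = 1e-12)
    }
  }
  # frozen exact rational value: weights C(5,x) C(5,5-x) 2^x are
  # (1, 50, 400, 800, 400, 32), so P(X = 3) = 800 / 1683
  expect_equal(nchg_pmf(3, 5, 5, 5, 2), 800 / 1683, tolerance = 1e-12)
  # outside the support the mass is zero, not an error
  expect_equal(nchg_pmf(c(-1, 6), 5, 5, 5, 2), c(0, 0))
  # boundary psi values are point masses at the support ends
  expect_equal(nchg_pmf(0:5, 5, 5, 5, 0), c(1, rep(0, 5)))
  expect_equal(nchg_pmf(0:5, 5, 5, 5, Inf), c(rep(0, 5), 1))
  expect_error(nchg_pmf(2, 5, 5, 5, -1), "psi")
})

test_that("two-sided p matches the exact-integer enumeration oracle", {
  expect_equal(fisher_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  # exhaustive over all non-degenerate tables with total <= 16
  for (N in 2:16) {
    for (a in 0:N) for (b in 0:(N - a)) for (cc in 0:(N - a - b)) {
      d <- N - a - b - cc
      tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_2x2(tab), oracle_fisher_2x2(tab),
                   tolerance = 1e-12)
    }
  }
})

test_that("p-values are transposition-invariant and degenerate-safe", {
  set.seed(101)
  for (i in 1:25) {
    tab <- random_table_2x2(sample(20:200, 1))
    expect_equal(fisher_2x2(tab), fisher_2x2(t(tab)), tolerance = 1e-12)
    expect_equal(fisher_2x2(tab), fisher_2x2(tab[2:1, 2:1]),
                 tolerance = 1e-12)
  }
  expect_warning(p <- fisher_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "degenerate")
  expect_equal(p, 1)
})

test_that("conditional MLE odds ratio solves the expected-count equation", {
  expect_equal(round(cmle_odds_ratio(ref$ventilation), 2), 27.16)
  expect_equal(round(cmle_odds_ratio(ref$sex), 2), 0.80)
  for (x in c(1, 4, 9)) {
    expect_equal(cmle_odds_ratio(matrix(x, 2, 2)), 1, tolerance = 1e-9)
  }
  # self-consistency: at the returned psi the expected count is observed
  set.seed(202)
  for (i in 1:20) {
    tab <- random_table_2x2(sample(10:120, 1))
    psi <- cmle_odds_ratio(tab)
    if (psi == 0 || is.infinite(psi)) next
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    sup <- max(0, k - n):min(k, m)
    e_x <- sum(sup * nchg_pmf(sup, m, n, k, psi))
    expect_equal(e_x, tab[1, 1], tolerance = 1e-6)
  }
  # boundary cells give the boundary estimates
  expect_equal(cmle_odds_ratio(matrix(c(0, 5, 3, 2), 2, byrow = TRUE)), 0)
  expect_equal(cmle_odds_ratio(matrix(c(5, 0, 2, 3), 2, byrow = TRUE)), Inf)
  expect_error(cmle_odds_ratio(matrix(c(0, 0, 2, 3), 2, byrow = TRUE)),
               "degenerate")
})

test_that("CMLE lies between 1 and the crude odds ratio", {
  expect_equal(round(crude_odds_ratio(ref$ventilation), 2), 27.48)
  expect_equal(crude_odds_ratio(matrix(1, 2, 2)), 1)
  expect_equal(round(crude_odds_ratio(ref$haemothorax), 2), 2.11)
  expect_equal(crude_odds_ratio(matrix(c(3, 0, 0, 4), 2)), Inf)
  set.seed(303)
  for (i in 1:25) {
    tab <- random_table_2x2(sample(10:150, 1))
    cmle <- cmle_odds_ratio(tab)
    crude <- crude_odds_ratio(tab)
    if (cmle %in% c(0, Inf) || crude %in% c(0, Inf)) next
    expect_true((cmle - 1) * (crude - 1) >= 0)
    expect_lte(abs(log(cmle)), abs(log(crude)) + 1e-9)
  }
})

test_that("exact confidence intervals invert the tails", {
  expect_equal(round(exact_or_ci(ref$ccts_dichotomy), 2),
               c(ci_low = 2.52, ci_high = 7.55))
  expect_equal(round(exact_or_ci(ref$ventilation), 2),
               c(ci_low = 8.04, ci_high = 143.61))
  ci <- exact_or_ci(ref$sacts_dichotomy)
  expect_equal(round(ci[["ci_low"]], 2), 2.38)
  # bounds bracket the CMLE, and wider confidence widens the interval
  set.seed(404)
  for (i in 1:15) {
    tab <- random_table_2x2(sample(15:150, 1))
    psi <- cmle_odds_ratio(tab)
    if (psi %in% c(0, Inf)) next
    ci95 <- exact_or_ci(tab, 0.95)
    ci99 <- exact_or_ci(tab, 0.99)
    expect_lt(ci95[1], psi); expect_gt(ci95[2], psi)
    expect_lt(ci99[1], ci95[1]); expect_gt(ci99[2], ci95[2])
  }
  # boundary conventions
  lo_tab <- matrix(c(0, 5, 3, 2), 2, byrow = TRUE)
  expect_equal(exact_or_ci(lo_tab)[["ci_low"]], 0)
  hi_tab <- matrix(c(5, 0, 2, 3), 2, byrow = TRUE)
  expect_equal(exact_or_ci(hi_tab)[["ci_high"]], Inf)
  expect_error(exact_or_ci(ref$sex, conf_level = 1.2), "conf_level")
})

test_that("engine agrees with an independent exact-test implementation", {
  set.seed(505)
  for (i in 1:20) {
    tab <- random_table_2x2(sample(20:250, 1))
    ft <- fisher.test(tab)
    expect_equal(fisher_2x2(tab), ft$p.value, tolerance = 1e-9)
    psi <- cmle_odds_ratio(tab)
    if (!psi %in% c(0, Inf)) {
      # the reference implementation solves its roots to a looser
      # tolerance than the 1e-9 tail inversion used here
      expect_equal(psi, unname(ft$estimate), tolerance = 1e-4)
      expect_equal(unname(exact_or_ci(tab)), as.numeric(ft$conf.int),
                   tolerance = 5e-3)
    }
  }
})

test_that("r x c exact test matches enumeration oracles and specialises", {
  expect_equal(round(fisher_rxc(ref$age_band), 3), 0.060)
  for (nm in c("sex", "ventilation", "ccts_dichotomy")) {
    expect_equal(fisher_rxc(ref[[nm]]), fisher_2x2(ref[[nm]]),
                 tolerance = 1e-12)
  }
  set.seed(606)
  for (i in 1:40) {
    N <- sample(6:15, 1)
    repeat {
      tab <- matrix(rmultinom(1, N, prob = runif(6, 0.05, 1)), 3)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    expect_equal(fisher_rxc(tab), oracle_fisher_3x2(tab), tolerance = 1e-12)
  }
  expect_error(fisher_rxc(ref$contusion, workload_cap = 100), "cap")
  expect_error(fisher_rxc(matrix(1:3, 3, 1)), "2x2")
  expect_warning(p <- fisher_rxc(matrix(c(0, 0, 0, 2, 3, 4), 3)),
                 "degenerate")
  expect_equal(p, 1)
})
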