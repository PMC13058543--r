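# Fixtures built in code: deterministic cohorts reproducing the reference
# marginal counts, and exact integer-arithmetic oracles for the exact
# tests. Grand totals are kept small enough in the oracles that every
# binomial / factorial weight is an exactly representable integer (all
# weights are bounded by C(30, 15) ~ 1.6e8 and 15! ~ 1.3e12, far below
# 2^53), so oracle p-values involve no rounding in the ordering step.

# expand a named count vector into a level vector: fill_levels(c(a=2,b=1))
fill_levels <- function(counts) {
  rep(names(counts), times = counts)
}

fill_flags <- function(n_yes, n_total) {
  rep(c(TRUE, FALSE), times = c(n_yes, n_total - n_yes))
}

# Deterministic 301-row cohort whose marginal counts per variable equal
# the reference cohort summary exactly. Variables are assigned
# independently along the row index; bilateral fractures are placed on
# rows with count >= 2.
make_reference_marginal_cohort <- function() {
  n <- 301
  ribs <- c(rep(0L, 190), rep(2L, 69), rep(4L, 41), rep(6L, 1))
  bilateral <- rep(FALSE, n)
  bilateral[260:273] <- TRUE  # 14 rows inside the count-4 block
  data.frame(
    patient_id = sprintf("REF%03d", seq_len(n)),
    age_years = as.integer(fill_levels(c("30" = 229, "50" = 55, "70" = 17))),
    sex = fill_levels(c(male = 213, female = 88)),
    mechanism = fill_levels(c(motor_vehicle_accident = 181,
                              pedestrian_vehicle_accident = 90,
                              fall_from_height = 21, assault = 6,
                              unknown = 3)),
    ventilated = fill_flags(32, n),
    disposition = fill_levels(c(death = 11, poor_outcome = 2, icu = 86,
                                ward = 200, discharged = 2)),
    rib_fracture_count = ribs,
    bilateral_rib_fractures = bilateral,
    contusion_grade = fill_levels(c(none = 108, unilateral_minor = 77,
                                    bilateral_minor = 37,
                                    unilateral_major = 53,
                                    bilateral_major = 26)),
    pneumothorax = fill_flags(26, n),
    haemothorax = fill_flags(113, n),
    stringsAsFactors = FALSE
  )
}

# Deterministic cohort whose variable-by-outcome tables equal the
# reference association tables exactly: 99 critical rows followed by 202
# non-critical rows, each stratum filled to its printed counts.
make_reference_stratified_cohort <- function() {
  crit_ribs <- c(rep(0L, 75), rep(4L, 23), rep(6L, 1))
  crit_bilat <- rep(FALSE, 99); crit_bilat[76:84] <- TRUE
  noncrit_ribs <- c(rep(0L, 184), rep(4L, 18))
  noncrit_bilat <- rep(FALSE, 202); noncrit_bilat[185:189] <- TRUE
  crit <- data.frame(
    patient_id = sprintf("CRIT%03d", 1:99),
    age_years = as.integer(fill_levels(c("30" = 81, "50" = 11, "70" = 7))),
    sex = fill_levels(c(male = 73, female = 26)),
    mechanism = "motor_vehicle_accident",
    ventilated = fill_flags(29, 99),
    disposition = "icu",
    rib_fracture_count = crit_ribs,
    bilateral_rib_fractures = crit_bilat,
    contusion_grade = fill_levels(c(none = 20, unilateral_minor = 20,
                                    bilateral_minor = 12,
                                    unilateral_major = 30,
                                    bilateral_major = 17)),
    pneumothorax = fill_flags(18, 99),
    haemothorax = fill_flags(49, 99),
    stringsAsFactors = FALSE
  )
  noncrit <- data.frame(
    patient_id = sprintf("NC%03d", 1:202),
    age_years = as.integer(fill_levels(c("30" = 148, "50" = 44, "70" = 10))),
    sex = fill_levels(c(male = 140, female = 62)),
    mechanism = "motor_vehicle_accident",
    ventilated = fill_flags(3, 202),
    disposition = "ward",
    rib_fracture_count = noncrit_ribs,
    bilateral_rib_fractures = noncrit_bilat,
    contusion_grade = fill_levels(c(none = 88, unilateral_minor = 57,
                                    bilateral_minor = 25,
                                    unilateral_major = 23,
                                    bilateral_major = 9)),
    pneumothorax = fill_flags(8, 202),
    haemothorax = fill_flags(64, 202),
    stringsAsFactors = FALSE
  )
  rbind(crit, noncrit)
}

write_cohort_fixture <- function(records, path = tempfile(fileext = ".csv")) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  path
}

# Exact-integer complete-enumeration oracle for the two-sided Fisher p of
# a 2x2 table (valid for grand totals where C(N, k) < 2^53, i.e. any
# total used in tests). Weights are exact integers, so the probability
# ordering is exact and no relative slack is needed.
oracle_fisher_2x2 <- function(tab) {
  x <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  sup <- seq(max(0, k - n), min(k, m))
  w <- choose(m, sup) * choose(n, k - sup)
  w_obs <- w[match(x, sup)]
  sum(w[w <= w_obs]) / sum(w)
}

# Brute-force oracle for a 3x2 table: enumerates every margin-consistent
# table; weights N! / prod(t_ij!) are exact integers for totals <= 15.
oracle_fisher_3x2 <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  w_of <- function(x1, x2, x3) {
    cells <- c(x1, rs[1] - x1, x2, rs[2] - x2, x3, rs[3] - x3)
    factorial(N) / prod(factorial(cells))
  }
  w_obs <- w_of(tab[1, 1], tab[2, 1], tab[3, 1])
  ws <- c()
  for (x1 in 0:min(rs[1], cs[1])) {
    for (x2 in 0:min(rs[2], cs[1] - x1)) {
      x3 <- cs[1] - x1 - x2
      if (x3 < 0 || x3 > rs[3]) next
      ws <- c(ws, w_of(x1, x2, x3))
    }
  }
  sum(ws[ws <= w_obs]) / sum(ws)
}

# random non-degenerate 2x2 table with grand total about `size`
random_table_2x2 <- function(size) {
  repeat {
    tab <- matrix(rmultinom(1, size, prob = runif(4, 0.05, 1)), 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}
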