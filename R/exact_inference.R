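# Exact contingency-table inference under the margin-fixed model.
#
# With both margins of a 2x2 table fixed, the count X in the (1,1) cell
# follows Fisher's noncentral hypergeometric distribution indexed by the
# odds ratio psi:
#
#   P_psi(X = x) = C(m, x) C(n, k - x) psi^x / sum_u C(m, u) C(n, k - u) psi^u
#
# where m, n are the row totals, k the first column total, and the sum
# runs over the support max(0, k - n) <= u <= min(k, m). Everything here
# is built on that distribution:
#   * two-sided Fisher p   — total central (psi = 1) probability of tables
#                            no more likely than the observed one;
#   * conditional MLE OR   — the psi making E_psi[X] equal the observed x;
#   * exact CI             — tail inversion: the psi values putting
#                            alpha/2 tail probability at or beyond x.
# All weights are handled in log space, so totals of several thousand are
# fine; exact integer arithmetic appears only in test oracles.

REL_SLACK <- 1 + 1e-7  # relative slack when comparing table probabilities

as_table2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("expected a 2x2 table")
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    stop("cell counts must be non-negative integers")
  }
  storage.mode(m) <- "double"
  m
}

# Margins of the conditional distribution of the (1,1) cell.
margins_2x2 <- function(m) {
  list(x = m[1, 1], m = sum(m[1, ]), n = sum(m[2, ]), k = sum(m[, 1]))
}

nchg_support <- function(m, n, k) seq(max(0, k - n), min(k, m))

# Unnormalised log weights over the support.
nchg_logweights <- function(m, n, k, psi) {
  sup <- nchg_support(m, n, k)
  lchoose(m, sup) + lchoose(n, k - sup) + sup * log(psi)
}

#' Fisher's noncentral hypergeometric probability mass function
#'
#' Distribution of the (1,1) cell of a 2x2 table with all margins fixed,
#' indexed by the odds ratio `psi`. `psi = 1` reduces to the central
#' hypergeometric distribution; `psi = 0` and `psi = Inf` are point masses
#' at the support minimum and maximum.
#'
#' @param x Integer vector of evaluation points; values outside the
#'   support return 0.
#' @param m,n First and second row totals.
#' @param k First column total.
#' @param psi Odds ratio, `>= 0` (may be `Inf`).
#' @return Numeric vector of probabilities.
#' @examples
#' nchg_pmf(0:5, m = 5, n = 5, k = 5, psi = 2)
#' @export
nchg_pmf <- function(x, m, n, k, psi) {
  if (length(psi) != 1 || is.na(psi) || psi < 0) {
    stop("psi must be a single non-negative number")
  }
  sup <- nchg_support(m, n, k)
  p <- numeric(length(sup))
  if (psi == 0) {
    p[1] <- 1
  } else if (is.infinite(psi)) {
    p[length(p)] <- 1
  } else {
    lw <- nchg_logweights(m, n, k, psi)
    p <- exp(lw - max(lw))
    p <- p / sum(p)
  }
  out <- numeric(length(x))
  hit <- x %in% sup
  out[hit] <- p[match(x[hit], sup)]
  out
}

# E_psi[X]; strictly increasing in psi on (0, Inf).
nchg_mean <- function(m, n, k, psi) {
  sup <- nchg_support(m, n, k)
  sum(sup * nchg_pmf(sup, m, n, k, psi))
}

# P_psi(X >= x) and P_psi(X <= x).
nchg_upper_tail <- function(x, m, n, k, psi) {
  sup <- nchg_support(m, n, k)
  sum(nchg_pmf(sup[sup >= x], m, n, k, psi))
}

nchg_lower_tail <- function(x, m, n, k, psi) {
  sup <- nchg_support(m, n, k)
  sum(nchg_pmf(sup[sup <= x], m, n, k, psi))
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Probability-mass ordering: the sum of central hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (up to a relative slack of
#' 1e-7). A zero row or column margin yields p = 1 by convention, with a
#' warning.
#'
#' @param table 2x2 matrix of counts; rows are exposure levels, columns
#'   outcome levels.
#' @return Two-sided p-value in `[0, 1]`.
#' @examples
#' fisher_2x2(matrix(c(199, 70, 3, 29), 2, byrow = TRUE))
#' @export
fisher_2x2 <- function(table) {
  tab <- as_table2x2(table)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin: returning p = 1")
    return(1)
  }
  mg <- margins_2x2(tab)
  sup <- nchg_support(mg$m, mg$n, mg$k)
  p <- nchg_pmf(sup, mg$m, mg$n, mg$k, 1)
  p_obs <- p[match(mg$x, sup)]
  min(1, sum(p[p <= p_obs * REL_SLACK]))
}

#' Crude (cross-product) odds ratio
#'
#' `a d / (b c)` for the table `[[a, b], [c, d]]`; `Inf` when `b c = 0`
#' with `a d > 0`, `NaN` when both products are zero.
#'
#' @inheritParams fisher_2x2
#' @return Odds ratio in `[0, Inf]`.
#' @export
crude_odds_ratio <- function(table) {
  tab <- as_table2x2(table)
  ad <- unname(tab[1, 1] * tab[2, 2])
  bc <- unname(tab[1, 2] * tab[2, 1])
  if (bc == 0) {
    if (ad > 0) Inf else NaN
  } else {
    ad / bc
  }
}

# Solve f(log psi) = 0 for a strictly monotone f with an expanding bracket.
solve_log_psi <- function(f, tol = 1e-9) {
  lo <- -1; hi <- 1
  for (i in 1:200) {
    if (f(lo) <= 0) break
    lo <- lo * 2
  }
  for (i in 1:200) {
    if (f(hi) >= 0) break
    hi <- hi * 2
  }
  if (f(lo) > 0 || f(hi) < 0) stop("failed to bracket root")
  r <- stats::uniroot(f, c(lo, hi), tol = tol)
  exp(r$root)
}

#' Conditional maximum-likelihood odds ratio for a 2x2 table
#'
#' The odds ratio psi under which the expected (1,1) cell of the
#' noncentral hypergeometric distribution equals the observed count, with
#' all margins fixed. This is the estimate reported alongside Fisher's
#' exact test (distinct from the crude cross-product ratio, to which it is
#' weakly closer to 1). Returns 0 / `Inf` when the observed count sits at
#' the support minimum / maximum.
#'
#' @inheritParams fisher_2x2
#' @return The conditional MLE odds ratio in `[0, Inf]`.
#' @examples
#' cmle_odds_ratio(matrix(c(199, 70, 3, 29), 2, byrow = TRUE))  # 27.16
#' @export
cmle_odds_ratio <- function(table) {
  tab <- as_table2x2(table)
  if (any(rowSums(tab) == 0)) stop("degenerate row margin")
  if (any(colSums(tab) == 0)) stop("degenerate column margin")
  mg <- margins_2x2(tab)
  sup <- nchg_support(mg$m, mg$n, mg$k)
  if (mg$x == min(sup)) return(0)
  if (mg$x == max(sup)) return(Inf)
  solve_log_psi(function(lp) nchg_mean(mg$m, mg$n, mg$k, exp(lp)) - mg$x)
}

#' Exact tail-inversion confidence interval for the odds ratio
#'
#' The lower bound is the psi at which the probability of observing a
#' count at least as large as the observed one equals `(1 - conf_level)/2`;
#' the upper bound inverts the opposite tail. Boundary conventions: the
#' lower bound is 0 when the observed count sits at the support minimum,
#' and the upper bound `Inf` at the maximum.
#'
#' @inheritParams fisher_2x2
#' @param conf_level Confidence level in (0, 1); default 0.95.
#' @return Numeric `c(ci_low, ci_high)`.
#' @examples
#' exact_or_ci(matrix(c(157, 44, 45, 55), 2, byrow = TRUE))  # 2.52, 7.55
#' @export
exact_or_ci <- function(table, conf_level = 0.95) {
  if (!is.numeric(conf_level) || length(conf_level) != 1 ||
      conf_level <= 0 || conf_level >= 1) {
    stop("conf_level must be in (0, 1)")
  }
  tab <- as_table2x2(table)
  if (any(rowSums(tab) == 0)) stop("degenerate row margin")
  if (any(colSums(tab) == 0)) stop("degenerate column margin")
  mg <- margins_2x2(tab)
  sup <- nchg_support(mg$m, mg$n, mg$k)
  alpha <- (1 - conf_level) / 2
  ci_low <- if (mg$x == min(sup)) 0 else {
    solve_log_psi(function(lp)
      nchg_upper_tail(mg$x, mg$m, mg$n, mg$k, exp(lp)) - alpha)
  }
  ci_high <- if (mg$x == max(sup)) Inf else {
    # lower-tail probability decreases in psi; negate for an increasing f
    solve_log_psi(function(lp)
      alpha - nchg_lower_tail(mg$x, mg$m, mg$n, mg$k, exp(lp)))
  }
  c(ci_low = ci_low, ci_high = ci_high)
}

#' Exact test summary for a 2x2 table
#'
#' Two-sided Fisher p, conditional-MLE odds ratio and exact tail-inversion
#' confidence interval in one object.
#'
#' @inheritParams exact_or_ci
#' @return A list of class `exact_test_result` with `p_two_sided`,
#'   `or_cmle`, `ci_low`, `ci_high`, `conf_level`, `estimate_kind`.
#' @export
exact_test_2x2 <- function(table, conf_level = 0.95) {
  ci <- exact_or_ci(table, conf_level)
  structure(list(p_two_sided = fisher_2x2(table),
                 or_cmle = cmle_odds_ratio(table),
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 conf_level = conf_level,
                 estimate_kind = "conditional_mle"),
            class = "exact_test_result")
}

#' @export
print.exact_test_result <- function(x, ...) {
  cat(sprintf("Exact 2x2 test: p = %s, OR (CMLE) = %.2f, %g%% CI %.2f-%.2f\n",
              format_p_value(x$p_two_sided), x$or_cmle,
              100 * x$conf_level, x$ci_low, x$ci_high))
  invisible(x)
}

# Enumerate compositions of `total` into parts bounded above by `caps`;
# returns a matrix with one composition per row.
compositions_under_caps <- function(total, caps) {
  nc <- length(caps)
  if (nc == 1) {
    if (total <= caps[1]) return(matrix(total, 1, 1)) else
      return(matrix(numeric(0), 0, 1))
  }
  hi <- min(caps[1], total)
  lo <- max(0, total - sum(caps[-1]))
  if (lo > hi) return(matrix(numeric(0), 0, nc))
  out <- lapply(lo:hi, function(v) {
    rest <- compositions_under_caps(total - v, caps[-1])
    if (nrow(rest) == 0) return(matrix(numeric(0), 0, nc))
    cbind(v, rest, deparse.level = 0)
  })
  do.call(rbind, out)
}

#' Exact test for an r x c contingency table
#'
#' Generalised Fisher exact test with all margins fixed: implicitly
#' enumerates every table consistent with the observed margins via a
#' row-by-row dynamic-programming sweep (states are the remaining column
#' margins; each state carries the log-probability weights of all partial
#' fills reaching it), then sums the multivariate hypergeometric
#' probabilities of the tables no more probable than the observed one
#' (relative slack 1e-7). For 2x2 input this reproduces [fisher_2x2()].
#'
#' @param table Integer matrix with at least 2 rows and 2 columns.
#' @param workload_cap Maximum number of tables visited before aborting
#'   with an error (default 1e7); no silent approximation is attempted.
#' @return Two-sided exact p-value.
#' @examples
#' fisher_rxc(matrix(c(148, 81, 44, 11, 10, 7), 3, byrow = TRUE))
#' @export
fisher_rxc <- function(table, workload_cap = 1e7) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) stop("table must be at least 2x2")
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    stop("cell counts must be non-negative integers")
  }
  rs <- rowSums(m); cs <- colSums(m); n_total <- sum(m)
  if (n_total < 1) stop("empty table")
  if (any(rs == 0) || any(cs == 0)) {
    warning("degenerate margin: returning p = 1")
    return(1)
  }
  nr <- nrow(m); nc <- ncol(m)
  # log P(T) = sum_i [r_i! / prod_j t_ij!] + sum_j log c_j! - log N!
  const <- sum(lfactorial(cs)) - lfactorial(n_total)
  row_lw <- function(comp_mat, r_tot) {
    lfactorial(r_tot) - rowSums(lfactorial(comp_mat))
  }
  log_p_obs <- const +
    sum(vapply(seq_len(nr),
               function(i) row_lw(m[i, , drop = FALSE], rs[i]), numeric(1)))
  thresh <- log_p_obs + log(REL_SLACK)

  # states: remaining column margins -> accumulated log-weight vectors
  # (kept as lists of chunks to avoid quadratic copying on append)
  states <- list()
  states[[paste(cs, collapse = ",")]] <- list(rem = cs, lw = list(0))
  visited <- 0
  for (i in seq_len(nr - 1)) {
    nxt <- list()
    for (st in states) {
      st_lw <- unlist(st$lw, use.names = FALSE)
      comps <- compositions_under_caps(rs[i], st$rem)
      if (nrow(comps) == 0) next
      lws <- row_lw(comps, rs[i])
      for (ci in seq_len(nrow(comps))) {
        rem2 <- st$rem - comps[ci, ]
        key <- paste(rem2, collapse = ",")
        visited <- visited + length(st_lw)
        if (visited > workload_cap) {
          stop("enumeration workload exceeds cap (", format(workload_cap),
               "); consider a Monte Carlo approach outside this package")
        }
        if (is.null(nxt[[key]])) {
          nxt[[key]] <- list(rem = rem2, lw = list(st_lw + lws[ci]))
        } else {
          nxt[[key]]$lw[[length(nxt[[key]]$lw) + 1L]] <- st_lw + lws[ci]
        }
      }
    }
    states <- nxt
  }
  # last row is forced to equal the remaining margins
  acc <- 0
  for (st in states) {
    if (sum(st$rem) != rs[nr]) next
    log_p <- const + unlist(st$lw, use.names = FALSE) +
      row_lw(matrix(st$rem, 1), rs[nr])
    acc <- acc + sum(exp(log_p[log_p <= thresh]))
  }
  min(1, acc)
}

#' Format a p-value for display
#'
#' Three decimals at or above 0.001; below that, a `< 0.001` flag with the
#' value in scientific notation at three significant digits.
#'
#' @param p Numeric p-value.
#' @return Character scalar.
#' @export
format_p_value <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p >= 0.001) sprintf("%.3f", p)
  else sprintf("< 0.001 (%s)", format(signif(p, 3), scientific = TRUE))
}
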