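---
title: "Chest trauma scores, exact contingency-table inference and cutpoint analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chest trauma scores, exact contingency-table inference and cutpoint analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacts)
```

## The clinical problem

Blunt chest trauma (BCT) injuries are often not clinically evident at
presentation, and the patients most at risk of pulmonary decompensation
benefit from early escalation — ventilation, intensive monitoring, or
up-referral for advanced imaging. Additive severity scores computed from
imaging findings are a practical triage aid, particularly in
resource-limited settings where CT is scarce and the chest X-ray (CXR) is
the workhorse modality.

This package implements two such scores and the statistical machinery
used to evaluate them against patient outcome:

* **C-CTS** (conventional chest trauma score): age band (`<45` → 1,
  `45–65` → 2, `>65` → 3) + rib fracture band (`<3` → 1, `3–5` → 2,
  `>5` → 3) + bilateral fractures (2) + pulmonary contusion grade (0–4).
  Published range 2–12, with a score of 5 or more flagged as high risk.
* **SA-CTS** (South African chest trauma score): an X-ray-only variant
  that drops age, scores zero rib fractures as zero (`0` → 0, `1–2` → 1,
  `3–5` → 2, `>5` → 3), and adds pneumothorax (1) and haemothorax (1).
  Range 0–11, with 4 or more flagged as high risk.
* **modified SA-CTS**: the SA-CTS with the age component re-added
  (range 1–14), kept as a sensitivity-analysis variant.

Outcome is dichotomised from final emergency-department disposition:
*critical* covers death, palliative T-piece ("poor outcome") and ICU
admission; *non-critical* covers ward admission and discharge.

## The zero-rib convention

The published C-CTS component table assigns the `<3` rib-fracture band a
score of 1, which read literally includes a count of zero — consistent
with the stated minimum total of 2. The published worked examples,
however, are split: one is consistent only with that literal reading,
while two others only work if zero fractures score zero. Both conventions
are therefore implemented (`zero_rib_rule = "table2_literal"`, the
default, or `"zero_scores_zero"`), no attempt is made to adjudicate the
original intent, and the SA-CTS avoids the ambiguity by construction
(zero fractures explicitly score zero).

```{r}
f0 <- findings()  # no radiographic abnormality
c(literal = ccts_score(27, f0, "table2_literal")$total,
  zero_rule = ccts_score(27, f0, "zero_scores_zero")$total,
  sacts = sacts_score(f0)$total)
```

Age-band edges are implemented with an inclusive upper bound (`45–65`
means 45 ≤ age ≤ 65), and the `3–5` rib band is inclusive; neither edge
rule is configurable.

## Exact inference under the margin-fixed model

All association results are exact, not asymptotic. For a 2×2 table with
both margins fixed, the count $X$ in the (1,1) cell follows Fisher's
noncentral hypergeometric distribution indexed by the odds ratio $\psi$:

$$
P_\psi(X = x) \;=\;
\frac{\binom{m}{x}\binom{n}{k-x}\,\psi^x}
     {\sum_{u}\binom{m}{u}\binom{n}{k-u}\,\psi^u},
$$

with $m, n$ the row totals, $k$ the first column total, and $u$ ranging
over $\max(0, k-n) \le u \le \min(k, m)$. Three quantities are built on
this distribution:

* **Two-sided p** (`fisher_2x2()`): the total central ($\psi = 1$)
  probability of all tables no more probable than the observed one. A
  relative slack of $1 + 10^{-7}$ guards the probability-mass comparison
  against floating-point ties; this matches the convention of the
  standard R implementation, and alternative two-sided definitions (such
  as doubling the smaller tail) are deliberately not offered.
* **Conditional MLE odds ratio** (`cmle_odds_ratio()`): the $\psi$
  solving $E_\psi[X] = x_{\text{obs}}$. Because $E_\psi[X]$ is strictly
  increasing in $\psi$, the root is unique; it is bracketed on
  $\log\psi$ and refined to $10^{-9}$ relative tolerance. The estimate
  is 0 at the support minimum and $\infty$ at the maximum. The crude
  cross-product ratio $ad/bc$ is available as a diagnostic companion
  (`crude_odds_ratio()`); the CMLE is always weakly closer to 1.
* **Exact CI** (`exact_or_ci()`): tail inversion. The lower bound solves
  $P_\psi(X \ge x_{\text{obs}}) = \alpha/2$ and the upper bound
  $P_\psi(X \le x_{\text{obs}}) = \alpha/2$, with the boundary
  conventions $[0, \cdot]$ / $[\cdot, \infty]$ at the support ends.
  Roots are again exact to $10^{-9}$ relative tolerance, which can
  differ in the third significant figure from implementations that stop
  at a looser tolerance on very wide intervals.

All weights are computed in log space (`lchoose`), so cohort-scale totals
(hundreds to thousands) are handled stably; exact integer arithmetic is
used only inside the test oracles, which enumerate small tables with
exactly representable binomial weights.

For $r \times c$ tables (`fisher_rxc()`) the same probability-mass
ordering is applied to the multivariate hypergeometric distribution over
all tables with the observed margins. Enumeration is a row-by-row
dynamic-programming sweep whose states are the remaining column margins,
each carrying the log-weights of all partial fills; a workload cap
(default $10^7$ visited fills) turns an over-large problem into an
explicit error rather than a silent approximation. The 5×2
contusion-by-outcome table of a 301-patient cohort enumerates about
4.4 million tables in well under a second.

```{r}
ref <- study_reference_tables()
exact_test_2x2(ref$ventilation)
fisher_rxc(ref$age_band)
```

No multiplicity correction is applied anywhere: each variable is tested
at its own raw p-value, flagged at 0.05, mirroring how the original
association battery was reported.

## Cutpoint analysis

The published thresholds (C-CTS ≥ 5, SA-CTS ≥ 4) were identified
visually from per-score percent-critical curves. A visual criterion is
not reproducible, so `cutpoint_sweep()` implements a documented
surrogate: dichotomise at every candidate cutoff (by default the
scheme's full theoretical range), run the exact 2×2 test at each
feasible split, and select the cutoff with the smallest two-sided p,
breaking ties toward the smaller cutoff. The full sweep — counts, p,
CMLE odds ratio, exact CI, sensitivity and specificity per cutoff — is
always returned so users can apply their own judgement; infeasible
cutoffs (an empty row) are flagged rather than dropped. Sensitivity and
specificity are descriptive companions only; no ROC/AUC machinery is
included because threshold selection here is association-driven, not
discrimination-driven.

## The synthetic cohort generator

The original per-patient data are not deposited; published marginal
frequencies and worked examples are the only cohort-level inputs
available. `generate_cohort()` therefore simulates cohorts whose
marginals match the published summary: sex (70.8% male), age bands
(76.1/18.3/5.6%), mechanism of injury, rib-fracture bands
(63.1/23.0/13.6/0.3%), contusion grades, pneumothorax (8.6%) and
haemothorax (37.5%). Rib counts are uniform within bands (the `>5` band
is realised as 6–8; any count above 5 scores identically), and
bilaterality is sampled only when the count allows it, with
$P(\text{bilateral} \mid \text{count} \ge 2) = 0.185$ chosen so the
marginal bilateral rate is the published 4.7%. Ages are uniform integers
within bands (18–44, 45–65, 66–90); scores depend on age only through
the band. All draws come from one seeded generator in a fixed field
order, so cohorts are bit-reproducible.

### Outcome model and calibration

Outcome depends on findings only through the SA-CTS — a deliberate
simplification that makes threshold recovery well-posed. The critical
probability follows a logistic link with two available shapes:

* **step** (default): $P(\text{critical} \mid s) =
  \operatorname{logit}^{-1}(a + b\,\mathbb{1}[s \ge 4])$. The population
  odds ratio of the high group is exactly $e^b$, so calibration to the
  published odds ratio (4.17) is closed-form in the slope, and the
  intercept is solved against the published critical fraction (0.328)
  under the exact score distribution. Under this design the threshold is
  recoverable: across 200 study-sized replicates the minimum-p sweep
  selects cutoff 4 in about 96% of cohorts.
* **linear**: $P(\text{critical} \mid s) = \operatorname{logit}^{-1}(a +
  b s)$. Both calibration targets are met equally well (two-target root
  finding on the exact score distribution), but a smooth link spreads
  the association across neighbouring cutoffs, no single cutpoint is
  statistically distinguished, and the selected cutoff scatters over
  roughly 2–5 at the study size. The linear link is retained for
  sensitivity analyses of the selection rule itself.

The exact SA-CTS distribution used by the calibration is computed by
convolving the component distributions (`sacts_pmf()`), tracking the
coupling between the rib band and bilaterality eligibility, so no
simulation is needed to hit the targets.

With the coupling removed (`calibrate_outcome_model(params, slope = 0)`),
every patient is critical with probability 0.328 regardless of score.
Because the sweep minimises p over about a dozen correlated cutoffs, the
rate of min-p < 0.05 under this null exceeds the nominal 5% — around
20% in 200 study-sized replicates — which is the expected selection
inflation and the reason the sweep reports the full table rather than
just a winner.

### What the generator does not emulate

Findings components are sampled independently, because only marginals
are published. Real cohorts correlate rib fractures with pleural injury
and contusions, so the simulated SA-CTS distribution has less mass at
high scores than the original cohort (about 13% at ≥ 4 versus the
observed 28%). Consequently, passing the recovery experiments shows the
pipeline recovers a threshold from data generated under its own
assumptions, not that the scores are valid in new clinical data. The
generator also ignores polytrauma outliers (low scores with critical
outcomes from extra-thoracic injury), referral-pattern censoring, and
any age-related confounding; ventilation is generated as a consequence
label of outcome (conditional rates 29/99 and 3/202), not as a cause.

## Numerical and design choices

* Percentages in cohort summaries are `round(100 * n / N, 1)`
  (round-to-nearest; a printed reference value that disagrees by 0.1 in
  the last digit reflects truncation in the source).
* Probability-mass orderings use the $1 + 10^{-7}$ relative slack; root
  finding uses monotone bracketing on $\log\psi$ plus `uniroot` at
  $10^{-9}$ relative tolerance.
* Degenerate margins: p = 1 with a warning for tests; an error for
  estimation, naming the margin.
* Missing or malformed cohort rows are rejected with a per-row reason
  (no imputation); `strict = TRUE` turns any rejection into an error.
* A bilateral-fracture flag with a count below 2 is a validation error,
  not a scorable state, and a missing findings field fails validation
  rather than scoring 0.
* Problem sizes in the replication experiments — 200 replicates of
  n = 301 — match the original study size while keeping the full test
  suite fast; marginal-convergence checks use one cohort of n = 50,000.

## Limitations

The package reproduces and stress-tests the published analysis; it does
not validate the scores. The exact reproduction results are fully
determined by published contingency tables, so they verify the
inferential machinery, not the underlying data collection. External
validity of the SA-CTS — and of any threshold — requires new cohorts,
ideally with the correlated-findings structure the generator lacks.
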