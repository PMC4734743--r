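---
title: "Matched-pair permutation inference for group-randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched-pair permutation inference for group-randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairperm)
```

## The design and the inferential model

`pairperm` analyzes two-arm trials that randomize intact groups — here,
high schools — rather than individuals. Schools are first matched into
pairs on baseline covariates (number of smokers, smoking prevalence,
fraction of students eligible for free or reduced-price meals, and mean
stage-of-readiness score), and one school of each pair is assigned to the
experimental condition by an independent fair coin flip.

That coin flip is the *only* randomness the analysis relies on. For an
endpoint summarized per school as events/eligible, the observed statistic
is

$$ T = 100\left(\frac{\sum_{k \in E} e_k}{\sum_{k \in E} n_k} -
       \frac{\sum_{k \in C} e_k}{\sum_{k \in C} n_k}\right), $$

the difference in pooled arm percentages in percentage points
(`statistic = "pooled"`), or alternatively the difference in unweighted
means of school-level percentages (`statistic = "school_mean"`). The
reference distribution re-enacts the randomization: for each of the $2^K$
vectors of within-pair arm swaps, the statistic is recomputed. The
two-sided p-value is the proportion of reference values at least as
extreme (in absolute value) as the observed one, with ties counted as
extreme and the observed arrangement included — which makes the test
exactly valid at its nominal level under the null of no effect, with no
distributional or modelling assumptions. Intraclass correlation of
outcomes within schools is automatically respected, because schools are
permuted as units.

The pooled statistic is the default because participant-level percentages
are what trial reports print, and their difference is the quantity the
tables call $\Delta$; the school-mean statistic is retained as an option
since practice in group-randomized analysis varies.

With $K \le$ `exact_threshold` (default 20) pairs the enumeration is
exhaustive and the p-value has denominator $2^K$. Above the threshold a
seeded Monte-Carlo sample of swap vectors is used, with the observed
arrangement included in the denominator (`n_resamples` + 1), which keeps
the estimated p-value valid.

## Confidence intervals by test inversion

The interval is the set of hypothesized effects $\delta$ (percentage
points) not rejected by the shifted test at the complementary level. The
shift follows the standard randomization-inference construction for an
additive effect on the percentage scale: the hypothesized effect is
removed from the observed-experimental schools (their event counts are
reduced by $\delta n_k / 100$), the swap enumeration is re-run on the
adjusted counts, and $\delta$ is retained when the two-sided p-value is at
least $1 - \mathrm{level}$. Endpoints are found by bisection to a
tolerance of 0.05 percentage points (configurable).

Two discreteness facts are worth knowing:

* The smallest attainable two-sided p-value is $2/2^K$ (the observed
  arrangement and its global mirror are always ties). With fewer than 6
  pairs a 95% interval is therefore the whole real line; `permutation_ci()`
  returns `c(-Inf, Inf)` with a warning rather than a misleading finite
  interval.
* When every school has the same event proportion the reference
  distribution is degenerate and the interval collapses to the observed
  (zero) difference, up to the bisection tolerance.

In Monte-Carlo mode the same seeded swap matrix is reused for every
$\delta$ visited by the bisection, so the p-value is a step function of
$\delta$ and the interval is reproducible from the seed.

## Stratified adjustment and subgroup handling

A chance imbalance in a baseline stratum (daily vs less-than-daily
smoking) is adjusted by a stratified statistic: $\sum_s w_s \Delta_s$,
with $w_s$ the stratum's share of endpoint-evaluable participants, frozen
at the observed data and held fixed across permutations. The same swap
vector applies to every stratum, since the school — not the stratum — is
the randomized unit.

Subgroup analyses apply the *pair-exclusion rule*: when a school has no
eligible participants in the subgroup, neither that school nor its matched
pair contributes to the test or to $\Delta$. The rule is applied to the
full school roster before complete-case filtering is visible, so a school
emptied by missingness is treated the same way as one emptied by subgroup
membership. All analyses are complete-case: participants with a missing
endpoint are excluded, no imputation is performed.

## Endpoint derivation

Prolonged abstinence is affirmed conservatively, requiring *consistent*
abstinence reports on three items: time since last cigarette, current
smoking frequency ("not at all"), and days smoked of the last 30 ("0
days"). The duration (6 years, 3 years, 1 year, 6 months) only moves the
threshold on the first item, so the four flags nest by construction.
Missing items are handled asymmetrically, in keeping with the
conservative reading: any non-missing item that contradicts abstinence
forces `FALSE`; if nothing contradicts but an item is missing, consistency
cannot be confirmed and the flag is missing. A follow-up report of "never
smoked" from a baseline smoker is internally inconsistent; we count it as
abstinent at every duration (the respondent is affirming non-smoking) and
surface it in the data-quality report of `read_participants()` so users
can audit the choice.

Baseline smoker status is the union of three positive responses
(at-least-monthly frequency, any smoking in the last 30 days, last
cigarette within 30 days); a missing item is a non-positive response, and
"less than once a month" is deliberately *not* positive. Daily status
requires the at-least-daily frequency code.

"Sustained progress" on the six progress measures is formalized as:
strict improvement from baseline to the first follow-up, no regression
from the first to the second follow-up, and a second follow-up strictly
better than baseline. Since "consistently reduced" admits a stricter
reading, `derive_progress_flags(mode = "strict-both")` requires strict
improvement at both steps; the default is the laxer reading, which treats
maintaining an improvement as sustaining it.

Item codes are small integers with a shipped plain-text code book
(`codebook()`), decoupling questionnaire wording dialects from the logic;
external files are adapted with a column map (`read_colmap()`).

## The synthetic-trial generator

`generate_trial()` exists so every stage of the pipeline is testable
without any external data. Its defaults are frozen to the study conditions
the package emulates: 25 pairs, negative-binomial school sizes with mean
43 (about 2,150 smokers in 50 schools; dispersion 8 gives a realistic
school-size spread), control six-year abstinence rate 13.1% with a +1.1
point arm effect, daily-smoker fractions 34.5% / 39.9% by arm, 81.5%
final-wave and 88.8% first-wave response, first-wave abstinence 17.8%
(+4.0 points in the experimental arm), 63.9% relapse and 7.9% delayed
abstinence between the waves, and shorter-duration abstinence margins at
the ratios 23.2 : 32.9 : 39.1 relative to 13.1.

Between-school heterogeneity is beta-binomial: school endpoint
probabilities are drawn from a Beta with mean equal to the arm rate and
shape sum $(1-\rho)/\rho$, so the configured $\rho$ *is* the intraclass
correlation of the binary endpoint. An ICC of 0.02 is used as the default
since the value assumed by the original design is unpublished and values
near 0.01–0.02 are typical of school-level smoking outcomes.

The final-wave duration is drawn as a single "time since last cigarette"
category against nested school-level thresholds, so duration nesting holds
by construction, and item codes are then generated to be consistent with
the drawn category — the generator writes *items*, and flags are recovered
through `derive_endpoints()`, exercising the same derivation path as real
data.

First-wave abstinence is drawn conditionally on the final-wave category,
with conditional probabilities solved from the arm margins so that the
first-wave rate and the relapse rate hold exactly. Matching the delayed
rate simultaneously is overdetermined; when the implied conditional
probability leaves $[0,1]$ it is clamped, giving a realized delayed rate
of about 8.1% against the configured 7.9% under the defaults. We accepted
this small distortion rather than distorting the (exactly calibrated)
main-endpoint margins.

What the generator does *not* emulate: covariate-outcome correlation at
the school level (matching covariates are drawn independently of the
endpoint probabilities, so matching does not increase efficiency in
simulations the way it can in real trials), informative non-response
(follow-up is missing completely at random at the configured rate),
within-participant correlation of the progress measures beyond a drift
around baseline, and any intervention-content or dose structure. Passing
simulation-based tests therefore demonstrates the statistical machinery is
correct under the stated model, not that the model captures every feature
of field data.

## Numerical and validation choices

* Tie comparisons in the p-value use a $10^{-9}$ absolute tolerance so
  floating-point noise cannot drop a tied swap from the extreme set.
* The matching algorithm is exact (branch-and-bound over all perfect
  matchings, first-found wins ties, hence lexicographic determinism) up to
  12 schools, and greedy nearest-pair construction with 2-opt refinement
  above; the refined cost never exceeds the identity-order pairing, and it
  equals the brute-force optimum on all random 8-school inputs we test.
  The distance is Euclidean on z-scored covariates; a constant covariate
  contributes zero rather than dividing by a zero standard deviation.
* Validation problem sizes were chosen to keep the default suite fast
  while leaving estimator noise well below the tolerances being checked:
  exact-oracle equivalence on fixtures up to 10 pairs, test size and CI
  coverage on 1,000 simulated 25-pair trials each (Monte-Carlo mode, 999
  resamples), ICC recovery on 1,000-school datasets, and power on grids of
  120–150 simulations per cell.
* The design-power check is qualitative by necessity: the original
  design's assumed control rate and ICC are unpublished, so we scan a
  small grid of plausible values and require high power (and monotonicity
  in the effect size) rather than a specific number.

## Known limitations

* The location-shift CI assumes an additive effect on the percentage
  scale; for rates near 0 or 100 the shifted pseudo-counts can leave
  $[0, n]$, which is harmless arithmetically but reflects the model's
  additive approximation.
* Exact enumeration above ~22 pairs is memory-hungry ($2^K \times K$
  doubles); the default switches to Monte Carlo at 21 pairs. A 25-pair
  exact run is possible but deliberately not the default.
* No multiple-testing adjustment is applied across subgroup analyses,
  matching the reporting practice the package mirrors.
* Model-based alternatives (GEE, random-effects logistic regression) are
  out of scope by design.
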