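---
title: "Why baseline-adjusted cross-lagged effects can be spurious: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why baseline-adjusted cross-lagged effects can be spurious: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosslagmeta)
```

## The problem

A standard way to quantify "influence" in two-wave observational data is the
baseline-adjusted cross-lagged effect: regress the outcome at time 2 (Y2) on
the predictor at time 1 (P1) while adjusting for the outcome at time 1 (Y1).
When only zero-order correlations are available — the typical situation in a
meta-analysis of published studies — the standardized coefficient follows
from the correlation algebra alone:

$$\beta_{P1,Y2.Y1} = \frac{r_{P1,Y2} - r_{P1,Y1}\,r_{Y1,Y2}}{1 - r_{P1,Y1}^2}.$$

The trouble is that adjusting for a baseline that is measured with error
conditions on that error. If P1 and Y1 share a common cause, P1 is
correlated with the error in Y1; measurement errors revert toward zero at
remeasurement; and the combination manufactures a positive adjusted
coefficient in data containing no influence at all. This package implements
three complementary estimands whose *joint* pattern separates genuine lagged
influence from this artifact, plus a generative null model in which the
artifact can be computed exactly.

## The three estimands

For each correlation triplet $(r_{P1,Y1}, r_{Y1,Y2}, r_{P1,Y2})$ with sample
size $n$:

1. **Forward** ($\beta_{P1,Y2.Y1}$, `beta_forward()`): the conventional
   adjusted cross-lag above.
2. **Reverse-time** ($\beta_{P1,Y1.Y2}$, `beta_reverse()`): the same formula
   with the two waves exchanged,
   $(r_{P1,Y1} - r_{P1,Y2}\,r_{Y1,Y2})/(1 - r_{P1,Y2}^2)$. Genuine
   influence pushes this negative (among youths alike at follow-up, those
   with high-scoring peers must have *declined* into that state); reversion
   toward the mean pushes it positive, because it does not depend on the
   direction of time.
3. **Difference score** ($\beta_{P1,Y2-Y1}$, `beta_diff()`):
   $(r_{P1,Y2} - r_{P1,Y1})/\sqrt{2(1 - r_{Y1,Y2})}$, the effect of P1 on
   the standardized change score without baseline adjustment. Genuine
   influence makes it positive; a distorted effect leaves it near zero (when
   the contemporaneous and cross-lagged correlations are similar) or
   negative (when the contemporaneous correlation is larger).

A positive forward effect is therefore uninformative on its own; positive
effects in *both* directions plus a null/negative difference-score effect is
the distortion signature.

The reverse-time formula deserves a note: it is the role-swapped forward
formula, which is the only reading consistent with "P1 predicting Y1
adjusting for Y2", and the package verifies it against a brute-force
normal-equations solver on the full $3\times 3$ correlation matrix (the
tests run 1,000 random positive-semidefinite triplets at tolerance
$10^{-10}$). The exchange symmetry
`beta_reverse(a, b, c) == beta_forward(c, b, a)` holds identically.

## The common-factor null model

The generative null has a latent common factor $CF$ (say, availability of
drugs in a peer group) loading $g$ on peers' and youths' *general* behavior
levels, each of which loads ($h$, $i$ respectively) on the *measured* scores
at two waves. All seven structural variables have unit variance; there is no
peer-to-youth path anywhere. The implied correlations are
$r_{P1,Y1} = r_{P1,Y2} = g^2hi$ and $r_{Y1,Y2} = i^2$, so the expected
adjusted effect is

$$\frac{g^2hi\,(1 - i^2)}{1 - (g^2hi)^2},$$

strictly positive whenever $g, h, i \in (0, 1)$. `path_covariance()` builds
the exact implied covariance (via the loading decomposition onto independent
shocks, so positive semidefiniteness is structural), `cov_regress()` solves
population regressions from it, and `expected_beta()` is the closed form;
the two agree to $10^{-12}$ across a $3^3$ grid in the tests.

The mechanism is exposed by the measurement-error term $D = Y\!SU_1 - gY\!SU$
(the error in the first youth measurement), which the covariance is extended
with: at $g=h=i=0.7$ the adjusted cross-lag 0.130 factors exactly into
(P1's association with the baseline error, $-0.186$) times (that error's
regression toward zero, $-0.700$), and adding $D$ as a covariate drives the
P1 coefficient to exactly zero. Two deliberate conventions here:

* $D$ is kept on its natural scale, $\mathrm{var}(D) = 2(1-i)$, *not*
  re-standardized. The coefficient pair $(-0.186, -0.700)$ and the
  decomposition identity hold on this scale; standardizing $D$ would rescale
  the pair while leaving their product invariant.
* `simulate_path_model()` draws each variable by its generative recipe with
  one seeded RNG stream per call, so Monte-Carlo columns are bit-reproducible
  and every column has unit population variance.

## Meta-analytic pooling

All pooling happens on the Fisher-z scale ($z = \mathrm{atanh}\,r$, variance
$1/(n-3)$), with results back-transformed through $\tanh$ for reporting. The
$1/(n-3)$ rule is also applied, by default, to the z-converted regression
effects — their exact sampling variance is not derivable from a correlation
triplet alone, and the large-sample treatment mirrors that of correlations;
a per-record `v` column overrides it.

Because a study can contribute several consecutive-wave effects (which share
waves and participants), two pooling routes are provided and labelled:

* **Study-level aggregation** (default): inverse-variance weighted mean of a
  study's z values, combined variance $1/\sum w$, then a two-level
  random-effects model on the independent study records. Treating the
  within-study effects as independent for the weighted mean is optimistic;
  the `rho` argument (0 by default; 0.5 is a conventional assumption)
  inflates the combined variance for an assumed within-study correlation.
* **Three-level model**: random intercepts at study and effect level fitted
  by REML (`metafor::rma.mv`), keeping all effects.

τ² is estimated by REML (iterative; DerSimonian–Laird closed form as an
alternative and as the fallback if REML does not converge, with a warning —
the three-level fit additionally retries with a Nelder–Mead optimizer before
failing). Cochran's $Q$ uses fixed-effect $1/v$ weights; $I^2$ is the
Higgins–Thompson point estimate $\max(0, 100(Q - df)/Q)$ with the test-based
interval built on $\mathrm{SE}[\ln H]$, chosen because it depends only on
$(Q, df)$ and is therefore identical across τ² estimators; the
τ²-based definition $100\,\tau^2/(\tau^2 + v_{\text{typical}})$ is available
behind a flag. Wald intervals on the z scale are back-transformed, so CI
endpoints are always $\tanh$ of the z-scale endpoints and monotone.

## What the synthetic generator emulates — and what it does not

`generate_meta_dataset()` emulates the statistical *structure* of the
motivating meta-analytic dataset: 58 independent studies, each contributing
$1 + \mathrm{Poisson}(1.62)$ consecutive-wave correlation triplets (expected
total ≈ 152), per-study sample sizes log-uniform on 50–3,000 (expected total
N ≈ 42,000, within 20% of the real total; the real per-study distribution
lives in the archived data file, not in print, so these are stated
assumptions adjustable via `synth_config()`). Each study is simulated as one
raw multivariate-normal sample over (P1, Y at $m+1$ waves) and its triplets
are *sample* Pearson correlations — hence automatically jointly consistent
(PSD) and realistically dependent across a study's effects, deliberately
stress-testing the aggregation step.

For an explicit asymmetric population triplet $(a, b, c)$ the multi-wave
extension takes youth waves AR(1) with lag-1 correlation $b$ and lets the
P1–wave correlation decay geometrically, $\mathrm{corr}(P1, Y_t) =
a\,(c/a)^{t-1}$: the first consecutive pair carries $(a, b, c)$ exactly and
every pair shares the same cross/contemporaneous ratio. Under a path-model
(null) population all waves are exchangeable and every triplet is exactly
$(g^2hi,\, i^2,\, g^2hi)$. Between-study heterogeneity, when requested, is
injected on the Fisher-z scale of the population correlations and mapped
back, resampling (up to 100 attempts) whenever a perturbed triplet or its
multi-wave extension fails the PSD check.

What it does *not* emulate: behavior domains and moderators, missing data,
non-normal measurement scales, selective reporting, or the real archive's
effects-per-study distribution. Passing recovery tests on these data
therefore show that the pipeline is consistent and calibrated under its own
assumptions — not that any particular real dataset satisfies them.

## Numerical choices and degenerate inputs

* Correlations at $|r| \ge 1$, $n < 4$, and non-PSD triplets
  ($1 + 2r_1r_2r_3 - r_1^2 - r_2^2 - r_3^2 < 0$) are hard errors naming the
  offending rows; nothing is silently clipped. Extracted correlations can be
  jointly inconsistent, so `coerce = TRUE` shrinks an offending triplet
  toward the identity on a $10^{-4}$ grid, taking the smallest shrinkage
  that restores PSD and flagging the row.
* Reports round to 3 decimals; all internal computation is full precision.
* A single-study input is reported with `k = 1` flagged and no pooling CIs.
* Every report embeds the input's MD5, the package version and the pooling
  configuration, and identical input plus configuration yields byte-identical
  CSVs (no timestamps in outputs).
* The report prints the adjusted-effect formula applied to the three
  *pooled* correlations beside the pooled per-study forward effect; the two
  differ by construction (order of pooling) and are never conflated.

## Problem sizes in the tests

The oracle comparisons run on 1,000 random PSD triplets; Monte-Carlo checks
of the null model use $N = 10^5$; the distortion-signature and
correlation-recovery properties run 200 seeded replicates of the full
58-study pipeline; the three-level variance-recovery and null simulations
use 200 replicates of 60 studies × 3 effects; CI coverage at $k = 58$ uses
500 replicates. These sizes make the stochastic assertions stable across
seeds while keeping the default test run fast.

## Limitations

The package is deliberately diagnostic, not curative: it shows when a
cross-lagged "influence" pattern is indistinguishable from correlated
measurement error plus regression to the mean, but it cannot recover a true
effect from such data. The common-factor model is generative only — there is
no SEM fitting — and the τ² estimator / aggregation choices of any given
published table can rarely be identified from its text, which is why both
routes are first-class and labelled rather than one being declared "the"
reproduction.
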