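# crosslagmeta

Diagnostics for baseline-adjusted cross-lagged effects in meta-analyses of
correlations.

Longitudinal peer-influence research (and much other developmental and
epidemiological work) often estimates "influence" as the standardized effect
of a predictor measured at time 1 (P1) on an outcome at time 2 (Y2) while
adjusting for the outcome at time 1 (Y1), computed from the three zero-order
correlations:

    β(P1, Y2.Y1) = (r_P1Y2 − r_P1Y1 · r_Y1Y2) / (1 − r_P1Y1²)

Such baseline-adjusted effects can be wholly spurious: when P1 and Y1 share a
common cause and Y1 is measured with error, P1 is correlated with the error
in Y1, and since measurement errors regress toward zero at the next wave, a
positive adjusted "effect" appears with no influence present. `crosslagmeta`
implements a triangulated reanalysis that makes this failure mode visible:

* **Effect-size algebra** (`beta_forward()`, `beta_reverse()`,
  `beta_diff()`): the forward adjusted effect, the same formula with the
  time direction reversed — β(P1, Y1.Y2) = (r_P1Y1 − r_P1Y2·r_Y1Y2) /
  (1 − r_P1Y2²), which genuine influence would drive *negative* — and the
  difference-score effect β(P1, Y2−Y1) = (r_P1Y2 − r_P1Y1) /
  √(2(1 − r_Y1Y2)). Positive effects in *both* time directions plus a null or
  negative difference-score effect is the signature of distortion.
* **Meta-analysis** (`meta_report()`, `pool_effects()`,
  `pool_three_level()`): Fisher-z random-effects pooling (REML or
  DerSimonian–Laird τ², via metafor) of all six parameters — three
  correlations, three regression effects — with Cochran's Q and
  Higgins–Thompson I², study-level aggregation of dependent effect sizes or a
  three-level model, caterpillar-plot exports, and ggplot2 helpers.
* **Common-factor null model** (`path_covariance()`, `expected_beta()`,
  `cov_regress()`, `simulate_path_model()`): a latent common factor CF loads
  (g) on peers' and youths' general behavior levels, which load (h, i) on the
  measured scores at two waves; there is no peer→youth path, yet the expected
  adjusted effect g²hi(1 − i²)/(1 − (g²hi)²) is strictly positive for all
  loadings in (0, 1). The implied covariance gives exact population
  coefficients; a seeded simulator echoes them.
* **Synthetic meta-dataset generator** (`synth_config()`,
  `generate_meta_dataset()`): 58 studies, ~152 consecutive-wave correlation
  triplets drawn from raw multivariate-normal study samples with known
  population truth, for end-to-end recovery tests without any download.

## Worked example

Generate a null-model dataset (no true influence anywhere) and run the
reanalysis:

```r
library(crosslagmeta)

d <- generate_meta_dataset(synth_config(seed = 1))   # 147 effects, 58 studies
tab <- meta_report(derive_effects(d))
dplyr::select(tab, parameter:I2)
#>      parameter estimate   ci_low ci_high  k     tau2    Q df   I2
#> 1       r_p1y1  0.24199  0.23595 0.24800 58 9.92e-05 83.4 57 31.7
#> 2       r_y1y2  0.48880  0.48391 0.49366 58 9.99e-05 76.3 57 25.3
#> 3       r_p1y2  0.23964  0.23243 0.24683 58 2.59e-04 98.2 57 41.9
#> 4 beta_forward  0.12946  0.12419 0.13472 58 0.00e+00 50.2 57  0.0
#> 5 beta_reverse  0.13258  0.12732 0.13783 58 0.00e+00 34.2 57  0.0
#> 6    beta_diff -0.00209 -0.00744 0.00326 58 0.00e+00 29.8 57  0.0
```

The data contain no influence, yet the forward adjusted effect (row 4) is
positive with a CI excluding zero — and so is the reverse-time effect
(row 5), which genuine influence cannot produce. The difference-score effect
(row 6) correctly sits at zero. The pooled correlations (rows 1–3) recover
the population values 0.2401 / 0.49 / 0.2401 implied by loadings
g = h = i = 0.7.

The simulation demonstration decomposes the spurious effect exactly:

```r
run_simulation_demo(n = 20000, seed = 3)
#>                                          quantity  analytic monte_carlo
#> 1        PSU1 -> YSU2 | YSU1 (adjusted cross-lag)  1.30e-01      0.1275
#> 2            PSU1 -> D | YSU1 (error association) -1.86e-01     -0.1841
#> 3     PSU1 -> YSU2 | YSU1, D (residual cross-lag)  5.11e-18     -0.0015
#> 4 D -> YSU2 | PSU1, YSU1 (regression to the mean) -7.00e-01     -0.7006
#> 5       decomposition product (error x reversion)  1.30e-01      0.1290
#> 6                         closed-form expectation  1.30e-01      NA
```

The adjusted cross-lag (0.130) is exactly the product of the predictor's
association with the baseline measurement error (−0.186) and that error's
regression toward the mean (−0.700); adjusting for the error term removes
the effect entirely (row 3).

Real extracted correlations go through the same pipeline from CSV
(`study_id,effect_id,n,r_p1y1,r_y1y2,r_p1y2`):

```r
run_reanalysis("correlations.csv", output_dir = "results")
```

which writes `table1.csv`, one `caterpillar_<parameter>.csv` per pooled
quantity, and `run_manifest.json`. A thin command-line front end with `run`,
`simulate`, `synth` and `report` subcommands is in
`inst/cli/crosslagmeta.R`.

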