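# crpgrowth

Growth-rate prediction for *E. coli* growing on **co-utilized carbon
substrate mixtures**, under the global cAMP-Crp catabolite-repression
feedback.

Carbon-catabolic gene expression under carbon limitation falls linearly
with growth rate (the *C-line*), E = E⁰(1 − λ/λ_C), because α-ketoacid
precursor pools inhibit cAMP synthesis: the feedback senses the cell's
*total* carbon-uptake flux, not which substrates supply it. For a strain
with C-line horizontal intercept λ_C (≈ 1.16/h for K-12 NCM3722), the
steady-state growth rate on a mixture of co-utilized substrates follows
from the single-substrate rates alone:

    S = Σᵢ λᵢ / (1 − λᵢ/λ_C),        λ_mix = S / (1 + S/λ_C)

with no adjustable parameters. λ_C acts as a "speed limit": λ_mix is always
below λ_C and below λ₁ + λ₂. The package is for quantitative microbial
physiologists and modellers who want to use this null model, test data
against it, or flag substrate pairs whose deviations reveal extra
regulation (inducer exclusion, metabolic feedback).

It provides the model primitives, the published single-/mixed-substrate
growth-rate table as a built-in dataset, the validation pipeline
(predictions, measured-vs-predicted regression, exact Mann–Whitney
comparison of substrate groups), C-line fitting with bootstrap confidence
intervals for λ_C, and a synthetic-study generator for parameter-recovery
work.

## Worked example

```r
library(crpgrowth)

# predicted growth rate on succinate (0.46/h) + pyruvate (0.61/h)
compose_growth_rates(c(0.46, 0.61))
#> [1] 0.7406573        # measured: 0.71/h

report <- run_full_analysis(builtin_table1())
report
#> <prediction_report> 22 pairs, lambda_C = 1.16/h, deviations / predicted
#> Group A OLS measured ~ predicted (n = 15)
#>   slope  0.9912  [0.8111, 1.1713] 95% CI
#>   offset 0.0029  [-0.1465, 0.1522] 1/h
#>   R^2    0.9158
#> Group deviations: A 2.6% (n = 15), B 11.8% (n = 7)
#>   Mann-Whitney U = 0, two-sided p = 1.17e-05 (exact)
#> checks: speed_limit=TRUE, sub_additive=TRUE, uptake_reduced_group_A=TRUE
```

Reading the numbers: for the 15 group-A pairs (a glycolytic "upper"
substrate with a TCA-entry "lower" substrate) the measured mixed rates fall
on the diagonal against the zero-parameter predictions — slope ≈ 1, offset
≈ 0, R² = 0.92 — with a mean relative deviation of 2.6%, i.e. at the
~5% replicate-noise scale. The 7 group-B pairs (glucose or glycerol with
another upper substrate, where inducer exclusion / FBP feedback act outside
the null model) deviate four-fold more (11.8%), and the exact rank test
shows the two deviation samples are cleanly separated (U = 0,
p = 2/C(22,7) ≈ 1.2 × 10⁻⁵). `write_prediction_report(report, "out/")`
serializes the per-pair records (`predictions.csv`) and the statistics
(`report.json`).

Estimating λ_C instead of assuming it:

```r
fit_cline(generate_cline_points(n = 20, noise_cv = 0.05, seed = 7),
          n_boot = 1000)
#> C-line fit (n = 20)
#>   e0          1027
#>   slope       -880.9
#>   lambda_C    1.1659 1/h
#>   R^2         0.9857
#>   95% CI      [1.1499, 1.1910] (bootstrap)

recover_lambda_c(builtin_table1(), n_boot = 1000)   # exploratory, growth data only
#> lambda_C recovered from 15 group-A pairs: 1.1448 1/h (SSE 0.00986)
#>   95% bootstrap CI [1.0918, 1.2017]
```

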