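# fetalface

Tools for analysing the developmental complexity of coded fetal facial
movements from 4-D ultrasound observation sessions.

## The problem

Frame-by-frame coding of fetal ultrasound scans yields timestamped onsets of
19 elementary facial movements (a fetal adaptation of the Facial Action
Coding System). Six of them — Brow Lowerer, Nose Wrinkle, Upper-Lip Raiser,
Nasolabial Furrow, Lips Parting, Mouth Stretch — make up the
**pain/distress gestalt**, a configuration an observer would read as a pain
or distress face (a statement about appearance, not felt experience). The
scientific question is developmental: as gestation advances from 24 to 36
weeks, do more distinct movements co-occur, and does the gestalt become more
complete?

`fetalface` implements the analysis chain for a longitudinal design of 15
fetuses observed at ~24/28/32/36 weeks with 600 s of codable scan per
session:

1. **Event coding** — movements whose onsets lie within 1 s of one another
   (single-linkage chaining by default) form a *co-occurrence event*; an
   event's complexity is its number of distinct codes, scored over all 19
   codes and over the 6 gestalt codes. Events are tabulated into ordinal
   category counts (single, double, triple, ... ) by session or pooled by
   gestational age.
2. **Reliability** — Cohen's kappa between two coders after aligning their
   streams on 1-s presence/absence bins per code.
3. **Ordinal model** — a from-scratch maximum-likelihood fit of the
   random-intercept proportional-odds model

   logit P(Y ≤ j) = α_j − (β₁·age + β₂·male + u_i),  u_i ~ N(0, σ²),

   using adaptive Gauss–Hermite quadrature for the per-fetus random
   intercept, analytic score, likelihood-ratio tests of nested models, and
   typical-fetus (u = 0) trajectory prediction. β₁ is the speed of
   progression toward more complex expressions per gestational week.
4. **Synthetic data** — a seeded generator that emulates the study design
   (sample sizes, per-age event totals, published fitted parameters as
   generative truth), so the entire pipeline is testable with no external
   data, and an annotation-stream inverse for exact round-trip tests.
5. **Pipeline** — `run_analysis()` goes from an annotations CSV to count and
   percentage tables, fits, LRTs and trajectories with deterministic
   formatting; `inst/scripts/run_analysis.R` is a thin command-line wrapper.

## Worked example

```r
library(fetalface)

design <- simulation_design(scheme = "gestalt", seed = 42) # study conditions
sim    <- simulate_counts(design)   # 15 fetuses x 4 sessions, known truth
fit    <- fit_clmm(sim$counts)      # random-intercept proportional-odds fit
fit
#> Random-intercept proportional-odds fit (5 categories)
#>   2205 events in 60 sessions from 15 fetuses; 21 GH nodes
#>   log-likelihood -2301.840  (converged)
#>      term estimate std.error statistic   p.value
#>   alpha_1   5.9787   0.35933        NA        NA
#>   alpha_2   7.6582   0.37531        NA        NA
#>   alpha_3   9.7665   0.39790        NA        NA
#>   alpha_4  12.7721   0.59166        NA        NA
#>  beta_age   0.2085   0.01082     19.28 8.486e-83
#>    sigma2   0.3903   0.15344        NA        NA
#>   random-intercept variance sigma2 = 0.3903
```

The generating truth was β₁ = 0.1965, σ² = 0.392: one simulated study of
~2,200 gestalt events recovers the age slope to about one standard error
(0.2085 ± 0.011) and the variance almost exactly. The age effect is
overwhelming by likelihood ratio:

```r
lrt(fit, fit_clmm(sim$counts, include_age = FALSE))
#> # A tibble: 1 × 3
#>   statistic    df  p_value
#>       <dbl> <int>    <dbl>
#> 1      412.     1 1.33e-91
```

and the fitted typical-fetus trajectory shows single-movement events
declining (0.73 → 0.18 between 24 and 36 weeks) while triples rise
(0.06 → 0.37):

```r
fitted_trajectory(fit, ages = c(24, 28, 32, 36))
#> # A tibble: 4 × 6
#>     age cat_1 cat_2  cat_3   cat_4    cat_5
#> 1    24 0.726 0.208 0.0573 0.00806 0.000423
#> 2    28 0.535 0.326 0.120  0.0183  0.000974
#> 3    32 0.333 0.395 0.229  0.0412  0.00224
#> 4    36 0.178 0.359 0.368  0.0894  0.00515
```

`autoplot(fit)` draws the trajectory; `tidy(fit)` and `glance(fit)` give the
broom-style summaries. See the vignette in `vignettes/` for the model,
its assumptions and the numerical choices.

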