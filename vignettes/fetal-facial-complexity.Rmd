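---
title: "Modelling the developmental complexity of fetal facial movements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the developmental complexity of fetal facial movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalface)
library(dplyr)
```

## The scientific question

Healthy fetuses move their faces. Frame-by-frame coding of 4-D ultrasound
scans can resolve those movements into 19 elementary facial actions
(a fetal adaptation of the Facial Action Coding System), and a longitudinal
design — 15 fetuses (8 girls, 7 boys), each observed for 600 seconds of
codable scan at roughly 24, 28, 32 and 36 weeks gestation — asks whether
facial movements become more *coordinated* with maturation: do more distinct
movements co-occur as gestation advances? A designated subset of six
movements (Brow Lowerer, Nose Wrinkle, Upper-Lip Raiser, Nasolabial Furrow,
Lips Parting, Mouth Stretch) forms the "pain/distress gestalt": a
configuration an observer would read as a pain or distress face. The term is
deliberately about appearance, not experience.

This package implements the full analysis chain for that question on coded
annotation streams: event coding, reliability, ordinal modelling, and a
synthetic-data generator that makes every step testable without access to the
original recordings (which were never deposited).

## Event coding

Coders produce timestamped onsets of movement codes. Two movements
*co-occur* when their onsets lie within one second of one another. Because
"within one second of one another" is ambiguous for more than two movements,
the package reads it, by default, as **single-linkage chaining**: annotations
belong to the same co-occurrence event whenever they are connected by a chain
of consecutive onset gaps each at most 1 s. Coded movements are point events
in a frame-by-frame scheme, so chaining is the natural closure of the
pairwise relation; the alternative reading — a fixed 1-s window anchored at
the event's first movement — is available as `rule = "anchor"` in
`cluster_events()`. Gap comparisons carry an absolute tolerance of 1e-9 s so
a gap of exactly one second cannot flip with floating-point representation.

An event's **complexity** is the number of *distinct* codes among its
members — a repeated Lips Parting within one event does not make the facial
configuration more complex. Complexity is computed twice: over all 19 codes,
and over the six gestalt codes only. For the gestalt analysis, events are
clustered over *all* annotations first and then scored on their gestalt
members; events with no gestalt movement are dropped. This ordering (cluster
everything, then subset) rather than the alternative (cluster gestalt
annotations only) is the package default because it preserves the physical
event structure — a gestalt movement embedded in a larger burst belongs to
that burst — and it is what makes gestalt table totals strictly smaller than
all-movement totals, as the published tables show. Both readings are
implementable with the exposed primitives; only the default is wired into
`tabulate_counts()`.

Complexities map onto ordinal response categories: single, double, triple,
quadruple, quintuple, "sextuple or more" (6 categories over all codes; the
observed maximum was 7 distinct movements) and single through "quintuple or
more" (5 categories for the gestalt, which has only 6 possible members).
Percentages are reported rounded half-up to one decimal, matching the
published tables — `round_half_up` exists because base `round()` rounds half
to even and visibly disagrees with the printed values.

Onset times live on the *accumulated codable time* axis: coding pauses while
the face is not visible, so a pause must not split or merge events. Streams
annotated in raw recording time can be rebased with `rebase_onsets()` given
the visible segments.

## Inter-rater reliability

About a third of sessions were independently re-coded in the original
design. The original report does not state how the two coders' streams were
aligned before computing Cohen's kappa, so the package makes the rule
explicit and configurable: the session timeline is cut into 1-s bins (the
same constant as the co-occurrence window) and each bin is scored
present/absent per movement code per coder. Kappa is then the standard
chance-corrected agreement on the resulting 2x2 table, summarised as an
unweighted mean and range over codes, overall and for the gestalt subset.
Codes never marked by either coder have undefined kappa and are excluded
with a warning. Because the alignment rule is a package choice, the
published mean kappa of 0.96 is a plausibility anchor, not a reproduction
target; the dual-coding simulator (`simulate_dual_coding()`) shows that a 5%
miss rate with 0.2-s jitter keeps the mean kappa above 0.85 under this
alignment.

## The ordinal model

The response for one co-occurrence event is its complexity category
$Y_{it} \in \{1, \dots, J\}$ for fetus $i$ at session $t$. The model is a
cumulative-logit (proportional-odds) regression with a per-fetus random
intercept:

$$\operatorname{logit} P(Y_{it} \le j) = \alpha_j - \big(\beta_1 x_{it} + \beta_2\,\mathrm{male}_i + u_i\big), \qquad u_i \sim N(0, \sigma^2),$$

with strictly increasing cutpoints $\alpha_1 < \dots < \alpha_{J-1}$ and
gestational age $x_{it}$ in weeks. The latent-variable sign convention means
a positive $\beta_1$ moves probability mass toward higher complexity as the
fetus matures; $\beta_1$ is the speed of developmental progression on the
cumulative log-odds scale. Females are the baseline for the sex contrast.
Ordinal (rather than linear) regression is used because the steps between
complexity categories need not be equally hard; the random intercept absorbs
stable between-fetus differences (early versus late developers) in a
repeated-measures design. The multinomial has no residual scale parameter,
so within-fetus variability is fixed by the distribution itself.

Session category counts are multinomial given $u_i$, so each fetus
contributes the integral of its multinomial likelihood over $u$. The
marginal log-likelihood is maximised directly:

* **Quadrature.** The $u$-integrals use Gauss–Hermite quadrature with 21
  nodes by default, *adaptively* centred and scaled at each fetus's posterior
  mode and curvature (found by a damped, vectorised Newton iteration; the
  cumulative-logit log-likelihood is concave in $u$). Adaptivity matters
  here: with ~150 events per fetus the posterior for $u_i$ is far narrower
  than its $N(0, \sigma^2)$ prior, and a prior-scaled grid loses roughly
  three to four digits of the log-likelihood, while the adaptive grid is
  stable to well below 1e-6 relative when the node count is doubled. A
  prior-scaled non-adaptive grid remains available (`adaptive = FALSE`).
  At $\sigma^2 = 0$ the likelihood degenerates to the fixed-effects
  multinomial and is evaluated exactly.
* **Optimisation.** BFGS on $(\alpha_1, \log$ cutpoint gaps, slopes,
  $\log\sigma)$ — the reparametrisation enforces increasing cutpoints and a
  non-negative variance — from a deterministic start (pooled empirical
  cumulative logits, zero slopes, $\sigma^2 = 0.1$), with the analytic
  gradient: the score of the marginal likelihood is the posterior-weighted
  expectation of the complete-data score, accumulated over the same
  quadrature grid. Finite-difference gradients proved too fragile on the
  cutpoint/slope ridge; the analytic score is checked against numerical
  differentiation in the test suite.
* **Standard errors.** Central-difference Hessian of the marginal
  log-likelihood at the optimum on the natural scale
  $(\alpha, \beta, \log\sigma)$; the error for $\sigma^2$ is
  delta-transformed. Wald and likelihood-ratio inference for the slopes are
  both available, since which of the two the original report printed for the
  per-coefficient p-value is not stated.
* **Degenerate data.** An ordinal category with zero total count has its
  adjacent cutpoint's MLE at infinity; the fit proceeds with a warning, and
  convergence is judged on the score components of the *identified*
  directions (plus explicit divergence guards: |slope| > 50 or cutpoint
  spread > 100 flags non-convergence). Sessions missing for a fetus — the
  original data have 59 rather than 60 scans — simply contribute nothing,
  with no imputation.

Nested models (no covariates ⊂ age ⊂ age + sex) are compared by
likelihood-ratio tests on an upper-tail $\chi^2$ with the parameter-count
difference as degrees of freedom. `fitted_trajectory()` evaluates the fitted
category probabilities at $u = 0$ across an age grid: the developmental
trajectory of a "typical fetus".

## The synthetic-data generator

`simulation_design()` encodes the study conditions: 15 fetuses, 8 female,
ages 24/28/32/36 weeks, 600 s of codable time per session. Events per
session default to the published pooled event totals divided by the 15
fetuses — 38/47/36/26 per session at the four ages for the gestalt scheme,
58/69/53/44 for all movements. The generative truth defaults to the
published fitted values ($\beta_1 = 0.1965$, $\sigma^2 = 0.392$ gestalt;
$\beta_1 = 0.2283$, $\sigma^2 = 0.417$ all movements) with cutpoints
calibrated so the model at the mid-study age of 30 weeks reproduces the
pooled observed category marginals. `simulate_counts()` draws $u_i$, then
session counts multinomially — exactly the generative direction of the
fitted model, so fitting simulated data is a genuine parameter-recovery
experiment.

`simulate_stream()` inverts event coding: each event of complexity $k$
receives $k$ distinct codes, within-event onsets are chained 0.3 s apart and
events are separated by 1.5 s — strictly beyond the 1-s window so that
round-trip tests (`simulate_stream()` then `cluster_events()` then
`tabulate_counts()`) are exact by construction and never sit on the window
boundary; boundary behaviour is tested separately and deliberately in the
event-coding tests. Code identities are sampled uniformly from the eligible
pool, a declared simplification: real per-code base rates were not
published.

What the generator does *not* emulate: per-code frequency structure,
within-session temporal clustering beyond the event definition, drifting
event rates within a session, coder-specific biases, or the single missing
24-week scan (unbalanced data are unit-tested separately). Passing
recovery tests therefore validate the estimation machinery under the stated
model, not the model's adequacy for real scans.

## Numerical and design choices worth knowing

* Ages enter in raw weeks; estimates are invariant to centring (the
  cutpoints absorb any shift).
* Age bins snap recorded ages to the nearest nominal week (24/28/32/36);
  anything further than 2 weeks from every nominal age is an error rather
  than a silent assignment.
* 21 quadrature nodes is deliberately conservative for a single scalar
  random effect; the node-doubling stability check is part of the test
  suite.
* Replicated simulation studies in the tests use 50 replicates at the study
  design for slope recovery and 200 replicates for null calibration of the
  sex-effect LRT; a single study-scale fit takes well under a second.

## Known limitations

* **Small-cluster inference.** With 15 fetuses, the likelihood-ratio test
  for a *between-fetus* covariate (sex) is anticonservative: under a true
  null at the study design its statistic averages roughly twice the
  $\chi^2_1$ mean and rejects at about 15–20% instead of 5%. The package's
  calibration test therefore runs at a 120-fetus design, where the rejection
  rate returns to the nominal level (~2–5%). Sex-effect p-values at the
  study scale should be read with that caveat; the age effect, identified
  within fetuses with thousands of events, is unaffected in practice.
* ML (not REML-like) estimation of $\sigma^2$ carries the usual downward
  small-sample bias with 15 clusters.
* The coder-alignment rule for kappa is a package convention; reported
  kappas are comparable within this package, not necessarily to values
  computed under a different alignment.
* The published per-fetus raw data are unavailable, so the published
  estimates are reproduced in distribution (simulation recovery), not
  numerically from the original scans.

## A complete run

```{r pipeline, eval = FALSE}
design <- simulation_design(scheme = "gestalt", seed = 42)
bundle <- simulate_annotations(design)
readr::write_csv(bundle$annotations, "annotations.csv")

report <- run_analysis(list(
  input = "annotations.csv",
  out_dir = "report",
  schemes = c("all", "gestalt")
))

report$gestalt$fits$age |> glance()
autoplot(report$gestalt$fits$age)
```

The same run is available from a shell via the thin wrapper
`inst/scripts/run_analysis.R`.
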