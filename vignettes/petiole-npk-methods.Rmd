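---
title: "Methods: yield-graded petiole NPK monitoring and optimized neural yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: yield-graded petiole NPK monitoring and optimized neural yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petiolenpk)
library(dplyr)
```

This vignette documents the models behind `petiolenpk`, the assumptions
they make, the choices taken where the underlying survey methodology left
the design open, and what the package's synthetic data can and cannot
show about real cotton fields.

## The monitoring model

Fields are graded into two yield classes at 6000 kg/ha of seed cotton
(`LOW`: 4800–6000 kg/ha, `HIGH`: 6000–7100 kg/ha). The monitor system is
deliberately simple: for each growth stage (full bud, full bloom, full
boll), yield class and analyte (NO₃⁻–N, PO₄³⁻–P, K⁺–K in petiole sap,
mg/L), the sufficiency interval is the observed `[min, max]` of the valid
survey fields in that cell. `build_grade_table()` implements exactly this
construction and `default_grade_table()` applies it to the reference
descriptive statistics shipped with the package.

Two design points needed a decision:

* **Interval endpoints.** Both endpoints are treated as closed; a value
  on a shared boundary belongs to both classes. The neighbouring-class
  intervals genuinely overlap (e.g. full-bud NO₃⁻–N spans 7000–9500 for
  `LOW` and 9000–11000 for `HIGH`), so a decision rule is unavoidable.
* **Classification rule.** `classify_sample()` lets each analyte vote for
  every class whose interval contains it; the aggregate class is the
  majority, and ties resolve to `LOW`. The conservative tie-break avoids
  over-stating a field's yield potential, which in practice would mean
  under-fertilising relative to need rather than over-promising. A sample
  with any analyte outside both intervals is reported `out_of_range`, and
  `undetermined` when all three are.

The rule is monotone by construction: raising an analyte from below an
interval into it can only add that class to the analyte's compatible set
(a property test exercises this on random probes).

## The synthetic survey generator

No field data are distributed, so `generate_fields()` draws surveys with
the same statistical skeleton: 30 `LOW` + 50 `HIGH` survey fields and 20
independent validation fields, the latter from `HIGH`-class parameters
because the validation fields' fertilisation matches the high-yield
survey management.

Within a class the joint model is a Gaussian copula:

* **Marginals** are normal distributions truncated to the published
  `[min, max]`, with the published mean and SD as the *underlying*
  normal parameters. Only moments and extrema are known, and yield is
  reported to be normally distributed, so a truncated normal is the
  minimal model honouring all four numbers. Note that truncation shrinks
  the realised SD below the underlying parameter — with bounds ~1.5–2 SD
  from the mean the truncated SD is roughly 20–25% smaller. This is a
  property of *any* distribution confined to the published ranges (even
  the uniform limit cannot reach the published SDs), so generator
  fidelity is asserted against the truncated distribution's own moments,
  computed independently by numerical integration in the test suite.
  Sample moments at n = 5000 per class agree with that oracle within
  ±3% (mean) / ±6% (SD).
* **Dependence** uses the yield's latent normal score as a single common
  factor: each nutrient's latent score correlates with it at
  `2 sin(π r / 6)`, the latent value whose Spearman correlation equals
  the target `r`. Rank-based targeting survives the monotone truncation
  and quantization transforms; the empirical Pearson correlation lands
  within ±0.05 (typically ±0.01) of the target at n = 5000. The
  one-factor structure also guarantees a positive-definite latent
  correlation matrix for any targets in `[0, 1)`. Six targets are
  published (0.93, 0.85, 0.92, 0.87, 0.90, 0.81 in their stage × analyte
  × class cells); the remaining twelve default to 0.80, consistent with
  the reported "significant positive correlation in every cell", and can
  be overridden in a YAML spec file.
* **Quantization** rounds NO₃⁻–N and K⁺–K to the nearest 100 mg/L and
  PO₄³⁻–P to the nearest 5 mg/L, inferred from the granularity of the
  published extrema; it is on by default and optional.
* **Abnormal fields.** `inject_outliers()` flags `floor(0.2 n)` records
  (mirroring 20 of 100 raw fields excluded) and replaces their yield
  with `class mean ± (3 + U(0,1)) × class SD`, leaving nutrients
  untouched, so the flagged fields deviate grossly from the
  nutrient–yield fit while remaining plausible readings analyte-wise.
  The displacement mechanism is invented; the survey only states that
  abnormal points deviated from the fit.

**What the generator does not emulate.** Real petiole surveys have
within-field replication (multiple sampling points and leaves per field),
spatial and site effects across growing regions, year effects, non-normal
tails, and heteroscedastic instrument error; none of these are modelled.
Passing tests therefore demonstrate that the pipeline's statistics and
models behave correctly under the stated marginal/correlation structure —
not that the published field-data results are recoverable. In particular,
the pooled 80-field yield sample is a mixture of two truncated normals
about 3 SD apart and is *not* consistent with a single normal
distribution (Shapiro–Wilk rejects it), whereas each class on its own
usually is; the published normality claim concerns the raw one-sample
survey that the two-class generator does not represent.

## Abnormal-sample screening

`filter_abnormal()` regresses yield on the three same-stage
concentrations per class by OLS and removes fields with any
externally-studentized residual above 2 in magnitude. No screening
threshold was published; |r*| > 2 is the common field-data convention.
One pass is not enough at 20% contamination: gross outliers inflate the
residual scale and mask one another, so the screen refits once after the
first removal round (two passes by default). On injected outliers this
recovers ≈99% of flagged fields while removing ≈2–3% of clean ones (test
suite, 10 seeds); iterating to convergence was rejected because
sequential deletion at a fixed quantile cascades and strips half the
clean sample.

## The prediction model

`bp_config()` fixes the published architecture and training settings:
3–10–1 network, learning rate 0.01, 200 full-batch iterations. Points the
description left open:

* **Activations**: tanh hidden layer, linear output — the conventional
  choice for small regression networks of this era and toolchain.
* **Scaling**: inputs and target are min-max scaled to `[-1, 1]` (fitted
  on training data), keeping tanh inputs in range; yield is converted to
  t/ha before scaling so inverse-scaled predictions and error metrics
  come out in t/ha.
* **Objective scaling**: descent is on the *mean* squared error in
  scaled space rather than the raw half-sum. The objectives differ only
  by a constant factor, and the mean convention is what makes the
  published learning rate of 0.01 a stable step size at n = 80; with a
  sum-scaled gradient the same rate oscillates.
* **No momentum, no early stopping, no internal validation split**: only
  the learning rate and iteration count were specified, so nothing else
  is added. Exactly 200 updates run; `loss_history` records the
  objective after each.
* **Initialisation**: uniform on `[-1, 1]` under a seed — the same box
  the metaheuristics search, so plain and optimized networks start from
  comparable regions.

Analytic gradients are verified against central finite differences
(ε = 1e-6) to a relative error below 1e-6 over 20 random networks;
training is bit-for-bit reproducible under a seed, and a non-finite loss
aborts with the offending epoch named.

## The metaheuristic initialisers

Both optimizers search the 51-dimensional flat weight vector
(`bp_encode()` layout: input→hidden weights row-major, hidden
thresholds, hidden→output weights, output threshold) over `[-1, 1]` with
population 20 and 20 iterations, minimising the *untrained* network's
training RMSE in scaled space. Optimising the initial state rather than
the post-training error keeps the 420-evaluation budget cheap and matches
the role of the optimizer as a supplier of initial weights; the fitness
closure is swappable for anyone wanting the expensive variant.

The published description names the algorithms without restating their
update equations, so the canonical forms are used:

* **GWO**: agents move to the mean of three encircling moves around the
  α, β, δ leaders, `X_l − A |C X_l − X|`, with `A = 2 a r₁ − a`,
  `C = 2 r₂` per dimension and `a` decreasing linearly 2 → 0.
* **SSO**: ranked producers (top 20%) forage multiplicatively
  (`X e^{−rank/(α T)}`) under a calm alarm (`R₂ < 0.8`) or take a unit
  normal step; scroungers follow the best producer or, in the worse
  half, flee the worst position; 10% random scouts step toward the
  global best (or jitter relative to the worst when already best).
  Producer/scout fractions and the safety threshold are the original
  algorithm's defaults (0.2 / 0.1 / 0.8).

Positions are clipped to the bounds. SSO accepts moves greedily (an
agent keeps its old position unless the move improves its fitness); GWO
follows its canonical unconditional update, with the best-ever solution
tracked separately. Both conventions make the best-so-far trace monotone
non-increasing, which every run asserts. On the 51-D sphere both beat
the mean of a random population by far more than 100×; SSO's margin is
astronomically large there because its multiplicative contraction pulls
straight toward the origin — the sphere's optimum. That same bias is
only sometimes the right prior for network weights, which is why SSO's
per-seed advantage over plain BP on validation R² fluctuates more than
GWO's even though both dominate on average.

## Evaluation protocol

`run_protocol()` fits each method per stage on all retained survey
fields and evaluates R², RMSE and MAE (t/ha) on the survey ("modeling")
and independent validation splits — the 80/20 layout under default
counts. Modeling metrics are training-set metrics by design: the
protocol uses a fixed independent validation set, not a random split.
Within a stage the methods share seeds, so comparisons are paired.
Presentation rounding is 2 decimals for metrics and 1 for percentages;
computation keeps full precision. `relative_change_table()` reproduces
every percentage-improvement figure derivable from the reference
comparison table exactly.

Two small inconsistencies in the reference tables are worth knowing:
two of the twenty printed CVs (full-bloom NO₃⁻–N low grade, printed 9.5;
full-boll NO₃⁻–N high grade, printed 12.9) disagree by 0.1 with the CV
recomputed from their own printed mean and SD (9.4, 12.8) — presumably
rounding from unrounded intermediates. The package reports what its own
definition (100·SD/mean, one decimal) computes.

## Problem sizes and determinism

The test suite and acceptance script run the generator at up to 5000
fields per class for fidelity checks, 10-seed replicates for every
stochastic property, 200-iteration optimizer runs for the benchmark
checks, and the full 80 + 20 protocol for the end-to-end comparison;
the whole suite completes in well under a minute on one core. Every
random draw flows from an explicit seed (generator spec, network config,
optimizer config, protocol base seed), and regeneration, training,
optimization and the full `run_all()` artifact bundle are byte-identical
under a fixed configuration.

## Known limitations

* The sufficiency intervals inherit the survey's empirical extrema; they
  are descriptive ranges, not causal fertiliser recommendations.
* The generator's truncated marginals cannot reproduce the published SDs
  exactly (see above); fidelity is defined against the truncated model.
* With 80 training fields and a fixed 200-step descent, absolute model
  accuracy depends strongly on the draw; the package's claims about the
  optimized variants are ordinal (they match or beat plain BP), not
  absolute reproductions of the reference metric values, which were
  computed on the unreleased field data.
* PO₄³⁻–P readings in the hundreds of mg/L exceed the nominal range of
  the reflectometric instrument they would be measured with; sample
  dilution is assumed and not modelled.
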