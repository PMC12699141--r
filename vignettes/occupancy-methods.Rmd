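---
title: "Occupancy estimation for camera-trap surveys: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy estimation for camera-trap surveys: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

camtrapocc estimates how often an elusive species uses survey sites when
every visit can miss it. This vignette describes the statistical model,
the decisions baked into the implementation, and what the synthetic-data
generator can and cannot tell you about real surveys.

## The model

Each of $n$ camera stations is surveyed on $J$ repeat occasions (here,
blocks of consecutive trap-days). Site $i$ is occupied with probability
$\psi_i$; conditional on occupancy, each occasion detects the species with
probability $p_i$. With detection history $y_{i1},\dots,y_{iJ}$ the
single-site likelihood is the zero-inflated binomial

$$L_i = \psi_i \prod_{j \in \text{surveyed}} p_i^{y_{ij}}(1-p_i)^{1-y_{ij}}
      \;+\; (1-\psi_i)\, \mathbf{1}\{\text{all } y_{ij} = 0\},$$

i.e. an all-zero history is ambiguous between "present but missed every
time" and "absent". Both probabilities take logit-linear covariates:
$\mathrm{logit}(\psi_i) = x_i^\top\beta_\psi$,
$\mathrm{logit}(p_i) = w_i^\top\beta_p$. The logit link is the standard
choice; no other link is implemented.

Assumptions: (1) closure — the occupancy state does not change across the
$J$ occasions; (2) no false positives — a detection always reflects
presence; (3) independence across sites. Detection covariates are
site-level habitat descriptors, constant over occasions; occasion-varying
detection covariates are out of scope. A practical consequence is that the
per-site likelihood depends on the data only through the number of
detections and the number of surveyed occasions, which makes one
likelihood evaluation $O(n)$ and keeps the replicate studies in the test
suite cheap.

Missing cells (occasions where the camera was not deployed) simply drop
out of the detection product — the usual missing-at-random treatment.

## From photos to histories

`build_detection_matrix()` partitions each site's deployment into
consecutive occasions of `occasion_length` days (default 4), anchored at
that site's own start date. Deployments in the emulated study span many
years and areas, so a shared calendar grid would be meaningless. Two
boundary decisions are deliberate and documented rather than universal:

* an occasion during which the camera was active for at least one day
  counts as surveyed (0/1), not missing — conservative use of effort;
* a deployment not divisible by the occasion length keeps its final,
  shorter occasion (flagged in the `anchors` metadata) rather than
  discarding those trap-days.

`independent_detections()` collapses same-site photos separated by less
than a configurable window (default 60 minutes). The occupancy pipeline
itself consumes only occasion-level 0/1 records, so this choice affects
reported detection totals, never the estimates.

## Covariate preparation

Covariates are z-scored (sample SD, $n-1$) so effect sizes are comparable;
the centers and scales are kept as attributes for back-transformation.
Collinearity is pruned by repeatedly dropping the lower-priority member of
the most-correlated pair until all pairwise $|r| \le 0.7$ — strictly
greater than the threshold is required to drop, so a pair at exactly 0.7
survives. The priority order defaults to column order and is
user-configurable; greedy pruning is used because the exhaustive
largest-subset search is exponential, and the test suite checks the greedy
result against a brute-force oracle on small chain-correlated cases.
Pearson $r$ is affine-invariant, so pruning before or after z-scoring
gives the same covariate set (also a test).

## Fitting and model selection

`occu_fit()` minimizes the negative log-likelihood with BFGS from an
all-zero start (equivalent to $\psi = p = 0.5$ at an average site, which
is why standardized covariates matter), with one restart from the naive
occupancy/detection logits if needed. Convergence requires the optimizer
to report success *and* a small numerical gradient norm (relative
tolerance $10^{-4}$ on the objective scale — tighter absolute thresholds
are not meaningful with finite-difference gradients on a likelihood of
several hundred units). The covariance matrix is the inverse observed
information; fits whose linear predictors run to the $\pm 12$ logit range
(fitted probabilities at the 0/1 boundary, e.g. every site detected on
every occasion) or whose information matrix is singular are flagged and
excluded from model sets.

`enumerate_model_specs()` builds the exhaustive set: every subset of
occupancy candidates crossed with every subset of detection candidates,
$2^{|\psi|} \cdot 2^{|p|}$ models, with a budget guard (default 20 000)
and an optional per-submodel term cap. Models are ranked by AICc with the
number of *sites* as the effective sample size — the alternative
(site × occasion) convention can be obtained by calling `aicc()` directly,
but sites is the default because each site contributes a single
(correlated) history. Ties in AICc are broken by fewer parameters, then
label, which affects only table order.

The confidence set keeps models with $\Delta\mathrm{AICc} < 2$ (strict)
and renormalizes weights over its members, while preserving the
full-set weights in `weight_all`; published model tables normalize weights
over the full set, which is why printed weights can be small even for the
best model. `model_average()` defaults to shrinkage averaging — a model
omitting a term contributes a zero estimate — which is unbiased toward
zero for weak effects; conditional averaging over only the containing
models is available via `method = "conditional"`. The unconditional
standard error adds between-model spread to the within-model variance.
Averaged probability predictions are weighted means on the probability
scale with intervals built on the logit scale around the averaged point,
so a single-member set reproduces `predict()` exactly and bounds stay in
$[0,1]$.

## Goodness of fit and validation

The Pearson $X^2$ compares observed detection-history frequencies with
model expectations. Sites are grouped into cohorts sharing a missingness
pattern, and fitted probabilities are averaged within a cohort — a
documented approximation under which a history's probability depends only
on its detection count. Because total expected mass in a cohort equals the
cohort size, the contribution of all never-observed histories is available
in closed form and the $2^J$ enumeration never materializes; the
implementation is exact under the cohort approximation for any $J$ and is
tested against full enumeration on small examples.

`bootstrap_gof()` simulates replicate datasets from the fitted model,
refits, and recomputes $X^2$; the overdispersion factor is
$\hat{c} = X^2_{\text{obs}} / \overline{X^2_{\text{boot}}}$ and the
p-value is the bootstrap tail share. When $\hat c > 1$, `adjust_se()`
scales the covariance by $\hat c$ (standard errors by $\sqrt{\hat c}$);
$\hat c \le 1$ is left alone, so the adjustment is deliberately one-sided
and not invertible. Defaults: $B = 500$ replicates for inference (the
pipeline default of 200 is a pragmatic compromise), seeds mandatory.

`cross_validate()` partitions *sites* (never occasions) into $k = 5$
folds by default. Held-out cells are predicted by the unconditional
probability $\hat\psi_i \hat p_i$ — the marginal chance of a 1 in any
cell — because the validation outcome is the raw cell, whose distribution
mixes over the latent state; a conditional variant ($\hat p_i$ alone) is
exposed for users who want detection-only error. Folds whose training
half has no detections are skipped with a warning and reported.

## Survey design

The cumulative probability of at least one detection in $K$ surveys is
$p^* = 1 - (1-p)^K$ (product form $1 - \prod_j (1 - p_j)$ for
occasion-varying detection). `p_star_curve()` propagates the uncertainty
of the baseline $p$ by the delta method,
$\mathrm{SE}(p^*) = K(1-p)^{K-1}\mathrm{SE}(p)$, with intervals truncated
to $[0,1]$ — matching the symmetric error bars conventionally drawn on
effort curves. Known limitation: the first-order band degenerates faster
than a parametric bootstrap as $p^*$ approaches 1 (for $p \approx 0.46$
both bands are narrower than 0.01 beyond ten surveys, but their ratio is
no longer close to one); near the asymptote the interval should be read
as "indistinguishable from 1", not as a calibrated width. In the fitted
detectability regime ($p \approx 0.46$) the curve exceeds 0.999 by 12–15
surveys, which is the quantitative basis for 60-day deployments at 4-day
occasions.

## The synthetic-data generator

`simulate_camtrap()` draws covariates from a multivariate normal
(exchangeable correlation 0.3 among land-cover proportions by default —
plausible landscape autocorrelation — configurable up to deliberately
collinear pairs for testing the pruning path), z-scores them, then draws
latent states and histories from the model above and scatters photo
records uniformly within detected occasions. `tapir_scenario()` is the
calibrated reference design: 380 sites, fifteen 4-day occasions, four
habitat covariates with occupancy effects (+0.334, +0.232, −0.100,
−0.354) and positive detection effects of dense forest and pasture. Its
intercepts (−0.4706, −0.2485) were fixed once by Monte-Carlo root-finding
(`tools/calibrate-intercepts.R`) so the expected naive occupancy is 0.392
and expected detectability 0.46, and are not revisited.

`inject_overdispersion()` adds a site-level normal random effect to the
detection logits and regenerates histories, keeping the latent states —
extra-binomial noise the binomial model cannot absorb, for exercising the
$\hat c > 1$ path.

What the generator does *not* emulate: spatial autocorrelation between
sites, diel activity, occasion-varying effort or weather, multi-year
dynamics, false positives, and unmodeled covariate nonlinearity. Green
tests therefore certify the estimator's internal consistency and its
calibration *under the model's own assumptions*, not robustness to their
violation — with one deliberate exception, the overdispersion injection
above.

A statistical limit worth stating plainly: with 380 sites, the sampling
SE of a standardized occupancy coefficient is about 0.12, so an effect of
magnitude 0.10 (the pasture effect in the reference scenario) has only
$\Phi(0.10/0.12) \approx 0.79$ probability of being sign-recovered in any
one replicate. Weak effects at this design size are directional evidence,
not reliably recoverable signs; the test suite measures this directly.

## Problem sizes used in the tests

The replicate studies run at 200 replicates (sign recovery at $n = 380$,
coverage at $n = 500$), the GOF calibration at $B = 500$, $n = 300$, and
the overdispersion detection at five replicate datasets of $B = 60$;
these sizes give binomial margins comfortably inside the asserted bands
while keeping the default suite quick on a single CPU.

## Pipeline determinism

`run_occupancy_pipeline()` derives all stage seeds from the single
configured seed, and every report it writes (model tables, estimates,
assessment, detection curve) is byte-identical across reruns with the
same configuration; only the run manifest and log carry wall-clock
timings. The pipeline is, by construction, a pure function of
(inputs, configuration, seed).
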