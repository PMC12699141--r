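# camtrapocc

Single-season occupancy analysis for camera-trap surveys of elusive
wildlife — detection-history construction, covariate preparation,
maximum-likelihood occupancy models with imperfect detection, exhaustive
AICc multimodel inference, goodness-of-fit and cross-validation
assessment, and cumulative-detection survey design.

## The problem

Camera-trap surveys of rare, wide-ranging species (the motivating case is
the lowland tapir across heterogeneous tropical landscapes) record the
species at only a fraction of visited sites, and a site with no photos may
be unoccupied *or* occupied-but-missed. The package separates those two
possibilities with the closed single-season occupancy model: site *i* is
occupied with probability ψᵢ, and each of *J* repeat survey occasions
detects the species with probability pᵢ given occupancy, so a detection
history **y**ᵢ has likelihood

```
L_i = ψ_i ∏_j p_i^{y_ij} (1 − p_i)^{1 − y_ij}  +  (1 − ψ_i) · 1{all y_ij = 0}
```

with logit-linear habitat covariates on both ψ and p. Around that core the
package implements the full working pipeline an occupancy analyst needs:

* `build_detection_matrix()`, `independent_detections()`,
  `naive_occupancy()` — timestamped photos + deployment periods →
  site × occasion 0/1/NA histories (fixed-length occasions, per-site
  anchoring);
* `standardize_covariates()`, `prune_correlated()` — z-scores and
  |r| > 0.7 collinearity pruning with a drop log;
* `occu_fit()`, `predict()`, `tidy()`, `glance()`, `autoplot()` — BFGS
  maximum likelihood, Wald inference, broom-style accessors;
* `enumerate_model_specs()`, `fit_models()`, `confidence_set()`,
  `model_average()`, `average_predictions()` — exhaustive covariate
  combinations, AICc/ΔAICc/Akaike weights, ΔAICc < 2 confidence sets,
  shrinkage model averaging with unconditional SEs;
* `pearson_chi2()`, `bootstrap_gof()`, `adjust_se()`,
  `cross_validate()` — parametric-bootstrap goodness of fit, ĉ
  overdispersion adjustment, site-level k-fold CV;
* `p_star()`, `p_star_curve()`, `required_surveys()` — survey-effort
  analysis via p\* = 1 − (1 − p)^K;
* `simulate_camtrap()`, `tapir_scenario()`, `inject_overdispersion()` — a
  calibrated synthetic-data generator so the whole pipeline is testable
  end-to-end without field data;
* `run_occupancy_pipeline()`, `validate_run_config()` — one-call
  orchestration with deterministic, machine-readable reports.

## Worked example

Simulate a survey with the statistical structure of a large multi-area
tapir study (380 sites, fifteen 4-day occasions, four standardized habitat
covariates), then fit and average the exhaustive model set:

```r
library(camtrapocc)

sim <- simulate_camtrap(tapir_scenario(), seed = 42)
sim$matrix
#> <detection_matrix> 380 sites x 15 occasions (4-day)
#>   naive occupancy: 0.4; surveyed cells: 5700

set <- fit_models(
  enumerate_model_specs(c("forest_d", "crops", "past", "d_streams"),
                        c("forest_d", "past")),
  sim$matrix, sim$covariates)
glance(set)
#> # A tibble: 1 × 5
#>   n_models n_excluded best_model                          best_AICc renormalized
#>      <int>      <int> <chr>                                   <dbl> <lgl>
#> 1       64          0 p(forest_d+past)Psi(forest_d+crops…     3586. FALSE

top <- confidence_set(set)   # ΔAICc < 2, weights renormalized
model_average(top)
#> # A tibble: 6 × 6
#>   submodel  term      estimate std.error n_models weight_sum
#>   <chr>     <chr>        <dbl>     <dbl>    <int>      <dbl>
#> 1 occupancy forest_d    0.267     0.115         2      1
#> 2 occupancy crops       0.246     0.115         2      1
#> 3 occupancy d_streams  -0.260     0.110         2      1
#> 4 detection forest_d    0.227     0.0461        2      1
#> 5 detection past        0.284     0.0465        2      1
#> 6 occupancy past        0.0166    0.0471        1      0.285
```

The averaged coefficients are on the logit scale per standard deviation of
each covariate: occupancy rises with dense-forest and crop cover and falls
with distance to streams; the weak pasture effect appears in only one
confidence-set member and is shrunk accordingly. Detection-side estimates
say the species is easier to photograph in dense forest and pasture.

Model-averaged detectability feeds straight into survey design:

```r
p_hat <- average_predictions(top, quantity = "p")
p_hat
#> # A tibble: 1 × 4
#>   quantity estimate lower upper
#>   <chr>       <dbl> <dbl> <dbl>
#> 1 p           0.449 0.428 0.471

required_surveys(p_hat$estimate, 0.95)
#> [1] 6
```

i.e. with per-occasion detectability ≈ 0.45, about six 4-day occasions
(~24 trap-days) give a 95% chance of detecting the species at an occupied
site, and the cumulative curve `p_star_curve(0.45, k_max = 15)` is
effectively saturated (> 0.999) by 12–15 occasions.

The whole analysis — including goodness of fit, overdispersion check, and
cross-validation — runs as one deterministic pipeline:

```r
res <- run_occupancy_pipeline(list(
  simulation = list(design = tapir_scenario()),
  seed = 42,
  psi_candidates = c("forest_d", "crops", "past", "d_streams"),
  p_candidates = c("forest_d", "past")
), out_dir = "run1")
```

writing `model_table.csv`, `confidence_set.csv`, `estimates.json`,
`assessment.json` and `p_star_curve.csv`.

## Documentation

The methods vignette (`vignettes/occupancy-methods.Rmd`) documents the
model and its assumptions, the numerical choices (initialization,
convergence, boundary handling), the model-averaging and goodness-of-fit
conventions, what the synthetic-data generator does and does not emulate,
and known limitations.
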