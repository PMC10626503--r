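# evaccum

Accumulator microcircuit models of evidence accumulation in spike trains.

`evaccum` is an R package for analyzing how neural populations accumulate
sensory evidence during two-alternative contrast discrimination. It is
aimed at systems neuroscientists who have (or simulate) spike times with
trial metadata — contrasts, choices, outcomes, stimulus-onset and
wheel-movement times — and want to run the full chain:

1. **Single-neuron selectivity** — combined-condition auROC statistics
   (stimulus selectivity, choice probability CP, detect probability DP,
   evidence selectivity ES) with shuffle-null significance, and
   accumulation-latency estimation.
2. **Population demixing** — demixed PCA of the contrast × decision ×
   time tensor, per-neuron stimulus/decision R², fuzzy C-means grouping,
   and an automated screen for "DDM-like" neurons (choice-selective,
   evidence-graded, ramping).
3. **Accumulator fitting** — single (drift-diffusion), independent-race
   and dependent-race microcircuits formulated as recurrent switching
   linear dynamical systems with Poisson spike emissions,

   x_t ~ N(A_z x_{t-1} + V_z u_t, Q_z),
   p(z_t | x_{t-1}) ∝ exp{γ(R x_{t-1} + r(t))},
   y_t ~ Poisson(softplus(C x_t + d) Δt),

   fitted by a variational Laplace-EM algorithm (constant or collapsing
   boundaries).
4. **Model selection** — sample-based AIC (posterior-sampled expected
   log-likelihood, 2k penalty), AIC-difference comparison with support
   threshold 10, and evidence-conditioned explained variance R².
5. **Integration timescales** — spike-count autocorrelations of simulated
   fixed-length trials, exponential fits R(kΔ) = A(exp(−kΔ/τ) + B),
   region-level bootstrap hierarchies, and strength–timescale
   correlations.

A synthetic-data module (`make_task_trials()`,
`simulate_accumulator_dataset()`, `make_selectivity_cohort()`,
`make_ar1_population()`) generates task trials and spike datasets with
known ground truth, so every stage is testable without external data.

## Worked example

Simulate a four-neuron subpopulation driven by a single accumulator,
fit it, and inspect the recovered circuit:

```r
library(evaccum)

trials <- make_task_trials(300, seed = 2)
spec <- build_accumulator("single", init = list(A = 0.98, V = 0.05, Q = 0.005))
spec <- set_emissions(spec, default_emission_weights("single", 2, 2), 15,
                      dt = 0.01)
ds <- simulate_accumulator_dataset(spec, trials, seed = 3)

fit <- fit_laplace_em(ds, "single",
                      init_grid = data.frame(A = 0.95, V = 0.05, Q = 0.005),
                      max_em = 25, tol = 1e-5)
fit
#> <fit_result> single, 155 trials, loglik -9720.5855 (max iterations)
#>   A_acc: 0.9814
fit$spec$d
#> [1] 14.40662
round(as.numeric(fit$spec$C), 1)
#> [1]  13.2  14.5 -15.6 -13.5
```

155 of the 300 trials pass the modeling filters (unequal contrasts, go
choice, reaction time in 0.15–0.5 s). The recurrent strength is recovered
at 0.981 (truth 0.98), the emission weights at ±13–16 Hz per unit latent
(truth ±15) and the shared offset at 14.4 (truth 15): the fitted circuit
is the generating circuit. `aic(fit)` then scores the model for the
AIC-difference comparison (`compare_models()`), and
`subpopulation_timescale(fit)` converts the fitted circuit into an
integration timescale.

The full chain — simulate regions, screen DDM-like neurons, form
subpopulations, fit and compare the three architectures, estimate
timescales, write CSV tables and a run manifest — is orchestrated by

```r
out <- run_pipeline(pipeline_config(), "results/run1")
```

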