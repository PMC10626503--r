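---
title: "Accumulator microcircuits for spike trains: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accumulator microcircuits for spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`evaccum` implements an analysis chain for asking how neural populations
accumulate sensory evidence during a two-alternative contrast
discrimination task: screen for choice-selective neurons whose ramping
firing rate is graded by evidence strength ("DDM-like" neurons), fit
single and race accumulator microcircuits to small subpopulations of them,
select among architectures by AIC, and characterize the integration
timescale of the selected circuits from spike-count autocorrelations.
Every stage can be exercised on synthetic data with known ground truth;
the synthetic generators are first-class, tested code and define the
conditions under which the package's claims are verified.

This vignette explains the models, the tunable parameters, the numerical
choices, and — importantly — what the synthetic experiments do and do not
establish about real recordings.

# The task and the synthetic trial generator

`make_task_trials()` emulates a 2AFC contrast task: gratings of contrast
$\{0, 0.25, 0.5, 1\}$ appear on the left and/or right screen; the subject
turns a wheel toward the higher-contrast side, or withholds a response
when both screens are blank. Signed evidence is the contrast difference
(right minus left), giving at most nine levels from $-1$ to $1$. Equal
contrast cells can be excluded, leaving the 12 unequal cells used by the
combined-condition statistics. Choices follow a simple lapse rule
(`accuracy`, default 0.8) and reaction times are uniform on
`rt_range`; both are placeholders that downstream accumulator simulation
replaces with its own boundary crossings.

# Accumulator microcircuits as switching linear dynamical systems

All three architectures share one generative skeleton
(`build_accumulator()`): a discrete state $z_t$ among $K$ states, a
continuous latent $x_t \in \mathbb{R}^D$ with state-specific linear
dynamics

$$x_t \sim \mathcal{N}(A_{z_t} x_{t-1} + V_{z_t} u_t,\; Q_{z_t}),$$

softmax transitions driven by the latent,

$$p(z_t \mid x_{t-1}) \propto \exp\{\gamma (R\, x_{t-1} + r(t))\},$$

and Poisson spike emissions through a softplus link,

$$y_t \sim \mathrm{Poisson}(\mathrm{softplus}(C x_t + d)\,\Delta t).$$

* **single** (drift-diffusion): $D = 1$, the latent integrates the signed
  contrast difference between boundaries at $\pm B$; $K = 3$ (accumulate,
  right wheel movement, left wheel movement).
* **independent race**: $D = 2$, each accumulator integrates one contrast
  stream; $A$, $V$, $Q$ diagonal; boundaries at $+B$; $K = 3$.
* **dependent race**: as the independent race but with fully connected
  $A$, $V$ (mutual/feedforward coupling, off-diagonal recurrence
  initialized at $-0.05$); coupled accumulators can be driven to either
  boundary, so $K = 5$ (positive/negative crossing states per
  accumulator).

Movement states have identity dynamics, zero input and are **absorbing**:
once a boundary is crossed the discrete state never returns. The dynamics
offset $b$ is excluded (fixed 0) and the latent starts at $x_0 = 0$
exactly — the symmetric, unbiased starting point of the classical DDM.
Collapsing boundaries multiply the effective boundary by
$f(t) = \beta + (1-\beta)e^{-t/\tau_c}$ (exponential mode; a linear mode
is also available), with $\tau_c$ in time steps.

## The transition gain

The boundary softness is controlled by the gain $\gamma$. With the
conventional unit gain, a boundary height of 1 and 0.01 s steps, the
movement hazard at $x = 0$ is $2e^{-1}/(1 + 2e^{-1}) \approx 0.42$ per
step — commitment would occur within ~25 ms regardless of the evidence,
which is incompatible with a task whose reaction times live in the
150–500 ms band that the fitting stage keeps. `evaccum` therefore treats
the gain as a model field with a sharp default ($\gamma = 25$,
boundary width $\approx 0.04$ in latent units), which produces
psychometric choice curves and chronometric reaction times while keeping
the transition structure (the $R$, $r$ parameterization above) fixed and
untrained. `transition_probs()` honors any gain, so the soft-gain
formulation remains available.

## Generator defaults are study conditions

Defaults were chosen once, on the criterion that a simulated session must
be analyzable by the package's own chain, and are not revisited:

* input weight $V = 0.05$ for the single accumulator (top of its
  initialization grid; smaller drifts push most reaction times beyond the
  0.5 s filter), $V = 0.03$ for races;
* accumulation noise $Q = 0.005$ (0.01 for the dependent race); task
  simulations meant to feed the selectivity/screening stages use
  $Q = 0.02$, which produces the within-condition behavioral variability
  (choice errors at fixed contrast pair) that combined-condition choice
  probability needs;
* emissions: weights $\pm 15$ on the choice-preferred latent, shared
  offset $d = 15$ (≈15 Hz baseline), 0.01 s bins. Contralateral-preferring
  neurons load positively on the right-choice (or single) latent,
  ipsilateral ones on the left-choice latent (or negatively on the single
  latent) — one recorded hemisphere, contralateral = right screen.
* trials that never cross within 1 s are labeled nogo; simulation
  continues 50 ms past the crossing, matching the fitted window.

# Selectivity statistics

All auROC statistics use midranks (ties contribute 0.5 per pair), are
computed on spike counts binned at 5 ms, smoothed with a causal
half-Gaussian kernel (SD 20 ms), and z-scored against the pre-stimulus
baseline (−0.9 to −0.1 s). Conditions are combined as trial-count-weighted
averages; conditions with fewer than 3 trials on a side are dropped (the
choice of weights and the minimum cell size are package decisions — the
combined-condition idea pools evidence across conditions, which
count-weighting expresses directly). Evidence selectivity compares each
signed-evidence level against **all lower levels pooled** (8 comparisons
for 9 levels); the alternative adjacent-level reading fits the "greater
than all those groups with lower evidence" description less well.

Shuffle significance permutes the compared labels *within* the metric's
grouping structure, 100 times by default; the null band is the
2.5th–97.5th percentile (a 95% band — the level is a package choice), and
significance additionally requires membership in a run of at least three
consecutive significant time points.

Latency is the first post-stimulus time at which the population mean rate
(100 ms causal boxcar) differs from the baseline point at −0.1 s by a
rank-sum test across go trials with reaction times in 0.15–0.5 s.
**Known limitation:** under 100 ms smoothing the pointwise significance
series is strongly serially correlated, so the run-length correction
leaves a family-wise false-positive rate of roughly 25–30% on stationary
data. On data with a genuine onset the estimate brackets the true latency
to within the boxcar width; on stationary data a latency is still reported
in a minority of runs. Interpret an isolated latency estimate accordingly.

# Demixing and neuron grouping

`build_marginalized_tensor()` averages each neuron's rate over
contralateral contrast (ordered 1, 0.5, 0.25, 0), decision (hit/miss) and
time (−0.1 to 0.3 s); neurons with an average of fewer than one spike
between stimulus onset and wheel movement are excluded. The demixed PCA
loss is minimized by reduced-rank **ridge** regression of each
marginalization on the full centered data; the ridge penalty is chosen by
generalized cross-validation over a log-spaced grid (the regularization
strength was an open choice; GCV requires no held-out data and is the
standard default for ridge problems). Twenty components are allocated
across marginalizations by ranking every candidate component's explained
variance — the allocation rule was unspecified, and variance ranking is
the allocation that the loss itself implies.

Fuzzy C-means (fuzzifier 2, tolerance $10^{-6}$, 300 iterations, seeded
random memberships) groups neurons on the $(R^2_{st}, R^2_{dt})$ plane;
cluster identity comes from centroid position. The implementation is
in-package (about forty lines) because the tests assert the per-iteration
objective decrease and need seeded initialization; `e1071::cmeans` serves
as an independent cross-check in the test suite.

The automated DDM screen replaces a manual visual inspection step with:
decision-cluster membership **and** significant choice probability **and**
significant evidence selectivity **and** a significant positive
movement-aligned ramp on preferred-choice trials. Movement alignment
matters: stimulus-aligned averages of an accumulator's rate flatten under
reaction-time heterogeneity (survivor bias), whereas the ramp-to-threshold
is invariant under movement alignment.

# Fitting: variational Laplace-EM

`fit_laplace_em()` alternates:

1. **Discrete E-step** — exact forward–backward over $z_{1:T}$
   conditioned on the current continuous mode path; the chain's "emission"
   terms are the state-specific dynamics densities, transitions out of the
   accumulation state follow the softmax rule, movement states absorb.
2. **Continuous E-step** — Newton ascent (with backtracking) to the mode
   of the per-trial objective given the discrete marginals. The objective
   is concave: Gaussian dynamics, log-softplus Poisson emissions and
   log-softmax transition terms all have negative-semidefinite Hessians.
   The Laplace covariance blocks come from the banded precision at the
   mode.
3. **M-step** — closed-form updates of the accumulation recurrence
   ($A_\mathrm{acc}$, with the architecture's structural zeros enforced)
   and the noise covariances using full Laplace second moments
   ($E[x_t x_t']$ and $E[x_t x_{t-1}']$), so the recurrence estimate is
   not attenuated by posterior smoothing; emission parameters $C$ and the
   shared scalar offset $d$ are refit by Newton on a Monte-Carlo
   approximation of the expected Poisson likelihood (five draws per bin
   from the marginal Laplace posteriors — the emission term factorizes
   over bins, and a mode-only update provably drifts the latent scale).
   Input weights $V$, the transition parameters and the boundary are held
   fixed; noise variances are floored at $10^{-6}$.

For the race architectures the emission weights are structurally
constrained to the neuron's preference-side accumulator (contralateral
pool to the right-choice latent, ipsilateral pool to the left), the
neuron-pool reading of the race circuits and the same convention the
generator uses. The constraint is not cosmetic: an unconstrained
two-dimensional emission map can rotate into a "difference" axis that
mimics the single accumulator plus a shared-gain axis that soaks up
Poisson variability through the latent posterior — flexibility that the
AIC's parameter count cannot penalize, which otherwise makes the
two-dimensional architectures spuriously win the model comparison on
one-dimensional data. The free-parameter count includes only the
unmasked weights.

Trials enter the fit only if they have unequal contrasts, a go choice and
a reaction time in 0.15–0.5 s; each trial's window runs from the
accumulation latency to 50 ms after wheel movement, binned at 0.01 s
(small enough to resolve the reaction-time band, large enough for count
statistics). The greedy initialization search refits from every row of
the architecture's initial-value grid and keeps the highest final
objective.

The recorded objective is a Laplace estimate of the marginal
log-likelihood (chain normalizer at the mode, plus the emission likelihood
and the Gaussian volume term). Two caveats, both verified in the test
suite and accepted as properties of this approximation family: the trace
can drift slightly while the parameters converge (monotonicity holds only
for exact EM), and the accumulation noise $Q$ is recovered with a
downward bias of roughly a third at 4-neuron/15 Hz information levels,
while $A$, $C$ and $d$ recover accurately. Emission parameters are
trained even though the original formulation is silent about them: the
latent-to-neuron map cannot be known a priori.

# Model selection

`aic()` computes $\mathrm{AIC} = 2k - 2\hat E$, where $\hat E$ averages
the Poisson emission log-likelihood over 100 draws of the continuous path
from the per-trial Laplace posteriors, and $k$ counts trainable scalars
only (including emissions): 9, 17 and 28 for the single, independent-race
and dependent-race architectures with four neurons. `compare_models()`
rescales to $\Delta_i = \mathrm{AIC}_i - \mathrm{AIC}_{\min}$ and declares
a preferred model only when every competitor has $\Delta \ge 10$;
otherwise the subpopulation is excluded. Unilateral subpopulations (one
choice preference only) are fitted with the single accumulator and never
enter the three-way comparison.

`explained_variance()` simulates the fitted model per trial, smooths data
and simulation with a 50 ms causal boxcar, averages within signed-evidence
levels over the window from the latency to the median reaction time, and
reports the $R^2$ with the grand-mean normalizer: 1 for a perfect match,
0 for the grand-mean predictor, negative when worse. All filtered trials
are used, not correct trials only (the restriction was unspecified; using
all trials keeps the evidence-level averages estimable on both sides).
One caveat: the data traces are conditioned on each trial's observed
crossing time (windows end 50 ms after wheel movement) while the model
simulations are not, so the late-window bins diverge systematically and
the statistic can be small or even negative for the generating model on
short synthetic sessions — it is a comparative measure across models, not
an absolute goodness score.

# Integration timescales

Spike counts of fixed-length simulated trials are binned at
$\Delta = 0.025$ s; Pearson correlations between all bin pairs are pooled
by lag across pairs and neurons and fitted with
$R(k\Delta) = A(e^{-k\Delta/\tau} + B)$ by Levenberg–Marquardt from five
fixed starts. Robustness decisions: $B \ge 0$ (it represents timescales
longer than the window), parameters bounded ($A \le 2$, $B \le 2$,
$\tau \in [10^{-4}, 5]$ s), solutions pinned at the $\tau$ bounds are
treated as failed fits, and the start-lag rule (one lag past the largest
single-step drop, targeting negative adaptation) searches only the first
quarter of lags and advances at all only when the candidate drop exceeds
1.5 times the median decay step. On smooth exponential curves an
unconditional rule discards a lag chosen by noise, and the shortened
curve falls into an offset-compensated local optimum with a strongly
biased timescale; requiring an anomalous drop restores the rule to its
purpose.

Timescale simulations run with the boundary disabled — the latent stays
in the accumulation state for the full 200 ms — because fixed-length
trials are incompatible with absorbing crossings. Each subpopulation
timescale averages 50 sample sets of 1000 trials (the per-set trial count
was unspecified; 1000 makes the autocorrelation amplitude resolvable at
4-neuron, ~15 Hz conditions, for which the timescale-study spec noise is
set to $Q = 0.02$). Region-level timescales pool subpopulation
autocorrelations, bootstrap subpopulations 100 times for a 95% percentile
interval, and compare regions by rank-sum tests on the bootstrap samples
with Bonferroni correction.

**Caveats established by simulation.** (i) The three-parameter
exponential is ill-identified when $\tau$ exceeds the 175 ms lag span:
the closed-form oracle check therefore uses 1 s trials, while the
subpopulation/region analyses keep the 200 ms convention and inherit a
downward bias for slow circuits (the hierarchy ordering is preserved
because the bias is monotone). (ii) The rank-sum test on bootstrap
replicates is anticonservative: regions generated from identical circuits
can differ "significantly" because the bootstrap spread and the
between-region sampling shift scale together. The pairwise p-values
should be read as ranking evidence, not calibrated error rates.

The hierarchy experiment uses four regions with recurrent strengths
$\{0.75, 0.87, 0.94, 0.975\}$ (timescales ~0.04–0.4 s, inside the
measurable band), 40 subpopulations each with 8000-trial autocorrelation
curves; the strength–timescale correlation spans $A \in [0.90, 0.995]$
over 30 subpopulations.

# What the synthetic experiments do and do not show

The generators produce Poisson spikes from exactly the model class the
fitters assume, with stationary baselines, no slow drifts, no spike-sorting
artifacts, no cross-neuron noise correlations beyond the shared latent,
and sharp boundary crossings. Passing tests therefore establish
*correctness of the implementations* and *identifiability under matched
conditions* — that the chain recovers what it is designed to recover at
realistic counts and trial numbers. They do not establish that real
circuits are accumulators, that the screen's selectivity thresholds
transfer to real signal-to-noise ratios, or that real-data timescale
estimates are unbiased. On real recordings the trial filters, latency
estimation and region grouping all add variability that these experiments
do not model.

# Analysis sizes

The test suite and the acceptance script verify, at fixed seeds: the
auROC implementation against brute-force pair counting (1000 samples);
timescale recovery at $a \in \{0.90, 0.95, 0.99\}$ with 5000 trials;
recurrent-strength recovery over 20 replicate fits (4 neurons, 300
trials, $A = 0.98$); architecture identification over 5 subpopulations
per architecture with single-start fits (the full greedy grids are
exercised separately); explained-variance endpoints; the four-region
hierarchy; the 30-subpopulation strength–timescale correlation; shuffle
calibration and power on a 200-neuron cohort; and dPCA demixing with
fuzzy C-means label recovery. The acceptance script reruns the same
chain at moderately smaller sizes and prints every quantity it computes.
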