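---
title: "Detecting Allee effects in small cell populations: models, inference, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Allee effects in small cell populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleegrowth)
```

## The scientific problem

Growth curves started from a handful of cells (1–20 per well) do not have to
follow the textbook exponential law. Two very different mechanisms can make
small populations *look* slow: demographic stochasticity — some wells drift
to extinction by chance, dragging the average down — and a genuine Allee
effect, where the per-capita growth rate itself depends on population size.
Telling these apart requires stochastic models fitted to many replicate
wells, not a deterministic curve fit to the average.

`alleegrowth` implements seven candidate continuous-time birth–death models
of cell number $n$, organised in three families by their mean behaviour:

* **exponential** (`simple_bd`): constant per-capita birth and death rates
  $b$ and $d$ (per cell per hour); the mean follows
  $\partial_t N = gN$ with net growth $g = b - d$;
* **strong Allee** (`strongA_*`): mean law
  $\partial_t N = g\,(1 - A/N)\,N$ — populations below the threshold $A > 0$
  shrink on average;
* **extended Allee** (`extA_*`): mean law
  $\partial_t N = g\,\bigl(1 - \tfrac{A+\tau}{N+\tau}\bigr)\,N$ — with
  $A < 0$ and $\tau > |A|$ this is a *weak* Allee effect: growth is positive
  at every size but depressed at small $n$.

Within each Allee family the `_birth`, `_death` and `_both` variants place
the Allee term on the birth rate, the death rate, or split it equally. All
members of a family share the same mean dynamics; only the *variance*
dynamics distinguish them, which is why the inference below fits the mean
and variance jointly.

### Stochastic event rates

The total event rates at count $n$ are, for example for the strong Allee on
birth model, $B(n) = bn - gA$ and $D(n) = dn$ (see `propensities()` for all
seven). Two regularisations apply everywhere:

* **clamping** — the model rate forms can go negative at small $n$
  (e.g. $bn - gA < 0$ for $n < gA/b$); negative totals are undefined in a
  jump process and are clamped at 0;
* **absorbing zero** — at $n = 0$ both rates are exactly 0; extinction is
  permanent.

`simulate_trajectory()` and `simulate_ensemble()` draw exact sample paths
with the Gillespie algorithm (exponential waiting time at rate $B+D$, event
type chosen proportionally), implemented in C++ for the inner loop, and
sample them onto the observation grid by last-value carry-forward (counts
are step functions between events).

## Moment closure and the likelihood

Fitting stochastic models by simulation-matching (e.g. ABC) is expensive.
Instead the package closes the master equation at the first two moments.
With $M = \langle n \rangle$ and $\Sigma$ the variance, all models share

$$\frac{dM}{dt} = g M (1 - \varphi), \qquad
  \varphi = 0,\; A/M,\; \tfrac{A+\tau}{M+\tau}$$

for the exponential, strong and extended families, and the variance obeys

$$\frac{d\Sigma}{dt} = 2 g \Sigma + (b{+}d) M + s\, g A \quad \text{(exponential/strong)},$$
$$\frac{d\Sigma}{dt} = 2 g \Sigma (1 - \varphi) + (b{+}d) M + s\, g M \varphi \quad \text{(extended)},$$

with $s = -1, +1, 0$ for the `_birth`, `_death`, `_both`/simple variants.
The strong-family equations are exact for the unclamped linear rates; the
extended-family equations close the nonlinear factor $1/(n+\tau)$ at the
mean, consistently in the first- and second-moment equations (the same
closure that yields the mean law). `solve_moments()` integrates these with
`deSolve::lsoda` at rtol $10^{-8}$, atol $10^{-10}$, from the exact initial
condition $(N_0, 0)$, clipping tiny negative variances at 0.

**Where the closure is trusted, and where not.** Two oracles validate it:
a truncated master-equation solver (`solve_master_equation()`, exact up to
truncation, with a checked tail-mass bound) and large Gillespie ensembles.
For the exponential family the closure is exact. For the strong family it
is exact except for the clamp region $n < gA/b$: from $N_0 = 3$ with
$A = 2$ the ensemble mean runs up to ~7% above the moment solution, while
from $N_0 = 5$ and 10 the overlay holds within Monte-Carlo error of 20,000
trajectories. For the extended family the mean closure is accurate at
moderate $N_0$, but the variance can deviate substantially when the
trajectory distribution is wide (at the weak-Allee parameters of the
`bt474_like` preset the closure variance is ~55% below the ensemble
variance at $N_0 = 2$ by 328 h). The concordance tests therefore check the
mean overlays at $N_0 = 5$, the condition the illustrative trajectory
figures use; the variance mismatch at extreme conditions is a property of
the closure itself and is documented rather than patched.

A consequence worth knowing: the $\tau \to 0$ limit of the extended
*variance* equation does not coincide with the strong-family equation (the
closure does not commute with the limit), although the mean equations do
coincide. Tests assert the mean reduction; the exact collapse
`extA_* -> simple_bd` at $A = -\tau$ holds for both moments and is tested.

### Likelihood

For each condition $i$ (initial number $N_{0,i}$, $R$ replicate wells) the
observed per-timepoint mean $\hat u_{i,k}$ and variance
$\hat\Sigma_{i,k}$ are modelled as Gaussian around the moment solutions
$\mu_i(t_k,\theta)$ and $\Sigma_i(t_k,\theta)$, with normal-theory sampling
standard deviations computed from the *model* variance:

$$\sigma_{\mu} = \sqrt{\Sigma(t_k,\theta)/R}, \qquad
  \sigma_{\Sigma} = \sqrt{2}\,\Sigma(t_k,\theta)/\sqrt{R-1},$$

both floored at $10^{-6}$. Mean and variance terms are weighted equally and
summed over conditions and timepoints. Three deliberate choices:

* **$t = 0$ is excluded** — at the exactly-known seeding point both the
  empirical and the model variance are 0, making the Gaussian terms
  singular.
* **Known injected noise enters in quadrature** — when the summaries carry
  deliberately added measurement noise (the simulation-study design adds
  zero-mean Gaussian noise of sd 0.5 cells to the mean and 5 cells² to the
  variance), the observation sd becomes
  $\sqrt{\Sigma/R + c_\mu^2}$ and $\sqrt{2\Sigma^2/(R-1) + c_\Sigma^2}$.
  Without this the near-zero model variance at early timepoints makes those
  few points dominate the likelihood by orders of magnitude and badly
  biases the rate constants. Defaults are $c = 0$ (pure sampling forms),
  used for real count data.
* **Integration failures are penalised, not fatal** — parameter sets where
  the moment ODEs blow up (e.g. $A \ge \min N_0$, which sends that
  condition's mean into decline towards the Allee-factor singularity)
  return a large finite NLL so the simplex can back out.

### Optimisation

`allee_fit()` minimises the NLL with Nelder–Mead (reltol $10^{-8}$, max
5,000 iterations, plus up to three deterministic restarts from the
incumbent — the simplex on these surfaces occasionally stalls short).
Rate constants are optimised as $\log b$, $\log d$; $A$ and $\tau$ are
affinely normalised to $[0,1]$ over $A \in [-20, 20]$, $\tau \in [0, 50]$
(scale-setting, not hard bounds). Starting values: the pooled OLS slope of
$\log(\text{mean})$ on time for $g$, $d_0 = 5\times10^{-4}$ per hour,
$A_0 = 1$ (strong) or $-1$ (extended), $\tau_0 = 2$. Fits are deterministic
given the data and settings.

### Profile likelihood

`profile()` fixes one parameter on an adaptively expanding grid around the
MLE, refits the remaining parameters at each value (warm-started), and
reports the 95% interval as the region within
$\chi^2_{0.95,1}/2 = 1.92$ of the minimum, linearly interpolated at the
crossings. Profiles run on the natural parameter scale; rate parameters are
bounded below at 0, and a side that never crosses the threshold (boundary
or step limit) is returned as `NA` and flagged practically unidentifiable.

**Calibration caveat.** The likelihood treats the 82 timepoints as
independent, but summary errors of a trajectory ensemble are strongly
autocorrelated in time. For large ensembles (thousands of trajectories per
condition) the nominal profile intervals are therefore markedly
anticonservative: the replicate-to-replicate spread of the MLEs is an
order of magnitude wider than the nominal intervals. For well-plate-scale
data (tens of wells) the mismatch is smaller. Interpret profile CIs as
curvature summaries of this likelihood, not as frequentist coverage
statements — a limitation inherited from the summary-statistic
pseudo-likelihood itself.

A related small-sample effect: because $\sigma(\theta)$ depends on the
parameters, the Gaussian normalisation term rewards shrinking the model
variance; at $R = 50$ replicates this biases rate constants downward by
several percent even on noiseless self-generated data, vanishing as $R$
grows.

## Model selection

`compare_models()` scores each fit with
$\mathrm{BIC} = 2\,\mathrm{NLL} + k \ln n_{\text{data}}$, where $k$ is the
number of free parameters (2, 3, 4 by family) and $n_{\text{data}}$ counts
*both* the mean and the variance observation at every fitted timepoint and
condition — they are separate likelihood terms (a mean-only count is
available via `use_variance = FALSE` fits for sensitivity checks). Evidence
is summarised by BIC weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$; ranking ties break
towards fewer parameters, then lexical id, with BIC values snapped at 1e-7
so float noise cannot flip a tie.

## The synthetic-data engine and what it does (not) emulate

`experiment_design()` + `simulate_ensemble()` stand in for the wet-lab
study: replicate wells seeded at exact small numbers, imaged every 4 h for
328 h. Presets:

* `simulation_study` — $N_0 = 3, 5, 10$, 5,000 trajectories each from the
  strong Allee on birth model ($b = 0.0238$, $d = 0.005$, $A = 2$ per
  hour/cells), plus additive summary noise (sd 0.5 cells on the mean, 5
  cells² on the variance — the magnitude is a package choice: large enough
  to visibly perturb the series, small enough not to destroy recovery);
* `bt474_like` — $N_0 = 2, 4, 10$, 30 wells each from the weak Allee on
  birth model at $b = 0.0101$, $d = 4.36\times10^{-5}$, $A = -3.158$,
  $\tau = 7.48$; no summary noise (the counts themselves are the data);
* `high_density` — $N_0 = 512, 1024$, 30 wells, simple birth–death at
  $b = 0.0118$, $d = 5\times10^{-4}$ ($g = 0.0113$ per hour, matching the
  reported high-density growth rates; the split between $b$ and $d$ is a
  package choice, as only $g$ is reported).

One master seed drives everything; it expands into one sub-seed per
trajectory drawn sequentially, so raising the replicate count extends an
ensemble without reshuffling existing trajectories.

What the generator does **not** emulate: segmentation/counting error on
individual wells (only summary-level noise), focus loss, well dropout,
plate effects, or any mechanistic source of cooperation. Passing tests on
synthetic data therefore demonstrate the *inference machinery* — they do
not validate the biological claim on real images.

## Pipelines

`run_simulation_study()` chains simulate → summarise → perturb → fit all
seven models → BIC selection → profile the winner, and writes CSV/JSON
artifacts when given an output directory. `run_data_pipeline()` is the
real-data path: filter and bin wells (the "died off / no growth" rule —
final count ≤ initial — is applied only when asked: it is curation for
imaging artefacts, and applying it to simulated data would induce
survivorship bias), per-well exponential growth rates by log-linear OLS on
positive counts, per-condition simple birth–death fits (the $b$, $d$ trend
with $N_0$ that signals an Allee effect), then the combined seven-model
fit, selection, and profiles.

```{r pipeline, eval = FALSE}
rep <- run_simulation_study(preset = "simulation_study",
                            replicates = 1000, seed = 1)
rep$selection          # BIC table; strongA_birth wins
confint(rep$profiles)  # profile CIs of the winner
```

## Problem sizes used by the shipped checks

The test suite and the reproduction script scale the full study design down
to keep a laptop run comfortable: the acceptance script regenerates the
simulation study at 2,000 trajectories per condition (the full design uses
5,000; both are supported), the in-suite replication study uses 1,000, and
oracle comparisons use 5,000–50,000 Gillespie trajectories depending on the
statistic. Scale choices are stated next to each check.

## Known limitations

* The moment closure degrades exactly where Allee dynamics are most
  interesting — very small $N_0$ with wide trajectory distributions; the
  master-equation solver is the reference there.
* Profile intervals are anticonservative for large simulated ensembles
  (temporal correlation; see above). One practical consequence: on
  synthetic weak-Allee data at well-plate scale, the extended-family MLE
  can land in a strong-regime corner of $(A, \tau)$ space that compensates
  the closure's variance deficit, even though model *selection* still
  identifies the right structure. Recovering the generating $(A, \tau)$
  point estimates from closure fits to exact simulations should not be
  expected at these scales.
* Only equal weighting of the mean and variance likelihood terms is
  implemented; the weighting is in principle tunable.
* No logistic/Gompertz saturation: the models target the low-density
  regime only, far below carrying capacity.
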