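# alleegrowth

Stochastic birth–death modelling of cell populations grown from very small
seeding numbers (1–20 cells per well), built to answer one question: when
growth from a few cells looks slower than exponential, is that demographic
stochasticity — random extinction of some wells dragging the average down —
or a genuine **Allee effect**, where the per-capita growth rate itself
depends on population size?

The package is aimed at quantitative cell biologists and modellers working
with replicate well-plate growth curves (time-lapse imaging counts), and at
anyone who needs a tested reference implementation of moment-closure
inference for small-population birth–death processes.

## The models and the method

Seven continuous-time birth–death models of cell number *n*, in three
families defined by the deterministic law their mean follows
(*g* = *b* − *d*, rates per cell per hour):

| family | mean law | variants | free parameters |
|---|---|---|---|
| exponential | dN/dt = gN | `simple_bd` | b, d |
| strong Allee | dN/dt = g(1 − A/N)N | `strongA_birth`, `strongA_death`, `strongA_both` | b, d, A |
| extended (weak) Allee | dN/dt = g(1 − (A+τ)/(N+τ))N | `extA_birth`, `extA_death`, `extA_both` | b, d, A, τ |

Within a family the variants place the Allee term on the birth rate, the
death rate, or both equally; they share the same mean dynamics and differ
only in their variance dynamics. A strong Allee effect (A > 0) makes
populations below A shrink on average; a weak one (A < 0, τ > |A|)
depresses growth at small *n* without a extinction threshold.

Inference follows the moment-closure approach: the master equation is
closed at the mean M(t) and variance Σ(t) (an ODE pair per model,
integrated with `deSolve`), and the per-timepoint empirical mean û_k and
variance Σ̂_k of R replicate wells are given a Gaussian likelihood around
the model moments with sampling standard deviations
σ_μ = √(Σ/R), σ_Σ = √2·Σ/√(R−1). The negative log likelihood

NLL(θ) = ½ Σ_{i,k} [ log(2πσ²_μ) + ((μ − û)/σ_μ)² ] +
½ Σ_{i,k} [ log(2πσ²_Σ) + ((Σ − Σ̂)/σ_Σ)² ]

is minimised by Nelder–Mead (log-transformed rates, normalised Allee
parameters). Uncertainty comes from profile likelihoods (95% CIs at
ΔNLL = 1.92) and model evidence from BIC = 2·NLL + k·log(n_data) with BIC
weights. Exact Gillespie simulation (C++ core) and a truncated
master-equation solver serve as oracles for everything above.

## Worked example

Simulate the validation design — 500 replicate wells per initial condition
N₀ = 3, 5, 10 from the strong Allee on birth model (b = 0.0238, d = 0.005
per hour, A = 2 cells), counts every 4 h for 328 h, plus constant
measurement noise on the summaries — then fit and compare models:

```r
library(alleegrowth)

pd  <- preset_design("simulation_study", replicates = 500, seed = 11)
ens <- simulate_ensemble(pd$design, pd$model, pd$params)
summaries <- empirical_moments(as_count_table(ens))
summaries <- perturb_summaries(summaries, 0.5, 5, seed = 12)

fit <- allee_fit(summaries, "strongA_birth", noise_sd = c(0.5, 5))
fit
#> Stochastic growth model fit: strongA_birth (strong_allee family)
#> Conditions N0: 3, 5, 10  | fitted observations: 492
#> Coefficients:
#>        b        d        A
#> 0.022800 0.004013 2.054000
#> Net growth g = b - d: 0.01879 per hour
#> NLL: 2303 | BIC: 4625 | converged: TRUE

null_fit <- allee_fit(summaries, "simple_bd", noise_sd = c(0.5, 5))
compare_models(list(fit, null_fit))
#> Model selection over 2 candidates (n_data = 492 )
#>          model k   nll   bic delta_bic bic_weight rank
#>  strongA_birth 3  2303  4625         0          1    1
#>      simple_bd 2 13230 26480     21860          0    2
#> Selected: strongA_birth
```

The generating parameters are recovered (b̂ = 0.0228, d̂ = 0.0040,
Â = 2.05 against the truth 0.0238 / 0.005 / 2; the net growth rate
ĝ = 0.0188 per hour is recovered almost exactly), and the Allee model is
preferred over plain exponential growth by an overwhelming BIC margin —
the variance trajectory, not just the mean, is what separates them.
`profile(fit)` adds confidence intervals, `predict`/`residuals`/`plot`
inspect the fit, and `simulate(fit)` draws new synthetic wells at the
fitted parameters.

Higher-level drivers chain the full analyses: `run_simulation_study()`
(simulate → summarise → fit all 7 models → BIC selection → profile the
winner) and `run_data_pipeline()` (well filtering, per-well exponential
growth rates, per-condition simple birth–death fits, combined 7-model fit)
for count tables in the CSV schema `well_id,n0,time_h,count`.

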