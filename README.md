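# idras

Identifying Dynamic Regulation with Adversarial Surrogates — an R package
for discovering, from multivariate time series alone, a scalar combination
of observed variables that the system regulates about a *time-varying*
reference value, together with a learned predictor of that reference.

## Who this is for

Systems biologists and quantitative biologists who have repeated
multivariate recordings (protein levels, single-cell lineage measurements,
physiological signals) and suspect a hidden control objective, but know
neither the regulated function of the observables nor the set-point it
tracks — especially when the set-point itself drifts or oscillates, which
defeats methods that look for combinations conserved about a constant.

## The method

Given series $z^k \in \mathbb{R}^n$ sampled every $\Delta t$, the package
learns $c^k = g(z^k;\theta)$ (a small neural network over channels) and a
one-step filter $\hat c^k = F(c^{k-T:k-1};\Theta)$ (encoder → latent drift
integrated over $\Delta t$ → decoder), by minimising the filtering-error
variance ratio

$$\frac{\mathrm{var}\left(c^k - \hat c^k \mid \text{data}\right)}
       {\mathrm{var}\left(c^k - \hat c^k \mid \text{surrogates}\right)}$$

against an adversarial *shuffle player*: surrogate windows keep a real
length-$T$ history but a final sample drawn from the pooled marginal, and
are importance-resampled (by the density ratio of the two error
distributions, $\zeta$) so that their filtering-error distribution matches
the data's under the current parameters. That reset forces the combination
player to exploit genuine temporal structure rather than support artefacts.
Setting $F \equiv 0$ (`iras_fit()`) recovers the fixed-set-point special
case with a per-channel component shuffle as its null.

Two ground-truth simulators ship with the package so every claim is
testable without external data: a regulated gene-expression kinetic model
(mRNA + two proteins whose sum tracks an oscillating transcription rate)
and a bacterial growth–division model whose cells divide at a stochastic
Ornstein–Uhlenbeck size threshold (a "sizer" with a drifting target), plus
a two-objective toy. Evaluation helpers report sign-aligned Pearson
correlation against ground truth, normalised mean-square prediction error,
and the sizer/adder/timer reference indicators.

## Worked example

```r
library(idras)

sim <- simulate_kinetic(kinetic_params(n_series = 8, n_steps = 300), seed = 2)
sim$ts
#> <ts_set> 8 series, 2 channels (P, S), dt = 2
#>   samples per series: 300, 300, 300, 300, 300, 300, 300, 300

cfg <- idras_config(T = 8, outer_iters = 15, inner_epochs = 20, seed = 11)
fit <- idras_fit(sim$ts, cfg)

glance(fit)
#> # A tibble: 1 × 6
#>   status    converged n_iterations final_ratio best_ratio   nmse
#>   <chr>     <lgl>            <int>       <dbl>      <dbl>  <dbl>
#> 1 converged TRUE                 6       0.234     0.0507 0.0118

truth <- sim$truth
truth$c_star <- truth$P_plus_S        # the regulated quantity, P + S
evaluate_fit(fit, truth)
#> # A tibble: 1 × 2
#>     rho   nmse
#>   <dbl>  <dbl>
#> 1 0.997 0.0118
```

`rho` is the sign-aligned correlation between the learned combination and
the true regulated sum $P+S$ — 0.997 means the combination was identified
essentially exactly, despite its oscillating set-point. `nmse` is
$\mathrm{var}(c-\hat c)/\mathrm{var}(c)$ for the learned filter: 0.012
means the set-point dynamics are predicted to within about a percent of the
combination's variance. `tidy(fit)` exposes the per-iteration variance
ratio and Kolmogorov–Smirnov trace; `autoplot(fit)` and
`autoplot(fit, type = "predictions")` plot them. On the same data the
static reduction `iras_fit()` lands near zero correlation with $P+S$ — a
fixed-set-point search cannot represent the oscillating objective.

A thin command-line wrapper is included for file-based runs:

```sh
Rscript inst/cli/idras.R simulate --preset lineage --out runs/lin --seed 1
Rscript inst/cli/idras.R fit --data runs/lin/observations.csv --out runs/lin/fit --T 5
Rscript inst/cli/idras.R evaluate --fit runs/lin/fit/fit.rds --truth runs/lin/truth.csv
```

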