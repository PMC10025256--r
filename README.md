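# nodefit

Fitting ordinary differential equation (ODE) and neural-ODE (NODE) models
to noisy oscillatory time series — the kind of multi-decade predator–prey
abundance records where a deterministic model must track several cycles of
rise and fall.

For ecologists and modellers who want to ask: *how well can a small
mechanistic ODE, or a flexible neural network derivative field, describe
and predict an observed oscillation — and how confident should I be in
the prediction?*

## What it does

Given a tabular series (a `time` column plus one column per observed
variable), the pipeline:

1. **Smooths** the record into a fitting target: natural log,
   per-variable mean-centering, a cubic-spline midpoint between each
   observation pair (T points → 2T−1; 91 yearly points → 181 half-yearly
   targets), then a renormalized discrete Gaussian filter.
2. **Models** the derivative field as either
   - ODE: du/dt = f(S u − b), with n²+n parameters (f = tanh by default), or
   - NODE: du/dt = W₂ f(W₁ u + b₁) + b₂ with N hidden nodes, (n+1)N + n(N+1)
     parameters — 102, 143, 184 for n = 2, 3, 4 at N = 20 —
   optionally adding unobserved *dummy* dimensions (n > n_obs) that let the
   trajectory unfold in a higher-dimensional phase space.
3. **Fits** by Adam, with exact gradients obtained by forward sensitivity
   analysis through a stiff solver, under a sequential curriculum that
   activates later time points with slowly ramped weights (loss = weighted
   sum of squared deviations at each target point; 362 components on the
   two-species 181-point grid).
4. **Samples** an approximate posterior around the optimum by
   preconditioned stochastic gradient Langevin dynamics (pSGLD), with a
   split-half Kolmogorov–Smirnov diagnostic for run length.
5. **Assesses predictions** by splitting the record into training and test
   windows and propagating posterior parameter draws into trajectory
   ensembles, summarized as mean ± SD window losses, repeated-sample model
   comparisons, and phase-space paths.

A synthetic Lotka–Volterra generator (`simulate_lv()`, `add_noise()`)
provides reproducible oscillatory data so everything can be exercised
without any external dataset.

## Worked example

```r
library(nodefit)

# a 41-year predator-prey record with multiplicative observation noise
raw <- add_noise(simulate_lv(lv_params(), 0, 40, 1), sigma = 0.1, seed = 1)
target <- preprocess_series(raw, sigma = 1)
nrow(target)
#> [1] 81

# fit a 2-variable ODE with the sequential curriculum
spec <- model_spec("ode", n = 2)
ctl <- solver_config(method = "lsoda", max_steps = 500)
fit <- fit_model(spec, target,
                 fit_config(segments = 4, ramp_iters = 30,
                            iters_per_segment = 100, lr = 0.05, seed = 1,
                            solver = ctl))
fit
#> <nodefit_fit> ode n=2: final loss 0.601194 after 400 iterations (0 integration failures)

glance(fit)
#> # A tibble: 1 × 6
#>   family     n n_parameters final_loss n_iterations n_integration_failures
#>   <chr>  <int>        <int>      <dbl>        <int>                  <int>
#> 1 ode        2            6      0.601          400                      0

# posterior sampling around the optimum, then a 30-member ensemble
ens <- psgld_sample(fit, target,
                    psgld_hyper(epsilon = 1e-4, n_warmup = 50,
                                n_collect = 200, seed = 2), control = ctl)
ens$diagnostic$ks_statistic
#> [1] 0.92

te <- ensemble_predict(ens, target$time, K = 30, seed = 3, control = ctl)
te
#> <trajectory ensemble> 30 members on 81 time points (0 excluded for divergence)
ensemble_loss_summary(ens, target, M = 100, seed = 4, control = ctl)
#> # A tibble: 1 × 4
#>    mean    sd     n n_failed
#>   <dbl> <dbl> <int>    <int>
#> 1  3.49  1.30   100        0
```

The final loss (0.60 summed over 162 squared-deviation components) says
the fitted trajectory tracks the smoothed oscillation closely. The
posterior mean loss (3.49 ± 1.30) is higher than the optimum because
pSGLD samples spread around it, and the split-half KS statistic of 0.92
correctly flags this demonstration run — 200 collected samples — as far
too short for a converged posterior; the full-scale defaults collect
10,000.

`autoplot(fit, target)` overlays the fitted trajectory on the target;
`autoplot(te, target, t_split = 25)` draws the posterior trajectory fan.

## Command line

A thin CLI over the same functions lives at `inst/cli/nodefit.R`:

```sh
Rscript inst/cli/nodefit.R simulate   --out run --seed 1
Rscript inst/cli/nodefit.R preprocess --out run
Rscript inst/cli/nodefit.R fit        --out run
Rscript inst/cli/nodefit.R sample     --out run
Rscript inst/cli/nodefit.R predict    --out run
Rscript inst/cli/nodefit.R report     --out run
Rscript inst/cli/nodefit.R --show-config   # print the default YAML config
```

Each stage reads/writes plain CSV/JSON/YAML artifacts in `--out` and
records a manifest (config snapshot, seeds, versions, wall time), so a
run is reproducible from its manifest alone.

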