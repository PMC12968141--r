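# pinnode

Physics-informed neural networks (PINNs) for systems of first-order
ordinary differential equations, aimed at the kinds of ODE models that
dominate biology and systems biology. The package solves

- the **forward problem** — approximate the solution trajectory of
  `dx_i/dt = f_i(x_1, …, x_n, t)` given parameters and an initial state, and
- the **inverse problem** — estimate unknown ODE parameters from sparse,
  noisy observations of the trajectory,

with one mechanism: a small tanh feedforward network `u(t)` approximates the
solution, and training minimizes the equally weighted sum

```
L = mean (u(t_obs) - y_obs)^2          data loss
  + mean (u(t0) - x0)^2                initial-condition loss
  + mean (du/dt(t_c) - f(u(t_c)))^2    physics loss at collocation points t_c
```

For the inverse problem the ODE parameters are trainable alongside the
network weights and receive their gradient through the physics residual.
`du/dt` is the exact network derivative, computed by propagating a tangent
through every layer (forward-mode differentiation); the backward pass
differentiates through both values and tangents, all implemented in the
package (R with an RcppArmadillo hot loop) and verified against finite
differences in the test suite.

Two classic case studies ship as fixtures:

| case | system | true parameters |
|---|---|---|
| `"logistic"` | logistic growth `dP/dt = r P (1 - P/K)` | `r = 0.5`, `K = 100`, `P0 = 1` |
| `"gene"` | promoter/transcription-factor binding (mass action) | `k_on = 1/60`, `k_off = 0.5/60`, ic `(17, 25, 0)` |

plus a synthetic-data generator, a plain neural-network baseline, and a
runner that reproduces the NN-vs-PINN comparison on sparse noisy data
(sample sizes 10–50, extrapolation-weighted scoring over `t` in `[0, 150]`).

## Worked example: recovering r and K

```r
library(pinnode)

case <- make_case_study("logistic")
obs  <- generate_observations(case$system, case$params,
                              times = case_obs_times(case, 50),
                              ic = case$ic, noise_sigma = 1.0, seed = 42)
cfg  <- training_config(iterations = 20000, log_every = 1000, seed = 42)
report <- run_inverse(case, obs, cfg, seed = 42)
print(report)
```

```
<recovery_report> logistic
 parameter  true   estimate   rel_error
         r   0.5  0.5041903 0.008380614
         K 100.0 99.8875558 0.001124442
```

From 50 observations with noise of 1 population unit (1% of the carrying
capacity), the growth rate is recovered within 0.9% and the carrying
capacity within 0.12%. The training history carries the loss breakdown and
the per-iteration parameter traces:

```r
h <- report$history
cat(sprintf("final losses: data %.4f | ic %.2e | physics %.2e\n",
            tail(h$data_loss, 1), tail(h$ic_loss, 1), tail(h$physics_loss, 1)))
#> final losses: data 1.0272 | ic 6.92e-04 | physics 4.43e-02
has_converged(h, window = 5, tol = 1e-2)
#> [1] TRUE
```

The final data loss sits near `noise_sigma^2 = 1`, i.e. the fit has reached
the noise floor rather than chasing it. `run_forward()` solves the forward
problem the same way with parameters held at truth, `fit_baseline()` trains
the physics-free regressor, and `run_comparison()` runs both on identical
data across sample sizes.

## Command line

A thin wrapper around the same functions:

```sh
exec/pinnode simulate    --case gene --points 300 --out runs/sim
exec/pinnode fit-inverse --case logistic --iterations 20000 --seed 1 --out runs/inv
exec/pinnode compare     --n 10,15,20,30,50 --seed 1 --out runs/cmp
```

Each run directory receives the resolved YAML config (seeds included), the
observations, loss history, parameter traces, predictions, and a model
checkpoint — enough to reproduce the run bit-for-bit.

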