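# stochpop

Spectral and sampling solvers for uncertainty quantification in the
stochastic Verhulst (logistic) population model

$$dX = (a X - \varepsilon X^2)\,dt + \lambda X\,dW, \qquad X(0) = x_0,$$

optionally with an uncertain growth rate
$a(\omega) = a_0 + a_1 \psi_1(\zeta)$, $\zeta \sim U[-1,1]$, $\psi_1$ the
orthonormal Legendre polynomial (so `a1` is the standard deviation of `a`).
The model describes density-limited population growth under environmental
noise; the package is aimed at modellers in population dynamics and
epidemiology who need the *moments* of such models — and a breakdown of
where the variance comes from — without brute-force sampling.

## What it computes

* **Second-order Wiener–Hermite expansion (WHE) solver** (`whe_solve`): the
  SDE is projected onto deterministic kernels $x^{(0)}(t)$,
  $x^{(1)}(t,t_1)$, $x^{(2)}(t,t_1,t_2)$ advanced by an explicit
  finite-difference scheme (stable for $\Delta t < 1/a$). Mean
  $E[X]=x^{(0)}$; variance $= I_1 + I_2$ with Gaussian part
  $I_1 = \int (x^{(1)})^2 dt_1$ and non-Gaussian part
  $I_2 = 2\iint (x^{(2)})^2 dt_1 dt_2$.
* **Coupled gPC–WHE solver** (`gpc_whe_solve`): each kernel is expanded in
  orthonormal Legendre chaos of the random growth rate; the resulting
  deterministic system yields the exact variance split
  $\mathrm{Var}[X] = \mathrm{Var}_{par} + \mathrm{Var}_{noise} +
  \mathrm{Var}_{mix}$ and variance-based sensitivity indices
  ($S_{noise} = \mathrm{Var}_{noise}/\mathrm{Var}[X]$, ...).
* **Analytic oracles**: logistic and Richards closed forms, stationary gamma
  moments ($\gamma(2a/\lambda^2-1, \lambda^2/2\varepsilon)$ for
  $a > \lambda^2/2$), exact geometric-Brownian-motion moments.
* **Sampling references**: Euler–Maruyama (`em_paths`), the exact pathwise
  solution (`exact_path_samples`), and nested parameter-plus-noise Monte
  Carlo (`nested_mc`) for independent validation.
* **Experiment presets and I/O**: `run_preset` ("fig2", "table1", "table2",
  ...) writes reproducible CSV tables with manifests; a thin CLI lives at
  `inst/cli/stochpop.R` (verbs `solve`, `preset`, `compare`).

See `vignettes/stochastic-logistic-uq.Rmd` for the kernel equations, the
discretization conventions, and the design decisions.

## Worked example

Growth rate uncertain by 2% (sd 0.01 around 0.5), noise $\lambda = 0.02$:

```r
library(stochpop)
p <- pop_params(a0 = 0.5, eps = 0.01, x0 = 0.5, lam = 0.02, a1 = 0.01)
fit <- gpc_whe_solve(p, time_grid(dt = 0.05, t_end = 50))
summary(fit)
#> Coupled gPC-WHE solution of the stochastic logistic model
#>   a0 = 0.5, eps = 0.01, lambda = 0.02, x0 = 0.5, a1 = 0.01 (reference, P = 1)
#>   grid: dt = 0.05, 1000 steps (t_end = 50); converged to steady state
#>   final mean = 49.9805, total variance = 1.97415
#>   variance split: par 0.999945 / noise 0.974001 / mix 0.000204
#>   nonGaussian share of total variance at t_end: 0.007184%
#>   sensitivity indices: S_noise = 49.3%, S_par = 50.7%, S_mix = 0.01%
```

Reading: the population settles just below the carrying capacity
$L = a_0/\varepsilon = 50$ (the noise shaves off $\lambda^2/2\varepsilon$).
A mere 2% spread in the growth rate contributes as much steady-state
variance (`var_par` ≈ 1.00) as the driving noise itself (`var_noise` ≈ 0.97,
which matches the stationary gamma variance 0.9996 for deterministic $a$),
so the sensitivity is split about 50/50; the noise–parameter interaction
(`var_mix`) is three orders of magnitude smaller, and the non-Gaussian
correction is negligible at this noise level. With a deterministic rate
(`a1 = 0`) the same call collapses to `whe_solve` output exactly.

Cross-check by simulation:

```r
sim <- simulate(fit, nsim = 500, seed = 11, dt_mc = 0.02, n_param_draws = 200)
round(as.data.frame(tail(sim, 1))[, c("mean", "variance", "var_between", "var_within")], 4)
#>         mean variance var_between var_within
#> 2501 49.8419    1.869       0.875     1.0003
```

(the between/within split is the sampling analogue of
`var_par` / `var_noise`, within its Monte Carlo error of the spectral
values).

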