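# demsoc

Social evolution under demographic stochasticity in well-mixed
populations of fluctuating size.

Whether an indiscriminate social trait — altruism or spite — is favoured
in a finite population depends on more than its effect on the expected
change in frequency. `demsoc` implements a complete workflow for the
two-type birth–death–mutation model in which social actors (density
`x1`) alter everyone's per-capita birth rate `b(x)` or death rate
`m(x)`, pay a cost `ε·c(x)`, and interconvert with non-actors at
mutation rate `μ` in a habitat of size `Ω`. On the slow evolutionary
timescale the actor frequency `p` follows the diffusion

```
dp = α(p) dt + √(σ²(p)) dW
α(p)  = μ(1 − 2p) − ε c(p) p(1 − p)
σ²(p) = p(1 − p) T(p) / (Ω n(p))
```

with `n(p)` the quasi-equilibrium density on the curve `b = m` and
`T(p) = b(p) + m(p) = 2m(p)` the population turnover. The drift carries
no noise-induced bias; what decides stochastic favourability is the
**turnover-to-size ratio `T(p)/n(p)`** — the process lingers where
populations are large and turnover is slow. The package computes the
ratio and its size/turnover decomposition, the stationary distribution
`π(p)` (general quadrature plus closed forms), the favourability
criterion `∫_{1/2}^1 π dp > 1/2`, selective-reversal scans, the optimal
social-action strength `ν*` minimizing `T/n`, and — as the exact
counterpart — seeded Gillespie simulation of the full individual-based
process and Euler–Maruyama integration of the frequency and multi-type
density SDEs.

## Worked example

Two altruism models with *identical* deterministic drift but different
turnover (`T/n` constant versus decreasing in `p`) get opposite
verdicts under a cost, at small habitat size:

```r
library(demsoc)

m1 <- model_preset("linear_altruism")    # b = 0.6 + x1, m = 1.2 n
m2 <- model_preset("turnover_altruism")  # b = 3 + x1,   m = 2.4 + 1.2 n

p <- seq(0, 1, 0.05)
max(abs(diffusion_coefficients(m1, p)$alpha -
        diffusion_coefficients(m2, p)$alpha))
#> [1] 4.336809e-19

reversal_scan(m2, omega_values = c(25, 100, 400, 800),
              epsilon_values = 0.003)[, 1:4]
#> # A tibble: 4 × 4
#>   omega epsilon mass_above_half favoured
#>   <dbl>   <dbl>           <dbl> <lgl>
#> 1    25   0.003           0.510 TRUE
#> 2   100   0.003           0.506 TRUE
#> 3   400   0.003           0.506 TRUE
#> 4   800   0.003           0.492 FALSE
```

For `m2` the costly altruist holds more than half the stationary mass
at small `Ω` — demographic stochasticity reverses selection — while the
same scan on `m1` stays below 1/2 at every habitat size. The exact
process agrees: a Gillespie run's time-weighted occupancy histogram
matches `π(p)` to a few percent total variation
(`simulate_ssa()`, `stationary_density()`, `favourability()`).

The optimal strength of social action in a monomorphic population:

```r
optimal_social_action("birth_altruism",
                      list(beta = 1, d = 0.5, kappa1 = 0.75, kappa2 = 0.01))
#> # A tibble: 1 × 7
#>   family         nu_star_closed nu_star_numeric theta objective boundary agree
#>   <chr>                   <dbl>           <dbl> <dbl>     <dbl> <lgl>    <lgl>
#> 1 birth_altruism           0.75           0.750  7.07      1.78 FALSE    TRUE
```

`β = 2d` makes the closed form `ν* = κ₁ − |β − 2d|/θ` collapse to `κ₁ =
0.75`, and direct minimization of `T(1)/n(1)` lands on the same value.

A thin CLI (`inst/cli/demsoc`) runs any analysis from a YAML config:
`demsoc run config.yaml --output out/` (see `?read_run_config`).

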