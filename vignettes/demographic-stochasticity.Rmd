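---
title: "Methods: social evolution under demographic stochasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social evolution under demographic stochasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demsoc)
```

## The model

`demsoc` studies a well-mixed population of `omega * n(t)` individuals of
two types: social actors (type 1), whose presence indiscriminately alters
the birth or death rate of every individual, and non-actors (type 2).
All individuals share a per-capita birth rate `b(x)` and death rate
`m(x)` that depend on the per-type densities `x = (x1, x2)`; actors pay
an extra per-capita cost `epsilon * c(x)`, and the two types interconvert
by mutation at per-capita rate `mu`. Altruism enhances the recipients'
vital rates (raises `b` or lowers `m`); spite inhibits them.

When selection is weak (`epsilon` small), mutation rare and the habitat
size `omega` large, demography is fast relative to evolution, and the
population sits near the curve of ecological equilibria `b = m`
parameterised by the actor frequency `p`. Eliminating the fast dynamics
leaves a one-dimensional diffusion for `p`:

    dp = alpha(p) dt + sqrt(sigma2(p)) dW
    alpha(p)  = mu (1 - 2 p) - epsilon c(p) p (1 - p)
    sigma2(p) = p (1 - p) T(p) / (omega n(p))

where `n(p)` is the quasi-equilibrium density and `T(p) = b(p) + m(p) =
2 m(p)` is the population turnover, equal at neutrality to the variance
in per-capita growth rate. Everything the package computes flows from
this pair of coefficients and from the exact individual-based process
they approximate.

The central object is the ratio `T(p) / n(p)`. The drift carries no
noise-induced directionality, so whether the actor is *stochastically*
favoured is decided by where the process moves slowly: states with large
populations (small frequency steps) and low turnover (infrequent steps).
Differentiating,

    d/dp [T/n] = (T/n) * ( -(dn/dp)/n  +  (dT/dp)/T )

splits the effect of the trait into a population-size term and a
turnover term (`slow_manifold()`, `turnover_ratio_decomposition()`).
For social action on the death rate the two terms agree in sign, so
altruism is always stochastically favoured and spite disfavoured. For
action on the birth rate they oppose, so either trait can win, and an
intermediate strength of social action can minimise `T/n`
(`optimal_social_action()`).

Favourability itself is an occupancy statement: the actor is favoured
when the stationary distribution `pi(p)` of the diffusion places more
than half its mass above `p = 1/2` (`favourability()`). With a cost
(`epsilon > 0`) a favourable verdict is a *selective reversal*:
demographic noise overcomes deterministic selection.

## Model families and parameters

All rate functions take densities (counts divided by `omega`), so the
analytic quantities are `omega`-free and `omega` enters only through
`sigma2` and the simulators. Time units are arbitrary but shared by all
rates. The shipped families and constraints are listed by
`list_models()`; the worked parameter sets used throughout the package
are available as `model_preset()` objects:

* death-rate action: `b = 3 (1 - n)`, `m = 1 + nu * x1 / n`,
  `omega = 900`, `mu = 0.006`, with `nu = -0.95`, `0`, `0.95`
  (altruism / neutral / spite);
* birth-rate altruism: `b = 1 + nu * x1`,
  `m = 0.5 + 0.75 n + 0.01 n^2`, `omega = 250`, `mu = 0.01`,
  `nu = 0.75` (the optimal strength);
* birth-rate spite: `b = 8 (1 - nu * x1 / (n + 0.05))`, same quadratic
  mortality form with `kappa1 = 0.05`, `kappa2 = 0.2`, `omega = 900`,
  `mu = 0.005`, `nu = 0.75`;
* the reversal pair: `linear_altruism` (`b = 0.6 + x1`, `m = 1.2 n`,
  cost `c = 0.6`) and `turnover_altruism` (`b = 3 + x1`,
  `m = 2.4 + 1.2 n`, `c = 0.6`). The two have identical per-capita
  growth rates, hence pointwise identical drift `alpha(p)`, but the
  second has elevated baseline turnover: `T/n` is constant in the first
  and linearly decreasing in the second, which is exactly what permits
  a reversal there and forbids it in the first.

The reversal presets carry `epsilon = 0.003` and `omega = 100`. Their
mutation rate is a package choice: the reversal phenomenon needs a
stationary distribution (`mu > 0`) but is otherwise robust to `mu`, and
we fix `mu = 0.01` in the presets so that `mu * omega` is of order one
-- the regime in which both U-shaped and unimodal distributions are
reachable by varying `omega` alone. Every scan function takes `mu`
explicitly via its model argument.

The cost enters the exact process on the actor's death channel by
default (`cost_on_death = TRUE`), which keeps every channel rate
non-negative; subtracting it from the actor's birth rate instead is a
constructor switch. At the order kept by the diffusion the two
placements give the same `alpha(p)`, and the package treats the choice
as a simulation detail, not a model difference. Mutation is implemented
as conversion of a living individual (rate `mu` per capita), not as
birth with mutation.

## Numerical choices

**Quasi-equilibrium roots.** The built-in families have closed-form
stable roots of `b = m` (linear, quadratic or cubic in `n`), and
`quasi_equilibrium_density()` uses them directly: the stationary
integrator evaluates `n(p)` thousands of times, and the closed forms
are exact and fast. Custom models use a bracketed scan-and-polish
search (`uniroot`, 512-point scan, expanding bracket) with stability
decided by the finite-difference sign of `d(b - m)/dn`; multiple stable
roots raise an error asking for an explicit bracket rather than picking
one silently. Tests pin the numeric path to the closed forms.

**Stationary quadrature.** `stationary_density()` uses the standard 1-D
diffusion formula `pi \propto (1/sigma2) exp(int 2 alpha / sigma2)`.
The integrand has `1/p` and `1/(1-p)` poles from mutation; writing
`g(p) = 2 omega n(p) / T(p)`, the poles are split off analytically,
giving exact boundary exponents `a0 = mu g(0)`, `a1 = mu g(1)` on `p`
and `1 - p` and a smooth remainder integrated by cumulative trapezoid
anchored at `p = 1/2` (so the cumulative integral never traverses a
boundary). Normalisation happens in log space with analytic power-law
tail corrections below the first and above the last grid point; the
default grid is 4001 points at distance `1e-4` from the boundaries.
The density is declared non-normalisable exactly when a boundary
exponent is `<= 0` (i.e. `mu = 0`), with the exponents returned as the
diagnostic; there is no silent renormalisation. Shape classification
('U', 'bell', 'boundary-unimodal') combines the boundary exponents
(divergence iff `a < 1`) with strict interior modes of the log-density
at a tie threshold of `1e-10`.

**Closed forms.** For `linear_altruism` the construction collapses to a
symmetric Beta density times an exponential cost tilt; for
`turnover_altruism` it gives
`p^(A-1) (1-p)^(B-1) (beta kappa - d nu p)^(E-A-B-1)` with
`A = mu omega r / (beta kappa)`, `B = mu omega r / (beta kappa - d nu)`,
`E = epsilon omega r^2 / (d nu)`. Both closed forms were derived
independently of the integrator and the two routes are required to
agree in the test suite (sup relative error `1e-6` and `1e-4`
respectively), which certifies the exponents.

**Exact simulation.** `simulate_ssa()` is the direct Gillespie method
with per-event rate recomputation; no tau-leaping, because the exact
process is the oracle against which the diffusion is judged.
Occupancy histograms weight each state by its holding time -- the
stationary density is an occupancy measure, and event sampling would
over-represent high-turnover states. Rate formulas that go negative on
stochastic excursions (e.g. logistic birth beyond `n = 1`) are clamped
at zero and counted. Replicate seeds derive from the master seed by a
fixed `sample.int` draw, and a given seed reproduces the event sequence
bit for bit.

**SDE integration.** The frequency SDE uses Euler-Maruyama with
coefficients interpolated from a 401-point table and the state clipped
to `[0, 1]`; the default step is `0.01 / max(T)` and steps above
`0.5 / max(T)` are refused. Clipping introduces no sticky boundary:
with `mu > 0` the tests bound the fraction of time spent exactly on a
boundary. The multi-type density system uses independent Wiener
increments per type with demographic noise pooled as `b + m + eps c`
per capita and a reflecting floor at zero (hits counted). Independence
of the increments is the standard diffusion limit of independent birth
and death channels; the package validates the resulting occupancy
against the exact process rather than assuming it.

**Optimal social action.** `nu*` is computed twice: from the printed
closed forms (`nu* = kappa1 - |beta - 2 d| / theta` for altruism,
`theta = sqrt(d / kappa2)`; `(a + theta)(beta - 2 d - kappa1 theta) /
(beta theta)` for spite) and by golden-section minimisation of
`T(1)/n(1)` at tolerance `1e-9`. The numeric optimum is authoritative:
for `beta < 2 d` the absolute value in the altruism formula points the
wrong way (the interior optimum sits at `kappa1 + (2 d - beta)/theta`),
and the result flags the disagreement instead of hiding it.

## What the simulations emulate, and what they do not

The package generates all of its own data: seeded Gillespie
realisations of the exact individual-based process and Euler-Maruyama
paths of the reduced SDEs. These reproduce demographic stochasticity --
integer-valued, density-dependent birth, death, cost and mutation
events -- under the stated well-mixed assumptions. They do not emulate
spatial or deme structure, age or stage structure, environmental
fluctuations, kin discrimination, or interaction heterogeneity of any
kind; agreement between simulation and analytics here therefore says
nothing about systems where those forces matter. The diffusion is an
`O(epsilon/omega, mu/omega)` approximation: at small `omega` (tens of
individuals) visible discrepancies between the exact occupancy and
`pi(p)` are expected and real.

Test problem sizes are deliberately desk-scale: occupancy comparisons
pool a few realisations of 1.5-2 x 10^4 time units (total-variation
tolerance 0.05 against the analytic density), fixation fractions use
1500-4000 replicates judged at three binomial standard errors, and the
drift-decomposition checks use ensembles of 400-800 short paths. The
qualitative claims they check (favourability verdicts, shape regimes,
reversal versus no-reversal) are insensitive to these sizes; the
quantitative tolerances are set by the Monte-Carlo error at the stated
ensemble sizes.

## Known limitations

* The slow-manifold reduction is one-dimensional and two-type; the
  multi-type trait-ladder analysis is simulation-only
  (`simulate_density_sde()`), as no k-type reduction is provided.
* `stationary_density()` requires `mu > 0`; quasi-stationary behaviour
  of the absorbing (`mu = 0`) process is out of scope, where only
  fixation probabilities are offered.
* Environmental state dependence of the rates is not supported: rate
  functions see densities only.
* The `birth_spite` cubic can in principle have multiple positive
  stable roots in extreme parameter corners; the constructor picks the
  smallest stable root, and custom models should be used with an
  explicit bracket if that is not the intended branch.

## A worked reversal analysis

```{r, eval = FALSE}
library(demsoc)

m1 <- model_preset("linear_altruism")    # T/n constant
m2 <- model_preset("turnover_altruism")  # T/n decreasing in p

# identical deterministic drift ...
max(abs(diffusion_coefficients(m1, seq(0, 1, 0.01))$alpha -
        diffusion_coefficients(m2, seq(0, 1, 0.01))$alpha))

# ... opposite stochastic verdicts across habitat sizes
reversal_scan(m1, omega_values = c(25, 50, 100, 400),
              epsilon_values = 0.003)
reversal_scan(m2, omega_values = c(25, 50, 100, 400),
              epsilon_values = 0.003)

# and the exact process agrees with the analytic stationary density
d <- stationary_density(model_preset("deathrate_altruism"))
sim <- simulate_ssa(model_preset("deathrate_altruism"), c(530, 59),
                    t_max = 20000, seed = 1, record = "none",
                    bins = 40, burn_in = 1000)
plot(sim$occupancy$p_mid, sim$occupancy$mass, type = "h")
lines(d$grid$p, d$grid$density / 40)
```
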