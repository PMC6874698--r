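# evofit

Tools for modelling natural selection in deterministic self-replicating
systems with strong inheritance — populations of genotypes, behavioural
strategies or functional traits in which offspring carry their parents'
strategy exactly.

## The problem and the approach

When many strategies compete simultaneously, comparing a handful of
"pure" types tells you little: selection acts on *sets* of strategies in
a compact strategy space *V*, and the natural bookkeeping device is a
measure μ(t)(A) of the presence of each strategy set *A*, represented by
a density η(v, t) so that μ(t)(A) = ∫_A η(v, t) dv.

`evofit` implements this measure-dynamics view end to end:

- **Selection** of a set *A*: the measure of its complement vanishes at
  large times while the measure of *A* does not.
- **Ranking order** v ≻ w: the ratio η(w′, t)/η(v′, t) tends to zero
  *uniformly* over neighbourhoods of the two strategies.  The uniformity
  matters: the package ships a benchmark (`transient_logistic_model()`)
  in which the density decays pointwise to zero at every strategy while
  the total measure stays identically 1.
- **Evolutionary fitness** J(v): any functional that preserves the
  ranking order.  Empirically, J₁(v) is the long-term time average of
  the per-capita growth rate of η, computable from a trajectory as
  (ln η(v, T) − ln η(v, T₀))/(T − T₀); at a selection equilibrium the
  maximal J₁ is zero (transversality).
- **Analytic fitness** for two model classes where J can be read off the
  coefficients, independent of initial conditions:
  - *stage-structured models* z′ = L(v)z − R(v)y(t)z:
    J(v) = λ₁(v)/R(v), the dominant eigenvalue of the life-history
    matrix over the limitation sensitivity;
  - *delay models* (maturation lags, age structure):
    J(v) = max Re λᵢ(v)/R(v), the rightmost root of the transcendental
    characteristic equation det(H(λ) − λE) = 0 with
    H_{lj}(λ) = Σᵢ q_{lji} e^{−λτᵢ} + r_{lj}.
  A von Foerster age-structured population with piecewise-constant
  rates reduces exactly to such a delay system
  (`foerster_to_delay()`).

The generalised density may be a strategy-dependent power of the
population density, η = ρ^{1/R(v)} (`transform_density()`), and the
package carries log-space representations so density ratios remain
meaningful down to e⁻¹⁰⁰ and beyond.

## Worked example

Logistic competition with a reproduction/competition trade-off
k(v) = 1 + v against r(v) = 1 + v²/2, whose analytic fitness k/r is
maximised at v* = √3 − 1 ≈ 0.732:

```r
library(evofit)
g     <- strategy_grid(101)                       # [0, 1], trapezoid weights
fam   <- tradeoff_family("linear-quadratic", g)
model <- nonlocal_logistic_model(g, k = fam$k, r = fam$r,
                                 rho0 = 1, coupling = "total")
field <- simulate_nonlocal_logistic(model, horizon = 600,
                                    times = seq(0, 600, length.out = 201))
eta   <- generalised_density(field, model)        # eta = rho^{1/r(v)}
land  <- fitness_landscape(eta, window = c(300, 600))
attr(land, "argmax")
#> [1] 0.73
land[land$v %in% c(0, 0.5, 0.73, 1), ]
#>        v            J1 converged
#> 1   0.00 -0.3651082864      TRUE
#> 51  0.50 -0.0317749530      TRUE
#> 74  0.73  0.0009148492      TRUE
#> 101 1.00 -0.0317749530      TRUE
rank_pair(eta, 0.73, 0.2)
#> ranking_report: v = 0.73 vs w = 0.2 -> v_better (radius 0.02, tol 1e-04)
```

The simulated winner is the grid node nearest √3 − 1; its long-term
average per-capita growth rate is ≈ 0 (the transversality property),
and every dominated strategy's density ratio vanishes, giving
`v_better` verdicts consistent with the landscape.

Analytic fitness needs no simulation:

```r
sm <- stage_model(2, b = function(v) c(0, 2 + v), a = c(0.1, 0.2),
                  p = 1, R = 1, grid = strategy_grid(21))
head(stage_fitness(sm), 3)       # J = lambda1 / R per strategy
#>      v   lambda1 R         J complex_dominant
#> 1 0.00 0.8340822 1 0.8340822            FALSE
#> 2 0.05 0.8508331 1 0.8508331            FALSE
#> 3 0.10 0.8673991 1 0.8673991            FALSE
rightmost_root(delay_model(1, tau = 1, q = 1, r = 0))
#>          re im residual
#> 1 0.5671433  0        0
```

A thin command-line interface lives at `inst/cli/evofit.R`
(`simulate | fitness | rank | roots | make-fixture`, each with
`--dry-run`), reading JSON model specs via `load_model_spec()` and
writing CSV/JSON results plus a manifest via `write_results()`.

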