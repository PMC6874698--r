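---
title: "Measure dynamics, ranking orders and evolutionary fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measure dynamics, ranking orders and evolutionary fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evofit)
```

## The model class

`evofit` models selection in deterministic self-replicating systems
with *strong inheritance*: offspring carry their parents' strategy
exactly, so no new strategies appear after the initial time.  The
strategy space $V$ is compact — here discretised to an ordered grid on
$[0,1]$ with positive quadrature weights (`strategy_grid()`).  The
presence of a strategy set $A$ at time $t$ is a measure
$\mu(t)(A) = \int_A \eta(v,t)\,dv$, computed as a quadrature of the
density $\eta$ over a node mask (`measure_of_set()`).  Subsets are node
masks: the finite $\sigma$-algebra of the discretisation.  Borel sets
are approximated by their grid traces, which means a set boundary
falling *on* a node carries that node's full weight; quadrature
additivity over disjoint masks is then exact (to floating point), and
the half-cell discrepancy against a continuum interval vanishes as
$O(h)$.

Three families of density dynamics are built in:

* the cyclic three-strategy replicator system
  (`simulate_replicator()`), whose interior equilibrium
  $(1/3,1/3,1/3)$ attracts all interior trajectories while each face
  (one strategy absent) selects a different winner — the standard
  example that ranking orders depend on initial conditions;
* nonlocal logistic competition
  $\dot\rho = k\rho - \text{(loss)}\cdot\rho$ with an integral
  competition term over the whole strategy space
  (`nonlocal_logistic_model()`), in the mean-reproduction form
  ($\text{loss} = \int k\rho\,dv$) and the weighted-total form
  ($\text{loss} = r(v)\int\rho\,dv$);
* stage-structured and delay life-history models (below).

## Ranking and empirical fitness

Strategy $v$ outranks $w$ when $\eta(w',t)/\eta(v',t)\to 0$ uniformly
over neighbourhoods of the two points.  A finite simulation cannot
observe a limit, so `rank_pair()` operationalises it as: the supremum
of the directed ratio over all node pairs in the two neighbourhoods
must fall below a tolerance (default $10^{-4}$) *and* decrease
monotonically across the last three dyadic time windows
($[T/8,T/4]$, $[T/4,T/2]$, $[T/2,T]$).  The trend test is deliberate:
the long-time limit may simply not exist (periodic successions), and
such runs must come back `incomparable` rather than as a number.  Both
directed ratios are computed, making verdicts anti-symmetric by
construction; `ranking_consistency_check()` audits a verdict set for
transitivity.  The default neighbourhood radius is two grid spacings —
one node would make uniformity over a neighbourhood vacuous, while a
large radius blurs distinct strategies together.

Empirical fitness is the long-term average per-capita growth rate of
$\eta$, estimated on a window as
$J_1(v) = (\ln\eta(v,T)-\ln\eta(v,T_0))/(T-T_0)$
(`time_average_fitness()`).  Convergence is assessed by comparing the
two half-window averages; `fitness_landscape()` flags non-converged
nodes and excludes them from the argmax set, because a window average
that is still drifting (typically a strategy whose density has
underflowed the solver's absolute tolerance) is solver noise, not a
fitness.  Ties within `tie_tol` of the maximum are reported as a set:
a polymorphic maximum is a set of strategies, not a point.

At a selection equilibrium the winner's average per-capita growth rate
is zero (transversality).  On the linear trade-off benchmark
($k = 1+v$, $r \equiv 1$, 101 nodes, horizon 500, window $[250,500]$)
the landscape argmax sits at $v=1$ with $J_1 \approx 6\times10^{-4}$:
the residual is the slow $1/t$ sharpening of the selection peak, and
shrinks as the horizon grows.

## A cautionary benchmark: density versus measure

`transient_logistic_model()` implements logistic dynamics with the
time-dependent reproduction $k(v,t) = vt e^{-vt}$ from a uniform
initial density.  Its closed-form solution is
$\rho = g/\!\int_0^1 g\,dv$ with
$g(v,t) = \exp(-te^{-vt} + (1-e^{-vt})/v)$; at $v=0$ the exponent's
second term has the analytic limit $t$, so $g(0,t)=1$ *exactly* — the
implementation uses the series limit rather than an $\varepsilon$
offset precisely to preserve this identity
(`transient_growth_factor()`).  The density decays to zero pointwise
at every strategy, yet the total measure is identically 1: pointwise
density decay does not imply measure decay, which is why ranking is
defined through uniform convergence over neighbourhoods.

Numerically the package reproduces this pathology discretely: the
integral coupling uses the same quadrature weights as
`measure_of_set()`, so the discrete total-measure identity holds
exactly along trajectories (to solver tolerance), and the discretised
system's exact solution is $g$ normalised by the *grid* quadrature of
$g$.  `transient_exact_density()` therefore offers both
normalisations; comparing the simulation with the grid-normalised form
isolates solver error ($\sim 10^{-10}$), while the continuum
normalisation adds the $O(h^2)$ quadrature error of $\int g$ on the
sharply peaked $g$ ($\sim 10^{-6}$ on 201 nodes at $t=50$).

## Log-space integration

Ranking reads off ratios of densities that separate exponentially: two
strategies whose fitnesses differ by $0.5$ reach a ratio of $e^{-100}$
by $t = 200$.  The nonlocal logistic solver therefore integrates
$\ln\rho$ at nodes with positive initial density (nodes starting at
zero stay exactly zero — strong inheritance is enforced structurally,
not numerically).  The integral coupling is reconstructed from
$e^{\ln\rho}$ at each step, so the scheme is the same dynamics in
different coordinates, but relative accuracy is uniform across 300
orders of magnitude and simulated fields carry a `"log_values"`
attribute that `rank_pair()` and `time_average_fitness()` use
directly.  The stage and delay solvers work in linear coordinates
(their stage-mixing is additive and has no useful log form); dominated
strategies there eventually underflow, which is exactly what the
convergence flags surface.

Default tolerances are `rtol = 1e-8` (stiff-capable `lsoda`
throughout), tightened to `1e-10` where a conservation identity is
itself the quantity of interest.

## Stage-structured models

`stage_model()` encodes $n$ developmental stages with fecundities
$b_i$ ($b_1 = 0$), mortalities $a_i$, transitions $p_i$ and limitation
sensitivity $R>0$; `build_stage_matrix()` assembles the Metzler
life-history matrix (first row $-p_1-a_1, b_2,\dots,b_n$; subdiagonal
$p_{i-1}$; diagonal $-p_i-a_i$ with $p_n = 0$).  The analytic fitness
is $\lambda_1(v)/R(v)$ (`stage_fitness()`), independent of initial
conditions.  The generalised reproduction coefficient of the frequency
dynamics uses the weighted-column-sum convention
$F = \sum_j (\sum_i q_{ij})\,\xi_j$ — the only reading under which the
frequency simplex is exactly invariant and the total-density equation
closes.  Eigenvectors are normalised to unit component sum only for
the dominant (Perron) vector of the Metzler matrix, where the
normalisation is meaningful; other eigenvectors are scaled by their
maximum-modulus component.  A complex or repeated dominant eigenvalue
violates the realness assumption under which $\lambda_1/R$ is a
fitness; such models are flagged and the real part is used.

## Delay models and characteristic roots

`delay_model()` covers systems
$\dot z_l = \sum_{j,i} q_{lji} z_j(t-\tau_i)
 e^{-R\int_{t-\tau_i}^{t} f} + \sum_j r_{lj} z_j - R z_l f$.
The running limitation integral $\Phi(t)=\int_0^t f$ is carried as an
auxiliary state so delayed survival factors use stored values
$\Phi(t)-\Phi(t-\tau_i)$, never re-quadrature; $\Phi$ is extended by 0
backwards of $t=0$ (the limitation history before observation starts
is taken as absent — a modelling choice, recorded here).  Integration
uses deSolve's delay solver (dense stored history with adaptive
stepping).  The substitution $\zeta = z\,e^{R\Phi}$ removes the
limitation exactly; `change_of_variables_check()` verifies this
identity numerically per strategy.

Fitness is $\max_i \Re\lambda_i(v)/R(v)$ with $\lambda_i$ the roots of
$\det(H(\lambda)-\lambda E)=0$.  `rightmost_root()` proceeds in three
stages: (i) a sign scan plus Newton polish (analytic derivative via
Jacobi's formula) along the real axis up to the row-sum bound
$\max_l \sum_j(\sum_i |q_{lji}| + |r_{lj}|)$, which bounds the real
part of any root; (ii) polish from local minima of $|\det|$ to catch
near-real complex pairs; (iii) argument-principle counting on
rectangles in the upper half plane with recursive bisection, polished
root located for every counted zero — a count/located mismatch raises
an error rather than a silently wrong answer.  Complex enumeration
covers real parts within 0.5 of the rightmost real root (or down to
the floor when no real root exists): enumerating much deeper is
possible via the `floor` argument but the number of roots grows
rapidly as the floor drops, and the fitness only ever consumes the
rightmost root.  Every reported root satisfies a residual contract
($|\det| < 10^{-10}$) and can be validated by substitution
(`validate_root()`).

`foerster_to_delay()` reduces an age-structured transport model with
piecewise-constant rates on age classes $[\tau_{i-1},\tau_i)$ to this
delay form: stage $l$ gains maturing individuals delayed by
$\tau_{l-1}$ and loses them delayed by $\tau_l$, each discounted by
cumulative survival $\exp(-\sum_{k} a_k(\tau_k-\tau_{k-1}))$; the last
stage has no outflow.  The newborn inflow of stage 1 is *undelayed*
($\tau_0 = 0$), and a zero delay with unit survival factor is exactly
an instantaneous term, so it is folded into the first row of $r$
(diagonal $-a_l$ otherwise).  The reduction is validated dynamically:
the simulated growth rate of the linear system equals its rightmost
characteristic root.

## Synthetic fixtures

All tests run on fixtures generated in code (`random_stage_model()`,
`random_delay_model()`, `tradeoff_family()`), deterministic in a
single seed.  Stage coefficients are positive low-order polynomials of
$v$ (the continuity the theory requires), with $p_i > 0$ and some
$b_i > 0$ guaranteeing irreducibility; delay fixtures have nonnegative
$q$, diagonally dominant negative $r$ and delays in $[0.1, 2]$, with
the rightmost root certified below a requested cap.  These fixtures
emulate the structure of the theory's model classes — smooth
coefficients, bounded measures, separated fitness where requested —
but not features of real data: no noise, no mutation, no stochastic
extinction.  Passing tests demonstrate the internal consistency of the
machinery (analytic fitness predicts simulated winners; identities
hold numerically), not the fit of any model to observations.

Problem sizes used by the test suite and the reproduction script —
grids of 101–201 nodes for logistic runs, 5–21 nodes for landscape
fixtures, horizons 200–500 (and $4\times10^4$ for the slowly
converging replicator faces), 10–20 seeded fixtures per property —
were chosen as the smallest sizes at which the asymptotic claims are
cleanly visible.

## Known limitations

* One-dimensional strategy spaces only; $d>1$ would need tensor grids
  and a different neighbourhood geometry.
* No mutation kernels, stochasticity or extinction thresholds; the
  strong-inheritance assumption is structural.
* Distributed (integral) delays are out of scope; only discrete lags.
* The finite-horizon ranking verdicts are conservative: `incomparable`
  means "not established at this horizon/tolerance", not "provably
  incomparable".
* For models whose dominant characteristic root is complex, the
  fitness uses the real part and the model is flagged as outside the
  realness assumptions of the underlying theory.
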