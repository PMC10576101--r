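---
title: "Modelling panic spread driven by an opinion-field game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling panic spread driven by an opinion-field game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panicseir)
```

## The model

When a major emergency hits, two "opinion fields" shape how panic moves
through a population. The *official* field (state media, authorities)
chooses between positive and negative guidance; the *public* field
(informal channels) chooses between positive and negative response. Their
interaction is an asymmetric 2x2 game, and the panic itself spreads like a
contagion through the population the two fields are addressing.

`panicseir` implements this as a one-way coupled system: an evolutionary
game layer whose strategy probabilities feed, but are not fed by, a delayed
SEIR compartment layer.

### The game layer

Let $x_1$ be the probability that the official field plays positive
guidance and $y_1$ the probability that the public field responds
positively ($x_2 = 1-x_1$, $y_2 = 1-y_1$ are derived, never stored, so the
simplex constraints hold by construction). The payoff constants are the
benefits $B_1, B_2$ (official) and $B_3,\dots,B_6$ (public, one per
strategy pair) and the costs $C_1, C_{11}, C_{21}$, with the orderings
$B_1 > B_2$ and $B_3 > B_4 > B_5 > B_6$ enforced at construction.

Classically, a strategy's share grows with its payoff advantage over the
population average. Here the replicator is *modified*: strategies within
the same group are not independent — how strongly one strategy's adherents
influence the group is an influence coefficient $\kappa_i$, and the ratio
$\kappa_\alpha/\kappa_i$ (the *dependence coefficient*) enters the share
dynamics. For a group with counts growing as
$n_i' = \kappa_i n_i u_i$, the shares obey

$$z_i' = z_i \kappa_i \Big[u_i - \bar u +
  \sum_\alpha \big(1 - \tfrac{\kappa_\alpha}{\kappa_i}\big) z_\alpha u_\alpha\Big],$$

which `general_replicator_rhs()` implements for any number of strategies
(derivatives sum to zero; equal $\kappa$ recovers the textbook
replicator). For the two two-strategy fields this specializes to

$$\dot x_1 = \lambda_1 x_1(1-x_1)\,(u_1^A - p_{21} u_2^A), \qquad
  \dot y_1 = \rho_1 y_1(1-y_1)\,(u_1^B - q_{21} u_2^B),$$

with $p_{21} = \lambda_2/\lambda_1$ and $q_{21} = \rho_2/\rho_1$
(`replicator_rhs()`). Values below 1 accelerate convergence to the stable
strategy pair, values above 1 slow it; $p_{21} = q_{21} = 1$ is the
classical replicator.

Both selection "brackets" are affine in the opposite field's probability,
so the four strategy corners are always fixed points, and an interior
point exists only when both brackets can vanish inside the unit square
(`find_equilibria()`; the closed form is used, and the point is reported
only when strictly interior — boundary or out-of-range values are
suppressed with a logged note, since a boundary "interior" point is
already one of the corners' basin boundaries, not a meaningful rest
point). Stability is read off the 2x2 Jacobian (hand-coded partials,
cross-checked against central finite differences): det $> 0$ and
trace $< 0$ is an evolutionarily stable strategy (ESS), det $> 0$ and
trace $> 0$ unstable, det $< 0$ a saddle (`classify_equilibrium()`).

`classify_scenario()` evaluates the sign conditions that partition
parameter space into the tabulated stability cases: when both degeneracy
conditions $B_5 - B_3 + C_{21} + q_{21}(B_4 - C_{21}) - q_{21}B_6$ and
$(1 - p_{21})(B_2 + C_{11} - B_1)$ vanish, two signs decide among four
subcases; when only the first vanishes, eight sign combinations each
single out one ESS corner. Everything else — including any deciding
quantity within the sign tolerance — falls back to numeric
per-equilibrium classification. We chose an absolute sign tolerance of
$10^{-9}$: the case analysis treats strict inequalities only, so anything
inside the band is honestly labelled degenerate rather than forced into a
case.

### The contagion layer

The population splits into susceptible, exposed, infective and recovered
individuals ("infection" here is panic, not a pathogen). New exposures
follow Holling type II saturated incidence
$\beta S I_\tau / (1 + \alpha I_\tau)$, evaluated at the *lagged*
infective count $I_\tau = I(t - \tau)$: it takes time $\tau$ for exposure
pressure to materialize. The game probabilities set the transition rates —
official authority $m$ moves susceptibles to recovered at rate $m x_1$ and
exposed to infective at rate $m x_2$; the public response moves exposed to
recovered at rate $y_1$ and exposed to infective at rate $y_2$; infectives
recover at rate $\gamma$; immigration enters at rate $a$. The four
derivatives sum to $a$ identically, and the recovered equation decouples,
so analysis works on the three-compartment subsystem (`seir3_rhs()`).

The threshold quantity is
$$R = \frac{\beta a x_2}{x_1 (m x_2 + y_1)(\gamma + y_2)},$$
(`basic_reproduction_number()`); it is singular at $x_1 = 0$, which the
package reports as an explicit error rather than `Inf` — at that vertex
the infection-free structure itself degenerates. The infection-free
equilibrium is $E^0 = (a/(m x_1), 0, 0)$. The endemic point is computed by
eliminating $S$ and $E$ from the steady-state equations (the infective
balance gives $E^* = (\gamma + y_2) I^*/(m x_2)$ exactly, and the
remaining balance is *linear* in $I^*$), then polishing with Newton steps
on the full residual to below $10^{-10}$; the printed ratio identity is
asserted on the result. We deliberately do not rely on a closed form for
$I^*$: the fixed-point residual is the ground truth.

### Stability verification

The package verifies stability numerically rather than reproducing
proofs. `stability_report()` collects three pieces of evidence at an
equilibrium of the delayed subsystem:

1. eigenvalues of the delay-free Jacobian;
2. the closed-form coefficient conditions (quadratic $A, B$ at the
   infection-free point; cubic Routh–Hurwitz $a_0,\dots,a_3$ at the
   endemic point), reported verbatim for comparison;
3. a pure-imaginary-root scan: splitting the characteristic function as
   $P(\lambda) + Q(\lambda)e^{-\lambda\tau}$ (the determinant is linear in
   $e^{-\lambda\tau}$ because only the incidence column is lagged), a root
   $i\omega$ exists for *some* delay iff
   $F(\omega) = |P(i\omega)|^2 - |Q(i\omega)|^2$ has a positive zero. The
   scan covers $(0, \omega_{\max}]$ with $10^4$ grid points
   ($\omega_{\max}$ = ten times the largest model rate — the linearized
   3-D system's spectrum is bounded by its rates) and refines sign
   changes by bisection.

The verdict `stable_all_tau` requires both negative delay-free spectrum
and an empty scan. Two findings from building this are worth recording:

* The closed-form threshold is *conservative in the wrong direction* in a
  sliver of parameter space: the exact delay-free stability condition at
  $E^0$ is $\beta a x_2/x_1 < (m x_2 + y_1)(\gamma + y_2) - m x_2 y_2$,
  whereas $R < 1$ only guarantees the bound without the $-m x_2 y_2$ term
  (the $y_2 I \to E$ recycling is dropped from the closed form). Parameter
  draws in the gap have $R < 1$ yet an unstable infection-free point — the
  report stays honest and says so. Under the additional condition
  $\gamma > \beta a/(m x_1)$ (the global-stability condition below) the
  discrepancy closes, and the test suite asserts stability on draws
  filtered that way.
* $\lambda = -m x_1$ is always an exact factor of the characteristic
  function at $E^0$; the suite checks this identity on random draws as a
  structural regression test.

`lyapunov_descent()` evaluates two Lyapunov candidates along stored
trajectories and returns finite-difference $dL/dt$ samples (tolerance
$+10^{-8}$ absorbs differencing noise). The infection-free candidate
$$L_1 = S - S^0 - S^0\ln(S/S^0) + E + I +
  \int_{t-\tau}^{t}\frac{\beta S^0 I(s)}{1+\alpha I(s)}\,ds$$
(the Volterra function; its integral term is evaluated by trapezoid on
the trajectory grid, so samples start at $t = \tau$) descends cleanly
whenever $R < 1$ and $\gamma > \beta a/(m x_1)$. The endemic candidate
$L_2 = [(S-S^*)+(E-E^*)+(I-I^*)]^2$ is *not* pointwise monotone along the
delayed flow: the deviation sum crosses zero during the oscillatory
approach, and $dL_2/dt$ has transient positive samples of order $10^{-3}$
even at $\tau = 0$. What does hold — and what the tests assert — is that
$L_2$ vanishes at the equilibrium, decays by many orders of magnitude
overall, and the trajectory converges to the endemic point.

### The integrator

The coupled system is a constant-lag DDE. `dde_integrate()` implements
fixed-step RK4 by the method of steps: the step size is shrunk so the lag
is an integer multiple of it (at least 20 steps per lag), making every
full-step lagged read an exact grid lookup and aligning the solution's
derivative-discontinuity breakpoints (multiples of $\tau$) with grid
nodes so no step straddles one. Half-step lagged reads fall mid-cell and
use cubic Hermite interpolation on the stored states *and derivatives*;
linear interpolation there would cap the observed convergence order near
two, while Hermite preserves the full fourth order (the suite measures
order $\approx 4$ by step halving, and the solver reproduces the analytic
piecewise-polynomial solution of $y'(t) = -y(t-1)$ to well below
$10^{-6}$ at $dt = 0.01$).

Coupling is one-way by construction — the replicator equations contain no
epidemic variables — so the game components of a coupled run are
bit-identical to a game-only run at the same step size, which the suite
asserts. The pre-history is constant at the initial state; nothing in the
model pins it down, constant history is the minimal standard choice, and
a history function can be supplied. Default horizons are 50 time units
for game-only runs and 200 for coupled runs at $dt = 0.01$ (the settling
phenomena of interest complete well inside these windows); time units are
model units throughout.

## Scenarios, settling times and sensitivity

The bundled preset (`load_scenario("paper_default")`) is the benchmark
parameterization $B_1{=}15, B_2{=}10, C_1{=}5, C_{21}{=}4, C_{11}{=}5,
B_3{=}7, B_4{=}5, B_5{=}3, B_6{=}1$, $\lambda_1{=}\rho_1{=}1$, $a{=}1,
\beta{=}0.2, \gamma{=}0.5, \alpha{=}1, m{=}0.5$, initial state
$(x_1, y_1) = (0.6, 0.5)$ and $(S, E, I) = (2, 8, 10)$, with $\tau = 1$
and $p_{21} = q_{21} = 1$ as the base values the figures vary around.
Note a structural quirk of these payoffs: $B_1 - C_{11} = B_2$ and
$B_4 - C_{21} = B_6$ make *both* degeneracy conditions vanish for every
dependence coefficient, so the official bracket is constant $9 - 5p_{21}$
and the public bracket constant $3 - q_{21}$ — each field is an exact
logistic flow, and for all $p_{21} \in \{0.5, 1, 1.5\}$,
$q_{21} \in \{0.5, 1, 1.5\}$ the scenario is the subcase whose ESS is
(positive guidance, positive response).

```{r settle}
sc <- load_scenario("paper_default")
tr <- integrate_game(sc$init_game, sc$payoffs, sc$rates, t_end = 50)
c(x1 = steady_state_time(tr, "x1", 1), y1 = steady_state_time(tr, "y1", 1))
```

`steady_state_time()` uses an absolute band of 0.01 with hold-to-end
semantics (the component must enter the band and stay). The settling
times this produces are the times the logistic flows need to cover their
remaining odds — about 1.05 and 2.30 time units above — far below the
reported instants of the source figures (15 s and 23 s); those figure
axes appear to be on a different scale, so the package treats the
reported instants as upper bounds, not point targets.

Delay sweeps (`delay_sweep()`) summarize each run by the susceptible
transient and the exposed settling time. Under the preset the susceptible
curve dips and recovers to $a/(m x_1^\infty) = 2$ without overshoot, so
the transient's extremum is its *trough*, which deepens with the delay
while the exposed compartment settles later — the two monotone orderings
the sweep asserts.

The sensitivity surface (`r_sensitivity()`) evaluates $R$ on a grid over
two of $(m, \gamma, \beta)$. Nothing in the source states the strategy
probabilities behind its surfaces, so the package defaults to
$(x_1, y_1) = (0.5, 0.5)$ and always prints them in the grid metadata;
the surfaces are checked for monotone signs ($R$ decreasing in $m$ and
$\gamma$, increasing in $\beta$), not point values.

## Known limitations

* The game feeds the contagion but not conversely — fidelity to the
  printed system, but real opinion fields react to panic levels.
* The population is well mixed with permanent immunity; no demography
  beyond constant inflow, no reinfection, no network structure.
* The case classification beyond the two tabulated regimes (both or one
  degeneracy condition active) is numeric only; no closed-form case
  labels are claimed there.
* Fixed-step RK4 with grid-aligned lags; no adaptive error control. The
  step-halving order test is the guard rail.
* Reported settling times depend on the band width (0.01 absolute) and
  grid resolution; they are upper-bound comparisons by design.
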