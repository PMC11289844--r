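---
title: "An evolutionary game of cross-regional direct settlement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An evolutionary game of cross-regional direct settlement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(settlegame)
```

## The model

Patients with malignant tumours in a territorially pooled health-insurance
system face a choice between *cross-regional treatment* (travelling to a
region with stronger oncology resources) and *in-area medical care*.
Hospitals in the destination regions face a choice between implementing
*direct settlement* — real-time insurance reimbursement at the point of
care — and leaving patients to advance the full cost and claim it back later
(*indirect settlement*). Neither side optimises instantaneously: both are
boundedly rational populations that gradually shift toward whichever
strategy is currently paying better. That is exactly the setting replicator
dynamics describes.

The state is a point $(x, y)$ on the unit square: $x$ is the frequency of
patients choosing cross-regional treatment, $y$ the frequency of hospitals
implementing direct settlement. Ten dimensionless payoff coefficients
parameterise the stage game:

| parameter | meaning |
|---|---|
| $U_1, U_2$ | patient utility of cross-regional / in-area care |
| $S_1, S_2$ | patient medical cost after cross-regional / in-area care |
| $C_1, C_2$ | patient nonmedical cost (travel, lodging, time) with / without direct settlement |
| $C_3$ | hospital input cost of direct settlement (IT systems, capital turnover) |
| $\pi_1, \pi_2$ | hospital financial / technological-advancement benefit of direct settlement |
| $\pi_3$ | hospital financial benefit without direct settlement |

The canonical regime assumes $U_1 > U_2$, $S_1 < S_2$ (the treating region's
insurance catalogue is broader, so out-of-pocket medical costs are *lower*
away from home), $C_1 < C_2$, $\pi_1 > \pi_3$, $\pi_2 > 0$, $C_3 > 0$.
`validate_params()` checks these six constraints; the default mode only
warns on violations because the sensitivity sweeps below deliberately cross
them.

The stage-game payoffs (patient, hospital) are

|  | direct | indirect |
|---|---|---|
| cross-regional | $U_1-S_1-C_1,\ \pi_1+\pi_2-C_3$ | $U_1-S_1-C_2,\ \pi_3$ |
| in-area | $U_2-S_2,\ -C_3$ | $U_2-S_2,\ 0$ |

and the replicator system is

$$\dot x = x(1-x)\,(EP_1 - EP_2), \qquad \dot y = y(1-y)\,(EH_1 - EH_2),$$

where $EP_1, EP_2$ ($EH_1, EH_2$) are the expected payoffs of the two
patient (hospital) strategies against the current opponent mix. Both payoff
advantages are affine in the opponent frequency:

$$EP_1 - EP_2 = \underbrace{(U_1 - S_1 - C_2 - U_2 + S_2)}_{a_p}
  + \underbrace{(C_2 - C_1)}_{b_p}\, y, \qquad
EH_1 - EH_2 = -C_3 + (\pi_1 + \pi_2 - \pi_3)\, x.$$

`analytic_advantage()` returns these coefficients together with their
min/max envelope over the square; they are the closed-form backbone of the
sweep cross-checks below. Note the dynamics depend only on payoff
*differences*, so common translations of $(U_1,U_2)$, $(S_1,S_2)$ or
$(\pi_1,\pi_3)$ leave the vector field unchanged — a property the test
suite asserts.

```{r}
p <- baseline_params()
payoff_matrix(p)
replicator_rhs(p, 0.5, 0.5)
```

## Equilibria, stability, and the seven scenarios

Setting both equations to zero gives the four corners plus one interior
candidate $D(x_0, y_0)$ with $x_0 = C_3/(\pi_1+\pi_2-\pi_3)$ and
$y_0 = (C_2+S_1-S_2-U_1+U_2)/(C_2-C_1)$; $D$ only exists when it lies
strictly inside the square, which happens exactly in the bistable regime
(scenario 4 below). Local stability follows the determinant/trace rule for
the $2\times 2$ Jacobian: an equilibrium is an evolutionarily stable
strategy (ESS) when $\det J > 0$ and $\operatorname{tr} J < 0$. At every
corner both off-diagonal Jacobian entries vanish identically, so the
determinant is the product and the trace the sum of the two diagonal
entries. The interior candidate has zero trace wherever it exists and is
therefore never an ESS.

```{r}
enumerate_equilibria(p)
corner_stability(p)
```

Three signed expressions determine every corner's classification: the
patient's cross-regional gain under indirect settlement
($S_2-S_1+U_1-U_2-C_2$), the same gain under direct settlement
($S_2-S_1+U_1-U_2-C_1$), and the hospital's direct-settlement gain at full
patient uptake ($\pi_1+\pi_2-\pi_3-C_3$). Their strict sign pattern indexes
seven scenarios; `classify_scenario()` evaluates the pattern and returns
the scenario's predicted ESS set, and `find_ess()` cross-checks that
prediction against the Jacobian classification. Scenarios 1–3 end in
universal defection $(0,0)$, scenario 4 is bistable with ESS at both
$(0,0)$ and $(1,1)$, scenarios 5–6 end at $(1,0)$ (patients travel,
hospitals decline direct settlement), and scenario 7 is the cooperative
outcome $(1,1)$. The eighth conceivable sign pattern requires $C_1 > C_2$
together with a positive hospital gain and maps to no scenario. Because the
seven patterns are built from *strict* inequalities, a parameter set with
any expression exactly zero is reported as a boundary (`scenario_id = NA`)
rather than silently assigned — degenerate equilibria are never certified
stable.

```{r}
classify_scenario(p)
find_ess(p)
```

The baseline set (`baseline_params()`: $U_1=6$, $U_2=4$, $S_1=3$, $S_2=4$,
$C_1=0.5$, $C_2=1$, $C_3=4$, $\pi_1=7$, $\pi_2=2$, $\pi_3=6$) falls in
scenario 6: the patient advantage $2+0.5y$ is positive everywhere, the
hospital advantage $3x-4$ negative everywhere, so the population state is
driven to $(1,0)$ from any interior starting point.

## Trajectories, basins, and numerical choices

`replicator_trajectory()` integrates the system with `deSolve`'s
Dormand–Prince 4(5) pair. The right-hand side is a smooth cubic polynomial
on a compact set, so a non-stiff adaptive method is appropriate. Numerical
choices, all adjustable through `integration_settings()`:

* **Tolerances** default to `rel_tol = 1e-10`, `abs_tol = 1e-12`. These are
  deliberately tight: the square is exactly invariant under the true flow,
  and at these tolerances the solver's dense output never overshoots it by
  more than $\sim 10^{-9}$, which the forward-invariance property test
  enforces. States are clipped back to the square after each accepted
  chunk; the largest pre-clipping excursion is recorded on the trajectory.
* **Convergence** is declared when the state is within `conv_eps = 1e-4`
  (Euclidean) of a corner *and* the velocity $\infty$-norm is below
  `stall_eps = 1e-9`. Both conditions matter: near a corner whose
  advantage is degenerate the state can be close without being attracted.
* **Horizon**: integration proceeds in chunks of 25 time units up to
  `t_max = 500`; convergence to a hyperbolic corner in this model is
  exponential and typically complete (to the criteria above) by $t\approx
  20$–$60$. A run that freezes away from every corner — which happens on
  degenerate boundaries where a whole edge consists of equilibria — is cut
  short once the state stops moving and reported as *not converged*, with
  no corner limit.
* **Edge starts** are fixed in one coordinate by the dynamics themselves,
  so the default basin grids use interior points only;
  `interior_grid(include_boundary = TRUE)` restores the full lattice.

`basin_scan()` integrates from a grid of initial conditions and summarises
whether all converged runs share one corner. For the headline baseline
result the full interior 0.1-step grid (81 starts) is used; the sensitivity
sweeps below default to a 3×3 grid (`sweep_grid()`), which is sufficient
because in this model a corner limit, where it exists at all, is the same
from every interior start — the affine advantage structure leaves no room
for basin boundaries except in the bistable scenario 4, which the default
sweeps never enter.

```{r, eval = FALSE}
glance(basin_scan(p))                       # 81 runs, unanimous at (1, 0)
autoplot(replicator_trajectory(p, 0.5, 0.5))
plot_phase(p, resolution = 15)
```

## Sensitivity sweeps and switch thresholds

`sweep_parameter()` varies one coefficient over a grid (consecutive
integers by default, which is where this model's observable switches fall
under the baseline set), re-running the scenario classification, ESS
computation and basin scan at each value. Two threshold notions are
deliberately distinguished in `detect_threshold()`:

* `direction = "up"` reports the first swept value at which the flip to a
  *new* behaviour is **confirmed**: a unanimous, fully converged corner
  limit different from the baseline end's. Values where the advantage
  touches zero on an edge are degenerate — the frequency drifts but stalls
  short of the corner as its driving opponent frequency decays — and are
  skipped with an ambiguity flag rather than counted as flips. Under the
  baseline this places the cross-regional-utility switch at $U_1 = 5$ (at
  $U_1 = 4$ the patient advantage is $0.5y$, degenerate at the edge
  $y = 0$).
* `direction = "down"` reports the last value at which the *original*
  behaviour still **persists**, counting weak persistence: where no corner
  limit exists but the advantage envelope is one-sidedly signed, the
  frequency still drifts toward the original corner. Under the baseline
  patients keep drifting toward cross-regional care through $C_2 = 3$
  (advantage $2.5y \ge 0$) and switch away only beyond it.

The asymmetry mirrors how the two questions are naturally posed — "from
which value on is the new strategy established?" versus "up to which value
does the old strategy survive?" — and both are anchored to the analytic
advantage envelope, not to solver behaviour.

`analytic_switch()` locates the parameter values at which the advantage
envelope changes sign, which are the only places the limiting behaviour can
change. For the hospital input cost the boundary is
$C_3 = \pi_1+\pi_2-\pi_3 = 3$ under the baseline: at $C_3 = 3$ the
scenario classification is a boundary (`NA`) and no corner limit exists, so
the first *confirmed* numeric flip appears only at $C_3 = 4$.
`sweep_discrepancies()` flags exactly this situation — a confirmed flip
lying strictly beyond an analytic boundary — so that the switch is read off
the analytic value (3) rather than the overstated confirmed one.

```{r, eval = FALSE}
sw <- sweep_parameter(p, "u1", 1:10)
glance(sw)                  # patient_up = 5
autoplot(sw)
sweep_discrepancies(sweep_parameter(p, "c3", 1:6))
```

## Fixture generators

`generate_random_params()` and `generate_scenario_params()` provide
seeded parameter sets for property testing. Rather than rejection-sampling
the six canonical constraints, they draw positive *gaps* (e.g.
$U_1 = U_2 + \delta_u$) so constraints hold by construction, then place
$C_1, C_2$ and $C_3$ on the required sides of the patient gain
$\delta_s + \delta_u$ and the hospital gain $\pi_1+\pi_2-\pi_3$ to hit a
requested scenario's sign pattern. One taxonomic fact falls out of the
algebra: scenario 5 requires the patient's cross-regional gain to be
positive under indirect settlement yet negative under direct settlement,
which forces $C_1 > C_2$; that scenario is unreachable inside the canonical
regime, and its generator relaxes the $C_1 < C_2$ constraint and records a
note on the returned list.

These generators emulate the *structure* of the game — sign patterns and
magnitudes of order 1–10 — and nothing else. They are not calibrated to
insurance-claims data, contain no measurement noise, and say nothing about
how real patient or hospital populations mix; passing tests certify the
mathematics of the model, not its empirical adequacy.

## Problem sizes and limitations

The package's own test and reproduction workloads are desk-scale by
construction: basin scans use 81 interior starts for the headline result
and 9 per swept value; the finite-difference Jacobian check runs 1000
randomized draws; sweeps cover the integer grids on which the switches
fall, with `analytic_switch()` available to refine any real-valued
boundary.

Known limitations, inherited from the model rather than the code: the
dynamics are deterministic two-population replicator equations (no finite
population noise, no time delays, no best-response or imitation variants);
patients are a single homogeneous population, with no high/low-mortality
tumour subtypes; policy instruments enter only through the ten payoff
coefficients; and degenerate boundary cases are reported as such rather
than resolved by higher-order (centre-manifold) analysis, which the
determinant/trace rule cannot see.
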