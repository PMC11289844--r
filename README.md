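# settlegame

Evolutionary game analysis of cross-regional direct settlement and the
treatment-seeking behaviour of patients with malignant tumours.

In territorially pooled health-insurance systems (China's city-level
pooling is the motivating case), patients with malignant tumours often
travel to other regions for better oncology care, and the hospitals that
receive them may or may not offer *direct settlement* — real-time insurance
reimbursement at the point of care instead of pay-first-claim-later.
`settlegame` implements the two-population evolutionary game between these
groups for health-services researchers and policy modellers: the payoff
model, replicator dynamics, equilibrium and local-stability analysis, a
seven-scenario taxonomy of evolutionarily stable strategies (ESS),
trajectory/basin simulation, and one-parameter sensitivity sweeps with
switch-threshold detection.

## The model

The state is $(x, y) \in [0,1]^2$: $x$ the frequency of patients choosing
cross-regional treatment, $y$ the frequency of hospitals implementing
direct settlement. Ten payoff coefficients — patient utilities $U_1, U_2$,
medical costs $S_1, S_2$, nonmedical costs $C_1, C_2$, hospital input cost
$C_3$ and benefits $\pi_1, \pi_2, \pi_3$ — define the stage game

|  | hospital: direct | hospital: indirect |
|---|---|---|
| patient: cross-regional | $U_1{-}S_1{-}C_1,\ \pi_1{+}\pi_2{-}C_3$ | $U_1{-}S_1{-}C_2,\ \pi_3$ |
| patient: in-area | $U_2{-}S_2,\ -C_3$ | $U_2{-}S_2,\ 0$ |

and the replicator dynamics

$$\dot x = x(1-x)(EP_1 - EP_2), \qquad \dot y = y(1-y)(EH_1 - EH_2).$$

Equilibria are the four corners plus one interior candidate; ESS are
identified by the Jacobian rule $\det J > 0,\ \operatorname{tr} J < 0$, and
the strict sign pattern of three payoff-difference expressions sorts every
parameter set into one of seven scenarios (or a degenerate boundary). See
`vignette("settlement-game", package = "settlegame")` for the full account.

## Worked example

```r
library(settlegame)

p <- baseline_params()   # U1=6 U2=4 S1=3 S2=4 C1=0.5 C2=1 C3=4 pi1=7 pi2=2 pi3=6

corner_stability(p)
#> # A tibble: 4 × 10
#>   point     x     y   j11   j12   j21   j22   det trace classification
#>   <chr> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <chr>
#> 1 O         0     0   2       0     0    -4  -8    -2   saddle
#> 2 A         1     0  -2       0     0    -1   2    -3   ess
#> 3 B         0     1   2.5     0     0     4  10     6.5 unstable
#> 4 C         1     1  -2.5     0     0     1  -2.5  -1.5 saddle
```

Only the corner $A(1,0)$ has positive determinant and negative trace: the
unique ESS has every patient seeking cross-regional treatment and no
hospital implementing direct settlement. The scenario classifier agrees —
the baseline's three condition expressions $(2, -1, 2.5)$ carry scenario
6's sign pattern:

```r
glance(classify_scenario(p))
#> # A tibble: 1 × 4
#>   scenario_id boundary n_ess ess
#>         <int> <lgl>    <int> <chr>
#> 1           6 FALSE        1 A
```

Forward integration confirms the prediction from every interior start — 81
initial conditions on the 0.1-step grid all reach $(1, 0)$:

```r
glance(basin_scan(p))
#> # A tibble: 1 × 6
#>   n_starts n_converged unanimous all_converged limit_x limit_y
#>      <int>       <int> <lgl>     <lgl>           <dbl>   <dbl>
#> 1       81          81 TRUE      TRUE                1       0
```

Sensitivity sweeps recompute all of this along a parameter grid and report
where the limiting behaviour flips. Raising the utility of cross-regional
treatment from 1 upward, patients switch from in-area care to travelling
at $U_1 = 5$ while hospitals never adopt direct settlement:

```r
sw <- sweep_parameter(p, "u1", 1:10)
glance(sw)
#> # A tibble: 1 × 6
#>   parameter n_values patient_up patient_down hospital_up hospital_down
#>   <chr>        <int>      <dbl>        <dbl>       <dbl>         <dbl>
#> 1 u1              10          5            3          NA            NA
```

`autoplot()` methods draw trajectories and sweep profiles, and
`plot_phase()` draws the vector field with trajectory overlays. A thin
command-line wrapper over the same functions ships in
`inst/cli/settlegame.R` (verbs `analyze`, `simulate`, `sweep`, `phase`,
`fixtures`).

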