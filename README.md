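# wendling

Simulation and dynamical analysis of the extended Wendling neural mass
model of epileptic depth-EEG, in R.

## The model

Neural mass models describe the average activity of interacting neuronal
populations rather than individual cells, and synthesize realistic
EEG-like signals at negligible computational cost.  The extended
Wendling model couples four subgroups of a hippocampal volume —
pyramidal cells, excitatory interneurons, slow (dendritic) inhibitory
interneurons and fast (somatic) inhibitory interneurons.  Each synaptic
pathway is a second-order linear "pulse-to-voltage" filter, e.g.
`ÿ = A·a·u − 2a·ẏ − a²·y`, and each population converts its summed
membrane potential back to a firing rate through the static sigmoid

    S(v) = 2·e0 / (1 + exp(r·(v0 − v)))

with `v0 = 6 mV`, `e0 = 2.5 s⁻¹`, `r = 0.56 mV⁻¹`.  Written in first-order
form the model is ten ODEs driven by a stochastic pulse-density input
`p(t)`; the simulated EEG is the pyramidal membrane sum
`y_out = y1 − y2 − y3`.  The synaptic gains `A` (excitatory), `B` (slow
inhibition) and `G` (fast inhibition) select the dynamical regime:
background activity, sporadic spiking, sustained spiking, gamma and
ictal activity.

The package provides, as first-class, tested functionality:

* the full 10-equation system and a mathematically equivalent reduced
  8-equation formulation (the redundant slow-inhibition PSP pair
  `y2 = C4·y4`, `y7 = C4·y9` is merged), with exact state maps between
  the two;
* fixed-step **classical** integrators (forward Euler and 4th-order
  Runge-Kutta) that treat the noisy input as an ordinary forcing term —
  deliberately reproducing the documented artifact that the output
  variance shrinks in proportion to the step size — and a **corrected
  stochastic forward Euler** whose noise increment scales with `√h`, so
  its variance is stable across step sizes and coincides with the
  classical scheme at the reference step `h = 0.001 s`;
* equilibrium analysis: all fixed points from the combined scalar
  nullcline equation (steady-state gains `A/a`, `B/b`, `G/g`), analytic
  Jacobians, eigenvalue stability classification, and bisection
  localization of the saddle-node and stability-transition bifurcations
  in `B`;
* multi-phase scenario simulation with state carried across phase
  boundaries, DC-offset removal (mean subtraction or first-order
  high-pass), CSV/JSON writers and a command-line interface
  (`inst/cli/wendling`).

## A worked example

```r
library(wendling)

m <- wendling_model(A = 5, B = 45, G = 20)   # background-activity gains
equilibria(m)
#> Equilibria at A = 5, B = 45, G = 20, p = 90: 3 point(s)
#>   y_out       y0     y1     y2      y3     y4 max_re stability
#>  -0.124 0.007847  6.097  5.882 0.33917 0.1743 -23.96    stable
#>   2.526 0.031256 11.777  8.962 0.28978 0.2655  46.89  unstable
#>   5.087 0.093711 30.864 25.749 0.02804 0.7629  20.03  unstable
```

Three equilibria; the stable one at `y_out = −0.124 mV` is the DC offset
around which the simulated background EEG fluctuates.  The other
regimes follow by lowering slow inhibition, and the two bifurcations
that separate them can be localized directly:

```r
find_saddle_node(m, 30, 45, resolution = 0.01)$value
#> [1] 37.29126        # stable + unstable point collide; spiking emerges
find_stability_transition(m, 5, 20, resolution = 0.005)$value
#> [1] 13.15002        # the lone equilibrium regains stability
```

Simulating ten seconds with the corrected stochastic scheme and
comparing the step-size behaviour of the two integrator families:

```r
m40 <- update(m, B = 40)
v <- function(scheme, h) output_variance(
  simulate(m40, seed = 1, scheme = scheme, h = h, duration = 11),
  discard = 1)
v("rk4_classical", 1e-3);  v("rk4_classical", 1e-5)
#> [1] 0.0676248       # classical, h = 1 ms
#> [1] 0.0007788597    # classical, h = 0.01 ms: variance collapsed ~100x
v("euler_sde", 1e-3);  v("euler_sde", 1e-5)
#> [1] 0.07051269      # corrected,  h = 1 ms
#> [1] 0.08348751      # corrected,  h = 0.01 ms: variance stable
```

The classical scheme loses a decade of output power per decade of step
size — a pure integration artifact — while the corrected scheme's
variance is step-size independent.

The standard four-phase scenario, from the command line:

```sh
inst/cli/wendling phases --seed 1 --out phases.csv --summary-json summary.json
```

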