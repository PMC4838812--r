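---
title: "The extended Wendling neural mass model: equations, integration and stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The extended Wendling neural mass model: equations, integration and stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wendling)
```

## The model

The extended Wendling model is a lumped-parameter description of a
hippocampal volume as four interacting neuronal subgroups: pyramidal
cells, excitatory interneurons, slow dendritic-projecting inhibitory
interneurons (GABA-A,slow) and fast somatic-projecting inhibitory
interneurons (GABA-A,fast).  Two conversion elements make up every
subgroup.  A *pulse-to-voltage* block turns an afferent pulse density
into a postsynaptic potential; it is a critically damped second-order
linear filter, `ÿ(t) = K·k·u(t) − 2k·ẏ(t) − k²·y(t)`, whose gain `K`
is `A`, `B` or `G` (mV) and whose lumped rate `k` is `a = 100`,
`b = 50` or `g = 350` s⁻¹.  A *voltage-to-pulse* block turns the summed
membrane potential into a firing rate through the sigmoid

$$S(v) = \frac{2 e_0}{1 + e^{r (v_0 - v)}},$$

bounded in `(0, 2·e0)` with `S(v0) = e0`.  Subgroups are wired through
the connectivity constants `C1..C7` (multiples of `C1 = 135`).  In
first-order form the model is ten ODEs in the PSP outputs `y0..y4` and
their derivatives `y5..y9`; the EEG-like output is the pyramidal
membrane sum `y_out = y1 − y2 − y3`.  The exogenous drive `p(t)` is a
normally distributed pulse density entering the `y6` equation only.

Two textual ambiguities in the family's published descriptions are
resolved as follows (they are forced by internal consistency, and both
choices are locked in by tests):

* **Rates are s⁻¹**, not seconds: `a = 100 s⁻¹` etc.
* **Noise amplitude**: the customary "N(90, 30)" input gives the
  amplitude that multiplies a unit-variance draw, i.e. a standard
  deviation of 30 s⁻¹ (`input_variance = 900`).  Reading 30 as the
  variance shrinks the documented output variances of all schemes by a
  factor of ~30 and is inconsistent with the stochastic update below.

## The reduced 8-equation system

The slow inhibitory interneurons drive two targets (pyramidal somata
and the fast interneurons) through two PSP filters that share one
input.  Linearity makes the pair redundant: on every trajectory from
consistent (e.g. zero) initial conditions, `y2 = C4·y4` and
`y7 = C4·y9` exactly.  Merging the pair and renaming `y4 → y2`,
`y9 → y6` yields an 8-equation system whose output is
`y1 − C4·y2 − y3`; `full_to_reduced()` / `reduced_to_full()` implement
the (exact) state maps, and `full_to_reduced()` refuses states that
violate the proportionality, because they have no reduced counterpart.

One subtlety: after renaming, the fast-inhibition drive must read
`C7·S(C5·y0 − C6·y2)` — the `C6` coupling acts on the renamed
slow-inhibition PSP, *not* on the new `y4` (which is now `ẏ0`).  The
literal transcription would break the full/reduced equivalence; the
package's regression suite holds the equivalence to `< 1e−9` over
10-second noisy trajectories under every scheme, which pins the
correct reading.

The reduction also explains a fingerprint in the eigenvalue spectra:
the dropped pair contributes a decoupled `(−b, −b) = (−50, −50)`
eigenvalue pair at every equilibrium, so the full 10×10 Jacobian
spectrum always equals the reduced 8×8 spectrum plus `{−50, −50}`.

## Numerical integration and the step-size artifact

The model is a set of *stochastic* differential equations: `p(t)` is
random.  The field has historically integrated it with classical
fixed-step methods, drawing one input value per step and treating it
as a constant forcing.  The noise contribution to a step then scales
as `h`, while a Wiener increment must scale as `√h`; halving the step
therefore halves the accumulated noise power.  `simulate()` with
`scheme = "euler_classical"` or `"rk4_classical"` reproduces this
legacy behaviour on purpose (one draw per step, held across all four
RK4 stages), and its output variance falls by a decade per decade of
`h` — with the standard gains (`A = 5, B = 40, G = 20`) about 0.07 mV²
at `h = 1` ms down to about 0.0007 mV² at `h = 0.01` ms.

The corrected scheme (`scheme = "euler_sde"`) separates drift and
diffusion: the drift uses the mean input `m`, and each Euler step adds

$$A\,a\,\sqrt{\sigma^2\, h_{\mathrm{ref}}\, h}\; r_n, \qquad r_n \sim N(0,1)$$

to the `y6` state (`y5` in the reduced system), with
`h_ref = 0.001 s`.  The `√h` makes the variance step-size stable, and
the `√h_ref` calibrates the scheme so that at `h = h_ref` it is
*algebraically identical* to classical Euler with the same noise
stream — the package asserts bit-level agreement to `< 1e−10`.  This
calibration means the corrected scheme reproduces, at any `h`, the
statistics that the legacy simulations produced at `h = 1 ms`; our
measured variance stays at ~0.077 mV² from `h = 1` ms down to
`h = 0.01` ms.

Numerical conventions, fixed once: integration loops run in compiled
code with noise streams drawn from R's RNG (so a seed gives bit-exact
reproducibility); every step is recorded; variances are population
variances (divide by `N`); variance experiments simulate 11 s from
zero initial conditions and discard the first second (the settling
transient of the zero start); divergence (any non-finite state) aborts
with the offending step number.

## Equilibria, stability and bifurcations in B

For the deterministic analysis the input is held at its mean
(`p = 90`).  At an equilibrium each PSP filter sits at its DC gain
`K/k`, which collapses the system to one scalar equation in the
output,

$$y_{\mathrm{out}} = \tfrac{A}{a}\bigl(p + C_2 S(C_1 y_0)\bigr)
 - \tfrac{B}{b} C_4 S(C_3 y_0) - \tfrac{G}{g} C_7 S(C_5 y_0 - C_6 y_4),$$

with `y0 = (A/a)·S(y_out)` and `y4 = (B/b)·S(C3·y0)`.
`nullcline_roots()` scans `y_out` on a grid over `[−20, 40]` mV (step
0.01 mV — the interval covers the sigmoid's full dynamic range with
margin; all known equilibria lie in `[−0.2, 10.1]`) and refines each
sign change by bisection plus a Newton polish to residual `< 5e−14`,
so the back-substituted state has drift below `1e−9`.  Roots closer
than `1e−4` mV are merged.  Stability comes from the eigenvalues of
the analytic Jacobian (built from the sigmoid slope
`S'(v) = 2 e_0 r\,/\,(e^{t/2}+e^{-t/2})^2`, `t = r(v_0-v)`, an
overflow-safe form): stable if all real parts are below `−10⁻⁶` s⁻¹,
unstable if any exceeds `+10⁻⁶`, marginal otherwise.

With `A = 5`, `G = 20` the model has three equilibria for
`B ≳ 37.3` (one stable — the background DC offset — and two unstable)
and one for smaller `B`.  `find_saddle_node()` bisects on the root
count and localizes the collision at `B = 37.291`; below it a stable
limit cycle (sustained spiking) surrounds the lone unstable
equilibrium.  `find_stability_transition()` bisects on the sign of the
maximal eigenvalue real part of that equilibrium.

### A discrepancy with previously published eigenvalue tables

Our analysis reproduces the published equilibrium states of all four
phases to every printed decimal, the published eigenvalue spectra of
the three *stable* equilibria and of the sustained-spiking equilibrium
(`B = 37`, largest real part `20.7 s⁻¹`) to one decimal, and the
saddle-node at `B = 37.3`.  Three published numbers do **not**
reproduce from the model equations:

1. the eigenvalue column attributed to the gamma-phase equilibrium
   (`B = 8`) — the Jacobian at that (correctly printed) state has
   spectrum `{−50, −50, −54.7±39.9i, −68.9±73.1i, −99.5, −100.5,
   −376.4±86.5i}`, not the published values;
2. the published stability-transition range `9.21 < B < 9.22` — the
   maximal eigenvalue real part of the unique equilibrium crosses zero
   at `B ≈ 13.15`; and
3. the eigenvalues published for the four *unstable* three-root
   equilibria, which agree only to ~0.3–6 s⁻¹ per component.

We verified our Jacobian against central finite differences of the
drift (relative error `< 1e−6`) and — decisively — against zero-noise
simulations: trajectories perturbed 0.1 mV off the equilibrium
converge back at `B = 12.5` and spiral away at `B = 13.3`, and
long simulations from zero initial conditions show no sustained
oscillation anywhere in `8.5 ≤ B ≤ 12`.  The eigenvalue labels the
package computes are therefore self-consistent with the dynamics it
simulates; the corresponding published entries appear to stem from a
flawed eigenvalue pipeline (note that the published stability *labels*
over those two table columns also contradict the published
eigenvalues' signs).  The package reports the computed values.

## The phase scenario

`run_phase_sequence()` chains parameter regimes while carrying the
state across boundaries, emulating the classical progression
background → sporadic spiking → sustained spiking → gamma (B = 45,
38, 37, 8 at `G = 20`); the shipped YAML schedule uses 5 s per phase.
The ictal fifth phase changes `G` simultaneously; its published gain
values are not machine-readable, so it ships only as a commented-out
placeholder and is excluded from all validated claims.  Each phase's
mean output is the DC offset selected by the active attractor: the
equilibrium value for the equilibrium-dominated phases (−0.124 mV in
background, 10.004 mV in gamma), but *not* for the spiking phases,
whose limit-cycle time-mean sits well below the coexisting unstable
equilibrium — which is why the per-phase means are not monotone in the
default sequence even though the equilibrium branch is.

Because the offset is a model artifact of the sigmoid's operating
point (no electrochemical mechanism of real DC shifts is modelled),
`remove_dc()` offers the two conventional removals: mean subtraction,
and a causal first-order recursive high-pass
`y[n] = α(y[n−1] + x[n] − x[n−1])`, `α = 1/(1 + 2π f_c h)`, validated
against the analytic one-pole response (a 0.5 Hz cutoff leaves 10 Hz
content within 1 dB while removing DC by construction).

## What the simulations do and do not show

All validation runs use the study conditions above: Table-style gains,
`p ~ N(90, 30²)`, 10-second windows (11 s minus 1 s transient),
steps `h ∈ {10⁻³, 10⁻⁴, 10⁻⁵}` s, and 3–5 independent seeds for
stochastic quantities — sizes chosen so the full suite runs in
seconds on one core while holding the stochastic comparisons within
their documented scatter (~±15% per seed for a 10-s variance).
Synthetic noise is white and Gaussian per step; real depth-EEG drive
is neither, and the model makes no claim about electrode physics, so
agreement here validates the numerics and the dynamical analysis, not
clinical realism.  Known limitations: no Floquet analysis of the
limit cycle (its existence is inferred from a unique unstable
equilibrium plus bounded zero-noise oscillation), one-parameter
bifurcation sweeps only (`B`, at fixed `G`), and no multi-column or
ictal-phase validation.
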