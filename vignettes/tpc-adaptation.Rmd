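---
title: "Adaptive dynamics of competition thermal performance curves under stochastic temperatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive dynamics of competition thermal performance curves under stochastic temperatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpcevol)
```

This vignette is the package's own account of the model it implements,
the numerical choices behind it, and what its tests do and do not
establish.

## The model

### Temperature

The environment is a dimensionless temperature on $(0,1)$,

$$\tau_t \;=\; \frac{\tau_0 + m\,\sin(\omega t)}{1 + e^{-\sigma_\epsilon X_t}},
\qquad X_t \sim N(0,1)\ \text{i.i.d.},$$

a predictable sinusoid (vertical shift $\tau_0$, magnitude $m$,
frequency $\omega$ in radians per discrete step) divided through a
sigmoid-transformed Gaussian. The construction has three properties that
matter downstream. First, whenever $\tau_0 - m > 0$ and $\tau_0 + m < 1$
(enforced at construction) every draw lies strictly inside $(0,1)$, so
the demographic functions below never see a boundary temperature.
Second, at $\sigma_\epsilon = 0$ the process reduces *exactly* to
$(\tau_0 + m\sin\omega t)/2$, giving a deterministic limit against which
the stochastic machinery can be checked. Third, by the symmetry of the
sigmoid under $X \mapsto -X$, the long-run mean is $\tau_0/2$ exactly
when the sine is inactive ($m = 0$, or $\omega$ an integer multiple of
$\pi$ sampled at integer steps); with an active sine the mean is only
approximately $\tau_0/2$, and the package treats it as such. Time is
discrete with no sub-step interpolation, and the noise is white:
autocorrelated (coloured) variants are out of scope.

Each regime carries a `seed` naming its frozen noise stream. All
comparative evaluations — resident versus mutant, every point of a
finite-difference stencil, every cell-internal computation — reuse one
frozen sequence (common random numbers). This is what makes selection
gradients smooth functions of traits rather than noisy Monte-Carlo
estimates, and nullclines well-defined curves.

### Ecology

A resident population follows the temperature-driven Ricker map
$N_{t+1} = N_t \exp\!\big(r(\tau_t)(1 - N_t/k(\tau_t))\big)$ with

$$r(\tau) = r_0 e^{-c/\tau} + r_1, \qquad
k(\tau) = k_0 e^{-(\tau - \tau_m)^2/\sigma_k}.$$

The growth rate rises monotonically with temperature and is floored at
$r_1$; the capacity is bell-shaped with its peak $k_0$ at $\tau_m$ and
critical limits fixed at 0 and 1. The reference parameterisation used
throughout — $r_0 = c = r_1 = 0.1$, $k_0 = 2$, $\tau_m = 0.5$,
$\sigma_k = 0.05$ — produces overdamped single-population dynamics whose
transients die within roughly a hundred steps; the alternate values
$r_0 = 5$, $k_0 = 1$ push the noise-free map through periodic and
chaotic regimes and are exposed through the same configuration surface.
Population sizes are assumed large enough that demographic stochasticity
is negligible; the only randomness is environmental.

### Competition TPCs

A type's competition TPC is a beta probability density
$\beta(\tau;\mu,s)$ with standard shape parameters $a = \mu/s$,
$b = (1-\mu)/s$. This parametrisation is the package's central
reverse-engineering commitment: it is the unique beta family in
$(\mu, s)$ whose mode is $(\mu - s)/(1 - 2s)$ *and* whose variance is
$s\mu(1-\mu)/(s+1)$, the two summary statistics (thermal optimum,
squared performance breadth) used to describe singular TPCs. Both
statistics are exported (`tpc_optimum()`, `tpc_breadth()`,
`tpc_breadth_squared()`); published tables in this literature are not
consistent about whether "$\sigma$" denotes the breadth or its square,
so the package exposes both rather than guessing.

The optimum formula has a pole at $s = 1/2$; it is only applied in the
interior-unimodal regime $a > 1,\ b > 1$ (which implies $s < 1/2$),
dispatch being driven by `classify_shape()`: monotone J-shaped curves
peak at a thermal boundary (`tau_opt` 0 or 1), and bimodal U-shaped
curves have no meaningful optimum and are flagged degenerate. Because
every TPC integrates to one, breadth trades off against height — the
generalist–specialist trade-off needs no extra parameter.

Competition between resident and rare mutant enters through
$\alpha_{MN}(\tau) = \beta_N(\tau)/\beta_M(\tau)$ and its reciprocal,
evaluated at the current temperature: whoever performs better at
$\tau_t$ suffers less crowding. Identical types give coefficients of
exactly one, so a resident's own dynamics never involve its TPC — an
innocuous-looking fact with a large computational payoff (below). The
ratio is computed as a difference of log densities and exponentiated;
log-ratios beyond 700 are outside double range and raise an informative
error instead of overflowing.

### Invasion fitness and selection

The invasion fitness of a rare mutant is the long-run average of its
per-capita growth rate on the resident's attractor,

$$\bar\lambda = \frac{1}{L - B}\sum_{t = B+1}^{L}
r(\tau_t)\Big(1 - \alpha_{MN}(\tau_t)\,\frac{N_t}{k(\tau_t)}\Big),$$

with burn-in $B$ and horizon $L$; the mutant exerts no feedback (true
rarity limit). Each temperature is paired with the *pre-update* resident
size $N_t$ — the state the mutant's growth over step $t$ actually
experiences. A resident is selectively neutral against itself: its
self-fitness telescopes to $(\log N_{L+1} - \log N_{B+1})/(L-B)$, which
on a bounded attractor is $O(1/L)$ — a sharp internal consistency check
the tests assert at $10^{-3}$ for $L = 10^5$.

Because the resident trajectory does not depend on the resident's TPC,
one simulated attractor per regime serves *every* fitness evaluation:
$\bar\lambda$ is a weighted average of the density ratio with fixed
weights $w_t = r_t N_t / k_t$. Selection gradients are central finite
differences in the mutant traits (step $10^{-4}$) on that shared
context, hence deterministic given the seed; the Hessian uses the
standard nine-point second-difference stencil with a larger step
($10^{-3}$), appropriate to curvature. An independent check exploits the
chain rule: since mutant traits enter only through
$-\alpha_{MN} = -\beta_N/\beta_M$, the gradient equals the attractor
average of $w_t\,\partial \log\beta(\tau_t;\mu,s)/\partial(\mu,s)$; the
test suite verifies the finite-difference and score-function forms agree
to 1% over a $5\times5$ resident grid, and that the time-average
fitness matches a genuinely independent oracle that co-simulates the
two-type system with a vanishingly rare mutant ($M_0 = 10^{-30}$;
anything much larger lets tail-amplified competition pressure
$\alpha_{NM} M$ perturb the resident measurably).

### Canonical dynamics, singularities, classification

Gradual evolution follows the canonical equations
$(\dot\mu, \dot s) = \tfrac12 \hat N_e \mathrm{E}\, (\bar g_\mu, \bar
g_s)$, with $\hat N_e$ the attractor mean of the resident size,
$\mathrm E$ the mutational covariance (identity by default) and the
factor $\tfrac12$ the surviving fraction of mutations under directional
selection. Mutation rate and variance only rescale time, so trait
trajectories have arbitrary time units; endpoints and signs are the
meaningful output. $\hat N_e$ is estimated once per regime — by the
TPC-independence of the resident dynamics, re-estimating it along the
trajectory would return the identical value.

`canonical_trajectory()` integrates this flow by arc-length
continuation: each move follows the *direction* of the canonical field
with an adaptive step length that shrinks when the direction reverses
(overshoot) and grows cautiously otherwise. An earlier design — explicit
Euler with step halving whenever the gradient norm increased — turned
out to be structurally unsound under anisotropic $\mathrm E$: the
gradient norm can legitimately rise along the true flow, so
norm-monitored halving drove the step to its floor and the trajectory
stalled far from the singularity. Direction-steered continuation is
invariant to the gradient's magnitude profile and converges to the same
endpoints where the Euler scheme worked.

`find_singularity()` first tries damped, box-clamped Newton iteration on
the gradient map (finite-difference Jacobian, step $10^{-3}$). Newton
alone is not trusted: far from a root it happily descends into the flat
far field where gradients are small but nonzero. If it fails to produce
an interior root below tolerance, the canonical flow is integrated from
the starting guess and Newton is re-run from its endpoint, accepting the
polish only if it stays within 0.05 of the flow's endpoint. The
admissible box is $\mu \in [0.01, 0.99]$, $s \in [0.005, 1.99]$;
convergence *onto* the box is a first-class outcome, not an error,
because the constant-environment limit genuinely drives the breadth to
zero: selection then pins $s$ at its floor and the remaining gradient
component is solved to zero along the edge (`uniroot`), yielding a
report flagged `boundary` whose optimum sits at the mean temperature.
In all interior cases the report carries the canonical Jacobian in
resident traits (convergence stability iff all eigenvalue real parts are
negative), the mutant-trait fitness Hessian (evolutionary stability iff
negative definite), and the combined verdict: CSS, ESS-only,
convergence-stable-only (branching candidate), or repeller. The
nullclines of the two gradients, extracted by edge-interpolated sign
changes on a trait grid, provide an independent route to the same point
and are exactly invariant under $\mathrm E$, which never enters the
gradients.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `tau0`, `m`, `omega`, `sigma_eps` | temperature process (dimensionless; `omega` rad/step) | 0.5, 0.25, $13\pi/20$, 0.5 | reference fluctuating regime; boundedness needs $\tau_0 \pm m \in (0,1)$ |
| `r0`, `c`, `r1` | growth-rate TPC | 0.1 each | overdamped reference ecology |
| `k0`, `tau_m`, `sigma_k` | capacity TPC | 2, 0.5, 0.05 | peak capacity at mid-temperature |
| `horizon_L`, `burn_in` | fitness averaging window | $10^5$, $10^3$ | transients die in ~100 steps; 10x margin; sweeps drop to $2\times10^4$ with proportionally larger cell-level noise |
| `fd_step` | gradient stencil step (trait units) | $10^{-4}$ | small against trait scales, large against double-precision noise of a deterministic average |
| `step_eta` | continuation step scale | 0.05 | steps of 0.005–0.02 trait units |
| `grad_tol` | singularity residual (fitness scale) | $10^{-3}$ | typical gradient magnitudes are $O(0.1\text{–}10)$ |
| `E` | mutational covariance | identity | independent mutations; results invariant (tested) |

## What the generator emulates — and what it does not

The synthetic environment reproduces the features this analysis needs:
strict boundedness, a tunable predictable component, white unpredictable
fluctuations whose standard deviation grows with both $m$ and
$\sigma_\epsilon$, and bit-reproducible streams. It does **not** emulate
autocorrelated (coloured) climate noise, seasonal asymmetry, trends, or
any mapping to physical degrees; and the ecology excludes demographic
stochasticity, age structure, and interspecific competition. Passing
tests therefore certify the model's internal mathematics — not that real
thermal time series would produce the same singular strategies. The
acceptance checks run at desk scale ($L = 5\times10^4$ for reference
singularities, $2\times10^4$ per sweep cell on $6\times6$ grids,
$10^6$ steps for the temperature mean), sizes at which the reported
quantities are stable to well under their stated tolerances across
seeds.

## Numerical choices and degenerate inputs

* Beta densities are evaluated in log space (`stats::dbeta(log = TRUE)`)
  and ratios exponentiated once; a log-ratio beyond 700 aborts with
  context rather than returning `Inf`.
* The Ricker update aborts when its exponent exceeds 700 (a genuinely
  divergent trajectory), reporting the step index. Mutant sizes
  underflowing $10^{-300}$ are clamped to exact zero and counted — the
  map never reaches zero analytically.
* $\tau \le 0$ and $\tau \ge 1$ are rejected wherever a temperature is
  consumed; the growth curve's essential singularity at $\tau = 0$ is
  thereby unreachable.
* Zero-noise, integer-multiple-of-$\pi$ frequencies make the temperature
  constant: histograms then collapse to one bin (with a warning) and the
  singularity solver reports boundary convergence instead of failing.
* Multiple nullcline intersections are all reported; cells are refined
  by a local linear solve and fall back to the cell centre if the refined
  point escapes the cell.
* Symmetry of a TPC ($\mu = 0.5$) is detected with tolerance $10^{-12}$,
  robust to serialisation round-trips.

## Known limitations

* The invasion criterion is a time-average growth rate on a frozen noise
  sequence — the standard stochastic-invasion-exponent machinery beyond
  time averaging is not implemented, and a single realisation (default)
  trades ensemble coverage for smooth gradients. An `ensemble_reps`
  option averages independent streams when robustness checks want it.
* Branching-point follow-through (dimorphic dynamics) is out of scope;
  the classifier only *labels* branching candidates, and none arise
  under the reference regimes.
* Sweep grids at $6\times6$ resolution with $L = 2\times10^4$ resolve
  the qualitative structure (optimum pinned to the mean where the sine
  is inactive at low noise; declining optimum and broadening TPC with
  noise; cold-specialist J-shapes under strong noise and large sine
  magnitude) but not fine contour positions.
* Trait trajectories carry no absolute time calibration (see above).
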