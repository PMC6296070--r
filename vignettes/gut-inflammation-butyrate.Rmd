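---
title: "Bistable gut inflammation–butyrate dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bistable gut inflammation–butyrate dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`gutswitch` implements a qualitative dynamical model of the cross-talk
between the inflammatory signalling system of gut epithelial cells and
two microbial products: butyrate (anti-inflammatory, a short-chain fatty
acid from fibre fermentation) and lipopolysaccharide (LPS,
pro-inflammatory, entering through a leaky epithelial barrier).  Five
state variables are tracked:

* `N` — nuclear NF-κB fraction (dimensionless, in [0, 1]),
* `R` — an aggregate repressor pool (IκB, A20, ...),
* `T` — pro-inflammatory cytokines (TNF, IL-1, IL-6),
* `L` — within-cell LPS,
* `B` — within-cell butyrate.

Three variants are provided.  The **base** variant is the four-variable
NF-κB/repressor/cytokine/LPS subsystem with constant LPS influx.  The
**core** variant couples butyrate in: butyrate blocks nuclear entry of
NF-κB (the `k_bn B` term beside the repressor in the `N` equation),
strengthens the barrier (a second-order Hill factor
`k_lb^2 / (B^2 + k_lb^2)` gating LPS influx), while cytokines
down-regulate the butyrate transporter (the Hill factor
`k_bt^2 / (T^2 + k_bt^2)` on the transporter term of the `B` equation).
Lumen butyrate enters as a constant environmental parameter `k_Bo`,
through the transporter and through passive diffusion (`k_d k_Bo`).
The **extended** variant multiplies the transporter term by a positive
feedback Hill factor `B^2 / (B^2 + k_2B^2)` standing for the
butyrate → mucin → mucin-adhering SCFA-producer loop.

All constants are qualitative (arbitrary concentration/time units).  The
`"reference"` preset of `gut_params()` is the published parameterisation
(`k_a = 12`, `k_s = 1`, `k_ai = 5`, `k_r = 0.5`, `k_bn = 4.7`,
`k_b = 5`, `k_br = 0.5`, `k_n = 0.2`, `k_p = 7`, `k_t = 0.2`,
`k_tl = 2.8`, `k_bl = 1.02`, `k_lb = 3.4`, `k_l = 0.7`, `k_bt = 2.1`,
`k_d = 0.125`, `k_B = 2.9`), completed by two values that the published
analysis leaves open and that are therefore package choices:

* `k_Bo = 130`, the lumen butyrate level at the bistable operating
  point, and
* `k_2B = 5`, the Hill threshold of the extended variant's feedback
  factor.  Any positive choice shifts both saddle-node points to larger
  `k_Bo` and widens the bistable window (see below); `5` sits below the
  non-inflamed `B` (≈ 50) and above the scale where the factor would
  suppress the transporter entirely, giving a clearly visible widening
  at an otherwise similar hysteresis.

`N` is kept in [0, 1] by validation only; the dynamics themselves bound
it through the `(1 − N)` recruitment and `N/(N + k_r)` saturation
terms, and the positive orthant is forward-invariant (verified
numerically by `verify_orthant_invariance()` and
`verify_box_invariance()`).

# Equilibria and stability

`find_fixed_points()` runs damped Newton (analytic Jacobian,
step-halving line search on the residual norm) from a deterministic
multistart grid: `N` on {0.001, 0.01, 0.1, 0.5, 0.9} and the remaining
components log-spaced on [1e-4, K] (default 4 points each, K = 1e4).
Residuals are scaled per component by `max(1, |x|)` because the two
stable states differ by four orders of magnitude in `N`; a root is
accepted at scaled residual 1e-9 and duplicates are merged at relative
1e-6.  Stability is read from the eigenvalues of the analytic Jacobian
with threshold 1e-8 on real parts; `"marginal"` is flagged with a
warning.

At the reference parameters the core model has three equilibria: the
stable inflamed state (low `B`, high `N`, `T`), the stable non-inflamed
state (high `B`, `N` smaller by ~1e4), and an unstable saddle between
them.

# Continuation, folds, and the normal-form coefficient

`trace_branch()` performs pseudo-arclength predictor–corrector
continuation of the equilibrium set against `k_Bo` or `k_bl`: the unit
tangent comes from a bordered linear solve, the corrector is Newton
orthogonal to the previous tangent, and the arclength step adapts
within [1e-3, 5] (initial 0.5, growth 1.4 on success, halving on
failure).  A corrector landing far from its predictor (more than three
step lengths) is rejected: such jumps can carry the trace straight past
a fold.  If the first sweep does not cover the requested range on all
layers, additional sweeps start from equilibria at the other end of the
range (the lumen-LPS hysteresis needs this: its layers are disconnected
over `k_bl ≥ 0`).

Folds are detected by a sign change of the parameter component of the
tangent and refined by Newton on the bordered extended system
`{f = 0, J q = 0, ⟨q,q⟩ = 1}` in the unknowns (state, parameter, right
null vector), to residual 1e-10.  The left null vector `p` comes from
the transposed Jacobian, normalised to `⟨p,q⟩ = 1`.  The quadratic
normal-form coefficient is

    a = 1/2 ⟨p, B₂(q, q)⟩,

with `B₂` the bilinear second derivative of the right-hand side,
evaluated as a central second difference along `q` (step 1e-4; the
states are O(1–100), which keeps truncation and round-off balanced near
1e-7 on `a`).

**Orientation convention.**  `a` flips sign under `q → −q`, so a
convention is required.  The package default (`orientation = "stable"`)
orients `q` along the secant from the fold towards the adjacent stable
layer.  Under this convention `a < 0` exactly when the reduced
one-dimensional dynamics `dw/dt = a w² + ...` make the flanking branch
on the `+q` side stable — so a negative coefficient at both folds
certifies a stable top and bottom layer of the hysteresis, which is the
reading the published values carry.  The alternative
(`orientation = "positive_B"`, `q` with positive butyrate component)
gives the same magnitudes but yields a positive coefficient at the
right fold, where the stable (inflamed) branch lies in the `−B`
direction from the fold.  Magnitudes are orientation-invariant and are
the robust quantity for comparison.

At the reference parameters the core hysteresis has folds near
`k_Bo ≈ 59.2` (upper-layer termination; printed threshold "≈ 55") and
`k_Bo ≈ 200.1` ("≈ 200"), with normal-form coefficients
≈ −0.10792 and ≈ −0.011147.  Hopf monitoring (a jump of two in the
unstable eigenvalue count away from a fold) is active but silent at
these parameters.

# Pulse-driven switching

`simulate_model()` integrates with deSolve's `lsoda` (analytic
Jacobian, `rtol = 1e-8`, `atol = 1e-10`), restarting the integrator at
every edge of the piecewise-constant drive so pulses stay rectangular.
Dense output is reported on a uniform grid (default spacing 1 time
unit); edge rows carry the incoming drive value.

The switching demonstration starts at the inflamed equilibrium under
baseline `k_Bo = 130`, applies a high pulse on t ∈ [50, 170] and a low
pulse (`k_Bo = 50`) on t ∈ [200, 270].  Two subtleties deserve note:

* the true switching threshold is the right fold at `k_Bo ≈ 200.12`.
  A pulse at exactly 200 — the rounded value quoted alongside the
  threshold itself — leaves the system marginally inside the bistable
  window, where the inflamed equilibrium still exists and attracts;
  no pulse duration can then switch it.  The demonstration therefore
  uses 210, safely above the fold.  The low pulse at 50 is safely
  below the left fold (≈ 59.2).
* during the high pulse the state converges to the non-inflamed
  equilibrium *at the pulse drive* (B ≈ 81), not at baseline, so
  endpoint classification against the baseline attractors
  (`classify_endpoint()`, relative tolerance 1e-2 with absolute floor
  1e-6 — the non-inflamed `N` is ~2e-5) is done at the end of each
  baseline window (t = 200 and t = 350).

Hysteresis memory is the operational definition of bistability used in
the tests: two runs with the same final constant drive but different
pulse histories settle on different attractors.

# The extended model broadens the window — and can only broaden it rightwards

Eliminating `N`, `R`, `T`, `L` at equilibrium leaves a scalar relation
`k_Bo(B) = k_B B / (g(B) + k_d)` for the core model, where `g(B)` is
the transporter saturation evaluated on the equilibrium cytokine level;
the folds are the interior extrema of this curve.  The extended model
replaces `g(B)` by `g(B) · B²/(B² + k_2B²) ≤ g(B)`, so
`k_Bo,ext(B) ≥ k_Bo,core(B)` pointwise, and both the local minimum
(left fold) and the local maximum (right fold) can only move to larger
`k_Bo`.  Strict containment of the core window in the extended one is
therefore impossible for every `k_2B > 0`; what the feedback does is
*broaden* the window while shifting it right.  With `k_2B = 5` the
window grows from [59.2, 200.1] (width ≈ 141) to [62.0, 209.2]
(width ≈ 147), which the tests assert as widening plus a strictly
larger right fold.

# Transforming the lumen-butyrate distribution

`transform_density()` pushes a Gaussian density `p(x)` of lumen
butyrate (default mean 130, sd 40 — centred on the operating point and
straddling both folds; truncated to nonnegative support and
renormalised) through the stable layers of the hysteresis by the change
of variables

    q(y) = w(x) · p(x) / |h'(x)|,   y = h(x),

where `h` is the layer map from lumen to within-cell butyrate.  The
unstable middle layer carries no probability.  Numerically each layer
is represented by a monotone cubic spline; the density is evaluated
through the *inverse* map `x = g(y)`, because `g' → 0` at a fold where
`h'` diverges, keeping the quotient well conditioned.  Points within a
relative window (default 1%) of a fold's parameter value are excluded:
there `h'` diverges and a real system jumps to the other layer rather
than settling.  Each exclusion window cuts only the layer that
terminates at that fold; the other layer passes through that parameter
region smoothly and keeps its mass.

Layer weights admit two readings, both implemented:

* `coverage = "fair"` (default): the layers carry fixed weights
  (default ½, ½) over their whole domains — every system picks a layer
  by an independent fair coin, and draws whose layer does not exist at
  their lumen level are lost.  The combined density has exactly two
  modes for a fold-straddling Gaussian: one below the fold butyrate of
  the lower layer, one above the fold butyrate of the upper layer.
* `coverage = "conditional"`: weights are renormalised over the layers
  that exist at each lumen level, so outside the bistable window all
  mass follows the surviving layer and the transformed mass equals the
  input mass minus the fold exclusions (to 1e-3; mass accounting uses
  exact truncated-Gaussian CDF differences over the piecewise-constant
  weight segments).  The price is a density step where a layer's
  domain ends, which adds genuine secondary local maxima at the
  fold-projected positions.

The two readings cannot be combined: exact mass conservation forces the
availability steps, and the clean two-mode picture requires fixed
weights.  The default follows the equal-probability assumption of the
published analysis.  `sample_transformed()` provides an independent
Monte-Carlo check (inverse-CDF draws mapped through the same scheme);
`tv_distance()` compares histogram and density, with agreement within
total-variation 0.03 at 1e5 draws in the tests.

# Verification suite

* positive-orthant invariance along 50 random trajectories
  (`verify_orthant_invariance()`),
* inward-pointing vector field on all faces of the invariant box
  `P = {0 ≤ N ≤ 1, 0 ≤ L ≤ k_bl/k_l + δ, 0 ≤ R,T,B ≤ K}` (defaults
  δ = 1, K = 1e4, 200 samples per face; strict inequality on the upper
  faces, non-outward on the coordinate faces where some components
  vanish identically),
* no equilibrium in the ε-ball at the origin (ε = 1e-4): both the LPS
  and butyrate derivatives are strictly positive there because every
  constant is positive.

# Problem sizes and numerical defaults

The package defaults are the sizes used throughout the tests and the
analysis driver: a 5 × 4⁴ = 1280-point multistart grid for equilibrium
scans (a 5 × 3⁴ grid for repeated scans along a parameter sweep),
continuation over `k_Bo ∈ [10, 300]` (≈ 140 accepted points at the
default step control), 1e5 Monte-Carlo draws for the density check, 50
trajectories / 200 face samples for the invariance suite.  Integrator
tolerances are `rtol = 1e-8` / `atol = 1e-10`; Newton accepts at scaled
residual 1e-9 (equilibria) and 1e-10 (folds, extended system).

# Limitations

* The model is qualitative: no unit calibration, no spatial/diffusion
  structure, no stochastic kinetics; conclusions are about the shape of
  the dynamics, not physiological concentrations.
* The synthetic lumen-butyrate distribution is a truncated Gaussian;
  real cohort distributions may be skewed or multi-component, and the
  layer weights are an assumption, not a fit.
* `k_2B` and the operating-point `k_Bo` are package choices documented
  above, not published values.
* Continuation assumes the branch is a one-dimensional manifold of
  hyperbolic equilibria away from folds; parameter sets with Hopf
  points would need the (implemented but untested-at-defaults)
  imaginary-axis monitoring taken seriously before trusting the layer
  decomposition.

# Reproducing the analysis

`reproduce_analysis(outdir)` regenerates every artifact — equilibria,
both hysteresis curves with folds and normal forms, the pulse
simulation, the extended-model comparison, the density transform, and
the verification suite — and writes `report.json` plus CSV/JSON files
per stage.  All deterministic stages are bit-reproducible; the
Monte-Carlo stages are reproducible given the seed.
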