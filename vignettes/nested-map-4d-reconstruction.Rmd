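---
title: "Temporally regularized nested-MAP 4D reconstruction of dynamic PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporally regularized nested-MAP 4D reconstruction of dynamic PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpet4d)
```

## The problem

Dynamic PET (dPET) splits a scan into time frames and asks for the
activity concentration of every voxel in every frame.  Reconstructing each
frame on its own leaves the early, short frames extremely noisy, and that
noise propagates into any kinetic parameters fitted to the voxel
time-activity curves (TACs) afterwards.  4D reconstruction instead couples
the frames: at every iteration, each voxel's TAC is replaced by the fit of
a temporally smooth model, so the whole time-course informs every frame.

This package implements that idea as a *nested-MAP* algorithm and uses it
to compare temporal models on synthetic phantoms, with particular interest
in the **spline-residue model**.

## Models

A voxel TAC is modelled as the convolution of the arterial input function
(AIF) $C_I(t)$ with a residue function $R(t)$ scaled by a flow constant,
$f(t) = K \int_0^t C_I(s) R(t-s)\,ds$.  The temporal model families are:

* **spline-residue** — $R(t)$ is a sum of cubic B-splines plus a delta
  term for fractional blood volume, so the TAC basis functions are
  $\eta_0 = C_I$ and $\eta_l = C_I \otimes \zeta_l$.  Convolution with the
  AIF constrains the basis at early times (where frames are short and
  noisy) while the splines keep late-time flexibility.
* **spectral** — basis functions $C_I \otimes e^{-\beta_k t}$ on a
  log-spaced grid of 100 decay constants between $1.1\times10^{-4}$ and
  $10^{-2}\,\mathrm{s}^{-1}$, plus a blood column.
* **adaptive-knot cubic B-splines** — per-voxel knots placed along equal
  segments of $\int |f''''|^{1/4}$, the density that is asymptotically
  optimal for cubic-spline approximation; 11 free knots by default.
* **2C3K / 3C5K** — irreversible two- and three-tissue compartment models.
  The macro-parameter of interest is the trapping flux
  $k_{flux} = K_1 k_3 / (k_2 + k_3)$.

Linear models are fitted per voxel inside the reconstruction by penalized
weighted least squares (weights $1/x$ from the current model prediction),
a Tikhonov problem $\min_\theta \sum_m w_m(\hat x_m - B\theta)_m^2 +
\gamma' \theta^\top \Omega \theta$ solved by Cholesky factorization, with
$\gamma'$ selected per voxel by generalized cross-validation over the grid
$\{0.001, 0.002, \ldots, 0.01\}$.  Two penalties are available:
$\Omega = I$ (an $L_2$ penalty on the coefficients) and the curvature
penalty $\Omega_{ab} = \int \ddot B_a \ddot B_b\,dt$.  The 2C3K model is
fitted without a temporal penalty, it being far more constrained than the
linear families.

The image update is one optimization-transfer MAP step per frame: the EM
surrogate for the Poisson likelihood (with the known additive background
$\epsilon$) plus a separable convexity surrogate for the edge-preserving
Lange prior $U(x) = \tfrac14\sum_j\sum_{k\in N_j} z_{jk}\,
\psi(x_j - x_k)$, $\psi(\xi) = \delta(|\xi|/\delta - \ln(1+|\xi|/\delta))$,
over the 8-neighbourhood with inverse-distance weights.  The decoupled
per-voxel problems are strictly concave and solved by guarded Newton
iteration, so a MAP update never decreases its frame's penalized
objective; with $\beta = 0$ it reduces exactly to MLEM.  Monotonicity of
the *nested* iteration as a whole is not guaranteed once the temporal fit
is recast as weighted least squares, and the driver stops with a warning
if the data objective falls for five consecutive iterations.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `nIter` | 30 (desk experiments: 10) | iterations | outer loop length |
| `beta` | 0.1 | – | spatial penalty weight |
| `delta` | 0.1 | counts | Lange edge scale |
| `gammaGrid` | 0.001…0.01 | – | temporal weight candidates (GCV) |
| `init` | 100 | Bq/cc | uniform initialization |
| `weightFloorFrac` | $10^{-3}$ | – | floor of $1/x$ weights, per frame |
| spectral grid | 100 points, $1.1\times10^{-4}$–$10^{-2}$ | 1/s | decay constants |
| free knots | 11 | – | adaptive spline placement |
| spline-residue knots | 4+4+4 boundary/rise/end + 6 uniform | – | residue basis |

Rate constants are seconds-based internally; per-minute values appear only
in printed summaries.

## Scaling conventions

Two normalizations make a single $\gamma'$ grid meaningful across models
and voxel intensities, since the absolute scale of basis functions and
counts is otherwise arbitrary:

* count-domain basis columns are scaled to unit maximum before fitting
  (coefficients then carry the TAC's count amplitude);
* the curvature penalty matrix is scaled to unit maximal diagonal and, per
  voxel, divided by the squared TAC amplitude, i.e. curvature is penalized
  on the amplitude-normalized curve.

A relative ridge of $10^{-10}$ stabilizes directions that the frame
schedule leaves unidentified: with late frames at 2 h and 4 h
post-injection, basis functions supported in the acquisition gaps have
near-zero frame integrals.

## The simulator

The generator builds a thoracic-like 2D slice (default 64×64 voxels of
3.1 mm; experiments here use 32×32) with soft-tissue background, two
lungs, spine, a blood pool, and a tumour with normoxic rim and hypoxic
core.  The acquisition follows a dynamic FMISO protocol: frames
1×30 s, 6×5 s, 6×20 s, 7×60 s, 10×120 s, 3×300 s and two 600 s frames at
2 h and 4 h post-injection, tracer injected 30 s into the scan,
fluorine-18 decay.  The AIF is a three-exponential bolus (delay 30 s, peak
about 3.3 kBq/cc, tail about 40 Bq/cc).

The *simplified* phantom fills every region with irreversible two-tissue
kinetics (rates of order 0.05–0.25 min⁻¹, hypoxic trapping
$k_3 = 0.012$ min⁻¹).  The *realistic-like* phantom gives the tumours
three-tissue kinetics with a strongly reversible middle exchange and the
normal tissues tabulated reversible-exchange shapes — curves that the
2C3K model demonstrably cannot fit (its best fits fail a runs test on the
noise-free frame values), which is the design point of that phantom: it
separates algorithms by their robustness to kinetic model misspecification
rather than by fit luck.

Projection uses an exact strip-integral (length-of-intersection) 2D
parallel-beam projector (desk default 48 angles × 47 bins at 32×32, 60×95
at 64×64), optional analytic ellipse attenuation, and a global calibration
chosen so one realization totals 3.5 million expected counts — the count
regime of a single-slice clinical acquisition.  Background (scatter plus
randoms stand-in) is spatially uniform per frame at 20% of true counts and
is treated as known by the reconstruction.  Poisson realizations are drawn
with seeds bound to the realization index, so scheduling and resumption
cannot change results.

What the simulator does *not* emulate: photon transport, scatter tails
with spatial structure, detector normalization errors, randoms estimation
noise, 3D geometry, patient motion, or intra-region kinetic heterogeneity
(regions are piecewise constant).  Passing tests therefore demonstrate
correctness of the algorithms and the orderings between them under ideal,
known-background conditions — not clinical image quality.

## Numerical choices

* Convolutions with a parametric AIF (spectral columns, compartment TACs)
  are evaluated in closed form; only AIF-with-spline convolutions use the
  sampled grid (1 s spacing, trapezoidal weights).
* Frame integration of continuous functions uses adaptive quadrature;
  grid-sampled curves use a cached sparse trapezoid weight matrix.
* The 2C3K fit is solved by variable projection: for fixed
  $\alpha = k_2 + k_3$ the model is linear in $(V_b, K_1 k_2/\alpha,
  k_{flux})$ and solved as a tiny box-constrained WLS (exact face
  enumeration); $\alpha$ is profiled on a 60-point log grid, refined by
  bracketed zooming (parametric maps) or Brent search plus optional
  Levenberg–Marquardt polish (single-TAC fits).  Profiling is exact, so
  every grid point acts as a start and the refined optimum is the global
  WLS minimum for practical purposes.
* The 3C5K topology is catenary and irreversible — plasma ⇄ C1
  ($K_1, k_2$), C1 ⇄ C2 ($k_3, k_4$), C2 → trap ($k_5$) — solved through
  the eigen-modes of the compartment ODE system.  The drawn model this
  mirrors is schematic; the adopted arrow assignment is this package's
  choice and is pinned by an ODE-integration oracle in the tests.
* The rise point for spline-residue knots is the first time the
  (GCV-smoothed) pilot fit of a TAC exceeds 5% of its maximum, falling
  back to the injection time; inside reconstruction the AIF delay is used,
  as every tissue TAC rises at tracer arrival.
* The 4th derivative for adaptive knot placement comes from 4th-order
  divided differences of the pilot fit over sliding windows of frame
  midpoints — exact for polynomial TACs, stable for noisy ones; a TAC with
  no usable curvature falls back to uniform knots.  The pilot is a
  GCV-smoothed cubic smoothing spline; when the internal GCV search fails
  (bolus-shaped curves on strongly nonuniform frame midpoints) a
  GCV-scored grid over the effective degrees of freedom replaces it.
  Because TACs are not $C^4$ at the tracer-arrival kink, the placement
  density can degenerate toward a point mass there; it is winsorized at
  its 98th percentile so the rise keeps a knot cluster without starving
  the rest of the curve.
* The adaptive knots for reconstruction are read from a *fully run*
  conventional-MAP prepass (30 iterations): knot densities estimated from
  an under-iterated prepass concentrate pathologically in the bolus and
  destabilize the spline fit.
* The $1/x$ fitting weights are floored at $10^{-3}$ of each frame's mean
  predicted value, the weight floor being necessary because predictions
  can reach zero.
* Fitted coefficients are left unconstrained (predicted TACs may dip
  negative); predictions are clipped at zero only where they feed the
  multiplicative EM core and the $1/x$ weights.

## Convergence behaviour worth knowing

EM-type updates converge slowly, and most slowly at region edges.  On
noiseless data the image error keeps decreasing for hundreds of
iterations; at the default 10–30 iterations reconstructed images are
*useful*, not converged, and thin structures (a 1–2 voxel tumour rim)
retain the largest residual error.  The comparisons this package makes are
therefore at matched iteration counts, which is also how the algorithms
are compared in practice.

The adaptive-knot spline model is the least constrained family at early
time-points and shows the weakest stability of the four: with no or weak
temporal penalty its nested iteration can amplify noise at later
iterations, and even with its preferred curvature penalty its error trace
can turn upward while the AIF-convolved models keep improving.  This is an
inherent property of unconstrained early-time splines, and it is the
motivation for the spline-residue construction.

## Experiment scale

Desk-scale experiment defaults — 32×32 voxels, 48×47 sinograms,
10 realizations, 10 iterations, the full five-algorithm roster — complete
in minutes on one CPU and preserve the orderings of interest (nested-MAP
variants less noisy than conventional MAP; spline-residue less biased than
2C3K under model misspecification).  Paper-scale settings (64×64, 60×95,
50 realizations, 30 iterations) are reachable through the same
configuration objects.

## Known limitations

* 2D single-slice geometry only; the projector is exact but idealized.
* The background term is known to the reconstruction; misspecifying it is
  possible through the API but no estimator is provided.
* GCV selects $\gamma'$ only on the configured grid; the grid is assumed
  to straddle the useful range (it does under the scaling conventions
  above).
* `fitAIF` fits frame-midpoint values; for very short bolus frames the
  frame-average/point-value distinction biases the peak by a few percent.
* No statistical tests across algorithms are provided — summaries are
  descriptive, matching the package's comparison design.
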