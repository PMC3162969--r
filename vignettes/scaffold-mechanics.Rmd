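---
title: "Constitutive modelling and data reduction for collagen scaffold mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constitutive modelling and data reduction for collagen scaffold mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gohbiax)
```

## Scope

`gohbiax` analyses planar equibiaxial tension and oscillatory rheometry of
collagen gel scaffolds. Its centrepiece is the Gasser–Ogden–Holzapfel (GOH)
fiber-dispersion strain-energy function, evaluated exactly for an
incompressible membrane under plane stress, together with the data-reduction
and parameter-identification conventions that turn raw test records into
fitted material parameters. This vignette records the model assumptions, the
numerical choices, and the design decisions made where conventions in the
field genuinely diverge.

## The constitutive model

The strain-energy density is

$$U = C_{10}(\bar I_1 - 3) + \frac{k_1}{2k_2}\sum_{\alpha=1}^{2}
\left\{\exp\left[k_2\langle\bar E_\alpha\rangle^2\right]-1\right\},
\qquad
\bar E_\alpha = \kappa(\bar I_1-3) + (1-3\kappa)(\bar I_4^{(\alpha\alpha)}-1),$$

with two in-plane fiber families at $\pm\gamma$ from the stiff ($x$) axis and
$\langle x \rangle = \max(x,0)$.

**Parameters.** $C_{10}$ (kPa, > 0) sets the isotropic matrix response — in a
pure collagen gel it is phenomenological (fiber uncoiling) rather than a
distinct ground-substance stiffness. $k_1$ (kPa, ≥ 0) and $k_2$
(dimensionless, > 0) govern the exponential fiber stiffening; they are
strongly inversely coupled (see *Identifiability* below). $\gamma$ (degrees,
[0, 90]) is the mean fiber angle and $\kappa$ ([0, 1/3]) the dispersion:
$\kappa = (1/4)\int_0^\pi \rho(\Theta)\sin^3\Theta\,d\Theta$ equals 1/3 for
an isotropic 3-D orientation density and 0 for perfect alignment. Fitted
collagen-gel values sit at 11–17 kPa for $C_{10}$, $10^3$–$10^4$ kPa for
$k_1$, $10^2$–$10^3$ for $k_2$, and 0.32–1/3 for $\kappa$; these magnitudes
fix the default fitting bounds.

**Incompressibility and plane stress.** The inverse bulk modulus $D$ is held
at zero: incompressibility is treated as an exact constraint rather than a
penalty, so the volumetric term is dropped, $\lambda_z =
1/(\lambda_x\lambda_y)$, and the distinction between isochoric and total
invariants disappears ($J \equiv 1$). The Cauchy stress is
$\sigma = -p I + 2 U_1 B + 2\sum_\alpha U_{4\alpha}\, m_\alpha \otimes
m_\alpha$ with $m_\alpha = F a_\alpha$; because both families are in-plane,
the membrane plane-stress condition $\sigma_{zz} = 0$ yields the reaction
pressure in closed form, $p = 2U_1\lambda_z^2$. These analytic stresses are
cross-checked in the test suite against central differences of the
constrained energy (the identities $\sigma_{ii} = \lambda_i\,\partial
U/\partial\lambda_i$ and $\sigma_{xy} = \lambda_y\,\partial U/\partial s$
for the shear parameter $s$) to a relative 10⁻⁶ over hundreds of random
admissible states, and against a brute-force tensor implementation of the
energy.

**Fiber activation.** The Macauley bracket is applied to $\bar E_\alpha$
exactly as the energy is written: a family is active iff $\bar E_\alpha > 0$.
An alternative convention activates fibers when $\bar I_4 > 1$; the two
differ whenever $\kappa > 0$ (the dispersed strain mixes $\bar I_1$ into the
switch). We follow the literal definition because it keeps the energy
$C^1$-consistent with its own stress; the choice matters only in strongly
compressed regimes that the equibiaxial protocol never visits.

**Orientation density.** No functional family is imposed on $\rho(\Theta)$;
$\kappa$ is fitted phenomenologically. `kappa_from_density()` exists for
validation — e.g. that the uniform density gives 1/3, or that a narrow peak
at $\Theta_0$ gives $\sin^2\Theta_0/2$ — not as a fitting path. It uses
composite Simpson quadrature on a fixed 20 000-panel grid rather than
adaptive quadrature, deliberately: near-delta densities are legitimate
inputs and adaptive subdivision can miss a narrow peak entirely.

**Overflow guard.** With $k_2$ up to ~10³, $\exp(k_2\langle\bar
E\rangle^2)$ explodes a short distance beyond the fitted strain range. Model
evaluations therefore raise a classed range error when $k_2\langle\bar
E\rangle^2$ exceeds a cap (default 50, overridable per call), naming the
offending family. The fitter evaluates with the guard active and converts
such states into large residuals, which simply repels the optimizer.

## Biaxial data reduction

Raw records are one row per frame: four marker positions (a nominal 5 mm
square at the specimen centre), two axial loads in grams-force, and a time
stamp, for a nominally 15 mm × 15 mm × 1 mm membrane.

* **Stretches** come from the best-fit homogeneous 2-D deformation gradient
  mapping centred reference marker coordinates to centred current ones
  (least squares over all four markers). This is the standard robust choice —
  edge-length ratios waste half the information and are noisier under marker
  jitter; centring makes the estimate translation-invariant. Off-diagonal
  components are returned for quality control.
* **Stress** is true (Cauchy) stress: load × 9.80665 × 10⁻³ N/gf over the
  current cross-section, which under homogeneous incompressible deformation
  is the reference section divided by the axial stretch:
  $\sigma_{xx} = f_x\lambda_x/(L_{0y}t_0)$. Thickness defaults to the
  nominal 1 mm; whether per-sample measured thickness should be used instead
  is a data-availability question, and the geometry object accepts any
  value.
* **Strain** is logarithmic, $\varepsilon = \ln\lambda$.
* **Reference state.** The preloaded state (2 g) is the strain reference.
  `reduce_experiment()` selects the frame whose loads are nearest the
  nominal preload (policy `"preload"`; `"first_frame"` is available, and
  switching policies shifts all strains by a constant $\ln\lambda_{\rm
  pre}$). The reference-frame load is treated as suture-straightening
  tension and subtracted before stress computation (`subtract_preload`,
  default `TRUE`); this is the convention under which the synthetic
  generate → reduce loop closes identically.
* **Loading branch.** A frame is kept if it lies between the reference and
  peak-load frames and both loads are non-decreasing within 0.5 % of the
  maximum load — enough slack for load-cell chatter without admitting the
  unloading half-cycle.
* **Tangent modulus.** The reported stiffness is $E_t = 0.5 \times
  d\sigma/d\varepsilon$, by central differences (one-sided at the ends) on
  an optionally moving-average-smoothed curve. The 0.5 factor is a reporting
  convention inherited from the biaxial-testing literature; its provenance
  is not derivable from the mechanics, so `raw_slope = TRUE` exposes the
  unscaled derivative. No smoothing is applied by default; the window is a
  user choice because the smoothing used historically before
  differentiation is not standardized.
* **Averaging.** Replicate tangent-modulus curves are averaged by linear
  interpolation onto a common strain grid, with the pointwise standard
  deviation reported; a grid point outside any curve's span is an error
  naming the curve rather than a silent extrapolation.

## The two-stage fitting protocol

Nonaligned scaffolds behave isotropically under equibiaxial load, so stage
one fixes $\gamma = 45°$, $\kappa = 0.333$ and fits $(C_{10}, k_1, k_2)$.
Stage two fits each aligned scaffold with $C_{10}$ pinned to its nonaligned
partner's value — the matrix is the same material; alignment should change
fiber architecture, not matrix stiffness — leaving $(k_1, k_2, \gamma,
\kappa)$ free with $\kappa \in [0, 1/3]$.

**Loss and residuals.** The loss is the sum of squared Cauchy-stress
residuals stacked over both axes simultaneously (a sequential per-axis fit
is the other conceivable reading; simultaneous stacking is the stated
choice, and is what makes $\gamma$ and $\kappa$ identifiable from the x/y
split). Observed strains are inverted to stretches, $\lambda =
e^\varepsilon$, and the model is evaluated along the equibiaxial stretch
path, so the two axis curves need not share a grid. Goodness of fit is
summarized as curve RMSE in kPa — a package choice, since no standard metric
is mandated for these fits.

**Optimizer.** Bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) over a transformed space: $k_1$ and $k_2$ are
optimized as log₁₀ (their plausible ranges span 3–9 decades), $C_{10}$,
$\gamma$, $\kappa$ linearly. Default bounds: $C_{10} \in [0.5, 100]$ kPa,
$k_1 \in [10^{-3}, 10^6]$ kPa, $k_2 \in [1, 10^4]$, $\gamma \in [0, 90]°$,
$\kappa \in [0, 1/3]$. The $k_1$ lower bound is deliberately tiny so that
matrix-only data can push the fiber term into irrelevance instead of
biasing $C_{10}$. Multistart: 16 Latin-hypercube draws over the transformed
box (seed 1234 by default; every draw flows from the configured seed, so
fits are deterministic). Ties among starts with numerically equal loss are
broken toward the smallest $k_2$ (the flattest exponent), then
lexicographically over the remaining parameters.

**Identifiability.** $k_1$ and $k_2$ trade off strongly — raising one and
lowering the other translates the stress upturn in strain. Every fit
therefore exposes the local free-parameter correlation matrix from
$(J^TJ)^{-1}$ at the optimum; on the packaged parameter sets the $k_1$–$k_2$
correlation is strongly negative, the quantitative face of that inverse
relationship. Isotropic data passed to the aligned fit is a degenerate
problem: any $(\gamma = 45°)$ or $(\kappa = 1/3)$ ridge point reproduces it,
so the fit flags $\kappa$ landing on the 1/3 boundary as
"isotropic-indistinguishable" rather than pretending the orientation is
identified.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, at the nominal
test conditions: equibiaxial loading of a 15 × 15 × 1 mm membrane from a 2 g
preload up to a 70 g maximum for the softest (0.03 % GP) scenario and 100 g
for the stiffer ones, 5 mm marker squares, and rheometry sweeps over
0.1–10 Hz (or 0.1–10 % strain amplitude) with $G'' / G' = 0.1$ and a weak
power-law frequency trend.

`generate_raw_records()` imposes an equibiaxial *stretch* grid whose end
point is found by root-finding (Brent, tolerance 10⁻¹²) on the monotone
load–stretch map so the stiffer axis lands exactly on the target maximum
load; recorded loads are inverted from the model stresses as
$\rm{load} = \rm{preload} + \sigma L_0 t_0/\lambda$. That preload offset —
carried at the reference state and subtracted again during reduction — is
what makes the generate → reduce loop close to numerical precision, which
the acceptance-level tests require at 10⁻¹⁰ for all six packaged scenarios.
Stress noise is multiplicative Gaussian, marker jitter additive Gaussian;
all draws derive from one protocol seed in a documented order (x-axis loads,
y-axis loads, then marker jitter frame by frame).

The generator does **not** emulate: preconditioning hysteresis, suture
compliance or edge effects (the homogeneous-deformation assumption is exact
here by construction, only approximately true between real loading bars),
spatial inhomogeneity of alignment, true load control (per-frame load
equality between axes for anisotropic samples), or any viscous/poroelastic
time dependence. Passing tests on synthetic data therefore validate the
*reduction and identification machinery*, not these physical confounders.

Six scenarios named `nonaligned_{0.03,0.1,0.25}` and
`aligned_{0.03,0.1,0.25}` ship as a JSON fixture of fitted parameter sets;
sweep magnitudes (~100 Pa storage modulus) are fixture conventions chosen to
sit in the experimentally reported order of magnitude, since sweep figures
publish trends rather than tabulated values.

## The tensile-to-shear ratio

For any incompressible isotropic elastic solid the small-strain Young's-to-
shear modulus ratio is exactly 3, and `small_strain_moduli()` recovers this
numerically for the GOH model with the fiber term off ($E_0 = 6C_{10}$,
$G_0 = 2C_{10}$) and, at $\kappa = 1/3$, with it on. Experimentally,
collagen gels show tangent-to-storage-modulus ratios of 10²–10³. That gap is
*not* a model defect to be fitted away: tension probes the fibrillar
network, while unconfined oscillatory shear of a highly hydrated biphasic
gel is dominated by interstitial fluid movement and plate lubrication. The
package therefore asserts the model-side value of 3, provides
`tensile_shear_ratio()` to quantify the experimental contrast, and leaves
biphasic simulation explicitly out of scope.

## Numerical conventions and problem sizes

* Angles are degrees at every interface, radians internally.
* CSV output is written at full double precision (`%.17g`), making
  write → read round trips exact.
* Small-strain moduli use central differences with step 10⁻⁴ on log strain;
  the lateral-stretch root for the uniaxial state is solved to 10⁻¹⁴.
* The test-suite recovery studies use 30-point curves on $\lambda \in
  [1, 1.06]$ (the few-percent strain range of these gels), 16 multistarts
  for the headline fits, 8 for replicated noise studies, 200 random draws
  for the stress–energy consistency property, and a 2 % noise / 20-ish
  replicate scale for the stochastic recovery checks — sizes chosen as
  representative desk-scale study conditions.
* Fit convergence tolerances are `ftol = ptol = 10⁻¹²`, tight enough that
  zero-noise recoveries are limited by arithmetic, not the stopping rule.

## Known limitations

* A point model of a homogeneous membrane: no finite-element discretization,
  so attachment/edge fields and spatial alignment gradients are outside the
  model.
* Purely elastic and monophasic: no viscoelastic or poroelastic branch, so
  rheometry is summarized, never fitted.
* Fiber dispersion is the scalar 3-D $\kappa$ of the GOH family; no
  out-of-plane-restricted (planar) dispersion variant is implemented.
* The aligned fit's parameter correlations warn about, but cannot remove,
  the intrinsic $k_1$–$k_2$ degeneracy; meaningful uncertainty statements
  beyond the local quadratic approximation would need replicate data or a
  Bayesian treatment, both out of scope.
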