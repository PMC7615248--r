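---
title: "Methods: estimating diffusion anisotropy from three gradient directions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating diffusion anisotropy from three gradient directions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dia3)
```

## The model

Diffusion-weighted MRI measures, for each gradient direction $u$ on a
single shell of b-value $b$, the attenuation of the water signal relative
to the non-weighted baseline. `dia3` assumes the mono-exponential model

$$E(u) = S(u)/S_0 = \exp(-b\,D(u)),$$

so each acquired direction yields one sample of the apparent diffusion
coefficient profile $D(u) = -\log E(u)/b$ (mm²/s). The profile of an ideal
diffusion tensor is the quadratic form $D(u) = u^\top T u$, but the method
makes no tensor assumption: $D$ is treated as an arbitrary non-negative
antipodally symmetric function on the sphere.

The Diffusion Anisotropy is the normalized distance between $D$ and its
isotropic equivalent,

$$\mathrm{DiA} \;=\; 1 - \frac{\left[\int_S D(u)\,du\right]^2}
  {4\pi \int_S D^2(u)\,du}
  \;=\; 1 - \frac{\langle D\rangle^2}{\langle D^2\rangle},$$

a Cauchy–Schwarz-type ratio: 0 exactly for isotropic profiles, approaching
1 only for profiles concentrated on a vanishing solid angle. For a tensor
it has the closed form
$1 - 5(\operatorname{tr}T)^2 / \left(3[(\operatorname{tr}T)^2 +
2\operatorname{tr}(T^2)]\right)$, which the test suite and
`dia_quadrature()` use as ground truth. Because only the two spherical
*means* $\langle D\rangle$ and $\langle D^2\rangle$ enter, the measure
survives extreme angular undersampling — this is the entire point.

## The estimators

**Spherical-harmonics path** (`dia_sh()`, `fit_sh()`). Both $D$ and $D^2$
are fitted in the real, antipodally symmetric (even-degree) SH basis with
the Laplace–Beltrami penalty $\lambda \sum_{l,m} l^2(l+1)^2 c_{lm}^2$. The
basis is normalized so $Y_{00} = 1/\sqrt{4\pi}$; then the degree-0
coefficient of a fit is $C_{00}\{H\} = \frac{1}{\sqrt{4\pi}}\int_S H$, and

$$\mathrm{DiA} = 1 - \frac{C_{00}^2\{D\}}{\sqrt{4\pi}\,C_{00}\{D^2\}}$$

is algebraically identical to the integral definition. Two conventions are
deliberate and pinned by tests:

* the *squared samples* are fitted, not the square of the fitted expansion
  — both integrals are then estimated from the data in the same basis, and
  the 3-direction case reduces exactly to the closed form below;
* the normalization pairing ($1/\sqrt{4\pi}$ inside $C_{00}$, a single
  $\sqrt{4\pi}$ in the denominator) is forced by requiring the SH form to
  coincide with the integral form; other pairings fail the
  `dia_quadrature()` cross-check by constant factors.

**Order rule.** For $N$ directions the fit uses the largest even degree
$L$ with $(L+1)(L+2)/2 \le N$: $N=3..5 \to L=0$, $N=6..14 \to L=2$,
$N=15..27 \to L=4$, … The rule makes $N=3$ collapse to the simplified
formula and lets 6 well-spread directions resolve the degree-2 tensor
profile exactly. It is overridable (`order =`) for experiments.

**Simplified path** (`dia_simplified()`). At degree 0 the fit of any
sample set is its arithmetic mean, so for three orthogonal samples

$$\mathrm{DiA} = 1 - \frac{(D_x+D_y+D_z)^2}{3(D_x^2+D_y^2+D_z^2)}
\in [0, 2/3],$$

with the supremum $2/3$ attained only on single-axis profiles. When the
three samples sit on a tensor's own eigenvectors this equals
$\tfrac{2}{3}\mathrm{FA}^2$ — the bridge between DiA and FA that the
worked example (FA $=0.6444$, DiA $=0.2768$) instantiates. Equality of the
two paths on *any* orthonormal triad (not only the axes) holds because the
degree-0 estimate is geometry-free; a property test checks it on 100
random triads to $10^{-10}$.

**Quadrature oracle** (`dia_quadrature()`). The reference integrator is a
product rule — Gauss–Legendre in $\cos\theta$ crossed with a uniform
azimuth grid, weights summing to $4\pi$ (about 2562 nodes by default). It
is exact for band-limited spherical polynomials, hence exact on tensor
profiles and rotation-invariant to machine precision. A committed point
file would have served the same role; generating the rule in code keeps
the repository text-only and is strictly more accurate than an
equal-weight design of the same size.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `lambda` | 0.006 | — | Laplace–Beltrami weight used for dense-shell map fitting; degree 0 is never penalized, so DiA is insensitive to it except through basis coupling on poorly spread schemes. The same value is reused for the $D^2$ fit — the simplest consistent choice. |
| `b0_tolerance` | 50 | s/mm² | volumes at or below it count as baseline; covers tables writing b0 as exactly 0. |
| `epsilon` (E clamp) | 1e-8 | — | floor for $E$ so $\log E$ stays finite on fully attenuated/noisy voxels; $E>1$ (noise above baseline) clamps to 1, giving $D=0$ exactly. |
| `ortho_tol_deg` | 2 | degrees | `estimator = "auto"` takes the simplified path only when the 3 directions are mutually orthogonal within this tolerance. |
| `dia_min` | 0.1 | — | mask removing near-isotropic voxels before clustering in the angular-resolution study. |
| `tol_deg` (variability) | 15 | degrees | near-orthogonality window for candidate 3-subsets; an unrestricted `"all"` mode exists because "every possible orientation" is the other defensible reading. |

Directions are interpreted in the **image frame** (FSL bvec convention).
The RGB code $r = \mathrm{DiA}\cdot D_x/D_{AV}$ (g, b likewise, clipped to
$[0,1]$, black where $D_{AV}=0$) therefore reads as orientation *relative
to the image axes* and is only produced on the 3-direction orthogonal
path. Clipping rather than renormalizing preserves hue ordering, matching
directional-FA practice.

## What the simulator emulates — and what it does not

`synthesize_phantom()` produces single-shell, mono-exponential signals
$S = S_0\exp(-b\,u^\top T u)$ at b = 1000 s/mm², $S_0 = 1000$, one
baseline volume — the acquisition geometry of a fast clinical protocol.
Rotation studies use the two schemes of `rotation_matrix()`: in-plane
(x–z) rotation, and spatial rotation about $(1,1,1)/\sqrt3$ (Rodrigues
form; at $2\pi/3$ it is the coordinate permutation, which pins the
convention). Rician noise — the modulus of a complex Gaussian — is opt-in;
the rotation and downsampling studies run noiseless by design, isolating
the purely geometric orientation effect.

The six-population phantom behind the angular-resolution study uses
prolate tensors $(1, r, r)\times10^{-3}$ mm²/s with
$r \in \{0.30, 0.25, 0.20, 0.15, 0.10, 0.05\}$ — dense-sampling DiA levels
of about 0.13–0.37, all above the 0.1 mask — and an independent uniformly
random orientation per voxel, because fiber bundles take arbitrary
orientations in tissue and it is precisely this spread that produces the
median underestimation at low direction counts (an axis-aligned phantom
would instead *over*-estimate at $N=3$: eigen-axis sampling yields
$\tfrac23\mathrm{FA}^2$, which exceeds the spherical value).

What the phantoms deliberately omit: crossing fibers and non-Gaussian
(non-tensor) profiles, partial-volume mixing, spatially correlated noise,
eddy-current/motion artifacts, and $T_2$ shine-through. Passing tests on
these phantoms therefore demonstrate the estimators' mathematical
behavior — equivalences, bounds, orientation dependence, noise
robustness at SNR 20 — not clinical image quality on real scanners.

## Direction schemes and downsampling

Schemes are deterministic: the Cartesian axes ($N=3$), the tetrahedral
cube-diagonal set ($N=4$), a committed electrostatic-repulsion optimum
($N=5$, pairwise antipodal angles 59.6°/73.0°), the icosahedral DTI set
($N=6$), and spherical-Fibonacci hemisphere sets otherwise (the
64-direction stand-in for a dense research shell). The icosahedral set is
a spherical 5-design: its equal-weight average integrates the degree-4
$D^2$ profile exactly, which is *why* six directions give the same DiA at
every tensor orientation (the sweep's std over angles is ~1e-16).

`downsample_directions()` selects subsets by greedy farthest-point
max–min angular distance under antipodal identification — deterministic
given input order, and verified to beat 1000 random subsets on minimum
pairwise angle. The 1-D k-means in `angular_consistency()` initializes at
evenly spaced quantiles of the reference DiA, making the clustering
deterministic without restarts.

## Numerical choices and degenerate inputs

* Background (all samples zero): DiA defined as 0, RGB black — background
  should render black, and $0/0$ is otherwise undefined.
* $C_{00}\{D^2\} \le 0$ (possible only for degenerate fits): DiA set to 0.
* Outputs clamped to $[0, 1)$ (simplified path: $[0, 2/3]$); equal samples
  return exactly 0 rather than a $10^{-16}$ residual.
* Unpenalized rank-deficient SH systems are refused with advice to raise
  $\lambda$ or lower the order rather than silently pseudo-inverted.
* Otsu masking of $S_0$ treats a constant baseline as all-foreground, so
  background-free phantoms pass through unmasked; noise studies pass an
  explicit full mask because Otsu on a unimodal noisy baseline splits it
  arbitrarily.

## Problem sizes

The shipped studies run at desk scale: phantoms of $10^3$–$2.4\times10^3$
voxels, 1000 noisy repetitions for the SNR-20 robustness check, 1-degree
sweep grids, 64-direction dense schemes, and 50–100 random
tensors/triads in the property loops. The full suite completes in well
under a minute; all stochastic pieces are seeded.

## Known limitations

The central caveat is inherited from the physics, not the code: with
fewer than six directions no method can characterize all orientations,
and DiA from three axes systematically underestimates structures oblique
to those axes — worst at 45°, where the 3-direction value drops to about
a third of its aligned value (0.087 vs 0.277 for the reference tensor).
The measure complements, and does not replace, a full-shell FA. Multi-shell
data are reduced to their innermost shell upstream of this package; DICOM
ingestion and gradient reorientation after motion correction are out of
scope.
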