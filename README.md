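# dia3 — diffusion anisotropy from three orthogonal gradient directions

Fast clinical diffusion-MRI protocols (EPI-DWI and similar) acquire one
baseline volume plus only **three orthogonal diffusion-weighted volumes**,
and report their average — a mean-diffusivity surrogate that carries no
information about the *orientation* of diffusion. Conventional anisotropy
indices such as the fractional anisotropy (FA) need at least the six
directions of a diffusion-tensor fit.

`dia3` computes the **Diffusion Anisotropy (DiA)** — the normalized distance
between the apparent diffusion coefficient (ADC) profile and its isotropic
equivalent — which remains estimable from exactly those three volumes,
because it only needs the spherical means of D and D²:

```
DiA = 1 − [∫_S D(u) du]² / (4π ∫_S D²(u) du)
```

Under the mono-exponential model E(u) = exp(−b·D(u)), the integrals are
estimated by fitting the samples in a real even-order spherical-harmonics
(SH) basis with a Laplace–Beltrami penalty (λ = 0.006 by default); the
degree-0 coefficient C₀₀ carries the spherical mean, so

```
DiA = 1 − C₀₀²{D} / (√(4π) · C₀₀{D²})
```

For three orthogonal, axis-aligned samples Dx, Dy, Dz this reduces to a
closed form that needs no gradient directions at all:

```
DiA = 1 − (Dx + Dy + Dz)² / (3 (Dx² + Dy² + Dz²)),     DAV = (Dx + Dy + Dz)/3
```

together with an RGB orientation code r = DiA·Dx/DAV (and likewise g, b).
The package also ships a diffusion-tensor phantom simulator and the
simulation studies that quantify the price of the reduced acquisition:
structures not aligned with the acquisition axes are **underestimated**,
worst at 45° to the axes, while six well-spread directions are already
orientation-independent.

## Worked example

Simulate a phantom of the reference tensor — eigenvalues
(1, 0.3, 0.3) × 10⁻³ mm²/s, principal axis along x — acquired with the three
Cartesian axes at b = 1000 s/mm², then run the full map pipeline:

```r
library(dia3)

tn <- make_tensor(c(1, 0.3, 0.3) * 1e-3)
tensor_fa(tn)
#> [1] 0.6444022

ph   <- synthesize_phantom(tn, layout = array(1L, c(4, 4, 4)),
                           directions = direction_scheme("axes"))
maps <- dia_compute(compute_adc(normalize_dwi(ph)))
maps
#> DiA maps (simplified estimator, 3 directions)
#>   DiA in mask: median 0.2768, IQR 0.2768-0.2768 (64 voxels)

maps$rgb[1, 1, 1, ]
#> [1] 0.5190678 0.1557203 0.1557203
```

The tensor's FA is 0.6444; sampled on its own eigen-axes the 3-direction
DiA is (2/3)·FA² = 0.2768, and the color code is dominated by red: the
principal diffusion direction is the x axis. The *full* spherical profile
of the same tensor has a lower DiA — `dia_quadrature(function(u)
tensor_adc(tn, u))` returns 0.1327913 — which is exactly why 3-direction
estimates of obliquely oriented structures come out low:

```r
sw <- rotation_sweep(n_directions = c(3, 6), rotation_schemes = "plane")
min(subset(sw, n_directions == 3)$dia)   # 0.08734, at theta = 45 degrees
sd(subset(sw, n_directions == 6)$dia)    # ~1e-16: orientation-independent
```

The same pipeline is available from a shell via the installed script
(`system.file("cli", "dia3", package = "dia3")`):

```sh
dia3 simulate --eigenvalues 1e-3,0.3e-3,0.3e-3 --scheme axes --out phantom
dia3 compute  --dwi phantom.nii.gz --bval phantom.bval --bvec phantom.bvec \
              --out-prefix maps     # writes maps_dav / maps_dia / maps_rgb .nii.gz
```

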