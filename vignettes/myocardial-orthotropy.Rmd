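---
title: "Measuring myocardial laminar orientation: models, conventions and design choices"
author: "myolam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring myocardial laminar orientation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myolam)
```

## The problem

Ventricular myocardium is orthotropic: at every point one can define the
local myocyte axis **m**, the sheet in-plane axis **s**, and the sheet
normal **n** of the local myolamina (a sheet of 4–6 myocytes, roughly
80–120 μm thick, separated from its neighbours by cleavage planes). Three
imaging routes measure these axes in fixed hearts, each with different
physics and failure modes:

1. **Structure tensor (ST)** of a high-resolution (≈50 μm) contrast-enhanced
   structural volume. Contrast agent fills the interstices, so laminae are
   dark and interstices bright; the direction of strongest intensity change
   is the putative sheet normal.
2. **Diffusion tensor imaging (DTI)** at ≈200 μm. Water diffuses most
   freely along myocytes and least across laminae; the principal
   eigenvector is the putative myocyte axis, the minor eigenvector the
   putative sheet normal.
3. **Direct isosurface measurement (FI)**. The lamina/interstice boundary
   is extracted as a mesh from the (upsampled) structural volume and its
   face normals are averaged per 200 μm box. This is a direct, per-box
   observation of **n** against which the two tensor methods are judged.

`myolam` implements all three plus the cardiac angle conventions and the
axial statistics for comparing them, and — because imaging data of this
kind are not publicly deposited — a synthetic phantom generator with exact
ground truth that stands in for the acquisition.

## The synthetic phantoms

`makeSlabPhantom()` builds a stack of planar laminae: intensity is a
periodic profile of the coordinate along the configured normal. The profile
is a power-shaped raised cosine
$g(u) = \left(\tfrac{1 + \cos 2\pi u}{2}\right)^p$, bright at interstice
centres, with $p$ set so that the full width at half maximum of the bright
pulse equals `intersticeFraction` of the period. Two properties motivated
this choice over a binary or flat-topped profile: it is smooth, so image
gradients are defined everywhere (a flat-topped profile leaves ~2-voxel
stretches of exactly zero gradient inside laminae, where the structure
tensor is degenerate and its eigenvectors meaningless), and it is
band-limited enough at 50 μm sampling to avoid aliasing.

Defaults are chosen once to emulate realistic acquisition conditions:
50 μm isotropic voxels; a 150 μm lamina period (lamina ≈90 μm — inside the
physiological 80–120 μm band — plus interstice ≈60 μm,
`intersticeFraction = 0.4`). A 100 μm period would place the pattern
exactly at the Nyquist limit of the grid, where central differences vanish
identically; three voxels per period is the smallest resolvable choice.
Intensities are baseline 20, contrast 80 (arbitrary units — the intensity
distribution of real interstices is not quantified anywhere, so contrast is
a free parameter); structural noise is additive Gaussian (a high-SNR
magnitude image), diffusion noise is Rician (magnitude of a complex
Gaussian), each behind a seed.

`makeAnnulusPhantom()` emulates a ventricular wall: inside a cylindrical
annulus (defaults 600–1400 μm radius, a rat-like ~0.8 mm wall) the myocyte
direction follows a helix angle linear in normalized transmural depth from
+60° (endo) to −60° (epi) — the classical ≈120° transmural span — and the
sheet normal is the radial direction tilted by a configurable
sheet-elevation rule (default 0°, i.e. radial). The laminar intensity is
periodic in radius, which is exactly consistent with the default radial
sheet normal; if a nonzero elevation rule is configured the ground-truth
triad follows it but the intensity pattern remains radial — a known
limitation of the generator, acceptable because the annulus is used to
validate angle conventions and transmural profiles rather than image-based
normal recovery.

What passing on these phantoms does *not* show about real data: phantoms
have a single laminar population per voxel, no branching, no perfusion
inhomogeneity, no susceptibility artefacts, and fixation-induced geometry
is not modelled. The phantoms validate the estimators, not the biology.

## Structure-tensor analysis

The intensity gradient is computed with a 3×3×3 (or 5×5×5) derivative
template: the central-difference stencil along the differentiated axis
(−½, 0, ½ or the fourth-order five-point stencil) combined with a matched
smoothing kernel along the two transverse axes — (1, 4, 1)/6 for width 3,
(−1, 4, 24, 4, −1)/30 for width 5. The matching is deliberate and is the
one place where this implementation goes beyond a bare 1D stencil: the
transverse kernel is chosen so that the ratio of derivative to smoothing
frequency responses is $\omega$ to the stencil's own order
($\sin\omega / S(\omega) = \omega + O(\omega^5)$ for width 3). Without it,
each gradient component of an oblique plane wave is attenuated by a
different factor and the gradient *direction* — the quantity this method
exists to measure — acquires a systematic bias we measured at 5–17° for
laminar wavelengths of ~3 voxels; with it the bias drops below ~2.5° for
arbitrary slab orientations. Convolutions run as FFT-based 1D passes after
mirror padding (reflection about the boundary sample), which avoids
wrap-around artefacts; boundary voxels remain less accurate than interior
ones, and the recovery guarantees quoted below are for interior voxels.

The tensor T = ∇I∇Iᵀ is then smoothed over resolution doublings with
normalized binomial kernels ((1,2,1)/4 at width 3, (1,4,6,4,1)/16 at
width 5), decimating by two per level while keeping even 0-based indices so
the coarse grid stays aligned with a 200 μm acquisition grid. Two levels
from 50 μm reach 200 μm with an effective native support of 9 voxels per
axis (`effectiveSupportWidth(3, 3, 2)`), i.e. each coarse tensor has seen a
≈450 μm neighbourhood — the reason ST is smoother but less local than a
single-voxel measurement. Eigenvalues are sorted descending; the
largest-eigenvalue eigenvector is the putative sheet normal and the
smallest the putative myocyte axis (`convention = "st"`); each
eigenvector's sign is fixed by making its largest-magnitude component
positive, with ties broken by the first such component.

## Diffusion-tensor reconstruction

The diffusion weighting of a monopolar pulse pair is
$b = \gamma^2\delta^2(\Delta - \delta/3)|g|^2$. The proton gyromagnetic
ratio is commonly quoted as 42 MHz/T; that figure is $\gamma/2\pi$, and
since the relation needs angular units the package uses
$\gamma = 2\pi \cdot 42.58\times10^6\,\mathrm{rad\,s^{-1}T^{-1}}$
(`bValue()` documents this). With the default timing (δ = 3.6 ms,
Δ = 11.5 ms) free water (D ≈ 2.3×10⁻³ mm²/s at 20 °C) moves only
`rmsDisplacement(2.3e-3, 11.5e-3)` ≈ 7 μm RMS — the physical scale a
diffusion measurement actually probes, and a reminder that sheetlet-scale
(≈100 μm) structure is at the edge of what such short mixing times resolve
in fixed tissue.

The tensor fit is log-linear least squares over all diffusion directions
(exact on noiseless monoexponential data; the era-standard reconstruction),
with one b0 per scheme. Built-in schemes: 6 optimized directions (the
dual-gradient set) or 12 (a deterministic hemispheric spiral), both plus a
single b0. Voxels with non-positive signals are flagged missing rather than
fitted; negative eigenvalues after noisy fits are clamped to zero under a
QC flag; isotropic fits (all eigenvalues equal to 10⁻⁶ relative) set an
arbitrary-eigenvector flag. Assignment follows the DTI convention: e₁ ↦
putative myocyte, e₃ ↦ putative sheet normal.

## Direct isosurface normals and concentration filtering

The structural volume is upsampled 4× (50 → 12.5 μm) by separable natural
cubic-spline interpolation ("tricubic"); interpolation matrices are
precomputed per axis, output voxel centres subdivide input voxels, and the
scheme is exact on constant and linear intensity fields. The
lamina/interstice boundary is extracted by marching tetrahedra (six
tetrahedra per cell sharing the main diagonal; crossing edges interpolated
linearly, so vertices lie exactly on the isosurface), with face normals
oriented toward the brighter side. Marching tetrahedra was chosen over
table-based marching cubes because it is unambiguous (no case-table holes)
and vectorizes cleanly; its area convergence is validated against the
analytic area of a sphere (within 2% at 12.5 μm, monotone in the
upsampling factor).

Face normals are axial data — a face's sign is an artefact of mesh
orientation — so the per-box mean normal is the principal eigenvector of
the area-weighted axial scatter matrix Σ wᵢnᵢnᵢᵀ, not an arithmetic
average (which is ill-defined under sign flips). Whether the original
procedure weighted by area is not documented; area weighting is the
measure-theoretically natural choice and is what an unweighted average over
a uniformly refined mesh approximates anyway. The mean resultant length R̄
is computed after aligning each normal's sign with the mean, and the von
Mises–Fisher concentration uses the closed-form estimator
$\hat K = \bar R(3-\bar R^2)/(1-\bar R^2)$ (validated against a
maximum-likelihood oracle on simulated vMF samples). Boxes are 200 μm,
anchored to the coarse acquisition grid (box index = coarse voxel index);
a box is kept when K ≥ 7.0 — the threshold is inclusive, the boundary case
being documented rather than material — and at least `minFaces = 10` faces
contributed (the face-count guard is this package's addition; a K estimate
from a handful of faces is meaningless). Perfectly aligned normals give
R̄ = 1 and K = ∞, which is reported as such and always kept.

## Cardiac frame and angle conventions

The cylindrical frame takes an explicit long-axis point and direction
(apex → base) instead of registering a model geometry — registration
against an atlas is deliberately out of scope, and an explicit axis makes
the measurement definitions exact and testable. Per voxel, the radial
basis vector is the normalized rejection of the voxel offset from the
axis, and circumferential = longitudinal × radial (right-handed; this
fixes the helix-angle sign). Voxels on the axis are flagged undefined.

For an axial unit vector v with components (v·c, v·l, v·r):

| angle | definition | formula |
|---|---|---|
| helix α′ | short-axis plane to projection on wall-tangent plane | atan2(v·l, v·c) |
| myocyte transverse α″ | wall-tangent plane to projection on short-axis plane | atan2(v·r, v·c) |
| sheet elevation β′ | short-axis plane to projection on long-axis plane | atan2(v·l, v·r) |
| sheet transverse β″ | longitudinal–radial plane to projection on short-axis plane | atan2(v·c, v·r) |

All four are folded to (−90°, 90°] (axial vectors), are invariant under
v → −v, and are flagged undefined when the projection is degenerate. The
methods literature contains an internal inconsistency in prose descriptions
of which plane the sheet transverse angle projects onto; the package
implements the explicit per-angle definitions above. These are *apparent*
(projected) sheet angles; the absolute sheet angle β^s is intentionally not
computed. ROIs are cuboids in frame coordinates (angular sector ×
radial span × longitudinal span) with normalized transmural depth (0 at
the endocardial radius, 1 at the epicardial) attached.

## Tissue mask

Tissue is dark in contrast-enhanced imaging, so `thresholdMask()` keeps
voxels at or below 20% (configurable) of the reference intensity, taken as
the 99.5th percentile — a robust maximum, since the natural reference
("maximum intensity") is hostage to hot voxels. The slice-wise 2D
morphology sequence then runs clean (drop isolated foreground), bridge
(connect foreground separated by one background pixel — implemented as:
set a background pixel whose 8-neighbour ring holds ≥2 mutually
non-adjacent foreground groups), fill (background with all 8 neighbours
foreground), open (3×3 erosion+dilation, background outside the image),
thicken (one growth iteration). Thicken adds a background pixel only when
all its foreground neighbours belong to one 8-connected component *and* no
adjacent candidate pixel carries a different component label — the second
clause matters because two simultaneously added pixels could otherwise
bridge two components, violating the rule that thickening never connects
previously unconnected objects (a property the test suite checks by
component counting). Connectivity conventions (8-connected for clean,
fill, and component labelling) are this package's documented choices where
the operation names alone do not pin them down.

## Comparison statistics

Deviation between axial vectors is acos(min(1, |a·b|)) ∈ [0°, 90°].
Quadrant rose histograms bin [0°, 90°] with half-open bins (last bin
closed) so counts always sum to n. Robust summaries report the median, the
*raw* MAD (median |x − median|, no normal-consistency factor — the spread
is reported as a descriptive statistic, not a σ estimate), IQR from
linear-interpolation quantiles (type 7; the convention is unstated in the
field, so it is fixed and documented here), mean and SD. Transmural
profiles use axial circular means (double the angles, average the unit
vectors, halve — period 180°) and the matching circular SD; whether
real-data profiles use circular or linear dispersion is unstated, and the
circular choice is the only one that behaves at the ±90° wrap.
Eigenvalue-ratio distributions (100·λ_small/λ_large per voxel) quantify
sorting confidence for the feature-relevant pair: laminar pair (λ₂, λ₃)
for DTI but (λ₁, λ₂) for ST, myocyte pair (λ₁, λ₂) for DTI and (λ₂, λ₃)
for ST. Voxels flagged undefined anywhere upstream are excluded pairwise.

A useful diagnostic reproduced in the tests: if the two smaller diffusion
eigenvalues swap roles (missorting, common when λ₂ ≈ λ₃ under noise), the
deviation of e₃ from the true normal concentrates *above* 45° — a mode
near 90° on phantoms — rather than spreading uniformly; this signature
separates eigenvector misassignment from mere noise.

## Numerical choices and problem sizes

Eigen-decompositions use the symmetric solver per voxel; ties are left in
solver order and re-orthonormalized by construction. The FFT and direct
convolution paths agree to 10⁻⁸ relative (tested). Degenerate isosurface
triangles (area < 10⁻⁹·spacing²) are dropped. The pipeline expands one
global seed into per-stage seeds by a fixed counter scheme, so a saved
configuration reproduces its outputs exactly.

The shipped demonstration and the test suite run on 32³ slabs and 48²×8
annuli (phantom generation through FI in tens of seconds); these sizes were
chosen so the full suite exercises every path at interactive speed, and all
quoted recovery figures (ST median deviation < 3° at interior voxels, FI
median < 3° on kept boxes, DTI round-trip exact to 10⁻⁹ relative on
noiseless data) are computed at those sizes. Nothing in the implementation
is size-specific; 256×256×512 volumes are simply slower.

## Known limitations

- The boundary-smoothing step applied to real segmented images before
  gradient computation is approximated by mirror padding plus the tissue
  mask; the original feathering procedure is not reproduced in detail.
- No anisotropic voxel support; volumes are assumed isotropic.
- The log-linear DTI fit is unweighted; at very low SNR a weighted or
  nonlinear fit is preferable (one is used as a test oracle, not exposed).
- The annulus phantom's intensity laminae are radial regardless of the
  configured sheet-elevation rule (see above).
- No HARDI or multi-compartment diffusion models; no registration-based
  frame fitting; no interactive threshold selection — thresholds are
  configuration inputs.
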