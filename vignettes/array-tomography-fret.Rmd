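---
title: "Array tomography with sensitized-emission FRET: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Array tomography with sensitized-emission FRET: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(atfret)
```

## The measurement problem

Synaptic terminals are smaller than the diffraction limit, so conventional
colocalization cannot say whether two proteins share a synapse, let alone
whether they touch. Array tomography addresses the axial problem physically:
tissue embedded in resin is cut into 70 nm serial sections, each imaged as
an ordinary 2D fluorescence image, so axial resolution is set by the knife,
not the optics. Sensitized-emission FRET addresses the lateral problem
photophysically: energy transfer from a donor to an acceptor fluorophore
occurs only below roughly 10 nm separation, so acceptor emission under donor
excitation reports molecular-scale proximity. `atfret` implements the
analysis chain that turns a multi-channel serial-section acquisition into
per-sample statistics: alignment, 3D segmentation, colocalization,
plaque-distance profiling, FRET correction and scoring, and group-level
modelling.

Because both the imaging and the biology are hard to share (raw
array-tomography data sets are large and rarely deposited), the package
carries a synthetic generator that emulates the statistical structure the
analysis assumes, with complete ground truth. All quantitative claims in the
test suite are claims about recovery of that known truth.

## The pipeline stage by stage

### Registration

Sections are physically independent, so each lands on the coverslip with
its own small translation, rotation and shear. `estimate_pairwise()` fits
the transform between consecutive sections in two stages:

1. **Rigid seed.** Translation by FFT phase correlation with parabolic
   sub-pixel refinement; rotation by a bounded grid search (default ±3°,
   step 0.75°, parabolic sub-grid refinement) scored by normalized
   cross-correlation.
2. **Affine refinement.** Gauss–Newton minimization of the intensity
   mean-squared error over all six affine parameters, with Cauchy robust
   weights rescaled each iteration from the residual MAD.

The robust weights matter: consecutive 70 nm sections show mostly the same
puncta, but objects genuinely start and end between sections, and those
content differences would otherwise bias a least-squares fit. Downweighting
them cut the per-pair error roughly tenfold in our synthetic benchmarks.
Exactly-zero pixels are excluded from both the fit and the score because a
previous warp fills out-of-frame regions with 0; without this, re-aligning
an already-aligned stack could chase its own border wedges.

`align_stack()` composes the pairwise fits against the **middle** section
(minimizing compounded drift — the choice is ours; the underlying method
family only specifies rigid-then-affine) and applies the same correction to
every channel. Interpolation is bilinear; pixels mapped from outside the
frame are zero-filled and recorded in a validity mask that later excludes
them from density denominators. Registration is driven by the post-synaptic
channel by default (densest, most uniform coverage), configurable.

### Segmentation

The thresholding rule is a local mean threshold: foreground iff
`I > mean_w(I) · (1 + offset)` with an odd window `w` (default 15 px) and a
fractional `offset`. In the originating workflow the offset is chosen
"semi-automatically" once per channel and then frozen for every image of the
study; the package mirrors that by making it an explicit, persisted
parameter. The default (1.0, i.e. twice the local mean) sits ≈ 4.5 noise
standard deviations above the synthetic background, giving a negligible
false-positive pixel rate at default noise. A local-mean rule has one
behaviour worth knowing: a bright object inside the window of a dim one
raises the dim object's threshold, so crowded fields clip faint voxels
first.

In-plane components (8-connectivity, two-pass union-find in C++) are linked
across consecutive sections when they share at least
`linking_min_overlap_px` (default 1) pixels at identical positions; the
transitive closure forms a 3D object. The **persistence filter** then keeps
only objects spanning at least two consecutive sections. This is the
method's central noise-suppression device: antibody speckle and detector
noise rarely reproduce at the same position in two physically distinct
sections, while a real synaptic terminal (≈ 200–500 nm across) must appear
in several 70 nm sections. Density is object count divided by the physical
volume of valid voxels, reported per mm³.

### Colocalization and plaque-distance profiles

`overlap_fraction()` is deliberately asymmetric: the denominator is always
the synaptic object, because the decision rule is "at least 10% of the
synaptic terminal is covered". Overlap is computed on 3D voxel sets, not
per-section areas; for 2–4-section objects the two are nearly identical,
and the 3D form is the natural one once objects are defined in 3D (we flag
this as an interpretation, since the source describes "area").

The plaque is segmented restrictively — high global threshold (3× channel
mean), largest contiguous 3D component, minimum single-section core area
25 µm² — so that small amyloid puncta in the halo do not count as plaque.
Distances from object centroids to the nearest plaque-edge voxel are
Euclidean in physical units with the 70 nm axial spacing (effectively
in-plane at these depths, stated for determinism), binned at 10 µm with
`[50 µm, ∞)` as the far-field reference. Each bin's density uses that bin's
own neuropil volume, computed with an exact anisotropic Euclidean distance
transform; empty bins report `NA` rather than 0. All objects passed in are
binned — centroids inside the core get distance 0 and land in the first bin
— so bin counts always sum to the number of objects profiled; callers who
want core objects excluded filter first.

### FRET correction and scoring

The raw FRET image I_DA (donor excitation, acceptor emission window)
contains true sensitized emission plus two contaminations: donor emission
bleeding into the acceptor window (β) and direct acceptor excitation by the
donor laser (γ). Both are estimated per imaging session from
single-fluorophore control stacks as robust slopes through the origin
(median of per-pixel ratios over pixels at least 5 background-MADs above
the channel median — the floor avoids the regression attenuation that
background pixels would cause). The per-pixel correction is

    Fc = I_DA − β · I_DD − γ · I_AA

with negative values retained. Calibrations are session-scoped: applying a
calibration to images from another session is an error unless explicitly
overridden.

The reported statistic is the percentage of pixels with **any** corrected
FRET signal (`Fc > 0`) among pixels inside all three segmented object masks
(donor ∩ acceptor ∩ synapse, post-persistence-filter objects). The literal
`Fc > 0` rule is the default because it is the rule the measure is defined
by; note that under symmetric zero-mean noise it has an expected
false-positive rate near 50% at true-negative pixels, which is why the
method is interpreted through its positive/negative control window rather
than as an absolute fraction. A `k_sigma` option thresholds at
`k · sd(background Fc)` instead for users who want a noise-referenced rule;
the default `k = 0` reproduces the standard behaviour.

### Statistics layer

* `effect_size()` divides the mean difference by the **positive group's**
  dispersion. This convention is chosen because it reproduces the printed
  worked example of the study design ((38.4 − 1.75)/9.66 ≈ 3.8), whereas
  the usual pooled-sd convention gives ≈ 5.1; the pooled variant is
  available behind `denominator = "pooled"`.
* `power_two_sample()` is the exact noncentral-*t* power with
  ncp = d·√(n₁n₂/(n₁+n₂)). A frozen 2×10⁵-replicate Monte-Carlo oracle in
  the test suite confirms it (0.2354 vs 0.2360 analytic at d = 0.79,
  n = 6). That value also documents a discrepancy we inherit knowingly: the
  design claim that d = 0.79 with n = 6/group yields 80% power is not
  reproducible under any standard two-sample t model.
* `tukey_transform()` searches the ladder (−2, −1, −½, log, ½, 1, 2) for
  the exponent maximizing the Shapiro–Wilk statistic, with a parsimony
  tie-break: identity is kept unless some rung improves W by more than
  0.01, because W differences below that are sampling noise at typical n
  and silently transforming near-normal data helps nobody.
* `fit_group_model()` fits `value ~ diagnosis*sex + (1|case/sample)` via
  `lme4`. One subtlety: the measurement table carries one value per
  (case, sample, measurement), so the sample-within-case variance is not
  separable from the residual; in that situation the identifiable
  equivalent `(1|case)` is fitted and the output notes it. Fixed effects
  are tested with Wald F using containment degrees of freedom (number of
  cases minus number of fixed-effect cells) — with balanced designs this is
  near-exact, and a 500-replicate null simulation in the acceptance suite
  verifies type-I control in [0.03, 0.07] at α = 0.05. Pairwise cell
  contrasts use the studentized-range (Tukey) adjustment.
* `receptor_occupancy()` is the single-site hyperbola
  `100·(c/Ki)/((c/Ki)+1)`; 80% occupancy (c = 4·Ki) is the efficacy
  threshold quoted for Sigma-2 modulators.

## The synthetic world

`sim_config()` states the world the tests live in:

| parameter | default | meaning |
|---|---|---|
| `geometry` | 100 nm/px, 70 nm sections | physical voxel size |
| `frame_size`, `n_sections` | 256², 10 | field of view |
| `n_synapses` | 120 | persistent synaptic puncta |
| `synapse_radius_xy` | 200–400 nm | half-max radius (diffraction-limited) |
| `synapse_span_sections` | 2–4 | consecutive-section extent |
| `synapse_amplitude` | 1500–3000 | peak over background (16-bit scale) |
| `background` | 100 | camera/stain pedestal |
| `frac_donor/acceptor_in_synapse` | 0.5 / 0.4 | marginal label fractions |
| `frac_coloc` | 0.3 | synapses carrying both labels |
| `fret_efficiency` | 0.3 | sensitized emission as fraction of donor |
| `beta_true`, `gamma_true` | 0.2, 0.1 | bleed-through coefficients |
| `noise` | Poisson (scale 0.25) + Gaussian (sd 8) | ≈ 6% shot noise at peak |
| `misalignment` | ≤ 4 px, ≤ 1.5°, ≤ 0.01 shear | per-section affine bounds |
| `single_section_noise_objects` | 25 | persistence-filter negatives |

Puncta are rendered as Gaussian profiles with a sharp axial extent (every
section in the span carries the full in-plane profile), matching how a
sub-diffraction punctum appears in physically cut sections; truth voxels
are the half-max disk. The plaque is a bright disk through all sections
plus single-section halo puncta that the restrictive plaque segmentation
must exclude. Label fractions are realized as **exact rounded counts**, not
Bernoulli draws: the configured fraction is then a property of every stack,
so a recovery test measures the pipeline rather than binomial noise.
Placement is rejection sampling with a minimum separation (avoiding merged
puncta) and a frame margin wide enough that misalignment plus registration
cropping can never delete a truth object; with a plaque present, placement
is weighted by `gradient_slope^bin`, producing the around-plaque density
gradients the profiling stage must recover.

What the generator does **not** emulate: a realistic PSF (no axial blur
across sections, no Airy rings), photobleaching, chromatic aberration or
channel mis-registration, staining heterogeneity, or the amplitude and
spatial statistics of real antibody background. A green test therefore
establishes that the algorithms are implemented correctly and recover known
structure under realistic noise and misalignment — not that any biological
effect size in real tissue will match. Defaults were chosen once for
testability (flagged: they are not fitted to published acquisitions, which
report no quantitative noise or puncta-size statistics).

## Numerical choices

* **TIFF I/O** is a minimal baseline codec (little-endian, uncompressed,
  16-bit grayscale, multi-page) written for this package because no
  TIFF-capable R package is available in the deployment environment; it is
  cross-checked against the reference Python reader (`tifffile`) in the
  test suite. Intensities are stored 16-bit on disk and processed in
  doubles.
* **Connected components** use two-pass union-find labelling;
  **distance maps** use the exact separable (Felzenszwalb–Huttenlocher)
  squared-distance transform with anisotropic spacing, implemented with a
  large finite sentinel instead of infinity to avoid ∞−∞ in the
  lower-envelope recursion. Both are C++ (Rcpp), where the field's image
  packages also keep such kernels.
* **Interpolation** is bilinear everywhere; validity masks track pixels
  mapped from outside the frame. Identity transforms reproduce images
  bit-exactly.
* **Degenerate inputs** fail loudly and early: constant images in
  registration, all-zero controls in calibration, empty synapse sets in
  colocalization, zero valid volume in densities, unreplicated designs in
  the model fit.
* **Seeding**: one integer seed drives a run; the pipeline derives
  per-stage sub-seeds so stages can be re-run in isolation. All generator
  output is bit-reproducible under a fixed seed.

## Known limitations

* Pairwise-chain registration accumulates error linearly in the distance
  from the reference section; for very long ribbons a global (bundle)
  refinement would be preferable.
* The persistence filter cannot distinguish a real single-section object
  (smaller than 70 nm axial) from noise; this is inherent to the rule, not
  the implementation.
* The mixed model's containment-df F test is approximate for unbalanced
  designs; for strongly unbalanced case structures a Satterthwaite or
  Kenward–Roger correction (not available in this environment) would be
  the usual upgrade.
* One plaque per field is assumed (fields are acquired "with a plaque in
  the field"); multi-plaque assignment is out of scope.
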