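---
title: "Quantifying chromosome territories and axial compaction from 3D FISH stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosome territories and axial compaction from 3D FISH stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucfish)
```

# Scope and model

`nucfish` quantifies interphase chromosome organization in large polyploid
nuclei imaged by multi-channel 3D FISH: whether chromosomes occupy compact
territories or extended Rabl-configured polytene fibers, how peripheral
pericentric heterochromatin sits, and how strongly chromosome arms are
axially compacted. The package operates on pre-cropped single-nucleus
stacks (one intensity volume per channel) with user-supplied voxel
dimensions; instance separation of touching nuclei, deconvolution and
proprietary microscope formats are out of scope.

The measurement chain is deliberately simple and fully parameterized so it
can be reproduced exactly:

1. **Thresholding.** A voxel belongs to signal iff its intensity is
   *greater than or equal to* an absolute per-channel threshold. Defaults
   are 25 (DAPI), 35 (Alexa488, Alexa647, GFP) and 55 (Alexa546) on the
   8-bit scale. The inclusive boundary is a documented convention: the
   original plugin-based analyses do not state it, and object counts are
   only reproducible if it is fixed.
2. **Labeling.** 3D connected components under 6-, 18- or 26-connectivity
   (default 26, which merges diagonal speckle; both extremes are covered by
   tests since the historical convention is unrecoverable). The labeler is
   a breadth-first search in C++ and is checked against an independent
   frontier flood-fill oracle on random masks.
3. **Size filter.** Components with fewer than 10 voxels are discarded
   (strictly smaller; a 10-voxel object survives).
4. **Features.** Per object: voxel count, volume, total intensity and the
   intensity-weighted centroid over member voxels (background below
   threshold never contributes). Centroids are in µm under a voxel-center
   convention with axis order (z, y, x); anisotropic calibration is
   mandatory input because the acquisition z-step is not knowable from the
   data.

# Nuclear coordinate system

The nuclear center is the center of DAPI fluorescence intensity. The DAPI
volume is the count of above-threshold, size-surviving DAPI voxels times
the voxel volume; interior gaps (interchromatin space) are *not* filled,
which makes the volume — and hence the sphere-equivalent radius
$R_V = (3V/4\pi)^{1/3}$ — a slight underestimate of the true radius for
nuclei with a pronounced interchromatin compartment. A second estimator
automates the manual procedure of fitting a circle to the nuclear outline:
the z-slice with the largest cross-section is selected and a least-squares
(Kasa) circle is fitted to the boundary pixels of that slice's mask. Here
holes *are* filled slice-wise first, because the manual procedure fits the
outer boundary of the DAPI signal; the rim alone determines the fit. On
synthetic spheres both estimators agree within voxelization error, and
across a batch of radii they correlate with $R^2 \ge 0.87$, the agreement
reported between volume-based and manual estimates on real nuclei.

Radial positions are distances from the nuclear center divided by the
nuclear radius ($R_V$ by default; the slice fit is a cross-check). Values
above 1 are kept and flagged rather than clipped, since centroid and
radius errors can legitimately place a peripheral locus nominally outside
the sphere. Radial positions are computed per probe centroid per nucleus;
group statistics use per-nucleus values as units.

# Territory metrics

A probe's position in a nucleus is the intensity-weighted centroid of its
objects (weights = object total intensities — not volumes, since the
definition is the center of total fluorescence intensity). When a locus is
partially unpaired and yields several spots, this single centroid still
represents the locus; multiplicity is quantified separately by
`spot_count()` (with a divisor of 5 for the five-telomere probe class).
Distances between probe centroids are Euclidean in µm. For assays with two
loci tagged in a single channel (LacO/LacI-GFP bands), the channel's
objects are split into two bands deterministically: the most-distant
object pair seeds the bands and every other object joins the nearer seed.

`weighted_pca()` decomposes the intensity-weighted covariance of object
centroids; the anisotropy ratio (largest/smallest eigenvalue)
distinguishes elongated Rabl fibers from globular territories.
`path_length()` integrates user- or simulator-traced polylines; automatic
skeletonization is out of scope because real traced paths were drawn
manually. `mean_random_sphere_distance()` provides the unlinked-locus
reference: the expected distance between two uniform points in a ball,
$36R/35 \approx 1.029R$, which is why the mean nuclear radius is a good
approximation for the expected separation of unrelated loci.

# Group statistics

Group summaries are mean ± SEM (sample SD, $n-1$ denominator) with the
number of nuclei as $n$. The original analyses never name their test;
this package fixes a two-sided Welch unequal-variance t-test on
per-nucleus values and documents it, with a permutation test on the
difference of means as a configurable alternative for skewed distance
distributions. Stars follow the .05/.01/.001 convention. No
multiple-testing correction is applied, matching per-pair star reporting;
outputs state this so users analysing many pairs can correct afterwards.
Nuclei are treated as independent units; egg-chamber nesting is not
modeled.

# The synthetic-nucleus generator

The simulator emulates the organizational states being measured, not
chromatin physics. A nucleus is a sphere of radius $R$ centered in the
stack. Chromosome backbones are polylines generated three ways:

* **polytene_rabl** — a persistent random walk (default step 0.2 µm,
  persistence 0.8; free simulator knobs, config-exposed) whose first point
  (the centromeric end) is anchored on the nuclear surface at a pole and
  whose steps are biased toward the opposite pole, confined to the
  nucleus.
* **territorial** — the same walk confined to a ball of
  `territory_radius` tangent to the nuclear envelope.
* **pinned** — when a chromosome carries `pin_separation`, the backbone is
  a random smooth bridge (straight chord plus a low-frequency random
  perpendicular displacement field vanishing at the endpoints) whose two
  probe positions are exactly the programmed Euclidean distance apart and
  whose arc length is solved by bisection to the programmed contour
  length. This is what lets a preset *program* a published mean separation
  as ground truth.

Total arc length is `genomic_length × compaction` (compaction in µm/Mb;
free walks hit it within 2%, bridges within 0.1%), and Mb positions map
linearly along arc length. Spot multiplicity follows a per-chromatid
Bernoulli model: one spot always marks the common backbone; each of the
remaining `n_chromatids − 1` chromatids unpairs with probability
`1 − pairing` and contributes a spot displaced by an isotropic Gaussian
offset. Probes tagged heterochromatin/telomere stay fully paired,
mirroring the retained allelic pairing of under-replicated repeats;
copy-number is not modeled.

Rendering: probe channels receive anisotropic Gaussian spots
($\sigma_z$, $\sigma_{xy}$; defaults 0.6/0.25 µm, thicker 0.8/0.5 µm
bands for salivary presets) with peak amplitude at least twice the
channel threshold. The DAPI channel is a filled ball at a nucleoplasmic
fill level *plus* brighter Gaussian chromatin density along the backbones.
The fill is a deliberate design choice: real nurse-cell nuclei show DAPI
throughout the nucleoplasm, and the nuclear-volume estimators are only
testable against a known radius if the rendered DAPI actually delimits the
nucleus; backbone-only DAPI would leave most of a large polytene nucleus
dark. All channels then get a constant background (default 8), additive
Gaussian noise (SD 3), clipping and 8-bit quantization. Background plus
three noise SDs stays below the lowest threshold, so spurious detections
are rare and the 10-voxel filter removes the rest. Every nucleus draws all
its randomness from one recorded seed; the same seed reproduces the stack
bit-for-bit.

What the simulator does **not** emulate: polymer dynamics and excluded
volume, optical aberrations beyond a Gaussian PSF, photobleaching,
chromatic shifts, nuclear shape irregularity, and segmentation-adversarial
speckle. Passing parameter-recovery tests therefore demonstrates that the
measurement chain is unbiased and internally consistent at realistic
signal levels — not that it is robust to every real-microscope artifact.

## Preset scenarios

Six presets program the true probe-pair separation to published
measurements: wild-type nurse cells stage 4 (1.18 µm) and stage 10
(0.80 µm) as compact territorial nuclei; Condensin II mutant stage 4
(2.17 µm) and stage 10 (9.88 µm) as polytene/Rabl nuclei — the stage-10
mutant backbone additionally has its contour length programmed to
12.87 µm, the directly traced curved-path value, so chord and arc are the
published pair of numbers; and salivary glands, control (14.2 µm) and
Cap-H2-overexpressing (6.0 µm), as two GFP band clusters in one shared
channel. Nuclear radii are simulator choices (5 µm at stage 4, 12 µm at
stage 10, 18 µm for salivary glands: box-plot figures for real nuclei
span roughly this range but print no numbers), as are voxel sizes
((0.4, 0.2, 0.2) µm for small nuclei, up to (0.6, 0.35, 0.35) µm for
salivary glands, keeping each stack under ~1 M voxels so a 15-replicate
recovery run takes seconds per preset).

```{r presets, eval = FALSE}
spec <- preset_scenarios("mutant_stage10", seed = 1)
sim <- simulate_nucleus(spec)
sim$truth$pair_distances          # programmed truth: 9.88 µm
path_length(sim$truth$backbones[[1]]$polyline)  # programmed arc: 12.87 µm
```

# Numerical choices and degenerate inputs

* Thresholding is inclusive; filtering is strict (`< min_voxels`
  removed). Both are parameterized and tested at the boundary.
* Labels are assigned in raster-scan order of each component's first
  voxel, making labelings comparable across implementations.
* The Kasa circle fit is linear least squares (no iteration, no
  tie-breaks); a slice with fewer than 3 boundary pixels returns half a
  voxel with a warning rather than failing.
* `compaction_fold()` puts the longer condition in the numerator so folds
  are ≥ 1, recording the direction as an attribute.
* Empty probe sets, missing probes in a requested pair, zero-object
  channels and corrupt input stacks are non-fatal where a batch should
  continue: pairs are skipped with warnings and failing stacks are logged
  and excluded, never silently imputed.
* `radial_fraction` > 1 is flagged, not clipped; `weighted_pca` with
  collinear points reports zero trailing eigenvalues and infinite
  anisotropy rather than erroring.

# Validation design and problem sizes

Every stage is validated by independent oracles: hand-computed weighted
means, a brute-force flood fill for labeling, voxel-count and analytic
ground truth for rasterized balls, the closed form $36R/35$ for the
sphere constant, binomial expectations for spot multiplicity, and
end-to-end parameter recovery on the presets (15 replicate nuclei per
preset, mean recovered separation within 15% of programmed truth — in
practice recovery is within ~1%, the tolerance mainly covers PSF, noise
and quantization). The type-I error of the Welch comparison is checked
under the null at 10,000 simulated comparisons, a size at which the
Monte-Carlo standard error (~0.002) is small against the 0.05 ± 0.01
acceptance band. These problem sizes (16³ labeling oracles, ≤ 1 M voxel
stacks, 10–30 replicates for stochastic properties) were chosen as the
smallest at which each property is statistically decisive.

# Known limitations

* Absolute thresholds presume consistent acquisition gain; there is no
  adaptive thresholding by design, so intensity calibration is the
  user's responsibility.
* Touching spots are not watershed-split; a fused pair counts as one
  object. Spot-count comparisons between conditions with very different
  crowding should be interpreted with this in mind.
* The sphere model of the nucleus biases radial fractions for flattened
  or truncated nuclei, and thresholded DAPI volume underestimates the
  radius when the interchromatin compartment is large.
* Nearest-spot pairing for multi-spot loci is not implemented; locus
  distances always use the probe centroid.
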