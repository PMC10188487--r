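---
title: "Models and methods behind gastruquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gastruquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

During fish gastrulation, lateral precursor cells migrate dorsally toward the
embryo midline to assemble the body axis. Studies of this process, and of the
Yap-dependent mechanoregulatory program that sustains it, rest on a recurring
set of quantifications: migration metrics from nuclei tracking, 2D cell
morphometry (compactness, filopodia, focal-adhesion length), 3D nuclear shape
(flatness, sphericity), neighbor-based cell density, chromatin-peak-to-gene
enrichment, and qPCR fold changes. `gastruquant` implements this whole set as
one tested pipeline, together with synthetic-data generators that produce
every input with known ground truth. The generators matter: raw microscopy for
such experiments is rarely deposited, so the package's correctness argument is
built on simulations whose true answer is known by construction.

# The track model and migration metrics

## Correlated random walk

Cell trajectories are simulated as correlated random walks: at each step of
`dt` minutes the heading turns by a zero-mean Gaussian angle with standard
deviation

$$\sigma(p) = \pi\,(1 - p), \qquad p \in [0, 1],$$

so `p = 0` is an uncorrelated walk and `p = 1` a straight path. This gives a
single interpretable knob that maps directly onto migratory persistence. A
constant drift (um/min) can be superimposed to emulate directed convergence,
and tracks reflect off the arena walls — reflection rather than clipping keeps
the track-length distribution intact near the field edge. Step length is
`speed * dt` with the default frame interval of 4 minutes, matching the
time-lapse acquisition rate the tracking parameters are calibrated for.

The generator does not model excluded volume: two simulated nuclei can pass
arbitrarily close to each other, which real nuclei (diameter several
micrometers) cannot. This matters only where trajectories are rendered into
images: sub-resolution pairs merge into a single blob, exactly as they would
in a real movie of overlapping nuclei. Detection recall is therefore always
quoted over resolvable centroids (nearest simultaneous neighbor at least two
blob diameters away). Track-level noise magnitudes are free parameters of the
generator; they are documented defaults, not claims about medaka embryos.

## Metrics

For a trajectory with positions $r_0 \dots r_n$:

* displacement $D = \lVert r_n - r_0 \rVert$;
* path length $L = \sum_i \lVert r_{i+1} - r_i \rVert$;
* persistence $P = D / L$ (straightness, in $[0,1]$; defined as 0 for a
  degenerate track with $L = 0$);
* mean velocity $v$ = mean over steps of step distance / step duration.

"Persistence" is sometimes described in time-like terms (how long a cell keeps
its direction). The straightness ratio $D/L$ is the standard bounded surrogate
and is what this package computes; it is exactly 1 for straight co-directional
motion and 0 for closed loops, and it is monotone in the simulator's `p`.

Displacement values are binned with the color code used for track overlays:
under 20 um `sub`, 20–50 `blue`, 50–80 `green`, 80–130 `yellow`, above 130
`red`. Bins are closed below and open above, except that 130 belongs to
`yellow` because red is strictly "above 130". The bin boundaries are in
micrometers.

## Detection, linking and filters

Frames are preprocessed the way such tracking movies usually are: maximum
projection
of two z sections, an unsharp mask with Gaussian sigma 15 px and weight 0.60
(`out = (in − w·blur)/(1 − w)`, clipped at zero), then a median filter of
radius 2 px. Nuclei are detected as Laplacian-of-Gaussian blobs at sigma
`7.9 / (2√2)` px (blob diameter 7.9 px at 0.189 um/px). The quality score is
the positive LoG response normalized to `[0, 1]` per frame, so a structureless
region scores 0 and the strongest blob 1; detections require quality above
0.23. A literal min–max normalization of the signed response would put the
zero-response baseline near 0.21 on noisy frames and make the 0.23 threshold
pass noise maxima, so the positive-response convention is used. Sub-pixel
positions come from an independent quadratic fit along each axis, clamped to
half a pixel.

Linking is greedy mutual nearest neighbor between consecutive frames with a
15-um default gate and no gap closing: a cell missing for one frame starts a
new track. This is deliberately the simplest deterministic linker; with the
4-minute frame interval and sub-micrometer per-frame displacements it recovers
over 95% of ground-truth identities in the rendered test movies.

Track filters apply the standard exclusion rules: tracks seen in fewer than
15 frames are dropped, as are tracks starting within the midline band. The
midline half-width has no canonical value; the default is
50 um and configurable. Group comparisons run on embryo-level means (never on
pooled cells): an F test for equal variances at alpha 0.05 gates the choice
between the pooled and the Welch two-sided t test.

# 2D morphometry

## Compactness

Compactness is the isoperimetric ratio $C = 4\pi A / P^2$ — the cell area over
the area of the circle with the same perimeter. The perimeter estimator is a
Crofton-style weighted count of differing neighbor pairs in the orthogonal and
diagonal directions, with weights

$$w_{diag} = \frac{4-\pi}{8-4\sqrt{2}} \approx 0.366,\qquad
  w_{orth} = 1 - 2\,w_{diag} \approx 0.267,$$

chosen so that the continuum limit is exact for both a disk and an
axis-aligned square. Naive pixel-edge counting would overestimate circle
perimeters by roughly $4/\pi$ and push $C$ far below 1 for circles; with this
estimator a rasterized disk of radius 100 px scores $C = 0.996$ and a square
comes out within 1% of $\pi/4$.

## Filopodia

Filopodia are counted by opening subtraction: protrusions are whatever a
morphological opening with a disk of radius 1.1 um removes from the mask, and
the count is the number of 8-connected components of that difference larger
than 0.077 um² (a debris gate). Thin protrusions (width below the 2.2 um disk
diameter) are erased by the opening and counted; wider lobes survive the
opening and are not. The synthetic star-cell fixture draws its spikes as
capsules (semicircular tips) because square-tipped bars would leave small
corner slivers under the opening that no rounded biological protrusion
produces.

## Focal-adhesion length

Adhesion masks are reduced to their medial line by Zhang–Suen thinning with a
sequential unit-width pass (pure Zhang–Suen leaves two-pixel staircases on
lines near 45°). Each skeleton component that is a simple path is measured as
a polyline resampled every 4 px, which removes the staircase bias that makes
chain-code counting overestimate oblique lines by up to 8%; branched
components fall back to counting unique 8-adjacencies (1 per orthogonal step,
√2 per diagonal). Endpoint retraction by about half the structure width is the
main residual bias; on bar patterns of 50 and 200 um total the estimator is
within 5% of truth. Adhesion length is conventionally summed inside a
135 × 135 um² window; the window is optional here and the whole image is
measured when no window is given.

## Intensities and counts

Mean intensity readouts use square ROIs of a requested physical area (default
56 um², i.e. side ≈ 7.48 um) centered on a user point. Nuclei counting
thresholds the nuclear channel (Otsu by default), labels 8-connected
components and keeps areas above 7.1 um²; density is reported per 100 um².
Positive-cell counting thresholds the antibody channel, splits touching
objects with a distance-transform watershed (h-maxima depth 2 px), keeps
regions of 6–200 um² that overlap a nucleus, and reports the positive
fraction. Workflows of this kind often segment such signals manually;
this package accepts masks from any source and ships the automated Otsu
default so the pipeline runs end to end — the automated default cannot claim
equivalence to manual thresholds, and the area gates are applied after
watershed splitting (either order is defensible; splitting first avoids
counting fused debris as one large object).

Embryo size is summarized as the area of the best-adjusted circle, via the
algebraic (Kasa) least-squares fit of $x^2+y^2 = 2ax+2by+c$.

# 3D nuclear shape

Stacks at the confocal calibration 0.132 × 0.132 × 0.24 um are smoothed with
a separable Gaussian of sigma 2 voxels per axis (replicate boundaries, so a
constant field and the mean intensity are preserved). Segmentation is a
deterministic replacement for an interactive-watershed step: global Otsu
threshold, 3-4-5 chamfer distance transform, h-dome extraction of the distance
map (h = 2 voxel units) as seeds, and marker-based watershed flooding from
high to low distance.

For each labeled region, semi-axes come from the eigenvalues of the
voxel-coordinate covariance matrix in physical units via the solid-ellipsoid
moment identity $s_i = \sqrt{5\lambda_i}$, sorted $a \ge b \ge c$. Flatness is
$F = b/c$ — the ratio of the second to the third axis, 1 for a sphere and
larger for flatter nuclei, so a rounder mutant nucleus means $F$ closer to 1.
Volume is voxel count times voxel volume. Surface area is the coarea integral
of the Gaussian-smoothed indicator function (sum of gradient magnitudes times
voxel volume, gradients taken with the physical spacings), and sphericity is
$\Psi = 36\pi V^2 / S^3$, which is 1 for a sphere; the formula is stated
explicitly because several sphericity conventions exist.

Because the smoothing that precedes segmentation is isotropic in voxels, it is
anisotropic in physical space and inflates the thin z axis of a segmented
region more than the lateral axes (roughly 10% error in $F$). Descriptors are
therefore refined against the raw stack when it is available: each region is
restricted to voxels above the raw-stack Otsu threshold before moments are
computed, which brings flatness recovery within 2% across aspect ratios 1–3
at the stated anisotropy, with rotation invariance within 2%.

Nuclei with volumes outside 100–350 are excluded, both bounds inclusive. The
volume unit of that gate is taken as voxels — the unit 3D segmentation
tools typically report — and a
`unit = "um3"` flag applies the gate in cubic micrometers instead.

# Neighbor-based density

The density statistic for each nucleus is the mean Euclidean distance to its
five nearest neighbors, computed exactly (the fields are small; no approximate
index). Before the statistic, centroids closer than 8 px are removed —
symmetrically, both members of each violating pair, since such a pair usually
reflects one oversegmented nucleus and keeping either member would be an
arbitrary choice; a near-border exclusion (default margin 8 px, configurable)
removes points whose neighborhood is censored by the field edge.

For a homogeneous Poisson process of intensity $\lambda$, the j-th neighbor
distance has expectation $\Gamma(j+\tfrac12)/\Gamma(j)\,/\sqrt{\pi\lambda}$,
so the mean 5-NN distance is

$$\mathbb{E}[\bar d_5] = \frac{1}{\sqrt{\pi\lambda}}\cdot\frac{1}{5}
  \sum_{j=1}^{5}\frac{\Gamma(j+\tfrac12)}{\Gamma(j)},$$

the closed form used as the oracle in the tests (exported as
`expected_knn_distance_poisson()`). The two-region generator plants Poisson
fields of different intensity in the marker-positive ("active") and negative
region; distances scale as $1/\sqrt{\lambda}$, so a 4:1 intensity contrast
yields a 2:1 distance ratio. Region comparisons aggregate to one mean per
embryo and region and then run the two-sided t test on embryo means — the
embryo, not the nucleus, is the statistical unit. The default demo field uses
0.01 points/um² in the active region versus 0.04 outside it, emulating the
observation that the marker-positive territory is the sparser one.

# Peak-to-gene enrichment

Chromatin peak lists are concatenated (a multiset union — duplicates are kept,
matching how the two profiles were combined), each peak is assigned to its
closest gene (distance 0 on overlap, otherwise the gap between nearest ends;
ties broken deterministically by the smaller gene start), and the
differential-expression table is filtered at padj < 0.05 and |log2FC| ≥ 1,
optionally to the downregulated side. Enrichment of peak-associated genes
among DEGs is tested with a pooled two-proportion Z:

$$z = \frac{\hat p_1 - \hat p_2}
  {\sqrt{\hat p(1-\hat p)\left(\tfrac1{n_1}+\tfrac1{n_2}\right)}},$$

where $\hat p_1$ is the DEG fraction that is peak-associated and $\hat p_2$
the corresponding control fraction. The choice of control set is genuinely
open; the default here is the whole expressed-gene universe
(genes surviving the low-count filter, supplied as input), with a `non_deg`
flag to use the non-DEG remainder instead. Distance is measured to the gene
body, the default semantics of interval-closest tools; genes whose
identifiers changed between annotation versions can simply be left out of the
supplied universe. The synthetic genome fixture places genes on a 10-kb grid
with one peak 600 bp upstream of each target gene, so closest-gene assignment
is unambiguous and the expected DEG-target overlap is exact by construction —
which is what makes the Z test's power and type-I calibration checkable.

# Shared statistics and qPCR

The F variance test puts the larger sample variance in the numerator and
doubles the upper tail. The t test on means is gated by that F test at alpha
0.05 (pooled when equality is not rejected, Welch otherwise); the gate level
is configurable, and the choice of an F test (rather than Levene) reflects
the briefest reading of "a variance test" — both sides of the gate are
exercised in tests against closed-form oracles. The two-proportion Z uses the
pooled variance by default (unpooled by flag) and returns z = 0 with a
warning on degenerate pooled proportions.

Relative expression follows delta-delta-Ct with amplification efficiency
exactly 2 (no amplification-efficiency correction is applied):
per replicate, dCt = Ct_target − Ct_reference (reference gene `ef1a`);
ddCt subtracts the mean control-group dCt per gene; fold change is
$2^{-\Delta\Delta Ct}$, reported per replicate with mean and SD.

# Determinism, problem sizes and limitations

Every generator is a pure function of its parameters and seed (RNG state is
restored afterwards), and `run_pipeline()` derives stage seeds from the config
seed, so rerunning a configuration reproduces every CSV byte for byte. The
test suite and the acceptance script size their simulations to run on a
single CPU in minutes: 10,000 tracks for the metric identities, 100 replicate
contrasts of 3 pseudo-embryos × 200 tracks, one 256 × 256 px × 40-frame
rendered movie, 50 star-cell fixtures, four ellipsoid aspect ratios with one
rotated replicate, 2,000 null simulations per statistical test, and 200
genome fixtures per enrichment condition.

What passing these tests shows — and what it does not: the synthetic data
exercise the estimators under known ground truth with realistic calibrations,
SNR and densities, but they do not reproduce uneven illumination, z drift,
segmentation bias from manual thresholds, nuclear texture, or spatial
correlation between neighboring cells. Results on real embryos inherit the
usual caveats of automated segmentation, and the automated Otsu defaults
stand in for manual segmentation steps without claiming
equivalence. The interfaces of this package are its R functions; analyses are
driven from R scripts or `run_pipeline()` configurations rather than a shell
tool, which is the natural mode for an R analysis package.
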