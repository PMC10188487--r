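# gastruquant

Quantitative analysis of directed cell migration and cellular mechanics in
fish gastrulation imaging, as one tested R pipeline.

During gastrulation, lateral precursor cells migrate dorsally toward the
embryo midline to assemble the body axis; mechanotransducers such as Yap
sustain that migration by keeping cells spread, adherent and under tension.
Studies of this process quantify a recurring set of readouts, and
`gastruquant` implements all of them:

* **Migration metrics from nuclei tracking** — LoG blob detection (diameter
  7.9 px, quality threshold 0.23 at 0.189 um/px, 4-min frames),
  mutual-nearest-neighbor linking, and per-track displacement
  `D = ||r_n − r_0||`, path length `L = Σ||Δr||`, persistence `P = D/L`, and
  mean velocity, with the 15-frame and midline exclusion rules and the
  blue/green/yellow/red displacement bins.
* **2D morphometry** — compactness `C = 4πA/Per²` with a Crofton-style
  perimeter estimator; filopodia counted as components of
  `mask AND NOT opening(mask, disk r = 1.1 um)` larger than 0.077 um²;
  focal-adhesion length by topological thinning and skeleton measurement;
  square-ROI mean intensities (56 um²); nuclei counts with the 7.1 um²
  debris gate; watershed-split positive-cell counts with the 6–200 um² gate;
  best-fit circle area for embryo size.
* **3D nuclear shape** — Gaussian blur (sigma 2 voxels), Otsu + chamfer
  distance + h-dome-seeded watershed segmentation, ellipsoid semi-axes from
  covariance moments (`s_i = √(5λ_i)`), flatness `F = b/c`, sphericity
  `Ψ = 36πV²/S³`, and the 100–350 voxel volume gate.
* **Neighbor density** — mean distance to the 5 nearest nuclei after 8-px
  deduplication and border exclusion, compared between marker-positive and
  negative regions on embryo means.
* **Peak-to-gene enrichment** — closest-gene assignment of chromatin peaks,
  DEG filtering (padj < 0.05, |log2FC| ≥ 1), and a pooled two-proportion
  Z test of DEG-versus-universe target fractions.
* **Shared statistics** — variance-test-gated pooled/Welch t tests on embryo
  means, the F variance test, the two-proportion Z, and qPCR delta-delta-Ct
  fold changes normalized to `ef1a`.

A synthetic-data module generates every input with known ground truth —
correlated-random-walk trajectories rendered as Gaussian-spot time-lapse
stacks, star-shaped cell masks, voxelized ellipsoid nuclei at the
0.132 × 0.132 × 0.24 um calibration, two-density Poisson centroid fields,
line-segment adhesion patterns, and a genome fixture with a controllable
enrichment factor — so the whole pipeline is testable without external data.

## Worked example

```r
library(gastruquant)

# simulate highly persistent cells, compute and filter migration metrics
tr <- simulate_persistent_tracks(n_tracks = 200, n_steps = 60,
                                 speed_um_min = 0.6, persistence_p = 0.9,
                                 seed = 42)
mt <- filter_tracks(track_metrics(tr))
summary(mt$persistence)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> 0.05333 0.35548 0.58682 0.55225 0.75249 0.95943
table(mt$displacement_bin)
#>   blue  green    red    sub yellow
#>     38     41      5     10    106

# a star-shaped cell with 7 planted protrusions
cm <- make_star_cell(n_spikes = 7, seed = 1)
compactness(cm)       # 0.371  (1 would be a perfect disk)
count_filopodia(cm)   # 7      (opening subtraction recovers the truth)
```

At persistence 0.9 most filtered tracks fall in the yellow (80–130 um)
displacement bin and the mean straightness is ~0.55 over 60 steps; the
filopodia counter recovers the planted protrusion count exactly.

The demo pipeline runs the three headline analyses (migration contrast,
morphometry contrast, density + enrichment, plus qPCR) on synthetic data and
writes CSV artifacts and a JSON summary:

```r
rep <- run_pipeline(default_config(out_dir = "demo_run", seed = 1))
str(rep$tracks)
#> persistence wt 0.406 vs mutant-like 0.094, Welch t = 12.6, p = 0.0056
str(rep$enrichment)
#> deg_fraction 0.3 vs control_fraction 0.1, z = 6.88, p = 5.9e-12
```

The simulated wild-type-like group (persistence 0.9) separates clearly from
the low-persistence group (0.4) on embryo means; the enrichment stage, built
with a 3x enrichment factor over a 10% background target fraction, recovers
exactly the constructed 30% vs 10% overlap.

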