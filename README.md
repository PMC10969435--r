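# nldrmri

Contrast-free identification of active multiple-sclerosis (MS) lesions from
multiparametric brain MRI by nonlinear dimensionality reduction (NLDR).

Active (enhancing) MS lesions are normally identified by injecting a
gadolinium-based contrast agent and looking for enhancement on post-contrast
T1-weighted images. Gadolinium retention and cost motivate contrast-free
alternatives. This package implements an unsupervised pipeline for that
problem: the four non-contrast channels of a co-registered multiparametric
exam — proton density (PD), T2-weighted (T2W), FLAIR, and pre-contrast
T1-weighted — are treated as a point cloud in R^4 (one point per voxel),
embedded into a single scalar image with isometric feature mapping (Isomap)
or locally linear embedding (LLE), and thresholded into a binary
active-lesion mask. The mask is scored with the Dice similarity coefficient
against a ground truth defined by the post-minus-pre contrast subtraction
image ("subimage"), which is the clinical definition of activity.

The package is aimed at quantitative-imaging researchers who want a
transparent, dependency-light reference implementation of this pipeline with
every numerical ingredient built from first principles and testable without
any clinical data.

## What is inside

**Manifold learning core** (from scratch, each piece exposed and tested):

* classical (Torgerson) MDS: eigendecomposition of the double-centered
  squared-distance matrix `B = -1/2 J D^2 J`;
* Isomap: k-nearest-neighbour graph → graph-geodesic distances → classical
  MDS on the geodesic matrix, minimizing
  `sum_ij (d_geo(x_i, x_j) - ||y_i - y_j||)^2` over configurations `Y`;
* two interchangeable all-pairs shortest-path backends — Floyd–Warshall
  (`d_ij^(k) = min(d_ij^(k-1), d_ik^(k-1) + d_kj^(k-1))`) and repeated
  binary-heap Dijkstra — with a run-time auto-selection policy and an
  elementwise cross-check between them;
* LLE: constrained reconstruction weights minimizing
  `eps(W) = sum_i ||x_i - sum_j w_ij x_ij||^2` subject to `sum_j w_ij = 1`,
  then the bottom non-constant eigenvectors of `(I - W)'(I - W)`.

**Imaging layer**: channel stacking and z-score normalization, a
joint-intensity codebook that makes exact geodesics tractable on a 256^2
slice, mapping embeddings back onto the grid with FLAIR-anchored polarity,
contrast-subtraction ground truth, Otsu / hierarchical-Otsu / percentile /
absolute thresholding, and block-mean resolution reduction.

**Evaluation**: Dice similarity `DS = 2|A∩B| / (|A| + |B|)` =
`2TP / (2TP + FN + FP)`, neighbourhood-size (K) and resolution sensitivity
sweeps, cohort summaries (median ± sd), tidy tibble outputs with
`tidy()`/`glance()`/`autoplot()` methods.

**Synthetic data**: a Swiss-roll benchmark with closed-form intrinsic
coordinates, and a calibrated multiparametric brain-phantom generator
(tissue geometry, WM lesions, an active subset whose signature on the
non-contrast channels is jointly but not marginally separable, structured
channel noise, optional Rician noise and bias field), plus jittered
synthetic cohorts. NIfTI + YAML round-trip and a thin command-line wrapper
(`inst/cli/nldrmri`) are included.

## Worked example

```r
library(nldrmri)

# Swiss-roll benchmark: Isomap unfolds, plain MDS does not
sr <- make_swiss_roll(1000, seed = 1)
intrinsic_distance_correlation(isomap(sr$points, k = 12, d = 2), sr)
#> [1] 0.9998
intrinsic_distance_correlation(
  classical_mds(as.matrix(dist(sr$points)), d = 2), sr)
#> [1] 0.3795

# Synthetic multiparametric phantom, noise-free limit: exact recovery
p0 <- make_phantom(phantom_spec(noise_scale = 0))
evaluate_volume(p0, method = "isomap", k = 100)$dice
#> [1] 1

# Default noisy phantom at 256^2, K = 100
p <- make_phantom(phantom_spec(seed = 1))
evaluate_volume(p, method = "isomap")
#> # A tibble: 1 × 9
#>   subject method     k resolution  dice    tp    fp    fn threshold
#>   <chr>   <chr>  <dbl>      <int> <dbl> <int> <int> <int>     <dbl>
#> 1 <NA>    isomap   100        256 0.641   339   214   166      7.55
```

The first two numbers say that Isomap's 2-D embedding preserves the roll's
intrinsic (unrolled) pairwise distances almost perfectly while linear MDS
does not — the classic justification for using NLDR on data that live on a
curved manifold. The phantom rows report the Dice overlap between the
thresholded embedded image and the subtraction-image ground truth: 1.0 in
the noise-free limit, and ~0.64 at the phantom's calibrated noise level,
where the activity signature is deliberately weak on every single channel
(best single-channel balanced accuracy ≤ 0.75) and only jointly separable.

A resolution sweep reproduces the degradation with coarser acquisition
matrices, and a K sweep shows the embeddings are insensitive to the
neighbourhood size once K ≥ 100:

```r
resolution_sensitivity_sweep(p, "isomap", c(256, 128, 64), k = 100)$dice
#> [1] 0.641 0.580 0.456
k_sensitivity_sweep(p, "lle", c(5, 100, 200, 300))$dice
#> [1] 0.000 0.665 0.601 0.627
```

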