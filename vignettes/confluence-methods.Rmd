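---
title: "Modelling the iso-to-allocortical confluence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the iso-to-allocortical confluence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

The mesiotemporal lobe harbours a continuous transition from six-layered
isocortex (parahippocampal, entorhinal, fusiform cortex) to three-layered
allocortex (subiculum, CA1-CA4), folded so that conventional isocortical
surface reconstructions skip over the hippocampus. `confluence` models this
transition explicitly: it stitches an isocortical surface pair to a
hippocampal surface pair at the subicular *bridgehead*, maps a signed
geodesic iso-to-allocortical axis over the joint mesh, and carries that axis
through depth-wise histology profiling, gradient decomposition, supervised
prediction, directed-connectivity estimation and macroscale functional
correspondence. Every stage can be run against synthetic data with known
ground truth; this vignette records the modelling choices, their defaults,
and what the synthetic world does and does not establish.

## The surface model

Two matched surface pairs enter: isocortical pial/white and allocortical
(hippocampal) inner/outer, the inner surface being continuous with the pial
sheet at the hippocampal fissure. The construction is:

1. **Bridgeheads** — per anterior-posterior row, the allocortical vertex
   with the minimum proximal-distal coordinate (the medial subiculum edge);
   `find_bridgeheads()`.
2. **Matching** — each bridgehead is matched to the nearest isocortical
   vertex with a strictly lower z coordinate. Only inferior candidates are
   admissible, which discounts the section of the isocortical sheet that
   passes above the hippocampus. Ties break to the lowest vertex index
   (determinism); `match_bridgeheads_to_isocortex()`.
3. **Stitching** — bridge triangles `{b_i, match(b_i), b_(i-1)}` and
   `{b_i, match(b_i), b_(i+1)}` join the sheets (terminal bridgeheads get a
   single triangle); isocortical vertices whose Euclidean-nearest bridgehead
   lies inferior to them are removed. Vertices are never moved, and the
   white/outer pair is linked by the identical triangle list;
   `stitch_confluence()`.
4. **Axis** — multi-source Dijkstra distance from the bridgehead set over
   the inner surface, negative on the isocortical side; `compute_axis()`.
   The anterior-posterior axis is simply the y coordinate.

*Seam manifoldness.* The bridging rule generically places three triangles
on a seam edge whenever neighbouring bridgeheads have distinct matches, so
a strict edge-manifold requirement would reject the canonical construction
itself. `stitch_confluence()` therefore warns (listing offending edges) by
default and offers `on_nonmanifold = "error"` for strict use. Nothing
downstream requires manifoldness; the geodesic graph tolerates the double
cover.

*Geodesics.* Distances are shortest paths over mesh edges augmented with
opposite-vertex connections across each interior edge. On a planar strip
with sources along one edge this is exact; on curved or jittered meshes the
graph metric overestimates slightly, and the error is non-increasing under
1-to-4 subdivision (`subdivide_mesh()`), which the tests verify.

## Equivolumetric depth profiling

Sixteen depth surfaces (14 intermediate) are placed per vertex between the
inner and outer sheets so that successive surfaces bound equal local tissue
volume. The local cortical wedge is modelled with cross-sectional area
varying quadratically across depth — linear in the square root of area
between the one-ring vertex areas `A_in` and `A_out` — giving

$$\rho(\alpha) = \frac{(\alpha A_{out}^{3/2} + (1-\alpha) A_{in}^{3/2})^{1/3}
  - A_{in}^{1/2}}{A_{out}^{1/2} - A_{in}^{1/2}},$$

which reduces to $\rho = \alpha$ for flat cortex and is exact on spherical
shells (the test anchor: the half-volume surface of a 1:2 shell sits at
$(4.5)^{1/3} \approx 1.651$). A simpler variant with area *linear* in depth
misses that anchor by 0.8% and is not used. Zero-area vertices fall back to
equidistant spacing with a warning.

Profiles are trilinear samples of the staining-intensity volume at the 16
depth points (`sample_profiles()`), darker = denser tissue, and are
summarised per vertex by population (biased) central moments: mean, SD,
skewness, kurtosis (`central_moments()`). The biased convention is recorded
in the output metadata; with a fixed 16-sample depth grid the choice only
rescales features uniformly. Moments are taken over the intensity *values*
across depths — a depth-symmetric mid-peak profile therefore has non-zero
skewness, and the shift from peaked to flat profiles is exactly what the
skewness feature indexes. Depth surfaces are named by their nominal
percentage depth (surface 3 of 16 is the ~13% surface, surface 9 the ~53%
surface) so feature names match the field's convention.

## Cytoarchitectural gradient

Microstructure profile covariance (MPC) is the pairwise partial correlation
of depth profiles controlling for the dataset-average profile, Fisher
r-to-z transformed, negatives zeroed (`mpc_matrix()`; a plain-covariance
mode exists behind a flag). Diffusion map embedding
(`diffusion_embedding()`) row-sparsifies the affinity (top 10% per row by
default, re-symmetrised by averaging), applies anisotropic normalisation
with `alpha = 0.5`, drops the trivial constant eigenvector and reports
eigenvalue-fraction variance explained. Eigenvector signs are aligned to
correlate non-negatively with the geometric axis when a reference is given,
and the flip is recorded.

The gradient-axis relation is summarised by polynomial fits of degree 1-5
with selection at the elbow of the adjusted-R² sequence. "Elbow" is
operationalised as the degree whose gain over its predecessor most exceeds
the gain of its successor (discrete second difference with zero-padded
boundary gains), ties to the lowest degree. On a sequence rising
0.58/0.59/0.65 and then flattening this selects the cubic; on a flat
sequence it selects the line. Consistency along the anterior-posterior axis
is assessed by cubic fits within 1 mm coronal slices (`per_slice_fits()`),
slices with fewer than degree + 2 vertices being skipped with a warning.

## Supervised axis prediction

Twenty features (16 depth intensities + 4 moments) are z-standardised on
the full table — the protocol standardises before splitting, a (minor,
documented) leakage that is kept for fidelity — and fed to a random-forest
regression of axis position. No random-forest package is available in the
supported environment, so the package carries a compact CART-forest in C++
(bootstrap bagging, per-node feature subsampling, variance-reduction
splits, impurity importance normalised to sum 1). Hyperparameters are
grid-searched by 5-fold CV (`default_rf_grid()`: mtry near p/3, sqrt(p) and
p/2; leaf sizes 3 and 10; 100 trees) on the first split's training set and
then reused across the repeated 70/30 splits; re-searching every split is
not stated by the protocol and would dominate the compute budget. Features
with above-uniform-average importance (> 1/20) are retained and the model
refit with the same hyperparameters (`select_and_refit()`), reporting a
mean-pairwise-Jaccard selection-stability score. Post-hoc cubic fits per
selected feature summarise the shape and monotonicity of each feature along
the axis (`feature_axis_curves()`).

## Directed connectivity along the axis

The standardised axis volume is divided into 4-14 equal-width bins
(equal-count by flag; `make_bin_atlas()`), the finest count keeping a
minimum voxel fill in every subject mask being selected by
`choose_n_bins()`. Bin-mean BOLD timeseries feed a deliberately transparent
effective-connectivity estimator (`estimate_ec()`): a discrete first-order
transition matrix by least squares (optional ridge), mapped to a
continuous-time coupling via the principal matrix logarithm over the
sampling interval. This inverts exactly the class of stable linear
stochastic (Ornstein-Uhlenbeck) models the synthetic generator simulates,
so estimator quality is testable by parameter recovery; a spectral-DCM
style tool can be substituted through the same interface. When the fitted
transition matrix has real negative eigenvalues (temporally unstructured
data), the principal logarithm does not exist and the estimator falls back
to the first-order inversion `(A_d - I)/dt` with a warning.

Edges are labelled by deviation from the axis (`|i - j| - 1`; 0-6 in the
8-bin model) and direction (towards isocortex vs towards allocortex), and
coupling strength is correlated with deviation per direction
(`deviation_analysis()`). The directional contrast uses the
dependent-correlation z-test, pairing each edge with its transpose (the two
directions share deviation labels); with fewer than 10 edges per direction
the z is reported as NA. Anterior-posterior interaction is probed by
repeating the model within voxel-count terciles of the y coordinate with
bin edges held fixed at the full-model edges (`ap_thirds_analysis()`), and
by the within- versus between-bin voxel correlation contrast
(`functional_homogeneity()`).

## Macroscale correspondence

Voxel-to-parcel connectivity is correlated, across MTL voxels, with voxel
axis position to give a parcel-wise r map (`axis_fc_map()`; positive =
stronger connectivity towards the allocortical end). Parcel connectomes are
transformed to normalised-angle affinities `1 - acos(r)/pi` and embedded
(`functional_gradients()`). Correspondence between r maps and gradients is
Spearman correlation with significance from spin permutations — uniform
random 3D rotations of the parcel centroids with nearest-centroid
reassignment, two-sided by default, `p = (1 + #{|rho_null| >= |rho_obs|}) /
(n_spins + 1)` — and specificity from the dependent-correlation z on
rank-transformed variables (the two gradients share the common map).
Signal-quality controls recompute the map with voxelwise spatial SNR
(temporal mean over the across-voxel SD of temporal means) and temporal SNR
(temporal mean over own temporal SD) partialled out, and the
temporal-lobe-exclusion analysis recomputes the correspondence on unflagged
parcels.

*Sparsity defaults.* The histology embedding keeps the standard 90%
row-sparsity. For the macroscale connectome the level is an open parameter;
the default is 75% because on low-rank synthetic connectomes the sparser
graph rotates recovered gradients within the latent subspace (matched
Spearman down to ~0.5), whereas 75% preserves them while still localising
the graph. Both are configurable and logged.

## The synthetic world

`make_toy_confluence()` extrudes an analytic cross-section along the
anterior-posterior direction: a straight isocortical segment meeting an
Archimedean-spiral allocortical sheet (default 4.5 rad of in-rolling, 1.5 mm
thickness, ~38 mm of total arc), so the ground-truth axis is exact arc
length and part of the isocortical sheet lies geometrically above the
allocortex. Curls below half a turn are rejected — without infolding the
bridging construction is untestable. The seam gap (~2.6 mm) is wider than
anatomical reality so that the two tissue slabs never overlap in the
rasterised volume; at histological gap widths the slabs interpenetrate and
depth assignment at the seam becomes ambiguous for any generator.

Depth profiles follow a smooth super-Gaussian bump family
`baseline * (1 + exp(-|(w(d)-0.5)/sigma|^6))` whose width maps monotonically
onto the 16-sample profile skewness (attainable range about -1.6 to +2.2);
a monotone spline inversion turns programmed skewness targets (default: -1
at the isocortical end to +1 at the allocortical end, slope 2 per unit
axis) into widths. The family is C¹ with bounded slope, so trilinear
rasterisation and resampling preserve the programmed skewness to within 0.1
at the default 0.12 mm voxels (at 0.15 mm a few percent of vertices drift
just past 0.1). Noise defaults to 10% of the profile amplitude in recovery
experiments.

Timeseries ground truth is an Ornstein-Uhlenbeck system integrated by
Euler-Maruyama; its stationary covariance is checked against the
continuous Lyapunov solution (to O(dt)) and the exact discrete solution. A
discrete autoregressive generator is provided for cross-checks. The chain
coupling used in the axis analyses decays geometrically with bin deviation,
so deviation-coupling correlations are negative in both directions by
construction.

The parcel-world generator (`make_gradient_parcel_data()`) programs
low-rank connectivity gradients over smooth spherical patterns (anchored
mixtures of first- and second-degree harmonics: distinct enough to be
recovered in order, mixed enough that spin-rotation nulls are
non-degenerate — pure harmonics of different degree stay orthogonal under
every rotation, which collapses the null) plus 40 weak smooth background
factors, since genuinely rank-3 connectomes let sampling noise masquerade
as programmed structure. Latent factors are made exactly sample-orthonormal
and voxel noise exactly mean-zero, factor-orthogonal and variance-equalised:
without these exactness constructions, finite-sample covariances and
voxel-SD fluctuations imprint the latent patterns onto null connectivity
maps at Spearman magnitudes up to ~0.5, defeating any zero-interaction
control. Voxel offsets and amplitudes vary independently of the axes so SNR
analyses have non-degenerate, non-collinear covariates.

**What a green test establishes — and what it does not.** The synthetic
world has exact vertex correspondence, no registration error, no
hemodynamics (no HRF convolution), no staining artefacts or tears,
stationary Gaussian dynamics, and exactly orthogonal axes. Green tests
establish that the implementations invert their own generative models at
realistic noise levels and that the statistical machinery is calibrated;
they do not establish robustness to registration error, non-stationarity,
or histological artefact, and no synthetic result reproduces the source
study's empirical effect sizes.

## Numerical and policy choices

- Ties everywhere resolve to the lowest vertex index or lowest degree.
- One hemisphere per run; hemisphere is a configuration flag, not inferred.
- MPC clamps correlations to ±(1 - 1e-7) before the Fisher transform;
  identical profiles therefore attain a large finite affinity.
- The dependent-correlation z returns 0 exactly at equal correlations, and
  errors when the two competing variables coincide (`r_ab = 1`) with
  unequal correlations.
- Spin tests reuse a precomputed assignment matrix where many maps share
  one centroid set; calibration was verified at α = 0.05 and 0.01 against
  kernel-smoothed random fields (bandwidth 0.3 on chordal distance).
- Binning outside 4-14 requires `force = TRUE`; empty bins are errors, not
  silently merged.
- File formats: GIFTI (ASCII encoding), NIfTI-1 (float32, sform affine),
  ASCII PLY and TSV are read/written by compact built-in routines because
  no neuroimaging I/O package is available in the supported environment.

## Known limitations

- Graph geodesics overestimate true polyhedral geodesics off-lattice; an
  exact polyhedral algorithm would be a drop-in upgrade for `compute_axis()`.
- The effective-connectivity estimator is a linear-Gaussian stand-in for
  hemodynamically-informed spectral estimators; its group model is a plain
  mean over subjects.
- The random forest is compact rather than tuned for large p; at the 20
  features of this pipeline it is exact enough, but it is not a
  general-purpose learner.
- Recovered gradient order can swap between close latent variances on
  unlucky seeds; analyses should match gradients to references by
  correlation, as the package's own tests do.
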