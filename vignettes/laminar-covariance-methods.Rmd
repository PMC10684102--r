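---
title: "Methods: laminar thickness covariance, gradients and spatial nulls"
author: "ltcov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar thickness covariance, gradients and spatial nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `ltcov`, the design
choices that were genuinely open, the synthetic study conditions under
which the package validates itself, and the limits of what those
validations show. The companion README gives the quick tour; here we give
the reasoning.

## 1. The covariance model

The unit of analysis is the 6-layer relative thickness profile: absolute
layer thicknesses (mm) divided by total cortical thickness, a composition
vector summing to 1. The pipeline applies, in this fixed order:

1. **Exclusion** of agranular/dysgranular parcels. A 6-layer model is not
   meaningful where layer IV is absent or indistinct, so these parcels are
   masked before anything else; their vertices are also excluded from all
   smoothing disks.
2. **Disk smoothing** of the *absolute* thickness maps: each vertex becomes
   the uniform average of the valid vertices within 10 mm Euclidean
   distance on the inflated surface. Folding compresses layers on the
   concave side and stretches them on the convex side; the 10 mm disk
   averages over a fold's cross-section and so cancels most of this local
   mechanical signal while preserving areal trends. Smoothing precedes
   normalization deliberately — the two operations do not commute, and
   averaging compositions instead of thicknesses would weight thin and
   thick cortex equally. `runPipeline()` hard-codes this order.
3. **Normalization** to relative thickness, then **median parcellation**.
   The median is robust to the skewed within-parcel distributions that
   survive masking at parcel borders.
4. **LTC**: for parcels i, j with profiles x_i, x_j and covariate z,
   `LTC_ij = arctanh((r_ij − r_iz r_jz) / sqrt((1 − r_iz²)(1 − r_jz²)))`.
   Controlling for z (the average profile) makes the matrix encode
   *greater-than-average* covariance: two parcels are similar only to the
   extent that they deviate from the cortex-wide composition in the same
   direction.

**The covariate.** "Average profile" could mean the vertex-level or the
parcel-level mean. We use the unweighted mean over the included *parcels*
(computed after parcellation), so that the covariate lives on the same
scale as the correlated objects and is invariant to parcel size. This is a
choice, exposed through the `covariate` argument of `buildLTC()`.

**The diagonal and saturation.** `arctanh` diverges at r = 1, so the
diagonal is stored as `NA` and every downstream statistic uses the defined
lower-triangle edges only. Off-diagonal correlations are clipped to
|r| ≤ 1 − 1e−15 before the transform: numerically identical profiles then
give a large finite value (≈ 17.6) rather than an infinity, while exact
collinearity with the covariate — which makes the partial correlation
genuinely undefined — remains an error. Note that `arctanh` amplifies the
last floating-point digits near |r| = 1; comparisons of near-saturated
entries should be made through `tanh`.

**Alternative metrics.** `metric = "pearson"` (full correlation + Fisher z)
and `metric = "euclidean"` are provided for robustness analyses. The
Euclidean variant is negated so that "larger = more similar" holds for
every kind; it is not Fisher-transformed.

Depth-intensity machinery reuses the same code path: microstructural
profile covariance (MPC) is the partial-correlation construction applied to
50-point depth profiles, and laminar intensity covariance (LIC) applies it
to per-layer mean intensities obtained by interpolating the profile at 10
equally spaced interior points of each layer's depth interval
(`samplesPerLayer = 1` reads the midpoint; a zero-thickness layer has no
interior and is masked). Equivolumetric depth sampling is approximated by
equispaced depth fractions within each layer: synthetic profiles live in
depth-fraction space, and real-data users are expected to supply profiles
sampled on whatever depth grid their atlas provides. LTC and LIC can be
fused by rank-normalizing both matrices, rescaling the second onto the
first's rank range, and concatenating horizontally; the fused table embeds
through the same gradient machinery.

## 2. Gradients

The embedding follows the standard gradient construction: per row, the
`p = 0.9` lowest-ranking cells are zeroed (ties keep the lower column
index, so results are reproducible; the row-sparsified matrix is
intentionally asymmetric), affinity is the normalized angle
`1 − arccos(cos θ)/π` between sparsified rows (which restores symmetry),
and the affinity is column-centered and decomposed by SVD. Loadings are the
projections onto the right singular vectors; explained variance is each
component's share of the total variance of the centered affinity. The
convention for "variance explained" is not unique — we report it on the
centered affinity because that is the matrix actually decomposed.
`nComponents` defaults to 10 and is configurable; components beyond G3 are
rarely interpretable. Diffusion-map (α = 0.5 anisotropic normalization) and
Laplacian-eigenmap embeddings are selectable; for these the
`explainedVariance` slot carries normalized spectral weights, a descending
analogue rather than a variance share. Component signs are arbitrary
everywhere; pass `reference` to have components flipped into a consistent
orientation, and the `signFlips` slot records what was done.

K-means on the raw profiles is the discrete alternative: k-means++
initialization, 10 restarts, Lloyd iterations, distortion = mean
within-cluster sum of squares, and the elbow chosen by the parameter-free
maximum-distance-to-chord rule on the min-max-normalized distortion curve.

## 3. Hierarchy, connectivity and edge models

The asymmetry-based hierarchy of a directed connectivity matrix is the
weighted unsigned out-degree minus in-degree (diagonal excluded); it sums
to zero by construction, and the in/out components are returned separately.
Edge-level models operate on the defined lower-triangle edges shared by all
input matrices:

* `exponentialDistanceFit()`: nonlinear least squares for
  `y = a·exp(−d/λ) + c`, initialized at `a = range(y)`, `λ = median(d)`,
  `c = min(y)`, with three deterministic fallback starts; R² is computed on
  the original scale (1 − SS_res/SS_tot), since the fit is.
* `scLikelihoodModel()`: maximum-likelihood logistic regression on
  internally standardized predictors. McFadden's pseudo-R²
  (1 − ℓ_model/ℓ_null) is the default because it is the convention of the
  statistical packages this analysis family uses; Cox–Snell is selectable.
  Complete separation is detected and refused rather than silently
  returning divergent coefficients. Single-predictor models mirror the
  usual reporting; a joint model is just a multi-element predictor list.
* `subsetLongRange()`: "long-range" has no canonical cutoff; the default is
  the upper tercile of geodesic distance and both quantile and absolute-mm
  thresholds are exposed. No particular cutoff is claimed faithful.

## 4. Geometry

**Curvature** is the cotangent-Laplacian mean-curvature normal with Meyer's
mixed Voronoi areas, signed against the outward vertex normal (positive =
convex/gyral). On subdivision-4 icospheres the estimate is within 0.001 %
of the analytic 1/R.

**Geodesic distances** between parcel centroids (exact Euclidean medoids,
ties to the lowest vertex index) are shortest paths on the mesh graph —
with one refinement. Pure edge-walk distances on a triangulated sphere
overestimate great-circle lengths by up to ~23 % in directions between the
lattice axes. We therefore augment the graph with straight chords to all
vertices within `ring = 3` mesh hops; this bounds the measured error below
2 % on a subdivision-5 icosphere at negligible cost, while remaining a pure
graph computation (no exact polyhedral geodesics, no external binaries).
`ring = 1` recovers the plain edge graph.

## 5. Spatially constrained nulls

Neighboring parcels are similar, so naive permutation nulls are wildly
anticonservative for map–map and matrix–matrix associations. Two null
families are provided:

* **Spin permutations**: uniform random rotations (QR of a Gaussian matrix,
  determinant +1) of the parcel centroids on the sphere; each parcel maps
  to the nearest rotated centroid. The mapping allows repeats (the standard
  parcel-level scheme); a greedy bijective variant is behind a flag.
  Applied to matrices, spins conjugate rows and columns jointly, preserving
  symmetry.
* **Variogram-matched surrogates**: random maps whose empirical variograms
  approximately match the original's. Per surrogate, the map is permuted,
  smoothed by exponentially weighted k-nearest-neighbor averaging for each
  candidate k, the empirical smoothed variogram (25 Gaussian-kernel bins up
  to the median pairwise distance) is regressed on the surrogate's, the
  best-SSE k wins, and the surrogate is `sqrt(α)·smoothed + sqrt(β)·noise`.
  One numerical guard matters: the intercept β feeds a white-noise term
  whose variogram contribution is |β|, so a negative fitted intercept would
  *bias surrogate variograms upward*; we constrain β ≥ 0 and refit the
  slope through the origin in that case. Surrogate value distributions are
  not resampled onto the original values by default (the noise term changes
  the marginals); `rankRemap = TRUE` restores them. The bin count, distance
  cap and kernel are declared defaults of this implementation, not claims
  about any external toolbox. Surrogates only match the variogram up to the
  fitted range (the median pairwise distance); beyond it they flatten, so
  fidelity checks should be confined to that range.

All tests use the add-one permutation p-value
`(1 + #extreme)/(nPerm + 1)`, which can never be 0; two-sided tests compare
|null| against |observed|. The tail convention for signed correlations is
two-sided because published reports of signed associations are. Calibration
is verified empirically: with 200 repetitions of independent smooth maps
(exponential-kernel fields, length 60 mm on a 100-parcel sphere) and 500
permutations each, both nulls give type-I error ≈ 0.06 at α = 0.05.

The categorical analyses (one-way ANOVA of a continuous map across types
with spin nulls and Bonferroni-corrected post hoc t tests; within- minus
between-type mean covariance with conjugated spins, one-sided for Δ > 0)
and the curvature-distribution similarity matrix (1 − Jensen–Shannon
divergence, base-2 logarithm so the result is bounded in [0, 1], histogram
densities on a shared global grid — deterministic, no bandwidth selection)
complete the inferential toolkit. An infinite observed F (zero within-group
variance) is treated as exceeding every null.

## 6. The synthetic cortex: what it emulates, and what it does not

The generator exists so that every pipeline stage can be tested against
known ground truth. Its defaults define the reference study conditions used
throughout the tests:

| knob | default | rationale |
|---|---|---|
| mesh | subdivision-5 icosphere, radius 100 mm | ~10k vertices, one hemisphere's working resolution; geodesics up to ~314 mm |
| parcels | 500 contiguous Voronoi-like patches | farthest-point seeding on graph geodesics; order of a high-resolution atlas after hemisphere split |
| base fractions | (.08, .06, .25, .07, .25, .29) | plausible cortex-average laminar composition |
| axis trends | linear slopes (0, .5, .9, .3, −.5, −.95) per layer (log scale) | layers II–IV thicken, V–VI thin along the planted axis, strongest in III and VI |
| trajectory curvature | log-quadratic component (2.4, .2, −.45, .15, .1, −.2) | see below |
| thickness noise | log-sd 0.06, correlation length 6 mm | smoothed-white-noise field; disk smoother reused as the autocorrelation engine |
| curvature field | disk-smoothed white noise, 4 mm length, sd 0.15 | a *high-frequency* field: the coupling must live below the 10 mm disk scale so smoothing can remove it, as it does for real folding |
| curvature coupling | 0.6 (logit units per curvature unit) | yields r ≈ −0.23 between curvature and superficial fraction before smoothing, ≈ −0.04 after |
| hierarchy | h ~ N(0, 1); weight `exp(−d/100)·exp(0.3(h_i−h_j))` + noise 0.02 | magnitudes decay with distance; asymmetry monotone in h_i − h_j, always positive before noise |
| SC / FC | logit = −1 + 1·z(LTC) − 1.5·z(GD); FC = exp(−d/60) + 0.05·z(LTC) + noise 0.1 | plants both headline connectome dependencies on standardized edge predictors |
| cortical types | sextiles of the parcel axis + 10 % label noise | a-/dysgranular types at the low pole, so exclusion removes a contiguous band |

Two design points deserve explanation.

**Why a log-quadratic trajectory component.** With purely linear log-trends
all profiles lie on a straight line in composition space; deviations from
the mean profile are then mutually (anti-)parallel, partial correlations
saturate to ±1, and the LTC degenerates toward a step function of the axis
— parcels at the axis poles become mutually indistinguishable and the
recovered G1 saturates there. Real laminar trends are not all monotone
(layer I in particular is irregular), and a trajectory whose direction
rotates along the axis keeps the covariance graded. The quadratic component
is therefore carried mostly by layer I, which has no required trend, and
the small components on the other layers were chosen by a feasibility
search so that layers II–IV remain strictly increasing and V–VI strictly
decreasing along the axis. With these defaults the end-to-end pipeline
recovers the planted axis at |Spearman| ≈ 0.91–0.96 across seeds and LTC G1
explains ~29 % of the variance.

**Why the curvature field is not low-order.** A long-wavelength curvature
field would pass through the 10 mm disk unchanged, and smoothing could not
reduce the curvature–thickness coupling — the opposite of what the
smoothing step is for. The synthetic curvature is therefore a
short-correlation (4 mm) field, not a low-order harmonic.

**What the generator does not emulate**: gyrification and real folding
geometry (curvature is a statistical stand-in, not a consequence of
geometry), vascular and staining artifacts, inter-subject variability,
non-6-layer architectures, real atlas parcel shapes, and any cellular-level
structure. Consequently, passing tests show that the *pipeline* is correct
and well calibrated under its stated assumptions — not that those
assumptions hold for any particular histological dataset.

At the small demonstration scales (~100 parcels on a subdivision-4 mesh)
the axis and trajectory-curvature eigencomponents of the LTC can come close
in variance and swap order for some seeds; at the default 500-parcel scale
the axis component dominates (EV1 ≈ 0.29 vs EV2 ≈ 0.16) and the ordering is
stable. Recovery claims are therefore always stated at the default scale.

**Seeding.** One integer seed determines everything. Module-level streams
are derived by repeated Lehmer steps (48271 modulo 2³¹ − 1 — exact in
doubles), so `sampleLaminarThickness()` and `sampleEffectiveConnectivity()`
can be re-run in isolation and still reproduce exactly what
`simulateCortex()` produced.

## 7. Problem sizes and runtimes in the test suite

The suite validates at the scales the methods are documented for while
staying interactive: oracle equivalences on 20-parcel / 200-edge fixtures;
curvature on subdivision-4 spheres; geodesic accuracy on the subdivision-5
sphere with 100 centroids; end-to-end recovery and determinism at the full
500-parcel default; parameter recovery at 5,000 and 20,100 edges; null
calibration with 200 repetitions × 500 permutations on a 100-parcel sphere
(the add-one p-value at 500 permutations resolves 0.05 exactly); elbow
selection over 40 seeds. The complete suite runs in roughly three minutes
on one core; `scripts/acceptance.R` recomputes the headline numbers in
about two.

## 8. Known limitations

* Geodesics are graph-based; the ≤ 2 % residual overestimate is a bias,
  not noise, and is shared by all pairs of a given direction class.
* The partial-correlation construction uses K = 6 points per profile;
  with so few degrees of freedom individual LTC entries are extremely
  noisy, and only the matrix-level structure (gradients, edge models) is
  interpretable. This mirrors the real analysis, but it means entry-wise
  confidence statements are meaningless.
* Parcel-spin nulls with nearest-neighbor repeats slightly distort the
  permutation distribution for small parcel counts; the bijective variant
  trades that for a different distortion. Calibration was verified at
  P = 100.
* Real-data mode expects inputs already in a common vertex space (the
  package performs no surface registration, inflation, or resampling) and
  GIFTI support covers the ASCII encoding written by its own writers plus
  validation of external files of that form; base64/compressed GIFTI is
  not parsed.
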