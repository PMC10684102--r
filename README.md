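# ltcov — laminar thickness covariance analysis of the cortical sheet

The six layers of the isocortex differ in relative thickness from area to
area, and areas with similar laminar composition tend to be wired together
and to occupy similar positions in the cortical hierarchy. `ltcov`
implements a complete, reproducible pipeline for studying this **laminar
thickness covariance (LTC)**: from per-vertex layer-thickness maps on a
triangulated cortical surface to parcel-by-parcel covariance matrices,
their principal axes, and their associations with hierarchy and
connectivity — with spatially constrained permutation inference at every
step. It is aimed at researchers in surface-based histology and
connectomics who want the full analysis chain as tested, scriptable R
functions rather than a collection of one-off notebooks.

## The model

For each cortical location the 6-layer thickness vector is normalized by
total thickness to a composition profile `f = (f_1, ..., f_6)`, `Σ f_l = 1`.
After disk smoothing of the absolute thickness on the inflated surface
(radius 10 mm, uniform average; this suppresses the local folding signal,
since layers inside a fold are compressed and layers outside are stretched)
and median aggregation into parcels, the LTC between parcels i and j is the
first-order partial correlation of their profiles controlling for the
cortex-average profile `z`:

    r_ij.z = (r_ij − r_iz r_jz) / sqrt((1 − r_iz²)(1 − r_jz²)),
    LTC_ij = arctanh(r_ij.z)

so only greater-than-average covariance counts, on a variance-stabilized
scale. The diagonal is undefined by convention. The principal axis **LTC
G1** comes from the standard gradient construction: each row keeps its top
10 % of entries, rows are compared with the normalized-angle kernel
`1 − arccos(cos θ)/π`, and the affinity matrix is decomposed by PCA
(diffusion maps and Laplacian eigenmaps are available as alternatives).
Downstream models include the asymmetry-based hierarchy (weighted unsigned
out-degree minus in-degree of a directed connectivity matrix), logistic
models of binary structural connectivity against LTC and geodesic distance,
exponential distance decay fits `y = a·exp(−d/λ) + c`, and within/between
cortical-type contrasts. Significance is assessed against spin permutations
(random sphere rotations of parcel centroids) or variogram-matched
surrogate maps, both of which preserve spatial autocorrelation.

Because the original histological inputs are large external atlases, the
package ships a seed-deterministic **synthetic cortex generator**: icosphere
meshes with planted monotone laminar trends along a hidden axis, a
curvature-to-superficial-thickness coupling, depth-intensity profiles,
directed connectivity with a planted hierarchy, and SC/FC planted on
laminar similarity and distance. Every planted parameter is recoverable by
the corresponding pipeline stage, which is what the test suite verifies.

## Worked example

```r
library(ltcov)

cfg <- simulationConfig(seed = 1)          # 500 parcels on a 10,242-vertex sphere
res <- runPipeline(cfg, outDir = "ltc_results")
res$gradients
#> GradientResult (pca): 332 parcels, 10 components; EV1 = 29.4%

cor(gradientLoadings(res$gradients)[, 1], res$plantedAxis, method = "spearman")
#> [1] -0.9614626

res$fits$scLtc
#> FitResult (logistic): (Intercept) = -0.2049, ltc = 0.5537; mcfadden = 0.05208; p = NA; n = 54946
res$fits$fcGd
#> FitResult (exponential): a = 1.043, lambda = 64.78, c = -0.006123; r.squared = 0.7291; p = NA; n = 54946
```

Reading these numbers: of the 500 simulated parcels, 332 survive the
agranular/dysgranular exclusion; the first principal axis of their LTC
explains 29.4 % of the covariance and orders the parcels almost exactly
along the planted axis (|ρ| = 0.96; the sign of a principal axis is
arbitrary). Higher laminar similarity raises the odds of a structural
connection (standardized log-odds +0.55, McFadden pseudo-R² = 0.052), and
functional coupling decays exponentially with geodesic distance (R² = 0.73,
fitted length constant 65 mm against a planted 60 mm plus a laminar
coupling term). `ltc_results/` holds the LTC matrix, gradient loadings,
explained variance, parcel table and a provenance log; pass `nPerm = 1000`
to add spin/variogram permutation tests to the result. A command-line
wrapper with `simulate` and `run-all` subcommands is installed under
`inst/scripts/ltc_pipeline.R`.

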