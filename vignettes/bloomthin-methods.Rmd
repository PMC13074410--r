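---
title: "Flowering-stage thinning simulation and early yield prediction: methods"
author: "bloomthin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flowering-stage thinning simulation and early yield prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Orchard yield forecasting usually waits for fruit-stage imagery or relies on
long meteorological series; both arrive too late to guide flowering-stage
management. Flowering canopies, however, already encode load structure: how
many flower clusters a tree carries, how large and dense they are, and how
evenly flowers are spread. `bloomthin` turns a binary flower mask (the output
of any segmentation model; non-zero pixel = flower) into interpretable
structural phenotypes, simulates two blossom-thinning policies on the image,
and regresses per-tree yield on the resulting 50-feature table.

The pipeline is: mask → pixel coordinates → adaptive multi-scale density
clustering (flower clusters, then single flowers) → two thinning simulations
→ phenotype features → Lasso selection → cross-validated regression panel.

## Adaptive multi-scale clustering

Clustering operates on the N × 2 matrix of (row, col) coordinates of flower
pixels with Euclidean distances, using DBSCAN semantics: a point is *core*
when at least `min_samples` points (itself included) lie within radius
`eps`; clusters are maximal density-reachable sets; border points attach to
the first cluster that discovers them. Neighbourhood queries go through a
2-D kd-tree (average O(log n) access), which matters because a single
1024 × 1024 mask can easily contain 10^5 flower pixels; a brute-force
neighbour scan is kept as an internal cross-check and returns identical
labels.

A fixed radius cannot serve isolated ~1200 px² flowers and 10^4–10^5 px²
clusters at once, so the radius adapts to the area of the region being
clustered:

    R   = max(area / area_target, 1)
    eps = clip(eps_base + beta * ln R, eps_min, eps_max)

with `area_target = 1200` px² (the reference single-flower area),
macro level `eps_base = 10`, `beta = 1.8`, cap 20 px, and micro level
`eps_base = 7`, `beta = 0.5`, cap 10 px. The logarithm makes the radius grow
slowly with area; the level cap — not the ratio — stabilises it for extreme
regions. Flooring `R` at 1 means regions at or below the target area keep
the base radius, so the mechanism only ever *widens* the neighbourhood for
large clusters. The micro coefficient is deliberately small because
within-cluster structure varies far less than cluster size does.

Macro clustering is two-pass: a provisional DBSCAN at `initial_eps = 10`
estimates cluster areas, then each provisional cluster is re-clustered on
its own pixels at its adapted radius. Provisional clusters are refined
independently and never re-merged. Because the adapted macro radius is never
below the provisional radius, the second pass mostly confirms the first; it
can still shed edge pixels whose neighbourhoods relied on points that were
provisional-pass noise.

`min_samples` is 5 (macro) and 4 (micro). Nothing forces these values; they
are small enough that an isolated single flower is never discarded as noise
and large enough to suppress single-pixel speckle. Both are configurable in
`eps_params()`.

Per-cluster shape statistics: the centroid, a marching-squares boundary
length (each 2 × 2 window of the padded binary grid contributes its
iso-contour segment length), circularity `4πA/P²` clipped to [0, 1], and
compactness defined as the squared boundary length `P²` (px²). The
compactness definition is a package choice: the thinning rule below
normalises compactness by 50,000, which is the order of `P²` for a compact
region of a few thousand px², so the squared boundary length is the
descriptor consistent with that normaliser. It is exposed as a separate
column so an alternative descriptor can be substituted.

### What the micro level can and cannot separate

DBSCAN on solid rasters can only split regions across *background gaps*
wider than the radius: interior pixels of a fused blob all have full
neighbourhoods. The micro level therefore separates flowers that the
segmentation left distinct (gaps wider than ~7 px inside a cluster held
together at 10 px), and counts a group of mutually overlapping flowers as
one. This is intrinsic to density clustering on masks, not an
implementation limit, and it shapes what the synthetic tests can assert:
micro-level recovery is tested on constructed masks whose inter-flower gaps
lie between the micro and macro radii, while heavily overlapping synthetic
clusters are expected to under-count single flowers.

## Thinning simulations

**Strategy 1 — density-graded dynamic retention.** Every cluster receives a
retention ratio

    r = clip(r_base · A_single · A_round · A_compact, 0.1, 1)

`r_base` follows a graded area ladder referenced to the single-flower area:
< 300 px² removed as noise (`r = 0`); < 500 px² fully retained (`r = 1`,
applied exactly — the adjustment factors are not allowed to nibble at
clusters that the ladder says to keep whole); < 1000 px² → 0.7; < 5000 px²
→ 0.5; < 10,000 px² → 0.3; else 0.2. The factors adjust for flower count
(`1 − min(n/20, 0.3)`), roundness (`1 + min(2·circularity, 0.2)`) and
compactness (`1 − 0.2·min(P²/50000, 1)`). With the default caps the product
cannot drop below 0.112, so the 0.1 floor is a safety net. The ratio is
realised by keeping the `⌈r·area⌉` pixels nearest the cluster centroid
(Euclidean; ties broken in row-major order) — the ceiling guarantees the
achieved fraction never falls below the floor.

**Strategy 2 — spatially uniform single-flower retention.** Clusters whose
centroids sit within `merge_distance` (default 30 px ≈ 1.5 × the macro cap)
of a larger cluster are dropped first, so retained clusters are pairwise
separated. Each surviving cluster keeps `T = max(1, round(ρ·n_flowers))`
flowers (`ρ = 0.2` by default — the retention level that a ~20% uniform
thinning policy targets), selected greedily by the score
`S_total = S_base · S_spatial` with

    S_base    = (flower area / median flower area in cluster) · (1 + circularity) / 2
    S_spatial = 1 / (1 + d_center/eps)                      before any pick
              = w·1/(1 + d_center/eps) + (1−w)·(mean distance to picks / cluster radius)

(`w = 0.5`; cluster radius = the maximal centroid-to-pixel distance). The
first pick is centre-first, subsequent picks trade centre proximity against
dispersion from what is already kept, recomputed after every pick; ties
break by flower index, so the procedure is deterministic. The score
functions realise the qualitative rule "large, round, central first — then
spread out"; both are small pure functions and can be swapped.

`retention_report()` summarises mean pixel retention per strategy and flags
whether it falls within 20–40%, the range practitioners consider a
reasonable thinning intensity.

## The phenotype table

`extract_features()` produces exactly 50 named features in three blocks —
23 from the original clustering, 13 from strategy 1, 14 from strategy 2 —
covering cluster counts (total and per size grade: small [300, 1000),
medium [1000, 5000), large [5000, 10000), supersized ≥ 10,000 px²), areas,
single-flower counts, morphology (mean circularity/compactness), spatial
statistics (cluster-area variance, mean flower distance to the canopy
centroid, uniformity = CV of flower nearest-neighbour distances), and
post-thinning counts, areas, fractions and spacing. "Dense" clusters hold
at least 8 single flowers (configurable). The published trait tables
constrain the block sizes, the seven trait categories and several names but
not the full membership; this schema is one consistent completion, frozen
in `feature_schema()` so tables are reproducible contracts. Statistics over
empty sets are reported as 0. Feature groups for modelling are `original`
(23), `strategy1` (13), `strategy2` (14), `mixed_strategy` (27) and
`mixed_all` (50).

## Selection and regression

Features are z-scored and an L1-penalised linear regression is fitted at a
fixed penalty `alpha = 0.01` on the 1/(2n) squared-loss scale (z-scored
predictors, raw response in kg). Features with non-zero coefficients are
ranked by |coefficient| — negative coefficients are informative, so the
magnitude, not the sign, drives the ranking — and the top 8 are kept.
Selection can be refitted inside every training fold (`fold_wise`, the
leakage-free default) or once on the full table (`global`, mirroring a
select-then-validate procedure); both are exposed because the difference is
itself of interest on small cohorts.

The panel spans the model families commonly compared for small-n yield
regression: forward-AIC stepwise linear regression, random forest, two
gradient-boosted tree variants (depth-wise, and histogram-binned with
leaf-wise growth), RBF support-vector regression, and two feed-forward
presets — a single-hidden-layer sigmoid network and a two-hidden-layer ReLU
network trained with Adam. Evaluation is shuffled 5-fold cross-validation
under one seed (folds partition the cohort; the same assignment is reused
across models and groups so comparisons are paired), reporting R², RMSE
(kg), MAE (kg) and relative error `mean(|y−ŷ|/y)` as a fraction, on both
splits. `ablation()` runs the chosen model over all five groups, raw and
Lasso-optimised.

## The synthetic canopy generator

Real flowering photographs and their yields are not shipped with the
package, so every end-to-end claim is validated on synthetic canopies with
known ground truth. The generator is a parent–offspring (Neyman–Scott
style) process: cluster parents are uniform with a minimum separation,
offspring flower centres are Gaussian (sd = `cluster_spread_px`) around
their parent, isolated single flowers are placed away from any cluster, and
each flower is rendered as a filled ellipse with area ~ Normal(1200, sd)
truncated positive, axis ratio ~ Uniform(0.7, 1) and random orientation (so
circularity actually varies). Overlap within clusters is allowed —
overlapping is exactly what real canopies do — and a shared pixel belongs
to the later-drawn flower in the truth bookkeeping. Layout packing restarts
from scratch when rejection sampling gets boxed in, and fails loudly if the
requested layout cannot fit.

The default parent separation is `5·spread + 6·√(area/π)`: five sigmas keep
the centre clouds apart and two flower diameters of clearance keep the
*rendered* clusters pixel-separated, which is what "well-separated" must
mean for a pixel-level clustering method. Under this regime macro
clustering recovers the planted partition (mean adjusted Rand index ≥ 0.9
over 20 seeds, flowers mapped to macro clusters by majority pixel vote).

Synthetic yields are linear in z-scored features plus Gaussian noise,
clipped to 4.6–35.9 kg around an 18.45 kg intercept (a realistic orchard
range). The default ground-truth model weights five features on distinct
phenotype axes — total flower area (+3), flowers per cluster (+2),
strategy-1 dynamic ratio (−2), strategy-2 retained spacing (+1.5), mean
circularity (+1.5) — with `noise_sd = 1.25` kg, about a quarter of the
signal SD. Cohort-scale checks use 200 trees of 512 × 512 px canopies
(3 clusters of 2–16 flowers plus 2 isolated flowers), small enough to
simulate in well under a minute yet spanning isolated flowers to
supersized clusters.

What the generator does *not* emulate: photometric effects (it produces
masks, not photographs), segmentation errors, within-cluster background
gaps between touching flowers (hence micro-level under-counting, above),
perspective distortion, or agronomic covariates such as tree age and
rootstock. Passing the synthetic suite therefore validates the machinery —
clustering correctness, rule arithmetic, selection and evaluation — not
field-level predictive accuracy.

## Numerical choices and degenerate inputs

* All-background masks are accepted; every operation returns a well-formed
  empty result and the feature vector is all zeros.
* Clusters whose pixels are all provisional-pass noise produce a warning
  and an empty cluster list.
* Circularity is clipped to [0, 1] (rasterised estimates of small round
  regions can exceed 1); a zero perimeter yields circularity 0.
* `T = max(1, round(ρ·n))` uses R's `round`; the `max(1, ·)` guarantees a
  cluster that reaches selection retains at least one flower.
* Tie-breaks everywhere are deterministic and seed-free: row-major pixel
  order (strategy 1), flower index (strategy 2), label order (merging),
  alphabetical feature names (equal Lasso coefficients).
* CSV round trips are bit-exact ("%.17g" serialisation); JSON artifacts are
  written with full precision, so pipeline reruns are byte-identical.
* Relative error refuses zero true yields, naming the offending index.

## Known limitations

* Micro-level flower counts are lower bounds under heavy overlap (see
  above); features built on them measure *resolvable* flowers.
* The strategy-2 pixel retention on fused synthetic clusters is close to 1
  (retaining one resolvable flower can mean retaining the whole fused
  blob), so the ~19% retention this strategy targets on real imagery is
  only reproduced where micro structure is resolvable.
* The 0.1 retention floor of strategy 1 is unreachable with the default
  factor caps; it exists as a guard for user-supplied parameterisations.
* Model hyperparameters are fixed documented defaults; the package
  deliberately does no hyperparameter search.
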