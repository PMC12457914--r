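---
title: "From hull colour to growth stage: the methods behind hullscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From hull colour to growth stage: the methods behind hullscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hullscape)
```

## The problem

Pistachio hulls change colour as the nut matures, and specific colour
patterns — notably red colouration around the tip — occur more often in
*blank* nuts (shells without a kernel). hullscape turns plate photographs of
nuts into quantitative colour features, screens those features for
association with kernel status, and uses the surviving "major" feature
categories to build a per-time-point *colour landscape*: a binary matrix
whose columns describe each nut's colour character. Landscapes support two
practical inferences for growers: placing a batch of nuts among six
developmental stages anchored at three critical time points (CT1 ≈ 1800,
CT2 ≈ 2100, CT3 ≈ 2500 growing degree days), and estimating the prevalence
of blanks.

This vignette explains each stage of the pipeline, the tunable parameters
and their defaults, the synthetic data generator used throughout the test
suite, and the numerical conventions that make every result reproducible
bit-for-bit from a seed.

## Plate images to pixel ensembles

`white_balance()` applies diagonal von-Kries chromatic adaptation. The white
point is estimated as the mean RGB of the brightest-quartile pixels (a plate
photograph is dominated by its white background), and each channel is scaled
so the estimate lands on neutral grey at its own mean level, preserving
luminance. Plates with no near-white region (brightest-quartile luminance
below 180/255, or under 5% of pixels above that floor) are rejected rather
than silently mis-corrected.

`segment_plate()` thresholds the luminance channel adaptively: a pixel is
nut material when it falls below the local mean over an odd `block_size`
window (default 51 px, computed exactly with an integral image) minus an
`offset` (default 5), *and* is clearly darker than the plate itself (an
absolute margin below the estimated background luminance; this suppresses
the bright-background halo a local mean develops next to dark objects).
Connected components are labelled, holes are filled so a nut record holds
every pixel inside its contour, border-touching components and specks below
`min_area_frac` (default 0.05% of the image) are discarded, and the
survivors are labelled 1..N top-to-bottom by centroid row (ties
left-to-right), matching how plates are laid out and later cut open for
kernel annotation. Coordinates are 0-based, x = column, y = row, origin
top-left.

Kernel status is copied from the paired open-plate image by position:
`annotate_kernel_status()` matches ordinals and refuses length mismatches,
naming the unmatched ordinals.

## Tip geometry

A pistachio is nearly elliptical with a slightly protruding tip.
`principal_axes()` runs PCA on the pixel coordinates; `locate_tip()` takes
the two extreme pixels along the long axis and declares the one farther
from the centre the tip. Exact ties are broken towards larger projected
distance, then smaller image y, and distance ties in the subsequent ranking
are broken by pixel index order — so region partitions are deterministic.
Tip detection is invariant (to within a pixel) under rotation and
translation of the ensemble; the test suite checks this on synthetic nuts
at several orientations. For nuts with no protrusion at all (a perfect
ellipse) the rule still returns a deterministic long-axis endpoint, but the
"tip" is then an arbitrary one of the two.

## The colour spectrum

`build_palette()` pools RGB pixels from a set of reference nuts chosen to
span kernel states and stages (ten in the original design), clusters them
with Euclidean distance and Ward-D2 linkage, and cuts the tree into nine
colour profiles. The lowest-luminance cluster is the black background/edge
cluster and is excluded from all colour proportions; the remaining eight are
the *major colours*. Because hierarchical clustering is quadratic in memory,
a seeded subsample (default 2000 pixels per nut) is clustered; remaining
pixels are assigned by proximity. Cluster ids are assigned by descending
centroid luminance so colour codes are stable across runs — any fixed
labelling would do, and code identities matter only within one palette.

`classify_pixels()` assigns each pixel to the nearest profile. The default
compares with cluster centroids; a `method = "member"` mode compares with a
stored sample of branch members instead, reflecting the view of a major
colour as a branch-specific collection of RGB coordinates rather than a
point. Centroid mode is the default because member mode's cost grows with
the stored sample and the two agree except near branch boundaries.
Equidistant ties go to the lower id.

## Features, filtering, categorization

Seven regions are defined per nut: the full hull, and the tip-closest-k and
tip-farthest-k sets for k = 30, 50, 70 (k is a percentage of the
*non-background* pixels, ranked by distance to the tip; background is
excluded before percentages are taken). Region sizes use the ceiling rule
`m = ceiling(k/100 * n)`. A consequence worth knowing: when k% of n is not
an integer, closest-k and farthest-(100−k) share exactly one boundary pixel;
their union is always the whole pixel set. Each region contributes the
8-vector of major-colour proportions, giving 56 features per nut, each in
[0, 1], with each region's 8 proportions summing to 1.

`variability_filter()` drops features whose sample standard deviation falls
below 0.01 (kept when `sd >= 0.01`) — features that are constant or nearly
so flag the absence of a colour at that time point. `categorize()` splits a
retained feature at its median (configurable per feature) into binary codes,
with values exactly at the cutoff going to code 0; the equality case is a
package convention, as the verbal rule ("smaller or larger than the
median") does not specify it. Order-2 variables are all `choose(56, 2) =
1540` unordered feature pairs; their categories are the joint cells of the
two binary codes, with empty cells skipped.

## CEDA: screening categories by ensemble overlap

Each categorized feature (or pair) is cross-tabulated against kernel status.
Two row statistics are available: the natural-log Shannon entropy of the
row's conditional blank/filled distribution (`row_entropy()`, with
0·log 0 = 0) and the blank odds `blank/filled` (`row_odds()`, `Inf` when the
filled count is zero). Natural log is used because it reproduces the
published worked-example entropies; odds are the default screening statistic
because their simulated distributions are more stable (no logarithm).

`simulate_ensembles()` builds two ensembles of M tables each (default
M = 1000): the *alternative* resamples each column as a multinomial with its
observed within-column row proportions; the *null* uses the marginal row
proportions, enforcing independence. Both preserve the observed column sums
exactly. The overlap of the row statistic's two distributions — estimated by
`overlap_area()` on a shared 50-bin equal-width histogram spanning the joint
finite range, with non-finite odds routed to a shared overflow bin — is
interpreted as the minimum sum of Type-I and Type-II errors of telling the
alternative from the null. A category is *major* when the overlap does not
exceed a threshold `tau`. `tau` is a required, logged analysis parameter
(default 0.1); different time points may warrant 0.1–0.3, because weak
designs (few blanks) push even real associations' overlaps up.

Numerical conventions: a simulated row with zero total has entropy 0 and
odds NaN (routed to the overflow bin); point-mass distributions occupy a
single shared bin, so identical degenerate samples overlap 1 and distinct
ones 0. The overlap estimator is invariant under a common affine transform
of both samples and symmetric in its arguments. One RNG stream seeded once
drives a whole `select_major()` sweep, making the entire selection
reproducible; the Monte-Carlo standard deviation of a single overlap
estimate at M = 1000 is about 0.004–0.005, which is why stochastic
comparisons in the tests carry explicit tolerance bands.

No multiple-testing correction is applied across the 1540 pairs: the
per-category overlap threshold is the method's only control, by design.

## Colour landscapes

`build_landscape()` encodes, for every major category, which nuts belong to
it (their categorized code equals the category), giving a binary categories
× nuts matrix. Both axes are clustered with Euclidean distance and Ward-D2
— chosen for balanced, variance-minimising clusters — and each nut's K
nearest neighbours (default K = 10, appropriate for 90 nuts per time point)
are recorded with ranked distances. Columns are the per-nut *individual
colour landscapes*; the column dendrogram defines the neighbourhood system
used by the growth-stage algorithm. The canonical outputs are the matrix
(TSV), the dendrograms (Newick, branch lengths = merge heights) and the
K-NN profile table; the heatmap (`autoplot()`) is a by-product.

`branch_blank_rates()` cuts the column tree and reports per-branch blank
fractions; the size-weighted overall rate equals the global blank fraction
at any cut, a conservation identity the tests verify.

## The growth-stage algorithm

A query nut is projected into each time point's category space
(`category_membership()` with that landscape's verdicts and cutoffs) and
scored by `odds_g()`: among its K nearest candidate neighbours, a candidate
*admits* the query when the query's distance to it does not exceed the
candidate's own K-th nearest-neighbour distance (its neighbourhood radius).
With zero admitting candidates the query lies outside the landscape's
topology and OddsG = 0; otherwise OddsG is the maximum, over admitting
candidates z, of |N[z] ∩ CandiG| / K. The admission gate is essential: the
bare maximum-intersection ratio is never zero for a nonempty candidate set,
yet the published worked example requires a zero score for an outlier query,
and the accompanying vote procedure (compare the query's distances against
each candidate's 10th-neighbour distance) is exactly the admission test.
`admission_votes()` reproduces that tabular form directly from printed
distance profiles.

The OddsG triplet across CT1–CT3 is matched to six stage patterns —
(0,0,0), (1,0,0), (δ,1−δ,0), (0,1,0), (0,δ,1−δ), (0,0,1) — by nearest
Euclidean distance, with the two transitional patterns treated as segments
with δ restricted to [tol, 1−tol]. δ is qualitative in the stage protocol,
so `tol` (default 0.2) is a package parameter; ties raise an `ambiguous`
flag. `batch_stage()` reports per-nut stages and the majority vote.
`blank_prevalence()` annotates each query with the branch-specific blank
rate of its nearest *admitting* neighbour at a chosen dendrogram cut;
queries admitted by nobody are flagged outliers and excluded from the
estimate, mirroring the worked example's treatment of an off-landscape nut.

## Phenology

`gdd_accumulate()` sums daily `max((tmax + tmin)/2 − 7, 0)` heat units (base
7 °C for pistachio). The accumulation is non-decreasing and below-base days
contribute nothing. Starting the series at full bloom is the caller's
responsibility.

## The synthetic data generator

Nothing in the test suite depends on the original photographs; the
generator provides every input with known ground truth.

* `make_plate()` renders non-overlapping elliptical nuts with a tapering
  wedge tip (protrusion ≈ 0.28–0.38 of the long semi-axis, echoing the
  visibly protruding pistachio tip) on a slightly warm white plate. Nut
  colours are drawn per pixel from per-zone mixtures over the palette's
  major colours, the zones being terciles of the distance to the tip apex;
  blank nuts add extra weight (`blank_effect`, default 0.35) on the deepest
  red colour near the tip. The truth manifest records centroids, tips and
  labels, so segmentation, labelling and tip detection can be scored
  without re-inspecting images.
* `make_feature_table()` builds 56-column tables whose region proportions
  stay on the simplex. Individually *planted* features take values in a
  high range with kernel-dependent probability (the acceptance checks plant
  bin-conditional blank odds of 10:1 vs 1:10 at n = 90). A *latent contrast
  axis* can additionally be requested: nuts split into two balanced colour
  blocks (sign of a per-nut score with a guaranteed gap), the block sign is
  kernel-biased, and a stage-specific feature set loads on the axis with
  alternating signs. This emulates the dominant co-varying colour contrast
  of a developmental stage — tight reference blocks aligned with kernel
  status whose feature set changes between stages — which is the structure
  that makes cross-stage queries genuine outliers under the admission rule.
* Defaults follow the study design: 90 nuts per time point (3 plates × 30),
  blank counts 9, 10 and 21 at CT1–CT3.

What the generator does *not* emulate: photorealistic texture, specular
highlights, lighting gradients, shadows, touching nuts, or the full
physiological covariance of real hull colouring. Passing tests therefore
demonstrate that the algorithms implement their definitions correctly and
recover planted structure of realistic size — not that the pipeline's
biological conclusions transfer to any particular orchard's images.

## Problem sizes and runtime choices

The test suite works at the study's natural scale: 90-nut feature tables,
M = 1000 ensembles for worked-example overlaps (M = 300–500 inside the
three-regime pipeline, where hundreds of categories are assessed), plates of
12–30 nuts at 640×480 to 900×700 pixels. These sizes keep the full suite in
the minutes range on one CPU while leaving every statistical check at the
paper-scale sample sizes that matter (n = 90, K = 10).

## Known limitations

* The white-balance step is a generic von-Kries neutralisation, not a
  reproduction of any specific published calibration algorithm; in-field
  lighting correction is out of scope.
* The published overlap areas were printed without the ensemble size or
  binning rule used; with M = 1000 and 50 bins the estimator reproduces
  them to within a few thousandths, and stochastic comparisons should carry
  tolerances of that order.
* Pixel classification by nearest member is quadratic in the stored member
  sample; centroid mode is the practical default.
* Stage patterns with substantial support at two time points (δ near ½) are
  intrinsically ambiguous between "at" and "between" readings; the
  `ambiguous` flag surfaces this rather than hiding it.
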