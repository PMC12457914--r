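# hullscape

Image-based, non-destructive assessment of **pistachio nut maturity and
blank-kernel incidence** from hull surface colour.

Pistachio hulls shift from green-yellow towards pink and red late in
development, and red colouration near the nut tip is seen more often in
*blank* nuts (shells without a kernel). hullscape implements a complete
pipeline from plate photographs to grower-facing inferences:

1. **Imaging** — white-balance plates (von-Kries chromatic adaptation),
   segment nuts by adaptive thresholding, label them top-to-bottom, attach
   kernel status from the paired open-plate image.
2. **Tip geometry** — locate each nut's tip as the farther long-axis extreme
   of a coordinate PCA, and rank pixels by distance to it.
3. **Colour palette** — cluster pooled reference-nut pixels (Euclidean +
   Ward-D2) into 9 profiles; the black background cluster is excluded and
   the remaining 8 are the *major colours*.
4. **Features** — 7 tip-anchored regions × 8 colour proportions = 56
   features per nut; a sample-SD ≥ 0.01 variability filter; binary median
   categorization; `choose(56, 2) = 1540` order-2 feature pairs.
5. **CEDA screening** (categorical exploratory data analysis) — each
   categorized feature is cross-tabulated against kernel status
   Y ∈ {blank, filled}. For a row with counts (b, f), the package computes
   the conditional entropy in nats, `H = −p log p − (1−p) log(1−p)` with
   `p = b/(b+f)`, and the blank odds `b/f`. Two column-multinomial ensembles
   of M simulated tables — *alternative* (observed within-column
   proportions) and *null* (marginal proportions, independence) — give the
   statistic two distributions whose histogram **overlap area** estimates
   the minimum sum of Type-I and Type-II errors; categories with overlap
   ≤ τ are *major*.
6. **Colour landscapes** — the binary nuts × major-categories matrix with
   Ward-D2 dendrograms on both axes and per-nut 10-nearest-neighbour
   distance profiles.
7. **Growth-stage determination (GSD)** — a query nut's
   `OddsG = max_z |N[z] ∩ CandiG| / K` over candidates z that *admit* it
   (query distance ≤ z's K-th neighbour distance; zero admissions ⇒
   OddsG = 0). The triplet (OddsG1, OddsG2, OddsG3) is matched to six stage
   patterns from before-CT1 to at-CT3, and blank prevalence is estimated
   from branch-specific blank rates of admitting neighbours.
8. **Phenology** — growing-degree-day accumulation
   `GDD[n] = Σ max((Tmax + Tmin)/2 − 7, 0)` anchoring the critical time
   points (CT1 ≈ 1800, CT2 ≈ 2100, CT3 ≈ 2500 GDD).

A seed-deterministic synthetic module (`make_plate()`,
`make_feature_table()`) generates plates and feature tables with planted
ground truth, so the whole pipeline is testable without the original
photographs; the published worked-example tables ship as plain-text
fixtures (`ct_fixtures()`, `nn_fixture()`).

## Worked example

Re-analyse the published CT3 contingency table of the categorized full-hull
colour-1 feature against kernel status:

```r
library(hullscape)

tab <- as_ceda_table(ct_fixtures()$T5)
tab
#> Contingency table (feature category x kernel status)
#>   blank filled row_sum entropy    odds
#> 0    19     26      45 0.68100 0.73077
#> 1     2     43      45 0.18182 0.04651
#> col-sums: 21 69 | baseline entropy 0.54327, baseline odds 0.30435
```

19 of the 21 blank nuts fall in category 0; its blank odds (0.73077) are
well above the marginal odds 21/69 = 0.30435. Is that association reliable
at this sample size? Compare the odds distributions under the alternative
and null ensembles:

```r
assess_category(tab, 1, statistic = "odds", M = 1000, seed = 42)
#> # A tibble: 1 × 6
#>   category statistic overlap   tau is_major     M
#>   <chr>    <chr>       <dbl> <dbl> <lgl>    <dbl>
#> 1 0        odds        0.021   0.1 TRUE      1000
```

The overlap 0.021 — the minimum sum of Type-I and Type-II errors — is far
below τ = 0.1, so `full-hull colour 1 = 0` is a major category: its colour
signal genuinely tracks blankness.

The growth-stage worked example: a stage-2 nut queried against the stage-3
landscape, using the published distance profiles of its ten candidate
neighbours:

```r
fx <- nn_fixture()
admission_votes(fx$nn, fx$query)
#> $votes
#> [1] 0
#>
#> $odds_g
#> [1] 0
```

Every query distance (9.27–10.44) exceeds every candidate's 10th-neighbour
distance, so the nut receives zero votes, OddsG3 = 0: it lies outside the
stage-3 colour landscape — evidence it is not yet at commercial harvest
stage.

For an end-to-end run on synthetic data (plate → segmentation → palette →
features → selection → landscape → staging), see the methods vignette in
`vignettes/hullscape-methods.Rmd`.

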