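---
title: "Automated oral cytomorphometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated oral cytomorphometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralcyto)
```

## The measurement problem

Chronic exposure of the oral mucosa to tobacco-smoke residues produces early
epithelial alterations -- nuclear enlargement and cytoplasmic reduction --
long before any macroscopic lesion. The classic quantitative readout is the
nucleus-to-cytoplasm area ratio of exfoliated epithelial cells,

$$\mathrm{N/C} = \frac{A_\mathrm{nucleus}}{A_\mathrm{cytoplasm}},$$

estimated per cell and aggregated per animal. Manual estimation under the
microscope is subjective; `oralcyto` implements a whole-slide digital
workflow in which region selection and compartment delineation are fully
programmatic, so that the only tunables are explicit, hashed configuration
values applied identically to every slide.

The package was built around a study design with two groups of indoor cats
(with and without smoker owners), two May-Grünwald-Giemsa (MGG) stained
smears per animal, urinary cotinine as the systemic exposure biomarker, and
ordinal smear scores for inflammation (0-3) and dysplasia (0-3). All of the
statistics it reports are nonparametric: Mann-Whitney U with Cliff's delta,
Fisher's exact test with odds ratios, and Spearman rank correlations with
Fisher-z intervals.

## Pipeline

1. **Tiling.** A slide raster is subdivided into 256 × 256 px tiles
   (half-open windows, 0-based row-major origins, default stride 256 so the
   tiles partition the covered region; ragged edges are discarded).
2. **Tissue mask.** Background is near-white and essentially unsaturated,
   so the mask thresholds the HSV saturation channel, block-averaged at a
   configurable downsample (default 8). The threshold is global Otsu; when
   the saturation channel is essentially unimodal (range < 0.05, e.g. an
   empty slide), Otsu would split noise, so a fixed floor of 0.15 is used
   instead.
3. **Tile QC.** The study protocol this automates excluded acellular
   fields, overlaps, debris, inflammatory aggregates and border-clipped
   cells by expert screening; `qc_filter_tile()` enforces the same
   exclusion list programmatically (codes `acellular`, `multiple_cells`,
   `debris`, `border_contact`, `low_contrast`), which removes the observer
   dependency of manual tile selection. A fixed number of accepted tiles
   per slide (default 250) is then sampled uniformly with a seed.
4. **Segmentation.** Tiles are converted sRGB → CIELAB (D65) and clustered
   by K-means with k = 3 in (L, a, b). Three clusters are the minimal
   complete model: violet chromatin, pale basophilic cytoplasm, and
   background are all present in almost every informative tile. Clusters
   are mapped to compartments by lightness rank (darkest = nucleus,
   lightest = background), with exact ties broken toward the higher-chroma
   centre (stained material is more chromatic than background). Masks are
   refined by morphological opening (disc r = 1), closing (disc r = 2) and
   nucleus hole filling; overlap created by refinement is resolved in
   favour of the nucleus so the compartments stay disjoint.
5. **One cell per tile.** Connected components (8-connectivity) of the
   nucleus mask are computed; components under 80 px are treated as debris
   (at 0.14 µm/px that floor is ~1.6 µm², far below any real nucleus). The
   largest remaining nucleus is selected and its cytoplasm is the
   cytoplasm-labelled portion of the connected nucleus-or-cytoplasm region
   containing it.
6. **Aggregation.** Per-cell ratios are aggregated to the case level as the
   median over all cells from the animal's slides (two slides of 250 cells
   by default; other counts produce a warning, not an error). Quantiles and
   IQRs everywhere use linear interpolation between order statistics.

## Numerical choices in the clustering step

The K-means stage is the one place where naive defaults fail in a
systematic way, so its policy is worth stating precisely.

* **Fitting on a pixel subsample.** Centres are fitted on a seeded random
  subsample (default 6000 px of the 65 536) and every pixel is then
  assigned to its nearest centre. On well-separated stain clusters the
  labels are indistinguishable from a full-tile fit (≥ 98% truth agreement
  on generated tiles) at a fraction of the cost.
* **Seeding.** Restarts use one deterministic maximin (farthest-point)
  initialization -- darkest pixel, brightest pixel, then the pixel farthest
  from both -- plus k-means++ draws (5 restarts total). Both schemes place
  seeds in minority colour classes, which uniform random seeding reliably
  misses when a nucleus occupies 1-3% of a tile.
* **Restart selection.** The best restart by within-cluster sum of squares
  wins, but near-ties (within 5%) are broken toward the solution with the
  largest minimum centre separation. The reason is a genuine k-means
  pathology: at high N/C the cytoplasm is a thin ring and a minority
  cluster, and the raw WCSS optimum can prefer splitting the broad
  background cloud in two while absorbing the ring -- a solution that is
  numerically better by a fraction of a percent and scientifically wrong.
  The separation tie-break recovers the three-class solution whenever it is
  competitive.
* **Degeneracy.** A tile with fewer distinct colours than clusters, or with
  all centres within the CIELAB margin (default 15), cannot support the
  three-compartment model. Such tiles are classified as `acellular` when
  the collapsed field is bright (background-like, L > 80) and
  `low_contrast` otherwise; a lone nucleus whose cytoplasm centre collapses
  onto the background (a bare nucleus) is `low_contrast`, since its
  cytoplasmic contour cannot be delineated. These are QC rejections, not
  errors.

## The synthetic generator

No raw slides are distributed with the package, so every imaging stage is
validated against a generator that produces MGG-like tiles with *exact*
ground truth: each cell is an ellipse-within-ellipse (random eccentricity
in [1, 2], random rotation, fully interior to the tile), the nucleus axes
are solved so the realized mask-pixel ratio is within 3% of the requested
N/C, and the truth masks are the rendering masks themselves. Colours come
from a stain profile (defaults: nucleus RGB ≈ (70, 40, 110), cytoplasm ≈
(180, 185, 215), background ≈ (245, 245, 248), global noise s.d. 8) that
must satisfy L(nucleus) < L(cytoplasm) < L(background) and a minimum
pairwise CIELAB separation of 15 between class means. Clutter tiles
reproduce each QC exclusion class by construction.

Cohort-level generation mirrors the study conditions: 20 exposed and 10
non-exposed animals; non-exposed case N/C uniform on [0.215, 0.236]
(tight, fully below the exposed range, as in the study's morphometry);
exposed case N/C a right-skewed scaled Beta(1.3, 3.2) on [0.24, 0.85];
urinary cotinine lognormal(log 60, 1.1) in the exposed group, which puts
roughly 14% of animals above 200 ng/mL, matching the reported heavy right
tail (2 of 13), and near-baseline lognormal(log 2, 0.5) in controls;
cotinine available for 13 exposed and 8 non-exposed animals (the rest
missing, handled by listwise deletion downstream). The cotinine-N/C
association is induced by a Gaussian copula whose correlation is
$r = 2\sin(\pi\rho_s/6)$, so the *population* Spearman correlation equals
the configured `coupling_strength` (default 0.85) exactly, without
constraining either marginal. Inflammation scores and dysplasia grades are
assigned by thresholding true case N/C (cutpoints (0.24, 0.46, 0.52) and
(0.35, 0.50, 0.70)), which makes stratum medians monotone by construction.
The lognormal distributional form for exposed cotinine is a modelling
choice -- only the variability and tail behaviour, not the form, are
constrained by the design the generator emulates.

What the generator deliberately does **not** model: chromatin texture,
staining gradients across a smear, scanner-specific colour response,
partial-focus blur, and touching-but-distinct cell pairs with shared
cytoplasm boundaries. Passing the recovery checks therefore demonstrates
that the algorithmic chain is correct and unbiased on well-formed input; it
does not certify performance on real scanner output, where stain
normalization and focus QC would need attention first.

All randomness flows from a single root seed through a documented
stream-splitting scheme (`split_seed()`, a multiplicative congruential mix
modulo 2³¹ − 1), so cohort → slide → tile generation is bit-reproducible
and any sub-stream can be re-derived in isolation.

## Statistics

* **Mann-Whitney U**: U counts pairs with ties as half (midranks). The
  p-value is the exact rank-permutation probability when both groups have
  ≤ 8 observations and the pooled sample is tie-free; otherwise the normal
  approximation with tie and continuity corrections is used.
* **Cliff's delta**: computed exactly over all pairs; its confidence
  interval is a seeded percentile bootstrap (default 10 000 replicates,
  groups resampled independently). With completely separated samples every
  replicate yields delta = 1 and the interval degenerates to [1, 1].
* **Fisher's exact test**: the two-sided p follows the probability-ordering
  rule. The odds-ratio point estimate is the sample cross-product ratio
  (a·d)/(b·c), not the conditional MLE. Two interval conventions are
  offered: the default Woolf (normal approximation on the log cross-product
  OR), under which the package's worked example prints its intervals, and
  the exact conditional interval from the noncentral hypergeometric
  likelihood (`ci_method = "exact"`). The two differ noticeably at these
  sample sizes; both are legitimate, and the choice is surfaced rather than
  hidden.
* **Spearman rho**: Pearson correlation of midranks, missing pairs dropped
  listwise. Exact permutation p for n ≤ 10 without ties, t approximation
  otherwise. The 95% interval is the Fisher-z closed form
  tanh(atanh ρ ± 1.96/√(n−3)); at |ρ| = 1 it degenerates to a point and is
  flagged. Simulation at n = 30 under a Gaussian copula puts its coverage
  near 94% -- the familiar mild undercoverage of the z interval for rank
  correlations.
* **No multiplicity correction** is applied anywhere; the report mirrors a
  single pre-specified battery, and adding one silently would change the
  meaning of the printed p-values.

## Problem sizes used in the shipped checks

The package's own test battery validates segmentation recovery on
100-tile batches (Dice ≥ 0.90 per compartment, median per-cell N/C error
≤ 5%), QC discrimination on 25 tiles per clutter class (≥ 95% rejection,
≥ 99% clean acceptance), case-median recovery on four synthetic cases at
the full two-slides-of-250-cells design (≤ 5% error), Fisher-z coverage on
2000 copula draws at n = 30, and coupling recovery on 100 replicate
cohorts at the study's exposed-cohort size (n = 13). The acceptance script
uses slightly smaller imaging batches (60 clean tiles, 15 per clutter
class, two cases of 2 × 100 cells); these sizes give stable estimates of
the same quantities while keeping a full from-scratch rerun comfortable on
a laptop.

## Known limitations

* The tile screening replaces expert judgement with five programmatic
  rules; artefact types outside that list (e.g. stain precipitate mimicking
  chromatin) would need new rules.
* Compartment assignment by lightness rank assumes a Romanowsky-type stain;
  Papanicolaou-stained smears are out of scope for morphometry.
* K-means with k = 3 assumes at most one dominant cell per tile plus
  background; tiles with many touching cells are rejected rather than
  resolved.
* The exact per-tile clustering is run independently per tile (matching a
  per-tile processing description); a per-slide shared-centres mode would
  trade adaptivity for even stronger cross-tile consistency and is a
  natural extension.
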