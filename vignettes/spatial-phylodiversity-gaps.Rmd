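---
title: "Spatial phylogenetic diversity and conservation gap analysis"
author: "phylogaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial phylogenetic diversity and conservation gap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylogaps)
```

## What the package computes

`phylogaps` implements a grid-based analysis of where the evolutionary
diversity of a plant inventory — typically crop wild relatives (CWR) — is
concentrated, how unusual that concentration is relative to a random
placement of species, and how well it is covered by ex-situ collections and
in-situ protection. The pipeline has six analytical stages, each usable on
its own:

1. **Occurrence gridding** — point records are cleaned (missing
   coordinates, excluded taxa, outside the study region) and aggregated to
   a square grid in geographic degrees (0.1° by default). Incidence is
   binary per cell and species, while the per-cell sample count `N` retains
   duplicates, because sampling redundancy is a statement about samples,
   not species.
2. **Per-cell diversity** — species richness SR; sampling redundancy
   `1 − SR/N` (1 = well sampled, 0 = every sample a new species); Faith's
   phylogenetic diversity PD, the summed length of all branches on the
   union of tip-to-root paths of the species present; and relative PD
   (RPD), the ratio of observed PD to PD of the same cell on a *comparison
   tree* with identical topology whose every branch equals the mean
   non-zero observed branch length. RPD > 1 flags an excess of long
   branches (deep, distantly related lineages), RPD < 1 an excess of short
   branches (recent radiations).
3. **Randomization null** — observed PD and RPD are ranked against
   realizations of a fixed-fixed null that shuffles species across cells
   while holding every cell's richness and every species' range size
   exactly constant.
4. **Conservation gap analysis** — per-species representativeness scores
   (0–100) for ex-situ collections and in-situ protection, averaged into
   final scores and binned into priority categories.
5. **Composite indicators** — raster layers locating cells that combine
   high PD with either large ex-situ collection gaps or high modelled
   richness.
6. **Protected-area assessment** — the share of diversity hot-spot cells
   inside protected areas, broken down by administrative department.

A synthetic-data module generates all inputs with the statistical structure
the analysis assumes, so the full pipeline is testable without any
downloads.

## Conventions that needed a decision

**Tree and PD.** The root is treated as having no subtending edge; a root
edge present in an input file is dropped with a warning. With that
convention the PD of the full species set equals the total tree length,
the standard Faith convention, and the `PD_frac` column (PD as a fraction
of total tree length) is exactly 1 for a cell holding every species.
Zero-length branches are retained (they add 0 to PD) but excluded from the
comparison-tree mean, which is defined on strictly positive lengths.
Polytomies are processed as-is; PD is well defined on multifurcations.

**Cell assignment.** Cells are half-open intervals `[edge, edge + size)`
in both axes, so a point on an interior shared edge belongs to the
higher-index cell; the outermost north and east edges are closed so the
grid's exact boundary is kept. Coordinates stay in geographic degrees
throughout — no projection — matching the degree-based grid definition;
only buffer distances are metric (great-circle kilometres).

**Redundancy.** Implemented as `1 − SR/N` rather than a literal
species-to-samples ratio: only the complement has the documented reading
that values near 1 are well sampled. Unoccupied cells carry *no* value
rather than a zero, so quantile-based hot-spot thresholds are not dragged
down by structural absences.

**Null model.** The randomization is the curveball algorithm: each trade
picks two cells, keeps their shared species and randomly re-deals the
symmetric difference, which preserves both marginals exactly at every
step. Realizations are chained (each starts from the previous one) with
`5 × presences` trades per realization and per-realization reseeding
(`seed + rep`), so a run is reproducible and extending `n_reps` never
alters earlier realizations. The trade loop is implemented in C++ (using
R's own RNG) because millions of trades per analysis are routine.

**Significance.** Rank p-values use the +1 correction,
`p = (count + 1)/(n_reps + 1)`, with ties counted on both tails, so p is
never 0 and `p_high + p_low ≥ 1 + 1/(n_reps + 1)`. A tail is significant
when `p ≤ alpha`. PD is classed on each tail at `alpha` — both
significantly *high* and significantly *low* PD are ecologically
meaningful (more, or less, of the tree than expected) — while RPD is a
genuinely two-tailed question and uses `alpha/2` per tail. The default is
`alpha = 0.05` with 999 realizations for field analyses; the synthetic
test scenario uses 199 to keep runtimes proportionate.

**Gap scores.** Ex-situ: SRSex is the germplasm share of records,
`100·G/(G+H)`; GRSex the share of suitable cells within the germplasm
buffer (50 km default, the conventional collection-representativeness
radius); ERSex the share of suitable-area ecoregions the buffered area
touches. In-situ analogues replace the germplasm buffer with the
protected-area mask buffered by 5 km (the conventional protected-area
buffer). Final scores are plain means of their three components, the
combined score the mean of the two final scores. Area ratios are fine-grid
cell counts, treating cells as equal-area — adequate at the sub-degree
extents the package targets and free of projection machinery. Scores are
capped to [0, 100] after computation as a cheap numeric guard. Categories
are left-closed: HP < 25 ≤ MP < 50 ≤ LP < 75 ≤ SC. Species without a
suitability model are assigned HP in all categories with `assessed =
FALSE` and no fabricated numeric scores, and never enter score means.

**Two display conventions.** Cohort percentage shares (e.g. "50 of 95
species = 52.6%") are *truncated* to one decimal — the convention that
reproduces the published category-share arithmetic this module mirrors.
The department assessment table instead *rounds* its displayed values to
one decimal, and all of its aggregation (row averages, column totals,
grand average) operates on the displayed values, which is the only
combination under which a table rebuilt from its own printed numbers
reproduces itself. Departments with no hot-spot cells for a metric are
"no data", excluded from that column's total rather than counted as 0.

**Hot spots.** The threshold is the `q`-th percentile (default 95) of
occupied-cell values under linear interpolation between order statistics
(R's type-7 quantile), with inclusive ties: a cell exactly at the
threshold is a hot spot. With values 1..100 the 95th percentile is 95.05
and the hot-spot set is {96, ..., 100}. For significance metrics the
"hot spots" are simply the cells carrying the class label. A cell counts
as protected when its cell id is flagged in the protected mask — a
deterministic cell-level intersection rule.

**Indicators.** The coarse PD surface is resampled to the suitability
grid by bilinear interpolation on cell centres (exact on linear fields;
nearest-edge beyond the centre lattice; cells with no occupied coarse cell
in their interpolation support stay no-data). The gap-richness layer is
defined per species as suitable cells *not* within the germplasm buffer —
the spatial complement of GRSex — summed over species; it can therefore
never exceed predicted richness anywhere. Composites are
`(a/max(a) + b/max(b))/2` over the common valid mask, which is invariant
to rescaling either input and reaches 1 only where one cell attains both
maxima.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical features the analysis is
sensitive to, at configurable scale:

* a Yule (pure-birth) species tree with exponential waiting times, so
  branch lengths are positive, ultrametric and realistically skewed;
* spatially clustered species ranges (Gaussian kernels around random
  centres) with log-normal abundance, so range sizes and record counts are
  uneven, every species keeping at least one record;
* spatially biased sampling effort (a smooth random weight surface raised
  to the `effort_bias` power thins candidate records), so redundancy
  varies across the map the way under-collected regions do in real
  inventories;
* a germplasm/reference split per record, blocky contiguous protected
  areas grown to an exact coverage target, contiguous department
  partitions (multi-source flood fill) and Voronoi ecoregions;
* per-species suitability surfaces decaying with distance from the range
  centre, slightly wider than the occurrence kernel, binarized at 0.5 on a
  grid refined by a factor of 2 (the 10 km → 5 km analogue); only the
  best-recorded ~55% of species are modelled (`sdm_fraction`), emulating
  inventories where under-recorded species cannot support a distribution
  model and fall to the assigned-high-priority rule.

Each generator draws from its own stream (`seed` + a fixed offset), so all
outputs are bit-reproducible and adding a generator call never perturbs
another's output.

It does **not** imitate real geography, climate predictors, gazetteer or
database quirks, taxonomic synonymy, or spatial autocorrelation in
suitability beyond the single-kernel shape. Passing tests on synthetic
data therefore demonstrate the correctness of the computations and the
statistical behaviour of the null (exact marginals, nominal type-I rate,
power against planted long-branch assemblages) — not that any particular
real landscape will show a given pattern.

## Default study conditions and problem sizes

The standard synthetic scenario is a 30 × 30 grid of 0.1° cells with 60
species and 3000 records, 25% germplasm, 25% protected coverage, 8
departments, 6 ecoregions and 199 null realizations; it completes in about
half a minute on one core. Statistical checks use dedicated designs: a
15 × 15 grid with 40 species (a 34-species short-branch clade plus a
planted 6-species long-branch clade) for power, and a fully occupied
20 × 10 grid for type-I calibration, both at 199 realizations. Unit-level
oracles run on trees of 2–8 tips, where PD can be enumerated exhaustively
over all subsets.

## Known limitations

* Equal-area treatment of degree cells ignores the cos(latitude)
  contraction of east-west distances; buffers, in contrast, are true
  great-circle distances. At high latitudes or continental extents a
  projected workflow would be preferable.
* The curveball chain length (5 × presences) is a pragmatic mixing choice,
  verified empirically on the matrix sizes used here (checkerboard states
  are reached, realizations decorrelate from the observed matrix); no
  formal mixing-time guarantee is claimed.
* Ecoregion representativeness counts region identities, not areas, so a
  sliver intersection counts as much as full coverage — consistent with
  the score family it mirrors.
* The assessment intersects cells with protection as whole cells; partial
  overlap of real polygons is out of scope (inputs are cell masks).
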