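---
title: "Methods: habitat connectivity and conservation scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat connectivity and conservation scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectiscape)
```

## The model in one page

`connectiscape` treats a landscape as a network of habitat patches. For one
species it proceeds:

occurrences → thinning → predictor pruning → suitability model → minimum
training presence (MTP) threshold → elevation clip → habitat cover mask →
forest-loss update → patch labeling → home-range filter → resistance
surface → least-cost patch distances → dispersal-thresholded graph →
(BC, dIIC, QA) → rescale + rank → connectivity areas → PA/PES scenarios.

The underlying assumptions are the classic ones of patch-based functional
connectivity: a patch must be able to hold at least one resident individual
(area ≥ median home range); movement cost through the matrix depends on
land cover only, via per-class resistance weights; areas outside the
climatic potential distribution are not traversable at all (habitat is
dichotomous, not probability-scaled); and dispersal has a hard range limit
given by home-range allometry.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| thinning distance | 2·√(HR/π) | km | home-range diameter; per-species override in the trait table |
| correlation threshold | 0.8 | – | \|Spearman ρ\| above which one predictor of a pair is dropped |
| minimum occurrences | 20 | – | species below it are skipped, not failed |
| envelope percentiles | 5/95 | % | presence envelope of the reference suitability model |
| patch connectivity | 8 | – | 8-neighbour labeling; 4 available |
| dispersal coefficient | 40 (max), 7 (median) | km·km⁻¹ | d = c·√HR; maximum mode is the link-threshold default |
| barrier mode | infinite | – | cells outside the distribution are impassable; `finite` mode uses a ×1000 weight |
| habitat target | 0.5 | fraction | prefix-selection target; 0.3 supported for Aichi-style goals |
| PES replicates | 100 | – | random allocations averaged per scenario |
| service threshold | ≥ 1 | services | PES-potential pixels |

### Decisions that were genuinely open

* **Quartile convention.** Tukey's 1.5·IQR rule needs a quartile
  definition; we pin linear interpolation of order statistics (R type 7)
  for reproducibility. The rule is applied literally, in a single pass:
  fences are computed on the input list only. Recomputing fences on the
  retained values can remove further points on skewed samples (we measured
  second-pass changes on 11–45% of log-normal samples depending on skew),
  so idempotence is deliberately not promised.
* **Dispersal mode for link thresholds.** The allometric literature gives
  both a median (c ≈ 7) and a maximum (c ≈ 40 per √km²) natal-dispersal
  coefficient. Links should reflect what a disperser *can* do, so maximum
  is the default; both are exposed, and an explicit `dispersal_km` in the
  trait table always wins.
* **Thinning distance.** When the trait table gives none, the home-range
  diameter 2·√(HR/π) is used: two records closer than a home-range width
  are plausibly the same individual.
* **"Continuous areas".** Patch labeling defaults to 8-connectivity, the
  more permissive reading of spatial continuity; configurable to 4.
* **Patch quality.** "Presence of natural or semi-natural coverage" is read
  as the *fraction* of natural cells, which makes QA informative and
  reduces ties; a strict binary mode (`mode = "binary"`) is available.
* **Order of the loss update.** The habitat mask is eroded by forest loss
  *before* labeling and the home-range filter, i.e. eligibility is
  re-assessed on the post-loss landscape. Patches that fall below the
  home-range floor after loss are therefore dropped entirely.
* **Step-cost convention.** A move between adjacent cells costs the mean of
  the two cells' resistance times the centre distance (×√2 diagonally) —
  the standard symmetric raster least-cost rule. Patches traverse at zero
  internal cost and each patch is collapsed to a single multi-source
  (distances are edge-to-edge, as in patch-graph tools). Consequently two
  patches separated by a single cost-1 cell on a 1-km grid are exactly
  1.0 km-equivalent apart.
* **Cost–kilometre equivalence.** Resistance 1 means "1 km-equivalent per
  km of ideal habitat", so accumulated cost is directly comparable to the
  allometric dispersal distance. This convention changes edge sets and is
  therefore recorded in every graph object (`dispersal_km`).
* **A_L.** IIC is normalized by the *full* landscape area, not habitat
  area — this preserves the boundary property IIC = 1 ⇔ the landscape is
  a single all-covering patch.
* **Path weighting for indices.** dIIC uses link-count shortest paths (the
  binary connection model that defines IIC). BC defaults to the same
  topological weighting for consistency, with a cost-weighted option.
* **Equal scales.** The three indices are min–max rescaled to [0, 1] per
  species (a constant index rescales to zeros, with a message), giving a
  composite in [0, 3]; a z-score alternative was rejected because the sum
  would be unbounded. Ranking ties break by larger area, then smaller id,
  so greedy prefix selection is deterministic.
* **PES replication.** A single random allocation would be noise-dominated,
  so the PES scenario is the mean over 100 replicate allocations (sd
  reported); each replicate's allocation is shared across species because
  all species share one landscape.

## The synthetic generator

The generator emulates exactly the statistical structure the pipeline
assumes and nothing more:

* climate layers are Gaussian-smoothed white noise (σ = 3 cells), i.e.
  spatially autocorrelated but stationary;
* land cover is a seeded-region-growing mosaic whose clump classes are
  natural with probability `natural_fraction` (default 0.6, roughly a
  forest-dominated frontier landscape);
* elevation is a north–south ramp (70%) plus smoothed relief (30%) over
  0–3000 m;
* forest loss erodes forest-clump edges (frontier-style deforestation),
  3% of forest cells by default, with years uniform over 2007–2016;
* service counts are Binomial(4, p) with p raised by 0.4 on natural cells,
  giving the positive service–nature association the PES analysis assumes;
* occurrences are drawn without replacement with probability ∝ truth ×
  optional bias.

What it does *not* reproduce: real class legends, anisotropic terrain-driven
climate, temporally autocorrelated deforestation, road networks, or the
clustered sampling bias of real biodiversity databases (a bias field can be
supplied, but none is realistic by default). Passing tests therefore show
the *algorithms* are correct under the stated assumptions, not that the
ecological conclusions transfer to any particular real landscape.

## Numerical choices

* Every generator and stochastic stage takes an explicit seed and restores
  the caller's RNG state; per-stage seeds derive from the master seed, so
  whole runs are bit-reproducible.
* Thinning maximizes retained records by greedy search over 25 random
  orderings (exact maximum independent set is NP-hard); the best ordering
  is kept, deterministically.
* MTP thresholding and the elevation/home-range bounds are all *inclusive*.
* Weighted shortest-path tie detection (cost-weighted BC) uses a relative
  tolerance of 1e-12.
* Degenerate cases: an empty distribution after clipping warns; a species
  with no patch above its home range is skipped with reason `no_habitat`;
  a constant index column rescales to zeros; a single-species assemblage
  reports sd = 0 with `sd_defined = FALSE`.
* Barriers are genuinely infinite (graph edges are simply absent), not a
  large finite weight, unless `barrier = "finite"` is chosen.

## Verification

The test suite checks each stage against an independent oracle: labeling
against min-label propagation, least-cost distances against exhaustive
path enumeration with cost-bound pruning on 5×5 grids, IIC/dIIC against a
shortest-path double sum and leave-one-out recomputation, BC against
simple-path enumeration (and igraph), selection against a cumulative-sum
scan, and the randomized PES scenario against its closed-form expectation
`baseline + 100·(k/H)·|conn ∩ hotspot \\ PA|/|conn|` within Monte-Carlo
error. End-to-end runs use 24×24 to 48×48 landscapes with 60–120
occurrences and 3-species assemblages — small enough to iterate quickly,
large enough that patch mosaics, graphs, and scenarios are nontrivial.

## Known limitations

* The built-in envelope model is a reference implementation: monotone,
  percentile-based, and deliberately simple. Serious applications should
  feed an externally fitted suitability surface (`suitability =` in
  `run_species()`).
* No stepping-stone analysis of sub-home-range patches; the home-range
  filter makes the connectivity estimate conservative.
* No multi-species weighted prioritization: results are per-species, plus
  assemblage summaries.
* Probabilistic connectivity indices (PC, flux) and circuit-theory
  resistance are out of scope.
* Polygons are handled by cell-centre rasterization only; sliver effects
  below cell resolution are invisible.
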