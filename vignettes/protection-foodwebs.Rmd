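---
title: "Quantifying protection effects on avian food webs: models and design choices"
author: "pawebs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protection effects on avian food webs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pawebs)
```

## The question and the data model

Protected areas are expected to shelter not just species but the
architecture of their interactions. `pawebs` estimates, for each network
of connected protected areas (a *PA network*: PAs less than 1 km apart in
one biogeographical region, together with the non-protected cells within
100 km used as its comparison), the inside–outside difference in sixteen
food-web metrics, and then asks which environmental features of the
networks explain the variation in those differences.

The package works from four plain tables: a species-level trophic
metaweb (trait table plus directed consumer→resource edge list), an
occurrence-record table from citizen-science surveys, a grid-cell
attribute table, and a protected-area table with disc geometry. Local
food webs are *induced subgraphs*: an interaction is assumed realized in
a cell whenever both species were detected there and the metaweb
contains the link. This "fixed interaction pool" assumption — standard
for metaweb studies because local diet data do not exist at this scale —
ignores interaction rewiring across environments, and is the main
structural simplification of the whole approach.

## Sampling-bias control

Citizen-science effort is extremely uneven. Three mechanisms deal with
it:

* **Survey events.** Records are grouped into unique visits
  (programme × date × time × grid cell); effort is the event count per
  cell. The event key uses the grid cell as "location": it is the
  coarsest keying consistent with per-cell effort counts, and finer
  location data are not preserved in the synthetic tables.
* **Effort floor.** Cells with fewer than 50 events (after the temporal
  filter; exactly 50 is kept) enter no biodiversity analysis. They still
  characterize the environment of their network, which is always
  computed over *all* member cells.
* **Rarefaction.** Within each network, every cell is subsampled without
  replacement to the smallest retained cell's event count, so effort is
  constant within a network. One seeded draw is performed; repeating the
  draw is a matter of changing the plan's seed, and we deliberately do
  not average over draws — the stage-1 effort smooth absorbs residual
  effort effects, and averaging would understate sampling noise.

## The sixteen metrics, precisely

Definitions were fixed as the most common choices in the food-web
literature; each lives behind one function so alternatives can be
swapped.

* **Roles.** Because only birds are observed, *basal* means "eats no
  other bird" (out-degree 0, isolated species included), *top* means
  out-degree > 0 with no bird predator, *intermediate* both. Role counts
  always sum to S.
* **Trophic levels** are prey-averaged: TL = 1 for basal species,
  otherwise 1 plus the mean TL of the prey, solved as a linear system so
  cycles are handled; a singular system (a closed cycle with no basal
  input) falls back to shortest-path levels with a warning. The familiar
  bound TL ≤ S holds on acyclic webs but provably not on cyclic ones,
  which the tests respect.
* **MFCL** is the mean number of links over all *maximal* food chains —
  directed paths that cannot be extended into a longer simple path at
  either end. On acyclic webs (the overwhelming majority) this equals
  the top-to-basal path set and is computed exactly by dynamic
  programming; cyclic webs fall back to depth-first enumeration of
  maximal simple paths guarded by a path cap (default 1e5, truncation
  logged). Webs with no consumer yield `NA`.
* **Omnivory** is the fraction of all species whose prey span at least
  two distinct integer-rounded trophic levels.
* **Generality / vulnerability** average prey counts over consumers and
  predator counts over preyed-upon species respectively; empty
  denominators yield `NA`.
* **Connectance** is L/S² ("fraction of realized links"; under induced
  subgraphs, normalizing by metaweb-possible links would be identically
  1 and carry no information). **Linkage density** is L/S.
* **Modularity** is Newman's Q of the best partition found by a seeded
  multi-restart Louvain search (local moves + aggregation, 8 restarts)
  on the undirected projection; the tests require the search to match an
  exhaustive-partition oracle exactly on all webs with ≤ 8 species.
  Whether the source analyses used the directed or undirected graph is
  not documented anywhere we could verify; the undirected projection is
  the common default.
* **Body masses** are arithmetic means (grams) per role; an empty role
  yields `NA`, never 0.

Degenerate webs follow one rule everywhere: counts are 0, undefined
ratios and means are missing, so the stage-1 models drop them rather
than absorb spurious zeros.

## Stage 1: the variable-slope GAMM

For each metric the model is

```
y ~ prot + s(effort) + s(richness) +
    s(network, bs = "re") + s(prot, network, bs = "re") +
    s(elevation, network, bs = "re") + s(remoteness, network, bs = "re") +
    s(land_cover, bs = "re")
```

fitted by REML in `mgcv` (`bam(discrete = TRUE)` is available as a
numerically equivalent fast engine and is used for the large simulation
studies). The richness smooth is omitted when richness is the response.
Families: negative binomial for the count metrics, quasi-binomial with
log link for connectance and omnivory, Gaussian otherwise (modularity is
Gaussian: its range includes negatives). Effort enters *before*
rarefaction, because rarefaction equalizes within networks only.

The per-network elevation and remoteness random slopes absorb the
well-documented placement bias of reserves towards high, remote terrain.
The protection random slopes and random intercepts are independent
terms; the notation admits a correlated-slopes reading, but nothing in
the source formulation pins it down, and the independent version is both
simpler and the `mgcv` default idiom.

Per-network effects are reported as βᵢ = β + conditional deviation, with
conditional 95% CIs from the fit's posterior covariance
(Var β + Var bᵢ + 2 Cov, multiplier fixed at 1.96). A network is flagged
as deviating when β lies outside [CI low, CI high]; a boundary touch
counts as overlap. Two calibration facts, verified by simulation in the
test suite: the CI for β covers the truth at ~95% under the model, and
under exactly homogeneous effects the deviation flags are *conservative*
— empirical-Bayes shrinkage pulls all βᵢ to β, so the false-flag rate
sits at or below the nominal 5%, approaching 0 in the homogeneous limit.

Parameter-recovery conditions used by the tests (chosen once as a
realistic desk-scale design): 40 networks × 50 cells, true β = 0.5,
between-network slope SD 0.2, random intercept SD 0.3, residual SD 0.5,
a sinusoidal effort nuisance, 200 replicates.

## Stage 2: drivers of the per-network effects

Each network is characterized over **all** its cells (the effort filter
never applies here): mean designation year and protection level, an
aggregation coefficient (largest member PA's share of total protected
area — a monotone, trivially testable proxy for the inverse of
fragmentation; alternatives are pluggable), forest fraction inside,
fraction of bird-directive PAs, mean elevation / slope / remoteness,
Shannon land-cover diversity, surrounding (outside-cell) human density
and urban/agricultural/forest fractions, and inside-minus-outside
differences for those four. The proportion of protected cells is a
permanent control. All seventeen enumerated drivers are implemented; the
candidate set is a configuration list, so any subset can be declared.

Selection is bidirectional stepwise under BIC = ln(n)·k − 2·ln(L),
starting from the control-only model, with ties broken by candidate
order. The search is authored in the package around its own `bic()`
(which the tests pin to the closed form at machine precision) rather
than delegating to `stats::step`, for one behavioural reason: with as
many candidates as networks, naive stepwise can walk to a saturated
model. A residual-df floor (default 3) makes that impossible; on
ordinary inputs the two implementations agree exactly (verified
case-by-case in the tests). Coefficients, SEs, p-values and adjusted R²
come from the final OLS refit on z-scored drivers (z-scored before
selection). The p-values are post-selection and reported as-is — they
inherit the usual selection optimism and should be read as descriptive.

## The synthetic world

The generator emulates the statistical structure the analysis has to
survive, with known truth:

* **Metaweb**: the niche model (each consumer eats a contiguous niche
  interval below its value), with log-normal body masses increasing in
  niche value so larger species sit higher. Realized connectance is
  within ±20% of target for S ≥ 50. A separate `metaweb_seed` lets one
  fixed interaction pool serve many replicate worlds, mirroring a real
  continental metaweb that does not change between study regions.
* **Landscape**: smooth elevation/slope/remoteness fields plus noise,
  human density declining with elevation, five top-level land-cover
  classes with elevation- and density-dependent odds, and contiguous
  axis-aligned region blocks (a biogeographical shapefile is replaced by
  the region label).
* **Protected areas**: discs with placement probability log-linear in
  the elevation z-score (`placement_bias`), gamma-distributed radii,
  ordinal protection levels, designation years mostly ≤ 2015 with a
  deliberate post-2015 minority so the temporal filters do real work.
* **Effort and detection**: per-cell event counts are negative binomial
  (`mean_events_per_cell`, `effort_dispersion`); each species has a
  baseline occupancy and a per-event detection probability. The
  occupancy × detection split is our modelling choice — public record
  streams document nothing about detection structure — and only the
  product is identified by the downstream analysis.
* **Protection effects** are injected at the *occupancy-logit* level,
  per network, as δᵢ = β + elevation_mod·z(network elevation) + N(0, sd),
  multiplied by a species-weight profile: uniform for richness effects,
  top-tail for top-body-mass effects, a mid-niche bump for
  intermediate-guild effects, and for composition metrics (MFCL, mean
  trophic level) a *richness-neutral tilt* — a concentrated uplift of
  the top trophic tail balanced by a diffuse negative offset. The tilt
  is richness-neutral so the injected signal is not absorbed by the
  stage-1 richness smooth. Effect sizes are therefore in logit units,
  not metric units: the generative chain (occupancy → detection →
  rarefied webs → metrics) is the same causal pathway the real data
  follow, and metric-scale effects are emergent. One consequence,
  established by direct response-curve simulation while designing the
  generator: the *direction* of a composition tilt's effect on MFCL
  depends on the metaweb realization (broad-diet apex consumers add many
  short chains and can pull the mean down), which is why the end-to-end
  recovery experiment in the tests fixes the metaweb and verifies the
  monotone region of its response curve.

What the generator does **not** emulate: spatial autocorrelation in
occupancy beyond what protection and the landscape induce, observer
heterogeneity within a programme, migratory phenology, range boundaries,
and rewiring. Passing tests therefore demonstrate that the pipeline
recovers truth *under its own assumptions*, not that those assumptions
hold for any particular real dataset.

## Spatial rules and tie-breaks

* Overlapping PAs at one cell resolve by the cascade: highest protection
  level → oldest designation → largest area → seeded uniform choice (a
  pure function of its inputs; the random leg derives its stream from
  the seed and the candidate ids).
* PA grouping uses *boundary* distance (adjacency of areas, not
  centroids) with a strict < 1 km rule; exact-1-km ties do not arise on
  continuous synthetic geometry and are documented as ungrouped.
* The 100-km comparison buffer is measured from cell centre to PA
  boundary; a cell reachable from two networks joins the nearest one, so
  analyzed cells partition cleanly.
* Area-threshold coverage (the 50%/90% sensitivity modes) is evaluated
  on a regular 20 × 20 subgrid of points per cell — exact to 0.25% of
  cell area, which is far below the thresholds' granularity.
* Networks are retained with ≥ 15 protected and ≥ 15 non-protected
  effort-retained cells and a sampled-cell ratio ≥ 0.10. The ratio
  default sits in the documented gap between a clearly under-sampled
  network (3%) and the usable range (12–97%); it is exposed in the
  configuration.

## Problem sizes

Default synthetic conditions were chosen once to emulate the study at
desk scale: a 64 × 64 grid of 10-km cells, 160 candidate PAs in 6
regions, 150 expected events per cell, a 70-species metaweb at
connectance 0.08, richness and top-body-mass effects injected by
default. This yields roughly 10–25 PA networks and 1,500–2,500 analyzed
cells per run. The test suite uses smaller worlds (26 × 26 to 40 × 40
grids) with proportionally relaxed inclusion floors, and states its
simulation designs explicitly; these are the package's own choices of
experiment size.

## Known limitations

* Constant interactions in space and time (induced-subgraph
  construction).
* No spatial error structure in stage 1; networks are the only spatial
  unit.
* Post-selection inference in stage 2 is uncorrected.
* The quasi-binomial log-link path cannot be fitted by the fast `bam`
  engine and falls back to `gam`.
* Modularity search is heuristic beyond exhaustive-oracle scale; the
  multi-restart Louvain matches the optimum on all tested small webs,
  but no optimality guarantee exists for large ones.
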