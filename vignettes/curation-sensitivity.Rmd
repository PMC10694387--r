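---
title: "Methods: measuring the sensitivity of richness gradients to record curation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring the sensitivity of richness gradients to record curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occsens)
```

`occsens` asks a procedural question rather than a biological one: *how
much does a macroecological conclusion depend on how the underlying
occurrence records were cleaned?* This vignette documents the models and
procedures the package implements, the parameters that matter, the
numerical choices behind them, and what the synthetic-data tests do and
do not demonstrate about real data.

## The pipeline

A run proceeds through fixed stages, each of which partitions its input
(`records_in = records_out + records_removed`, itemised per rule):

1. **Record-level cleaning.** Fossils; dates that are present but not
   calendar dates, or in the future; coordinates that are missing, zero,
   exactly equal in latitude and longitude, integer in both members, or
   south of the study limit (20° N by default); records whose
   coordinates fall outside their declared country (buffered by 0.1°,
   roughly 10 km); records within a small radius of country centroids or
   institution localities; and names above species rank. All rules are
   per-record predicates, so the kept set is independent of the order in
   which they are applied — a property the test suite checks.
2. **Gridding.** Coordinates are projected with a cylindrical equal-area
   projection on the WGS84 ellipsoid (standard parallel 30° N, the
   EASE-Grid 2.0 Global parameterisation) and indexed into 100-km square
   half-open cells. Rows become latitudinal bands, numbered 1 at 20° N
   northwards — the 20–90° N span is 48.4 rows, hence 49 bands. Regions
   are cut by meridians (−30° and 60° by default, separating North
   America, Europe/North Africa and Asia); the exact meridians are
   configuration, since any regionalisation of a global grid is a
   modelling choice.
3. **Taxonomy.** Raw name strings are normalised to binomials
   (authorship, infraspecific epithets and rank markers stripped; case
   and whitespace canonicalised) and looked up in each of five offline
   standardisation sources. The *consensus list* contains every accepted
   binomial endorsed by at least 3 of the 5 sources. Votes are counted
   on accepted binomials, not raw names, so two sources that reach the
   same accepted name through different synonym paths agree. A record
   is retained iff some source maps it into the consensus; its final
   name is the consensus member chosen by the most sources, with exact
   ties broken lexicographically and flagged rather than hidden.
   Fuzzy matching (edit distance ≤ 1, ties unresolved) exists but is off
   by default: an offline lookup should not guess.
4. **Curation scenarios.** A scenario names a taxonomy source, an
   optional basis-of-record restriction, an optional collection-year
   window and a duplicate key. Stages apply in that order with
   deduplication last, so duplicate detection sees exactly the records
   that survive extraction; when duplicates differ in basis of record
   this ordering changes the outcome, which is the point. Duplicates
   are records agreeing on species name, coordinates and collection
   date, optionally also collector; a record missing any key component
   can never be positively identified as a duplicate and is kept.
   Coordinates are compared by canonical decimal representation without
   rounding — rounding would silently merge distinct localities — though
   a rounding precision is exposed for users who want it.
5. **Completeness and well-sampled cells.** Per cell, the species
   accumulation curve is the exact hypergeometric expectation
   E[S(m)] = S_obs − Σᵢ C(N−Nᵢ, m)/C(N, m), evaluated at up to 100
   subsample sizes. Analytic rarefaction removes the permutation noise
   of randomised accumulation orderings; there is nothing stochastic
   about the curve. Asymptotic richness comes from the rational model
   S(m) = (a + bm)/(1 + cm) (asymptote b/c); completeness is
   100·S_obs/(b/c), capped at 100 and flagged if the fit lands below the
   observed richness. The terminal slope is the least-squares slope of
   the curve over the last tenth of the effort range (at minimum the
   final two points) — "one new species per ten further records" at the
   0.1 threshold. A cell is well-sampled when all four criteria hold,
   bounds inclusive: N ≥ 100, completeness ≥ 70%, N/S_obs ≥ 5,
   slope ≤ 0.1. The asymptote supplies predicted richness; the exact
   curve supplies the slope. The roles are configurable because
   reasonable practitioners split them differently.
6. **The gradient.** Per latitudinal band, medians of observed and
   predicted richness over well-sampled cells only (bands with none are
   omitted). The band series is fitted with a single-breakpoint
   piecewise regression y = β₀ + β₁x + β₂(x−ψ)·1[x>ψ]; ψ is the
   estimated latitude of peak richness. Scenario-by-region breakpoints
   are tabulated and pairs differing by more than a configurable number
   of bands (3 by default) are flagged as shifted.

## Numerical choices

**Rational fit.** The textbook linearisation S + c·mS = a + b·m is solved
by least squares and works perfectly when the data are exactly rational —
but for near-saturated curves the regressors m and m·S are almost
collinear and the linear solution routinely returns c ≤ 0, precisely on
the densely sampled cells one cares about. The package therefore fits
the true residuals by Levenberg–Marquardt with c bounded positive,
starting from the linearised solution when it is usable and otherwise
from a Michaelis–Menten-style half-saturation guess; if the start
already fits to numerical precision it is accepted directly (a
zero-residual start makes the gradient matrix singular). Everything is
deterministic; there is no random restart. Cells whose fit still fails
are flagged and can never classify as well-sampled.

**Breakpoint estimation.** ψ is estimated by exhaustive profiling: the
two-segment model is fitted by OLS at every candidate ψ on a grid over
the interior of the observed x values and the SSE minimiser is kept.
The default grid step is a quarter of the median spacing of distinct x
values (quarter-band resolution for unit-spaced bands). Profiling is
slower than iterative linearisation but global and deterministic — no
initialisation sensitivity, identical answers on reruns. Because the
grid is defined relative to the data spacing, the fit is
affine-equivariant in x: band indices and degrees latitude give the
same R² and correspondingly transformed ψ. A fit is *degenerate* (ψ
undefined) when the SSE improvement over a single line is below 1e-9
relative, when fewer than five distinct x values exist, or when y is
constant.

**Half-open cells.** Grid cells are [low, high) in projected x and y,
with the global upper edge assigned to the last row, so tessellation is
a function with no boundary ambiguity.

**Date legitimacy.** A date is illegitimate when present but
unparseable as a calendar date, or future-dated. Records with *no* date
are kept by the cleaning stage: missing metadata is not an error, and
undated records matter later precisely because the temporal filters
treat them differently (the strict "includes year ≥ 1600" filter drops
them; the plain windows keep them).

## The synthetic generator

The generator is first-class, tested code: it emulates the documented
pathologies of public occurrence data so every stage can be verified
against a ground-truth ledger.

*What it plants.* Per-record independent error classes (zero, integer,
lat = lon and centroid coordinates; wrong country codes; missing and
invalid dates; fossil basis), each at configurable rates — defaults put
~4% of records without dates, matching what large moss compilations
report. Duplicate copies are appended at rate 0.26 with 15% carrying a
different collector string, so a date-keyed deduplication removes ~20%
of the emitted dataset and a collector-inclusive key ~17% — the relative
ordering (collector keys remove less, because collector strings are
unstandardised) mirrors real repositories. Name variation per record:
synonyms (a disjoint-genus binomial), orthographic variants, authorship
suffixes, infraspecific expansions; per-source lookup tables differ in
coverage (0.9), variant detection (0.8) and occasional divergence about
which name is accepted (0.03), which is what makes a 3-of-5 consensus
non-trivial.

*Geometry.* Countries are axis-aligned rectangles with known centroids,
three per region, so the country-mismatch and centroid filters are
exactly checkable without polygon data. Clean coordinates are
continuous draws inside a cell (measure zero on every coordinate rule)
and are resampled away from gazetteer localities; error classes are
applied centroid → integer → lat=lon → zero, so a zero-labelled record
is always exactly (0, 0). Consequently each cleaning filter, run on data
where only its class is planted, removes exactly the planted records —
precision = recall = 1 by construction, and asserted in the acceptance
tests.

*Gradient.* Per region, true richness follows a two-segment
piecewise-linear profile of band index (profiles are rounded to integer
species counts); species are activated as richness rises and retired
first-in-first-out as it falls, giving contiguous band ranges whose
per-band occupancy reproduces the profile exactly. Default breakpoints
are bands 30 (North America), 40 (Europe/N. Africa) and 18 (Asia), with
Asia declining at −1 species/band because a steeper fall would drive
richness negative before band 49 — the generator validates positivity.
Sampling effort is log-normal across active cells (clustered effort),
with records split 25/70/5% across the three regions.

*What it does not emulate.* Real spatial autocorrelation, range shapes
beyond contiguous band intervals, abundance structure (species are
sampled uniformly within a cell, so rarefaction curves saturate faster
than with log-series abundances), collector-name chaos beyond a clean
pool, or drifting taxonomic concepts over time. Passing tests therefore
demonstrate that the machinery is correct and the inferential chain
recovers planted truth under controlled bias — not that any particular
real dataset is clean.

## Study conditions used by the tests

The suite and acceptance script run at desk scale, chosen so the full
suite completes in about a minute: rarefaction is checked against
exhaustive enumeration at N ≤ 12 (enumeration is exact and cheap there);
filter-recovery runs use 4,000-record single-class worlds;
breakpoint recovery under noise uses 45 bands with a mid-series
breakpoint (band 23), slopes ±2 and Gaussian noise with σ = 10% of peak
richness over 200 replicates — the mid-series position is the
informative regime for a change-point estimator, since a break near the
series end leaves too few points above it to estimate the upper slope
regardless of estimator. The end-to-end sensitivity check builds a
two-stratum world in one region: preserved specimens following a
breakpoint at band 29 (gentle ±0.5 slopes) and human observations
peaking at band 40 (slopes +3/−6) sharing the same cells, so the
all-records gradient peaks near band 40 while the specimen-only
scenario recovers band 29 — an 11-band planted shift that the fitted
breakpoints reproduce within a couple of bands.

## Limitations

- One breakpoint per fit; multimodal gradients will be summarised by
  whichever kink dominates the SSE.
- No spatial autocorrelation correction and no covariates; the gradient
  model is deliberately the minimal descriptive one.
- Country geometry is rectangle-based; real-boundary workflows need
  their own point-in-polygon step upstream.
- The consensus protocol is plain counting over sources; it has no
  notion of source authority, and a majority of outdated sources will
  outvote a better one.
- Band medians weight every well-sampled cell equally; regions whose
  few cells pass the thresholds (Asia, typically) produce fragile fits —
  visible in the reported per-band cell counts, not hidden.
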