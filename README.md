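# occsens

Sensitivity analysis of macroecological conclusions to the way species
occurrence records are curated.

Public biodiversity repositories (GBIF and friends) hold millions of
opportunistic occurrence records riddled with coordinate errors,
duplicates, inconsistent taxonomy and wildly uneven sampling effort.
Before analysing them, ecologists clean: drop fossils and impossible
dates, discard suspect coordinates, standardise names against a taxonomic
backbone, deduplicate, maybe keep only preserved specimens or recent
records. Every one of those choices changes the data — and sometimes the
conclusion. `occsens` makes that sensitivity measurable: it runs the same
macroecological analysis (the latitudinal gradient of species richness
over well-sampled grid cells) under alternative, explicitly named
*curation scenarios* and compares the outcomes.

It is aimed at macroecologists and biodiversity informaticians who work
with Darwin-Core-style occurrence tables and want their filtering
decisions to be auditable rather than folkloric.

## What it computes

- **Record-level cleaning** — fossils, illegitimate dates, suspect
  coordinates (lat = lon, zeros, integer pairs, missing, south of the
  study limit), country/coordinate mismatches (with a 0.1° buffer),
  proximity to country centroids and institution localities, and
  taxonomic rank, with full per-rule accounting
  (`records_in = records_out + records_removed`, always).
- **Equal-area gridding** — records are projected to a cylindrical
  equal-area plane (EASE-Grid 2.0 style, WGS84, standard parallel 30°)
  and indexed into 100-km cells, 49 latitudinal bands (numbered
  northwards from 20° N) and three regions.
- **Consensus taxonomy** — raw names are normalised to binomials and
  standardised against five offline lookup sources; the *consensus list*
  is every accepted binomial endorsed by ≥ 3 of the 5 sources, and
  per-cell richness under each source is classified
  Increase/Decrease/Equal against it.
- **Inventory completeness** — per cell, the species accumulation curve
  is built by exact (analytic) rarefaction,

  E[S(m)] = S_obs − Σᵢ C(N−Nᵢ, m) / C(N, m),

  and extrapolated with the rational model S(m) = (a + b·m)/(1 + c·m),
  whose asymptote b/c gives predicted richness and
  completeness = 100·S_obs/(b/c). A cell is *well-sampled* when
  N ≥ 100, completeness ≥ 70 %, N/S_obs ≥ 5 and the terminal slope of the
  curve is ≤ 0.1 species per record (all bounds inclusive).
- **The latitudinal gradient** — per-band medians of observed and
  predicted richness over well-sampled cells are fitted with a
  single-breakpoint piecewise regression
  y = β₀ + β₁x + β₂(x − ψ)·1[x > ψ], with ψ estimated by exhaustive SSE
  profiling; ψ is read as the latitude of peak richness, and scenarios
  whose ψ differ materially are flagged.
- **A synthetic-data generator** — occurrence datasets with a known
  planted structure (error classes, duplicate groups, name variants
  across sources, clustered log-normal effort, a piecewise-linear
  richness gradient with known breakpoint) plus a ground-truth ledger,
  so every stage above is testable end to end without downloads.

## Worked example

```r
library(occsens)

cfg <- pipeline_config(
  synthetic = synthetic_config(seed = 7, n_records = 60000),
  scenarios = default_scenarios())
run <- run_pipeline(cfg)

run$report
#> # A tibble: 7 × 4
#>   stage                 n_in n_removed n_out
#>   <chr>                <int>     <int> <int>
#> 1 acquire              75742         0 75742
#> 2 preprocess           75742      4780 70962
#> 3 taxonomy_annotation  70962         0 70962
#> 4 scenario:date-TNRS   70962     18264 52698
#> 5 scenario:date-cons   70962     14682 56280
#> 6 scenario:date-specim 70962     42849 28113
#> 7 scenario:date-1970   70962     45698 25264

nrow(run$consensus)
#> [1] 196

dplyr::filter(run$comparison, region == "all")
#> # A tibble: 4 × 7
#>   scenario    region bp_observed bp_predicted r2_observed r2_predicted shifted
#>   <chr>       <chr>        <dbl>        <dbl>       <dbl>        <dbl> <lgl>
#> 1 date-TNRS   all           42.5         42.8       0.856        0.863 FALSE
#> 2 date-cons   all           42.5         42.8       0.836        0.843 FALSE
#> 3 date-specim all           37.8         37.5       1.000        0.998 TRUE
#> 4 date-1970   all           37           37         1            0.998 TRUE
```

Reading this: the generator planted 75,742 records (60,000 base records
plus duplicate copies) with region-specific richness peaks; preprocessing
removed 4,780 records for planted geographic/temporal errors; the
consensus list recovered 196 of the 200 true species. Under the two
permissive scenarios the fitted global richness peak sits at band ≈ 42.5,
while restricting to preserved specimens (`date-specim`) or post-1970
records (`date-1970`) moves the peak several bands south and is flagged
`shifted` — the same qualitative sensitivity that motivates running more
than one curation scenario on real data.

The smaller building blocks are plain functions:

```r
rarefaction_exact(c(Bryum_argenteum = 2, Tortula_muralis = 1), 2)
#> [1] 1.666667

sac <- build_sac(c(12, 7, 5, 3, 2, 1, 1))
fit <- fit_rational(sac)
c(predicted = fit$asymptote, completeness = 100 * 7 / fit$asymptote,
  slope = terminal_slope(sac))
#> predicted = 8.95, completeness = 78.2 %, slope = 0.067
```

## Scope

Inputs arrive as files (CSV/TSV occurrence tables, per-source synonymy
lookups, a country-rectangle table, a gazetteer); the package contains no
live repository or name-resolution clients, and produces tabular outputs
rather than maps. See `vignettes/curation-sensitivity.Rmd` for the
methods, parameter choices and limitations.
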