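# islandSTR

Tools for analysing temporal turnover in island-like microbial
communities: species–time relationships (STRs), their power-law scaling
exponents, and the ecological processes behind them.

## The problem

The species–area relationship `S = cA^z` is one of ecology's few
generalizations; its temporal analogue, the species–time relationship
`S = cT^w`, describes how the observed richness of a fixed community grows
with the length of time over which it is monitored. The slope `w` of the
log–log fit measures temporal turnover: higher `w`, faster turnover.
Island biogeography predicts that turnover falls with island size, and the
balance between deterministic and stochastic assembly processes —
homogenizing dispersal, dispersal limitation (selection), and ecological
drift — should shift with it.

`islandSTR` is written for microbial ecologists who have censused a set of
discrete habitats ("islands", e.g. water-filled tree-holes on a beech
tree) repeatedly over time and hold a taxon-by-sample presence/absence (or
count) table. It provides:

- **Three STR constructions** from one presence/absence time series:
  - *moving window* (MW): adjoining censuses compared pairwise; a taxon
    counts again every time it re-appears after a local absence;
  - *cumulative moving window* (CMW): running union — only each taxon's
    first appearance counts;
  - *every possible window* (EPW): richness of every contiguous window of
    every span, averaged within spans.
- **Power-law fitting** of STRs and of species–area / species–volume
  relationships by ordinary least squares on `log10` scales, with the
  regression statistics (R², F, df, p) ecologists report, plus one-way
  ANOVA comparisons of exponents between construction methods.
- **Raup–Crick analysis**: the probability-based similarity of every pair
  of censuses within an island, estimated by Monte-Carlo draws from the
  archipelago-wide regional pool at fixed richness (occurrence-weighted or
  equiprobable), rescaled to `[-1, 1]` as a similarity. Pairs with
  `s_rc >= 0.95` indicate homogenizing dispersal, `s_rc <= -0.95`
  dispersal limitation, anything between indicates drift. A hypergeometric
  closed form (`exact_src_unweighted`) backs the equiprobable case.
- **A neutral archipelago simulator** (`generate_archipelago`): islands of
  log-spaced volumes share one lognormally-weighted taxon pool; richness
  follows a species–volume law, per-census extinction falls with volume,
  and immigration restores richness every census. It reproduces the
  qualitative structure the analysis assumes, so the whole pipeline can be
  exercised and tested without any sequence data.

## Worked example

```r
library(islandSTR)

arch <- generate_archipelago(sim_config(), seed = 1)
arch
#> Archipelago: 10 islands, 465 taxa in the regional pool
#>   volumes (mL): 50 83.4 139 232 387 646 1080 1800 3000 5000

cu <- build_str(arch$islands$TH01)       # smallest island, fastest turnover
fit_power_law(cu$CMW)
#> Power-law fit [TH01, CMW]: S = 47.2 * X^0.5275
#>   R2 = 0.992, F(1,18) = 2.26e+03, p = 2.2e-20, n = 20
fit_power_law(cu$MW)
#> Power-law fit [TH01, MW]: S = 41.01 * X^0.6987
#>   R2 = 0.977, F(1,18) = 762, p = 3.48e-16, n = 20

rc <- raup_crick_island(arch$islands$TH01, arch, n_rand = 1000, seed = 2)
classify_processes(rc)
#>   island_id   pct_HD pct_DL pct_drift n_pairs
#> 1      TH01 41.57895      0  58.42105     190
```

The MW exponent exceeds the CMW exponent because taxa that go locally
extinct and re-immigrate are re-counted; the smallest island mixes
homogenizing dispersal with substantial drift. Running everything at once:

```r
b <- run_all(run_config(seed = 1))
report(b)
#> Temporal scaling exponents (w), per STR method:
#>   MW   mean w = 0.393 +/- 0.172  (range 0.188-0.699, n = 10)
#>   CMW  mean w = 0.305 +/- 0.127  (range 0.148-0.527, n = 10)
#>   EPW  mean w = 0.306 +/- 0.125  (range 0.150-0.520, n = 10)
#> ...
#> Turnover vs island volume (w ~ log10 V):
#>   MW   slope = -0.2503, R2 = 0.96, F(1,8) = 214, p = 4.68e-07
```

Turnover declines significantly with island volume for every construction
method, drift is concentrated on the small islands, and homogenizing
dispersal dominates the large ones — the inverse size–turnover pattern the
package is built to detect. `run_config(out_dir = ...)` additionally
writes every table as TSV plus a `run_summary.json`; identical seeds give
byte-identical bundles.

Real data enter through `read_archipelago(taxon_table, metadata)`: a TSV
taxon-by-sample table (first column `taxon_id`) and a sample metadata TSV
with columns `sample_id`, `island_id`, `day`, `area_cm2`, `volume_ml`.

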