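---
title: "Methods: species-time relationships and assembly processes in island communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-time relationships and assembly processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandSTR)
```

## Scope and model

`islandSTR` analyses presence/absence censuses of a set of discrete,
island-like habitats that share a common immigration source — the
motivating system is water-filled tree-holes at the base of a single
beech tree, each hole a small aquatic island, censused repeatedly over
about a year. Three questions structure the pipeline:

1. How does observed richness grow with observation time (the
   species-time relationship, STR), and how steeply — the temporal
   scaling exponent $w$ of $S = cT^w$?
2. Does $w$ depend on how the STR is constructed from the series?
3. Which assembly processes (homogenizing dispersal, dispersal
   limitation/selection, ecological drift) account for the turnover, and
   do turnover and processes scale with island size?

### The three STR constructions

In every construction a taxon is *new* at the closing census of a window
only if it is absent from the window's earlier census(es).

* **Moving window (MW).** Adjoining censuses pairwise along the series:
  the curve starts at the richness of census 1 and each point adds the
  taxa present at census $t$ but absent at $t-1$. A taxon that goes
  locally extinct and re-immigrates is counted at every re-appearance, so
  MW incorporates repeated immigration/extinction.
* **Cumulative moving window (CMW).** Only first appearances count: the
  point at span $t$ is the richness of the union of censuses $1..t$.
* **Every possible window (EPW).** For each span $k$, all $n-k+1$
  contiguous windows are scored; within a window, the richness of its
  first census plus taxa new to each later census relative to the
  cumulative earlier ones — for presence/absence data this telescopes to
  the richness of the window's union. The curve records the mean over the
  windows of each span, so a 20-census series contributes 20 single-census
  values at span 1, 19 values at span 2, 18 at span 3, and so on.

These identities give free internal checks, asserted in the test suite:
MW $\ge$ CMW pointwise, with equality exactly when no taxon re-appears
after an absence; EPW at span $n$ equals the CMW endpoint; EPW at span 1
is the mean per-census richness.

### Span units

The span axis defaults to *number of censuses* ($T = 1, 2, \dots, n$).
This is the only unit that is well defined for single-census windows
(whose day extent is zero, where $\log T$ would be undefined) and it
matches the window bookkeeping above, which groups windows purely by
census count even under irregular sampling. An optional `"days"` unit
uses the mean day extent of each span's windows shifted by the median
inter-census gap; the mean day span per group is always reported in the
curve table so either axis can be reconstructed. Single-census points are
included in fits by default (`include_span1 = TRUE`) because the EPW
construction explicitly records them; the toggle exists because curves
without them are sometimes preferred and the choice is not forced by the
method.

### Power-law fits

STRs and species-area/species-volume relationships are fitted by ordinary
least squares of $\log_{10} S$ on $\log_{10} T$ (or size), the convention
under which the field's regression statistics ($R^2$, $F_{1,n-2}$, $p$)
are reported; nonlinear least squares is deliberately not the default.
The exponent is the slope and $c = 10^{\text{intercept}}$. Degenerate
inputs: fits with fewer than 3 points are flagged (`degenerate = TRUE`,
zero residual df); a response with no variance on the log scale returns
exponent 0 with $R^2 = 0$ and undefined $F/p$ rather than failing.
Exponent sets from two construction methods are compared by one-way ANOVA
(via `stats::lm`/`anova`); the variance explained is reported as
eta-squared (between-group over total sum of squares) and labelled as
such, since an ANOVA "R²" is ambiguous.

## The Raup-Crick null model

For every unordered pair of censuses within an island, the observed
shared-taxon count is compared with draws in which each community is
replaced by a random one of the *same richness* drawn without replacement
from the regional pool — all taxa observed anywhere in the archipelago
over the whole survey, applied identically to every island. Fixing
richness is the core of the construction: it makes the index insensitive
to richness differences between censuses. With $n_{\text{less}}$ null
draws sharing fewer taxa than observed and $n_{\text{tie}}$ sharing
exactly as many, the rescaled similarity is

$$ s_{RC} \;=\; 2\,\frac{n_{\text{less}} + 0.5\,n_{\text{tie}}}{n_{\text{rand}}} - 1 \in [-1, 1], $$

oriented so $+1$ means more similar than chance. Ties get half weight:
this is the standard rescaling choice, and it pins the degenerate case
(both communities equal to the whole pool, sharing forced) at exactly 0.
Pairs with $s_{RC} \ge 0.95$ are classified as homogenizing dispersal,
$s_{RC} \le -0.95$ as dispersal limitation (selection), and everything
between as drift; the boundary is inclusive on the deterministic side.

**Weighting.** Null draws default to inclusion probabilities proportional
to each taxon's dataset-wide occurrence frequency, the Chase-style
choice; `null_weighting = "equiprobable"` is available. For the
equiprobable null the shared-count distribution is hypergeometric, and
`exact_src_unweighted()` evaluates $s_{RC}$ in closed form — it is the
independent oracle against which the Monte-Carlo estimator is tested (to
within three Monte-Carlo standard errors at $n_{\text{rand}} = 10^4$),
and `vegan::raupcrick` under its `r0` null provides a second, external
cross-check. Which weighting the original PAST-based analyses used is not
determinable, which is exactly why both are exposed and the exact oracle
anchors the equiprobable case.

**Randomization mechanics.** $n_{\text{rand}}$ defaults to 1000. Within
an island, each randomization draws one null community per census and
scores all pairs from that draw (shared counts via a single cross
product), the usual implementation of this family of null models; it
keeps within-pair draws independent while making the island-level
computation $O(n_{\text{rand}} \cdot n \cdot P)$. Every island gets its
own seed, derived as `seed + island index` (and `seed + 10000 + index`
inside the pipeline), recorded in the results.

## The synthetic archipelago

`generate_archipelago()` emulates the survey design the analysis assumes:
10 islands, one shared 500-taxon regional pool with lognormal occupancy
weights (sdlog 1), 20 censuses per island at irregular intervals (gaps
uniform on 7-35 days, giving roughly year-long series), and volumes
log-spaced over two orders of magnitude (50-5000 mL). Equilibrium
richness follows a species-volume law $S_j = \text{round}(c_v V_j^{z_v})$
with $c_v = 20$, $z_v = 0.25$ — a typical aquatic-microbial scaling that
yields ~50-170 taxa per island. Each census, every resident taxon goes
locally extinct with probability $e_j = \min(1, e_0 (V_{\text{ref}}/V_j)^{\alpha})$
($e_0 = 0.1$, $\alpha = 0.5$, $V_{\text{ref}}$ the geometric mean
volume, so extinction spans ~0.03-0.32 across the size range), and
weighted immigration from the pool restores richness to $S_j$. Surface
areas are generated as $5 V^{2/3}$ with 20% lognormal noise, keeping area
correlated with, but noisier than, volume.

Three design choices matter for what the simulator can show:

* Richness is restored every census, so richness is trend-free and STR
  curvature reflects turnover, not richness drift — the quasi-stationary
  assumption of STR theory.
* Re-immigration after local extinction is allowed; without it MW and
  CMW would coincide and the method comparison would be vacuous.
* Dispersal is global: all islands draw from one pool, which is what
  produces high between-island overlap and homogenizing-dispersal
  classifications.

`generate_null_archipelago()` removes temporal persistence entirely
(every census an independent draw), the negative control under which
census pairs match the null model and should classify as drift.

**What the generator does not emulate:** read counts and sequencing-depth
variation (communities are presence/absence; depth robustness regressions
run only when real count data are loaded), per-census refilling of
volume/area (metadata carries a single measurement, SD 0 — the loader
does support per-census size series and then reports their mean and SD),
taxon niche differences or selection, and spatial dispersal structure.
Passing tests on synthetic data therefore demonstrate the machinery and
the direction of size-driven effects, not any claim about a particular
real community.

Problem sizes used in the test suite are deliberately modest (islands of
4-10, pools of 250-500, 100-1000 randomizations, 10 simulation
replicates for the parameter-recovery check); they are the sizes at which
the checked properties are already unambiguous.

## Pipeline and reproducibility

`run_all()` chains simulate/load → STR curves → power-law fits → method
comparisons → species-area/volume fits → turnover-vs-volume → Raup-Crick
→ classification → process-vs-volume, writing one TSV per result family
plus `run_summary.json` (parameters, seeds, package version — no
timestamps, so identical inputs give byte-identical bundles). Floating
point is written at fixed precision for the same reason. All randomness
descends from one top-level seed. Every number `report()` prints is
recomputed from the emitted tables.

The command-line wrapper (`inst/scripts/island-str`) exposes `simulate`,
`run-all` and `report`; finer-grained stage commands were folded into
`run-all`'s method/option flags, since each intermediate stage is a cheap
pure function of the stage before and separate TSV round-trips would add
surface without adding control.

## Known limitations

* Successive STR points (all three constructions) are cumulative or
  overlapping, so the OLS regression's independence assumption is
  violated, as it is throughout the STR literature; reported $p$ values
  should be read as descriptive. Autocorrelation-aware fits are out of
  scope.
* The Raup-Crick classification thresholds ($\pm 0.95$) are conventional,
  not estimated; with 1000 randomizations the granularity of $s_{RC}$ is
  0.002, comfortably below the threshold.
* Speciation is not represented in either the index or the simulator.
* No multiple-testing correction is applied anywhere, matching standard
  practice for these descriptive regression families.
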