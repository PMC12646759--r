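# hummnet

Tools for analysing the structure of quantitative plant–hummingbird
pollination networks sampled by monthly camera transects, and for asking
*why* that structure arises — specifically, how much of it is driven by the
matching between hummingbird bill length and flower corolla length.

## Who this is for

Ecologists with long-format monthly visitation records (site, month, plant,
hummingbird, visit count, camera recording hours), species trait tables,
and optionally a phylogeny, who want site-level network descriptors that
are standardized against ecologically honest null models, plus
species-level statements about which species shape those descriptors.

## What it computes

For each site's hummingbird x plant matrix of visitation rates
(visits per hour of recording):

* **Community descriptors** — weighted Barber bipartite modularity
  *Q* (label-propagation search with module merging), connectance *C*,
  specialization *H2′* (standardized interaction entropy), and weighted
  nestedness *WNODF*.
* **Null-model z-scores** — `z = (observed − null mean) / null sd` against
  a temporally constrained randomization that only allows visits on plants
  filmed (flowering) in the same month, preserves every hummingbird's
  monthly visit totals, and allocates visits proportionally to each
  plant's recording hours; a liberal variant drops the temporal
  constraint.
* **Species contributions** — each community metric recomputed under
  randomization of only the focal species' visits (row-wise for
  hummingbirds, column-wise for plants); positive z means the species'
  real interactions raise the metric.
* **Trait mismatch** — per species, the visitation-weighted mean absolute
  bill–corolla difference (mm),
  `TM_i = Σ_j |bill_i − corolla_j| · rate_ij / Σ_j rate_ij`,
  with a standardized effect size under the same focal nulls; negative
  `z_TM` indicates reliance on trait matching.
* **Diversity** — richness, Faith's phylogenetic diversity and its
  standardized effect size against a regional pool, and hull-based
  functional divergence per guild.
* **Synthetic data** — a generator with a Gaussian bill–corolla matching
  kernel (`sigmaMatch`, mm), phenology, camera effort and an elevational
  gradient, used for calibration and power experiments. `sigmaMatch = Inf`
  reproduces the null model's own generative process exactly.

## Worked example

```r
library(hummnet)

sim <- generateCommunity(simulationConfig(sigmaMatch = 2), seed = 42)
net <- buildNetwork(sim$table, "site1")
net
#> QuantitativeNetwork 'site1': 8 hummingbirds x 14 plants, 59 links, 3.04 visits/h total

communityZScores(sim$table, "site1", nSims = 200, seed = 7)
#> ZScoreReport [Q]:     observed 0.3868, null 0.09681 +/- 0.006786, z =  42.738 (n = 200, dropped 0)
#> ZScoreReport [C]:     observed 0.5268, null 0.9682  +/- 0.01185,  z = -37.262 (n = 200, dropped 0)
#> ZScoreReport [H2]:    observed 0.337,  null 0.04468 +/- 0.005062, z =  57.757 (n = 200, dropped 0)
#> ZScoreReport [WNODF]: observed 40.07,  null 71.41   +/- 1.686,    z = -18.591 (n = 200, dropped 0)

tmZScore(sim$table, "site1", "H01", "bird", sim$traits, nSims = 200, seed = 3)
#> ZScoreReport [TM]: observed 3.626, null 8.033 +/- 0.444, z = -9.926 (n = 200, dropped 0)
```

Read: this simulated community, built with a strong (2 mm) bill–corolla
matching kernel, is far more modular and specialized and far less connected
and nested than the phenology/effort/abundance-constrained null expects —
and hummingbird H01 visits flowers that match its bill about 3.6 mm on
average, much closer than the ~8 mm expected if it sampled flowers in
proportion to camera effort (`z_TM` ≈ −9.9, i.e. strong reliance on trait
matching). The full pipeline over many sites is one call:

```r
g <- generateGradient(simulationConfig(), seed = 1)
runAnalysis(g$table, g$traits, birdTree = g$birdTree, plantTree = g$plantTree,
            nSims = 200, seed = 1, outDir = "results/run1")
```

which writes tidy CSVs (`metrics`, `community_zscores`, `contributions`,
`trait_mismatch`, `diversity`) plus a JSON manifest; identical config and
seed give byte-identical CSVs. `summarizeZScores()` turns any of the
z-score tables into per-metric means with confidence intervals.

See `vignettes/hummnet-methods.Rmd` for the models, assumptions, numerical
choices and limitations.

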