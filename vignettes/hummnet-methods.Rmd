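---
title: "Models and methods behind hummnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hummnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hummnet)
```

# The data model

hummnet analyses plant–hummingbird visitation sampled by monthly
camera transects. The observational unit is the monthly record: at a given
site, in a given month, a plant species was filmed for some number of hours
and received some number of visits from each hummingbird species. Plants
that were filmed but never visited are kept as zero-visit rows because they
carry the sampling effort that the null models condition on. Validity rules
enforce that a visit can only occur on a filmed plant-month, that recording
hours agree across records of the same plant-month, and that keys are
unique.

A site's quantitative network is the hummingbird-by-plant matrix of
visitation rates. The rate for bird $i$ on plant $j$ is the total visit
count across months divided by the **total hours plant $j$ was filmed at
that site**. The per-plant denominator was a genuine design choice (a
per-site grand total is the alternative): it makes rates comparable across
plants with unequal camera effort and is the convention consistent with the
null models, which allocate visits proportionally to each plant's recording
time. Species without any realized interaction are dropped from the
network; rows and columns are sorted lexicographically so construction is
order-invariant.

# Community descriptors

Four standard descriptors summarize a weighted bipartite network $A$ with
total weight $m$, row totals $k_i$ and column totals $d_j$:

* **Connectance** $C$ — realized links over possible links,
  $\#\{A_{ij}>0\}/(RC)$.
* **Specialization** $H_2'$ — the standardized two-dimensional Shannon
  entropy $H_2 = -\sum p_{ij}\ln p_{ij}$ of the cell proportions:
  $H_2' = (H_{2max}-H_2)/(H_{2max}-H_{2min})$. $H_{2max}$ is the entropy of
  the outer product of the marginals (partner use proportional to
  availability); $H_{2min}$ comes from a greedy continuous mass-packing
  that repeatedly assigns $\min$(remaining row mass, remaining column mass)
  to the currently largest marginals. The greedy packing is a continuous
  relaxation of the integer-swap heuristic used for count matrices: rates
  are real-valued, and the relaxation is deterministic, order-independent,
  and exact in the exclusive-diagonal and outer-product limit cases (giving
  $H_2'=1$ and $0$ respectively). Results are clamped to $[0,1]$.
* **Nestedness (WNODF)** — mean pairwise "overlap under decreasing order"
  score over all row pairs and column pairs: a pair (u above v) scores 100
  times the fraction of v's positive cells that are strictly smaller than
  u's corresponding entries, and 0 when the ordering condition ties or
  reverses. Two gating conventions are implemented.
  The default gates on strictly decreasing *weighted marginal totals*:
  because rates are continuous, ties have probability zero and the metric
  discriminates even among dense matrices. The `comparison = "fill"`
  variant reproduces the binary-derived published algorithm (and the
  vegan/bipartite implementations, against which it is tested): sorting by
  occupied-cell counts with totals as tie-break and gating on strictly
  decreasing fill. On near-saturated matrices — which the
  proportional-allocation null model produces routinely — almost all fills
  tie under that convention and the score collapses to 0 regardless of how
  the weights are arranged, so the totals rule is the default for rate
  matrices. Field data sparse enough for the two conventions to agree
  closely are the common case; the choice matters for dense simulated
  communities.
* **Modularity** $Q$ — weighted Barber bipartite modularity
  $Q=\frac{1}{m}\sum_{ij}\left(A_{ij}-\frac{k_i d_j}{m}\right)
  \delta(g_i,g_j)$, maximized over partitions by a label-propagation search
  with agglomerative merging (the strategy of the DIRTLPAwb+ family): rows
  repeatedly adopt the column-side module with the best modularity gain and
  vice versa until $Q$ stops improving, then module pairs are merged
  greedily while $Q$ increases. The best of `restarts` initializations is
  kept; the first initialization is deterministic and ties are always
  broken toward the smallest module id, so results are reproducible under a
  seed. The search never returns less than the single-module partition
  ($Q \ge 0$). Defaults: 10 restarts for a one-off observed network, 3
  inside null-model loops (the hot path), merge tolerance $10^{-10}$.
  Like any stochastic modularity search, permuting rows and columns can
  change which local optimum a finite restart budget finds on unstructured
  matrices; planted modular structure is recovered exactly.

# Null models and z-scores

All randomizations reallocate **visit counts by multinomial draws**; they
never permute matrix cells. This is the only operationalization that
simultaneously (i) respects phenology — visits can only land on plants
filmed in the same month, (ii) preserves each hummingbird's visit totals,
and (iii) allocates visits proportionally to each plant's recording time.

* **Temporal community null** (default): per month and bird, the bird's
  monthly visit total is redistributed across that month's filmed plants
  with probabilities proportional to recording hours. Bird totals are
  conserved *per month* — the stricter of the two readings of monthly
  reshuffling, and the one implied by re-drawing each month independently.
* **Liberal null**: the temporal constraint is dropped; each bird's pooled
  visits are allocated over all filmed plant-months of the site.
* **Focal-species nulls**: only the focal hummingbird's rows (reallocated
  as in the temporal null) or the focal plant's monthly visitor identities
  (reallocated proportionally to each bird's total visits that month, the
  camera-derived relative abundance) are randomized; every other record is
  identical to the observed table.

A z-score compares an observed statistic with the mean and sample standard
deviation of its null distribution. Degenerate nulls (zero variance, e.g. a
focal species whose allocation is fully forced) yield `NA`, never an
infinity. Null draws in which a metric is undefined (a draw collapsing
below 2x2 after dropping empty species) are excluded and counted; reports
are flagged when more than 10% of draws are dropped. The observed
modularity inside a z-score computation uses the *same* number of restarts
as the null draws, so optimizer noise cancels instead of biasing $z_Q$.
Default ensemble size is 1000 draws, scaled down in the package's own
experiments (200 draws) where many replicate communities are analysed; a
running-z trace is available to diagnose convergence.

Species-level **contributions** recompute each community metric after
randomizing only the focal species, so a positive z means the species'
real interactions raise the metric above its focal-null expectation. Inside
this loop the modularity search is re-optimized for every draw with its own
sub-seed (3 restarts by default) — re-optimizing rather than reusing the
observed partition avoids crediting the partition itself to the focal
species.

**Trait mismatch** for a focal hummingbird is its visitation-weighted mean
absolute bill–corolla difference (in mm), and symmetrically for plants; the
statistic uses raw lengths, no standardization, and only bill and corolla
length enter it (the remaining traits serve the diversity module).
Its standardized effect uses the same focal nulls; rates in null draws keep
the observed per-plant hour denominators, which reshuffling leaves
unchanged. Negative $z_{TM}$ indicates reliance on trait matching.

# Diversity metrics

Richness counts a guild's species with any record at a site (for plants,
being filmed counts as presence). Faith's PD is the summed branch length of
the minimal subtree connecting a species set and the root; a single taxon
contributes its root-to-tip path (the rooted convention; the alternative,
returning 0, is not used). Its standardized effect size compares the
community against random equally sized draws from a species pool — by
default the regional pool, i.e. all species observed across the sites of
the input table. Functional divergence follows the hull-based definition:
traits are standardized (they mix mm, g and 1/mm), the convex-hull vertex
species in trait space are identified by a separating-hyperplane linear
program, and abundance weights measure how far toward the hull the
community's mass sits. Abundances are each species' total visitation rate
at the site, the only abundance surrogate the sampling design provides.
FDiv is undefined (with a warning) when a guild has fewer species than
traits + 1.

# The synthetic generator

`generateCommunity()` emulates the sampling design the data model assumes:
monthly surveys over two years, one contiguous flowering window of 3–12
months per plant, 60–72 recording hours per flowering plant-month (three
3-day deployments at one frame per second), hummingbirds present in a month
with probability 0.7 paying a Poisson(10) number of visits. Bills and
corollas are log-normal around 20 mm (roughly 10–40 mm). Visits are
allocated with probability proportional to
`hours * exp(-(bill - corolla)^2 / (2 sigmaMatch^2))`. The kernel width is
the single knob tying the generator to the trait-matching mechanism:
`sigmaMatch = 2` mm produces strong matching; `sigmaMatch = Inf` removes
the kernel, making the generator *identical* to the temporal null's
generative process — the identity on which all z-score calibration tests
rest. `generateGradient()` adds a 32-site elevational design with a linear
richness decline controlled by `elevationEffect`. Phylogenies are random
bifurcating trees with exponential branch lengths, independent of traits —
sufficient to exercise the PD machinery, but carrying no trait signal
(an acknowledged simplification).

What the generator does **not** emulate: nectar robbing, camera false
negatives, intraspecific trait variation, trait–phylogeny correlation, and
the sparsity of real networks. Generated communities are denser than field
networks because every present bird samples every flowering plant under the
kernel. Passing calibration and sign-recovery experiments therefore shows
the estimators and nulls are internally coherent and directionally correct
under the assumed mechanism, not that effect sizes match any field system.

# Experiment sizes and numerical choices

The package's own validation experiments (test suite and
`scripts/acceptance.R`) use 20 strong-matching and 100 neutral replicate
communities at the generator defaults with 200 null draws per ensemble, and
pool roughly 300 focal species across 20 communities for the species-level
analysis; these sizes give standard errors comfortably inside the margins
being asserted while keeping the whole suite re-runnable in minutes. The
species-level association between $z_{TM}$ and each contribution z is
assessed by rank correlation after centring ranks within guild — the
rank-based analog of including the species group as a covariate, since the
two guilds differ systematically in both quantities — with directional
tests matching the hypothesized signs. Tie-breaks, tolerances and
degenerate-input behaviour are stated on each function's help page;
everything stochastic accepts an integer seed and derives independent
sub-streams per site and per focal species, so batch results do not depend
on iteration order.

# A worked run

```{r example, eval = FALSE}
sim <- generateCommunity(simulationConfig(sigmaMatch = 2), seed = 42)
net <- buildNetwork(sim$table, "site1")
net
communityZScores(sim$table, "site1", nSims = 200, seed = 7)
```

A strong-matching community typically shows large positive z for
modularity and specialization and large negative z for connectance and
nestedness, with species-level $z_{TM}$ predominantly negative — the
qualitative structure expected when bill–corolla matching drives link
formation.
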