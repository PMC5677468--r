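---
title: "Stage-conditional odds and spatial clustering of seed-cache fates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-conditional odds and spatial clustering of seed-cache fates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cachescape)
```

## The problem

Bird-dispersed pines such as whitebark pine recruit from buried seed caches.
Between caching and establishment, each cache passes through a chain of
conditional filters: granivorous rodents may pilfer some or all of its
seeds; surviving seeds may germinate in the first year (or, with delayed
germination, in the second); and first-year seedlings may or may not survive
their first winter. Two questions follow from this chain. First, do the
odds of surviving each filter differ between study areas, between elevation
zones (closed-canopy subalpine forest vs. the high-stress alpine treeline
ecotone), and among cache microsites (near a rock, at a tree base, or in the
open)? Second, are the successes at each stage spatially clustered relative
to the failures — is recruitment being restructured in space, not only in
the marginal rates?

`cachescape` implements both analyses over a single validated data model —
the cache-fate table, one row per cache with its design attributes, planar
coordinates and observed counts across two years — plus a synthetic
generator that emulates a stratified two-area caching experiment, so the
whole pipeline is testable end to end without field data.

## Stage-conditional cohorts

The sampling unit is the cache, not the seed: seeds within a cache share
their fate environment, and seedling clusters often fuse into a single
tree, so cache-level binary outcomes keep observations independent. Cohort
sizes shrink along the chain because each stage conditions on surviving the
previous one:

* **Pilferage** — every cache located in year 1 is eligible; success means
  one or more seeds missing. Caches never relocated after caching are
  excluded from *all* cohorts (nothing was observed about them).
* **Year-1 germination** — eligible if at least one intact seed remained
  after pilferage *and/or* the cache already had a first-year seedling (a
  cache can lose every seed yet still count as germinated if a seedling
  emerged first); success means one or more first-year seedlings.
* **Survival** — eligible if the cache had one or more first-year
  seedlings; success means one or more live seedlings in year 2.
* **Two-year germination** — the germination cohort restricted to caches
  relocated in year 2; success means germination in year 1 or year 2.

The year-2 denominators deserve a note: the reference study's two-year
tables do not state whether their denominators shrank when caches could not
be relocated in 2014. The schema therefore records relocation explicitly
(`relocated_y2`) and the cohort rule here is the literal one — a cache not
relocated in year 2 drops out of the two-year denominator. With full
relocation (as in [mirror_study_table()]) the two conventions coincide.

`derive_outcomes()` computes the per-cache flags, `build_cohort()` assembles
a stage cohort under an optional stratum filter, and the invariants (cohort
nesting, stratum partition) are enforced by tests rather than trusted.

## Odds-ratio contrasts

For a stage success proportion $p$, the odds are $p/(1-p)$; for two groups
with $2\times2$ counts $a,b$ (successes, failures in group 1) and $c,d$
(group 2), the odds ratio is the cross-product ratio

$$\widehat{OR} = \frac{a\,d}{b\,c},$$

with the "null model" $OR = 1$ meaning equal odds. The decision rule is
interval-based: if the 95% CI contains 1.0, no difference is concluded.
`pairwise_odds_ratios()` computes every unordered pair of levels of a
stratum factor in a fixed canonical orientation (rock/tree, rock/open,
tree/open; treeline/subalpine; study areas in order of appearance), and
`run_odds_analysis()` runs the full plan — area pair, zone pair within each
area, microsite pairs within each area × zone — for every stage cohort.

Three numerical choices were genuinely open:

* **CI method.** The reference study never names its interval procedure,
  and no standard method exactly recovers its printed intervals from the
  reconstructible counts. The default is the Wald interval on the
  log-odds-ratio scale, $\exp(\ln\widehat{OR} \pm z\sqrt{1/a+1/b+1/c+1/d})$,
  with `"adjusted"` (+0.5 to all cells) and `"exact"` (conditional exact
  interval from `fisher.test()`, keeping the cross-product point estimate)
  selectable. Point estimates, which *are* exactly reproducible, are the
  quantity the package treats as authoritative.
* **Zero cells.** Any zero cell triggers the conventional +0.5 adjustment
  to all four cells, flagged in the output, so contrasts never silently
  fail.
* **Multiplicity.** No adjustment by default, mirroring the purely pairwise
  reference analysis; Bonferroni and Benjamini–Hochberg columns are opt-in
  (`adjust =`).

Proportion summaries use the exact Clopper–Pearson interval by default
(which reproduces the reference study's printed percentage intervals in
spot checks, e.g. 197/366 → 48.6–59.0%), Wilson by option. Reports round
odds ratios to 2 decimals and percentages to 1, matching field convention.

One reconstruction caveat is documented rather than patched: the subalpine
tree/open pilferage contrast computes to 2.54 from the published counts,
while the reference text prints 2.58. The package treats counts as
authoritative and reports the computed value.

## Ripley's K, the K difference, and random labeling

For a stationary point process of intensity $\lambda$, $\lambda K(r)$ is
the expected number of further points within distance $r$ of a typical
point; under complete spatial randomness (CSR) $K(r) = \pi r^2$. The
estimator on a rectangular window $W$ is

$$\hat K(r) = \frac{|W|}{n(n-1)} \sum_{i \ne j} w_{ij}\, \mathbf{1}(d_{ij} \le r),$$

with edge-correction weights $w_{ij}$: 1 (`"none"`), the translation
correction $|W| / ((\mathrm{width}-|\Delta x_{ij}|)(\mathrm{height}-|\Delta
y_{ij}|))$, or Ripley's isotropic correction (the reciprocal of the
fraction of the circle of radius $d_{ij}$ centred on point $i$ that lies
inside $W$, assembled from per-edge arcs minus corner overlaps). The
translation correction is the default: it is exactly unbiased under CSR on
rectangles and well-defined for all $r$ below the shorter window side.

Whether successes cluster *relative to* failures is asked through the
difference $\hat K_S(r) - \hat K_F(r)$ of the two mark classes' K
functions, under the assumption that both classes are driven by the same
spatial intensity up to a proportionality constant. The null is the
**random labeling hypothesis**: holding all cache locations fixed, marks
are permuted so every cache has the same success probability, preserving
the observed success count. `random_labeling_envelope()` simulates
`n_sim` relabelings (default 1000) and forms pointwise envelope bounds at
each distance from the order statistics of rank
$\lfloor \alpha (n_\mathrm{sim}+1) \rfloor$ and
$\lceil (1-\alpha)(n_\mathrm{sim}+1) \rceil$, $\alpha = (1-\mathrm{level})/2$
— for 1000 simulations at the 95% level, the 25th and 976th. This exact
rank convention gives each grid point an exceedance probability of
$2\lfloor \alpha(n_\mathrm{sim}+1)\rfloor / (n_\mathrm{sim}+1)$ under the
null (0.05 at the defaults), and requires `n_sim` ≥ 39 at the 95% level,
which is enforced. Departures are reported as the maximal contiguous grid
intervals where the observed curve lies strictly above the upper bound
(successes clustered relative to failures) or strictly below the lower
bound (failures clustered); values equal to a bound are inside.

The envelopes are **pointwise, not simultaneous**, because the scientific
reading is per-distance ("clustered at scales beyond 110 m"); across a
128-point grid the family-wise exceedance rate is of course higher than 5%,
which is exactly what the calibration tests measure (~5% of grid points
outside, on average, under the null).

Two more defaults the data cannot supply:

* **Window.** Observation windows are rarely published. The default per
  analysis group is the axis-aligned bounding box of the group's caches,
  expandable by a `margin`; any rectangle can be passed explicitly.
  Coordinates must be projected planar meters — geographic coordinates are
  not accepted.
* **r grid.** 128 equally spaced distances from 0 to one quarter of the
  shorter window side, standard practice for K validity; corrected
  estimators reject grids reaching the shorter side, where the weights
  degenerate.

`run_spatial_analysis()` applies the machinery per study area × elevation
zone: the stage cohort's outcome becomes the binary mark, groups with
fewer than two points in either class are reported as skipped, and each
group's permutation stream is seeded as `seed + group index` for
reproducibility without coupling.

## The synthetic cachescape

The generator's defaults *are* the reference study conditions: 734 caches
across two study areas (372 southern, 362 northern), stratified by
elevation zone × microsite in the published located-cache proportions; one
700 m × 700 m window (~49 ha, the magnitude of the ~50-ha study areas) per
area × zone; cache sizes drawn from Poisson($\lambda$ = 3) truncated to
1–7 seeds (renormalisation, equivalent in law to rejection); locate
probability 717/734; stage probabilities equal to the published per-stratum
percentages; and, among pilfered caches, total loss of all seeds with
probability 0.749. Points are uniform within their window, mirroring the
random-point placement of the field design; microsite labels are a design
attribute of each stratum rather than a spatial covariate.

Where the reference study is silent, the generator takes the simplest
defensible stand-in, documented here and in the configuration docs:

* **Partial pilferage.** No distribution of partially lost seed counts was
  published; partial losses are uniform on $1, \dots, n_\mathrm{seeds}-1$
  (single-seed caches can only lose everything).
* **Germinant and survivor counts.** Within a cache, the number of
  germinants (given germination) is uniform on the intact seeds, and live
  year-2 seedlings (given survival) uniform on the germinants. Only the
  binary cache-level outcome enters any analysis, so these choices affect
  realism of the counts, not the statistics.
* **Delayed germination.** The stratum's two-year probability $p_{2}$ is
  decomposed into the year-1 rate $p_g$ plus a conditional year-2 rate
  $(p_2 - p_g)/(1 - p_g)$ among year-1 non-germinators with seeds left.
* **Unlocated caches.** The 17 never-located caches are spread near-evenly
  across strata, since their true strata were not published.
* **Clustered fates.** Spatial structure in a stage is injected by a
  two-rate model: success probability `inside_prob` within `radius` of any
  of `n_centers` uniform cluster centers, `outside_prob` elsewhere. A
  latent Gaussian field would be smoother and more "ecological", but the
  two-rate model makes the clustering scale an explicit, controllable
  parameter — which is what power tests need — at the cost of a sharp
  boundary no real pilferage field would have.

What passing tests on this generator do **not** show about real data: real
cache fates are driven by continuous habitat covariates and rodent
territories, not discs; real point patterns are not uniform (nutcrackers
choose sites); and the generator draws stages independently given the
stratum, so it cannot represent residual within-cache or between-stage
correlation beyond the explicit conditioning. The tests establish that the
*machinery* is correct and calibrated under a null and an alternative it
can construct exactly — not that any particular field system matches the
generator.

`mirror_study_table()` is the deterministic companion: a table whose
stratum-level cohort sizes and success counts equal, exactly, the integer
counts implied by the published summary tables (successes are
`round(pct/100 * n)` per stratum; the per-stratum integers recombine to
every published zone, area and stage total). Only coordinates are random.
It exists to audit the odds pipeline against the reference study's printed
odds ratios, which it reproduces to 2 decimals for every contrast whose
counts are reconstructible.

## Problem sizes and tolerances in the test suite

The suite checks exactness where exactness is claimed and calibration
elsewhere, at sizes chosen to keep Monte-Carlo error well below the
assertion tolerance: uncorrected K equals a brute-force double loop on 100
random patterns of up to 50 points; translation-corrected K averages over
200 CSR replicates of 500 points agree with $\pi r^2$ within 3 Monte-Carlo
standard errors; envelope coverage uses 400 outer replicates at
`n_sim = 199` (the smallest size with exact 2.5% ranks) against a 3-sigma
binomial band around 95%; power uses 100 generator runs at n = 200 caches
with 2 clusters of radius 50 m in a 300 m window (detection threshold 80%);
the truncated-Poisson sampler faces a chi-square goodness-of-fit test on
$10^5$ draws. Identical seeds must reproduce tables, envelopes and whole
pipeline runs byte-for-byte.

## Known limitations

* Only rectangular observation windows are supported; irregular study-area
  polygons would need a different edge-correction implementation.
* The isotropic correction omits the large-$r$ boundary adjustment some
  implementations add; the default grid (≤ quarter window side) keeps it
  in its accurate range, and the translation correction is the default.
* Envelopes are pointwise by design; a global rank envelope is not
  implemented, so "number of departure intervals" must not be read as a
  family-wise-corrected test.
* The two-year within-area odds ratios of the reference study are not
  reproducible from its published tables (ambiguous 2014 denominators);
  the package computes them under the explicit relocation rule above
  rather than guessing the original convention.
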