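---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models `dietscape` implements, the
parameters that matter (units, defaults, rationale), what the synthetic-data
generator does and does not emulate, and the design choices made where the
design was genuinely open. It states no empirical result that the package's
tests and example code do not themselves compute.

## 1. Diet-table processing

Metabarcoding read tables arrive with one row per (physical sample, PCR
replicate). Processing order is fixed:

1. **Replicate averaging** — cell value = arithmetic mean of the sample's
   replicate counts. Means are rounded *half-up* to integers
   (`floor(x + 0.5)`), because the downstream rarefaction is a multivariate
   hypergeometric draw and needs integer counts; half-up is deterministic
   where R's banker's rounding is not.
2. **Rare-mOTU filter** — per sample, taxa with strictly less than 1% of
   that sample's (averaged) reads are zeroed. The inequality is strict: a
   taxon at exactly 1% is kept. The threshold is computed within sample on
   averaged counts, not per replicate.
3. **Rarefaction** — subsampling *without replacement* to exactly 7000
   reads. Samples below 7000 total reads are dropped with a warning rather
   than resampled with replacement: rarefaction "to" a depth implies a
   floor, and upsampling would manufacture precision.
4. **Profiles** — relative read abundance (RRA, count/7000) and a 0/1
   occurrence view.

*Open order question.* Whether the 1% filter should precede or follow
rarefaction is not determined by the procedure's usual narration; we apply
it first (the narrative order) and expose `order = "rarefy_first"` in
`process_read_table()` as a sensitivity switch. Under the alternative order
filtered samples are simply renormalized rather than re-rarefied.

## 2. Standardized diets and richness

Individuals differ in sampling effort (6–14 samples), and richness
estimators are effort-sensitive, so all individual-level quantities are
computed on **bootstrap-standardized diets**: B = 1000 iterations, each
drawing k = 6 of the individual's samples and recording the iteration's
mean RRA, taxon count, and Shannon index. Individuals with fewer than k
samples are excluded.

- Draws are **without replacement** ("rarefying to six samples" is
  subsampling, not a classical bootstrap); `replace = TRUE` is available as
  a sensitivity switch.
- The standardized diet is the across-iteration mean RRA, renormalized to
  sum to 1. (Renormalization is a no-op except in dropped-sample edge
  cases; we renormalize for the invariant's sake.)
- The per-iteration taxon counts have a closed-form expectation: taxon i
  with sample frequency f_i out of N samples enters a k-subsample with
  probability 1 − C(N−f_i, k)/C(N, k). The test suite holds the bootstrap
  to this hypergeometric oracle within 3 standard errors, and the exact
  species-accumulation curve uses the same identity, making it
  deterministic (no permutation averaging).
- Population richness counts, per iteration, the union of taxa over all
  individuals' iteration diets, so it dominates every individual richness
  iterationwise.

**Diet quality** is the RRA-weighted mean digestible protein (DP, % dry
mass) of the standardized diet. Taxa without DP data are excluded and
weights renormalized; the reported `coverage` is the RRA mass with DP data,
so a low-coverage value flags itself. The occurrence-weighted variant
(equal weight per covered taxon) is the standard sensitivity companion.

**Single-sample comparison.** The expected richness of one randomly drawn
sample (B = 1000 uniform draws) is compared with the standardized richness
via Welch's t across individuals — quantifying what longitudinal sampling
adds. By union monotonicity the single-sample value can never exceed the
k = 6 value for the same individual.

## 3. Space use

- **Percent MCP**: centroid = arithmetic mean of *all* fixes; the
  `ceiling(level·n)` fixes nearest the centroid (Euclidean) are retained;
  the home range is their convex hull, area by the shoelace formula. This
  is the classical percent-MCP convention; vertex peeling is not
  implemented. 95% is the home-range level, 100% feeds intensity of use.
- **Intensity of use** IU = total path length (km) / (100% MCP area, km²)²,
  computed on the track truncated to 21 days after the first fix. Units are
  km⁻³ and the index is covariant c⁻³ under spatial rescaling, so only
  relative comparisons are meaningful — which is all the regressions use.
  The 21-day window removes effort differences between field seasons; the
  tests check that windowed and full-track IU agree in rank on synthetic
  tracks.
- **Habitat affiliation**: floodplain-associated iff the 95% MCP intersects
  the floodplain polygon with positive area (convex clipping); the fraction
  of fixes inside the polygon is reported alongside.
- **Structure profiles**: LiDAR heights binned into ground / low / medium /
  high. The nominal classes "ground (0 m)" and "low (< 0.3 m)" overlap at
  zero, so ground is defined as height ≤ ε with ε = 0.05 m (half the
  typical vertical sensor resolution), and the 0.3 m and 1.6 m boundaries
  are closed on the medium side. Both choices are explicit arguments.

## 4. Statistics engine

All procedures are implemented in the package; `vegan` appears only as an
independent oracle in the test suite.

- **perMANOVA**: sequential (Type-I) partition of the Gower-centered matrix
  G = −½·C·D²·C via hat-matrix traces. The year **block** is honoured
  twice: fitted as the first sequential term *and* used as permutation
  strata. With 160 samples in 15 individuals over two years this reproduces
  the familiar df pattern (1 block, 14 group, 144 residual). Either half is
  switchable (`block_term`, `strata`) because the convention cannot be
  pinned down further; the df reproduction is evidence, not proof.
- **Permutation p-values** use the plus-one rule
  p = (#{F* ≥ F} + 1)/(n_perm + 1) — never exactly zero — with a dedicated
  RNG stream per operation (`op_seed()`), giving stage-level
  reproducibility. Default n_perm = 9999.
- **Pairwise contrasts** run one perMANOVA per unordered pair and
  Holm-adjust over the family. Note the resolution floor: with m contrasts
  the smallest achievable Holm-adjusted p is m/(n_perm+1), so the pairwise
  default also stays at 9999 (at 999 permutations a 105-contrast family
  could never reject at 0.05).
- **Mantel**: Pearson r of strictly-lower-triangle vectors, one-sided
  (greater) permutation test, joint row/column permutation of the second
  matrix.
- **NMDS** is explicitly visualization-grade: classical-scaling start,
  alternating isotonic regression and Guttman-transform updates, reported
  stress-1 sequence kept nonincreasing by retaining the best configuration.
  No Procrustes alignment across runs.
- **OLS/AICc**: AIC = n·ln(RSS/n) + 2k with k counting coefficients *plus*
  the residual variance; AICc adds 2k(k+1)/(n−k−1). The parameter-counting
  convention matters only through AICc *differences*, which is what the
  ranking uses. The candidate set is fixed at the seven standard models
  over {condition, habitat, lactation}.
- **Condition index**: z-score the measurement columns, take PC1, orient so
  the rump-fat loading is positive (higher score = better condition). PCA's
  component sign is arbitrary; the anchor makes it deterministic. Note that
  orientation is necessarily covariant with the data — negating a
  measurement column negates its contribution; no data-driven rule can be
  invariant to that.

## 5. The synthetic-data generator

The generator is first-class, tested code: it produces worlds with the
statistical structure the analysis assumes, so every stage is verifiable by
parameter recovery without field data.

**What it emulates.** Two habitats (a floodplain strip and woodland) with
distinct taxon pools; floodplain taxa drawn with higher DP (means 25 vs 14%
dry mass, SD 4, enforced strictly at the pool level); availability as a
normalized Gaussian-kernel mixture so community dissimilarity grows with
distance (the generator's own Mantel property); 15 individuals (7
floodplain, 8 woodland) with standard-normal condition; mean-reverting
(discrete Ornstein–Uhlenbeck) movement with hourly fixes for 21 days; diet
samples whose expected composition is availability × DP^β with
β = β0 + β1·condition and Dirichlet sample-to-sample noise; triplicate-PCR
multinomial reads at depths 8000–16000; contaminant mOTUs at expected RRA
0.1–0.9% per sample (below the 1% filter in expectation, so the filter
removes them); and LiDAR clouds driven by a spatially autocorrelated
woodland canopy field with a treeless floodplain.

**Movement model.** A discrete OU walk is used because it produces bounded
home ranges with path length tunable *independently* of range area — the
reversion strength θ rises with condition while the step noise is rescaled
to hold the stationary spread fixed, so intensity of use rises with
condition at constant range size. That separation is exactly what the
IU-condition contrast needs; no claim is made that real bushbuck movement
is OU.

**Calibration of effect sizes.** The source design gives no quantitative
effect sizes for the condition mechanisms, so defaults were calibrated once
to produce *detectable* effects at n = 15 — not to match any real system —
and then frozen: β0 = 2, β1 = 2, Dirichlet concentration 60, movement
θ0 = 0.35 with condition slope 0.3 (clamped to [0.05, 0.9]), range SD
0.35 km, landscape bandwidth 1.6 km with 4 kernel centers per taxon. On
100 independent replicate worlds the full pipeline recovers a negative
richness–condition slope, a positive IU–condition slope, and a significant
positive population Mantel (diet vs centroid distance) in well over 90% of
worlds each (the acceptance suite re-verifies this), while null worlds
(β1 = 0, movement decoupled) reject at roughly the nominal 5%.

**What it does not emulate** — and hence what a green test does not
establish: amplification bias and chloroplast-density variation in RRA;
taxonomic misassignment; temporal autocorrelation in diets; seasonal
change; irregular fix schedules or GPS error; a realistic taxon pool size
(60 synthetic taxa, so population-level richness saturates the pool,
unlike a real trnL reference library); and any geodesy (planar km
throughout — appropriate for a ~10 km study area, wrong for large ones).

## 6. Degenerate inputs and numerical conventions

Zero-variance distance triangles make Mantel r undefined (error, not NA).
All-zero abundance rows are an error naming the row. Samples with all-zero
counts after filtering are dropped with a warning. Collinear fixes give a
zero-area hull (error). Empty habitat strata in the pipeline mark their
report sections "not applicable" instead of aborting. Compositions are
validated to sum to 1 within 1e-9; distance matrices to be symmetric and
hollow within 1e-8. All stochastic operations take explicit seeds and
derive a private stream via `op_seed(seed, op_name)`.

## 7. Known limitations

- The blocked-permutation convention (term + strata) is one defensible
  reading; `adonis2`-style strata-only analysis is available via
  `block_term = FALSE`.
- NMDS is for plots; its stress is not compared across datasets.
- The CSV loader reorders taxa columns lexicographically, so
  file-round-tripped analyses can differ from in-memory ones in the last
  decimals of bootstrap quantities (the RNG consumes taxa in column
  order); all tests that compare the two use tolerances accordingly.
- Intensity of use in km⁻³ is scale-covariant; absolute values are not
  comparable across studies using meters.
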