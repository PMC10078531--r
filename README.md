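# dietscape

Individual dietary niche variation in GPS-collared herbivores, from diet DNA
metabarcoding read tables and movement tracks.

## The problem

Many consumer populations are made of relatively specialized individuals that
eat only a subset of the population's diet. Quantifying that variation in a
wild browser takes three data streams that rarely meet in one toolchain:

1. **Diet** — trnL-P6 style metabarcoding of repeated fecal samples per
   individual, delivered as per-PCR-replicate read-count tables over plant
   mOTUs (molecular operational taxonomic units);
2. **Space use** — hourly GPS fixes per individual, summarized as minimum
   convex polygon (MCP) home ranges, centroid distances, and an
   intensity-of-use index;
3. **Environment** — classified LiDAR point clouds giving each home range a
   vegetation-structure profile, plus per-taxon digestible protein (DP) as a
   forage-quality trait.

`dietscape` implements the full post-bioinformatic analysis connecting them,
for ecologists asking *why* individual diets differ: spatial heterogeneity
(do nearby animals eat more similar diets?) and state-dependent foraging
(do animals in better nutritional condition search harder for fewer,
higher-quality foods?).

## What it computes

**Diet tables.** PCR replicates are averaged per sample; mOTUs below 1% of a
sample's reads are removed (strict `<`); samples are rarefied without
replacement to a common depth (7000 reads); relative read abundance (RRA)
and occurrence profiles follow.

**Standardized diets.** Sampling effort is unequal (6–14 samples per
animal), so each individual's diet is standardized by bootstrap: each of
B = 1000 iterations draws k = 6 samples without replacement and records the
mean RRA vector and its taxon count. Dietary richness is the mean ± SD of
the per-iteration counts; the exact species-accumulation curve

    E[S_j] = sum_i ( 1 - C(N - f_i, j) / C(N, j) )

(f_i = number of samples containing taxon i) gives the deterministic
benchmark. Diet quality is the RRA-weighted mean DP of the standardized
diet, renormalized over taxa with DP data.

**Space use.** Percent MCPs (95%/100%) retain the `ceiling(level * n)` fixes
nearest the arithmetic-mean centroid; area is by the shoelace formula.
Intensity of use is `path length / (100% MCP area)^2` over a 21-day window.
An individual is floodplain-associated if its 95% MCP overlaps the treeless
floodplain polygon. LiDAR heights are binned into ground / low (< 0.3 m) /
medium (0.3–1.6 m) / high (> 1.6 m) proportions.

**Statistics** (all implemented in the package; vegan is used only as a test
oracle): Bray–Curtis dissimilarity; perMANOVA with a year block (fitted as
the first sequential term *and* used as permutation strata) and pairwise
contrasts under Holm–Bonferroni; Mantel tests; NMDS; OLS with AICc ranking
and Akaike weights over the seven standard candidate models; Welch's t; and
a PCA-based nutritional condition index. Permutation p-values use the
plus-one rule with 9999 permutations by default.

**Synthetic worlds.** `simulate_world()` generates a two-habitat landscape
(kernel-mixture plant availability with distance decay, floodplain taxa
richer in DP), individuals with condition-dependent selectivity
(`diet weight ∝ availability × DP^(β0 + β1·condition)`), mean-reverting
movement whose path length rises with condition at fixed range size,
triplicate-PCR multinomial read noise, sub-1% contaminant mOTUs, and
habitat-driven LiDAR clouds — so every pipeline stage can be validated by
parameter recovery against known truth.

## Worked example

```r
library(dietscape)

world  <- simulate_world(seed = 1)                       # 15 individuals, 2 habitats
bundle <- run_pipeline(world = world,
                       config = list(B = 500L, n_perm = 999L, seed = 1))
cat(report(bundle)$markdown)
```

Selected lines of the output (computed by the code above):

```
Individuals analyzed: 15 (7 floodplain, 8 woodland); seed 1; 999 permutations; k = 6, B = 500.
- population: pseudo-F(14, 117) = 19.82, R2 = 0.65, p = 0.001 (999 perms)
- pairwise contrasts: 44 of 105 significant at Holm-adjusted p < 0.05
- diet ~ centroid distance: population r = 0.787, p = 0.001; ...
- dietary richness ~ condition: slope = -4.651, p = 0.04753, R2 = 0.27
single-sample mean richness 23.2 vs standardized 37.9 (Welch t = -6.09, df = 20.8, p = 4.93e-06)
```

Reading: individual identity explains 65% of diet dissimilarity after the
year block; diets diverge with distance between home-range centroids
(Mantel r = 0.79); better-condition animals eat fewer taxa (negative
richness slope — the generator's built-in state-dependent selectivity,
recovered); and a single fecal sample captures well under the longitudinal
richness estimate. The 15-individual design always yields 105 pairwise
contrasts.

## Files and CLI

`write_world(world, dir)` emits `reads.csv`, `gps.csv`, `lidar.csv`,
`traits.csv`, `animals.csv`, `samples.csv`, `truth.json`;
`run_pipeline(data_dir = dir, config = read_config("cfg.yaml"))` consumes
the same layout for user-supplied data. A thin CLI lives at
`inst/cli/dietscape.R`:

```sh
Rscript inst/cli/dietscape.R simulate --seed 1 --out world/
Rscript inst/cli/dietscape.R run --data world/ --out results/
```

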