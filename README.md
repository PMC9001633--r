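# divscape

Comparative-phylogenetics toolkit for asking where and how a clade
diversified: which regions concentrate species richness and old or young
lineages, and whether climate niches evolved (or were conserved) along the
way. It is aimed at macroecologists and phylogeneticists working with a
dated species-level tree, point occurrences, and gridded climate layers —
the standard ingredients of diversification-and-niche studies on groups
such as tropical amphibian radiations spanning mainlands and islands.

## What it computes

**Tip speciation rates.** The equal-splits measure for tip *i* is

    ES_i = sum_{j=1..N_i} l_j * 2^-(j-1)

with *l₁* the terminal branch and deeper branches discounted by halving
along the root-to-tip path; the DR statistic is `DR_i = 1/ES_i`
(Myr⁻¹). Species age (SA) is the terminal branch length. Species are
ranked by DR into quartiles (Q1 = oldest, least diverse lineages; Q4 =
youngest, fastest-diversifying).

**Gridded diversity and endemism.** Occurrences become a presence–absence
matrix (PAM) on a half-open 0.5° grid. Per cell: species richness SR,
Faith's PD (root path included, so a cell with every species has PD equal
to the tree's total branch length), quartile-richness residuals from an
OLS fit of quartile richness on total richness, and phylogenetic
endemism `PE(cell) = Σ_b l_b / |range(b)|` over branches present in the
cell. CANAPE compares PE on the observed tree and on an
equal-branch-length comparison tree against curveball-randomized PAMs
(fixed row and column sums) and labels significant cells neo / paleo /
mixed, with a super flag at the stricter level.

**Climate niches and their evolution.** Per-species climate means feed a
correlation-matrix PCA with broken-stick axis retention; time-sliced
layers yield relative climate-stability surfaces. Niche evolution is
modelled by Brownian motion: ML σ² and root state via Felsenstein
pruning, GLS ancestral states and traitgrams, disparity-through-time with
a resampled null envelope and the MDI statistic, equal-rates Mk fitting
and stochastic character mapping, multi-rate BM over painted trees
(state-specific σ² accumulated along branch segments) compared to the
single-rate model by AICc with Akaike-weight model averaging, and the
ES-sim test correlating a tip trait with log DR against a
Brownian-simulation null.

**Synthetic data.** Seeded generators for birth–death trees, BM/Mk
traits, gradient-plus-noise climate landscapes, and niche-driven
occurrences (65% single-record "point endemics" by default), bundled as
four scenario fixtures with known truth.

## Worked example

```r
library(divscape)
library(dplyr)

scen  <- scenario_fixture("two_rate_niche", seed = 11)  # island lineages evolve niches 10x faster
rates <- equal_splits_dr(scen$tree) |> left_join(species_age(scen$tree), by = "species")
head(rates, 4)
#>   species    es     dr  rank quartile   age
#> 1 t1       25.8 0.0388     2        1  9.28
#> 2 t2       14.0 0.0716    26        2  2.16
#> 3 t3       14.0 0.0716    27        2  2.16
#> 4 t4       14.1 0.0712    24        1  7.35
```

`t1` sits on a long, isolated branch (ES ≈ 26 Myr of discounted path), so
its speciation rate DR ≈ 0.04 Myr⁻¹ lands in quartile 1 — an old,
species-poor lineage; `t2` and `t3` are a recent cherry with triple the
rate.

```r
pam <- build_pam(scen$occurrences, scen$grid)
canape_classify(pam, scen$tree, n_reps = 999, seed = 11) |> count(endemism_type)
#>   endemism_type       n
#> 1 mixed              16
#> 2 neo                 1
#> 3 not_significant   153
#> 4 paleo               4
```

Of 174 occupied cells, 21 carry significantly concentrated branch
length; four are paleo-endemic (unusually long branches restricted
there), one neo-endemic.

```r
niche  <- setNames(scen$traits$niche,  scen$traits$species)
island <- setNames(scen$traits$island, scen$traits$species)
maps   <- stochastic_map(scen$tree, island, n_maps = 10, seed = 11)
multirate_bm(maps, niche)
#> <multirate_bm> 10 map(s), 100 tips
#>   single-rate sigma2 = 0.426221 (AICc 425.904)
#>   mean Akaike weight of multi-rate model: 0.631
#>   state    sigma2_ml sigma2_averaged
#> 1 island       0.464           0.450
#> 2 mainland     0.153           0.250

essim(scen$tree, niche, n_sim = 100, seed = 11)
#> <essim_result> rho = -0.3135, p = 0.07921 (100 null simulations, 100 tips)
```

Averaged over ten stochastic maps of the island/mainland history, the
two-rate model carries most of the AICc weight and recovers a faster
island rate (ML 0.46 vs 0.15; model averaging shrinks the contrast
toward the single-rate fit where the weight is equivocal). ES-sim finds
no significant niche–speciation-rate coupling on this realization
(p ≈ 0.08).

Every result has `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
graphics; `run_pipeline()` drives the whole chain from a YAML config and
writes per-stage CSVs plus a JSON manifest.

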