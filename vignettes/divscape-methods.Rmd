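---
title: "Models and methods in divscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in divscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

divscape connects three layers of comparative analysis — tip-level
diversification rates, their geography, and the evolution of climate
niches — on a dated, binary, ultrametric species tree. This vignette
explains the models, the conventions and tunable parameters, the design
choices made where the design was genuinely open, and what the bundled
synthetic data can and cannot tell you about real data.

## Trees and time

Time runs from the root (depth 0) toward the present; reported "ages"
are crown age minus depth, in Myr. Trees must be binary with branch
lengths on every edge; polytomies are either rejected or, on request,
resolved into zero-length binary splits — a transformation that leaves
every likelihood in the package unchanged while satisfying the binary
bookkeeping that contrasts and equal-splits weights assume.
Ultrametricity is checked with a *relative* tolerance, by default 1e-6
of the crown age, because dating software emits tip depths that agree
only to numerical jitter. Functions that are meaningful on non-ultrametric
trees expose `check_ultrametric = FALSE`.

## Tip rates

The equal-splits measure discounts each branch on the root-to-tip path
by successive halving, terminal branch first; DR is its inverse. DR is
deliberately non-model-based: it is a summary of branching density near
the tip, high inside young radiations and low on long isolated branches.
Quartiles are assigned on species *ranks* of DR (ties broken by species
name so output is reproducible), which makes the assignment invariant to
monotone transforms — whether one quartiles raw or log DR is therefore
immaterial, and raw DR is used. Quartile sizes differ by at most one.

## Grids, PD, and endemism

Grid cells are half-open `[x, x+s) × [y, y+s)` intervals anchored at the
south-west corner (default s = 0.5°), so boundary points belong to
exactly one cell; points on the north/east outer boundary are dropped
with a warning. PAM construction is point-based; range polygons are out
of scope.

Faith's PD includes the path to the root. The package prefers this
convention because it yields the conservation identity used throughout:
a cell holding all species has PD equal to the tree's total branch
length, and summed over cells the phylogenetic-endemism surface
reconstitutes that same total exactly (the PD and PE code share one
branch-incidence computation, so the identity is structural, not
numerical). Quartile residual regressions use only occupied cells —
with empty ocean cells included, the intercept would be fit to zeros and
every occupied cell would look like a hotspot.

CANAPE follows the canonical two-step classification. Significance:
a cell is flagged when its observed-tree PE *or* its comparison-tree PE
(same topology, all branches set to the mean length) exceeds the
one-tailed `1 - alpha` quantile of `n_reps` curveball randomizations
(fixed row and column sums — the null preserves both each species'
prevalence and each cell's richness). Categorisation among flagged
cells: relative PE (observed / comparison) in the upper `alpha/2` tail
is paleo, lower tail neo, otherwise mixed; cells whose two PE values
both clear `1 - super_alpha` carry the super flag. Defaults
`alpha = 0.05`, `super_alpha = 0.01`, `n_reps = 999` are the method's
canonical values and are config-exposed. P-values are rank-based with
the +1 correction, so the smallest attainable p is `1/(n_reps + 1)`;
resolving the `alpha/2` RPE tails therefore *requires* enough
replicates (999 comfortably resolves 0.025; 199 sits on the boundary
and will push borderline cells into "mixed").

A property worth knowing: because the significance step is a union of
two level-`alpha` tests that are far from perfectly correlated under
the fixed-margins null, the fraction of cells flagged on null data is
between `alpha` and `2*alpha` (empirically ≈ 0.10 at `alpha = 0.05`),
even though each constituent test is individually calibrated. This is a
property of the published classification rule, not of this
implementation; the per-test p-values are all reported so users can
apply a single-test reading if they prefer.

Null draws are taken along a single curveball chain thinned by
`n_swaps` trades (default 1000) after an equal burn-in. For the
desk-scale matrices the package targets (hundreds of cells, tens to
hundreds of species), mixing times are on the order of the number of
presences, so 1000 trades between samples is conservative.

## Climate niches

Per-species climate means average raster values at occurrence points;
points on no-data cells are excluded per variable, and duplicated
records deliberately weight the mean — point density is treated as
information, matching how opportunistic occurrence compilations are
used. Species lacking a valid extraction for any variable are dropped
(with a warning) so the climate matrix has no missing cells.

The PCA is of the variable *correlation* matrix (all variables
standardized), appropriate when mixing °C and mm units. Axis retention
uses the broken-stick rule: axis k is kept while its eigenvalue
proportion exceeds the expectation `b_k = (1/p) Σ_{i=k..p} 1/i`. Each
loading vector is oriented so its largest-magnitude element is positive;
this pins down the sign convention, which is otherwise
backend-dependent. Climate stability divides each consecutive-slice
absolute change by its time step before averaging (so unevenly spaced
paleo slices are handled), inverts with a guard
(`1/(deviation + 1e-9)`), rescales to a maximum of 1, and combines
variables multiplicatively; stability is thus invariant to adding a
constant to all slices, and the two-layer default (one temperature, one
precipitation variable) mirrors common practice.

## Niche evolution

Single-rate BM is fit by Felsenstein pruning: the contrast quadratic
form and log-determinant give `σ²_ML = Q/n` and the GLS root state in
O(n). Ancestral states are the GLS conditional means, so the root
reconstruction equals the fitted root state, and traitgrams connect
parent and child states in (time, trait) space.

Disparity-through-time uses mean squared pairwise Euclidean distance
(computable per clade from axis variances). At each branching time the
mean *relative* disparity of the lineages alive then is recorded — 1 at
the root by construction, 0 at the present where every lineage is a
single tip. The null resamples the curve from BM simulations at the ML
rate of each axis (multiple axes are simulated independently and their
disparities summed, matching the Euclidean treatment of the observed
data); the envelope is pointwise, default 95%, and MDI is the
trapezoidal signed area between the observed curve and the null median
in relative time. The default of 999 resamplings can be lowered for
exploration but envelopes below ~200 get visibly ragged.

The Mk model is restricted to equal rates (ER) with a uniform root
prior — the minimal choice when no transition structure is asserted —
and both binary island/mainland states and the four reproductive modes
route through the same machinery. The ER transition probability has a
closed form, and the 1-D likelihood is maximized by a deterministic
bounded search; a coarse log-grid scan brackets the optimum first,
because the profile flattens toward the high-rate plateau and a plain
golden-section search can stall there. Stochastic maps sample node
states from their conditional distributions and fill branch histories
by rejection sampling against the endpoint states (cap 1000 attempts
per branch), falling back to exact uniformization — for ER the
uniformized jump chain is uniform over states, which makes the
conditional event-count distribution available in closed form.

Multi-rate BM accumulates state-specific rates along painted branch
segments: the tip covariance is the state-time-weighted shared path
length. The root state and the overall rate scale are profiled
analytically, so only k−1 rate ratios are searched numerically; with a
single state the fit reduces *exactly* to single-rate BM. Models are
compared by AICc (n = number of tips, k = 2 vs 1 + number of states)
and Akaike weights; per-state rates are model-averaged and then
averaged across stochastic maps, which propagates mapping uncertainty
and characteristically shrinks rate contrasts toward the single-rate
estimate when the weight is equivocal. Beware degenerate designs: on
very small trees the multi-rate likelihood is unbounded (a state
observed on effectively one contrast can absorb all variance), a known
property of the model rather than of the optimizer.

ES-sim correlates a tip trait with log DR and simulates the trait under
BM at its ML rate on the same tree to build the null; the p-value is
two-tailed with the +1 correction. The default of 100 simulations keeps
exploratory runs fast, but its p-value granularity is 1/101 — use 999+
for publication-grade inference. A binary 0/1 trait is accepted with a
warning: simulating a binary trait under BM is conceptually strained,
and the option exists purely for comparability with that practice.

## Synthetic data and what the tests show

The generators emulate the statistical regime the pipeline assumes:
Yule/birth–death trees of desk scale (default 100 tips, speciation
0.09 Myr⁻¹, giving crown ages of tens of Myr), single- or multi-rate BM
niche traits (default σ² = 0.05 per Myr), ER Mk discrete traits,
temperature layers with a 15 °C latitudinal gradient plus smooth
elevation and noise fields, non-negative precipitation layers, and
occurrences scattered around niche centroids with 65% single-record
species. Centroid latitude is coupled to the niche trait (cool-adapted
species sit poleward), so the climate PCA has recoverable
temperature-dominated structure. The four fixtures encode known truths:
no structure (`null`), a 10× island niche-rate contrast
(`two_rate_niche`), a relict lineage twice the crown age old and
endemic to one cell (`paleo_island`), and mode-dependent niche rates
(`mode_shift`).

What passing tests demonstrate: the estimators agree with independent
oracles (brute-force path enumeration, dense multivariate-normal
algebra, exhaustive Mk sums, Fitch parsimony, picante and phytools),
conservation identities hold, null procedures are calibrated where the
theory says they should be, and constructed endemism signals are
recovered end to end. What they do not demonstrate: robustness to the
pathologies of real data — spatially biased sampling, polygon-derived
ranges, phylogenetic and dating uncertainty, correlated climate axes
with non-Gaussian evolution — none of which the generators emulate.
Problem sizes in the routine tests (trees of 100–500 tips, grids of
400 cells, 199–999 randomizations) were chosen as the scale at which
the statistical assertions stabilize; all replicate counts are
arguments, and the same code runs unchanged at larger sizes.

## Known limitations

* CANAPE's union significance step over-flags on null data by up to a
  factor of two relative to `alpha` (see above); interpret the overall
  significant fraction, not only per-cell categories.
* PAMs are dense cell × species matrices — appropriate for regional
  grids, wasteful for global 0.5° grids with narrow-ranged species.
* Multi-rate BM assumes the painting is known per map; uncertainty
  enters only through averaging across stochastic maps.
* The Mk machinery is ER-only by design; asymmetric transition models
  would need a generalized pruning and mapping layer.
* Posterior tree sets are handled by looping the same pipeline; no
  joint integration across topologies is attempted.
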