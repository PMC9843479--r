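---
title: "Methods: community structure metrics, nulls, signal tests, spatial models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community structure metrics, nulls, signal tests, spatial models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commstruct)
```

This vignette documents the models implemented by `commstruct`, the choices
that were genuinely open when the package was designed, and what the
synthetic-data tests do and do not establish. No empirical number is stated
here that the test suite or `scripts/acceptance.R` does not itself compute.

## Diversity indices

**SR** is the row sum of the site × species incidence matrix. **PD** (Faith)
is the branch-length sum of the smallest subtree spanning a site's species;
an edge belongs to that subtree iff at least one present species descends
through it (with the root path) or iff present species occur both below and
not below it (without). Whether the root path counts is a genuine convention
split in the literature; `include_root = TRUE` is the default, under which a
single-species site gets its tip's root-path depth rather than zero, and the
flag is exposed because field studies rarely state their choice. **FD** is
the same computation on the functional dendrogram. **MPD/MFD** are unweighted
means over unordered pairs of present species; sites with fewer than two
species are reported `NA` with a warning rather than aborting a batch —
surveys do contain near-empty sites.

## Gower distance and the functional dendrogram

For mixed traits, `d(i,j) = Σ w_k δ_k / Σ w_k`, with range-normalized
absolute differences for continuous columns and symmetric mismatch for
binary columns (0/0 counts as agreement: shared absence of a diet or nest
category is informative for birds, unlike, say, species occurrence data
where Jaccard-style asymmetry would be right). The default gives every
column equal weight — so a categorical family expanded into many indicator
columns weighs more than one continuous trait. That reading of "same weight
to different types of variables" is ambiguous, so `weights = "group"`
alternatively downweights each family to total weight 1; the choice
materially affects FD and is the first thing to vary in a sensitivity
analysis. Traits are not log-transformed by default (`log_continuous` flag
available).

UPGMA merges the closest pair at height d/2 (cophenetic distance on the
dendrogram then equals the merge dissimilarity) with size-weighted average
linkage. Ties are broken by the lowest (row, column) index pair in current
label order; this affects topology on tied data — common with coarse binary
traits — and is therefore fixed rather than platform-dependent.

## Nulls and standardized effect sizes

The default null (`taxa_labels`) shuffles species labels on the distance
matrix, preserving each site's richness and the distance distribution — the
standard null for SES of MPD; `richness_random` (uniform draws of SR species
per site) is provided as an alternative. The published formula this package
follows prints a −1 factor in front of (obs − mean)/sd, yet interprets
SES < 0 as clustered and SES > 0 as dispersed, which only holds for the
un-negated quantity; the two conventions (plain `ses` vs negated `nri`)
contradict each other in that source. The default is `ses`, consistent with
the interpretation rule; `nri` gives the literal negated formula. Rank
p-values use the add-one correction with mid-rank tie handling, so p is
never exactly 0 or 1 and an observation equal to every replicate sits near
0.5. Two-sided significance at α = .05 is p < .025 or p > .975.

## Phylogenetic signal

**Blomberg's K** is the observed MSE0/MSE ratio (mean squared error about
the phylogenetically corrected mean over the GLS error under the Brownian
covariance C) divided by its Brownian expectation, computed exactly as
`(tr(C) − n / Σ C⁻¹) / (n − 1)` rather than by simulation — exact and fast
at n = 164. The permutation test shuffles trait values across tips
(999 permutations by default; replicate counts are a package default, as the
motivating study does not state its own).

**Fritz–Purvis D** scores the observed sum of sister-clade state changes
(nodal values as unweighted daughter means) between two prevalence-
preserving references: random shuffles and a threshold-Brownian model in
which a Brownian liability is cut at the minority-state count. Using the
minority count makes D exactly invariant to relabeling 0 ↔ 1 (the change
sum is invariant under set complement). Conservatism is flagged when D < 0
with p < .05 against the random reference.

## Spatial regression

Weights are the main unreported modelling choice in studies of this type and
the main reproducibility risk for their regression tables. The package
default is row-standardized inverse distance on great-circle km; k-nearest-
neighbour weights are provided for sensitivity analysis. Moran's I uses the
normal-approximation variance (permutation p optional). The SAR is the
spatial-**error** variant (not the lag model), fitted by profile maximum
likelihood with `ln|I − λW| = Σ ln(1 − λω_i)` from the eigenvalues of W
(computed via the symmetric similar matrix when W is a row-standardized
symmetric base); AIC = 2k − 2 logL with k = #β + 2 (λ, σ²). Residuals for
the Moran check are the spatially filtered innovations `(I − λW)(y − Xβ)`.
Published tables of this kind sometimes print "standardized" OLS
coefficients larger than 1 (impossible for a fully standardized bivariate
slope, which equals Pearson's r), so both scalings are emitted: `coef_ols`
(both variables z-scored) and `coef_xstd` (predictor-only standardized).

## Piecewise SEM

One linear model per endogenous node on z-scored variables; the d-separation
basis set contains one claim per non-adjacent pair, conditioned on the union
of both nodes' parents, with the topologically later node as the regression
response (the basis-set definition leaves the orientation open; this choice
makes every claim testable as a partial coefficient). Fisher's
C = −2 Σ ln p is referred to χ² with 2k df. Component models are ordinary,
not spatial, least squares — a documented limitation matching common
practice. A default habitat DAG (nine exogenous factors plus an
`Altitude.HD → Plant.ric → response` indirect route) ships as a plausible,
fully overridable stand-in; it is not a claim about any particular study's
topology, which is typically published only as a figure.

## The synthetic world

The generator mirrors the motivating study's scale: a 164-species Yule pool
(birth rate 1), 37 sites, site richness 30–91, 6 continuous + 20 binary
traits, 12 habitat covariates on plateau-plausible scales with
`Altitude.HD = Altitude.max − Altitude.min` exact. Continuous traits evolve
by Brownian motion; binary traits threshold an independent liability at its
median (prevalence 0.5). Assembly processes:

* *random* — uniform draws (the null-calibration world);
* *filtering* — focal species per site, co-members sampled with probability
  `exp(−strength · d / mean d)`; strength 10 is the "strong" demonstration
  value, producing unambiguous clustering (site-mean SESmpd far below −0.5);
* *competition* — iterative uniform draws rejecting candidates within
  `strength ×` (mean nearest-neighbour patristic distance) of any current
  member, with site-level restarts because a greedy no-backtracking draw can
  dead-end even when a valid assemblage exists.

Two generator design points deserve honesty. First, the exclusion threshold
is scaled by nearest-neighbour distance, not by a pairwise-distance
quantile: on Yule trees pairwise distances pile up near twice the tree
height, so even low quantiles are infeasibly deep thresholds. Second,
dispersion detectable by SESmpd under pairwise exclusion is intrinsically
weak: the feasible exclusion radius is capped by the pool's conflict-graph
independence number, and MPD is dominated by the bulk of deep distances, so
on a 164-species pool the attainable site-mean SESmpd stays near +0.3–0.4 at
any feasible strength (nearest-taxon metrics would be more sensitive, but
are out of scope). The "strong competition" demonstration world is therefore
a denser, guild-like 64-species pool with richness 8–16 and strength 2.5 —
near the sampler's feasibility limit, where mean SESmpd reliably exceeds
+0.5; at that strength some pool trees are infeasible, in which case the
generator errors with advice rather than silently weakening the process.
Competition also caps attainable richness — that is the biology of
exclusion, not a shortcut.

Spatially autocorrelated responses use `u = (I − λW)⁻¹ε` on the weights of
the generated coordinates, by default k = 8 nearest neighbours: dense
inverse-distance weights on uniformly scattered points act almost like a
global mean shift and leave λ weakly identified, whereas neighbourhood
weights carry local structure that maximum likelihood recovers (the
acceptance run at true λ = 0.7, β = 0.5 recovers both within the stated
bands). Recovery of β is scored on the generator's scale — raw response,
z-scored predictor — because the spatial error inflates var(y), so
re-standardizing y would shrink the target.

What a green suite establishes: the metrics match brute-force oracles on
small instances; the nulls, permutation tests and Fisher's C have correct
size on data generated under their own assumptions; and known assembly and
spatial parameters are recovered at realistic scale. What it does not
establish: behaviour under the features real survey data add — detection
error, abundance structure, non-Brownian trait evolution, range cohesion, or
habitat-driven covariance between traits and space.

## Numerical choices and degenerate inputs

Zero-length branches are accepted (pruning creates them); negative lengths
are rejected. Zero-range continuous trait columns are an error, never a
silent drop. Sites with SR < 2 yield `NA` MPD with a warning; zero null SD
yields `NA` SES with the rank p still reported. Coincident sites make
inverse-distance weights undefined (error advising jitter or knn). The MCC
summarizer selects among sample members only — never a consensus topology —
and annotates mean per-clade heights, clamping the occasional negative
branch that mean heights imply (the familiar TreeAnnotator artefact) to zero
with a warning. All generators save and restore the caller's RNG state, and
every pipeline stage derives its seed deterministically from one master
seed, so reruns are byte-identical.
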