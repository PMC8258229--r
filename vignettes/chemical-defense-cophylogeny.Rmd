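---
title: "Methods: herbivore assemblages, host chemistry and cophylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: herbivore assemblages, host chemistry and cophylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Herbivorous insects are constrained in host choice by plant chemical
defenses. Two competing structures could therefore explain why two plant
families share many of the same herbivore species: the families are close
relatives (phylogenetic conservatism of host use), or they deploy similar
secondary-metabolite defenses regardless of relatedness (chemical
convergence of host use). `chemcophy` implements a complete pipeline for
separating these signals in a bipartite herbivore x plant-family network:

1. **Defensogram construction** — cluster plant families on their binary
   secondary-metabolite profiles, selecting the clustering algorithm by an
   explicit criterion.
2. **Mantel matrix correlations** — does assemblage overlap between plant
   families track chemical dissimilarity or phylogenetic distance?
3. **PACo** — Procrustean global congruence of the two phylogenies (or of
   one phylogeny and the defensogram) through the observed links, with a
   margin-preserving permutation null.
4. **Random Tanglegram Partitions** — a per-link view of congruence with a
   global inequality statistic G*.

A synthetic-data module generates every input the pipeline needs under
known conditions, so all statistical behavior is verifiable without any
external data set.

## Data model

- **Trees** are `ape::phylo` objects; branch lengths are ages (for input
  phylogenies, typically millions of years) or dissimilarity units (for
  defensograms). Leaf labels must be unique; negative branch lengths are
  rejected, zero lengths allowed.
- **Trait matrices** (`trait_matrix`) are strictly binary family x trait
  tables; each trait carries a chemotaxonomic hierarchy entry
  (group / type / class / optional subclass), e.g. phenolic / flavonoid /
  flavonol / flavonol glycoside. `aggregate_traits()` condenses the traits
  to class-level diversity counts (the source table for heatmap figures);
  row sums are conserved by construction.
- **Interaction networks** (`interaction_network`) are deduplicated link
  sets with a herbivore taxonomy table (family, subfamily) used to define
  assemblage subsets.
- **Distance matrices** are plain labeled symmetric matrices with zero
  diagonals, validated by `as_distmatrix()`.

Label matching is exact (after trimming whitespace) and case-sensitive:
taxonomic reconciliation is data curation, not statistics, and belongs
upstream of this package.

### Filtering and subsetting

`filter_network()` applies the canonical preprocessing: plant families
without chemical data are removed, then herbivores left with no hosts.
The report records both dropped sets. Note the rule is exactly this and
nothing more; if an external data set was curated with additional,
unstated exclusions, counts can differ and the discrepancy should be
reported rather than papered over. "Monocot removal" (for dicot-only
analyses) is an explicit plant-family list, defaulting to
Poaceae / Cyperaceae / Juncaceae; published analyses are not always
consistent about which grasses-and-allies list was used, so the list is a
parameter, not a constant.

## Dissimilarities

All three matrices of the correlation analysis use deliberately simple,
unnormalized measures:

- **Chemical**: Manhattan distance on the raw 0/1 trait matrix — the
  number of traits present in exactly one of the two families.
- **Assemblage**: Manhattan distance between the rows of the binary
  family x herbivore incidence matrix — the number of herbivore species
  feeding on exactly one of the two families.
- **Phylogenetic**: patristic (cophenetic) distance on the host tree.

Keeping the Manhattan index unnormalized makes reported correlation
values well-defined and reproducible; the choice of index is a
configuration decision here, not an inference step.

## Defensograms and algorithm selection

`select_algorithm()` runs the eight classical Lance-Williams
agglomerations (single, complete, UPGMA, WPGMA, UPGMC, WPGMC, Ward.D,
Ward.D2 — delegated to `stats::hclust`) plus BIONJ, and scores each by
the Pearson correlation between the condensed source distances and the
condensed cophenetic (or patristic, for BIONJ) distances of the result.
The selected algorithm is the argmax: the dendrogram that retains the
most of the original chemical variation. On genuinely ultrametric input
UPGMA attains r = 1; on additive but non-ultrametric input BIONJ attains
r = 1 — both are enforced as tests.

BIONJ is implemented in the package in double precision (Q-criterion
pair selection, two-point branch-length formulas, variance-weighted
matrix reduction). Negative estimated branch lengths, which can occur on
non-additive input, are clamped to zero with a message. Ties in merge
order are resolved by the deterministic behavior of `hclust` and of the
first-minimum scan in BIONJ, so reports are reproducible. For display,
`export_defensogram()` midpoint-roots the unrooted BIONJ tree; all
statistics use unrooted patristic distances.

A note on reporting: correlation here is the coefficient r on condensed
triangles (some published tables label such columns R² while printing
values consistent with r; we compute and report r).

## Mantel tests

`mantel_test()` uses the Pearson correlation of condensed triangles and
a one-tailed (greater) permutation null that jointly permutes rows and
columns of the second matrix; `p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)`.
The default `n_perm = 9999` resolves p-values to the 1e-4 scale. Monte
Carlo p-values converge to the exhaustive enumeration value (tested
against all 120 permutations at n = 5), and the null p distribution is
approximately uniform on independent random matrices.

`run_mantel_suite()` assembles the report over subsets: the total
network, each (sufficiently large) herbivore family, and optionally the
network with listed plant families excluded. Subsets with fewer than 4
plant families are flagged and skipped, since a 3-object Mantel
correlation is meaningless.

## PACo

`paco_fit()` embeds both distance matrices by principal coordinates and
measures congruence after Procrustes superimposition of the two
link-expanded coordinate sets (each taxon's row repeated once per link).

- **Cailliez correction** (default): Manhattan and cophenetic matrices
  are usually non-Euclidean; the smallest additive constant making the
  off-diagonal distances Euclidean is computed from the classical
  2n x 2n eigenproblem, so no axes are discarded. `correction = "none"`
  drops negative-eigenvalue axes with a warning instead.
- **Symmetric mode** (default): both configurations are centered and
  scaled to unit trace before the optimal rotation, so neither party is
  declared the evolutionary driver a priori; `m2_xy = 1 - (sum of
  singular values)^2` is the residual sum of squares, decomposable into
  per-link squared residuals that sum to m2 exactly. The asymmetric
  (host-driven) variant is retained as an option.
- **Null model**: `n_perm` randomizations of the binary link matrix that
  preserve every species' interaction count exactly (see below);
  `p = (#{m2_perm <= m2_obs} + 1) / (n_perm + 1)`. Identical trees joined
  1:1 give m2 = 0 and the minimal attainable p.

### The quasiswap null, made uniform

The fixed-fixed null ("quasiswap") must sample uniformly from all binary
matrices with the observed margins. The common fill-and-repair
construction is measurably biased on small matrices — enumerating a
3 x 3 margin class and drawing 1e5 matrices rejects uniformity
catastrophically. `quasiswap_matrix()` therefore uses the checkerboard
*trial-swap* chain (via `vegan`'s `"tswap"` null model) with a long
burn-in and draws thinned proportionally to the number of presences: the
chain is symmetric, so its stationary distribution is uniform, and the
same enumeration test passes. Burn-in and thinning default to
`100 * sum(B)` and `2 * sum(B)` swap attempts.

## Random TaPas and G*

`random_tapas()` repeatedly (default `N = 10000`) samples one-to-one
subsets of `n` links (no shared endpoints; drawn by uniform shuffling
with greedy acceptance and rejection-retry), evaluates the PACo `m2` of
each partial tanglegram on the trimmed, re-embedded distance matrices,
and keeps the best `percentile` (default the top 1%). The feasible
maximum for `n` is the maximum bipartite matching (`max_one2one()`,
exact); `n = "auto"` takes 20% of the links capped by that maximum,
following the convention that subsamples should span 10-20% of the
links.

Each network link is then scored by its frequency among the kept
subsets. Links attached to taxa with many partners are intrinsically
sampled less often, so raw counts are corrected by their expectation
under random keeping: `percentile` times the link's occurrence across
all `N` subsamples. The global statistic G* is a normalized Gini
coefficient of these corrected frequencies, using the
Raffinetti-Siletti-Vernizzi form that accommodates signed values:
`G* = mean |r_i - r_j| / (2 * mean |r|) * k/(k-1)`, and 0 when all
residuals vanish.

Calibration properties (all enforced as tests):

- If the kept subsets are effectively a random draw — no cophylogenetic
  signal — the corrected frequencies are symmetric around zero and G*
  sits near 2/3 (exactly 2/3 for uniform residuals, ~0.71 for Gaussian).
  Simulated random multi-link networks give a mean G* of about 0.70.
- With increasing cospeciation the congruent links dominate the kept
  subsets uniformly and G* falls; with none it rises. Across synthetic
  tanglegrams with cospeciation 1.0 / 0.5 / 0.0, mean G* (and mean PACo
  m2) increases strictly as cospeciation decreases.
- A raw-count Gini (the exported primitive `gini_star()`, kept for
  direct use on nonnegative frequency vectors) does *not* have the 2/3
  null and responds in the opposite direction on multi-link networks,
  because raw frequencies conflate fit with degree structure; this is
  why the corrected-residual form is the network statistic.

The per-link "frequency residuals" exported for tanglegram coloring are
the corrected frequencies z-scored (sum zero, diverging around 0); raw
and expected frequencies are exported too, so any other rescaling can be
applied downstream.

G* depends visibly on `percentile` and `N`; both are always reported in
the result object and should be quoted alongside any G* value.

## The synthetic-data generator

The generator produces data with the statistical structure the pipeline
assumes, under known, tunable conditions:

- `simulate_tree()`: pure-birth (Yule) trees, rescaled to unit depth.
- `simulate_tanglegram(host, c, lambda)`: the herbivore tree is a copy of
  the host tree whose leaf labels undergo `floor((1 - c) * n)` random
  pairwise swaps — `c = 1` is a perfectly congruent mirror, `c = 0` a
  heavily shuffled one. Label swaps (rather than subtree regrafts) keep
  the branch-length distribution fixed while destroying congruence
  monotonically in expectation; that is all the congruence statistics
  need, and it is cheap and exactly reproducible. Multi-host herbivores
  gain Poisson(`lambda`) extra links to random additional families.
  Links are drawn *before* the swaps, so a fixed seed yields the same
  link set across `c` values with nested swap sequences — comparisons
  across `c` at equal seeds are paired, which the monotonicity tests
  exploit. Note the swap count saturates: beyond roughly half the
  leaves swapped, additional swaps change congruence little, so the
  response flattens between c = 0.5 and c = 0.
- `simulate_traits(tree, n_traits, mu, rho)`: a fraction `1 - rho` of
  traits evolves by a symmetric two-state Markov process (flip
  probability `(1 - exp(-2 mu t))/2` per branch); the convergent
  fraction `rho` is generated from tree-independent "defense syndromes":
  families are partitioned into `n_syndromes` (default 6) random groups
  and each convergent trait is present in a random half of the groups,
  with 5% per-cell flip noise. Syndromes — suites of defense traits
  shared by unrelated families — are the biologically meaningful form of
  convergence and give the chemical distance matrix cluster structure
  that is decoupled from the phylogeny. (Independent random blocks per
  trait produce a noise-like distance matrix whose structure no
  assemblage statistic can recover; with syndromes, chemically driven
  assemblages are recovered in essentially every run.)
- `simulate_assemblage(..., driver, beta)`: each herbivore receives a
  focal family (balanced assignment: focal counts differ by at most one,
  so family degree reflects the driver rather than focal sampling noise)
  and links to each family with probability
  `exp(-(d - d_min)/beta)`, `d` the driver's distance from the focal
  family. Subtracting the minimal off-diagonal distance makes the kernel
  act on the distance *contrast* — binary-trait Manhattan distances have
  a large constant offset (any two families differ in many traits), and
  without the shift no bandwidth discriminates near from far hosts.
  `beta` defaults to the off-diagonal standard deviation.

What the generator does **not** emulate: real metabolite chemistry and
its hierarchical correlations, host-switch dating, abundance or
preference weights, sampling effort, and taxonomic error. Passing the
recovery tests therefore shows the statistics respond correctly to the
structures they target, not that any particular empirical data set is
clean.

## Numerical and design choices

- PCoA keeps eigenvalues above `1e-8` of the spectral radius; the
  Cailliez constant comes from the real eigenvalues of the standard
  block matrix.
- Procrustes configurations are padded with zero columns to a common
  dimension before rotation.
- Mantel/PACo p-values use the `+1` (observed-included) estimator, so
  `p >= 1/(n_perm + 1)` always.
- All stochastic functions take an explicit `seed` and are bit
  reproducible given it; the pipeline derives per-stage seeds from one
  master seed.
- Test problem sizes were chosen to exercise each property at desk
  scale: 200 null-calibration replicates at 99 permutations each,
  20 networks of 30 x 15 for the G* null with `N = 2000`, 20 paired
  replicates per cospeciation level, 50 runs per driver-recovery
  direction.

## Limitations

- The Mantel and PACo subsets share the same underlying network, so
  per-family results are not independent of the total.
- G* has no closed-form null distribution here; the 2/3 reference is an
  asymptotic argument and simulation result, not a test threshold with
  controlled error rates.
- The per-link residual scale is relative to the network at hand;
  residuals are not comparable across networks with different `n`, `N`
  or percentile.
- With heavily multi-host herbivores the one-to-one subsampling can only
  cover a small fraction of links per draw; frequencies then carry more
  sampling noise at fixed `N`.
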