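# keysteps

Do the discrete characters that taxonomists invent to *tell species apart*
behave well when conscripted for *phylogenetics*? `keysteps` quantifies one
side of that tension: it measures how fast each character evolves on a
reference phylogeny — as the minimum number of parsimony steps — and how
diagnostically useful the same character is in an interactive identification
key — as its rank under a "Best"-style evenness score — and correlates the
two. In the empirical system that motivates the package (a hyperdiverse
complex of Neotropical doryctine wasps keyed with ~47 discrete characters
over ~350 species), fast, homoplastic characters turn out to be the *most*
useful for identification, which is exactly why they should be treated with
caution in tree inference.

The package is aimed at systematists and methodologists who want to run this
analysis on their own matrix + tree, or to study the mechanism on simulated
data with known ground truth.

## What it computes

For a rooted tree `T` (polytomies allowed) and a taxon × character matrix
with missing (`?`) and polymorphic (`a/b`) cells:

* **Parsimony steps** `s`: the minimum number of state changes over all
  single-state assignments to internal nodes, via unit-cost dynamic
  programming (`cost[v,s] = Σ_c min_t (cost[c,t] + [s≠t])`), exact on
  arbitrary-arity trees — the Fitch count on binary trees, Hartigan's
  minimum on polytomies. Missing leaves are full wildcards.
* **Homoplasy indices**: minimum steps `m`, maximum steps `g`, consistency
  index `CI = m/s`, retention index `RI = (g−s)/(g−m)`; a character is
  homoplastic iff `CI < 1`.
* **Best score**: with `n_s` active taxa carrying state `s`, `u` unscored
  active taxa, and `N` active taxa, the expected retained fraction after one
  selection, `b = Σ_s (n_s/Σ_t n_t) · (n_s+u)/N`; lower = better. Rank 1 is
  the most useful character.
* **The correlation**: Spearman's ρ (mid-rank Pearson) between steps and
  Best rank, with two-tailed permutation p-values (exact `n ≤ 9`, seeded
  Monte-Carlo otherwise), overall and stratified by state count. Fast
  characters being most useful shows up as a **negative** ρ.
* **Simulators**: ultrametric Yule trees (unit height), jump-chain Mk
  characters with recorded true change counts, and partitioned 4-state
  alignments, so the whole pipeline can be validated against known rates.

## Worked example

Simulate a 100-taxon study with the default character composition (47
characters: 19 binary, 17 three-state, 8 four-state, 3 six-state; rates
log-uniform on [0.05, 5] changes per unit tree height; 2% missing cells) and
run the analysis:

```r
library(keysteps)
cfg <- sim_config(n_taxa = 100, seed = 42)
report <- run_study(cfg, n_perm = 10000)
report
#> study_report
#>   characters: 47 (matrix 100 taxa, tree 100 leaves)
#>   mean steps: 11.13; homoplastic: 34; invariant: 4
#>   steps vs Best rank: rho = -0.885, p = 9.999e-05, n = 43 (4 excluded)
#>   by state count:
#>     k = 2: n = 18, rho = -0.888, p = 0.0002
#>     k = 3: n = 14, rho = -0.889, p = 0.0003
#>     k = 4: n = 8, rho = -0.916, p = 0.003175
#>     k = 6: n = 3, not tested
```

Reading this: of 47 simulated characters, 34 are homoplastic on the tree
(CI < 1) and 4 never change at all; those 4 cannot be ranked and are
excluded, leaving n = 43 pairs. The correlation between a character's step
count and its Best rank is strongly negative (ρ = −0.885; permutation
p ≈ 10⁻⁴): characters that change state often are ranked most useful. The
relationship persists within each state-count class, so it is not an
artifact of state number; the 6-state stratum (3 characters) is below the
minimum stratum size and is reported untested.

Per-character detail sits in `report$per_character` (steps, CI, RI, Best
score and rank, and — for simulated data — the true rate and realized change
count):

```r
head(report$per_character[, c("char_id","k","steps","ci","best_score","rank","true_rate")], 3)
#>   char_id k steps         ci best_score rank  true_rate
#> 1       1 2    11 0.09090909  0.5855670   22 0.46670813
#> 2       2 2    29 0.03448276  0.5062626   13 3.31514154
#> 3       3 2     1 1.00000000  0.9802062   42 0.06521054
```

Empirical data enter the same way: `read_newick()` for the tree,
`read_char_matrix()` for a CSV/TSV or simple NEXUS matrix, then
`run_study(tree = ..., matrix = ...)`. `read_alignment()` +
`column_steps()` add per-class molecular step averages (e.g. COI third
positions vs nuclear first/second) for comparison with the morphological
classes. `write_study_report()` emits `report.json` plus TSV tables. A thin
command-line wrapper with subcommands (`simulate-tree`, `steps`, `rank`,
`run-study`, ...) lives at `inst/cli/keysteps.R`.

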