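---
title: "Character evolutionary rate versus diagnostic utility: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Character evolutionary rate versus diagnostic utility: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keysteps)
```

## The question

Taxonomists build discrete characters to tell species apart; phylogeneticists
map characters onto trees to reconstruct history. `keysteps` quantifies the
tension between the two uses for a single character set: it measures each
character's evolutionary lability as the minimum number of state changes
(parsimony steps) required on a reference phylogeny, measures its diagnostic
utility as its rank under a "Best"-style interactive-key score, and asks
whether the two are correlated. The motivating empirical system is a
hyperdiverse complex of Neotropical doryctine wasps keyed out with ~47
discrete morphological characters over ~350 species, with a ~95-species
molecular phylogeny available for character mapping; because that character
matrix and tree are not publicly deposited, the package ships a simulation
layer that reproduces the *structure* of such a study with known
ground truth.

## Parsimony steps and homoplasy

For an unordered (Fitch-type) character, `count_steps()` computes the minimum
number of changes over all assignments of single states to internal nodes.
The implementation is unit-cost dynamic programming over the rooted tree
(`cost[v, s]` = minimal changes in the subtree of `v` given `v` carries state
`s`), which is exact on trees of arbitrary arity — the same minimum Hartigan's
generalization of the Fitch algorithm yields on polytomies. Unordered
parsimony is unrooted, so the count is invariant under re-rooting; the test
suite checks this, along with exact agreement with exhaustive enumeration
over all internal-node assignments on small trees.

Cell semantics matter and differ between the two analyses:

* **Parsimony**: a missing cell is a full wildcard (it can never force a
  change); a polymorphic cell enters as its observed state set — the same
  mechanics, restricted.
* **Key ranking**: a missing (unscored) taxon is never eliminated by a
  selection; a polymorphic taxon is retained whenever any of its states
  matches.

`summarize_character()` adds the classical homoplasy bookkeeping: the minimum
conceivable steps `m` on any tree, the maximum `g` on the given leaf data
(scored leaves minus the count of the most frequent state, a polymorphic leaf
counting toward that state when it contains it), the consistency index
`ci = m/s`, and the retention index `ri = (g - s)/(g - m)`. A character is
*homoplastic* when `s > m`, equivalently `ci < 1`: some state must arise more
than once or revert. With polymorphic cells we define `m` as one less than
the size of the smallest set of states that intersects every scored cell
(computable exactly for `k <= 6` by subset enumeration). Without polymorphism
this is the usual "observed states minus one"; with polymorphism it is the
only definition that preserves `m <= s` and "`s = 0` iff one state suffices",
so it is the one the package uses. `ci` and `ri` are reported as `NA` (never
0 or 1) for degenerate characters, so class averages are not silently biased.

## The "Best" score

Interactive keys eliminate candidate taxa as the user selects observed
states. The published description of the ranking we emulate is an ordering
principle — the best characters are those whose states are most evenly
distributed across the remaining taxa — not a formula; the vendor's exact
algorithm is proprietary. `best_score()` therefore adopts a parameter-free
realization of that principle as its normative definition: the expected
fraction of active taxa retained after one state selection,

\[ b = \sum_s p_s \frac{n_s + u}{N}, \qquad p_s = \frac{n_s}{\sum_t n_t}, \]

with `n_s` the number of active taxa carrying state `s`, `u` the number of
unscored taxa (always retained), and `N` the number of active taxa. With
complete data `b` reduces to the Simpson concentration of the state
frequencies, so it is minimized exactly at the most even split — verified
exhaustively over all binary splits up to `N = 12` in the tests. Any
monotone evenness measure (entropy, expected elimination) induces nearly the
same ordering; the downstream correlation is insensitive to this choice.
Ranks are assigned ascending in `b` (rank 1 = most useful) with
deterministic ties by character id, and for the study correlation the
ranking is computed once with *all* taxa active, mirroring how a key ranks
characters over the full fauna rather than per identification session.

`greedy_key_path()` plays the key against a known specimen: at each step it
selects the target's own state for the top-ranked usable character still
unused. For a polymorphic target cell it selects the rarest matching state
(ties to the lowest state index). Because the target always matches its own
states and unscored taxa are never eliminated, the target provably survives
every step; identification terminates when the target is alone or characters
are exhausted, and non-unique endpoints are reported, not raised.

## The simulation layer

`simulate_yule_tree()` draws a pure-birth tree conditioned on the number of
tips and rescales it to unit root height, standing in for an ultrametric
chronogram inferred without absolute age calibration. Rates are thereby
expressed in expected changes per unit tree height. `simulate_mk_character()`
implements the symmetric k-state Markov (Mk) model as its jump chain: Poisson
change events along each branch, each jumping uniformly to one of the other
`k - 1` states. Simulating events rather than endpoint transition
probabilities is deliberate: the realized event count is recorded, so the
changes parsimony cannot see are known exactly and `steps <=
true_change_count` is a testable invariant (the calibration
`E[count] = rate × total branch length` is checked to three standard errors
in the acceptance suite).

`simulate_matrix()` draws one character per entry of the configured
state-count composition. Defaults mirror the empirical study's shape: 350
taxa, 47 characters — 19 binary, 17 three-state, 8 four-state, 3 six-state —
with per-character rates log-uniform on [0.05, 5] changes per unit height
(spanning two orders of magnitude, as the gap between the slowest and fastest
observed character classes suggests) and 2% of cells missing completely at
random, keeping completeness above 95%. The published stratified counts sum
to 49 over 47 characters; the generator takes the composition as
configuration and the default uses 8 four-state characters so the total is
47. All rates are drawn in a single block before any character is evolved,
so two configurations differing only in `rate_high` and sharing a seed have
per-character rates that are coupled monotonically — which is what makes the
rate-ladder monotonicity of homoplasy a sharp test rather than a noisy one.

What the generator does **not** emulate: structural missingness (e.g. males
lacking ovipositor characters — missingness here is uniform), rate
autocorrelation or correlated evolution among characters, extinction, and
taxon sampling biases. Passing tests on this generator therefore demonstrate
that the pipeline recovers a rate-utility relationship when one exists under
clean Mk assumptions; they do not certify behaviour under structured
missingness or non-Mk evolution.

## Correlation and inference

`spearman_rho()` is the Pearson correlation of mid-ranks (average ranks for
ties); degenerate inputs (n < 3, zero rank variance) return `NA` with a
warning rather than a silent 0. p-values are two-tailed permutation tests:
exact enumeration of all `n!` relabelings for `n <= 9`, otherwise seeded
Monte-Carlo with the add-one estimator `(b + 1)/(n_perm + 1)` (default
10,000 resamples). No t-approximation is used — tied ranks at the study's
stratum sizes make it unreliable, and seeded permutation is exactly
reproducible.

Sign convention: rank 1 is the *most* useful character, so "fast characters
are the most useful" appears as a **negative** rho between steps and rank.
Characters that never change on the tree are included with `steps = 0`
(matching how an empirical census counts invariant characters), but
characters unusable for ranking (fewer than two observed states) or with
undefined steps are excluded and counted. Stratified correlations are run
within each state count `k`; strata smaller than `stratum_min` (default 5)
are reported as not tested — the empirical precedent tested a stratum of 10
and declined one of 3, and 5 interpolates that rule.

## Numerical and design choices

* Internal indices (states, alignment columns) are 1-based, following R
  convention; partition files remain 1-based inclusive RAxML coordinates, so
  `mt3 = 3-9\3` means columns 3, 6, 9.
* Zero-length branches are legal (chronograms contain near-zero edges);
  simulation on them yields zero expected changes.
* Ultrametricity is a predicate (`is_ultrametric()`, relative tolerance
  `1e-8` on the depth spread), never an assumption.
* All tie-breaks (ranking, greedy state choice) are by ascending id/index,
  making every pipeline run byte-reproducible given a seed.
* `run_study()` derives sub-seeds deterministically (tree, matrix,
  permutations) from one master seed.
* Alignment columns are deduplicated by site pattern before the step DP, so
  long alignments cost one DP per distinct pattern.

## Scale of the shipped analyses

The test and acceptance analyses run at sizes chosen to exercise the
asymptotics the method cares about while staying comfortable on a laptop:
exhaustive parsimony oracles on all tree shapes up to 7 leaves (2,000 random
characters), simulator calibration with 10,000 replicate characters on a
50-leaf tree, and 20 replicate studies of 47 characters on 100-leaf trees
for the correlation-recovery check. The packaged default study (350 taxa,
47 characters) runs in a few seconds.

## Known limitations

* The Best score is a declared stand-in for a proprietary ranking; only the
  ordering principle, not the constant structure, is reproduced.
* The homoplasy census counts extra steps; it does not distinguish true
  reversal (return to an ancestral state) from convergence, since a
  step-count workflow cannot.
* `mean_key_depth()` follows the greedy Best path only; it is an upper bound
  on optimal identification depth, not a key-optimality analysis.
* No ordered or cost-matrix characters, no likelihood ancestral-state
  mapping, no tree inference.
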