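---
title: "Phylogenetic flexibility: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic flexibility: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloflex)
```

## The question

A *taxon coverage pattern* is a collection τ of blocks — subsets of a
taxon set X — recording which species each input tree was built on. The
pattern is **phylogenetically flexible** when *every* assignment of a
rooted tree to each block yields a compatible collection, i.e. one
displayed by a single rooted supertree on X. Flexibility is the regime in
which supertree pipelines that require consistent inputs (BUILD-style
algorithms) are safe for any inputs whatsoever — and, dually, the regime
in which observed compatibility says nothing about tree accuracy,
because it was unavoidable.

## The model

For a sub-collection τ′ write L(τ′) for its covered taxa. The package
works with two Hall-type sparsity conditions:

* **thin** (uniform block size r ≥ 2): every non-empty τ′ satisfies
  exc(τ′) = |L(τ′)| − |τ′| − (r − 1) ≥ 0;
* **slim** (mixed sizes ≥ 3): every non-empty τ′ satisfies
  exc′(τ′) = |L(τ′)| − 2 − Σ_{s∈τ′}(|s| − 2) ≥ 0.

At r = 3 the two notions coincide; for uniform r > 3 slim is strictly
stronger than thin. The two flexibility theorems the deciders embody:
a size-3 system is flexible iff it is thin (`is_flexible_triples`), and
a mixed-size system is flexible iff it is slim (`is_flexible_general`).
Both deciders offer an `exhaustive` route (enumerate all assignments,
test each with BUILD), a criterion route, and a `both` mode that errors
on any disagreement — the form in which the theorems are continuously
re-verified by the test suite.

Compatibility of a triple set is decided with the Aho BUILD recursion:
partition the current taxon set by connected components of the cluster
graph (an edge {a,b} for each triple ab|c with all leaves present); a
connected level of size ≥ 2 certifies incompatibility, otherwise the
recursion assembles the canonical supertree. A collection of larger
trees is reduced to the union of its induced triples first; this is the
standard display equivalence for binary trees.

## Polynomial-time decisions

σ(τ′) = |L(τ′)| − |τ′| and γ(τ′) = |L(τ′)| − Σ(|s| − 2) are submodular
(verified empirically by `check_submodularity`, exhaustively up to 8
blocks). Their minima σ*, γ* over non-empty sub-collections decide
thin/slim by a threshold test. Rather than generic submodular
minimisation (polynomial but impractical), the package exploits the
coverage structure: for each *forced* block s, minimising
|N(Y)| − w(Y) over block sets Y containing s is a minimum-cut problem on
the bipartite incidence graph (source → block edges of capacity w,
block → taxon and the forced source edge "infinite", taxon → sink unit),
and σ*/γ* is the minimum over the |τ| forced choices. "Infinite" is
realised as Σw + Σdeg + 1, which strictly exceeds any finite cut. The
brute-force subset enumeration remains available as the independent
oracle, and the two routes are cross-validated on hundreds of seeded
systems in the acceptance tests.

One correction was needed here: the threshold for *thin* under σ* is
σ* ≥ r − 1, not a constant 2. On uniform size-r subsets
exc = σ − (r − 1), so a constant-2 threshold is right only at r = 3 (a
three-block counterexample at r = 4 appears in the test suite). γ* ≥ 2
for slim is exact at all sizes, since exc′ = γ − 2 identically.

### Witness conventions

All deciders return certificates. When several sub-collections attain
the minimum excess, the brute-force route returns the lexicographically
least by (subset size, canonical block order) — so e.g. for the
five-block worked example the witness is a four-block sub-collection of
excess −1, not the full collection, which also attains −1. The min-cut
route returns the cut-derived argmin for the first forced block
attaining the minimum; reporting an argmin at all is an extension of the
minimisation (the theory only needs the value). Flexibility
counterexamples found via the criterion route are reconstructed by an
exhaustive search restricted to the witness sub-collection, padded with
an arbitrary triple per remaining block — supersets of incompatible sets
stay incompatible.

## Caterpillar representations

A thin size-3 system admits a **median representation** by an unrooted
caterpillar: a binary tree whose interior vertices form a path, with the
block ↦ median-vertex map injective. The package's construction rests on
a structural reduction: in a caterpillar with leaf order x₁…xₙ, the
median of a block is the spine vertex carrying its *middle* leaf (the
member of median position). Injectivity is therefore equivalent to a
linear order of X under which block middles are pairwise distinct.

`build_caterpillar_median` searches for such an order by the inductive
peel: pick a taxon x of minimal occurrence (≤ 2 for a thin system
covering its universe); remove its block (occurrence 1) or replace its
two blocks by a single merged block (occurrence 2), recurse, then
re-insert the peeled taxa. Because the published case analysis of the
re-attachment step is intricate (and its subcase labelling internally
inconsistent), re-insertion is *verified* rather than decoded: every
insertion position is tried and the first one preserving
middle-injectivity is kept, with candidate merged blocks filtered by a
thinness check. A complete backtracking search over leaf orders (placing
taxa left to right; a block's middle is fixed the moment its last member
is placed, so collisions prune early) serves as the base case (|X| ≤ 6)
and as a fallback, making correctness a property of the verified
postcondition rather than of the proof's letter. Universe taxa outside
L(τ) are appended at the right end of the spine, where no median can
land.

For pair systems (r = 2) the analogues are: a rooted binary caterpillar
whose block ↦ lca map is injective (`build_rooted_caterpillar_lca`,
constructed by peeling an occurrence-1 taxon and attaching it at the
top); the incidence graph being a forest (`incidence_forest_check`); and
**total-order flexibility** — every orientation of the pairs extends to
a total order, equivalently every orientation digraph is acyclic
(`is_total_order_flexible`, exhaustive over the 2^|τ| orientations with
a Kahn-style acyclicity test, cyclic counterexample returned).

## Synthetic data

Two seeded generators drive the property tests. `random_set_system`
samples distinct blocks uniformly without replacement — at the oracle
scales used throughout (|X| ≤ 7 with ≤ 5 size-3 blocks for the
triple-flexibility equivalence; sizes 3–4 with ≤ 3 blocks for the
general equivalence; ≤ 12 blocks for minimiser cross-validation) both
thin and non-thin draws occur with substantial frequency, so both
branches of every equivalence are exercised. These scales are the
stated test conditions, chosen so the exhaustive oracles
(3^|τ| assignments, (2n−3)!! tree enumerations, 2^|τ| subset sweeps)
stay exact. `random_thin_system` uses the sequential construction —
every block after the first contains a fresh taxon — which guarantees
thinness but does not reach every thin system (the four-block system
`sec1_tau()` is a certified non-example, covered by a fixed test); random
draws from it therefore exercise the *construction* side of the
caterpillar theorem, while the unreachable fixtures cover the rest.
`random_rooted_binary_tree` inserts taxa in sorted order at uniform node
positions, which is uniform over the (2n−3)!! shapes.

What a green run establishes is consequently bounded: the theorems are
verified exactly, but only at enumeration scale and over the generators'
distributions; the polynomial routes are what extends the deciders
beyond that scale, and they are validated against the oracles on the
same distributions.

## Numerical and design choices

* **Determinism.** Blocks are stored sorted and in canonical
  (lexicographic) order; tree children are ordered by smallest
  descendant leaf; enumeration streams are fixed; all generators take
  seeds. Ties everywhere break toward the smallest label or canonical
  order.
* **Capacity ceilings.** Brute-force subset enumeration refuses above
  20 blocks (configurable); `auto` methods switch to the polynomial
  route above 15 blocks. Exhaustive flexibility sweeps refuse above 12
  blocks (3^12 assignments) or a 10^6 shape-count product; tree
  enumeration above 9 taxa; the degree-2 forest search is a test
  utility with its own combination cap.
* **Blocks of size 2** are valid in `set_system` (the r = 2 theory
  needs them) but rejected by all slim-related operations, which require
  size ≥ 3. Mixed sizes are rejected by `exc`/thin, whose definition is
  uniform; slim/γ handle them.
* **Duplicate blocks** are an error by default (`dedupe = TRUE`
  downgrades to a warning), since the theory treats τ as a set.
* **Empty subsets**: σ(∅) = γ(∅) = 0; the excess functions refuse empty
  input, matching their definitions.
* **BUILD output** is the canonical, possibly non-binary tree;
  `binary_refinement` resolves each multifurcation as a left-leaning
  caterpillar over canonically ordered children when a binary supertree
  is wanted.

## Limitations

* No heuristic supertree assembly for incompatible inputs:
  incompatibility is reported with a witness, never repaired.
* Median representations are implemented for size-3 blocks only; no
  minimality optimisation among valid caterpillars is attempted.
* The exhaustive oracles are exact but small-scale by design; beyond
  the ceilings only the criterion routes are available.
* No weighted blocks, multisets, or partial membership.
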