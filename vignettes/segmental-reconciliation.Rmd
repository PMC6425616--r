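---
title: "Reconciling gene forests with segmental duplications: model, solver, simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling gene forests with segmental duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segrec)
```

## The problem

Gene families do not evolve independently: a segmental duplication — at the
extreme, a whole-genome duplication — copies many genes in one
macro-evolutionary event. Classic duplication–loss reconciliation charges
each gene tree separately, so a single WGD is paid once per family.
`segrec` reconciles a whole gene forest $\mathcal G$ against one species
tree $S$ and charges co-mapped duplications as shared events.

## Model and conventions

A mapping $\alpha$ sends each gene node to a species node, anchored at the
leaves by the gene-to-species map $s(\cdot)$ (total, not necessarily
injective or surjective). Events are derived, not stored: an internal node
is a speciation iff its image is the LCA of its children's images and those
images are incomparable; otherwise it is a duplication. This is the
cost-minimal convention — relabelling a node from duplication to speciation
when allowed never increases the cost — and makes the LCA-mapping $\mu$
unique. Losses use the standard distance formulas
($\mathrm{dist}(\alpha(u),\alpha(u_1)) + \mathrm{dist}(\alpha(u),\alpha(u_2))$,
minus 2 at speciations).

For a species node $x$, the duplications mapped to $x$ induce a forest in
$\mathcal G$; its height $h_\alpha(x)$, counted in **nodes** (one
duplication has height 1), equals the minimum number of antichains covering
that set — each antichain is one possible segmental event. The objective is
$\delta \hat d(\alpha) + \lambda\, l(\alpha)$ with
$\hat d(\alpha) = \sum_x h_\alpha(x)$.

Two conventions deserve a note:

* `par_k(f, x, 0)` is already the *parent* of `x` (the `k`-th-parent
  convention the candidate-bound argument is stated in); an
  identity-at-zero variant is deliberately not exposed.
* Internal nodes have no reliable names in Newick practice, so all text
  outputs identify nodes by their sorted leaf-label sets (`B|C`); internal
  labels and branch lengths are parsed and ignored — the model is
  topology-only.

Degenerate inputs: a one-leaf gene tree is legal and contributes nothing;
an empty forest is an error; non-binary nodes are rejected at parse time.

## The two cost regimes

**$\delta \le \lambda$.** The LCA-mapping is optimal, uniquely so when
$\lambda > \delta$: remapping any node down one arc toward $\mu$ saves at
least one loss (the shift-down argument) and adds at most one duplication
event. `solve_mprst()` therefore returns $\mu$ without searching.

**$\delta > \lambda$.** The problem is NP-hard even with $\lambda = 0$ and
a single gene tree, so we use an exact bounded search over *partial*
mappings (undetermined nodes carry `NA`; determinedness is downward-closed):

1. *Initial cleanup*: every node that can be a speciation in some completion
   is fixed to the LCA of its children's images, bottom-up. What remains
   undetermined are exactly the *required duplications* (a child's image
   already dominates $\mu(v)$).
2. *Branching*: pick a lowest minimal undetermined node $v$ and try the
   species from $\mu_\alpha(v)$ (the LCA of its children's images) up
   $\lceil \delta/\lambda \rceil$ ancestors, inclusive — mapping higher can
   never pay off, since shifting down $k$ arcs saves $\ge k$ losses at the
   price of at most one extra event. The inclusive set has
   $\lceil \delta/\lambda \rceil + 1$ members before root clamping.
3. *Forcing*: once $v \mapsto x$, every other minimal undetermined node
   whose candidate lies at or below $x$ must share that event and is mapped
   to $x$ too; then *easy* nodes (speciations-to-be, or duplications that
   slot into an existing chain without raising any height) are fixed until
   none remain. Each branching step raises $\hat d$ by exactly one, which
   bounds the search depth by the duplication budget $d$.

The driver iterates $d = 0, 1, 2, \dots$, keeping the best completion found
(seeded with $\mu$, always feasible), and stops when
$(d+1)\,\delta \ge$ best cost — any unexplored mapping has
$\hat d \ge d + 1$ — or when $d + 1 \ge \hat d(\mu)$, because $\mu$
minimizes losses over all valid mappings (iterated shift-down), so any
mapping with $\hat d \ge \hat d(\mu)$ costs at least $\mathrm{cost}(\mu)$.

Numerical/determinism choices, made once:

* Ties among lowest branching nodes: deepest candidate species first, then
  smallest canonical node name. Correctness holds for any choice; this one
  makes runs reproducible bit-for-bit.
* Easy nodes are fixed in increasing depth of their forced image, same
  rationale.
* Pruning: a branch is abandoned when $\hat d$ exceeds the budget or when
  the partial cost $\delta \hat d + \lambda\, l$ reaches the incumbent —
  admissible because both terms only grow as nodes are determined.
* No cross-branch memoization: partial states are not cheaply canonical;
  caches are per-state increments, and the test-suite re-derives them from
  scratch at every checked expansion.
* $\lambda = 0$: solved under
  $\lambda' = \delta / (2\,|V(\mathcal G)||V(S)| + 1)$, so even the maximal
  possible loss count stays below one duplication; the optimum then has the
  minimum $\hat d$, with fewest losses as the induced tie-break, and results
  are reported with the true $\lambda = 0$ (losses shown, not charged).
* An optional expansion limit acts as a safety valve; hitting it flags the
  result as non-optimal instead of failing.

The experiments sweep on the 16-eukaryote dataset reports both $\hat d$ and
$\max_x h_\alpha(x)$, because "duplication height" is ambiguous between the
two readings; the bundled summary TSV always carries both.

## What the simulator emulates — and what it does not

`plant_episodes()` grows each family top-down inside the species tree. On
entering a species branch a lineage (i) is lost with probability
`loss_rate`, (ii) undergoes a planted episode duplication if one is placed
there for its family, (iii) each resulting copy duplicates **at most once**
more with probability `dup_rate`. The at-most-once rule keeps `dup_rate = 1`
meaningful (exactly one background duplication rather than an unbounded
chain); duplication chains still arise across branches and via
episode-plus-background stacking. Planted episodes duplicate each listed
family once per entering lineage, so on otherwise event-free instances one
episode is an antichain of height 1 and the ground-truth duplication sum
equals the episode count. Fully lost subtrees are pruned with unary
suppression; the recorded ground-truth loss count is always the
reconciliation-formula count on the recorded mapping (the quantity the
solver optimizes), which can differ from the raw number of pruning draws in
either direction — an extinct clade of many prunings is witnessed above as
one missing branch, and prunings on the root path leave no witness at all.

Defaults mirror a modest phylogenomics screen: the simulator itself takes
all rates explicitly; the test-suite uses species trees of 4–8 leaves,
1–4 families, background rates in $[0, 0.45]$, and 1–3 planted episodes,
which keeps brute-force cross-checks exhaustive. The generator produces
topologies only — no branch lengths, no sequence evolution, no rate
heterogeneity, no transfers, no incomplete lineage sorting. A green
recovery test therefore establishes that the *optimizer* finds the planted
combinatorial scenario, not that the model is identifiable on real data.

## Validation strategy

The unit and acceptance suites check, among others: solver cost equals an
independent exhaustive enumeration on hundreds of small random instances
across $\delta/\lambda \in \{0.5, 1, 1.5, 2, 3, 10\}$; node-identity with
$\mu$ whenever $\lambda > \delta$; the shift-down inequality on hundreds of
sampled remappings; per-species heights against an exhaustive minimum
antichain partition; the exactly-plus-one height contract and the clean-state
invariants at every checked expansion; and recovery of planted episode
counts on loss-free replicates. The bundled worked example reproduces a
duplication-height sum of 6 under the LCA-mapping (heights 1 at `A`, `B`,
`C`, `B|C`; 2 at `A|B|C`) and 4 under the bundled alternative scenario
(1 at `A`, 3 at `A|B|C`); it is a reconstruction built to those quantities,
as its README states, since no drawing of the original example ships with
the package.

## Known limitations

* No horizontal transfer, segmental losses, or non-binary input trees.
* Exact search only; no approximation mode. Practical instances should keep
  $\lceil \delta/\lambda \rceil$ and the optimal $\hat d$ moderate (the
  search tree has degree $\lceil \delta/\lambda \rceil + 1$ and depth
  $\le \hat d$).
* One optimum is returned deterministically; co-optima are not enumerated.
* The 16-eukaryote and yeast datasets are not redistributed; the yeast
  analysis additionally depends on out-of-scope branch-refinement
  preprocessing and is not reproduced here.
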