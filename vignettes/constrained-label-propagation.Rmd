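---
title: "Deterministic community detection with constrained label propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic community detection with constrained label propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clpagnr)
```

## The problem

Label propagation (LPA) is one of the fastest community-detection heuristics:
every node repeatedly adopts the label most frequent among its neighbours
until no node wants to change. Its weakness is instability — the update order
and the tie-breaks are random, so repeated runs on the same network return
different partitions, and practitioners resort to running it hundreds of
times and cherry-picking by modularity. `clpagnr` implements a fully
deterministic variant: all randomness is replaced by fixed update sequences
(keyed on node degree, community size, and canonical node order) and by
explicit tie-breaking quantities, so one run is the answer and two runs are
byte-identical.

## The model

The pipeline (`detect_communities()`) has six parts.

**Seeding by mutual neighbours.** The mutual-neighbour score (MNS) of an
adjacent pair is the number of neighbours they share. Pairs that are each
other's best-scoring partner (score > 0) are grouped transitively; remaining
nodes get one asynchronous adoption sweep in ascending-degree order, each
adopting the label of its best-scoring neighbour (ties resolved toward the
label held by most of the tied neighbours). Nodes with no shared neighbours
stay *solo*. Scores are only ever needed between adjacent nodes, so the MNS
table is restricted to edges and costs O(m).

**Merging.** A community A (intra-links $m_A$, size $n_A$) is absorbed by a
neighbouring community B when

$$\frac{\ell_{AB}}{n_B} > \alpha \, \frac{m_A}{n_A},$$

where $\ell_{AB}$ counts the links between them and $\alpha \in (0, 1]$
controls how hard merging is. The scan processes targets in ascending size
and candidate absorbers in descending inter-link count (ties broken by
identifier) and restarts after every merge, so the outcome is deterministic.

**Constrained growth (CLPA).** Solo nodes are admitted to communities under
four progressively relaxed conditions comparing $\ell$, the candidate's links
into the community, with $q$, the community's minimum per-member
intra-link count: $\ell > q$, $\ell \ge q$, $\ell > q/2$, $\ell \ge q/2$
($q/2$ kept exact). Seven passes use these conditions with different sweep
orders; ties between equally plausible communities are resolved by the
*acceptance capability* — the sum over the candidate's neighbours inside a
community of their capacity (inter-community links / degree, links to solo
nodes counting as inter). One pass additionally requires a strict modularity
increase, with solo nodes treated as singleton communities so modularity is
well defined mid-pipeline.

**Refinement (GNR).** Grouped nodes are re-examined in ascending-degree
order: a node whose label is the strict plurality of its neighbourhood stays;
one beaten by another label switches if the admission condition holds (or is
removed back to solo, in the stricter variants); tied pluralities go to the
community with the strictly highest acceptance capability. Two-node
communities are dissolved ("dual removal"), except in the final variant used
in part 6, which must preserve a total partition. The first variant also
prunes, once, every member whose intra-link count falls below the first
quartile of its community's counts.

**Solo-subgraph recursion.** If at least `subgraph_threshold` (default 10)
solo nodes survive the first growth phase, the subgraph they induce is
clustered recursively (parts 1–3), its communities are imported, and the
growth phase re-runs. Any node still solo after the relaxed passes joins the
adjacent community with the highest acceptance capability; nodes with no
grouped neighbour (including isolated nodes) become singletons.

**Modularity-guided final merge.** Merging re-runs with $\alpha$ descending
from 1.0 to 0.1 in steps of 0.1, each round followed by the final refinement
pass; the sweep stops as soon as modularity drops below the best seen, and
the best-modularity state is returned. The returned partition therefore never
has lower modularity than any intermediate part-6 state.

## Parameters that matter

* `alpha_grid` (default `seq(1, 0.1, -0.1)`): the merge thresholds of part 6,
  descending. Coarser steps merge more aggressively per round.
* `subgraph_threshold` (default 10 nodes): minimum residual solo count that
  justifies the recursive subgraph pass; below it the relaxed passes mop up.
* `final_gnr` (default 5): the refinement variant used in part 6. Variant 5
  performs no removals and no dual removal, so totality of the partition is
  preserved; variant 4 (dual removal active) is available for comparison.
* `part5_clpa` (default `c(4, 5, 6, 7)`): the relaxation schedule of part 5,
  ordered from more to less restrictive.

## Numerical and design choices

* **Tie-breaking.** Every ordering uses canonical node order (numeric when
  all identifiers parse as integers, else lexicographic in the C locale) as
  the final key; degree and size orderings use it as the secondary key.
  Capability comparisons use exact floating-point comparison; a capability
  tie falls back to the smallest community identifier (or, in the removing
  GNR variants, to removal).
* **First quartile.** Quantile convention with the lower hinge at position
  $(n+2)/4$ (`stats::quantile(type = 5)`), under which the multiset
  $\{1,\dots,8\}$ has $Q_1 = 2.5$; pruning uses a snapshot of the counts so
  the step is genuinely one-shot.
* **Oscillation.** Asynchronous switching can enter a short limit cycle (two
  nodes trading places each sweep) on weakly structured graphs. A revisited
  labeling carries no new information, so the refinement loop also terminates
  when a labeling recurs; together with a `100 * n` sweep cap (exceeding it
  is an error, never a silent return) every pass terminates deterministically.
* **Degenerate inputs.** Self-loops are dropped and duplicate edges collapsed
  with warnings; empty graphs are an error; isolated nodes ride through the
  pipeline untouched and are emitted as singleton communities. Modularity of
  a single all-node community is 0; the internal density of a singleton
  community is defined as 0 so modularity density stays finite.

## Quality metrics

`evaluate_partition()` reports modularity $Q$, modularity density $Q_{ds}$
(the density-weighted variant that counteracts the resolution limit), and —
against a reference partition — the normalized variation of information
(NVI, 0 = identical) and normalized mutual information (NMI, 1 = identical).
Natural logarithms are used throughout; both normalized quantities are
base-invariant. $Q$ can be negative for adversarial partitions, so only
$Q \le 1$ is enforced.

## Benchmark generators

Three seeded generator families reproduce the standard evaluation corpus
without external data. All three are stub-matching (configuration-model)
constructions with rejection/repair of self-loops, duplicate edges and
same-community inter stubs; per-node intra stub counts are
$\mathrm{round}\bigl((1-\mu)\,d\bigr)$ (half-up), the remainder inter.

* `generate_lfr()`: power-law degrees (exponent $\gamma$, mean exactly
  calibrated via a fractional boundary weight, maximum `max_degree`) and
  power-law community sizes (exponent $\beta$) summing to $n$; nodes are
  placed by random assignment with kick-outs so every node fits its
  community ($d_{in} \le n_c - 1$). Defaults follow the small / small-degree
  / small-community configuration ($n = 1000$, $\langle k \rangle = 10$,
  maxk 50, sizes 10–50, $\gamma = 2$, $\beta = 1$).
* `generate_gn()`: 128 nodes, four planted groups of 32, degree 16.
* `generate_rc()`: 16 cliques on 512 nodes degraded by rewiring a fraction
  $D$ of each clique's edges to other communities. The reference size law is
  not published beyond its range; sizes are drawn from a truncated power law
  on $[2, 157]$ with exponent 1, resampled until they sum exactly to 512 —
  with exponent 1 the expected sum of 16 draws ($\approx 570$) makes that
  literal rejection loop terminate quickly while keeping the sizes highly
  heterogeneous. An explicit size vector can be supplied instead.

What the generators emulate is the *degree/size heterogeneity and tunable
mixing* of the published corpus, not any particular realization: a fresh
implementation cannot reproduce the exact graphs behind the published
figures, so recovery results are checked as distributions over seeds
(realized mixing, modal outcomes) rather than graph identity. Real networks
additionally carry degree correlations, clustering and overlapping structure
that none of these families model — perfect benchmark recovery therefore
bounds, but does not guarantee, field performance.

## Problem sizes used in the tests

The bundled suite exercises the study conditions at desk scale: LFR at
$n = 1000$ with 10 seeds per configuration, Girvan–Newman and relaxed-caveman
scans with 5 seeds per grid level, plus 50 random graphs for the determinism
property and 200 random ≤30-node instances for metric-oracle equivalence.

## Known limitations

* Trivial detection: like its randomized ancestor, the method collapses to a
  single all-node community once mixing is heavy (Girvan–Newman $\mu \ge
  0.5$; small-degree LFR $\mu \ge 0.7$); the onset for the relaxed-caveman
  family is sensitive to the (unpublished) community-size law.
* Undirected, unweighted, simple graphs only; no overlapping communities.
* The per-pass sweep orders inside parts 3–6 are reconstructions of a prose
  description; the two largest reconstructions (which refinement variant
  follows each growth pass, and the final refinement variant) are exposed as
  options (`final_gnr`, `part5_clpa`) so their effect can be tested.

## A worked example

```{r example, eval = FALSE}
inst <- generate_gn(mu = 0.2, seed = 1)
fit <- detect_communities(inst$graph)
glance(fit)
evaluate_partition(inst$graph, fit, truth = inst$truth)
```
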