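---
title: "Community-based link prediction and network reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-based link prediction and network reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cblink)
```

## The problem

Link prediction ranks the non-adjacent node pairs of an observed network by
their likelihood of being true but unobserved links. Local similarity
indices do this cheaply and often accurately: common neighbours (CN),
`s_xy = |Γ(x) ∩ Γ(y)|`, and resource allocation (RA),
`s_xy = Σ_{z ∈ Γ(x) ∩ Γ(y)} 1/k_z`, where `Γ(x)` is the neighbour set and
`k_z` the degree. Both indices, however, score a pair by the triangles it
would close, and in a network with community structure almost all triangles
live *inside* communities. The few links that bridge communities close
almost no triangles, so similarity-based predictors systematically miss
them — yet those bridges dominate global properties: shortest paths,
betweenness, congestion, synchronization and epidemic spreading. A
reconstruction that restores only intra-community links can score a high
AUC while producing a network whose global behaviour is badly distorted.

`cblink` addresses this by making community membership an explicit part of
the ranking. It is aimed at anyone reconstructing partially observed
networks — protein interaction maps, neural wiring diagrams, social or
collaboration networks — who cares about the reconstructed network's global
structure, not only the hit rate.

## The method

1. **Partition.** Communities are detected on the *training* graph by
   maximizing Newman modularity `Q = Σ_r (e_rr − a_r²)` with an extremal
   optimization (EO) search (see below).
2. **Score and classify.** Every non-adjacent pair gets a CN or RA score
   and is classified intra- or inter-community by the partition. Each class
   is ranked by descending score (lexicographic tie-break on the node pair,
   so pure rankings are deterministic).
3. **β-interleave.** The combined list R is built head-to-tail: at each
   step the head of the intra list is taken with probability β, else the
   head of the inter list; an exhausted list is drained. β = 1 ranks all
   intra candidates first, β = 0 all inter candidates first; both
   degenerate cases are deterministic. The relative order within each
   source list is always preserved (a merge, never a shuffle).
4. **Predict.** The top `L` pairs of R are the predicted links, with `L`
   taken as the (roughly known) number of missing links.

CN/RA combined with this scheme are called CBCN and CBRA.

### Choosing β: matching the betweenness of held-out links

Large β maximizes AUC (intra links are simply easier to predict); small β
recovers bridges. The tuning target is the mean edge betweenness ⟨B⟩ of the
predicted links once inserted into the training graph: bridges carry many
shortest paths, so ⟨B⟩ is a direct readout of how many inter-community
links a prediction list contains. Betweenness is counted over *ordered*
endpoint pairs throughout the package (each unordered pair counted twice);
a single isolated edge has betweenness 2 under this convention.

- The **hindsight optimum** `β*` picks, on a β grid, the value whose ⟨B⟩
  best matches that of the probe links themselves (`oracle_beta_star()`).
  It uses knowledge a practitioner does not have.
- The **learned** `β̂*` (`learn_beta_hat()`) uses threefold validation:
  edges are split into training `E_T` (80%), learning `E_L` (10%) and probe
  `E_P` (10%) sets. The ⟨B⟩ of the `E_L` links added to the `E_T` graph is
  the target, and the β curve is computed ranking `E_T`'s candidates
  against `E_L`. The probe set is never inspected; during learning, probe
  pairs are deliberately indistinguishable from nonexistent pairs (the
  package's tests assert that replacing `E_P` changes nothing upstream).
- The **constrained** `β̂*` additionally bounds the accuracy cost: with
  `AUC_o` the plain CN/RA AUC on the same split, the matching β is kept
  only if its learning-set AUC stays above `(1 − s)·AUC_o`; otherwise the
  smallest β reaching that floor is returned. Since AUC grows with β, the
  constraint can only pull β upward. The sacrifice `s` defaults to 0.1,
  i.e. at most 10% of the baseline accuracy is given up for bridge
  recovery; it is a tunable argument.

"Matching" is nearest-on-grid: on a stochastic curve exact equality is a
measure-zero event, and grid ties resolve toward the larger (higher-AUC) β.

### Evaluation

- **AUC** is computed *exhaustively*: over all probe × nonexistent pair
  comparisons, `AUC = (n′ + 0.5 n″)/n` with `n′` strictly-better and `n″`
  tied comparisons. This is the deterministic `n → ∞` limit of the usual
  sampled estimator, which is also provided (`auc_sampled()`) and agrees
  within sampling error. Two entries count as tied when they are
  equal-score members of the same source list — their relative order is an
  arbitrary tie-break, so giving either one full credit would bias the
  result on sparse graphs where most candidates share score 0.
  "Nonexistent" pairs are the candidates outside every true-link set
  available at that stage (`E_P` and `E_L` at evaluation time; only `E_L`
  during learning, by the hygiene argument above).
- **Precision** is the hit fraction of the top `L` (default `L = |E_P|`).
- **⟨B⟩** inserts all `L` predictions at once and averages edge
  betweenness over the inserted links only.

## The EO community detector

Modularity is maximized by recursive bipartitioning. Each community is
tentatively split by a τ-EO search: starting from a random balanced
bipartition, nodes are ranked by fitness `λ_i = k_i(c_i)/k_i − a_{c_i}`
(their normalized contribution to Q) and the rank-`j` node is flipped
across the cut with probability ∝ `j^(−τ)`, `τ = 1 + 1/ln n`. The best
configuration seen is kept; a search stops after `n²` consecutive
non-improving flips (capped at 20 000, both configurable). A split is
accepted when it raises global modularity, and accepted parts are split
recursively. A final refinement — single-node relocations to neighbouring
communities plus pairwise community merges while Q increases — polishes the
partition. The search runs in compiled code and uses R's RNG, so a seed
makes it reproducible.

The contract is partition *quality*, not the search trajectory: any
modularity maximizer can be substituted behind
`detect_communities(graph, seed)`. On all ≤8-node test graphs the detector
attains the global optimum found by exhaustive partition enumeration, and
on the karate-club network it reaches the known maximum Q = 0.4198.

## The planted benchmark generator

`generate_gn()` builds the classic four-community test graph: 128 nodes in
four blocks of 32; each intra-community pair is connected independently
with `p_in = k_in/31` and each inter pair with `p_out = (16 − k_in)/96`, so
expected total degree is 16 (the canonical value; configurable) and `k_in`
dials the sharpness of the structure. Edges are Bernoulli, so realized
degrees fluctuate binomially around their expectation — an expected-degree
model rather than an exact-degree rewiring, matching the "on average"
construction. Planted-partition recovery is scored by
`classification_accuracy()`, which aligns labels by maximum-weight
bipartite matching on the confusion table before counting agreements.

What the generator emulates — homogeneous equal-sized communities with
independent edges — is also what it does not: real networks have broad
degree distributions, unequal communities, and bridges that themselves
close triangles (which is exactly why inter-link *precision* is better on
real co-authorship data than on the benchmark). Passing the benchmark
tests therefore demonstrates the machinery and its trends, not performance
guarantees on any particular real network.

## Reconstruction protocol

`reconstruction_protocol()` runs the full pipeline per replicate: split
80/10/10; learn the constrained β̂* from `E_T`/`E_L`; merge
`E_T ∪ E_L` into the observed graph; rank its candidates once; and build
four reconstructions from the same partition and scores (a paired design):
β = 0, the constrained β̂*, β = 1, and the plain CN/RA ranking. Each adds
the top `|E_P|` predictions, so every reconstruction has exactly as many
edges as the true network. Six indices are then averaged across replicates
and set against the original's:

| index | definition |
|---|---|
| avg shortest path | mean hop distance over *connected* pairs (reconstructions may be disconnected; the convention is flagged in the output) |
| clustering | mean local clustering; degree < 2 nodes contribute 0 |
| assortativity | degree Pearson over edges; `NA` (not 0) when undefined, e.g. regular graphs |
| congestibility | maximum node betweenness, ordered-pair convention |
| synchronizability | Laplacian eigenratio λ_max/λ_2 of the largest component (1 for complete graphs) |
| spreading ability | mean outbreak size of a discrete-time SIR: one uniformly random seed, per-contact transmission probability, recovery after one step |

The SIR transmission probability defaults to `1.5 × ⟨k⟩/(⟨k²⟩ − ⟨k⟩)` —
1.5 times the heterogeneous mean-field epidemic threshold — so outbreaks
are supercritical without saturating; the value is derived once from the
original graph and reused for every variant so the index is comparable
across them. Because this parameter is a package choice, spreading-ability
values are comparable *within* a run, not against external tables.

## Numerical choices and degenerate inputs

- β grid default `seq(0, 1, by = 0.01)` with 10 interleaving replicates per
  point (replicate r re-seeded as `seed + r`); β ∈ {0, 1} are evaluated
  once since they are deterministic.
- Ties: score ties break lexicographically on the canonical pair;
  betweenness-matching ties toward the larger β; the constraint floor uses
  a 1e−12 slack against floating-point equality.
- Edgeless graphs: modularity and detection raise errors (Q divides by M).
  Graphs left disconnected by a split are handled throughout (mean distance
  over connected pairs, eigenratio on the largest component, candidate
  universe keeps isolated nodes).
- A single-community graph has no inter candidates: every β yields the
  same list, the curve is flat, and the tie-break returns β = 1.
- Edge lists are whitespace-delimited text, `#` comments, duplicate lines
  collapsed with a warning, self-loops rejected with the offending line.

## Problem sizes used by the test suite

The distribution's checks run the benchmark at its native size (128 nodes)
with replicate counts chosen to keep the whole suite under a few minutes
on one core: the β trade-off trend uses 30 replicates at the deterministic
endpoints β ∈ {0, 1}; β recovery compares mean β̂* against mean β* over 10
replicates on a 0.05 grid with 5 interleaving replicates; detector
robustness uses 50 realizations. These sizes are the package's own choices
and are arguments everywhere, so heavier studies only change a number.

## Known limitations

- Unweighted, undirected simple graphs only.
- The method needs a meaningful partition; on networks without community
  structure the intra/inter split is arbitrary and β has little effect.
- On the planted benchmark, *correctly* predicted inter links remain few —
  bridges close no triangles there, so CN/RA simply cannot see them; the
  gain is in how many bridges enter the prediction list at all (and on real
  networks, where bridges do close triangles, in correct inter hits too).
- Exhaustive AUC is O(|probe| × |nonexistent|) via rank sums; for very
  large sparse networks the sampled estimator is the practical choice.
- The congestibility and spreading-ability indices are documented
  interpretations (max node betweenness; near-threshold SIR outbreak), and
  the output records the parameters used.
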