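# cblink — community-based link prediction and network reconstruction

`cblink` predicts missing links in undirected networks **with community
structure** and reconstructs networks whose *global* topology — shortest
paths, betweenness, congestion, synchronizability, epidemic spreading —
stays close to the truth, not just the link-level hit rate.

Classic local similarity indices score a candidate pair by the triangles it
would close:

- **CN** (common neighbours): `s_xy = |Γ(x) ∩ Γ(y)|`
- **RA** (resource allocation): `s_xy = Σ_{z ∈ Γ(x)∩Γ(y)} 1/k_z`

In a modular network almost all triangles are inside communities, so these
indices recover intra-community links and systematically miss the
inter-community bridges that carry shortest-path traffic. `cblink`
implements the community-based variants **CBCN**/**CBRA**: partition the
training graph by modularity maximization (an extremal-optimization search
in compiled code), rank intra- and inter-community candidates separately,
and merge the two lists by drawing the head of the intra list with
probability **β** (β = 1: all intra first; β = 0: all inter first). The
parameter is learned by **threefold validation**: β̂\* is chosen so that the
mean edge betweenness ⟨B⟩ of the predicted links matches that of a held-out
learning set, optionally constrained so that at most a set fraction
(default 10%) of the plain method's AUC is sacrificed. The probe set is
never touched during learning.

Also included: a planted four-community benchmark generator (128 nodes,
tunable intra-degree k_in), exhaustive and sampled AUC, precision@L,
intra/inter prediction accounting, a six-index structural/dynamical
comparison of reconstructed networks, and a command-line interface.

## Worked example

The bundled fixture is the Zachary karate club network (34 nodes, 78
edges), a small social network with two-to-four-way community structure.

```r
library(cblink)
karate <- read_edge_list(system.file("extdata/karate.edgelist", package = "cblink"))
structural_summary(karate, seed = 1)
#> Network indices
#>   avg shortest path : 2.408
#>   clustering        : 0.571
#>   assortativity     : -0.4756
#>   congestibility    : 462.1
#>   synchronizability : 38.71
#>   spreading ability : 6.32 (transmission 0.222, 1000 reps)
```

Mean distance 2.41 and clustering 0.571 are the familiar textbook values;
congestibility (maximum node betweenness, ordered-pair convention) 462 is
dominated by the instructor hub, and the Laplacian eigenratio 38.7 says the
network is far from optimally synchronizable.

Learn β from the data alone (80/10/10 train/learn/probe split), then
evaluate against fresh splits:

```r
fit <- learn_beta_hat(karate, "CBRA", grid = seq(0, 1, by = 0.05), reps = 10, seed = 1)
fit
#> Learned interleaving parameter (CBRA)
#>   beta_hat (matches <B> = 30.92) : 0.90
#>   constrained beta (<= 10% AUC loss vs 0.6223): 0.90

evaluate_method(karate, "CBRA", beta = fit$constrained_beta, reps = 10, seed = 1)
#> Link prediction evaluation: CBRA (beta = 0.9, 10 reps, probe 10%)
#>   auc                0.7596 +/- 0.0815
#>   ...
evaluate_method(karate, "RA", reps = 10, seed = 1)
#> Link prediction evaluation: RA (beta = 1, 10 reps, probe 10%)
#>   auc                0.7364 +/- 0.0924
#>   ...
```

The learner matches the held-out betweenness at β̂\* = 0.9, and the
community-based ranking edges out plain RA on AUC (0.760 vs 0.736 here)
while controlling how many bridges enter the prediction list. The full
reconstruction comparison — original vs reconstructions at β = 0, the
learned constrained β̂\*, β = 1, and the plain ranking, across six indices —
is one call:

```r
reconstruction_protocol(karate, "CBRA", reps = 10, seed = 1)
```

## Command line

```sh
exec/cblink gn-generate --kin 12 --seed 7 --out gn.txt     # benchmark + planted truth
exec/cblink predict --edgelist gn.txt --method cbcn --beta 0.8 --top 20 --seed 1
exec/cblink learn-beta --edgelist gn.txt --method cbra --seed 1 --out beta.json
exec/cblink evaluate --edgelist gn.txt --method cbcn --beta 0.8 --reps 10 --seed 1
exec/cblink reconstruct --edgelist gn.txt --method cbcn --reps 10 --seed 1 --out report.tsv
```

Every output embeds the exact invocation and seed that produced it.

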