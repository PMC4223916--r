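# flowscope

Flow-based communities and roles in directed networks.

In a directed network — who follows whom on a social platform, who preys
on whom in a food web, which region projects to which in a brain — the
*orientation* of edges carries information that plain connection density
does not. `flowscope` analyses what flows *do* on such a network:

- **Interest communities at all scales.** A teleported continuous-time
  random walk (jump chain `M = tau * D_out^-1 A + (1 - tau)/N`, PageRank
  stationary distribution `pi`) scans the network, and the quality of a
  partition with indicator matrix `H` at Markov time `t` is its
  **Markov Stability**

  `r(t, H) = trace[ H' (Pi P(t) - pi pi') H ]`,   `P(t) = expm(t (M - I))`,

  the probability that a walker started at stationarity is found in its
  starting community at time `t`, in excess of chance. Maximizing `r`
  with a generalized Louvain over a grid of times yields fine, granular
  communities at small `t` and coarse ones at large `t`; long windows of
  `t` on which the optimal partition is reproducible (low variation of
  information across optimizer restarts and across neighbouring times)
  mark the network's natural scales.
- **Directed versus symmetrized.** The same sweep run on `(A + A')/2`
  shows what is lost when orientation is ignored; the package ships a
  `flow_trap` generator whose planted blocks are provably invisible to
  any symmetrized analysis yet (partially) recoverable from directed
  flow.
- **Interest distance.** From any vantage node, every other node's
  distance is the earliest Markov time at which the two share a
  community — an ultrametric-like, personalized map of attention.
- **Flow roles.** Each node gets a feature vector of geometrically
  scaled counts of its incoming and outgoing walks of every length
  (role-based similarity, RBS); cosine similarities `Y` are sparsified
  by a relaxed minimum spanning tree (RMST: keep the MST of the chord
  distance `d = sqrt(2 (1 - y))` plus every pair whose direct distance
  beats the tree's bottleneck path after a local-scale relaxation
  `gamma (d_i + d_j)`), and communities of that role-similarity graph —
  found with the same stability sweep — are the network's flow roles
  (references, mediators, listeners, ...), with no role count imposed a
  priori.
- **Organigrams.** Each interest community is summarized by its mix of
  roles; k-means on these mixes classifies communities into
  informational organigram types (broadcast-like, dialogue-like, ...).

Synthetic generators with planted ground truth (directed SBM, flow-trap,
role template) make every stage testable end to end.

## Worked example

```r
library(flowscope)

g  <- generate_directed_sbm(rep(25, 4), p_in = 0.3, p_out = 0.02, seed = 42)
g$net
#> directed_network: 100 nodes, 814 edges, total weight 814

sw <- stability_sweep(g$net, times = 10^seq(-1, 1, length.out = 15),
                      n_runs = 4, seed = 1)
head(summary(sw), 4)
#>        time  k stability   vi_runs
#> 1 0.1000000 73 0.8952519 0.0000000
#> 2 0.1389495 55 0.8634327 0.3114402
#> 3 0.1930698 39 0.8234651 0.3350316
#> 4 0.2682696 29 0.7740202 0.5525558

wins <- select_robust_partitions(sw, min_plateau = 3)
#> plateau t = [0.72, 10]: k = 4, VI to planted = 0
```

At small Markov times the sweep resolves 73 granular communities; from
`t ≈ 0.7` onward it settles on a robust plateau of exactly the four
planted blocks (variation of information 0 to the ground truth). From
the same sweep, `interest_distance(sw, "n001")` reports each node's
earliest co-clustering time with node `n001`: its 24 block-mates join in
the first batches, the remaining blocks stay unreached within this grid.

The role pipeline runs the other half of the method:

```r
Xf  <- build_feature_matrix(g$net)        # RBS walk-count features
Y   <- cosine_similarity(Xf)
rsg <- rmst(similarity_to_distance(Y), gamma = 0.5, Y = Y)
ra  <- detect_roles(rsg, g$net)           # roles = communities of rsg
mix <- role_mix(wins[[1]]$partition, ra)  # role fractions per community
org <- cluster_role_mixes(mix)            # organigram types
```

`run_pipeline(default_config(edges = "edges.tsv"))` chains all stages
and writes CSV/GraphML artifacts plus a deterministic `summary.json`.

A command-line interface with subcommands `synth`, `sweep`, `interest`,
`rbs`, `rmst`, `roles`, `organigrams` and `run` is installed at

```sh
Rscript $(Rscript -e 'cat(system.file("cli/flowscope.R", package = "flowscope"))') \
    sweep --edges edges.tsv --tmin 0.01 --tmax 10 --ntimes 40 --runs 10 --seed 1 --out-dir out
```

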