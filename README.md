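# tegem

Interpretable contrastive embeddings of time-evolving graphs with
metastable dynamics.

Longitudinal microbiome studies (and many other dynamical systems) produce
a *time-evolving graph*: a sequence of interaction networks
𝔾 = (G₁, …, G_T) over a fixed node set — taxa connected by co-occurrence
edges — that dwells for long stretches in one of a few configurations
(e.g. healthy vs. infected community states) with rare transitions between
them. `tegem` is for researchers who want to (1) detect and visualise such
metastable states from the graph sequence alone, (2) benchmark detection
methods on synthetic data with known dynamics, and (3) identify which
nodes make the states different.

## The method

Each snapshot Gₜ is encoded by a Transformer encoder whose self-attention
is **masked by the adjacency matrix** — attention weights are exactly 0 on
absent edges — with a **master node** connected to all nodes. The master
output zₜ ∈ ℝ^{d_m} is the snapshot representation and is passed
recurrently as the master input of the next snapshot over a temporal
window of length *l*:

    z_t = R(z_{t−1}, x_t, A_t)

A projection head maps zₜ to the embedding ĝₜ ∈ ℝ^d. Training is
contrastive: consecutive snapshots are positives (metastability implies
G_t and G_{t+1} almost surely share a state) and other sampled time points
are negatives, under the InfoNCE loss

    L = −log [ exp(ĝ_t · ĝ_{t+1} / τ) / Σ_{i=1}^B exp(ĝ_t · ĝ_i / τ) ]

with dot-product similarity and temperature τ. States are read out by
k-means on the embeddings and scored with the adjusted Rand index (ARI)
against ground truth, next to a PCA-on-flattened-adjacency baseline.
Per-node relevance maps are computed by attention rollout through the
encoder (Chefer-style attention-gradient weighting, or attention-only for
planted structural patterns), aggregated per state, and contrasted across
states to find discriminating nodes.

The package also contains the full synthetic benchmark stack: an
Euler–Maruyama integrator for overdamped Langevin dynamics in a double-well
or an s-well ring potential, graph generators that plant
state-discriminating topology driven by the simulated trajectory, and an
OTU-count path (Pearson co-occurrence graph + zero-count edge masking)
with a synthetic regime-switching count fixture. The encoder forward and
backward passes are implemented in C++ (RcppArmadillo); everything is
seeded and exactly reproducible.

## Worked example

Generate the reduced non-positional two-well benchmark, train the model,
and compare it with the PCA baseline:

```r
library(tegem)

cfg <- experiment_preset("npos_2well_small", seed = 1)
g   <- generate_dataset(cfg)
print(g)
#> tevograph: n = 50 nodes, T = 2000 snapshots, mean edges 1138.8, 2 states, with coordinates

snapshot_edge_stats(g)$per_state
#>   state     mean  min  max
#> 1     0 1096.842 1041 1153
#> 2     1 1182.655 1137 1214

res <- run_experiment(cfg)      # trains ~2 min on one CPU
str(res$report)
#> $ ari_model             : num 0.846
#> $ ari_pca               : num 0.837
#> $ stay_probability_model: num 0.968
#> $ stay_probability_truth: num 0.968
```

The two metastable states are degree regimes (nodes inside a moving circle
keep at most 2 vs. 14 within-circle neighbours), visible in the per-state
edge counts. Both the contrastive model and the PCA baseline recover the
states almost perfectly on the held-out test block (ARI ≈ 0.84 here;
1.0 would be perfect, 0 random), and the predicted state sequence is as
metastable as the true one (stay-probability 0.97).

Interpretability — recover *which* nodes discriminate the states of the
positional double-well benchmark:

```r
cfg2  <- experiment_preset("pos_2well_small", seed = 1)
g2    <- generate_dataset(cfg2)
model <- train_graph_embedder(g2, cfg2$model)
ev    <- evaluate_embedding(model$embeddings, g2$states, k = 2,
                            split = model$split)
te    <- model$split$test
rel   <- relevance_map(model, g2, te, weighting = "attention")
top   <- top_state_nodes(rel, ev$labels[te], state = 1,
                         q = length(attr(g2, "upper_nodes")))
mean(top %in% attr(g2, "upper_nodes"))
#> [1] 1
```

All of the planted "upper" nodes — the set whose internal edges are
removed in state 1 — are recovered.

A thin command-line front end (`exec/tegem`) wraps the same functions as
`generate / train / embed / evaluate / interpret` subcommands.

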