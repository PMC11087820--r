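# dpisketch

Global–local scoring of candidate drug–protein interactions (DPIs) in a
bipartite interaction graph, for computational drug-discovery work at desk
scale: screening candidate pairs, studying what structural signal link
predictors actually use, and benchmarking feature channels against exact
oracles.

## The method

Nodes are drugs and proteins; edges are observed interactions. Every node
gets two complementary representations, fused by a perceptron into a score
in (0, 1) for each candidate pair
[d_local ‖ d_global ‖ p_local ‖ p_global] → MLP → σ:

**Local channel — subgraph sketches into a GNN.** Each node carries, per hop
t = 0..k, a MinHash signature `b_v^t` and HyperLogLog registers `a_v^t`,
propagated by neighbour merges `a_v^t = max_{u∈N(v)} a_u^{t-1}`,
`b_v^t = min_{u∈N(v)} b_u^{t-1}` (exact union algebra). For a pair (d, p)
the overlap of their hop neighbourhoods is estimated as

    |N_dd(d) ∩ N_dp(p)| ≈ H(b_d^dd, b_p^dp) · hyper(max(a_d^dd, a_p^dp))

(Hamming similarity of signatures × HLL estimate of the union cardinality),
from which the inclusion–exclusion features S1[dd, dp] and the
beyond-subgraph counts S2[t] are assembled and injected as structural edge
features into a 2-layer message-passing encoder (output dim 64).

**Global channel — diffusion attention over all nodes.** Initial features
are projected as Z = σ(LayerNorm(XW + b)); per layer and head, rows of K and
Q are L2-normalized and the all-pair affinity `1 + Q̂ᵢ·K̂ⱼ ≥ 0` is
row-normalized into a stochastic diffusion-rate matrix; features propagate
as AV (computed in O(N) by associativity), heads average, and
`Z ← (1−α)Z + α·avg` (2 layers, 4 heads, output dim 256). Attention spans
every node pair, connected or not.

Initial node features come from pluggable string embedding backends (SMILES
for drugs, amino-acid sequences for proteins); the default is a
deterministic offline trigram-hashing embedder, so nothing needs downloading.
Training: Adam (lr 0.001, batch 512), binary cross-entropy, 7:1:2
positive-edge split with 1:1 uniform negatives, early stopping after 10
non-improving validation-AUC epochs, everything computed on the
training-only graph and fully seeded. Metrics: AUC, AUPR, ACC, SEN, PRE,
SPE, F1, MCC.

Every estimator ships with an exact brute-force oracle
(`exact_khop_shells()`, `exact_walk_sets()`, `exact_structural_features()`)
and a planted-community benchmark generator whose two channels both carry
learnable signal. See the methods vignette
(`vignettes/dpisketch-methods.Rmd`) for the model details, design decisions
and the benchmark's ideal-observer ceiling.

## Worked example

```r
library(dpisketch)

ds <- generate_dataset(synthetic_spec(n_drugs = 100, n_proteins = 100, seed = 7))
print(ds$graph)
#> bipartite_graph: 100 drugs, 100 proteins, 568 edges

sk <- propagate_sketches(ds$graph, init_sketches(ds$graph, 256, 10, 1), 3)
d <- ds$graph$edges$drug[1]; p <- ds$graph$edges$protein[1]
structural_features(sk, d, p)        # sketch-estimated pair features
#> structural_feature for (D0002, P0001), k = 3
#> S1 (rows dd, cols dp):
#>    dp
#> dd     1    2     3
#>   1 0.00 4.18  0.00
#>   2 5.92 0.00 11.18
#>   3 0.00 8.53  0.00
#> S2: 4.01 5.07 6.96
exact_structural_features(ds$graph, d, p, 3)  # exact oracle for the same pair
#> S1 (rows dd, cols dp):
#>    dp
#> dd  1  2 3
#>   1 0  4 0
#>   2 6  0 9
#>   3 0 10 0
#> S2: 4 5 9

run <- dpi_run(ds, dpi_config(seed = 1))
print(run$fit)
#> dpi_fit: mode full, 35 epoch(s), best epoch 25
#> metrics_report (threshold 0.50): AUC 0.8233  AUPR 0.7734  ACC 0.7763  SEN 0.7719
#>   PRE 0.7788  SPE 0.7807  F1 0.7753  MCC 0.5527
#> counts: TP 88  FP 25  TN 89  FN 26
```

The S1 matrix estimates how many nodes sit at hop `dd` from the drug and hop
`dp` from the protein (zeros at even `dd + dp` are structural: hop sets of a
drug and a protein can only share a node side at odd hop sums). The trained
model's test AUC of 0.82 is essentially this generator's ideal-observer
level — a true-community oracle scores 0.83 — so the pipeline is extracting
the full planted signal; the estimated features track the exact oracle
within a fraction of a node:

```r
verify_sketches(seed = 1)
#> sketch_report (num_perm = 256 , precision = 10 , k = 3 )
#>   jaccard  error 0.0131  (tol 0.050)  PASS
#>   hll      error 0.0279  (tol 0.100)  PASS
#>   S1 MAE   error 0.2488  (tol 1.000)  PASS
```

Real interaction tables load from a TSV
(`drug_id  smiles  protein_id  sequence  label`) via `load_interactions()`
or `dpi_run("file.tsv", ...)`; a thin command-line wrapper lives at
`inst/cli/dpi.R` (`synth`, `train`, `verify-sketches`, `export-features`).

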