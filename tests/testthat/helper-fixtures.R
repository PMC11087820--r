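# Shared fixtures built in code: small graphs with hand-checkable structure
# and fast model configurations for the training tests.

# d1 - p1 - d2 - p2 (a path of four nodes)
path4_graph <- function() {
  bipartite_graph(c("d1", "d2"), c("p1", "p2"),
                  data.frame(drug = c("d1", "d2", "d2"),
                             protein = c("p1", "p1", "p2")))
}

# protein hub with `leaves` drug leaves
star_graph <- function(leaves = 3) {
  drugs <- paste0("d", seq_len(leaves))
  bipartite_graph(drugs, "hub",
                  data.frame(drug = drugs, protein = "hub"))
}

# G(n, p) bipartite graph, seeded; isolated nodes kept
random_bipartite <- function(nd, np, p, seed) {
  withr::with_seed(seed, {
    drugs <- sprintf("d%03d", seq_len(nd))
    proteins <- sprintf("p%03d", seq_len(np))
    hit <- matrix(runif(nd * np) < p, nd, np)
    idx <- which(hit, arr.ind = TRUE)
    bipartite_graph(drugs, proteins,
                    data.frame(drug = drugs[idx[, 1]],
                               protein = proteins[idx[, 2]]))
  })
}

# small planted dataset + fast config for end-to-end training tests
small_benchmark <- function(seed = 3) {
  generate_dataset(synthetic_spec(n_drugs = 40L, n_proteins = 40L,
                                  n_communities = 2L, p_in = 0.3,
                                  p_out = 0.02, seed = seed))
}

fast_config <- function(...) {
  defaults <- list(embed_dim = 16L, local_dim = 16L, global_dim = 32L,
                   heads = 2L, mlp_hidden = c(32L, 16L), batch_size = 128L,
                   max_epochs = 3L, num_perm = 64L, hll_precision = 6L)
  do.call(dpi_config, utils::modifyList(defaults, list(...)))
}

# write a small interaction TSV and return its path
write_tsv_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("drug_id\tsmiles\tprotein_id\tsequence\tlabel", rows), path)
  path
}

# exact membership of walk-length-t reachability via adjacency powers,
# fully independent of the BFS-shell route used by the package
walkset_by_adjacency <- function(graph, node, t) {
  nodes <- graph_nodes(graph)
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(graph$edges))) {
    d <- graph$edges$drug[i]; p <- graph$edges$protein[i]
    A[d, p] <- 1; A[p, d] <- 1
  }
  v <- as.numeric(nodes == node)
  for (s in seq_len(t)) v <- as.numeric(A %*% v)
  sort(nodes[v > 0])
}
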