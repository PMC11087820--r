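test_that("interaction TSV loading builds the graph from positive rows", {
  path <- write_tsv_fixture(c("d1\tCCO\tp1\tMKV\t1",
                              "d1\tCCO\tp2\tMKL\t1",
                              "d2\tCCN\tp1\tMKV\t1"))
  loaded <- suppressMessages(load_interactions(path))
  expect_equal(length(loaded$graph$drugs), 2)
  expect_equal(length(loaded$graph$proteins), 2)
  expect_equal(nrow(loaded$graph$edges), 3)

  # duplicated edge rows collapse to one edge
  path2 <- write_tsv_fixture(c("d1\tCCO\tp1\tMKV\t1",
                               "d1\tCCO\tp1\tMKV\t1"))
  loaded2 <- suppressMessages(load_interactions(path2))
  expect_equal(nrow(loaded2$graph$edges), 1)
  expect_equal(loaded2$graph$n_duplicates_dropped, 1)

  # label outside {0,1} names the label domain and the line
  path3 <- write_tsv_fixture(c("d1\tCCO\tp1\tMKV\t2"))
  expect_error(load_interactions(path3, quiet = TRUE), "label")
})

test_that("graph construction enforces bipartite invariants", {
  g <- path4_graph()
  expect_true(dpisketch:::check_bipartite(g))
  expect_setequal(graph_neighbors(g, "d2"), c("p1", "p2"))
  expect_true(all(g$side[graph_neighbors(g, "d2")] == "protein"))
  expect_error(bipartite_graph("x", "x", data.frame(drug = "x", protein = "x")),
               "disjoint")
  expect_error(bipartite_graph("d1", "p1",
                               data.frame(drug = "d9", protein = "p1")),
               "unknown drug")
})

test_that("edge splitting honours ratios, seeds and leakage guarantees", {
  g <- random_bipartite(10, 10, 0.3, seed = 42)
  # exact rounding on 10 edges
  g10 <- bipartite_graph(g$drugs, g$proteins, g$edges[1:10, ])
  sp <- split_edges(g10, c(0.7, 0.1, 0.2), seed = 0)
  expect_equal(c(nrow(sp$train), nrow(sp$valid), nrow(sp$test)), c(7, 1, 2))

  # determinism
  spA <- split_edges(g, seed = 7)
  spB <- split_edges(g, seed = 7)
  expect_identical(spA$train, spB$train)
  expect_identical(spA$test, spB$test)

  # disjoint exhaustive partition and no leakage into the training graph
  g100 <- random_bipartite(25, 25, 0.25, seed = 1)
  stopifnot(nrow(g100$edges) >= 100)
  g100 <- bipartite_graph(g100$drugs, g100$proteins, g100$edges[1:100, ])
  sp <- split_edges(g100, c(0.7, 0.1, 0.2), seed = 3)
  key <- function(df) paste(df$drug, df$protein)
  all_keys <- c(key(sp$train), key(sp$valid), key(sp$test))
  expect_equal(sort(all_keys), sort(key(g100$edges)))
  expect_equal(anyDuplicated(all_keys), 0L)
  expect_equal(nrow(sp$graph_train$edges), 70)
  expect_false(any(key(sp$valid) %in% key(sp$graph_train$edges)))
  expect_false(any(key(sp$test) %in% key(sp$graph_train$edges)))

  expect_error(split_edges(g10, c(0.5, 0.5, 0.1)), "sum to 1")
})

test_that("negative sampling draws uniform non-edges and detects exhaustion", {
  # complete bipartite graph: no non-edges left
  gc <- bipartite_graph(c("d1", "d2"), c("p1", "p2"),
                        expand.grid(drug = c("d1", "d2"),
                                    protein = c("p1", "p2")))
  sp <- split_edges(gc, c(0.5, 0.25, 0.25), seed = 0)
  expect_error(sample_negatives(sp, ratio = 1), "non-edges")

  # 2x2 graph with 3 positives: the only negative is the one missing pair
  g3 <- bipartite_graph(c("d1", "d2"), c("p1", "p2"),
                        data.frame(drug = c("d1", "d1", "d2"),
                                   protein = c("p1", "p2", "p1")))
  sp3 <- split_edges(g3, c(0.34, 0.33, 0.33), seed = 1)
  neg <- sample_negatives(sp3, ratio = 1, seed = 5, which = "test")
  added <- neg$test[neg$test$label == 0, ]
  expect_equal(nrow(added), 1)
  expect_true(all(added$drug == "d2" & added$protein == "p2"))

  # determinism and count contract
  g <- random_bipartite(15, 15, 0.2, seed = 9)
  spl <- split_edges(g, seed = 2)
  n1 <- sample_negatives(spl, ratio = 1, seed = 11)
  n2 <- sample_negatives(spl, ratio = 1, seed = 11)
  expect_identical(n1$train, n2$train)
  expect_equal(sum(n1$train$label == 0), nrow(spl$train))
  # sampled negatives are non-edges of the full graph
  negs <- n1$train[n1$train$label == 0, ]
  expect_false(any(mapply(graph_has_edge, negs$drug, negs$protein,
                          MoreArgs = list(graph = g))))
})

test_that("exact BFS shells are disjoint, side-alternating and oracle-exact", {
  g <- path4_graph()
  sh <- exact_khop_shells(g, "d1", 2)
  expect_equal(sh, list("d1", "p1", "d2"))

  iso <- bipartite_graph(c("d1", "dI"), "p1",
                         data.frame(drug = "d1", protein = "p1"))
  expect_equal(exact_khop_shells(iso, "dI", 3),
               list("dI", character(0), character(0), character(0)))
  expect_error(exact_khop_shells(g, "zz", 1), "unknown node")

  skip_if_not_installed("igraph")
  g <- random_bipartite(20, 20, 0.12, seed = 4)
  ig <- igraph::graph_from_edgelist(
    as.matrix(g$edges[, c("drug", "protein")]), directed = FALSE)
  dist <- igraph::distances(ig)
  for (node in sample(graph_nodes(g), 8)) {
    sh <- exact_khop_shells(g, node, 4)
    expect_equal(anyDuplicated(unlist(sh)), 0L)
    # igraph drops isolated nodes from its edgelist-built vertex set
    in_ig <- node %in% colnames(dist)
    for (t in 0:4) {
      if (in_ig) {
        reach <- colnames(dist)[is.finite(dist[node, ]) & dist[node, ] == t]
        expect_setequal(sh[[t + 1]], reach)
      }
      # shells alternate node sides by parity
      if (length(sh[[t + 1]]) > 0) {
        expected_side <- if (t %% 2 == 0) g$side[[node]] else
          setdiff(c("drug", "protein"), g$side[[node]])
        expect_true(all(g$side[sh[[t + 1]]] == expected_side))
      }
    }
  }
})

test_that("random-walk subgraphs stay inside the k-hop ball and converge to it", {
  g <- star_graph(3)
  sub <- random_walk_subgraph(g, "hub", k = 1, walks = 100, seed = 1)
  expect_true(all(sub %in% c("hub", paste0("d", 1:3))))

  g <- random_bipartite(8, 8, 0.25, seed = 6)
  node <- g$drugs[1]
  ball <- unique(unlist(exact_khop_shells(g, node, 3)))
  for (s in 1:5) {
    expect_true(all(random_walk_subgraph(g, node, 3, walks = 10, seed = s)
                    %in% ball))
  }
  # with many walks the visited set covers the whole <= k ball
  expect_setequal(random_walk_subgraph(g, node, 3, walks = 2000, seed = 0), ball)
  expect_identical(random_walk_subgraph(g, node, 3, walks = 7, seed = 9),
                   random_walk_subgraph(g, node, 3, walks = 7, seed = 9))
})

test_that("walk-t sets equal same-parity shell unions and the adjacency oracle", {
  g <- random_bipartite(12, 12, 0.15, seed = 13)
  for (node in c(g$drugs[1:3], g$proteins[1:3])) {
    ws <- exact_walk_sets(g, node, 4)
    for (t in 0:4) {
      expect_setequal(ws[[t + 1]], walkset_by_adjacency(g, node, t))
    }
  }
})
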