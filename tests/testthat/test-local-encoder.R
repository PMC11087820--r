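test_that("edge-feature vectors follow the layer layout with weight slot", {
  f <- structure(list(S1 = matrix(1:9, 3, 3), S2 = c(10, 20, 30), k = 3),
                 class = "structural_feature")
  # layer 1: only S2[1] and the weight slot are populated
  v1 <- build_edge_features(f, 1, k = 3)
  expect_equal(v1, c(10, 0, 0, 0, 0, 0, 1))
  # layer 2, k = 3: S2[2], S1[1,2], S1[2,1] populated, then padding + weight
  v2 <- build_edge_features(f, 2, k = 3)
  expect_equal(v2, c(20, f$S1[1, 2], f$S1[2, 1], 0, 0, 0, 1))
  expect_equal(sum(v2[4:6] != 0), 0)
  # layer 3: S2[3], S1[1:2,3], S1[3,1:2]
  v3 <- build_edge_features(f, 3, k = 3, weight = 0)
  expect_equal(v3, c(30, f$S1[1, 3], f$S1[2, 3], f$S1[3, 1], f$S1[3, 2], 0, 0))
  expect_error(build_edge_features(f, 4, k = 3), "exceeds")
  # an all-zero feature gives an all-zero vector apart from the weight slot
  f0 <- structure(list(S1 = matrix(0, 3, 3), S2 = numeric(3), k = 3),
                  class = "structural_feature")
  expect_equal(build_edge_features(f0, 2, weight = 0), numeric(7))
})

test_that("gnn layer handles empty neighbourhoods by the closed form", {
  # graph with no edges: x' = phi([x || 0]) for every node
  g <- bipartite_graph(c("d1", "d2"), c("p1", "p2"),
                       data.frame(drug = character(0), protein = character(0)))
  withr::with_seed(1, {
    x <- matrix(rnorm(4 * 3), 4, 3)
    tau_W <- matrix(rnorm((3 + 3 + 7) * 2), 13, 2); tau_b <- matrix(0, 1, 2)
    phi_W <- matrix(rnorm(5 * 2), 5, 2); phi_b <- matrix(rnorm(2), 1, 2)
  })
  out <- gnn_layer(x, g, matrix(0, 0, 7), tau_W, tau_b, phi_W, phi_b,
                   activation = FALSE)
  manual <- sweep(cbind(x, matrix(0, 4, 2)) %*% phi_W, 2,
                  as.numeric(phi_b), "+")
  expect_equal(unname(out), manual)
})

test_that("nodes with identical neighbourhoods and features embed identically", {
  # d1 and d2 both connect only to p1 with identical edge features
  g <- bipartite_graph(c("d1", "d2"), "p1",
                       data.frame(drug = c("d1", "d2"), protein = c("p1", "p1")))
  x <- rbind(c(1, 2), c(1, 2), c(0.5, -1))
  ef <- matrix(rep(c(1, 0, 0, 0, 0, 0, 1), 2), 2, 7, byrow = TRUE)
  withr::with_seed(2, {
    tau_W <- matrix(rnorm(11 * 3), 11, 3); phi_W <- matrix(rnorm(5 * 3), 5, 3)
  })
  out <- gnn_layer(x, g, ef, tau_W, matrix(0, 1, 3), phi_W, matrix(0, 1, 3))
  expect_equal(out["d1", ], out["d2", ])
})

test_that("local encoding is equivariant to within-side node permutation", {
  ds <- small_benchmark(seed = 11)
  g <- ds$graph
  cfg <- fast_config(seed = 4)
  model <- dpi_model_init(cfg)
  be <- offline_backend(cfg$embed_dim, 1)
  X0 <- rbind(embed_drugs(unname(ds$smiles[g$drugs]), be, g$drugs),
              embed_proteins(unname(ds$sequences[g$proteins]), be, g$proteins))
  sk <- propagate_sketches(g, init_sketches(g, 64, 6, 9), cfg$k)
  enc <- encode_local(g, X0, model, sk)

  # permute drug order in the graph construction; embeddings must follow ids
  perm <- withr::with_seed(5, sample(g$drugs))
  g2 <- bipartite_graph(perm, g$proteins, g$edges)
  X0p <- X0[graph_nodes(g2), , drop = FALSE]
  sk2 <- propagate_sketches(g2, init_sketches(g2, 64, 6, 9), cfg$k)
  enc2 <- encode_local(g2, X0p, model, sk2)
  expect_equal(enc2$d_local[g$drugs, ], enc$d_local[g$drugs, ],
               tolerance = 1e-10)
  expect_equal(enc2$p_local[g$proteins, ], enc$p_local[g$proteins, ],
               tolerance = 1e-10)
})

test_that("a 2-layer encoder is blind to features beyond distance 2", {
  # path d1-p1-d2-p2-d3: with L = 2, x_{d1} ignores features of d3
  drugs <- c("d1", "d2", "d3"); proteins <- c("p1", "p2")
  g <- bipartite_graph(drugs, proteins,
                       data.frame(drug = c("d1", "d2", "d2", "d3"),
                                  protein = c("p1", "p1", "p2", "p2")))
  cfg <- dpi_config(embed_dim = 8L, local_dim = 8L, num_perm = 32L,
                    hll_precision = 4L, seed = 3)
  model <- dpi_model_init(cfg)
  sk <- propagate_sketches(g, init_sketches(g, 32, 4, 1), cfg$k)
  X0 <- matrix(0.1, 5, 8, dimnames = list(graph_nodes(g), NULL))
  encA <- encode_local(g, X0, model, sk)
  X0b <- X0; X0b["d3", ] <- 5 # d3 is at distance 4 from d1
  encB <- encode_local(g, X0b, model, sk)
  expect_equal(encA$d_local["d1", ], encB$d_local["d1", ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(encA$d_local["d2", ], encB$d_local["d2", ])))
})

test_that("stacked gnn_layer calls reproduce the trained encoder's forward pass", {
  ds <- small_benchmark(seed = 13)
  g <- ds$graph
  cfg <- fast_config(seed = 5)
  model <- dpi_model_init(cfg)
  X0 <- withr::with_seed(6, matrix(rnorm(length(graph_nodes(g)) * cfg$embed_dim),
                                   ncol = cfg$embed_dim))
  sk <- propagate_sketches(g, init_sketches(g, cfg$num_perm, cfg$hll_precision, 8),
                           cfg$k)
  enc <- encode_local(g, X0, model, sk)

  fb <- structural_features_batch(sk, g$edges, cfg$k)
  x <- X0
  for (l in 1:2) {
    E <- dpisketch:::edge_feature_matrix(fb, l)
    x <- gnn_layer(x, g, E,
                   model$params[[paste0("local.tau", l, ".W")]],
                   model$params[[paste0("local.tau", l, ".b")]],
                   model$params[[paste0("local.phi", l, ".W")]],
                   model$params[[paste0("local.phi", l, ".b")]],
                   activation = l < 2)
  }
  expect_equal(unname(rbind(enc$d_local, enc$p_local)), unname(x),
               tolerance = 1e-10)
})

test_that("encoder contract errors are informative", {
  ds <- small_benchmark(seed = 12)
  cfg <- fast_config(seed = 1, mode = "no_local")
  model <- dpi_model_init(cfg)
  X0 <- matrix(0, length(graph_nodes(ds$graph)), cfg$embed_dim)
  expect_error(encode_local(ds$graph, X0, model), "no local encoder")
  expect_error(dpi_config(local_layers = 0L), "local_layers")
  expect_error(dpi_config(local_layers = 4L, k = 3L), "exceed")
})
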