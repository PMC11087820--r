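test_that("hop-0 sketches encode singletons deterministically", {
  g <- path4_graph()
  sk <- init_sketches(g, num_perm = 256, hll_precision = 10, seed = 1)
  sk2 <- init_sketches(g, num_perm = 256, hll_precision = 10, seed = 1)
  expect_identical(sk$minhash[[1]], sk2$minhash[[1]])

  # distinct singletons share no signature positions (up to hash collisions)
  expect_lt(estimate_jaccard(node_signature(sk, "d1", 0),
                             node_signature(sk, "d2", 0)), 0.02)
  # HLL of a singleton estimates 1 exactly under linear counting
  m <- 2^10
  expect_equal(estimate_cardinality(node_registers(sk, "d1", 0)),
               m * log(m / (m - 1)), tolerance = 1e-12)
  expect_error(init_sketches(g, num_perm = 8), "num_perm")
  expect_error(init_sketches(g, hll_precision = 3), "precision")
})

test_that("union algebra of MinHash and HLL sketches is bit-exact", {
  withr::with_seed(99, {
    for (rep in 1:10) {
      a <- paste0("a", sample.int(500, 60))
      b <- paste0("a", sample.int(500, 60)) # overlapping universes
      sa <- minhash_signature(a, 64, seed = rep)
      sb <- minhash_signature(b, 64, seed = rep)
      su <- minhash_signature(union(a, b), 64, seed = rep)
      expect_identical(as.numeric(sketch_union(sa, sb)), as.numeric(su))
      ha <- hll_registers(a, 8, seed = rep)
      hb <- hll_registers(b, 8, seed = rep)
      hu <- hll_registers(union(a, b), 8, seed = rep)
      expect_identical(as.integer(sketch_union(ha, hb)), as.integer(hu))
    }
  })
  s1 <- minhash_signature("x", 64, seed = 1)
  s2 <- minhash_signature("x", 64, seed = 2)
  expect_error(estimate_jaccard(s1, s2), "seed")
})

test_that("sketch propagation represents walk-reachable sets", {
  g <- path4_graph() # d1-p1-d2-p2
  sk <- propagate_sketches(g, init_sketches(g, 256, 10, 1), 3)

  # a_p1^1 sketches {d1, d2}: estimate close to 2
  expect_equal(estimate_cardinality(node_registers(sk, "p1", 1)), 2,
               tolerance = 0.1)
  # b_d1^2 is exactly the direct sketch of the walk-2 set {d1, d2}
  direct <- minhash_signature(c("d1", "d2"), 256, seed = 1)
  expect_identical(as.numeric(node_signature(sk, "d1", 2)), as.numeric(direct))

  # star: hop-1 sketch of the hub estimates the leaf count within the HLL bound
  c_leaves <- 24
  gs <- star_graph(c_leaves)
  sks <- propagate_sketches(gs, init_sketches(gs, 64, 10, 5), 2)
  est <- estimate_cardinality(node_registers(sks, "hub", 1))
  expect_lt(abs(est - c_leaves), 2 * (1.04 / sqrt(2^10)) * c_leaves + 1)

  # isolated nodes have empty sketches at t >= 1
  iso <- bipartite_graph(c("d1", "dI"), "p1",
                         data.frame(drug = "d1", protein = "p1"))
  ski <- propagate_sketches(init_sketches(iso, 64, 8, 1), graph = iso, k = 2)
  expect_equal(estimate_cardinality(node_registers(ski, "dI", 1)), 0)
  expect_true(all(is.infinite(node_signature(ski, "dI", 2))))
})

test_that("MinHash Jaccard estimates are calibrated and near-unbiased", {
  # identity
  b <- minhash_signature(letters, 64, 3)
  expect_equal(estimate_jaccard(b, b), 1.0)
  # disjoint sets
  bx <- minhash_signature(paste0("l", 1:100), 256, 3)
  by <- minhash_signature(paste0("r", 101:200), 256, 3)
  expect_lte(estimate_jaccard(bx, by), 1 / 256)
  # J = 1/2 at high num_perm
  a <- c(paste0("s", 1:2), "a4")
  expect_equal(estimate_jaccard(minhash_signature(c("s1", "s2", "s3"), 4096, 7),
                                minhash_signature(c("s2", "s3", "s4"), 4096, 7)),
               0.5, tolerance = 0.05)
  # near-unbiasedness over hash seeds at exact J = 1/3
  seeds <- 1:200
  np <- 64
  ests <- vapply(seeds, function(s) {
    # |A ^ B| = 20, |A u B| = 60 -> J = 1/3
    estimate_jaccard(minhash_signature(c(paste0("c", 1:20), paste0("a", 1:20)), np, s),
                     minhash_signature(c(paste0("c", 1:20), paste0("b", 1:20)), np, s))
  }, numeric(1))
  expect_lt(abs(mean(ests) - 1 / 3), 3 / sqrt(length(seeds) * np))
})

test_that("HLL cardinality estimates hit their theoretical error bounds", {
  expect_equal(estimate_cardinality(hll_registers(character(0), 10, 1)), 0)
  # order and duplication invariance
  x <- paste0("x", 1:500)
  r1 <- hll_registers(x, 8, 2)
  r2 <- hll_registers(rev(c(x, x[1:100])), 8, 2)
  expect_identical(as.integer(r1), as.integer(r2))
  # relative error across the 100..10000 range, averaged over seeds
  rse <- 1.04 / sqrt(2^10)
  for (n in c(100, 1000, 10000)) {
    rel <- vapply(1:20, function(s) {
      est <- estimate_cardinality(hll_registers(paste0("i", 1:n), 10, s))
      (est - n) / n
    }, numeric(1))
    expect_lt(abs(mean(rel)), 3 * rse)
    expect_lt(max(abs(rel)), 5 * rse)
  }
})

test_that("intersection estimates track the exact shell oracle", {
  # identical 1-hop neighbourhoods: estimate ~ shell size, J ~ 1
  nd <- 6
  drugs <- c("dA", "dB"); proteins <- paste0("p", 1:nd)
  ed <- expand.grid(drug = drugs, protein = proteins)
  g <- bipartite_graph(drugs, proteins, ed)
  sk <- propagate_sketches(g, init_sketches(g, 256, 10, 1), 2)
  est <- estimate_intersection(sk, "dA", "dB", 1, 1)
  expect_equal(est, nd, tolerance = 0.15 * nd)

  # disjoint shells: estimate near 0
  g2 <- bipartite_graph(c("d1", "d2"), c("p1", "p2"),
                        data.frame(drug = c("d1", "d2"),
                                   protein = c("p1", "p2")))
  sk2 <- propagate_sketches(g2, init_sketches(g2, 256, 10, 1), 1)
  expect_lt(estimate_intersection(sk2, "d1", "p2", 1, 1), 0.2)
  expect_error(estimate_intersection(sk2, "d1", "p2", 1, 2), "hop")

  # random graphs: estimated |N_dd(d) ^ N_dp(p)| close to exact walk-set overlap
  errs <- c()
  for (gseed in 1:10) {
    g <- random_bipartite(30, 30, 0.1, seed = gseed)
    sk <- propagate_sketches(g, init_sketches(g, 256, 10, gseed), 3)
    pairs <- withr::with_seed(gseed, cbind(sample(g$drugs, 10),
                                           sample(g$proteins, 10)))
    for (i in 1:nrow(pairs)) {
      wd <- exact_walk_sets(g, pairs[i, 1], 3)
      wp <- exact_walk_sets(g, pairs[i, 2], 3)
      for (dd in 1:3) for (dp in 1:3) {
        exact <- length(intersect(wd[[dd + 1]], wp[[dp + 1]]))
        est <- estimate_intersection(sk, pairs[i, 1], pairs[i, 2], dd, dp)
        errs <- c(errs, abs(est - exact))
      }
    }
  }
  expect_lt(mean(errs), 1.0)
})
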