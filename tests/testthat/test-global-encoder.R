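test_that("input projection lands strictly inside (0,1) with known zero case", {
  withr::with_seed(3, X <- matrix(rnorm(20), 5, 4))
  W <- matrix(rnorm(12), 4, 3); b <- matrix(rnorm(3), 1, 3)
  Z <- input_projection(X, W, b)
  expect_true(all(Z > 0 & Z < 1))
  # zero weights and bias: layernorm of zeros is zeros, sigmoid -> 0.5
  Z0 <- input_projection(X, matrix(0, 4, 3), matrix(0, 1, 3))
  expect_true(all(Z0 == 0.5))
  # rowwise map: duplicate input rows give duplicate outputs
  Xd <- rbind(X[1, ], X[1, ])
  Zd <- input_projection(Xd, W, b)
  expect_equal(Zd[1, ], Zd[2, ])
  expect_error(input_projection(matrix(c(1, NA), 1, 2), matrix(0, 2, 2),
                                matrix(0, 1, 2)), "finite")
})

test_that("QKV projections are linear maps with identity special case", {
  withr::with_seed(4, Z <- matrix(rnorm(12), 4, 3))
  id <- diag(3)
  kqv <- qkv_projection(Z, id, id, id)
  expect_equal(kqv$K, Z); expect_equal(kqv$Q, Z); expect_equal(kqv$V, Z)
  withr::with_seed(5, {
    Wk <- matrix(rnorm(6), 3, 2); Wq <- matrix(rnorm(6), 3, 2)
    Wv <- matrix(rnorm(9), 3, 3)
    Z2 <- matrix(rnorm(12), 4, 3)
  })
  a <- 0.7; b <- -1.3
  lhs <- qkv_projection(a * Z + b * Z2, Wk, Wq, Wv)
  rhs_K <- a * qkv_projection(Z, Wk, Wq, Wv)$K + b * qkv_projection(Z2, Wk, Wq, Wv)$K
  expect_equal(lhs$K, rhs_K, tolerance = 1e-12)
  expect_error(qkv_projection(Z, matrix(0, 2, 2), Wq, Wv), "mismatch")
})

test_that("L2 normalization produces unit rows and guards zeros", {
  M <- rbind(c(3, 4), c(0, 2))
  nz <- l2_normalize_heads(M, M)
  expect_equal(nz$K[1, ], c(0.6, 0.8))
  expect_equal(unname(sqrt(rowSums(nz$K^2))), c(1, 1))
  expect_equal(l2_normalize_heads(nz$K, nz$Q)$K, nz$K) # idempotent
  expect_warning(l2_normalize_heads(rbind(c(0, 0), c(1, 0)), M), "zero row")
})

test_that("diffusion attention is row-stochastic, residual-consistent and
           equal between dense and linear-time computations", {
  withr::with_seed(6, {
    Z <- matrix(rnorm(50 * 8), 50, 8)
    heads <- lapply(1:3, function(g) list(Wk = matrix(rnorm(8 * 4), 8, 4),
                                          Wq = matrix(rnorm(8 * 4), 8, 4),
                                          Wv = matrix(rnorm(8 * 8), 8, 8)))
  })
  # explicit attention rows sum to one
  kqv <- qkv_projection(Z, heads[[1]]$Wk, heads[[1]]$Wq, heads[[1]]$Wv)
  nz <- l2_normalize_heads(kqv$K, kqv$Q)
  A <- dpisketch:::attention_rowstochastic(nz$Q, nz$K)
  expect_true(all(abs(rowSums(A) - 1) < 1e-6))
  expect_true(all(A >= 0))

  # dense and associativity-trick propagation agree
  Zd <- diffusion_attention_layer(Z, heads, alpha = 0.5, method = "dense")
  Zl <- diffusion_attention_layer(Z, heads, alpha = 0.5, method = "linear")
  expect_lt(max(abs(Zd - Zl)), 1e-5)

  # alpha = 0 is outside the domain; alpha -> small keeps Z nearly frozen
  expect_error(diffusion_attention_layer(Z, heads, alpha = 0), "alpha")
  Zs <- diffusion_attention_layer(Z, heads, alpha = 1e-9)
  expect_equal(Zs, Z, tolerance = 1e-6)

  # single node: A = [[1]], update is (1 - a) Z + a V
  z1 <- matrix(c(0.3, -0.2, 0.5), 1, 3)
  h1 <- list(list(Wk = diag(3), Wq = diag(3), Wv = 2 * diag(3)))
  out1 <- diffusion_attention_layer(z1, h1, alpha = 0.25)
  expect_equal(out1, 0.75 * z1 + 0.25 * (z1 %*% (2 * diag(3))))
})

test_that("row-stochastic propagation with V = Z stays in the convex hull", {
  withr::with_seed(8, {
    Z <- matrix(runif(30 * 6), 30, 6)
    heads <- lapply(1:2, function(g) list(Wk = matrix(rnorm(24), 6, 4),
                                          Wq = matrix(rnorm(24), 6, 4),
                                          Wv = diag(6)))
  })
  out <- diffusion_attention_layer(Z, heads, alpha = 1, method = "dense")
  for (j in 1:ncol(Z)) {
    expect_gte(min(out[, j]), min(Z[, j]) - 1e-10)
    expect_lte(max(out[, j]), max(Z[, j]) + 1e-10)
  }
})

test_that("tape-based global forward equals the numeric encoder", {
  cfg <- fast_config(seed = 15)
  model <- dpi_model_init(cfg)
  withr::with_seed(16, X <- matrix(rnorm(12 * cfg$embed_dim), 12))
  enc <- encode_global(X, n_drugs = 5, model)
  tape <- dpisketch:::ad_tape()
  prefs <- lapply(model$params, function(m) dpisketch:::ad_input(tape, m))
  Z <- dpisketch:::ad_value(
    dpisketch:::forward_global_ad(tape, prefs, dpisketch:::ad_input(tape, X), cfg))
  expect_equal(unname(rbind(enc$d_global, enc$p_global)), unname(Z),
               tolerance = 1e-10)
})

test_that("global encoding is permutation-equivariant and feature-determined", {
  cfg <- fast_config(seed = 9)
  model <- dpi_model_init(ablate(cfg, "no_local"))
  withr::with_seed(10, X <- matrix(rnorm(20 * cfg$embed_dim), 20, cfg$embed_dim))
  rownames(X) <- sprintf("n%02d", 1:20)
  enc <- encode_global(X, n_drugs = 8, model)
  out <- rbind(enc$d_global, enc$p_global)

  perm <- withr::with_seed(11, sample(20))
  encP <- encode_global(X[perm, ], n_drugs = 8, model)
  outP <- rbind(encP$d_global, encP$p_global)
  expect_equal(outP, out[perm, ], tolerance = 1e-10)

  # identical input rows receive identical global features
  X2 <- X; X2[2, ] <- X2[1, ]
  enc2 <- encode_global(X2, n_drugs = 8, model)
  expect_equal(enc2$d_global[1, ], enc2$d_global[2, ], tolerance = 1e-12)

  # finite outputs across random inputs
  for (s in 1:20) {
    withr::with_seed(s, Xs <- matrix(rnorm(10 * cfg$embed_dim, sd = 3), 10))
    encS <- encode_global(Xs, n_drugs = 5, model)
    expect_true(all(is.finite(encS$d_global)) && all(is.finite(encS$p_global)))
  }
})
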