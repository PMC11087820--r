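#' Structural subgraph features for a (drug, protein) pair
#'
#' `structural_features` estimates, from propagated sketches, the pairwise
#' neighbourhood-overlap matrix S1 and the beyond-overlap vector S2 that
#' summarize how the k-hop subgraphs of a drug and a protein interlock:
#'
#' * `S1[dd, dp]` = estimated `|N_dd(d) intersect N_dp(p)|` minus the
#'   estimated sizes of every smaller-hop intersection
#'   (`x <= dd`, `y <= dp`, `(x, y) != (dd, dp)`), clamped at 0. Hop-0 terms
#'   are excluded: hop-0 sets are singletons of opposite node types whose
#'   intersection is always empty.
#' * `S2[t]` = estimated `|N_t(d)|` minus `S2[t-1]` minus the sum of
#'   `S1[i, j]` over `i, j <= t`, with base `S2[0] = 0`, clamped at 0 -- a
#'   proxy for nodes near the drug but outside the joint k-hop overlap.
#'
#' Here `N_t(v)` is the walk-t neighbourhood (see [exact_walk_sets()]): the
#' set the sketch propagation represents. In a bipartite graph `N_dd(d)` and
#' `N_dp(p)` lie on a common side only when `dd + dp` is odd, so entries of
#' S1 at even `dd + dp` are structural zeros (up to estimation noise).
#'
#' Both subtractions can go negative under estimation noise (and, for S1, even
#' with exact counts, since raw intersection sizes rather than disjoint counts
#' are subtracted); counts are non-negative by definition, so every entry is
#' clamped at 0.
#'
#' @param sketches propagated [node_sketches][init_sketches()].
#' @param d,p drug and protein node ids.
#' @param k subgraph depth (default: the sketches' propagation depth).
#' @return object of class `structural_feature`: list with `S1` (k x k matrix,
#'   rows dd, cols dp), `S2` (length-k vector, t = 1..k), `drug`, `protein`,
#'   `k`.
#' @seealso [exact_structural_features()] for the brute-force counterpart.
#' @export
structural_features <- function(sketches, d, p, k = sketches$k) {
  if (k > sketches$k) stop("sketches propagated only to depth ", sketches$k)
  Nhat <- matrix(0, k, k)
  for (dd in 1:k) for (dp in 1:k) {
    Nhat[dd, dp] <- estimate_intersection(sketches, d, p, dd, dp)
  }
  ncard <- vapply(1:k, function(t) {
    estimate_cardinality(node_registers(sketches, d, t))
  }, numeric(1))
  assemble_structural(Nhat, ncard, d, p, k)
}

#' Exact structural features via breadth-first search
#'
#' Same S1/S2 formulas as [structural_features()], but every neighbourhood
#' intersection and cardinality is computed by exact set arithmetic on the
#' walk-t sets derived from BFS shells. Used as the test oracle for the
#' sketch-based estimates; the two agree as `num_perm` and `2^precision` grow.
#'
#' @param graph a [bipartite_graph()].
#' @param d,p drug and protein node ids.
#' @param k subgraph depth.
#' @return a `structural_feature` object (see [structural_features()]).
#' @export
exact_structural_features <- function(graph, d, p, k) {
  wd <- exact_walk_sets(graph, d, k)
  wp <- exact_walk_sets(graph, p, k)
  Nex <- matrix(0, k, k)
  for (dd in 1:k) for (dp in 1:k) {
    Nex[dd, dp] <- length(intersect(wd[[dd + 1]], wp[[dp + 1]]))
  }
  ncard <- vapply(1:k, function(t) length(wd[[t + 1]]), numeric(1))
  assemble_structural(Nex, ncard, d, p, k)
}

# Shared assembly of S1/S2 from a matrix of (estimated or exact) intersection
# sizes and the drug-side neighbourhood cardinalities.
assemble_structural <- function(Nmat, ncard, d, p, k) {
  S1 <- matrix(0, k, k, dimnames = list(dd = 1:k, dp = 1:k))
  for (dd in 1:k) for (dp in 1:k) {
    sub <- sum(Nmat[1:dd, 1:dp]) - Nmat[dd, dp]
    S1[dd, dp] <- max(0, Nmat[dd, dp] - sub)
  }
  S2 <- numeric(k)
  prev <- 0
  for (t in 1:k) {
    S2[t] <- max(0, ncard[t] - prev - sum(S1[1:t, 1:t]))
    prev <- S2[t]
  }
  structure(list(S1 = S1, S2 = S2, drug = d, protein = p, k = k),
            class = "structural_feature")
}

#' @export
print.structural_feature <- function(x, ...) {
  cat(sprintf("structural_feature for (%s, %s), k = %d\n", x$drug, x$protein, x$k))
  cat("S1 (rows dd, cols dp):\n"); print(round(x$S1, 2))
  cat("S2:", paste(round(x$S2, 2), collapse = " "), "\n")
  invisible(x)
}

#' Batch structural features for many pairs
#'
#' Vectorized equivalent of calling [structural_features()] per pair; used by
#' the encoders, where thousands of (drug, protein) pairs are featurized at
#' once.
#'
#' @param sketches propagated `node_sketches`.
#' @param pairs data.frame with character columns `drug` and `protein`.
#' @param k subgraph depth.
#' @return list with `S1` (array n_pairs x k x k) and `S2`
#'   (matrix n_pairs x k).
#' @export
structural_features_batch <- function(sketches, pairs, k = sketches$k) {
  if (k > sketches$k) stop("sketches propagated only to depth ", sketches$k)
  n <- nrow(pairs)
  di <- unname(sketches$node_index[pairs$drug])
  pj <- unname(sketches$node_index[pairs$protein])
  if (anyNA(di) || anyNA(pj)) stop("pair references a node missing from the sketches")
  m <- 2^sketches$precision
  alpha <- hll_alpha(m)

  hll_est_cols <- function(regmat) {
    est <- alpha * m^2 / colSums(2^(-regmat))
    v <- colSums(regmat == 0)
    small <- est <= 2.5 * m & v > 0
    est[small] <- m * log(m / v[small])
    est
  }

  Nhat <- array(0, dim = c(n, k, k))
  for (dd in 1:k) {
    sig_d <- sketches$minhash[[dd + 1]][, di, drop = FALSE]
    reg_d <- sketches$hll[[dd + 1]][, di, drop = FALSE]
    for (dp in 1:k) {
      sig_p <- sketches$minhash[[dp + 1]][, pj, drop = FALSE]
      reg_p <- sketches$hll[[dp + 1]][, pj, drop = FALSE]
      jac <- colMeans(sig_d == sig_p)
      uni <- hll_est_cols(pmax(reg_d, reg_p))
      Nhat[, dd, dp] <- jac * uni
    }
  }
  ncard <- matrix(0, n, k)
  for (t in 1:k) {
    ncard[, t] <- hll_est_cols(sketches$hll[[t + 1]][, di, drop = FALSE])
  }

  S1 <- array(0, dim = c(n, k, k))
  for (dd in 1:k) for (dp in 1:k) {
    sub <- apply(Nhat[, 1:dd, 1:dp, drop = FALSE], 1, sum) - Nhat[, dd, dp]
    S1[, dd, dp] <- pmax(0, Nhat[, dd, dp] - sub)
  }
  S2 <- matrix(0, n, k)
  prev <- numeric(n)
  for (t in 1:k) {
    S2[, t] <- pmax(0, ncard[, t] - prev - apply(S1[, 1:t, 1:t, drop = FALSE], 1, sum))
    prev <- S2[, t]
  }
  list(S1 = S1, S2 = S2, k = k, pairs = pairs)
}

#' Export structural features for a set of pairs to TSV
#'
#' Writes one row per pair: ids, flattened S1 (row-major in (dd, dp)) and S2,
#' plus a JSON sidecar recording `num_perm`, `precision`, `k` and the hash
#' seed.
#'
#' @inheritParams structural_features_batch
#' @param path output TSV path (sidecar is `<path>.json`).
#' @return `path`, invisibly.
#' @export
export_structural_features <- function(sketches, pairs, path, k = sketches$k) {
  fb <- structural_features_batch(sketches, pairs, k)
  cols <- list(drug_id = pairs$drug, protein_id = pairs$protein)
  for (dd in 1:k) for (dp in 1:k) {
    cols[[sprintf("S1_%d_%d", dd, dp)]] <- fb$S1[, dd, dp]
  }
  for (t in 1:k) cols[[sprintf("S2_%d", t)]] <- fb$S2[, t]
  write.table(as.data.frame(cols), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(num_perm = sketches$num_perm,
                            precision = sketches$precision, k = k,
                            seed = sketches$seed),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
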