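#' MinHash signature of a set of string items
#'
#' One signature slot per hash permutation; slot i holds the minimum over the
#' set of the i-th seeded 64-bit hash (truncated to 53 bits so the value is
#' exact in a double). The empty set has all slots `Inf`, the identity of the
#' min-merge, so the union algebra `min(sig_A, sig_B) == sig(A union B)` is
#' bit-exact.
#'
#' @param items character vector of set elements (duplicates are harmless).
#' @param num_perm number of hash permutations (>= 16).
#' @param seed integer hash-family seed.
#' @return numeric vector of class `minhash_signature` with attributes
#'   `num_perm` and `seed`.
#' @export
minhash_signature <- function(items, num_perm = 256L, seed = 1L) {
  if (num_perm < 16) stop("num_perm must be >= 16")
  items <- unique(as.character(items))
  sig <- if (length(items) == 0) {
    rep(Inf, num_perm)
  } else {
    h <- minhash_hash_keys(items, as.integer(num_perm), as.double(seed))
    apply(h, 1, min)
  }
  structure(sig, num_perm = as.integer(num_perm), seed = as.integer(seed),
            class = "minhash_signature")
}

#' HyperLogLog registers of a set of string items
#'
#' `2^precision` rank registers under a single seeded 64-bit hash. Register
#' merge is elementwise max, which is exact for set union; the empty sketch is
#' all zeros and estimates cardinality 0.
#'
#' @inheritParams minhash_signature
#' @param precision register-index bit width p, in 4..16 (2^p registers).
#' @return integer vector of class `hll_registers` with attributes `precision`
#'   and `seed`.
#' @export
hll_registers <- function(items, precision = 10L, seed = 1L) {
  if (precision < 4 || precision > 16) stop("hll precision must be in [4, 16]")
  m <- 2L^as.integer(precision)
  reg <- integer(m)
  items <- unique(as.character(items))
  if (length(items) > 0) {
    h <- hll_hash_keys(items, as.integer(precision), as.double(seed))
    for (j in seq_along(items)) {
      i <- h$index[j]
      if (h$rank[j] > reg[i]) reg[i] <- h$rank[j]
    }
  }
  structure(reg, precision = as.integer(precision), seed = as.integer(seed),
            class = "hll_registers")
}

#' Union merge of two sketches
#'
#' Exact algebra: the MinHash signature of a union is the elementwise minimum
#' of the operands' signatures; the HLL registers of a union are the
#' elementwise maximum.
#'
#' @param x,y two `minhash_signature`s or two `hll_registers` built with the
#'   same parameters and seed.
#' @return a sketch of the union, same class as the inputs.
#' @export
sketch_union <- function(x, y) {
  if (inherits(x, "minhash_signature") && inherits(y, "minhash_signature")) {
    check_same_family(x, y)
    return(structure(pmin(unclass(x), unclass(y)),
                     num_perm = attr(x, "num_perm"), seed = attr(x, "seed"),
                     class = "minhash_signature"))
  }
  if (inherits(x, "hll_registers") && inherits(y, "hll_registers")) {
    check_same_family(x, y)
    return(structure(pmax(unclass(x), unclass(y)),
                     precision = attr(x, "precision"), seed = attr(x, "seed"),
                     class = "hll_registers"))
  }
  stop("sketch_union needs two sketches of the same class")
}

check_same_family <- function(x, y) {
  if (length(x) != length(y)) stop("sketch lengths differ")
  if (!identical(attr(x, "seed"), attr(y, "seed"))) {
    stop("sketches built with different hash seeds are not comparable")
  }
  invisible(TRUE)
}

#' Estimate Jaccard similarity from two MinHash signatures
#'
#' The Hamming similarity of the signatures: the fraction of positions at
#' which the two minimum hash values agree, an unbiased estimator of
#' `|A intersect B| / |A union B|` with standard error about
#' `sqrt(J(1-J)/num_perm)`.
#'
#' @param bx,by `minhash_signature`s with equal `num_perm` and seed.
#' @return numeric scalar in \[0, 1\].
#' @export
estimate_jaccard <- function(bx, by) {
  if (!inherits(bx, "minhash_signature") || !inherits(by, "minhash_signature")) {
    stop("estimate_jaccard expects minhash_signature objects")
  }
  check_same_family(bx, by)
  mean(unclass(bx) == unclass(by))
}

# alpha_m bias-correction constant of the HLL harmonic-mean estimator
hll_alpha <- function(m) {
  if (m == 16) 0.673
  else if (m == 32) 0.697
  else if (m == 64) 0.709
  else 0.7213 / (1 + 1.079 / m)
}

#' Estimate set cardinality from HLL registers
#'
#' Harmonic-mean estimate `alpha_m m^2 / sum(2^-M_j)` with the standard
#' small-range correction: when the raw estimate is below `2.5 m` and empty
#' registers remain, linear counting `m log(m / V)` is used instead (`V` =
#' number of zero registers). The hash is 64-bit, so the classical 32-bit
#' large-range correction never activates at realistic cardinalities.
#'
#' @param a an `hll_registers` object.
#' @return non-negative numeric estimate; exactly 0 for the empty sketch.
#' @export
estimate_cardinality <- function(a) {
  if (!inherits(a, "hll_registers")) stop("expects an hll_registers object")
  reg <- unclass(a)
  m <- length(reg)
  est <- hll_alpha(m) * m^2 / sum(2^(-reg))
  v <- sum(reg == 0)
  if (est <= 2.5 * m && v > 0) est <- m * log(m / v)
  est
}

#' Per-node, per-hop sketches over a bipartite graph
#'
#' `init_sketches` builds the hop-0 sketches: for every node v, the MinHash
#' signature and HLL registers of the singleton set \{v\}. Hashing is keyed by
#' `(seed, permutation index)` over the node-id string, so identical calls are
#' bit-identical across platforms.
#'
#' @param graph a [bipartite_graph()].
#' @param num_perm MinHash permutations (default 256).
#' @param hll_precision HLL precision p (default 10, i.e. 1024 registers).
#' @param seed hash-family seed.
#' @return object of class `node_sketches`: matrices `minhash[[t+1]]`
#'   (`num_perm` x n nodes) and `hll[[t+1]]` (`2^p` x n) for hop t = 0, plus
#'   node bookkeeping. Extend to hops 1..k with [propagate_sketches()].
#' @export
init_sketches <- function(graph, num_perm = 256L, hll_precision = 10L, seed = 1L) {
  if (num_perm < 16) stop("num_perm must be >= 16")
  if (hll_precision < 4 || hll_precision > 16) stop("hll precision must be in [4, 16]")
  nodes <- graph_nodes(graph)
  n <- length(nodes)
  mh <- minhash_hash_keys(nodes, as.integer(num_perm), as.double(seed))
  colnames(mh) <- nodes
  m <- 2L^as.integer(hll_precision)
  hh <- hll_hash_keys(nodes, as.integer(hll_precision), as.double(seed))
  reg <- matrix(0L, nrow = m, ncol = n, dimnames = list(NULL, nodes))
  reg[cbind(hh$index, seq_len(n))] <- hh$rank
  structure(list(minhash = list(mh), hll = list(reg), nodes = nodes,
                 node_index = stats::setNames(seq_len(n), nodes),
                 num_perm = as.integer(num_perm),
                 precision = as.integer(hll_precision),
                 seed = as.integer(seed), k = 0L),
            class = "node_sketches")
}

#' Propagate node sketches to hops 1..k
#'
#' One propagation step realizes the neighbour merge: the hop-t HLL registers
#' of node v are the elementwise max over v's neighbours' hop t-1 registers,
#' and the hop-t MinHash signature the elementwise min. By the exact union
#' algebra, the hop-t sketch therefore represents the set of nodes reachable
#' from v by a walk of length exactly t (see [exact_walk_sets()]). Isolated
#' nodes get empty-set sketches at every hop t >= 1.
#'
#' @param graph the same [bipartite_graph()] the sketches were built on.
#' @param sketches a [init_sketches()] result.
#' @param k target depth (default 3).
#' @return the `node_sketches` object with hops 0..k populated.
#' @export
propagate_sketches <- function(graph, sketches, k = 3L) {
  stopifnot(inherits(sketches, "node_sketches"))
  if (k <= sketches$k) return(sketches)
  nodes <- sketches$nodes
  n <- length(nodes)
  m <- nrow(sketches$hll[[1]])
  nb_idx <- lapply(graph$adj[nodes], function(nb) unname(sketches$node_index[nb]))
  for (t in (sketches$k + 1L):k) {
    prev_mh <- sketches$minhash[[t]]
    prev_reg <- sketches$hll[[t]]
    mh <- matrix(Inf, nrow = sketches$num_perm, ncol = n,
                 dimnames = list(NULL, nodes))
    reg <- matrix(0L, nrow = m, ncol = n, dimnames = list(NULL, nodes))
    for (v in seq_len(n)) {
      nb <- nb_idx[[v]]
      if (length(nb) == 1) {
        mh[, v] <- prev_mh[, nb]
        reg[, v] <- prev_reg[, nb]
      } else if (length(nb) > 1) {
        mh[, v] <- do.call(pmin, asplit(prev_mh[, nb, drop = FALSE], 2))
        reg[, v] <- do.call(pmax, asplit(prev_reg[, nb, drop = FALSE], 2))
      }
    }
    sketches$minhash[[t + 1L]] <- mh
    sketches$hll[[t + 1L]] <- reg
  }
  sketches$k <- as.integer(k)
  sketches
}

#' Extract one node's sketch at a given hop
#'
#' @param sketches a `node_sketches` object.
#' @param node node id.
#' @param hop hop t in 0..k.
#' @return `node_signature`: a `minhash_signature`; `node_registers`: an
#'   `hll_registers`.
#' @export
node_signature <- function(sketches, node, hop) {
  idx <- sketch_node_idx(sketches, node, hop)
  structure(sketches$minhash[[hop + 1L]][, idx],
            num_perm = sketches$num_perm, seed = sketches$seed,
            class = "minhash_signature")
}

#' @rdname node_signature
#' @export
node_registers <- function(sketches, node, hop) {
  idx <- sketch_node_idx(sketches, node, hop)
  structure(as.integer(sketches$hll[[hop + 1L]][, idx]),
            precision = sketches$precision, seed = sketches$seed,
            class = "hll_registers")
}

sketch_node_idx <- function(sketches, node, hop) {
  if (hop < 0 || hop > sketches$k) {
    stop("hop ", hop, " outside propagated range 0..", sketches$k)
  }
  idx <- sketches$node_index[node]
  if (is.na(idx)) stop("unknown node: ", node)
  unname(idx)
}

#' Estimate the size of the intersection of two hop neighbourhoods
#'
#' For drug d and protein p, estimates `|N_dd(d) intersect N_dp(p)|` as the
#' product of the MinHash Jaccard estimate and the HLL estimate of the union
#' cardinality (union registers = elementwise max):
#' `H(b_d^dd, b_p^dp) * hyper(max(a_d^dd, a_p^dp))`.
#'
#' @param sketches propagated `node_sketches`.
#' @param d,p node ids (any two nodes; typically a drug and a protein).
#' @param dd,dp hop depths for d and p, each in 0..k.
#' @return non-negative numeric estimate.
#' @export
estimate_intersection <- function(sketches, d, p, dd, dp) {
  bx <- node_signature(sketches, d, dd)
  by <- node_signature(sketches, p, dp)
  ax <- node_registers(sketches, d, dd)
  ay <- node_registers(sketches, p, dp)
  estimate_jaccard(bx, by) * estimate_cardinality(sketch_union(ax, ay))
}
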