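#' Structural edge-feature vector for one pair and layer
#'
#' Assembles the layer-l edge embedding from a pair's structural features:
#' `[S2[l], S1[1,l], ..., S1[l-1,l], S1[l,1], ..., S1[l,l-1]]`, zero-padded to
#' a fixed length of `2k + 1`. The final padding slot carries the observed
#' edge weight (1 for training-graph edges, 0 for non-edges), which is
#' otherwise undefined for binary interaction data.
#'
#' @param feat a [structural_features()] result (estimated or exact).
#' @param layer GNN layer index l, `1 <= layer <= k`.
#' @param k subgraph depth (default: the feature's depth).
#' @param weight observed-edge weight placed in the last slot.
#' @return numeric vector of length `2k + 1`.
#' @export
build_edge_features <- function(feat, layer, k = feat$k, weight = 1) {
  if (layer < 1) stop("layer must be >= 1")
  if (layer > k) stop("layer ", layer, " exceeds subgraph depth k = ", k)
  v <- numeric(2L * k + 1L)
  v[1] <- feat$S2[layer]
  if (layer > 1) {
    lo <- seq_len(layer - 1)
    v[1 + lo] <- feat$S1[lo, layer]
    v[layer + lo] <- feat$S1[layer, lo]
  }
  v[2L * k + 1L] <- weight
  v
}

# Batch edge-feature matrix (n_edges x (2k+1)) for layer l from a
# structural_features_batch() result. Count entries are log1p-compressed
# before entering the encoder: subgraph counts are heavy-tailed and raw
# magnitudes would dominate the linear message maps.
edge_feature_matrix <- function(fb, layer, weight = 1, compress = log1p) {
  k <- fb$k
  if (layer > k) stop("layer exceeds k")
  n <- nrow(fb$S2)
  E <- matrix(0, n, 2L * k + 1L)
  E[, 1] <- fb$S2[, layer]
  if (layer > 1) {
    for (x in seq_len(layer - 1)) {
      E[, 1 + x] <- fb$S1[, x, layer]
      E[, layer + x] <- fb$S1[, layer, x]
    }
  }
  E <- compress(E)
  E[, 2L * k + 1L] <- weight
  E
}

# Precompute the message-passing scaffold of a graph: directed edge endpoints
# (receiver, neighbour), the mean-aggregation sparse matrix, and per-layer
# edge-feature matrices from the training-edge structural features.
local_graph_structure <- function(graph, sketches, k, layers) {
  nodes <- graph_nodes(graph)
  nidx <- stats::setNames(seq_along(nodes), nodes)
  ed <- graph$edges
  recv <- c(nidx[ed$drug], nidx[ed$protein])
  nbr <- c(nidx[ed$protein], nidx[ed$drug])
  ne <- length(recv)
  deg <- tabulate(recv, nbins = length(nodes))
  S <- Matrix::sparseMatrix(i = recv, j = seq_len(ne),
                            x = 1 / deg[recv],
                            dims = c(length(nodes), ne))
  fb <- structural_features_batch(sketches, ed, k)
  efeats <- lapply(seq_len(layers), function(l) {
    E1 <- edge_feature_matrix(fb, l, weight = 1)
    rbind(E1, E1) # same undirected pair feeds both directions
  })
  list(recv = recv, nbr = nbr, S = S, efeats = efeats, nodes = nodes,
       node_index = nidx)
}

# Tape-based forward pass of the local GNN; returns the ad_ref of the final
# node-embedding matrix (nodes in graph order).
forward_local_ad <- function(tape, prefs, X0ref, ls, config) {
  x <- X0ref
  L <- config$local_layers
  for (l in seq_len(L)) {
    Eref <- ad_input(tape, ls$efeats[[l]])
    msg_in <- ad_cbind(ad_rows(x, ls$recv), ad_rows(x, ls$nbr), Eref)
    M <- ad_add(ad_matmul(msg_in, prefs[[paste0("local.tau", l, ".W")]]),
                prefs[[paste0("local.tau", l, ".b")]])
    agg <- ad_spmatmul(ls$S, M)
    x <- ad_add(ad_matmul(ad_cbind(x, agg), prefs[[paste0("local.phi", l, ".W")]]),
                prefs[[paste0("local.phi", l, ".b")]])
    if (l < L) x <- ad_relu(x)
  }
  x
}

#' One GNN message-passing layer with structural edge features
#'
#' For every node v, messages `tau([x_v || x_u || e_{v,u}])` from each
#' neighbour u are averaged (isolated nodes receive a zero aggregate) and
#' combined through `phi([x_v || aggregate])`. `tau` and `phi` are trainable
#' linear maps applied to concatenations.
#'
#' @param x node-embedding matrix, one row per node in `graph_nodes()` order.
#' @param graph a [bipartite_graph()].
#' @param edge_feats matrix of edge-feature vectors, one row per edge of
#'   `graph$edges` (see [build_edge_features()]).
#' @param tau_W,tau_b,phi_W,phi_b linear-map parameters.
#' @param activation apply ReLU to the output (used between layers, not after
#'   the last).
#' @return updated node-embedding matrix.
#' @export
gnn_layer <- function(x, graph, edge_feats, tau_W, tau_b, phi_W, phi_b,
                      activation = TRUE) {
  nodes <- graph_nodes(graph)
  if (nrow(x) != length(nodes)) stop("x must have one row per node")
  nidx <- stats::setNames(seq_along(nodes), nodes)
  ed <- graph$edges
  if (nrow(edge_feats) != nrow(ed)) stop("edge_feats must have one row per edge")
  recv <- c(nidx[ed$drug], nidx[ed$protein])
  nbr <- c(nidx[ed$protein], nidx[ed$drug])
  E2 <- rbind(edge_feats, edge_feats)
  if (ncol(x) * 2 + ncol(E2) != nrow(tau_W)) stop("dimension mismatch in tau")
  M <- cbind(x[recv, , drop = FALSE], x[nbr, , drop = FALSE], E2) %*% tau_W
  M <- sweep(M, 2, as.numeric(tau_b), "+")
  agg <- matrix(0, length(nodes), ncol(M))
  if (length(recv) > 0) {
    sums <- rowsum(M, group = recv)
    deg <- tabulate(recv, nbins = length(nodes))
    rows <- as.integer(rownames(sums))
    agg[rows, ] <- sums / deg[rows]
  }
  if (ncol(x) + ncol(agg) != nrow(phi_W)) stop("dimension mismatch in phi")
  out <- cbind(x, agg) %*% phi_W
  out <- sweep(out, 2, as.numeric(phi_b), "+")
  if (activation) out <- pmax(out, 0)
  rownames(out) <- nodes
  out
}

#' Encode local node features with the sketch-informed GNN
#'
#' Stacks [gnn_layer()] applications on the training-only graph, injecting the
#' per-layer structural edge features of every observed edge, and returns the
#' final drug-side and protein-side embedding matrices.
#'
#' @param graph the training-only [bipartite_graph()].
#' @param X0 initial feature matrix (one row per node, drugs first).
#' @param model a [dpi_model_init()] result holding the `local.*` parameters
#'   (mode `"full"` or `"no_global"`).
#' @param sketches optional propagated sketches on `graph`; built on the fly
#'   when missing.
#' @return list with `d_local` and `p_local` matrices (rows named by id).
#' @export
encode_local <- function(graph, X0, model, sketches = NULL) {
  config <- model$config
  if (is.null(model$params[["local.tau1.W"]])) {
    stop("model has no local encoder (mode '", config$mode, "')")
  }
  if (nrow(X0) != length(graph_nodes(graph))) {
    stop("X0 must have one row per node (drugs first)")
  }
  if (is.null(sketches)) {
    sketches <- propagate_sketches(
      graph, init_sketches(graph, config$num_perm, config$hll_precision,
                           derive_seed(config$seed, "sketch")), config$k)
  }
  ls <- local_graph_structure(graph, sketches, config$k, config$local_layers)
  tape <- ad_tape()
  prefs <- lapply(model$params, function(m) ad_input(tape, m))
  out <- ad_value(forward_local_ad(tape, prefs, ad_input(tape, X0), ls, config))
  rownames(out) <- graph_nodes(graph)
  nd <- length(graph$drugs)
  list(d_local = out[seq_len(nd), , drop = FALSE],
       p_local = out[-seq_len(nd), , drop = FALSE])
}
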