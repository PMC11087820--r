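#' Bipartite drug-protein interaction graph
#'
#' Container for an undirected bipartite graph whose two node sides are drugs
#' and proteins and whose edges are observed interactions. Drug and protein
#' identifiers must be disjoint sets, since nodes are addressed by id
#' throughout the package.
#'
#' @param drugs character vector of drug node ids (order is preserved).
#' @param proteins character vector of protein node ids.
#' @param edges data.frame with character columns `drug` and `protein`; one row
#'   per interaction. Duplicate rows are collapsed to a single edge.
#'
#' @return An object of class `bipartite_graph` with elements `drugs`,
#'   `proteins`, `edges` (deduplicated data.frame), `adj` (named list of
#'   neighbour id vectors), and `side` (named character vector, `"drug"` or
#'   `"protein"` per node).
#' @export
#' @examples
#' g <- bipartite_graph(c("d1", "d2"), c("p1", "p2"),
#'                      data.frame(drug = c("d1", "d1", "d2"),
#'                                 protein = c("p1", "p2", "p1")))
#' graph_degree(g, "d1")
bipartite_graph <- function(drugs, proteins, edges) {
  drugs <- as.character(drugs)
  proteins <- as.character(proteins)
  if (anyDuplicated(drugs)) stop("duplicate drug ids")
  if (anyDuplicated(proteins)) stop("duplicate protein ids")
  overlap <- intersect(drugs, proteins)
  if (length(overlap) > 0) {
    stop("drug and protein id sets must be disjoint; shared ids: ",
         paste(head(overlap, 3), collapse = ", "))
  }
  if (!is.data.frame(edges) || !all(c("drug", "protein") %in% names(edges))) {
    stop("edges must be a data.frame with columns 'drug' and 'protein'")
  }
  edges <- data.frame(drug = as.character(edges$drug),
                      protein = as.character(edges$protein),
                      stringsAsFactors = FALSE)
  bad_d <- setdiff(edges$drug, drugs)
  if (length(bad_d) > 0) stop("edge references unknown drug: ", bad_d[1])
  bad_p <- setdiff(edges$protein, proteins)
  if (length(bad_p) > 0) stop("edge references unknown protein: ", bad_p[1])
  key <- paste(edges$drug, edges$protein, sep = "\t")
  dup <- duplicated(key)
  if (any(dup)) edges <- edges[!dup, , drop = FALSE]
  rownames(edges) <- NULL

  side <- c(rep("drug", length(drugs)), rep("protein", length(proteins)))
  names(side) <- c(drugs, proteins)

  adj <- vector("list", length(side))
  names(adj) <- names(side)
  adj[] <- list(character(0))
  if (nrow(edges) > 0) {
    by_d <- split(edges$protein, edges$drug)
    by_p <- split(edges$drug, edges$protein)
    adj[names(by_d)] <- by_d
    adj[names(by_p)] <- by_p
  }

  structure(list(drugs = drugs, proteins = proteins, edges = edges,
                 adj = adj, side = side,
                 n_duplicates_dropped = sum(dup)),
            class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("bipartite_graph: %d drugs, %d proteins, %d edges\n",
              length(x$drugs), length(x$proteins), nrow(x$edges)))
  invisible(x)
}

#' Neighbours, degree and edge membership
#'
#' @param graph a [bipartite_graph()].
#' @param node a node id present in the graph.
#' @return `graph_neighbors` returns the character vector of adjacent node ids
#'   (proteins for a drug, drugs for a protein); `graph_degree` its length;
#'   `graph_has_edge` a logical.
#' @export
graph_neighbors <- function(graph, node) {
  if (!node %in% names(graph$side)) stop("unknown node: ", node)
  graph$adj[[node]]
}

#' @rdname graph_neighbors
#' @export
graph_degree <- function(graph, node) length(graph_neighbors(graph, node))

#' @rdname graph_neighbors
#' @param drug,protein endpoints of the queried edge.
#' @export
graph_has_edge <- function(graph, drug, protein) {
  paste(drug, protein, sep = "\t") %in%
    paste(graph$edges$drug, graph$edges$protein, sep = "\t")
}

#' All node ids of a graph, drugs first
#' @param graph a [bipartite_graph()].
#' @return character vector of node ids.
#' @export
graph_nodes <- function(graph) c(graph$drugs, graph$proteins)

# Internal strict bipartiteness check via two-colouring from scratch; used by
# property tests, not on the construction hot path (construction enforces the
# invariant structurally).
check_bipartite <- function(graph) {
  col <- graph$side
  for (i in seq_len(nrow(graph$edges))) {
    d <- graph$edges$drug[i]; p <- graph$edges$protein[i]
    if (col[[d]] == col[[p]]) return(FALSE)
    if (d == p) return(FALSE)
  }
  all(vapply(graph$drugs, function(d) {
    all(graph$side[graph$adj[[d]]] == "protein")
  }, logical(1))) &&
    all(vapply(graph$proteins, function(p) {
      all(graph$side[graph$adj[[p]]] == "drug")
    }, logical(1)))
}

#' Exact k-hop shells of a node (breadth-first search)
#'
#' Returns the sets of nodes at graph distance exactly 0, 1, ..., k from
#' `node`. Shells are pairwise disjoint and shell 0 is the node itself;
#' unreachable distances yield empty shells. This is the brute-force
#' neighbourhood oracle against which all sketch estimators are tested.
#'
#' @param graph a [bipartite_graph()].
#' @param node node id.
#' @param k maximum hop distance, non-negative integer.
#' @return list of length `k + 1`; element `t + 1` is the character vector of
#'   nodes at distance exactly `t`.
#' @export
exact_khop_shells <- function(graph, node, k) {
  if (!node %in% names(graph$side)) stop("unknown node: ", node)
  if (k < 0) stop("k must be >= 0")
  shells <- vector("list", k + 1)
  shells[[1]] <- node
  visited <- node
  frontier <- node
  for (t in seq_len(k)) {
    nxt <- unique(unlist(graph$adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, visited)
    shells[[t + 1]] <- if (is.null(nxt)) character(0) else nxt
    visited <- c(visited, nxt)
    frontier <- nxt
    if (length(frontier) == 0 && t < k) {
      for (s in (t + 1):k) shells[[s + 1]] <- character(0)
      break
    }
  }
  shells
}

#' Exact walk-reachable node sets per hop
#'
#' The hop-t set is defined as all nodes reachable from `node` by a walk of
#' length exactly `t`. This is precisely the set that the sketch propagation
#' rule (neighbour min/max merge of hop t-1 sketches) represents. In a
#' bipartite graph it equals the union of the exact-distance shells
#' t, t-2, t-4, ... (same parity), so hop-t sets of a drug alternate strictly
#' between the protein side (odd t) and the drug side (even t).
#'
#' @inheritParams exact_khop_shells
#' @return list of length `k + 1` of node id vectors; element `t + 1` is the
#'   walk-t set.
#' @export
exact_walk_sets <- function(graph, node, k) {
  shells <- exact_khop_shells(graph, node, k)
  out <- vector("list", k + 1)
  for (t in 0:k) {
    idx <- seq(t, 0, by = -2) + 1
    out[[t + 1]] <- unique(unlist(shells[idx], use.names = FALSE))
    if (is.null(out[[t + 1]])) out[[t + 1]] <- character(0)
  }
  # a walk of length t>=1 exists only if the node has at least one neighbour
  if (graph_degree(graph, node) == 0 && k >= 1) {
    for (t in 1:k) out[[t + 1]] <- character(0)
  }
  out
}

#' Random-walk k-hop subgraph extraction
#'
#' Union of the nodes visited by `walks` independent random walks of `k` steps
#' started at `node`. Always a subset of the exact <= k-hop ball; converges to
#' it as `walks` grows. Provided for scalability parity; the deterministic
#' exact shells are the default feature path.
#'
#' @inheritParams exact_khop_shells
#' @param walks number of random walks (>= 1).
#' @param seed integer seed.
#' @return character vector of visited node ids (including `node`).
#' @export
random_walk_subgraph <- function(graph, node, k, walks, seed) {
  if (walks < 1) stop("walks must be >= 1")
  if (k < 1) stop("k must be >= 1")
  if (!node %in% names(graph$side)) stop("unknown node: ", node)
  withr::with_seed(seed, {
    visited <- node
    for (w in seq_len(walks)) {
      cur <- node
      for (s in seq_len(k)) {
        nb <- graph$adj[[cur]]
        if (length(nb) == 0) break
        cur <- nb[[sample.int(length(nb), 1)]]
        visited <- c(visited, cur)
      }
    }
    unique(visited)
  })
}
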