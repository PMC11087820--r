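#' Specification of a synthetic planted-community DPI benchmark
#'
#' A bipartite planted-partition model: drugs and proteins are assigned
#' uniformly to `n_communities` communities; each (drug, protein) pair is an
#' interaction independently with probability `p_in` inside a community and
#' `p_out` across. Within-community excess of common neighbours makes the
#' sketch channel informative, and community-templated strings make the
#' embedding channel informative, so both feature paths carry learnable
#' signal. The defaults are the package's standard benchmark.
#'
#' @param n_drugs,n_proteins node counts (defaults 200 / 200).
#' @param n_communities number of planted communities C (default 4).
#' @param p_in,p_out within- and cross-community edge probabilities
#'   (defaults 0.2 / 0.01); requires `0 <= p_out < p_in <= 1`.
#' @param drug_template_len,protein_template_len lengths of the per-community
#'   template strings.
#' @param mutation_rate per-character mutation probability applied to each
#'   node's copy of its community template (default 0.1).
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 200L, n_proteins = 200L,
                           n_communities = 4L, p_in = 0.2, p_out = 0.01,
                           drug_template_len = 40L, protein_template_len = 120L,
                           mutation_rate = 0.1, seed = 0L) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  if (n_communities < 1) stop("need at least one community")
  structure(as.list(environment()), class = "synthetic_spec")
}

# character sets: SMILES-shaped for drugs (syntax-shaped, not chemically
# valid), the 20-letter amino-acid alphabet for proteins
smiles_alphabet <- function() {
  c("C", "N", "O", "S", "P", "F", "I", "c", "n", "o", "s",
    "(", ")", "=", "#", "1", "2", "3")
}
aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a planted-community bipartite graph
#'
#' @param spec a [synthetic_spec()].
#' @return list with `graph` (a [bipartite_graph()]) and `communities` (named
#'   integer vector of hidden community labels per node).
#' @export
generate_graph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(derive_seed(spec$seed, "graph"), {
    drugs <- sprintf("D%04d", seq_len(spec$n_drugs))
    proteins <- sprintf("P%04d", seq_len(spec$n_proteins))
    cd <- sample.int(spec$n_communities, spec$n_drugs, replace = TRUE)
    cp <- sample.int(spec$n_communities, spec$n_proteins, replace = TRUE)
    prob <- ifelse(outer(cd, cp, "=="), spec$p_in, spec$p_out)
    hit <- matrix(runif(length(prob)) < prob, nrow = spec$n_drugs)
    idx <- which(hit, arr.ind = TRUE)
    g <- bipartite_graph(drugs, proteins,
                         data.frame(drug = drugs[idx[, 1]],
                                    protein = proteins[idx[, 2]]))
    list(graph = g,
         communities = stats::setNames(c(cd, cp), c(drugs, proteins)))
  })
}

#' Generate community-templated strings for every node
#'
#' Each community receives a random template (SMILES-shaped characters for
#' drugs, amino-acid letters for proteins); each node's string is its
#' community template with independent per-character mutations at
#' `spec$mutation_rate`, so within-community strings are more similar than
#' cross-community ones.
#'
#' @param graph the generated [bipartite_graph()].
#' @param communities hidden labels from [generate_graph()].
#' @param spec the [synthetic_spec()].
#' @return list with character vectors `smiles` (named by drug id) and
#'   `sequences` (named by protein id).
#' @export
generate_strings <- function(graph, communities, spec) {
  mutate_string <- function(template, alphabet, rate) {
    chars <- strsplit(template, "")[[1]]
    flip <- runif(length(chars)) < rate
    if (any(flip)) {
      chars[flip] <- sample(alphabet, sum(flip), replace = TRUE)
    }
    paste(chars, collapse = "")
  }
  withr::with_seed(derive_seed(spec$seed, "strings"), {
    d_templates <- vapply(seq_len(spec$n_communities), function(c) {
      paste(sample(smiles_alphabet(), spec$drug_template_len, replace = TRUE),
            collapse = "")
    }, character(1))
    p_templates <- vapply(seq_len(spec$n_communities), function(c) {
      paste(sample(aa_alphabet(), spec$protein_template_len, replace = TRUE),
            collapse = "")
    }, character(1))
    smiles <- vapply(graph$drugs, function(d) {
      mutate_string(d_templates[communities[[d]]], smiles_alphabet(),
                    spec$mutation_rate)
    }, character(1))
    sequences <- vapply(graph$proteins, function(p) {
      mutate_string(p_templates[communities[[p]]], aa_alphabet(),
                    spec$mutation_rate)
    }, character(1))
    list(smiles = smiles, sequences = sequences)
  })
}

#' Generate a complete synthetic dataset
#'
#' Bundles [generate_graph()] and [generate_strings()] and, optionally,
#' writes the standard interaction TSV (every positive edge as a label-1 row;
#' isolated nodes are kept representable through label-0 rows) plus a JSON
#' sidecar with the hidden community labels.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory; when given, writes
#'   `interactions.tsv` and `communities.json` there.
#' @return list with `graph`, `communities`, `smiles`, `sequences`, `pairs`
#'   (the TSV rows as a data.frame), and `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec(), dir = NULL) {
  gg <- generate_graph(spec)
  st <- generate_strings(gg$graph, gg$communities, spec)
  g <- gg$graph
  pairs <- data.frame(drug_id = g$edges$drug,
                      smiles = unname(st$smiles[g$edges$drug]),
                      protein_id = g$edges$protein,
                      sequence = unname(st$sequences[g$edges$protein]),
                      label = 1L, stringsAsFactors = FALSE)
  # keep isolated nodes representable: pair them with the first counterpart
  # node as an explicit label-0 row
  iso_d <- g$drugs[vapply(g$drugs, function(d) graph_degree(g, d) == 0, logical(1))]
  iso_p <- g$proteins[vapply(g$proteins, function(p) graph_degree(g, p) == 0, logical(1))]
  if (length(iso_d) > 0 && length(g$proteins) > 0) {
    pairs <- rbind(pairs, data.frame(
      drug_id = iso_d, smiles = unname(st$smiles[iso_d]),
      protein_id = g$proteins[1], sequence = unname(st$sequences[g$proteins[1]]),
      label = 0L))
  }
  if (length(iso_p) > 0 && length(g$drugs) > 0) {
    pairs <- rbind(pairs, data.frame(
      drug_id = g$drugs[1], smiles = unname(st$smiles[g$drugs[1]]),
      protein_id = iso_p, sequence = unname(st$sequences[iso_p]),
      label = 0L))
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_interactions(pairs, file.path(dir, "interactions.tsv"))
    jsonlite::write_json(as.list(gg$communities),
                         file.path(dir, "communities.json"), auto_unbox = TRUE)
  }
  list(graph = g, communities = gg$communities, smiles = st$smiles,
       sequences = st$sequences, pairs = pairs, spec = spec)
}
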