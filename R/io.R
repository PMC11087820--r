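#' Read a drug-protein interaction table
#'
#' Parses the package's TSV dialect: a header line
#' `drug_id<TAB>smiles<TAB>protein_id<TAB>sequence<TAB>label`, UTF-8, with
#' comment lines starting with `#`. The bipartite graph is built from rows
#' whose label is 1; label-0 rows contribute nodes and attributes only.
#'
#' @param path path to the TSV file.
#' @param format dialect tag; only `"tsv"` is currently understood.
#' @param quiet suppress the summary message.
#' @return list with `graph` (a [bipartite_graph()]), `drug_attrs` and
#'   `protein_attrs` (data.frames keyed by node id with the SMILES /
#'   amino-acid strings), and `pairs` (all rows with labels).
#' @export
load_interactions <- function(path, format = "tsv", quiet = FALSE) {
  if (!identical(format, "tsv")) stop("unknown format: ", format)
  if (!file.exists(path)) stop("file not found: ", path)
  # only whole lines starting with '#' are comments; '#' inside a SMILES
  # string (triple bond) is data
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  raw <- read.delim(text = paste(lines, collapse = "\n"), header = TRUE,
                    sep = "\t", comment.char = "", colClasses = "character",
                    quote = "", check.names = FALSE)
  expected <- c("drug_id", "smiles", "protein_id", "sequence", "label")
  if (!identical(names(raw), expected)) {
    stop("header must be: ", paste(expected, collapse = ", "),
         " (got: ", paste(names(raw), collapse = ", "), ")")
  }
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    if (any(is.na(row)) || any(row[c(1, 3, 5)] == "")) {
      stop("malformed row at data line ", i, " of ", path)
    }
    if (!row$label %in% c("0", "1")) {
      stop("label outside {0,1} at data line ", i, ": got '", row$label,
           "' (label domain is binary)")
    }
  }
  raw$label <- as.integer(raw$label)

  drug_attrs <- unique(raw[, c("drug_id", "smiles")])
  protein_attrs <- unique(raw[, c("protein_id", "sequence")])
  if (anyDuplicated(drug_attrs$drug_id)) {
    stop("conflicting SMILES strings for a single drug id")
  }
  if (anyDuplicated(protein_attrs$protein_id)) {
    stop("conflicting sequences for a single protein id")
  }

  pos <- raw[raw$label == 1L, ]
  g <- bipartite_graph(drug_attrs$drug_id, protein_attrs$protein_id,
                       data.frame(drug = pos$drug_id, protein = pos$protein_id))
  if (!quiet) {
    message(sprintf(
      "load_interactions: %d rows, %d drugs, %d proteins, %d edges, %d duplicate edge row(s) dropped",
      nrow(raw), length(g$drugs), length(g$proteins), nrow(g$edges),
      g$n_duplicates_dropped))
  }
  list(graph = g,
       drug_attrs = drug_attrs,
       protein_attrs = protein_attrs,
       pairs = raw)
}

#' Write an interaction table in the package TSV dialect
#'
#' @param pairs data.frame with columns `drug_id`, `smiles`, `protein_id`,
#'   `sequence`, `label`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(pairs, path) {
  expected <- c("drug_id", "smiles", "protein_id", "sequence", "label")
  if (!all(expected %in% names(pairs))) {
    stop("pairs must have columns: ", paste(expected, collapse = ", "))
  }
  write.table(pairs[, expected], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Split positive edges into train / validation / test sets
#'
#' Uniformly random partition of the positive edges, honouring the ratios by
#' nearest-integer rounding with the remainder assigned to training. The
#' returned training-only graph excludes every validation and test positive,
#' so sketches and message passing computed on it cannot leak evaluation
#' edges.
#'
#' @param graph a [bipartite_graph()] of observed (positive) interactions.
#' @param ratios numeric triple (train, valid, test); positive, summing to 1.
#'   Default `c(0.7, 0.1, 0.2)`.
#' @param seed integer seed; identical seeds give identical splits.
#' @return object of class `split_dataset`: list with `train`, `valid`, `test`
#'   (data.frames `drug`, `protein`, `label = 1`), `graph_full`,
#'   `graph_train` (training-only graph over the full node sets), `ratios`,
#'   `seed`.
#' @export
split_edges <- function(graph, ratios = c(0.7, 0.1, 0.2), seed = 0L) {
  if (length(ratios) != 3 || any(ratios <= 0)) stop("ratios must be 3 positive fractions")
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  m <- nrow(graph$edges)
  if (m < 3) stop("need at least 3 positive edges to split")
  n_valid <- round(ratios[2] * m)
  n_test <- round(ratios[3] * m)
  n_train <- m - n_valid - n_test
  if (n_train < 1 || n_valid < 0 || n_test < 0) stop("degenerate split sizes")
  perm <- withr::with_seed(seed, sample.int(m))
  idx_train <- perm[seq_len(n_train)]
  idx_valid <- perm[n_train + seq_len(n_valid)]
  idx_test <- perm[n_train + n_valid + seq_len(n_test)]
  take <- function(idx) {
    df <- graph$edges[idx, , drop = FALSE]
    rownames(df) <- NULL
    df$label <- 1L
    df
  }
  g_train <- bipartite_graph(graph$drugs, graph$proteins,
                             graph$edges[idx_train, , drop = FALSE])
  structure(list(train = take(idx_train), valid = take(idx_valid),
                 test = take(idx_test), graph_full = graph,
                 graph_train = g_train, ratios = ratios, seed = seed),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("split_dataset: %d/%d/%d positives (train/valid/test), seed %d\n",
              nrow(x$train), nrow(x$valid), nrow(x$test), x$seed))
  invisible(x)
}

#' Sample negative drug-protein pairs per split
#'
#' Uniform sampling over global non-edges: a sampled pair is not a positive in
#' any split and is not sampled twice across splits. Each split receives
#' `round(ratio * positives)` negatives with label 0.
#'
#' @param split a [split_edges()] result.
#' @param ratio negatives per positive (default 1).
#' @param seed integer seed.
#' @param which the splits to receive negatives (default all three).
#' @return the `split_dataset` with negatives appended to the chosen splits.
#' @export
sample_negatives <- function(split, ratio = 1, seed = 0L,
                             which = c("train", "valid", "test")) {
  if (ratio <= 0) stop("ratio must be positive")
  which <- match.arg(which, several.ok = TRUE)
  g <- split$graph_full
  nd <- length(g$drugs); np <- length(g$proteins)
  pos_key <- paste(g$edges$drug, g$edges$protein, sep = "\t")
  n_pos <- vapply(c("train", "valid", "test"), function(nm) {
    if (nm %in% which) nrow(split[[nm]]) else 0L
  }, integer(1))
  needed <- round(ratio * n_pos)
  total_needed <- sum(needed)
  n_nonedges <- nd * np - length(pos_key)
  if (total_needed > n_nonedges) {
    stop("requested ", total_needed, " negatives but only ", n_nonedges,
         " non-edges exist")
  }
  neg <- withr::with_seed(seed, {
    chosen <- character(0)
    out_d <- character(total_needed); out_p <- character(total_needed)
    got <- 0L
    while (got < total_needed) {
      n_draw <- max(16L, 2L * (total_needed - got))
      di <- sample.int(nd, n_draw, replace = TRUE)
      pi <- sample.int(np, n_draw, replace = TRUE)
      key <- paste(g$drugs[di], g$proteins[pi], sep = "\t")
      ok <- !(key %in% pos_key) & !(key %in% chosen) & !duplicated(key)
      di <- di[ok]; pi <- pi[ok]; key <- key[ok]
      n_take <- min(length(key), total_needed - got)
      if (n_take > 0) {
        sel <- seq_len(n_take)
        out_d[got + sel] <- g$drugs[di[sel]]
        out_p[got + sel] <- g$proteins[pi[sel]]
        chosen <- c(chosen, key[sel])
        got <- got + n_take
      }
    }
    data.frame(drug = out_d, protein = out_p, label = 0L,
               stringsAsFactors = FALSE)
  })
  bounds <- cumsum(needed)
  starts <- c(1L, bounds[-3] + 1L)
  for (i in 1:3) {
    nm <- c("train", "valid", "test")[i]
    if (needed[i] > 0) {
      block <- neg[starts[i]:bounds[i], , drop = FALSE]
      rownames(block) <- NULL
      split[[nm]] <- rbind(split[[nm]], block)
    }
  }
  split$negative_ratio <- ratio
  split$negative_seed <- seed
  split
}

#' Write a split manifest: three TSVs plus JSON metadata
#'
#' @param split a `split_dataset` (after [sample_negatives()] if desired).
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("train", "valid", "test")) {
    write.table(split[[nm]], file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  meta <- list(ratios = split$ratios, seed = split$seed,
               negative_ratio = split$negative_ratio,
               counts = lapply(split[c("train", "valid", "test")], nrow))
  jsonlite::write_json(meta, file.path(dir, "split.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
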