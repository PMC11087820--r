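#' Run the full prediction pipeline
#'
#' End to end: load (or accept) a dataset, split positives 7:1:2, sample
#' negatives, build sketches on the training-only graph, embed strings, train
#' the fused scorer, and evaluate on the test pairs. Every random choice is
#' derived from `config$seed`, so a rerun with the same inputs reproduces the
#' manifest bit for bit.
#'
#' @param dataset either a path to an interaction TSV (see
#'   [load_interactions()]) or a list with elements `graph`, `smiles`,
#'   `sequences` such as [generate_dataset()] returns.
#' @param config a [dpi_config()].
#' @param backend embedding backend for both node sides; default
#'   [offline_backend()] at `config$embed_dim`.
#' @param out_dir optional directory: writes `manifest.json` and
#'   `predictions.tsv` there.
#' @param verbose print training progress.
#' @return list of class `dpi_run`: `fit` (a [dpi_train()] result),
#'   `manifest` (config, counts, history, final metrics), `predictions`
#'   (test-pair data.frame with scores).
#' @export
dpi_run <- function(dataset, config = dpi_config(),
                    backend = offline_backend(config$embed_dim,
                                              derive_seed(config$seed, "embed")),
                    out_dir = NULL, verbose = FALSE) {
  if (is.character(dataset)) {
    loaded <- load_interactions(dataset, quiet = !verbose)
    graph <- loaded$graph
    smiles <- stats::setNames(loaded$drug_attrs$smiles, loaded$drug_attrs$drug_id)
    sequences <- stats::setNames(loaded$protein_attrs$sequence,
                                 loaded$protein_attrs$protein_id)
    data_id <- dataset
  } else {
    graph <- dataset$graph
    smiles <- dataset$smiles
    sequences <- dataset$sequences
    data_id <- "in-memory"
  }
  if (backend$dim != config$embed_dim) {
    stop("backend dimension ", backend$dim, " differs from config$embed_dim")
  }

  split <- split_edges(graph, config$ratios, derive_seed(config$seed, "split"))
  split <- sample_negatives(split, config$negative_ratio,
                            derive_seed(config$seed, "negatives"))
  X0 <- rbind(embed_drugs(unname(smiles[graph$drugs]), backend, graph$drugs),
              embed_proteins(unname(sequences[graph$proteins]), backend,
                             graph$proteins))
  fit <- dpi_train(split, X0, config, verbose = verbose)

  predictions <- split$test
  names(predictions) <- c("drug_id", "protein_id", "label")
  predictions$score <- fit$test_scores
  predictions <- predictions[, c("drug_id", "protein_id", "score", "label")]

  tm <- fit$test_metrics
  manifest <- list(
    config = unclass(config),
    data = list(source = data_id, n_drugs = length(graph$drugs),
                n_proteins = length(graph$proteins),
                n_edges = nrow(graph$edges),
                edge_hash = dataset_hash(graph)),
    split = list(ratios = config$ratios,
                 counts = lapply(split[c("train", "valid", "test")], nrow)),
    training = list(epochs_run = nrow(fit$history),
                    best_epoch = fit$best_epoch,
                    stopped_epoch = fit$stopped_epoch,
                    history = fit$history),
    test_metrics = list(AUC = tm$auc, AUPR = tm$aupr, ACC = tm$acc,
                        SEN = tm$sen, PRE = tm$pre, SPE = tm$spe, F1 = tm$f1,
                        MCC = tm$mcc, threshold = tm$threshold,
                        counts = tm$counts))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write.table(predictions, file.path(out_dir, "predictions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(fit = fit, manifest = manifest, predictions = predictions),
            class = "dpi_run")
}

# order-independent content hash of the edge set (djb2 over sorted keys)
dataset_hash <- function(graph) {
  keys <- sort(paste(graph$edges$drug, graph$edges$protein, sep = "|"))
  h <- 5381
  for (key in keys) {
    for (cc in utf8ToInt(key)) h <- (h * 33 + cc) %% 2147483647
  }
  sprintf("%d:%d", length(keys), as.integer(h))
}

#' @export
print.dpi_run <- function(x, ...) {
  cat("dpi_run on", x$manifest$data$source, "\n")
  print(x$fit)
  invisible(x)
}

#' Verify sketch estimators against exact oracles
#'
#' Re-estimates MinHash Jaccard values at known similarities, HLL
#' cardinalities at known sizes, and the S1/S2 structural features of sampled
#' pairs on a given graph, comparing everything to exact set arithmetic.
#' Intended both as a user-facing sanity harness and as the engine of the
#' package's calibration checks.
#'
#' @param graph a [bipartite_graph()] (at most a few hundred nodes); default
#'   is a small planted benchmark.
#' @param num_perm,hll_precision,k sketch parameters.
#' @param n_pairs number of (drug, protein) pairs sampled for the S1
#'   comparison.
#' @param seed integer seed.
#' @param tolerances named list with `jaccard` (mean abs error), `hll_rel`
#'   (relative error), `s1_mae` (mean abs error, nodes).
#' @return list of class `sketch_report`: per-statistic observed errors,
#'   tolerances, and `pass` flags.
#' @export
verify_sketches <- function(graph = NULL, num_perm = 256L, hll_precision = 10L,
                            k = 3L, n_pairs = 100L, seed = 1L,
                            tolerances = list(jaccard = 0.05, hll_rel = 0.1,
                                              s1_mae = 1.0)) {
  if (is.null(graph)) {
    graph <- generate_graph(synthetic_spec(n_drugs = 60L, n_proteins = 60L,
                                           p_in = 0.2, p_out = 0.02,
                                           seed = seed))$graph
  }
  # MinHash calibration on constructed sets with known exact Jaccard
  jac_err <- mean(vapply(1:50, function(i) {
    sets <- jaccard_case(i %% 4, i)
    abs(estimate_jaccard(
      minhash_signature(sets$a, num_perm, seed + i),
      minhash_signature(sets$b, num_perm, seed + i)) - sets$j)
  }, numeric(1)))
  # HLL calibration across cardinalities
  hll_err <- mean(vapply(c(100, 1000, 10000), function(n) {
    items <- paste0("x", seq_len(n))
    abs(estimate_cardinality(hll_registers(items, hll_precision, seed)) - n) / n
  }, numeric(1)))
  # estimated vs exact structural features on sampled pairs
  sk <- propagate_sketches(
    graph, init_sketches(graph, num_perm, hll_precision, seed), k)
  pairs <- withr::with_seed(seed, data.frame(
    drug = sample(graph$drugs, n_pairs, replace = TRUE),
    protein = sample(graph$proteins, n_pairs, replace = TRUE)))
  fb <- structural_features_batch(sk, pairs, k)
  s1_err <- mean(vapply(seq_len(n_pairs), function(i) {
    ex <- exact_structural_features(graph, pairs$drug[i], pairs$protein[i], k)
    mean(abs(fb$S1[i, , ] - ex$S1))
  }, numeric(1)))

  out <- list(
    jaccard = list(error = jac_err, tolerance = tolerances$jaccard,
                   pass = jac_err <= tolerances$jaccard),
    hll = list(error = hll_err, tolerance = tolerances$hll_rel,
               pass = hll_err <= tolerances$hll_rel),
    s1 = list(error = s1_err, tolerance = tolerances$s1_mae,
              pass = s1_err <= tolerances$s1_mae),
    num_perm = num_perm, hll_precision = hll_precision, k = k, seed = seed)
  class(out) <- "sketch_report"
  out
}

# fixed-overlap set constructions with exact Jaccard 0, 0.25, 0.5 or 1
jaccard_case <- function(which, tag) {
  u <- function(pre, n) paste0(pre, tag, "_", seq_len(n))
  switch(as.character(which),
         "0" = list(a = u("a", 100), b = u("b", 100), j = 0),
         "1" = list(a = c(u("s", 40), u("a", 60)),
                    b = c(u("s", 40), u("b", 60)), j = 0.25),
         "2" = list(a = c(u("s", 80), u("a", 40)),
                    b = c(u("s", 80), u("b", 40)), j = 0.5),
         "3" = {
           s <- u("s", 100); list(a = s, b = s, j = 1)
         })
}

#' @export
print.sketch_report <- function(x, ...) {
  fmt <- function(nm, st) sprintf("  %-8s error %.4f  (tol %.3f)  %s", nm,
                                  st$error, st$tolerance,
                                  if (st$pass) "PASS" else "FAIL")
  cat("sketch_report (num_perm =", x$num_perm, ", precision =",
      x$hll_precision, ", k =", x$k, ")\n")
  cat(fmt("jaccard", x$jaccard), "\n")
  cat(fmt("hll", x$hll), "\n")
  cat(fmt("S1 MAE", x$s1), "\n")
  invisible(x)
}
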