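# Training loop: minibatch Adam on binary cross-entropy with validation-AUC
# early stopping, fully seeded. The encoders run on the training-only graph;
# evaluation pairs are scored from the same encoders, so no test or validation
# edge influences message passing or sketches.

# early-stopping state machine: strict improvement by more than min_delta
# resets the patience counter
es_init <- function() list(best = -Inf, best_epoch = 0L, wait = 0L)

es_update <- function(state, metric, min_delta = 1e-4) {
  if (metric > state$best + min_delta) {
    state$best <- metric
    state$best_epoch <- state$best_epoch + state$wait + 1L
    state$wait <- 0L
    state$improved <- TRUE
  } else {
    state$wait <- state$wait + 1L
    state$improved <- FALSE
  }
  state
}

#' Trace the early-stopping decision over a metric sequence
#'
#' Pure helper exposing the stopping rule used by [dpi_train()]: training
#' halts after `patience` consecutive epochs whose validation metric fails to
#' exceed the best seen by more than `min_delta`, and the best epoch's
#' parameters are restored.
#'
#' @param metrics numeric vector of per-epoch validation metrics.
#' @param patience consecutive non-improving epochs tolerated.
#' @param min_delta minimum improvement that counts.
#' @return list with `stop_epoch` (NA if the sequence ends first) and
#'   `best_epoch`.
#' @export
#' @examples
#' early_stop_trace(c(.6, .7, rep(.7, 10)), patience = 10)
early_stop_trace <- function(metrics, patience = 10L, min_delta = 1e-4) {
  st <- es_init()
  best_epoch <- 0L
  stop_epoch <- NA_integer_
  for (e in seq_along(metrics)) {
    st <- es_update(st, metrics[e], min_delta)
    if (st$improved) best_epoch <- e
    if (st$wait >= patience) { stop_epoch <- e; break }
  }
  list(stop_epoch = stop_epoch, best_epoch = best_epoch)
}

# Assemble everything the forward passes need: node ordering, sketches and
# GNN scaffold on the training-only graph, per-split pair indices and labels.
training_context <- function(split, X0, config) {
  g <- split$graph_train
  nodes <- graph_nodes(g)
  if (nrow(X0) != length(nodes)) stop("X0 must have one row per node")
  nidx <- stats::setNames(seq_along(nodes), nodes)
  need_local <- config$mode %in% c("full", "no_global")
  ls <- NULL
  if (need_local) {
    sk <- propagate_sketches(
      g, init_sketches(g, config$num_perm, config$hll_precision,
                       derive_seed(config$seed, "sketch")), config$k)
    ls <- local_graph_structure(g, sk, config$k, config$local_layers)
  }
  pair_idx <- function(df) list(d = unname(nidx[df$drug]),
                                p = unname(nidx[df$protein]),
                                y = df$label)
  list(graph = g, X0 = X0, ls = ls, nidx = nidx,
       train = pair_idx(split$train), valid = pair_idx(split$valid),
       test = pair_idx(split$test))
}

# forward pass producing pair logits on the tape; rows = requested pairs
forward_logits_ad <- function(tape, prefs, ctx, config, d_idx, p_idx) {
  X0ref <- ad_input(tape, ctx$X0)
  blocks <- list()
  if (config$mode == "pretrain_only") {
    blocks <- list(ad_rows(X0ref, d_idx), ad_rows(X0ref, p_idx))
  } else {
    loc <- glob <- NULL
    if (config$mode %in% c("full", "no_global")) {
      loc <- forward_local_ad(tape, prefs, X0ref, ctx$ls, config)
    }
    if (config$mode %in% c("full", "no_local")) {
      glob <- forward_global_ad(tape, prefs, X0ref, config)
    }
    if (config$mode == "full") {
      blocks <- list(ad_rows(loc, d_idx), ad_rows(glob, d_idx),
                     ad_rows(loc, p_idx), ad_rows(glob, p_idx))
    } else if (config$mode == "no_global") {
      blocks <- list(ad_rows(loc, d_idx), ad_rows(loc, p_idx))
    } else {
      blocks <- list(ad_rows(glob, d_idx), ad_rows(glob, p_idx))
    }
  }
  x <- do.call(ad_cbind, blocks)
  nl <- length(config$mlp_hidden) + 1L
  for (i in seq_len(nl)) {
    x <- ad_add(ad_matmul(x, prefs[[paste0("mlp.W", i)]]),
                prefs[[paste0("mlp.b", i)]])
    if (i < nl) x <- ad_relu(x)
  }
  x
}

# numeric pair scores under the current parameters (forward only)
score_pairs_ctx <- function(params, config, ctx, idx) {
  tape <- ad_tape()
  prefs <- lapply(params, function(m) ad_input(tape, m))
  z <- ad_value(forward_logits_ad(tape, prefs, ctx, config, idx$d, idx$p))
  as.numeric(1 / (1 + exp(-z)))
}

#' Train the scoring model on a split dataset
#'
#' Minimizes binary cross-entropy over the training pairs with Adam
#' (minibatches of `config$batch_size`), evaluates validation AUC after every
#' epoch, and stops once `config$patience` consecutive epochs bring no
#' improvement above `config$min_delta`, restoring the best-validation
#' parameters. Fully deterministic for a fixed config and seed.
#'
#' @param split a [split_edges()] result with negatives appended by
#'   [sample_negatives()] (all three splits need both classes).
#' @param X0 initial node feature matrix, one row per node of the graph
#'   (drugs first), e.g. from [embed_drugs()] / [embed_proteins()].
#' @param config a [dpi_config()].
#' @param verbose print per-epoch progress.
#' @return list of class `dpi_fit`: `model` (trained), `history` (data.frame
#'   epoch / train_loss / valid_auc), `best_epoch`, `stopped_epoch`, and
#'   `test_metrics` (a [evaluate()] report on the test pairs).
#' @export
dpi_train <- function(split, X0, config = dpi_config(), verbose = FALSE) {
  for (nm in c("train", "valid", "test")) {
    y <- split[[nm]]$label
    if (length(y) == 0) stop("empty ", nm, " split")
    if (length(unique(y)) < 2) {
      stop(nm, " split needs both classes; run sample_negatives() first")
    }
  }
  ctx <- training_context(split, X0, config)
  model <- dpi_model_init(config)
  params <- model$params
  opt <- adam_init(params)
  n_train <- length(ctx$train$y)
  st <- es_init()
  best_params <- params
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        valid_auc = numeric(0))
  stopped_epoch <- NA_integer_
  base_seed <- derive_seed(config$seed, "train")

  for (epoch in seq_len(config$max_epochs)) {
    perm <- withr::with_seed(base_seed + epoch, sample.int(n_train))
    losses <- numeric(0)
    for (start in seq(1, n_train, by = config$batch_size)) {
      rows <- perm[start:min(start + config$batch_size - 1, n_train)]
      tape <- ad_tape()
      prefs <- lapply(params, function(m) ad_input(tape, m))
      logits <- forward_logits_ad(tape, prefs, ctx, config,
                                  ctx$train$d[rows], ctx$train$p[rows])
      loss <- ad_bce_logits(logits, ctx$train$y[rows])
      lval <- as.numeric(ad_value(loss))
      if (!is.finite(lval)) stop("non-finite training loss at epoch ", epoch)
      grads_by_id <- ad_backward(tape, loss)
      grads <- stats::setNames(
        lapply(seq_along(params), function(i) grads_by_id[[prefs[[i]]$id]]),
        names(params))
      upd <- adam_step(params, grads, opt, lr = config$lr)
      params <- upd$params
      opt <- upd$state
      losses <- c(losses, lval * length(rows))
    }
    vauc <- evaluate(score_pairs_ctx(params, config, ctx, ctx$valid),
                     ctx$valid$y)$auc
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = sum(losses) / n_train,
                                         valid_auc = vauc))
    st <- es_update(st, vauc, config$min_delta)
    if (st$improved) best_params <- params
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  valid AUC %.4f%s", epoch,
                      sum(losses) / n_train, vauc,
                      if (st$improved) "  *" else ""))
    }
    if (st$wait >= config$patience) { stopped_epoch <- epoch; break }
  }

  model$params <- best_params
  trace <- early_stop_trace(history$valid_auc, config$patience,
                            config$min_delta)
  test_scores <- score_pairs_ctx(best_params, config, ctx, ctx$test)
  structure(list(model = model, history = history,
                 best_epoch = trace$best_epoch, stopped_epoch = stopped_epoch,
                 test_scores = test_scores,
                 test_metrics = evaluate(test_scores, ctx$test$y,
                                         config$threshold),
                 ctx = ctx),
            class = "dpi_fit")
}

#' Score arbitrary candidate pairs with a trained fit
#'
#' Features are computed on the training-only graph stored in the fit.
#'
#' @param fit a [dpi_train()] result.
#' @param pairs data.frame with columns `drug` and `protein`.
#' @return numeric scores in (0, 1).
#' @export
dpi_score <- function(fit, pairs) {
  idx <- list(d = unname(fit$ctx$nidx[pairs$drug]),
              p = unname(fit$ctx$nidx[pairs$protein]))
  if (anyNA(idx$d) || anyNA(idx$p)) stop("pair references an unknown node")
  score_pairs_ctx(fit$model$params, fit$model$config, fit$ctx, idx)
}

#' @export
print.dpi_fit <- function(x, ...) {
  cat(sprintf("dpi_fit: mode %s, %d epoch(s), best epoch %d\n",
              x$model$config$mode, nrow(x$history), x$best_epoch))
  print(x$test_metrics)
  invisible(x)
}
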