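# Parameter initialization and the Adam optimizer used by the training loop.

# Glorot-uniform matrix, seeded deterministically
glorot <- function(nin, nout, seed) {
  lim <- sqrt(6 / (nin + nout))
  withr::with_seed(seed, matrix(runif(nin * nout, -lim, lim), nin, nout))
}

#' Model configuration with the training-protocol defaults
#'
#' Defaults mirror the evaluation protocol: 7:1:2 split, Adam with learning
#' rate 0.001 and batch size 512, early stopping after 10 non-improving
#' validation epochs, subgraph depth k = 3, local output dimension 64 with a
#' 2-layer GNN, global output dimension 256 with a 2-layer / 4-head
#' transformer.
#'
#' @param k subgraph (sketch) depth.
#' @param local_dim,local_layers GNN output dimension and depth.
#' @param global_dim,global_layers,heads transformer output dimension, depth
#'   and attention heads (`global_dim` must be divisible by `heads`).
#' @param alpha diffusion step size in (0, 1]; the residual weight of the
#'   attention update.
#' @param embed_dim dimension of the initial (pretrained or offline) features.
#' @param num_perm,hll_precision sketch parameters.
#' @param lr,batch_size,max_epochs,patience,min_delta Adam learning rate,
#'   minibatch size, epoch cap, early-stop patience, and the minimum
#'   validation-AUC improvement counted as progress.
#' @param ratios train/valid/test split fractions.
#' @param negative_ratio negatives sampled per positive.
#' @param mode ablation mode: `"full"`, `"pretrain_only"`, `"no_global"`, or
#'   `"no_local"`.
#' @param threshold decision threshold for the hard classification metrics.
#' @param mlp_hidden hidden-layer widths of the scoring perceptron.
#' @param seed global seed; per-module seeds are derived from it.
#' @return a list of class `dpi_config`.
#' @export
dpi_config <- function(k = 3L, local_dim = 64L, local_layers = 2L,
                       global_dim = 256L, global_layers = 2L, heads = 4L,
                       alpha = 0.5, embed_dim = 64L, num_perm = 256L,
                       hll_precision = 10L, lr = 0.001, batch_size = 512L,
                       max_epochs = 100L, patience = 10L, min_delta = 1e-4,
                       ratios = c(0.7, 0.1, 0.2), negative_ratio = 1,
                       mode = "full", threshold = 0.5,
                       mlp_hidden = c(256L, 64L), seed = 1L) {
  if (global_dim %% heads != 0) stop("global_dim must be divisible by heads")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (local_layers < 1) stop("local_layers must be >= 1")
  if (local_layers > k) stop("local_layers cannot exceed k (edge features undefined)")
  mode <- match.arg(mode, c("full", "pretrain_only", "no_global", "no_local"))
  structure(as.list(environment()), class = "dpi_config")
}

#' Switch a configuration to an ablation variant
#'
#' `pretrain_only` feeds the initial features straight to the fusion head;
#' `no_global` drops the transformer channel; `no_local` drops the GNN
#' channel; `full` uses all of them. The fusion input shrinks to the
#' concatenation of the remaining blocks.
#'
#' @param config a [dpi_config()].
#' @param mode one of `"full"`, `"pretrain_only"`, `"no_global"`, `"no_local"`.
#' @return the modified config.
#' @export
ablate <- function(config, mode) {
  mode <- match.arg(mode, c("full", "pretrain_only", "no_global", "no_local"))
  config$mode <- mode
  config
}

# width of the fusion input under an ablation mode
fusion_dim <- function(config) {
  switch(config$mode,
         full = 2L * (config$local_dim + config$global_dim),
         pretrain_only = 2L * config$embed_dim,
         no_global = 2L * config$local_dim,
         no_local = 2L * config$global_dim)
}

# deterministic per-module seed fan-out from the global seed
derive_seed <- function(seed, module) {
  offsets <- c(graph = 11L, strings = 23L, split = 37L, negatives = 41L,
               sketch = 53L, embed = 67L, params = 71L, train = 83L,
               benchmark = 97L)
  off <- offsets[[module]]
  as.integer((as.numeric(seed) * 1000003 + off) %% 2147483647)
}

#' Initialize all trainable parameters of the model
#'
#' @param config a [dpi_config()].
#' @return object of class `dpi_model`: list with `params` (flat named list of
#'   matrices; biases are 1 x d), and `config`.
#' @export
dpi_model_init <- function(config) {
  p <- list()
  s <- derive_seed(config$seed, "params")
  nxt <- function() { s <<- s + 1L; s }
  ef <- 2L * config$k + 1L

  if (config$mode %in% c("full", "no_global")) {
    din <- config$embed_dim
    for (l in seq_len(config$local_layers)) {
      p[[paste0("local.tau", l, ".W")]] <- glorot(2L * din + ef, config$local_dim, nxt())
      p[[paste0("local.tau", l, ".b")]] <- matrix(0, 1, config$local_dim)
      p[[paste0("local.phi", l, ".W")]] <- glorot(din + config$local_dim, config$local_dim, nxt())
      p[[paste0("local.phi", l, ".b")]] <- matrix(0, 1, config$local_dim)
      din <- config$local_dim
    }
  }
  if (config$mode %in% c("full", "no_local")) {
    hd <- config$global_dim %/% config$heads
    p[["global.in.W"]] <- glorot(config$embed_dim, config$global_dim, nxt())
    p[["global.in.b"]] <- matrix(0, 1, config$global_dim)
    for (u in seq_len(config$global_layers)) for (g in seq_len(config$heads)) {
      p[[sprintf("global.l%d.h%d.Wk", u, g)]] <- glorot(config$global_dim, hd, nxt())
      p[[sprintf("global.l%d.h%d.Wq", u, g)]] <- glorot(config$global_dim, hd, nxt())
      p[[sprintf("global.l%d.h%d.Wv", u, g)]] <- glorot(config$global_dim, config$global_dim, nxt())
    }
  }
  din <- fusion_dim(config)
  for (i in seq_along(config$mlp_hidden)) {
    p[[paste0("mlp.W", i)]] <- glorot(din, config$mlp_hidden[i], nxt())
    p[[paste0("mlp.b", i)]] <- matrix(0, 1, config$mlp_hidden[i])
    din <- config$mlp_hidden[i]
  }
  nl <- length(config$mlp_hidden) + 1L
  p[[paste0("mlp.W", nl)]] <- glorot(din, 1L, nxt())
  p[[paste0("mlp.b", nl)]] <- matrix(0, 1, 1)
  structure(list(params = p, config = config), class = "dpi_model")
}

# Adam state and update (decoupled from the tape; operates on flat param lists)
adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
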