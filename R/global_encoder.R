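#' Input projection of the global encoder
#'
#' `Z = sigmoid(layernorm(X W + b))`: a linear map, layer normalization across
#' the feature axis, then the logistic function, so every entry of `Z` lies
#' strictly in (0, 1).
#'
#' @param X input feature matrix (one row per node).
#' @param W,b trainable weight matrix (`ncol(X)` x d) and bias (1 x d).
#' @return projected matrix Z.
#' @export
input_projection <- function(X, W, b) {
  if (any(!is.finite(X))) stop("non-finite input features")
  A <- sweep(X %*% W, 2, as.numeric(b), "+")
  mu <- rowMeans(A)
  xc <- A - mu
  sig <- sqrt(rowMeans(xc^2) + 1e-5)
  1 / (1 + exp(-xc / sig))
}

#' Per-head query/key/value projections
#'
#' @param Z layer embedding matrix.
#' @param Wk,Wq,Wv trainable projection matrices of one attention head.
#' @return list with matrices `K`, `Q`, `V`.
#' @export
qkv_projection <- function(Z, Wk, Wq, Wv) {
  if (ncol(Z) != nrow(Wk) || ncol(Z) != nrow(Wq) || ncol(Z) != nrow(Wv)) {
    stop("dimension mismatch between Z and projection weights")
  }
  list(K = Z %*% Wk, Q = Z %*% Wq, V = Z %*% Wv)
}

#' Row-wise L2 normalization of the key and query matrices
#'
#' Each row is divided by its Euclidean norm, so the pairwise dot products
#' that drive the diffusion attention are cosine similarities in \[-1, 1\].
#' Zero rows are mapped to zero with a warning rather than an error.
#'
#' @param K,Q key and query matrices.
#' @return list with `K` and `Q` replaced by their unit-row versions.
#' @export
l2_normalize_heads <- function(K, Q) {
  norm_rows <- function(M, label) {
    nrm <- sqrt(rowSums(M^2))
    zero <- nrm < 1e-12
    if (any(zero)) {
      warning(sum(zero), " zero row(s) in ", label, " mapped to zero")
      nrm[zero] <- 1
    }
    M / nrm
  }
  list(K = norm_rows(K, "K"), Q = norm_rows(Q, "Q"))
}

# Row-stochastic all-pair attention from unit-normalized queries and keys:
# A_ij = (1 + Qh_i . Kh_j) / rowsum. Non-negative because rows are unit
# vectors (dot >= -1). Explicit N x N realization, used as the reference for
# the linear-time path.
attention_rowstochastic <- function(Qh, Kh) {
  A <- 1 + tcrossprod(Qh, Kh)
  A / rowSums(A)
}

#' One energy-constrained diffusion attention layer
#'
#' Per head, the all-pair affinity `1 + Qhat_i . Khat_j` is row-normalized to
#' a stochastic matrix `A` whose entries act as diffusion rates between every
#' node pair (connected or not); features propagate as `A V`. Heads are
#' averaged and blended with the previous layer through the residual step
#' `Z' = (1 - alpha) Z + alpha * head_average`, the source term of the
#' diffusion. `method = "linear"` computes `A V` without materializing the
#' N x N matrix via `(1 1^T V + Qhat (Khat^T V))`, then row-scales; it equals
#' the dense computation up to floating-point roundoff.
#'
#' @param Z current layer embedding (N x d).
#' @param heads list of per-head parameter lists with elements `Wk`, `Wq`,
#'   `Wv`.
#' @param alpha diffusion step size in (0, 1].
#' @param method `"linear"` (default) or `"dense"`.
#' @return updated embedding matrix `Z`.
#' @export
diffusion_attention_layer <- function(Z, heads, alpha = 0.5,
                                      method = c("linear", "dense")) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (any(!is.finite(Z))) stop("non-finite embedding entering attention")
  N <- nrow(Z)
  acc <- 0
  for (h in heads) {
    kqv <- qkv_projection(Z, h$Wk, h$Wq, h$Wv)
    nz <- l2_normalize_heads(kqv$K, kqv$Q)
    if (method == "dense") {
      A <- attention_rowstochastic(nz$Q, nz$K)
      P <- A %*% kqv$V
    } else {
      num <- matrix(colSums(kqv$V), N, ncol(kqv$V), byrow = TRUE) +
        nz$Q %*% crossprod(nz$K, kqv$V)
      r <- N + as.numeric(nz$Q %*% colSums(nz$K))
      P <- num / r
    }
    if (any(!is.finite(P))) stop("non-finite attention propagation")
    acc <- acc + P
  }
  (1 - alpha) * Z + alpha * acc / length(heads)
}

# collect the per-head parameter lists of layer u from a flat param list
global_layer_heads <- function(params, u, heads) {
  lapply(seq_len(heads), function(g) list(
    Wk = params[[sprintf("global.l%d.h%d.Wk", u, g)]],
    Wq = params[[sprintf("global.l%d.h%d.Wq", u, g)]],
    Wv = params[[sprintf("global.l%d.h%d.Wv", u, g)]]))
}

#' Encode global node features with the diffusion transformer
#'
#' Projects the initial features (see [input_projection()]) and applies
#' `global_layers` diffusion attention layers over all nodes jointly -- drugs
#' and proteins together, with no restriction to observed edges -- then splits
#' the result by node side.
#'
#' @param X initial feature matrix, one row per node, drugs first.
#' @param n_drugs number of drug rows at the top of `X`.
#' @param model a [dpi_model_init()] result with `global.*` parameters (mode
#'   `"full"` or `"no_local"`).
#' @param method attention realization, see [diffusion_attention_layer()].
#' @return list with `d_global` and `p_global` matrices.
#' @export
encode_global <- function(X, n_drugs, model, method = "linear") {
  config <- model$config
  if (is.null(model$params[["global.in.W"]])) {
    stop("model has no global encoder (mode '", config$mode, "')")
  }
  Z <- input_projection(X, model$params[["global.in.W"]],
                        model$params[["global.in.b"]])
  for (u in seq_len(config$global_layers)) {
    Z <- diffusion_attention_layer(
      Z, global_layer_heads(model$params, u, config$heads),
      alpha = config$alpha, method = method)
  }
  rownames(Z) <- rownames(X)
  list(d_global = Z[seq_len(n_drugs), , drop = FALSE],
       p_global = Z[-seq_len(n_drugs), , drop = FALSE])
}

# Tape-based forward pass mirroring encode_global (linear-time attention).
forward_global_ad <- function(tape, prefs, Xref, config) {
  N <- nrow(ad_value(Xref))
  Z <- ad_sigmoid(ad_layernorm(ad_add(ad_matmul(Xref, prefs[["global.in.W"]]),
                                      prefs[["global.in.b"]])))
  for (u in seq_len(config$global_layers)) {
    acc <- NULL
    for (g in seq_len(config$heads)) {
      K <- ad_matmul(Z, prefs[[sprintf("global.l%d.h%d.Wk", u, g)]])
      Q <- ad_matmul(Z, prefs[[sprintf("global.l%d.h%d.Wq", u, g)]])
      V <- ad_matmul(Z, prefs[[sprintf("global.l%d.h%d.Wv", u, g)]])
      Kh <- ad_l2norm_rows(K)
      Qh <- ad_l2norm_rows(Q)
      num <- ad_add(ad_matmul(Qh, ad_matmul(Kh, V, tx = TRUE)), ad_colsums(V))
      r <- ad_add_const(ad_matmul(Qh, ad_colsums(Kh), ty = TRUE), N)
      P <- ad_divide_rows(num, r)
      acc <- if (is.null(acc)) P else ad_add(acc, P)
    }
    Z <- ad_add(ad_scale(Z, 1 - config$alpha),
                ad_scale(acc, config$alpha / config$heads))
  }
  Z
}
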