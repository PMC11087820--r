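# Minimal reverse-mode automatic differentiation over dense matrices.
#
# A tape is an environment accumulating nodes in topological order; each node
# stores its value, its parents' ids, and a backward closure mapping the
# node's output gradient to a list of parent gradients. backward() walks the
# tape in reverse. Only the operations the encoders and the scoring head need
# are implemented; each gradient is verified against finite differences in
# the test suite.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$k <- 0L
  class(e) <- "ad_tape"
  e
}

ad_push <- function(tape, value, parents = integer(0), backward = NULL) {
  tape$k <- tape$k + 1L
  if (tape$k > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$k]] <- list(value = value, parents = parents,
                               backward = backward)
  structure(list(tape = tape, id = tape$k), class = "ad_ref")
}

# leaf node (input, parameter, or constant)
ad_input <- function(tape, value) ad_push(tape, as.matrix(value))

ad_value <- function(ref) ref$tape$nodes[[ref$id]]$value

ad_matmul <- function(x, y, tx = FALSE, ty = FALSE) {
  X <- ad_value(x); Y <- ad_value(y)
  val <- if (tx) crossprod(X, Y) else if (ty) tcrossprod(X, Y) else X %*% Y
  ad_push(x$tape, val, c(x$id, y$id), function(G) {
    if (tx)      list(Y %*% t(G), X %*% G)
    else if (ty) list(G %*% Y, crossprod(G, X))
    else         list(tcrossprod(G, Y), crossprod(X, G))
  })
}

# x + y, with y either same shape, a 1 x ncol row vector (bias broadcast over
# rows), or a n x 1 column vector broadcast over columns
ad_add <- function(x, y) {
  X <- ad_value(x); Y <- ad_value(y)
  if (identical(dim(X), dim(Y))) {
    ad_push(x$tape, X + Y, c(x$id, y$id), function(G) list(G, G))
  } else if (nrow(Y) == 1 && ncol(Y) == ncol(X)) {
    ad_push(x$tape, sweep(X, 2, as.numeric(Y), "+"), c(x$id, y$id),
            function(G) list(G, matrix(colSums(G), 1)))
  } else if (ncol(Y) == 1 && nrow(Y) == nrow(X)) {
    ad_push(x$tape, X + as.numeric(Y), c(x$id, y$id),
            function(G) list(G, matrix(rowSums(G), ncol = 1)))
  } else stop("ad_add: incompatible shapes")
}

ad_scale <- function(x, a) {
  ad_push(x$tape, ad_value(x) * a, x$id, function(G) list(G * a))
}

ad_add_const <- function(x, a) {
  ad_push(x$tape, ad_value(x) + a, x$id, function(G) list(G))
}

ad_mul <- function(x, y) {
  X <- ad_value(x); Y <- ad_value(y)
  stopifnot(identical(dim(X), dim(Y)))
  ad_push(x$tape, X * Y, c(x$id, y$id), function(G) list(G * Y, G * X))
}

ad_relu <- function(x) {
  X <- ad_value(x)
  mask <- X > 0
  ad_push(x$tape, X * mask, x$id, function(G) list(G * mask))
}

ad_sigmoid <- function(x) {
  S <- 1 / (1 + exp(-ad_value(x)))
  ad_push(x$tape, S, x$id, function(G) list(G * S * (1 - S)))
}

# row selection with repetition; gradient scatter-adds into the source rows
ad_rows <- function(x, idx) {
  X <- ad_value(x)
  idx <- as.integer(idx)
  ad_push(x$tape, X[idx, , drop = FALSE], x$id, function(G) {
    dX <- matrix(0, nrow(X), ncol(X))
    agg <- rowsum(G, group = idx)
    dX[as.integer(rownames(agg)), ] <- agg
    list(dX)
  })
}

ad_cbind <- function(...) {
  refs <- list(...)
  vals <- lapply(refs, ad_value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths); starts <- c(1L, head(ends, -1) + 1L)
  ad_push(refs[[1]]$tape, do.call(cbind, vals),
          vapply(refs, function(r) r$id, integer(1)), function(G) {
    lapply(seq_along(refs), function(i) G[, starts[i]:ends[i], drop = FALSE])
  })
}

ad_colsums <- function(x) {
  X <- ad_value(x)
  ad_push(x$tape, matrix(colSums(X), 1), x$id, function(G) {
    list(matrix(rep(as.numeric(G), each = nrow(X)), nrow(X)))
  })
}

# multiply by a constant sparse matrix on the left: S %*% x
ad_spmatmul <- function(S, x) {
  val <- as.matrix(S %*% ad_value(x))
  ad_push(x$tape, val, x$id, function(G) list(as.matrix(Matrix::crossprod(S, G))))
}

# rowwise layer normalization: (x - mean) / sqrt(var + eps), population var
ad_layernorm <- function(x, eps = 1e-5) {
  X <- ad_value(x)
  d <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  sig <- sqrt(rowMeans(xc^2) + eps)
  Y <- xc / sig
  ad_push(x$tape, Y, x$id, function(G) {
    gm <- rowMeans(G)
    gy <- rowMeans(G * Y)
    list((G - gm - Y * gy) / sig)
  })
}

# rowwise L2 normalization; rows with norm below eps map to zero with zero grad
ad_l2norm_rows <- function(x, eps = 1e-12) {
  X <- ad_value(x)
  nrm <- sqrt(rowSums(X^2))
  inv <- ifelse(nrm > eps, 1 / nrm, 0)
  Y <- X * inv
  ad_push(x$tape, Y, x$id, function(G) {
    list((G - Y * rowSums(G * Y)) * inv)
  })
}

# divide each row of x by the matching entry of the n x 1 node r
ad_divide_rows <- function(x, r) {
  X <- ad_value(x); R <- as.numeric(ad_value(r))
  Y <- X / R
  ad_push(x$tape, Y, c(x$id, r$id), function(G) {
    list(G / R, matrix(-rowSums(G * Y) / R, ncol = 1))
  })
}

# numerically stable mean binary cross-entropy over logits (fused with the
# sigmoid: gradient is (sigmoid(z) - y) / n)
ad_bce_logits <- function(z, y) {
  Z <- as.numeric(ad_value(z))
  y <- as.numeric(y)
  n <- length(Z)
  loss <- mean(pmax(Z, 0) - Z * y + log1p(exp(-abs(Z))))
  ad_push(z$tape, matrix(loss, 1, 1), z$id, function(G) {
    g <- as.numeric(G)[1]
    p <- 1 / (1 + exp(-Z))
    list(matrix(g * (p - y) / n, ncol = 1))
  })
}

# reverse pass; returns a list mapping node id -> gradient (NULL if untouched)
ad_backward <- function(tape, loss) {
  grads <- vector("list", tape$k)
  grads[[loss$id]] <- matrix(1, 1, 1)
  for (id in seq(loss$id, 1L)) {
    g <- grads[[id]]
    node <- tape$nodes[[id]]
    if (is.null(g) || is.null(node$backward)) next
    pg <- node$backward(g)
    for (j in seq_along(node$parents)) {
      pid <- node$parents[j]
      if (is.null(grads[[pid]])) grads[[pid]] <- pg[[j]]
      else grads[[pid]] <- grads[[pid]] + pg[[j]]
    }
  }
  grads
}
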