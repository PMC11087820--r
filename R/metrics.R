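#' Evaluate interaction scores against binary labels
#'
#' Computes the full metric suite: AUC by the rank statistic (tied scores get
#' averaged ranks), AUPR by step integration of the precision-recall curve,
#' and the threshold metrics ACC, SEN, PRE, SPE, F1 and MCC from the
#' confusion counts at `threshold` (prediction positive when
#' `score >= threshold`). Degenerate denominators yield 0 by convention
#' (MCC, PRE, F1, SPE, SEN). With one-class labels AUC and AUPR are undefined
#' and returned as `NA` with a warning; the hard metrics are still computed.
#'
#' @param scores numeric vector of predicted scores.
#' @param labels binary vector (0/1) of the same length.
#' @param threshold decision threshold for the hard metrics (default 0.5).
#' @return object of class `metrics_report`: list with `auc`, `aupr`, `acc`,
#'   `sen`, `pre`, `spe`, `f1`, `mcc`, `threshold` and `counts`
#'   (tp, fp, tn, fn).
#' @export
#' @examples
#' evaluate(c(.9, .8, .2, .1), c(1, 1, 0, 0))
evaluate <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (any(!is.finite(scores))) stop("non-finite scores")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)

  if (n_pos == 0L || n_neg == 0L) {
    warning("labels contain a single class; AUC and AUPR are undefined")
    auc <- NA_real_
    aupr <- NA_real_
  } else {
    r <- rank(scores) # ties averaged
    auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    ord <- order(scores, decreasing = TRUE)
    tp_cum <- cumsum(labels[ord])
    precision <- tp_cum / seq_along(tp_cum)
    recall <- tp_cum / n_pos
    dr <- diff(c(0, recall))
    aupr <- sum(dr * precision)
  }

  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  acc <- safe_div(tp + tn, tp + fp + tn + fn)
  sen <- safe_div(tp, tp + fn)
  pre <- safe_div(tp, tp + fp)
  spe <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * pre * sen, pre + sen)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  structure(list(auc = auc, aupr = aupr, acc = acc, sen = sen, pre = pre,
                 spe = spe, f1 = f1, mcc = mcc, threshold = threshold,
                 counts = list(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("metrics_report (threshold %.2f): AUC %.4f  AUPR %.4f  ",
                     "ACC %.4f  SEN %.4f  PRE %.4f  SPE %.4f  F1 %.4f  MCC %.4f\n"),
              x$threshold, x$auc, x$aupr, x$acc, x$sen, x$pre, x$spe, x$f1,
              x$mcc))
  cat(sprintf("counts: TP %d  FP %d  TN %d  FN %d\n", x$counts$tp, x$counts$fp,
              x$counts$tn, x$counts$fn))
  invisible(x)
}

#' Fuse per-pair feature blocks and score with the perceptron head
#'
#' Concatenates the supplied blocks (`[d_local || d_global || p_local ||
#' p_global]` in full mode; ablations drop blocks) and passes them through a
#' rectifier MLP with a sigmoid output, giving a score in (0, 1) per row.
#'
#' @param blocks list of numeric matrices with equal row counts, one row per
#'   candidate pair, in fusion order.
#' @param model a [dpi_model_init()] result (only the `mlp.*` parameters are
#'   used).
#' @return numeric vector of scores in (0, 1).
#' @export
fuse_and_score <- function(blocks, model) {
  x <- do.call(cbind, blocks)
  if (any(!is.finite(x))) stop("non-finite fusion input")
  p <- model$params
  nl <- length(model$config$mlp_hidden) + 1L
  if (ncol(x) != nrow(p[["mlp.W1"]])) {
    stop("fusion input width ", ncol(x), " does not match the head (",
         nrow(p[["mlp.W1"]]), ")")
  }
  for (i in seq_len(nl)) {
    x <- sweep(x %*% p[[paste0("mlp.W", i)]], 2,
               as.numeric(p[[paste0("mlp.b", i)]]), "+")
    if (i < nl) x <- pmax(x, 0)
  }
  as.numeric(1 / (1 + exp(-x)))
}
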