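#' Quantile-based synapse reduction
#'
#' Network compression by pruning: the distribution of absolute synaptic
#' weights is pooled over all prunable layers (both convolutions and the
#' fully-connected stack; pooling layers have no trainable synapses and
#' are always exempt), an empirical quantile of it is taken as threshold,
#' and every synapse whose absolute weight is less than or equal to the
#' threshold is removed. Typical operating points are the first quartile
#' (q = 0.25), the median and the third quartile, retaining roughly 75, 50
#' and 25 percent of the synapses. A masked fine-tuning pass then retrains
#' the surviving weights while constraining the eliminated ones to exactly
#' zero.
#'
#' @name compression
NULL

#' Prune synapses at or below a weight quantile
#'
#' The threshold is the linear-interpolation empirical `q`-quantile of the
#' pooled `|w|` distribution; ties at the threshold are removed (the
#' "less than or equal" convention). Optionally the quantile can be taken
#' per layer instead of globally.
#'
#' @param net A trained [build_cnn()] network.
#' @param q Quantile level in (0, 1).
#' @param scope `"global"` (one pooled distribution, default) or
#'   `"per_layer"`.
#' @return List with `net` (pruned weights), `mask` (logical-valued
#'   matrices, 1 = retained), `threshold` and `retained_fraction`.
#' @export
prune_by_quantile <- function(net, q, scope = c("global", "per_layer")) {
  stopifnot(inherits(net, "cnn_net"))
  scope <- match.arg(scope)
  if (!(q > 0 && q < 1)) stop("`q` must lie strictly between 0 and 1")
  W <- net$weights
  if (scope == "global") {
    pooled <- abs(c(as.vector(W$conv1), as.vector(W$conv2),
                    unlist(lapply(W$fc, as.vector))))
    thr <- as.numeric(stats::quantile(pooled, q, type = 7))
    keep <- function(w) (abs(w) > thr) * 1
  } else {
    thr <- NA_real_
    keep <- function(w) (abs(w) > as.numeric(stats::quantile(abs(w), q, type = 7))) * 1
  }
  mask <- list(conv1 = keep(W$conv1), conv2 = keep(W$conv2),
               fc = lapply(W$fc, keep))
  net$weights <- mask_weights(W, mask)
  n_total <- n_parameters(net)
  n_kept <- sum(mask$conv1) + sum(mask$conv2) + sum(vapply(mask$fc, sum, numeric(1L)))
  list(net = net, mask = mask, threshold = thr,
       retained_fraction = n_kept / n_total)
}

#' Fine-tune a pruned network under its mask
#'
#' Retrains the surviving synapses with [train_cnn()] while the mask
#' forces every eliminated weight to exactly zero after each update.
#'
#' @param net A pruned network (from [prune_by_quantile()]).
#' @param mask The prune mask.
#' @param images,labels Training data as in [train_cnn()].
#' @param epochs Retraining epochs (default 5; 0 returns `net` unchanged).
#' @param lr,batch_size,seed Passed to [train_cnn()].
#' @return The fine-tuned `cnn_net`; masked weights remain exactly 0.
#' @export
fine_tune <- function(net, mask, images, labels, epochs = 5L,
                      lr = 0.05, batch_size = 8L, seed = 1L) {
  if (epochs == 0L) return(net)
  train_cnn(net, images, labels, epochs = epochs, lr = lr,
            batch_size = batch_size, seed = seed, mask = mask)
}

#' Summarize a compression run
#'
#' @param q Quantile level used for pruning.
#' @param retained_fraction Surviving synapses / total prunable synapses.
#' @param acc_full,acc_pruned,acc_finetuned Test accuracies of the
#'   unpruned, pruned, and fine-tuned networks.
#' @return A one-row data frame.
#' @export
compression_report <- function(q, retained_fraction, acc_full, acc_pruned,
                               acc_finetuned = NA_real_) {
  data.frame(q = q, retained_fraction = retained_fraction,
             acc_full = acc_full, acc_pruned = acc_pruned,
             acc_finetuned = acc_finetuned)
}
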