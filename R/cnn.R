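#' Constrained convolutional network for sonogram classification
#'
#' A small CNN with the structure conv(I) -> average pool -> conv(J) ->
#' average pool -> K fully-connected layers -> softmax, named
#' `C{I}-C{J}-F{K}`. The network is built under conversion-safe
#' constraints so that its weights can be copied verbatim into a spiking
#' twin: every bias is fixed at zero, pooling is average (realizable as a
#' uniform synaptic fan-in), and the activation is a rectifier with unit
#' positive slope and an optional saturation cap. Under these constraints
#' the network is positively homogeneous, so per-layer rescaling never
#' changes the predicted class.
#'
#' @name cnn
NULL

#' Specify a C{I}-C{J}-F{K} network
#'
#' @param I,J Feature maps of the first and second convolutional layer.
#' @param K Number of fully-connected layers (the last is the softmax
#'   output; any earlier ones are rectified hidden layers).
#' @param input_shape `c(channels, bins)` of the input sonograms.
#' @param n_classes Number of output classes.
#' @param kernel Square convolution kernel size (default 3).
#' @param pool Square average-pooling size (default 2).
#' @param fc_hidden Width of each hidden fully-connected layer (default 32).
#' @param relu_cap Saturation level of the rectifier (default `Inf`, i.e.
#'   the plain rectifier).
#' @return A `network_spec` object; its name renders as `"C{I}-C{J}-F{K}"`.
#' @export
network_spec <- function(I, J, K, input_shape, n_classes,
                         kernel = 3L, pool = 2L, fc_hidden = 32L,
                         relu_cap = Inf) {
  if (I < 1L || J < 1L || K < 1L) stop("invalid network spec: I, J, K must be positive")
  if (n_classes < 2L) stop("invalid network spec: need at least 2 classes")
  if (any(input_shape < kernel)) stop("invalid network spec: input smaller than kernel")
  structure(
    list(I = as.integer(I), J = as.integer(J), K = as.integer(K),
         input_shape = as.integer(input_shape), n_classes = as.integer(n_classes),
         kernel = as.integer(kernel), pool = as.integer(pool),
         fc_hidden = as.integer(fc_hidden), relu_cap = relu_cap),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %s, input %dx%d, %d classes\n",
              network_name(x), x$input_shape[1L], x$input_shape[2L], x$n_classes))
  invisible(x)
}

#' Canonical architecture name
#' @param spec A [network_spec()].
#' @return Character, e.g. `"C6-C12-F2"`.
#' @export
network_name <- function(spec) sprintf("C%d-C%d-F%d", spec$I, spec$J, spec$K)

# ---- index precomputation ---------------------------------------------------

# patch index matrix for valid convolution over an (h, w, maps) volume
# flattened column-major; rows = output positions, cols = patch elements
im2col_index <- function(h, w, maps, k) {
  h_out <- h - k + 1L; w_out <- w - k + 1L
  pos_i <- rep(seq_len(h_out), times = w_out)
  pos_j <- rep(seq_len(w_out), each = h_out)
  offs <- expand.grid(a = seq_len(k) - 1L, b = seq_len(k) - 1L, m = seq_len(maps) - 1L)
  idx <- matrix(0L, nrow = h_out * w_out, ncol = k * k * maps)
  for (col in seq_len(nrow(offs))) {
    idx[, col] <- (pos_i + offs$a[col]) +
      (pos_j + offs$b[col] - 1L) * h + offs$m[col] * h * w
  }
  list(idx = idx, h_out = h_out, w_out = w_out)
}

# pooling index matrix: rows = pooled cells (over all maps), cols = p^2 members
pool_index <- function(h, w, maps, p) {
  h_out <- h %/% p; w_out <- w %/% p
  pos_i <- rep(seq_len(h_out), times = w_out * maps)
  pos_j <- rep(rep(seq_len(w_out), each = h_out), times = maps)
  pos_m <- rep(seq_len(maps), each = h_out * w_out)
  offs <- expand.grid(a = seq_len(p) - 1L, b = seq_len(p) - 1L)
  idx <- matrix(0L, nrow = h_out * w_out * maps, ncol = p * p)
  for (col in seq_len(nrow(offs))) {
    idx[, col] <- ((pos_i - 1L) * p + 1L + offs$a[col]) +
      ((pos_j - 1L) * p + offs$b[col]) * h + (pos_m - 1L) * h * w
  }
  list(idx = idx, h_out = h_out, w_out = w_out)
}

# layer geometry shared by the CNN and its spiking twin
network_geometry <- function(spec) {
  h <- spec$input_shape[1L]; w <- spec$input_shape[2L]
  k <- spec$kernel; p <- spec$pool
  c1 <- im2col_index(h, w, 1L, k)
  p1 <- pool_index(c1$h_out, c1$w_out, spec$I, p)
  c2 <- im2col_index(p1$h_out, p1$w_out, spec$I, k)
  p2 <- pool_index(c2$h_out, c2$w_out, spec$J, p)
  dims <- c(c1$h_out, c1$w_out, p1$h_out, p1$w_out,
            c2$h_out, c2$w_out, p2$h_out, p2$w_out)
  if (any(dims < 1L)) {
    stop("invalid network spec: input ", h, "x", w, " collapses to an empty ",
         "feature map through conv(", k, ")/pool(", p, ") twice; ",
         "use a larger input or smaller kernel/pool")
  }
  n_flat <- p2$h_out * p2$w_out * spec$J
  fc_dims <- if (spec$K == 1L) {
    list(c(n_flat, spec$n_classes))
  } else {
    dims <- list(c(n_flat, spec$fc_hidden))
    if (spec$K > 2L) {
      for (i in seq_len(spec$K - 2L)) dims <- c(dims, list(c(spec$fc_hidden, spec$fc_hidden)))
    }
    c(dims, list(c(spec$fc_hidden, spec$n_classes)))
  }
  list(c1 = c1, p1 = p1, c2 = c2, p2 = p2, n_flat = n_flat, fc_dims = fc_dims,
       conv1_in = h * w, conv2_in = p1$h_out * p1$w_out * spec$I)
}

#' Build a trainable network from its specification
#'
#' Weights are He-initialized from a seeded normal draw; biases do not
#' exist in this architecture (identically zero, non-trainable).
#'
#' @param spec A [network_spec()].
#' @param seed RNG seed for the weight initialization.
#' @return A `cnn_net` object with fields `spec`, `geom` and `weights`
#'   (`conv1`, `conv2`, `fc` = list of matrices).
#' @export
build_cnn <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  geom <- network_geometry(spec)
  set.seed(seed)
  he <- function(n_in, n_out) {
    matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), nrow = n_in)
  }
  k2 <- spec$kernel^2
  weights <- list(
    conv1 = he(k2 * 1L, spec$I),
    conv2 = he(k2 * spec$I, spec$J),
    fc = lapply(geom$fc_dims, function(d) he(d[1L], d[2L]))
  )
  structure(list(spec = spec, geom = geom, weights = weights), class = "cnn_net")
}

#' @export
print.cnn_net <- function(x, ...) {
  cat(sprintf("<cnn_net> %s, %d parameters (all biases fixed at 0)\n",
              network_name(x$spec), n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param net A [build_cnn()] network.
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) {
  length(net$weights$conv1) + length(net$weights$conv2) +
    sum(vapply(net$weights$fc, length, numeric(1L)))
}

relu <- function(z, cap = Inf) pmin(pmax(z, 0), cap)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass for one input image (matrix h x w), keeping intermediates
cnn_forward <- function(net, img) {
  g <- net$geom; W <- net$weights; cap <- net$spec$relu_cap
  x0 <- as.vector(img)
  xc1 <- matrix(x0[g$c1$idx], nrow = nrow(g$c1$idx))
  z1 <- xc1 %*% W$conv1
  a1 <- relu(z1, cap)                       # (h1*w1) x I
  a1v <- as.vector(a1)
  p1 <- rowMeans(matrix(a1v[g$p1$idx], nrow = nrow(g$p1$idx)))
  xc2 <- matrix(p1[g$c2$idx], nrow = nrow(g$c2$idx))
  z2 <- xc2 %*% W$conv2
  a2 <- relu(z2, cap)
  a2v <- as.vector(a2)
  p2 <- rowMeans(matrix(a2v[g$p2$idx], nrow = nrow(g$p2$idx)))
  acts <- list(p2)
  h <- p2
  n_fc <- length(W$fc)
  for (l in seq_len(n_fc)) {
    z <- as.vector(h %*% W$fc[[l]])
    h <- if (l < n_fc) relu(z, cap) else z
    acts <- c(acts, list(h))
  }
  list(x0 = x0, xc1 = xc1, z1 = z1, a1 = a1, p1 = p1,
       xc2 = xc2, z2 = z2, a2 = a2, p2 = p2,
       fc_acts = acts, logits = h)
}

# scatter-add `vals` at positions `idx` into a zero vector of length n
scatter_add <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, group = idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

# backward pass for one input; returns weight gradients
cnn_backward <- function(net, fwd, d_logits) {
  g <- net$geom; W <- net$weights; cap <- net$spec$relu_cap
  n_fc <- length(W$fc)
  d_fc <- vector("list", n_fc)
  dh <- d_logits
  for (l in rev(seq_len(n_fc))) {
    h_in <- fwd$fc_acts[[l]]
    d_fc[[l]] <- outer(h_in, dh)
    dh <- as.vector(W$fc[[l]] %*% dh)
    if (l > 1L) {
      # rectifier derivative read off the (post-activation) layer output
      dh <- dh * as.numeric(fwd$fc_acts[[l]] > 0 & fwd$fc_acts[[l]] < cap)
    }
  }
  # dh is now the gradient w.r.t. the flattened pool-2 output
  dp2 <- dh
  # pool2 backward: each member gets grad / p^2
  p2sq <- ncol(g$p2$idx)
  da2v <- scatter_add(rep(dp2 / p2sq, times = p2sq), as.vector(g$p2$idx),
                      length(fwd$a2))
  da2 <- matrix(da2v, nrow = nrow(fwd$a2))
  dz2 <- da2 * (fwd$z2 > 0 & fwd$z2 < cap)
  d_conv2 <- t(fwd$xc2) %*% dz2
  dxc2 <- dz2 %*% t(W$conv2)
  dp1 <- scatter_add(as.vector(dxc2), as.vector(g$c2$idx), length(fwd$p1))
  p1sq <- ncol(g$p1$idx)
  da1v <- scatter_add(rep(dp1 / p1sq, times = p1sq), as.vector(g$p1$idx),
                      length(fwd$a1))
  da1 <- matrix(da1v, nrow = nrow(fwd$a1))
  dz1 <- da1 * (fwd$z1 > 0 & fwd$z1 < cap)
  d_conv1 <- t(fwd$xc1) %*% dz1
  list(conv1 = d_conv1, conv2 = d_conv2, fc = d_fc)
}

#' Class probabilities for a batch of sonogram images
#'
#' @param net A [build_cnn()] network.
#' @param images List of `channels x bins` matrices (already normalized;
#'   see [sonogram_input()]).
#' @return Matrix `n_images x n_classes` of softmax probabilities.
#' @export
predict_cnn_prob <- function(net, images) {
  logits <- t(vapply(images, function(img) cnn_forward(net, img)$logits,
                     numeric(net$spec$n_classes)))
  softmax_rows(logits)
}

#' Predicted classes for a batch of sonogram images
#'
#' Ties in the logits are broken toward the lowest class index, matching
#' the spiking twin's decision rule.
#'
#' @inheritParams predict_cnn_prob
#' @return Integer vector of 1-based class predictions.
#' @export
predict_cnn <- function(net, images) {
  apply(predict_cnn_prob(net, images), 1L, which.max)
}

#' Normalize a sonogram into network input scale
#'
#' Divides counts by the sonogram's global maximum so that the densest
#' cell maps to 1 -- the same scaling [sonogram_to_rates()] applies, so
#' the CNN and its spiking twin see the same image up to the rate factor.
#'
#' @param s A [time_bin()] sonogram.
#' @return Numeric matrix in `[0, 1]`.
#' @export
sonogram_input <- function(s) {
  m <- max(s$counts)
  if (m == 0) return(s$counts * 0)
  s$counts / m
}

#' Train the network by stochastic gradient descent
#'
#' Minimizes softmax cross-entropy with plain seeded SGD. Biases do not
#' exist in the architecture, so the zero-bias constraint holds trivially
#' throughout training. An optional mask (from [prune_by_quantile()])
#' constrains the masked-out weights to exactly 0 after every update,
#' which is how masked fine-tuning is realized.
#'
#' @param net A [build_cnn()] network.
#' @param images List of normalized input matrices (see [sonogram_input()]).
#' @param labels Integer class labels in `1..n_classes`.
#' @param epochs Number of passes over the data (0 returns `net` unchanged).
#' @param lr Learning rate.
#' @param batch_size Minibatch size.
#' @param seed RNG seed controlling shuffling (training is deterministic
#'   given `seed` and the initial weights).
#' @param mask Optional prune mask (same shapes as the weights).
#' @param verbose Print per-epoch loss.
#' @return The trained `cnn_net`, with a `training_log` data frame
#'   (epoch, mean loss, training accuracy) attached.
#' @export
train_cnn <- function(net, images, labels, epochs = 30L, lr = 0.05,
                      batch_size = 8L, seed = 1L, mask = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "cnn_net"))
  n <- length(images)
  stopifnot(length(labels) == n, all(labels >= 1L), all(labels <= net$spec$n_classes))
  if (epochs == 0L) return(net)
  set.seed(seed)
  W <- net$weights
  if (!is.null(mask)) W <- mask_weights(W, mask)
  log_rows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    correct <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1L, n)]
      grad <- NULL
      for (b in batch) {
        net$weights <- W
        fwd <- cnn_forward(net, images[[b]])
        p <- softmax_rows(matrix(fwd$logits, nrow = 1L))[1L, ]
        y <- labels[b]
        losses <- c(losses, -log(max(p[y], 1e-12)))
        correct <- correct + as.integer(which.max(fwd$logits) == y)
        d_logits <- p
        d_logits[y] <- d_logits[y] - 1
        gb <- cnn_backward(net, fwd, d_logits / length(batch))
        grad <- if (is.null(grad)) gb else add_grads(grad, gb)
      }
      W$conv1 <- W$conv1 - lr * grad$conv1
      W$conv2 <- W$conv2 - lr * grad$conv2
      for (l in seq_along(W$fc)) W$fc[[l]] <- W$fc[[l]] - lr * grad$fc[[l]]
      if (!is.null(mask)) W <- mask_weights(W, mask)
    }
    log_rows[[ep]] <- data.frame(epoch = ep, loss = mean(losses), accuracy = correct / n)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep, mean(losses), correct / n))
    }
  }
  net$weights <- W
  net$training_log <- do.call(rbind, log_rows)
  net
}

add_grads <- function(a, b) {
  a$conv1 <- a$conv1 + b$conv1
  a$conv2 <- a$conv2 + b$conv2
  for (l in seq_along(a$fc)) a$fc[[l]] <- a$fc[[l]] + b$fc[[l]]
  a
}

mask_weights <- function(W, mask) {
  W$conv1 <- W$conv1 * mask$conv1
  W$conv2 <- W$conv2 * mask$conv2
  for (l in seq_along(W$fc)) W$fc[[l]] <- W$fc[[l]] * mask$fc[[l]]
  W
}
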