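#' Spiking twin of the convolutional network
#'
#' The trained CNN is converted into a structurally identical spiking
#' network of leaky integrate-and-fire (LIF) neurons: every synaptic
#' weight is copied bit-exactly, average pooling becomes a fixed uniform
#' fan-in of weight `1 / pool_area`, and the input layer receives Poisson
#' spikes drawn from the rate image produced by [sonogram_to_rates()].
#' Because the rectifier network is positively homogeneous, per-layer
#' threshold balancing (scaling each layer's firing threshold by a high
#' percentile of the CNN's activations in that layer over a calibration
#' set) keeps every LIF unit in its linear rate-coding regime without
#' touching the copied weights and without changing the predicted class.
#'
#' @name snn
NULL

#' LIF neuron and simulation parameters
#'
#' @param tau_m Membrane time constant in seconds (default 0.02).
#' @param v_th Base firing threshold (default 1).
#' @param v_reset Post-spike reset potential (default 0; must be < `v_th`).
#' @param dt_sim Simulation step in seconds (default 0.001; must satisfy
#'   `dt_sim <= tau_m / 5` so the discrete leak is well resolved).
#' @param t_sim Simulation duration in seconds (default 0.5).
#' @param max_rate Peak Poisson input rate in Hz (default 500).
#' @return A `lif_params` list.
#' @export
lif_params <- function(tau_m = 0.02, v_th = 1, v_reset = 0,
                       dt_sim = 0.001, t_sim = 0.5, max_rate = 500) {
  stopifnot(tau_m > 0, v_th > v_reset, dt_sim > 0, t_sim > 0, max_rate > 0)
  if (dt_sim > tau_m / 5) stop("dt_sim must be <= tau_m / 5 for a stable leak update")
  structure(list(tau_m = tau_m, v_th = v_th, v_reset = v_reset,
                 dt_sim = dt_sim, t_sim = t_sim, max_rate = max_rate),
            class = "lif_params")
}

#' Build the spiking twin of a trained CNN
#'
#' @param net A trained [build_cnn()] network.
#' @param lif A [lif_params()] object.
#' @return An `snn_net` with the CNN's weights (bit-exact copy), the
#'   shared layer geometry, the LIF parameters and unit per-layer
#'   threshold factors (see [threshold_balance()]).
#' @export
transfer_weights <- function(net, lif = lif_params()) {
  stopifnot(inherits(net, "cnn_net"), inherits(lif, "lif_params"))
  n_layers <- 4L + length(net$weights$fc)  # conv1, pool1, conv2, pool2, fc...
  structure(
    list(spec = net$spec, geom = net$geom, weights = net$weights, lif = lif,
         thr_factors = rep(1, n_layers)),
    class = "snn_net"
  )
}

#' @export
print.snn_net <- function(x, ...) {
  cat(sprintf("<snn_net> twin of %s, T_sim %g s, dt %g s, max input rate %g Hz\n",
              network_name(x$spec), x$lif$t_sim, x$lif$dt_sim, x$lif$max_rate))
  invisible(x)
}

# per-layer activations of the CNN on one image, in twin layer order
layer_activations <- function(net, img) {
  fwd <- cnn_forward(net, img)
  n_fc <- length(net$weights$fc)
  fc_out <- fwd$fc_acts[-1L]
  c(list(as.vector(fwd$a1), fwd$p1, as.vector(fwd$a2), fwd$p2), fc_out)
}

#' Balance the spiking twin's firing thresholds on calibration data
#'
#' Runs the CNN forward over a calibration set, pools each layer's
#' positive activations, and sets the layer's threshold factor to
#' `act_scale(layer) / act_scale(previous layer)` where `act_scale` is a
#' high percentile of the pooled activations (inputs are in `[0, 1]`, so
#' the zeroth scale is 1). Weights are untouched; by positive homogeneity
#' of the rectifier/average-pooling stack the CNN's argmax is invariant
#' to this per-layer rescaling, while the LIF units are kept near (and
#' rarely above) one spike per step. A percentile slightly below the
#' maximum is more robust than the maximum itself, which is dominated by
#' activation outliers and starves the deeper layers of spikes.
#'
#' @param snn An [transfer_weights()] twin.
#' @param images List of normalized calibration inputs
#'   (see [sonogram_input()]).
#' @param percentile Quantile of the pooled positive activations used as
#'   each layer's scale (default 0.9).
#' @return The twin with calibrated `thr_factors`.
#' @export
threshold_balance <- function(snn, images, percentile = 0.9) {
  stopifnot(inherits(snn, "snn_net"), percentile > 0, percentile <= 1)
  net <- structure(list(spec = snn$spec, geom = snn$geom, weights = snn$weights),
                   class = "cnn_net")
  pooled <- NULL
  for (img in images) {
    acts <- layer_activations(net, img)
    pooled <- if (is.null(pooled)) lapply(acts, function(a) a[a > 0]) else
      Map(function(p, a) c(p, a[a > 0]), pooled, acts)
  }
  scales <- vapply(pooled, function(a) {
    if (length(a) == 0L) 1e-9 else as.numeric(stats::quantile(a, percentile, type = 7))
  }, numeric(1L))
  scales <- pmax(scales, 1e-9)
  prev <- c(1, scales[-length(scales)])
  snn$thr_factors <- as.numeric(scales / prev)
  snn
}

#' Simulate the spiking twin on a Poisson rate image
#'
#' Input neurons emit Bernoulli spikes with probability `rate * dt_sim`
#' each step. Every LIF unit integrates its synaptic current with an
#' exponential leak (`v <- v * exp(-dt_sim / tau_m) + current`), fires
#' when `v >= v_th * thr_factor(layer)` and resets to `v_reset`. Average
#' pooling is a fixed fan-in of weight `1 / pool_area` onto LIF units.
#'
#' @param snn A [transfer_weights()] twin (ideally after
#'   [threshold_balance()]).
#' @param rates Non-negative rate matrix (Hz) shaped like the input
#'   sonogram, e.g. from [sonogram_to_rates()].
#' @param seed RNG seed for the Poisson input spikes.
#' @return List with `counts` (output-layer spike counts per class) and
#'   `layer_rates` (mean firing rate per layer, spikes/second).
#' @export
simulate_snn <- function(snn, rates, seed = 1L) {
  stopifnot(inherits(snn, "snn_net"))
  if (any(rates < 0)) stop("input rates must be non-negative")
  lif <- snn$lif; g <- snn$geom; W <- snn$weights
  set.seed(seed)
  n_steps <- round(lif$t_sim / lif$dt_sim)
  alpha <- exp(-lif$dt_sim / lif$tau_m)
  p_in <- pmin(as.vector(rates) * lif$dt_sim, 1)
  n_fc <- length(W$fc)
  sizes <- c(nrow(g$c1$idx) * snn$spec$I,
             nrow(g$p1$idx),
             nrow(g$c2$idx) * snn$spec$J,
             nrow(g$p2$idx),
             vapply(W$fc, ncol, numeric(1L)))
  v <- lapply(sizes, numeric)
  thr <- lif$v_th * snn$thr_factors
  out_counts <- numeric(snn$spec$n_classes)
  spike_totals <- numeric(length(sizes))
  p1sq <- ncol(g$p1$idx); p2sq <- ncol(g$p2$idx)
  for (step in seq_len(n_steps)) {
    s0 <- as.numeric(stats::runif(length(p_in)) < p_in)
    s_prev <- s0
    spikes <- vector("list", length(sizes))
    for (l in seq_along(sizes)) {
      current <- switch(as.character(l),
        "1" = as.vector(matrix(s_prev[g$c1$idx], nrow = nrow(g$c1$idx)) %*% W$conv1),
        "2" = rowSums(matrix(s_prev[g$p1$idx], nrow = nrow(g$p1$idx))) / p1sq,
        "3" = as.vector(matrix(s_prev[g$c2$idx], nrow = nrow(g$c2$idx)) %*% W$conv2),
        "4" = rowSums(matrix(s_prev[g$p2$idx], nrow = nrow(g$p2$idx))) / p2sq,
        as.vector(s_prev %*% W$fc[[l - 4L]])
      )
      v[[l]] <- v[[l]] * alpha + current
      fired <- v[[l]] >= thr[l]
      v[[l]][fired] <- lif$v_reset
      s_prev <- as.numeric(fired)
      spike_totals[l] <- spike_totals[l] + sum(fired)
      spikes[[l]] <- s_prev
    }
    out_counts <- out_counts + spikes[[length(sizes)]]
  }
  list(counts = out_counts,
       layer_rates = spike_totals / (sizes * lif$t_sim))
}

#' Classify a sonogram with the spiking twin
#'
#' Converts the sonogram to Poisson rates, simulates the twin and returns
#' the class with the highest output spike count; ties are broken toward
#' the lowest class index.
#'
#' @param snn A [transfer_weights()] twin.
#' @param s A [time_bin()] sonogram.
#' @param seed RNG seed for the input spikes.
#' @return Integer 1-based class prediction.
#' @export
classify_snn <- function(snn, s, seed = 1L) {
  rates <- sonogram_to_rates(s, max_rate = snn$lif$max_rate)
  res <- simulate_snn(snn, rates, seed = seed)
  which.max(res$counts)
}
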