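#' Spike train characterization metrics
#'
#' Five summary metrics describing an encoded spike train: Shannon entropy
#' of the raster symbols (bits/symbol), mutual information with the source
#' signal normalized by symbol entropy (MIS), Hoyer sparsity (HS), spiking
#' efficiency (epsilon) and spike density (spikes/second), plus a symbolic
#' computational-cost label per algorithm. The raster alphabet is ternary
#' {-1, 0, +1} so bipolar and unipolar encoders are treated uniformly.
#' S, MIS and epsilon are reconstructions of the cited quantities (their
#' exact published formulas are not available) and are versioned in the
#' record metadata.
#'
#' @name spiketrain-metrics
NULL

METRICS_VERSION <- "spikebench-reconstruction-1"

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon entropy of the encoded spike train
#'
#' Rasterizes the train at its `dt`, pools the per-step ternary symbols
#' over all channels and returns the empirical entropy of their
#' distribution in bits per symbol. A silent train has entropy 0.
#'
#' @param st A [spike_train()].
#' @return Entropy in bits/symbol (>= 0).
#' @export
shannon_entropy <- function(st) {
  sym <- as.vector(rasterize(st, "sign"))
  entropy_bits(table(sym) / length(sym))
}

#' Mutual information with the source, normalized by symbol entropy
#'
#' Discretizes the source amplitudes into `q_bins` equal-width bins,
#' aligns them step-by-step with the raster symbols (each source sample is
#' repeated when the raster is finer than the sample grid) and returns
#' `I(source; symbols) / H(symbols)`, which lies in `[0, 1]`. By
#' convention the value is 0 when the train is silent (`H(symbols) = 0`).
#'
#' @param st A [spike_train()].
#' @param src The source [as_signal()] the train was encoded from (same
#'   channel count).
#' @param q_bins Number of amplitude bins (default 8).
#' @return Normalized mutual information in `[0, 1]`.
#' @export
normalized_mutual_information <- function(st, src, q_bins = 8L) {
  stopifnot(inherits(st, "spike_train"), is_signal(src))
  if (n_channels(src) != st$n_channels) stop("channel counts differ between train and source")
  raster <- rasterize(st, "sign")
  n_steps <- ncol(raster)
  L <- n_samples(src)
  # map raster step -> source sample index
  src_idx <- pmin(floor((seq_len(n_steps) - 1L) * L / n_steps) + 1L, L)
  rng <- range(src$samples)
  if (rng[1L] == rng[2L]) {
    amp_bins <- matrix(1L, nrow = n_channels(src), ncol = L)
  } else {
    amp_bins <- matrix(pmin(floor((src$samples - rng[1L]) / (rng[2L] - rng[1L]) * q_bins) + 1L, q_bins),
                       nrow = n_channels(src))
  }
  xsym <- as.vector(amp_bins[, src_idx, drop = FALSE])
  ysym <- as.vector(raster)
  hy <- entropy_bits(table(ysym) / length(ysym))
  if (hy == 0) return(0)
  joint <- table(xsym, ysym) / length(ysym)
  hx <- entropy_bits(rowSums(joint))
  hxy <- entropy_bits(as.vector(joint))
  mi <- hx + hy - hxy
  min(max(mi / hy, 0), 1)
}

#' Hoyer sparsity of a spike train
#'
#' For each channel's binned spike-count vector `x` of length `n`,
#' `HS = (sqrt(n) - ||x||_1 / ||x||_2) / (sqrt(n) - 1)`: 1 for a one-hot
#' vector, 0 for a uniform positive vector. Channels are averaged; an
#' all-zero channel contributes 1 by convention.
#'
#' @param st A [spike_train()].
#' @return Sparsity in `[0, 1]`.
#' @export
hoyer_sparsity <- function(st) {
  counts <- rasterize(st, "count")
  n <- ncol(counts)
  if (n <= 1L) return(1)
  hs <- apply(counts, 1L, function(x) {
    l2 <- sqrt(sum(x^2))
    if (l2 == 0) return(1)
    (sqrt(n) - sum(x) / l2) / (sqrt(n) - 1)
  })
  mean(hs)
}

#' Spiking efficiency
#'
#' One minus the fraction of raster slots occupied by spikes,
#' `1 - N_spikes / (n_steps * n_channels)`, clipped into `[0, 1]`: a
#' silent train scores 1, a fully occupied raster 0.
#'
#' @param st A [spike_train()].
#' @return Efficiency in `[0, 1]`.
#' @export
spiking_efficiency <- function(st) {
  n_steps <- max(1L, round(st$duration / st$dt))
  min(max(1 - n_events(st) / (n_steps * st$n_channels), 0), 1)
}

#' Spike density
#'
#' @param st A [spike_train()].
#' @return List with `total` (spikes/second over all channels) and
#'   `per_channel` (numeric vector, spikes/second in each channel).
#' @export
spike_density <- function(st) {
  per_ch <- tabulate(st$channels, nbins = st$n_channels) / st$duration
  list(total = n_events(st) / st$duration, per_channel = per_ch)
}

#' Symbolic computational-cost label of an encoder
#'
#' Asymptotic cost in terms of `l` (signal length), `c` (channels),
#' `n` (bitwise representation length) and `w` (kernel width).
#'
#' @param algorithm Encoder name (case-insensitive).
#' @return A string such as `"O(l*c)"`.
#' @export
complexity_label <- function(algorithm) {
  labels <- c(
    poisson = "O(l*c)", tbr = "O(l*c)", mw = "O(l*c*w)", sf = "O(l*c)",
    zcsf = "O(l*c)", hsa = "O(l*c*w)", mhsa = "O(l*c*w)", bsa = "O(l*c*w)",
    phase = "O(l*c*n)", ttfs = "O(l*c*n)", burst = "O(l*c*n)"
  )
  key <- tolower(algorithm)
  if (!key %in% names(labels)) {
    stop("unknown encoder \"", algorithm, "\"; valid names: ",
         paste(names(labels), collapse = ", "))
  }
  unname(labels[key])
}

#' Full metrics record for one encoded train
#'
#' @param st A [spike_train()].
#' @param src Source [as_signal()].
#' @param q_bins Amplitude bins for the mutual-information term.
#' @return A one-row data frame: `encoder`, `S`, `MIS`, `HS`, `epsilon`,
#'   `density`, `complexity`, `metrics_version`.
#' @export
metrics_record <- function(st, src, q_bins = 8L) {
  enc <- if (is.null(st$meta$encoder)) NA_character_ else st$meta$encoder
  data.frame(
    encoder = enc,
    S = shannon_entropy(st),
    MIS = normalized_mutual_information(st, src, q_bins),
    HS = hoyer_sparsity(st),
    epsilon = spiking_efficiency(st),
    density = spike_density(st)$total,
    complexity = if (is.na(enc)) NA_character_ else complexity_label(enc),
    metrics_version = METRICS_VERSION,
    stringsAsFactors = FALSE
  )
}
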