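#' Spike encoding algorithms
#'
#' Eleven algorithms translating continuous signals into spike trains, in
#' five families:
#' \itemize{
#'   \item Rate coding: Poisson rate (`poisson`).
#'   \item Temporal contrast: threshold-based representation (`tbr`),
#'     moving window (`mw`), step-forward (`sf`), zero-crossing
#'     step-forward (`zcsf`). These may emit both polarities (except
#'     `zcsf`, which half-wave rectifies and is unipolar).
#'   \item Deconvolution-based: Hough spiker (`hsa`), modified Hough spiker
#'     (`mhsa`), Ben's spiker (`bsa`). Spike times are chosen so that the
#'     spike train convolved with a FIR kernel approximates the signal;
#'     unipolar.
#'   \item Global referenced: phase (`phase`), time-to-first-spike
#'     (`ttfs`); unipolar.
#'   \item Latency/ISI: burst (`burst`); unipolar.
#' }
#' All encoders process channels independently, use strict inequalities at
#' thresholds (a constant signal is silent), and accept `tau_ref` (seconds)
#' to enforce a refractory period by dropping violating events; with
#' `tau_ref = 0` the unconstrained encoding is returned.
#'
#' @name encoders
NULL

# ---- shared helpers ---------------------------------------------------------

check_signal_finite <- function(x) {
  stopifnot(is_signal(x))
  if (!all(is.finite(x$samples))) stop("signal contains non-finite values")
  invisible(x)
}

# population standard deviation, as printed threshold formulas use it
sd_pop <- function(v) sqrt(mean((v - mean(v))^2))

# rectify then min-max normalize one channel into [0, 1]
rectified_unit <- function(v) {
  v <- pmax(v, 0)
  rng <- max(v) - min(v)
  if (rng == 0) return(rep(0, length(v)))
  (v - min(v)) / rng
}

# default rectangular deconvolution kernel for one channel: width
# max(2, floor(L/32)) samples, unit mass scaled to the channel's peak
default_fir_kernel <- function(v, L = length(v)) {
  w <- max(2L, floor(L / 32))
  rep(max(abs(v)) / w, w)
}

finish_train <- function(times, channels, polarities, x, dt, encoder, params,
                         tau_ref = 0) {
  st <- spike_train(times, channels, polarities,
                    n_channels = n_channels(x), duration = x$duration, dt = dt,
                    meta = c(list(encoder = encoder), params, list(tau_ref = tau_ref)))
  apply_refractory(st, tau_ref)
}

# ---- rate coding ------------------------------------------------------------

#' Poisson rate encoding
#'
#' Treats amplitudes as firing rates and draws spike times from the
#' corresponding (piecewise-homogeneous) Poisson process: inter-spike
#' intervals are generated by inversion, `ISI = -log(1 - x) / r` with
#' `x ~ U(0, 1)`, and cumulated until the encoding interval is exhausted.
#' With a matrix signal each sample is a rate held constant over its `dt`
#' bin; alternatively a constant `rate` (scalar or per channel, Hz) can be
#' supplied to ignore the sample values.
#'
#' @param x A [as_signal()] object; sample values must be non-negative
#'   rates in Hz unless `rate` is given.
#' @param rate Optional constant rate in Hz (scalar or one per channel).
#' @param tau_ref Refractory period in seconds.
#' @param seed Optional RNG seed for reproducibility.
#' @return A [spike_train()]; unipolar.
#' @export
encode_poisson <- function(x, rate = NULL, tau_ref = 0, seed = NULL) {
  check_signal_finite(x)
  if (!is.null(seed)) set.seed(seed)
  L <- n_samples(x); dt <- x$duration / L
  times <- numeric(0); channels <- integer(0)
  for (ch in seq_len(n_channels(x))) {
    if (!is.null(rate)) {
      r_ch <- if (length(rate) > 1L) rate[ch] else rate
      if (r_ch < 0) stop("Poisson rate must be non-negative")
      times_ch <- poisson_homogeneous(r_ch, 0, x$duration)
    } else {
      r_seq <- x$samples[ch, ]
      if (any(r_seq < 0)) stop("Poisson rate must be non-negative")
      # memorylessness makes an independent restart at each bin exact
      times_ch <- unlist(lapply(seq_len(L), function(i) {
        poisson_homogeneous(r_seq[i], (i - 1L) * dt, i * dt)
      }))
    }
    times <- c(times, times_ch)
    channels <- c(channels, rep(ch, length(times_ch)))
  }
  finish_train(times, channels, rep(1L, length(times)), x, dt,
               "poisson", list(rate = rate, seed = seed), tau_ref)
}

# homogeneous Poisson process on (t0, t1] at rate r, by ISI inversion
poisson_homogeneous <- function(r, t0, t1) {
  if (r <= 0) return(numeric(0))
  out <- numeric(0)
  t <- t0
  repeat {
    t <- t - log(1 - stats::runif(1L)) / r
    if (t > t1) break
    out <- c(out, t)
  }
  out
}

# ---- temporal contrast ------------------------------------------------------

#' Threshold-based representation (TBR) encoding
#'
#' Emits a spike wherever the first difference of the signal exceeds, in
#' absolute value, a per-channel threshold
#' `mean(variation) + gamma * sd(variation)` (population standard
#' deviation over the signed variations). Spike polarity is the sign of the
#' variation. Larger `gamma` widens the noise-rejection band and reduces
#' the spike count.
#'
#' @param x A [as_signal()] object.
#' @param gamma Non-negative width multiplier of the threshold band.
#' @param tau_ref Refractory period in seconds.
#' @return A [spike_train()]; bipolar.
#' @export
encode_tbr <- function(x, gamma = 1, tau_ref = 0) {
  check_signal_finite(x)
  stopifnot(gamma >= 0)
  L <- n_samples(x); dt <- x$duration / L
  times <- numeric(0); channels <- integer(0); pols <- integer(0)
  for (ch in seq_len(n_channels(x))) {
    v <- diff(x$samples[ch, ])
    thr <- mean(v) + gamma * sd_pop(v)
    idx <- which(abs(v) > thr)
    times <- c(times, idx * dt)
    channels <- c(channels, rep(ch, length(idx)))
    pols <- c(pols, as.integer(sign(v[idx])))
  }
  finish_train(times, channels, pols, x, dt, "tbr", list(gamma = gamma), tau_ref)
}

#' Moving window (MW) encoding
#'
#' Tracks a sliding baseline (mean of the previous `window` samples,
#' initialized as the mean of the first `window` samples) and emits a
#' positive spike where the signal strictly exceeds `base + threshold` and
#' a negative one where it falls below `base - threshold`. The threshold is
#' the mean absolute first difference of the channel.
#'
#' @param x A [as_signal()] object.
#' @param window Sliding window length in samples (default `max(2, L/10)`).
#' @param tau_ref Refractory period in seconds.
#' @return A [spike_train()]; bipolar.
#' @export
encode_mw <- function(x, window = NULL, tau_ref = 0) {
  check_signal_finite(x)
  L <- n_samples(x); dt <- x$duration / L
  if (is.null(window)) window <- max(2L, floor(L / 10))
  stopifnot(window >= 1L, window <= L)
  times <- numeric(0); channels <- integer(0); pols <- integer(0)
  for (ch in seq_len(n_channels(x))) {
    s <- x$samples[ch, ]
    thr <- mean(abs(diff(s)))
    base0 <- mean(s[seq_len(window)])
    for (i in seq_len(L)) {
      base <- if (i <= window) base0 else mean(s[(i - window):(i - 1L)])
      if (s[i] > base + thr) {
        times <- c(times, (i - 1L) * dt); channels <- c(channels, ch); pols <- c(pols, 1L)
      } else if (s[i] < base - thr) {
        times <- c(times, (i - 1L) * dt); channels <- c(channels, ch); pols <- c(pols, -1L)
      }
    }
  }
  finish_train(times, channels, pols, x, dt, "mw", list(window = window), tau_ref)
}

# shared step-forward threshold: mean over channels of per-channel peak-to-peak
sf_threshold <- function(x, gamma) {
  if (gamma <= 0) stop("`gamma` must be positive (threshold = mean(jump) / gamma)")
  jumps <- apply(x$samples, 1L, function(s) max(s) - min(s))
  mean(jumps) / gamma
}

#' Step-forward (SF) encoding
#'
#' Maintains a per-channel baseline initialized at the first sample. When
#' the signal strictly exceeds `base + threshold` a positive spike is
#' emitted and the baseline steps up by `threshold`; symmetrically for
#' negative spikes. The threshold is shared across channels:
#' `mean(per-channel max - min) / gamma`.
#'
#' @param x A [as_signal()] object.
#' @param gamma Positive divisor of the mean peak-to-peak jump.
#' @param tau_ref Refractory period in seconds.
#' @return A [spike_train()]; bipolar.
#' @export
encode_sf <- function(x, gamma = 2, tau_ref = 0) {
  check_signal_finite(x)
  L <- n_samples(x); dt <- x$duration / L
  thr <- sf_threshold(x, gamma)
  times <- numeric(0); channels <- integer(0); pols <- integer(0)
  for (ch in seq_len(n_channels(x))) {
    s <- x$samples[ch, ]
    base <- s[1L]
    for (i in 2:L) {
      if (s[i] > base + thr) {
        times <- c(times, (i - 1L) * dt); channels <- c(channels, ch); pols <- c(pols, 1L)
        base <- base + thr
      } else if (s[i] < base - thr) {
        times <- c(times, (i - 1L) * dt); channels <- c(channels, ch); pols <- c(pols, -1L)
        base <- base - thr
      }
    }
  }
  finish_train(times, channels, pols, x, dt, "sf", list(gamma = gamma), tau_ref)
}

#' Zero-crossing step-forward (ZCSF) encoding
#'
#' Inherits the step-forward threshold but replaces the baseline with a
#' half-wave rectifying condition: a (always positive) spike is emitted at
#' sample `i` iff `signal[i] > 0` and `signal[i] > threshold`.
#'
#' @inheritParams encode_sf
#' @return A [spike_train()]; unipolar.
#' @export
encode_zcsf <- function(x, gamma = 2, tau_ref = 0) {
  check_signal_finite(x)
  L <- n_samples(x); dt <- x$duration / L
  thr <- sf_threshold(x, gamma)
  times <- numeric(0); channels <- integer(0)
  for (ch in seq_len(n_channels(x))) {
    s <- x$samples[ch, ]
    idx <- which(s > 0 & s > thr)
    times <- c(times, (idx - 1L) * dt)
    channels <- c(channels, rep(ch, length(idx)))
  }
  finish_train(times, channels, rep(1L, length(times)), x, dt,
               "zcsf", list(gamma = gamma), tau_ref)
}

# ---- deconvolution-based ----------------------------------------------------

#' Hough spiker algorithm (HSA) encoding
#'
#' Greedy deconvolution: scanning the signal left to right, a spike is
#' emitted at step `i` whenever the signal segment dominates the FIR kernel
#' pointwise (`signal[i + j - 1] >= kernel[j]` for every in-range `j`), and
#' the kernel is then subtracted from the segment. Convolving the resulting
#' unipolar train with the kernel approximates the signal.
#'
#' @param x A [as_signal()] object.
#' @param fir_kernel Numeric FIR kernel. Default: per-channel rectangular
#'   window of width `max(2, floor(L/32))` whose mass equals the channel's
#'   peak absolute amplitude. A silent (all-zero) channel emits no spikes.
#' @param tau_ref Refractory period in seconds.
#' @return A [spike_train()]; unipolar.
#' @export
encode_hsa <- function(x, fir_kernel = NULL, tau_ref = 0) {
  deconv_encode(x, fir_kernel, tau_ref, mode = "hsa")
}

#' Modified Hough spiker algorithm (MHSA) encoding
#'
#' As [encode_hsa()], but the pointwise-dominance gate is softened: the
#' shortfall `sum_j max(0, kernel[j] - signal[i + j - 1])` is accumulated
#' over the kernel support and a spike is emitted (with subtraction) when
#' this error does not exceed `threshold`.
#'
#' @inheritParams encode_hsa
#' @param threshold Maximum tolerated shortfall. Default: 5 percent of the
#'   channel's peak absolute amplitude.
#' @return A [spike_train()]; unipolar.
#' @export
encode_mhsa <- function(x, fir_kernel = NULL, threshold = NULL, tau_ref = 0) {
  deconv_encode(x, fir_kernel, tau_ref, mode = "mhsa", threshold = threshold)
}

#' Ben's spiker algorithm (BSA) encoding
#'
#' At each step two cumulative errors over the kernel support are compared:
#' `error1 = sum |signal - kernel|` and `error2 = sum |signal|`. A spike is
#' emitted (and the kernel subtracted) when `error1 <= error2 * threshold`.
#'
#' @inheritParams encode_hsa
#' @param threshold Relative error gate (default 0.955).
#' @return A [spike_train()]; unipolar.
#' @export
encode_bsa <- function(x, fir_kernel = NULL, threshold = 0.955, tau_ref = 0) {
  deconv_encode(x, fir_kernel, tau_ref, mode = "bsa", threshold = threshold)
}

deconv_encode <- function(x, fir_kernel, tau_ref, mode, threshold = NULL) {
  check_signal_finite(x)
  L <- n_samples(x); dt <- x$duration / L
  times <- numeric(0); channels <- integer(0)
  for (ch in seq_len(n_channels(x))) {
    s <- x$samples[ch, ]
    h <- if (is.null(fir_kernel)) default_fir_kernel(s, L) else fir_kernel
    if (all(s == 0) && is.null(fir_kernel)) next  # silent channel: degenerate kernel
    thr_ch <- threshold
    if (mode == "mhsa" && is.null(thr_ch)) thr_ch <- 0.05 * max(abs(s))
    w <- length(h)
    idx <- integer(0)
    for (i in seq_len(L)) {
      jmax <- min(w, L - i + 1L)
      seg <- s[i:(i + jmax - 1L)]
      kseg <- h[seq_len(jmax)]
      emit <- switch(mode,
        hsa  = all(seg >= kseg),
        mhsa = sum(pmax(0, kseg - seg)) <= thr_ch,
        bsa  = sum(abs(seg - kseg)) <= sum(abs(seg)) * thr_ch
      )
      if (emit) {
        idx <- c(idx, i)
        s[i:(i + jmax - 1L)] <- seg - kseg
      }
    }
    times <- c(times, (idx - 1L) * dt)
    channels <- c(channels, rep(ch, length(idx)))
  }
  finish_train(times, channels, rep(1L, length(times)), x, dt,
               mode, list(fir_kernel = fir_kernel, threshold = threshold), tau_ref)
}

#' Reconstruct a signal from a deconvolution-family spike train
#'
#' Convolves each channel's spike indicator with the FIR kernel, the
#' inverse operation the deconvolution encoders approximate.
#'
#' @param st A [spike_train()] from [encode_hsa()], [encode_mhsa()] or
#'   [encode_bsa()].
#' @param fir_kernel The kernel used at encoding time.
#' @param L Length of the reconstructed signal in samples.
#' @return Numeric matrix `n_channels x L`.
#' @export
reconstruct_deconv <- function(st, fir_kernel, L) {
  stopifnot(inherits(st, "spike_train"))
  out <- matrix(0, nrow = st$n_channels, ncol = L)
  w <- length(fir_kernel)
  if (n_events(st) > 0L) {
    idx <- round(st$times / st$dt) + 1L
    for (k in seq_len(n_events(st))) {
      i <- idx[k]; jmax <- min(w, L - i + 1L)
      if (jmax >= 1L) {
        out[st$channels[k], i:(i + jmax - 1L)] <-
          out[st$channels[k], i:(i + jmax - 1L)] + fir_kernel[seq_len(jmax)]
      }
    }
  }
  out
}

# ---- global referenced ------------------------------------------------------

# first `beta` fractional bits of v in [0, 1]; v == 1 maps to all ones
fractional_bits <- function(v, beta) {
  if (v >= 1) return(rep(1L, beta))
  v <- min(max(v, 0), 1 - 2^(-beta))
  vapply(seq_len(beta), function(k) as.integer(floor(v * 2^k) %% 2), integer(1L))
}

#' Phase encoding
#'
#' Each channel is rectified and min-max normalized into `[0, 1]`; every
#' sample is then expanded into `beta` sub-steps carrying its truncated
#' binary (fractional-bit) representation, a spike marking each 1 bit. The
#' channel maximum (normalized value exactly 1) maps to the all-ones burst;
#' other values are clipped into `[0, 1 - 2^-beta]` before expansion.
#'
#' @param x A [as_signal()] object.
#' @param beta Number of fractional bits per sample (>= 1, default 8).
#' @param tau_ref Refractory period in seconds.
#' @return A [spike_train()] with `dt = duration / (L * beta)`; unipolar.
#' @export
encode_phase <- function(x, beta = 8L, tau_ref = 0) {
  check_signal_finite(x)
  stopifnot(beta >= 1L)
  L <- n_samples(x); dt_sub <- x$duration / (L * beta)
  times <- numeric(0); channels <- integer(0)
  for (ch in seq_len(n_channels(x))) {
    v <- rectified_unit(x$samples[ch, ])
    for (i in seq_len(L)) {
      if (v[i] <= 0) next
      bits <- fractional_bits(v[i], beta)
      k <- which(bits == 1L)
      if (length(k) > 0L) {
        times <- c(times, ((i - 1L) * beta + (k - 1L)) * dt_sub)
        channels <- c(channels, rep(ch, length(k)))
      }
    }
  }
  finish_train(times, channels, rep(1L, length(times)), x, dt_sub,
               "phase", list(beta = beta), tau_ref)
}

#' Time-to-first-spike (TTFS) encoding
#'
#' Values are rectified and min-max normalized per channel; each value `v`
#' crosses the exponentially decaying membrane threshold
#' `P_th(t) = theta0 * exp(-t / tau_th)` at `t* = -tau_th * log(v / theta0)`
#' and emits one spike at the earliest point of a uniform `n_grid`-point
#' latency grid over the encoding interval at or after `t*`. Latencies
#' beyond the interval (and `v = 0`, which never crosses) emit nothing.
#' The optional `bitwise` mode additionally expands each value into a
#' burst: one spike per 1 bit of its `beta`-bit expansion, spaced by one
#' grid step from `t*` (a reconstruction of a bin-based binary variant).
#'
#' @param x A [as_signal()] object.
#' @param theta0 Initial threshold (default 1).
#' @param tau_th Threshold decay time constant in seconds (default 0.1).
#' @param n_grid Number of uniform latency grid points (default 64).
#' @param bitwise If `TRUE`, apply the binary burst expansion.
#' @param beta Bits used in `bitwise` mode (default 8).
#' @param tau_ref Refractory period in seconds.
#' @return A [spike_train()] with `dt = duration / n_grid`; unipolar.
#' @export
encode_ttfs <- function(x, theta0 = 1, tau_th = 0.1, n_grid = 64L,
                        bitwise = FALSE, beta = 8L, tau_ref = 0) {
  check_signal_finite(x)
  stopifnot(theta0 > 0, tau_th > 0, n_grid >= 2L)
  L <- n_samples(x); g_step <- x$duration / n_grid
  times <- numeric(0); channels <- integer(0)
  for (ch in seq_len(n_channels(x))) {
    v <- rectified_unit(x$samples[ch, ]) * theta0
    for (i in seq_len(L)) {
      if (v[i] <= 0) next
      t_star <- -tau_th * log(v[i] / theta0)
      k0 <- ceiling(t_star / g_step - 1e-12)
      if (bitwise) {
        bits <- fractional_bits(v[i] / theta0, beta)
        kk <- k0 + which(bits == 1L) - 1L
      } else {
        kk <- k0
      }
      tt <- kk * g_step
      tt <- tt[tt <= x$duration + 1e-12]
      if (length(tt) > 0L) {
        times <- c(times, pmin(tt, x$duration))
        channels <- c(channels, rep(ch, length(tt)))
      }
    }
  }
  finish_train(times, channels, rep(1L, length(times)), x, g_step, "ttfs",
               list(theta0 = theta0, tau_th = tau_th, n_grid = n_grid,
                    bitwise = bitwise, beta = beta), tau_ref)
}

# ---- latency / ISI ----------------------------------------------------------

#' Burst encoding
#'
#' Each channel's rectified, min-max normalized sample value (`rate` in
#' `[0, 1]`) controls both the number of spikes in a burst,
#' `ceiling(rate * n_max)`, and their spacing in raster steps,
#' `ceiling(t_max - rate * (t_max - t_min))` when more than one spike is
#' emitted (`t_max` otherwise). Bursts start at the sample's timestamp;
#' spikes falling beyond the encoding interval are dropped.
#'
#' @param x A [as_signal()] object.
#' @param n_max Maximum spikes per burst (>= 1, default 5).
#' @param t_min,t_max Minimum / maximum inter-spike interval in raster
#'   steps (`t_min <= t_max`; defaults 2 and 10).
#' @param tau_ref Refractory period in seconds.
#' @return A [spike_train()]; unipolar.
#' @export
encode_burst <- function(x, n_max = 5L, t_min = 2L, t_max = 10L, tau_ref = 0) {
  check_signal_finite(x)
  stopifnot(n_max >= 1L, t_min <= t_max, t_min >= 1L)
  L <- n_samples(x); dt <- x$duration / L
  times <- numeric(0); channels <- integer(0)
  for (ch in seq_len(n_channels(x))) {
    rate <- rectified_unit(x$samples[ch, ])
    for (i in seq_len(L)) {
      n_sp <- ceiling(rate[i] * n_max)
      if (n_sp < 1L) next
      isi <- if (n_sp > 1L) ceiling(t_max - rate[i] * (t_max - t_min)) else t_max
      tt <- (i - 1L) * dt + (seq_len(n_sp) - 1L) * isi * dt
      tt <- tt[tt <= x$duration + 1e-12]
      if (length(tt) > 0L) {
        times <- c(times, pmin(tt, x$duration))
        channels <- c(channels, rep(ch, length(tt)))
      }
    }
  }
  finish_train(times, channels, rep(1L, length(times)), x, dt, "burst",
               list(n_max = n_max, t_min = t_min, t_max = t_max), tau_ref)
}

# ---- dispatch ---------------------------------------------------------------

encoder_registry <- function() {
  list(
    poisson = encode_poisson, tbr = encode_tbr, mw = encode_mw,
    sf = encode_sf, zcsf = encode_zcsf, hsa = encode_hsa,
    mhsa = encode_mhsa, bsa = encode_bsa, phase = encode_phase,
    ttfs = encode_ttfs, burst = encode_burst
  )
}

#' Encoder family taxonomy
#'
#' @return Named character vector mapping each algorithm to its coding
#'   class: Rate, Temporal Contrast, Deconvolution-based, Global
#'   Referenced or Latency/ISI.
#' @export
encoder_classes <- function() {
  c(poisson = "Rate",
    tbr = "Temporal Contrast", mw = "Temporal Contrast",
    sf = "Temporal Contrast", zcsf = "Temporal Contrast",
    hsa = "Deconvolution-based", mhsa = "Deconvolution-based",
    bsa = "Deconvolution-based",
    phase = "Global Referenced", ttfs = "Global Referenced",
    burst = "Latency/ISI")
}

#' Encode a signal with a named algorithm
#'
#' Case-insensitive dispatch over the eleven registered encoders; the
#' algorithm name and parameters are recorded in the result's `meta`.
#'
#' @param x A [as_signal()] object.
#' @param algorithm One of `names(encoder_classes())` (case-insensitive).
#' @param params Named list of parameters passed to the encoder.
#' @return A [spike_train()].
#' @export
encode <- function(x, algorithm, params = list()) {
  reg <- encoder_registry()
  key <- tolower(algorithm)
  if (!key %in% names(reg)) {
    stop("unknown encoder \"", algorithm, "\"; valid names: ",
         paste(names(reg), collapse = ", "))
  }
  do.call(reg[[key]], c(list(x), params))
}
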