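#' Cochlea-inspired filter banks
#'
#' The basilar membrane performs a frequency decomposition of incoming
#' sound; banks of band-pass filters are the standard engineering analogue.
#' Two realizations are provided: 4th-order gammatone filters with center
#' frequencies spaced on the Glasberg-Moore ERB-rate scale, and 2nd-order
#' Butterworth band-passes with contiguous, logarithmically spaced band
#' edges. Both are applied forward-backward (zero phase) so that no
#' per-channel group delay skews the downstream time binning.
#'
#' @name filterbank
NULL

# Glasberg-Moore equivalent rectangular bandwidth (Hz) at frequency f (Hz)
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

# ERB-rate scale and its inverse
erb_rate <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)
erb_rate_inv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' Specify a filter bank
#'
#' @param kind `"gammatone"` or `"butterworth"`.
#' @param n_channels Number of frequency channels. The usual design points
#'   are 4, 8, 16, 32 or 64; other values work but trigger a notice.
#' @param f_low,f_high Passband limits in Hz; `0 < f_low < f_high <= fs/2`.
#' @param fs Sampling rate (Hz) of the signals the bank will be applied to.
#' @param order Filter order (default 4 for gammatone, 2 for Butterworth).
#' @return A `filterbank_spec` list.
#' @export
filterbank_spec <- function(kind = c("gammatone", "butterworth"),
                            n_channels, f_low, f_high, fs,
                            order = NULL) {
  kind <- match.arg(kind)
  if (n_channels < 1L) stop("`n_channels` must be a positive integer")
  if (!(f_low > 0)) stop("invalid band: f_low must be > 0 (got ", f_low, ")")
  if (!(f_high > f_low)) stop("invalid band: f_high must exceed f_low")
  if (f_high > fs / 2) {
    stop("invalid band: f_high = ", f_high, " Hz exceeds the Nyquist frequency fs/2 = ", fs / 2, " Hz")
  }
  if (!(n_channels %in% c(4L, 8L, 16L, 32L, 64L))) {
    message("filterbank_spec: n_channels = ", n_channels,
            " is outside the usual design points {4, 8, 16, 32, 64}")
  }
  if (is.null(order)) order <- if (kind == "gammatone") 4L else 2L
  structure(
    list(kind = kind, n_channels = as.integer(n_channels),
         f_low = f_low, f_high = f_high, fs = fs, order = as.integer(order)),
    class = "filterbank_spec"
  )
}

#' Design a filter bank from its specification
#'
#' Gammatone channels have center frequencies equally spaced on the ERB-rate
#' scale between `f_low` and `f_high` and are realized as truncated
#' impulse-response FIR filters normalized to unit gain at the center
#' frequency. The nominal gammatone bandwidth `1.019 * ERB(fc)` is capped at
#' `0.8 * fc` so that very low center frequencies (inertial-range banks)
#' keep a band-pass character with the response peak at `fc`. Butterworth
#' channels partition `[f_low, f_high]` into contiguous bands with
#' logarithmically spaced edges (constant edge ratio); the nominal center is
#' the geometric mean of each band's edges.
#'
#' @param spec A [filterbank_spec()].
#' @return A `filter_bank` object: `kind`, `fs`, `centers` (strictly
#'   increasing, Hz), `edges` (Butterworth only) and the per-channel filter
#'   realizations.
#' @export
design_filterbank <- function(spec) {
  stopifnot(inherits(spec, "filterbank_spec"))
  n <- spec$n_channels
  if (spec$kind == "gammatone") {
    e <- seq(erb_rate(spec$f_low), erb_rate(spec$f_high), length.out = n + 2L)
    centers <- erb_rate_inv(e[2:(n + 1L)])
    filters <- lapply(centers, function(fc) gammatone_fir(fc, spec$fs, spec$order))
    edges <- NULL
  } else {
    edges <- spec$f_low * (spec$f_high / spec$f_low)^(seq(0L, n) / n)
    centers <- sqrt(edges[-(n + 1L)] * edges[-1L])
    filters <- lapply(seq_len(n), function(k) {
      signal::butter(spec$order, c(edges[k], edges[k + 1L]) / (spec$fs / 2), type = "pass")
    })
  }
  structure(
    list(kind = spec$kind, fs = spec$fs, centers = centers,
         edges = edges, filters = filters, spec = spec),
    class = "filter_bank"
  )
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %s, %d channels, centers %.3g..%.3g Hz @ fs %g Hz\n",
              x$kind, length(x$centers), min(x$centers), max(x$centers), x$fs))
  invisible(x)
}

# 4th-order gammatone as a truncated impulse response FIR, unit gain at fc
gammatone_fir <- function(fc, fs, order = 4L) {
  bw <- min(1.019 * erb_bandwidth(fc), 0.8 * fc)
  # envelope t^(order-1) exp(-2 pi bw t): cover well past its decay
  t_len <- (order - 1 + 9) / (2 * pi * bw)
  n_taps <- max(8L, ceiling(t_len * fs))
  t <- (seq_len(n_taps) - 1L) / fs
  h <- t^(order - 1) * exp(-2 * pi * bw * t) * cos(2 * pi * fc * t)
  # normalize |H(fc)| to 1
  gain <- Mod(sum(h * exp(-2i * pi * fc * t)))
  h <- h / gain
  list(h = h, fc = fc, bw = bw)
}

#' Apply a filter bank to a single-channel signal
#'
#' Each filter is run forward and backward over the input, yielding a
#' zero-phase decomposition: output channel `k` is the input restricted to
#' band `k`, time-aligned with the original.
#'
#' @param x A single-channel [as_signal()] object.
#' @param bank A [design_filterbank()] result with `bank$fs == x$fs`.
#' @return A [as_signal()] with `n_channels` rows and the same length.
#' @export
apply_filterbank <- function(x, bank) {
  stopifnot(is_signal(x), inherits(bank, "filter_bank"))
  if (n_channels(x) != 1L) {
    stop("apply_filterbank() expects a single-channel signal; ",
         "apply the bank to each channel (see decompose_signal())")
  }
  if (!isTRUE(all.equal(bank$fs, x$fs))) {
    stop("filter bank fs (", bank$fs, ") does not match signal fs (", x$fs, ")")
  }
  s <- x$samples[1L, ]
  out <- t(vapply(bank$filters, function(f) {
    if (!is.null(f$h)) {
      as.numeric(signal::filtfilt(signal::Ma(f$h), s))
    } else {
      as.numeric(signal::filtfilt(f, s))
    }
  }, numeric(length(s))))
  as_signal(out, fs = x$fs,
            channel_labels = sprintf("%.4g Hz", bank$centers))
}

#' Decompose a possibly multichannel signal through a filter bank
#'
#' Applies [apply_filterbank()] to every input channel and stacks the
#' results, so a 3-axis inertial signal through an `n`-channel bank yields
#' `3 * n` rows (grouped by input channel).
#'
#' @inheritParams apply_filterbank
#' @return A [as_signal()] with `n_channels(x) * length(bank$centers)` rows.
#' @export
decompose_signal <- function(x, bank) {
  stopifnot(is_signal(x))
  parts <- lapply(seq_len(n_channels(x)), function(ch) {
    apply_filterbank(as_signal(x$samples[ch, , drop = FALSE], x$fs), bank)$samples
  })
  as_signal(do.call(rbind, parts), fs = x$fs)
}
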