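#' Spike train container
#'
#' Sparse event-list representation of an encoded signal: each event has a
#' time in seconds within `[0, duration]`, an integer channel index and a
#' polarity of +1 or -1. Events are kept sorted by time, with ties broken by
#' channel index. `dt` is the nominal raster step of the encoding
#' (`duration / L` for sample-locked encoders, a sub-step for phase- and
#' latency-based ones); it drives rasterization in the metrics module.
#'
#' @param times Numeric vector of event times in seconds.
#' @param channels Integer vector of 1-based channel indices.
#' @param polarities Integer vector of +1 / -1 (unipolar encoders use +1).
#' @param n_channels Total number of channels in the source signal.
#' @param duration Encoding interval in seconds.
#' @param dt Raster step in seconds.
#' @param meta List of provenance fields (encoder name, parameters).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, channels, polarities, n_channels, duration, dt,
                        meta = list()) {
  stopifnot(length(times) == length(channels), length(times) == length(polarities))
  if (length(times) > 0L) {
    if (any(!is.finite(times)) || any(times < 0) || any(times > duration + 1e-12)) {
      stop("event times must be finite and within [0, duration]")
    }
    if (!all(polarities %in% c(-1L, 1L))) stop("polarities must be -1 or +1")
    if (any(channels < 1L) || any(channels > n_channels)) {
      stop("channel indices out of range")
    }
    ord <- order(times, channels)
    times <- times[ord]; channels <- channels[ord]; polarities <- polarities[ord]
  }
  structure(
    list(times = as.numeric(times), channels = as.integer(channels),
         polarities = as.integer(polarities), n_channels = as.integer(n_channels),
         duration = as.numeric(duration), dt = as.numeric(dt), meta = meta),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d events, %d channel(s), duration %.4g s, dt %.4g s (%s)\n",
              n_events(x), x$n_channels, x$duration, x$dt,
              if (is.null(x$meta$encoder)) "?" else x$meta$encoder))
  invisible(x)
}

#' Number of events in a spike train
#' @param x A [spike_train()].
#' @return Integer event count.
#' @export
n_events <- function(x) length(x$times)

#' Enforce a refractory period on a spike train
#'
#' Scans each channel in time order and drops any event closer than
#' `tau_ref` seconds to the previously retained event on that channel.
#' With `tau_ref = 0` the train is returned unchanged.
#'
#' @param x A [spike_train()].
#' @param tau_ref Minimum allowed inter-spike interval in seconds (>= 0).
#' @return A [spike_train()] respecting the refractory constraint.
#' @export
apply_refractory <- function(x, tau_ref) {
  stopifnot(inherits(x, "spike_train"), tau_ref >= 0)
  if (tau_ref == 0 || n_events(x) == 0L) return(x)
  keep <- logical(n_events(x))
  last <- rep(-Inf, x$n_channels)
  for (k in seq_len(n_events(x))) {
    ch <- x$channels[k]
    if (x$times[k] - last[ch] >= tau_ref) {
      keep[k] <- TRUE
      last[ch] <- x$times[k]
    }
  }
  meta <- x$meta
  meta$tau_ref <- tau_ref
  spike_train(x$times[keep], x$channels[keep], x$polarities[keep],
              x$n_channels, x$duration, x$dt, meta)
}

# bin index on the raster grid: half-open [k*dt, (k+1)*dt), final boundary closed
raster_bin <- function(times, dt, n_steps) {
  pmin(floor(times / dt), n_steps - 1L) + 1L
}

#' Rasterize a spike train onto its dt grid
#'
#' @param x A [spike_train()].
#' @param mode `"sign"` for a ternary {-1, 0, +1} symbol raster (sign of the
#'   net polarity per step), or `"count"` for absolute event counts.
#' @return Integer matrix `n_channels x n_steps` with
#'   `n_steps = round(duration / dt)`.
#' @export
rasterize <- function(x, mode = c("sign", "count")) {
  mode <- match.arg(mode)
  n_steps <- max(1L, round(x$duration / x$dt))
  m <- matrix(0L, nrow = x$n_channels, ncol = n_steps)
  if (n_events(x) > 0L) {
    bins <- raster_bin(x$times, x$dt, n_steps)
    vals <- if (mode == "sign") x$polarities else rep(1L, n_events(x))
    for (k in seq_along(bins)) {
      m[x$channels[k], bins[k]] <- m[x$channels[k], bins[k]] + vals[k]
    }
    if (mode == "sign") m <- sign(m)
  }
  m
}

#' Write a spike train to CSV
#'
#' Plain-text interchange format: comment lines carry the container fields
#' (`n_channels`, `duration`, `dt`, encoder name), followed by
#' `time_s,channel,polarity` rows sorted by time. Times are printed with 17
#' significant digits so a read/write round trip is bit exact.
#'
#' @param x A [spike_train()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spiketrain_csv <- function(x, path) {
  stopifnot(inherits(x, "spike_train"))
  hdr <- c(
    sprintf("# n_channels=%d", x$n_channels),
    sprintf("# duration=%.17g", x$duration),
    sprintf("# dt=%.17g", x$dt),
    sprintf("# encoder=%s", if (is.null(x$meta$encoder)) "unknown" else x$meta$encoder),
    "time_s,channel,polarity"
  )
  rows <- sprintf("%.17g,%d,%d", x$times, x$channels, x$polarities)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a spike train written by [write_spiketrain_csv()]
#' @param path Path to the CSV file.
#' @return A [spike_train()].
#' @export
read_spiketrain_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read spike train CSV: ", path)
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, "="), "", grep(paste0("^# ", key, "="), hdr, value = TRUE))
  body <- lines[!grepl("^# ", lines)][-1L]
  if (length(body) > 0L) {
    parts <- strsplit(body, ",", fixed = TRUE)
    times <- vapply(parts, function(p) as.numeric(p[1L]), numeric(1L))
    channels <- vapply(parts, function(p) as.integer(p[2L]), integer(1L))
    polarities <- vapply(parts, function(p) as.integer(p[3L]), integer(1L))
  } else {
    times <- numeric(0); channels <- integer(0); polarities <- integer(0)
  }
  spike_train(times, channels, polarities,
              n_channels = as.integer(get("n_channels")),
              duration = as.numeric(get("duration")),
              dt = as.numeric(get("dt")),
              meta = list(encoder = get("encoder")))
}
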