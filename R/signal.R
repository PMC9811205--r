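#' Multichannel time-varying signal
#'
#' Container for a real-valued, uniformly sampled signal. Samples are stored
#' as a `channels x L` matrix so that a mono audio recording is a 1-row
#' matrix and a tri-axial accelerometer trace is a 3-row matrix.
#'
#' @param samples Numeric vector (one channel) or `channels x L` matrix of
#'   amplitudes, arbitrary units. All values must be finite and `L >= 2`.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Optional character vector of channel names.
#' @return An object of class `signal_ts` with fields `samples`, `fs`,
#'   `duration` (seconds, exactly `L / fs`) and `channel_labels`.
#' @examples
#' s <- as_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 100)), fs = 100)
#' n_samples(s)
#' @export
as_signal <- function(samples, fs, channel_labels = NULL) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1L)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric vector or matrix [channels x L]")
  }
  if (ncol(samples) < 2L) stop("signal must contain at least 2 samples (L >= 2)")
  if (!all(is.finite(samples))) stop("signal contains non-finite sample values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be a single positive number")
  if (!is.null(channel_labels) && length(channel_labels) != nrow(samples)) {
    stop("`channel_labels` length must equal the number of channels")
  }
  structure(
    list(
      samples = unname(samples),
      fs = as.numeric(fs),
      duration = ncol(samples) / as.numeric(fs),
      channel_labels = channel_labels
    ),
    class = "signal_ts"
  )
}

#' @export
print.signal_ts <- function(x, ...) {
  cat(sprintf(
    "<signal_ts> %d channel(s) x %d samples @ %g Hz (%.4g s)\n",
    n_channels(x), n_samples(x), x$fs, x$duration
  ))
  invisible(x)
}

#' Number of samples per channel
#' @param x A `signal_ts`.
#' @return Integer sample count `L`.
#' @export
n_samples <- function(x) ncol(x$samples)

#' Number of channels
#' @param x A `signal_ts` or `spike_train`.
#' @return Integer channel count.
#' @export
n_channels <- function(x) {
  if (inherits(x, "spike_train")) return(x$n_channels)
  nrow(x$samples)
}

is_signal <- function(x) inherits(x, "signal_ts")

#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the uncompressed mono PCM files used by
#' spoken-digit style corpora. Amplitudes are rescaled to `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @return A [as_signal()] object with `fs` taken from the file header.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("cannot read WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; n_chan <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2L, size = 2L, endian = "little", signed = FALSE)
      n_chan <- fmt[2L]
      fs <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      invisible(readBin(con, "integer", 1L, size = 4L, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1L, size = 2L, endian = "little")) # block align
      bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (size > 16L) invisible(readBin(con, "raw", size - 16L))
      if (fmt[1L] != 1L) stop("only uncompressed PCM WAV is supported: ", path)
    } else if (identical(id, "data")) {
      data <- readBin(con, "integer", size / 2L, size = 2L, endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(fs) || is.null(data)) stop("malformed WAV file (missing fmt/data chunk): ", path)
  if (n_chan != 1L) stop("non-mono WAV not supported (", n_chan, " channels): ", path)
  if (bits != 16L) stop("only 16-bit PCM WAV is supported: ", path)
  as_signal(data / 32768, fs = fs)
}

#' Write a mono signal as a 16-bit PCM WAV file
#'
#' Amplitudes are clipped to `[-1, 1]` and quantized to 16 bits, so a
#' write/read round trip preserves samples up to PCM quantization.
#'
#' @param x A single-channel [as_signal()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(is_signal(x))
  if (n_channels(x) != 1L) stop("write_wav() requires a single-channel signal")
  pcm <- as.integer(pmin(pmax(round(x$samples[1L, ] * 32767), -32768), 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16L), con, size = 4L, endian = "little")
  writeBin(as.integer(c(1L, 1L)), con, size = 2L, endian = "little")      # PCM, mono
  writeBin(as.integer(x$fs), con, size = 4L, endian = "little")
  writeBin(as.integer(x$fs * 2L), con, size = 4L, endian = "little")      # byte rate
  writeBin(as.integer(2L), con, size = 2L, endian = "little")             # block align
  writeBin(as.integer(16L), con, size = 2L, endian = "little")            # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a WISDM-style inertial CSV recording
#'
#' Expects rows `subject,activity,timestamp,x,y,z` (header optional). The
#' acquisition rate of such wearable recordings is fixed (20 Hz by default);
#' timestamps are not used for resampling.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz attributed to the rows (default 20).
#' @return A list with `signal` (3-channel [as_signal()], channels x/y/z) and
#'   `label` (the activity value of the first row).
#' @export
read_imu_csv <- function(path, fs = 20) {
  if (!file.exists(path)) stop("cannot read IMU CSV file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("x", "y", "z")
  if (!all(required %in% names(df))) {
    # headerless WISDM-style rows
    df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 6L) {
      missing <- setdiff(required, names(df))
      stop("IMU CSV is missing coordinate column(s): ", paste(missing, collapse = ", "))
    }
    names(df)[1:6] <- c("subject", "activity", "timestamp", "x", "y", "z")
  }
  missing <- required[!vapply(required, function(cc) is.numeric(df[[cc]]), logical(1L))]
  if (length(missing) > 0L) {
    stop("IMU CSV is missing coordinate column(s): ", paste(missing, collapse = ", "))
  }
  sig <- as_signal(t(as.matrix(df[, required])), fs = fs, channel_labels = required)
  label <- if ("activity" %in% names(df)) df$activity[1L] else NA_character_
  list(signal = sig, label = label)
}
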