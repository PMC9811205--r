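#' Synthetic labelled signal corpora
#'
#' Generators for two regimes of time-varying signals so that the whole
#' pipeline is exercisable without external downloads: a mid-frequency
#' audio-like corpus (mono, 8 kHz, class-specific multi-tone templates
#' with spectral content between 500 and 2000 Hz, silence-padded like
#' trimmed spoken-digit recordings) and a very-low-frequency tri-axial
#' inertial corpus (20 Hz, classes differing in periodicity: gait-like
#' oscillation, near-static posture, impulsive bursts, with a gravity
#' offset on the third axis). Class difficulty is controlled by the
#' template frequency spacing and the noise level; regeneration with the
#' same seed is bit-identical.
#'
#' @name synthetic-data
NULL

new_corpus <- function(signals, labels, class_spec, split, seed, kind) {
  structure(
    list(signals = signals, labels = labels, class_spec = class_spec,
         split = split, seed = seed, kind = kind),
    class = "synthetic_corpus"
  )
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %s: %d signals, %d classes (seed %d)\n",
              x$kind, length(x$signals), length(unique(x$labels)), x$seed))
  invisible(x)
}

# balanced stratified train/test split
stratified_split <- function(labels, train_frac) {
  split <- character(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    n_train <- round(length(idx) * train_frac)
    split[idx[seq_len(n_train)]] <- "train"
    split[idx[-seq_len(n_train)]] <- "test"
  }
  split
}

#' Generate an audio-like synthetic corpus
#'
#' Each class is a fixed multi-tone template: two sinusoidal components
#' with geometrically spaced fundamentals inside `[500, 2000]` Hz, a
#' raised-cosine onset/offset envelope and silence pads at both ends.
#' Individual samples add uniform random phase, +/- 10 percent amplitude
#' jitter and white Gaussian noise of standard deviation `noise_sd`.
#'
#' @param n_classes Number of classes (default 3).
#' @param n_per_class Samples per class (default 20).
#' @param fs Sampling rate in Hz (default 8000).
#' @param duration Signal duration in seconds, including pads
#'   (default 0.25).
#' @param noise_sd Additive noise standard deviation relative to unit
#'   tone amplitude (default 0.05).
#' @param train_frac Fraction of each class assigned to the training
#'   split (default 0.75).
#' @param seed RNG seed.
#' @return A `synthetic_corpus`: `signals` (list of mono [as_signal()]),
#'   `labels` (integers `1..n_classes`), `class_spec`, `split`, `seed`.
#' @export
gen_audio_like <- function(n_classes = 3L, n_per_class = 20L, fs = 8000,
                           duration = 0.25, noise_sd = 0.05,
                           train_frac = 0.75, seed = 1L) {
  stopifnot(n_classes >= 2L, n_per_class >= 2L)
  set.seed(seed)
  L <- round(fs * duration)
  t <- (seq_len(L) - 1L) / fs
  f_lo <- 500; f_hi <- 2000
  # geometric spacing keeps class fundamentals in distinct cochlear bands
  fundamentals <- f_lo * (f_hi / f_lo)^((seq_len(n_classes) - 0.5) / n_classes)
  class_spec <- lapply(seq_len(n_classes), function(k) {
    list(f1 = fundamentals[k], f2 = min(1.31 * fundamentals[k], f_hi),
         amp = c(1, 0.6), noise_sd = noise_sd)
  })
  pad <- round(0.1 * L)
  env <- rep(0, L)
  core <- L - 2L * pad
  env[(pad + 1L):(L - pad)] <- 0.5 * (1 - cos(2 * pi * seq_len(core) / core))
  signals <- list(); labels <- integer(0)
  for (k in seq_len(n_classes)) {
    cs <- class_spec[[k]]
    for (i in seq_len(n_per_class)) {
      ph <- stats::runif(2L, 0, 2 * pi)
      amp <- cs$amp * (1 + stats::runif(2L, -0.1, 0.1))
      s <- amp[1L] * sin(2 * pi * cs$f1 * t + ph[1L]) +
        amp[2L] * sin(2 * pi * cs$f2 * t + ph[2L])
      s <- s * env + stats::rnorm(L, sd = noise_sd)
      signals <- c(signals, list(as_signal(s, fs = fs)))
      labels <- c(labels, k)
    }
  }
  new_corpus(signals, labels, class_spec,
             stratified_split(labels, train_frac), seed, "audio_like")
}

#' Generate an inertial-like synthetic corpus
#'
#' Three-channel (x, y, z) signals at a wearable-sensor rate. Classes
#' cycle through three motion archetypes: gait-like oscillation (a 1-3 Hz
#' fundamental with a weaker harmonic on x and y), near-static posture
#' (constant axes) and impulsive bursts (sparse random transients). All
#' classes carry a constant gravity offset of 1 on the z axis plus white
#' Gaussian noise.
#'
#' @param n_classes Number of classes (default 3).
#' @param n_per_class Samples per class (default 20).
#' @param fs Sampling rate in Hz (default 20).
#' @param duration Signal duration in seconds (default 10).
#' @param noise_sd Additive noise standard deviation (default 0.1).
#' @param train_frac Training fraction per class (default 0.75).
#' @param seed RNG seed.
#' @return A `synthetic_corpus` of 3-channel [as_signal()] objects.
#' @export
gen_imu_like <- function(n_classes = 3L, n_per_class = 20L, fs = 20,
                         duration = 10, noise_sd = 0.1,
                         train_frac = 0.75, seed = 1L) {
  stopifnot(n_classes >= 2L, n_per_class >= 2L)
  set.seed(seed)
  L <- round(fs * duration)
  t <- (seq_len(L) - 1L) / fs
  archetypes <- c("gait", "static", "burst")
  class_spec <- lapply(seq_len(n_classes), function(k) {
    arch <- archetypes[(k - 1L) %% 3L + 1L]
    list(archetype = arch,
         f0 = 1 + 2 * (k - 1L) / max(1L, n_classes - 1L),  # 1..3 Hz
         noise_sd = noise_sd)
  })
  signals <- list(); labels <- integer(0)
  for (k in seq_len(n_classes)) {
    cs <- class_spec[[k]]
    for (i in seq_len(n_per_class)) {
      base <- switch(cs$archetype,
        gait = {
          ph <- stats::runif(2L, 0, 2 * pi)
          rbind(sin(2 * pi * cs$f0 * t + ph[1L]) + 0.3 * sin(2 * pi * 2 * cs$f0 * t + ph[2L]),
                0.8 * sin(2 * pi * cs$f0 * t + ph[1L] + pi / 3),
                rep(0, L))
        },
        static = matrix(0, nrow = 3L, ncol = L),
        burst = {
          s <- matrix(0, nrow = 3L, ncol = L)
          n_bursts <- max(2L, round(duration / 2))
          at <- sample.int(L - 4L, n_bursts)
          for (b in at) {
            s[1:2, b:(b + 3L)] <- s[1:2, b:(b + 3L)] +
              outer(stats::runif(2L, 1.5, 2.5), c(1, -0.6, 0.3, -0.1))
          }
          s
        }
      )
      base[3L, ] <- base[3L, ] + 1  # gravity offset on z
      s <- base + matrix(stats::rnorm(3L * L, sd = noise_sd), nrow = 3L)
      if (noise_sd == 0 && cs$archetype == "static") {
        s <- base  # exactly constant channels in the noiseless static class
      }
      signals <- c(signals, list(as_signal(s, fs = fs, channel_labels = c("x", "y", "z"))))
      labels <- c(labels, k)
    }
  }
  new_corpus(signals, labels, class_spec,
             stratified_split(labels, train_frac), seed, "imu_like")
}

#' Export a corpus to disk in its native interchange format
#'
#' Audio-like corpora are written as one 16-bit PCM WAV per sample plus a
#' `labels.csv` (`file,label,split`); inertial corpora as one WISDM-style
#' CSV per sample (`subject,activity,timestamp,x,y,z`) plus the same
#' labels file. Files are loadable with [read_wav()] / [read_imu_csv()].
#'
#' @param corpus A [gen_audio_like()] or [gen_imu_like()] corpus.
#' @param dir Output directory (created if missing).
#' @return The labels CSV path, invisibly.
#' @export
export_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(corpus$signals)
  files <- character(n)
  for (i in seq_len(n)) {
    if (corpus$kind == "audio_like") {
      files[i] <- sprintf("sample_%03d.wav", i)
      x <- corpus$signals[[i]]
      peak <- max(abs(x$samples))
      if (peak > 1) x <- as_signal(x$samples / peak, x$fs)
      write_wav(x, file.path(dir, files[i]))
    } else {
      files[i] <- sprintf("sample_%03d.csv", i)
      x <- corpus$signals[[i]]
      df <- data.frame(
        subject = 1L, activity = corpus$labels[i],
        timestamp = round((seq_len(n_samples(x)) - 1L) / x$fs * 1e9),
        x = x$samples[1L, ], y = x$samples[2L, ], z = x$samples[3L, ]
      )
      utils::write.csv(df, file.path(dir, files[i]), row.names = FALSE)
    }
  }
  labels_path <- file.path(dir, "labels.csv")
  utils::write.csv(
    data.frame(file = files, label = corpus$labels, split = corpus$split),
    labels_path, row.names = FALSE
  )
  invisible(labels_path)
}
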