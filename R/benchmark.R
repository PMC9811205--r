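#' Benchmark grid orchestration
#'
#' Runs the full pipeline -- filter bank, spike encoding, sonogram
#' extraction, CNN training, transfer to the spiking twin, simulation,
#' and optional compression -- over a grid of encoder, filter, bin and
#' architecture configurations, producing one result row per grid cell.
#' Completed cells are cached on disk by a configuration fingerprint so
#' interrupted runs resume without recomputation; one global seed fans
#' out deterministically into per-cell child seeds.
#'
#' @name benchmark
NULL

# deterministic child seed, kept below 2^31
child_seed <- function(seed, i) as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647L)

#' Assemble a benchmark configuration
#'
#' @param dataset List describing the corpus: `kind` (`"audio_like"` or
#'   `"imu_like"`) plus arguments of the matching generator.
#' @param filters List of filter cells, each `list(kind, n_channels)`;
#'   band limits default to 100-3800 Hz for audio-like and 0.1-9.5 Hz for
#'   inertial-like signals (Nyquist-bounded for their standard rates).
#' @param encoders Named list mapping encoder names to parameter lists.
#' @param bins Integer vector of sonogram bin counts.
#' @param architectures List of `c(I, J, K)` triples.
#' @param lif [lif_params()] for the spiking twin.
#' @param train List of training settings (`epochs`, `lr`, `batch_size`).
#' @param compression_q Optional numeric vector of pruning quantiles.
#' @param finetune_epochs Fine-tuning epochs after pruning (default 5).
#' @param seed Global seed.
#' @param out_dir Output/cache directory.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(dataset, filters, encoders, bins, architectures,
                             lif = lif_params(), train = list(),
                             compression_q = NULL, finetune_epochs = 5L,
                             seed = 1L, out_dir = tempfile("spikebench_")) {
  stopifnot(length(filters) > 0L, length(encoders) > 0L,
            length(bins) > 0L, length(architectures) > 0L)
  train_defaults <- list(epochs = 30L, lr = 0.05, batch_size = 8L)
  train <- utils::modifyList(train_defaults, train)
  structure(
    list(dataset = dataset, filters = filters, encoders = encoders,
         bins = bins, architectures = architectures, lif = lif,
         train = train, compression_q = compression_q,
         finetune_epochs = finetune_epochs, seed = seed, out_dir = out_dir),
    class = "benchmark_config"
  )
}

#' Read / write a benchmark configuration as YAML
#' @param path YAML file path.
#' @return For `read_benchmark_config`, a `benchmark_config`.
#' @export
read_benchmark_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lif <- do.call(lif_params, if (is.null(cfg$lif)) list() else cfg$lif)
  benchmark_config(
    dataset = cfg$dataset, filters = cfg$filters, encoders = cfg$encoders,
    bins = unlist(cfg$bins), architectures = cfg$architectures, lif = lif,
    train = if (is.null(cfg$train)) list() else cfg$train,
    compression_q = unlist(cfg$compression_q),
    finetune_epochs = if (is.null(cfg$finetune_epochs)) 5L else cfg$finetune_epochs,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed,
    out_dir = if (is.null(cfg$out_dir)) tempfile("spikebench_") else cfg$out_dir
  )
}

#' @rdname read_benchmark_config
#' @param config A `benchmark_config`.
#' @return For `write_benchmark_config`, `path` invisibly.
#' @export
write_benchmark_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$lif <- unclass(cfg$lif)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

default_band <- function(kind) {
  if (kind == "audio_like") c(100, 3800) else c(0.1, 9.5)
}

make_corpus <- function(dataset, seed) {
  args <- dataset[setdiff(names(dataset), "kind")]
  args$seed <- if (is.null(args$seed)) seed else args$seed
  gen <- switch(dataset$kind,
                audio_like = gen_audio_like,
                imu_like = gen_imu_like,
                stop("unknown dataset kind: ", dataset$kind))
  do.call(gen, args)
}

#' Encode a corpus into sonograms through a filter bank
#'
#' Decomposes every signal through the bank, encodes each decomposition
#' with the named algorithm and bins the events into sonograms.
#'
#' @param corpus A synthetic corpus (or compatible list with `signals`,
#'   `labels`, `split`).
#' @param bank A [design_filterbank()] bank.
#' @param encoder Encoder name.
#' @param encoder_params Parameter list for the encoder.
#' @param n_bins Sonogram bins.
#' @return List with `sonograms`, `images` (normalized inputs), `labels`,
#'   `split` and `trains` (the spike trains).
#' @export
corpus_sonograms <- function(corpus, bank, encoder, encoder_params = list(),
                             n_bins = 20L) {
  trains <- lapply(corpus$signals, function(sig) {
    dec <- decompose_signal(sig, bank)
    encode(dec, encoder, encoder_params)
  })
  sonos <- lapply(trains, time_bin, n_bins = n_bins)
  list(sonograms = sonos,
       images = lapply(sonos, sonogram_input),
       labels = corpus$labels, split = corpus$split, trains = trains)
}

cell_fingerprint <- function(parts) {
  s <- paste(unlist(parts), collapse = "_")
  gsub("[^A-Za-z0-9._-]", "-", s)
}

run_cell <- function(corpus, filt, enc_name, enc_params, n_bins, arch, cfg, seed) {
  band <- default_band(corpus$kind)
  fs <- corpus$signals[[1L]]$fs
  spec <- filterbank_spec(filt$kind, filt$n_channels, band[1L], band[2L], fs)
  bank <- design_filterbank(spec)
  feats <- corpus_sonograms(corpus, bank, enc_name, enc_params, n_bins)
  tr <- which(feats$split == "train"); te <- which(feats$split == "test")
  img_rows <- nrow(feats$images[[1L]])
  nspec <- network_spec(arch[1L], arch[2L], arch[3L],
                        input_shape = c(img_rows, n_bins),
                        n_classes = length(unique(feats$labels)))
  net <- build_cnn(nspec, seed = seed)
  net <- train_cnn(net, feats$images[tr], feats$labels[tr],
                   epochs = cfg$train$epochs, lr = cfg$train$lr,
                   batch_size = cfg$train$batch_size, seed = seed)
  cnn_pred <- predict_cnn(net, feats$images[te])
  cnn_acc <- mean(cnn_pred == feats$labels[te])
  snn <- transfer_weights(net, cfg$lif)
  snn <- threshold_balance(snn, feats$images[tr])
  snn_pred <- vapply(seq_along(te), function(i) {
    classify_snn(snn, feats$sonograms[[te[i]]], seed = child_seed(seed, i))
  }, integer(1L))
  snn_acc <- mean(snn_pred == feats$labels[te])
  agreement <- mean(snn_pred == cnn_pred)
  med_spikes <- stats::median(vapply(feats$trains, n_events, numeric(1L)))
  met <- metrics_record(feats$trains[[te[1L]]],
                        decompose_signal(corpus$signals[[te[1L]]], bank))
  row <- data.frame(
    encoder = enc_name, encoder_class = unname(encoder_classes()[enc_name]),
    filter = filt$kind, n_channels = filt$n_channels, bins = n_bins,
    architecture = network_name(nspec),
    cnn_accuracy = cnn_acc, snn_accuracy = snn_acc, agreement = agreement,
    median_spike_count = med_spikes,
    S = met$S, MIS = met$MIS, HS = met$HS, epsilon = met$epsilon,
    density = met$density, stringsAsFactors = FALSE
  )
  if (!is.null(cfg$compression_q)) {
    for (q in cfg$compression_q) {
      pr <- prune_by_quantile(net, q)
      acc_pruned <- mean(predict_cnn(pr$net, feats$images[te]) == feats$labels[te])
      ft <- fine_tune(pr$net, pr$mask, feats$images[tr], feats$labels[tr],
                      epochs = cfg$finetune_epochs, lr = cfg$train$lr,
                      batch_size = cfg$train$batch_size, seed = seed)
      acc_ft <- mean(predict_cnn(ft, feats$images[te]) == feats$labels[te])
      tag <- sprintf("q%02.0f", q * 100)
      row[[paste0("retained_", tag)]] <- pr$retained_fraction
      row[[paste0("acc_pruned_", tag)]] <- acc_pruned
      row[[paste0("acc_finetuned_", tag)]] <- acc_ft
    }
  }
  row
}

#' Run the benchmark grid
#'
#' @param config A [benchmark_config()].
#' @param verbose Print a line per cell.
#' @return Data frame with one row per grid cell (accuracies, agreement,
#'   spike counts and characterization metrics; compression columns when
#'   `compression_q` is set). Failed cells are logged and skipped; the
#'   returned table carries them in `attr(, "failures")`.
#' @export
run_benchmark <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  dir.create(file.path(config$out_dir, "cells"), showWarnings = FALSE, recursive = TRUE)
  corpus <- make_corpus(config$dataset, config$seed)
  grid <- expand.grid(
    f = seq_along(config$filters), e = seq_along(config$encoders),
    b = seq_along(config$bins), a = seq_along(config$architectures)
  )
  rows <- list(); failures <- character(0)
  for (g in seq_len(nrow(grid))) {
    filt <- config$filters[[grid$f[g]]]
    enc_name <- names(config$encoders)[grid$e[g]]
    enc_params <- config$encoders[[grid$e[g]]]
    if (is.null(enc_params)) enc_params <- list()
    n_bins <- config$bins[grid$b[g]]
    arch <- unlist(config$architectures[[grid$a[g]]])
    fp <- cell_fingerprint(list(config$dataset$kind, filt$kind, filt$n_channels,
                                enc_name, n_bins, paste(arch, collapse = "-"),
                                config$seed))
    cache <- file.path(config$out_dir, "cells", paste0(fp, ".rds"))
    if (file.exists(cache)) {
      rows[[g]] <- readRDS(cache)
      next
    }
    res <- tryCatch(
      run_cell(corpus, filt, enc_name, enc_params, n_bins, arch, config,
               seed = child_seed(config$seed, g)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("[%s] %s", fp, conditionMessage(res)))
      next
    }
    saveRDS(res, cache)
    rows[[g]] <- res
    if (verbose) {
      message(sprintf("cell %d/%d %s: cnn %.2f snn %.2f", g, nrow(grid), fp,
                      res$cnn_accuracy, res$snn_accuracy))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  if (length(failures) > 0L) {
    warning("benchmark cells failed:\n", paste(failures, collapse = "\n"))
  }
  attr(out, "failures") <- failures
  out
}

#' Aggregate benchmark results
#'
#' Median SNN accuracy grouped by encoder class, by filter type and by
#' bin count -- the summary views of the benchmark.
#'
#' @param results A [run_benchmark()] table.
#' @return List of data frames `by_encoder_class`, `by_filter`, `by_bins`.
#' @export
report_benchmark <- function(results) {
  med_by <- function(key) {
    agg <- stats::aggregate(results$snn_accuracy, by = list(results[[key]]), FUN = stats::median)
    names(agg) <- c(key, "median_snn_accuracy")
    agg
  }
  list(by_encoder_class = med_by("encoder_class"),
       by_filter = med_by("filter"),
       by_bins = med_by("bins"))
}
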