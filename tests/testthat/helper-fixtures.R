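# Shared pipeline fixtures, built once per test run and memoized: the
# default 3-class audio-like corpus pushed through the gammatone bank, a
# temporal-contrast encoder and the C6-C12-F2 network.

.fixture_env <- new.env(parent = emptyenv())

pipeline_fixture <- function(seed = 42L) {
  key <- paste0("pipe_", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  corpus <- gen_audio_like(seed = seed)
  bank <- design_filterbank(filterbank_spec("gammatone", 16, 100, 3800, 8000))
  feats <- corpus_sonograms(corpus, bank, "tbr", list(gamma = 1), n_bins = 20)
  tr <- which(feats$split == "train")
  te <- which(feats$split == "test")
  net <- build_cnn(network_spec(6, 12, 2, input_shape = c(16, 20), n_classes = 3),
                   seed = seed)
  net <- train_cnn(net, feats$images[tr], feats$labels[tr],
                   epochs = 30L, lr = 0.05, batch_size = 8L, seed = seed)
  cnn_pred <- predict_cnn(net, feats$images[te])
  fx <- list(corpus = corpus, bank = bank, feats = feats, tr = tr, te = te,
             net = net, cnn_pred = cnn_pred,
             cnn_acc = mean(cnn_pred == feats$labels[te]))
  .fixture_env[[key]] <- fx
  fx
}
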