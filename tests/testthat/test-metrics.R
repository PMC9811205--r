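mk_train <- function(times, channels, pols, n_ch, duration, dt) {
  spike_train(times, channels, pols, n_ch, duration, dt, meta = list(encoder = "tbr"))
}

test_that("entropy matches closed forms on hand-built rasters", {
  # silent train: single symbol
  silent <- mk_train(numeric(0), integer(0), integer(0), 1, 1, 0.1)
  expect_equal(shannon_entropy(silent), 0)
  # half 0 / half +1: fair binary
  st <- mk_train((0:4) * 0.2 + 0.05, rep(1, 5), rep(1, 5), 1, 2, 0.2)
  expect_equal(shannon_entropy(st), 1.0)
  # quarter -1 / half 0 / quarter +1 over 8 steps
  st3 <- mk_train(c(0.05, 1.05, 2.05, 3.05), c(1, 1, 1, 1),
                  c(1, 1, -1, -1), 1, 8, 1)
  expect_equal(shannon_entropy(st3), 1.5)
  # closed form on an arbitrary distribution
  p <- c(0.2, 0.5, 0.3)
  expect_equal(-sum(p * log2(p)), 1.4854752972273344, tolerance = 1e-12)
})

test_that("normalized mutual information hits its boundary cases", {
  # silent train: 0 by convention
  silent <- mk_train(numeric(0), integer(0), integer(0), 1, 1, 0.125)
  src <- as_signal(c(0, 1, 0, 1, 1, 0, 0, 1), fs = 8)
  expect_equal(normalized_mutual_information(silent, src), 0)
  # raster identical to the binarized source: MIS = 1
  on <- which(src$samples[1, ] == 1)
  st <- mk_train((on - 1) / 8, rep(1, length(on)), rep(1, length(on)), 1, 1, 1 / 8)
  expect_equal(normalized_mutual_information(st, src), 1)
  # independent pairing on a long raster: MIS near 0
  set.seed(9)
  n <- 10000
  src2 <- as_signal(rnorm(n), fs = n)
  times <- (which(runif(n) < 0.3) - 1) / n
  st2 <- mk_train(times, rep(1, length(times)), rep(1, length(times)), 1, 1, 1 / n)
  expect_lt(normalized_mutual_information(st2, src2), 0.05)
  # always within [0, 1]
  expect_lte(normalized_mutual_information(st, src), 1)
})

test_that("Hoyer sparsity: one-hot 1, uniform 0, counts 1:3 match closed form", {
  one_hot <- mk_train(0.55, 1, 1, 1, 1, 0.1)
  expect_equal(hoyer_sparsity(one_hot), 1)
  uniform <- mk_train((0:9) * 0.1 + 0.05, rep(1, 10), rep(1, 10), 1, 1, 0.1)
  expect_equal(hoyer_sparsity(uniform), 0)
  # counts (1, 2, 3): (sqrt(3) - 6/sqrt(14)) / (sqrt(3) - 1)
  times <- c(0.1, 1.1, 1.2, 2.1, 2.2, 2.3)
  c123 <- mk_train(times, rep(1, 6), rep(1, 6), 1, 3, 1)
  expect_equal(hoyer_sparsity(c123), (sqrt(3) - 6 / sqrt(14)) / (sqrt(3) - 1),
               tolerance = 1e-12)
  expect_equal(hoyer_sparsity(c123), 0.1755, tolerance = 1e-3)
  # all-zero channel contributes 1 by convention
  empty <- mk_train(numeric(0), integer(0), integer(0), 2, 1, 0.25)
  expect_equal(hoyer_sparsity(empty), 1)
})

test_that("spiking efficiency is one minus raster occupancy", {
  silent <- mk_train(numeric(0), integer(0), integer(0), 2, 1, 0.1)
  expect_equal(spiking_efficiency(silent), 1)
  full <- mk_train(rep((0:9) * 0.1 + 0.01, 2), rep(1:2, each = 10),
                   rep(1, 20), 2, 1, 0.1)
  expect_equal(spiking_efficiency(full), 0)
  # 50 spikes over 1000 slots in one channel
  st <- mk_train((seq_len(50) - 1) * 0.02 + 0.001, rep(1, 50), rep(1, 50),
                 1, 1, 0.001)
  expect_equal(spiking_efficiency(st), 0.95)
})

test_that("spike density counts events per second, total and per channel", {
  empty <- mk_train(numeric(0), integer(0), integer(0), 1, 1, 0.1)
  expect_equal(spike_density(empty)$total, 0)
  st <- mk_train(runif(80, 0, 2), sample(1:2, 80, TRUE), rep(1, 80), 2, 2, 0.01)
  d <- spike_density(st)
  expect_equal(d$total, 40)
  expect_equal(sum(d$per_channel), 40)
  # Poisson train at 100 Hz: density within 3 sigma of 100
  po <- encode_poisson(as_signal(rep(0, 10), fs = 10), rate = 100, seed = 21)
  expect_lt(abs(spike_density(po)$total - 100), 3 * sqrt(100))
})

test_that("complexity labels follow the per-family cost structure", {
  expect_equal(complexity_label("tbr"), "O(l*c)")
  expect_equal(complexity_label("HSA"), "O(l*c*w)")
  expect_equal(complexity_label("phase"), "O(l*c*n)")
  expect_error(complexity_label("nope"), "valid names")
})

test_that("S and MIS are channel-permutation invariant, HS time-permutation invariant", {
  set.seed(31)
  sig <- random_signal(32, 3)
  st <- encode_tbr(sig, gamma = 0.5)
  perm <- c(2, 3, 1)
  sig_p <- as_signal(sig$samples[perm, ], sig$fs)
  st_p <- encode_tbr(sig_p, gamma = 0.5)
  expect_equal(shannon_entropy(st_p), shannon_entropy(st))
  expect_equal(normalized_mutual_information(st_p, sig_p),
               normalized_mutual_information(st, sig))
  # HS from permuted count bins is unchanged
  counts <- rasterize(st, "count")
  n <- ncol(counts)
  set.seed(32)
  tp <- sample(n)
  st_shuffled <- local({
    bins <- spikebench:::raster_bin(st$times, st$dt, n)
    new_bins <- tp[bins]
    mk_train((new_bins - 0.5) * st$dt, st$channels, st$polarities,
             st$n_channels, st$duration, st$dt)
  })
  expect_equal(hoyer_sparsity(st_shuffled), hoyer_sparsity(st))
})

test_that("metrics records carry all five values plus provenance", {
  set.seed(41)
  sig <- random_signal(32, 2)
  st <- encode_tbr(sig, gamma = 0.5)
  rec <- metrics_record(st, sig)
  expect_equal(rec$encoder, "tbr")
  expect_true(all(c("S", "MIS", "HS", "epsilon", "density") %in% names(rec)))
  expect_true(rec$MIS >= 0 && rec$MIS <= 1)
  expect_true(rec$HS >= 0 && rec$HS <= 1)
  expect_true(rec$epsilon >= 0 && rec$epsilon <= 1)
  expect_match(rec$metrics_version, "reconstruction")
})
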