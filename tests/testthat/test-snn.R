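test_that("weight transfer copies tensors bit-exactly and keeps structure", {
  net <- build_cnn(network_spec(3, 5, 2, c(10, 10), 4), seed = 1)
  snn <- transfer_weights(net, lif_params())
  expect_identical(snn$weights, net$weights)
  expect_identical(snn$geom, net$geom)
  # a pruned-to-zero weight stays zero in the twin
  net$weights$conv1[1] <- 0
  snn2 <- transfer_weights(net, lif_params())
  expect_identical(snn2$weights$conv1[1], 0)
})

test_that("LIF parameter invariants are enforced", {
  expect_error(lif_params(tau_m = 0.002, dt_sim = 0.001), "tau_m / 5")
  expect_error(lif_params(v_th = 0, v_reset = 0), "v_th")
  expect_s3_class(lif_params(), "lif_params")
})

test_that("zero input rates produce zero output spikes", {
  net <- build_cnn(network_spec(2, 3, 1, c(10, 10), 3), seed = 2)
  snn <- transfer_weights(net, lif_params(t_sim = 0.1))
  res <- simulate_snn(snn, matrix(0, 10, 10), seed = 1)
  expect_true(all(res$counts == 0))
  expect_error(simulate_snn(snn, matrix(-1, 10, 10)), "non-negative")
})

# a 1x1-kernel, 1x1-pool chain is a single synaptic path per channel,
# giving closed-form LIF rates to compare against
chain_snn <- function(w1, lif, input_shape = c(1, 1), n_classes = 2) {
  spec <- network_spec(1, 1, 1, input_shape, n_classes, kernel = 1, pool = 1)
  net <- build_cnn(spec, seed = 1)
  net$weights$conv1 <- matrix(w1, 1, 1)
  net$weights$conv2 <- matrix(1, 1, 1)
  net
}

test_that("a no-leak unit path fires at the closed-form rate", {
  # single input neuron -> conv weights (0.5, then 1) -> class-1 readout;
  # without leak the output rate is w * r_in / v_th, capped at 1/dt_sim.
  # v_th sits a hair below 1 so that two 0.5 increments cross it despite
  # the infinitesimal leak decay between input spikes.
  lif <- lif_params(tau_m = 1e6, t_sim = 1, dt_sim = 0.001, max_rate = 400,
                    v_th = 0.9999)
  net <- chain_snn(0.5, lif)
  net$weights$fc[[1]] <- matrix(c(1, 0), 1, 2)
  snn <- transfer_weights(net, lif)
  res <- simulate_snn(snn, matrix(400, 1, 1), seed = 3)
  expect_equal(res$counts[1], 0.5 * 400 * lif$t_sim, tolerance = 0.05)
  expect_equal(res$counts[2], 0)
})

test_that("doubling the simulation time about doubles the output counts", {
  net <- chain_snn(0.8, lif_params())
  net$weights$fc[[1]] <- matrix(c(1, 0), 1, 2)
  lif1 <- lif_params(tau_m = 1e6, t_sim = 0.5, max_rate = 300)
  lif2 <- lif_params(tau_m = 1e6, t_sim = 1.0, max_rate = 300)
  c1 <- simulate_snn(transfer_weights(net, lif1), matrix(300, 1, 1), seed = 4)$counts[1]
  c2 <- simulate_snn(transfer_weights(net, lif2), matrix(300, 1, 1), seed = 4)$counts[1]
  expect_gt(c1, 0)
  expect_lt(abs(c2 / c1 - 2), 0.2 + 6 * sqrt(c2) / c1)
})

test_that("a crafted routing network steers active channels to their class", {
  # 3 input rows, 1x1 kernels: fc routes flattened position k to class k
  spec <- network_spec(1, 1, 1, c(3, 1), 3, kernel = 1, pool = 1)
  net <- build_cnn(spec, seed = 5)
  net$weights$conv1 <- matrix(1, 1, 1)
  net$weights$conv2 <- matrix(1, 1, 1)
  net$weights$fc[[1]] <- diag(3)
  snn <- transfer_weights(net, lif_params(t_sim = 0.2))
  rates <- matrix(c(0, 400, 0), 3, 1)
  res <- simulate_snn(snn, rates, seed = 6)
  expect_equal(which.max(res$counts), 2L)
})

test_that("all-zero input classifies to the first class by tie-break", {
  net <- build_cnn(network_spec(2, 3, 1, c(10, 10), 3), seed = 7)
  snn <- transfer_weights(net, lif_params(t_sim = 0.05))
  empty <- spike_train(numeric(0), integer(0), integer(0), 10, 1, 1 / 10)
  s <- time_bin(empty, 10)
  expect_equal(classify_snn(snn, s, seed = 1), 1L)
})

test_that("classification is reproducible given the seed", {
  fx <- pipeline_fixture(42L)
  snn <- threshold_balance(transfer_weights(fx$net, lif_params(t_sim = 0.1)),
                           fx$feats$images[fx$tr])
  s <- fx$feats$sonograms[[fx$te[1]]]
  expect_identical(classify_snn(snn, s, seed = 11), classify_snn(snn, s, seed = 11))
})

test_that("threshold balancing keeps factors positive and rescales by layer", {
  fx <- pipeline_fixture(42L)
  snn <- transfer_weights(fx$net, lif_params())
  expect_true(all(snn$thr_factors == 1))
  bal <- threshold_balance(snn, fx$feats$images[fx$tr])
  expect_true(all(bal$thr_factors > 0))
  expect_identical(bal$weights, fx$net$weights)  # weights untouched
})
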