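# Worked examples for each encoder, checked against hand-evaluated values.

sig1 <- function(v, fs = 1) as_signal(v, fs = fs)

test_that("Poisson encoding follows the inverse-CDF inter-spike intervals", {
  # r = 0: infinite ISI, empty train
  st0 <- encode_poisson(sig1(c(5, 5, 5, 5)), rate = 0, seed = 1)
  expect_equal(n_events(st0), 0L)
  expect_error(encode_poisson(sig1(c(5, 5)), rate = -1), "non-negative")
  expect_error(encode_poisson(sig1(c(-1, 2))), "non-negative")
  # first spike time is -log(1 - x1) / r for the first uniform draw x1
  set.seed(7); x1 <- runif(1)
  st <- encode_poisson(sig1(rep(0, 100), fs = 10), rate = 1, seed = 7)
  if (n_events(st) > 0) expect_equal(st$times[1], -log(1 - x1) / 1, tolerance = 1e-12)
  # x1 = 0.6321 -> first spike at about 1.0 s (unit rate)
  expect_equal(-log(1 - 0.6321) / 1, 1.0, tolerance = 1e-4)
})

test_that("TBR spikes where first differences exceed the gamma band", {
  s <- sig1(c(0, 1, 0, 1, 0))
  st <- encode_tbr(s, gamma = 0)
  expect_equal(n_events(st), 4L)
  expect_equal(st$polarities, c(1L, -1L, 1L, -1L))
  expect_equal(n_events(encode_tbr(s, gamma = 2)), 0L)  # threshold 2 > |v| = 1
  expect_equal(n_events(encode_tbr(sig1(rep(3, 10)), gamma = 0)), 0L)
})

test_that("MW spikes against a sliding baseline, symmetric in sign", {
  step <- sig1(c(0, 0, 0, 10, 10, 10))
  st <- encode_mw(step, window = 3)
  expect_gt(n_events(st), 0L)
  expect_equal(st$times[1], 3 / 6 * step$duration)  # step onset (sample 4)
  expect_equal(st$polarities[1], 1L)
  neg <- encode_mw(sig1(-c(0, 0, 0, 10, 10, 10)), window = 3)
  expect_equal(neg$times, st$times)
  expect_equal(neg$polarities, -st$polarities)
  expect_equal(n_events(encode_mw(sig1(rep(2, 8)), window = 3)), 0L)
})

test_that("SF tracks a stepping baseline with threshold mean(jump)/gamma", {
  s <- sig1(c(0, 1, 2, 3, 4))
  st <- encode_sf(s, gamma = 2)  # threshold (4 - 0) / 2 = 2
  expect_equal(n_events(st), 1L)
  expect_equal(st$polarities, 1L)
  expect_equal(st$times, 3 / 5 * s$duration)  # the sample with value 3
  flip <- encode_sf(sig1(-c(0, 1, 2, 3, 4)), gamma = 2)
  expect_equal(flip$times, st$times)
  expect_equal(flip$polarities, -st$polarities)
  expect_equal(n_events(encode_sf(sig1(rep(1, 6)), gamma = 2)), 0L)
  expect_error(encode_sf(s, gamma = 0), "positive")
})

test_that("ZCSF half-wave rectifies and emits positive spikes only", {
  expect_equal(n_events(encode_zcsf(sig1(c(-3, -1, -2, -5)), gamma = 2)), 0L)
  t <- (0:63) / 64
  sine <- sig1(sin(2 * pi * t + 0.01), fs = 64)  # samples off the exact peak
  expect_equal(n_events(encode_zcsf(sine, gamma = 2)), 0L)  # threshold ~1
  st <- encode_zcsf(sine, gamma = 4)  # threshold ~0.5
  thr <- (max(sine$samples) - min(sine$samples)) / 4
  expect_equal(n_events(st), sum(sine$samples > 0 & sine$samples > thr))
  expect_true(all(st$polarities == 1L))
})

test_that("HSA emits on pointwise kernel dominance and subtracts", {
  expect_equal(n_events(encode_hsa(sig1(rep(0, 8)), fir_kernel = c(1, 1))), 0L)
  one <- encode_hsa(sig1(c(0, 0, 1, 1, 0, 0)), fir_kernel = c(1, 1))
  expect_equal(n_events(one), 1L)
  expect_equal(one$times, 2 / 6 * 6)  # kernel onset, sample index 3
  two <- encode_hsa(sig1(c(1, 1, 0, 0, 1, 1, 0)), fir_kernel = c(1, 1))
  expect_equal(n_events(two), 2L)
})

test_that("MHSA gates emission on the accumulated shortfall", {
  expect_equal(n_events(encode_mhsa(sig1(rep(0, 6)), fir_kernel = c(1, 1),
                                    threshold = 0)), 0L)
  exact <- encode_mhsa(sig1(c(0.5, 0.7, 0, 0)), fir_kernel = c(0.5, 0.7),
                       threshold = 0)
  expect_equal(n_events(exact), 1L)
  # an effectively infinite threshold opens the gate at every step
  all_open <- encode_mhsa(sig1(rnorm(16)), fir_kernel = c(0.3, 0.3),
                          threshold = 1e12)
  expect_equal(n_events(all_open), 16L)
})

test_that("BSA compares the two cumulative errors per the Petro condition", {
  expect_equal(n_events(encode_bsa(sig1(rep(0, 6)), fir_kernel = c(0.5, 0.5),
                                   threshold = 1)), 0L)
  st <- encode_bsa(sig1(c(0.5, 0.5, 0, 0)), fir_kernel = c(0.5, 0.5), threshold = 1)
  expect_equal(n_events(st), 1L)
  expect_equal(st$times, 0)
  # and the residual after subtraction suppresses further spikes:
  # reconstruction equals the original two-sample plateau
  rec <- reconstruct_deconv(st, c(0.5, 0.5), 4)
  expect_equal(as.vector(rec), c(0.5, 0.5, 0, 0))
})

test_that("phase encoding expands samples into fractional-bit spike patterns", {
  # values 0 / 0.5 / 1 with beta = 3: nothing, .100, .111
  s <- sig1(c(0, 0.5, 1))
  st <- encode_phase(s, beta = 3)
  dt_sub <- s$duration / (3 * 3)
  expect_equal(st$times, c(3 * dt_sub, 6 * dt_sub, 7 * dt_sub, 8 * dt_sub))
  expect_true(all(st$polarities == 1L))
})

test_that("TTFS latency inverts the exponential threshold decay", {
  # v = 1 crosses at t = 0; v = exp(-1) at t = tau_th
  s <- sig1(c(0, exp(-1), 1), fs = 3 / 6.4)  # duration 6.4 s, grid step 0.1 s
  st <- encode_ttfs(s, theta0 = 1, tau_th = 0.1, n_grid = 64)
  expect_equal(st$times, c(0, 0.1), tolerance = 1e-9)
  expect_equal(n_events(encode_ttfs(sig1(c(0, 0, 0)), tau_th = 0.1)), 0L)
})

test_that("burst encoding maps rate to spike count and ISI", {
  # rates 0 / 0.5 / 1 with N_max = 5, t_min = 2, t_max = 10 timesteps
  s <- sig1(c(0, 0.5, 1, rep(0, 47)), fs = 1)  # zero tail leaves room for bursts
  st <- encode_burst(s, n_max = 5, t_min = 2, t_max = 10)
  # rate 0.5 at t = 1: ceil(2.5) = 3 spikes, ISI ceil(10 - 0.5 * 8) = 6 steps
  # rate 1   at t = 2: N_max = 5 spikes, ISI t_min = 2 steps
  expect_equal(st$times, sort(c(1, 7, 13, 2, 4, 6, 8, 10)))
  expect_true(all(st$polarities == 1L))
})

test_that("the dispatcher is case-insensitive and lists valid names", {
  s <- sig1(c(0, 1, 0, 1, 0))
  direct <- encode_tbr(s, gamma = 0)
  expect_equal(encode(s, "tbr", list(gamma = 0))$times, direct$times)
  expect_equal(encode(s, "TBR", list(gamma = 0))$times, direct$times)
  expect_error(encode(s, "foo"), "valid names.*tbr")
  expect_equal(sort(names(encoder_classes())),
               sort(c("poisson", "tbr", "mw", "sf", "zcsf", "hsa", "mhsa",
                      "bsa", "phase", "ttfs", "burst")))
})

test_that("spike train CSV round-trips bit exactly", {
  set.seed(3)
  st <- encode_tbr(as_signal(matrix(rnorm(80), 2), fs = 10), gamma = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spiketrain_csv(st, path)
  r <- read_spiketrain_csv(path)
  expect_identical(r$times, st$times)
  expect_identical(r$channels, st$channels)
  expect_identical(r$polarities, st$polarities)
  expect_identical(r$duration, st$duration)
  expect_identical(r$dt, st$dt)
})
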