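test_that("network spec validates and renders its canonical name", {
  spec <- network_spec(6, 12, 2, input_shape = c(32, 50), n_classes = 10)
  expect_equal(network_name(spec), "C6-C12-F2")
  expect_error(network_spec(0, 12, 2, c(32, 50), 10), "positive")
  expect_error(network_spec(6, 12, 2, c(32, 50), 1), "classes")
  expect_error(network_spec(6, 12, 2, c(2, 50), 10), "kernel")
})

test_that("parameter count matches the closed-form layer arithmetic", {
  # C6-C12-F2 on 32 x 50, 10 classes, 3x3 kernels, 2x2 pools, hidden 32:
  # conv1 3*3*1*6; conv2 3*3*6*12; 32x50 ->30x48 ->15x24 ->13x22 ->6x11;
  # fc1 (6*11*12)*32; fc2 32*10
  net <- build_cnn(network_spec(6, 12, 2, c(32, 50), 10), seed = 1)
  expected <- 9 * 6 + 9 * 6 * 12 + (6 * 11 * 12) * 32 + 32 * 10
  expect_equal(n_parameters(net), expected)
  expect_equal(dim(net$weights$conv1), c(9L, 6L))
  expect_equal(dim(net$weights$conv2), c(54L, 12L))
  expect_equal(dim(net$weights$fc[[1]]), c(792L, 32L))
  expect_equal(dim(net$weights$fc[[2]]), c(32L, 10L))
})

test_that("zero input yields uniform softmax in a zero-bias network", {
  net <- build_cnn(network_spec(4, 6, 2, c(10, 12), 5), seed = 2)
  p <- predict_cnn_prob(net, list(matrix(0, 10, 12)))
  expect_equal(as.vector(p), rep(0.2, 5))
})

test_that("positive weight scaling preserves the argmax", {
  set.seed(3)
  net <- build_cnn(network_spec(4, 6, 2, c(10, 12), 4), seed = 3)
  imgs <- replicate(6, matrix(runif(120), 10, 12), simplify = FALSE)
  base <- predict_cnn(net, imgs)
  scaled <- net
  scaled$weights$conv1 <- scaled$weights$conv1 * 2.5
  scaled$weights$fc[[1]] <- scaled$weights$fc[[1]] * 0.3
  expect_equal(predict_cnn(scaled, imgs), base)
})

test_that("the network rejects inputs that collapse through conv/pool", {
  expect_error(build_cnn(network_spec(2, 3, 1, c(8, 8), 3)), "collapses")
})

test_that("zero epochs returns initial weights unchanged", {
  net <- build_cnn(network_spec(2, 3, 1, c(10, 10), 3), seed = 4)
  set.seed(99)
  imgs <- replicate(6, matrix(runif(100), 10, 10), simplify = FALSE)
  out <- train_cnn(net, imgs, c(1, 2, 3, 1, 2, 3), epochs = 0)
  expect_identical(out$weights, net$weights)
})

test_that("training separates a linearly separable synthetic set", {
  # three classes activating disjoint row bands of the image
  set.seed(5)
  mk <- function(cls) {
    img <- matrix(runif(12 * 12, 0, 0.1), 12, 12)
    img[(cls * 4 - 3):(cls * 4), ] <- img[(cls * 4 - 3):(cls * 4), ] + 0.8
    img
  }
  labels <- rep(1:3, each = 10)
  imgs <- lapply(labels, mk)
  net <- build_cnn(network_spec(4, 6, 2, c(12, 12), 3), seed = 5)
  net <- train_cnn(net, imgs, labels, epochs = 20, lr = 0.1, seed = 5)
  expect_gte(mean(predict_cnn(net, imgs) == labels), 0.95)
  # permutation control: shuffled labels stay near chance on held-out data
  set.seed(6)
  shuffled <- sample(labels)
  net2 <- build_cnn(network_spec(4, 6, 2, c(12, 12), 3), seed = 6)
  net2 <- train_cnn(net2, imgs, shuffled, epochs = 5, lr = 0.05, seed = 6)
  fresh <- lapply(rep(1:3, each = 10), mk)
  acc <- mean(predict_cnn(net2, fresh) == rep(1:3, each = 10))
  sigma <- sqrt(1 / 3 * 2 / 3 / 30)
  expect_lt(acc, 1 / 3 + 3 * sigma)
})

test_that("training is deterministic given the seed", {
  set.seed(7)
  imgs <- replicate(9, matrix(runif(100), 10, 10), simplify = FALSE)
  labels <- rep(1:3, 3)
  a <- train_cnn(build_cnn(network_spec(2, 3, 1, c(10, 10), 3), seed = 8),
                 imgs, labels, epochs = 3, seed = 9)
  b <- train_cnn(build_cnn(network_spec(2, 3, 1, c(10, 10), 3), seed = 8),
                 imgs, labels, epochs = 3, seed = 9)
  expect_identical(a$weights, b$weights)
})

test_that("gradients match finite differences on a tiny network", {
  net <- build_cnn(network_spec(2, 2, 2, c(10, 10), 3, fc_hidden = 4), seed = 10)
  set.seed(10)
  img <- matrix(runif(100), 10, 10)
  y <- 2L
  loss_at <- function(w_mod) {
    n <- net; n$weights <- w_mod
    p <- predict_cnn_prob(n, list(img))[1, ]
    -log(p[y])
  }
  fwd <- spikebench:::cnn_forward(net, img)
  p <- exp(fwd$logits - max(fwd$logits)); p <- p / sum(p)
  d_logits <- p; d_logits[y] <- d_logits[y] - 1
  grad <- spikebench:::cnn_backward(net, fwd, d_logits)
  eps <- 1e-6
  for (slot in list(c("conv1", 3), c("conv2", 5))) {
    w <- net$weights[[slot[1]]]
    i <- as.integer(slot[2])
    wp <- net$weights; wp[[slot[1]]][i] <- w[i] + eps
    wm <- net$weights; wm[[slot[1]]][i] <- w[i] - eps
    num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
    expect_equal(grad[[slot[1]]][i], num, tolerance = 1e-4)
  }
  wp <- net$weights; wp$fc[[1]][2] <- wp$fc[[1]][2] + eps
  wm <- net$weights; wm$fc[[1]][2] <- wm$fc[[1]][2] - eps
  num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
  expect_equal(grad$fc[[1]][2], num, tolerance = 1e-4)
})
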