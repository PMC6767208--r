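test_that("pad_or_crop pads symmetrically and centre-crops", {
  x <- embedded_signal(matrix(seq_len(3 * 1000), 3, 1000))
  expect_identical(pad_or_crop(x, 1000)$channels, x$channels)

  short <- embedded_signal(matrix(1, 3, 900))
  p <- pad_or_crop(short, 1000)$channels
  expect_equal(ncol(p), 1000L)
  expect_true(all(p[, 1:50] == 0) && all(p[, 951:1000] == 0))
  expect_true(all(p[, 51:950] == 1))

  long <- embedded_signal(matrix(seq_len(1100), 1, 1100))
  cr <- pad_or_crop(long, 1000)$channels
  # samples 50..1050 kept (0-based, half-open)
  expect_equal(cr[1, 1], 51)
  expect_equal(cr[1, 1000], 1050)
  expect_error(pad_or_crop(x, 10), ">= 60")
})

test_that("the head shape chain follows the conv/maxpool arithmetic", {
  # 1000 -> 95 -> 91 -> 18
  expect_equal(floorgait:::head_flat_dim(1000), 18L)
  # any length >= 65 yields a consistent chain
  for (Tl in c(65, 200, 777, 1500)) {
    Tf <- (Tl - 60) %/% 10 + 1
    expect_equal(floorgait:::head_flat_dim(Tl), (Tf - 5 + 1) %/% 5)
  }
  cfg <- train_config(input_len = 1000, seed = 2)
  net <- build_activity_net(NULL, cfg, in_ch = 3L)
  x <- matrix(0, 3, 1000)
  yh <- predict_activity(net, list(x))
  expect_true(yh > 0 && yh < 1)
  # zeroed biases and zero input: sigmoid(0) = 0.5
  net0 <- net
  for (nm in c("conv1", "conv2", "conv3", "conv5", "fc1", "fc2", "fc3"))
    net0$params[[nm]]$b[] <- 0
  expect_equal(predict_activity(net0, list(x)), 0.5)
  expect_error(predict_activity(net, list(matrix(0, 2, 1000))), "channels")
})

test_that("binary cross-entropy matches hand computations", {
  expect_equal(bce_loss(1 - 1e-9, 1), 0, tolerance = 1e-5)
  expect_equal(bce_loss(0.5, 1), -log(0.5), tolerance = 1e-12)
  expect_equal(bce_loss(c(0.9, 0.1), c(1, 0)), -2 * log(0.9),
               tolerance = 1e-12)
  expect_error(bce_loss(c(0.5, 0.5), 1), "mismatch")
  # permutation invariance and non-negativity
  withr::with_seed(6, {
    yh <- runif(10); y <- rbinom(10, 1, 0.5)
    o <- sample(10)
    expect_equal(bce_loss(yh, y), bce_loss(yh[o], y[o]))
    expect_gte(bce_loss(yh, y), 0)
  })
})

test_that("classification threshold is inclusive and monotone", {
  expect_equal(classify_scores(0.2, 0.2), "staff")
  expect_equal(classify_scores(0.19, 0.2), "elderly")
  expect_true(all(classify_scores(c(0, 0.3, 1), 0) == "staff"))
  # as tau sweeps up, each signal flips staff -> elderly at most once
  yh <- c(0.1, 0.5, 0.9)
  taus <- seq(0, 1, by = 0.05)
  lab <- sapply(taus, function(t) classify_scores(yh, t) == "staff")
  flips <- apply(lab, 1, function(v) sum(diff(v) != 0))
  expect_true(all(flips <= 1))
  expect_error(classify_scores(0.5, 1.5), "tau")
})

test_that("transferred trunk blocks are copied and stay bitwise frozen", {
  spn <- spn_init(3L, seed = 9)
  cfg <- train_config(max_epochs = 5, patience = 3, seed = 13,
                      batch_size = 4)
  net <- build_activity_net(spn, cfg)
  blocks <- c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3")
  expect_identical(net$params[blocks], spn$params[blocks])
  expect_true(net$frozen)

  withr::with_seed(99, {
    inputs <- lapply(1:10, function(i) {
      amp <- if (i <= 5) 1 else 0.3
      matrix(amp * rnorm(3 * 1000), 3, 1000)
    })
  })
  y <- c(rep(1, 5), rep(0, 5))
  trained <- train_activity_net(net, inputs, y, cfg)
  expect_identical(trained$params[blocks], spn$params[blocks])
  # head parameters did change
  expect_false(identical(trained$params$fc3, net$params$fc3))
})

test_that("head initialisation is seeded Gaussian with the configured spread", {
  cfg <- train_config(seed = 21)
  n1 <- build_activity_net(NULL, cfg, in_ch = 3L, seed = 77)
  n2 <- build_activity_net(NULL, cfg, in_ch = 3L, seed = 77)
  expect_identical(n1$params, n2$params)
  # empirical sd over >= 1e4 draws within 0.2 +/- 0.01
  n3 <- build_activity_net(NULL, cfg, in_ch = 3L, seed = 78)
  draws <- unlist(lapply(list(n1, n3), function(nn)
    c(as.vector(nn$params$fc1$W), as.vector(nn$params$fc2$W),
      as.vector(nn$params$conv1$W), as.vector(nn$params$conv2$W),
      as.vector(nn$params$conv3$W))))
  expect_gt(length(draws), 1e4)
  expect_equal(stats::sd(draws), 0.2, tolerance = 0.01)
})

test_that("training descends on linearly separable inputs", {
  withr::with_seed(15, {
    inputs <- lapply(1:14, function(i) {
      amp <- if (i %% 2) 3 else 0.2
      matrix(amp * abs(rnorm(3 * 1000)), 3, 1000)
    })
  })
  y <- rep(c(1, 0), 7)
  cfg <- train_config(lr = 1e-3, max_epochs = 40, patience = 40, seed = 3,
                      batch_size = 4)
  net <- build_activity_net(NULL, cfg, in_ch = 3L)
  trained <- train_activity_net(net, inputs, y, cfg)
  expect_lt(trained$best_train_loss, trained$loss0_train)
  # single-class training data warns but proceeds
  expect_warning(
    train_activity_net(build_activity_net(NULL, cfg, in_ch = 3L),
                       inputs[c(1, 3)], c(1, 1),
                       train_config(max_epochs = 2, seed = 1,
                                    batch_size = 2)),
    "single-class")
})
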