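test_that("interval IoU matches a brute-force sample-counting oracle", {
  expect_equal(box_iou(c(0L, 20L), step_boxes(0L, 20L)), 1)
  expect_equal(box_iou(c(0L, 20L), step_boxes(30L, 50L)), 0)
  expect_equal(box_iou(c(0L, 20L), step_boxes(c(10L, 100L), c(30L, 140L))),
               10 / 30)
  expect_equal(box_iou(c(0L, 20L), step_boxes()), 0)

  withr::with_seed(11, {
    for (i in 1:200) {
      s1 <- sample(0:80, 1); e1 <- s1 + sample(1:40, 1)
      ng <- sample(0:3, 1)
      gs <- sample(0:80, ng, replace = TRUE)
      gt <- step_boxes(gs, gs + sample(1:40, max(ng, 1),
                                       replace = TRUE)[seq_len(ng)])
      expect_equal(box_iou(c(s1, e1), gt), iou_oracle(c(s1, e1), gt))
      # symmetry of the pairwise IoU
      if (ng == 1L)
        expect_equal(box_iou(c(s1, e1), gt),
                     box_iou(gt[1, ], step_boxes(s1, e1)))
    }
  })
})

test_that("anchor grids tile the signal at stride 10", {
  g <- anchor_grid(1000)
  expect_equal(g$feature_len, 95L)
  expect_equal(anchor_grid(60)$feature_len, 1L)
  a <- floorgait:::grid_anchors(g)
  expect_equal(nrow(a), 95L * 3L)
  expect_equal(a[1, ], c(start = 0L, end = 20L))
  expect_equal(unname(a[95 + 1, 2] - a[95 + 1, 1]), 30L)
  expect_error(anchor_grid(59), "60")
})

test_that("anchors partition into positive, negative and neutral", {
  g <- anchor_grid(300)
  gt <- step_boxes(c(40L, 200L), c(70L, 230L))
  lab <- assign_anchors(g, gt)
  expect_true(all(lab %in% c("positive", "negative", "neutral")))
  iou <- floorgait:::anchors_iou(floorgait:::grid_anchors(g), gt)
  expect_equal(as.vector(lab) == "positive", iou > 0.7)
  expect_equal(as.vector(lab) == "negative", iou < 0.3)
  # a 10/30 overlap (iou 1/3) is neutral
  lab2 <- assign_anchors(anchor_grid(60), step_boxes(10L, 30L))
  iou2 <- floorgait:::anchors_iou(
    floorgait:::grid_anchors(anchor_grid(60)), step_boxes(10L, 30L))
  expect_equal(lab2[1, 1], "neutral")
  expect_equal(iou2[1], 1 / 3)
  # empty ground truth: everything negative
  expect_true(all(assign_anchors(g, step_boxes()) == "negative"))
  expect_error(assign_anchors(g, step_boxes(0L, 10L), hi = 0.2, lo = 0.5),
               "below")
})

test_that("the forward pass has the documented shape and zero-input value", {
  m <- spn_init(3L, init_std = 0.2, seed = 1)
  x <- matrix(0, 3, 1000)
  W <- spn_forward(x, m)
  expect_equal(dim(W), c(95L, 3L))
  expect_true(all(W > 0 & W < 1))
  expect_equal(dim(spn_forward(matrix(0, 3, 60), m)), c(1L, 3L))
  # zeroed biases and zero input: sigmoid(0) = 0.5 everywhere
  m0 <- m
  for (nm in c("conv1", "conv2", "conv3", "conv4")) m0$params[[nm]]$b[] <- 0
  expect_equal(unname(spn_forward(x, m0)), matrix(0.5, 95, 3))
  expect_error(spn_forward(matrix(0, 2, 100), m), "channels")
  expect_error(spn_forward(matrix(0, 3, 59), m), "shorter")
})

test_that("the anchor loss scores only non-neutral anchors", {
  labels <- matrix("neutral", 4, 3)
  W <- matrix(0.37, 4, 3)
  expect_equal(spn_loss(W, labels), 0)
  labels[1, 1] <- "positive"; labels[2, 2] <- "negative"
  W[1, 1] <- 1 - 1e-9; W[2, 2] <- 1e-9
  expect_equal(spn_loss(W, labels), 0, tolerance = 1e-5)
  # single positive at 0.5: -log(0.5)
  labels2 <- matrix("neutral", 2, 3); labels2[1, 1] <- "positive"
  W2 <- matrix(0.5, 2, 3)
  expect_equal(spn_loss(W2, labels2), -log(0.5), tolerance = 1e-12)
  expect_error(spn_loss(matrix(0.5, 2, 3), matrix("neutral", 3, 3)),
               "mismatch")
  # gradient w.r.t. neutral entries is exactly zero: perturbing a neutral
  # entry leaves the loss unchanged
  W2[2, 2] <- 0.9
  expect_equal(spn_loss(W2, labels2), -log(0.5), tolerance = 1e-12)
})

test_that("box decoding applies the score floor and greedy suppression", {
  g <- anchor_grid(1000)
  W <- matrix(0, 95, 3)
  expect_equal(nrow(decode_boxes(W, g, 0.5, 0.5)), 0L)
  W[10, 2] <- 0.9
  d <- decode_boxes(W, g, 0.5, 0.5)
  expect_equal(nrow(d), 1L)
  expect_equal(d$start, 90L)
  expect_equal(d$end, 120L)
  # two overlapping anchors: [90,130) scored 0.8 vs [90,120) scored 0.9,
  # IoU 30/40 = 0.75 > 0.5 -> only the higher survives
  W[10, 3] <- 0.8
  d2 <- decode_boxes(W, g, 0.5, 0.5)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$score, 0.9)
})

test_that("average precision matches the enumeration oracle", {
  # 2 ground-truth boxes, ranked predictions (TP, FP, TP) -> 0.8333
  gt <- list(step_boxes(c(0L, 100L), c(30L, 130L)))
  preds <- list(data.frame(start = c(0L, 50L, 100L),
                           end = c(30L, 80L, 130L),
                           score = c(0.9, 0.8, 0.7)))
  expect_equal(average_precision(preds, gt, 0.99),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  # perfect predictions -> 1; disjoint predictions -> 0
  expect_equal(average_precision(list(data.frame(start = 0L, end = 30L,
                                                 score = 1)),
                                 list(step_boxes(0L, 30L)), 0.5), 1)
  expect_equal(average_precision(list(data.frame(start = 500L, end = 530L,
                                                 score = 1)),
                                 list(step_boxes(0L, 30L)), 0.5), 0)
  expect_error(average_precision(preds, list(step_boxes()), 0.5), "ground")

  # randomised equivalence with the brute-force oracle (<= 10 predictions)
  withr::with_seed(21, {
    for (rep in 1:30) {
      n_sig <- sample(1:3, 1)
      gt <- lapply(seq_len(n_sig), function(i) {
        k <- sample(1:3, 1)
        s <- sort(sample(seq(0, 200, by = 40), k))
        step_boxes(s, s + sample(20:35, k, replace = TRUE))
      })
      preds <- lapply(seq_len(n_sig), function(i) {
        np <- sample(0:4, 1)
        if (np == 0) return(data.frame(start = integer(), end = integer(),
                                       score = numeric()))
        s <- sample(0:220, np)
        data.frame(start = s, end = s + sample(15:40, np, replace = TRUE),
                   score = round(runif(np), 3))
      })
      thr <- sample(c(0.3, 0.5, 0.7), 1)
      expect_equal(average_precision(preds, gt, thr),
                   ap_oracle(preds, gt, thr), tolerance = 1e-12)
    }
  })
})

test_that("shifting the input by one stride shifts the score map one row", {
  m <- spn_init(3L, seed = 3)
  withr::with_seed(8, x <- matrix(rnorm(3 * 500), 3, 500))
  xs <- cbind(matrix(0, 3, 10), x[, 1:490])
  W <- spn_forward(x, m)
  Ws <- spn_forward(xs, m)
  inner <- 5:40
  expect_equal(Ws[inner + 1, ], W[inner, ], tolerance = 1e-8)
})

test_that("the learning-rate schedule decays geometrically every 10 epochs", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 0), 1e-5)
  expect_equal(lr_at_epoch(cfg, 9), 1e-5)
  expect_equal(lr_at_epoch(cfg, 25), 1e-5 * 0.9^2)
})

test_that("short training runs are deterministic and reduce the loss", {
  withr::with_seed(31, {
    atom <- planted_atom()
    dct <- step_dictionary(matrix(atom, ncol = 1))
    walks <- list(); boxes <- list()
    prof <- person_profile("staff")
    for (i in 1:8) {
      w <- synth_walk(prof, 6)
      mono <- colSums(w$channels)
      e <- rbind(mono, mono, mono)   # 3 channels for the network input
      walks[[i]] <- embedded_signal(e)
      boxes[[i]] <- w$boxes
    }
  })
  cfg <- train_config(max_epochs = 8, patience = 5, seed = 5)
  m1 <- train_spn(walks, boxes, cfg)
  m2 <- train_spn(walks, boxes, cfg)
  expect_identical(m1$params, m2$params)
  expect_lte(m1$best_train_loss, m1$loss0_train)
  # a signal with no positive anchor is skipped with a warning
  expect_warning(
    train_spn(c(walks, list(walks[[1]])), c(boxes, list(step_boxes())),
              cfg),
    "skipped")
  expect_error(train_spn(list(), list(), cfg), "empty")
})
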