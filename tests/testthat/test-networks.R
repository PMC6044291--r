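# architecture contracts, shared-layer identity, gradient correctness,
# and training sanity for the two networks

test_that("concatenation and pooling widths match the architecture", {
  cfg <- model_config() # full-scale defaults
  expect_equal(cfg$shared_lstm_units + cfg$emb_dim, 600L) # c1/c2
  # c3 concatenates l1 (300) + l2 (300) + v1 (48) + v2 (6)
  expect_equal(2L * cfg$shared_lstm_units + cfg$i4_conv_filters +
                 cfg$i5_conv_filters, 654L)
  expect_equal(2L * cfg$l3_units, 256L) # pooled p1

  set.seed(1)
  small <- tiny_cfg(emb_dim = 8L, shared_lstm_units = 8L)
  sh <- build_shared_layers(small, 10L)
  pre <- build_pretraining_network(small, sh)
  expect_equal(pre$concat_width, 16L) # 2 * emb_dim at equal sizes
  rec <- build_recognition_network(small, sh)
  expect_equal(rec$concat_width, 2L * 8L + 2L + 2L)
  expect_equal(rec$pooled_width, 2L * small$l3_units)
})

test_that("LSTM parameter count matches the standard closed form", {
  set.seed(2)
  l <- lstm_init(300L, 300L)
  expect_equal(param_count(l), 4L * ((300L + 300L) * 300L + 300L))
})

test_that("softmax scores are normalized and prediction is deterministic", {
  set.seed(3)
  cfg <- tiny_cfg()
  sh <- build_shared_layers(cfg, 12L,
                            emb_init = matrix(rnorm(12L * 4L) * 0.3, 12L, 4L))
  net <- build_recognition_network(cfg, sh)
  b <- random_recognition_batch(V = 12L, B = 4L, Tt = 6L)
  b$idx <- 1:4
  s1 <- predict_scores(net, list(b))
  expect_equal(dim(s1), c(4L, 6L))
  expect_equal(unname(rowSums(s1)), rep(1, 4L), tolerance = 1e-6)
  expect_true(all(s1 >= 0))
  s2 <- predict_scores(net, list(b))
  expect_identical(s1, s2)
})

test_that("phase-1 and phase-2 networks share identical parameter tensors", {
  set.seed(4)
  cfg <- tiny_cfg(dropout = 0.5, recurrent_dropout = 0.5)
  sh <- build_shared_layers(cfg, 12L)
  pre <- build_pretraining_network(cfg, sh)
  rec <- build_recognition_network(cfg, sh)
  # literally the same environments
  expect_true(identical(pre$shared$e1, rec$shared$e1))
  expect_true(identical(pre$shared$l1$W, rec$shared$l1$W))
  # a phase-1 update is visible bitwise through the recognition network
  train_step(pre, random_pretrain_batch(V = 12L, B = 3L, Tt = 6L))
  expect_identical(rec$shared$l1$W$w, pre$shared$l1$W$w)
  expect_identical(rec$shared$e1$w, pre$shared$e1$w)
})

test_that("analytic gradients match finite differences on both networks", {
  set.seed(42)
  cfg <- tiny_cfg()
  V <- 12L
  sh <- build_shared_layers(cfg, V,
                            emb_init = matrix(rnorm(V * 4L) * 0.3, V, 4L))
  pre <- build_pretraining_network(cfg, sh)
  rec <- build_recognition_network(cfg, sh)
  pb <- random_pretrain_batch(V = V, B = 2L, Tt = 5L)
  rb <- random_recognition_batch(V = V, B = 2L, Tt = 5L)

  loss_of <- function(net, batch) {
    if (inherits(net, "pretrain_network")) {
      fwd <- chemrel:::pretrain_forward(net, batch)
      bl <- chemrel:::masked_bce(fwd$s_left, batch$y_left, batch$loss_mask, 0.5)
      br <- chemrel:::masked_bce(fwd$s_right, batch$y_right, batch$loss_mask, 0.5)
      bl$loss + br$loss
    } else {
      fwd <- chemrel:::recognition_forward(net, batch)
      Y <- matrix(0, 2L, 6L)
      Y[cbind(1:2, batch$labels + 1L)] <- 1
      chemrel:::softmax_mse(fwd$scores, Y)$loss
    }
  }
  for (spec in list(list(pre, pb), list(rec, rb))) {
    net <- spec[[1L]]; batch <- spec[[2L]]
    zero_grads(net$params)
    if (inherits(net, "pretrain_network")) {
      fwd <- chemrel:::pretrain_forward(net, batch)
      chemrel:::pretrain_backward(net, batch, fwd)
    } else {
      fwd <- chemrel:::recognition_forward(net, batch)
      chemrel:::recognition_backward(net, batch, fwd)
    }
    eps <- 1e-5
    for (p in net$params) {
      for (i in sample(length(p$w), min(4L, length(p$w)))) {
        w0 <- p$w[i]
        p$w[i] <- w0 + eps; lp <- loss_of(net, batch)
        p$w[i] <- w0 - eps; lm <- loss_of(net, batch)
        p$w[i] <- w0
        num <- (lp - lm) / (2 * eps)
        expect_lt(abs(num - p$g[i]),
                  1e-4 * max(1, abs(num) + abs(p$g[i])))
      }
    }
  }
})

test_that("repeated steps on one batch reduce the loss (overfit smoke test)", {
  set.seed(9)
  cfg <- tiny_cfg(learning_rate = 0.01)
  sh <- build_shared_layers(cfg, 12L,
                            emb_init = matrix(rnorm(12L * 4L) * 0.3, 12L, 4L))
  rec <- build_recognition_network(cfg, sh)
  rb <- random_recognition_batch(V = 12L, B = 4L, Tt = 6L)
  l0 <- train_step(rec, rb)
  for (i in 1:49) l_end <- train_step(rec, rb)
  expect_lt(l_end, l0)

  pre <- build_pretraining_network(cfg, sh)
  pb <- random_pretrain_batch(V = 12L, B = 4L, Tt = 6L)
  p0 <- train_step(pre, pb)
  for (i in 1:49) p_end <- train_step(pre, pb)
  expect_lt(p_end, p0)
})

test_that("batch prediction returns one score vector per candidate", {
  set.seed(10)
  cfg <- tiny_cfg()
  sh <- build_shared_layers(cfg, 12L)
  rec <- build_recognition_network(cfg, sh)
  b1 <- random_recognition_batch(V = 12L, B = 3L, Tt = 4L); b1$idx <- 1:3
  b2 <- random_recognition_batch(V = 12L, B = 2L, Tt = 7L); b2$idx <- 4:5
  s <- predict_scores(rec, list(b1, b2))
  expect_equal(nrow(s), 5L)
  expect_false(anyNA(s))
})

test_that("the convolutional second-stage variant preserves widths", {
  set.seed(11)
  cfg <- tiny_cfg(l3_type = "conv")
  sh <- build_shared_layers(cfg, 12L)
  rec <- build_recognition_network(cfg, sh)
  expect_equal(rec$pooled_width, 2L * cfg$l3_units)
  b <- random_recognition_batch(V = 12L, B = 2L, Tt = 5L)
  expect_equal(dim(predict_scores(rec, list(b))), c(2L, 6L))
})
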