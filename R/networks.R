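# The two networks of the system.
#
# Pre-training network (phase 1): three applications of one shared
# embedding table (original sequence i1, right-shifted substituted
# sequence i2, left-shifted substituted sequence i3); a forward LSTM l1
# and a reversed LSTM l2 over the embedded original; per-position
# concatenations c1 = [l1, e2] and c2 = [l2, e3]; rectified dense d1/d3
# then sigmoid d2/d4 judging, per position, whether the substituted
# token is original or a negative sample. Loss: masked binary
# cross-entropy, averaged over the two outputs.
#
# Recognition network (phase 2): the shared e1/l1/l2 over the masked
# candidate token sequence; width-3 relu convolutions v1 (48 filters
# over the 10 entity-context features i4) and v2 (6 filters over the
# 2 pair-membership features i5); c3 = [l1, l2, v1, v2] (652 wide at
# full scale); a bidirectional LSTM l3 (128 units per direction);
# global max pooling over positions; a 6-way softmax d5. Loss: mean
# squared error against the one-hot label. Both networks train with
# RMSProp; e1/l1/l2 are literally the same parameter tensors in both.

#' Model configuration
#'
#' Layer sizes and training constants. Full-scale defaults mirror the
#' published architecture; desk-scale runs shrink `emb_dim`,
#' `shared_lstm_units` and `l3_units` while preserving the topology.
#'
#' @param emb_dim Embedding width (default 300).
#' @param shared_lstm_units Units in each shared LSTM l1/l2 (default 300).
#' @param i4_conv_filters,i5_conv_filters Convolution filters over the
#'   entity-context (i4) and pair-membership (i5) feature sequences
#'   (defaults 48 and 6).
#' @param conv_width Convolution kernel width (default 3).
#' @param l3_units Units per direction of the second-stage bidirectional
#'   LSTM (default 128).
#' @param pretrain_dense_units Width of the rectified comparison layers
#'   d1/d3 in the pre-training network (default 300).
#' @param dropout,recurrent_dropout LSTM dropout rates (default 0.5 each),
#'   active only during training.
#' @param learning_rate RMSProp learning rate (default 0.001).
#' @param n_classes Output classes (default 6: NONE + five CPR groups).
#' @param l3_type `"bilstm"` (default) or `"conv"`, a width-3 relu
#'   convolution variant of the second stage.
#' @return A list of class `model_config`.
#' @export
model_config <- function(emb_dim = 300L, shared_lstm_units = 300L,
                         i4_conv_filters = 48L, i5_conv_filters = 6L,
                         conv_width = 3L, l3_units = 128L,
                         pretrain_dense_units = 300L,
                         dropout = 0.5, recurrent_dropout = 0.5,
                         learning_rate = 0.001, n_classes = 6L,
                         l3_type = c("bilstm", "conv")) {
  cfg <- list(emb_dim = as.integer(emb_dim),
              shared_lstm_units = as.integer(shared_lstm_units),
              i4_conv_filters = as.integer(i4_conv_filters),
              i5_conv_filters = as.integer(i5_conv_filters),
              conv_width = as.integer(conv_width),
              l3_units = as.integer(l3_units),
              pretrain_dense_units = as.integer(pretrain_dense_units),
              dropout = dropout, recurrent_dropout = recurrent_dropout,
              learning_rate = learning_rate,
              n_classes = as.integer(n_classes),
              l3_type = match.arg(l3_type))
  stopifnot(all(vapply(cfg[1:7], function(v) v > 0L, TRUE)))
  structure(cfg, class = "model_config")
}

#' Desk-scale model configuration
#'
#' The reduced layer sizes used throughout the synthetic-corpus runs:
#' embedding 24, shared LSTMs 24 units, second-stage LSTM 16 units per
#' direction. Because a desk-scale schedule takes two orders of
#' magnitude fewer gradient updates than a full-scale run, the RMSProp
#' learning rate is raised to 0.01 so that optimization progress matches
#' the shortened schedule; everything else keeps the full-scale
#' defaults.
#'
#' @param ... Overrides passed on to [model_config()].
#' @return A `model_config`.
#' @export
scaled_config <- function(...) {
  args <- list(...)
  defaults <- list(emb_dim = 24L, shared_lstm_units = 24L, l3_units = 16L,
                   pretrain_dense_units = 24L, learning_rate = 0.01)
  do.call(model_config, utils::modifyList(defaults, args))
}

#' Build the layers shared by both networks
#'
#' The embedding table e1 and the two shared LSTMs l1 (forward) and l2
#' (reversed). Both networks hold references to these same parameter
#' environments, so a phase-1 update is immediately visible in phase 2.
#'
#' @param cfg A [model_config()].
#' @param vocab_size Number of vocabulary entries (embedding rows).
#' @param emb_init Optional initial embedding matrix
#'   (vocab_size x emb_dim), e.g. from [build_embedding_matrix()];
#'   `NULL` for all-zero initialization.
#' @return A list with elements `e1`, `l1`, `l2`.
#' @export
build_shared_layers <- function(cfg, vocab_size, emb_init = NULL) {
  if (is.null(emb_init)) {
    emb_init <- matrix(0, vocab_size, cfg$emb_dim)
  }
  stopifnot(nrow(emb_init) == vocab_size, ncol(emb_init) == cfg$emb_dim)
  list(
    e1 = nn_param(unname(as.matrix(emb_init))),
    l1 = lstm_init(cfg$emb_dim, cfg$shared_lstm_units),
    l2 = lstm_init(cfg$emb_dim, cfg$shared_lstm_units)
  )
}

#' Build the pre-training network
#'
#' @param cfg A [model_config()].
#' @param shared Shared layers from [build_shared_layers()].
#' @return A list of class `pretrain_network`.
#' @export
build_pretraining_network <- function(cfg, shared) {
  cwidth <- cfg$shared_lstm_units + cfg$emb_dim # c1/c2 width (600 at full scale)
  layers <- list(
    d1 = dense_init(cwidth, cfg$pretrain_dense_units),
    d2 = dense_init(cfg$pretrain_dense_units, 1L),
    d3 = dense_init(cwidth, cfg$pretrain_dense_units),
    d4 = dense_init(cfg$pretrain_dense_units, 1L)
  )
  structure(
    list(cfg = cfg, shared = shared, layers = layers,
         concat_width = cwidth,
         params = collect_params(list(shared, layers))),
    class = "pretrain_network"
  )
}

#' Build the recognition network
#'
#' @param cfg A [model_config()].
#' @param shared Shared layers from [build_shared_layers()].
#' @return A list of class `recognition_network`.
#' @export
build_recognition_network <- function(cfg, shared) {
  c3_width <- 2L * cfg$shared_lstm_units + cfg$i4_conv_filters + cfg$i5_conv_filters
  layers <- list(
    v1 = conv1d_init(cfg$conv_width, 10L, cfg$i4_conv_filters),
    v2 = conv1d_init(cfg$conv_width, 2L, cfg$i5_conv_filters)
  )
  if (cfg$l3_type == "bilstm") {
    layers$l3f <- lstm_init(c3_width, cfg$l3_units)
    layers$l3b <- lstm_init(c3_width, cfg$l3_units)
    pooled <- 2L * cfg$l3_units
  } else {
    layers$l3c <- conv1d_init(cfg$conv_width, c3_width, 2L * cfg$l3_units)
    pooled <- 2L * cfg$l3_units
  }
  layers$d5 <- dense_init(pooled, cfg$n_classes)
  structure(
    list(cfg = cfg, shared = shared, layers = layers,
         concat_width = c3_width, pooled_width = pooled,
         params = collect_params(list(shared, layers))),
    class = "recognition_network"
  )
}

#' @export
print.pretrain_network <- function(x, ...) {
  cat("<pretrain_network> concat width ", x$concat_width, ", ",
      param_count(x$params), " trainable parameters\n", sep = "")
  invisible(x)
}

#' @export
print.recognition_network <- function(x, ...) {
  cat("<recognition_network> concat width ", x$concat_width,
      ", pooled width ", x$pooled_width, ", ",
      param_count(x$params), " trainable parameters\n", sep = "")
  invisible(x)
}

.cat3 <- function(...) {
  arrs <- list(...)
  d1 <- dim(arrs[[1L]])
  ds <- vapply(arrs, function(a) dim(a)[3L], 1L)
  out <- array(0, c(d1[1L], d1[2L], sum(ds)))
  off <- 0L
  for (a in arrs) {
    out[, , off + seq_len(dim(a)[3L])] <- a
    off <- off + dim(a)[3L]
  }
  out
}

.split3 <- function(A, widths) {
  off <- 0L
  lapply(widths, function(w) {
    sl <- A[, , off + seq_len(w), drop = FALSE]
    off <<- off + w
    sl
  })
}

# forward pass of the pre-training network; returns per-position sigmoid
# outputs s_left/s_right (B x T) plus caches for the backward pass
pretrain_forward <- function(net, batch, training = FALSE) {
  cfg <- net$cfg; sh <- net$shared; ly <- net$layers
  e1 <- emb_forward(batch$i1, sh$e1)
  e2 <- emb_forward(batch$i2, sh$e1)
  e3 <- emb_forward(batch$i3, sh$e1)
  f1 <- lstm_forward(e1, sh$l1, reverse = FALSE, dropout = cfg$dropout,
                     recurrent_dropout = cfg$recurrent_dropout, training = training)
  f2 <- lstm_forward(e1, sh$l2, reverse = TRUE, dropout = cfg$dropout,
                     recurrent_dropout = cfg$recurrent_dropout, training = training)
  c1 <- .cat3(f1$out, e2)
  c2 <- .cat3(f2$out, e3)
  fd1 <- td_dense_forward(c1, ly$d1)
  a1 <- pmax(fd1$out, 0)
  fd2 <- td_dense_forward(a1, ly$d2)
  s_left <- .sigmoid(matrix(fd2$out, dim(fd2$out)[1L], dim(fd2$out)[2L]))
  fd3 <- td_dense_forward(c2, ly$d3)
  a3 <- pmax(fd3$out, 0)
  fd4 <- td_dense_forward(a3, ly$d4)
  s_right <- .sigmoid(matrix(fd4$out, dim(fd4$out)[1L], dim(fd4$out)[2L]))
  list(s_left = s_left, s_right = s_right,
       cache = list(f1 = f1, f2 = f2, fd1 = fd1, fd2 = fd2, fd3 = fd3,
                    fd4 = fd4, a1 = a1, a3 = a3, e1 = e1))
}

# loss + gradient accumulation for one pre-training batch
pretrain_backward <- function(net, batch, fwd) {
  cfg <- net$cfg; sh <- net$shared; ly <- net$layers
  d <- dim(fwd$cache$e1)
  B <- d[1L]; Tt <- d[2L]
  bl <- masked_bce(fwd$s_left, batch$y_left, batch$loss_mask, weight = 0.5)
  br <- masked_bce(fwd$s_right, batch$y_right, batch$loss_mask, weight = 0.5)
  # left branch
  dz2 <- array(bl$dZ, c(B, Tt, 1L))
  da1 <- td_dense_backward(dz2, fwd$cache$fd2, ly$d2)
  dc1 <- td_dense_backward(da1 * (fwd$cache$a1 > 0), fwd$cache$fd1, ly$d1)
  parts <- .split3(dc1, c(cfg$shared_lstm_units, cfg$emb_dim))
  dl1 <- parts[[1L]]; de2 <- parts[[2L]]
  # right branch
  dz4 <- array(br$dZ, c(B, Tt, 1L))
  da3 <- td_dense_backward(dz4, fwd$cache$fd4, ly$d4)
  dc2 <- td_dense_backward(da3 * (fwd$cache$a3 > 0), fwd$cache$fd3, ly$d3)
  parts2 <- .split3(dc2, c(cfg$shared_lstm_units, cfg$emb_dim))
  dl2 <- parts2[[1L]]; de3 <- parts2[[2L]]
  de1 <- lstm_backward(dl1, fwd$cache$f1, sh$l1) +
    lstm_backward(dl2, fwd$cache$f2, sh$l2)
  emb_backward(de1, batch$i1, sh$e1)
  emb_backward(de2, batch$i2, sh$e1)
  emb_backward(de3, batch$i3, sh$e1)
  bl$loss + br$loss
}

# forward pass of the recognition network; returns softmax scores (B x 6)
recognition_forward <- function(net, batch, training = FALSE) {
  cfg <- net$cfg; sh <- net$shared; ly <- net$layers
  e1 <- emb_forward(batch$token_ids, sh$e1)
  f1 <- lstm_forward(e1, sh$l1, reverse = FALSE, dropout = cfg$dropout,
                     recurrent_dropout = cfg$recurrent_dropout, training = training)
  f2 <- lstm_forward(e1, sh$l2, reverse = TRUE, dropout = cfg$dropout,
                     recurrent_dropout = cfg$recurrent_dropout, training = training)
  fv1 <- conv1d_forward(batch$i4, ly$v1)
  fv2 <- conv1d_forward(batch$i5, ly$v2)
  c3 <- .cat3(f1$out, f2$out, fv1$out, fv2$out)
  if (cfg$l3_type == "bilstm") {
    f3f <- lstm_forward(c3, ly$l3f, reverse = FALSE, dropout = cfg$dropout,
                        recurrent_dropout = cfg$recurrent_dropout,
                        training = training)
    f3b <- lstm_forward(c3, ly$l3b, reverse = TRUE, dropout = cfg$dropout,
                        recurrent_dropout = cfg$recurrent_dropout,
                        training = training)
    l3 <- .cat3(f3f$out, f3b$out)
    f3c <- NULL
  } else {
    f3c <- conv1d_forward(c3, ly$l3c)
    l3 <- f3c$out
    f3f <- f3b <- NULL
  }
  fp <- maxpool_forward(l3, batch$pos_mask)
  fz <- dense_forward(fp$out, ly$d5)
  P <- row_softmax(fz$out)
  list(scores = P,
       cache = list(f1 = f1, f2 = f2, fv1 = fv1, fv2 = fv2, f3f = f3f,
                    f3b = f3b, f3c = f3c, fp = fp, fz = fz, e1 = e1))
}

recognition_backward <- function(net, batch, fwd) {
  cfg <- net$cfg; sh <- net$shared; ly <- net$layers
  Y <- matrix(0, nrow(fwd$scores), cfg$n_classes)
  Y[cbind(seq_len(nrow(Y)), batch$labels + 1L)] <- 1
  lo <- softmax_mse(fwd$scores, Y)
  dp <- dense_backward(lo$dZ, fwd$cache$fz, ly$d5)
  dl3 <- maxpool_backward(dp, fwd$cache$fp)
  if (cfg$l3_type == "bilstm") {
    parts <- .split3(dl3, c(cfg$l3_units, cfg$l3_units))
    dc3 <- lstm_backward(parts[[1L]], fwd$cache$f3f, ly$l3f) +
      lstm_backward(parts[[2L]], fwd$cache$f3b, ly$l3b)
  } else {
    dc3 <- conv1d_backward(dl3, fwd$cache$f3c, ly$l3c)
  }
  u <- cfg$shared_lstm_units
  parts <- .split3(dc3, c(u, u, cfg$i4_conv_filters, cfg$i5_conv_filters))
  conv1d_backward(parts[[3L]], fwd$cache$fv1, ly$v1)
  conv1d_backward(parts[[4L]], fwd$cache$fv2, ly$v2)
  de1 <- lstm_backward(parts[[1L]], fwd$cache$f1, sh$l1) +
    lstm_backward(parts[[2L]], fwd$cache$f2, sh$l2)
  emb_backward(de1, batch$token_ids, sh$e1)
  lo$loss
}

#' One training step on a batch
#'
#' Zeroes gradients, runs the forward and backward passes with dropout
#' active, and applies one RMSProp update. Works for both network types.
#'
#' @param net A `pretrain_network` or `recognition_network`.
#' @param batch A batch from [batch_by_length()] or [batch_candidates()].
#' @return The batch loss (scalar), invisibly.
#' @export
train_step <- function(net, batch) {
  zero_grads(net$params)
  loss <- if (inherits(net, "pretrain_network")) {
    fwd <- pretrain_forward(net, batch, training = TRUE)
    pretrain_backward(net, batch, fwd)
  } else {
    fwd <- recognition_forward(net, batch, training = TRUE)
    recognition_backward(net, batch, fwd)
  }
  rmsprop_step(net$params, lr = net$cfg$learning_rate)
  invisible(loss)
}

#' Predict class scores for candidate batches
#'
#' Dropout is disabled; given fixed parameters the output is
#' deterministic. Scores are returned in input order.
#'
#' @param net A `recognition_network`.
#' @param batches List of batches from [batch_candidates()].
#' @return A numeric matrix (n_candidates x 6) of softmax scores; column
#'   order NONE, CPR:3, CPR:4, CPR:5, CPR:6, CPR:9.
#' @export
predict_scores <- function(net, batches) {
  stopifnot(inherits(net, "recognition_network"))
  n <- sum(vapply(batches, function(b) nrow(b$token_ids), 1L))
  out <- matrix(NA_real_, n, net$cfg$n_classes)
  colnames(out) <- c("NONE", cpr_groups())
  for (b in batches) {
    fwd <- recognition_forward(net, b, training = FALSE)
    out[b$idx, ] <- fwd$scores
  }
  out
}

#' Per-position discrimination accuracy of the pre-training network
#'
#' Runs the pre-training network with dropout off and scores, over all
#' positions with a nonzero loss mask, whether thresholding the two
#' sigmoid outputs at 0.5 recovers the original-vs-substituted flags.
#'
#' @param net A `pretrain_network`.
#' @param batches List of batches from [batch_by_length()].
#' @return Accuracy in `[0, 1]`.
#' @export
pretrain_accuracy <- function(net, batches) {
  stopifnot(inherits(net, "pretrain_network"))
  hits <- 0; n <- 0
  for (b in batches) {
    fwd <- pretrain_forward(net, b, training = FALSE)
    m <- b$loss_mask == 1
    hits <- hits + sum((fwd$s_left > 0.5)[m] == (b$y_left == 1)[m]) +
      sum((fwd$s_right > 0.5)[m] == (b$y_right == 1)[m])
    n <- n + 2 * sum(m)
  }
  if (n == 0) return(NA_real_)
  hits / n
}
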