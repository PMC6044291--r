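# Neural-network primitives: parameters, layers, losses, optimizer.
#
# The layer set is exactly what the two relation-extraction networks
# need: a shared trainable embedding, LSTM layers (optionally processing
# the reversed sequence) with input and recurrent dropout, time-distributed
# dense layers, width-3 same-padded 1-D convolutions, global max pooling
# over positions, sigmoid/softmax heads, masked binary cross-entropy and
# mean-squared-error losses, and RMSProp. Gradients are hand-derived
# (backpropagation through time for the LSTMs) and validated against
# finite differences in the test suite.
#
# Array convention: batched sequences are numeric arrays of shape
# (batch B, time T, features); per-timestep slices are B x features
# matrices. Parameters live in environments so that layers shared
# between two networks are literally the same tensors.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.slice_t <- function(X, t) {
  d <- dim(X)
  matrix(X[, t, , drop = FALSE], d[1L], d[3L])
}

#' Create a trainable parameter
#'
#' Parameters are environments holding the weight array `w`, the gradient
#' accumulator `g` and the RMSProp cache `m`, so two networks that share
#' a layer share (and co-update) the identical tensor.
#'
#' @param w Initial numeric array.
#' @return An environment of class `nn_param`.
#' @export
nn_param <- function(w) {
  e <- new.env(parent = emptyenv())
  e$w <- w
  e$g <- w * 0
  e$m <- w * 0
  class(e) <- "nn_param"
  e
}

#' @export
print.nn_param <- function(x, ...) {
  cat("<nn_param> ", paste(dim(as.matrix(x$w)), collapse = "x"), "\n", sep = "")
  invisible(x)
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# orthogonal init (QR of a Gaussian matrix), used per recurrent gate block
.orthogonal <- function(n) {
  q <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  q * sign(diag(q))[1L] # fix sign convention for reproducibility
}

#' Initialize an LSTM layer
#'
#' Gate order in the fused matrices is input, forget, candidate, output.
#' The input kernel uses Glorot-uniform init, the recurrent kernel is
#' block-orthogonal, biases start at zero except the forget gate at one.
#'
#' @param din Input feature width.
#' @param units Number of memory cells.
#' @return A list with `nn_param`s `W` (din x 4u), `U` (u x 4u), `b` (4u)
#'   plus `din` and `units`.
#' @export
lstm_init <- function(din, units) {
  U <- do.call(cbind, lapply(1:4, function(k) .orthogonal(units)))
  b <- rep(0, 4 * units)
  b[units + seq_len(units)] <- 1 # forget-gate bias
  list(W = nn_param(.glorot(din, 4 * units)), U = nn_param(U),
       b = nn_param(b), din = din, units = units)
}

#' Initialize a dense layer
#' @param din,dout Input/output widths.
#' @return List with `nn_param`s `W`, `b`.
#' @export
dense_init <- function(din, dout) {
  list(W = nn_param(.glorot(din, dout)), b = nn_param(rep(0, dout)),
       din = din, dout = dout)
}

#' Initialize a 1-D convolution layer
#' @param width Kernel width (odd; default 3).
#' @param fin,fout Input/output feature widths.
#' @return List with `nn_param`s `W` ((width*fin) x fout), `b`.
#' @export
conv1d_init <- function(width = 3L, fin, fout) {
  list(W = nn_param(.glorot(width * fin, fout)), b = nn_param(rep(0, fout)),
       width = as.integer(width), fin = fin, fout = fout)
}

#' Collect all `nn_param`s of a (nested) layer structure
#' @param x A layer or nested list of layers.
#' @return Flat list of `nn_param` environments (deduplicated).
#' @export
collect_params <- function(x) {
  out <- list()
  walk <- function(y) {
    if (inherits(y, "nn_param")) {
      out[[length(out) + 1L]] <<- y
    } else if (is.list(y)) {
      for (el in y) walk(el)
    }
  }
  walk(x)
  # deduplicate by environment identity (shared layers appear once)
  uniq <- list()
  for (p in out) {
    if (!any(vapply(uniq, identical, FALSE, y = p))) uniq[[length(uniq) + 1L]] <- p
  }
  uniq
}

#' Total number of trainable scalars in a layer structure
#' @param x A layer or nested list of layers.
#' @return Integer count.
#' @export
param_count <- function(x) {
  sum(vapply(collect_params(x), function(p) length(p$w), 1))
}

#' Reset gradient accumulators to zero
#' @param params List of `nn_param`s (from [collect_params()]).
#' @return Invisibly, `params`.
#' @export
zero_grads <- function(params) {
  for (p in params) p$g <- p$w * 0
  invisible(params)
}

#' One RMSProp update over a parameter list
#'
#' `m <- rho * m + (1 - rho) * g^2 ; w <- w - lr * g / (sqrt(m) + eps)`.
#'
#' @param params List of `nn_param`s.
#' @param lr Learning rate (default 0.001).
#' @param rho Decay of the squared-gradient average (default 0.9).
#' @param eps Numerical floor (default 1e-7).
#' @return Invisibly, `params`.
#' @export
rmsprop_step <- function(params, lr = 0.001, rho = 0.9, eps = 1e-7) {
  for (p in params) {
    p$m <- rho * p$m + (1 - rho) * p$g^2
    p$w <- p$w - lr * p$g / (sqrt(p$m) + eps)
  }
  invisible(params)
}

## ---- embedding ----

# ids: B x T integer matrix of 0-based vocab indices
emb_forward <- function(ids, E) {
  B <- nrow(ids); Tt <- ncol(ids); d <- ncol(E$w)
  array(E$w[as.vector(ids) + 1L, ], c(B, Tt, d))
}

emb_backward <- function(dY, ids, E) {
  d <- dim(dY)
  M <- matrix(dY, d[1L] * d[2L], d[3L])
  agg <- rowsum(M, group = as.vector(ids) + 1L)
  rows <- as.integer(rownames(agg))
  E$g[rows, ] <- E$g[rows, , drop = FALSE] + agg
  invisible(NULL)
}

## ---- LSTM ----

# X: (B, T, din). With reverse = TRUE the sequence is processed back to
# front and the per-position outputs re-reversed, so position t of the
# output summarizes context at and to the right of t. Dropout masks are
# drawn once per sequence and reused across timesteps (variational
# dropout); inverted scaling keeps expectations unchanged.
lstm_forward <- function(X, layer, reverse = FALSE, dropout = 0,
                         recurrent_dropout = 0, training = FALSE) {
  dd <- dim(X)
  B <- dd[1L]; Tt <- dd[2L]; din <- dd[3L]; u <- layer$units
  stopifnot(din == layer$din)
  if (reverse) X <- X[, Tt:1, , drop = FALSE]
  MW <- MU <- NULL
  if (training && dropout > 0) {
    MW <- matrix(stats::rbinom(B * din, 1L, 1 - dropout) / (1 - dropout), B, din)
  }
  if (training && recurrent_dropout > 0) {
    MU <- matrix(stats::rbinom(B * u, 1L, 1 - recurrent_dropout) /
                   (1 - recurrent_dropout), B, u)
  }
  W <- layer$W$w; U <- layer$U$w
  bmat <- matrix(layer$b$w, B, 4L * u, byrow = TRUE)
  I <- Fg <- G <- O <- C <- H <- array(0, c(B, Tt, u))
  hprev <- cprev <- matrix(0, B, u)
  ui <- seq_len(u)
  for (t in seq_len(Tt)) {
    xt <- .slice_t(X, t)
    if (!is.null(MW)) xt <- xt * MW
    hd <- if (!is.null(MU)) hprev * MU else hprev
    A <- xt %*% W + hd %*% U + bmat
    i <- .sigmoid(A[, ui, drop = FALSE])
    f <- .sigmoid(A[, u + ui, drop = FALSE])
    g <- tanh(A[, 2L * u + ui, drop = FALSE])
    o <- .sigmoid(A[, 3L * u + ui, drop = FALSE])
    cc <- f * cprev + i * g
    h <- o * tanh(cc)
    I[, t, ] <- i; Fg[, t, ] <- f; G[, t, ] <- g; O[, t, ] <- o
    C[, t, ] <- cc; H[, t, ] <- h
    hprev <- h; cprev <- cc
  }
  out <- if (reverse) H[, Tt:1, , drop = FALSE] else H
  list(out = out,
       cache = list(X = X, I = I, Fg = Fg, G = G, O = O, C = C, H = H,
                    MW = MW, MU = MU, reverse = reverse, B = B, Tt = Tt,
                    din = din, u = u))
}

lstm_backward <- function(dH, fwd, layer) {
  cc <- fwd$cache
  B <- cc$B; Tt <- cc$Tt; din <- cc$din; u <- cc$u
  if (cc$reverse) dH <- dH[, Tt:1, , drop = FALSE]
  W <- layer$W$w; U <- layer$U$w
  gW <- W * 0; gU <- U * 0; gb <- layer$b$w * 0
  dX <- array(0, c(B, Tt, din))
  dh_next <- dc_next <- matrix(0, B, u)
  for (t in Tt:1) {
    i <- .slice_t(cc$I, t); f <- .slice_t(cc$Fg, t)
    g <- .slice_t(cc$G, t); o <- .slice_t(cc$O, t)
    ct <- .slice_t(cc$C, t)
    cprev <- if (t > 1L) .slice_t(cc$C, t - 1L) else matrix(0, B, u)
    hprev <- if (t > 1L) .slice_t(cc$H, t - 1L) else matrix(0, B, u)
    th <- tanh(ct)
    dh <- .slice_t(dH, t) + dh_next
    do_ <- dh * th
    dc <- dc_next + dh * o * (1 - th^2)
    di <- dc * g; df <- dc * cprev; dg <- dc * i
    dA <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g^2), do_ * o * (1 - o))
    xt <- .slice_t(cc$X, t)
    if (!is.null(cc$MW)) xt <- xt * cc$MW
    hd <- if (!is.null(cc$MU)) hprev * cc$MU else hprev
    gW <- gW + crossprod(xt, dA)
    gU <- gU + crossprod(hd, dA)
    gb <- gb + colSums(dA)
    dxt <- dA %*% t(W)
    if (!is.null(cc$MW)) dxt <- dxt * cc$MW
    dX[, t, ] <- dxt
    dh_next <- dA %*% t(U)
    if (!is.null(cc$MU)) dh_next <- dh_next * cc$MU
    dc_next <- dc * f
  }
  layer$W$g <- layer$W$g + gW
  layer$U$g <- layer$U$g + gU
  layer$b$g <- layer$b$g + gb
  if (cc$reverse) dX <- dX[, Tt:1, , drop = FALSE]
  dX
}

## ---- time-distributed dense ----

# X: (B, T, din) -> (B, T, dout); activation handled by caller
td_dense_forward <- function(X, layer) {
  d <- dim(X)
  Xm <- matrix(X, d[1L] * d[2L], d[3L])
  Z <- Xm %*% layer$W$w + matrix(layer$b$w, nrow(Xm), layer$dout, byrow = TRUE)
  list(out = array(Z, c(d[1L], d[2L], layer$dout)), cache = list(Xm = Xm, d = d))
}

td_dense_backward <- function(dZ, fwd, layer) {
  d <- fwd$cache$d
  dZm <- matrix(dZ, d[1L] * d[2L], layer$dout)
  layer$W$g <- layer$W$g + crossprod(fwd$cache$Xm, dZm)
  layer$b$g <- layer$b$g + colSums(dZm)
  array(dZm %*% t(layer$W$w), d)
}

# plain dense on a (N, din) matrix
dense_forward <- function(Xm, layer) {
  Z <- Xm %*% layer$W$w + matrix(layer$b$w, nrow(Xm), layer$dout, byrow = TRUE)
  list(out = Z, cache = Xm)
}

dense_backward <- function(dZ, fwd, layer) {
  layer$W$g <- layer$W$g + crossprod(fwd$cache, dZ)
  layer$b$g <- layer$b$g + colSums(dZ)
  dZ %*% t(layer$W$w)
}

## ---- 1-D convolution (same padding) with relu ----

.conv_stack <- function(X, width) {
  d <- dim(X)
  B <- d[1L]; Tt <- d[2L]; f <- d[3L]
  half <- (width - 1L) %/% 2L
  Xcat <- matrix(0, B * Tt, width * f)
  for (k in seq_len(width)) {
    s <- k - half - 1L # shift: -half .. +half
    src <- seq_len(Tt) + s
    ok <- src >= 1L & src <= Tt
    Xsh <- array(0, d)
    Xsh[, which(ok), ] <- X[, src[ok], , drop = FALSE]
    Xcat[, (k - 1L) * f + seq_len(f)] <- matrix(Xsh, B * Tt, f)
  }
  Xcat
}

conv1d_forward <- function(X, layer) {
  d <- dim(X)
  Xcat <- .conv_stack(X, layer$width)
  Z <- Xcat %*% layer$W$w + matrix(layer$b$w, nrow(Xcat), layer$fout, byrow = TRUE)
  A <- pmax(Z, 0)
  list(out = array(A, c(d[1L], d[2L], layer$fout)),
       cache = list(Xcat = Xcat, Z = Z, d = d))
}

conv1d_backward <- function(dA, fwd, layer) {
  cc <- fwd$cache
  d <- cc$d
  B <- d[1L]; Tt <- d[2L]; f <- d[3L]
  dZ <- matrix(dA, B * Tt, layer$fout) * (cc$Z > 0)
  layer$W$g <- layer$W$g + crossprod(cc$Xcat, dZ)
  layer$b$g <- layer$b$g + colSums(dZ)
  dXcat <- dZ %*% t(layer$W$w)
  half <- (layer$width - 1L) %/% 2L
  dX <- array(0, d)
  for (k in seq_len(layer$width)) {
    s <- k - half - 1L
    dXsh <- array(dXcat[, (k - 1L) * f + seq_len(f)], d)
    src <- seq_len(Tt) + s
    ok <- src >= 1L & src <= Tt
    dX[, src[ok], ] <- dX[, src[ok], , drop = FALSE] + dXsh[, which(ok), , drop = FALSE]
  }
  dX
}

## ---- global max pooling over positions ----

# H: (B, T, u); pos_mask: B x T with 1 at real positions. Padded
# positions are excluded from the maximum.
maxpool_forward <- function(H, pos_mask) {
  d <- dim(H)
  B <- d[1L]; Tt <- d[2L]; u <- d[3L]
  A2 <- matrix(aperm(H, c(1L, 3L, 2L)), B * u, Tt) # rows: b fastest, then j
  Mrow <- pos_mask[rep(seq_len(B), u), , drop = FALSE]
  A2[Mrow == 0] <- -Inf
  arg <- max.col(A2, ties.method = "first")
  val <- A2[cbind(seq_len(B * u), arg)]
  list(out = matrix(val, B, u), cache = list(arg = arg, d = d))
}

maxpool_backward <- function(dM, fwd) {
  d <- fwd$cache$d
  B <- d[1L]; u <- d[3L]
  dH <- array(0, d)
  bj <- expand.grid(b = seq_len(B), j = seq_len(u)) # same order as rows of A2
  dH[cbind(bj$b, fwd$cache$arg, bj$j)] <- as.vector(dM)
  dH
}

## ---- heads and losses ----

row_softmax <- function(Z) {
  E <- exp(Z - apply(Z, 1L, max))
  E / rowSums(E)
}

# masked binary cross-entropy over a (B, T) sigmoid output.
# Returns loss and gradient w.r.t. the pre-sigmoid activation.
masked_bce <- function(S, Y, mask, weight = 1) {
  n <- sum(mask)
  if (n == 0) return(list(loss = 0, dZ = S * 0))
  eps <- 1e-12
  loss <- -sum(mask * (Y * log(S + eps) + (1 - Y) * log(1 - S + eps))) / n
  list(loss = weight * loss, dZ = weight * mask * (S - Y) / n)
}

# mean squared error of softmax probabilities against one-hot labels.
# Returns loss and gradient w.r.t. the pre-softmax logits.
softmax_mse <- function(P, Y) {
  N <- length(P)
  loss <- sum((P - Y)^2) / N
  dP <- 2 * (P - Y) / N
  dZ <- P * (dP - rowSums(dP * P))
  list(loss = loss, dZ = dZ)
}
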