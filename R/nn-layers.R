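## Neural-network layer primitives. Tensor layout: 5D arrays with
## dim = (channels, depth, height, width, batch) — channels fastest, so a
## matrix view with nrow = channels exposes per-channel statistics to fast
## row operations. Fully-connected activations are (features x batch)
## matrices. Every layer has an explicit backward; correctness is anchored
## by finite-difference gradient tests.

conv3dForward <- function(x, W, b, stride, pad) {
  kdim <- attr(W, "kdim")
  .conv3d_fwd(x, dim(x), W, b, as.integer(kdim), as.integer(stride),
              as.integer(pad))
}

conv3dBackward <- function(x, W, dout, stride, pad) {
  kdim <- attr(W, "kdim")
  .conv3d_bwd(x, dim(x), W, dout, as.integer(kdim), as.integer(stride),
              as.integer(pad))
}

# conv weight: (Cout x Cin*kd*kh*kw) matrix carrying its kernel geometry;
# Kaiming-uniform init with fan_in = Cin*kd*kh*kw
convWeight <- function(cin, cout, kdim) {
  fanIn <- cin * prod(kdim)
  bound <- sqrt(6 / fanIn)
  W <- matrix(runif(cout * cin * prod(kdim), -bound, bound), nrow = cout)
  attr(W, "kdim") <- as.integer(kdim)
  W
}

fcWeight <- function(nin, nout) {
  bound <- sqrt(6 / nin)
  matrix(runif(nout * nin, -bound, bound), nrow = nout)
}

maxpool3dForward <- function(x, kdim) {
  .maxpool3d_fwd(x, dim(x), as.integer(kdim))
}

maxpool3dBackward <- function(dout, argmax, xdim) {
  .maxpool3d_bwd(dout, argmax, as.integer(xdim))
}

reluForward <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

reluBackward <- function(dy, x) {
  dy * (x > 0)
}

## Batch normalization on a channel-first matrix view (C x M). For conv
## tensors M = D*H*W*N; for FC activations M = N. Biased batch variance is
## used both for normalization and the running estimate.
bnForward <- function(x, gamma, beta, running, momentum = 0.1, eps = 1e-5,
                      training = TRUE) {
  d <- dim(x)
  C <- d[1L]
  m <- matrix(x, nrow = C)
  M <- ncol(m)
  if (training) {
    mu <- rowMeans(m)
    xc <- m - mu
    v <- rowMeans(xc * xc)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
    xc <- m - mu
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * invstd
  y <- gamma * xhat + beta
  dim(y) <- d
  list(out = y, running = running,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, dims = d,
                    training = training))
}

bnBackward <- function(dy, cache) {
  C <- nrow(cache$xhat)
  dym <- matrix(dy, nrow = C)
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  if (cache$training) {
    M <- ncol(dym)
    dxhat <- dym * cache$gamma
    dx <- cache$invstd *
      (dxhat - rowSums(dxhat) / M - cache$xhat * rowSums(dxhat * cache$xhat) / M)
  } else {
    dx <- dym * cache$gamma * cache$invstd
  }
  dim(dx) <- cache$dims
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

fcForward <- function(x, W, b) {
  W %*% x + b
}

fcBackward <- function(dy, x, W) {
  list(dx = crossprod(W, dy), dW = tcrossprod(dy, x), db = rowSums(dy))
}

dropoutForward <- function(x, rate, training = TRUE) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  keep <- 1 - rate
  mask <- (matrix(runif(length(x)), nrow = nrow(x)) < keep) / keep
  list(out = x * mask, mask = mask)
}

dropoutBackward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## Channel attention (squeeze-and-excitation with avg and max descriptors).
## Global average and max pooling over (depth, height, width) per channel
## each pass through the shared two-layer bottleneck MLP; the two outputs
## are summed and squashed by a sigmoid into per-channel weights that
## rescale the input.
attentionForward <- function(x, W1, b1, W2, b2) {
  d <- dim(x)
  C <- d[1L]; S <- prod(d[2:4]); N <- d[5L]
  arr <- x
  dim(arr) <- c(C, S, N)
  avg <- matrix(0, C, N)
  mx <- matrix(0, C, N)
  amax <- matrix(0L, C, N)
  for (n in seq_len(N)) {
    sl <- arr[, , n, drop = FALSE]
    dim(sl) <- c(C, S)
    avg[, n] <- rowMeans(sl)
    am <- max.col(sl, ties.method = "first")
    amax[, n] <- am
    mx[, n] <- sl[cbind(seq_len(C), am)]
  }
  a1a <- W1 %*% avg + b1; h1a <- reluForward(a1a)
  a1m <- W1 %*% mx + b1;  h1m <- reluForward(a1m)
  z <- (W2 %*% h1a + b2) + (W2 %*% h1m + b2)
  s <- sigmoid(z)  # C x N channel weights, strictly in (0, 1)
  scale <- s[, rep(seq_len(N), each = S), drop = FALSE]
  y <- x
  dim(y) <- c(C, S * N)
  ym <- y * scale
  dim(ym) <- d
  list(out = ym,
       cache = list(x = x, avg = avg, mx = mx, amax = amax, a1a = a1a,
                    h1a = h1a, a1m = a1m, h1m = h1m, s = s, dims = d))
}

attentionBackward <- function(dy, cache, W1, W2) {
  d <- cache$dims
  C <- d[1L]; S <- prod(d[2:4]); N <- d[5L]
  dym <- dy; dim(dym) <- c(C, S * N)
  xm <- cache$x; dim(xm) <- c(C, S * N)
  scale <- cache$s[, rep(seq_len(N), each = S), drop = FALSE]
  dx <- dym * scale

  prod_ <- dym * xm
  dim(prod_) <- c(C, S, N)
  ds <- matrix(0, C, N)
  for (n in seq_len(N)) {
    sl <- prod_[, , n, drop = FALSE]
    dim(sl) <- c(C, S)
    ds[, n] <- rowSums(sl)
  }
  dz <- ds * cache$s * (1 - cache$s)

  # shared MLP: both descriptor paths accumulate into the same weights
  dW2 <- tcrossprod(dz, cache$h1a) + tcrossprod(dz, cache$h1m)
  db2 <- 2 * rowSums(dz)
  dh1a <- reluBackward(crossprod(W2, dz), cache$a1a)
  dh1m <- reluBackward(crossprod(W2, dz), cache$a1m)
  dW1 <- tcrossprod(dh1a, cache$avg) + tcrossprod(dh1m, cache$mx)
  db1 <- rowSums(dh1a) + rowSums(dh1m)
  davg <- crossprod(W1, dh1a)
  dmx <- crossprod(W1, dh1m)

  dim(dx) <- c(C, S, N)
  for (n in seq_len(N)) {
    sl <- matrix(dx[, , n], C, S)  # keep matrix shape even when S == 1
    sl <- sl + davg[, n] / S
    idx <- cbind(seq_len(C), cache$amax[, n])
    sl[idx] <- sl[idx] + dmx[, n]
    dx[, , n] <- sl
  }
  dim(dx) <- d
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

#' Weighted softmax cross-entropy
#'
#' Loss over a batch of logits with per-class weights: each item
#' contributes `w[y_i] * (-log p_i[y_i])`; the batch loss is normalized by
#' the total weight, so with all weights equal to 1 it is exactly the
#' unweighted mean cross-entropy. The gradient consumes logits directly
#' (log-softmax internally) for numerical stability.
#'
#' @param logits `classes x batch` matrix.
#' @param yIdx integer true-class indices (1-based), length = batch.
#' @param classWeights per-class weights (default: all 1).
#' @return list with `loss`, `probs` (softmax), and `dlogits`.
#' @export
weightedCrossEntropy <- function(logits, yIdx, classWeights = NULL) {
  K <- nrow(logits); N <- ncol(logits)
  if (is.null(classWeights)) classWeights <- rep(1, K)
  shifted <- sweep(logits, 2L, apply(logits, 2L, max), "-")
  logZ <- log(colSums(exp(shifted)))
  logp <- sweep(shifted, 2L, logZ, "-")
  probs <- exp(logp)
  wi <- classWeights[yIdx]
  loss <- -sum(wi * logp[cbind(yIdx, seq_len(N))]) / sum(wi)
  onehot <- matrix(0, K, N)
  onehot[cbind(yIdx, seq_len(N))] <- 1
  dlogits <- sweep(probs - onehot, 2L, wi / sum(wi), "*")
  list(loss = loss, probs = probs, dlogits = dlogits)
}

## Adam optimizer with decoupled-from-nothing torch-style weight decay
## (decay added to the gradient). State: first/second moments per parameter
## plus the step counter.
adamInit <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weightDecay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weightDecay > 0) g <- g + weightDecay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    kd <- attr(params[[nm]], "kdim")
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    if (!is.null(kd)) attr(params[[nm]], "kdim") <- kd
  }
  list(params = params, state = state)
}
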