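# naive direct 3D convolution, the oracle for the im2col/GEMM kernel
convByHand <- function(x, W, b, stride, pad, cout) {
  kd <- attr(W, "kdim")
  d <- dim(x)
  C <- d[1]; D <- d[2]; H <- d[3]; Wd <- d[4]; N <- d[5]
  OD <- (D + 2 * pad[1] - kd[1]) %/% stride[1] + 1
  OH <- (H + 2 * pad[2] - kd[2]) %/% stride[2] + 1
  OW <- (Wd + 2 * pad[3] - kd[3]) %/% stride[3] + 1
  out <- array(0, c(cout, OD, OH, OW, N))
  for (n in 1:N) for (co in 1:cout) for (od in 1:OD) for (oh in 1:OH)
    for (ow in 1:OW) {
      acc <- b[co]
      for (zw in 1:kd[3]) for (zh in 1:kd[2]) for (zd in 1:kd[1])
        for (ci in 1:C) {
          id <- (od - 1) * stride[1] - pad[1] + zd
          ih <- (oh - 1) * stride[2] - pad[2] + zh
          iw <- (ow - 1) * stride[3] - pad[3] + zw
          if (id >= 1 && id <= D && ih >= 1 && ih <= H && iw >= 1 && iw <= Wd) {
            k <- ci + C * ((zd - 1) + kd[1] * ((zh - 1) + kd[2] * (zw - 1)))
            acc <- acc + W[co, k] * x[ci, id, ih, iw, n]
          }
        }
      out[co, od, oh, ow, n] <- acc
    }
  out
}

test_that("conv3d kernel matches the direct convolution", {
  set.seed(12)
  x <- array(rnorm(2 * 5 * 4 * 4 * 2), c(2, 5, 4, 4, 2))
  W <- hafnet:::convWeight(2L, 3L, c(3L, 3L, 3L))
  b <- rnorm(3)
  for (cfg in list(list(s = c(1, 1, 1), p = c(1, 1, 1)),
                   list(s = c(2, 1, 1), p = c(2, 1, 1)),
                   list(s = c(1, 2, 2), p = c(0, 0, 0)))) {
    got <- hafnet:::conv3dForward(x, W, b, cfg$s, cfg$p)
    want <- convByHand(x, W, b, cfg$s, cfg$p, 3L)
    expect_equal(got, want, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("max pooling matches a direct window maximum and routes gradients", {
  set.seed(13)
  x <- array(rnorm(3 * 4 * 6 * 6 * 2), c(3, 4, 6, 6, 2))
  mp <- hafnet:::maxpool3dForward(x, c(2, 2, 2))
  expect_equal(dim(mp$out), c(3L, 2L, 3L, 3L, 2L))
  for (i in 1:10) {
    idx <- c(sample(3, 1), sample(2, 1), sample(3, 1), sample(3, 1),
             sample(2, 1))
    win <- x[idx[1], (idx[2] * 2 - 1):(idx[2] * 2),
             (idx[3] * 2 - 1):(idx[3] * 2), (idx[4] * 2 - 1):(idx[4] * 2),
             idx[5]]
    expect_equal(mp$out[idx[1], idx[2], idx[3], idx[4], idx[5]], max(win))
  }
  dout <- array(rnorm(length(mp$out)), dim(mp$out))
  dx <- hafnet:::maxpool3dBackward(dout, mp$argmax, dim(x))
  expect_equal(sum(dx != 0), length(dout))
  expect_equal(sum(dx), sum(dout), tolerance = 1e-10)
})

test_that("layer primitives pass finite-difference gradient checks", {
  set.seed(14)
  # conv
  x <- array(rnorm(2 * 4 * 5 * 5 * 2), c(2, 4, 5, 5, 2))
  W <- hafnet:::convWeight(2L, 3L, c(3L, 3L, 3L))
  b <- rnorm(3)
  dout <- hafnet:::conv3dForward(x, W, b, c(2, 1, 1), c(1, 1, 1)) * 0 + 1
  dout <- dout * array(rnorm(length(dout)), dim(dout))
  bw <- hafnet:::conv3dBackward(x, W, dout, c(2, 1, 1), c(1, 1, 1))
  f <- function(xx) sum(hafnet:::conv3dForward(xx, W, b, c(2, 1, 1),
                                               c(1, 1, 1)) * dout)
  for (ii in sample(length(x), 5))
    expect_lt(relErr(fdAt(f, x, ii), bw$dx[ii]), 1e-6)

  # batch norm (training mode, gradients through batch statistics)
  xm <- matrix(rnorm(4 * 20), 4, 20)
  g <- runif(4, 0.5, 1.5); be <- rnorm(4)
  run <- list(mean = rep(0, 4), var = rep(1, 4))
  dy <- matrix(rnorm(80), 4, 20)
  fwd <- hafnet:::bnForward(xm, g, be, run, training = TRUE)
  bb <- hafnet:::bnBackward(dy, fwd$cache)
  fb <- function(xx) sum(hafnet:::bnForward(xx, g, be, run,
                                            training = TRUE)$out * dy)
  for (ii in sample(length(xm), 5))
    expect_lt(relErr(fdAt(fb, xm, ii), bb$dx[ii]), 1e-5)

  # channel attention, including the degenerate single-voxel feature map
  for (dims in list(c(4, 2, 3, 3, 2), c(4, 1, 1, 1, 2))) {
    xa <- array(rnorm(prod(dims)), dims)
    W1 <- hafnet:::fcWeight(4L, 2L); b1 <- rnorm(2)
    W2 <- hafnet:::fcWeight(2L, 4L); b2 <- rnorm(4)
    att <- hafnet:::attentionForward(xa, W1, b1, W2, b2)
    da <- array(rnorm(length(att$out)), dim(att$out))
    ab <- hafnet:::attentionBackward(da, att$cache, W1, W2)
    fa <- function(xx) sum(hafnet:::attentionForward(xx, W1, b1, W2,
                                                     b2)$out * da)
    v <- array(rnorm(length(xa)), dims)
    num <- (fa(xa + 1e-6 * v) - fa(xa - 1e-6 * v)) / 2e-6
    expect_lt(relErr(num, sum(ab$dx * v)), 1e-5)
  }
})

test_that("channel attention with zero MLP weights halves the input", {
  x <- array(rnorm(4 * 2 * 3 * 3 * 2), c(4, 2, 3, 3, 2))
  z2 <- matrix(0, 2, 4); z4 <- matrix(0, 4, 2)
  out <- channelAttention(x, z2, rep(0, 2), z4, rep(0, 4))
  expect_equal(out$weights, matrix(0.5, 4, 2))
  expect_equal(out$out, x / 2, tolerance = 1e-12)
})

test_that("channel attention weights are strictly inside (0, 1)", {
  set.seed(15)
  x <- array(rnorm(8 * 2 * 4 * 4 * 3), c(8, 2, 4, 4, 3))
  W1 <- hafnet:::fcWeight(8L, 2L); W2 <- hafnet:::fcWeight(2L, 8L)
  out <- channelAttention(x, W1, rnorm(2), W2, rnorm(8))
  expect_true(all(out$weights > 0 & out$weights < 1))
  expect_error(channelAttention(x, matrix(0, 3, 8), rep(0, 3), t(matrix(0, 3, 8)),
                                rep(0, 8)), "divide")
})

test_that("a two-channel attention block matches a hand computation", {
  x <- array(c(1, 2, 3, 4, 5, 6, 7, 8), c(2, 1, 2, 2, 1))
  W1 <- matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2)
  b1 <- c(0.1, -0.1)
  W2 <- matrix(c(0.2, 0.4, -0.3, 0.6), 2, 2)
  b2 <- c(0, 0.2)
  # by hand: channel 1 holds {1,3,5,7}, channel 2 {2,4,6,8}
  avg <- c(4, 5); mx <- c(7, 8)
  h <- function(v) pmax(W1 %*% v + b1, 0)
  z <- (W2 %*% h(avg) + b2) + (W2 %*% h(mx) + b2)
  s <- 1 / (1 + exp(-z))
  out <- channelAttention(x, W1, b1, W2, b2)
  expect_equal(as.numeric(out$weights), as.numeric(s), tolerance = 1e-12)
  expect_equal(out$out[1, 1, , , 1], x[1, 1, , , 1] * s[1], tolerance = 1e-12)
  expect_equal(out$out[2, 1, , , 1], x[2, 1, , , 1] * s[2], tolerance = 1e-12)
})

test_that("weighted cross-entropy reduces to the unweighted mean at unit weights", {
  set.seed(16)
  logits <- matrix(rnorm(4 * 6), 4, 6)
  y <- sample(4, 6, replace = TRUE)
  ce <- weightedCrossEntropy(logits, y, rep(1, 4))
  p <- apply(logits, 2, function(z) exp(z - max(z)) / sum(exp(z - max(z))))
  expect_equal(ce$loss, mean(-log(p[cbind(y, 1:6)])), tolerance = 1e-9)
  expect_equal(ce$probs, p, tolerance = 1e-12)
  # gradient matches finite differences
  w <- c(2, 1, 0.5, 1)
  cew <- weightedCrossEntropy(logits, y, w)
  f <- function(L) weightedCrossEntropy(L, y, w)$loss
  for (ii in sample(length(logits), 5))
    expect_lt(relErr(fdAt(f, logits, ii), cew$dlogits[ii]), 1e-6)
})
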