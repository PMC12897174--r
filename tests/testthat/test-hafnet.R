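test_that("shape trace reproduces the floor-division arithmetic", {
  cfg <- hafnetConfig()  # 20 bands, 100x100
  tr <- shapeTrace(cfg)
  stem <- tr[tr$layer == "stem_conv", ]
  # bands: floor((20 + 2*2 - 5)/2) + 1 = 10; spatial preserved at 100
  expect_equal(stem$depth, 10L)
  expect_equal(stem$height, 100L)
  expect_equal(stem$channels, 32L)
  pool <- tr[tr$layer == "stem_pool", ]
  expect_equal(c(pool$depth, pool$height, pool$width), c(5L, 50L, 50L))
  last <- tr[nrow(tr), ]
  expect_equal(attr(tr, "flattenWidth"),
               last$channels * last$depth * last$height * last$width)
})

test_that("pathological pooling chains raise an architecture error naming the layer", {
  expect_error(shapeTrace(hafnetConfig(inBands = 2L, patchSize = 4L)),
               "pool")
})

test_that("the fusion head concatenates 512 + 256 = 768 features", {
  cfg <- hafnetConfig(inBands = 8L, patchSize = 16L)
  expect_equal(cfg@hsiProjDim + cfg@mriHiddenDims[2L], 768L)
  m <- buildModel(cfg, seed = 1)
  expect_equal(ncol(m@params$fus.W), 768L)
  expect_equal(nrow(m@params$fus.W), 512L)
})

test_that("forward pass emits one probability per class, summing to one", {
  cfg <- tinyNetConfig()
  m <- buildModel(cfg, seed = 2, classes = c("A2", "A3", "A4"))
  set.seed(2)
  xh <- array(rnorm(8 * 8 * 8 * 4), c(8, 8, 8, 4))
  xm <- matrix(rnorm(7 * 4), 7, 4)
  pr <- predictProbs(m, xh, xm)
  expect_equal(dim(pr), c(3L, 4L))
  expect_equal(colSums(pr), rep(1, 4), tolerance = 1e-6)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("shape trace equals instantiated tensor shapes for random configs", {
  set.seed(3)
  for (rep in 1:8) {
    cfg <- tinyNetConfig(
      inBands = sample(7:12, 1), patchSize = sample(c(8L, 10L, 12L), 1),
      stemOut = sample(c(2L, 4L), 1), block1Out = sample(c(4L, 6L), 1),
      block2Out = sample(c(4L, 8L), 1), attentionReduction = 2L)
    tr <- shapeTrace(cfg)
    m <- buildModel(cfg, seed = rep)
    xh <- array(rnorm(cfg@inBands * cfg@patchSize^2 * 2),
                c(cfg@inBands, cfg@patchSize, cfg@patchSize, 2))
    xm <- matrix(rnorm(cfg@mriInDim * 2), cfg@mriInDim, 2)
    fw <- hafnet:::hafnetForward(cfg, m@params, m@state, xh, xm)
    for (i in seq_len(nrow(tr))) {
      expect_equal(as.integer(fw$shapes[[tr$layer[i]]]),
                   c(tr$channels[i], tr$depth[i], tr$height[i], tr$width[i]),
                   info = sprintf("rep %d layer %s", rep, tr$layer[i]))
    }
  }
})

test_that("permuting a batch permutes the outputs identically", {
  cfg <- tinyNetConfig()
  m <- buildModel(cfg, seed = 4, classes = c("A2", "A3", "A4"))
  set.seed(4)
  xh <- array(rnorm(8 * 8 * 8 * 5), c(8, 8, 8, 5))
  xm <- matrix(rnorm(7 * 5), 7, 5)
  pr <- predictProbs(m, xh, xm)
  perm <- c(3, 1, 5, 2, 4)
  pr2 <- predictProbs(m, xh[, , , perm, drop = FALSE], xm[, perm])
  expect_equal(pr2, pr[, perm], tolerance = 1e-10)
})

test_that("unimodal variants ignore the other modality", {
  set.seed(5)
  xh <- array(rnorm(8 * 8 * 8 * 3), c(8, 8, 8, 3))
  xm1 <- matrix(rnorm(7 * 3), 7, 3)
  xm2 <- matrix(rnorm(7 * 3), 7, 3)
  mh <- buildModel(tinyNetConfig(mode = "hsi_only"), seed = 5,
                   classes = c("A2", "A3", "A4"))
  expect_equal(predictProbs(mh, xh, xm1), predictProbs(mh, xh, xm2))
  mm <- buildModel(tinyNetConfig(mode = "mri_only"), seed = 5,
                   classes = c("A2", "A3", "A4"))
  xh2 <- array(rnorm(length(xh)), dim(xh))
  expect_equal(predictProbs(mm, xh, xm1), predictProbs(mm, xh2, xm1))
})

test_that("residual block with zero conv branch is a pure ReLU shortcut", {
  C <- 4L
  p <- list()
  p[["rb.c1.W"]] <- hafnet:::convWeight(C, C, c(3L, 3L, 3L)) * 0
  p[["rb.c1.b"]] <- rep(0, C)
  p[["rb.bn1.g"]] <- rep(1, C); p[["rb.bn1.b"]] <- rep(0, C)
  p[["rb.c2.W"]] <- hafnet:::convWeight(C, C, c(3L, 3L, 3L)) * 0
  p[["rb.c2.b"]] <- rep(0, C)
  p[["rb.bn2.g"]] <- rep(1, C); p[["rb.bn2.b"]] <- rep(0, C)
  s <- list(rb.bn1 = list(mean = rep(0, C), var = rep(1, C)),
            rb.bn2 = list(mean = rep(0, C), var = rep(1, C)))
  set.seed(6)
  x <- array(rnorm(C * 2 * 4 * 4 * 2), c(C, 2, 4, 4, 2))
  out <- hafnet:::resBlockForward(x, "rb", p, s, training = TRUE)$out
  expect_equal(out, hafnet:::reluForward(x), tolerance = 1e-12)
})

test_that("projection shortcut expands channels", {
  cfg <- tinyNetConfig()
  m <- buildModel(cfg, seed = 7)
  set.seed(7)
  x <- array(rnorm(cfg@stemOut * 2 * 4 * 4 * 2), c(cfg@stemOut, 2, 4, 4, 2))
  out <- hafnet:::resBlockForward(x, "rb1", m@params, m@state, TRUE)$out
  expect_equal(dim(out)[1L], cfg@block1Out)
})

test_that("analytic gradients match finite differences through the whole graph", {
  cfg <- tinyNetConfig(mode = "multimodal")
  m <- buildModel(cfg, seed = 8, classes = c("A2", "A3", "A4"))
  set.seed(8)
  xh <- array(rnorm(8 * 8 * 8 * 3), c(8, 8, 8, 3))
  xm <- matrix(rnorm(7 * 3), 7, 3)
  y <- c(1L, 2L, 3L); w <- c(1.3, 0.9, 0.8)
  lossOf <- function(params) {
    f <- hafnet:::hafnetForward(cfg, params, m@state, xh, xm, training = TRUE)
    weightedCrossEntropy(f$logits, y, w)$loss
  }
  fw <- hafnet:::hafnetForward(cfg, m@params, m@state, xh, xm, training = TRUE)
  ce <- weightedCrossEntropy(fw$logits, y, w)
  gr <- hafnet:::hafnetBackward(cfg, m@params, fw$cache, ce$dlogits)
  set.seed(9)
  for (nm in c("stem.W", "rb1.c2.W", "rb1.bn2.b", "rb2.pj.W", "att.W2",
               "hsi.W", "mri1.W", "fus.W", "out.b")) {
    for (ii in sample(length(m@params[[nm]]), 2)) {
      pp <- m@params
      kd <- attr(pp[[nm]], "kdim")
      pp[[nm]][ii] <- pp[[nm]][ii] + 1e-6
      if (!is.null(kd)) attr(pp[[nm]], "kdim") <- kd
      pm <- m@params
      pm[[nm]][ii] <- pm[[nm]][ii] - 1e-6
      if (!is.null(kd)) attr(pm[[nm]], "kdim") <- kd
      num <- (lossOf(pp) - lossOf(pm)) / 2e-6
      expect_lt(relErr(num, gr[[nm]][ii]) *
                  (abs(num) + abs(gr[[nm]][ii]) > 1e-7), 1e-3)
    }
  }
})

test_that("the network overfits a handful of patches (learnability smoke)", {
  spec <- tinySpec(classPatchCounts = rep(4L, 2L), nClasses = 2L,
                   patientsPerClass = 1L, signatureCenters = list(415, 435),
                   noiseSd = 0.01)
  ds <- generateDataset(spec)
  ids <- patchIds(ds)
  labs <- patchLabels(ds)
  # six patches to memorize, one held-out patch per class for monitoring
  valIds <- c(ids[labs == ds@classes[1L]][1L], ids[labs == ds@classes[2L]][1L])
  sp <- new("SplitPlan", trainIds = setdiff(ids, valIds), valIds = valIds,
            testIds = character(0), foldIndex = 1L, seed = 1L,
            groupOn = "none")
  # default backbone widths; only the input geometry is reduced
  cfg <- hafnetConfig(nClasses = 2L, inBands = 16L, patchSize = 10L,
                      mriInDim = 30L)
  rk <- rankBands(bandSummary(ds@patches), k = 16L, bins = 8L)
  sc <- fitScaler(ds@radiomics)
  tc <- trainConfig(lr = 1e-3, maxEpochs = 30L, batchSize = 4L,
                    augment = FALSE, earlyStopPatience = 30L, seed = 1L)
  fit <- trainModel(buildModel(cfg, seed = 1, classes = ds@classes),
                    ds, sp, tc, ranking = rk, scaler = sc)
  expect_gte(max(fit@history$train_acc), 1.0)
})
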