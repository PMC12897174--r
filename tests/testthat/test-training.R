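test_that("stratified splitting preserves counts and proportions", {
  labels <- rep(GLIOMA_CLASSES, each = 50)
  ids <- sprintf("p%03d", seq_along(labels))
  splits <- makeSplits(labels, ids, ratio = 0.2, nFolds = 5L, seed = 3L)
  expect_length(splits, 5L)
  for (sp in splits) {
    expect_length(sp@testIds, 60L)
    expect_length(sp@valIds, 48L)
    expect_length(sp@trainIds, 192L)
    expect_length(intersect(sp@trainIds, sp@valIds), 0L)
    expect_length(intersect(sp@trainIds, sp@testIds), 0L)
    # per-class balance in every partition
    for (part in list(sp@testIds, sp@valIds, sp@trainIds)) {
      counts <- table(labels[match(part, ids)])
      expect_true(max(counts) - min(counts) <= 1L)
    }
    # test set is fixed across folds
    expect_setequal(sp@testIds, splits[[1L]]@testIds)
  }
  # validation folds partition the training pool
  pool <- setdiff(ids, splits[[1L]]@testIds)
  expect_setequal(unlist(lapply(splits, function(s) s@valIds)), pool)
})

test_that("an 80:20 split of 1931 patches holds out 386 test patches", {
  counts <- c(A2 = 212L, A3 = 302L, A4 = 160L, O2 = 418L, O3 = 343L,
              G4 = 496L)
  labels <- rep(names(counts), counts)
  ids <- sprintf("p%04d", seq_along(labels))
  sp <- makeSplits(labels, ids, ratio = 0.2, nFolds = 5L, seed = 1L)[[1L]]
  expect_true(length(sp@testIds) %in% c(386L, 387L))
})

test_that("degenerate and invalid split requests are handled", {
  labels <- rep(c("A2", "A3"), each = 10)
  ids <- sprintf("p%02d", 1:20)
  one <- makeSplits(labels, ids, nFolds = 1L, seed = 2L)
  expect_length(one, 1L)
  # single stratified train/val split of the 16-patch pool
  expect_length(one[[1L]]@valIds, 4L)
  expect_length(one[[1L]]@trainIds, 12L)
  expect_error(makeSplits(rep(c("A2", "A3"), c(3, 20)),
                          sprintf("q%d", 1:23), nFolds = 5L),
               "fewer than")
})

test_that("grouped splitting never lets a patient span partitions", {
  set.seed(4)
  labels <- rep(GLIOMA_CLASSES, each = 20)
  pids <- paste0(labels, "_pt", rep(rep(1:4, each = 5), 6))
  ids <- sprintf("p%03d", seq_along(labels))
  splits <- makeSplits(labels, ids, nFolds = 3L, seed = 4L,
                       groupOn = "patient", patientIds = pids)
  for (sp in splits) {
    pts <- list(train = unique(pids[match(sp@trainIds, ids)]),
                val = unique(pids[match(sp@valIds, ids)]),
                test = unique(pids[match(sp@testIds, ids)]))
    expect_length(intersect(pts$train, pts$val), 0L)
    expect_length(intersect(pts$train, pts$test), 0L)
    expect_length(intersect(pts$val, pts$test), 0L)
  }
})

test_that("balanced class weights follow N/(K*n_c)", {
  expect_equal(unname(classWeights(c(a = 5, b = 5))), c(1, 1))
  counts <- c(A2 = 212, A3 = 302, A4 = 160, O2 = 418, O3 = 343, G4 = 496)
  w <- classWeights(counts)
  expect_equal(unname(w), unname(1931 / (6 * counts)))
  expect_equal(names(which.max(w)), "A4")  # rarest class, largest weight
  expect_equal(sum(w * counts), 1931)
  expect_equal(unname(classWeights(c(x = 1, y = 3))), c(2, 2 / 3))
  expect_error(classWeights(c(a = 0, b = 3)), "positive")
})

test_that("class balancing resamples to the requested counts", {
  ids <- sprintf("p%02d", 1:15)
  labels <- rep(c("A2", "A3"), c(10, 5))
  expect_identical(balanceClasses(ids[1:10], rep(c("A2", "A3"), each = 5)),
                   ids[1:10])  # already balanced: order-preserving identity
  over <- balanceClasses(ids, labels, mode = "oversample", seed = 5L)
  expect_length(over, 20L)
  expect_true(all(ids %in% over))  # originals all retained
  expect_equal(as.integer(table(labels[match(over, ids)])), c(10L, 10L))
  under <- balanceClasses(ids, labels, mode = "undersample", seed = 5L)
  expect_equal(as.integer(table(labels[match(under, ids)])), c(5L, 5L))
  tgt <- balanceClasses(ids, labels, mode = "target", targetCount = 7L,
                        seed = 5L)
  expect_equal(as.integer(table(labels[match(tgt, ids)])), c(7L, 7L))
  expect_error(balanceClasses(ids, labels, mode = "target", targetCount = 0L),
               "positive")
})

test_that("augmentation preserves shape, labels and the rotation group", {
  ds <- generateDataset(tinySpec(classPatchCounts = rep(2L, 6L),
                                 patientsPerClass = 1L))
  p <- ds@patches[[1L]]
  # identity draw: no flips, no rotation, unit brightness
  same <- augmentPatch(p, flips = FALSE, rotations = FALSE,
                       brightnessRange = c(1, 1), seed = 1L)
  expect_equal(same@values, p@values, tolerance = 1e-12)
  expect_equal(same@label, p@label)

  # four successive quarter turns restore the original
  r <- p@values
  for (i in 1:4) r <- aperm(r, c(1L, 3L, 2L))[, , dim(r)[2L]:1, drop = FALSE]
  expect_equal(r, p@values, tolerance = 1e-12)

  # a pure brightness draw scales each band's spatial mean exactly
  f <- 1.13
  bright <- augmentPatch(p, flips = FALSE, rotations = FALSE,
                         brightnessRange = c(f, f), seed = 2L)
  expect_equal(rowMeans(matrix(bright@values, nrow = nBands(p))),
               f * rowMeans(matrix(p@values, nrow = nBands(p))),
               tolerance = 1e-12)

  # augmented draws keep the spatial multiset of every band
  aug <- augmentPatch(p, brightnessRange = NULL, seed = 3L)
  expect_equal(dim(aug@values), dim(p@values))
  expect_equal(sort(aug@values[3L, , ]), sort(p@values[3L, , ]),
               tolerance = 1e-12)

  ns <- p
  ns@values <- p@values[, , 1:5, drop = FALSE]
  ns@wavelengths <- p@wavelengths
  expect_error(augmentPatch(ns), "square")
})

test_that("training is seed-deterministic and records a sane schedule", {
  spec <- tinySpec(classPatchCounts = rep(6L, 2L), nClasses = 2L,
                   patientsPerClass = 2L,
                   signatureCenters = list(415, 435))
  ds <- generateDataset(spec)
  sp <- makeSplits(patchLabels(ds), patchIds(ds), nFolds = 2L,
                   seed = 1L)[[1L]]
  ids <- patchIds(ds)
  rk <- rankBands(bandSummary(ds@patches[match(sp@trainIds, ids)]), k = 16L,
                  bins = 8L, forbiddenIds = c(sp@valIds, sp@testIds))
  sc <- fitScaler(ds@radiomics[unique(patientIds(ds)[ids %in% sp@trainIds]),
                               , drop = FALSE])
  cfg <- hafnetConfig(nClasses = 2L, inBands = 16L, patchSize = 10L,
                      stemOut = 4L, block1Out = 4L, block2Out = 8L,
                      attentionReduction = 2L, hsiProjDim = 16L,
                      mriInDim = 30L, mriHiddenDims = c(12L, 6L),
                      fusionDim = 16L)
  tc <- trainConfig(lr = 1e-3, maxEpochs = 6L, batchSize = 4L,
                    earlyStopPatience = 6L, seed = 9L)
  m <- buildModel(cfg, seed = 9L, classes = ds@classes)
  fit1 <- trainModel(m, ds, sp, tc, ranking = rk, scaler = sc)
  fit2 <- trainModel(m, ds, sp, tc, ranking = rk, scaler = sc)
  expect_identical(fit1@history, fit2@history)
  expect_identical(fit1@params, fit2@params)
  # learning rate never increases, and changes only by the scheduler factor
  lr <- fit1@history$lr
  steps <- lr[-1] / lr[-length(lr)]
  expect_true(all(steps %in% c(1, tc$schedulerFactor)))
  expect_true(all(c("epoch", "lr", "train_loss", "train_acc", "val_loss",
                    "val_acc") %in% names(fit1@history)))
})

test_that("an uninformative input drives the loss to the entropy floor", {
  # two balanced classes with identical flat patches and pure-noise
  # radiomics: the best achievable loss is log 2
  spec <- tinySpec(classPatchCounts = rep(8L, 2L), nClasses = 2L,
                   patientsPerClass = 2L, noiseSd = 0, textureAmplitude = 0,
                   signatureDepths = 0, radiomicsEffectSize = 0)
  ds <- generateDataset(spec)
  sp <- makeSplits(patchLabels(ds), patchIds(ds), nFolds = 2L,
                   seed = 2L)[[1L]]
  cfg <- hafnetConfig(nClasses = 2L, inBands = 24L, patchSize = 10L,
                      stemOut = 4L, block1Out = 4L, block2Out = 8L,
                      attentionReduction = 2L, hsiProjDim = 16L,
                      mriInDim = 30L, mriHiddenDims = c(12L, 6L),
                      fusionDim = 16L, mode = "hsi_only")
  tc <- trainConfig(lr = 1e-3, maxEpochs = 10L, batchSize = 4L,
                    earlyStopPatience = 10L, augment = FALSE, seed = 2L)
  fit <- trainModel(buildModel(cfg, seed = 2L, classes = ds@classes), ds, sp,
                    tc)
  expect_lt(abs(min(fit@history$val_loss) - log(2)), 0.2)
})
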