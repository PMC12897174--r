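#' Stratified train/test split with cross-validation folds
#'
#' First draws a stratified test split (per-class rounding of
#' `ratio * n_c`), then partitions the remaining pool into `nFolds`
#' stratified folds; fold k's validation set is the k-th part and its
#' training set the rest. The test set is identical across folds. With
#' `groupOn = "patient"` whole patients are allocated instead of patches,
#' so no patient spans two sets (at the cost of looser stratification).
#'
#' @param labels class label per patch.
#' @param ids patch ids, same length as `labels`.
#' @param ratio test fraction in (0,1) (default 0.2).
#' @param nFolds number of folds (default 5); 1 degenerates to a single
#'   train/validation split (the last fifth, stratified, becomes validation).
#' @param seed RNG seed.
#' @param groupOn `"none"` (patch-level, default) or `"patient"`.
#' @param patientIds patient per patch (required for grouped splitting).
#' @return list of [SplitPlan-class], one per fold.
#' @export
makeSplits <- function(labels, ids, ratio = 0.2, nFolds = 5L, seed = 1L,
                       groupOn = c("none", "patient"), patientIds = NULL) {
  groupOn <- match.arg(groupOn)
  stopifnot(length(labels) == length(ids), ratio > 0, ratio < 1)
  nFolds <- as.integer(nFolds)
  counts <- table(labels)
  if (any(counts < nFolds))
    stop(sprintf("makeSplits: class '%s' has %d patches, fewer than %d folds",
                 names(counts)[which.min(counts)], min(counts), nFolds))
  withSeed(seed, {
    testIds <- character(0)
    foldOf <- setNames(integer(length(ids)), ids)
    for (cl in names(counts)) {
      clIds <- ids[labels == cl]
      if (groupOn == "patient") {
        stopifnot(!is.null(patientIds))
        clPts <- patientIds[labels == cl]
        pts <- sample(unique(clPts))
        byPt <- split(clIds, clPts)[as.character(pts)]
        nTest <- round(ratio * length(clIds))
        taken <- 0L; ti <- character(0); rest <- list()
        for (g in byPt) {
          if (taken < nTest) { ti <- c(ti, g); taken <- taken + length(g) }
          else rest[[length(rest) + 1L]] <- g
        }
        testIds <- c(testIds, ti)
        for (i in seq_along(rest))
          foldOf[rest[[i]]] <- ((i - 1L) %% max(nFolds, 1L)) + 1L
      } else {
        clIds <- sample(clIds)
        nTest <- round(ratio * length(clIds))
        testIds <- c(testIds, clIds[seq_len(nTest)])
        pool <- clIds[-seq_len(nTest)]
        if (nFolds == 1L && length(pool)) {
          # degenerate case: one stratified train/validation split of the
          # pool, reusing `ratio` as the validation fraction
          nVal <- max(1L, round(ratio * length(pool)))
          foldOf[pool[seq_len(nVal)]] <- 1L
          foldOf[pool[-seq_len(nVal)]] <- 2L
        } else if (length(pool)) {
          foldOf[pool] <- ((seq_along(pool) - 1L) %% nFolds) + 1L
        }
      }
    }
    lapply(seq_len(max(nFolds, 1L)), function(f) {
      valIds <- names(foldOf)[foldOf == f]
      trainIds <- names(foldOf)[foldOf != f & foldOf > 0L]
      new("SplitPlan", trainIds = trainIds, valIds = valIds,
          testIds = testIds, foldIndex = as.integer(f),
          seed = as.integer(seed), groupOn = groupOn)
    })
  })
}

#' Balanced class weights for the weighted cross-entropy loss
#'
#' `w_c = N_total / (K * n_c)`, so the weighted count `sum_c w_c n_c`
#' equals `N_total` and equal counts give unit weights; the rarest class
#' receives the largest weight.
#'
#' @param classCounts named positive counts per class.
#' @return named weight vector.
#' @export
classWeights <- function(classCounts) {
  if (any(classCounts <= 0))
    stop("classWeights: every class must have a positive count")
  n <- sum(classCounts)
  K <- length(classCounts)
  setNames(n / (K * as.numeric(classCounts)), names(classCounts))
}

#' Equalize per-class counts by seeded resampling
#'
#' Oversampling resamples with replacement up to the majority count
#' (retaining every original), undersampling samples down to the minority
#' count, and `target` resamples every class to a fixed count. An already
#' balanced input at the implied target is returned unchanged
#' (order-preserving).
#'
#' @param ids patch ids.
#' @param labels class labels, same length.
#' @param mode `"oversample"`, `"undersample"` or `"target"`.
#' @param targetCount per-class count for `mode = "target"`.
#' @param seed RNG seed.
#' @return character vector of resampled ids.
#' @export
balanceClasses <- function(ids, labels,
                           mode = c("oversample", "undersample", "target"),
                           targetCount = NULL, seed = 1L) {
  mode <- match.arg(mode)
  counts <- table(labels)
  target <- switch(mode,
    oversample = max(counts),
    undersample = min(counts),
    target = {
      if (is.null(targetCount) || targetCount < 1)
        stop("balanceClasses: targetCount must be a positive count")
      as.integer(targetCount)
    })
  if (all(counts == target)) return(ids)
  withSeed(seed, {
    out <- character(0)
    for (cl in names(counts)) {
      clIds <- ids[labels == cl]
      n <- length(clIds)
      res <- if (n == target) clIds
      else if (n < target) c(clIds, sample(clIds, target - n, replace = TRUE))
      else sample(clIds, target, replace = FALSE)
      out <- c(out, res)
    }
    out
  })
}

# one random spatial/brightness transform on a (bands, p, p) array;
# spatial ops are applied identically to every band so spectral
# registration is preserved
augmentArray <- function(x, flips = TRUE, rotations = TRUE,
                         brightnessRange = c(0.8, 1.2)) {
  p <- dim(x)[2L]
  if (flips) {
    if (runif(1) < 0.5) x <- x[, , p:1, drop = FALSE]
    if (runif(1) < 0.5) x <- x[, p:1, , drop = FALSE]
  }
  if (rotations) {
    k <- sample(0:3, 1L)
    for (i in seq_len(k))
      x <- aperm(x, c(1L, 3L, 2L))[, , p:1, drop = FALSE]
  }
  if (!is.null(brightnessRange)) {
    f <- runif(1, brightnessRange[1L], brightnessRange[2L])
    x <- x * f
  }
  x
}

#' Randomly augment a patch
#'
#' Draws one transform: independent horizontal/vertical flips, a multiple
#' of 90 degrees rotation applied identically to every band, and a global
#' brightness factor drawn uniformly from `brightnessRange`. Label, patient
#' and shape are unchanged.
#'
#' @param patch an [HSIPatch-class] (square).
#' @param flips,rotations enable the spatial transforms.
#' @param brightnessRange two-element range of the brightness multiplier,
#'   or NULL to disable.
#' @param seed optional seed for a reproducible draw.
#' @return the augmented [HSIPatch-class].
#' @export
augmentPatch <- function(patch, flips = TRUE, rotations = TRUE,
                         brightnessRange = c(0.8, 1.2), seed = NULL) {
  stopifnot(is(patch, "HSIPatch"))
  d <- dim(patch@values)
  if (rotations && d[2L] != d[3L])
    stop("augmentPatch: 90-degree rotation requires a square patch")
  vals <- withSeed(seed, augmentArray(patch@values, flips, rotations,
                                      brightnessRange))
  new("HSIPatch", values = vals, wavelengths = patch@wavelengths,
      label = patch@label, patientId = patch@patientId,
      patchId = patch@patchId, origin = patch@origin)
}

#' Training hyperparameters
#'
#' Defaults follow the reference optimization recipe: Adam at learning rate
#' 1e-4 with weight decay 1e-4, learning-rate halving on a validation-loss
#' plateau (factor 0.5, patience 5), early stopping after 5 epochs without
#' validation-loss improvement, at most 100 epochs, batch size 16, and
#' on-the-fly augmentation of training batches.
#'
#' @param lr learning rate.
#' @param weightDecay L2 penalty added to the gradients.
#' @param schedulerFactor,schedulerPatience plateau scheduler parameters.
#' @param earlyStopPatience epochs without improvement before stopping.
#' @param maxEpochs epoch cap.
#' @param batchSize minibatch size.
#' @param augment apply random flips/rotations/brightness to training
#'   batches.
#' @param brightnessRange brightness-multiplier range.
#' @param stopAccuracy optional: stop as soon as validation accuracy
#'   reaches this value (used by the fast reduced-scale experiments).
#' @param seed RNG seed governing shuffling, augmentation and dropout.
#' @param verbose print per-epoch progress.
#' @return a named list of validated settings.
#' @export
trainConfig <- function(lr = 1e-4, weightDecay = 1e-4, schedulerFactor = 0.5,
                        schedulerPatience = 5L, earlyStopPatience = 5L,
                        maxEpochs = 100L, batchSize = 16L, augment = TRUE,
                        brightnessRange = c(0.8, 1.2), stopAccuracy = NULL,
                        seed = 1L, verbose = FALSE) {
  stopifnot(lr > 0, schedulerFactor > 0, schedulerFactor < 1,
            schedulerPatience >= 1, earlyStopPatience >= 1, maxEpochs >= 1,
            batchSize >= 1)
  list(lr = lr, weightDecay = weightDecay, schedulerFactor = schedulerFactor,
       schedulerPatience = as.integer(schedulerPatience),
       earlyStopPatience = as.integer(earlyStopPatience),
       maxEpochs = as.integer(maxEpochs), batchSize = as.integer(batchSize),
       augment = augment, brightnessRange = brightnessRange,
       stopAccuracy = stopAccuracy, seed = as.integer(seed),
       verbose = verbose)
}

#' Assemble network input tensors for a set of patches
#'
#' Applies the band selection to each patch, stacks the patch arrays into a
#' `(bands, size, size, N)` tensor, standardizes each patch's patient
#' radiomic vector with the fitted scaler (every patch of a patient
#' receives that patient's single vector), and encodes labels as indices
#' into the dataset's class alphabet.
#'
#' @param dataset a [GliomaDataset-class].
#' @param ids patch ids to assemble, in order.
#' @param ranking optional [WavelengthRanking-class] band selection.
#' @param scaler optional [FeatureScaler-class] for the radiomics.
#' @return list with `xhsi`, `xmri`, `yIdx`, `labels`, `ids`.
#' @export
assembleTensors <- function(dataset, ids, ranking = NULL, scaler = NULL) {
  idx <- match(ids, patchIds(dataset))
  if (anyNA(idx))
    stop("assembleTensors: unknown patch id(s): ",
         paste(head(ids[is.na(idx)], 3), collapse = ", "))
  patches <- dataset@patches[idx]
  if (!is.null(ranking))
    patches <- lapply(patches, applySelection, ranking = ranking)
  d <- dim(patches[[1L]]@values)
  xhsi <- array(0, dim = c(d, length(patches)))
  for (i in seq_along(patches)) xhsi[, , , i] <- patches[[i]]@values
  pids <- vapply(patches, function(p) p@patientId, character(1))
  xmri <- dataset@radiomics[pids, , drop = FALSE]
  if (!is.null(scaler)) xmri <- applyScaler(scaler, xmri)
  labels <- vapply(patches, function(p) p@label, character(1))
  list(xhsi = xhsi, xmri = t(xmri), yIdx = match(labels, dataset@classes),
       labels = labels, ids = ids)
}

# batched inference returning probs (K x N), loss and accuracy
evalOnSet <- function(config, params, state, xhsi, xmri, yIdx, weights,
                      batchSize = 32L) {
  N <- length(yIdx)
  K <- config@nClasses
  probs <- matrix(0, K, N)
  loss <- 0; wsum <- 0
  for (start in seq(1L, N, by = batchSize)) {
    sel <- start:min(start + batchSize - 1L, N)
    fw <- hafnetForward(config, params, state,
                        if (config@mode != "mri_only")
                          xhsi[, , , sel, drop = FALSE] else NULL,
                        if (config@mode != "hsi_only")
                          xmri[, sel, drop = FALSE] else NULL,
                        training = FALSE)
    ce <- weightedCrossEntropy(fw$logits, yIdx[sel], weights)
    probs[, sel] <- ce$probs
    wi <- sum(weights[yIdx[sel]])
    loss <- loss + ce$loss * wi
    wsum <- wsum + wi
  }
  pred <- apply(probs, 2L, which.max)
  list(probs = probs, loss = loss / wsum, accuracy = mean(pred == yIdx))
}

#' Train a network on one fold
#'
#' End-to-end optimization of the weighted cross-entropy with Adam,
#' learning-rate halving when the validation loss plateaus, and early
#' stopping. Training batches are augmented on the fly; validation is
#' evaluated in inference mode each epoch. Returns the best-validation-loss
#' checkpoint with the full per-epoch history, and stores the band ranking
#' and feature scaler in the checkpoint so inference is self-contained.
#' Fully deterministic for a fixed configuration and seed.
#'
#' @param model an untrained [HAFNetModel-class].
#' @param dataset a [GliomaDataset-class].
#' @param split a [SplitPlan-class]; training uses `trainIds`, monitoring
#'   uses `valIds`.
#' @param config a [trainConfig()] list.
#' @param ranking band selection fitted on this fold's training patches.
#' @param scaler radiomic scaler fitted on this fold's training patients.
#' @return the trained [HAFNetModel-class] with `@history` filled.
#' @export
trainModel <- function(model, dataset, split, config = trainConfig(),
                       ranking = NULL, scaler = NULL) {
  stopifnot(is(model, "HAFNetModel"), is(split, "SplitPlan"))
  mode <- model@config@mode
  tr <- assembleTensors(dataset, split@trainIds, ranking, scaler)
  va <- assembleTensors(dataset, split@valIds, ranking, scaler)
  counts <- table(factor(tr$labels, levels = dataset@classes))
  weights <- classWeights(counts)

  withSeed(config$seed, {
    params <- model@params
    state <- model@state
    opt <- adamInit(params)
    lr <- config$lr
    best <- list(loss = Inf, params = params, state = state)
    histRows <- list()
    stagnantSched <- 0L; stagnantStop <- 0L
    N <- length(tr$ids)

    for (epoch in seq_len(config$maxEpochs)) {
      ord <- sample.int(N)
      epochLoss <- 0; epochCorrect <- 0L
      for (start in seq(1L, N, by = config$batchSize)) {
        sel <- ord[start:min(start + config$batchSize - 1L, N)]
        xh <- NULL; xm <- NULL
        if (mode != "mri_only") {
          xh <- tr$xhsi[, , , sel, drop = FALSE]
          if (config$augment) {
            for (i in seq_along(sel)) {
              xh[, , , i] <- augmentArray(
                xh[, , , i, drop = TRUE],
                brightnessRange = config$brightnessRange)
            }
          }
        }
        if (mode != "hsi_only") xm <- tr$xmri[, sel, drop = FALSE]
        fw <- hafnetForward(model@config, params, state, xh, xm,
                            training = TRUE)
        state <- fw$state
        ce <- weightedCrossEntropy(fw$logits, tr$yIdx[sel], weights)
        if (!is.finite(ce$loss))
          stop(sprintf(
            "trainModel: non-finite loss at epoch %d, batch starting %d (ids %s...)",
            epoch, start, paste(head(tr$ids[sel], 3), collapse = ", ")))
        grads <- hafnetBackward(model@config, params, fw$cache, ce$dlogits)
        step <- adamStep(params, grads, opt, lr,
                         weightDecay = config$weightDecay)
        params <- step$params
        opt <- step$state
        epochLoss <- epochLoss + ce$loss * length(sel)
        epochCorrect <- epochCorrect +
          sum(apply(ce$probs, 2L, which.max) == tr$yIdx[sel])
      }
      ev <- evalOnSet(model@config, params, state, va$xhsi, va$xmri,
                      va$yIdx, weights)
      histRows[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, train_loss = epochLoss / N,
        train_acc = epochCorrect / N, val_loss = ev$loss,
        val_acc = ev$accuracy)
      if (config$verbose)
        message(sprintf(
          "epoch %3d  lr %.2e  train %.4f/%.3f  val %.4f/%.3f", epoch, lr,
          epochLoss / N, epochCorrect / N, ev$loss, ev$accuracy))

      if (ev$loss < best$loss - 1e-8) {
        best <- list(loss = ev$loss, params = params, state = state)
        stagnantSched <- 0L; stagnantStop <- 0L
      } else {
        stagnantSched <- stagnantSched + 1L
        stagnantStop <- stagnantStop + 1L
        if (stagnantSched >= config$schedulerPatience) {
          lr <- lr * config$schedulerFactor
          stagnantSched <- 0L
        }
      }
      if (!is.null(config$stopAccuracy) &&
          ev$accuracy >= config$stopAccuracy) break
      if (stagnantStop >= config$earlyStopPatience) break
    }
    out <- model
    out@params <- best$params
    out@state <- best$state
    out@history <- do.call(rbind, histRows)
    out@extras <- list(ranking = ranking, scaler = scaler,
                       classWeights = weights, split = split)
    out
  })
}
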