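#' HAFNetConfig: architecture hyperparameters
#'
#' The attention-fusion network consumes spectral patches as 5D tensors
#' (batch, 1 channel, selected bands, height, width) and per-patient
#' radiomic vectors. The convolutional backbone is fixed by construction:
#' a stem 3D convolution with kernel (5,3,3), stride (2,1,1) and padding
#' (2,1,1) into `stemOut` channels followed by (2,2,2) max pooling; a
#' residual block to `block1Out` channels with (2,2,2) pooling; a residual
#' block to `block2Out` channels with (1,2,2) pooling; channel attention;
#' then flatten. The fusion head projects HSI features to `hsiProjDim`,
#' reduces radiomics through two FC layers to `mriHiddenDims[2]`,
#' concatenates, and maps through a fusion FC layer with dropout to the
#' class logits.
#'
#' @slot nClasses number of output classes.
#' @slot inBands number of (selected) spectral bands of the input.
#' @slot patchSize spatial input edge (pixels).
#' @slot stemOut,block1Out,block2Out channel widths of the backbone.
#' @slot attentionReduction bottleneck ratio of the channel attention.
#' @slot hsiProjDim width of the flattened-HSI projection.
#' @slot mriInDim radiomic input width.
#' @slot mriHiddenDims the two FC widths of the radiomic branch.
#' @slot fusionDim width of the fusion FC layer.
#' @slot dropout dropout rate before the classifier.
#' @slot mode `"multimodal"`, `"hsi_only"` or `"mri_only"`.
#' @export
setClass("HAFNetConfig",
  representation(nClasses = "integer", inBands = "integer",
                 patchSize = "integer", stemOut = "integer",
                 block1Out = "integer", block2Out = "integer",
                 attentionReduction = "integer", hsiProjDim = "integer",
                 mriInDim = "integer", mriHiddenDims = "integer",
                 fusionDim = "integer", dropout = "numeric",
                 mode = "character")
)

setValidity("HAFNetConfig", function(object) {
  dims <- c(object@nClasses, object@inBands, object@patchSize,
            object@stemOut, object@block1Out, object@block2Out,
            object@hsiProjDim, object@mriInDim, object@mriHiddenDims,
            object@fusionDim)
  if (any(dims < 1L)) return("all dimensions must be positive")
  if (!object@mode %in% c("multimodal", "hsi_only", "mri_only"))
    return("mode must be multimodal, hsi_only or mri_only")
  if (object@block2Out %% object@attentionReduction != 0L)
    return(sprintf("attention reduction %d must divide the attended channel count %d",
                   object@attentionReduction, object@block2Out))
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must lie in [0, 1)")
  if (length(object@mriHiddenDims) != 2L)
    return("mriHiddenDims must give exactly two FC widths")
  TRUE
})

setMethod("show", "HAFNetConfig", function(object) {
  cat(sprintf(
    "HAFNetConfig (%s): %d bands x %dx%d -> %d/%d/%d ch, attention 1/%d, proj %d; MRI %d -> %s; fusion %d -> %d classes\n",
    object@mode, object@inBands, object@patchSize, object@patchSize,
    object@stemOut, object@block1Out, object@block2Out,
    object@attentionReduction, object@hsiProjDim, object@mriInDim,
    paste(object@mriHiddenDims, collapse = "/"), object@fusionDim,
    object@nClasses))
})

#' Build an architecture configuration
#'
#' @param nClasses number of classes (default 6).
#' @param inBands selected spectral bands (default 20).
#' @param patchSize spatial edge in pixels (default 100).
#' @param stemOut,block1Out,block2Out backbone channel widths
#'   (defaults 32/64/128).
#' @param attentionReduction channel-attention bottleneck ratio (default 16).
#' @param hsiProjDim HSI projection width (default 512).
#' @param mriInDim radiomic input width (default 5650).
#' @param mriHiddenDims the two radiomic FC widths (default 1024, 256).
#' @param fusionDim fusion FC width (default 512).
#' @param dropout dropout rate (default 0.3).
#' @param mode `"multimodal"` (default), `"hsi_only"` or `"mri_only"`.
#' @return a validated [HAFNetConfig-class].
#' @export
hafnetConfig <- function(nClasses = 6L, inBands = 20L, patchSize = 100L,
                         stemOut = 32L, block1Out = 64L, block2Out = 128L,
                         attentionReduction = 16L, hsiProjDim = 512L,
                         mriInDim = 5650L, mriHiddenDims = c(1024L, 256L),
                         fusionDim = 512L, dropout = 0.3,
                         mode = c("multimodal", "hsi_only", "mri_only")) {
  mode <- match.arg(mode)
  new("HAFNetConfig", nClasses = as.integer(nClasses),
      inBands = as.integer(inBands), patchSize = as.integer(patchSize),
      stemOut = as.integer(stemOut), block1Out = as.integer(block1Out),
      block2Out = as.integer(block2Out),
      attentionReduction = as.integer(attentionReduction),
      hsiProjDim = as.integer(hsiProjDim), mriInDim = as.integer(mriInDim),
      mriHiddenDims = as.integer(mriHiddenDims),
      fusionDim = as.integer(fusionDim), dropout = dropout, mode = mode)
}

convOutDim <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

#' Shape trace: pure arithmetic propagation through the backbone
#'
#' Propagates (channels, depth, height, width) through the configured
#' convolution/pooling chain by floor-division arithmetic alone — no tensor
#' is allocated — and reports every intermediate shape plus the flattened
#' feature width. A configuration whose pooling chain drives any dimension
#' to zero is an architecture error naming the offending layer.
#'
#' @param config a [HAFNetConfig-class].
#' @return data.frame with columns `layer, channels, depth, height, width`
#'   and attribute `flattenWidth`.
#' @export
shapeTrace <- function(config) {
  validObject(config)
  rows <- list()
  addRow <- function(layer, c, d, h, w) {
    if (any(c(d, h, w) < 1L))
      stop(sprintf("shapeTrace: layer '%s' has empty output (%d x %d x %d)",
                   layer, d, h, w))
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = layer, channels = c, depth = d, height = h, width = w,
      stringsAsFactors = FALSE)
  }
  d <- config@inBands; h <- config@patchSize; w <- config@patchSize
  addRow("input", 1L, d, h, w)
  d <- convOutDim(d, 5L, 2L, 2L)
  h <- convOutDim(h, 3L, 1L, 1L)
  w <- convOutDim(w, 3L, 1L, 1L)
  addRow("stem_conv", config@stemOut, d, h, w)
  d <- d %/% 2L; h <- h %/% 2L; w <- w %/% 2L
  addRow("stem_pool", config@stemOut, d, h, w)
  addRow("resblock1", config@block1Out, d, h, w)
  d <- d %/% 2L; h <- h %/% 2L; w <- w %/% 2L
  addRow("pool1", config@block1Out, d, h, w)
  addRow("resblock2", config@block2Out, d, h, w)
  h <- h %/% 2L; w <- w %/% 2L
  addRow("pool2", config@block2Out, d, h, w)
  addRow("attention", config@block2Out, d, h, w)
  out <- do.call(rbind, rows)
  attr(out, "flattenWidth") <- config@block2Out * d * h * w
  out
}

#' HAFNetModel: a built (optionally trained) network
#'
#' @slot config the [HAFNetConfig-class].
#' @slot params named list of weight matrices/vectors.
#' @slot state named list of batch-norm running statistics.
#' @slot classes class labels, in logit order.
#' @slot history per-epoch training history (empty before training).
#' @slot extras checkpoint companions: the band ranking and feature scaler
#'   the model was trained with, so inference is self-contained.
#' @export
setClass("HAFNetModel",
  representation(config = "HAFNetConfig", params = "list", state = "list",
                 classes = "character", history = "data.frame",
                 extras = "list"),
  prototype(history = data.frame(), extras = list())
)

setMethod("show", "HAFNetModel", function(object) {
  npar <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf("HAFNetModel (%s): %s parameters, %s\n", object@config@mode,
              format(npar, big.mark = ","),
              if (nrow(object@history)) sprintf("trained %d epochs",
                                                max(object@history$epoch))
              else "untrained"))
})

bnPair <- function(n) list(mean = rep(0, n), var = rep(1, n))

#' Assemble an untrained network
#'
#' Allocates and initializes all weights (Kaiming-uniform for convolutions
#' and FC layers, batch norm at gamma 1 / beta 0) for the configured mode.
#' The flatten width is computed by [shapeTrace()], never assumed.
#'
#' @param config a [HAFNetConfig-class].
#' @param seed RNG seed for the initialization.
#' @param classes class labels in logit order.
#' @return an untrained [HAFNetModel-class].
#' @export
buildModel <- function(config, seed = 1L,
                       classes = GLIOMA_CLASSES[seq_len(config@nClasses)]) {
  validObject(config)
  tr <- shapeTrace(config)
  flat <- attr(tr, "flattenWidth")
  withSeed(seed, {
    p <- list()
    s <- list()
    if (config@mode != "mri_only") {
      p$stem.W <- convWeight(1L, config@stemOut, c(5L, 3L, 3L))
      p$stem.b <- rep(0, config@stemOut)
      p$bn0.g <- rep(1, config@stemOut); p$bn0.b <- rep(0, config@stemOut)
      s$bn0 <- bnPair(config@stemOut)
      for (blk in list(list(pfx = "rb1", cin = config@stemOut,
                            cout = config@block1Out),
                       list(pfx = "rb2", cin = config@block1Out,
                            cout = config@block2Out))) {
        p[[paste0(blk$pfx, ".c1.W")]] <- convWeight(blk$cin, blk$cout, c(3L, 3L, 3L))
        p[[paste0(blk$pfx, ".c1.b")]] <- rep(0, blk$cout)
        p[[paste0(blk$pfx, ".bn1.g")]] <- rep(1, blk$cout)
        p[[paste0(blk$pfx, ".bn1.b")]] <- rep(0, blk$cout)
        p[[paste0(blk$pfx, ".c2.W")]] <- convWeight(blk$cout, blk$cout, c(3L, 3L, 3L))
        p[[paste0(blk$pfx, ".c2.b")]] <- rep(0, blk$cout)
        p[[paste0(blk$pfx, ".bn2.g")]] <- rep(1, blk$cout)
        p[[paste0(blk$pfx, ".bn2.b")]] <- rep(0, blk$cout)
        p[[paste0(blk$pfx, ".pj.W")]] <- convWeight(blk$cin, blk$cout, c(1L, 1L, 1L))
        p[[paste0(blk$pfx, ".pj.b")]] <- rep(0, blk$cout)
        p[[paste0(blk$pfx, ".bnp.g")]] <- rep(1, blk$cout)
        p[[paste0(blk$pfx, ".bnp.b")]] <- rep(0, blk$cout)
        s[[paste0(blk$pfx, ".bn1")]] <- bnPair(blk$cout)
        s[[paste0(blk$pfx, ".bn2")]] <- bnPair(blk$cout)
        s[[paste0(blk$pfx, ".bnp")]] <- bnPair(blk$cout)
      }
      cr <- config@block2Out %/% config@attentionReduction
      p$att.W1 <- fcWeight(config@block2Out, cr); p$att.b1 <- rep(0, cr)
      p$att.W2 <- fcWeight(cr, config@block2Out)
      p$att.b2 <- rep(0, config@block2Out)
      p$hsi.W <- fcWeight(flat, config@hsiProjDim)
      p$hsi.b <- rep(0, config@hsiProjDim)
      p$hbn.g <- rep(1, config@hsiProjDim); p$hbn.b <- rep(0, config@hsiProjDim)
      s$hbn <- bnPair(config@hsiProjDim)
    }
    if (config@mode != "hsi_only") {
      h1 <- config@mriHiddenDims[1L]; h2 <- config@mriHiddenDims[2L]
      p$mri1.W <- fcWeight(config@mriInDim, h1); p$mri1.b <- rep(0, h1)
      p$mbn1.g <- rep(1, h1); p$mbn1.b <- rep(0, h1)
      p$mri2.W <- fcWeight(h1, h2); p$mri2.b <- rep(0, h2)
      p$mbn2.g <- rep(1, h2); p$mbn2.b <- rep(0, h2)
      s$mbn1 <- bnPair(h1); s$mbn2 <- bnPair(h2)
    }
    headIn <- switch(config@mode,
      multimodal = config@fusionDim,
      hsi_only = config@hsiProjDim,
      mri_only = config@mriHiddenDims[2L])
    if (config@mode == "multimodal") {
      concatDim <- config@hsiProjDim + config@mriHiddenDims[2L]
      p$fus.W <- fcWeight(concatDim, config@fusionDim)
      p$fus.b <- rep(0, config@fusionDim)
      p$fbn.g <- rep(1, config@fusionDim); p$fbn.b <- rep(0, config@fusionDim)
      s$fbn <- bnPair(config@fusionDim)
    }
    p$out.W <- fcWeight(headIn, config@nClasses)
    p$out.b <- rep(0, config@nClasses)
    new("HAFNetModel", config = config, params = p, state = s,
        classes = classes)
  })
}

#' Channel attention as a standalone operation
#'
#' Reweights the channels of a 5D feature block
#' (channels, depth, height, width, batch) by squeeze-and-excitation
#' weights computed from global average- and max-pooled descriptors passed
#' through a shared bottleneck MLP and a sigmoid.
#'
#' @param features 5D numeric array.
#' @param W1,b1,W2,b2 shared MLP weights: `W1` is `(C/r) x C`, `W2` is
#'   `C x (C/r)`.
#' @return list with `out` (reweighted features, same shape) and `weights`
#'   (the `C x batch` sigmoid channel weights, all strictly in (0, 1)).
#' @export
channelAttention <- function(features, W1, b1, W2, b2) {
  stopifnot(length(dim(features)) == 5L)
  if (nrow(W1) < 1L || dim(features)[1L] %% nrow(W1) != 0L)
    stop(sprintf("channelAttention: reduction %d does not divide %d channels",
                 nrow(W1), dim(features)[1L]))
  f <- attentionForward(features, W1, b1, W2, b2)
  list(out = f$out, weights = f$cache$s)
}

## ---- forward / backward over the full graph --------------------------------

resBlockForward <- function(x, pfx, p, s, training) {
  g <- function(nm) p[[paste0(pfx, ".", nm)]]
  c1 <- conv3dForward(x, g("c1.W"), g("c1.b"), c(1, 1, 1), c(1, 1, 1))
  b1 <- bnForward(c1, g("bn1.g"), g("bn1.b"), s[[paste0(pfx, ".bn1")]],
                  training = training)
  s[[paste0(pfx, ".bn1")]] <- b1$running
  r1 <- reluForward(b1$out)
  c2 <- conv3dForward(r1, g("c2.W"), g("c2.b"), c(1, 1, 1), c(1, 1, 1))
  b2 <- bnForward(c2, g("bn2.g"), g("bn2.b"), s[[paste0(pfx, ".bn2")]],
                  training = training)
  s[[paste0(pfx, ".bn2")]] <- b2$running
  # shortcut: identity when channels match and no projection weights exist,
  # else 1x1x1 conv + BN
  if (is.null(g("pj.W"))) {
    pre <- b2$out + x
    bpc <- NULL
  } else {
    pj <- conv3dForward(x, g("pj.W"), g("pj.b"), c(1, 1, 1), c(0, 0, 0))
    bp <- bnForward(pj, g("bnp.g"), g("bnp.b"), s[[paste0(pfx, ".bnp")]],
                    training = training)
    s[[paste0(pfx, ".bnp")]] <- bp$running
    pre <- b2$out + bp$out
    bpc <- bp$cache
  }
  list(out = reluForward(pre), state = s,
       cache = list(x = x, c1 = c1, bn1 = b1$cache, r1 = r1, b1out = b1$out,
                    c2 = c2, bn2 = b2$cache, bnp = bpc, pre = pre))
}

resBlockBackward <- function(dout, pfx, p, cache) {
  g <- function(nm) p[[paste0(pfx, ".", nm)]]
  gr <- list()
  dpre <- reluBackward(dout, cache$pre)
  # main branch
  bb2 <- bnBackward(dpre, cache$bn2)
  gr[[paste0(pfx, ".bn2.g")]] <- bb2$dgamma
  gr[[paste0(pfx, ".bn2.b")]] <- bb2$dbeta
  cb2 <- conv3dBackward(cache$r1, g("c2.W"), bb2$dx, c(1, 1, 1), c(1, 1, 1))
  gr[[paste0(pfx, ".c2.W")]] <- cb2$dW
  gr[[paste0(pfx, ".c2.b")]] <- cb2$db
  dr1 <- reluBackward(cb2$dx, cache$b1out)
  bb1 <- bnBackward(dr1, cache$bn1)
  gr[[paste0(pfx, ".bn1.g")]] <- bb1$dgamma
  gr[[paste0(pfx, ".bn1.b")]] <- bb1$dbeta
  cb1 <- conv3dBackward(cache$x, g("c1.W"), bb1$dx, c(1, 1, 1), c(1, 1, 1))
  gr[[paste0(pfx, ".c1.W")]] <- cb1$dW
  gr[[paste0(pfx, ".c1.b")]] <- cb1$db
  # shortcut path
  if (is.null(cache$bnp)) {
    dxShort <- dpre
  } else {
    bbp <- bnBackward(dpre, cache$bnp)
    gr[[paste0(pfx, ".bnp.g")]] <- bbp$dgamma
    gr[[paste0(pfx, ".bnp.b")]] <- bbp$dbeta
    cbp <- conv3dBackward(cache$x, g("pj.W"), bbp$dx, c(1, 1, 1), c(0, 0, 0))
    gr[[paste0(pfx, ".pj.W")]] <- cbp$dW
    gr[[paste0(pfx, ".pj.b")]] <- cbp$db
    dxShort <- cbp$dx
  }
  list(dx = cb1$dx + dxShort, grads = gr)
}

# Full forward pass. xhsi: (bands, P, P, N) array or NULL; xmri:
# (features x N) matrix or NULL, already scaled. Returns logits, the
# layer caches needed for backward, updated BN state, and the
# layer-by-layer instantiated shapes.
hafnetForward <- function(config, p, s, xhsi, xmri, training = FALSE) {
  cache <- list()
  shapes <- list()
  hFeat <- NULL
  mFeat <- NULL
  if (config@mode != "mri_only") {
    d <- dim(xhsi)
    N <- d[4L]
    x0 <- xhsi
    dim(x0) <- c(1L, d[1L], d[2L], d[3L], N)
    shapes$input <- dim(x0)[1:4]
    c0 <- conv3dForward(x0, p$stem.W, p$stem.b, c(2, 1, 1), c(2, 1, 1))
    shapes$stem_conv <- dim(c0)[1:4]
    b0 <- bnForward(c0, p$bn0.g, p$bn0.b, s$bn0, training = training)
    s$bn0 <- b0$running
    r0 <- reluForward(b0$out)
    p0 <- maxpool3dForward(r0, c(2, 2, 2))
    shapes$stem_pool <- dim(p0$out)[1:4]
    rb1 <- resBlockForward(p0$out, "rb1", p, s, training)
    s <- rb1$state
    shapes$resblock1 <- dim(rb1$out)[1:4]
    p1 <- maxpool3dForward(rb1$out, c(2, 2, 2))
    shapes$pool1 <- dim(p1$out)[1:4]
    rb2 <- resBlockForward(p1$out, "rb2", p, s, training)
    s <- rb2$state
    shapes$resblock2 <- dim(rb2$out)[1:4]
    p2 <- maxpool3dForward(rb2$out, c(1, 2, 2))
    shapes$pool2 <- dim(p2$out)[1:4]
    att <- attentionForward(p2$out, p$att.W1, p$att.b1, p$att.W2, p$att.b2)
    shapes$attention <- dim(att$out)[1:4]
    flat <- att$out
    dim(flat) <- c(prod(dim(att$out)[1:4]), N)
    hf <- fcForward(flat, p$hsi.W, p$hsi.b)
    hb <- bnForward(hf, p$hbn.g, p$hbn.b, s$hbn, training = training)
    s$hbn <- hb$running
    hFeat <- reluForward(hb$out)
    cache$hsi <- list(x0 = x0, c0 = c0, bn0 = b0$cache, b0out = b0$out,
                      r0 = r0, p0 = p0, rb1 = rb1$cache, p1in = rb1$out,
                      p1 = p1, rb2 = rb2$cache, p2in = rb2$out, p2 = p2,
                      att = att$cache, flat = flat, hf = hf, hbn = hb$cache,
                      hbout = hb$out)
  }
  if (config@mode != "hsi_only") {
    m1 <- fcForward(xmri, p$mri1.W, p$mri1.b)
    mb1 <- bnForward(m1, p$mbn1.g, p$mbn1.b, s$mbn1, training = training)
    s$mbn1 <- mb1$running
    mr1 <- reluForward(mb1$out)
    m2 <- fcForward(mr1, p$mri2.W, p$mri2.b)
    mb2 <- bnForward(m2, p$mbn2.g, p$mbn2.b, s$mbn2, training = training)
    s$mbn2 <- mb2$running
    mFeat <- reluForward(mb2$out)
    cache$mri <- list(xmri = xmri, m1 = m1, mbn1 = mb1$cache,
                      mb1out = mb1$out, mr1 = mr1, m2 = m2,
                      mbn2 = mb2$cache, mb2out = mb2$out)
  }
  if (config@mode == "multimodal") {
    z <- rbind(hFeat, mFeat)
    ff <- fcForward(z, p$fus.W, p$fus.b)
    fb <- bnForward(ff, p$fbn.g, p$fbn.b, s$fbn, training = training)
    s$fbn <- fb$running
    fr <- reluForward(fb$out)
    dr <- dropoutForward(fr, config@dropout, training = training)
    head <- dr$out
    cache$fus <- list(z = z, ff = ff, fbn = fb$cache, fbout = fb$out,
                      fr = fr, mask = dr$mask)
  } else {
    head <- if (config@mode == "hsi_only") hFeat else mFeat
  }
  logits <- fcForward(head, p$out.W, p$out.b)
  cache$head <- head
  list(logits = logits, cache = cache, state = s, shapes = shapes)
}

hafnetBackward <- function(config, p, cache, dlogits) {
  gr <- list()
  ob <- fcBackward(dlogits, cache$head, p$out.W)
  gr$out.W <- ob$dW; gr$out.b <- ob$db
  dhFeat <- NULL; dmFeat <- NULL
  if (config@mode == "multimodal") {
    fc <- cache$fus
    dfr <- dropoutBackward(ob$dx, fc$mask)
    dfb <- reluBackward(dfr, fc$fbout)
    fb <- bnBackward(dfb, fc$fbn)
    gr$fbn.g <- fb$dgamma; gr$fbn.b <- fb$dbeta
    ffb <- fcBackward(fb$dx, fc$z, p$fus.W)
    gr$fus.W <- ffb$dW; gr$fus.b <- ffb$db
    dhFeat <- ffb$dx[seq_len(config@hsiProjDim), , drop = FALSE]
    dmFeat <- ffb$dx[config@hsiProjDim + seq_len(config@mriHiddenDims[2L]), ,
                     drop = FALSE]
  } else if (config@mode == "hsi_only") {
    dhFeat <- ob$dx
  } else {
    dmFeat <- ob$dx
  }
  if (!is.null(dmFeat)) {
    mc <- cache$mri
    dmb2 <- reluBackward(dmFeat, mc$mb2out)
    b2 <- bnBackward(dmb2, mc$mbn2)
    gr$mbn2.g <- b2$dgamma; gr$mbn2.b <- b2$dbeta
    f2 <- fcBackward(b2$dx, mc$mr1, p$mri2.W)
    gr$mri2.W <- f2$dW; gr$mri2.b <- f2$db
    dmr1 <- reluBackward(f2$dx, mc$mb1out)
    b1 <- bnBackward(dmr1, mc$mbn1)
    gr$mbn1.g <- b1$dgamma; gr$mbn1.b <- b1$dbeta
    f1 <- fcBackward(b1$dx, mc$xmri, p$mri1.W)
    gr$mri1.W <- f1$dW; gr$mri1.b <- f1$db
  }
  if (!is.null(dhFeat)) {
    hc <- cache$hsi
    dhb <- reluBackward(dhFeat, hc$hbout)
    hb <- bnBackward(dhb, hc$hbn)
    gr$hbn.g <- hb$dgamma; gr$hbn.b <- hb$dbeta
    hf <- fcBackward(hb$dx, hc$flat, p$hsi.W)
    gr$hsi.W <- hf$dW; gr$hsi.b <- hf$db
    datt <- hf$dx
    dim(datt) <- dim(hc$p2$out)
    ab <- attentionBackward(datt, hc$att, p$att.W1, p$att.W2)
    gr$att.W1 <- ab$dW1; gr$att.b1 <- ab$db1
    gr$att.W2 <- ab$dW2; gr$att.b2 <- ab$db2
    dp2 <- maxpool3dBackward(ab$dx, hc$p2$argmax, dim(hc$p2in))
    rb2 <- resBlockBackward(dp2, "rb2", p, hc$rb2)
    gr <- c(gr, rb2$grads)
    dp1 <- maxpool3dBackward(rb2$dx, hc$p1$argmax, dim(hc$p1in))
    rb1 <- resBlockBackward(dp1, "rb1", p, hc$rb1)
    gr <- c(gr, rb1$grads)
    dp0 <- maxpool3dBackward(rb1$dx, hc$p0$argmax, dim(hc$r0))
    dr0 <- reluBackward(dp0, hc$b0out)
    b0 <- bnBackward(dr0, hc$bn0)
    gr$bn0.g <- b0$dgamma; gr$bn0.b <- b0$dbeta
    c0 <- conv3dBackward(hc$x0, p$stem.W, b0$dx, c(2, 1, 1), c(2, 1, 1))
    gr$stem.W <- c0$dW; gr$stem.b <- c0$db
  }
  gr
}

#' Class probabilities for a batch (inference mode)
#'
#' Runs the network in evaluation mode (running batch-norm statistics, no
#' dropout) and applies the softmax. Rows are classes in the model's class
#' order; columns are batch items.
#'
#' @param model a [HAFNetModel-class].
#' @param xhsi `(bands, size, size, N)` array of selected-band patches
#'   (ignored in `mri_only` mode).
#' @param xmri `(features x N)` scaled radiomic matrix (ignored in
#'   `hsi_only` mode).
#' @return `nClasses x N` matrix of class probabilities (columns sum to 1).
#' @export
predictProbs <- function(model, xhsi = NULL, xmri = NULL) {
  fw <- hafnetForward(model@config, model@params, model@state, xhsi, xmri,
                      training = FALSE)
  softmaxCols(fw$logits)
}

softmaxCols <- function(logits) {
  shifted <- sweep(logits, 2L, apply(logits, 2L, max), "-")
  e <- exp(shifted)
  probs <- sweep(e, 2L, colSums(e), "/")
  rownames(probs) <- rownames(logits)
  probs
}
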