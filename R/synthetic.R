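#' SyntheticSpec: parameters of the synthetic glioma dataset generator
#'
#' Describes a synthetic stand-in for the study data: calibrated reflectance
#' patches whose classes differ by Gaussian absorption dips at class-specific
#' wavelengths, paired with per-patient radiomic vectors that carry class
#' information partially complementary to the spectral signal.
#'
#' @slot nClasses number of classes.
#' @slot classPatchCounts patches per class.
#' @slot bands number of spectral bands.
#' @slot wavelengthStart,wavelengthStep wavelength grid (nm): the grid is
#'   `start + (0:(bands-1)) * step`; the defaults give 400-998 nm in 300
#'   bands of 2 nm.
#' @slot patchSize spatial edge length in pixels.
#' @slot signatureCenters list (per class) of absorption-peak centres (nm).
#' @slot signatureDepths per-class peak depths in reflectance units.
#' @slot signatureWidth Gaussian width (nm) of the absorption dips.
#' @slot noiseSd i.i.d. pixel noise SD in reflectance units.
#' @slot textureAmplitude amplitude of the smooth spatial texture field
#'   (reflectance units); defaults to `noiseSd`.
#' @slot radiomicsDim radiomic vector length.
#' @slot radiomicsInformativeDim number of class-informative coordinates.
#' @slot radiomicsEffectSize class-mean separation in noise-SD units.
#' @slot complementarity fraction in [0,1] of class pairs made spectrally
#'   identical (so their information is exclusive to the radiomic modality).
#' @slot patientsPerClass patients per class; patches are assigned to
#'   patients round-robin.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticSpec",
  representation(nClasses = "integer", classPatchCounts = "integer",
                 bands = "integer", wavelengthStart = "numeric",
                 wavelengthStep = "numeric", patchSize = "integer",
                 signatureCenters = "list", signatureDepths = "numeric",
                 signatureWidth = "numeric", noiseSd = "numeric",
                 textureAmplitude = "numeric", radiomicsDim = "integer",
                 radiomicsInformativeDim = "integer",
                 radiomicsEffectSize = "numeric", complementarity = "numeric",
                 patientsPerClass = "integer", seed = "integer")
)

setValidity("SyntheticSpec", function(object) {
  if (object@nClasses < 1L || object@bands < 1L || object@patchSize < 1L ||
      object@patientsPerClass < 1L || any(object@classPatchCounts < 1L) ||
      object@radiomicsDim < 1L)
    return("all counts must be strictly positive")
  if (length(object@classPatchCounts) != object@nClasses)
    return("classPatchCounts must have one entry per class")
  if (object@complementarity < 0 || object@complementarity > 1)
    return("complementarity must lie in [0, 1]")
  if (object@radiomicsInformativeDim > object@radiomicsDim)
    return("radiomicsInformativeDim cannot exceed radiomicsDim")
  wl <- syntheticWavelengths(object)
  ctr <- unlist(object@signatureCenters)
  if (length(ctr) && (min(ctr) < min(wl) || max(ctr) > max(wl)))
    return("every signature centre must lie on the wavelength grid's span")
  if (any(object@classPatchCounts < object@patientsPerClass))
    return("each class needs at least one patch per patient (classPatchCounts >= patientsPerClass)")
  TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d classes (%s patches), %d bands %.0f-%.0f nm, %dx%d px, complementarity %.2f, seed %d\n",
    object@nClasses, paste(object@classPatchCounts, collapse = "/"),
    object@bands, min(syntheticWavelengths(object)),
    max(syntheticWavelengths(object)), object@patchSize, object@patchSize,
    object@complementarity, object@seed))
})

syntheticWavelengths <- function(spec) {
  spec@wavelengthStart + (seq_len(spec@bands) - 1L) * spec@wavelengthStep
}

#' Build a synthetic-data specification
#'
#' Defaults mirror the acquisition platform: 300 bands on a uniform 2 nm
#' grid from 400 to 998 nm and 100x100-pixel patches. Absorption-peak
#' centres default to an even spread over the middle 70% of the wavelength
#' span, one peak per class.
#'
#' @param nClasses number of classes (default 6).
#' @param classPatchCounts per-class patch counts (default 30 each).
#' @param bands,wavelengthStart,wavelengthStep wavelength grid.
#' @param patchSize spatial patch edge (pixels).
#' @param signatureCenters list of per-class centre vectors (nm), or NULL
#'   for the even-spread default.
#' @param signatureDepths per-class dip depths (recycled; default 0.3).
#' @param signatureWidth Gaussian dip width in nm (default 20).
#' @param noiseSd pixel noise SD (default 0.02).
#' @param textureAmplitude smooth-texture amplitude; NULL = `noiseSd`.
#' @param radiomicsDim radiomic vector length (default 5650).
#' @param radiomicsInformativeDim class-informative coordinates (default 24).
#' @param radiomicsEffectSize class-mean separation in noise-SD units
#'   (default 3).
#' @param complementarity fraction of class pairs with identical spectral
#'   signatures (default 0).
#' @param patientsPerClass patients per class (default 5).
#' @param seed RNG seed (default 1).
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nClasses = 6L, classPatchCounts = rep(30L, nClasses),
                          bands = 300L, wavelengthStart = 400,
                          wavelengthStep = 2, patchSize = 100L,
                          signatureCenters = NULL, signatureDepths = 0.3,
                          signatureWidth = 20, noiseSd = 0.02,
                          textureAmplitude = NULL, radiomicsDim = 5650L,
                          radiomicsInformativeDim = 24L,
                          radiomicsEffectSize = 3,
                          complementarity = 0, patientsPerClass = 5L,
                          seed = 1L) {
  if (is.null(signatureCenters)) {
    span <- (bands - 1L) * wavelengthStep
    lo <- wavelengthStart + 0.15 * span
    hi <- wavelengthStart + 0.85 * span
    ctr <- seq(lo, hi, length.out = nClasses)
    signatureCenters <- as.list(ctr)
  }
  new("SyntheticSpec",
      nClasses = as.integer(nClasses),
      classPatchCounts = as.integer(classPatchCounts),
      bands = as.integer(bands), wavelengthStart = wavelengthStart,
      wavelengthStep = wavelengthStep, patchSize = as.integer(patchSize),
      signatureCenters = lapply(signatureCenters, as.numeric),
      signatureDepths = rep_len(as.numeric(signatureDepths), nClasses),
      signatureWidth = signatureWidth, noiseSd = noiseSd,
      textureAmplitude = if (is.null(textureAmplitude)) noiseSd
                         else textureAmplitude,
      radiomicsDim = as.integer(radiomicsDim),
      radiomicsInformativeDim = as.integer(radiomicsInformativeDim),
      radiomicsEffectSize = radiomicsEffectSize,
      complementarity = complementarity,
      patientsPerClass = as.integer(patientsPerClass),
      seed = as.integer(seed))
}

#' A reduced-scale specification for fast experiments
#'
#' The scale the package's own experiments run at on a single CPU: 6 classes
#' of 30 patches, 64 bands, 50x50-pixel patches, 128 radiomic features. All
#' arguments of [syntheticSpec()] can be overridden.
#'
#' @param ... overrides passed to [syntheticSpec()].
#' @return a [SyntheticSpec-class].
#' @export
ciSyntheticSpec <- function(...) {
  args <- list(bands = 64L, patchSize = 50L, radiomicsDim = 128L,
               radiomicsInformativeDim = 24L, signatureWidth = 12,
               noiseSd = 0.02, ...)
  do.call(syntheticSpec, args[!duplicated(names(args), fromLast = TRUE)])
}

# per-class spectral signature curves (bands x classes), after the
# complementarity collapse: with complementarity c, the first
# round(c * floor(K/2)) of the pairs (1,2), (3,4), ... share class-identical
# signatures (the second member copies the first), so those pairs are
# spectrally indistinguishable and separable only through radiomics.
classSignatures <- function(spec) {
  wl <- syntheticWavelengths(spec)
  K <- spec@nClasses
  sig <- matrix(0, nrow = spec@bands, ncol = K)
  for (k in seq_len(K)) {
    for (ctr in spec@signatureCenters[[k]]) {
      sig[, k] <- sig[, k] + spec@signatureDepths[k] *
        exp(-(wl - ctr)^2 / (2 * spec@signatureWidth^2))
    }
  }
  nPairs <- K %/% 2L
  nShared <- round(spec@complementarity * nPairs)
  if (nShared > 0) {
    for (p in seq_len(nShared)) sig[, 2L * p] <- sig[, 2L * p - 1L]
  }
  sig
}

# class-mean radiomic vectors (features x classes): each class gets a
# disjoint block of the informative coordinates raised by the effect size
# (in units of the unit patient-noise SD); remaining coordinates are zero.
classRadiomicMeans <- function(spec) {
  K <- spec@nClasses
  mu <- matrix(0, nrow = spec@radiomicsDim, ncol = K)
  blk <- max(1L, spec@radiomicsInformativeDim %/% K)
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * blk + 1L):min(k * blk, spec@radiomicsDim)
    mu[idx, k] <- spec@radiomicsEffectSize
  }
  mu
}

smoothTexture <- function(p, amplitude) {
  if (amplitude <= 0) return(matrix(0, p, p))
  g <- seq(0, 1, length.out = p)
  tex <- matrix(0, p, p)
  for (j in 1:3) {
    f <- runif(2, 1, 4)
    phase <- runif(2, 0, 2 * pi)
    tex <- tex + outer(cos(2 * pi * f[1] * g + phase[1]),
                       cos(2 * pi * f[2] * g + phase[2]))
  }
  amplitude * tex / 3
}

#' Generate a synthetic glioma dataset
#'
#' Emits labelled reflectance patches (baseline 0.8 minus the class's
#' Gaussian absorption dips, plus a mild smooth spatial texture and i.i.d.
#' pixel noise, clipped to `[0, 1.5]`) together with one radiomic vector per
#' patient (class mean plus unit Gaussian noise). Class labels use the
#' WHO-2021 alphabet for up to six classes. Deterministic for a fixed spec.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [GliomaDataset-class].
#' @export
generateDataset <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    K <- spec@nClasses
    classes <- if (K <= length(GLIOMA_CLASSES)) GLIOMA_CLASSES[seq_len(K)]
               else sprintf("C%02d", seq_len(K))
    wl <- syntheticWavelengths(spec)
    sig <- classSignatures(spec)
    mu <- classRadiomicMeans(spec)
    p <- spec@patchSize

    featNames <- if (spec@radiomicsDim == 5650L) enumerateSchema(radiomicSchema())
                 else sprintf("feat_%04d", seq_len(spec@radiomicsDim))
    patients <- character(0)
    radiomics <- NULL
    patches <- vector("list", sum(spec@classPatchCounts))
    n <- 0L
    for (k in seq_len(K)) {
      pids <- sprintf("P_%s_%02d", classes[k], seq_len(spec@patientsPerClass))
      patients <- c(patients, pids)
      rad <- matrix(rnorm(spec@patientsPerClass * spec@radiomicsDim),
                    nrow = spec@patientsPerClass)
      rad <- sweep(rad, 2L, mu[, k], "+")
      rownames(rad) <- pids
      radiomics <- rbind(radiomics, rad)

      base <- 0.8 - sig[, k]  # per-band class mean reflectance
      for (i in seq_len(spec@classPatchCounts[k])) {
        n <- n + 1L
        tex <- smoothTexture(p, spec@textureAmplitude)
        vals <- array(base, dim = c(spec@bands, p, p)) +
          rep(tex, each = spec@bands)
        if (spec@noiseSd > 0)
          vals <- vals + rnorm(length(vals), sd = spec@noiseSd)
        vals[vals < 0] <- 0
        vals[vals > 1.5] <- 1.5
        patches[[n]] <- new("HSIPatch", values = vals, wavelengths = wl,
          label = classes[k],
          patientId = pids[((i - 1L) %% spec@patientsPerClass) + 1L],
          patchId = sprintf("syn_%s_%03d", classes[k], i),
          origin = list(cubeId = "synthetic", row = 1L, col = 1L))
      }
    }
    colnames(radiomics) <- head(featNames, spec@radiomicsDim)
    new("GliomaDataset", patches = patches, radiomics = radiomics,
        classes = classes, spec = list(spec = spec))
  })
}

#' Generate raw sample / white / dark reference cubes
#'
#' Builds a known synthetic reflectance cube (class-1 signature plus texture
#' and noise per the spec) and synthesizes the raw, white-reference and
#' dark-reference count cubes that the standard calibration
#' `R = (I - D)/(W - D)` maps back onto it — exactly so when `noiseSd = 0`.
#' White exceeds dark at every element.
#'
#' @param spec a [SyntheticSpec-class].
#' @param rows,cols spatial extent of the cubes (defaults: the spec's patch
#'   size).
#' @return list with elements `raw`, `white`, `dark` ([RawCube-class]) and
#'   `truth` (the generated [ReflectanceCube-class]).
#' @export
generateReferenceCubes <- function(spec, rows = spec@patchSize,
                                   cols = spec@patchSize) {
  validObject(spec)
  withSeed(spec@seed + 1L, {
    wl <- syntheticWavelengths(spec)
    sig <- classSignatures(spec)
    base <- 0.8 - sig[, 1L]
    tex <- smoothTexture(max(rows, cols), spec@textureAmplitude)[
      seq_len(rows), seq_len(cols), drop = FALSE]
    refl <- array(base, dim = c(spec@bands, rows, cols)) +
      rep(tex, each = spec@bands)
    if (spec@noiseSd > 0)
      refl <- refl + rnorm(length(refl), sd = spec@noiseSd)
    refl[refl < 0] <- 0
    refl[refl > 1.5] <- 1.5
    truth <- new("ReflectanceCube", reflectance = refl, wavelengths = wl,
                 clipMax = 1.5)

    # spectrally shaped illumination; dark current flat and positive
    illum <- 3000 * (0.6 + 0.4 * sin(seq(0, pi, length.out = spec@bands)))
    dark <- array(100, dim = dim(refl))
    white <- dark + array(illum, dim = dim(refl))
    raw <- dark + refl * (white - dark)
    list(raw = rawCube(raw, wl), white = rawCube(white, wl),
         dark = rawCube(dark, wl), truth = truth)
  })
}
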