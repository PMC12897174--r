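#' @include AllGenerics.R
NULL

## S4 containers for the pipeline. Axis convention, enforced by every
## validity method: spectral cubes and patches are bands-first arrays,
## dim = (bands, rows, cols).

#' RawCube: an uncalibrated hyperspectral data cube
#'
#' Sensor counts as acquired, bands-first (`bands x rows x cols`), with the
#' wavelength grid in nanometres. White/dark reference captures use the same
#' container.
#'
#' @slot intensities numeric array, `bands x rows x cols`, nonnegative counts.
#' @slot wavelengths numeric vector of band-centre wavelengths (nm), strictly
#'   increasing, length equal to the number of bands.
#' @slot meta free-form acquisition metadata.
#' @export
setClass("RawCube",
  representation(intensities = "array", wavelengths = "numeric", meta = "list"),
  prototype(meta = list())
)

setValidity("RawCube", function(object) {
  d <- dim(object@intensities)
  if (length(d) != 3L) return("intensities must be a 3D array (bands x rows x cols)")
  if (d[1L] != length(object@wavelengths))
    return(sprintf("bands (%d) != length(wavelengths) (%d)", d[1L],
                   length(object@wavelengths)))
  if (length(object@wavelengths) > 1L && any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  if (anyNA(object@intensities) || min(object@intensities) < 0)
    return("intensities must be nonnegative and finite")
  TRUE
})

#' ReflectanceCube: a calibrated hyperspectral cube
#'
#' Reflectance values obtained from white/dark reference calibration,
#' clipped to `[0, clipMax]`.
#'
#' @slot reflectance numeric array, `bands x rows x cols`.
#' @slot wavelengths band-centre wavelengths (nm), strictly increasing.
#' @slot clipMax upper clipping bound applied during calibration.
#' @export
setClass("ReflectanceCube",
  representation(reflectance = "array", wavelengths = "numeric",
                 clipMax = "numeric"),
  prototype(clipMax = 1.5)
)

setValidity("ReflectanceCube", function(object) {
  d <- dim(object@reflectance)
  if (length(d) != 3L) return("reflectance must be a 3D array (bands x rows x cols)")
  if (d[1L] != length(object@wavelengths))
    return("bands != length(wavelengths)")
  if (length(object@wavelengths) > 1L && any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  r <- range(object@reflectance)
  if (anyNA(object@reflectance) || r[1L] < 0 || r[2L] > object@clipMax + 1e-12)
    return(sprintf("reflectance must lie in [0, %g]", object@clipMax))
  TRUE
})

#' HSIPatch: a labelled spatial-spectral patch
#'
#' A square tile cut from a calibrated cube (`bands x size x size`), carrying
#' its class label (or `NA` before annotation), patient identifier, and the
#' cube/row/col origin it was cut from.
#'
#' @slot values numeric array, `bands x size x size`.
#' @slot wavelengths band-centre wavelengths (nm) of the retained bands.
#' @slot label one of the six glioma classes, or `NA_character_`.
#' @slot patientId patient identifier.
#' @slot patchId unique patch identifier.
#' @slot origin list with `cubeId`, `row`, `col` offsets (1-based).
#' @export
setClass("HSIPatch",
  representation(values = "array", wavelengths = "numeric",
                 label = "character", patientId = "character",
                 patchId = "character", origin = "list"),
  prototype(label = NA_character_, patientId = NA_character_,
            patchId = NA_character_, origin = list())
)

setValidity("HSIPatch", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3D array (bands x rows x cols)")
  if (d[2L] != d[3L]) return("patches must be spatially square")
  if (d[1L] != length(object@wavelengths))
    return("bands != length(wavelengths)")
  if (!is.na(object@label) && !object@label %in% GLIOMA_CLASSES)
    return(sprintf("label '%s' is not one of %s", object@label,
                   paste(GLIOMA_CLASSES, collapse = ", ")))
  TRUE
})

#' BandSummary: per-patch per-band mean intensities with labels
#'
#' The summary statistic consumed by mutual-information wavelength ranking:
#' entry (i, b) is the mean over all spatial pixels of patch i at band b.
#'
#' @slot values numeric matrix, `n_patches x n_bands`.
#' @slot labels character vector of class labels, one per patch.
#' @slot patchIds patch identifiers (used by the leakage guard).
#' @slot wavelengths band-centre wavelengths (nm).
#' @export
setClass("BandSummary",
  representation(values = "matrix", labels = "character",
                 patchIds = "character", wavelengths = "numeric")
)

setValidity("BandSummary", function(object) {
  if (nrow(object@values) != length(object@labels))
    return("one label per patch required")
  if (nrow(object@values) != length(object@patchIds))
    return("one patch id per patch required")
  if (ncol(object@values) != length(object@wavelengths))
    return("one wavelength per band required")
  if (anyNA(object@values)) return("band summaries must not contain NA")
  TRUE
})

#' WavelengthRanking: mutual-information band ranking
#'
#' Per-band MI scores (nats) between patch mean intensity and class label,
#' with the indices and wavelengths of the top-k bands.
#'
#' @slot miScores nonnegative per-band MI scores, nats.
#' @slot selected integer indices (1-based) of the k selected bands, ordered
#'   by decreasing score (ties broken by lower band index).
#' @slot wavelengths wavelengths (nm) of the selected bands.
#' @slot k number of selected bands.
#' @slot bins histogram bin count used by the estimator.
#' @export
setClass("WavelengthRanking",
  representation(miScores = "numeric", selected = "integer",
                 wavelengths = "numeric", k = "integer", bins = "integer")
)

setValidity("WavelengthRanking", function(object) {
  if (any(object@miScores < -1e-12)) return("MI scores must be nonnegative")
  if (length(object@selected) != object@k) return("|selected| must equal k")
  if (any(object@selected < 1L) ||
      any(object@selected > length(object@miScores)))
    return("selected band indices out of range")
  TRUE
})

#' RadiomicSchema: the per-patient radiomic feature-vector contract
#'
#' Five MRI sequences crossed with image types (original, three LoG scales,
#' eight first-level wavelet sub-bands) and feature families; shape features
#' appear only under the original image type. With the defaults the schema
#' enumerates exactly 5650 named features.
#'
#' @slot sequences MRI sequence names.
#' @slot logSigmas Laplacian-of-Gaussian sigma values.
#' @slot waveletSubbands first-level wavelet sub-band codes.
#' @slot familyCardinalities named integer vector: features per family.
#' @slot shapeFamily name of the family restricted to the original images.
#' @export
setClass("RadiomicSchema",
  representation(sequences = "character", logSigmas = "numeric",
                 waveletSubbands = "character",
                 familyCardinalities = "integer", shapeFamily = "character")
)

setValidity("RadiomicSchema", function(object) {
  if (!object@shapeFamily %in% names(object@familyCardinalities))
    return("shapeFamily must be one of the declared families")
  if (any(object@familyCardinalities <= 0L))
    return("family cardinalities must be positive")
  TRUE
})

#' FeatureScaler: per-feature z-score parameters fitted on training data
#'
#' @slot center per-feature training means.
#' @slot scale per-feature training SDs (zero-variance features get scale 0
#'   and are mapped to 0 on transform).
#' @slot featureNames feature names, in schema order.
#' @export
setClass("FeatureScaler",
  representation(center = "numeric", scale = "numeric",
                 featureNames = "character")
)

#' GliomaDataset: patches, radiomic vectors and ground truth
#'
#' The unit the training/evaluation pipeline consumes: a list of
#' [HSIPatch-class] objects, a per-patient radiomic feature matrix
#' (patients in rows, schema order in columns), and the generating spec
#' (for synthetic data) or acquisition metadata.
#'
#' @slot patches list of [HSIPatch-class].
#' @slot radiomics numeric matrix, patients x features, rownames = patient ids.
#' @slot classes the class alphabet.
#' @slot spec generating specification or metadata (list).
#' @export
setClass("GliomaDataset",
  representation(patches = "list", radiomics = "matrix",
                 classes = "character", spec = "list"),
  prototype(spec = list())
)

setValidity("GliomaDataset", function(object) {
  pids <- vapply(object@patches, function(p) p@patientId, character(1))
  if (!all(pids %in% rownames(object@radiomics)))
    return("every patch's patient must have a radiomic vector")
  labs <- vapply(object@patches, function(p) p@label, character(1))
  if (!all(labs[!is.na(labs)] %in% object@classes))
    return("patch labels must come from the declared class set")
  TRUE
})

#' SplitPlan: one cross-validation fold of a stratified split
#'
#' A fixed stratified test set plus the train/validation partition of the
#' remaining pool for one fold.
#'
#' @slot trainIds,valIds,testIds patch-id character vectors, pairwise disjoint.
#' @slot foldIndex fold number (1-based).
#' @slot seed seed the split was drawn under.
#' @slot groupOn `"none"` or `"patient"` (grouped splitting).
#' @export
setClass("SplitPlan",
  representation(trainIds = "character", valIds = "character",
                 testIds = "character", foldIndex = "integer",
                 seed = "integer", groupOn = "character"),
  prototype(groupOn = "none")
)

setValidity("SplitPlan", function(object) {
  ids <- c(object@trainIds, object@valIds, object@testIds)
  if (anyDuplicated(ids)) return("train/val/test sets must be pairwise disjoint")
  TRUE
})

#' EvalReport: classification metrics for one evaluation
#'
#' @slot perClassAuc one-vs-rest AUC per class (NA when a class is absent).
#' @slot macroAuc unweighted mean of the defined per-class AUCs.
#' @slot accuracy overall fraction correct.
#' @slot macroF1 unweighted mean of per-class F1 scores.
#' @slot confusion count matrix, rows = true class, cols = predicted.
#' @slot nTest number of evaluated items.
#' @slot foldIndex fold the report belongs to (NA for aggregate reports).
#' @export
setClass("EvalReport",
  representation(perClassAuc = "numeric", macroAuc = "numeric",
                 accuracy = "numeric", macroF1 = "numeric",
                 confusion = "matrix", nTest = "integer",
                 foldIndex = "integer"),
  prototype(foldIndex = NA_integer_)
)

setValidity("EvalReport", function(object) {
  if (any(object@confusion < 0)) return("confusion counts must be nonnegative")
  if (sum(object@confusion) != object@nTest)
    return("confusion total must equal nTest")
  TRUE
})

#' PairedTestResult: paired t-test between per-fold metrics of two models
#'
#' @slot metric name of the compared metric.
#' @slot differences per-fold paired differences (a - b).
#' @slot statistic t statistic.
#' @slot pValue two-sided p value.
#' @slot df degrees of freedom (folds - 1).
#' @slot degenerate TRUE when the differences had zero variance.
#' @export
setClass("PairedTestResult",
  representation(metric = "character", differences = "numeric",
                 statistic = "numeric", pValue = "numeric", df = "numeric",
                 degenerate = "logical")
)

## ---- accessors -------------------------------------------------------------

#' @rdname hafnet-generics
setMethod("wavelengths", "RawCube", function(x) x@wavelengths)
#' @rdname hafnet-generics
setMethod("wavelengths", "ReflectanceCube", function(x) x@wavelengths)
#' @rdname hafnet-generics
setMethod("wavelengths", "HSIPatch", function(x) x@wavelengths)
#' @rdname hafnet-generics
setMethod("wavelengths", "WavelengthRanking", function(x) x@wavelengths)

#' @rdname hafnet-generics
setMethod("nBands", "RawCube", function(x) dim(x@intensities)[1L])
#' @rdname hafnet-generics
setMethod("nBands", "ReflectanceCube", function(x) dim(x@reflectance)[1L])
#' @rdname hafnet-generics
setMethod("nBands", "HSIPatch", function(x) dim(x@values)[1L])

#' @rdname hafnet-generics
setMethod("spatialDim", "RawCube", function(x) dim(x@intensities)[2:3])
#' @rdname hafnet-generics
setMethod("spatialDim", "ReflectanceCube", function(x) dim(x@reflectance)[2:3])
#' @rdname hafnet-generics
setMethod("spatialDim", "HSIPatch", function(x) dim(x@values)[2:3])

#' @rdname hafnet-generics
setMethod("values3d", "RawCube", function(x) x@intensities)
#' @rdname hafnet-generics
setMethod("values3d", "ReflectanceCube", function(x) x@reflectance)
#' @rdname hafnet-generics
setMethod("values3d", "HSIPatch", function(x) x@values)

#' @rdname hafnet-generics
setMethod("patchLabels", "HSIPatch", function(x) x@label)
#' @rdname hafnet-generics
setMethod("patchLabels", "GliomaDataset",
  function(x) vapply(x@patches, function(p) p@label, character(1)))

#' @rdname hafnet-generics
setMethod("patientIds", "HSIPatch", function(x) x@patientId)
#' @rdname hafnet-generics
setMethod("patientIds", "GliomaDataset",
  function(x) vapply(x@patches, function(p) p@patientId, character(1)))

#' @rdname hafnet-generics
setMethod("patchIds", "HSIPatch", function(x) x@patchId)
#' @rdname hafnet-generics
setMethod("patchIds", "GliomaDataset",
  function(x) vapply(x@patches, function(p) p@patchId, character(1)))
#' @rdname hafnet-generics
setMethod("patchIds", "BandSummary", function(x) x@patchIds)

#' @rdname hafnet-generics
setMethod("miScores", "WavelengthRanking", function(x) x@miScores)
#' @rdname hafnet-generics
setMethod("selectedBands", "WavelengthRanking", function(x) x@selected)

#' @rdname hafnet-generics
setMethod("macroAUC", "EvalReport", function(x) x@macroAuc)
#' @rdname hafnet-generics
setMethod("confusionMatrix", "EvalReport", function(x) x@confusion)

## ---- show methods ----------------------------------------------------------

setMethod("show", "RawCube", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("RawCube: %d bands x %d rows x %d cols, %.0f-%.0f nm\n",
              d[1], d[2], d[3], min(object@wavelengths),
              max(object@wavelengths)))
})

setMethod("show", "ReflectanceCube", function(object) {
  d <- dim(object@reflectance)
  cat(sprintf(
    "ReflectanceCube: %d bands x %d rows x %d cols, %.0f-%.0f nm, clip %.2f\n",
    d[1], d[2], d[3], min(object@wavelengths), max(object@wavelengths),
    object@clipMax))
})

setMethod("show", "HSIPatch", function(object) {
  d <- dim(object@values)
  cat(sprintf("HSIPatch %s: %d bands x %dx%d, label %s, patient %s\n",
              object@patchId, d[1], d[2], d[3], object@label,
              object@patientId))
})

setMethod("show", "GliomaDataset", function(object) {
  labs <- patchLabels(object)
  cat(sprintf("GliomaDataset: %d patches, %d patients, %d radiomic features\n",
              length(object@patches), nrow(object@radiomics),
              ncol(object@radiomics)))
  print(table(factor(labs, levels = object@classes)))
})

setMethod("show", "WavelengthRanking", function(object) {
  cat(sprintf(
    "WavelengthRanking: top %d of %d bands (%.0f-%.0f nm), %d-bin histogram MI\n",
    object@k, length(object@miScores), min(object@wavelengths),
    max(object@wavelengths), object@bins))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport%s: accuracy %.4f, macro AUC %.4f, macro F1 %.4f (n = %d)\n",
    if (is.na(object@foldIndex)) "" else sprintf(" (fold %d)", object@foldIndex),
    object@accuracy, object@macroAuc, object@macroF1, object@nTest))
})

setMethod("show", "PairedTestResult", function(object) {
  cat(sprintf(
    "Paired t-test on %s: t = %.4f (df = %g), p = %.4g%s\n",
    object@metric, object@statistic, object@df, object@pValue,
    if (object@degenerate) " [degenerate variance]" else ""))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan fold %d: %d train / %d val / %d test (%s)\n",
              object@foldIndex, length(object@trainIds),
              length(object@valIds), length(object@testIds), object@groupOn))
})
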