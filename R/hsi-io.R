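#' Construct a raw hyperspectral cube
#'
#' @param intensities numeric array, `bands x rows x cols`, nonnegative.
#' @param wavelengths strictly increasing band-centre wavelengths (nm).
#' @param meta optional metadata list.
#' @return a [RawCube-class].
#' @export
rawCube <- function(intensities, wavelengths, meta = list()) {
  new("RawCube", intensities = intensities,
      wavelengths = as.numeric(wavelengths), meta = meta)
}

#' White/dark reference reflectance calibration
#'
#' Converts raw sensor counts to reflectance with the standard push-broom
#' convention `R = (I - D) / (W - D)`, elementwise over identical
#' `bands x rows x cols` grids, followed by clipping to `[0, clipMax]`.
#' References may optionally be spatially averaged per band before use,
#' which is the common choice when the references are noisy but the
#' illumination is spatially flat.
#'
#' @param raw,white,dark [RawCube-class] objects on identical shapes and
#'   wavelength grids; `white` must exceed `dark` everywhere (after optional
#'   averaging).
#' @param clipMax upper clipping bound for the reflectance (default 1.5;
#'   values slightly above 1 occur where the sample transmits more than the
#'   white reference).
#' @param averageReferences if TRUE, replace each reference by its per-band
#'   spatial mean before calibrating.
#' @return a [ReflectanceCube-class].
#' @export
calibrate <- function(raw, white, dark, clipMax = 1.5,
                      averageReferences = FALSE) {
  stopifnot(is(raw, "RawCube"), is(white, "RawCube"), is(dark, "RawCube"))
  d <- dim(raw@intensities)
  if (!identical(d, dim(white@intensities)) ||
      !identical(d, dim(dark@intensities)))
    stop("calibrate: raw, white and dark cubes must share one shape")
  if (!isTRUE(all.equal(raw@wavelengths, white@wavelengths)) ||
      !isTRUE(all.equal(raw@wavelengths, dark@wavelengths)))
    stop("calibrate: wavelength grids differ between cubes")

  w <- white@intensities
  dk <- dark@intensities
  if (averageReferences) {
    bandMeanW <- rowMeans(matrix(w, nrow = d[1L]))
    bandMeanD <- rowMeans(matrix(dk, nrow = d[1L]))
    w <- array(bandMeanW, dim = d)
    dk <- array(bandMeanD, dim = d)
  }
  denom <- w - dk
  bad <- which(denom <= 0)
  if (length(bad)) {
    idx <- arrayInd(bad[1L], d)
    stop(sprintf(
      "calibrate: white <= dark at %d element(s); first at band %d, pixel (%d, %d)",
      length(bad), idx[1L], idx[2L], idx[3L]))
  }
  refl <- (raw@intensities - dk) / denom
  refl[refl < 0] <- 0
  refl[refl > clipMax] <- clipMax
  new("ReflectanceCube", reflectance = refl, wavelengths = raw@wavelengths,
      clipMax = clipMax)
}

#' Extract non-overlapping tumor patches from a calibrated cube
#'
#' Tiles the cube on a regular grid anchored at the top-left corner (partial
#' edge tiles are discarded) and keeps only tiles whose tumor-pixel fraction
#' reaches `minTumorFrac`. This implements the patching rule that patches
#' with substantial background (< 80% tumor area by default) are excluded.
#'
#' @param cube a [ReflectanceCube-class].
#' @param mask logical matrix, `rows x cols`, TRUE = tumor tissue. Defaults
#'   to an all-TRUE mask.
#' @param patchSize tile edge length in pixels (default 100).
#' @param minTumorFrac minimum tumor-pixel fraction for a tile to be kept
#'   (default 0.8).
#' @param cubeId identifier recorded in each patch's origin.
#' @param patientId,label annotation propagated to every emitted patch.
#' @return list of [HSIPatch-class].
#' @export
extractPatches <- function(cube, mask = NULL, patchSize = 100L,
                           minTumorFrac = 0.8, cubeId = "cube",
                           patientId = NA_character_,
                           label = NA_character_) {
  stopifnot(is(cube, "ReflectanceCube"))
  d <- dim(cube@reflectance)
  if (is.null(mask)) mask <- matrix(TRUE, d[2L], d[3L])
  if (!identical(dim(mask), d[2:3]))
    stop("extractPatches: mask shape must equal the cube's rows x cols")
  patchSize <- as.integer(patchSize)
  if (patchSize > min(d[2:3]))
    stop(sprintf("extractPatches: patch size %d exceeds cube extent %d x %d",
                 patchSize, d[2L], d[3L]))
  stopifnot(minTumorFrac >= 0, minTumorFrac <= 1)

  nr <- d[2L] %/% patchSize
  nc <- d[3L] %/% patchSize
  out <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      r0 <- (i - 1L) * patchSize + 1L
      c0 <- (j - 1L) * patchSize + 1L
      rows <- r0:(r0 + patchSize - 1L)
      cols <- c0:(c0 + patchSize - 1L)
      frac <- mean(mask[rows, cols])
      if (frac >= minTumorFrac) {
        out[[length(out) + 1L]] <- new("HSIPatch",
          values = cube@reflectance[, rows, cols, drop = FALSE],
          wavelengths = cube@wavelengths, label = label,
          patientId = patientId,
          patchId = sprintf("%s_r%d_c%d", cubeId, r0, c0),
          origin = list(cubeId = cubeId, row = r0, col = c0))
      }
    }
  }
  out
}

#' Heuristic background mask from luminance
#'
#' For transmitted-light microscopy the background (no tissue) is near-white:
#' its mean reflectance across bands is high. This helper thresholds the
#' per-pixel mean reflectance and labels pixels below the threshold as
#' tissue. It is a heuristic convenience only — a manually delineated tumor
#' mask is the intended input to [extractPatches()].
#'
#' @param cube a [ReflectanceCube-class].
#' @param threshold luminance cut-off; pixels with mean reflectance below it
#'   are flagged as tissue (default 0.9).
#' @return logical `rows x cols` matrix, TRUE = tissue.
#' @export
luminanceTissueMask <- function(cube, threshold = 0.9) {
  stopifnot(is(cube, "ReflectanceCube"))
  d <- dim(cube@reflectance)
  lum <- colMeans(matrix(cube@reflectance, nrow = d[1L]))
  matrix(lum < threshold, d[2L], d[3L])
}

#' Write / read a patch manifest
#'
#' The manifest records patch provenance and annotation as CSV with columns
#' `patch_id, cube_id, row, col, patient_id, label`.
#'
#' @param patches list of [HSIPatch-class].
#' @param path CSV file path.
#' @return `writePatchManifest` returns `path` invisibly;
#'   `readPatchManifest` returns a data.frame.
#' @export
writePatchManifest <- function(patches, path) {
  df <- data.frame(
    patch_id = vapply(patches, function(p) p@patchId, character(1)),
    cube_id = vapply(patches, function(p)
      as.character(p@origin$cubeId %||% NA), character(1)),
    row = vapply(patches, function(p) as.integer(p@origin$row %||% NA), integer(1)),
    col = vapply(patches, function(p) as.integer(p@origin$col %||% NA), integer(1)),
    patient_id = vapply(patches, function(p) p@patientId, character(1)),
    label = vapply(patches, function(p) p@label, character(1)),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePatchManifest
#' @export
readPatchManifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
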