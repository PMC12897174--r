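#' Histogram mutual information between a continuous summary and class labels
#'
#' Discretizes `x` into `bins` equal-width bins over its observed range,
#' forms the joint histogram with `y`, and evaluates
#' `I(X;Y) = sum p(x,y) log[ p(x,y) / (p(x) p(y)) ]` with the convention
#' `0 log 0 = 0`. A constant `x` occupies a single bin and yields exactly 0.
#'
#' @param x numeric vector (finite values).
#' @param y class labels, same length as `x`.
#' @param bins number of equal-width bins (default 32).
#' @param unit `"nats"` (natural log, default) or `"bits"`.
#' @return nonnegative scalar mutual information.
#' @export
mutualInformation <- function(x, y, bins = 32L, unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  if (length(x) != length(y))
    stop("mutualInformation: x and y must have equal length")
  if (length(x) < 2L) stop("mutualInformation: need at least 2 observations")
  if (!all(is.finite(x))) stop("mutualInformation: x must be finite")
  bins <- as.integer(bins)
  if (bins < 2L) stop("mutualInformation: bins must be >= 2")

  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    xb <- rep.int(1L, length(x))  # constant x: single occupied bin, MI = 0
  } else {
    xb <- findInterval(x, seq(rng[1L], rng[2L], length.out = bins + 1L),
                       rightmost.closed = TRUE, all.inside = TRUE)
  }
  joint <- table(xb, y)
  miFromJoint(joint, unit = unit)
}

# exact evaluation of the MI sum over a discrete joint count table
miFromJoint <- function(joint, unit = "nats") {
  n <- sum(joint)
  pj <- joint / n
  px <- rowSums(pj)
  py <- colSums(pj)
  outer_p <- outer(px, py)
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / outer_p[nz]))
  mi <- max(mi, 0)  # guard tiny negative rounding
  if (unit == "bits") mi / log(2) else mi
}

#' Summarize patches to per-band spatial mean intensities
#'
#' Builds the `n_patches x n_bands` matrix of per-patch, per-band mean
#' intensities — the X variable of the mutual-information ranking — together
#' with the class labels Y and the patch ids (used by the leakage guard).
#'
#' @param patches list of labelled [HSIPatch-class] objects on one common
#'   band grid.
#' @return a [BandSummary-class].
#' @export
bandSummary <- function(patches) {
  stopifnot(length(patches) > 0L)
  wl <- patches[[1L]]@wavelengths
  vals <- t(vapply(patches, function(p) {
    if (!isTRUE(all.equal(p@wavelengths, wl)))
      stop("bandSummary: patches are not on a common band grid")
    rowMeans(matrix(p@values, nrow = dim(p@values)[1L]))
  }, numeric(length(wl))))
  new("BandSummary", values = vals,
      labels = vapply(patches, function(p) p@label, character(1)),
      patchIds = vapply(patches, function(p) p@patchId, character(1)),
      wavelengths = wl)
}

#' Rank spectral bands by mutual information and select the top k
#'
#' Scores every band by the histogram mutual information between its patch
#' mean intensities and the class labels, then selects the k highest-scoring
#' bands (ties broken in favour of the lower band index). To prevent
#' selection-induced leakage the summary must come from training patches
#' only; pass the held-out ids as `forbiddenIds` to have this asserted.
#'
#' @param summary a [BandSummary-class] built from training patches.
#' @param k number of bands to keep (default 20).
#' @param bins histogram bins for the MI estimator (default 32).
#' @param forbiddenIds patch ids that must NOT appear in the summary
#'   (e.g. validation/test ids); an overlap is an error.
#' @return a [WavelengthRanking-class].
#' @export
rankBands <- function(summary, k = 20L, bins = 32L, forbiddenIds = NULL) {
  stopifnot(is(summary, "BandSummary"))
  if (!is.null(forbiddenIds)) {
    leak <- intersect(summary@patchIds, forbiddenIds)
    if (length(leak))
      stop(sprintf(
        "rankBands: band summary contains %d held-out patch id(s) (e.g. %s); refusing to rank on leaked data",
        length(leak), leak[1L]))
  }
  if (length(unique(summary@labels)) < 2L)
    stop("rankBands: at least 2 classes are required to score bands")
  k <- as.integer(k)
  nb <- ncol(summary@values)
  if (k > nb) stop(sprintf("rankBands: k = %d exceeds %d bands", k, nb))

  scores <- vapply(seq_len(nb), function(b)
    mutualInformation(summary@values[, b], summary@labels, bins = bins),
    numeric(1))
  # order by decreasing score; ties resolved toward the lower band index
  ord <- order(-scores, seq_len(nb))
  sel <- as.integer(ord[seq_len(k)])
  new("WavelengthRanking", miScores = scores, selected = sel,
      wavelengths = summary@wavelengths[sel], k = k, bins = as.integer(bins))
}

#' Restrict a patch to the selected bands
#'
#' Returns the patch reduced to the ranking's selected bands, reordered to
#' ascending band index; label, patient and origin are preserved.
#'
#' @param patch an [HSIPatch-class].
#' @param ranking a [WavelengthRanking-class].
#' @return the band-restricted [HSIPatch-class].
#' @export
applySelection <- function(patch, ranking) {
  stopifnot(is(patch, "HSIPatch"), is(ranking, "WavelengthRanking"))
  sel <- sort(ranking@selected)
  if (max(sel) > dim(patch@values)[1L])
    stop(sprintf("applySelection: band index %d out of range (%d bands)",
                 max(sel), dim(patch@values)[1L]))
  new("HSIPatch",
      values = patch@values[sel, , , drop = FALSE],
      wavelengths = patch@wavelengths[sel],
      label = patch@label, patientId = patch@patientId,
      patchId = patch@patchId, origin = patch@origin)
}

#' Serialize / load a wavelength ranking as JSON
#'
#' @param ranking a [WavelengthRanking-class].
#' @param path JSON file path.
#' @export
writeRanking <- function(ranking, path) {
  jsonlite::write_json(list(
    mi_scores = ranking@miScores, selected = ranking@selected,
    wavelengths = ranking@wavelengths, k = ranking@k, bins = ranking@bins,
    estimator = "equal-width histogram", unit = "nats"),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeRanking
#' @export
readRanking <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("WavelengthRanking", miScores = as.numeric(j$mi_scores),
      selected = as.integer(j$selected),
      wavelengths = as.numeric(j$wavelengths),
      k = as.integer(j$k), bins = as.integer(j$bins))
}
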