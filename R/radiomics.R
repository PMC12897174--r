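#' The per-patient radiomic feature-vector schema
#'
#' Radiomic vectors are extracted per patient from five MRI sequences (T1WI,
#' T1CE, T2 FLAIR, T2WI, ADC). For each sequence, shape features are
#' computed on the original image only, while first-order and texture
#' families (GLCM, GLDM, GLRLM, NGTDM, GLSZM) are computed on the original
#' image, on three Laplacian-of-Gaussian filtered variants (sigma 1, 2, 3)
#' and on the eight first-level wavelet sub-bands — twelve image types in
#' all. With the de-facto standard family cardinalities (shape 14,
#' first-order 18, GLCM 24, GLDM 14, GLRLM 16, NGTDM 5, GLSZM 16) the schema
#' totals 5 x (14 + 93 x 12) = 5650 features.
#'
#' @param sequences MRI sequence names.
#' @param logSigmas LoG filter sigmas.
#' @param waveletSubbands wavelet sub-band codes (all low/high combinations
#'   per axis).
#' @param familyCardinalities named integer vector of features per family.
#' @param shapeFamily family restricted to the original image type.
#' @return a [RadiomicSchema-class].
#' @export
radiomicSchema <- function(
    sequences = c("T1WI", "T1CE", "T2FLAIR", "T2WI", "ADC"),
    logSigmas = c(1, 2, 3),
    waveletSubbands = c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"),
    familyCardinalities = c(shape = 14L, firstorder = 18L, glcm = 24L,
                            gldm = 14L, glrlm = 16L, ngtdm = 5L, glszm = 16L),
    shapeFamily = "shape") {
  new("RadiomicSchema", sequences = sequences, logSigmas = logSigmas,
      waveletSubbands = waveletSubbands,
      familyCardinalities = setNames(as.integer(familyCardinalities),
                                     names(familyCardinalities)),
      shapeFamily = shapeFamily)
}

schemaImageTypes <- function(schema) {
  c("original",
    sprintf("log-sigma-%g", schema@logSigmas),
    sprintf("wavelet-%s", schema@waveletSubbands))
}

#' Enumerate the ordered feature names of a radiomic schema
#'
#' Deterministic enumeration: sequence-major, then image type, then family,
#' then feature index. Shape features appear only under the original image
#' type. Names are positional identifiers of the form
#' `<sequence>_<imagetype>_<family>_f<nn>`.
#'
#' @param schema a [RadiomicSchema-class].
#' @return character vector of feature names; 5650 long with the defaults.
#' @export
enumerateSchema <- function(schema) {
  stopifnot(is(schema, "RadiomicSchema"))
  fams <- schema@familyCardinalities
  types <- schemaImageTypes(schema)
  out <- character(0)
  for (s in schema@sequences) {
    for (it in types) {
      for (fam in names(fams)) {
        if (fam == schema@shapeFamily && it != "original") next
        out <- c(out, sprintf("%s_%s_%s_f%02d", s, it, fam,
                              seq_len(fams[[fam]])))
      }
    }
  }
  out
}

#' Total feature count of a schema
#'
#' Closed form: `sequences x (shape + (other families) x image types)`.
#'
#' @param schema a [RadiomicSchema-class].
#' @return integer feature count.
#' @export
schemaLength <- function(schema) {
  fams <- schema@familyCardinalities
  nShape <- fams[[schema@shapeFamily]]
  nOther <- sum(fams) - nShape
  nTypes <- length(schemaImageTypes(schema))
  length(schema@sequences) * (nShape + nOther * nTypes)
}

#' Load per-patient radiomic vectors from a CSV table
#'
#' Expects a `patient_id` column plus one column per schema feature.
#' Columns may appear in any order; they are validated against the schema
#' (missing and unknown columns are itemized) and reordered to schema order.
#' Non-finite entries are a data error.
#'
#' @param path CSV file path.
#' @param schema a [RadiomicSchema-class] (default: the 5650-feature schema).
#' @return numeric matrix, patients x features, rownames = patient ids,
#'   colnames in schema order.
#' @export
loadRadiomics <- function(path, schema = radiomicSchema()) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df))
    stop("loadRadiomics: table must have a 'patient_id' column")
  want <- enumerateSchema(schema)
  have <- setdiff(names(df), "patient_id")
  missing <- setdiff(want, have)
  extra <- setdiff(have, want)
  if (length(missing) || length(extra))
    stop(sprintf(
      "loadRadiomics: schema mismatch — %d missing column(s)%s; %d unknown column(s)%s",
      length(missing),
      if (length(missing)) paste0(" [", paste(head(missing, 5), collapse = ", "),
                                  if (length(missing) > 5) ", ..." else "", "]") else "",
      length(extra),
      if (length(extra)) paste0(" [", paste(head(extra, 5), collapse = ", "),
                                if (length(extra) > 5) ", ..." else "", "]") else ""))
  m <- as.matrix(df[, want, drop = FALSE])
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)
    stop(sprintf(
      "loadRadiomics: %d non-finite value(s); first at patient '%s', feature '%s'",
      nrow(bad), df$patient_id[bad[1L, 1L]], want[bad[1L, 2L]]))
  }
  rownames(m) <- as.character(df$patient_id)
  m
}

#' Write per-patient radiomic vectors to CSV
#'
#' @param radiomics patients x features matrix with rownames.
#' @param path CSV file path.
#' @export
writeRadiomics <- function(radiomics, path) {
  df <- data.frame(patient_id = rownames(radiomics), radiomics,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Fit and apply per-feature z-score normalization
#'
#' Fits per-feature mean/SD on the training matrix and standardizes any
#' matrix with them; zero-variance features map to 0. The scaler is fitted
#' on training-fold patients only — pass held-out patient ids as
#' `forbiddenIds` to have the fold-hygiene assertion enforced.
#'
#' @param train patients x features training matrix (>= 2 rows).
#' @param forbiddenIds patient ids that must not be in the fit set.
#' @return a [FeatureScaler-class].
#' @export
fitScaler <- function(train, forbiddenIds = NULL) {
  if (nrow(train) < 2L)
    stop("fitScaler: at least 2 training vectors are required")
  if (!is.null(forbiddenIds)) {
    leak <- intersect(rownames(train), forbiddenIds)
    if (length(leak))
      stop(sprintf(
        "fitScaler: fit set contains %d held-out patient id(s) (e.g. %s)",
        length(leak), leak[1L]))
  }
  mu <- colMeans(train)
  sdv <- apply(train, 2L, sd)
  sdv[!is.finite(sdv)] <- 0
  new("FeatureScaler", center = mu, scale = sdv,
      featureNames = colnames(train) %||% character(0))
}

#' @rdname fitScaler
#' @param scaler a fitted [FeatureScaler-class].
#' @param x matrix to standardize (same feature order as the fit).
#' @export
applyScaler <- function(scaler, x) {
  stopifnot(is(scaler, "FeatureScaler"))
  if (ncol(x) != length(scaler@center))
    stop("applyScaler: feature count mismatch")
  s <- scaler@scale
  inv <- ifelse(s > 0, 1 / s, 0)  # zero-variance features -> 0
  sweep(sweep(x, 2L, scaler@center, "-"), 2L, inv, "*")
}

#' @rdname fitScaler
#' @param path JSON path for scaler serialization.
#' @export
writeScaler <- function(scaler, path) {
  jsonlite::write_json(list(center = scaler@center, scale = scaler@scale,
                            feature_names = scaler@featureNames),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname fitScaler
#' @export
readScaler <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("FeatureScaler", center = as.numeric(j$center),
      scale = as.numeric(j$scale),
      featureNames = as.character(j$feature_names))
}
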