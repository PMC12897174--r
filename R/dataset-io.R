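#' Write / read a dataset directory
#'
#' On-disk layout: `manifest.csv` (patch provenance and labels, see
#' [writePatchManifest()]), `radiomics.csv` (per-patient feature table),
#' `patches.bin` (all patch arrays concatenated, little-endian float64) and
#' `patches.json` (shape, ids and wavelengths). Lossless round-trip.
#'
#' @param dataset a [GliomaDataset-class].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writePatchManifest(dataset@patches, file.path(dir, "manifest.csv"))
  writeRadiomics(dataset@radiomics, file.path(dir, "radiomics.csv"))
  d <- dim(dataset@patches[[1L]]@values)
  con <- file(file.path(dir, "patches.bin"), "wb")
  for (p in dataset@patches)
    writeBin(as.vector(p@values), con, size = 8L, endian = "little")
  close(con)
  jsonlite::write_json(list(
    dim = d, n = length(dataset@patches),
    ids = vapply(dataset@patches, function(p) p@patchId, character(1)),
    wavelengths = dataset@patches[[1L]]@wavelengths,
    classes = dataset@classes),
    file.path(dir, "patches.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "patches.json"),
                              simplifyVector = TRUE)
  man <- readPatchManifest(file.path(dir, "manifest.csv"))
  d <- as.integer(meta$dim)
  n <- as.integer(meta$n)
  wl <- as.numeric(meta$wavelengths)
  con <- file(file.path(dir, "patches.bin"), "rb")
  on.exit(close(con))
  patches <- vector("list", n)
  per <- prod(d)
  for (i in seq_len(n)) {
    v <- readBin(con, what = "numeric", n = per, size = 8L,
                 endian = "little")
    row <- man[man$patch_id == meta$ids[i], ]
    patches[[i]] <- new("HSIPatch", values = array(v, dim = d),
      wavelengths = wl, label = as.character(row$label[1L]),
      patientId = as.character(row$patient_id[1L]),
      patchId = meta$ids[i],
      origin = list(cubeId = as.character(row$cube_id[1L]),
                    row = row$row[1L], col = row$col[1L]))
  }
  rad <- read.csv(file.path(dir, "radiomics.csv"), check.names = FALSE,
                  stringsAsFactors = FALSE)
  radm <- as.matrix(rad[, setdiff(names(rad), "patient_id"), drop = FALSE])
  rownames(radm) <- as.character(rad$patient_id)
  new("GliomaDataset", patches = patches, radiomics = radm,
      classes = as.character(meta$classes))
}
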