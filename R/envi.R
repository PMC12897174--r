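## ENVI raster I/O: a flat binary file plus a text .hdr companion. Only the
## subset of the dialect needed for hyperspectral cubes is supported: data
## types 4 (float32) / 5 (float64), interleaves BSQ / BIL / BIP, little- or
## big-endian, and a wavelength list in the header. Cubes are normalized to
## the package's bands-first (bands x rows x cols) convention on read.

#' Write a hyperspectral cube as an ENVI raster
#'
#' @param cube a [RawCube-class] or [ReflectanceCube-class].
#' @param path path of the binary data file; the header is written to
#'   `<path>.hdr`.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param dataType 4 (float32) or 5 (float64).
#' @return `path`, invisibly.
#' @export
writeENVI <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                      dataType = 5L) {
  interleave <- match.arg(interleave)
  stopifnot(dataType %in% c(4L, 5L))
  a <- if (is(cube, "RawCube")) cube@intensities else cube@reflectance
  wl <- wavelengths(cube)
  d <- dim(a)  # (bands, lines, samples)
  onDisk <- switch(interleave,
    bsq = aperm(a, c(3L, 2L, 1L)),  # sample fastest, then line, then band
    bil = aperm(a, c(3L, 1L, 2L)),  # sample, band, line
    bip = aperm(a, c(1L, 3L, 2L)))  # band, sample, line
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(onDisk), con, size = if (dataType == 4L) 4L else 8L,
           endian = "little")
  hdr <- c(
    "ENVI",
    "description = { hafnet hyperspectral cube }",
    sprintf("samples = %d", d[3L]),
    sprintf("lines = %d", d[2L]),
    sprintf("bands = %d", d[1L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", dataType),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = { %s }",
            paste(format(wl, trim = TRUE, scientific = FALSE),
                  collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Read an ENVI raster into a raw cube
#'
#' Parses `<path>.hdr` (or `path` itself if it ends in `.hdr`), validates the
#' declared geometry against the file size, and returns the cube normalized
#' to bands-first order. A missing wavelength list is a format error: the
#' pipeline requires wavelength metadata.
#'
#' @param path binary data file (with `<path>.hdr` next to it) or the header.
#' @return a [RawCube-class].
#' @export
readENVI <- function(path) {
  if (grepl("\\.hdr$", path)) {
    hdrPath <- path
    path <- sub("\\.hdr$", "", path)
  } else hdrPath <- paste0(path, ".hdr")
  if (!file.exists(hdrPath)) stop("readENVI: header file not found: ", hdrPath)
  hdr <- parseENVIHeader(hdrPath)
  for (key in c("samples", "lines", "bands", "data type", "interleave"))
    if (is.null(hdr[[key]])) stop("readENVI: header missing '", key, "'")
  if (is.null(hdr[["wavelength"]]))
    stop("readENVI: header has no wavelength list; wavelength metadata is required")
  S <- as.integer(hdr$samples); L <- as.integer(hdr$lines)
  B <- as.integer(hdr$bands)
  wl <- as.numeric(strsplit(hdr$wavelength, ",")[[1]])
  if (length(wl) != B)
    stop(sprintf("readENVI: header declares %d bands but lists %d wavelengths",
                 B, length(wl)))
  dataType <- as.integer(hdr[["data type"]])
  if (!dataType %in% c(4L, 5L))
    stop("readENVI: unsupported data type ", dataType)
  size <- if (dataType == 4L) 4L else 8L
  endian <- if (!is.null(hdr[["byte order"]]) &&
                as.integer(hdr[["byte order"]]) == 1L) "big" else "little"
  n <- as.numeric(S) * L * B
  if (file.size(path) != n * size)
    stop(sprintf("readENVI: file size %d does not match %d x %d x %d elements",
                 file.size(path), B, L, S))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = size, endian = endian)
  interleave <- tolower(hdr$interleave)
  a <- switch(interleave,
    bsq = aperm(array(v, dim = c(S, L, B)), c(3L, 2L, 1L)),
    bil = aperm(array(v, dim = c(S, B, L)), c(2L, 3L, 1L)),
    bip = aperm(array(v, dim = c(B, S, L)), c(1L, 3L, 2L)),
    stop("readENVI: unsupported interleave '", interleave, "'"))
  rawCube(a, wl, meta = list(source = path, interleave = interleave))
}

parseENVIHeader <- function(hdrPath) {
  lines <- readLines(hdrPath, warn = FALSE)
  if (!length(lines) || !grepl("^ENVI", lines[1L]))
    stop("readENVI: not an ENVI header (missing magic line)")
  out <- list()
  # accumulate lines until { ... } braces balance, then split at the first '='
  buf <- ""
  for (ln in lines[-1L]) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    nOpen <- lengths(regmatches(buf, gregexpr("\\{", buf)))
    nClose <- lengths(regmatches(buf, gregexpr("\\}", buf)))
    if (nOpen > nClose) next
    m <- regmatches(buf, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", buf))[[1]]
    if (length(m) == 3L) {
      val <- m[3L]
      val <- gsub("^\\{\\s*|\\s*\\}$", "", val)
      out[[tolower(m[2L])]] <- trimws(val)
    }
    buf <- ""
  }
  out
}

#' Write / read the package's plain-array cube container
#'
#' A portable alternative to ENVI: wavelengths and shape as a JSON sidecar,
#' data as a flat little-endian float64 file. Lossless round-trip.
#'
#' @param cube a [RawCube-class].
#' @param path data file path; metadata goes to `<path>.json`.
#' @return `writeCube`: `path` invisibly; `readCube`: a [RawCube-class].
#' @export
writeCube <- function(cube, path) {
  stopifnot(is(cube, "RawCube"))
  meta <- list(dim = dim(cube@intensities), wavelengths = cube@wavelengths)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(cube@intensities), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname writeCube
#' @export
readCube <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = prod(d), size = 8L,
               endian = "little")
  rawCube(array(v, dim = d), as.numeric(meta$wavelengths))
}
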