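#' @title Generics for hafnet data containers
#' @name hafnet-generics
#' @keywords internal
NULL

#' @describeIn hafnet-generics wavelength grid (nm) of a cube, patch or ranking
#' @param x an object
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @describeIn hafnet-generics number of spectral bands
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @describeIn hafnet-generics spatial dimensions (rows, cols)
#' @export
setGeneric("spatialDim", function(x) standardGeneric("spatialDim"))

#' @describeIn hafnet-generics the underlying data array
#' @export
setGeneric("values3d", function(x) standardGeneric("values3d"))

#' @describeIn hafnet-generics class label(s) carried by an object
#' @export
setGeneric("patchLabels", function(x) standardGeneric("patchLabels"))

#' @describeIn hafnet-generics patient identifier(s)
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @describeIn hafnet-generics patch identifier(s)
#' @export
setGeneric("patchIds", function(x) standardGeneric("patchIds"))

#' @describeIn hafnet-generics per-band mutual-information scores
#' @export
setGeneric("miScores", function(x) standardGeneric("miScores"))

#' @describeIn hafnet-generics indices of the selected spectral bands
#' @export
setGeneric("selectedBands", function(x) standardGeneric("selectedBands"))

#' @describeIn hafnet-generics macro-averaged one-vs-rest AUC
#' @export
setGeneric("macroAUC", function(x) standardGeneric("macroAUC"))

#' @describeIn hafnet-generics confusion matrix (rows = truth, cols = predicted)
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
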