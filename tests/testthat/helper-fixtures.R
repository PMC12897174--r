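# shared fixtures: everything is generated in code at test time

# a small synthetic spec that keeps every downstream stage fast
tinySpec <- function(...) {
  args <- utils::modifyList(
    list(classPatchCounts = rep(8L, 6L), bands = 24L, patchSize = 10L,
         patientsPerClass = 2L, radiomicsDim = 30L,
         radiomicsInformativeDim = 12L, seed = 11L),
    list(...))
  do.call(ciSyntheticSpec, args)
}

# a small architecture whose forward pass runs in milliseconds
tinyNetConfig <- function(...) {
  args <- list(nClasses = 3L, inBands = 8L, patchSize = 8L, stemOut = 4L,
               block1Out = 6L, block2Out = 8L, attentionReduction = 2L,
               hsiProjDim = 10L, mriInDim = 7L, mriHiddenDims = c(6L, 5L),
               fusionDim = 9L, dropout = 0, ...)
  do.call(hafnetConfig, args[!duplicated(names(args), fromLast = TRUE)])
}

relErr <- function(a, b) abs(a - b) / pmax(1e-8, abs(a) + abs(b))

# central finite difference of f at x[ii]
fdAt <- function(f, x, ii, eps = 1e-6) {
  xp <- x; xp[ii] <- xp[ii] + eps
  xm <- x; xm[ii] <- xm[ii] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

# flat reflectance cube fixture
flatCube <- function(bands = 5L, rows = 12L, cols = 10L, value = 0.5) {
  new("ReflectanceCube",
      reflectance = array(value, dim = c(bands, rows, cols)),
      wavelengths = seq(400, by = 2, length.out = bands), clipMax = 1.5)
}
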