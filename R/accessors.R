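## Constructors, accessors and show methods for the container classes.

#' Construct a hypercomplex FID from P- and N-type complex matrices
#'
#' A phase-modulated 2D acquisition yields two complex matrices: the P-type
#' (Echo) dataset with `+i` indirect-frequency modulation and the N-type
#' (Anti-Echo) dataset with `-i` modulation.  Rows index the indirect
#' evolution time t1, columns the direct acquisition time t2.
#'
#' @param pData complex matrix, P-type (Echo) time-domain data.
#' @param nData complex matrix, N-type (Anti-Echo) time-domain data.
#' @return A [HypercomplexFID-class] object.
#' @export
hypercomplexFid <- function(pData, nData) {
  if (is.numeric(pData)) storage.mode(pData) <- "complex"
  if (is.numeric(nData)) storage.mode(nData) <- "complex"
  new("HypercomplexFID", pData = pData, nData = nData)
}

#' @describeIn hypercomplexFid P-type component.
#' @param fid a `HypercomplexFID`.
#' @export
fidP <- function(fid) fid@pData

#' @describeIn hypercomplexFid N-type component.
#' @export
fidN <- function(fid) fid@nData

#' Construct an absorptive (real, frequency-domain) spectrum
#'
#' @param values real matrix, indirect x direct, unshifted frequency layout.
#' @param metadata free-form provenance list.
#' @return An [AbsorptiveSpectrum-class].
#' @export
absorptiveSpectrum <- function(values, metadata = list()) {
  storage.mode(values) <- "double"
  new("AbsorptiveSpectrum", values = values, metadata = metadata)
}

#' @rdname absorptiveSpectrum
#' @param flavor `"echo"` or `"anti_echo"`.
#' @export
newEchoSpectrum <- function(values, flavor, metadata = list()) {
  storage.mode(values) <- "double"
  new("EchoSpectrum", values = values, flavor = flavor, metadata = metadata)
}

#' Spectrum intensity matrix
#'
#' @param x a spectrum-like object.
#' @name specValues
#' @export
setMethod("specValues", "Spectrum2D", function(x) x@values)

#' @rdname specValues
#' @export
setMethod("specValues", "VirtualEcho", function(x) x@values)

#' @rdname specValues
#' @export
setMethod("specValues", "UncertaintyMap", function(x) x@sigma)

#' @describeIn absorptiveSpectrum Echo/Anti-Echo flavor of a twist spectrum.
#' @param x an `EchoSpectrum`.
#' @export
echoFlavor <- function(x) x@flavor

#' @describeIn absorptiveSpectrum per-iteration IST residual history, if the
#'   spectrum came out of a compressed-sensing reconstruction.
#' @export
residualHistory <- function(x) x@metadata$residuals

#' Per-point uncertainty map accessor
#' @param x an `UncertaintyMap`.
#' @export
sigmaValues <- function(x) x@sigma

#' NUS schedule constructor and accessors
#'
#' A non-uniform sampling schedule is a strictly increasing set of zero-based
#' indirect-dimension increment indices.
#'
#' @param indices integer vector of sampled increments (zero-based).
#' @param nIncrements total number of indirect increments of the full grid.
#' @return A [NUSSchedule-class].
#' @export
nusSchedule <- function(indices, nIncrements) {
  new("NUSSchedule", indices = as.integer(sort(unique(indices))),
      nIncrements = as.integer(nIncrements))
}

#' @describeIn nusSchedule sampled increment indices (zero-based, sorted).
#' @param schedule a `NUSSchedule`.
#' @export
scheduleIndices <- function(schedule) schedule@indices

#' @describeIn nusSchedule total increments of the full grid.
#' @export
scheduleSize <- function(schedule) schedule@nIncrements

#' @export
setMethod("dim", "HypercomplexFID", function(x) dim(x@pData))

#' @export
setMethod("dim", "Spectrum2D", function(x) dim(x@values))

#' @export
setMethod("dim", "VirtualEcho", function(x) dim(x@values))

#' @export
setMethod("dim", "UncertaintyMap", function(x) dim(x@sigma))

#' @export
setMethod("length", "SpectrumPairSet", function(x) length(x@inputs))

#' @describeIn generatePairs input (corrupted) spectra of the pair set.
#' @param x a `SpectrumPairSet`.
#' @export
pairInputs <- function(x) x@inputs

#' @describeIn generatePairs reference absorptive spectra of the pair set.
#' @export
pairReferences <- function(x) x@references

#' @describeIn generatePairs per-pair derived seeds.
#' @export
pairSeeds <- function(x) x@seeds

setMethod("show", "HypercomplexFID", function(object) {
  d <- dim(object)
  cat("HypercomplexFID:", d[1], "x", d[2],
      "complex points (indirect x direct), P/N pair\n")
})

setMethod("show", "AbsorptiveSpectrum", function(object) {
  d <- dim(object)
  cat("AbsorptiveSpectrum:", d[1], "x", d[2],
      "real points; max |S| =", format(max(abs(object@values)), digits = 4),
      "\n")
})

setMethod("show", "EchoSpectrum", function(object) {
  d <- dim(object)
  cat("EchoSpectrum (", object@flavor, "): ", d[1], " x ", d[2],
      " real points (phase-twisted)\n", sep = "")
})

setMethod("show", "VirtualEcho", function(object) {
  d <- dim(object)
  cat("VirtualEcho:", d[1], "x", d[2], "complex time-domain points\n")
})

setMethod("show", "UncertaintyMap", function(object) {
  d <- dim(object)
  cat("UncertaintyMap:", d[1], "x", d[2], "points; median sigma =",
      format(median(object@sigma), digits = 4), "\n")
})

setMethod("show", "NUSSchedule", function(object) {
  cat("NUSSchedule:", length(object@indices), "of", object@nIncrements,
      "increments sampled\n")
})

setMethod("show", "QualityReport", function(object) {
  cat("QualityReport: RMSD =", format(object@rmsd, digits = 5),
      "; R2s =", format(object@r2, digits = 5),
      "; support =", object@nSupport, "points (threshold",
      object@threshold, ")\n")
})

setMethod("show", "PSQReport", function(object) {
  cat("pSQ (normalized sigma over support, n =", object@nPoints, "):\n",
      "  median =", format(object@median, digits = 5),
      " mean =", format(object@mean, digits = 5),
      " IQR = [", format(object@q1, digits = 5), ",",
      format(object@q3, digits = 5), "]\n")
})

setMethod("show", "SpectrumPairSet", function(object) {
  cat("SpectrumPairSet:", length(object@inputs), "pairs, mode =",
      object@mode, "\n")
})

setMethod("show", "WNNModel", function(object) {
  cat("WNNModel:", nrow(object@spec@kernels), "dilated conv layers +",
      "1x1 projection;", wnnParamCount(object), "parameters\n")
})

setMethod("show", "CascadeModel", function(object) {
  cat("CascadeModel:", length(object@models), "stage(s), flavor =",
      object@cascade@flavor, "\n")
})

#' Quality-report accessors
#' @param x a `QualityReport`.
#' @export
reportRmsd <- function(x) x@rmsd

#' @rdname reportRmsd
#' @export
reportR2 <- function(x) x@r2

#' pSQ report accessors
#' @param x a `PSQReport`.
#' @export
psqMedian <- function(x) x@median

#' @rdname psqMedian
#' @export
psqMean <- function(x) x@mean
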