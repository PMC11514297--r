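#' @export
setGeneric("specValues", function(x) standardGeneric("specValues"))

#' @export
setGeneric("processSpectrum", function(fid, ...)
  standardGeneric("processSpectrum"))

#' @export
setGeneric("toVirtualEcho", function(spectrum, ...)
  standardGeneric("toVirtualEcho"))

#' @export
setGeneric("fromVirtualEcho", function(ve, ...)
  standardGeneric("fromVirtualEcho"))

#' @export
setGeneric("zeroQuadrants", function(ve, which, ...)
  standardGeneric("zeroQuadrants"))

#' @export
setGeneric("echoSpectrum", function(spectrum, flavor, ...)
  standardGeneric("echoSpectrum"))

#' @export
setGeneric("nusCorrupt", function(x, schedule, ...)
  standardGeneric("nusCorrupt"))

#' @export
setGeneric("addNoise", function(fid, snr, seed, ...)
  standardGeneric("addNoise"))

#' @export
setGeneric("applyImbalance", function(fid, deficit)
  standardGeneric("applyImbalance"))
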