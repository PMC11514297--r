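## Central S4 containers.  All 2D arrays are stored indirect x direct
## (rows = indirect dimension t1/omega1, columns = direct dimension t2/omega2)
## in the standard unshifted FFT layout: index 1 is t = 0 (or omega = 0),
## indices 2..T are positive times ascending, index T + 1 is Nyquist, and the
## remaining indices are negative times ascending towards -1.

setClass("SimConfig",
  representation(
    nIndirect = "integer", nDirect = "integer", nExponentials = "integer",
    snr = "numeric",
    freqRange = "numeric", phaseRange = "numeric", ampRange = "numeric",
    tauIndirectRange = "numeric", tauDirectRange = "numeric",
    imbalanceDeficit = "numeric", literalIndirectGrowth = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@nIndirect < 2L || object@nDirect < 2L)
      msg <- c(msg, "nIndirect and nDirect must be >= 2")
    if (object@nExponentials < 0L)
      msg <- c(msg, "nExponentials must be >= 0")
    if (!(object@snr > 0))
      msg <- c(msg, "snr must be positive (Inf disables noise)")
    for (nm in c("freqRange", "phaseRange", "ampRange",
                 "tauIndirectRange", "tauDirectRange")) {
      r <- slot(object, nm)
      if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
        msg <- c(msg, paste0(nm, " must be a finite (lo, hi) pair with lo <= hi"))
    }
    if (all(is.finite(object@tauIndirectRange)) &&
        object@tauIndirectRange[1] <= 0)
      msg <- c(msg, "indirect decay times must be positive")
    if (all(is.finite(object@tauDirectRange)) && object@tauDirectRange[1] <= 0)
      msg <- c(msg, "direct decay times must be positive")
    if (object@imbalanceDeficit < 0 || object@imbalanceDeficit >= 1)
      msg <- c(msg, "imbalanceDeficit must be in [0, 1)")
    if (length(msg)) msg else TRUE
  })

setClass("HypercomplexFID",
  representation(pData = "matrix", nData = "matrix"),
  validity = function(object) {
    if (!is.complex(object@pData) || !is.complex(object@nData))
      return("pData and nData must be complex matrices")
    if (!identical(dim(object@pData), dim(object@nData)))
      return("pData and nData must have identical shape")
    if (any(!is.finite(object@pData)) || any(!is.finite(object@nData)))
      return("FID entries must be finite")
    TRUE
  })

setClass("Spectrum2D",
  representation(values = "matrix", metadata = "list", "VIRTUAL"))

setClass("AbsorptiveSpectrum", contains = "Spectrum2D",
  validity = function(object) {
    if (!is.numeric(object@values)) return("values must be a real matrix")
    TRUE
  })

setClass("EchoSpectrum", contains = "Spectrum2D",
  representation(flavor = "character"),
  validity = function(object) {
    if (!is.numeric(object@values)) return("values must be a real matrix")
    if (!object@flavor %in% c("echo", "anti_echo"))
      return("flavor must be 'echo' or 'anti_echo'")
    TRUE
  })

setClass("VirtualEcho",
  representation(values = "matrix", metadata = "list"),
  validity = function(object) {
    if (!is.complex(object@values)) return("values must be a complex matrix")
    if (any(dim(object@values) %% 2L != 0L))
      return("VE grids must have even extents (doubled FID grid)")
    TRUE
  })

setClass("UncertaintyMap",
  representation(sigma = "matrix", metadata = "list"),
  validity = function(object) {
    if (!is.numeric(object@sigma)) return("sigma must be a real matrix")
    if (any(object@sigma <= 0)) return("sigma entries must be positive")
    TRUE
  })

setClass("NUSSchedule",
  representation(indices = "integer", nIncrements = "integer"),
  validity = function(object) {
    idx <- object@indices
    if (length(idx) < 1L) return("schedule must be non-empty")
    if (any(duplicated(idx))) return("schedule indices must be unique")
    if (is.unsorted(idx, strictly = TRUE))
      return("schedule indices must be strictly increasing")
    if (any(idx < 0L) || any(idx >= object@nIncrements))
      return("schedule indices must lie in [0, nIncrements)")
    TRUE
  })

setClass("ISTConfig",
  representation(
    nIterations = "integer", thresholdFactor = "numeric",
    noiseFloorFactor = "numeric", relFloor = "numeric",
    enforceConsistency = "logical"),
  validity = function(object) {
    if (object@nIterations < 1L) return("nIterations must be >= 1")
    if (object@thresholdFactor <= 0 || object@thresholdFactor >= 1)
      return("thresholdFactor must be in (0, 1)")
    if (object@relFloor < 0) return("relFloor must be >= 0")
    TRUE
  })

setClass("CompletionProblem",
  representation(known = "matrix", mask = "matrix", flavor = "character"),
  validity = function(object) {
    if (!is.complex(object@known)) return("known data must be complex")
    if (!identical(dim(object@known), dim(object@mask)))
      return("known data and mask must share a grid")
    if (any(object@mask < 0 | object@mask > 1))
      return("mask weights must lie in [0, 1]")
    if (any(abs(object@known[object@mask == 0]) > 0))
      return("known data must vanish outside the mask support")
    TRUE
  })

setClass("WNNSpec",
  representation(kernels = "matrix", dilations = "matrix",
                 filters = "integer"),
  validity = function(object) {
    if (ncol(object@kernels) != 2L || ncol(object@dilations) != 2L)
      return("kernels and dilations must be n x 2 integer matrices")
    if (nrow(object@kernels) != nrow(object@dilations))
      return("kernels and dilations must describe the same layers")
    if (nrow(object@kernels) > 0 &&
        (any(object@kernels < 1) || any(object@dilations < 1)))
      return("kernel and dilation entries must be >= 1")
    if (object@filters < 1L) return("filters must be >= 1")
    TRUE
  })

setClass("CascadeConfig",
  representation(nStages = "integer", flavor = "character"),
  validity = function(object) {
    if (object@nStages < 1L) return("nStages must be >= 1")
    if (!object@flavor %in% c("echo", "anti_echo"))
      return("flavor must be 'echo' or 'anti_echo'")
    TRUE
  })

setClass("TrainConfig",
  representation(
    learningRate = "numeric", batchSize = "integer", maxEpochs = "integer",
    patience = "integer", valFraction = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@learningRate <= 0) return("learningRate must be positive")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@maxEpochs < 0L) return("maxEpochs must be >= 0")
    if (object@valFraction <= 0 || object@valFraction >= 1)
      return("valFraction must be in (0, 1)")
    TRUE
  })

setClass("TileScheme",
  representation(specDims = "integer", outExtent = "integer",
                 inExtent = "integer", padBefore = "integer",
                 gridDims = "integer"))

setClass("WNNModel",
  representation(spec = "WNNSpec", layers = "list", seed = "integer"))

setClass("CascadeModel",
  representation(models = "list", spec = "WNNSpec",
                 cascade = "CascadeConfig", outExtent = "integer",
                 histories = "list"))

setClass("UncertaintyModel",
  representation(model = "WNNModel", floor = "numeric",
                 outExtent = "integer", history = "list"))

setClass("QualityReport",
  representation(rmsd = "numeric", r2 = "numeric", nSupport = "integer",
                 threshold = "numeric"),
  validity = function(object) {
    if (object@rmsd < 0) return("rmsd must be >= 0")
    if (object@r2 < 0 || object@r2 > 1) return("r2 must be in [0, 1]")
    if (object@nSupport < 1L) return("support must contain >= 1 point")
    TRUE
  })

setClass("PSQReport",
  representation(mean = "numeric", median = "numeric",
                 q1 = "numeric", q3 = "numeric",
                 whiskerLow = "numeric", whiskerHigh = "numeric",
                 nPoints = "integer", threshold = "numeric"),
  validity = function(object) {
    if (object@nPoints < 1L) return("nPoints must be >= 1")
    if (object@median < object@whiskerLow - 1e-12 ||
        object@median > object@whiskerHigh + 1e-12)
      return("median must lie within the whiskers")
    TRUE
  })

setClass("SpectrumPairSet",
  representation(inputs = "list", references = "list", seeds = "integer",
                 mode = "character", config = "SimConfig"),
  validity = function(object) {
    if (length(object@inputs) != length(object@references))
      return("inputs and references must pair up")
    if (length(object@seeds) != length(object@inputs))
      return("one seed per pair is required")
    if (!object@mode %in% c("echo", "anti_echo", "nus"))
      return("mode must be echo, anti_echo or nus")
    TRUE
  })
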