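## The multi-stage reconstruction cascade: networks alternate with an
## inter-stage data-consistency correction that restores the measured
## (Echo-side) Virtual Echo quadrants and slightly attenuates the predicted
## opposite-side quadrants.

#' Cascade configuration
#'
#' @param nStages number of network stages (default 5).
#' @param flavor `"echo"` or `"anti_echo"`; Anti-Echo data are handled by
#'   reflecting the indirect frequency axis and reusing Echo-trained
#'   weights.
#' @export
cascadeConfig <- function(nStages = 5L, flavor = "echo") {
  new("CascadeConfig", nStages = as.integer(nStages), flavor = flavor)
}

#' Step-dependent correction factor
#'
#' `C(i) = 1 - 0.05 * 2^(1 - i)`: 0.95, 0.975, 0.9875, 0.99375 for stages
#' 1-4.  Strictly increasing towards (but never reaching) 1, so early-stage
#' predictions of the missing quadrants are trusted less than late ones.
#'
#' @param stage stage index `i >= 1`.
#' @export
correctionFactor <- function(stage) {
  if (any(stage < 1)) stop("stage must be >= 1")
  1 - 0.05 * 2^(1 - stage)
}

#' Inter-stage consistency correction
#'
#' For Echo-flavor input, computes
#' `S_cor = S_echo + C(i) * FT[Z_E[iFT[S_pred]]]`: the predicted spectrum's
#' Anti-Echo part (Echo quadrants zeroed in its Virtual Echo presentation)
#' is attenuated by `C(i)` and added to the measured twist spectrum, which
#' restores the measured quadrants exactly as `C -> 1`.  Roles of the
#' projectors swap for Anti-Echo flavor.  The correction is not applied
#' after the final stage.
#'
#' @param sEcho the measured `EchoSpectrum`.
#' @param sPred predicted `AbsorptiveSpectrum` (or matrix) from the current
#'   stage.
#' @param stage stage index (1-based; must precede the final stage).
#' @param nStages total stages, used to validate `stage` (default 5).
#' @return An `AbsorptiveSpectrum`, the corrected input for the next stage.
#' @export
correctionStep <- function(sEcho, sPred, stage, nStages = 5L) {
  if (stage < 1 || stage > nStages - 1L)
    stop("correction applies to stages 1..", nStages - 1L, " only")
  pred <- if (is(sPred, "Spectrum2D")) sPred@values else sPred
  ve <- ifft2(pred)
  side <- if (echoFlavor(sEcho) == "echo") "anti" else "echo"
  mask <- quadrantWeights(dim(pred), side)
  predMissing <- Re(fft2(ve * mask))
  absorptiveSpectrum(sEcho@values + correctionFactor(stage) * predMissing,
                     metadata = sEcho@metadata)
}

#' Train the reconstruction cascade
#'
#' Stages are trained sequentially: stage 1 on the measured twist spectra,
#' each later stage on the consistency-corrected outputs of the frozen
#' upstream stages.  Inputs and targets of every stage are normalized by the
#' Euclidean norm of that stage's input spectrum; spectra larger than the
#' network output extent are tiled (see [makeTileScheme()]).  Zero-norm
#' inputs are skipped with a warning.
#'
#' @param pairs a `SpectrumPairSet` of (twist input, absorptive reference)
#'   pairs, or a list with elements `inputs` and `references`.
#' @param trainCfg a [trainConfig()].
#' @param cascadeCfg a [cascadeConfig()].
#' @param spec a [wnnSpec()].
#' @param outExtent output tile extent; defaults to
#'   `pmin(spectrum extent, c(32, 64))`.
#' @return A `CascadeModel` with per-stage training histories.
#' @export
trainCascade <- function(pairs, trainCfg, cascadeCfg = cascadeConfig(1L),
                         spec = wnnSpec(), outExtent = NULL) {
  inputs <- if (is(pairs, "SpectrumPairSet")) pairs@inputs else pairs$inputs
  refs <- if (is(pairs, "SpectrumPairSet")) pairs@references
          else pairs$references
  if (length(inputs) == 0L) stop("empty training set")
  getVals <- function(x) if (is(x, "Spectrum2D")) x@values else x
  echoVals <- lapply(inputs, getVals)
  refVals <- lapply(refs, getVals)
  if (cascadeCfg@flavor == "anti_echo") {
    echoVals <- lapply(echoVals, reflectIndirect)
    refVals <- lapply(refVals, reflectIndirect)
  }
  dims <- dim(echoVals[[1]])
  if (is.null(outExtent)) outExtent <- pmin(dims, c(32L, 64L))
  outExtent <- as.integer(outExtent)
  red <- receptiveReduction(spec)
  scheme <- makeTileScheme(dims, outExtent, red)
  models <- vector("list", cascadeCfg@nStages)
  histories <- vector("list", cascadeCfg@nStages)
  current <- echoVals
  for (stage in seq_len(cascadeCfg@nStages)) {
    samples <- list()
    for (p in seq_along(current)) {
      nu <- sqrt(sum(current[[p]]^2))
      if (nu == 0) {
        warning("skipping zero-norm input spectrum ", p)
        next
      }
      ins <- tileInputs(current[[p]] / nu, scheme)
      tgts <- tileTargets(refVals[[p]] / nu, scheme)
      for (q in seq_along(ins))
        samples[[length(samples) + 1L]] <-
          list(input = ins[[q]], target = tgts[[q]])
    }
    if (length(samples) == 0L) stop("no usable training samples")
    model <- buildWnn(spec, seed = trainCfg@seed + stage)
    fit <- trainWnn(samples, model, cfg = trainCfg, loss = "mse")
    models[[stage]] <- fit$model
    histories[[stage]] <- fit$history
    if (stage < cascadeCfg@nStages) {
      current <- lapply(seq_along(current), function(p) {
        pred <- applyWnn(fit$model, current[[p]], outExtent)
        sE <- newEchoSpectrum(echoVals[[p]], "echo")
        correctionStep(sE, pred, stage, cascadeCfg@nStages)@values
      })
    }
  }
  new("CascadeModel", models = models, spec = spec, cascade = cascadeCfg,
      outExtent = outExtent, histories = histories)
}

#' Reconstruct a pure-absorption spectrum with a trained cascade
#'
#' Alternates network application (tile, normalize, predict, stitch,
#' denormalize) with the inter-stage consistency correction for all stages
#' but the last; the final stage output is returned uncorrected.  Anti-Echo
#' input is reflected along the indirect frequency axis, run through the
#' Echo-trained cascade, and reflected back.
#'
#' @param echo an `EchoSpectrum`.
#' @param cascadeModel a trained `CascadeModel`.
#' @return An `AbsorptiveSpectrum`.
#' @export
reconstructAi <- function(echo, cascadeModel) {
  stopifnot(is(echo, "EchoSpectrum"))
  vals <- echo@values
  reflected <- echoFlavor(echo) == "anti_echo"
  if (reflected) vals <- reflectIndirect(vals)
  sE <- newEchoSpectrum(vals, "echo")
  n <- length(cascadeModel@models)
  current <- vals
  pred <- current
  for (stage in seq_len(n)) {
    pred <- applyWnn(cascadeModel@models[[stage]], current,
                     cascadeModel@outExtent)
    if (stage < n)
      current <- correctionStep(sE, pred, stage, n)@values
  }
  if (reflected) pred <- reflectIndirect(pred)
  absorptiveSpectrum(pred, metadata = echo@metadata)
}
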