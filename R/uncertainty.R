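## Per-point uncertainty prediction and the reference-free pSQ score.
##
## A network trained with the Gaussian negative log-likelihood learns, from
## the corrupted input spectrum alone, the standard deviation sigma of the
## error a fixed reconstruction method makes at every spectral point.  The
## distribution of predicted sigma, normalized by the reconstruction's
## maximum intensity over its support, is the pSQ score.

#' Gaussian negative log-likelihood (up to a constant)
#'
#' `nll(y, mu, sigma) = (y - mu)^2 / (2 sigma^2) + log(sigma)`.
#' For fixed `|y - mu| = d` the expression is minimized at `sigma = d`.
#'
#' @param y ground-truth value(s).
#' @param mu value(s) produced by the reconstruction method.
#' @param sigma predicted standard deviation(s), strictly positive.
#' @export
nll <- function(y, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  (y - mu)^2 / (2 * sigma^2) + log(sigma)
}

#' Train an uncertainty network for a fixed reconstruction method
#'
#' The network sees only the corrupted input spectrum and outputs a sigma
#' map; the loss is the mean negative log-likelihood with the method's
#' reconstruction held fixed as the Gaussian mean.  Positivity of sigma is
#' enforced by a rectifier on the network output plus a small floor.
#' Inputs and residuals are normalized per spectrum by the input's
#' Euclidean norm, so predictions scale with the data.
#'
#' @param inputs list of corrupted input spectra (matrices or `Spectrum2D`).
#' @param reconstructions list of reconstructions by the fixed method.
#' @param truths list of ground-truth absorptive spectra.
#' @param spec a [wnnSpec()].
#' @param trainCfg a [trainConfig()].
#' @param outExtent output tile extent (default
#'   `pmin(spectrum extent, c(32, 64))`).
#' @param floor sigma floor added after the rectifier (default 1e-6, in
#'   input-normalized units).
#' @return An `UncertaintyModel`.
#' @export
trainUncertainty <- function(inputs, reconstructions, truths, spec,
                             trainCfg, outExtent = NULL, floor = 1e-6) {
  if (length(inputs) == 0L) stop("empty training set")
  if (length(inputs) != length(reconstructions) ||
      length(inputs) != length(truths))
    stop("inputs, reconstructions and truths must have equal length")
  getVals <- function(x) if (is(x, "Spectrum2D")) x@values else x
  dims <- dim(getVals(inputs[[1]]))
  if (is.null(outExtent)) outExtent <- pmin(dims, c(32L, 64L))
  outExtent <- as.integer(outExtent)
  scheme <- makeTileScheme(dims, outExtent, receptiveReduction(spec))
  samples <- list()
  for (p in seq_along(inputs)) {
    x <- getVals(inputs[[p]])
    mu <- getVals(reconstructions[[p]])
    y <- getVals(truths[[p]])
    if (!identical(dim(x), dim(mu)) || !identical(dim(x), dim(y)))
      stop("mismatched grids in training triple ", p)
    nu <- sqrt(sum(x^2))
    if (nu == 0) {
      warning("skipping zero-norm input spectrum ", p)
      next
    }
    ins <- tileInputs(x / nu, scheme)
    res2 <- tileTargets(((y - mu) / nu)^2, scheme)
    for (q in seq_along(ins))
      samples[[length(samples) + 1L]] <-
        list(input = ins[[q]], target = res2[[q]])
  }
  if (length(samples) == 0L) stop("no usable training samples")
  ## start sigma at the RMS of the observed residuals so the network only
  ## has to learn the spatial variation, not the overall scale
  res2Mean <- mean(vapply(samples, function(s) mean(s$target), numeric(1)))
  model <- buildWnn(spec, seed = trainCfg@seed,
                    finalBias = max(sqrt(res2Mean), floor),
                    finalScale = 0.1)
  fit <- trainWnn(samples, model, cfg = trainCfg, loss = "nll",
                  sigmaFloor = floor)
  new("UncertaintyModel", model = fit$model, floor = floor,
      outExtent = outExtent, history = fit$history)
}

#' Predict the per-point uncertainty map for an input spectrum
#'
#' @param input the corrupted input spectrum (matrix or `Spectrum2D`) on
#'   the training grid.
#' @param model a trained `UncertaintyModel`.
#' @return An `UncertaintyMap` covering the full grid (all entries > 0).
#' @export
predictSigma <- function(input, model) {
  x <- if (is(input, "Spectrum2D")) input@values else input
  nu <- sqrt(sum(x^2))
  if (nu == 0) nu <- 1
  scheme <- makeTileScheme(dim(x), model@outExtent,
                           receptiveReduction(model@model@spec))
  ins <- tileInputs(x / nu, scheme)
  preds <- lapply(ins, function(p) {
    raw <- cppWnnForward(p, model@model@layers)
    pmax(raw, 0) + model@floor
  })
  sigma <- stitchPatches(preds, scheme) * nu
  new("UncertaintyMap", sigma = sigma)
}

#' Empirical confidence-interval coverage
#'
#' Fraction of points whose true value lies within the central
#' `level`-probability band of the predicted Gaussian:
#' `|y - mu| <= z(level) * sigma` with `z(0.95) = 1.959964`.
#'
#' @param y,mu,sigma matched arrays of truth, reconstruction and predicted
#'   standard deviation.
#' @param level coverage level in (0, 1).
#' @export
coverage <- function(y, mu, sigma, level = 0.95) {
  if (length(y) != length(mu) || length(y) != length(sigma))
    stop("y, mu and sigma must have matching shapes")
  if (!(level > 0 && level < 1)) stop("level must lie in (0, 1)")
  z <- qnorm((1 + level) / 2)
  mean(abs(y - mu) <= z * sigma)
}

#' Reference-free spectrum quality score (pSQ)
#'
#' Predicted uncertainties are normalized by the maximum absolute intensity
#' of the reconstruction, and their distribution is summarized over the
#' points whose reconstructed intensity exceeds `threshold` of that
#' maximum.  Lower values mean better predicted spectrum quality; the score
#' needs no reference spectrum.  The median is the headline (robust)
#' statistic; the mean is also reported.
#'
#' @param sigmaMap an `UncertaintyMap`.
#' @param reconstruction the reconstructed spectrum the map refers to.
#' @param threshold support threshold as a fraction of the maximum
#'   intensity (default 0.01).
#' @return A `PSQReport` (mean, median, quartiles, Tukey whiskers, n).
#' @export
psqScore <- function(sigmaMap, reconstruction, threshold = 0.01) {
  vals <- if (is(reconstruction, "Spectrum2D")) reconstruction@values
          else reconstruction
  sigma <- if (is(sigmaMap, "UncertaintyMap")) sigmaMap@sigma else sigmaMap
  if (!identical(dim(vals), dim(sigma)))
    stop("sigma map and reconstruction grids differ")
  mx <- max(abs(vals))
  if (mx == 0) stop("reconstruction is identically zero")
  support <- if (threshold > 0) abs(vals) > threshold * mx
             else matrix(TRUE, nrow(vals), ncol(vals))
  if (!any(support)) stop("empty support at this threshold")
  sn <- sigma[support] / mx
  qs <- quantile(sn, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- qs[3] - qs[1]
  lowCand <- sn[sn >= qs[1] - 1.5 * iqr]
  highCand <- sn[sn <= qs[3] + 1.5 * iqr]
  new("PSQReport", mean = mean(sn), median = qs[2], q1 = qs[1], q3 = qs[3],
      whiskerLow = min(lowCand), whiskerHigh = max(highCand),
      nPoints = as.integer(sum(support)), threshold = threshold)
}
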