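## Dilated-convolution network (WNN): architecture spec, construction,
## forward pass, tiling of full spectra into network-sized patches, and the
## Adam/early-stopping training engine shared by the reconstruction cascade
## and the uncertainty estimator.

#' Dilated-convolution network architecture
#'
#' The default is the five-layer stack used for 2D spectral pattern
#' recognition: layer 1 has a 2 x 4 kernel without dilation; layer m
#' (m = 2..5) has a 2 x 2 kernel with dilation `(2^(m-1), 2^m)`; every layer
#' carries `filters` channels with rectifier activations and no padding, and
#' a final 1 x 1 linear projection reduces to one channel (no rectifier, so
#' negative spectral values stay representable).  With the default stack the
#' receptive field shrinks a 63 x 127 input to a 32 x 64 output.
#'
#' @param nLayers number of dilated convolution layers.
#' @param filters channels per layer (default 50).
#' @param kernels optional `nLayers x 2` matrix of kernel extents; default
#'   `(2,4)` then `(2,2)`.
#' @param dilations optional `nLayers x 2` matrix of dilation rates; default
#'   `(1,1)` then `(2^(m-1), 2^m)`.
#' @return A `WNNSpec`.
#' @export
wnnSpec <- function(nLayers = 5L, filters = 50L, kernels = NULL,
                    dilations = NULL) {
  nLayers <- as.integer(nLayers)
  if (is.null(kernels)) {
    kernels <- matrix(2L, nLayers, 2L)
    if (nLayers >= 1L) kernels[1, ] <- c(2L, 4L)
  }
  if (is.null(dilations)) {
    dilations <- matrix(1L, nLayers, 2L)
    if (nLayers >= 2L)
      for (m in 2:nLayers) dilations[m, ] <- c(2L^(m - 1L), 2L^m)
  }
  storage.mode(kernels) <- "integer"
  storage.mode(dilations) <- "integer"
  new("WNNSpec", kernels = kernels, dilations = dilations,
      filters = as.integer(filters))
}

## Per-dimension shrink of the valid dilated stack:
## sum over layers of (kernel - 1) * dilation.
receptiveReduction <- function(spec) {
  if (nrow(spec@kernels) == 0L) return(c(0L, 0L))
  as.integer(colSums((spec@kernels - 1L) * spec@dilations))
}

#' Input extent required for a given output extent
#'
#' For a valid (no-padding) dilated stack the input must exceed the output
#' by `sum((kernel - 1) * dilation)` in each dimension; the default
#' five-layer spec needs `output + (31, 63)`.
#'
#' @param spec a [wnnSpec()].
#' @param outputExtent integer pair (rows, columns).
#' @return Integer pair: the required input extent.
#' @export
receptiveExtent <- function(spec, outputExtent) {
  if (any(outputExtent < 1)) stop("output extents must be positive")
  as.integer(outputExtent) + receptiveReduction(spec)
}

#' Build a randomly initialized WNN
#'
#' He-scaled Gaussian initialization, seeded for reproducibility.  The model
#' maps a real patch of extent `receptiveExtent(spec, out)` to a real patch
#' of extent `out`.
#'
#' @param spec a [wnnSpec()] with at least one layer.
#' @param seed integer seed for the initialization.
#' @param finalBias initial bias of the 1 x 1 projection (use a positive
#'   value for uncertainty networks so the rectified sigma starts positive).
#' @param finalScale multiplier on the projection-layer initialization;
#'   uncertainty networks use a small value so the initial sigma map is
#'   dominated by the calibrated bias and stays positive (a rectified
#'   output that starts negative receives no gradient).
#' @return A `WNNModel`.
#' @export
buildWnn <- function(spec, seed = 1L, finalBias = 0, finalScale = 1) {
  validObject(spec)
  n <- nrow(spec@kernels)
  if (n < 1L) stop("spec must have at least one layer")
  set.seed(seed)
  layers <- vector("list", n + 1L)
  for (i in seq_len(n)) {
    cin <- if (i == 1L) 1L else spec@filters
    cout <- spec@filters
    fanIn <- spec@kernels[i, 1] * spec@kernels[i, 2] * cin
    layers[[i]] <- list(
      W = matrix(rnorm(cout * fanIn, sd = sqrt(2 / fanIn)), cout, fanIn),
      b = numeric(cout),
      kh = spec@kernels[i, 1], kw = spec@kernels[i, 2],
      dh = spec@dilations[i, 1], dw = spec@dilations[i, 2],
      relu = TRUE)
  }
  fanIn <- spec@filters
  layers[[n + 1L]] <- list(
    W = matrix(rnorm(fanIn, sd = finalScale * sqrt(2 / fanIn)), 1L, fanIn),
    b = finalBias,
    kh = 1L, kw = 1L, dh = 1L, dw = 1L, relu = FALSE)
  new("WNNModel", spec = spec, layers = layers, seed = as.integer(seed))
}

#' @describeIn buildWnn total number of trainable parameters.
#' @param model a `WNNModel`.
#' @export
wnnParamCount <- function(model) {
  sum(vapply(model@layers,
             function(L) length(L$W) + length(L$b), numeric(1)))
}

#' @describeIn buildWnn forward pass on a single real patch.
#' @param patch real matrix of the model's input extent.
#' @export
wnnForward <- function(model, patch) {
  cppWnnForward(patch, model@layers)
}

#' Tiling of a full spectrum into network-sized patches
#'
#' Output tiles partition the (zero-padded) spectrum without overlap with
#' stride equal to the output extent; each input patch extends the tile by
#' the receptive-field margin, split `floor(r/2)` before / `ceil(r/2)` after
#' and zero-padded at the edges.  `stitchPatches(tileTargets(x)) == x`
#' exactly.
#'
#' @param specDims spectrum extents (rows, columns).
#' @param outExtent output tile extent.
#' @param reduction receptive-field shrink per dimension (see
#'   [receptiveExtent()]).
#' @return A `TileScheme`.
#' @export
makeTileScheme <- function(specDims, outExtent, reduction) {
  specDims <- as.integer(specDims)
  outExtent <- as.integer(outExtent)
  reduction <- as.integer(reduction)
  grid <- as.integer(ceiling(specDims / outExtent))
  new("TileScheme", specDims = specDims, outExtent = outExtent,
      inExtent = outExtent + reduction,
      padBefore = as.integer(floor(reduction / 2)), gridDims = grid)
}

#' @rdname makeTileScheme
#' @param values real spectrum matrix.
#' @param scheme a `TileScheme`.
#' @return `tileInputs`/`tileTargets`: list of patches in row-major tile
#'   order; `stitchPatches`: the reassembled spectrum.
#' @export
tileInputs <- function(values, scheme) {
  red <- scheme@inExtent - scheme@outExtent
  paddedOut <- scheme@gridDims * scheme@outExtent
  P <- matrix(0, paddedOut[1] + red[1], paddedOut[2] + red[2])
  pb <- scheme@padBefore
  P[pb[1] + seq_len(nrow(values)), pb[2] + seq_len(ncol(values))] <- values
  patches <- vector("list", prod(scheme@gridDims))
  idx <- 1L
  for (a in seq_len(scheme@gridDims[1])) {
    r0 <- (a - 1L) * scheme@outExtent[1]
    for (b in seq_len(scheme@gridDims[2])) {
      c0 <- (b - 1L) * scheme@outExtent[2]
      patches[[idx]] <- P[r0 + seq_len(scheme@inExtent[1]),
                          c0 + seq_len(scheme@inExtent[2]), drop = FALSE]
      idx <- idx + 1L
    }
  }
  patches
}

#' @rdname makeTileScheme
#' @export
tileTargets <- function(values, scheme) {
  paddedOut <- scheme@gridDims * scheme@outExtent
  P <- matrix(0, paddedOut[1], paddedOut[2])
  P[seq_len(nrow(values)), seq_len(ncol(values))] <- values
  patches <- vector("list", prod(scheme@gridDims))
  idx <- 1L
  for (a in seq_len(scheme@gridDims[1])) {
    r0 <- (a - 1L) * scheme@outExtent[1]
    for (b in seq_len(scheme@gridDims[2])) {
      c0 <- (b - 1L) * scheme@outExtent[2]
      patches[[idx]] <- P[r0 + seq_len(scheme@outExtent[1]),
                          c0 + seq_len(scheme@outExtent[2]), drop = FALSE]
      idx <- idx + 1L
    }
  }
  patches
}

#' @rdname makeTileScheme
#' @param patches list of output tiles in row-major tile order.
#' @export
stitchPatches <- function(patches, scheme) {
  paddedOut <- scheme@gridDims * scheme@outExtent
  P <- matrix(0, paddedOut[1], paddedOut[2])
  idx <- 1L
  for (a in seq_len(scheme@gridDims[1])) {
    r0 <- (a - 1L) * scheme@outExtent[1]
    for (b in seq_len(scheme@gridDims[2])) {
      c0 <- (b - 1L) * scheme@outExtent[2]
      P[r0 + seq_len(scheme@outExtent[1]),
        c0 + seq_len(scheme@outExtent[2])] <- patches[[idx]]
      idx <- idx + 1L
    }
  }
  P[seq_len(scheme@specDims[1]), seq_len(scheme@specDims[2]), drop = FALSE]
}

#' Apply a WNN to a full spectrum via tiling
#'
#' Normalizes the spectrum by its Euclidean norm, tiles it, runs the model
#' per patch, stitches the outputs and restores the scale.
#'
#' @param model a `WNNModel`.
#' @param values real spectrum matrix.
#' @param outExtent output tile extent.
#' @export
applyWnn <- function(model, values, outExtent) {
  nu <- sqrt(sum(values^2))
  if (nu == 0) return(values * 0)
  scheme <- makeTileScheme(dim(values), outExtent,
                           receptiveReduction(model@spec))
  ins <- tileInputs(values / nu, scheme)
  preds <- lapply(ins, function(p) cppWnnForward(p, model@layers))
  stitchPatches(preds, scheme) * nu
}

#' Training configuration
#'
#' Defaults follow the full-scale protocol: Adam with learning rate 1e-4,
#' mini-batches of 64, mean-squared-error loss, up to 1000 epochs with early
#' stopping on the validation loss (patience 20), 90/10 train/validation
#' split.  Small desk-scale problems train better with a larger learning
#' rate and smaller batches; see the methods vignette.
#'
#' @param learningRate Adam step size.
#' @param batchSize mini-batch size.
#' @param maxEpochs epoch cap (0 returns the initialization unchanged).
#' @param patience early-stopping patience in epochs.
#' @param valFraction validation fraction in (0, 1).
#' @param seed integer seed for the split and shuffling.
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 64L,
                        maxEpochs = 1000L, patience = 20L,
                        valFraction = 0.1, seed = 1L) {
  new("TrainConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      patience = as.integer(patience), valFraction = valFraction,
      seed = as.integer(seed))
}

## Shared Adam + early-stopping engine.  `samples` is a list of
## list(input = patch, target = patch) pairs already normalized by caller.
trainWnn <- function(samples, model, cfg, loss = "mse", sigmaFloor = 1e-6) {
  validObject(cfg)
  n <- length(samples)
  if (n == 0L) stop("empty training set")
  set.seed(cfg@seed)
  nVal <- max(1L, as.integer(round(cfg@valFraction * n)))
  if (nVal >= n) nVal <- n - 1L
  perm <- sample(n)
  valIdx <- perm[seq_len(nVal)]
  trainIdx <- perm[-seq_len(nVal)]
  if (length(trainIdx) == 0L) {
    trainIdx <- valIdx
  }
  layers <- model@layers
  nL <- length(layers)
  mW <- lapply(layers, function(L) L$W * 0)
  vW <- mW
  mB <- lapply(layers, function(L) L$b * 0)
  vB <- mB
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  t <- 0L
  evalLoss <- function(lyr, idx) {
    tot <- 0
    for (s in idx) {
      r <- cppWnnGrad(samples[[s]]$input, lyr, samples[[s]]$target,
                      loss, sigmaFloor)
      tot <- tot + r$loss
    }
    tot / length(idx)
  }
  history <- list(train = numeric(0), val = numeric(0))
  bestVal <- evalLoss(layers, valIdx)
  bestLayers <- layers
  history$val <- bestVal
  wait <- 0L
  for (epoch in seq_len(cfg@maxEpochs)) {
    order <- sample(trainIdx)
    epochLoss <- 0
    nb <- 0L
    for (start in seq(1L, length(order), by = cfg@batchSize)) {
      batch <- order[start:min(start + cfg@batchSize - 1L, length(order))]
      gW <- lapply(layers, function(L) L$W * 0)
      gB <- lapply(layers, function(L) L$b * 0)
      bl <- 0
      for (s in batch) {
        r <- cppWnnGrad(samples[[s]]$input, layers, samples[[s]]$target,
                        loss, sigmaFloor)
        bl <- bl + r$loss
        for (j in seq_len(nL)) {
          gW[[j]] <- gW[[j]] + r$grads[[j]]$W
          gB[[j]] <- gB[[j]] + r$grads[[j]]$b
        }
      }
      nb <- nb + 1L
      epochLoss <- epochLoss + bl / length(batch)
      t <- t + 1L
      corr1 <- 1 - b1^t
      corr2 <- 1 - b2^t
      for (j in seq_len(nL)) {
        g <- gW[[j]] / length(batch)
        mW[[j]] <- b1 * mW[[j]] + (1 - b1) * g
        vW[[j]] <- b2 * vW[[j]] + (1 - b2) * g^2
        layers[[j]]$W <- layers[[j]]$W -
          cfg@learningRate * (mW[[j]] / corr1) /
          (sqrt(vW[[j]] / corr2) + epsA)
        g <- gB[[j]] / length(batch)
        mB[[j]] <- b1 * mB[[j]] + (1 - b1) * g
        vB[[j]] <- b2 * vB[[j]] + (1 - b2) * g^2
        layers[[j]]$b <- layers[[j]]$b -
          cfg@learningRate * (mB[[j]] / corr1) /
          (sqrt(vB[[j]] / corr2) + epsA)
      }
    }
    vl <- evalLoss(layers, valIdx)
    history$train <- c(history$train, epochLoss / max(nb, 1L))
    history$val <- c(history$val, vl)
    if (vl < bestVal) {
      bestVal <- vl
      bestLayers <- layers
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > cfg@patience) break
    }
  }
  model@layers <- bestLayers
  list(model = model, history = history, bestVal = bestVal)
}
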