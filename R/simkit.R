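## Synthetic hypercomplex FID simulator.
##
## The simulated signal is a sum of N damped 2D exponentials.  For exponential
## n with amplitude A_n, normalized frequencies w1_n, w2_n (cycles per dwell,
## in [-0.5, 0.5]), phases phi1_n, phi2_n (degrees) and decay times tau1_n,
## tau2_n (dwell points):
##
##   X_P(t1, t2) = sum_n A_n e^{+i(2 pi w1 t1 + phi1)} e^{-t1/tau1}
##                         e^{ i(2 pi w2 t2 + phi2)} e^{-t2/tau2}
##   X_N(t1, t2) = as above with -i in the indirect exponent
##
## plus independent complex Gaussian noise on both components.  The indirect
## envelope is implemented as a decay; `literalIndirectGrowth = TRUE` switches
## to a growing envelope e^{+t1/tau1} for users who want that variant.

#' Simulation configuration for synthetic 2D FIDs
#'
#' Defaults describe a 1H-15N-correlation-like 2D dataset: 128 x 256 complex
#' points (indirect x direct), 512 exponentials, uniform frequencies in
#' [-0.5, 0.5] cycles/dwell, phases in [-3, 3] degrees, amplitudes in
#' [-0.2, 1], decay times 256-1280 points (indirect) and 12.8-128 points
#' (direct), and additive Gaussian noise at SNR 500.
#'
#' @param nIndirect,nDirect complex-point counts per dimension.
#' @param nExponentials number of damped exponentials.
#' @param snr amplitude signal-to-noise ratio; `Inf` disables noise.  The
#'   per-component noise standard deviation is `1 / snr`, pegging noise to
#'   the maximum attainable single-exponential amplitude (1).
#' @param freqRange,phaseRange,ampRange,tauIndirectRange,tauDirectRange
#'   uniform sampling ranges for the exponential parameters.
#' @param imbalanceDeficit fractional P-type amplitude deficit in [0, 1);
#'   see [applyImbalance()].
#' @param literalIndirectGrowth logical; use a growing indirect envelope.
#' @return A `SimConfig` object.
#' @export
simConfig <- function(nIndirect = 128L, nDirect = 256L,
                      nExponentials = 512L, snr = 500,
                      freqRange = c(-0.5, 0.5), phaseRange = c(-3, 3),
                      ampRange = c(-0.2, 1),
                      tauIndirectRange = c(256, 1280),
                      tauDirectRange = c(12.8, 128),
                      imbalanceDeficit = 0,
                      literalIndirectGrowth = FALSE) {
  new("SimConfig",
      nIndirect = as.integer(nIndirect), nDirect = as.integer(nDirect),
      nExponentials = as.integer(nExponentials), snr = snr,
      freqRange = as.numeric(freqRange), phaseRange = as.numeric(phaseRange),
      ampRange = as.numeric(ampRange),
      tauIndirectRange = as.numeric(tauIndirectRange),
      tauDirectRange = as.numeric(tauDirectRange),
      imbalanceDeficit = imbalanceDeficit,
      literalIndirectGrowth = literalIndirectGrowth)
}

#' Desk-scale simulation configuration
#'
#' Shrinks the default configuration to a smaller grid while preserving peak
#' density (exponentials per spectral point) and relative decay (decay time
#' over acquisition length), so small test spectra have the same character as
#' the full-size ones.
#'
#' @param nIndirect,nDirect reduced complex-point counts.
#' @param snr signal-to-noise ratio.
#' @param ... further arguments passed to [simConfig()].
#' @export
scaledSimConfig <- function(nIndirect, nDirect, snr = 500, ...) {
  full <- 128L * 256L
  nExp <- max(1L, as.integer(round(512 * (nIndirect * nDirect) / full)))
  simConfig(nIndirect = nIndirect, nDirect = nDirect,
            nExponentials = nExp, snr = snr,
            tauIndirectRange = c(256, 1280) * nIndirect / 128,
            tauDirectRange = c(12.8, 128) * nDirect / 256, ...)
}

#' Draw random exponential parameters
#'
#' Each of the `nExponentials` exponentials gets amplitude, frequencies,
#' phases and decay times drawn uniformly from the configured ranges.
#'
#' @param config a `SimConfig`.
#' @param seed integer seed; identical seeds give identical draws.
#' @return A data.frame with columns `amplitude`, `freq1`, `freq2`,
#'   `phase1`, `phase2` (degrees), `tau1`, `tau2` (dwell points).
#' @export
sampleParams <- function(config, seed) {
  validObject(config)
  n <- config@nExponentials
  if (n == 0L)
    return(data.frame(amplitude = numeric(0), freq1 = numeric(0),
                      freq2 = numeric(0), phase1 = numeric(0),
                      phase2 = numeric(0), tau1 = numeric(0),
                      tau2 = numeric(0)))
  set.seed(seed)
  rng <- function(r) runif(n, r[1], r[2])
  data.frame(
    amplitude = rng(config@ampRange),
    freq1 = rng(config@freqRange),
    freq2 = rng(config@freqRange),
    phase1 = rng(config@phaseRange),
    phase2 = rng(config@phaseRange),
    tau1 = rng(config@tauIndirectRange),
    tau2 = rng(config@tauDirectRange))
}

#' Synthesize a noiseless hypercomplex FID from exponential parameters
#'
#' Evaluates the damped-exponential model on the `nIndirect x nDirect` time
#' grid (times indexed 0 ... T-1).  The P-type component carries `+i` and the
#' N-type `-i` before the indirect-frequency exponent; the direct-dimension
#' factor is identical in both.  The synthesis is linear in the amplitudes.
#'
#' @param params data.frame as returned by [sampleParams()].
#' @param config a `SimConfig` (grid sizes and envelope convention).
#' @return A [hypercomplexFid()] object (noise-free).
#' @export
synthesizeFid <- function(params, config) {
  validObject(config)
  k <- config@nIndirect
  l <- config@nDirect
  if (nrow(params) == 0L) {
    z <- matrix(0 + 0i, k, l)
    return(hypercomplexFid(z, z))
  }
  t1 <- 0:(k - 1)
  t2 <- 0:(l - 1)
  s1 <- if (config@literalIndirectGrowth) 1 else -1
  ph1 <- params$phase1 * pi / 180
  ph2 <- params$phase2 * pi / 180
  ## k x N matrix of indirect factors (phase-modulated, damped)
  arg1 <- outer(t1, 2 * pi * params$freq1) +
    matrix(ph1, k, nrow(params), byrow = TRUE)
  env1 <- exp(outer(t1, s1 / params$tau1))
  U <- exp(1i * arg1) * env1
  arg2 <- outer(2 * pi * params$freq2, t2) + matrix(ph2, nrow(params), l)
  env2 <- exp(outer(-1 / params$tau2, t2))
  V <- (exp(1i * arg2) * env2) * params$amplitude
  hypercomplexFid(U %*% V, Conj(U) %*% V)
}

#' Add Gaussian noise to a hypercomplex FID
#'
#' Independent zero-mean Gaussian noise of standard deviation
#' `amplitude / snr` is added to the real and imaginary parts of both the
#' P- and N-type components (they are separate acquisitions).
#'
#' @param fid a `HypercomplexFID`.
#' @param snr signal-to-noise ratio (> 0); `Inf` returns the input unchanged.
#' @param seed integer seed.
#' @param amplitude reference amplitude the SNR is measured against
#'   (default 1, the maximum single-exponential amplitude of the simulator).
#' @export
setMethod("addNoise", "HypercomplexFID",
  function(fid, snr, seed, amplitude = 1) {
    if (!(snr > 0)) stop("snr must be positive")
    if (is.infinite(snr)) return(fid)
    sigma <- amplitude / snr
    set.seed(seed)
    d <- dim(fid@pData)
    n <- prod(d)
    noiseP <- matrix(complex(real = rnorm(n, sd = sigma),
                             imaginary = rnorm(n, sd = sigma)), d[1], d[2])
    noiseN <- matrix(complex(real = rnorm(n, sd = sigma),
                             imaginary = rnorm(n, sd = sigma)), d[1], d[2])
    hypercomplexFid(fid@pData + noiseP, fid@nData + noiseN)
  })

#' Apply a P-type amplitude deficit
#'
#' Scales the P-type (Echo) component by `1 - deficit`, leaving the N-type
#' untouched.  Emulates the experimental amplitude imbalance between the two
#' gradient-selected acquisitions; at `deficit = 0.10` the P-type is 10%
#' smaller than the N-type.
#'
#' @param fid a `HypercomplexFID`.
#' @param deficit fraction in [0, 1).
#' @export
setMethod("applyImbalance", "HypercomplexFID", function(fid, deficit) {
  if (deficit < 0 || deficit >= 1) stop("deficit must lie in [0, 1)")
  hypercomplexFid(fid@pData * (1 - deficit), fid@nData)
})

## Deterministic counter-based seed splitting: per-pair seeds depend only on
## the master seed and the pair index, so datasets are order-independent.
deriveSeed <- function(master, index, stream = 0L) {
  as.integer((as.double(master) + 7919 * index + 104729 * stream) %%
               2147483646) + 1L
}

#' Generate (input, reference) spectrum pairs for training or testing
#'
#' For each pair a fresh random FID is drawn, optionally imbalanced and
#' noise-corrupted, and processed into a pure-absorption reference spectrum.
#' The input is the Echo (or Anti-Echo) phase-twisted counterpart, or the
#' NUS-corrupted spectrum for `mode = "nus"`.
#'
#' @param config a `SimConfig`.
#' @param count number of pairs.
#' @param mode `"echo"`, `"anti_echo"` or `"nus"`.
#' @param seed master seed; per-pair seeds are derived from it.
#' @param schedule optional `NUSSchedule` for `mode = "nus"`; by default a
#'   50% Poisson-gap schedule is generated from the master seed.
#' @param ... processing options forwarded to [processSpectrum()].
#' @return A `SpectrumPairSet`.
#' @export
generatePairs <- function(config, count, mode = c("echo", "anti_echo", "nus"),
                          seed = 1L, schedule = NULL, ...) {
  mode <- match.arg(mode)
  validObject(config)
  if (mode == "nus" && is.null(schedule))
    schedule <- poissonGap(config@nIndirect, 0.5, seed)
  inputs <- vector("list", count)
  refs <- vector("list", count)
  seeds <- integer(count)
  for (i in seq_len(count)) {
    si <- deriveSeed(seed, i)
    seeds[i] <- si
    params <- sampleParams(config, si)
    fid <- synthesizeFid(params, config)
    if (config@imbalanceDeficit > 0)
      fid <- applyImbalance(fid, config@imbalanceDeficit)
    fid <- addNoise(fid, config@snr, deriveSeed(seed, i, 1L))
    ref <- processSpectrum(fid, ...)
    refs[[i]] <- ref
    inputs[[i]] <- switch(mode,
      echo = echoSpectrum(ref, "echo"),
      anti_echo = echoSpectrum(ref, "anti_echo"),
      nus = nusCorrupt(fid, schedule, ...))
  }
  new("SpectrumPairSet", inputs = inputs, references = refs,
      seeds = seeds, mode = mode, config = config)
}
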