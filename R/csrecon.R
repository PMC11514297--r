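## Compressed-sensing reconstruction by iterative soft thresholding (IST):
## completion of the missing Virtual Echo quadrants from Echo/Anti-Echo data,
## NUS reconstruction, and Poisson-gap schedule generation.

#' IST solver configuration
#'
#' The soft-threshold schedule is geometric: it starts at
#' `thresholdFactor * max|FT[known]|` and decays to a floor estimated from
#' the data (`noiseFloorFactor * median|FT[known]|`, but never below
#' `relFloor` times the maximum) at the final iteration.  Thresholds are
#' relative to the input scale, so the reconstruction commutes with global
#' rescaling of the data.
#'
#' @param nIterations number of IST iterations (default 200).
#' @param thresholdFactor initial threshold as a fraction of the spectrum
#'   maximum (default 0.9).
#' @param noiseFloorFactor multiple of the median absolute spectrum value
#'   used as the final threshold (default 5).
#' @param relFloor lower bound on the final threshold relative to the
#'   spectrum maximum (default 1e-8; keeps noiseless problems well-posed).
#' @param enforceConsistency replace the reconstruction's Virtual Echo by
#'   the measured data on the known support after the last iteration
#'   (default TRUE; the measured quadrants are exact data).
#' @export
istConfig <- function(nIterations = 200L, thresholdFactor = 0.9,
                      noiseFloorFactor = 5, relFloor = 1e-8,
                      enforceConsistency = TRUE) {
  new("ISTConfig", nIterations = as.integer(nIterations),
      thresholdFactor = thresholdFactor,
      noiseFloorFactor = noiseFloorFactor, relFloor = relFloor,
      enforceConsistency = enforceConsistency)
}

#' Construct a Virtual Echo completion problem
#'
#' @param known complex matrix of measured Virtual Echo data (zero outside
#'   the known support).
#' @param mask known-support weights in [0, 1] (boundary lines of quadrant
#'   splits carry 1/2).
#' @param flavor `"echo"`, `"anti_echo"` or `"nus"`.
#' @export
completionProblem <- function(known, mask, flavor = "echo") {
  if (is.numeric(known)) storage.mode(known) <- "complex"
  new("CompletionProblem", known = known, mask = mask, flavor = flavor)
}

#' Complete missing Virtual Echo data by iterative soft thresholding
#'
#' Iterates `x <- SoftThreshold(FT[known + (1 - mask) * iFT[x]])` with a
#' geometrically decaying threshold.  The algorithm promotes spectral
#' sparsity, filling the unmeasured quadrants with the most compact
#' (absorptive) signal consistent with the measured data while suppressing
#' the broad dispersive features of the phase twist.
#'
#' @param problem a `CompletionProblem`.
#' @param config an [istConfig()].
#' @return An `AbsorptiveSpectrum`; `metadata$residuals` holds the history
#'   of `||known - mask * iFT[x]||` per iteration (non-convergence shows up
#'   there, it is never an error).
#' @export
istComplete <- function(problem, config = istConfig()) {
  validObject(problem)
  known <- problem@known
  M <- problem@mask
  base <- Re(fft2(known))
  mx <- max(abs(base))
  if (mx == 0)
    return(absorptiveSpectrum(base, metadata = list(residuals = numeric(0))))
  lam0 <- config@thresholdFactor * mx
  lamFinal <- max(config@noiseFloorFactor * median(abs(base)),
                  config@relFloor * mx)
  lamFinal <- min(lamFinal, lam0)
  nIter <- config@nIterations
  ratio <- if (nIter > 1) (lamFinal / lam0)^(1 / (nIter - 1)) else 1
  x <- matrix(0, nrow(known), ncol(known))
  resid <- numeric(nIter)
  knownNorm <- sqrt(sum(Mod(known)^2))
  for (j in seq_len(nIter)) {
    ve <- known + (1 - M) * ifft2(x)
    y <- Re(fft2(ve))
    lam <- lam0 * ratio^(j - 1)
    x <- sign(y) * pmax(abs(y) - lam, 0)
    resid[j] <- sqrt(sum(Mod(known - M * ifft2(x))^2)) /
      max(knownNorm, .Machine$double.eps)
  }
  if (config@enforceConsistency) {
    ve <- known + (1 - M) * ifft2(x)
    x <- Re(fft2(ve))
  }
  absorptiveSpectrum(x, metadata = list(residuals = resid,
                                        lambda = c(lam0, lamFinal),
                                        flavor = problem@flavor))
}

#' Reconstruct a pure-absorption spectrum from a single Echo/Anti-Echo dataset
#'
#' Builds the Virtual Echo completion problem from the phase-twisted
#' spectrum (known support = the quadrants retained by its flavor) and
#' solves it with [istComplete()].
#'
#' @param echo an `EchoSpectrum`.
#' @param config an [istConfig()].
#' @return An `AbsorptiveSpectrum`.
#' @export
csEcho <- function(echo, config = istConfig()) {
  stopifnot(is(echo, "EchoSpectrum"))
  ve <- ifft2(echo@values)
  side <- if (echo@flavor == "echo") "echo" else "anti"
  mask <- quadrantWeights(dim(ve), side)
  ve[mask == 0] <- 0 + 0i  # clean numerical dust outside the support
  istComplete(completionProblem(ve, mask, echo@flavor), config)
}

#' Reconstruct a NUS spectrum by IST
#'
#' Known support = the sampled indirect increments (and their mirrored
#' negative-time rows in the Virtual Echo presentation).
#'
#' @param nusSpectrum `AbsorptiveSpectrum` with aliasing artifacts (see
#'   [nusCorrupt()]).
#' @param schedule the `NUSSchedule` used for sampling.
#' @param config an [istConfig()].
#' @export
csNus <- function(nusSpectrum, schedule, config = istConfig()) {
  stopifnot(is(nusSpectrum, "AbsorptiveSpectrum"))
  K <- nrow(nusSpectrum@values)
  if (2L * schedule@nIncrements != K)
    stop("schedule does not match the spectrum's indirect extent")
  rows <- nusRowMask(K, schedule)
  mask <- matrix(rows, K, ncol(nusSpectrum@values))
  ve <- ifft2(nusSpectrum@values) * mask
  istComplete(completionProblem(ve, mask, "nus"), config)
}

#' Generate a Poisson-gap NUS schedule
#'
#' Gaps between sampled increments are drawn from a Poisson law whose mean
#' is sinusoidally modulated across the grid (small gaps early, large gaps
#' late), the standard early-weighted Poisson-gap scheme.  The rate is tuned
#' by bisection so the schedule contains exactly `round(fraction * n)`
#' indices; index 0 is always sampled.  Deterministic for a fixed seed.
#'
#' @param nIncrements total indirect increments `n`.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return A [nusSchedule()] with exactly `round(fraction * n)` indices.
#' @export
poissonGap <- function(nIncrements, fraction, seed) {
  n <- as.integer(nIncrements)
  if (n < 1L) stop("nIncrements must be >= 1")
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must lie in (0, 1]")
  target <- max(1L, as.integer(round(fraction * n)))
  if (target >= n) return(nusSchedule(0:(n - 1), n))
  gen <- function(adj) {
    set.seed(seed)
    idx <- integer(0)
    p <- 0L
    while (p < n) {
      idx <- c(idx, p)
      gap <- rpois(1, adj * sin((p + 1) / (n + 1) * pi / 2))
      p <- p + 1L + gap
    }
    idx
  }
  lo <- 0
  hi <- 4 * (n / target - 1) / 0.64 + 1
  best <- gen(hi)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    idx <- gen(mid)
    if (length(idx) == target) {
      best <- idx
      break
    }
    if (length(idx) > target) lo <- mid else hi <- mid
    if (abs(length(idx) - target) < abs(length(best) - target)) best <- idx
  }
  idx <- best
  ## discreteness can leave the count off by a few; fix up deterministically
  set.seed(seed + 1L)
  if (length(idx) > target) {
    removable <- setdiff(idx, 0L)
    drop <- sample(removable, length(idx) - target)
    idx <- setdiff(idx, drop)
  } else if (length(idx) < target) {
    missing <- setdiff(0:(n - 1), idx)
    add <- sample(missing, target - length(idx))
    idx <- c(idx, add)
  }
  nusSchedule(idx, n)
}
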