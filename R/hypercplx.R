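## Hypercomplex (States-equivalent) 2D processing, the Virtual Echo transform
## and the Echo/Anti-Echo quadrant projectors.
##
## Index/time convention on an axis of length 2m (doubled grid): index 1 is
## t = 0, indices 2..m are t = 1..m-1, index m+1 is the Nyquist point (t = -m
## == +m), and indices m+2..2m are t = -(m-1)..-1.  The quadrant projectors
## give the shared boundary lines (t = 0 and Nyquist) weight 1/2 on each side
## so that the Echo and Anti-Echo projectors sum exactly to the identity.

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

apodWindow <- function(n, type) {
  switch(type,
         cos2 = cos(pi * (0:(n - 1)) / (2 * n))^2,
         none = rep(1, n),
         stop("unknown apodization window: ", type))
}

#' Process a hypercomplex FID into a pure-absorption spectrum
#'
#' Converts the P/N pair into amplitude-modulated components
#' (`cos = (X_P + X_N)/2`, `sin = (X_P - X_N)/(2i)`), apodizes, zero-fills,
#' Fourier-transforms the direct then the indirect dimension keeping the
#' hypercomplex bookkeeping, applies zero-order phase correction and returns
#' the real absorptive part on the doubled `2k x 2l` grid.
#'
#' @param fid a `HypercomplexFID` (`k x l` complex points).
#' @param apodization `"cos2"` (cosine-squared, default) or `"none"`.
#' @param zeroFill zero-filling factor per dimension (default 2).
#' @param firstPointScale scaling of the first time-domain point in each
#'   dimension (default 0.5, the standard baseline-offset correction).
#' @param phase0 zero-order phase correction in degrees, `c(indirect,
#'   direct)`.
#' @return An [absorptiveSpectrum()] of extent `zeroFill*k x zeroFill*l`.
#' @export
setMethod("processSpectrum", "HypercomplexFID",
  function(fid, apodization = "cos2", zeroFill = 2L, firstPointScale = 0.5,
           phase0 = c(0, 0)) {
    k <- nrow(fid@pData)
    l <- ncol(fid@pData)
    cosC <- (fid@pData + fid@nData) / 2
    sinC <- (fid@pData - fid@nData) / (2i)
    w1 <- apodWindow(k, apodization)
    w2 <- apodWindow(l, apodization)
    w1[1] <- w1[1] * firstPointScale
    w2[1] <- w2[1] * firstPointScale
    W <- outer(w1, w2)
    cosC <- cosC * W
    sinC <- sinC * W
    K <- as.integer(zeroFill * k)
    L <- as.integer(zeroFill * l)
    padCols <- function(m) cbind(m, matrix(0 + 0i, nrow(m), L - l))
    ftDirect <- function(m) t(stats::mvfft(t(padCols(m))))
    Fc <- ftDirect(cosC)
    Fs <- ftDirect(sinC)
    if (phase0[2] != 0) {
      ph <- exp(1i * phase0[2] * pi / 180)
      Fc <- Fc * ph
      Fs <- Fs * ph
    }
    H <- Re(Fc) + 1i * Re(Fs)
    H <- rbind(H, matrix(0 + 0i, K - k, L))
    F1 <- stats::mvfft(H)
    if (phase0[1] != 0) F1 <- F1 * exp(1i * phase0[1] * pi / 180)
    absorptiveSpectrum(Re(F1),
                       metadata = list(fidDims = c(k, l),
                                       apodization = apodization,
                                       zeroFill = zeroFill))
  })

#' Quadrant retention weights of the Virtual Echo grid
#'
#' For a doubled grid, returns the weight matrix retained by the projector
#' that keeps the requested side: `"echo"` keeps the P and P-tilde quadrants
#' (both times of equal sign), `"anti"` keeps N and N-tilde (opposite signs).
#' Boundary lines (t = 0 and Nyquist in each dimension) carry weight 1/2 so
#' the two retention masks sum to 1 everywhere.
#'
#' @param dims doubled-grid extents `c(2k, 2l)`.
#' @param side `"echo"` or `"anti"`.
#' @return A numeric matrix of weights in `{0, 1/2, 1/4, 1}`.
#' @export
quadrantWeights <- function(dims, side = c("echo", "anti")) {
  side <- match.arg(side)
  half <- function(M) {
    m <- M %/% 2L
    w <- numeric(M)
    w[1] <- 0.5
    if (m > 1) w[2:m] <- 1
    w[m + 1] <- 0.5
    w
  }
  w1 <- half(dims[1])
  w2 <- half(dims[2])
  if (side == "echo")
    outer(w1, w2) + outer(1 - w1, 1 - w2)
  else
    outer(w1, 1 - w2) + outer(1 - w1, w2)
}

#' Virtual Echo transform of a real spectrum
#'
#' The inverse 2D Fourier transform of a real spectrum; a complex
#' time-domain array on the doubled grid satisfying the conjugate symmetry
#' `VE(-t) = Conj(VE(t))`.  Its four time quadrants hold the P- and N-type
#' signals and their time-reversed conjugates.
#'
#' @param spectrum a real `Spectrum2D`.
#' @return A [VirtualEcho-class].
#' @export
setMethod("toVirtualEcho", "Spectrum2D", function(spectrum, ...) {
  new("VirtualEcho", values = ifft2(spectrum@values),
      metadata = spectrum@metadata)
})

#' Forward transform of a Virtual Echo back to a spectrum
#'
#' Real part of the forward 2D Fourier transform.  A warning is issued when
#' the imaginary residual exceeds `warnTol` times the spectrum maximum,
#' which signals broken conjugate symmetry.
#'
#' @param ve a `VirtualEcho`.
#' @param warnTol relative tolerance for the imaginary residual.
#' @export
setMethod("fromVirtualEcho", "VirtualEcho", function(ve, warnTol = 1e-8) {
  F <- fft2(ve@values)
  mx <- max(abs(F))
  if (mx > 0 && max(abs(Im(F))) > warnTol * mx)
    warning("Virtual Echo lost conjugate symmetry; imaginary residual ",
            format(max(abs(Im(F))) / mx, digits = 3), " of max")
  absorptiveSpectrum(Re(F), metadata = ve@metadata)
})

#' Zero the P- or N-side quadrants of a Virtual Echo
#'
#' `which = "N_side"` zeroes the N and N-tilde quadrants, leaving Echo
#' (P-type) data; `which = "P_side"` zeroes P and P-tilde, leaving Anti-Echo
#' data.  Shared boundary lines are halved so the two projectors sum to the
#' identity.
#'
#' @param ve a `VirtualEcho`.
#' @param which `"N_side"` or `"P_side"`.
#' @export
setMethod("zeroQuadrants", "VirtualEcho", function(ve, which, ...) {
  if (!which %in% c("N_side", "P_side"))
    stop("which must be 'N_side' or 'P_side'")
  side <- if (which == "N_side") "echo" else "anti"
  mask <- quadrantWeights(dim(ve@values), side)
  new("VirtualEcho", values = ve@values * mask, metadata = ve@metadata)
})

#' Echo or Anti-Echo spectrum of an absorptive spectrum
#'
#' Computes `FT[Z[iFT[S]]]`: the Virtual Echo of the spectrum with the
#' opposite-type quadrants zeroed, transformed back.  The result carries the
#' characteristic phase-twist lineshape of single-quadrature detection.
#'
#' @param spectrum a real `Spectrum2D`.
#' @param flavor `"echo"` (keep P-type) or `"anti_echo"` (keep N-type).
#' @return An `EchoSpectrum`.
#' @export
setMethod("echoSpectrum", "Spectrum2D", function(spectrum, flavor, ...) {
  if (!flavor %in% c("echo", "anti_echo"))
    stop("flavor must be 'echo' or 'anti_echo'")
  zq <- zeroQuadrants(toVirtualEcho(spectrum),
                      if (flavor == "echo") "N_side" else "P_side")
  newEchoSpectrum(fromVirtualEcho(zq)@values, flavor,
                  metadata = spectrum@metadata)
})

## Rows of the doubled VE grid associated with sampled increment i: the
## positive-time row i and its mirror -i (the Nyquist row is never measured).
nusRowMask <- function(K, schedule) {
  mask <- numeric(K)
  for (i in schedule@indices) {
    mask[i + 1L] <- 1
    if (i > 0L) mask[K - i + 1L] <- 1
  }
  mask
}

#' Corrupt data with a non-uniform sampling schedule
#'
#' Unsampled indirect increments are zeroed in the time domain and the data
#' are processed to a spectrum containing the aliasing artifacts of the
#' schedule.  Applied to a `HypercomplexFID`, rows of both P- and N-type
#' components are zeroed before processing; applied to an
#' `AbsorptiveSpectrum`, the equivalent mirrored row masking is performed in
#' the Virtual Echo presentation (the two routes agree exactly).
#'
#' @param x a `HypercomplexFID` or `AbsorptiveSpectrum`.
#' @param schedule a `NUSSchedule` on the FID's indirect increments.
#' @param ... processing options, see [processSpectrum()].
#' @return An `AbsorptiveSpectrum` with aliasing artifacts.
#' @name nusCorrupt
#' @export
setMethod("nusCorrupt", "HypercomplexFID", function(x, schedule, ...) {
  k <- nrow(x@pData)
  if (schedule@nIncrements != k)
    stop("schedule covers ", schedule@nIncrements,
         " increments but the FID has ", k)
  keep <- rep(FALSE, k)
  keep[schedule@indices + 1L] <- TRUE
  p <- x@pData
  n <- x@nData
  p[!keep, ] <- 0 + 0i
  n[!keep, ] <- 0 + 0i
  s <- processSpectrum(hypercomplexFid(p, n), ...)
  s@metadata$schedule <- schedule@indices
  s
})

#' @rdname nusCorrupt
#' @export
setMethod("nusCorrupt", "AbsorptiveSpectrum", function(x, schedule, ...) {
  K <- nrow(x@values)
  if (2L * schedule@nIncrements != K)
    stop("schedule does not match the spectrum's indirect extent")
  ve <- toVirtualEcho(x)
  vals <- ve@values * nusRowMask(K, schedule)
  out <- fromVirtualEcho(new("VirtualEcho", values = vals,
                             metadata = x@metadata))
  out@metadata$schedule <- schedule@indices
  out
})

#' Reflect the indirect frequency axis
#'
#' Maps omega1 to -omega1 on the unshifted grid (index for omega = 0 stays,
#' the remaining rows reverse).  Converts Echo-type phase twist into
#' Anti-Echo-type twist and vice versa; used to reuse Echo-trained models on
#' Anti-Echo data.
#'
#' @param values a matrix (rows = indirect frequency axis).
#' @export
reflectIndirect <- function(values) {
  n <- nrow(values)
  values[c(1L, n:2L), , drop = FALSE]
}
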