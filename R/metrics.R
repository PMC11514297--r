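## Reference-based quality metrics: point-to-point RMSD and squared Pearson
## correlation over the joint 1%-of-max support, on max-normalized spectra.

metricVals <- function(x) if (is(x, "Spectrum2D")) x@values else x

normalizeByMax <- function(v) {
  mx <- max(abs(v))
  if (mx == 0) stop("cannot normalize an all-zero spectrum")
  v / mx
}

#' Joint support mask of a reconstruction/reference pair
#'
#' Both spectra are normalized by their own maximum absolute intensity; the
#' mask is true wherever either normalized intensity exceeds `threshold`.
#' Absolute intensities are used so negative (dispersive) artifacts count:
#' the metrics stay sensitive to false-positive and false-negative
#' artifacts while near-noise points are ignored.
#'
#' @param rec,ref reconstruction and reference spectra (matrices or
#'   `Spectrum2D`) on matching grids.
#' @param threshold support threshold (fraction of the maximum, default
#'   0.01); `threshold = 0` selects the full grid.
#' @return A logical matrix.
#' @export
supportMask <- function(rec, ref, threshold = 0.01) {
  r1 <- metricVals(rec)
  r2 <- metricVals(ref)
  if (!identical(dim(r1), dim(r2))) stop("spectra grids differ")
  if (threshold <= 0) return(matrix(TRUE, nrow(r1), ncol(r1)))
  abs(normalizeByMax(r1)) > threshold | abs(normalizeByMax(r2)) > threshold
}

#' Point-to-point RMSD between reconstruction and reference
#'
#' Root mean square of the difference over the joint support mask.  With
#' `normalize = TRUE` (default) both spectra are first normalized by their
#' own maximum absolute intensity, making the metric dimensionless and
#' invariant under separate rescaling of either spectrum.
#'
#' @inheritParams supportMask
#' @param normalize normalize each spectrum by its own maximum first.
#' @export
rmsd <- function(rec, ref, threshold = 0.01, normalize = TRUE) {
  r1 <- metricVals(rec)
  r2 <- metricVals(ref)
  mask <- supportMask(r1, r2, threshold)
  if (normalize) {
    r1 <- normalizeByMax(r1)
    r2 <- normalizeByMax(r2)
  }
  sqrt(mean((r1[mask] - r2[mask])^2))
}

#' Squared correlation between reconstruction and reference
#'
#' Squared Pearson correlation of the two spectra over the joint support
#' mask; 1 for any positive affine relation between them.
#'
#' @inheritParams supportMask
#' @export
r2s <- function(rec, ref, threshold = 0.01) {
  r1 <- metricVals(rec)
  r2 <- metricVals(ref)
  mask <- supportMask(r1, r2, threshold)
  if (sum(mask) < 2L) stop("support too small for a correlation")
  cor(r1[mask], r2[mask])^2
}

#' Reference-based quality report
#'
#' Bundles [rmsd()] and [r2s()] with the support bookkeeping.
#'
#' @inheritParams supportMask
#' @return A `QualityReport`.
#' @export
qualityReport <- function(rec, ref, threshold = 0.01) {
  mask <- supportMask(rec, ref, threshold)
  new("QualityReport",
      rmsd = rmsd(rec, ref, threshold),
      r2 = r2s(rec, ref, threshold),
      nSupport = as.integer(sum(mask)), threshold = threshold)
}
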