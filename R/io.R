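## File I/O: NMRPipe-style 2D binary for real spectra, RDS containers for
## FIDs/datasets/models/sigma maps, plain-text NUS schedules, YAML run
## configuration.

## NMRPipe header layout (512 float32 words).  Only the fields needed for a
## single real 2D plane are populated; indices are zero-based as in the
## format definition.
.FD <- list(MAGIC = 0L, FLTFORMAT = 1L, FLTORDER = 2L, DIMCOUNT = 9L,
            DIMORDER1 = 24L, DIMORDER2 = 25L, DIMORDER3 = 26L,
            DIMORDER4 = 27L, FDF2QUADFLAG = 56L, FDF1QUADFLAG = 55L,
            SIZE = 99L, QUADFLAG = 106L, SPECNUM = 219L,
            TRANSPOSED = 221L, FD2DPHASE = 256L)
.NMRPIPE_ORDER_MAGIC <- 2.345

#' Write a real 2D spectrum to an NMRPipe-style binary file
#'
#' Single-file real 2D plane: a 512-float header followed by float32
#' intensities, one direct-dimension trace per indirect row.  Values round
#' to 32-bit precision.
#'
#' @param spectrum a real `Spectrum2D` (or plain matrix).
#' @param path output file path.
#' @export
writeNmrPipe <- function(spectrum, path) {
  vals <- if (is(spectrum, "Spectrum2D")) spectrum@values else spectrum
  h <- numeric(512)
  h[.FD$FLTFORMAT + 1L] <- 4008636160  # IEEE float marker
  h[.FD$FLTORDER + 1L] <- .NMRPIPE_ORDER_MAGIC
  h[.FD$DIMCOUNT + 1L] <- 2
  h[.FD$DIMORDER1 + 1L] <- 2
  h[.FD$DIMORDER2 + 1L] <- 1
  h[.FD$DIMORDER3 + 1L] <- 3
  h[.FD$DIMORDER4 + 1L] <- 4
  h[.FD$SIZE + 1L] <- ncol(vals)
  h[.FD$SPECNUM + 1L] <- nrow(vals)
  h[.FD$QUADFLAG + 1L] <- 1
  h[.FD$FDF2QUADFLAG + 1L] <- 1
  h[.FD$FDF1QUADFLAG + 1L] <- 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(h, con, size = 4L, endian = "little")
  writeBin(as.numeric(t(vals)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an NMRPipe-style 2D binary spectrum
#'
#' @param path file written by [writeNmrPipe()] (or any single-plane real
#'   NMRPipe 2D file in little-endian float order).
#' @return An `AbsorptiveSpectrum`.
#' @export
readNmrPipe <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readBin(con, numeric(), n = 512L, size = 4L, endian = "little")
  if (length(h) < 512L ||
      abs(h[.FD$FLTORDER + 1L] - .NMRPIPE_ORDER_MAGIC) > 1e-4)
    stop("not an NMRPipe-style spectrum (bad float-order magic)")
  if (h[.FD$DIMCOUNT + 1L] != 2)
    stop("only 2D NMRPipe planes are supported")
  nc <- as.integer(h[.FD$SIZE + 1L])
  nr <- as.integer(h[.FD$SPECNUM + 1L])
  if (nr < 1L || nc < 1L) stop("corrupt NMRPipe header: bad sizes")
  data <- readBin(con, numeric(), n = nr * nc, size = 4L,
                  endian = "little")
  if (length(data) != nr * nc)
    stop("truncated NMRPipe data section")
  absorptiveSpectrum(matrix(data, nr, nc, byrow = TRUE),
                     metadata = list(source = path, format = "nmrpipe"))
}

#' Read or write a spectrum, dispatching on the file extension
#'
#' `.ft`, `.ft2`, `.dat`, `.pipe` use the NMRPipe-style binary;
#' `.rds` uses R's lossless native serialization.
#'
#' @param spectrum a `Spectrum2D`.
#' @param path file path.
#' @export
writeSpectrum <- function(spectrum, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ft", "ft2", "dat", "pipe")) writeNmrPipe(spectrum, path)
  else if (ext == "rds") saveRDS(spectrum, path)
  else stop("unsupported spectrum format: .", ext)
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ft", "ft2", "dat", "pipe")) return(readNmrPipe(path))
  if (ext == "rds") {
    obj <- readRDS(path)
    if (!is(obj, "Spectrum2D")) stop("RDS file does not hold a spectrum")
    return(obj)
  }
  stop("unsupported spectrum format: .", ext)
}

#' Plain-text NUS schedule I/O
#'
#' One zero-based increment index per line (mddnmr/hmsIST style).  Ordering
#' is normalized on read; duplicate entries are an error.
#'
#' @param schedule a `NUSSchedule`.
#' @param path file path.
#' @export
writeSchedule <- function(schedule, path) {
  writeLines(as.character(schedule@indices), path)
  invisible(path)
}

#' @rdname writeSchedule
#' @param nIncrements total increments of the full grid; defaults to
#'   `max(index) + 1`.
#' @export
readSchedule <- function(path, nIncrements = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  idx <- suppressWarnings(as.integer(lines))
  if (any(is.na(idx))) stop("schedule file contains non-integer lines")
  if (any(duplicated(idx))) stop("schedule file contains duplicate indices")
  if (is.null(nIncrements)) nIncrements <- max(idx) + 1L
  nusSchedule(idx, nIncrements)
}

#' Persist a training/test pair set
#'
#' Stored as an RDS container holding the input and reference arrays, the
#' per-pair seeds and the generating configuration echoed as YAML for
#' provenance.
#'
#' @param pairs a `SpectrumPairSet`.
#' @param path `.rds` output path.
#' @export
writePairs <- function(pairs, path) {
  cfg <- pairs@config
  cfgList <- list(nIndirect = cfg@nIndirect, nDirect = cfg@nDirect,
                  nExponentials = cfg@nExponentials, snr = cfg@snr,
                  imbalanceDeficit = cfg@imbalanceDeficit)
  saveRDS(list(inputs = pairs@inputs, references = pairs@references,
               seeds = pairs@seeds, mode = pairs@mode, config = pairs@config,
               configYaml = yaml::as.yaml(cfgList)), path)
  invisible(path)
}

#' @rdname writePairs
#' @export
readPairs <- function(path) {
  obj <- readRDS(path)
  new("SpectrumPairSet", inputs = obj$inputs, references = obj$references,
      seeds = obj$seeds, mode = obj$mode, config = obj$config)
}

.runConfigKeys <- c("seed", "outDir", "nPairs", "nIndirect", "nDirect",
                    "snr", "imbalanceDeficit", "istIterations", "epochs",
                    "filters", "verbose")

#' Read and validate a YAML run configuration
#'
#' Keys: `seed` (mandatory), `outDir`, `nPairs`, `nIndirect`, `nDirect`,
#' `snr`, `imbalanceDeficit`, `istIterations`, `epochs`, `filters`,
#' `verbose`.  Unknown keys are rejected; the configuration round-trips
#' losslessly through [writeRunConfig()].
#'
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .runConfigKeys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("run configuration must declare a seed")
  cfg
}

#' @rdname readRunConfig
#' @param config named list of configuration values.
#' @export
writeRunConfig <- function(config, path) {
  unknown <- setdiff(names(config), .runConfigKeys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  yaml::write_yaml(config, path)
  invisible(path)
}
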