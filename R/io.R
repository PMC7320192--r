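## On-disk formats: CCP4/MRC 2014 maps (mode 2, little-endian float), multi-
## section MRC tilt stacks with IMOD-style ".tlt" angle files, PDB atom
## models (parsed by bio3d), and two-column FSC tables (TSV).
##
## Grid convention: the MRC column/row/section axes map to in-memory
## (x, y, z); x is the fastest-varying index both on disk and in the R
## array. The tilt axis is the in-memory Y axis. Header origin fields are
## written as 0; the box center is the voxel at 0-based index n/2 per axis.

MRC_HEADER_BYTES <- 1024L

#' Write a density map as a CCP4/MRC 2014 file (mode 2)
#'
#' @param map a \linkS4class{DensityMap}.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeMRC <- function(map, path) {
  stopifnot(is(map, "DensityMap"))
  v <- map@values
  d <- dim(v)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wInt(d)                                   # nx ny nz
  wInt(2L)                                  # mode 2: 32-bit float
  wInt(c(0L, 0L, 0L))                       # nxstart nystart nzstart
  wInt(d)                                   # mx my mz
  wFlt(d * map@voxelSize)                   # cella
  wFlt(c(90, 90, 90))                       # cellb
  wInt(c(1L, 2L, 3L))                       # mapc mapr maps
  wFlt(c(min(v), max(v), mean(v)))          # dmin dmax dmean
  wInt(c(0L, 0L))                           # ispg nsymbt
  wInt(integer(25L))                        # extra
  wFlt(c(0, 0, 0))                          # origin
  writeBin(charToRaw("MAP "), con)          # map id
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wFlt(stats::sd(v))                        # rms
  wInt(1L)                                  # nlabl
  lab <- substr(paste0(map@label, strrep(" ", 80L)), 1L, 80L)
  writeBin(charToRaw(lab), con)
  writeBin(raw(720L), con)                  # remaining 9 labels
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  invisible(path)
}

readMRCHeader <- function(con) {
  rInt <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rFlt <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  h <- list()
  h$dim <- rInt(3L)
  h$mode <- rInt(1L)
  h$nstart <- rInt(3L)
  h$m <- rInt(3L)
  h$cella <- rFlt(3L)
  h$cellb <- rFlt(3L)
  h$axes <- rInt(3L)
  h$dstats <- rFlt(3L)
  h$ispg <- rInt(1L)
  h$nsymbt <- rInt(1L)
  rInt(25L)
  h$origin <- rFlt(3L)
  h$map <- rawToChar(readBin(con, "raw", 4L))
  readBin(con, "raw", 4L)
  h$rms <- rFlt(1L)
  h$nlabl <- rInt(1L)
  h$label <- trimws(rawToChar(readBin(con, "raw", 80L)))
  h
}

readMRCData <- function(path) {
  if (!file.exists(path)) stop("cannot read map: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readMRCHeader(con)
  if (any(h$dim <= 0L) || any(h$dim > 1e5L))
    stop("not a valid MRC file (implausible dimensions): ", path)
  if (h$mode != 2L)
    stop(sprintf("unsupported MRC mode %d in %s (only mode 2, 32-bit float, is supported)",
                 h$mode, path))
  seek(con, MRC_HEADER_BYTES + h$nsymbt)
  n <- prod(h$dim)
  v <- readBin(con, "numeric", n, size = 4L, endian = "little")
  if (length(v) != n)
    stop(sprintf("truncated MRC data block in %s: expected %d values, got %d",
                 path, n, length(v)))
  dim(v) <- h$dim
  vox <- if (h$m[1] > 0L && h$cella[1] > 0) h$cella[1] / h$m[1] else 1
  list(values = v, voxelSize = vox, label = h$label)
}

#' Read a CCP4/MRC 2014 density map (mode 2)
#'
#' Round-trips bit-exactly with \code{\link{writeMRC}} for mode-2 data.
#'
#' @param path path to an MRC/CCP4 map file.
#' @return a \linkS4class{DensityMap}; voxel size is taken from the header
#'   cell fields.
#' @export
readMRC <- function(path) {
  r <- readMRCData(path)
  if (length(dim(r$values)) != 3L) stop("map is not 3D: ", path)
  DensityMap(r$values, voxelSize = r$voxelSize, label = r$label)
}

#' Write a tilt series as a multi-section MRC stack plus a .tlt angle file
#'
#' @param ts a \linkS4class{TiltSeries}.
#' @param stackPath output stack path (multi-section MRC, mode 2).
#' @param anglesPath output angle file (one angle in degrees per line).
#' @return invisibly, `stackPath`.
#' @export
writeTiltSeries <- function(ts, stackPath, anglesPath) {
  stopifnot(is(ts, "TiltSeries"))
  m <- DensityMap(ts@images, voxelSize = ts@voxelSize, label = "tilt stack")
  writeMRC(m, stackPath)
  writeLines(formatC(ts@angles, format = "f", digits = 2), anglesPath)
  invisible(stackPath)
}

#' Read a tilt series from an MRC stack and a .tlt angle file
#'
#' The angle file holds one angle in degrees per section, in section order
#' (IMOD ".tlt" convention); blank lines and trailing whitespace are ignored.
#'
#' @param stackPath multi-section MRC stack.
#' @param anglesPath text file of tilt angles.
#' @return a \linkS4class{TiltSeries}.
#' @export
readTiltSeries <- function(stackPath, anglesPath) {
  r <- readMRCData(stackPath)
  if (!file.exists(anglesPath))
    stop("cannot read angle file: no such file: ", anglesPath)
  ang <- scan(anglesPath, what = numeric(), quiet = TRUE)
  nsec <- dim(r$values)[3L]
  if (length(ang) != nsec)
    stop(sprintf("tilt stack has %d sections but angle file has %d angles",
                 nsec, length(ang)))
  if (length(ang) > 1L && any(diff(ang) <= 0))
    stop("tilt angles must be strictly increasing")
  TiltSeries(r$values, angles = ang, voxelSize = r$voxelSize)
}

## standard atomic weights (Da) for elements common in biomolecules
ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, MN = 54.938,
  CA = 40.078, "NA" = 22.990, K = 39.098, CL = 35.45, CU = 63.546,
  CO = 58.933, NI = 58.693, MO = 95.95, I = 126.904, BR = 79.904,
  F = 18.998, AU = 196.967, W = 183.84)

elementMass <- function(elements) {
  key <- toupper(trimws(elements))
  m <- ATOMIC_MASSES[key]
  unk <- is.na(m)
  if (any(unk)) {
    warning(sprintf("%d atom(s) with unknown element (%s); using carbon mass",
                    sum(unk), paste(unique(key[unk]), collapse = ", ")))
    m[unk] <- ATOMIC_MASSES[["C"]]
  }
  unname(m)
}

#' Read an atom model from a PDB file
#'
#' Parses ATOM and HETATM records (via \code{bio3d::read.pdb}); the element
#' is taken from the element column, falling back to the first letter of the
#' atom name where that column is blank. Masses come from a built-in
#' standard-atomic-weight table; atoms with an unrecognized element get the
#' mass of carbon with a warning.
#'
#' @param path path to a PDB-format file.
#' @return an \linkS4class{AtomModel}.
#' @export
readAtomModel <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB: no such file: ", path)
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L)
    stop("no ATOM/HETATM records found in ", path)
  elem <- a$elesy
  if (is.null(elem)) elem <- rep("", nrow(a))
  elem <- trimws(elem)
  blank <- is.na(elem) | elem == ""
  if (any(blank)) {
    ## fallback: leading alphabetic character(s) of the atom name
    nm <- gsub("[^A-Za-z].*$", "", trimws(a$elety[blank]))
    elem[blank] <- substr(nm, 1L, 1L)
  }
  mass <- elementMass(elem)
  atoms <- data.frame(element = toupper(elem), x = a$x, y = a$y, z = a$z,
                      mass = mass)
  new("AtomModel", atoms = atoms, totalMass = sum(mass))
}

#' Write an FSC curve as a two-column TSV
#'
#' Columns are `freq_inv_angstrom` and `fsc`, with a one-line header.
#'
#' @param curve an \linkS4class{FSCCurve}.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFSCTable <- function(curve, path) {
  stopifnot(is(curve, "FSCCurve"))
  df <- data.frame(freq_inv_angstrom = curve@shellFreq, fsc = curve@fsc)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an FSC curve from a two-column TSV
#'
#' @param path path to a table written by \code{\link{writeFSCTable}}.
#' @param voxelSize Angstrom per voxel of the source maps (recorded on the
#'   returned curve; default derived from the Nyquist shell).
#' @return an \linkS4class{FSCCurve}.
#' @export
readFSCTable <- function(path, voxelSize = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("freq_inv_angstrom", "fsc") %in% names(df)))
    stop("FSC table must have columns freq_inv_angstrom and fsc: ", path)
  freq <- df$freq_inv_angstrom
  if (is.null(voxelSize)) voxelSize <- 1 / (2 * max(freq))
  nshell <- length(freq)
  new("FSCCurve", shellFreq = freq, fsc = df$fsc,
      voxelSize = voxelSize, box = 2L * (nshell - 1L))
}
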