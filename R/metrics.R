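## Quantitative map evaluation: Fourier shell correlation, resolution at a
## threshold, real-space cross-correlation, and the shared low-pass filter.

sameGrid <- function(a, b) identical(dim(a), dim(b))

## per-shell sums over the full centered Fourier grid (shell = round(|k|)
## in voxel units, no smoothing). Returns sums for every occupied shell,
## including the corner shells beyond Nyquist, so power bookkeeping over all
## shells reconciles with total power exactly.
shellSums <- function(Fa, Fb) {
  d <- dim(Fa)
  r <- ifftShift(radiusGrid(d))   # radius in natural (unshifted) layout
  s <- as.integer(round(r))
  num <- rowsum(cbind(Re(Fa * Conj(Fb)), abs(Fa)^2, abs(Fb)^2,
                      rep(1, length(s))), s)
  list(shell = as.integer(rownames(num)), cross = num[, 1],
       powerA = num[, 2], powerB = num[, 3], count = num[, 4])
}

#' Fourier shell correlation between two maps
#'
#' FSC per integer-radius shell s: \code{Re(sum(Fa * Conj(Fb))) /
#' sqrt(sum(|Fa|^2) * sum(|Fb|^2))} over voxels with \code{round(|k|) = s}.
#' Shells run from DC to Nyquist (s = box/2); a shell where either map has
#' zero power is reported as NA.
#'
#' @param a,b \linkS4class{DensityMap}s on the same grid and voxel size.
#' @return an \linkS4class{FSCCurve}.
#' @export
fsc <- function(a, b) {
  stopifnot(is(a, "DensityMap"), is(b, "DensityMap"))
  if (!sameGrid(a@values, b@values))
    stop("maps have different grids: ", paste(dim(a@values), collapse = "x"),
         " vs ", paste(dim(b@values), collapse = "x"))
  if (a@voxelSize != b@voxelSize)
    stop("maps have different voxel sizes")
  Fa <- stats::fft(a@values)
  Fb <- stats::fft(b@values)
  ss <- shellSums(Fa, Fb)
  n <- dim(a@values)[1L]
  smax <- n %/% 2L
  keep <- ss$shell <= smax
  shell <- ss$shell[keep]
  denom <- sqrt(ss$powerA[keep] * ss$powerB[keep])
  val <- ifelse(denom > 0, ss$cross[keep] / denom, NA_real_)
  ## guard tiny numerical excursions beyond +/-1
  val <- pmin(pmax(val, -1), 1)
  new("FSCCurve", shellFreq = shell / (n * a@voxelSize), fsc = val,
      voxelSize = a@voxelSize, box = as.integer(n))
}

#' Resolution at an FSC threshold
#'
#' Finds the first shell pair where the curve falls through the threshold and
#' linearly interpolates the crossing frequency; the resolution is its
#' reciprocal in Angstrom. A curve that never falls below the threshold
#' yields the Nyquist resolution (2 x voxel size) with attribute
#' \code{flag = "at-Nyquist"}; a curve already below the threshold at DC
#' yields the lowest measurable resolution with \code{flag = "no-signal"}.
#' Reported resolutions are clamped at Nyquist.
#'
#' @param curve an \linkS4class{FSCCurve}.
#' @param threshold FSC threshold (default 0.5).
#' @return resolution in Angstrom (numeric scalar, possibly with a
#'   \code{flag} attribute).
#' @export
resolutionAt <- function(curve, threshold = 0.5) {
  stopifnot(is(curve, "FSCCurve"))
  f <- curve@fsc
  fr <- curve@shellFreq
  ok <- !is.na(f)
  f <- f[ok]; fr <- fr[ok]
  if (length(f) == 0L) stop("FSC curve is empty")
  nyq <- 2 * curve@voxelSize
  if (f[1] < threshold) {
    res <- if (length(fr) >= 2L && fr[2] > 0) 1 / fr[2] else Inf
    attr(res, "flag") <- "no-signal"
    return(res)
  }
  below <- which(f < threshold)
  if (length(below) == 0L) {
    res <- nyq
    attr(res, "flag") <- "at-Nyquist"
    return(res)
  }
  i <- below[1L]          # f[i-1] >= threshold > f[i]
  f0 <- f[i - 1L]; f1 <- f[i]
  x0 <- fr[i - 1L]; x1 <- fr[i]
  xc <- x0 + (f0 - threshold) / (f0 - f1) * (x1 - x0)
  res <- 1 / xc
  if (res < nyq) {
    res <- nyq
    attr(res, "flag") <- "at-Nyquist"
  }
  res
}

#' Real-space cross-correlation coefficient between two maps
#'
#' Pearson correlation over all voxels: mean-subtracted and normalized by
#' both standard deviations, hence invariant to affine intensity changes.
#'
#' @param a,b \linkS4class{DensityMap}s on the same grid.
#' @return correlation in [-1, 1].
#' @export
ccc <- function(a, b) {
  stopifnot(is(a, "DensityMap"), is(b, "DensityMap"))
  if (!sameGrid(a@values, b@values)) stop("maps have different grids")
  va <- as.vector(a@values); vb <- as.vector(b@values)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("cannot correlate a zero-variance map")
  stats::cor(va, vb)
}

#' Low-pass filter a density map
#'
#' Multiplies the map transform by a radially symmetric kernel with gain 0.5
#' at frequency 1/resolution (Gaussian by default). DC is unchanged and the
#' output is real.
#'
#' @param map a \linkS4class{DensityMap}.
#' @param resolution target resolution in Angstrom (>= 2 x voxel size).
#' @param shape kernel shape, "gaussian" (default) or "cosine".
#' @return the filtered \linkS4class{DensityMap}.
#' @export
lowpassMap <- function(map, resolution, shape = c("gaussian", "cosine")) {
  stopifnot(is(map, "DensityMap"))
  shape <- match.arg(shape)
  if (resolution < 2 * map@voxelSize)
    stop(sprintf("resolution %.3g A is below Nyquist (%.3g A)",
                 resolution, 2 * map@voxelSize))
  d <- dim(map@values)
  freq <- ifftShift(radiusGrid(d)) / (d[1] * map@voxelSize)
  gain <- lowpassGain(freq, resolution, shape)
  out <- Re(stats::fft(stats::fft(map@values) * gain, inverse = TRUE)) /
    prod(d)
  DensityMap(out, voxelSize = map@voxelSize, label = map@label)
}

#' Half-map FSC from a tilt series
#'
#' Convenience wrapper for the resolution estimate used with experimental
#' data, where no reference object exists: the odd- and even-indexed frames
#' are reconstructed separately and the FSC between the two half-maps is
#' returned. Phantom benchmarks use map-vs-object FSC instead.
#'
#' @param ts a \linkS4class{TiltSeries} with at least four frames.
#' @return an \linkS4class{FSCCurve} between the two half-set
#'   reconstructions.
#' @export
halfMapFSC <- function(ts) {
  stopifnot(is(ts, "TiltSeries"))
  n <- nTilt(ts)
  if (n < 4L) stop("need at least four frames for a half-map FSC")
  odd <- seq(1L, n, by = 2L)
  even <- seq(2L, n, by = 2L)
  a <- backproject(TiltSeries(ts@images[, , odd, drop = FALSE],
                              ts@angles[odd], ts@voxelSize))
  b <- backproject(TiltSeries(ts@images[, , even, drop = FALSE],
                              ts@angles[even], ts@voxelSize))
  fsc(a, b)
}

#' Anisotropy (elongation) of a map's support along the beam axis
#'
#' Ratio of the support extent along z to the extent along x, measured as the
#' bounding range of voxels above a fraction of the map maximum. A wedge-free
#' reconstruction of a globular particle gives a ratio near 1; a missing
#' wedge stretches the map along z and pushes the ratio above 1.
#'
#' @param map a \linkS4class{DensityMap}.
#' @param frac threshold as a fraction of the maximum (default 0.5).
#' @return extent(z) / extent(x), dimensionless.
#' @export
elongationRatio <- function(map, frac = 0.5) {
  stopifnot(is(map, "DensityMap"))
  v <- map@values
  thr <- frac * max(v)
  above <- which(v >= thr, arr.ind = TRUE)
  if (nrow(above) == 0L) stop("no voxels above threshold")
  ext <- function(i) diff(range(above[, i])) + 1L
  ext(3L) / ext(1L)
}
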