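## Tilt-series simulation and reconstruction.
##
## Rotation convention (used identically by projection, backprojection and
## the data zone, so the three stay mutually consistent): a frame at tilt
## angle phi is the line integral along lab z of the map rotated by -phi
## about the +Y axis. Sampling the rotated map at target coordinates
## (x', y, z') reads the source point
##     x = cos(phi) x' + sin(phi) z',  z = -sin(phi) x' + cos(phi) z'
## (y unchanged), with trilinear (here: in-plane bilinear) interpolation.
## By the projection-slice theorem the frame's 2D transform then equals the
## map transform on the central plane (kx', ky) -> (kx' cos phi, ky,
## -kx' sin phi), which is where backprojection re-inserts it.

#' Project a density map into a tilt series
#'
#' Each frame is the line integral of the map along the beam (lab z) after
#' rotating the map by minus the tilt angle about Y, with bilinear
#' interpolation in the x-z plane. Frames have the map's x-y dimensions.
#' If the rotated particle support is clipped by the box edge the projected
#' mass drops; a warning reports the clipped fraction.
#'
#' @param map a cubic \linkS4class{DensityMap}.
#' @param angles tilt angles in degrees, strictly increasing, in (-90, 90].
#' @return a \linkS4class{TiltSeries}.
#' @export
projectTiltSeries <- function(map, angles) {
  stopifnot(is(map, "DensityMap"))
  d <- dim(map@values)
  if (length(unique(d)) != 1L) stop("map must be cubic")
  n <- d[1L]
  ctr <- n %/% 2L               # 0-based center
  t <- seq_len(n) - 1L - ctr    # centered voxel coordinate
  X <- rep(t, times = n)        # x' fastest
  Z <- rep(t, each = n)
  ## map reshaped to rows = (x, z), cols = y
  M2 <- aperm(map@values, c(1, 3, 2))
  dim(M2) <- c(n * n, n)
  mapSum <- sum(map@values)
  frames <- array(0, c(n, n, length(angles)))
  grp <- rep(seq_len(n), times = n)   # x' group of each (x', z') row
  for (j in seq_along(angles)) {
    phi <- angles[j] * pi / 180
    cs <- cos(phi); sn <- sin(phi)
    sx <- cs * X + sn * Z + ctr       # 0-based source coords
    sz <- -sn * X + cs * Z + ctr
    i0 <- floor(sx); k0 <- floor(sz)
    fx <- sx - i0; fz <- sz - k0
    acc <- numeric(n * n)
    for (corner in 1:4) {
      ii <- i0 + (corner == 2L | corner == 4L)
      kk <- k0 + (corner >= 3L)
      w <- (if (corner %% 2L == 1L) 1 - fx else fx) *
           (if (corner <= 2L) 1 - fz else fz)
      ok <- ii >= 0 & ii <= n - 1 & kk >= 0 & kk <= n - 1 & w > 0
      if (!any(ok)) next
      rows <- ii[ok] + 1L + kk[ok] * n
      ## accumulate weighted source columns over y lazily: sum over z' later
      idx <- which(ok)
      contrib <- M2[rows, , drop = FALSE] * w[ok]
      part <- rowsum(contrib, grp[idx])
      gi <- as.integer(rownames(part))
      frames[gi, , j] <- frames[gi, , j] + part
    }
    fsum <- sum(frames[, , j])
    if (mapSum > 0 && (mapSum - fsum) / mapSum > 0.005)
      warning(sprintf("frame at %+.1f deg: rotated support clipped by box edge (%.2f%% of mass lost)",
                      angles[j], 100 * (mapSum - fsum) / mapSum))
  }
  TiltSeries(frames, angles = angles, voxelSize = map@voxelSize)
}

#' Add Gaussian noise to a tilt series at a target SNR
#'
#' Per frame, adds i.i.d. Gaussian noise with standard deviation equal to
#' that frame's signal standard deviation divided by \code{snr} (so
#' \code{snr = 0.3} adds noise with s.d. 1/0.3 = 3.33x the particle's).
#' Deterministic for a fixed seed; \code{snr = Inf} returns the input
#' unchanged.
#'
#' @param ts a \linkS4class{TiltSeries}.
#' @param snr target signal-to-noise ratio (> 0, or Inf for no noise).
#' @param seed integer RNG seed.
#' @return the noisy \linkS4class{TiltSeries}.
#' @export
addNoise <- function(ts, snr, seed = 0L) {
  stopifnot(is(ts, "TiltSeries"))
  if (is.infinite(snr)) return(ts)
  if (snr <= 0) stop("snr must be positive")
  d <- dim(ts@images)
  im <- ts@images
  withSeed(seed, {
    for (j in seq_len(d[3L])) {
      s <- stats::sd(im[, , j])
      if (s == 0)
        stop(sprintf("frame %d has zero variance; cannot scale noise to SNR", j))
      im[, , j] <- im[, , j] + stats::rnorm(d[1L] * d[2L], 0, s / snr)
    }
  })
  TiltSeries(im, angles = ts@angles, voxelSize = ts@voxelSize)
}

#' Measure the SNR of a frame from a particle mask
#'
#' Implements SNR = (I_s - I_b) / N_b, where I_s is the mean intensity
#' inside the particle, I_b the mean outside, and N_b the standard deviation
#' of the background.
#'
#' @param image a 2D numeric matrix.
#' @param particleMask logical matrix, TRUE inside the particle; must have
#'   both foreground and background pixels.
#' @return a list with elements \code{Is}, \code{Ib}, \code{Nb}, \code{snr}.
#' @export
estimateSNR <- function(image, particleMask) {
  stopifnot(is.matrix(image), is.logical(particleMask),
            identical(dim(image), dim(particleMask)))
  if (!any(particleMask)) stop("particle mask has no foreground pixels")
  if (all(particleMask)) stop("particle mask has no background pixels")
  Is <- mean(image[particleMask])
  bg <- image[!particleMask]
  Ib <- mean(bg)
  Nb <- stats::sd(bg)
  if (!is.finite(Nb) || Nb == 0)
    stop("background has zero variance; SNR undefined")
  list(Is = Is, Ib = Ib, Nb = Nb, snr = (Is - Ib) / Nb)
}

#' Fourier data zone of a single-axis tilt range
#'
#' Boolean membership on the centered Fourier grid of a cubic box: a voxel
#' (kx, ky, kz) belongs to the data zone iff the angle of (|kx|, |kz|) from
#' the kx axis is at most \code{tiltMax} plus the half-slice angular
#' thickness \code{delta = atan(0.5 / (box/2))} (half a voxel at the box
#' edge), or it lies on the tilt-axis line kx = kz = 0. Membership is
#' independent of ky and symmetric under k -> -k.
#'
#' @param box voxels per axis.
#' @param tiltMax half tilt range in degrees, in (0, 90].
#' @return a \linkS4class{DataZone}.
#' @export
makeDataZone <- function(box, tiltMax) {
  if (tiltMax <= 0 || tiltMax > 90) stop("tiltMax must lie in (0, 90]")
  box <- as.integer(box)
  k <- centeredCoords(box)
  delta <- atan(0.5 / (box / 2)) * 180 / pi
  ang <- atan2(abs(rep(k, each = box)), abs(rep(k, times = box))) * 180 / pi
  m2 <- matrix(ang <= tiltMax + delta, box, box)   # [kx, kz]
  m2[k == 0, k == 0] <- TRUE                       # tilt-axis line
  ## expand over ky: member[i, j, l] = m2[i, l]
  member <- aperm(array(m2, c(box, box, box)), c(1, 3, 2))
  new("DataZone", membership = member, tiltMax = tiltMax)
}

#' Fraction of Fourier space missing outside the data zone
#'
#' By default the count is restricted to the in-plane Nyquist disc
#' (sqrt(kx^2 + kz^2) <= box/2), where the angular fraction of a bow-tie
#' zone is exact: the missing fraction of a +/- theta tilt range tends to
#' (90 - theta)/90 in the continuum. Counting over the full cubic grid
#' instead weights the square's corners and is available via
#' \code{withinNyquist = FALSE}.
#'
#' @param zone a \linkS4class{DataZone}.
#' @param withinNyquist restrict to the in-plane Nyquist disc (default TRUE).
#' @return missing fraction in [0, 1].
#' @export
missingFraction <- function(zone, withinNyquist = TRUE) {
  stopifnot(is(zone, "DataZone"))
  d <- dim(zone@membership)
  k <- centeredCoords(d[1])
  r2 <- outer(k^2, k^2, "+")                       # [kx, kz]
  inDisc <- r2 <= (d[1] / 2)^2
  sel <- if (withinNyquist) aperm(array(inDisc, c(d[1], d[1], d[1])),
                                  c(1, 3, 2))
         else TRUE
  1 - sum(zone@membership & sel) / sum(sel & array(TRUE, d))
}

#' Reconstruct a map from a tilt series by direct Fourier inversion
#'
#' Each frame's centered 2D transform is inserted as a central slice of the
#' 3D transform -- the plane through the k_y axis rotated by the tilt angle
#' about it -- with bilinear gridding in the (kx, kz) plane and per-voxel
#' accumulation of interpolation weights. Voxels with positive accumulated
#' weight are normalized by it; the real part of the inverse transform is
#' returned.
#'
#' Normalization divides by \code{max(weight, minWeight)} rather than the
#' raw weight: a voxel grazed only by the bilinear tail of a distant slice
#' has a weight far below 1, and dividing by it would amplify that leakage
#' to full slice amplitude, filling the missing wedge with artifacts. The
#' clamp leaves properly sampled voxels (weight ~1 or more) untouched and
#' attenuates grazed ones in proportion to their sampling.
#'
#' @param ts a \linkS4class{TiltSeries} with at least two square frames.
#' @param minWeight clamp for the gridding-weight normalization (default 0.5).
#' @return a \linkS4class{DensityMap} with the frame dimensions cubed.
#' @export
backproject <- function(ts, minWeight = 0.5) {
  stopifnot(is(ts, "TiltSeries"))
  d <- dim(ts@images)
  if (d[1L] != d[2L]) stop("frames must be square")
  if (d[3L] < 2L) stop("need at least two frames")
  n <- d[1L]
  k <- centeredCoords(n)
  Fre <- numeric(n^3); Fim <- numeric(n^3); wt <- numeric(n^3)
  iy <- seq_len(n)                       # ky = v occupies exact grid rows
  for (j in seq_len(d[3L])) {
    phi <- ts@angles[j] * pi / 180
    F2 <- fftShift(stats::fft(ifftShift(ts@images[, , j])))   # [u, v]
    kx <- k * cos(phi)
    kz <- -k * sin(phi)
    i0 <- floor(kx); l0 <- floor(kz)
    fx <- kx - i0; fz <- kz - l0
    for (corner in 1:4) {
      ii <- i0 + (corner == 2L | corner == 4L)
      ll <- l0 + (corner >= 3L)
      w <- (if (corner %% 2L == 1L) 1 - fx else fx) *
           (if (corner <= 2L) 1 - fz else fz)
      ix <- ii + n %/% 2L + 1L           # 1-based centered indices
      iz <- ll + n %/% 2L + 1L
      ok <- ix >= 1L & ix <= n & iz >= 1L & iz <= n & w > 0
      if (!any(ok)) next
      ## scatter the whole ky column for each sampled u
      u <- which(ok)
      base <- ix[ok] + (iz[ok] - 1L) * n * n        # at iy = 1
      idx <- rep(base, each = n) + rep((iy - 1L) * n, times = length(u))
      val <- as.vector(t(F2[u, , drop = FALSE]))    # v fastest within each u
      ww <- rep(w[ok], each = n)
      s <- rowsum(cbind(Re(val) * ww, Im(val) * ww, ww), idx)
      at <- as.numeric(rownames(s))
      Fre[at] <- Fre[at] + s[, 1]
      Fim[at] <- Fim[at] + s[, 2]
      wt[at] <- wt[at] + s[, 3]
    }
  }
  pos <- wt > 0
  Fvol <- complex(real = Fre, imaginary = Fim)
  Fvol[pos] <- Fvol[pos] / pmax(wt[pos], minWeight)
  dim(Fvol) <- c(n, n, n)
  ## the measured region is exactly the data zone of the tilt range used;
  ## bilinear gridding tails that graze unmeasured voxels (severe near DC,
  ## where amplitudes are largest) are cleared so that filled region and
  ## data zone coincide by construction
  zone <- makeDataZone(n, min(90, max(abs(ts@angles))))
  Fvol[!zone@membership] <- 0
  vol <- Re(cIFFT(Fvol))
  DensityMap(vol, voxelSize = ts@voxelSize,
             label = sprintf("backprojection of %d frames, tilt %+.1f..%+.1f",
                             d[3L], min(ts@angles), max(ts@angles)))
}

#' Low-pass filter every frame of a tilt series
#'
#' Applies the same kernel family as \code{\link{lowpassMap}} (gain 0.5 at
#' 1/resolution) in 2D to each frame; the DC value of each frame is
#' unchanged. Used to suppress image noise before reconstruction.
#'
#' @param ts a \linkS4class{TiltSeries}.
#' @param resolution target resolution in Angstrom (>= 2 x pixel size).
#' @param shape kernel shape, "gaussian" (default) or "cosine".
#' @return the filtered \linkS4class{TiltSeries}.
#' @export
lowpassTiltSeries <- function(ts, resolution, shape = c("gaussian", "cosine")) {
  stopifnot(is(ts, "TiltSeries"))
  shape <- match.arg(shape)
  if (resolution < 2 * ts@voxelSize)
    stop(sprintf("resolution %.3g A is below Nyquist (%.3g A)",
                 resolution, 2 * ts@voxelSize))
  d <- dim(ts@images)
  kx <- centeredCoords(d[1L]) / (d[1L] * ts@voxelSize)
  ky <- centeredCoords(d[2L]) / (d[2L] * ts@voxelSize)
  freq <- ifftShift(sqrt(outer(kx^2, ky^2, "+")))
  gain <- lowpassGain(freq, resolution, shape)
  im <- ts@images
  for (j in seq_len(d[3L]))
    im[, , j] <- Re(stats::fft(stats::fft(im[, , j]) * gain,
                               inverse = TRUE)) / (d[1L] * d[2L])
  TiltSeries(im, angles = ts@angles, voxelSize = ts@voxelSize)
}
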