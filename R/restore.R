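## The missing-wedge restoration itself: support-mask generation, the
## real-space constraint / Fourier data-zone locking cycle, fixed-length
## iteration rounds, and multi-round mask regeneration.
##
## One iteration: (real-space) zero outside the mask, discard imaginary
## parts, clamp negatives inside the mask to zero -> forward FFT -> lock the
## data zone to the transform of the *initial* map (held fixed throughout)
## -> inverse FFT. The measured data are never altered; only the
## missing-wedge voxels evolve.

#' Build a support mask from a map
#'
#' Low-passes the map to \code{maskFilterRes}, then thresholds it at the
#' density cutoff whose above-threshold volume equals
#' \code{volumeFactor x mwDa x vPerDa} (the molecular-weight-equivalent
#' volume times the chosen factor). The cutoff is the corresponding order
#' statistic of the filtered densities, so the volume is matched to within
#' one voxel (well inside the 1% contract). The default conversion
#' \code{vPerDa = 1.21} A^3/Da corresponds to a protein partial specific
#' volume of 0.73 cm^3/g.
#'
#' @param map a nonzero \linkS4class{DensityMap}.
#' @param params a \linkS4class{RestoreParams} (uses maskFilterRes,
#'   volumeFactor, mwDa, vPerDa).
#' @param source provenance string recorded on the mask.
#' @return a \linkS4class{SupportMask}.
#' @export
makeMask <- function(map, params, source = "initial") {
  stopifnot(is(map, "DensityMap"), is(params, "RestoreParams"))
  if (all(map@values == 0)) stop("cannot build a mask from an all-zero map")
  nvox <- length(map@values)
  targetVox <- round(params@volumeFactor * params@mwDa * params@vPerDa /
                     map@voxelSize^3)
  if (targetVox >= nvox)
    stop(sprintf("target mask volume (%.0f voxels) exceeds the box (%d voxels); reduce volumeFactor or enlarge the box",
                 targetVox, nvox))
  if (targetVox < 1) stop("target mask volume is below one voxel")
  filt <- lowpassMap(map, params@maskFilterRes)
  sv <- sort(as.vector(filt@values), decreasing = TRUE)
  thr <- sv[targetVox]
  member <- filt@values >= thr
  new("SupportMask", membership = member, filterRes = params@maskFilterRes,
      volumeFactor = params@volumeFactor, threshold = thr, source = source)
}

## raw-array kernel of the real-space constraints (hot path)
.realConstrain <- function(x, member) {
  v <- Re(x)
  v[!member | v < 0] <- 0
  ## a clamped voxel outside the mask is already 0; the single expression
  ## zeroes both the outside and the negative-inside voxels
  dim(v) <- dim(member)
  v
}

#' Apply the real-space constraints of the restoration
#'
#' Sets every voxel outside the mask to zero, discards imaginary parts, and
#' clamps negative real values inside the mask to zero. The output is purely
#' real, non-negative inside the mask and zero outside.
#'
#' @param map a \linkS4class{DensityMap}, or a (possibly complex) 3D array
#'   as produced by an inverse Fourier transform.
#' @param mask a \linkS4class{SupportMask} on the same grid.
#' @param voxelSize voxel size for the result when `map` is a raw array.
#' @return a \linkS4class{DensityMap}.
#' @export
applyRealConstraints <- function(map, mask, voxelSize = NULL) {
  stopifnot(is(mask, "SupportMask"))
  if (is(map, "DensityMap")) {
    v <- map@values
    voxelSize <- map@voxelSize
  } else {
    v <- map
    if (is.null(voxelSize)) voxelSize <- 1
  }
  if (!identical(dim(v), dim(mask@membership)))
    stop("map and mask have different grids")
  DensityMap(.realConstrain(v, mask@membership), voxelSize = voxelSize)
}

#' Lock the measured Fourier data zone
#'
#' Returns a complex volume equal to `original` on data-zone voxels and to
#' `current` elsewhere: the measured data are locked while the missing-wedge
#' voxels remain free variables. Because the zone is symmetric under
#' k -> -k, Hermitian symmetry of the inputs is preserved.
#'
#' @param current complex 3D array (centered layout), the evolving transform.
#' @param original complex 3D array (centered layout), the fixed transform
#'   of the initial map.
#' @param zone a \linkS4class{DataZone} on the same grid.
#' @return complex 3D array.
#' @export
replaceDataZone <- function(current, original, zone) {
  stopifnot(is(zone, "DataZone"))
  if (!identical(dim(current), dim(original)) ||
      !identical(dim(current), dim(zone@membership)))
    stop("current, original and zone must share one grid")
  current[zone@membership] <- original[zone@membership]
  current
}

#' Run one restoration round (fixed mask)
#'
#' Iterates the constraint cycle \code{nIter} times from the initial map:
#' real-space constraints -> forward transform -> data-zone locking to the
#' transform of the initial map -> inverse transform. Returns the map after
#' a final real-space constraint application, plus the per-iteration
#' relative-change trace (Frobenius norm of the difference between
#' successive constrained maps over the norm of the previous one).
#'
#' @param initialMap the low-tilt reconstruction (\linkS4class{DensityMap});
#'   its transform supplies the locked data-zone values.
#' @param mask a \linkS4class{SupportMask} on the same grid.
#' @param zone a \linkS4class{DataZone} on the same grid.
#' @param nIter number of iterations (>= 0; 0 returns the start unchanged).
#' @param startMap map to iterate from (default: \code{initialMap}); a later
#'   round passes the previous round's output here while the data zone stays
#'   locked to the initial map.
#' @param tol optional early-stop tolerance on the relative per-iteration
#'   change (default NULL: run the full fixed iteration count, as the method
#'   prescribes).
#' @return list with elements \code{map} (\linkS4class{DensityMap}) and
#'   \code{trace} (numeric, length <= nIter).
#' @export
runRound <- function(initialMap, mask, zone, nIter, startMap = initialMap,
                     tol = NULL) {
  stopifnot(is(initialMap, "DensityMap"), is(mask, "SupportMask"),
            is(zone, "DataZone"), is(startMap, "DensityMap"))
  v0 <- initialMap@values
  if (!identical(dim(v0), dim(mask@membership)) ||
      !identical(dim(v0), dim(zone@membership)) ||
      !identical(dim(v0), dim(startMap@values)))
    stop("map, mask and zone must share one grid")
  if (all(v0 == 0)) stop("initial map is all zero")
  nIter <- as.integer(nIter)
  if (nIter == 0L) return(list(map = startMap, trace = numeric(0)))
  F0 <- stats::fft(v0)
  zoneU <- ifftShift(zone@membership)   # natural FFT layout
  member <- mask@membership
  nvox <- length(v0)
  m <- startMap@values
  prev <- m
  prevNorm <- sqrt(sum(prev^2))
  trace <- numeric(nIter)
  nDone <- nIter
  for (i in seq_len(nIter)) {
    cm <- .realConstrain(m, member)
    trace[i] <- if (prevNorm > 0) sqrt(sum((cm - prev)^2)) / prevNorm else 0
    prev <- cm
    prevNorm <- sqrt(sum(cm^2))
    if (!is.null(tol) && i > 1L && trace[i] < tol) { nDone <- i; break }
    Fm <- stats::fft(cm)
    Fm[zoneU] <- F0[zoneU]
    m <- stats::fft(Fm, inverse = TRUE) / nvox
    if (!all(is.finite(Re(m))))
      stop(sprintf("non-finite values arose at iteration %d", i))
  }
  trace <- trace[seq_len(nDone)]
  out <- .realConstrain(m, member)
  ## trace entry i measures the change introduced by cycle i-1; shift so the
  ## last entry reflects the final cycle
  trace <- c(trace[-1L],
             if (prevNorm > 0) sqrt(sum((out - prev)^2)) / prevNorm else 0)
  list(map = DensityMap(out, voxelSize = initialMap@voxelSize,
                        label = sprintf("%s + %d restoration iteration(s)",
                                        initialMap@label, nIter)),
       trace = trace)
}

#' Restore the missing wedge of a low-tilt reconstruction
#'
#' Runs \code{nRounds} rounds of \code{nIterPerRound} constraint-cycle
#' iterations. Round 1 masks with \code{makeMask(initialMap, params)} (or
#' \code{maskOverride} if supplied); each later round regenerates the mask
#' from the previous round's output with the same filter resolution and
#' volume factor, which sharpens the support as the elongation artifact
#' recedes.
#'
#' @param initialMap the low-tilt reconstruction (\linkS4class{DensityMap}).
#' @param params a \linkS4class{RestoreParams}.
#' @param verbose print a one-line summary per round.
#' @return a \linkS4class{RestorationResult}.
#' @export
restoreMissingWedge <- function(initialMap, params, verbose = FALSE) {
  stopifnot(is(initialMap, "DensityMap"), is(params, "RestoreParams"))
  if (all(initialMap@values == 0)) stop("initial map is all zero")
  box <- dim(initialMap@values)[1L]
  zone <- makeDataZone(box, params@tiltMax)
  mask <- if (!is.null(params@maskOverride)) params@maskOverride
          else makeMask(initialMap, params, source = "initial")
  maps <- vector("list", params@nRounds)
  conv <- numeric(0)
  cur <- initialMap
  for (r in seq_len(params@nRounds)) {
    if (r > 1L)
      mask <- makeMask(maps[[r - 1L]], params,
                       source = sprintf("round_%d", r - 1L))
    rr <- runRound(initialMap, mask, zone, params@nIterPerRound,
                   startMap = cur)
    maps[[r]] <- rr$map
    cur <- rr$map
    conv <- c(conv, rr$trace)
    if (verbose)
      message(sprintf("round %d/%d: final relative change %.3g",
                      r, params@nRounds, utils::tail(rr$trace, 1)))
  }
  new("RestorationResult", finalMap = maps[[params@nRounds]],
      perRoundMaps = maps, convergence = conv, params = params)
}
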