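## Constructors, generics, accessors and show() methods.

#' Construct a DensityMap
#'
#' @param values numeric 3D array of densities.
#' @param voxelSize Angstrom per voxel.
#' @param label optional provenance string.
#' @return a \linkS4class{DensityMap}.
#' @export
DensityMap <- function(values, voxelSize = 1, label = "") {
  new("DensityMap", values = values, voxelSize = as.numeric(voxelSize),
      label = label)
}

#' Construct a TiltSeries
#'
#' @param images px x py x n_tilt numeric array of projection frames.
#' @param angles tilt angles in degrees, one per frame, strictly increasing.
#' @param voxelSize Angstrom per pixel.
#' @return a \linkS4class{TiltSeries}.
#' @export
TiltSeries <- function(images, angles, voxelSize = 1) {
  new("TiltSeries", images = images, angles = as.numeric(angles),
      voxelSize = as.numeric(voxelSize))
}

#' Construct restoration parameters
#'
#' @param tiltMax half tilt range of the data in degrees.
#' @param mwDa molecular mass of the particle in Dalton.
#' @param voxelSize Angstrom per voxel of the map.
#' @param maskFilterRes mask-generation low-pass resolution in Angstrom
#'   (default 40; sensible range ~40-80).
#' @param volumeFactor mask volume as a multiple of the molecular-weight
#'   equivalent volume (default 3; sensible range ~1.5-4).
#' @param nIterPerRound constraint-cycle iterations per round (default 1000).
#' @param nRounds number of rounds; each round after the first regenerates
#'   the mask from the previous round's output (default 5).
#' @param maskOverride optional \linkS4class{SupportMask} to use in round 1
#'   instead of deriving one from the initial map (e.g. a precise mask built
#'   from the known object).
#' @param vPerDa protein volume per Dalton in Angstrom^3 (default 1.21,
#'   from a partial specific volume of 0.73 cm^3/g).
#' @return a \linkS4class{RestoreParams}.
#' @export
RestoreParams <- function(tiltMax, mwDa, voxelSize, maskFilterRes = 40,
                          volumeFactor = 3, nIterPerRound = 1000L,
                          nRounds = 5L, maskOverride = NULL, vPerDa = 1.21) {
  new("RestoreParams", tiltMax = as.numeric(tiltMax), mwDa = as.numeric(mwDa),
      voxelSize = as.numeric(voxelSize),
      maskFilterRes = as.numeric(maskFilterRes),
      volumeFactor = as.numeric(volumeFactor),
      nIterPerRound = as.integer(nIterPerRound), nRounds = as.integer(nRounds),
      maskOverride = maskOverride, vPerDa = as.numeric(vPerDa))
}

#' Construct a synthetic phantom specification
#'
#' @param box voxels per axis (even, >= 32).
#' @param voxelSize Angstrom per voxel.
#' @param nBlobs Gaussian blob clusters before symmetrization.
#' @param symmetryOrder n-fold rotational symmetry about Z (1 = none).
#' @param radiusRange c(min, max) radial placement of blobs in Angstrom;
#'   defaults to (0, 0.45 * box * voxelSize / 2) so the particle stays well
#'   inside the box.
#' @param nDetail count of sharp (sub-voxel-width) blobs layered on the
#'   smooth body, emulating atomic-scale detail; 0 for a smooth phantom.
#' @param seed integer seed controlling blob placement.
#' @return a \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(box, voxelSize = 1, nBlobs = 12L, symmetryOrder = 1L,
                        radiusRange = NULL, nDetail = 0L, seed = 0L) {
  if (is.null(radiusRange))
    radiusRange <- c(0, 0.45 * box * voxelSize / 2)
  new("PhantomSpec", box = as.integer(box), voxelSize = as.numeric(voxelSize),
      nBlobs = as.integer(nBlobs), symmetryOrder = as.integer(symmetryOrder),
      radiusRange = as.numeric(radiusRange), nDetail = as.integer(nDetail),
      seed = as.integer(seed))
}

#' @rdname mapData
#' @export
setGeneric("mapData", function(x) standardGeneric("mapData"))

#' Extract the raw voxel/pixel data of a container
#'
#' @param x a DensityMap, TiltSeries, DataZone or SupportMask.
#' @return the underlying array (numeric or logical).
#' @export
setMethod("mapData", "DensityMap", function(x) x@values)

#' @rdname mapData
#' @export
setMethod("mapData", "TiltSeries", function(x) x@images)

#' @rdname mapData
#' @export
setMethod("mapData", "DataZone", function(x) x@membership)

#' @rdname mapData
#' @export
setMethod("mapData", "SupportMask", function(x) x@membership)

#' @rdname voxelSize
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Voxel (pixel) size in Angstrom
#'
#' @param x a DensityMap, TiltSeries or FSCCurve.
#' @return Angstrom per voxel.
#' @export
setMethod("voxelSize", "DensityMap", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "TiltSeries", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "FSCCurve", function(x) x@voxelSize)

#' Tilt angles of a series, in degrees
#'
#' @param x a TiltSeries.
#' @return numeric vector of angles.
#' @export
setGeneric("tiltAngles", function(x) standardGeneric("tiltAngles"))

#' @rdname tiltAngles
#' @export
setMethod("tiltAngles", "TiltSeries", function(x) x@angles)

#' Number of frames in a tilt series
#'
#' @param x a TiltSeries.
#' @return integer frame count.
#' @export
setGeneric("nTilt", function(x) standardGeneric("nTilt"))

#' @rdname nTilt
#' @export
setMethod("nTilt", "TiltSeries", function(x) dim(x@images)[3L])

#' Atoms of an AtomModel
#'
#' @param x an AtomModel.
#' @return data.frame with columns element, x, y, z, mass.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "AtomModel", function(x) x@atoms)

#' Total mass of an AtomModel in Dalton
#'
#' @param x an AtomModel.
#' @return numeric, Da.
#' @export
setGeneric("totalMass", function(x) standardGeneric("totalMass"))

#' @rdname totalMass
#' @export
setMethod("totalMass", "AtomModel", function(x) x@totalMass)

#' Final restored map of a RestorationResult
#'
#' @param x a RestorationResult.
#' @return a DensityMap.
#' @export
setGeneric("finalMap", function(x) standardGeneric("finalMap"))

#' @rdname finalMap
#' @export
setMethod("finalMap", "RestorationResult", function(x) x@finalMap)

#' Per-round restored maps
#'
#' @param x a RestorationResult.
#' @return list of DensityMap, one per round.
#' @export
setGeneric("perRoundMaps", function(x) standardGeneric("perRoundMaps"))

#' @rdname perRoundMaps
#' @export
setMethod("perRoundMaps", "RestorationResult", function(x) x@perRoundMaps)

#' Per-iteration convergence trace
#'
#' Relative change of the map between successive iterations, concatenated
#' across rounds.
#'
#' @param x a RestorationResult.
#' @return numeric vector (>= 0).
#' @export
setGeneric("convergenceTrace", function(x) standardGeneric("convergenceTrace"))

#' @rdname convergenceTrace
#' @export
setMethod("convergenceTrace", "RestorationResult", function(x) x@convergence)

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityMap %dx%dx%d voxels, %.3g A/voxel\n",
              d[1], d[2], d[3], object@voxelSize))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(object@values), max(object@values), mean(object@values)))
  if (nzchar(object@label)) cat("  label:", object@label, "\n")
})

setMethod("show", "TiltSeries", function(object) {
  d <- dim(object@images)
  cat(sprintf("TiltSeries: %d frames of %dx%d px, %.3g A/px\n",
              d[3], d[1], d[2], object@voxelSize))
  cat(sprintf("  tilt %+.1f to %+.1f deg about Y\n",
              min(object@angles), max(object@angles)))
})

setMethod("show", "AtomModel", function(object) {
  cat(sprintf("AtomModel: %d atoms, total mass %.4g kDa\n",
              nrow(object@atoms), object@totalMass / 1000))
})

setMethod("show", "DataZone", function(object) {
  d <- dim(object@membership)
  cat(sprintf("DataZone: box %d^3, tilt half-range %.1f deg, %.1f%% of Fourier voxels sampled\n",
              d[1], object@tiltMax, 100 * mean(object@membership)))
})

setMethod("show", "SupportMask", function(object) {
  cat(sprintf("SupportMask: %d voxels (%.1f%% of box), source '%s'\n",
              sum(object@membership), 100 * mean(object@membership),
              object@source))
  if (is.finite(object@filterRes))
    cat(sprintf("  filter %.3g A, volume factor %.3g, threshold %.4g\n",
                object@filterRes, object@volumeFactor, object@threshold))
})

setMethod("show", "FSCCurve", function(object) {
  res <- resolutionAt(object, 0.5)
  cat(sprintf("FSCCurve: %d shells to Nyquist (%.3g A/voxel, box %d)\n",
              length(object@fsc), object@voxelSize, object@box))
  cat(sprintf("  resolution (FSC = 0.5): %.3g A%s\n", res,
              if (!is.null(attr(res, "flag"))) paste0(" [", attr(res, "flag"), "]")
              else ""))
})

setMethod("show", "RestorationResult", function(object) {
  cat(sprintf("RestorationResult: %d round(s) x %d iteration(s)\n",
              object@params@nRounds, object@params@nIterPerRound))
  cat(sprintf("  final relative change per iteration: %.3g\n",
              utils::tail(object@convergence, 1)))
  show(object@finalMap)
})

setMethod("show", "RestoreParams", function(object) {
  cat(sprintf(paste0(
    "RestoreParams: tilt +/-%g deg, MW %.4g kDa, %.3g A/voxel\n",
    "  mask: %.3g A filter, %.3g x MW volume; %d iter x %d round(s)%s\n"),
    object@tiltMax, object@mwDa / 1000, object@voxelSize,
    object@maskFilterRes, object@volumeFactor,
    object@nIterPerRound, object@nRounds,
    if (!is.null(object@maskOverride)) "; external mask" else ""))
})
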