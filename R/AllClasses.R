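#' @import methods
NULL

## Central containers. All voxel grids are base-R numeric arrays indexed
## [x, y, z] with x the fastest-varying (MRC column) axis; the box/rotation
## center sits at 0-based index n/2 on each axis (1-based n/2 + 1), the same
## voxel that carries DC in the centered Fourier layout.

#' DensityMap: a real-valued 3D voxel grid with a physical voxel size
#'
#' The fundamental container of the package: a cubic (or rectangular) grid of
#' real densities in arbitrary units, with an isotropic voxel size in
#' Angstrom. Both the restoration input (the low-tilt reconstruction) and all
#' intermediate/restored maps are `DensityMap`s.
#'
#' @slot values numeric 3D array, all finite.
#' @slot voxelSize Angstrom per voxel (isotropic, > 0).
#' @slot label free-text provenance.
#' @export
setClass("DensityMap",
  representation(values = "array", voxelSize = "numeric", label = "character"),
  prototype(label = ""))

setValidity("DensityMap", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3D array")
  if (!is.numeric(v)) return("values must be numeric (real)")
  if (!all(is.finite(v))) return("values must all be finite")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0) return("voxelSize must be a single positive number")
  TRUE
})

#' TiltSeries: an ordered stack of 2D projections with tilt angles
#'
#' Frames are stored as a px x py x n_tilt array; angles are in degrees about
#' the fixed in-plane Y axis, strictly increasing, each in (-90, 90].
#'
#' @slot images numeric array px x py x n_tilt.
#' @slot angles numeric, degrees, one per frame.
#' @slot voxelSize Angstrom per pixel.
#' @export
setClass("TiltSeries",
  representation(images = "array", angles = "numeric", voxelSize = "numeric"))

setValidity("TiltSeries", function(object) {
  im <- object@images
  if (length(dim(im)) != 3L) return("images must be a px x py x n_tilt array")
  n <- dim(im)[3L]
  a <- object@angles
  if (length(a) != n)
    return(sprintf("angle count (%d) does not match frame count (%d)",
                   length(a), n))
  if (any(!is.finite(a)) || any(a <= -90) || any(a > 90))
    return("angles must lie in (-90, 90] degrees")
  if (n > 1L && any(diff(a) <= 0))
    return("angles must be strictly increasing")
  if (!all(is.finite(im))) return("frames must be finite")
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    return("voxelSize must be a single positive number")
  TRUE
})

#' AtomModel: a point-atom model with per-atom masses
#'
#' @slot atoms data.frame with columns element, x, y, z (Angstrom), mass (Da).
#' @slot totalMass total mass in Da.
#' @export
setClass("AtomModel",
  representation(atoms = "data.frame", totalMass = "numeric"))

setValidity("AtomModel", function(object) {
  a <- object@atoms
  need <- c("element", "x", "y", "z", "mass")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("model contains no atoms")
  if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
    return("atom coordinates must be finite")
  if (object@totalMass <= 0) return("totalMass must be positive")
  TRUE
})

#' DataZone: Fourier-space membership of the measured single-axis tilt range
#'
#' A boolean volume on the centered Fourier grid: TRUE where a central slice
#' of the tilt series passes (the bow-tie shaped "data zone"), FALSE in the
#' missing wedge. Membership depends only on (k_x, k_z) because the tilt axis
#' is Y; it is symmetric under k -> -k so that Hermitian symmetry of the map
#' transform is preserved when the zone is locked.
#'
#' @slot membership logical 3D array on the centered Fourier grid.
#' @slot tiltMax half tilt range in degrees.
#' @export
setClass("DataZone",
  representation(membership = "array", tiltMax = "numeric"))

setValidity("DataZone", function(object) {
  m <- object@membership
  if (length(dim(m)) != 3L || !is.logical(m))
    return("membership must be a logical 3D array")
  if (object@tiltMax <= 0 || object@tiltMax > 90)
    return("tiltMax must lie in (0, 90]")
  TRUE
})

#' SupportMask: the binary real-space support region of the particle
#'
#' Generated by thresholding a heavily low-pass-filtered map at a density
#' cutoff calibrated so that the enclosed volume equals a chosen multiple of
#' the protein's molecular-weight-equivalent volume. The mask need not be a
#' single connected component.
#'
#' @slot membership logical 3D array (same grid as the map).
#' @slot filterRes Angstrom low-pass resolution used on the source map.
#' @slot volumeFactor mask volume / molecular-weight-equivalent volume.
#' @slot threshold density cutoff that produced the mask.
#' @slot source which map generated it ("initial", "round_k", "object", ...).
#' @export
setClass("SupportMask",
  representation(membership = "array", filterRes = "numeric",
                 volumeFactor = "numeric", threshold = "numeric",
                 source = "character"),
  prototype(filterRes = NA_real_, volumeFactor = NA_real_,
            threshold = NA_real_, source = "external"))

setValidity("SupportMask", function(object) {
  m <- object@membership
  if (length(dim(m)) != 3L || !is.logical(m))
    return("membership must be a logical 3D array")
  if (!any(m)) return("mask is empty")
  if (all(m)) return("mask covers the whole box")
  TRUE
})

#' FSCCurve: per-shell Fourier shell correlation between two maps
#'
#' @slot shellFreq spatial frequency (1/Angstrom) at each shell center.
#' @slot fsc correlation per shell, in [-1, 1] (NA for empty shells).
#' @slot voxelSize Angstrom per voxel of the compared maps.
#' @slot box voxels per axis of the compared maps.
#' @export
setClass("FSCCurve",
  representation(shellFreq = "numeric", fsc = "numeric",
                 voxelSize = "numeric", box = "integer"))

setValidity("FSCCurve", function(object) {
  if (length(object@shellFreq) != length(object@fsc))
    return("shellFreq and fsc must have equal length")
  if (any(diff(object@shellFreq) <= 0))
    return("shellFreq must be strictly increasing")
  ok <- !is.na(object@fsc)
  if (any(abs(object@fsc[ok]) > 1 + 1e-6))
    return("fsc values must lie in [-1, 1]")
  TRUE
})

#' RestoreParams: tunable parameters of the missing-wedge restoration
#'
#' Defaults follow the recommended operating point: a 40 Angstrom mask filter
#' (valid range ~40-80), a mask volume of 3x the molecular-weight-equivalent
#' volume (valid ~1.5-4), 1,000 iterations per round and 5 rounds.
#'
#' @slot tiltMax half tilt range of the data, degrees.
#' @slot mwDa molecular mass of the particle, Da.
#' @slot voxelSize Angstrom per voxel.
#' @slot maskFilterRes Angstrom low-pass used to build the mask (default 40).
#' @slot volumeFactor mask volume as a multiple of the MW volume (default 3).
#' @slot nIterPerRound iterations per round (default 1000).
#' @slot nRounds number of mask-regeneration rounds (default 5).
#' @slot maskOverride optional externally supplied SupportMask (or NULL).
#' @slot vPerDa Angstrom^3 of particle volume per Dalton (default 1.21).
#' @export
setClass("RestoreParams",
  representation(tiltMax = "numeric", mwDa = "numeric", voxelSize = "numeric",
                 maskFilterRes = "numeric", volumeFactor = "numeric",
                 nIterPerRound = "integer", nRounds = "integer",
                 maskOverride = "ANY", vPerDa = "numeric"),
  prototype(maskFilterRes = 40, volumeFactor = 3, nIterPerRound = 1000L,
            nRounds = 5L, maskOverride = NULL, vPerDa = 1.21))

setValidity("RestoreParams", function(object) {
  if (object@tiltMax <= 0 || object@tiltMax > 90)
    return("tiltMax must lie in (0, 90]")
  if (object@mwDa <= 0) return("mwDa must be positive")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  if (object@nIterPerRound < 0L) return("nIterPerRound must be >= 0")
  if (object@nRounds < 1L) return("nRounds must be >= 1")
  if (!is.null(object@maskOverride) && !is(object@maskOverride, "SupportMask"))
    return("maskOverride must be NULL or a SupportMask")
  if (object@vPerDa <= 0) return("vPerDa must be positive")
  TRUE
})

#' RestorationResult: output of a multi-round missing-wedge restoration
#'
#' @slot finalMap the restored DensityMap after the last round.
#' @slot perRoundMaps list of DensityMap, one per round.
#' @slot convergence per-iteration relative map change, concatenated over rounds.
#' @slot params the RestoreParams used.
#' @export
setClass("RestorationResult",
  representation(finalMap = "DensityMap", perRoundMaps = "list",
                 convergence = "numeric", params = "RestoreParams"))

setValidity("RestorationResult", function(object) {
  if (length(object@perRoundMaps) != object@params@nRounds)
    return("perRoundMaps length must equal nRounds")
  if (any(object@convergence < 0, na.rm = TRUE))
    return("convergence values must be >= 0")
  TRUE
})

#' PhantomSpec: parameters of the synthetic globular phantom generator
#'
#' Describes a compact particle made of Gaussian pseudo-atom blobs, with
#' optional n-fold rotational symmetry about Z, used as a download-free test
#' object for the simulation pipeline.
#'
#' @slot box voxels per axis (even, >= 32).
#' @slot voxelSize Angstrom per voxel.
#' @slot nBlobs number of Gaussian blob clusters before symmetrization.
#' @slot symmetryOrder n for n-fold symmetry about Z (1 = none).
#' @slot radiusRange min/max radial blob placement, Angstrom.
#' @slot nDetail count of sharp sub-voxel-scale blobs layered on the body,
#'   emulating the atomic-scale detail of a crystal-structure object
#'   (0 = smooth body only).
#' @slot seed integer seed; same seed gives the same phantom.
#' @export
setClass("PhantomSpec",
  representation(box = "integer", voxelSize = "numeric", nBlobs = "integer",
                 symmetryOrder = "integer", radiusRange = "numeric",
                 nDetail = "integer", seed = "integer"),
  prototype(voxelSize = 1, nBlobs = 12L, symmetryOrder = 1L, nDetail = 0L,
            seed = 0L))

setValidity("PhantomSpec", function(object) {
  if (object@box < 32L || object@box %% 2L != 0L)
    return("box must be even and >= 32")
  if (object@nBlobs < 1L) return("nBlobs must be >= 1")
  if (object@nDetail < 0L) return("nDetail must be >= 0")
  if (object@symmetryOrder < 1L) return("symmetryOrder must be >= 1")
  if (length(object@radiusRange) != 2L || any(object@radiusRange < 0) ||
      diff(object@radiusRange) < 0)
    return("radiusRange must be c(min, max) with 0 <= min <= max")
  TRUE
})
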