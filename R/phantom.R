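## Test-object generation: atom-model-derived density maps (the classical
## pdb-to-map Gaussian splat) and fully synthetic seeded phantoms for
## download-free testing.

## run expr with a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

## splat one Gaussian of integrated weight `w` (density units x voxel^3)
## centered at 0-based voxel position p (length 3) into `vol`, in place-ish.
## sigma in voxels. The kernel is renormalized over its sampled footprint so
## each atom contributes exactly w to the map sum.
splatGaussian <- function(vol, p, sigma, w, radius = NULL) {
  d <- dim(vol)
  if (is.null(radius)) radius <- max(2L, ceiling(4 * sigma))
  i0 <- floor(p) # 0-based
  rng <- lapply(1:3, function(a) {
    r <- (i0[a] - radius):(i0[a] + radius + 1L)
    r[r >= 0L & r <= d[a] - 1L]
  })
  k <- lapply(1:3, function(a) exp(-((rng[[a]] - p[a])^2) / (2 * sigma^2)))
  tot <- prod(vapply(k, sum, 0))
  if (tot <= 0) return(vol)
  block <- outer(outer(k[[1]], k[[2]]), k[[3]]) * (w / tot)
  ix <- rng[[1]] + 1L; iy <- rng[[2]] + 1L; iz <- rng[[3]] + 1L
  vol[ix, iy, iz] <- vol[ix, iy, iz] + block
  vol
}

#' Rasterize an atom model into a density map
#'
#' Each atom contributes an isotropic Gaussian whose integrated weight is
#' proportional to its atomic mass. The model is recentered so its center of
#' mass sits at the box center. The Gaussian real-space standard deviation is
#' \code{blurRes / (pi * sqrt(2))}, which puts the half-maximum of the
#' corresponding Fourier envelope at \code{1/blurRes}; the default
#' \code{blurRes = 2 * voxelSize} makes atoms just resolved at Nyquist.
#'
#' @param model an \linkS4class{AtomModel}.
#' @param box voxels per axis of the (cubic) output map.
#' @param voxelSize Angstrom per voxel.
#' @param blurRes Gaussian blur resolution in Angstrom.
#' @param center recenter the model's center of mass on the box center
#'   (default TRUE); with FALSE, coordinates are taken relative to the box
#'   center as origin.
#' @return a \linkS4class{DensityMap} whose sum equals the total model mass
#'   (atoms fully inside the box).
#' @export
atomsToMap <- function(model, box, voxelSize = 1, blurRes = 2 * voxelSize,
                       center = TRUE) {
  stopifnot(is(model, "AtomModel"))
  a <- model@atoms
  box <- as.integer(box)
  com <- if (center)
    c(sum(a$x * a$mass), sum(a$y * a$mass), sum(a$z * a$mass)) / sum(a$mass)
  else c(0, 0, 0)
  ctr <- box %/% 2L           # 0-based center index
  px <- (a$x - com[1]) / voxelSize + ctr
  py <- (a$y - com[2]) / voxelSize + ctr
  pz <- (a$z - com[3]) / voxelSize + ctr
  out <- px < 0 | px > box - 1 | py < 0 | py > box - 1 | pz < 0 | pz > box - 1
  if (any(out))
    stop(sprintf("%d atom(s) fall outside the %d^3 box after centering; use a larger box",
                 sum(out), box))
  sigma <- blurRes / (pi * sqrt(2)) / voxelSize   # in voxels
  vol <- array(0, c(box, box, box))
  rad <- max(2L, ceiling(4 * sigma))
  for (i in seq_len(nrow(a)))
    vol <- splatGaussian(vol, c(px[i], py[i], pz[i]), sigma, a$mass[i], rad)
  DensityMap(vol, voxelSize = voxelSize,
             label = sprintf("atom model, %d atoms, blur %.3g A",
                             nrow(a), blurRes))
}

#' Generate a synthetic globular phantom
#'
#' Builds a compact particle from Gaussian blobs placed at seeded random
#' positions around the box center. The first blob is always a central core
#' (so a one-blob phantom is centered); with \code{symmetryOrder = n > 1}
#' every blob is replicated at the n rotations of its azimuth about Z, making
#' the map n-fold rotationally symmetric by construction. Blob placement is
#' constrained so the particle support stays within 0.8x the box half-width.
#' The map is deterministic for a fixed seed.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a non-negative \linkS4class{DensityMap}.
#' @export
makeSyntheticPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  n <- spec@box
  vox <- spec@voxelSize
  halfA <- n / 2 * vox
  withSeed(spec@seed, {
    nb <- spec@nBlobs
    sigma <- runif(nb, 0.05, 0.10) * halfA           # blob width, Angstrom
    rmax <- pmin(spec@radiusRange[2], 0.8 * halfA - 3.5 * sigma)
    rr <- runif(nb, spec@radiusRange[1], pmax(spec@radiusRange[1], rmax))
    rr[1] <- 0                                       # central core
    sigma[1] <- max(sigma)
    az <- runif(nb, 0, 2 * pi)
    ## isotropic placement on the sphere: globular, no preferred axis
    polar <- acos(runif(nb, -1, 1))
    amp <- runif(nb, 0.5, 1.5)
    vol <- array(0, c(n, n, n))
    ctr <- n %/% 2L
    sym <- spec@symmetryOrder
    for (i in seq_len(nb)) {
      for (k in seq_len(sym)) {
        phi <- az[i] + 2 * pi * (k - 1) / sym
        pA <- rr[i] * c(cos(phi) * sin(polar[i]), sin(phi) * sin(polar[i]),
                        cos(polar[i]))
        p <- pA / vox + ctr
        vol <- splatGaussian(vol, p, sigma[i] / vox, amp[i])
      }
    }
    if (spec@nDetail > 0L) {
      ## sharp speckle emulating atomic-scale structure: keeps the spectrum
      ## populated out to Nyquist, as a rasterized crystal structure would be
      nd <- spec@nDetail
      dSig <- runif(nd, 0.45, 0.75) * vox            # Angstrom, sub-voxel
      dAmp <- runif(nd, 0.1, 0.25) * max(amp)
      dR <- pmin(abs(rnorm(nd, 0, 0.25 * halfA)), 0.7 * halfA)
      dAz <- runif(nd, 0, 2 * pi)
      dPol <- acos(runif(nd, -1, 1))
      for (i in seq_len(nd)) {
        for (k in seq_len(sym)) {
          phi <- dAz[i] + 2 * pi * (k - 1) / sym
          pA <- dR[i] * c(cos(phi) * sin(dPol[i]), sin(phi) * sin(dPol[i]),
                          cos(dPol[i]))
          vol <- splatGaussian(vol, pA / vox + ctr, dSig[i] / vox, dAmp[i])
        }
      }
    }
    DensityMap(vol, voxelSize = vox,
               label = sprintf("synthetic phantom, %d blobs, C%d, seed %d",
                               nb, sym, spec@seed))
  })
}
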