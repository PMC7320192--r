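## End-to-end experiment grid: phantom -> project -> (noise) -> (prefilter)
## -> reconstruct -> restore -> evaluate, over tilt ranges and SNRs.

## apparent molecular weight of a map from its support volume, used when no
## nominal mass is supplied (synthetic phantoms have no physical mass)
apparentMw <- function(map, vPerDa = 1.21, frac = 0.1) {
  v <- map@values
  sum(v > frac * max(v)) * map@voxelSize^3 / vPerDa
}

resolveBenchObject <- function(object, box, voxelSize) {
  if (is(object, "DensityMap")) return(object)
  if (is(object, "PhantomSpec")) return(makeSyntheticPhantom(object))
  if (is.character(object) && length(object) == 1L) {
    model <- readAtomModel(object)
    return(atomsToMap(model, box = box, voxelSize = voxelSize))
  }
  stop("object must be a DensityMap, a PhantomSpec, or a PDB file path")
}

#' Run a benchmark grid of missing-wedge restorations
#'
#' Expands \code{tiltMax x snr} into independent cells. Each cell projects
#' the object into a tilt series (1.5-degree steps by default), optionally
#' adds Gaussian noise at the requested SNR and low-pass filters the frames,
#' reconstructs an initial map by direct Fourier backprojection, restores it,
#' and evaluates resolution (FSC = 0.5 against the object) and CCC before
#' and after. Failures in one cell are recorded in the table and do not stop
#' the run.
#'
#' @param object a \linkS4class{DensityMap}, a \linkS4class{PhantomSpec}, or
#'   the path to a PDB file (rasterized at \code{box}/\code{voxelSize}).
#' @param tiltMax vector of half tilt ranges in degrees.
#' @param snr vector of SNRs; \code{Inf} means noise-free.
#' @param prefilter optional tilt-series low-pass resolution in Angstrom
#'   (NULL = none), applied after noise.
#' @param maskRecipe "map" (mask from the initial reconstruction) or
#'   "precise" (mask from the object itself).
#' @param mwDa nominal molecular mass in Da; default: the model mass for a
#'   PDB object, otherwise the map's apparent support-volume mass.
#' @param volumeFactor,maskFilterRes,nIter,nRounds restoration parameters
#'   (see \code{\link{RestoreParams}}).
#' @param step tilt increment in degrees (default 1.5).
#' @param box,voxelSize rasterization grid used when `object` is a PDB path.
#' @param seed base RNG seed; cell i uses seed + i.
#' @param outDir optional directory: writes `bench.tsv`, a `config.txt`
#'   provenance echo, and (with `saveIntermediates`) all intermediate maps.
#' @param saveIntermediates write object/initial/restored maps per cell.
#' @return a data.frame with one row per cell: tilt_max, snr, prefilter,
#'   initial_res, res_round_1..nRounds, initial_ccc, restored_ccc, error.
#' @export
runBench <- function(object, tiltMax = c(15, 30, 45, 60), snr = Inf,
                     prefilter = NULL, maskRecipe = c("map", "precise"),
                     mwDa = NULL, volumeFactor = 3, maskFilterRes = 40,
                     nIter = 1000L, nRounds = 1L, step = 1.5,
                     box = 256L, voxelSize = 1, seed = 0L, outDir = NULL,
                     saveIntermediates = FALSE) {
  maskRecipe <- match.arg(maskRecipe)
  if (is.character(object) && is.null(mwDa))
    mwDa <- totalMass(readAtomModel(object))
  obj <- resolveBenchObject(object, box, voxelSize)
  if (is.null(mwDa)) mwDa <- apparentMw(obj)
  n <- dim(obj@values)[1L]
  fullAngles <- seq(-90 + step, 90, by = step)
  ts <- projectTiltSeries(obj, fullAngles)
  cells <- expand.grid(snr = snr, tilt_max = tiltMax)[, c("tilt_max", "snr")]
  resCols <- sprintf("res_round_%d", seq_len(nRounds))
  out <- data.frame(cells, prefilter = if (is.null(prefilter)) NA_real_
                                       else prefilter,
                    initial_res = NA_real_)
  out[resCols] <- NA_real_
  out$initial_ccc <- NA_real_
  out$restored_ccc <- NA_real_
  out$error <- ""
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeLines(c(
      sprintf("seed: %d", seed),
      sprintf("object: %s", obj@label),
      sprintf("mwDa: %.6g", mwDa),
      sprintf("tiltMax: %s", paste(tiltMax, collapse = ",")),
      sprintf("snr: %s", paste(snr, collapse = ",")),
      sprintf("prefilter: %s", if (is.null(prefilter)) "none" else prefilter),
      sprintf("maskRecipe: %s", maskRecipe),
      sprintf("volumeFactor: %g", volumeFactor),
      sprintf("maskFilterRes: %g", maskFilterRes),
      sprintf("nIter: %d  nRounds: %d  step: %g", nIter, nRounds, step)),
      file.path(outDir, "config.txt"))
    if (saveIntermediates)
      writeMRC(obj, file.path(outDir, "object.mrc"))
  }
  for (i in seq_len(nrow(out))) {
    t <- out$tilt_max[i]; s <- out$snr[i]
    res <- try({
      keep <- ts@angles >= -t - 1e-9 & ts@angles <= t + 1e-9
      sub <- TiltSeries(ts@images[, , keep, drop = FALSE], ts@angles[keep],
                        ts@voxelSize)
      if (is.finite(s)) sub <- addNoise(sub, s, seed = seed + i)
      if (!is.null(prefilter)) sub <- lowpassTiltSeries(sub, prefilter)
      initial <- backproject(sub)
      params <- RestoreParams(tiltMax = t, mwDa = mwDa,
                              voxelSize = obj@voxelSize,
                              maskFilterRes = maskFilterRes,
                              volumeFactor = volumeFactor,
                              nIterPerRound = nIter, nRounds = nRounds)
      if (maskRecipe == "precise")
        params@maskOverride <- makeMask(obj, params, source = "object")
      rest <- restoreMissingWedge(initial, params)
      out$initial_res[i] <- as.numeric(resolutionAt(fsc(initial, obj)))
      out$initial_ccc[i] <- ccc(initial, obj)
      for (r in seq_len(nRounds))
        out[i, resCols[r]] <-
          as.numeric(resolutionAt(fsc(perRoundMaps(rest)[[r]], obj)))
      out$restored_ccc[i] <- ccc(finalMap(rest), obj)
      if (!is.null(outDir) && saveIntermediates) {
        tag <- sprintf("tilt%02d_snr%s", t, ifelse(is.finite(s), s, "inf"))
        writeMRC(initial, file.path(outDir, paste0(tag, "_initial.mrc")))
        writeMRC(finalMap(rest), file.path(outDir,
                                           paste0(tag, "_restored.mrc")))
      }
      NULL
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      out$error[i] <- conditionMessage(attr(res, "condition"))
  }
  if (!is.null(outDir))
    utils::write.table(format(out, digits = 6), file.path(outDir, "bench.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  out
}
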