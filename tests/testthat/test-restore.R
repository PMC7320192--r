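test_that("support masks hit the molecular-weight-equivalent target volume", {
  ph <- seededPhantom(1, box = 64, sym = 7)
  mw <- 8e5 / 600   # scaled-down nominal mass so the target fits a 64-box
  p38 <- RestoreParams(15, mw, 1, volumeFactor = 3.8)
  m38 <- makeMask(ph, p38)
  target <- 3.8 * mw * 1.21        # voxels at 1 A/voxel
  expect_lt(abs(sum(mapData(m38)) - target) / target, 0.01)
  # a 1.75x mask has (1.75/3.8) times the voxels
  p175 <- RestoreParams(15, mw, 1, volumeFactor = 1.75)
  m175 <- makeMask(ph, p175)
  expect_equal(sum(mapData(m175)) / sum(mapData(m38)), 1.75 / 3.8,
               tolerance = 0.01)
  # provenance is recorded
  expect_identical(m38@filterRes, 40)
  expect_identical(m38@volumeFactor, 3.8)
})

test_that("masks of spherically symmetric maps inherit the symmetry", {
  sp <- shellTestMap(64, radiusFrac = 0.2, widthFrac = 0.1)
  mw <- sum(mapData(sp) > 0.3) * 1 / 1.21 / 2
  mask <- mapData(makeMask(sp, RestoreParams(15, mw, 1, volumeFactor = 2)))
  # symmetry of the input is preserved up to threshold ties on the boundary
  # shell: voxels whose filtered densities agree to float precision can fall
  # on either side of the volume cutoff
  symDiff <- function(a, b) mean(a != b)
  expect_lt(symDiff(mask, aperm(mask, c(3, 2, 1))), 0.01 * mean(mask))
  sub <- mask[2:64, 2:64, 2:64]
  expect_lt(symDiff(sub, sub[63:1, 63:1, 63:1]), 0.01 * mean(mask))
})

test_that("mask construction rejects impossible volumes and empty maps", {
  ph <- seededPhantom(1, box = 32)
  expect_error(makeMask(ph, RestoreParams(15, 1e9, 1)), "exceeds the box")
  zero <- DensityMap(array(0, c(32, 32, 32)))
  expect_error(makeMask(zero, RestoreParams(15, 1e3, 1)), "all-zero")
})

test_that("real-space constraints equal the per-voxel scalar definition", {
  set.seed(50)
  n <- 4
  member <- array(runif(n^3) > 0.4, c(n, n, n))
  member[1, 1, 1] <- TRUE; member[2, 2, 2] <- FALSE   # both classes present
  mask <- new("SupportMask", membership = member)
  x <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)), c(n, n, n))
  got <- mapData(applyRealConstraints(x, mask))
  ref <- array(0, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (member[i, j, k]) {
      re <- Re(x[i, j, k])
      ref[i, j, k] <- if (re < 0) 0 else re
    } else ref[i, j, k] <- 0
  }
  expect_equal(got, ref, tolerance = 0)
  # trivial cases
  pos <- array(abs(rnorm(n^3)) + 0.1, c(n, n, n))
  gotPos <- mapData(applyRealConstraints(pos, mask))
  expect_equal(gotPos[member], pos[member], tolerance = 0)
  expect_true(all(gotPos[!member] == 0))
  expect_true(all(mapData(applyRealConstraints(array(-1, c(n, n, n)),
                                               mask)) == 0))
  expect_error(applyRealConstraints(array(1, c(8, 8, 8)), mask),
               "different grids")
})

test_that("data-zone locking equals the per-voxel conditional", {
  set.seed(51)
  n <- 8
  cur <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)), c(n, n, n))
  ori <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)), c(n, n, n))
  z <- makeDataZone(n, 45)
  got <- replaceDataZone(cur, ori, z)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    want <- if (mapData(z)[i, j, k]) ori[i, j, k] else cur[i, j, k]
    expect_identical(got[i, j, k], want)
  }
  # all-true zone returns the original voxel-exactly
  zAll <- new("DataZone", membership = array(TRUE, c(n, n, n)), tiltMax = 90)
  expect_identical(replaceDataZone(cur, ori, zAll), ori)
  # all-false zone (not constructible via makeDataZone) returns current
  zNone <- new("DataZone", membership = array(FALSE, c(n, n, n)),
               tiltMax = 45)   # membership set directly, not via makeDataZone
  expect_identical(replaceDataZone(cur, ori, zNone), cur)
  expect_error(replaceDataZone(cur, ori[1:4, 1:4, 1:4], z), "share one grid")
})

test_that("locking a Hermitian transform through a symmetric zone stays Hermitian", {
  set.seed(52)
  n <- 16
  a <- array(rnorm(n^3), c(n, n, n))
  b <- array(rnorm(n^3), c(n, n, n))
  z <- makeDataZone(n, 30)
  Fa <- tomowedge:::cFFT(a); Fb <- tomowedge:::cFFT(b)
  out <- replaceDataZone(Fa, Fb, z)
  back <- tomowedge:::cIFFT(out)
  expect_lt(max(abs(Im(back))), 1e-10 * max(abs(back)))
})

test_that("one full restoration iteration matches a scalar reference implementation", {
  set.seed(53)
  n <- 4
  v0 <- array(rnorm(n^3)^2, c(n, n, n))       # positive-ish start
  v0[1, , ] <- -abs(v0[1, , ])                # some negatives too
  member <- array(TRUE, c(n, n, n)); member[ , 4, ] <- FALSE
  mask <- new("SupportMask", membership = member)
  z <- makeDataZone(n, 45)
  initial <- DensityMap(v0)
  got <- runRound(initial, mask, z, 1L)$map

  # scalar reference: naive centered DFTs and explicit voxel loops
  c1 <- array(0, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    c1[i, j, k] <- if (member[i, j, k] && v0[i, j, k] > 0) v0[i, j, k] else 0
  F0 <- naiveCenteredDFT3(v0)
  Fc <- naiveCenteredDFT3(c1)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    if (mapData(z)[i, j, k]) Fc[i, j, k] <- F0[i, j, k]
  m1 <- naiveCenteredDFT3(Fc, inverse = TRUE)
  ref <- array(0, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    re <- Re(m1[i, j, k])
    ref[i, j, k] <- if (member[i, j, k] && re > 0) re else 0
  }
  expect_equal(mapData(got), ref, tolerance = 1e-10)
})

test_that("an all-true zone makes the constrained initial map a fixed point", {
  ph <- seededPhantom(4, box = 32)
  mw <- tomowedge:::apparentMw(ph) / 3
  params <- RestoreParams(90, mw, 1)
  mask <- makeMask(ph, params)
  z <- makeDataZone(32, 90)
  one <- runRound(ph, mask, z, 1L)$map
  expect_equal(mapData(one), mapData(applyRealConstraints(ph, mask)),
               tolerance = 1e-10)
  more <- runRound(ph, mask, z, 5L)$map
  expect_equal(mapData(more), mapData(one), tolerance = 1e-9)
})

test_that("zero iterations return the start unchanged; zero maps are rejected", {
  ph <- seededPhantom(4, box = 32)
  mask <- makeMask(ph, RestoreParams(15, tomowedge:::apparentMw(ph) / 3, 1))
  z <- makeDataZone(32, 15)
  out <- runRound(ph, mask, z, 0L)
  expect_identical(mapData(out$map), mapData(ph))
  expect_length(out$trace, 0)
  zero <- DensityMap(array(0, c(32, 32, 32)))
  expect_error(runRound(zero, mask, z, 1L), "all zero")
  expect_error(restoreMissingWedge(zero, RestoreParams(15, 100, 1)),
               "all zero")
})

test_that("the optional early-stop tolerance truncates a round", {
  ph <- seededPhantom(4, box = 32)
  mw <- tomowedge:::apparentMw(ph) / 3
  mask <- makeMask(ph, RestoreParams(90, mw, 1))
  z <- makeDataZone(32, 90)
  # all-true zone: the map is a fixed point after one cycle, so a loose
  # tolerance stops well before the requested 50 iterations
  out <- runRound(ph, mask, z, 50L, tol = 1e-6)
  expect_lt(length(out$trace), 50L)
})

test_that("iteration fills the wedge and the convergence trace settles", {
  sh <- shellTestMap(64)
  init <- backproject(projectTiltSeries(sh, tiltGrid(30)))
  mw <- tomowedge:::apparentMw(sh) / 3
  params <- RestoreParams(30, mw, 1, volumeFactor = 3)
  mask <- makeMask(init, params)
  z <- makeDataZone(64, 30)
  wedgeEnergy <- function(m) {
    Fm <- tomowedge:::cFFT(mapData(m))
    sum(abs(Fm[!mapData(z)])^2) / sum(abs(Fm)^2)
  }
  expect_lt(wedgeEnergy(init), 0.01)      # empty before
  rr <- runRound(init, mask, z, 200L)
  expect_gt(wedgeEnergy(rr$map), 0.02)    # filled after
  expect_lt(rr$trace[200], rr$trace[1])   # change shrinks
})

test_that("restoration output satisfies the real-space constraints exactly", {
  ph <- seededPhantom(5, box = 48)
  init <- backproject(projectTiltSeries(ph, tiltGrid(30)))
  mw <- tomowedge:::apparentMw(ph)
  params <- RestoreParams(30, mw, 1, nIterPerRound = 150L, nRounds = 1L)
  res <- restoreMissingWedge(init, params)
  out <- mapData(finalMap(res))
  mask <- makeMask(init, params)
  expect_true(all(out[!mapData(mask)] == 0))
  expect_true(all(out[mapData(mask)] >= 0))
  expect_true(all(Im(out) == 0))
})

test_that("converged restorations keep the locked data zone within 5%", {
  # a self-consistent fixture: the initial map is the object with its wedge
  # zeroed, so a masked non-negative map matching the zone exists (the
  # object itself), provided the mask covers the object's support
  ph <- seededPhantom(5, box = 48)
  z <- makeDataZone(48, 30); zm <- mapData(z)
  Fp <- tomowedge:::cFFT(mapData(ph))
  Fw <- Fp; Fw[!zm] <- 0
  init <- DensityMap(Re(tomowedge:::cIFFT(Fw)), 1)
  mw <- tomowedge:::apparentMw(ph, frac = 0.02)
  params <- RestoreParams(30, mw, 1, volumeFactor = 4)
  mask <- makeMask(ph, params, source = "object")
  # the mask must genuinely contain the particle for fidelity to hold
  expect_lt(sum(mapData(ph)[!mapData(mask)]) / sum(mapData(ph)), 0.01)
  r <- runRound(init, mask, makeDataZone(48, 30), 400L)
  F0 <- tomowedge:::cFFT(mapData(init))
  Fo <- tomowedge:::cFFT(mapData(r$map))
  relErr <- sqrt(sum(abs(Fo[zm] - F0[zm])^2) / sum(abs(F0[zm])^2))
  expect_lt(relErr, 0.05)
  expect_gt(ccc(r$map, ph), 0.85)
})

test_that("a single round through the top-level driver reduces to runRound", {
  ph <- seededPhantom(6, box = 32)
  init <- backproject(projectTiltSeries(ph, tiltGrid(30)))
  mw <- tomowedge:::apparentMw(ph)
  params <- RestoreParams(30, mw, 1, nIterPerRound = 20L, nRounds = 1L)
  res <- restoreMissingWedge(init, params)
  direct <- runRound(init, makeMask(init, params), makeDataZone(32, 30), 20L)
  expect_equal(mapData(finalMap(res)), mapData(direct$map), tolerance = 1e-12)
  expect_length(perRoundMaps(res), 1L)
  expect_equal(convergenceTrace(res), direct$trace, tolerance = 1e-12)
})

test_that("restoration improves resolution and corrects elongation on one fixture", {
  ph <- seededPhantom(7, box = 64, sym = 3)
  init <- backproject(projectTiltSeries(ph, tiltGrid(30)))
  params <- RestoreParams(30, tomowedge:::apparentMw(ph), 1,
                          nIterPerRound = 200L, nRounds = 1L)
  res <- restoreMissingWedge(init, params)
  rInit <- as.numeric(resolutionAt(fsc(init, ph)))
  rRest <- as.numeric(resolutionAt(fsc(finalMap(res), ph)))
  expect_lte(rRest, rInit)
  eObj <- elongationRatio(ph)
  eInit <- elongationRatio(init)
  eRest <- elongationRatio(finalMap(res))
  expect_lt(abs(eRest - 1), abs(eInit - 1))
})

test_that("a precise object-derived mask restores at least as well as a map-derived one", {
  ph <- seededPhantom(8, box = 64, sym = 2)
  init <- backproject(projectTiltSeries(ph, tiltGrid(15)))
  mw <- tomowedge:::apparentMw(ph)
  base <- RestoreParams(15, mw, 1, nIterPerRound = 150L, nRounds = 1L)
  mapMask <- restoreMissingWedge(init, base)
  precise <- base
  precise@maskOverride <- makeMask(ph, base, source = "object")
  preciseRes <- restoreMissingWedge(init, precise)
  # compare FSC area against the object (higher = closer to the truth)
  area <- function(m) sum(fsc(m, ph)@fsc, na.rm = TRUE)
  expect_gte(area(finalMap(preciseRes)), area(finalMap(mapMask)))
})
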