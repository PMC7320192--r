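# Fixture builders and independent reference implementations used as
# oracles. Everything here is deliberately written as plain scalar loops /
# naive formulas, independent of the package's vectorized code paths.

# minimal PDB writer: atoms = data.frame(element, x, y, z), optional record
# type ("ATOM"/"HETATM"); returns the file path
writeToyPDB <- function(atoms, path = tempfile(fileext = ".pdb"),
                        record = "ATOM") {
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    lines[i] <- sprintf(
      "%-6s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      record, i, atoms$element[i], "UNK", i,
      atoms$x[i], atoms$y[i], atoms$z[i], 1.0, 0.0, atoms$element[i])
  }
  writeLines(c(lines, "END"), path)
  path
}

# independent bilinear rotation of a volume about the Z axis, slice by slice
rotateMapZ <- function(vol, angleDeg) {
  n <- dim(vol)[1]
  ctr <- n %/% 2
  a <- angleDeg * pi / 180
  out <- array(0, dim(vol))
  xy <- seq_len(n) - 1 - ctr
  for (iz in seq_len(n)) {
    sl <- vol[, , iz]
    for (j in seq_len(n)) {
      for (i in seq_len(n)) {
        # source coords: inverse rotation
        xs <- cos(a) * xy[i] + sin(a) * xy[j] + ctr
        ys <- -sin(a) * xy[i] + cos(a) * xy[j] + ctr
        x0 <- floor(xs); y0 <- floor(ys)
        fx <- xs - x0; fy <- ys - y0
        acc <- 0
        for (dx in 0:1) for (dy in 0:1) {
          xi <- x0 + dx; yi <- y0 + dy
          if (xi >= 0 && xi < n && yi >= 0 && yi < n) {
            w <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
            acc <- acc + w * sl[xi + 1, yi + 1]
          }
        }
        out[i, j, iz] <- acc
      }
    }
  }
  out
}

# naive scalar 3D DFT with the centered convention: both spatial and
# frequency indices run over -n/2 .. n/2-1, F(k) = sum_r f(r) e^{-2pi i k.r/n}
naiveCenteredDFT3 <- function(x, inverse = FALSE) {
  n <- dim(x)[1]
  cc <- seq_len(n) - 1 - n %/% 2
  sgn <- if (inverse) 2i * pi / n else -2i * pi / n
  out <- array(0i, dim(x))
  for (k1 in seq_len(n)) for (k2 in seq_len(n)) for (k3 in seq_len(n)) {
    s <- 0i
    for (r1 in seq_len(n)) for (r2 in seq_len(n)) for (r3 in seq_len(n)) {
      ph <- sgn * (cc[k1] * cc[r1] + cc[k2] * cc[r2] + cc[k3] * cc[r3])
      s <- s + x[r1, r2, r3] * exp(ph)
    }
    out[k1, k2, k3] <- s
  }
  if (inverse) out / n^3 else out
}

# a smooth compact test map: sum of a few fixed Gaussians (no RNG)
smoothTestMap <- function(n = 32, voxelSize = 1) {
  ctr <- n %/% 2
  g <- seq_len(n) - 1 - ctr
  r2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  v <- exp(-r2 / (2 * (0.12 * n)^2))
  off <- outer(outer((g - 0.15 * n)^2, g^2, "+"), (g + 0.1 * n)^2, "+")
  v <- v + 0.6 * exp(-off / (2 * (0.08 * n)^2))
  DensityMap(v, voxelSize = voxelSize, label = "smooth test map")
}

# hollow spherical-shell phantom (strong features along every axis)
shellTestMap <- function(n = 64, radiusFrac = 0.28, widthFrac = 0.06) {
  ctr <- n %/% 2
  g <- seq_len(n) - 1 - ctr
  r <- sqrt(outer(outer(g^2, g^2, "+"), g^2, "+"))
  v <- exp(-(r - radiusFrac * n)^2 / (2 * (widthFrac * n)^2))
  DensityMap(v, voxelSize = 1, label = "spherical shell")
}

# seeded standard phantom used across restoration tests
seededPhantom <- function(seed, box = 64, sym = 1) {
  makeSyntheticPhantom(PhantomSpec(box, seed = seed, symmetryOrder = sym))
}

# tilt angles covering +/- tiltMax in 1.5 degree steps
tiltGrid <- function(tiltMax, step = 1.5) seq(-tiltMax, tiltMax, by = step)
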