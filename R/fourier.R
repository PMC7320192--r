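## Centered-FFT plumbing shared by the simulation, metrics and restoration
## code. All user-facing Fourier volumes use the centered layout: DC at
## 0-based index n/2 per axis, i.e. the same voxel as the real-space box
## center. fftShift moves DC from index 0 to n/2; ifftShift is its inverse
## (they coincide for even n, which the box invariants guarantee, but both
## are kept for clarity).

## centered integer frequency coordinate along an axis of length n:
## -n/2 ... n/2 - 1 for even n
centeredCoords <- function(n) seq_len(n) - 1L - (n %/% 2L)

shiftIdx <- function(n, inverse = FALSE) {
  h <- if (inverse) ceiling(n / 2) else floor(n / 2)
  c(seq.int(h + 1L, n), seq_len(h))
}

fftShift <- function(x) {
  d <- dim(x)
  if (is.null(d)) return(x[shiftIdx(length(x))])
  if (length(d) == 2L) return(x[shiftIdx(d[1]), shiftIdx(d[2]), drop = FALSE])
  x[shiftIdx(d[1]), shiftIdx(d[2]), shiftIdx(d[3]), drop = FALSE]
}

ifftShift <- function(x) {
  d <- dim(x)
  if (is.null(d)) return(x[shiftIdx(length(x), TRUE)])
  if (length(d) == 2L)
    return(x[shiftIdx(d[1], TRUE), shiftIdx(d[2], TRUE), drop = FALSE])
  x[shiftIdx(d[1], TRUE), shiftIdx(d[2], TRUE), shiftIdx(d[3], TRUE),
    drop = FALSE]
}

## centered forward/inverse transforms (any dimensionality handled by fft)
cFFT <- function(x) fftShift(stats::fft(ifftShift(x)))
cIFFT <- function(X) fftShift(stats::fft(ifftShift(X), inverse = TRUE)) / length(X)

## |k| in voxel units on the centered grid (3D)
radiusGrid <- function(d) {
  kx <- centeredCoords(d[1]); ky <- centeredCoords(d[2]); kz <- centeredCoords(d[3])
  sqrt(outer(outer(kx^2, ky^2, "+"), kz^2, "+"))
}

## Gaussian low-pass gain with half-max at cutoff (1/resolution), evaluated
## at |k| given in cycles per Angstrom. Shared by map and tilt-series filters.
gaussianLowpassGain <- function(freq, resolution) {
  exp(-log(2) * (freq * resolution)^2)
}

## raised-cosine alternative: gain 1 below half the cutoff, 0 above 1.5x
cosineLowpassGain <- function(freq, resolution) {
  fc <- 1 / resolution
  t <- (freq - 0.5 * fc) / fc
  g <- 0.5 * (1 + cos(pi * pmin(pmax(t, 0), 1)))
  g
}

lowpassGain <- function(freq, resolution, shape = c("gaussian", "cosine")) {
  shape <- match.arg(shape)
  switch(shape,
         gaussian = gaussianLowpassGain(freq, resolution),
         cosine = cosineLowpassGain(freq, resolution))
}
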