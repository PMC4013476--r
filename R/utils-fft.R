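# Internal DFT helpers shared by stimulus synthesis, template construction,
# whitening and the localization decision function.  All convolutions in the
# package are circular (wrap-around), matching the generation model of the
# stimuli; frequencies are DFT frequencies in cycles/pixel.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# DFT frequencies for an even-length axis, in cycles/pixel
fftFreqs <- function(n) {
  c(0:(n / 2 - 1), -(n / 2):-1) / n
}

# |f| = sqrt(fx^2 + fy^2) on the full 2-D DFT grid
radialFreqGrid <- function(n) {
  f2 <- fftFreqs(n)^2
  sqrt(outer(f2, f2, "+"))
}

# Circular shift of matrix content by (+dr, +dc): result[i, j] = x[i-dr, j-dc]
# with 1-based indices taken modulo the matrix extent.
circShift <- function(x, dr, dc) {
  n <- nrow(x)
  m <- ncol(x)
  x[((seq_len(n) - 1L - dr) %% n) + 1L,
    ((seq_len(m) - 1L - dc) %% m) + 1L,
    drop = FALSE]
}

# Unit-peak Gaussian profile wrapped onto the torus, peak at index (1, 1).
# Centered versions are circular shifts of this; the two agree exactly
# because wrapped distances are symmetric.
targetOrigin <- function(n, sigma) {
  d <- pmin(0:(n - 1), n - (0:(n - 1)))
  exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
}

# Binary disk kernel (<= radius, Euclidean) wrapped at the origin.
diskKernelOrigin <- function(n, radius) {
  d <- pmin(0:(n - 1), n - (0:(n - 1)))
  (outer(d^2, d^2, "+") <= radius^2) * 1
}

# Integer lattice offsets with dx^2 + dy^2 <= radius^2 (81 offsets at radius 5)
diskOffsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

# First position of the maximum in row-major (reading) order, returned as
# c(row, col).  Row-major tie-breaking is part of the decision-rule contract
# so that the convolutional and brute-force observers agree exactly.
rowMajorArgmax <- function(x) {
  k <- which.max(t(x))
  c((k - 1L) %/% ncol(x) + 1L, (k - 1L) %% ncol(x) + 1L)
}

# Search region bounds: the central half-side square (rows and columns
# n/4+1 .. 3n/4), one quarter of the image area.
searchRegionBounds <- function(n) {
  if (n < 8L) stop("image side must be at least 8 pixels")
  c(lo = n / 4 + 1, hi = 3 * n / 4)
}

searchRegionMask <- function(n) {
  b <- searchRegionBounds(n)
  m <- matrix(FALSE, n, n)
  m[b["lo"]:b["hi"], b["lo"]:b["hi"]] <- TRUE
  m
}

# Derived seeds for trial loops; kept inside 32-bit integer range.
deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i)) %% 2147483647)
}
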