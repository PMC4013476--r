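# Per-session memoization of deterministic, frequently rebuilt objects
# (spectra, disk-kernel FFTs, search masks).  Keys are parameter strings;
# values are pure functions of the key, so caching cannot change results.

.iolocCache <- new.env(parent = emptyenv())

cached <- function(key, compute) {
  if (!exists(key, envir = .iolocCache, inherits = FALSE))
    assign(key, compute(), envir = .iolocCache)
  get(key, envir = .iolocCache, inherits = FALSE)
}

cachedSpectrum <- function(spec) {
  key <- sprintf("spec|%g|%g|%g|%d", spec@beta, spec@rmsContrast,
                 spec@meanLevel, spec@shape)
  cached(key, function() buildSpectrum(spec))
}

cachedDiskF <- function(n, radius) {
  cached(sprintf("diskF|%d|%g", n, radius),
         function() fft2(diskKernelOrigin(n, radius)))
}

cachedMask <- function(n) {
  cached(sprintf("mask|%d", n), function() searchRegionMask(n))
}

cachedTargetOrigin <- function(spec, n) {
  key <- sprintf("target|%g|%s|%d", spec@sigmaPixels, spec@profileKind, n)
  cached(key, function() targetProfileOrigin(spec, n))
}
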