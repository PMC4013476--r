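# Shared fixtures for the test suite.  Everything is generated in code; the
# only frozen numbers are *inputs*: approximate 80%-correct operating
# contrasts for the reduced simulation geometries the tests run at,
# determined once by coarse LUT inversion at those geometries.

# free-localization operating contrasts, 128 px images (64 px search region)
locThreshold128 <- c("0" = 0.137, "1" = 0.337, "2" = 0.481, "3" = 0.288)

# convenience constructors for small test conditions
testNoise <- function(beta = 1, shape = 64L) noiseSpec(beta = beta, shape = shape)

testSpectrum <- function(beta = 1, shape = 64L) buildSpectrum(testNoise(beta, shape))

testTemplate <- function(beta = 1, shape = 64L)
  buildTemplate(targetSpec(), testSpectrum(beta, shape))

# radially averaged mean periodogram of a list of fields (cycles/pixel bins)
meanPeriodogramProfile <- function(fields) {
  n <- nrow(fields[[1]])
  acc <- matrix(0, n, n)
  for (f in fields) acc <- acc + Mod(stats::fft(f))^2 / (n * n)
  acc <- acc / length(fields)
  f <- ioloc:::radialFreqGrid(n)
  bin <- round(f * n)
  keep <- bin >= 1 & bin <= n / 4          # mid frequencies, drop DC + top octave
  data.frame(freq = tapply(f[keep], bin[keep], mean),
             power = tapply(acc[keep], bin[keep], mean))
}

# log-log slope of a periodogram profile
periodogramSlope <- function(prof) {
  unname(stats::coef(stats::lm(log(power) ~ log(freq), data = prof))[2])
}
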