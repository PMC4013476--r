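test_that("whitening is linear, trivial for white noise, and inverts the spectrum", {
  sp0 <- testSpectrum(0, 32L)
  f <- sampleNoise(sp0, seed = 3)
  q <- whitenNoise(f, sp0)
  # white covariance: q is the field up to one constant
  expect_lt(diff(range(q / f)), 1e-9)

  sp2 <- testSpectrum(2, 32L)
  a <- sampleNoise(sp2, seed = 4)
  b <- sampleNoise(sp2, seed = 5)
  expect_equal(whitenNoise(a + b, sp2), whitenNoise(a, sp2) + whitenNoise(b, sp2),
               tolerance = 1e-9)

  # the average periodogram of whitened fields is proportional to 1/S
  qs <- lapply(1:300, function(i) whitenNoise(sampleNoise(sp2, 900 + i), sp2))
  n <- 32L
  acc <- Reduce(`+`, lapply(qs, function(x) Mod(stats::fft(x))^2 / n^2)) / 300
  ratio <- acc * spectrumValues(sp2)        # should be flat
  mid <- ioloc:::radialFreqGrid(n) > 0.1 & ioloc:::radialFreqGrid(n) < 0.4
  expect_lt(stats::sd(ratio[mid]) / mean(ratio[mid]), 0.15)

  expect_error(whitenNoise(matrix(0, 16, 16), sp2), "shapes")
})

test_that("the detection classification image recovers a known linear template", {
  shape <- 64L
  nz <- testNoise(2, shape)
  sp <- testSpectrum(2, shape)
  tm <- distortTemplate(buildTemplate(targetSpec(), sp), "lowfreqSuppressed",
                        0.04)
  mod <- observerModel(tm, internalNoiseSd = 0.5, templateKind = "test")
  k <- analyticDprime(targetSpec(), sp)
  cObs <- 1.7 / (k * sqrt(linearObserverEfficiency(mod, targetSpec(), sp)))
  mod@criterion <- observerUnbiasedCriterion(
    mod, targetSpec(contrast = cObs), sp)

  smoothTpl <- butterworthSmooth(
    new("ClassImage",
        weights = ioloc:::circShift(spatialWeights(tm), shape / 2, shape / 2),
        task = "detection", beta = 2, nTrialsUsed = 0L))
  ctr <- shape / 2 + 1
  crop <- (ctr - 20):(ctr + 19)
  corWithTemplate <- function(n, seed) {
    rec <- runExperiment("detection", mod, nz, contrasts = cObs,
                         nPerLevel = n, seed = seed, keepNoise = TRUE)
    ci <- butterworthSmooth(detectionCI(rec, attr(rec, "noiseFields"), sp))
    stats::cor(c(ci@weights[crop, crop]), c(smoothTpl@weights[crop, crop]))
  }
  r500 <- corWithTemplate(500, 17)
  r2000 <- corWithTemplate(2000, 17)
  # convergence toward the template with trial count, and a clear
  # correlation at n = 2000 (bar set by simulation at these parameters)
  expect_gt(r2000, r500)
  expect_gt(r2000, 0.25)

  # label randomization kills the expectation
  rec <- runExperiment("detection", mod, nz, contrasts = cObs,
                       nPerLevel = 400, seed = 23, keepNoise = TRUE)
  set.seed(1)
  shuf <- rec
  shuf$detected <- sample(shuf$detected)
  ciS <- detectionCI(shuf, attr(rec, "noiseFields"), sp)
  ciT <- detectionCI(rec, attr(rec, "noiseFields"), sp)
  expect_lt(stats::cor(c(butterworthSmooth(ciS)@weights[crop, crop]),
                       c(smoothTpl@weights[crop, crop])), 0.25)
  expect_gt(abs(stats::cor(c(butterworthSmooth(ciT)@weights[crop, crop]),
                           c(smoothTpl@weights[crop, crop]))), 0.1)

  # an empty outcome class is an error that reports the counts
  recBad <- rec
  recBad$detected <- TRUE
  expect_error(detectionCI(recBad, attr(rec, "noiseFields"), sp), "TN=0")
})

test_that("the response-aligned localization estimator behaves as false-localization reverse correlation", {
  shape <- 64L
  nz <- testNoise(1, shape)
  sp <- testSpectrum(1, shape)

  # uniformly random responses average to (near) zero
  set.seed(6)
  nT <- 150
  recs <- data.frame(correct = rep(FALSE, nT),
                     response_x = sample(16:47, nT, TRUE),
                     response_y = sample(16:47, nT, TRUE))
  fields <- lapply(1:nT, function(i) sampleNoise(sp, 40000 + i))
  ci <- localizationCI(recs, fields, sp)
  # compare against the per-pixel sd of a single aligned whitened field
  sd1 <- stats::sd(c(whitenNoise(fields[[1]], sp)))
  expect_lt(max(abs(ci@weights)), 6 * sd1 / sqrt(nT))

  expect_error(localizationCI(recs[0, ], list(), sp), "incorrect")
  recs$correct <- TRUE
  expect_error(localizationCI(recs, fields, sp), "incorrect")

  # a peak-shifted template is recovered with its shifted peak
  tm <- distortTemplate(buildTemplate(targetSpec(), sp), "peakShifted", 1.5)
  mod <- observerModel(tm, templateKind = "shifted")
  rec <- runExperiment("localization", mod, nz, contrasts = 0.22,
                       nPerLevel = 1200, seed = 29, keepNoise = TRUE)
  ciL <- localizationCI(rec, attr(rec, "noiseFields"), sp)
  prof <- radialProfile(ciL)
  tplCI <- new("ClassImage",
               weights = ioloc:::circShift(spatialWeights(tm),
                                           shape / 2, shape / 2),
               task = "localization", beta = 1, nTrialsUsed = 0L)
  profT <- radialProfile(tplCI)
  pkEst <- freqBins(prof)[which.max(profileWeights(prof))]
  pkTrue <- freqBins(profT)[which.max(profileWeights(profT))]
  binW <- diff(freqBins(profT))[1]
  expect_lt(abs(pkEst - pkTrue), 1.5 * binW + 1e-9)
})

test_that("Butterworth smoothing has unit DC gain and half power at the cutoff", {
  n <- 64L
  asCI <- function(w) new("ClassImage", weights = w, task = "detection",
                          beta = 0, nTrialsUsed = 0L)
  flat <- butterworthSmooth(asCI(matrix(2.5, n, n)))
  expect_equal(flat@weights, matrix(2.5, n, n), tolerance = 1e-9)

  # radial gain at the cutoff frequency is 1/sqrt(2): probe with a cosine
  fc <- 5.6 * pixelAngle()                  # cutoff in cycles/pixel
  kc <- round(fc * n)
  cosmat <- cos(2 * pi * kc * (0:(n - 1)) / n)
  ciC <- butterworthSmooth(asCI(matrix(cosmat, n, n, byrow = TRUE)))
  gainObs <- max(ciC@weights) / 1
  gainExp <- 1 / sqrt(1 + ((kc / n) / fc)^8)
  expect_equal(gainObs, gainExp, tolerance = 1e-6)
  expect_lt(abs(gainExp - 1 / sqrt(2)), 0.03)   # kc/n is fc up to rounding
  # the default cutoff corresponds to 0.29 cyc/pixel
  expect_lt(abs(fc - 0.29), 0.005)
})

test_that("radial profiles localize pure tones and normalize to unit peak", {
  n <- 64L
  f0 <- 8 / n
  r <- sqrt(outer((seq_len(n) - 33)^2, (seq_len(n) - 33)^2, "+"))
  tone <- cos(2 * pi * f0 * r) * exp(-r^2 / (2 * 15^2))
  prof <- radialProfile(new("ClassImage", weights = tone, task = "detection",
                            beta = 0, nTrialsUsed = 0L))
  expect_identical(max(profileWeights(prof)), 1)
  pk <- freqBins(prof)[which.max(profileWeights(prof))]
  expect_lt(abs(pk - f0 / pixelAngle()), 1.5 * diff(freqBins(prof))[1])
  expect_error(radialProfile(new("ClassImage", weights = matrix(0, n, n),
                                 task = "detection", beta = 0,
                                 nTrialsUsed = 0L)), "zero")
})

test_that("analytic ideal-observer weights peak at sqrt(beta)/(2 pi sigma)", {
  # white noise: low-pass, monotone non-increasing profile peaking at 0
  p0 <- ioFrequencyWeights(0, 3, pixelAngle(), 128L)
  expect_identical(freqBins(p0)[which.max(profileWeights(p0))],
                   min(freqBins(p0)))
  expect_true(all(diff(profileWeights(p0)) <= 1e-9))

  # the closed-form peak matches a dense numerical argmax
  for (b in c(1, 2, 3)) {
    sigmaDeg <- 3 * pixelAngle()
    fGrid <- seq(1e-4, 4, by = 1e-4)
    wt <- fGrid^b * exp(-2 * pi^2 * sigmaDeg^2 * fGrid^2)
    expect_equal(ioPeakFrequency(b, sigmaDeg), fGrid[which.max(wt)],
                 tolerance = 1e-3)
  }

  # peak migration from 0 to about 1.7 cyc/deg across the noise conditions
  peaks <- vapply(0:3, function(b) {
    p <- ioFrequencyWeights(b, 3, pixelAngle(), 256L)
    freqBins(p)[which.max(profileWeights(p))]
  }, numeric(1))
  expect_identical(peaks[1], 0)
  expect_true(all(diff(peaks) > 0))
  expect_lt(abs(peaks[4] - 1.7) / 1.7, 0.05)
})
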