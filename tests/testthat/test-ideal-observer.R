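test_that("the template is the matched filter in white noise and prewhitens otherwise", {
  # beta = 0: spatial weights proportional to the target itself
  tm0 <- testTemplate(beta = 0)
  s0 <- ioloc:::targetOrigin(64L, 3)
  ratio <- spatialWeights(tm0)[s0 > 1e-4] / s0[s0 > 1e-4]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)

  # beta = 2: frequency-weight magnitude follows f^2 exp(-2 pi^2 sigma^2 f^2)
  tm2 <- testTemplate(beta = 2)
  f <- ioloc:::radialFreqGrid(64L)
  pick <- which(f > 0.05 & f < 0.2)
  expect_fw <- f[pick]^2 * exp(-2 * pi^2 * 9 * f[pick]^2)
  got <- Mod(freqWeights(tm2))[pick]
  expect_lt(stats::sd(got / expect_fw) / mean(got / expect_fw), 0.02)

  # positive-definite whitening: the template always correlates with the target
  for (b in 0:3) {
    tm <- testTemplate(beta = b, shape = 32L)
    expect_gt(sum(spatialWeights(tm) * ioloc:::targetOrigin(32L, 3)), 0)
  }
  # zero spectrum values are refused
  spBad <- testSpectrum(0, 32L)
  spBad@values[3, 3] <- 0
  expect_error(buildTemplate(targetSpec(), spBad), "zero")
})

test_that("detection statistic behaves and Monte-Carlo PC matches pnorm(d'/2)", {
  nz <- testNoise(1); sp <- testSpectrum(1); tm <- testTemplate(1)
  st <- makeTrial("detection", nz, targetSpec(contrast = 0.1), seed = 2)
  expect_true(detected(detectTarget(st, tm, -Inf)))

  # no signal, criterion at zero: PC converges to 1/2
  pc0 <- mean(vapply(1:300, function(i) {
    s <- makeTrial("detection", nz, targetSpec(contrast = 0), seed = 100 + i)
    detected(detectTarget(s, tm, 0)) == truthPresent(s)
  }, logical(1)))
  expect_lt(abs(pc0 - 0.5), 3 * sqrt(0.25 / 300))

  # closed form at the unbiased criterion, one beta (the acceptance suite
  # covers all four): d' from the frequency-domain sum
  k <- analyticDprime(targetSpec(), sp)
  contrast <- 1.7 / k
  tc <- unbiasedCriterion(targetSpec(), sp, contrast)
  n <- 800
  pc <- mean(vapply(1:n, function(i) {
    s <- makeTrial("detection", nz, targetSpec(contrast = contrast),
                   seed = 4000 + i)
    detected(detectTarget(s, tm, tc)) == truthPresent(s)
  }, logical(1)))
  expected <- stats::pnorm(contrast * k / 2)
  expect_lt(abs(pc - expected), 3 * sqrt(expected * (1 - expected) / n))

  # white-noise matched-filter identity, evaluated by direct pixel sums
  sp0 <- testSpectrum(0)
  direct <- 100 * sqrt(sum(ioloc:::targetOrigin(64L, 3)^2)) / 20
  expect_equal(analyticDprime(targetSpec(), sp0), direct, tolerance = 1e-9)
})

test_that("localization score maps satisfy their probability invariants", {
  # the acceptance disk holds exactly the 81 offsets with norm <= 5
  off <- ioloc:::diskOffsets(5)
  expect_identical(nrow(off), 81L)
  expect_true(all(off$dr^2 + off$dc^2 <= 25))
  expect_identical(sum(ioloc:::diskKernelOrigin(64L, 5)), 81)

  nz <- testNoise(1)
  tm <- testTemplate(1)
  st <- makeTrial("localization", nz, targetSpec(contrast = 0.3), seed = 8)
  sc <- localizationScore(st, tm)
  expect_lt(abs(sum(posterior(sc)) - 1), 1e-9)
  expect_true(all(posterior(sc)[!searchMask(sc)] == 0))
  expect_true(all(diskScore(sc) >= 0))
  expect_lt(max(diskScore(sc)), 1 + 1e-9)

  # a dominant target maximizes the disk score at the true location (the
  # whole acceptance disk ties at score 1, so the response lies within it)
  stBig <- makeTrial("localization", nz, targetSpec(contrast = 3), seed = 9)
  scBig <- localizationScore(stBig, tm)
  tl <- truthLocation(stBig)
  expect_equal(diskScore(scBig)[tl[1], tl[2]], max(diskScore(scBig)),
               tolerance = 1e-9)
  d <- localize(scBig)
  expect_lte(sum((responseLocation(d) - tl)^2), 25)

  stBad <- stBig
  stBad@pixels[1, 1] <- NaN
  expect_error(localizationScore(stBad, tm), "finite")
})

test_that("the response maximizes the disk score with row-major tie-breaking", {
  n <- 32L
  mask <- ioloc:::searchRegionMask(n)
  p <- matrix(0, n, n)
  p[mask] <- 1 / sum(mask)
  ds <- matrix(0, n, n)
  ds[12, 20] <- ds[20, 12] <- ds[12, 12] <- 0.5   # three-way tie
  sm <- new("ScoreMap", posterior = p, diskScore = ds, searchMask = mask,
            radiusPx = 5)
  expect_identical(responseLocation(localize(sm)), c(12L, 12L))
  # responses always fall inside the search region
  for (i in 1:20) {
    st <- makeTrial("localization", testNoise(2, 32L),
                    targetSpec(contrast = 0.2), seed = 300 + i)
    loc <- responseLocation(localize(localizationScore(st,
                    testTemplate(2, 32L))))
    expect_true(all(loc >= 9 & loc <= 24))
  }
})

test_that("the convolutional localizer equals the brute-force oracle", {
  # small version of the full acceptance check: random conditions,
  # exact location agreement required on every instance
  for (i in 1:150) {
    b <- (i %% 4)
    contrast <- c(0.1, 0.3, 0.6)[1 + (i %% 3)]
    nz <- testNoise(b, 32L)
    st <- makeTrial("localization", nz, targetSpec(contrast = contrast),
                    seed = 7000 + i)
    sp <- testSpectrum(b, 32L)
    conv <- responseLocation(localize(localizationScore(st,
              buildTemplate(targetSpec(), sp), radiusPx = 2)))
    oracle <- bruteForceLocalize(st, targetSpec(contrast = contrast), sp,
                                 radiusPx = 2)
    expect_identical(conv, oracle)
  }
  expect_error(bruteForceLocalize(
    makeTrial("localization", testNoise(1, 128L), targetSpec(), seed = 1),
    targetSpec(), testSpectrum(1, 128L)), "64")
  # radius 0 reduces to the MAP location
  st <- makeTrial("localization", testNoise(1, 32L),
                  targetSpec(contrast = 0.4), seed = 12)
  sp <- testSpectrum(1, 32L)
  sc <- localizationScore(st, buildTemplate(targetSpec(), sp), radiusPx = 0)
  mp <- posterior(sc)
  mp[!searchMask(sc)] <- -Inf
  expect_identical(responseLocation(localize(sc)),
                   as.integer(ioloc:::rowMajorArgmax(mp)))
})

test_that("detect-and-localize thresholds trace a monotone trade-off", {
  nz <- testNoise(1, 32L)
  tm <- testTemplate(1, 32L)
  scores <- numeric(200)
  present <- logical(200)
  correct <- logical(200)
  for (i in 1:200) {
    st <- makeTrial("dandl", nz, targetSpec(contrast = 0.25), seed = 600 + i)
    d <- localize(localizationScore(st, tm))
    scores[i] <- decisionStatistic(d)
    present[i] <- truthPresent(st)
    correct[i] <- present[i] &&
      sum((responseLocation(d) - truthLocation(st))^2) <= 25
  }
  # threshold 0 never yields "absent", threshold 1 always does
  expect_true(all(scores > 0))
  st1 <- makeTrial("dandl", nz, targetSpec(contrast = 0.25), seed = 99)
  sc1 <- localizationScore(st1, tm)
  expect_true(detected(detectAndLocalize(sc1, 0)))
  expect_false(detected(detectAndLocalize(sc1, 1)))
  expect_length(responseLocation(detectAndLocalize(sc1, 1)), 0)

  thr <- seq(0, 1, by = 0.05)
  cdl <- vapply(thr, function(t) mean(correct & scores > t), numeric(1))
  fp <- vapply(thr, function(t) mean(!present & scores > t) /
                 max(mean(!present), 1e-9), numeric(1))
  expect_true(all(diff(cdl) <= 0))
  expect_true(all(diff(fp) <= 0))
})

test_that("localization PC rises with contrast and varies smoothly with radius", {
  lut <- simulateLUT("localization", 1, nPerPoint = 400L, seed = 31,
                     shape = 64L, contrasts = seq(0.1, 0.5, by = 0.1))
  pc <- proportionCorrect(lut)
  # statistically non-decreasing: no decrease beyond 2 pooled s.e.
  se2 <- 2 * sqrt(0.5 / 400)
  expect_true(all(diff(pc) > -se2))
  expect_gt(pc[5], pc[1] + 0.2)

  pcByRadius <- vapply(4:7, function(r) {
    ok <- vapply(1:300, function(i) {
      st <- makeTrial("localization", testNoise(1), targetSpec(contrast = 0.27),
                      seed = 80000 + i)
      d <- localize(localizationScore(st, testTemplate(1), radiusPx = r))
      sum((responseLocation(d) - truthLocation(st))^2) <= r^2
    }, logical(1))
    mean(ok)
  }, numeric(1))
  # same trials, growing acceptance disk: PC non-decreasing and smooth
  expect_true(all(diff(pcByRadius) >= -2 * sqrt(0.25 / 300)))
  expect_lt(max(abs(diff(pcByRadius))), 0.15)
})
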