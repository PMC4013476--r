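test_that("a noiseless ideal-template model reproduces the ideal observer", {
  nz <- testNoise(1, 32L)
  sp <- testSpectrum(1, 32L)
  tm <- testTemplate(1, 32L)
  mod <- observerModel(tm, diskIntegration = TRUE)
  tc <- unbiasedCriterion(targetSpec(), sp, 0.3)
  modD <- observerModel(tm, criterion = tc)
  for (i in 1:25) {
    stD <- makeTrial("detection", nz, targetSpec(contrast = 0.3),
                     seed = 1500 + i)
    io <- detectTarget(stD, tm, tc)
    rec <- respondDetection(stD, modD, sp, seed = i)
    expect_identical(rec$detected, detected(io))
    expect_equal(rec$statistic, decisionStatistic(io), tolerance = 1e-9)

    stL <- makeTrial("localization", nz, targetSpec(contrast = 0.3),
                     seed = 2500 + i)
    ioL <- localize(localizationScore(stL, tm))
    recL <- respondLocalization(stL, mod, sp, seed = i)
    expect_identical(c(recL$response_y + 1L, recL$response_x + 1L),
                     responseLocation(ioL))
  }
})

test_that("overwhelming internal or motor noise drives performance to chance", {
  nz <- testNoise(1, 32L)
  sp <- testSpectrum(1, 32L)
  tm <- testTemplate(1, 32L)
  tg <- targetSpec(contrast = 0.4)
  modNoisy <- observerModel(tm, internalNoiseSd = 200)
  modNoisy@criterion <- observerUnbiasedCriterion(modNoisy, tg, sp)
  pc <- mean(vapply(1:400, function(i) {
    st <- makeTrial("detection", nz, tg, seed = 6000 + i)
    respondDetection(st, modNoisy, sp, seed = i)$correct
  }, logical(1)))
  expect_lt(abs(pc - 0.5), 3 * sqrt(0.25 / 400) + 0.01)

  modJitter <- observerModel(tm, motorJitterSd = 40)
  pcj <- mean(vapply(1:150, function(i) {
    st <- makeTrial("localization", nz, tg, seed = 6600 + i)
    respondLocalization(st, modJitter, sp, seed = i)$correct
  }, logical(1)))
  expect_lt(pcj, 0.35)        # chance on the 16x16 region is 81/256
})

test_that("a zero-suboptimality localizer performs at the ideal LUT level", {
  contrast <- 0.27
  lut <- simulateLUT("localization", 1, nPerPoint = 500L, seed = 71,
                     shape = 64L, contrasts = contrast)
  pcIO <- proportionCorrect(lut)
  nz <- testNoise(1)
  sp <- testSpectrum(1)
  mod <- observerModel(testTemplate(1))      # raw-map argmax, no disk step
  pcModel <- mean(vapply(1:500, function(i) {
    st <- makeTrial("localization", nz, targetSpec(contrast = contrast),
                    seed = 42000 + i)
    respondLocalization(st, mod, sp, seed = i)$correct
  }, logical(1)))
  # omitting the disk integration costs less than the Monte-Carlo
  # resolution at these parameters
  expect_lt(abs(pcModel - pcIO), 2 * sqrt(2 * 0.2 * 0.8 / 500))
})

test_that("criterion jitter degrades detection and criteria order false positives", {
  nz <- testNoise(1, 32L)
  sp <- testSpectrum(1, 32L)
  tm <- testTemplate(1, 32L)
  tg <- targetSpec(contrast = 0.35)
  crit <- observerUnbiasedCriterion(observerModel(tm), tg, sp)
  n <- 700
  pcFor <- function(jit) {
    mod <- observerModel(tm, criterion = crit, criterionJitterSd = jit)
    mean(vapply(1:n, function(i) {
      st <- makeTrial("detection", nz, tg, seed = 7000 + i)  # paired stimuli
      respondDetection(st, mod, sp, seed = 90000 + i)$correct
    }, logical(1)))
  }
  expect_gt(pcFor(0) - pcFor(1.5), 2 * sqrt(0.5 / n))

  # false-positive rate is monotone decreasing in the criterion
  stats0 <- vapply(1:200, function(i) {
    st <- makeTrial("dandl", nz, targetSpec(contrast = 0), seed = 7900 + i)
    respondDandl(st, observerModel(tm, criterion = -Inf), sp,
                 seed = i)$statistic
  }, numeric(1))
  fp <- vapply(stats::quantile(stats0, c(0.2, 0.5, 0.8)),
               function(q) mean(stats0 > q), numeric(1))
  expect_true(all(diff(fp) < 0))
})

test_that("a criterion of -Inf reduces detect-and-localize to localization", {
  nz <- testNoise(1, 32L)
  sp <- testSpectrum(1, 32L)
  mod <- observerModel(testTemplate(1, 32L), criterion = -Inf)
  for (i in 1:15) {
    st <- makeTrial("localization", nz, targetSpec(contrast = 0.3),
                    seed = 8200 + i)
    a <- respondDandl(st, mod, sp, seed = 500 + i)
    b <- respondLocalization(st, mod, sp, seed = 500 + i)
    expect_true(a$detected)
    expect_identical(c(a$response_x, a$response_y),
                     c(b$response_x, b$response_y))
  }
})

test_that("measured detection efficiency matches the closed-form oracle", {
  shape <- 64L
  nz <- testNoise(2, shape)
  sp <- testSpectrum(2, shape)
  tm <- distortTemplate(buildTemplate(targetSpec(), sp), "lowfreqSuppressed",
                        0.05)
  mod <- observerModel(tm, internalNoiseSd = 0.5)
  etaStar <- linearObserverEfficiency(mod, targetSpec(), sp)
  k <- analyticDprime(targetSpec(), sp)
  cObs <- 1.7 / (k * sqrt(etaStar))
  mod@criterion <- observerUnbiasedCriterion(
    mod, targetSpec(contrast = cObs), sp)
  rec <- runExperiment("detection", mod, nz, contrasts = cObs,
                       nPerLevel = 1500L, seed = 131)
  hit <- mean(rec$detected[rec$present])
  fa <- mean(rec$detected[!rec$present])
  eff <- efficiencyDetection(hit, fa, cObs, targetSpec(), sp)
  nP <- sum(rec$present); nA <- sum(!rec$present)
  seD <- sqrt(hit * (1 - hit) / (nP * stats::dnorm(stats::qnorm(hit))^2) +
              fa * (1 - fa) / (nA * stats::dnorm(stats::qnorm(fa))^2))
  seEta <- efficiency(eff) * 2 * seD / (stats::qnorm(hit) - stats::qnorm(fa))
  expect_lt(abs(efficiency(eff) - etaStar), 3 * seEta)
})

test_that("localization efficiency falls monotonically with template distortion", {
  contrast <- 0.27
  lut <- simulateLUT("localization", 1, nPerPoint = 800L, seed = 77,
                     shape = 64L, contrasts = seq(0.08, 0.44, by = 0.03))
  nz <- testNoise(1)
  sp <- testSpectrum(1)
  tmIO <- testTemplate(1)
  etas <- vapply(c(0.03, 0.06, 0.12), function(a) {
    tm <- distortTemplate(tmIO, "lowfreqSuppressed", a)
    mod <- observerModel(tm, templateKind = sprintf("lfs%.2f", a))
    pc <- mean(vapply(1:500, function(i) {
      st <- makeTrial("localization", nz, targetSpec(contrast = contrast),
                      seed = 50000 + i)          # common stimuli across models
      respondLocalization(st, mod, sp, seed = 70000 + i)$correct
    }, logical(1)))
    efficiency(efficiencyLocalization(contrast, pc, lut))
  }, numeric(1))
  expect_true(all(diff(etas) < 0))
  expect_lt(etas[1], 1.05)
  expect_lt(etas[3], 0.75)
})

test_that("experiments have the designed structure and are reproducible", {
  nz <- testNoise(0, 32L)
  mod <- observerModel(testTemplate(0, 32L))
  rec <- runExperiment("localization", mod, nz,
                       contrasts = c(0.1, 0.2), nPerLevel = 60L,
                       blockSize = 20L, seed = 5)
  expect_identical(nrow(rec), 120L)
  expect_identical(as.integer(table(rec$contrast)), c(60L, 60L))
  expect_identical(sort(unique(rec$session)), 1:3)
  expect_identical(rec$trial_id, 1:120)
  rec2 <- runExperiment("localization", mod, nz,
                        contrasts = c(0.1, 0.2), nPerLevel = 60L,
                        blockSize = 20L, seed = 5)
  expect_identical(rec, rec2)

  # analytic ordering for a fixed beta=2-tuned template across conditions:
  # efficiency is highest in its own condition and lowest in white noise
  tm2 <- buildTemplate(targetSpec(), testSpectrum(2, 64L))
  et <- vapply(0:3, function(b)
    linearObserverEfficiency(observerModel(tm2), targetSpec(),
                             testSpectrum(b, 64L)), numeric(1))
  expect_identical(which.max(et), 3L)       # beta = 2
  expect_identical(which.min(et), 1L)       # beta = 0
})
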