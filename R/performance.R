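# Monte-Carlo performance machinery: contrast/PC look-up tables, LUT
# inversion, psychometric fitting, criterion matching and efficiency.

# Internal engine for localization-type simulations.  For a fixed seed it
# precomputes, per trial, the whitened-template correlation with the noise
# alone (cropped to the search region) together with the truth draws; the
# score map at any contrast then follows from the identity
#   corr(w, noise + a s_l0) = corr(w, noise) + a * shift(corr(w, s), l0),
# so a whole contrast grid reuses one set of noise fields (common random
# numbers).  The acceptance-disk convolution runs on the zero-padded
# region crop, which is exact because the posterior vanishes outside the
# search region and the pad exceeds the disk radius.
locEngine <- function(task, beta, nPerPoint, seed, shape = 256L,
                      sigmaPixels = 3, rmsContrast = 0.2, meanLevel = 100,
                      radiusPx = 5, profileKind = "gaussian") {
  n <- as.integer(shape)
  spec <- noiseSpec(beta = beta, rmsContrast = rmsContrast,
                    meanLevel = meanLevel, shape = n)
  sp <- buildSpectrum(spec)
  tg <- targetSpec(sigmaPixels = sigmaPixels, profileKind = profileKind)
  s0 <- targetProfileOrigin(tg, n)
  fw <- fft2(s0) / sp@values
  ac <- Re(ifft2(Conj(fw) * fft2(s0)))    # template/target correlation map
  b <- searchRegionBounds(n)
  idx <- b["lo"]:b["hi"]
  m <- length(idx)
  pad <- as.integer(ceiling(radiusPx))
  P <- stats::nextn(m + 2L * pad, c(2L, 3L, 5L))
  diskF <- fft2(diskKernelOrigin(P, radiusPx))
  sqrtS <- sqrt(sp@values)

  present <- logical(nPerPoint)
  truth <- matrix(NA_integer_, nPerPoint, 2)
  ccNoise <- vector("list", nPerPoint)
  for (i in seq_len(nPerPoint)) {
    set.seed(deriveSeed(seed, i))
    present[i] <- if (task == "dandl") stats::runif(1) < 0.5 else TRUE
    if (present[i])
      truth[i, ] <- as.integer(sample(idx, 2, replace = TRUE))
    w <- matrix(stats::rnorm(n * n), n, n)
    ccNoise[[i]] <- Re(ifft2(Conj(fw) * (fft2(w) * sqrtS)))[idx, idx]
  }

  pmat <- matrix(0, P, P)
  inner <- (pad + 1L):(pad + m)

  # Evaluate every trial at one contrast; returns max disk score, whether
  # the argmax lies within the acceptance radius of truth, and presence.
  evalContrast <- function(contrast) {
    a <- contrast * meanLevel
    maxScore <- numeric(nPerPoint)
    locCorrect <- logical(nPerPoint)
    for (i in seq_len(nPerPoint)) {
      e <- a * ccNoise[[i]]
      if (present[i] && a > 0) {
        acS <- circShift(ac, truth[i, 1] - 1L, truth[i, 2] - 1L)[idx, idx]
        e <- e + a * a * acS
      }
      e <- exp(e - max(e))
      pmat[inner, inner] <- e / sum(e)
      ds <- Re(ifft2(fft2(pmat) * diskF))[inner, inner]
      loc <- rowMajorArgmax(ds)
      maxScore[i] <- ds[loc[1], loc[2]]
      if (present[i]) {
        dr <- loc[1] + pad - (truth[i, 1] - b["lo"] + 1L + pad)
        dc <- loc[2] + pad - (truth[i, 2] - b["lo"] + 1L + pad)
        locCorrect[i] <- (dr^2 + dc^2) <= radiusPx^2
      }
    }
    list(maxScore = maxScore, locCorrect = locCorrect, present = present)
  }

  list(evalContrast = evalContrast, nPerPoint = nPerPoint,
       templateEnergy = mean(Mod(fft2(s0))^2 / sp@values))
}

# Detection counterpart: per trial only the center statistic is needed,
# and the signal adds a deterministic offset, so one noise statistic per
# trial serves the whole contrast grid.
detEngine <- function(beta, nPerPoint, seed, shape = 256L, sigmaPixels = 3,
                      rmsContrast = 0.2, meanLevel = 100,
                      profileKind = "gaussian") {
  n <- as.integer(shape)
  sp <- buildSpectrum(noiseSpec(beta = beta, rmsContrast = rmsContrast,
                                meanLevel = meanLevel, shape = n))
  tg <- targetSpec(sigmaPixels = sigmaPixels, profileKind = profileKind)
  s0 <- targetProfileOrigin(tg, n)
  fw <- fft2(s0) / sp@values
  V <- mean(Mod(fft2(s0))^2 / sp@values)
  sqrtS <- sqrt(sp@values)
  c0 <- n / 2 + 1
  present <- logical(nPerPoint)
  wn <- numeric(nPerPoint)
  for (i in seq_len(nPerPoint)) {
    set.seed(deriveSeed(seed, i))
    present[i] <- stats::runif(1) < 0.5
    w <- matrix(stats::rnorm(n * n), n, n)
    wn[i] <- Re(ifft2(Conj(fw) * (fft2(w) * sqrtS)))[c0, c0]
  }
  evalContrast <- function(contrast) {
    a <- contrast * meanLevel
    stat <- wn + ifelse(present, a * V, 0)
    crit <- a * V / 2                       # unbiased midpoint criterion
    mean(ifelse(present, stat > crit, stat <= crit))
  }
  list(evalContrast = evalContrast, templateEnergy = V)
}

#' Simulate an ideal-observer contrast / PC look-up table
#'
#' Runs the task's ideal observer on freshly sampled stimuli over a grid of
#' contrasts (step 0.01 from 0 by default) and records the proportion of
#' correct responses, stopping once PC exceeds `stopPC`.  A localization
#' response is correct iff it falls within the acceptance radius of the
#' true location; a detect-and-localize response additionally requires the
#' correct presence call at the supplied score threshold; a detection
#' response uses the unbiased midpoint criterion.  The same noise fields
#' are reused across the contrast grid (common random numbers), which
#' leaves each point's PC unbiased while making the grid sweep cheap and
#' the threshold estimate smooth in contrast.
#'
#' @param task `"localization"`, `"dandl"` or `"detection"`.
#' @param beta background power-law exponent.
#' @param nPerPoint trials per contrast point (2000 by default, giving
#'   binomial standard errors below 1\% near PC = 0.8).
#' @param step contrast increment of the grid.
#' @param stopPC the grid extends until PC exceeds this value.
#' @param seed integer seed.
#' @param shape image side length in pixels.
#' @param sigmaPixels,rmsContrast,meanLevel stimulus parameters.
#' @param radiusPx acceptance radius (localization tasks).
#' @param profileKind target profile kind.
#' @param dlThreshold disk-score detection threshold (required for
#'   `task = "dandl"`).
#' @param contrasts optional explicit contrast grid overriding the
#'   step/stop rule (used for narrowed re-runs around an operating point).
#' @param maxContrast error guard: the grid must reach `stopPC` by here.
#' @return A [ContrastLUT-class].
#' @export
simulateLUT <- function(task = c("localization", "dandl", "detection"),
                        beta, nPerPoint = 2000L, step = 0.01,
                        stopPC = 0.94, seed = 1L, shape = 256L,
                        sigmaPixels = 3, rmsContrast = 0.2, meanLevel = 100,
                        radiusPx = 5, profileKind = "gaussian",
                        dlThreshold = NULL, contrasts = NULL,
                        maxContrast = 2) {
  task <- match.arg(task)
  nPerPoint <- as.integer(nPerPoint)
  if (task == "dandl" && is.null(dlThreshold))
    stop("task 'dandl' needs a dlThreshold on the disk score")
  if (task == "detection") {
    eng <- detEngine(beta, nPerPoint, seed, shape, sigmaPixels,
                     rmsContrast, meanLevel, profileKind)
    pcAt <- eng$evalContrast
  } else {
    eng <- locEngine(task, beta, nPerPoint, seed, shape, sigmaPixels,
                     rmsContrast, meanLevel, radiusPx, profileKind)
    pcAt <- function(contrast) {
      ev <- eng$evalContrast(contrast)
      if (task == "localization") mean(ev$locCorrect)
      else mean(ifelse(ev$present,
                       ev$maxScore > dlThreshold & ev$locCorrect,
                       ev$maxScore <= dlThreshold))
    }
  }
  if (!is.null(contrasts)) {
    grid <- sort(unique(contrasts))
    pc <- vapply(grid, pcAt, numeric(1))
  } else {
    grid <- numeric(0)
    pc <- numeric(0)
    ci <- 0
    repeat {
      p <- pcAt(ci)
      grid <- c(grid, ci)
      pc <- c(pc, p)
      if (p > stopPC) break
      ci <- ci + step
      if (ci > maxContrast)
        stop(sprintf(
          "PC did not exceed %.2f by contrast %.2f (last PC %.3f)",
          stopPC, maxContrast, p))
    }
  }
  new("ContrastLUT", task = task, beta = beta, contrastGrid = grid,
      pc = pc, nPerPoint = nPerPoint, seed = as.integer(seed),
      shape = as.integer(shape), radiusPx = radiusPx)
}

#' Invert a look-up table at a target proportion correct
#'
#' Monte-Carlo PC curves are not exactly monotone, so the curve is first
#' regularized by isotonic regression and the threshold contrast is then
#' read off by linear interpolation between the bracketing grid points.
#'
#' @param lut a [ContrastLUT-class].
#' @param pcTarget proportion correct to invert at (0.80 by default).
#' @return The threshold contrast.
#' @export
invertLUT <- function(lut, pcTarget = 0.80) {
  stopifnot(is(lut, "ContrastLUT"))
  fit <- stats::isoreg(lut@contrastGrid, lut@pc)$yf
  if (pcTarget < fit[1])
    stop(sprintf("pcTarget %.3f below the LUT's chance level %.3f",
                 pcTarget, fit[1]))
  if (pcTarget > max(fit))
    stop(sprintf("pcTarget %.3f above the LUT's attained range (max %.3f)",
                 pcTarget, max(fit)))
  i <- which(fit >= pcTarget)[1]
  if (fit[i] == pcTarget || i == 1L) return(lut@contrastGrid[i])
  g <- lut@contrastGrid
  g[i - 1] + (g[i] - g[i - 1]) *
    (pcTarget - fit[i - 1]) / (fit[i] - fit[i - 1])
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood binomial fit of
#' `p(c) = floor + (1 - floor) * pnorm((c - mu) / sigma)` to the per-level
#' correct counts.  The chance floor is fixed, not fitted: 0.5 for yes-no
#' detection, approximately the acceptance-disk / search-area ratio
#' (about 0.5\%) for free localization.
#'
#' @param levels contrast levels (>= 3).
#' @param nCorrect correct counts per level.
#' @param nTrials trials per level.
#' @param floor fixed chance level in `[0, 1)`.
#' @return A [PsychFit-class].
#' @seealso [thresholdAt()]
#' @export
fitPsychometric <- function(levels, nCorrect, nTrials, floor = 0.5) {
  k <- length(levels)
  if (k < 3) stop("need at least 3 contrast levels")
  if (length(nCorrect) != k || length(nTrials) != k)
    stop("levels, nCorrect and nTrials must have equal length")
  if (any(nCorrect < 0 | nCorrect > nTrials))
    stop("invalid counts")
  pObs <- nCorrect / nTrials
  if (all(pObs >= 1))
    stop("degenerate data: 100% correct at every level; ",
         "no slope information -- use lower contrasts")
  if (max(pObs) <= floor)
    stop("degenerate data: performance at or below the chance floor at ",
         "every level; no threshold is identifiable -- use higher contrasts")
  ord <- order(levels)
  levels <- levels[ord]; nCorrect <- nCorrect[ord]; nTrials <- nTrials[ord]
  pObs <- pObs[ord]

  nll <- function(par) {
    mu <- par[1]
    sg <- exp(par[2])
    p <- floor + (1 - floor) * stats::pnorm((levels - mu) / sg)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(nCorrect * log(p) + (nTrials - nCorrect) * log(1 - p))
  }
  mid <- floor + (1 - floor) * 0.5
  mu0 <- tryCatch(stats::approx(pObs, levels, xout = mid, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(mu0)) mu0 <- stats::median(levels)
  sg0 <- max(diff(range(levels)) / 3, 1e-3)
  opt <- stats::optim(c(mu0, log(sg0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  new("PsychFit", mu = opt$par[1], sigma = exp(opt$par[2]), floor = floor,
      nLevels = as.integer(k), logLik = -opt$value)
}

#' Read a threshold off a fitted psychometric function
#'
#' @param fit a [PsychFit-class].
#' @param pc performance level to invert at (0.80 by default); must lie
#'   strictly between the floor and 1.
#' @return The contrast at which the fitted curve equals `pc`.
#' @export
thresholdAt <- function(fit, pc = 0.80) {
  stopifnot(is(fit, "PsychFit"))
  if (pc <= fit@floor || pc >= 1)
    stop("pc must lie strictly between the chance floor and 1")
  fit@mu + fit@sigma * stats::qnorm((pc - fit@floor) / (1 - fit@floor))
}

#' Localization efficiency from a look-up table
#'
#' Efficiency is the squared contrast ratio
#' `(C_IO(pcObs) / cObs)^2`, where `C_IO(pcObs)` is the ideal observer's
#' threshold contrast for the observer's attained proportion correct, read
#' off the simulated LUT.
#'
#' @param cObs contrast the observer ran at.
#' @param pcObs the observer's proportion correct at that contrast.
#' @param lut the ideal observer's [ContrastLUT-class] for the condition.
#' @param pcSessions optional vector of session-wise PC values; each is
#'   inverted separately to give session-wise efficiencies and their
#'   standard error.  Sessions whose PC falls outside the LUT's attained
#'   range are dropped with a warning (short sessions can exceed it by
#'   chance).
#' @return An [EfficiencyEstimate-class].
#' @export
efficiencyLocalization <- function(cObs, pcObs, lut, pcSessions = NULL) {
  cIO <- invertLUT(lut, pcObs)
  eta <- (cIO / cObs)^2
  per <- numeric(0)
  se <- NA_real_
  if (!is.null(pcSessions) && length(pcSessions) >= 2) {
    per <- vapply(pcSessions, function(p) {
      tryCatch((invertLUT(lut, p) / cObs)^2,
               error = function(e) NA_real_)
    }, numeric(1))
    if (anyNA(per))
      warning(sum(is.na(per)),
              " session(s) outside the LUT range were dropped")
    per <- per[!is.na(per)]
    if (length(per) >= 2) se <- sessionSE(per)
  }
  new("EfficiencyEstimate", eta = eta, cObs = cObs, cIO = cIO,
      perSession = per, se = se, task = lut@task, beta = lut@beta)
}

#' Match the detection ideal observer to observed hit / false-alarm rates
#'
#' Solves the two-parameter Gaussian system for the contrast and criterion
#' at which the detection ideal observer reproduces the observed rates:
#' `qnorm(hit) - qnorm(fa)` equals the ideal detectability
#' `cIO * analyticDprime(...)`, and the criterion is placed to reproduce
#' the false-alarm rate.
#'
#' @param hitRate,faRate observed rates, `0 < faRate <= hitRate < 1`;
#'   equal rates give the zero-contrast limit, rates below the diagonal
#'   admit no valid contrast and are an error.
#' @param target a [TargetSpec-class].
#' @param spectrum the condition's [SpectrumGrid-class].
#' @param meanLevel background gray level.
#' @return List with `cIO` (matched contrast) and `tCrit` (criterion in
#'   statistic units).
#' @export
matchDetectionCriterion <- function(hitRate, faRate, target, spectrum,
                                    meanLevel = 100) {
  if (!(faRate > 0 && hitRate < 1 && faRate <= hitRate))
    stop("need 0 < faRate <= hitRate < 1")
  k <- analyticDprime(target, spectrum, meanLevel)
  dprime <- stats::qnorm(hitRate) - stats::qnorm(faRate)
  cIO <- dprime / k
  sdStat <- sqrt(templateEnergy(target, spectrum))
  list(cIO = cIO, tCrit = stats::qnorm(1 - faRate) * sdStat)
}

#' Detection efficiency from matched rates
#'
#' Convenience wrapper: matches the ideal observer to the observed hit and
#' false-alarm rates and returns the squared contrast ratio.  Session-wise
#' rates, when given, yield session-wise efficiencies and their standard
#' error.
#'
#' @inheritParams matchDetectionCriterion
#' @param cObs contrast the observer ran at.
#' @param sessions optional data frame with columns `hit` and `fa`.
#' @param beta condition label for the returned estimate.
#' @return An [EfficiencyEstimate-class].
#' @export
efficiencyDetection <- function(hitRate, faRate, cObs, target, spectrum,
                                meanLevel = 100, sessions = NULL,
                                beta = spectrum@beta) {
  m <- matchDetectionCriterion(hitRate, faRate, target, spectrum, meanLevel)
  eta <- (m$cIO / cObs)^2
  per <- numeric(0)
  se <- NA_real_
  if (!is.null(sessions) && nrow(sessions) >= 2) {
    per <- apply(sessions, 1, function(r) {
      mm <- matchDetectionCriterion(r["hit"], r["fa"], target, spectrum,
                                    meanLevel)
      (mm$cIO / cObs)^2
    })
    se <- sessionSE(per)
  }
  new("EfficiencyEstimate", eta = eta, cObs = cObs, cIO = m$cIO,
      perSession = per, se = se, task = "detection", beta = beta)
}

#' Match the detect-and-localize ideal observer to observed rates
#'
#' Adjusts target contrast and the disk-score detection threshold until the
#' simulated ideal observer reproduces an observed correct
#' detect-and-localize rate (present trials responded at a location within
#' the acceptance radius of truth) and false-positive rate (absent trials
#' responded "present").  For each candidate contrast the threshold is set
#' at the empirical quantile of the absent-trial maximum scores that
#' reproduces the FP rate, and the contrast is then found by bisection on
#' the (monotone) correct-rate curve; all candidates share one set of
#' simulated noise fields (common random numbers), so the solve is
#' deterministic given the seed.
#'
#' @param correctRate observed P(correct location response | present).
#' @param fpRate observed P("present" response | absent).
#' @param beta background exponent.
#' @param nPerPoint simulated trials (half present, half absent on average).
#' @param seed integer seed.
#' @param shape,sigmaPixels,rmsContrast,meanLevel,radiusPx,profileKind
#'   stimulus and scoring parameters.
#' @param maxContrast upper bound for the contrast search.
#' @param tol bisection tolerance on contrast.
#' @return List with `cIO`, `threshold`, and the achieved rates.
#' @export
matchDLCriterion <- function(correctRate, fpRate, beta, nPerPoint = 2000L,
                             seed = 1L, shape = 256L, sigmaPixels = 3,
                             rmsContrast = 0.2, meanLevel = 100,
                             radiusPx = 5, profileKind = "gaussian",
                             maxContrast = 2, tol = 1e-3) {
  if (!(correctRate > 0 && correctRate < 1 && fpRate > 0 && fpRate < 1))
    stop("rates must lie strictly in (0, 1)")
  eng <- locEngine("dandl", beta, as.integer(nPerPoint), seed, shape,
                   sigmaPixels, rmsContrast, meanLevel, radiusPx,
                   profileKind)
  rateAt <- function(contrast) {
    ev <- eng$evalContrast(contrast)
    absent <- ev$maxScore[!ev$present]
    thr <- stats::quantile(absent, probs = 1 - fpRate, type = 1,
                           names = FALSE)
    pres <- ev$present
    cr <- mean(ev$maxScore[pres] > thr & ev$locCorrect[pres])
    list(cr = cr, thr = thr,
         fp = mean(absent > thr))
  }
  lo <- 0
  hi <- 0.1
  rHi <- rateAt(hi)
  while (rHi$cr < correctRate) {
    lo <- hi
    hi <- hi * 2
    if (hi > maxContrast) {
      stop(sprintf(
        "correct-D&L rate %.3f unattainable at fpRate %.3f: feasible max %.3f at contrast %.2f",
        correctRate, fpRate, rHi$cr, hi / 2))
    }
    rHi <- rateAt(hi)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (rateAt(mid)$cr < correctRate) lo <- mid else hi <- mid
  }
  cIO <- (lo + hi) / 2
  r <- rateAt(cIO)
  list(cIO = cIO, threshold = r$thr, achievedCorrectRate = r$cr,
       achievedFpRate = r$fp)
}

#' Mean deviation of correct localization responses
#'
#' Average Euclidean distance between response and true target location
#' over the correctly localized trials (those within the acceptance
#' radius), in pixels and degrees of visual angle, together with the
#' baseline expected if responses were uniform over the discrete
#' acceptance region.
#'
#' @param records a trial-record data frame (see [runExperiment()]) with
#'   truth columns `loc_x`, `loc_y` and response columns `response_x`,
#'   `response_y`.
#' @param radiusPx acceptance radius defining correctness.
#' @param pixelAngleDeg degrees per pixel for the degree-valued outputs.
#' @return List with `meanPx`, `meanDeg`, `n`, `uniformPx`, `uniformDeg`.
#' @export
localizationDeviation <- function(records, radiusPx = 5,
                                  pixelAngleDeg = pixelAngle()) {
  ok <- !is.na(records$response_x) & !is.na(records$loc_x)
  d <- sqrt((records$response_x - records$loc_x)^2 +
            (records$response_y - records$loc_y)^2)
  corr <- ok & d <= radiusPx
  if (!any(corr)) stop("no correctly localized trials in the records")
  u <- uniformDeviationBaseline(radiusPx)
  list(meanPx = mean(d[corr]), meanDeg = mean(d[corr]) * pixelAngleDeg,
       n = sum(corr), uniformPx = u, uniformDeg = u * pixelAngleDeg)
}

#' Uniform-response deviation baseline
#'
#' Mean distance from the center over the integer lattice offsets within
#' the acceptance radius (81 offsets at radius 5), i.e. the deviation a
#' responder uniform over the discrete acceptance region would show.
#'
#' @param radiusPx acceptance radius in pixels.
#' @return Mean distance in pixels.
#' @export
uniformDeviationBaseline <- function(radiusPx = 5) {
  off <- diskOffsets(radiusPx)
  mean(sqrt(off$dr^2 + off$dc^2))
}

#' Standard error across sessions
#'
#' @param perSessionValues numeric vector of session-wise values (>= 2).
#' @return `sd / sqrt(n)` across sessions.
#' @export
sessionSE <- function(perSessionValues) {
  n <- length(perSessionValues)
  if (n < 2) stop("need at least 2 sessions")
  stats::sd(perSessionValues) / sqrt(n)
}
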