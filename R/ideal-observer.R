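#' Build the prewhitened matched-filter template
#'
#' Frequency weights are the Fourier transform of the (unit-peak,
#' origin-wrapped) target profile divided pointwise by the noise power
#' spectrum, with the DC term following the spectrum's first-harmonic rule;
#' spatial weights follow by inverse transform.  For white noise
#' (`beta = 0`) the spatial weights are proportional to the target itself;
#' for correlated noise the division by the spectrum prewhitens, shifting
#' the template's frequency weighting toward \eqn{f^\beta}.
#'
#' The DFT scaling convention used throughout the package is that for a
#' unit-peak profile `s`, `t(s) %*% solve(Sigma) %*% s` equals
#' `mean(Mod(fft(s))^2 / S)` over the DFT grid; every template-based
#' statistic, d-prime, and whitening operation uses this convention, and
#' any global rescaling of it cancels in all decisions and efficiencies.
#'
#' @param target a [TargetSpec-class].
#' @param spectrum a [SpectrumGrid-class] with strictly positive values.
#' @return An [IOTemplate-class], stored origin-wrapped.
#' @export
buildTemplate <- function(target, spectrum) {
  stopifnot(is(target, "TargetSpec"), is(spectrum, "SpectrumGrid"))
  if (any(spectrum@values <= 0))
    stop("spectrum has zero values off DC; template undefined")
  n <- spectrum@shape
  s0 <- targetProfileOrigin(target, n)
  fw <- fft2(s0) / spectrum@values
  sw <- ifft2(fw)
  if (max(abs(Im(sw))) > 1e-9 * max(abs(Re(sw))))
    stop("template spatial weights are not real; inconsistent spectrum")
  new("IOTemplate", spatialWeights = Re(sw), freqWeights = fw,
      beta = spectrum@beta, sigmaPixels = target@sigmaPixels,
      profileKind = target@profileKind)
}

# Cross-correlation map of an origin-wrapped real template with the
# mean-subtracted stimulus: m(l) = sum_x w(x - l) g0(x), circularly.
corrMap <- function(freqTemplate, g0) {
  Re(ifft2(Conj(freqTemplate) * fft2(g0)))
}

# s' Sigma^{-1} s for the unit-peak profile, in the package's DFT scaling.
templateEnergy <- function(target, spectrum) {
  s0 <- targetProfileOrigin(target, spectrum@shape)
  mean(Mod(fft2(s0))^2 / spectrum@values)
}

#' Detectability per unit contrast
#'
#' Returns `meanLevel * sqrt(s' Sigma^-1 s)` for the unit-peak target
#' profile, so that the detection index is `d' = contrast * value`.  For
#' white noise this reduces to the matched-filter identity
#' `meanLevel * ||s|| / noise sd`.
#'
#' @param target a [TargetSpec-class].
#' @param spectrum a [SpectrumGrid-class].
#' @param meanLevel background gray level the contrast is defined against.
#' @return d-prime per unit target contrast (dimensionless).
#' @export
analyticDprime <- function(target, spectrum, meanLevel = 100) {
  meanLevel * sqrt(templateEnergy(target, spectrum))
}

#' Unbiased detection criterion
#'
#' The midpoint criterion for a 50/50 yes-no detection task: half the mean
#' statistic under target-present, `contrast * meanLevel * s' Sigma^-1 s / 2`.
#' At this criterion the ideal observer's proportion correct is
#' `pnorm(dprime / 2)`.
#'
#' @inheritParams analyticDprime
#' @param contrast target contrast.
#' @return Criterion in statistic units.
#' @export
unbiasedCriterion <- function(target, spectrum, contrast, meanLevel = 100) {
  contrast * meanLevel * templateEnergy(target, spectrum) / 2
}

#' Ideal observer yes-no detection
#'
#' Computes the template statistic `w' (g - meanLevel)` at the cued center
#' pixel and reports "present" iff it exceeds `tCrit` (exact ties resolve
#' to "absent").
#'
#' @param stim a [StimulusImage-class].
#' @param tmpl an [IOTemplate-class] of matching shape.
#' @param tCrit detection criterion in statistic units.
#' @return An [IODecision-class] with the statistic and response.
#' @export
detectTarget <- function(stim, tmpl, tCrit) {
  stopifnot(is(stim, "StimulusImage"), is(tmpl, "IOTemplate"))
  n <- nrow(stim@pixels)
  if (nrow(tmpl@spatialWeights) != n)
    stop("stimulus and template shapes differ")
  m <- corrMap(tmpl@freqWeights, stim@pixels - stim@meanLevel)
  stat <- m[n / 2 + 1, n / 2 + 1]
  new("IODecision", task = "detection", detected = stat > tCrit,
      location = integer(0), statistic = stat, criterionUsed = tCrit)
}

#' Localization score map (posterior and acceptance-disk score)
#'
#' Implements the convolutional localization decision function:
#' (1) correlate the prewhitened template with the mean-subtracted
#' stimulus and scale by the target amplitude, giving the log-likelihood
#' of each location; (2) exponentiate (after subtracting the in-region
#' maximum, which leaves the normalized posterior unchanged but avoids
#' overflow); (3) zero outside the search region; (4) normalize to sum to
#' one; (5) convolve with the acceptance disk.  All convolutions are
#' circular; the border region guarantees the disk convolution cannot wrap
#' posterior mass across image edges.
#'
#' @param stim a [StimulusImage-class]; its `contrast` slot sets the
#'   assumed target amplitude (`contrast * meanLevel`).
#' @param tmpl an [IOTemplate-class] built for the stimulus' noise.
#' @param radiusPx acceptance radius in pixels (5 by default; the disk
#'   contains all integer offsets with Euclidean norm <= radius).
#' @return A [ScoreMap-class].
#' @export
localizationScore <- function(stim, tmpl, radiusPx = 5) {
  stopifnot(is(stim, "StimulusImage"), is(tmpl, "IOTemplate"))
  if (any(!is.finite(stim@pixels))) stop("non-finite stimulus")
  n <- nrow(stim@pixels)
  if (nrow(tmpl@spatialWeights) != n)
    stop("stimulus and template shapes differ")
  a <- stim@contrast * stim@meanLevel
  m <- corrMap(tmpl@freqWeights, stim@pixels - stim@meanLevel)
  mask <- cachedMask(n)
  e <- a * m
  e <- e - max(e[mask])               # log-domain stabilization (exact)
  p <- exp(e)
  p[!mask] <- 0
  p <- p / sum(p)
  ds <- Re(ifft2(fft2(p) * cachedDiskF(n, radiusPx)))
  ds[ds < 0] <- 0                     # clip fft round-off
  new("ScoreMap", posterior = p, diskScore = ds, searchMask = mask,
      radiusPx = radiusPx)
}

#' Choose the localization response
#'
#' The response is the location of the maximum acceptance-disk score within
#' the search region; exact ties break to the first occurrence in row-major
#' (reading) order.
#'
#' @param score a [ScoreMap-class].
#' @return An [IODecision-class] with `location` and the maximal score.
#' @export
localize <- function(score) {
  stopifnot(is(score, "ScoreMap"))
  ds <- score@diskScore
  ds[!score@searchMask] <- -Inf
  loc <- rowMajorArgmax(ds)
  new("IODecision", task = "localization", detected = NA,
      location = as.integer(loc), statistic = ds[loc[1], loc[2]],
      criterionUsed = NA_real_)
}

#' Detect-and-localize decision
#'
#' As [localize()], but the maximum disk score is compared with a detection
#' threshold: above it the observer responds with the maximizing location,
#' otherwise "target absent".
#'
#' @param score a [ScoreMap-class].
#' @param threshold detection threshold on the disk score (in \[0, 1\]).
#' @return An [IODecision-class]; `location` is `integer(0)` for "absent".
#' @export
detectAndLocalize <- function(score, threshold) {
  d <- localize(score)
  hit <- d@statistic > threshold
  new("IODecision", task = "dandl", detected = hit,
      location = if (hit) d@location else integer(0),
      statistic = d@statistic, criterionUsed = threshold)
}

#' Brute-force localization oracle
#'
#' Reference implementation of the localization ideal observer by direct
#' enumeration: the whitened stimulus is formed once, then the
#' log-likelihood of every search-region location is computed as an
#' explicit inner product with the circularly shifted template, the
#' posterior is normalized over the region, acceptance-disk scores are
#' accumulated by direct summation over the integer disk offsets, and the
#' row-major argmax is returned.  Cost grows as the fourth power of the
#' image side, so shapes above 64 are refused; the function exists as an
#' independent check of the convolutional observer.
#'
#' @param stim a [StimulusImage-class] (side <= 64).
#' @param target a [TargetSpec-class].
#' @param spectrum the generating [SpectrumGrid-class].
#' @param radiusPx acceptance radius in pixels.
#' @return Integer `(row, col)` response location.
#' @export
bruteForceLocalize <- function(stim, target, spectrum, radiusPx = 5) {
  n <- nrow(stim@pixels)
  if (n > 64) stop("brute-force oracle is restricted to shapes <= 64")
  a <- stim@contrast * stim@meanLevel
  q <- Re(ifft2(fft2(stim@pixels - stim@meanLevel) / spectrum@values))
  s0 <- targetProfileOrigin(target, n)
  b <- searchRegionBounds(n)
  idx <- b["lo"]:b["hi"]
  loglik <- matrix(-Inf, n, n)
  for (r in idx) for (cc in idx) {
    loglik[r, cc] <- a * sum(circShift(s0, r - 1L, cc - 1L) * q)
  }
  mx <- max(loglik[idx, idx])
  p <- exp(loglik - mx)
  p[-idx, ] <- 0
  p[, -idx] <- 0
  p <- p / sum(p)
  off <- diskOffsets(radiusPx)
  score <- matrix(-Inf, n, n)
  for (r in idx) for (cc in idx) {
    rr <- ((r + off$dr - 1L) %% n) + 1L   # wrap, as the circular conv does
    cs <- ((cc + off$dc - 1L) %% n) + 1L
    score[r, cc] <- sum(p[cbind(rr, cs)])
  }
  as.integer(rowMajorArgmax(score))
}
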