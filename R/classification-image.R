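# Classification-image estimation: whitening, the signed detection
# estimator, the response-aligned false-localization estimator, display
# smoothing, and radial frequency profiles.

#' Whiten a noise field
#'
#' Applies the inverse noise covariance: the field's DFT is divided by the
#' power spectrum (DC by the spectrum's first-harmonic rule) and
#' inverse-transformed.  For white noise this is a constant rescaling of
#' the field; in general the whitened field is the quantity whose class
#' means form classification images.
#'
#' @param field numeric matrix (zero-mean noise, gray levels).
#' @param spectrum the generating [SpectrumGrid-class]; it must be the
#'   same spectrum (including the DC rule) the noise was generated from --
#'   mismatched shapes are an error.
#' @return A real matrix.
#' @export
whitenNoise <- function(field, spectrum) {
  stopifnot(is(spectrum, "SpectrumGrid"))
  if (nrow(field) != spectrum@shape || ncol(field) != spectrum@shape)
    stop("field and spectrum shapes differ")
  if (any(spectrum@values <= 0)) stop("spectrum has zero values")
  Re(ifft2(fft2(field) / spectrum@values))
}

# classify a detection record into FP/TN/TP/FN
.detClass <- function(present, detected) {
  ifelse(present,
         ifelse(detected, "TP", "FN"),
         ifelse(detected, "FP", "TN"))
}

#' Detection classification image
#'
#' The signed combination of class-mean whitened noise fields,
#' `mean(q | FP) - mean(q | TN) + mean(q | TP) - mean(q | FN)`,
#' which for a linear-template observer is an unbiased estimate (up to
#' scale) of its template.  The four outcome classes must all be
#' non-empty.
#'
#' @param records trial-record data frame with logical columns `present`
#'   and `detected`.
#' @param noiseFields list of noise-field matrices, one per record row
#'   (the pure noise, no target, no mean background).
#' @param spectrum the generating [SpectrumGrid-class].
#' @return A [ClassImage-class] centered at the image center.
#' @export
detectionCI <- function(records, noiseFields, spectrum) {
  if (nrow(records) != length(noiseFields))
    stop("one noise field per record row is required")
  cls <- .detClass(records$present, records$detected)
  counts <- table(factor(cls, levels = c("FP", "TN", "TP", "FN")))
  if (any(counts == 0))
    stop("all four outcome classes must be non-empty; counts: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  n <- spectrum@shape
  sums <- list(FP = matrix(0, n, n), TN = matrix(0, n, n),
               TP = matrix(0, n, n), FN = matrix(0, n, n))
  for (i in seq_len(nrow(records))) {
    q <- whitenNoise(noiseFields[[i]], spectrum)
    sums[[cls[i]]] <- sums[[cls[i]]] + q
  }
  w <- sums$FP / counts["FP"] - sums$TN / counts["TN"] +
       sums$TP / counts["TP"] - sums$FN / counts["FN"]
  new("ClassImage", weights = w, task = "detection",
      beta = spectrum@beta, nTrialsUsed = as.integer(nrow(records)))
}

# Align one whitened field so the response pixel lands on the image center.
.alignToCenter <- function(q, respRow, respCol) {
  n <- nrow(q)
  c0 <- n / 2 + 1
  circShift(q, c0 - respRow, c0 - respCol)
}

#' Response-aligned localization classification image
#'
#' The false-localization estimator: for every incorrectly localized
#' trial, the whitened noise field is circularly shifted so the response
#' pixel moves to the image center, and these aligned fields are averaged.
#' On such trials the response is driven entirely by the noise at the
#' chosen location, so roughly the 20\% of trials that are incorrect at
#' PC = 80\% suffice for a strong estimate.
#'
#' @param records trial-record data frame with columns `correct`,
#'   `response_x`, `response_y` (0-based column/row, as in the CSV
#'   schema).
#' @param noiseFields list of noise-field matrices, one per record row.
#' @param spectrum the generating [SpectrumGrid-class].
#' @return A [ClassImage-class] centered at the image center.
#' @export
localizationCI <- function(records, noiseFields, spectrum) {
  if (nrow(records) != length(noiseFields))
    stop("one noise field per record row is required")
  fl <- which(!records$correct & !is.na(records$response_x))
  if (length(fl) == 0)
    stop("no incorrectly localized trials; the estimator needs at least one")
  n <- spectrum@shape
  acc <- matrix(0, n, n)
  for (i in fl) {
    q <- whitenNoise(noiseFields[[i]], spectrum)
    acc <- acc + .alignToCenter(q, records$response_y[i] + 1L,
                                records$response_x[i] + 1L)
  }
  new("ClassImage", weights = acc / length(fl), task = "localization",
      beta = spectrum@beta, nTrialsUsed = as.integer(length(fl)))
}

#' Run the ideal observer and estimate its localization classification image
#'
#' Convenience driver for the self-check of the false-localization
#' estimator: simulates free-localization trials, lets the ideal observer
#' respond, and accumulates the response-aligned whitened noise of the
#' incorrect trials online (so arbitrarily many trials fit in memory).
#'
#' @param beta background exponent.
#' @param contrast target contrast (choose near the 80\% correct point so
#'   roughly 20\% of trials are incorrect).
#' @param nTrials number of simulated trials.
#' @param seed integer seed.
#' @param shape,sigmaPixels,rmsContrast,meanLevel,radiusPx condition
#'   parameters.
#' @return A list with the [ClassImage-class] (`ci`), the proportion
#'   correct (`pc`), and the number of false-localization trials used.
#' @export
ioLocalizationCI <- function(beta, contrast, nTrials = 2000L, seed = 1L,
                             shape = 256L, sigmaPixels = 3,
                             rmsContrast = 0.2, meanLevel = 100,
                             radiusPx = 5) {
  n <- as.integer(shape)
  nz <- noiseSpec(beta = beta, rmsContrast = rmsContrast,
                  meanLevel = meanLevel, shape = n)
  sp <- buildSpectrum(nz)
  tg <- targetSpec(sigmaPixels = sigmaPixels, contrast = contrast)
  tmpl <- buildTemplate(tg, sp)
  s0 <- targetProfileOrigin(tg, n)
  a <- contrast * meanLevel
  acc <- matrix(0, n, n)
  nFL <- 0L
  nCorrect <- 0L
  for (i in seq_len(nTrials)) {
    stim <- makeTrial("localization", nz, tg, seed = deriveSeed(seed, i))
    resp <- localize(localizationScore(stim, tmpl, radiusPx))
    tl <- stim@truthLocation
    rl <- resp@location
    if (sum((rl - tl)^2) <= radiusPx^2) {
      nCorrect <- nCorrect + 1L
    } else {
      # recover the pure noise by subtracting the embedded target exactly
      noise <- stim@pixels - meanLevel -
        a * circShift(s0, tl[1] - 1L, tl[2] - 1L)
      q <- whitenNoise(noise, sp)
      acc <- acc + .alignToCenter(q, rl[1], rl[2])
      nFL <- nFL + 1L
    }
  }
  if (nFL == 0L) stop("no incorrect trials; reduce the contrast")
  list(ci = new("ClassImage", weights = acc / nFL, task = "localization",
                beta = beta, nTrialsUsed = nFL),
       pc = nCorrect / nTrials, nFalseLoc = nFL)
}

#' Butterworth low-pass smoothing of a classification image
#'
#' Radial frequency-domain gain `1 / sqrt(1 + (f / fc)^(2 * order))`
#' (unit DC gain, half power at the cutoff), used for display smoothing of
#' noisy classification images.
#'
#' @param ci a [ClassImage-class].
#' @param order filter order (4 by default).
#' @param cutoffCycPerDeg roll-off frequency in cycles/degree (5.6 by
#'   default, i.e. 0.29 cycles/pixel at the default pixel angle).
#' @param pixelAngleDeg degrees per pixel.
#' @return The smoothed [ClassImage-class].
#' @export
butterworthSmooth <- function(ci, order = 4, cutoffCycPerDeg = 5.6,
                              pixelAngleDeg = pixelAngle()) {
  stopifnot(is(ci, "ClassImage"))
  n <- nrow(ci@weights)
  fDeg <- radialFreqGrid(n) / pixelAngleDeg
  gain <- 1 / sqrt(1 + (fDeg / cutoffCycPerDeg)^(2 * order))
  initialize(ci, weights = Re(ifft2(fft2(ci@weights) * gain)))
}

# Radial average over annuli one DFT step wide; bin center = mean radius
# of the member frequencies.  Returns bins in cycles/pixel.
.radialAverage <- function(valGrid, n) {
  f <- radialFreqGrid(n)
  binIdx <- round(f * n)                 # annulus index in DFT steps
  keep <- binIdx <= n / 2                # up to Nyquist
  agg <- tapply(valGrid[keep], binIdx[keep], mean)
  ctr <- tapply(f[keep], binIdx[keep], mean)
  list(freq = as.numeric(ctr), value = as.numeric(agg))
}

#' Radial frequency profile of a classification image
#'
#' Applies a radial Butterworth spatial window about the image center
#' (cutoff 1.05 degrees, i.e. 20 pixels, by default) to suppress
#' estimation noise far from the target, Fourier-transforms, radially
#' averages the real part in annuli one DFT step wide, and normalizes the
#' peak weight to 1.  The imaginary part is discarded for the profile
#' (templates are symmetric in expectation); its RMS is attached as the
#' attribute `imagRMS` as a diagnostic.
#'
#' @param ci a [ClassImage-class] centered at the image center.
#' @param windowCutoffDeg spatial window cutoff in degrees.
#' @param windowOrder spatial window order.
#' @param pixelAngleDeg degrees per pixel.
#' @return A [RadialProfile-class] with bins in cycles/degree.
#' @export
radialProfile <- function(ci, windowCutoffDeg = 1.05, windowOrder = 4,
                          pixelAngleDeg = pixelAngle()) {
  stopifnot(is(ci, "ClassImage"))
  w <- ci@weights
  if (all(w == 0)) stop("all-zero classification image")
  n <- nrow(w)
  c0 <- n / 2 + 1
  r <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+"))
  rc <- windowCutoffDeg / pixelAngleDeg
  w <- w / sqrt(1 + (r / rc)^(2 * windowOrder))
  # move the center to the origin so a symmetric template transforms real
  w <- circShift(w, 1L - c0, 1L - c0)
  W <- fft2(w)
  ra <- .radialAverage(Re(W), n)
  prof <- ra$value / max(ra$value)
  out <- new("RadialProfile", freqBins = ra$freq / pixelAngleDeg,
             weights = prof, units = "cyc/deg")
  attr(out, "imagRMS") <- sqrt(mean(Im(W)^2)) / max(abs(Re(W)))
  out
}

#' Analytic ideal-observer frequency weights
#'
#' The ideal template's frequency weights are the target transform divided
#' by the noise spectrum, i.e. proportional to
#' \eqn{f^\beta \exp(-2 \pi^2 \sigma^2 f^2)}.  This evaluates that closed
#' form on the DFT grid, radially averages it, and normalizes the peak to
#' 1 -- the reference curve classification images are compared against.
#' The continuous-form peak frequency is `sqrt(beta) / (2 pi sigma)`; see
#' [ioPeakFrequency()].
#'
#' @param beta noise exponent (>= 0).
#' @param sigmaPixels target scale in pixels.
#' @param pixelAngleDeg degrees per pixel (for the cyc/deg bin centers).
#' @param shape DFT grid side.
#' @return A [RadialProfile-class] with bins in cycles/degree.
#' @export
ioFrequencyWeights <- function(beta, sigmaPixels = 3,
                               pixelAngleDeg = pixelAngle(),
                               shape = 256L) {
  stopifnot(beta >= 0)
  n <- as.integer(shape)
  f <- radialFreqGrid(n)
  wt <- f^beta * exp(-2 * pi^2 * sigmaPixels^2 * f^2)
  if (beta == 0) wt[1, 1] <- 1
  ra <- .radialAverage(wt, n)
  new("RadialProfile", freqBins = ra$freq / pixelAngleDeg,
      weights = ra$value / max(ra$value), units = "cyc/deg")
}

#' Peak frequency of the ideal-observer weights
#'
#' Closed-form argmax of \eqn{f^\beta \exp(-2 \pi^2 \sigma^2 f^2)}:
#' `sqrt(beta) / (2 * pi * sigma)`.  With sigma expressed in degrees the
#' result is in cycles/degree; the default geometry moves the peak from 0
#' (white noise) to about 1.7 cyc/deg at beta = 3.
#'
#' @param beta noise exponent.
#' @param sigmaDeg target scale in degrees (3 px at the default pixel
#'   angle if omitted).
#' @return Peak frequency (same reciprocal units as `sigmaDeg`).
#' @export
ioPeakFrequency <- function(beta, sigmaDeg = 3 * pixelAngle()) {
  sqrt(beta) / (2 * pi * sigmaDeg)
}
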