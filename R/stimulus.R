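#' Create a noise texture specification
#'
#' @param beta power-law exponent of the noise power spectrum (>= 0).
#' @param rmsContrast RMS contrast of the noise relative to the mean
#'   background level; 0.20 gives pixel variance 400 gl^2 on a 100 gl mean.
#' @param meanLevel mean background gray level.
#' @param shape image side length in pixels (even, >= 8).
#' @return A [NoiseSpec-class] object.
#' @examples
#' noiseSpec(beta = 2)
#' @export
noiseSpec <- function(beta = 2, rmsContrast = 0.20, meanLevel = 100,
                      shape = 256L) {
  new("NoiseSpec", beta = as.numeric(beta),
      rmsContrast = as.numeric(rmsContrast),
      meanLevel = as.numeric(meanLevel), shape = as.integer(shape))
}

#' Create a target specification
#'
#' @param sigmaPixels spatial standard deviation of the Gaussian bump (px).
#' @param contrast peak target amplitude divided by the mean background
#'   level (dimensionless).
#' @param profileKind `"gaussian"` for the raw bump, `"filtered"` for the
#'   profile after the white-to-pink processing filter.
#' @return A [TargetSpec-class] object.
#' @export
targetSpec <- function(sigmaPixels = 3, contrast = 0, profileKind = "gaussian") {
  new("TargetSpec", sigmaPixels = as.numeric(sigmaPixels),
      contrast = as.numeric(contrast), profileKind = profileKind)
}

#' Build the discrete power-law spectrum
#'
#' Constructs \eqn{S_\beta(f) = C_\beta / f^\beta} on the 2-D DFT grid of
#' the requested shape, with the DC value replaced by the first-harmonic
#' value (frequency 1/shape) to avoid the singularity at f = 0.  The
#' normalization constant is chosen so that the implied pixel variance of a
#' synthesized field, `mean(values)`, equals
#' `(rmsContrast * meanLevel)^2` exactly.
#'
#' @param spec a [NoiseSpec-class].
#' @return A [SpectrumGrid-class].
#' @examples
#' sp <- buildSpectrum(noiseSpec(beta = 2, shape = 64L))
#' mean(spectrumValues(sp))  # 400 gl^2
#' @export
buildSpectrum <- function(spec) {
  stopifnot(is(spec, "NoiseSpec"))
  validObject(spec)
  n <- spec@shape
  f <- radialFreqGrid(n)
  f[1, 1] <- 1 / n                  # DC -> first harmonic
  v <- f^(-spec@beta)
  targetVar <- (spec@rmsContrast * spec@meanLevel)^2
  cBeta <- targetVar / mean(v)
  new("SpectrumGrid", values = cBeta * v, shape = n, beta = spec@beta,
      normConstant = cBeta, dcRule = "first-harmonic")
}

#' Sample a stationary Gaussian noise field
#'
#' Filters a white Gaussian field in the frequency domain by the square
#' root of the power spectrum and inverse-transforms.  The returned field
#' is real, zero-mean in expectation, with per-pixel variance equal to the
#' mean of the spectrum values.
#'
#' @param spectrum a [SpectrumGrid-class].
#' @param seed integer seed; the same `(spectrum, seed)` pair always
#'   yields the same field.  `NULL` continues the current RNG stream.
#' @return A numeric matrix in gray levels.
#' @export
sampleNoise <- function(spectrum, seed = NULL) {
  stopifnot(is(spectrum, "SpectrumGrid"))
  if (!is.null(seed)) set.seed(seed)
  n <- spectrum@shape
  w <- matrix(stats::rnorm(n * n), n, n)
  Re(ifft2(fft2(w) * sqrt(spectrum@values)))
}

#' Gaussian target profile
#'
#' Unit-peak rotationally symmetric Gaussian, `exp(-r^2 / (2 sigma^2))`,
#' centered on the pixel `(shape/2 + 1, shape/2 + 1)`.  When embedded in a
#' stimulus the profile is scaled by `contrast * meanLevel`.
#'
#' @param spec a [TargetSpec-class] (only `sigmaPixels` is used).
#' @param shape image side length.
#' @return A numeric matrix with value 1 at the center pixel.
#' @export
gaussianTarget <- function(spec, shape = 256L) {
  stopifnot(is(spec, "TargetSpec"))
  n <- as.integer(shape)
  c0 <- n / 2
  circShift(targetOrigin(n, spec@sigmaPixels), c0, c0)
}

# Origin-wrapped profile of either kind; templates and embedding use this.
targetProfileOrigin <- function(spec, shape) {
  n <- as.integer(shape)
  s0 <- targetOrigin(n, spec@sigmaPixels)
  if (spec@profileKind == "filtered") {
    h <- pinkFilterAmplitude(n)
    s0 <- Re(ifft2(fft2(s0) * h))
  }
  s0
}

#' Full width at half maximum of the target
#'
#' For the Gaussian profile, FWHM = `2 * sqrt(2 * log(2)) * sigma`; with a
#' pixel angle the width is also returned in degrees of visual angle.
#'
#' @param spec a [TargetSpec-class].
#' @param pixelAngleDeg degrees subtended by one pixel (see [pixelAngle()]).
#' @return Named vector with elements `px` and `deg`.
#' @export
targetFWHM <- function(spec, pixelAngleDeg = pixelAngle()) {
  w <- 2 * sqrt(2 * log(2)) * spec@sigmaPixels
  c(px = w, deg = w * pixelAngleDeg)
}

#' Compose one trial's stimulus
#'
#' Draws the ground truth for the requested task, samples a noise field,
#' and embeds the target additively:
#' `pixels = meanLevel + noise + contrast * meanLevel * shifted profile`.
#' * `detection`: the target is present with probability 1/2 and, when
#'   present, centered on the cued center pixel.
#' * `localization`: the target is always present, uniformly located in the
#'   central search region (the central half-side square, one quarter of
#'   the image area).
#' * `dandl`: present with probability 1/2; location uniform over the
#'   search region when present.
#'
#' Target locations are integer pixel positions and the embedding uses
#' circular shifts of the origin-wrapped profile, so
#' `makeTrial(contrast = c) - makeTrial(contrast = 0)` at the same seed is
#' exactly `c * meanLevel * shifted profile`.
#'
#' @param task `"detection"`, `"localization"` or `"dandl"`.
#' @param noise a [NoiseSpec-class].
#' @param target a [TargetSpec-class] (its `contrast` slot is used).
#' @param seed integer seed; truth draws and the noise field both derive
#'   from it.
#' @return A [StimulusImage-class].
#' @export
makeTrial <- function(task = c("detection", "localization", "dandl"),
                      noise = noiseSpec(), target = targetSpec(),
                      seed = 1L) {
  task <- match.arg(task)
  stopifnot(is(noise, "NoiseSpec"), is(target, "TargetSpec"))
  validObject(noise)
  n <- noise@shape
  b <- searchRegionBounds(n)
  seed <- as.integer(seed)
  set.seed(seed)

  present <- TRUE
  loc <- integer(0)
  if (task == "detection") {
    present <- stats::runif(1) < 0.5
    if (present) loc <- as.integer(c(n / 2 + 1, n / 2 + 1))
  } else if (task == "localization") {
    loc <- as.integer(sample(b["lo"]:b["hi"], 2, replace = TRUE))
  } else {
    present <- stats::runif(1) < 0.5
    if (present) loc <- as.integer(sample(b["lo"]:b["hi"], 2, replace = TRUE))
  }

  field <- sampleNoise(cachedSpectrum(noise), seed = NULL)
  px <- noise@meanLevel + field
  if (present && target@contrast > 0) {
    s0 <- cachedTargetOrigin(target, n)
    px <- px + target@contrast * noise@meanLevel *
      circShift(s0, loc[1] - 1L, loc[2] - 1L)
  }
  new("StimulusImage", pixels = px, meanLevel = noise@meanLevel,
      truthPresent = present, truthLocation = if (present) loc else integer(0),
      task = task, beta = noise@beta, contrast = target@contrast,
      seed = seed, processed = FALSE)
}

# Amplitude filter used for white-to-pink processing: proportional to 1/f
# with the DC value set by the first-harmonic rule, normalized so that
# mean(h^2) = 1 (filtering a white background then preserves its variance,
# i.e. the 20% RMS contrast, deterministically).
pinkFilterAmplitude <- function(n) {
  f <- radialFreqGrid(n)
  f[1, 1] <- 1 / n
  h <- 1 / f
  h / sqrt(mean(h^2))
}

#' Filter a white-noise stimulus to a beta = 2 background
#'
#' Applies the image-processing step of the design: the mean level is
#' removed, the DFT is multiplied by an amplitude filter proportional to
#' 1/f (DC by the first-harmonic rule, normalized so the background RMS
#' contrast is preserved at its 20\% value), and the mean is restored.  The
#' white background acquires an exact beta = 2 power-law spectrum, and the
#' embedded Gaussian target becomes the "filtered" profile with much
#' heavier tails.  Ground-truth metadata are preserved.
#'
#' @param stim a [StimulusImage-class] generated with `beta = 0` and not
#'   already processed.
#' @return The processed [StimulusImage-class] (`processed = TRUE`).
#' @export
processWhiteToPink <- function(stim) {
  stopifnot(is(stim, "StimulusImage"))
  if (stim@beta != 0)
    stop("processing is defined for beta = 0 stimuli only")
  if (stim@processed)
    stop("stimulus has already been processed")
  n <- nrow(stim@pixels)
  h <- pinkFilterAmplitude(n)
  out <- Re(ifft2(fft2(stim@pixels - stim@meanLevel) * h)) + stim@meanLevel
  initialize(stim, pixels = out, processed = TRUE)
}
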