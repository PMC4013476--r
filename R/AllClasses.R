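#' @import methods
NULL

#' Noise texture specification
#'
#' Describes a stationary Gaussian power-law noise texture: power spectrum
#' \eqn{S_\beta(f) = C_\beta / f^\beta} with the DC term set to the
#' first-harmonic value.  The defaults reproduce the study conditions used
#' throughout the package: 256 x 256 images, 20\% RMS-contrast noise on a
#' mean background of 100 gray levels (gl), i.e. pixel variance 400 gl^2.
#'
#' @slot beta power-law exponent (dimensionless, >= 0)
#' @slot rmsContrast noise RMS amplitude relative to the mean level
#' @slot meanLevel background gray level
#' @slot shape image side length in pixels (even)
#' @export
setClass("NoiseSpec",
  representation(beta = "numeric", rmsContrast = "numeric",
                 meanLevel = "numeric", shape = "integer"),
  validity = function(object) {
    if (length(object@beta) != 1 || object@beta < 0)
      return("beta must be a single nonnegative number")
    if (object@rmsContrast <= 0 || object@rmsContrast >= 1)
      return("rmsContrast must lie in (0, 1)")
    if (object@meanLevel <= 0) return("meanLevel must be positive")
    if (object@shape < 8L) return("shape must be at least 8")
    if (object@shape %% 2L != 0L) return("shape must be even")
    TRUE
  })

#' Discrete power spectrum on the DFT grid
#'
#' Nonnegative power at every 2-D DFT frequency, standing in for the
#' stationary noise covariance.  The scaling convention is that the mean of
#' the grid values equals the pixel variance of the synthesized field (so
#' the grid values are the eigenvalues of the circulant covariance).
#'
#' @slot values matrix of power values (gl^2 pixel^2)
#' @slot shape image side length
#' @slot beta exponent the spectrum was built for
#' @slot normConstant the constant \eqn{C_\beta}
#' @slot dcRule how the f = 0 singularity was handled
#' @export
setClass("SpectrumGrid",
  representation(values = "matrix", shape = "integer", beta = "numeric",
                 normConstant = "numeric", dcRule = "character"),
  validity = function(object) {
    if (any(!is.finite(object@values)) || any(object@values < 0))
      return("spectrum values must be finite and nonnegative")
    if (nrow(object@values) != object@shape ||
        ncol(object@values) != object@shape)
      return("values must be shape x shape")
    TRUE
  })

#' Target profile specification
#'
#' A rotationally symmetric Gaussian bump, \eqn{\exp(-r^2 / 2\sigma^2)},
#' with unit peak.  Target contrast is defined as peak amplitude divided by
#' the mean background level.  `profileKind = "filtered"` denotes the
#' profile after the white-to-pink processing filter (heavier tails).
#'
#' @slot sigmaPixels spatial standard deviation in pixels
#' @slot contrast peak amplitude / mean level (dimensionless, >= 0)
#' @slot profileKind `"gaussian"` or `"filtered"`
#' @export
setClass("TargetSpec",
  representation(sigmaPixels = "numeric", contrast = "numeric",
                 profileKind = "character"),
  validity = function(object) {
    if (object@sigmaPixels <= 0) return("sigmaPixels must be positive")
    if (object@contrast < 0) return("contrast must be nonnegative")
    if (!object@profileKind %in% c("gaussian", "filtered"))
      return("profileKind must be 'gaussian' or 'filtered'")
    TRUE
  })

#' One trial's stimulus
#'
#' Pixel array in gray levels plus the ground truth needed to score a
#' response.  Locations are 1-based `(row, col)` indices into the pixel
#' matrix; `integer(0)` means no target.
#'
#' @slot pixels matrix of gray levels
#' @slot meanLevel background gray level
#' @slot truthPresent whether a target was embedded
#' @slot truthLocation `(row, col)` of the target center, or `integer(0)`
#' @slot task `"detection"`, `"localization"` or `"dandl"`
#' @slot beta background exponent the noise was generated with
#' @slot contrast embedded target contrast
#' @slot seed RNG seed the trial was generated from
#' @slot processed whether the white-to-pink processing filter was applied
#' @export
setClass("StimulusImage",
  representation(pixels = "matrix", meanLevel = "numeric",
                 truthPresent = "logical", truthLocation = "integer",
                 task = "character", beta = "numeric", contrast = "numeric",
                 seed = "integer", processed = "logical"),
  validity = function(object) {
    if (any(!is.finite(object@pixels))) return("pixels must be finite")
    if (!object@truthPresent && length(object@truthLocation) != 0)
      return("absent trials must have empty truthLocation")
    if (object@truthPresent && length(object@truthLocation) != 2)
      return("present trials need a (row, col) truthLocation")
    TRUE
  })

#' Prewhitened matched-filter template
#'
#' The optimal linear weights for a known target in stationary Gaussian
#' noise: frequency weights equal to the target's Fourier transform divided
#' by the noise power spectrum, spatial weights by inverse transform.  The
#' template is stored wrapped at the origin; decision functions shift it to
#' candidate locations by circular indexing.
#'
#' @slot spatialWeights real spatial weights (origin-wrapped)
#' @slot freqWeights complex frequency weights
#' @slot beta noise exponent the template was built for
#' @slot sigmaPixels target scale
#' @slot profileKind target profile kind
#' @export
setClass("IOTemplate",
  representation(spatialWeights = "matrix", freqWeights = "matrix",
                 beta = "numeric", sigmaPixels = "numeric",
                 profileKind = "character"))

#' Localization score map
#'
#' Posterior probability over target locations (uniform prior, zero outside
#' the search region, sums to one) and its convolution with the acceptance
#' disk, which is the quantity the localization ideal observer maximizes.
#'
#' @slot posterior nonnegative matrix summing to 1 over the search region
#' @slot diskScore posterior convolved with the radius-`radiusPx` disk
#' @slot searchMask logical matrix marking the search region
#' @slot radiusPx acceptance radius in pixels
#' @export
setClass("ScoreMap",
  representation(posterior = "matrix", diskScore = "matrix",
                 searchMask = "matrix", radiusPx = "numeric"),
  validity = function(object) {
    if (abs(sum(object@posterior) - 1) > 1e-9)
      return("posterior must sum to 1")
    if (any(object@posterior < 0)) return("posterior must be nonnegative")
    TRUE
  })

#' An observer decision for one trial
#'
#' @slot task the task the decision was made in
#' @slot detected presence response (`NA` for pure localization)
#' @slot location `(row, col)` response, or `integer(0)` for "absent"
#' @slot statistic decision statistic (detection: template inner product;
#'   localization / detect-and-localize: maximum disk score)
#' @slot criterionUsed the criterion the statistic was compared with
#' @export
setClass("IODecision",
  representation(task = "character", detected = "logical",
                 location = "integer", statistic = "numeric",
                 criterionUsed = "numeric"))

#' Monte-Carlo contrast / proportion-correct look-up table
#'
#' @slot task task the table was simulated for
#' @slot beta background exponent
#' @slot contrastGrid increasing contrasts
#' @slot pc estimated proportion correct at each contrast
#' @slot nPerPoint trials per contrast point
#' @slot seed RNG seed
#' @slot shape image side used in the simulation
#' @slot radiusPx acceptance radius
#' @export
setClass("ContrastLUT",
  representation(task = "character", beta = "numeric",
                 contrastGrid = "numeric", pc = "numeric",
                 nPerPoint = "integer", seed = "integer",
                 shape = "integer", radiusPx = "numeric"),
  validity = function(object) {
    if (length(object@contrastGrid) != length(object@pc))
      return("contrastGrid and pc must have equal length")
    if (any(diff(object@contrastGrid) <= 0))
      return("contrastGrid must be strictly increasing")
    if (any(object@pc < 0 | object@pc > 1))
      return("pc must lie in [0, 1]")
    TRUE
  })

#' Fitted cumulative-Gaussian psychometric function
#'
#' Performance model `floor + (1 - floor) * pnorm((c - mu) / sigma)` fit by
#' maximum likelihood to binomial counts.
#'
#' @slot mu location parameter (contrast units)
#' @slot sigma slope parameter (contrast units, > 0)
#' @slot floor chance level
#' @slot nLevels number of contrast levels fit
#' @slot logLik attained binomial log-likelihood
#' @export
setClass("PsychFit",
  representation(mu = "numeric", sigma = "numeric", floor = "numeric",
                 nLevels = "integer", logLik = "numeric"),
  validity = function(object) {
    if (object@sigma <= 0) return("sigma must be positive")
    if (object@floor < 0 || object@floor >= 1)
      return("floor must lie in [0, 1)")
    TRUE
  })

#' Observer efficiency estimate
#'
#' Efficiency is the squared ratio of the ideal observer's threshold
#' contrast to the observer's contrast at matched performance,
#' \eqn{\eta = (C_{IO} / C_{Obs})^2}.
#'
#' @slot eta efficiency (fraction)
#' @slot cObs observer contrast
#' @slot cIO matched ideal-observer contrast
#' @slot perSession session-wise efficiencies (possibly empty)
#' @slot se standard error across sessions (NA if not computed)
#' @slot task,beta condition labels
#' @export
setClass("EfficiencyEstimate",
  representation(eta = "numeric", cObs = "numeric", cIO = "numeric",
                 perSession = "numeric", se = "numeric",
                 task = "character", beta = "numeric"),
  validity = function(object) {
    if (length(object@se) == 1 && !is.na(object@se) && object@se < 0)
      return("se must be nonnegative")
    TRUE
  })

#' Estimated classification image
#'
#' Spatial decision weights estimated from trial-by-trial noise fields and
#' responses, in whitened-noise units.  Centered at the image center
#' (detection) or at the aligned response location (localization).
#'
#' @slot weights spatial weight matrix
#' @slot task,beta condition labels
#' @slot nTrialsUsed number of trials entering the estimate
#' @export
setClass("ClassImage",
  representation(weights = "matrix", task = "character", beta = "numeric",
                 nTrialsUsed = "integer"),
  validity = function(object) {
    if (any(!is.finite(object@weights))) return("weights must be finite")
    TRUE
  })

#' Radially averaged frequency-weight profile
#'
#' @slot freqBins increasing bin centers
#' @slot weights radially averaged weights, peak normalized to 1
#' @slot units frequency units of the bin centers
#' @export
setClass("RadialProfile",
  representation(freqBins = "numeric", weights = "numeric",
                 units = "character"),
  validity = function(object) {
    if (length(object@freqBins) != length(object@weights))
      return("freqBins and weights must have equal length")
    if (any(diff(object@freqBins) <= 0))
      return("freqBins must be increasing")
    TRUE
  })

#' Synthetic (model-human) linear observer
#'
#' A linear-template observer with the suboptimalities commonly invoked for
#' human performance: a possibly mistuned template, additive internal noise
#' on the decision variable, trial-to-trial criterion jitter, and integer
#' motor jitter on localization responses.  With the ideal template and all
#' noise terms at zero it reproduces the ideal observer's decisions (up to
#' the localizer's optional omission of the acceptance-disk integration).
#'
#' @slot freqTemplate complex frequency-domain template (origin-wrapped)
#' @slot templateKind label for the template used
#' @slot internalNoiseSd sd of additive decision noise, in units of the
#'   template statistic's noise sd (scale-free)
#' @slot criterion detection criterion (statistic units)
#' @slot criterionJitterSd sd of trial-to-trial criterion noise (same
#'   relative units as `internalNoiseSd`)
#' @slot motorJitterSd sd of isotropic integer-rounded response jitter (px)
#' @slot diskIntegration whether the localizer performs the acceptance-disk
#'   integration of the posterior (the ideal step); FALSE by default
#' @slot beta condition the template was built for
#' @export
setClass("ObserverModel",
  representation(freqTemplate = "matrix", templateKind = "character",
                 internalNoiseSd = "numeric", criterion = "numeric",
                 criterionJitterSd = "numeric", motorJitterSd = "numeric",
                 diskIntegration = "logical", beta = "numeric"),
  validity = function(object) {
    if (object@internalNoiseSd < 0 || object@criterionJitterSd < 0 ||
        object@motorJitterSd < 0)
      return("noise standard deviations must be nonnegative")
    if (any(!is.finite(Mod(object@freqTemplate))))
      return("template must be finite")
    TRUE
  })

#' Run configuration for the analysis workbench
#'
#' Bundles the condition grid, display geometry and simulation sizes used
#' by the command-line workbench and the reporting helpers.  Defaults are
#' the package's study conditions.
#'
#' @slot tasks,betas condition grid
#' @slot shape image side (px)
#' @slot pixelMm,distanceMm display geometry (effective pixel pitch and
#'   viewing distance, mm)
#' @slot sigmaPixels,meanLevel,rmsContrast target and noise defaults
#' @slot radiusPx acceptance radius (px)
#' @slot nPerPoint,step,stopPC LUT simulation sizes
#' @slot seed base RNG seed
#' @slot outputDir where workbench subcommands write results
#' @export
setClass("RunConfig",
  representation(tasks = "character", betas = "numeric", shape = "integer",
                 pixelMm = "numeric", distanceMm = "numeric",
                 sigmaPixels = "numeric", meanLevel = "numeric",
                 rmsContrast = "numeric", radiusPx = "numeric",
                 nPerPoint = "integer", step = "numeric", stopPC = "numeric",
                 seed = "integer", outputDir = "character"),
  validity = function(object) {
    if (object@pixelMm < 0 || object@distanceMm <= 0 ||
        object@sigmaPixels <= 0 || object@radiusPx <= 0)
      return("geometry parameters must be positive")
    TRUE
  })
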