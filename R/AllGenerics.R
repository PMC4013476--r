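#' @title Accessor generics
#' @description Small accessor API for the package's S4 containers.
#' @param x an object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("spectrumValues", function(x) standardGeneric("spectrumValues"))

#' @rdname accessors
#' @export
setGeneric("noiseExponent", function(x) standardGeneric("noiseExponent"))

#' @rdname accessors
#' @export
setGeneric("truthLocation", function(x) standardGeneric("truthLocation"))

#' @rdname accessors
#' @export
setGeneric("truthPresent", function(x) standardGeneric("truthPresent"))

#' @rdname accessors
#' @export
setGeneric("posterior", function(x) standardGeneric("posterior"))

#' @rdname accessors
#' @export
setGeneric("diskScore", function(x) standardGeneric("diskScore"))

#' @rdname accessors
#' @export
setGeneric("searchMask", function(x) standardGeneric("searchMask"))

#' @rdname accessors
#' @export
setGeneric("spatialWeights", function(x) standardGeneric("spatialWeights"))

#' @rdname accessors
#' @export
setGeneric("freqWeights", function(x) standardGeneric("freqWeights"))

#' @rdname accessors
#' @export
setGeneric("responseLocation", function(x) standardGeneric("responseLocation"))

#' @rdname accessors
#' @export
setGeneric("detected", function(x) standardGeneric("detected"))

#' @rdname accessors
#' @export
setGeneric("decisionStatistic", function(x) standardGeneric("decisionStatistic"))

#' @rdname accessors
#' @export
setGeneric("contrastGrid", function(x) standardGeneric("contrastGrid"))

#' @rdname accessors
#' @export
setGeneric("proportionCorrect", function(x) standardGeneric("proportionCorrect"))

#' @rdname accessors
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))

#' @rdname accessors
#' @export
setGeneric("freqBins", function(x) standardGeneric("freqBins"))

#' @rdname accessors
#' @export
setGeneric("profileWeights", function(x) standardGeneric("profileWeights"))

setMethod("pixels", "StimulusImage", function(x) x@pixels)
setMethod("spectrumValues", "SpectrumGrid", function(x) x@values)
setMethod("noiseExponent", "SpectrumGrid", function(x) x@beta)
setMethod("noiseExponent", "NoiseSpec", function(x) x@beta)
setMethod("noiseExponent", "StimulusImage", function(x) x@beta)
setMethod("noiseExponent", "IOTemplate", function(x) x@beta)
setMethod("truthLocation", "StimulusImage", function(x) x@truthLocation)
setMethod("truthPresent", "StimulusImage", function(x) x@truthPresent)
setMethod("posterior", "ScoreMap", function(x) x@posterior)
setMethod("diskScore", "ScoreMap", function(x) x@diskScore)
setMethod("searchMask", "ScoreMap", function(x) x@searchMask)
setMethod("spatialWeights", "IOTemplate", function(x) x@spatialWeights)
setMethod("freqWeights", "IOTemplate", function(x) x@freqWeights)
setMethod("responseLocation", "IODecision", function(x) x@location)
setMethod("detected", "IODecision", function(x) x@detected)
setMethod("decisionStatistic", "IODecision", function(x) x@statistic)
setMethod("contrastGrid", "ContrastLUT", function(x) x@contrastGrid)
setMethod("proportionCorrect", "ContrastLUT", function(x) x@pc)
setMethod("efficiency", "EfficiencyEstimate", function(x) x@eta)
setMethod("freqBins", "RadialProfile", function(x) x@freqBins)
setMethod("profileWeights", "RadialProfile", function(x) x@weights)

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf(
    "NoiseSpec: beta = %g, %d x %d px, mean %g gl, RMS contrast %g\n",
    object@beta, object@shape, object@shape, object@meanLevel,
    object@rmsContrast))
})

setMethod("show", "SpectrumGrid", function(object) {
  cat(sprintf(
    "SpectrumGrid: beta = %g on a %d x %d DFT grid (C_beta = %.4g, DC: %s)\n",
    object@beta, object@shape, object@shape, object@normConstant,
    object@dcRule))
  cat(sprintf("  implied pixel variance: %.6g gl^2\n", mean(object@values)))
})

setMethod("show", "StimulusImage", function(object) {
  loc <- if (length(object@truthLocation))
    sprintf("(%d, %d)", object@truthLocation[1], object@truthLocation[2])
  else "none"
  cat(sprintf(
    "StimulusImage: %s task, beta = %g, contrast %.3g, %d x %d px\n",
    object@task, object@beta, object@contrast,
    nrow(object@pixels), ncol(object@pixels)))
  cat(sprintf("  target %s at %s%s; seed %d\n",
              if (object@truthPresent) "present" else "absent", loc,
              if (object@processed) " [processed]" else "", object@seed))
})

setMethod("show", "IOTemplate", function(object) {
  cat(sprintf(
    "IOTemplate: prewhitened %s target, beta = %g, %d x %d px\n",
    object@profileKind, object@beta,
    nrow(object@spatialWeights), ncol(object@spatialWeights)))
})

setMethod("show", "ScoreMap", function(object) {
  cat(sprintf(
    "ScoreMap: %d x %d, acceptance radius %g px, max disk score %.4g\n",
    nrow(object@posterior), ncol(object@posterior), object@radiusPx,
    max(object@diskScore[object@searchMask])))
})

setMethod("show", "IODecision", function(object) {
  loc <- if (length(object@location))
    sprintf(" at (%d, %d)", object@location[1], object@location[2]) else ""
  det <- if (is.na(object@detected)) "" else
    sprintf("%s", if (object@detected) "present" else "absent")
  cat(sprintf("IODecision [%s]: %s%s (statistic %.4g)\n",
              object@task, det, loc, object@statistic))
})

setMethod("show", "ContrastLUT", function(object) {
  cat(sprintf(
    "ContrastLUT: %s, beta = %g; %d contrasts in [%.3g, %.3g], n = %d/point\n",
    object@task, object@beta, length(object@contrastGrid),
    min(object@contrastGrid), max(object@contrastGrid), object@nPerPoint))
})

setMethod("show", "PsychFit", function(object) {
  cat(sprintf(
    "PsychFit: floor %.3g + %.3g * Phi((c - %.4g) / %.4g), logLik %.3f\n",
    object@floor, 1 - object@floor, object@mu, object@sigma, object@logLik))
})

setMethod("show", "EfficiencyEstimate", function(object) {
  se <- if (is.na(object@se)) "" else sprintf(" +/- %.1f%%", 100 * object@se)
  cat(sprintf(
    "EfficiencyEstimate [%s, beta = %g]: eta = %.1f%%%s (C_IO %.4g / C_Obs %.4g)\n",
    object@task, object@beta, 100 * object@eta, se, object@cIO, object@cObs))
})

setMethod("show", "ClassImage", function(object) {
  cat(sprintf("ClassImage [%s, beta = %g]: %d x %d, %d trials\n",
              object@task, object@beta, nrow(object@weights),
              ncol(object@weights), object@nTrialsUsed))
})

setMethod("show", "RadialProfile", function(object) {
  pk <- object@freqBins[which.max(object@weights)]
  cat(sprintf("RadialProfile: %d bins up to %.3g %s, peak at %.3g %s\n",
              length(object@freqBins), max(object@freqBins), object@units,
              pk, object@units))
})

setMethod("show", "ObserverModel", function(object) {
  cat(sprintf(
    "ObserverModel: %s template (beta = %g), internal sd %.3g, criterion %.4g (jitter %.3g), motor sd %.3g px%s\n",
    object@templateKind, object@beta, object@internalNoiseSd,
    object@criterion, object@criterionJitterSd, object@motorJitterSd,
    if (object@diskIntegration) ", disk integration" else ""))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig: tasks {%s} x beta {%s}; %d px images, pixel %.3g mm at %.0f mm\n",
    paste(object@tasks, collapse = ", "),
    paste(object@betas, collapse = ", "),
    object@shape, object@pixelMm, object@distanceMm))
  cat(sprintf("  LUT: n = %d, step %.3g, stop at PC > %.2f; seed %d; out: %s\n",
              object@nPerPoint, object@step, object@stopPC, object@seed,
              object@outputDir))
})
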