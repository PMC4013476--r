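# Synthetic (model-human) observer: a linear template with internal noise,
# criterion jitter and motor jitter.  Its efficiency has a closed form, so
# the whole efficiency pipeline can be validated against ground truth
# without human data.

#' Construct a synthetic linear observer
#'
#' @param template an [IOTemplate-class] (typically the ideal template or
#'   a distorted one from [distortTemplate()]).
#' @param internalNoiseSd sd of additive decision noise, expressed as a
#'   multiple of the template statistic's noise sd (so 1 doubles the
#'   decision variance); applied per pixel of the response map for
#'   localization tasks.
#' @param criterion detection criterion in statistic units (see
#'   [observerUnbiasedCriterion()] for the midpoint value).
#' @param criterionJitterSd sd of trial-to-trial criterion noise, in the
#'   same relative units as `internalNoiseSd`.
#' @param motorJitterSd sd of the isotropic, integer-rounded jitter added
#'   to localization responses (pixels).
#' @param diskIntegration if TRUE the localizer performs the full
#'   acceptance-disk posterior integration (the ideal computation); the
#'   default FALSE takes the argmax of the raw template response map, a
#'   principled suboptimality whose cost is small at these parameters.
#' @param templateKind label recorded with the model.
#' @return An [ObserverModel-class].
#' @export
observerModel <- function(template, internalNoiseSd = 0, criterion = 0,
                          criterionJitterSd = 0, motorJitterSd = 0,
                          diskIntegration = FALSE, templateKind = "io") {
  stopifnot(is(template, "IOTemplate"))
  new("ObserverModel", freqTemplate = template@freqWeights,
      templateKind = templateKind,
      internalNoiseSd = internalNoiseSd, criterion = criterion,
      criterionJitterSd = criterionJitterSd, motorJitterSd = motorJitterSd,
      diskIntegration = diskIntegration, beta = template@beta)
}

#' Distort an ideal template
#'
#' Produces mistuned linear templates emulating suboptimal human tuning:
#' * `"lowfreqSuppressed"` multiplies the frequency weights by
#'   `f^2 / (f^2 + f0^2)` (suppresses low spatial frequencies, the
#'   signature seen in white-noise conditions), `amount` = f0 in
#'   cycles/pixel;
#' * `"peakShifted"` multiplies by `f^amount`, moving the peak to higher
#'   frequencies;
#' * `"io"` returns the template unchanged.
#'
#' A template built for one beta and applied across conditions ("fixed
#' template") is obtained by simply passing that template to
#' [observerModel()] for another condition's stimuli.
#'
#' @param template an [IOTemplate-class].
#' @param kind distortion kind.
#' @param amount distortion strength (see above; 0 is the identity).
#' @return The distorted [IOTemplate-class].
#' @export
distortTemplate <- function(template,
                            kind = c("lowfreqSuppressed", "peakShifted",
                                     "io"),
                            amount = 0.05) {
  kind <- match.arg(kind)
  if (kind == "io" || amount == 0) return(template)
  n <- nrow(template@freqWeights)
  f <- radialFreqGrid(n)
  g <- switch(kind,
    lowfreqSuppressed = f^2 / (f^2 + amount^2),
    peakShifted = {fk <- f; fk[1, 1] <- 1 / n; fk^amount})
  fw <- template@freqWeights * g
  initialize(template, freqWeights = fw,
             spatialWeights = Re(ifft2(fw)))
}

# Noise sd of the template statistic w'n: sqrt(w' Sigma w) in the
# package's DFT scaling.  Used to express internal noise in scale-free
# units and to predict performance.
templateStatSd <- function(freqTemplate, spectrum) {
  sqrt(mean(Mod(freqTemplate)^2 * spectrum@values))
}

# w's for a unit-peak profile: the statistic's mean per unit amplitude.
templateSignalGain <- function(freqTemplate, target, spectrum) {
  s0 <- targetProfileOrigin(target, spectrum@shape)
  Re(mean(Conj(freqTemplate) * fft2(s0)))
}

#' Closed-form efficiency of a linear observer
#'
#' For a linear template w with additive internal (and criterion) noise,
#' detection performance is Gaussian with detectability
#' `d' = a w's / sqrt(w' Sigma w + sd_int^2 + sd_jit^2)`, so matching the
#' ideal observer's rates gives the analytic efficiency
#' \deqn{\eta^* = \frac{(w's)^2}{(w'\Sigma w + \sigma^2_{int} +
#'   \sigma^2_{jit}) \; s'\Sigma^{-1} s}.}
#' This is the ground-truth oracle the measured efficiency pipeline is
#' validated against.
#'
#' @param model an [ObserverModel-class].
#' @param target a [TargetSpec-class].
#' @param spectrum the condition's [SpectrumGrid-class].
#' @return Efficiency in (0, 1].
#' @export
linearObserverEfficiency <- function(model, target, spectrum) {
  wTs <- templateSignalGain(model@freqTemplate, target, spectrum)
  sdMap <- templateStatSd(model@freqTemplate, spectrum)
  varTot <- sdMap^2 * (1 + model@internalNoiseSd^2 +
                         model@criterionJitterSd^2)
  wTs^2 / (varTot * templateEnergy(target, spectrum))
}

#' Midpoint criterion for a synthetic observer
#'
#' Half the mean statistic on target-present trials,
#' `contrast * meanLevel * w's / 2`: the unbiased detection criterion for
#' the model's own template.
#'
#' @param model an [ObserverModel-class].
#' @param target a [TargetSpec-class] (its contrast is used).
#' @param spectrum the condition's [SpectrumGrid-class].
#' @param meanLevel background gray level.
#' @return Criterion in statistic units.
#' @export
observerUnbiasedCriterion <- function(model, target, spectrum,
                                      meanLevel = 100) {
  target@contrast * meanLevel *
    templateSignalGain(model@freqTemplate, target, spectrum) / 2
}

# one trial record row (coordinates 0-based x = col, y = row in exports)
.recordRow <- function(stim, detectedResp, respLoc, statistic, session,
                       correct) {
  tl <- stim@truthLocation
  data.frame(
    task = stim@task, beta = stim@beta, contrast = stim@contrast,
    present = stim@truthPresent,
    loc_x = if (length(tl)) tl[2] - 1L else NA_integer_,
    loc_y = if (length(tl)) tl[1] - 1L else NA_integer_,
    response_x = if (length(respLoc)) respLoc[2] - 1L else NA_integer_,
    response_y = if (length(respLoc)) respLoc[1] - 1L else NA_integer_,
    detected = detectedResp, statistic = statistic, correct = correct,
    session = session, seed = stim@seed, processed = stim@processed,
    stringsAsFactors = FALSE)
}

#' Synthetic-observer response to a detection trial
#'
#' Statistic = template correlation at the cued center plus internal
#' noise; the response is "present" iff it exceeds the criterion plus a
#' criterion-jitter draw.  With the ideal template, zero noise and a fixed
#' criterion this reproduces [detectTarget()] exactly.
#'
#' @param stim a [StimulusImage-class].
#' @param model an [ObserverModel-class].
#' @param spectrum the condition's [SpectrumGrid-class] (sets the internal
#'   noise scale).
#' @param seed integer seed for the observer's noise draws (`NULL`
#'   continues the RNG stream).
#' @param session session label stored in the record.
#' @return One trial-record data frame row.
#' @export
respondDetection <- function(stim, model, spectrum, seed = NULL,
                             session = 1L) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(stim@pixels)
  sdMap <- templateStatSd(model@freqTemplate, spectrum)
  m <- corrMap(model@freqTemplate, stim@pixels - stim@meanLevel)
  stat <- m[n / 2 + 1, n / 2 + 1] +
    stats::rnorm(1, 0, model@internalNoiseSd * sdMap)
  crit <- model@criterion +
    stats::rnorm(1, 0, model@criterionJitterSd * sdMap)
  resp <- stat > crit
  .recordRow(stim, resp, integer(0), stat, session,
             correct = (resp == stim@truthPresent))
}

# shared localization machinery: response map, argmax, motor jitter
.locRespond <- function(stim, model, spectrum, radiusPx) {
  n <- nrow(stim@pixels)
  sdMap <- templateStatSd(model@freqTemplate, spectrum)
  m <- corrMap(model@freqTemplate, stim@pixels - stim@meanLevel)
  if (model@internalNoiseSd > 0)
    m <- m + matrix(stats::rnorm(n * n, 0, model@internalNoiseSd * sdMap),
                    n, n)
  mask <- cachedMask(n)
  if (model@diskIntegration) {
    a <- stim@contrast * stim@meanLevel
    e <- a * m
    e <- e - max(e[mask])
    p <- exp(e)
    p[!mask] <- 0
    p <- p / sum(p)
    m <- Re(ifft2(fft2(p) * cachedDiskF(n, radiusPx)))
  }
  m[!mask] <- -Inf
  loc <- rowMajorArgmax(m)
  if (model@motorJitterSd > 0) {
    b <- searchRegionBounds(n)
    loc <- round(loc + stats::rnorm(2, 0, model@motorJitterSd))
    loc <- pmin(pmax(loc, b["lo"]), b["hi"])
  }
  list(loc = as.integer(loc), max = m[loc[1], loc[2]],
       maxRaw = max(m[is.finite(m)]), sdMap = sdMap)
}

#' Synthetic-observer response to a free-localization trial
#'
#' The response map is the template correlation plus an independent white
#' internal-noise map; the response is its argmax over the search region
#' (without the acceptance-disk integration unless the model requests it),
#' plus integer-rounded motor jitter clipped to the region.
#'
#' @inheritParams respondDetection
#' @param radiusPx acceptance radius used to score correctness.
#' @return One trial-record data frame row.
#' @export
respondLocalization <- function(stim, model, spectrum, seed = NULL,
                                session = 1L, radiusPx = 5) {
  if (!is.null(seed)) set.seed(seed)
  r <- .locRespond(stim, model, spectrum, radiusPx)
  tl <- stim@truthLocation
  correct <- length(tl) == 2 && sum((r$loc - tl)^2) <= radiusPx^2
  .recordRow(stim, NA, r$loc, r$max, session, correct)
}

#' Synthetic-observer response to a detect-and-localize trial
#'
#' As [respondLocalization()], but the maximum of the response map is
#' first compared with the criterion (plus jitter): below it the observer
#' responds "target absent".
#'
#' @inheritParams respondLocalization
#' @return One trial-record data frame row.
#' @export
respondDandl <- function(stim, model, spectrum, seed = NULL, session = 1L,
                         radiusPx = 5) {
  if (!is.null(seed)) set.seed(seed)
  r <- .locRespond(stim, model, spectrum, radiusPx)
  crit <- model@criterion +
    stats::rnorm(1, 0, model@criterionJitterSd * r$sdMap)
  hit <- r$maxRaw > crit
  tl <- stim@truthLocation
  correct <- if (hit)
    length(tl) == 2 && sum((r$loc - tl)^2) <= radiusPx^2
  else
    length(tl) == 0
  .recordRow(stim, hit, if (hit) r$loc else integer(0), r$maxRaw,
             session, correct)
}

#' Run a synthetic-observer experiment
#'
#' Generates a full trial table for one task and condition: `nPerLevel`
#' trials at each contrast, grouped into sessions (blocks) of
#' `blockSize` trials, every trial reproducible from the base seed.  The
#' standard psychometric design is 5 levels x 200 trials; threshold-level
#' efficiency runs use one contrast and 2000 trials in 40 sessions of 50.
#'
#' @param task `"detection"`, `"localization"` or `"dandl"`.
#' @param model an [ObserverModel-class].
#' @param noise a [NoiseSpec-class].
#' @param sigmaPixels target scale.
#' @param contrasts vector of contrast levels.
#' @param nPerLevel trials per level.
#' @param blockSize trials per session label.
#' @param seed base seed; trial seeds derive from it.
#' @param radiusPx acceptance radius for scoring.
#' @param keepNoise if TRUE, also return the per-trial noise fields (for
#'   classification images); memory scales with `nPerLevel`.
#' @return A trial-record data frame, with the noise fields in
#'   `attr(, "noiseFields")` when requested.
#' @export
runExperiment <- function(task, model, noise = noiseSpec(),
                          sigmaPixels = 3, contrasts, nPerLevel = 200L,
                          blockSize = 50L, seed = 1L, radiusPx = 5,
                          keepNoise = FALSE) {
  sp <- buildSpectrum(noise)
  rows <- vector("list", length(contrasts) * nPerLevel)
  fields <- if (keepNoise) vector("list", length(rows)) else NULL
  k <- 0L
  for (ci in contrasts) {
    tg <- targetSpec(sigmaPixels = sigmaPixels, contrast = ci)
    s0 <- targetProfileOrigin(tg, noise@shape)
    for (i in seq_len(nPerLevel)) {
      k <- k + 1L
      sd1 <- deriveSeed(seed, 2L * k)
      stim <- makeTrial(task, noise, tg, seed = sd1)
      row <- switch(task,
        detection = respondDetection(stim, model, sp,
                                     seed = deriveSeed(seed, 2L * k + 1L)),
        localization = respondLocalization(stim, model, sp,
                                           seed = deriveSeed(seed, 2L * k + 1L),
                                           radiusPx = radiusPx),
        dandl = respondDandl(stim, model, sp,
                             seed = deriveSeed(seed, 2L * k + 1L),
                             radiusPx = radiusPx))
      row$session <- (i - 1L) %/% blockSize + 1L
      row$trial_id <- k
      rows[[k]] <- row
      if (keepNoise) {
        tl <- stim@truthLocation
        f <- stim@pixels - noise@meanLevel
        if (length(tl))
          f <- f - ci * noise@meanLevel *
            circShift(s0, tl[1] - 1L, tl[2] - 1L)
        fields[[k]] <- f
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("trial_id", setdiff(names(out), "trial_id"))]
  if (keepNoise) attr(out, "noiseFields") <- fields
  out
}
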