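# Geometry, configuration, and file formats tying the pipeline together.

#' Degrees of visual angle subtended by one pixel
#'
#' `(180 / pi) * atan(pixelMm / distanceMm)`.  The defaults are the
#' package's display geometry -- an effective pixel pitch of 0.583 mm
#' viewed at 640 mm -- giving 0.052 degrees per pixel.
#'
#' @param pixelMm effective pixel pitch in mm (>= 0).
#' @param distanceMm viewing distance in mm (> 0).
#' @return Degrees per pixel.
#' @examples
#' pixelAngle()            # 0.0522
#' @export
pixelAngle <- function(pixelMm = 0.583, distanceMm = 640) {
  if (pixelMm < 0 || distanceMm <= 0)
    stop("pixelMm must be nonnegative and distanceMm positive")
  (180 / pi) * atan(pixelMm / distanceMm)
}

#' Create a run configuration
#'
#' @param tasks,betas the condition grid.
#' @param shape image side length (px).
#' @param pixelMm,distanceMm display geometry.
#' @param sigmaPixels,meanLevel,rmsContrast target and noise defaults.
#' @param radiusPx acceptance radius (px).
#' @param nPerPoint,step,stopPC LUT simulation sizes.
#' @param seed base seed recorded in every output.
#' @param outputDir output directory for the workbench subcommands.
#' @return A [RunConfig-class].
#' @export
runConfig <- function(tasks = c("detection", "localization", "dandl"),
                      betas = c(0, 1, 2, 3), shape = 256L,
                      pixelMm = 0.583, distanceMm = 640,
                      sigmaPixels = 3, meanLevel = 100, rmsContrast = 0.2,
                      radiusPx = 5, nPerPoint = 2000L, step = 0.01,
                      stopPC = 0.94, seed = 1L, outputDir = ".") {
  new("RunConfig", tasks = tasks, betas = betas, shape = as.integer(shape),
      pixelMm = pixelMm, distanceMm = distanceMm,
      sigmaPixels = sigmaPixels, meanLevel = meanLevel,
      rmsContrast = rmsContrast, radiusPx = radiusPx,
      nPerPoint = as.integer(nPerPoint), step = step, stopPC = stopPC,
      seed = as.integer(seed), outputDir = outputDir)
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @param config a [RunConfig-class].
#' @return `readRunConfig` returns a [RunConfig-class];
#'   `writeRunConfig` returns `path` invisibly.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(runConfig, y)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  sl <- slotNames(config)
  y <- lapply(sl, function(s) slot(config, s))
  names(y) <- sl
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialization; embedded in output files so
#' re-runs can be matched to their configuration.
#'
#' @param config a [RunConfig-class].
#' @return Hex string.
#' @export
configHash <- function(config) {
  sl <- slotNames(config)
  y <- lapply(sl, function(s) slot(config, s))
  names(y) <- sl
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(y, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Write / read trial records as CSV
#'
#' Comma-separated, UTF-8, header row, '.' decimal.  Coordinates are
#' 0-based `(x = column, y = row)` with the origin at the top-left pixel.
#' Writing is byte-deterministic for identical inputs.
#'
#' @param records trial-record data frame.
#' @param path file path.
#' @return `readTrialRecords` returns the data frame; `writeTrialRecords`
#'   returns `path` invisibly.
#' @export
writeTrialRecords <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTrialRecords
#' @export
readTrialRecords <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a look-up table to JSON
#'
#' Grids, estimates, and the seed and trial counts needed to reproduce
#' them.
#'
#' @param lut a [ContrastLUT-class].
#' @param path file path.
#' @return `readLUT` returns a [ContrastLUT-class]; `writeLUT` returns
#'   `path` invisibly.
#' @export
writeLUT <- function(lut, path) {
  x <- list(task = lut@task, beta = lut@beta,
            contrast = lut@contrastGrid, pc = lut@pc,
            n_per_point = lut@nPerPoint, seed = lut@seed,
            shape = lut@shape, radius_px = lut@radiusPx)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLUT
#' @export
readLUT <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ContrastLUT", task = x$task, beta = x$beta,
      contrastGrid = x$contrast, pc = x$pc,
      nPerPoint = as.integer(x$n_per_point), seed = as.integer(x$seed),
      shape = as.integer(x$shape), radiusPx = x$radius_px)
}

#' Export a stimulus as a 16-bit grayscale PNG
#'
#' Gray levels are mapped linearly by `pixels / (2 * meanLevel)` (so the
#' mean background sits at half range) and clipped to `[0, 1]`; the
#' scaling is for preview purposes only -- use [saveStimulusArray()] for a
#' lossless record.
#'
#' @param stim a [StimulusImage-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStimulusPNG <- function(stim, path) {
  img <- stim@pixels / (2 * stim@meanLevel)
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path, dpi = NULL)
  invisible(path)
}

#' Lossless stimulus export
#'
#' Saves the full object (pixels and ground-truth metadata) in R's
#' platform-neutral serialization format, with the trial metadata also
#' written to a CSV sidecar (`<path>.csv`): columns `trial_id, task,
#' beta, contrast, present, loc_x, loc_y, seed, processed`, coordinates
#' 0-based `(x = column, y = row)`.
#'
#' @param stim a [StimulusImage-class].
#' @param path output path (`.rds`).
#' @param trialId identifier written to the sidecar.
#' @return `path`, invisibly.
#' @export
saveStimulusArray <- function(stim, path, trialId = 1L) {
  saveRDS(stim, path)
  tl <- stim@truthLocation
  meta <- data.frame(
    trial_id = trialId, task = stim@task, beta = stim@beta,
    contrast = stim@contrast, present = stim@truthPresent,
    loc_x = if (length(tl)) tl[2] - 1L else NA_integer_,
    loc_y = if (length(tl)) tl[1] - 1L else NA_integer_,
    seed = stim@seed, processed = stim@processed)
  utils::write.csv(meta, paste0(path, ".csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
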