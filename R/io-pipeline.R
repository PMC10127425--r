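# Shared I/O and the pipeline front end. CSV is the single tabular
# interchange format; images are PNG (8-bit RGB) with single-channel PNG
# masks; the run manifest is JSON. All randomness flows from seeds named in
# the configuration.

#' Read a spectrum from CSV
#'
#' Expects a header row and two numeric columns (wavelength in nm, value).
#' Rows out of wavelength order are sorted with a warning; duplicate
#' wavelengths and non-numeric entries are errors (with the offending line
#' numbers).
#'
#' @param path file path.
#' @return A [Spectrum-class].
#' @export
readSpectrumCSV <- function(path) {
  if (!file.exists(path)) stop(sprintf("spectrum file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character")
  if (ncol(raw) < 2) stop("spectrum CSV needs two columns (wavelength, value)")
  w <- suppressWarnings(as.numeric(raw[[1]]))
  v <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(w) | is.na(v))
  if (length(bad) > 0)
    stop(sprintf("non-numeric spectrum rows at line(s): %s",
                 paste(bad + 1, collapse = ", ")))
  if (anyDuplicated(w))
    stop(sprintf("duplicate wavelengths at line(s): %s",
                 paste(which(duplicated(w)) + 1, collapse = ", ")))
  if (is.unsorted(w)) {
    warning("wavelengths out of order: sorting ascending")
    o <- order(w); w <- w[o]; v <- v[o]
  }
  Spectrum(w, v)
}

#' Write a spectrum to CSV
#'
#' Two columns, `wavelength_nm` and `value`; the inverse of
#' [readSpectrumCSV()] (round-trip identity).
#'
#' @param spectrum a [Spectrum-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectrumCSV <- function(spectrum, path) {
  utils::write.csv(data.frame(wavelength_nm = spectrum@wavelength,
                              value = spectrum@values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write / read a synthetic fish image and its masks
#'
#' The image is written as 8-bit RGB PNG, the masks as single-channel PNGs,
#' and the ground truth as a JSON sidecar.
#'
#' @param sim a [FishImageSim-class].
#' @param prefix output path prefix; writes `<prefix>.png`,
#'   `<prefix>_body.png`, `<prefix>_belly.png`, `<prefix>_truth.json`.
#' @return The image path, invisibly.
#' @export
writeFishImage <- function(sim, prefix) {
  png::writePNG(sim@image, paste0(prefix, ".png"))
  png::writePNG(sim@bodyMask * 1, paste0(prefix, "_body.png"))
  png::writePNG(sim@bellyMask * 1, paste0(prefix, "_belly.png"))
  truth <- sim@truth
  truth$patchMask <- NULL  # masks live in their own files
  truth$whitePatch <- as.integer(sim@whitePatch)
  jsonlite::write_json(truth, paste0(prefix, "_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, ".png"))
}

#' Read an RGB image (PNG or TIFF)
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return Numeric array (h x w x 3) in \[0, 1\].
#' @export
readFishImage <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  ext <- tolower(sub(".*\\.", "", path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF images")
    tiff::readTIFF(path)
  } else stop(sprintf("unsupported image format: .%s", ext))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Pipeline configuration
#'
#' Collects the knobs of a full synthetic run: the simulation config, HSB
#' thresholds, receptor peaks, bootstrap size and seed.
#'
#' @param sim a [simConfig()].
#' @param truth an [imageGroundTruth()] for the photo stage.
#' @param thresholds a [colorThresholds()] (default [maleThresholds()]).
#' @param lambdaMax receptor peaks, nm.
#' @param nBoot bootstrap draws for repeatability.
#' @param alpha significance level for reporting.
#' @param seed master seed.
#' @return A validated list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(sim = simConfig(), truth = imageGroundTruth(),
                           thresholds = maleThresholds(),
                           lambdaMax = c(455, 518, 560),
                           nBoot = 500, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(sim, "simConfig"), inherits(truth, "imageGroundTruth"),
            inherits(thresholds, "colorThresholds"),
            length(lambdaMax) == 3, nBoot >= 100,
            alpha > 0, alpha < 1, seed == round(seed))
  structure(list(sim = sim, truth = truth, thresholds = thresholds,
                 lambdaMax = lambdaMax, nBoot = nBoot, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in order on data generated from the
#' configuration -- `simulate` (write images/spectra/tables), `photo` (the
#' image chain), `spectra` (the visual model), `rpt` (repeatability) and
#' `stats` (the dominance models) -- writing each stage's CSV outputs and a
#' JSON run manifest (configuration echo, seed, package version, warnings)
#' to `outDir`. A stage failure aborts with a stage-named error; stages
#' already written remain and are listed in the manifest as completed.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if missing).
#' @param stages character vector of stage names, in order.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
                        stages = c("simulate", "photo", "spectra", "rpt",
                                   "stats")) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  done <- character(0)
  warnings <- character(0)
  logw <- function(w) warnings <<- c(warnings, conditionMessage(w))
  runStage <- function(name, fun) {
    if (!name %in% stages) return()
    withCallingHandlers(
      tryCatch(fun(), error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) { logw(w); invokeRestart("muffleWarning") })
    done <<- c(done, name)
  }

  sim <- NULL; repData <- NULL; dyad <- NULL; spectra <- NULL

  runStage("simulate", function() {
    truth <- config$truth; truth$seed <- config$seed
    sim <<- genFishImage(truth)
    writeFishImage(sim, file.path(outDir, "fish"))
    cfg <- config$sim; cfg$seed <- config$seed
    repData <<- genRepeatedMeasures(cfg)
    utils::write.csv(repData, file.path(outDir, "repeated_measures.csv"),
                     row.names = FALSE)
    dyad <<- genDyadData(cfg)
    utils::write.csv(dyad, file.path(outDir, "dyads.csv"), row.names = FALSE)
    spectra <<- genReflectanceSet(seed = config$seed)
    for (i in seq_along(spectra))
      writeSpectrumCSV(spectra[[i]],
                       file.path(outDir, sprintf("reflectance_%02d.csv", i)))
  })
  runStage("photo", function() {
    if (is.null(sim))
      sim <<- genFishImage(`class<-`(modifyList(unclass(config$truth),
        list(seed = config$seed)), "imageGroundTruth"))
    m <- measureFishImage(sim, thresholds = config$thresholds)
    m <- cbind(data.frame(id = "fish", rca_truth = sim@truth$rca), m)
    utils::write.csv(m, file.path(outDir, "photo_measurements.csv"),
                     row.names = FALSE)
  })
  runStage("spectra", function() {
    if (is.null(spectra)) spectra <<- genReflectanceSet(seed = config$seed)
    res <- spectraPipeline(spectra, genIllumination("lens"),
                           genIllumination("irradiance"),
                           receptorSet(config$lambdaMax))
    pt <- res$point
    utils::write.csv(data.frame(
      id = "fish", Q1 = res$Q[1], Q2 = res$Q[2], Q3 = res$Q[3],
      q1 = pt@q[1], q2 = pt@q[2], q3 = pt@q[3],
      x = pt@xy[1], y = pt@xy[2], r = pt@r, hue = pt@hueAngle, r_A = pt@rA),
      file.path(outDir, "visual_model.csv"), row.names = FALSE)
  })
  runStage("rpt", function() {
    if (is.null(repData)) {
      cfg <- config$sim; cfg$seed <- config$seed
      repData <<- genRepeatedMeasures(cfg)
    }
    r <- rptGaussian(repData$value, repData$id, nBoot = config$nBoot,
                     seed = config$seed)
    utils::write.csv(data.frame(
      variable = "value", n = r@nGroups, R = r@R, SE = r@SE,
      CI_lower = r@CI[1], CI_upper = r@CI[2], p = r@p),
      file.path(outDir, "repeatability.csv"), row.names = FALSE)
  })
  runStage("stats", function() {
    if (is.null(dyad)) {
      cfg <- config$sim; cfg$seed <- config$seed
      dyad <<- genDyadData(cfg)
    }
    glmm <- fitDominanceGLMM(dyad)
    glmm$model <- "dominance_glmm"
    lmmAll <- do.call(rbind, lapply(c("RCA", "LC"), function(rv) {
      x <- fitColorLMM(dyad, response = rv, subset = "all")
      x$model <- paste0(rv, "_all"); x
    }))
    lmmSub <- do.call(rbind, lapply(c("RCA", "LC"), function(rv)
      do.call(rbind, lapply(c("dominant", "subordinate"), function(ss) {
        x <- fitColorLMM(dyad, response = rv, subset = ss)
        x$model <- paste(rv, ss, sep = "_"); x
      }))))
    res <- rbind(glmm, lmmAll, lmmSub)
    utils::write.csv(res[, c("model", "term", "chisq", "df", "p", "sign")],
                     file.path(outDir, "model_terms.csv"), row.names = FALSE)
    cm <- correlationMatrix(dyad[, c("SL", "CI", "LC", "RCA")],
                            alpha = config$alpha)
    utils::write.csv(as.data.frame(cm$r),
                     file.path(outDir, "correlation_r.csv"))
    utils::write.csv(as.data.frame(cm$p),
                     file.path(outDir, "correlation_p.csv"))
  })

  manifest <- list(
    package = "chromaFish",
    version = as.character(utils::packageVersion("chromaFish")),
    seed = config$seed,
    stagesRequested = stages,
    stagesCompleted = done,
    config = list(sim = unclass(config$sim),
                  truth = unclass(config$truth),
                  thresholds = unclass(config$thresholds),
                  lambdaMax = config$lambdaMax, nBoot = config$nBoot,
                  alpha = config$alpha),
    warnings = warnings)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
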