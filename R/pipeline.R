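#' Default run configuration
#'
#' Nested per-stage configuration for [runPipeline]: the simulated modes,
#' the synthetic image/network/proteome generators and the quantification
#' parameters. Values can be overridden by editing the list or a YAML copy
#' ([saveRunConfig] / [loadRunConfig] round-trip losslessly).
#'
#' @return Nested configuration list.
#' @export
defaultRunConfig <- function() {
  list(
    simulate = list(shape = "round", m = 0L, n = 4L, chamberDim = 21,
                    gridResolution = 512L),
    image = list(geometry = "rings", imageSize = 1024L, pixelPitch = 2.5,
                 cellRadius = 7.5, lineWidth = 100,
                 backgroundFraction = 0.05, enhancementPct = 438),
    network = list(days = c(1L, 3L, 5L), condition = "patterned",
                   ribbonCount = 30L, imageSize = 512L, pixelPitch = 1.25),
    proteome = list(nProteins = 4000L, nUp = 643L, nDown = 261L,
                    effectMean = 2, effectSd = 0.3, residualSd = 0.25),
    ## ring peaks are ~5x background, so ring detection uses a high
    ## prominence; smoothWindow in profile samples
    quantify = list(dr = 2.5, prominence = 0.5, smoothWindow = 15L,
                    sigmaPx = 4, energyThreshold = 0.30),
    de = list(alpha = 0.05, varEqual = FALSE))
}

#' Load / save a run configuration as YAML
#'
#' @param path YAML path.
#' @return `loadRunConfig` returns the configuration list; `saveRunConfig`
#'   returns `path` invisibly.
#' @export
loadRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname loadRunConfig
#' @param config configuration list.
#' @export
saveRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full simulate - synthesize - quantify - test pipeline
#'
#' Executes the stages in order on synthetic data, with every stochastic
#' stage seeded deterministically from `seed`: (1) simulate the configured
#' standing mode and extract its nodal set; (2) generate the patterned image
#' plus stationary control, day 1/3/5 ribbon networks and the two-group
#' proteome; (3) quantify — radial profile peaks, per-ring FWHM,
#' valley-to-peak ratio, ROI density enhancement for the first and second
#' rings (rings geometry only), local-thickness statistics per day,
#' orientation distribution; (4) differential expression and PCA. Given the
#' same `(config, seed)` the report tables are identical between runs.
#'
#' @param config configuration list, see [defaultRunConfig].
#' @param seed master seed; stage seeds are derived as `seed * 100 + offset`.
#' @param outDir optional output directory; when given, report tables are
#'   written as CSV and the run manifest as JSON.
#' @return List with `report` (named list of data.frames), `manifest`
#'   (config echo, stage seeds, package version) and the intermediate
#'   objects (`field`, `nodal`, `images`, `proteome`, `de`).
#' @export
runPipeline <- function(config = defaultRunConfig(), seed = 1L,
                        outDir = NULL) {
  seed <- as.integer(seed)
  stageSeed <- function(k) seed * 100L + k
  report <- list()

  ## -- simulate ---------------------------------------------------------
  sim <- config$simulate
  mspec <- ModeSpec(sim$shape, sim$m, sim$n, sim$chamberDim,
                    sim$gridResolution)
  field <- if (sim$shape == "round") roundModeField(mspec)
           else squareModeField(mspec)
  nodal <- extractNodalSet(field)
  if (length(nodalRadii(nodal)))
    report$nodal_radii <- data.frame(ring = seq_along(nodalRadii(nodal)),
                                     radius_mm = nodalRadii(nodal))

  ## -- synthesize -------------------------------------------------------
  imc <- config$image
  ispec <- ImageSpec(imc$geometry, imc$imageSize, imc$pixelPitch,
                     imc$cellRadius, imc$lineWidth, imc$backgroundFraction,
                     imc$enhancementPct, seed = stageSeed(1L))
  patterned <- if (imc$geometry == "random") generateRandomImage(ispec)
               else generatePatternImage(ispec, field)
  control <- generateRandomImage(
    ImageSpec("random", imc$imageSize, imc$pixelPitch, imc$cellRadius,
              imc$lineWidth, imc$backgroundFraction, 0,
              seed = stageSeed(2L)))
  nwc <- config$network
  networks <- lapply(seq_along(nwc$days), function(k)
    generateNetworkImage(
      networkSpecForDay(nwc$days[k], nwc$condition,
                        ribbonCount = nwc$ribbonCount,
                        imageSize = nwc$imageSize,
                        pixelPitch = nwc$pixelPitch,
                        seed = stageSeed(10L + k)),
      field = field))
  prc <- config$proteome
  proteome <- generateProteome(
    ProteomeSpec(nProteins = prc$nProteins, nUp = prc$nUp,
                 nDown = prc$nDown, effectMean = prc$effectMean,
                 effectSd = prc$effectSd, residualSd = prc$residualSd,
                 seed = stageSeed(20L)))

  ## -- quantify ---------------------------------------------------------
  qc <- config$quantify
  if (imc$geometry != "random") {
    ## one common threshold (pooled histogram) keeps the patterned/control
    ## area-fraction ratio comparable
    lv <- attr(segmentForeground(cbind(intensity(patterned),
                                       intensity(control))),
               "provenance")$level
    mask <- segmentForeground(patterned, "fixed", lv)
    cmask <- segmentForeground(control, "fixed", lv)
    prof <- smoothProfile(
      radialProfile(patterned, dr = qc$dr,
                    rmax = (imc$imageSize - 1) * imc$pixelPitch / 2),
      window = qc$smoothWindow %||% 15L)
    pks <- detectPeaks(prof, qc$prominence)
    report$radial_peaks <- pks@peaks
    if (nrow(pks@peaks) >= 2)
      report$valley_to_peak <- data.frame(ratio = valleyToPeakRatio(pks))
    fw <- lapply(seq_len(nrow(pks@peaks)),
                 function(k) suppressWarnings(ringFWHM(prof, pks, k)))
    report$ring_fwhm <- data.frame(ring = seq_along(fw),
                                   fwhm_um = vapply(fw, as.numeric,
                                                    numeric(1)))
    centerUm <- rep((imc$imageSize - 1) * imc$pixelPitch / 2, 2)
    enh <- lapply(seq_len(min(2L, nrow(pks@peaks))), function(k) {
      ringAt <- attr(fw[[k]], "center")
      if (is.null(ringAt)) ringAt <- pks@peaks$position[k]
      lay <- roiLayout(centerUm, ringAt, imc$lineWidth)
      roiDensityEnhancement(mask, lay, cmask, imc$pixelPitch)
    })
    if (length(enh))
      report$enhancement <- data.frame(
        ring = seq_along(enh),
        enhancement_pct = vapply(enh, `[[`, numeric(1), "enhancementPct"))
  }
  thick <- lapply(networks, function(nw) {
    tm <- localThickness(imageTruth(nw)$cellMask, pixelPitch(nw))
    thicknessStats(tm)
  })
  report$thickness <- data.frame(
    day = nwc$days,
    mean_um = vapply(thick, `[[`, numeric(1), "mean"),
    sd_um = vapply(thick, `[[`, numeric(1), "sd"))
  oh <- orientationDistribution(fftHighpass(patterned),
                                sigmaPx = qc$sigmaPx,
                                energyThreshold = qc$energyThreshold)
  report$orientation <- data.frame(angle_deg = oh@angles,
                                   weight = oh@weights)

  ## -- differential expression -----------------------------------------
  de <- differentialExpression(normalizeAbundance(proteome),
                               alpha = config$de$alpha,
                               varEqual = isTRUE(config$de$varEqual))
  cnt <- deCounts(de)
  report$de_summary <- data.frame(direction = names(cnt),
                                  count = as.integer(cnt))
  pca <- pcaScores(normalizeAbundance(proteome))
  report$pca_scores <- data.frame(sample = rownames(pca@scores),
                                  PC1 = pca@scores[, 1],
                                  PC2 = pca@scores[, 2])

  manifest <- list(config = config, seed = seed,
                   stageSeeds = list(image = stageSeed(1L),
                                     control = stageSeed(2L),
                                     networks = stageSeed(10L) + seq_along(nwc$days),
                                     proteome = stageSeed(20L)),
                   package = as.character(utils::packageVersion("SonoMorph")))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(report))
      utils::write.csv(report[[nm]], file.path(outDir, paste0(nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(report = report, manifest = manifest, field = field, nodal = nodal,
       images = list(patterned = patterned, control = control,
                     networks = networks),
       proteome = proteome, de = de)
}
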