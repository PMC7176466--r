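## Pipeline orchestration: per-step reconstruction with the two-pass
## peak-expiration reference, respiratory filtering, breath detection, fEIT
## ROI identification, and regional mechanics across the protocol.

#' Analyze one protocol step
#'
#' Runs the per-step chain: provisional reference, reconstruction, automatic
#' bandpass, breath detection, refined peak-expiration reference, final
#' reconstruction and detection, tidal difference image, fEIT image and ROI.
#'
#' @param series raw \linkS4class{VoltageSeries} for the step.
#' @param recon \linkS4class{ReconModel}.
#' @param nTaps bandpass filter length.
#' @param fLower nominal lower corner, Hz.
#' @param thetaGrid candidate fEIT thresholds.
#' @param breathTable optional externally corrected breath table used in
#'   place of the automatic detection (manual-adjustment stand-in).
#' @return list with the step's analysis products.
#' @export
analyzeStep <- function(series, recon, nTaps = 128L, fLower = 0.01,
                        thetaGrid = seq(0.05, 0.60, by = 0.025),
                        breathTable = NULL) {
  V <- series@frames
  fps <- series@frameRate

  ## pass 1: provisional reference -> images -> breaths
  ref1 <- peakExpirationReference(series)
  y1 <- normalizedDifference(V, ref1)
  img1 <- reconstructSeries(
    new("VoltageSeries", frames = y1, frameRate = fps,
        metadata = c(series@metadata, list(reference = "provisional"))),
    recon
  )
  gs1 <- globalSignal(img1)
  fPeak <- dominantFrequency(gs1, fMin = fLower)
  bp <- designBandpass(fPeak, fps, nTaps = nTaps, fLower = fLower)
  bt1 <- detectBreaths(zeroPhaseFilter(gs1, bp))

  ## pass 2: peak-expiration reference from detected breaths
  ref2 <- if (nrow(bt1) >= 2L) peakExpirationReference(series, bt1) else {
    warning("pass-2 reference unavailable; keeping provisional reference")
    ref1
  }
  y2 <- normalizedDifference(V, ref2)
  img2 <- reconstructSeries(
    new("VoltageSeries", frames = y2, frameRate = fps,
        metadata = c(series@metadata, list(reference = "peak-expiration"))),
    recon
  )
  filt <- zeroPhaseFilter(img2, bp)
  gf <- globalSignal(filt)
  breaths <- if (is.null(breathTable)) detectBreaths(gf) else breathTable

  tidal <- if (nrow(breaths) >= 1L) tidalDifferenceImage(filt, breaths) else NULL
  feit <- feitImage(filt)
  theta <- autoThreshold(feit, grid = thetaGrid)
  roi <- roiFromThreshold(feit, theta)

  list(
    step_label = series@metadata$step_label %||% "",
    stage = series@metadata$stage %||% "",
    fPeak = fPeak, bandpass = bp, breaths = breaths,
    globalFiltered = gf, tidal = tidal, feit = feit,
    theta = theta, roi = roi,
    reference = ref2, nFrames = nrow(V)
  )
}

#' Analyze a full protocol
#'
#' Applies \code{\link{analyzeStep}} to every step, merges the per-step lung
#' ROIs into the aggregate ROI, builds compliance stacks per stage
#' (recruitment uses plateau pressure, titration uses PEEP), derives
#' C_max / P* summaries and F(P) maps, and correlates whole-ROI EIT
#' compliance with the ventilator compliance when available.
#'
#' @param stepSeries list of raw \linkS4class{VoltageSeries}, one per step.
#' @param ventLog ventilator log data.frame (step_label, stage, mode, PEEP,
#'   P_plat, optional C_vent).
#' @param recon \linkS4class{ReconModel}; built on \code{meshCoarse} when
#'   omitted.
#' @param meshCoarse reconstruction mesh (defaults to the packaged thorax
#'   coarse mesh).
#' @param nfTarget noise-figure target for the reconstruction model.
#' @param includeMovement model electrode movement in the inverse.
#' @param ... forwarded to \code{\link{analyzeStep}}.
#' @return list: \code{steps}, \code{roiAggregate}, \code{stacks},
#'   \code{summaries}, \code{fMaps}, \code{stepSummaries},
#'   \code{complianceSeries}, \code{correlation}, \code{recon}.
#' @export
analyzeProtocol <- function(stepSeries, ventLog, recon = NULL,
                            meshCoarse = NULL, nfTarget = 0.60,
                            includeMovement = TRUE, ...) {
  if (nrow(ventLog) != length(stepSeries))
    stop("ventilator log rows must match the number of voltage series")
  if (is.null(recon)) {
    if (is.null(meshCoarse)) meshCoarse <- thoraxMeshPair()$coarse
    recon <- buildReconModel(meshCoarse, nfTarget = nfTarget,
                             includeMovement = includeMovement)
  }
  steps <- lapply(stepSeries, analyzeStep, recon = recon, ...)

  roiAgg <- aggregateRoi(lapply(steps, `[[`, "roi"))

  deltaP <- deltaPawo(ventLog$P_plat, ventLog$PEEP)
  stageP <- ifelse(ventLog$stage == "titration", ventLog$PEEP, ventLog$P_plat)

  stacks <- summaries <- fMaps <- stepSummaries <- list()
  for (sc in c("recruitment", "titration")) {
    idx <- which(ventLog$stage == sc)
    if (length(idx) < 2L) next
    maps <- lapply(idx, function(i) cdynMap(steps[[i]]$tidal, deltaP[i], roiAgg))
    st <- complianceStack(maps, stageP[idx], ventLog$step_label[idx], sc, roiAgg)
    sm <- cmaxPstar(st)
    stacks[[sc]] <- st
    summaries[[sc]] <- sm
    fMaps[[sc]] <- lapply(seq_along(idx), function(k) odAtelMap(st, sm, k))
    stepSummaries[[sc]] <- lapply(fMaps[[sc]], stepSummary, summary = sm)
  }

  sel <- roiAgg$mask
  eitC <- vapply(seq_along(steps), function(i) {
    td <- steps[[i]]$tidal
    mean(td[sel & !is.na(td)]) / deltaP[i]
  }, numeric(1))
  corr <- NULL
  if (!is.null(ventLog$C_vent) && length(eitC) >= 3L) {
    corr <- complianceCorrelation(eitC, ventLog$C_vent)
  }

  list(
    steps = steps, roiAggregate = roiAgg, stacks = stacks,
    summaries = summaries, fMaps = fMaps, stepSummaries = stepSummaries,
    complianceSeries = data.frame(
      step_label = ventLog$step_label, stage = ventLog$stage,
      pressure = stageP, delta_p = deltaP, eit_cdyn = eitC,
      vent_c = if (is.null(ventLog$C_vent)) NA_real_ else ventLog$C_vent
    ),
    correlation = corr, recon = recon
  )
}

#' Default pipeline configuration
#'
#' All protocol constants surface here with their reference defaults: noise
#' figure 0.60, lower corner 0.01 Hz, 128 filter taps, theta grid
#' 0.05-0.60, 0.5 s breath match tolerance.
#'
#' @param outDir output directory.
#' @param voltagePrefixes character vector of voltage file prefixes (CSV +
#'   JSON sidecars); when NULL the simulator stage runs first.
#' @param ventLogPath ventilator log CSV path (required when voltage
#'   prefixes are given).
#' @param seed master seed.
#' @return a config list.
#' @export
pipelineConfig <- function(outDir, voltagePrefixes = NULL, ventLogPath = NULL,
                           seed = 1L) {
  list(
    outDir = outDir, voltagePrefixes = voltagePrefixes,
    ventLogPath = ventLogPath,
    nfTarget = 0.60, fLower = 0.01, nTaps = 128L,
    thetaGrid = c(0.05, 0.60), matchTolS = 0.5,
    includeMovement = TRUE, seed = as.integer(seed),
    simulate = is.null(voltagePrefixes),
    breathsPerStep = 15L, stepIndices = NULL
  )
}

#' Run the full pipeline
#'
#' Stages: simulate (when no input voltages are configured), reconstruct,
#' breaths, ROI, mechanics, report. Deterministic given the config and
#' seed. Outputs (CSV/JSON) and a MANIFEST are written under the output
#' directory; on a stage failure the partial outputs are retained and the
#' MANIFEST marks the run incomplete.
#'
#' @param config a list from \code{\link{pipelineConfig}}, or a path to a
#'   YAML file with the same fields.
#' @return invisibly, the \code{\link{analyzeProtocol}} result.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(out, "MANIFEST.txt")
  writeLines(c("status: incomplete"), manifest)
  logLine <- function(...) message(sprintf(...))

  if (isTRUE(config$simulate)) {
    logLine("stage simulate: default protocol, seed %d", config$seed)
    meshes <- thoraxMeshPair()
    scenario <- simScenario(seed = config$seed,
                            breathsPerStep = config$breathsPerStep %||% 15L)
    protocol <- defaultProtocol()
    if (!is.null(config$stepIndices))
      protocol <- protocol[config$stepIndices, , drop = FALSE]
    sim <- simulateProtocol(meshes$fine, scenario, protocol)
    vdir <- file.path(out, "voltages")
    dir.create(vdir, showWarnings = FALSE)
    prefixes <- file.path(vdir, sprintf("step_%02d", seq_along(sim$steps)))
    for (i in seq_along(sim$steps)) {
      writeVoltageSeries(sim$steps[[i]]$voltages, prefixes[i])
    }
    ventPath <- file.path(out, "ventilator_log.csv")
    writeVentilatorLog(sim$ventLog, ventPath)
    config$voltagePrefixes <- prefixes
    config$ventLogPath <- ventPath
    meshCoarse <- meshes$coarse
  } else {
    meshCoarse <- thoraxMeshPair()$coarse
  }

  if (is.null(config$ventLogPath) || !file.exists(config$ventLogPath))
    stop("ventilator log not found; aborting before reconstruction")
  ventLog <- readVentilatorLog(config$ventLogPath)
  stepSeries <- lapply(config$voltagePrefixes, readVoltageSeries)

  logLine("stage reconstruct: calibrating lambda to noise figure %.2f",
          config$nfTarget)
  thetaGrid <- seq(config$thetaGrid[1], config$thetaGrid[2], by = 0.025)
  res <- analyzeProtocol(
    stepSeries, ventLog,
    meshCoarse = meshCoarse, nfTarget = config$nfTarget,
    includeMovement = isTRUE(config$includeMovement),
    nTaps = config$nTaps, fLower = config$fLower, thetaGrid = thetaGrid
  )

  logLine("stage report: writing outputs to %s", out)
  for (i in seq_along(res$steps)) {
    s <- res$steps[[i]]
    writeBreathTable(s$breaths,
                     file.path(out, sprintf("breaths_%02d.csv", i)))
    writeMaskCsv(s$roi$mask,
                 file.path(out, sprintf("roi_%02d.csv", i)),
                 meta = list(theta = s$theta, source = s$step_label))
    if (!is.null(s$tidal))
      writeRasterCsv(s$tidal, file.path(out, sprintf("tidal_%02d.csv", i)))
  }
  writeMaskCsv(res$roiAggregate$mask, file.path(out, "roi_aggregate.csv"),
               meta = list(theta = NA, source = "aggregate"))
  summaryRows <- res$complianceSeries
  summaryRows$od_pct <- NA_real_
  summaryRows$atel_pct <- NA_real_
  summaryRows$pct_at_max <- NA_real_
  for (sc in names(res$stepSummaries)) {
    lab <- res$stacks[[sc]]$labels
    for (k in seq_along(lab)) {
      j <- match(lab[k], summaryRows$step_label)
      ss <- res$stepSummaries[[sc]][[k]]
      summaryRows$od_pct[j] <- ss$od_pct
      summaryRows$atel_pct[j] <- ss$atel_pct
      summaryRows$pct_at_max[j] <- ss$pct_at_max
    }
    writeRasterCsv(res$summaries[[sc]]$cmax,
                   file.path(out, sprintf("cmax_%s.csv", sc)))
    writeRasterCsv(res$summaries[[sc]]$pstar,
                   file.path(out, sprintf("pstar_%s.csv", sc)))
    for (k in seq_along(res$fMaps[[sc]])) {
      writeRasterCsv(res$fMaps[[sc]][[k]]$F,
                     file.path(out, sprintf("fmap_%s_%02d.csv", sc, k)))
    }
  }
  write.csv(summaryRows, file.path(out, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      lambda = res$recon@lambda, noise_figure = res$recon@noiseFigure,
      thetas = vapply(res$steps, `[[`, numeric(1), "theta"),
      f_peaks = vapply(res$steps, `[[`, numeric(1), "fPeak"),
      breaths_detected = vapply(res$steps, function(s) nrow(s$breaths), integer(1)),
      correlation_r = if (is.null(res$correlation)) NA else res$correlation$r,
      seed = config$seed, nf_target = config$nfTarget,
      n_taps = config$nTaps, f_lower = config$fLower
    ),
    file.path(out, "provenance.json"),
    auto_unbox = TRUE, digits = NA
  )
  writeLines(c("status: complete"), manifest)
  invisible(res)
}
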