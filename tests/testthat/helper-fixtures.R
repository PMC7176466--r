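## Shared fixtures, built lazily and memoized for the whole test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fixPattern <- function() memo("pattern", adjacentPattern(16))

fixCircleMesh <- function() memo("circle", buildThoraxMesh(circleContour(64), 96))

fixThoraxCoarse <- function() memo("coarse", buildThoraxMesh(thoraxContour(), 256))

fixThoraxFine <- function() {
  memo("fine", buildThoraxMesh(thoraxContour(), 1024, refinement = "fine"))
}

fixRecon <- function() memo("recon", buildReconModel(fixThoraxCoarse()))

fixFineRaster <- function() memo("fineRaster", buildRaster(fixThoraxFine()))

## one simulated step, moderate size, default noise conditions
fixSmallSim <- function() {
  memo("smallSim", {
    scen <- simScenario(seed = 11, breathsPerStep = 8)
    step <- as.list(defaultProtocol()[12, ]) # T7
    list(
      scenario = scen, step = step,
      sim = simulateStep(fixThoraxFine(), scen, step, seed = 11)
    )
  })
}

## the full default protocol at the study conditions (resp 23.5, heart 109,
## 30% cardiac, SNR 20 dB, 15 breaths/step), analyzed end to end
fixFullRun <- function() {
  memo("fullRun", {
    scen <- simScenario(seed = 1)
    sim <- simulateProtocol(fixThoraxFine(), scen)
    res <- analyzeProtocol(
      lapply(sim$steps, `[[`, "voltages"), sim$ventLog, recon = fixRecon()
    )
    list(scenario = scen, sim = sim, res = res)
  })
}

## noiseless titration-only run for parameter recovery
fixRecoveryRun <- function() {
  memo("recoveryRun", {
    scen <- simScenario(seed = 3, noiseSnrDb = Inf, cardiacRatio = 0,
                        breathsPerStep = 8)
    proto <- defaultProtocol()
    proto <- proto[proto$stage == "titration", ]
    sim <- simulateProtocol(fixThoraxFine(), scen, proto)
    res <- analyzeProtocol(
      lapply(sim$steps, `[[`, "voltages"), sim$ventLog, recon = fixRecon()
    )
    list(scenario = scen, sim = sim, res = res, protocol = proto)
  })
}

## pooled detection metrics + timing/amplitude errors over an analyzed run
pooledDetection <- function(sim, res, frameRate = 20, matchTolS = 0.5) {
  TP <- FN <- FP <- TN <- 0L
  tErr <- dzErr <- numeric(0)
  for (i in seq_along(res$steps)) {
    s <- res$steps[[i]]
    tb <- sim$steps[[i]]$truth$breaths
    m <- detectionMetrics(s$breaths, tb, frameRate = frameRate,
                          matchTolS = matchTolS)
    TP <- TP + m$TP; FN <- FN + m$FN; FP <- FP + m$FP; TN <- TN + m$TN
    g <- s$globalFiltered$values
    if (!is.null(m$matches)) {
      for (r in seq_len(nrow(m$matches))) {
        d <- m$matches[r, 1]; t <- m$matches[r, 2]
        tErr <- c(tErr,
                  abs(s$breaths$insp_frame[d] - tb$insp_frame[t]) / frameRate,
                  abs(s$breaths$exp_frame[d] - tb$exp_frame[t]) / frameRate)
        dzT <- g[tb$insp_frame[t]] - g[tb$exp_frame[t]]
        dzE <- g[s$breaths$insp_frame[d]] - g[s$breaths$exp_frame[d]]
        dzErr <- c(dzErr, abs(dzE - dzT) / abs(dzT))
      }
    }
  }
  list(
    TP = TP, FN = FN, FP = FP, TN = TN,
    sensitivity = 100 * TP / (TP + FN),
    specificity = 100 * TN / (TN + FP),
    meanTimeErr = mean(tErr), meanDzErrPct = 100 * mean(dzErr)
  )
}

## build a small ImageSeries from a frames matrix (pixels all valid)
makeImageSeries <- function(frames, side, frameRate = 20) {
  new("ImageSeries",
    frames = frames, insideMask = matrix(TRUE, side, side),
    side = as.integer(side), frameRate = frameRate, provenance = list()
  )
}

## sinusoid amplitude at frequency f via least squares
sineAmplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  b <- stats::coef(stats::lm(x ~ X))
  sqrt(sum(b[2:3]^2))
}
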