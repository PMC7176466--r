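## Phantom simulator: ventilation protocol datasets with full ground truth.
## Conductivity per frame = baseline + tidal term (lung elements, raised-cosine
## breath waveform scaled by the true compliance at the step pressure) +
## cardiac sinusoid (central region), solved on the fine mesh, plus white
## measurement noise at a prescribed SNR.

#' Default ventilation protocol
#'
#' Baseline (VC), lung recruitment R1..R4 (PC, PEEP 15/20/25/30 cm H2O with
#' a driving pressure of 15), and PEEP titration T1..T8 (VC, PEEP 20 down to
#' 6 in steps of 2).
#'
#' @param baselinePeep baseline PEEP in cm H2O (clinical-practice setting).
#' @param vcDeltaP driving pressure measured during the VC stages, cm H2O.
#' @return a data.frame with one row per protocol step: step_label, stage,
#'   mode, PEEP, P_plat.
#' @export
defaultProtocol <- function(baselinePeep = 10, vcDeltaP = 12) {
  recPeep <- c(15, 20, 25, 30)
  titPeep <- seq(20, 6, by = -2)
  data.frame(
    step_label = c("B", paste0("R", seq_along(recPeep)), paste0("T", seq_along(titPeep))),
    stage = c("baseline", rep("recruitment", length(recPeep)), rep("titration", length(titPeep))),
    mode = c("VC", rep("PC", length(recPeep)), rep("VC", length(titPeep))),
    PEEP = c(baselinePeep, recPeep, titPeep),
    P_plat = c(baselinePeep + vcDeltaP, recPeep + 15, titPeep + vcDeltaP),
    stringsAsFactors = FALSE
  )
}

#' Simulation scenario
#'
#' Population-level defaults: respiratory rate 23.5/min, heart rate 109/min,
#' cardiac amplitude 30\% of the respiratory amplitude, 20 dB measurement SNR,
#' 20 Hz frame rate, 15 breaths per protocol step. The regional compliance
#' ground truth is a per-element tent function peaking at (P*, C_max): C_max
#' around \code{cmaxScale} delta-Z-units/cmH2O with smooth heterogeneity, P*
#' increasing ventral-to-dorsal over \code{pstarRange} (dependent lung opens
#' at higher pressure), tent half-width \code{tentHalfWidth} cm H2O.
#'
#' @param respRate breaths per minute.
#' @param heartRate beats per minute.
#' @param cardiacRatio cardiac amplitude as a fraction of respiratory
#'   amplitude.
#' @param noiseSnrDb measurement signal-to-noise ratio in dB (\code{Inf} for
#'   noiseless).
#' @param frameRate frames per second.
#' @param breathsPerStep breaths recorded per protocol step.
#' @param cmaxScale mean maximum regional compliance (conductivity units per
#'   cm H2O).
#' @param tentHalfWidth half-width of the compliance tent, cm H2O.
#' @param pstarRange ventral-to-dorsal range of the pressure of maximum
#'   compliance, cm H2O.
#' @param seed master seed for the measurement-noise stream.
#' @return a validated scenario list.
#' @export
simScenario <- function(respRate = 23.5, heartRate = 109, cardiacRatio = 0.30,
                        noiseSnrDb = 20, frameRate = 20, breathsPerStep = 15,
                        cmaxScale = 0.015, tentHalfWidth = 40,
                        pstarRange = c(8, 18), seed = 1L) {
  stopifnot(
    respRate > 0, heartRate > 0, cardiacRatio >= 0,
    frameRate > 0, breathsPerStep >= 1
  )
  if (abs(heartRate - respRate) < 1e-9)
    stop("cardiac frequency must differ from respiratory frequency")
  if (frameRate <= 2 * heartRate / 60)
    stop("frame rate must exceed twice the cardiac frequency")
  if (noiseSnrDb <= 0) warning("SNR <= 0 dB: noise dominates the signal")
  structure(
    list(
      respRate = respRate, heartRate = heartRate, cardiacRatio = cardiacRatio,
      noiseSnrDb = noiseSnrDb, frameRate = frameRate,
      breathsPerStep = breathsPerStep, cmaxScale = cmaxScale,
      tentHalfWidth = tentHalfWidth, pstarRange = pstarRange,
      seed = as.integer(seed)
    ),
    class = "SimScenario"
  )
}

## Normalized element-centroid coordinates relative to the mesh bounding box:
## xn in [-1, 1] left-right, yn in [-1, 1] dorsal(-)-ventral(+).
elementCentroidsNorm <- function(mesh) {
  el <- mesh@elements
  nd <- mesh@nodes
  cx <- (nd[el[, 1], 1] + nd[el[, 2], 1] + nd[el[, 3], 1]) / 3
  cy <- (nd[el[, 1], 2] + nd[el[, 2], 2] + nd[el[, 3], 2]) / 3
  rx <- range(nd[mesh@boundary, 1])
  ry <- range(nd[mesh@boundary, 2])
  list(
    xn = (cx - mean(rx)) / (diff(rx) / 2),
    yn = (cy - mean(ry)) / (diff(ry) / 2),
    cx = cx, cy = cy
  )
}

#' Ground-truth regional fields for a scenario on a mesh
#'
#' Two elliptical lung regions (left/right) carry the tidal signal; a central
#' ventral region carries the cardiac signal. C_max is smoothly heterogeneous
#' and P* increases from ventral to dorsal lung.
#'
#' @param mesh the (fine) simulation \linkS4class{EitMesh}.
#' @param scenario a scenario from \code{\link{simScenario}}.
#' @return list with per-element \code{lungMask}, \code{cardiacMask},
#'   \code{cmax}, \code{pstar}.
#' @export
scenarioFields <- function(mesh, scenario) {
  cc <- elementCentroidsNorm(mesh)
  inEllipse <- function(x0, y0, a, b) {
    ((cc$xn - x0) / a)^2 + ((cc$yn - y0) / b)^2 <= 1
  }
  lung <- inEllipse(-0.48, -0.10, 0.34, 0.52) | inEllipse(0.48, -0.10, 0.34, 0.52)
  heart <- inEllipse(0.08, 0.35, 0.20, 0.24) & !lung
  ## smooth heterogeneity, deterministic so truth does not depend on the seed
  cmax <- scenario$cmaxScale *
    (1 + 0.35 * sin(3.1 * cc$xn) * cos(2.3 * cc$yn))
  cmax[!lung] <- 0
  ## dorsal fraction within the lung vertical extent
  if (any(lung)) {
    yr <- range(cc$yn[lung])
    depth <- (yr[2] - cc$yn) / max(yr[2] - yr[1], 1e-9)
  } else {
    depth <- rep(0, length(cc$yn))
  }
  pstar <- scenario$pstarRange[1] +
    diff(scenario$pstarRange) * pmin(pmax(depth, 0), 1)
  pstar[!lung] <- NA_real_
  list(lungMask = lung, cardiacMask = heart, cmax = cmax, pstar = pstar)
}

#' Tent-shaped true regional compliance
#'
#' Piecewise-linear compliance-versus-pressure curve peaking at
#' \code{(pstar, cmax)} with the given half-width; zero far from the peak.
#'
#' @param cmax peak compliance (delta-Z per cm H2O), vectorized.
#' @param pstar pressure of the peak, cm H2O.
#' @param halfWidth pressure half-width of the tent, cm H2O.
#' @param P evaluation pressure(s), cm H2O (>= 0).
#' @return compliance values, same shape as the broadcast inputs.
#' @examples
#' tentCompliance(0.4, 20, 10, 25) # 0.2
#' @export
tentCompliance <- function(cmax, pstar, halfWidth, P) {
  if (any(P < 0)) stop("P must be nonnegative")
  pmax(0, cmax * (1 - abs(P - pstar) / halfWidth))
}

#' True per-element dynamic compliance at a pressure
#'
#' @inheritParams scenarioFields
#' @param P stage-relevant pressure, cm H2O.
#' @param fields optional precomputed \code{\link{scenarioFields}} result.
#' @return numeric vector of per-element compliance (zero outside the lung).
#' @export
trueCdyn <- function(mesh, scenario, P, fields = scenarioFields(mesh, scenario)) {
  out <- numeric(nrow(mesh@elements))
  lm <- fields$lungMask
  out[lm] <- tentCompliance(
    fields$cmax[lm], fields$pstar[lm], scenario$tentHalfWidth, P
  )
  out
}

## raised-cosine breath waveform on phase tau in [0, 1): inspiration over the
## first 40% of the cycle, expiration over the remaining 60%; 0 at
## peak-expiration (tau = 0), 1 at peak-inspiration (tau = 0.4)
breathWaveform <- function(tau, inspFraction = 0.4) {
  ifelse(
    tau < inspFraction,
    (1 - cos(pi * tau / inspFraction)) / 2,
    (1 + cos(pi * (tau - inspFraction) / (1 - inspFraction))) / 2
  )
}

stagePressure <- function(step) {
  if (identical(step$stage, "titration")) step$PEEP else step$P_plat
}

deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Simulate one protocol step
#'
#' Generates the voltage frame stream for one ventilation step by solving the
#' forward problem per frame on the fine mesh, then adding white Gaussian
#' channel noise at the scenario SNR. Ground truth (breath peak frames, true
#' tidal conductivity-change image, lung mask, compliance fields) is returned
#' alongside.
#'
#' @param meshFine fine simulation mesh.
#' @param scenario a \code{\link{simScenario}}.
#' @param step one row of a protocol data.frame (as a list or 1-row
#'   data.frame).
#' @param seed integer seed for the noise stream.
#' @param pattern stimulation pattern (defaults to adjacent, 16 electrodes).
#' @param fields optional precomputed \code{\link{scenarioFields}}.
#' @return list with \code{voltages} (a \linkS4class{VoltageSeries}) and
#'   \code{truth} (list: breaths, tidalImage, lungMask, cdyn, cmax, pstar,
#'   pressure, deltaP, cVent).
#' @export
simulateStep <- function(meshFine, scenario, step, seed = scenario$seed,
                         pattern = adjacentPattern(16),
                         fields = scenarioFields(meshFine, scenario)) {
  step <- as.list(step)
  if (step$P_plat <= step$PEEP) stop("P_plat must exceed PEEP")
  fs <- femStructure(meshFine)
  nEl <- fs$nEl
  P <- stagePressure(step)
  dP <- step$P_plat - step$PEEP
  cdyn <- trueCdyn(meshFine, scenario, P, fields)
  tidalAmp <- cdyn * dP # conductivity-change magnitude at peak inspiration

  ## cardiac conductivity pattern: total |amplitude|*area matched to
  ## cardiacRatio x tidal total
  heart <- fields$cardiacMask
  cardAmp <- numeric(nEl)
  if (any(heart) && scenario$cardiacRatio > 0) {
    tot <- sum(tidalAmp * fs$areas)
    cardAmp[heart] <- scenario$cardiacRatio * tot / sum(fs$areas[heart])
  }

  fps <- scenario$frameRate
  nFrames <- round(60 / scenario$respRate * scenario$breathsPerStep * fps)
  tt <- (seq_len(nFrames) - 1) / fps
  tau <- (tt * scenario$respRate / 60) %% 1
  w <- breathWaveform(tau)
  b <- sin(2 * pi * scenario$heartRate / 60 * tt)

  ## affine conductivity: sigma(t) = 1 + w(t) * p1 + b(t) * p2
  p1 <- -tidalAmp # conductivity falls during inspiration
  p2 <- cardAmp
  lowest <- 1 - max(tidalAmp) - max(cardAmp)
  clip <- FALSE
  if (lowest <= 0) {
    clip <- TRUE
    warning("non-positive conductivity excursion; clipping at 1e-3")
  }

  ## precompute stiffness value vectors for the affine decomposition
  v0 <- fs$sv
  v1 <- fs$sv * p1[fs$elemOf]
  v2 <- fs$sv * p2[fs$elemOf]
  dims <- c(fs$nNd - 1L, fs$nNd - 1L)
  K0 <- sparseMatrix(i = fs$ti, j = fs$tj, x = v0, dims = dims)
  chol <- Cholesky(forceSymmetric(K0))
  nE <- length(fs$elecRows)
  Bmat <- matrix(0, fs$nNd - 1L, nE)
  Bmat[cbind(fs$elecRows, seq_len(nE))] <- 1
  elecFull <- meshFine@electrodeNodes
  elecRed <- fs$remap[elecFull]

  V <- matrix(0, nFrames, pattern@nMeasurements)
  for (f in seq_len(nFrames)) {
    if (clip) {
      sig <- pmax(1 + w[f] * p1 + b[f] * p2, 1e-3)
      vals <- fs$sv * sig[fs$elemOf]
    } else {
      vals <- v0 + w[f] * v1 + b[f] * v2
    }
    K <- sparseMatrix(i = fs$ti, j = fs$tj, x = vals, dims = dims)
    ch <- Matrix::update(chol, forceSymmetric(K))
    Ured <- as.matrix(Matrix::solve(ch, Bmat, system = "A"))
    V[f, ] <- channelVoltages(Ured[elecRed, , drop = FALSE], pattern)
  }

  ## additive white Gaussian noise at the prescribed per-channel SNR
  set.seed(seed)
  if (is.finite(scenario$noiseSnrDb)) {
    sdSig <- sqrt(mean(apply(V, 2, stats::var)))
    sdN <- sdSig * 10^(-scenario$noiseSnrDb / 20)
    V <- V + matrix(rnorm(length(V), sd = sdN), nrow(V), ncol(V))
  }

  ## true breath table: peaks fully inside the recorded frames
  Tb <- 60 / scenario$respRate
  k <- seq_len(scenario$breathsPerStep + 1L) - 1L
  inspT <- (k + 0.4) * Tb
  expT <- (k + 1) * Tb
  inspF <- round(inspT * fps) + 1L
  expF <- round(expT * fps) + 1L
  ok <- inspF >= 1L & expF <= nFrames
  breaths <- data.frame(insp_frame = inspF[ok], exp_frame = expF[ok])

  vs <- new("VoltageSeries",
    frames = V, frameRate = fps,
    metadata = list(
      pattern = patternHash(pattern), units = "V (unit drive)",
      seed = seed, step_label = step$step_label, stage = step$stage,
      PEEP = step$PEEP, P_plat = step$P_plat
    )
  )
  list(
    voltages = vs,
    truth = list(
      breaths = breaths, tidalImage = tidalAmp, lungMask = fields$lungMask,
      cdyn = cdyn, cmax = fields$cmax, pstar = fields$pstar,
      pressure = P, deltaP = dP, cVent = sum(cdyn)
    )
  )
}

#' Simulate a full ventilation protocol
#'
#' Runs \code{\link{simulateStep}} for every protocol step with per-step
#' derived seeds and assembles the ventilator log (PEEP, plateau pressure,
#' blood gases, whole-lung compliance).
#'
#' @inheritParams simulateStep
#' @param protocol protocol data.frame from \code{\link{defaultProtocol}}.
#' @return list with \code{steps} (per step: voltages, truth) and
#'   \code{ventLog} (data.frame).
#' @export
simulateProtocol <- function(meshFine, scenario, protocol = defaultProtocol(),
                             pattern = adjacentPattern(16)) {
  fields <- scenarioFields(meshFine, scenario)
  steps <- vector("list", nrow(protocol))
  cvent <- pao2 <- paco2 <- numeric(nrow(protocol))
  for (i in seq_len(nrow(protocol))) {
    st <- as.list(protocol[i, ])
    res <- simulateStep(meshFine, scenario, st,
      seed = deriveSeed(scenario$seed, i),
      pattern = pattern, fields = fields
    )
    steps[[i]] <- res
    cvent[i] <- res$truth$cVent
    ## plausible blood-gas course: oxygenation improves with recruitment
    pao2[i] <- round(80 + 8 * st$PEEP + ifelse(st$stage == "titration", 60, 0))
    paco2[i] <- 45
  }
  ventLog <- data.frame(
    step_label = protocol$step_label, stage = protocol$stage,
    mode = protocol$mode, PEEP = protocol$PEEP, P_plat = protocol$P_plat,
    PaO2 = pao2, PaCO2 = paco2, C_vent = cvent,
    stringsAsFactors = FALSE
  )
  list(steps = steps, ventLog = ventLog, scenario = scenario)
}
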