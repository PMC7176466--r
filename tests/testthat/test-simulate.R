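test_that("default protocol follows the staged pressure course", {
  pr <- defaultProtocol()
  expect_identical(nrow(pr), 13L)
  rec <- pr[pr$stage == "recruitment", ]
  expect_equal(rec$P_plat - rec$PEEP, rep(15, 4)) # PC driving pressure 15
  expect_equal(rec$PEEP, c(15, 20, 25, 30)) # +5 cm H2O per step
  tit <- pr[pr$stage == "titration", ]
  expect_equal(tit$PEEP[1], 20) # titration starts at 20
  expect_equal(diff(tit$PEEP), rep(-2, 7)) # -2 cm H2O per step
  expect_true(all(pr$P_plat > pr$PEEP))
})

test_that("tent compliance evaluates the piecewise-linear curve", {
  expect_equal(tentCompliance(0.4, 20, 10, 20), 0.4) # at the peak
  expect_equal(tentCompliance(0.4, 20, 10, 25), 0.2) # halfway down
  expect_equal(tentCompliance(0.4, 20, 10, 55), 0) # beyond support
  expect_equal(tentCompliance(0.4, 20, 10, 15), 0.2) # symmetric
  expect_error(tentCompliance(0.4, 20, 10, -1), "nonnegative")
})

test_that("simulated step has the specified frame count and determinism", {
  fix <- fixSmallSim()
  sim <- fix$sim
  ## frame count formula at the reference conditions
  expect_identical(
    round(60 / 23.5 * 15 * 20), 766
  )
  expect_equal(nrow(voltageFrames(sim$voltages)), round(60 / 23.5 * 8 * 20))
  ## bit-identical reproduction under the same seed
  sim2 <- simulateStep(fixThoraxFine(), fix$scenario, fix$step, seed = 11)
  expect_identical(voltageFrames(sim2$voltages), voltageFrames(sim$voltages))
})

test_that("noiseless acardiac signal is periodic at the breath period", {
  scen <- simScenario(seed = 2, noiseSnrDb = Inf, cardiacRatio = 0,
                      breathsPerStep = 8)
  sim <- simulateStep(fixThoraxFine(), scen, as.list(defaultProtocol()[12, ]),
                      seed = 2)
  g <- rowMeans(voltageFrames(sim$voltages))
  lagT <- round(60 / scen$respRate * scen$frameRate)
  ac <- stats::acf(g - mean(g), lag.max = lagT + 5, plot = FALSE)$acf[-1]
  ## autocorrelation peak (beyond half a period) at one breath period +/- 1
  search <- (lagT %/% 2):(lagT + 5)
  expect_lte(abs(search[which.max(ac[search])] - lagT), 1)
})

test_that("default-scenario spectrum peaks at the respiratory rate", {
  fix <- fixSmallSim()
  g <- rowMeans(voltageFrames(fix$sim$voltages))
  f <- dominantFrequency(g, frameRate = fix$scenario$frameRate)
  nfft <- 2^ceiling(log2(4 * length(g)))
  bin <- fix$scenario$frameRate / nfft
  expect_lte(abs(f - fix$scenario$respRate / 60), bin + 1e-9)
})

test_that("measurement noise is white at the prescribed SNR", {
  scen20 <- simScenario(seed = 9, breathsPerStep = 8)
  scenInf <- simScenario(seed = 9, noiseSnrDb = Inf, breathsPerStep = 8)
  step <- as.list(defaultProtocol()[8, ])
  fine <- fixThoraxFine()
  v20 <- voltageFrames(simulateStep(fine, scen20, step, seed = 9)$voltages)
  vInf <- voltageFrames(simulateStep(fine, scenInf, step, seed = 9)$voltages)
  noise <- v20 - vInf
  ## SNR: channel-rms signal sd over noise sd, in dB
  snr <- 20 * log10(sqrt(mean(apply(vInf, 2, var))) / sd(as.vector(noise)))
  expect_lt(abs(snr - 20), 0.5)
  ## Ljung-Box whiteness on a few channels
  set.seed(1)
  for (ch in sample(ncol(noise), 4)) {
    p <- stats::Box.test(noise[, ch], lag = 10, type = "Ljung-Box")$p.value
    expect_gt(p, 1e-3)
  }
})

test_that("protocol bundle is consistent with its ground truth", {
  fix <- fixFullRun()
  sim <- fix$sim
  expect_length(sim$steps, 13L)
  expect_identical(nrow(sim$ventLog), 13L)
  ## ventilator-log compliance equals the summed per-element true compliance
  fields <- scenarioFields(fixThoraxFine(), fix$scenario)
  for (i in c(1, 5, 13)) {
    P <- sim$steps[[i]]$truth$pressure
    expect_equal(sim$ventLog$C_vent[i],
                 sum(trueCdyn(fixThoraxFine(), fix$scenario, P, fields)))
  }
  ## true breath tables are ordered and within the recorded frames
  for (st in sim$steps) {
    tb <- st$truth$breaths
    expect_true(all(tb$insp_frame < tb$exp_frame))
    expect_true(all(diff(tb$insp_frame) > 0))
    expect_lte(max(tb$exp_frame), nrow(voltageFrames(st$voltages)))
  }
})

test_that("ground-truth F(P) respects its bounds and vanishes at P*", {
  scen <- simScenario()
  fine <- fixThoraxFine()
  fields <- scenarioFields(fine, scen)
  lung <- which(fields$lungMask)
  P <- seq(20, 6, by = -2)
  C <- sapply(P, function(p) tentCompliance(
    fields$cmax[lung], fields$pstar[lung], scen$tentHalfWidth, p))
  cmax <- apply(C, 1, max)
  for (j in seq_along(P)) {
    below <- P[j] < fields$pstar[lung]
    Fv <- ifelse(below, (C[, j] - cmax) / cmax, (cmax - C[, j]) / cmax)
    expect_true(all(Fv >= -1 - 1e-12 & Fv <= 1 + 1e-12))
  }
  ## F at each element's own P* is zero when P* is attainable on the grid
  atPeak <- tentCompliance(fields$cmax[lung], fields$pstar[lung],
                           scen$tentHalfWidth, fields$pstar[lung])
  expect_equal(atPeak, fields$cmax[lung])
})
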