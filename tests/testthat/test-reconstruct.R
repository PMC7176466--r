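test_that("peak-expiration reference follows the two-pass contract", {
  ## constant series: reference equals the constant frame
  V <- matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  vs <- new("VoltageSeries", frames = V, frameRate = 20, metadata = list())
  expect_equal(peakExpirationReference(vs), c(1, 2, 3))

  ## empty breath table: fallback with warning
  empty <- data.frame(insp_frame = integer(), exp_frame = integer())
  expect_warning(ref <- peakExpirationReference(vs, empty), "fall")
  expect_equal(ref, c(1, 2, 3))

  ## pass-2 reference on a noiseless simulated step is close to the true
  ## end-expiratory frame
  scen <- simScenario(seed = 4, noiseSnrDb = Inf, cardiacRatio = 0,
                      breathsPerStep = 8)
  sim <- simulateStep(fixThoraxFine(), scen, as.list(defaultProtocol()[10, ]),
                      seed = 4)
  truth <- sim$truth$breaths
  ref2 <- peakExpirationReference(sim$voltages, truth)
  trueRef <- voltageFrames(sim$voltages)[truth$exp_frame[3], ]
  expect_lt(sqrt(mean((ref2 - trueRef)^2)) / sqrt(mean(trueRef^2)), 0.01)
})

test_that("normalized difference is elementwise and guards zero channels", {
  Vref <- c(1, 2, 4)
  expect_equal(normalizedDifference(Vref, Vref), c(0, 0, 0))
  expect_equal(normalizedDifference(1.1 * Vref, Vref), rep(0.1, 3))
  M <- rbind(Vref, 2 * Vref)
  expect_equal(normalizedDifference(M, Vref)[2, ], rep(1, 3))
  expect_error(normalizedDifference(Vref, c(1, 0, 4)), "channel")
})

test_that("regularizer has Laplacian and movement block structure", {
  rspec <- buildRegularizer(fixThoraxCoarse(), includeMovement = TRUE)
  L <- rspec$Rcond
  expect_equal(max(abs(rowSums(L))), 0) # graph Laplacian row sums
  expect_equal(L, t(L))
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8) # positive semidefinite
  nN <- nrow(fixThoraxCoarse()@elements)
  R <- lungeit:::assembleR(rspec, nN)
  expect_identical(dim(R), c(nN + 32L, nN + 32L))
  ## movement disabled: conductivity block only
  rspec0 <- buildRegularizer(fixThoraxCoarse(), includeMovement = FALSE)
  expect_identical(dim(lungeit:::assembleR(rspec0, nN)), c(nN, nN))
})

test_that("noise figure is scale invariant and calibratable to 0.60", {
  ## scale invariance and the one-channel degenerate case
  J1 <- matrix(2)
  B1 <- matrix(0.5)
  expect_equal(noiseFigure(B1, J1, targetElement = 1L), 1)
  recon <- fixRecon()
  nN <- nrow(fixThoraxCoarse()@elements)
  Jc <- recon@jacobian[, seq_len(nN)]
  ce <- lungeit:::centralElement(fixThoraxCoarse())
  nf1 <- noiseFigure(recon@B, Jc, targetElement = ce)
  nf2 <- noiseFigure(recon@B * 3.7, Jc, targetElement = ce)
  expect_equal(nf1, nf2, tolerance = 1e-12)

  ## the calibrated model achieves the target within tolerance
  expect_lte(abs(recon@noiseFigure - 0.60), 0.01)
  expect_equal(nf1, recon@noiseFigure, tolerance = 1e-9)
})

test_that("noise figure decreases monotonically in lambda", {
  recon <- fixRecon()
  nN <- nrow(fixThoraxCoarse()@elements)
  R <- lungeit:::assembleR(recon@regularizer, nN)
  J <- recon@jacobian
  ce <- lungeit:::centralElement(fixThoraxCoarse())
  lams <- recon@lambda * 10^seq(-1.5, 1.5, by = 0.5)
  nfs <- vapply(lams, function(l) {
    B <- lungeit:::solveGN(J, R, l)[seq_len(nN), , drop = FALSE]
    noiseFigure(B, J[, seq_len(nN)], targetElement = ce)
  }, numeric(1))
  expect_true(all(diff(nfs) < 0))
})

test_that("lambda calibration finds fixed points and reports failure", {
  recon <- fixRecon()
  nN <- nrow(fixThoraxCoarse()@elements)
  ce <- lungeit:::centralElement(fixThoraxCoarse())
  R <- lungeit:::assembleR(recon@regularizer, nN)
  ## fixed point: ask for the NF of a probed lambda, recover that lambda
  lam0 <- recon@lambda * 3
  B0 <- lungeit:::solveGN(recon@jacobian, R, lam0)[seq_len(nN), , drop = FALSE]
  nf0 <- noiseFigure(B0, recon@jacobian[, seq_len(nN)], targetElement = ce)
  cal <- calibrateLambda(recon@jacobian, recon@regularizer, nN,
                         nfTarget = nf0, tol = 0.01, targetElement = ce)
  expect_lt(abs(log(cal$lambda / lam0)), 0.2)
  ## unreachable target
  expect_error(
    calibrateLambda(recon@jacobian, recon@regularizer, nN,
                    nfTarget = 1e6, tol = 0.01, targetElement = ce),
    "unreachable"
  )
})

test_that("reconstruction is linear and recovers target position", {
  recon <- fixRecon()
  p <- fixPattern()
  fine <- fixThoraxFine()
  sig0 <- rep(1, nrow(fine@elements))
  cc <- lungeit:::elementCentroidsNorm(fine)
  targ <- which((cc$xn - 0.4)^2 + (cc$yn - 0.3)^2 < 0.03)
  sig1 <- sig0
  sig1[targ] <- 0.8
  V0 <- solveForward(fine, sig0, p)
  y <- (solveForward(fine, sig1, p) - V0) / V0

  mk <- function(Y) new("VoltageSeries", frames = Y, frameRate = 20,
                        metadata = list())
  imgA <- reconstructSeries(mk(matrix(y, 1)), recon)
  img0 <- reconstructSeries(mk(matrix(0, 1, length(y))), recon)
  imgS <- reconstructSeries(mk(matrix(2.5 * y, 1)), recon)

  valid <- as.vector(insideMask(imgA))
  expect_equal(imageFrames(img0)[1, valid], numeric(sum(valid))) # zero in, zero out
  expect_equal(imageFrames(imgS)[1, valid], 2.5 * imageFrames(imgA)[1, valid],
               tolerance = 1e-10) # linearity

  ## conductivity decrease appears as positive delta-Z at the true location
  z <- matrix(imageFrames(imgA)[1, ], 32, 32)
  zp <- pmax(z, 0); zp[is.na(zp)] <- 0
  ras <- recon@raster
  xs <- ras$cx - ras$half + (col(z) - 0.5) * ras$px
  ys <- ras$cy + ras$half - (row(z) - 0.5) * ras$px
  comx <- sum(xs * zp) / sum(zp)
  comy <- sum(ys * zp) / sum(zp)
  err <- sqrt((comx - mean(cc$cx[targ]))^2 + (comy - mean(cc$cy[targ]))^2)
  expect_lt(err, 0.15 * 2 * ras$half) # within 15% of the domain diameter
})

test_that("rasterization preserves constants and integrals", {
  coarse <- fixThoraxCoarse()
  ras <- fixRecon()@raster
  nEl <- nrow(coarse@elements)

  cst <- rasterize(rep(3.5, nEl), raster = ras)
  expect_equal(unique(cst$raster[cst$mask]), 3.5)
  expect_true(all(is.na(cst$raster[!cst$mask])))

  ## quadrature: coverage-weighted pixel sum matches the element integral
  set.seed(8)
  vals <- runif(nEl)
  pixInt <- sum(as.numeric(ras$W %*% vals)) * ras$pixelArea
  elInt <- sum(vals * lungeit:::triangleAreas(coarse@nodes, coarse@elements))
  expect_lt(abs(pixInt - elInt) / elInt, 0.02)

  ## mirror symmetry of the mask for a symmetric contour
  circ <- buildRaster(fixCircleMesh())
  expect_identical(circ$mask, circ$mask[, 32:1])
})
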