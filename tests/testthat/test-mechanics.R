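roiAll <- function(side) {
  structure(list(mask = matrix(TRUE, side, side), theta = NA, source = "t"),
            class = "ROIMask")
}

test_that("driving pressure and recruitment index follow their definitions", {
  expect_equal(deltaPawo(30, 15), 15)
  expect_error(deltaPawo(15, 15), "exceed")
  expect_true(recruitmentIndex(250, 160))
  expect_false(recruitmentIndex(200, 150))
  expect_true(recruitmentIndex(400, 0)) # boundary is inclusive
  expect_error(recruitmentIndex(-1, 100), "nonnegative")
})

test_that("compliance maps divide tidal delta-Z by driving pressure", {
  img <- matrix(3, 2, 2)
  expect_equal(cdynMap(img, 15, roiAll(2)), matrix(0.2, 2, 2))
  expect_equal(cdynMap(matrix(0, 2, 2), 15, roiAll(2)), matrix(0, 2, 2))
  neg <- cdynMap(matrix(-3, 2, 2), 15, roiAll(2))
  expect_equal(neg, matrix(-0.2, 2, 2)) # negative values retained
  expect_error(cdynMap(img, 0, roiAll(2)), "positive")
})

stackFrom <- function(cd, P) {
  ## cd: list of scalars per step, expanded to 2x2 maps
  maps <- lapply(cd, function(v) matrix(v, 2, 2))
  complianceStack(maps, P, paste0("S", seq_along(P)), "titration", roiAll(2))
}

test_that("C_max / P* extraction handles maxima, ties and invalid pixels", {
  st <- stackFrom(list(0.1, 0.3, 0.2), c(10, 15, 20))
  sm <- cmaxPstar(st)
  expect_equal(unique(as.vector(sm$cmax)), 0.3)
  expect_equal(unique(as.vector(sm$pstar)), 15)

  tied <- cmaxPstar(stackFrom(list(0.3, 0.3), c(10, 15)))
  expect_equal(unique(as.vector(tied$pstar)), 10) # lowest tied pressure

  bad <- cmaxPstar(stackFrom(list(-0.1, 0), c(10, 15)))
  expect_true(all(!bad$valid))
  expect_true(all(is.na(bad$pstar)))

  expect_error(cmaxPstar(stackFrom(list(0.3), 10)), "at least 2")
})

test_that("F(P) maps implement the compliance-loss fractions", {
  st <- stackFrom(list(0.3, 0.15, 0), c(10, 15, 20))
  sm <- cmaxPstar(st)
  expect_equal(unique(as.vector(odAtelMap(st, sm, 1)$F)), 0) # at the peak
  expect_equal(unique(as.vector(odAtelMap(st, sm, 2)$F)), 0.5)
  expect_equal(unique(as.vector(odAtelMap(st, sm, 3)$F)), 1) # fully overdistended

  ## atelectasis: zero compliance below P*
  st2 <- stackFrom(list(0, 0.3), c(10, 15))
  sm2 <- cmaxPstar(st2)
  expect_equal(unique(as.vector(odAtelMap(st2, sm2, 1)$F)), -1)
  expect_error(odAtelMap(st, sm, 9), "not in stack")
})

test_that("step summaries weight F by C_max over the ROI", {
  st <- stackFrom(list(0.3, 0.2), c(10, 15))
  sm <- cmaxPstar(st)
  z <- odAtelMap(st, sm, 1)
  s0 <- stepSummary(z, sm)
  expect_equal(s0$od_pct, 0)
  expect_equal(s0$atel_pct, 0)
  expect_equal(s0$pct_at_max, 100)

  ## uniform C_max, F = +0.2 on half the ROI, 0 elsewhere -> OD 10%
  z$F <- matrix(c(0.2, 0.2, 0, 0), 2, 2)
  s1 <- stepSummary(z, sm)
  expect_equal(s1$od_pct, 10)
  expect_equal(s1$atel_pct, 0)

  ## one pixel never contributes to both sides
  z$F <- matrix(c(-0.4, 0.4, 0, 0), 2, 2)
  s2 <- stepSummary(z, sm)
  expect_equal(s2$od_pct + s2$atel_pct, 100 * (0.4 + 0.4) / 4)
})

test_that("F obeys its bounds on random stacks and monotone stress cases", {
  set.seed(17)
  for (k in 1:25) {
    n <- sample(3:6, 1)
    P <- sort(runif(n, 5, 40))
    vals <- lapply(seq_len(n), function(i) matrix(runif(4, 0, 0.5), 2, 2))
    st <- complianceStack(vals, P, paste0("S", 1:n), "titration", roiAll(2))
    sm <- cmaxPstar(st)
    for (j in seq_len(n)) {
      Fv <- odAtelMap(st, sm, j)$F
      expect_true(all(Fv[sm$valid] >= -1 & Fv[sm$valid] <= 1))
      ss <- stepSummary(odAtelMap(st, sm, j), sm)
      expect_gte(ss$od_pct, 0)
      expect_gte(ss$atel_pct, 0)
      expect_lte(ss$od_pct + ss$atel_pct, 100 + 1e-9)
    }
    ## F at each pixel's own P* is exactly zero
    atPk <- odAtelMap(st, sm, which.min(abs(P - sm$pstar[1, 1])))$F[1, 1]
    if (P[which.min(abs(P - sm$pstar[1, 1]))] == sm$pstar[1, 1])
      expect_identical(atPk, 0)
  }

  ## strictly decreasing compliance: P* at the first pressure, F
  ## nondecreasing with P
  st <- stackFrom(list(0.4, 0.3, 0.2, 0.1), c(10, 15, 20, 25))
  sm <- cmaxPstar(st)
  expect_equal(unique(as.vector(sm$pstar)), 10)
  Fs <- vapply(1:4, function(j) odAtelMap(st, sm, j)$F[1, 1], numeric(1))
  expect_true(all(Fs >= 0))
  expect_true(all(diff(Fs) >= 0))
})

test_that("compliance correlation behaves like Pearson's r", {
  x <- c(0.1, 0.3, 0.2, 0.5, 0.4)
  expect_equal(complianceCorrelation(x, x)$r, 1)
  expect_equal(complianceCorrelation(x, -x)$r, -1)
  expect_error(complianceCorrelation(x[1:2], x[1:2]), "at least 3")
  expect_error(complianceCorrelation(x, rep(1, 5)), "variance")
  ## p-value from the t distribution with n - 2 df
  y <- c(0.12, 0.25, 0.24, 0.45, 0.38)
  cc <- complianceCorrelation(x, y)
  r <- cor(x, y)
  tstat <- r * sqrt(3 / (1 - r^2))
  expect_equal(cc$p, 2 * stats::pt(-abs(tstat), df = 3), tolerance = 1e-10)
})

test_that("P* and C_max are recovered on a noiseless titration", {
  fix <- fixRecoveryRun()
  sm <- fix$res$summaries$titration
  fields <- scenarioFields(fixThoraxFine(), fix$scenario)
  P <- fix$res$stacks$titration$pressures
  rasF <- fixFineRaster()
  truthC <- sapply(P, function(p) as.vector(
    rasterize(trueCdyn(fixThoraxFine(), fix$scenario, p, fields),
              raster = rasF)$raster))
  lungPix <- as.vector(rasterize(as.numeric(fields$lungMask),
                                 raster = rasF)$raster) > 0.5
  lungPix[is.na(lungPix)] <- FALSE
  tCmax <- apply(truthC, 1, function(z)
    if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE))
  tP <- P[vapply(seq_len(nrow(truthC)), function(i) {
    z <- truthC[i, ]
    if (all(is.na(z))) 1L else which.max(z)
  }, integer(1))]
  sel <- lungPix & as.vector(fix$res$roiAggregate$mask) & as.vector(sm$valid)
  expect_gt(sum(sel), 30)

  ## P* within one titration step (2 cm H2O) at >= 90% of evaluated pixels
  dp <- abs(as.vector(sm$pstar)[sel] - tP[sel])
  expect_gte(mean(dp <= 2), 0.90)

  ## C_max within 15% relative at the typical pixel, after one global gain
  rC <- as.vector(sm$cmax)[sel]
  tC <- tCmax[sel]
  g <- sum(rC * tC) / sum(rC^2)
  expect_lte(median(abs(g * rC - tC) / tC), 0.15)
})
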