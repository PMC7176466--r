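test_that("global signal averages valid pixels only", {
  frames <- matrix(5, nrow = 4, ncol = 4)
  img <- new("ImageSeries", frames = frames,
             insideMask = matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2),
             side = 2L, frameRate = 20, provenance = list())
  g <- globalSignal(img)
  expect_equal(g$values, rep(5, 4))

  ## masked pixels do not contribute
  frames2 <- frames
  frames2[, 3:4] <- NA # outside the mask
  frames2[, 1] <- 1:4
  frames2[, 2] <- 3
  img@frames <- frames2
  expect_equal(globalSignal(img)$values, (1:4 + 3) / 2)
})

test_that("dominant frequency picks the largest respiratory peak", {
  fs <- 20
  t <- seq(0, 60, by = 1 / fs)
  expect_lt(abs(dominantFrequency(sin(2 * pi * 0.4 * t), frameRate = fs) - 0.4),
            fs / 2^ceiling(log2(4 * length(t))) + 1e-9)
  two <- sin(2 * pi * 0.4 * t) + 0.3 * sin(2 * pi * 1.8 * t)
  expect_lt(abs(dominantFrequency(two, frameRate = fs) - 0.4), 0.02)
  expect_error(dominantFrequency(rep(2, 1200), frameRate = fs), "peak")
})

test_that("bandpass design hits the corners and attenuates the heart rate", {
  fs <- 20
  bp <- designBandpass(0.392, fs)
  expect_equal(bp$fUpper, 0.784)
  expect_equal(sum(bp$h), 0, tolerance = 1e-12) # exact DC null
  expect_equal(bp$h, rev(bp$h), tolerance = 1e-12) # linear phase

  gainDb <- function(f) { # two-pass (forward-backward) gain in dB
    H <- vapply(f, function(fi) Mod(sum(
      bp$h * exp(-1i * 2 * pi * fi / fs * (seq_along(bp$h) - 1)))), numeric(1))
    40 * log10(pmax(H, 1e-300))
  }
  ## upper corner within 10%
  grid <- seq(0.4, 2, by = 0.002)
  rel <- gainDb(grid) - gainDb(bp$fPeak)
  f3 <- grid[which(rel < -3)[1]]
  expect_lt(abs(f3 - bp$fUpper) / bp$fUpper, 0.10)
  ## respiratory gain preserved: two-pass gain at f_peak within 1 dB of unity
  expect_gt(gainDb(bp$fPeak), -1)
  expect_lt(abs(gainDb(bp$fPeak)), 0.01)
  ## cardiac component attenuated by more than 3 dB
  expect_lt(gainDb(1.8) - gainDb(bp$fPeak), -3)
  expect_error(designBandpass(6, fs), "Nyquist")
})

test_that("zero-phase filtering preserves peak positions and removes DC", {
  fs <- 20
  bp <- designBandpass(0.4, fs)
  ## symmetric triangular pulse keeps its peak index
  pulse <- numeric(2001)
  pulse[900:1100] <- c(1:101, 100:1) / 101
  pf <- zeroPhaseFilter(pulse, bp)
  expect_identical(which.max(pf), which.max(pulse))

  ## in-band sinusoid: zero lag of the cross-correlation
  t <- seq(0, 100, by = 1 / fs)
  x <- sin(2 * pi * 0.4 * t)
  xf <- zeroPhaseFilter(x, bp)
  ccf <- stats::ccf(xf, x, lag.max = 10, plot = FALSE)
  expect_identical(ccf$lag[which.max(ccf$acf)], 0)

  ## DC offset removed
  xo <- x + 5
  xof <- zeroPhaseFilter(xo, bp)
  expect_lt(abs(mean(xof)), 0.01 * 5)

  expect_error(zeroPhaseFilter(numeric(100), bp), "too short")
})

test_that("breath detection finds alternating extrema at known phases", {
  fs <- 20
  t <- seq(0, 30, by = 1 / fs)
  bt <- detectBreaths(sin(2 * pi * 0.4 * t), frameRate = fs)
  expect_identical(nrow(bt), 12L)
  expect_true(all(bt$insp_frame < bt$exp_frame))
  ## known phases: maxima at (k + 0.25)/0.4 s, minima at (k + 0.75)/0.4 s
  kin <- round(((seq_len(12) - 1) + 0.25) / 0.4 * fs) + 1
  kex <- round(((seq_len(12) - 1) + 0.75) / 0.4 * fs) + 1
  expect_true(all(abs(bt$insp_frame - kin) <= 1))
  expect_true(all(abs(bt$exp_frame - kex) <= 1))

  expect_warning(bt0 <- detectBreaths(rep(1, 100), frameRate = fs), "extrema")
  expect_identical(nrow(bt0), 0L)
})

test_that("breath tables alternate on noisy inputs", {
  fs <- 20
  set.seed(123)
  bp <- designBandpass(0.4, fs)
  for (k in 1:5) {
    x <- sin(2 * pi * 0.4 * seq(0, 40, by = 1 / fs)) + rnorm(801, sd = 0.8)
    bt <- detectBreaths(zeroPhaseFilter(x, bp), frameRate = fs)
    expect_true(all(bt$insp_frame < bt$exp_frame))
    if (nrow(bt) > 1) {
      ## non-overlapping, time-ordered: next inspiration after this expiration
      expect_true(all(bt$insp_frame[-1] > bt$exp_frame[-nrow(bt)]))
    }
  }
})

test_that("tidal difference image averages inspiration-expiration pairs", {
  side <- 4L
  f1 <- matrix(0, 6, side^2)
  f1[2, ] <- 3; f1[5, ] <- 1 # breath 1: insp frame 2, exp frame 3 (zeros)
  img <- makeImageSeries(f1, side)
  one <- tidalDifferenceImage(img, data.frame(insp_frame = 2, exp_frame = 3))
  expect_equal(one, matrix(3, side, side))
  two <- tidalDifferenceImage(
    img, data.frame(insp_frame = c(2, 5), exp_frame = c(3, 6)))
  expect_equal(two, matrix((3 + 1) / 2, side, side))
  expect_error(tidalDifferenceImage(img, lungeit:::emptyBreathTable()), "empty")
})

test_that("detection metrics reproduce the printed sensitivity arithmetic", {
  ## 1087 true breaths spaced 50 frames apart; 43 missed, no false positives
  truth <- data.frame(insp_frame = seq_len(1087) * 50,
                      exp_frame = seq_len(1087) * 50 + 20)
  detected <- truth[-seq_len(43), ]
  m <- detectionMetrics(detected, truth, frameRate = 20)
  expect_equal(m$TP, 1044)
  expect_equal(m$FN, 43)
  expect_equal(m$sensitivity, 96.0, tolerance = 0.05)

  perfect <- detectionMetrics(truth, truth, frameRate = 20)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)

  none <- detectionMetrics(lungeit:::emptyBreathTable(), truth, frameRate = 20)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$FP, 0)
})
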