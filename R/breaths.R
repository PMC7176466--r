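## Respiratory-band isolation and breath detection: global signal, dominant
## frequency, auto-configured zero-phase FIR bandpass, extrema-based
## peak-inspiration/peak-expiration detection, intra-tidal difference images
## and detection-accuracy metrics.

#' Global impedance signal of an image series
#'
#' Per-frame mean of delta-Z over all valid pixels.
#'
#' @param images an \linkS4class{ImageSeries}.
#' @return list with \code{values} (numeric per frame) and \code{frameRate}.
#' @export
globalSignal <- function(images) {
  if (nrow(images@frames) == 0L) stop("empty image series")
  valid <- as.vector(images@insideMask)
  if (!any(valid)) stop("all pixels masked")
  vals <- rowMeans(images@frames[, valid, drop = FALSE])
  if (anyNA(vals)) stop("masked values inside the valid region")
  structure(list(values = vals, frameRate = images@frameRate),
            class = "GlobalSignal")
}

asGlobalSignal <- function(x, frameRate = NULL) {
  if (inherits(x, "GlobalSignal")) return(x)
  if (is.null(frameRate)) stop("frameRate required for a bare numeric signal")
  structure(list(values = as.numeric(x), frameRate = frameRate),
            class = "GlobalSignal")
}

#' Dominant spectral frequency above a floor
#'
#' Mean-detrended, Hann-tapered magnitude spectrum, zero-padded to at least
#' four times the series length; returns the frequency of the largest peak
#' above \code{fMin}.
#'
#' @param signal a \code{globalSignal} result, or a numeric vector with
#'   \code{frameRate} supplied.
#' @param fMin lower frequency bound in Hz.
#' @param frameRate sampling rate when \code{signal} is a bare vector.
#' @return the peak frequency in Hz.
#' @export
dominantFrequency <- function(signal, fMin = 0.01, frameRate = NULL) {
  sig <- asGlobalSignal(signal, frameRate)
  x <- sig$values - mean(sig$values)
  n <- length(x)
  if (n < 8L) stop("signal too short")
  taper <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  x <- x * taper
  nfft <- 2^ceiling(log2(4L * n))
  spec <- Mod(fft(c(x, numeric(nfft - n))))[seq_len(nfft %/% 2)]
  freq <- (seq_len(nfft %/% 2) - 1) * sig$frameRate / nfft
  band <- freq > fMin
  if (!any(band) || max(spec[band]) <= 1e-12 * max(1, max(spec)))
    stop("no spectral peak above the frequency floor")
  fpk <- freq[band][which.max(spec[band])]
  ## require at least two full cycles at the candidate frequency
  if (fpk * n / sig$frameRate < 2)
    stop("fewer than two full cycles at the candidate frequency")
  fpk
}

#' Design the respiratory bandpass filter
#'
#' Linear-phase FIR bandpass with the upper corner set to twice the dominant
#' respiratory frequency. The taps are de-meaned so the DC gain is exactly
#' zero (the nominal 0.01 Hz lower corner is not realizable at this filter
#' length; its only role is to exclude the mean). The upper cutoff is
#' calibrated numerically so that the zero-phase (forward-backward) response
#' crosses -3 dB at \code{2 * fPeak}.
#'
#' @param fPeak dominant respiratory frequency, Hz.
#' @param frameRate sampling rate, Hz.
#' @param nTaps filter length (default 128).
#' @param fLower nominal lower corner, Hz.
#' @return list of class \code{BandpassSpec}: coefficients \code{h},
#'   effective two-pass kernel \code{g}, corners, \code{frameRate},
#'   \code{nTaps}.
#' @export
designBandpass <- function(fPeak, frameRate, nTaps = 128L, fLower = 0.01) {
  fUpper <- 2 * fPeak
  if (fUpper >= frameRate / 2) stop("upper corner at or above Nyquist")
  if (fLower <= 0 || fLower >= fUpper) stop("invalid lower corner")
  nyq <- frameRate / 2

  twoPassGainDb <- function(h, f) {
    w <- 2 * pi * f / frameRate
    H <- vapply(w, function(wi) {
      Mod(sum(h * exp(-1i * wi * (seq_along(h) - 1))))
    }, numeric(1))
    40 * log10(pmax(H, 1e-300)) # forward-backward: |H|^2
  }

  design <- function(fc) {
    h <- signal::fir1(nTaps - 1L, c(fLower, fc) / nyq, type = "pass")
    h <- as.numeric(h)
    h - mean(h) # exact DC null
  }

  ## calibrate the cutoff so the two-pass -3 dB crossing sits at fUpper
  fc <- fUpper
  h <- design(fc)
  for (i in 1:6) {
    grid <- seq(fPeak, min(nyq * 0.98, 4 * fUpper), length.out = 400)
    g <- twoPassGainDb(h, grid) - twoPassGainDb(h, fPeak)
    cross <- which(g < -3)[1]
    if (is.na(cross) || cross == 1L) break
    f3 <- approx(g[(cross - 1):cross], grid[(cross - 1):cross], xout = -3)$y
    if (abs(f3 - fUpper) < 0.005 * fUpper) break
    fc <- fc * fUpper / f3
    if (fc >= nyq * 0.98) { fc <- nyq * 0.95; h <- design(fc); break }
    h <- design(fc)
  }
  ## normalize to unit gain at the respiratory peak so the tidal amplitude
  ## is preserved through filtering
  wpk <- 2 * pi * fPeak / frameRate
  h <- h / Mod(sum(h * exp(-1i * wpk * (seq_along(h) - 1))))
  g <- signal::conv(h, rev(h)) # symmetric two-pass kernel

  structure(
    list(
      h = h, g = as.numeric(g), fLower = fLower, fUpper = fUpper,
      fPeak = fPeak, frameRate = frameRate, nTaps = as.integer(nTaps)
    ),
    class = "BandpassSpec"
  )
}

#' Zero-phase bandpass filtering
#'
#' Forward-backward application of the designed FIR (equivalently, one pass
#' of its symmetric autocorrelation kernel), with reflect padding at the
#' edges; the group delay is zero, so extrema positions are preserved. For
#' an \linkS4class{ImageSeries}, every pixel series is filtered identically.
#'
#' @param x numeric vector, matrix (frames in rows), \code{globalSignal}
#'   result, or \linkS4class{ImageSeries}.
#' @param spec a \code{\link{designBandpass}} result.
#' @return the filtered object, same type as the input.
#' @export
zeroPhaseFilter <- function(x, spec) {
  g <- spec$g
  half <- (length(g) - 1L) %/% 2L
  filtMat <- function(M) {
    n <- nrow(M)
    if (n <= 3L * spec$nTaps)
      stop("series too short for zero-phase filtering (need > 3 * nTaps frames)")
    pad <- min(half + 1L, n - 1L)
    idxTop <- (pad + 1L):2L
    idxBot <- (n - 1L):(n - pad)
    Mp <- rbind(M[idxTop, , drop = FALSE], M, M[idxBot, , drop = FALSE])
    F <- stats::filter(Mp, g, method = "convolution", sides = 2L)
    matrix(F[(pad + 1L):(pad + n), ], n, ncol(M))
  }
  if (inherits(x, "ImageSeries")) {
    valid <- as.vector(x@insideMask)
    out <- x@frames
    out[, valid] <- filtMat(x@frames[, valid, drop = FALSE])
    res <- x
    res@frames <- out
    return(res)
  }
  if (inherits(x, "GlobalSignal")) {
    res <- x
    res$values <- as.numeric(filtMat(matrix(x$values, ncol = 1L)))
    return(res)
  }
  if (is.matrix(x)) return(filtMat(x))
  as.numeric(filtMat(matrix(x, ncol = 1L)))
}

localExtrema <- function(v) {
  d <- diff(v)
  s <- sign(d)
  ## carry signs through flat stretches
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  chg <- which(diff(s) != 0) + 1L
  if (!length(chg)) return(data.frame(idx = integer(), type = character()))
  data.frame(
    idx = chg,
    type = ifelse(s[chg - 1L] > 0, "max", "min"),
    stringsAsFactors = FALSE
  )
}

#' Detect breaths from a filtered global signal
#'
#' Local maxima are peak-inspiration and the following local minimum
#' peak-expiration. Extrema are taken from sign changes of the discrete
#' derivative; swings smaller than 20\% of the signal's interquartile
#' amplitude are discarded; output is strictly alternating
#' inspiration-expiration pairs, with unpaired leading/trailing extrema
#' dropped.
#'
#' @param filtered a filtered \code{globalSignal} result (or numeric vector
#'   with \code{frameRate}).
#' @param frameRate sampling rate when a bare vector is given.
#' @param prominenceFrac minimum swing as a fraction of the interquartile
#'   amplitude.
#' @return data.frame (class \code{BreathTable}): breath_id, insp_frame,
#'   exp_frame, insp_time_s, exp_time_s, quality.
#' @export
detectBreaths <- function(filtered, frameRate = NULL, prominenceFrac = 0.20) {
  sig <- asGlobalSignal(filtered, frameRate)
  v <- sig$values
  ex <- localExtrema(v)
  thr <- prominenceFrac * IQR(v)

  mergeSame <- function(ex) {
    ## collapse runs of same-type extrema, keeping the most extreme
    if (nrow(ex) < 2L) return(ex)
    keepIdx <- 1L
    for (i in 2L:nrow(ex)) {
      last <- keepIdx[length(keepIdx)]
      if (ex$type[i] == ex$type[last]) {
        better <- if (ex$type[i] == "max") v[ex$idx[i]] > v[ex$idx[last]]
                  else v[ex$idx[i]] < v[ex$idx[last]]
        if (better) keepIdx[length(keepIdx)] <- i
      } else {
        keepIdx <- c(keepIdx, i)
      }
    }
    ex[keepIdx, , drop = FALSE]
  }
  ex <- mergeSame(ex)
  ## prune alternating extrema whose swing is below the prominence threshold
  while (nrow(ex) >= 2L) {
    swings <- abs(diff(v[ex$idx]))
    if (min(swings) >= thr) break
    k <- which.min(swings)
    ex <- mergeSame(ex[-c(k, k + 1L), , drop = FALSE])
  }
  if (nrow(ex) < 2L) {
    warning("no valid extrema; empty breath table")
    return(emptyBreathTable())
  }
  ## pair each max with the following min
  breaths <- NULL
  for (i in seq_len(nrow(ex) - 1L)) {
    if (ex$type[i] == "max" && ex$type[i + 1L] == "min") {
      breaths <- rbind(breaths, c(ex$idx[i], ex$idx[i + 1L]))
    }
  }
  if (is.null(breaths)) {
    warning("no inspiration-expiration pairs; empty breath table")
    return(emptyBreathTable())
  }
  fps <- sig$frameRate
  out <- data.frame(
    breath_id = seq_len(nrow(breaths)),
    insp_frame = breaths[, 1], exp_frame = breaths[, 2],
    insp_time_s = (breaths[, 1] - 1) / fps,
    exp_time_s = (breaths[, 2] - 1) / fps,
    quality = "ok", stringsAsFactors = FALSE
  )
  class(out) <- c("BreathTable", "data.frame")
  out
}

emptyBreathTable <- function() {
  out <- data.frame(
    breath_id = integer(), insp_frame = integer(), exp_frame = integer(),
    insp_time_s = numeric(), exp_time_s = numeric(),
    quality = character(), stringsAsFactors = FALSE
  )
  class(out) <- c("BreathTable", "data.frame")
  out
}

#' Intra-tidal difference image
#'
#' Mean over accepted breaths of (peak-inspiration frame minus
#' peak-expiration frame), per pixel; negative pixels are retained.
#'
#' @param filteredImages filtered \linkS4class{ImageSeries}.
#' @param table a breath table from \code{\link{detectBreaths}}.
#' @return side x side delta-Z matrix (NA outside the mask).
#' @export
tidalDifferenceImage <- function(filteredImages, table) {
  if (nrow(table) < 1L) stop("breath table is empty")
  Fm <- filteredImages@frames
  D <- Fm[table$insp_frame, , drop = FALSE] - Fm[table$exp_frame, , drop = FALSE]
  img <- colMeans(D)
  matrix(img, filteredImages@side, filteredImages@side)
}

#' Breath-detection accuracy against ground truth
#'
#' Greedy one-to-one matching of detected to true peak-inspiration times
#' within a tolerance. Each inter-breath period counts as one true negative
#' unless it contains a false detection.
#'
#' @param detected,truth breath tables (frames on the same time base).
#' @param frameRate frames per second.
#' @param matchTolS matching tolerance in seconds.
#' @return list: TP, FN, FP, TN, sensitivity, specificity (percent), and
#'   the matched index pairs.
#' @export
detectionMetrics <- function(detected, truth, frameRate, matchTolS = 0.5) {
  if (nrow(truth) > 1L && any(diff(truth$insp_frame) <= 0))
    stop("overlapping or unordered truth breaths")
  tolF <- matchTolS * frameRate
  dt <- detected$insp_frame
  tr <- truth$insp_frame
  pairs <- expand.grid(d = seq_along(dt), t = seq_along(tr))
  if (nrow(pairs)) {
    pairs$err <- abs(dt[pairs$d] - tr[pairs$t])
    pairs <- pairs[pairs$err <= tolF, , drop = FALSE]
    pairs <- pairs[order(pairs$err), , drop = FALSE]
  }
  usedD <- logical(length(dt)); usedT <- logical(length(tr))
  match <- NULL
  for (r in seq_len(nrow(pairs))) {
    d <- pairs$d[r]; t <- pairs$t[r]
    if (!usedD[d] && !usedT[t]) {
      usedD[d] <- TRUE; usedT[t] <- TRUE
      match <- rbind(match, c(d, t))
    }
  }
  TP <- sum(usedT)
  FN <- sum(!usedT)
  FP <- sum(!usedD)
  ## inter-breath segments bounded by true inspiration peaks
  nSeg <- length(tr) + 1L
  fpFrames <- dt[!usedD]
  segWithFp <- if (length(fpFrames)) {
    length(unique(findInterval(fpFrames, sort(tr)))) } else 0L
  TN <- nSeg - segWithFp
  list(
    TP = TP, FN = FN, FP = FP, TN = TN,
    sensitivity = 100 * TP / max(TP + FN, 1L),
    specificity = 100 * TN / max(TN + FP, 1L),
    matches = match
  )
}
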