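## Functional-EIT lung segmentation: per-pixel standard deviation of the
## filtered delta-Z series, thresholded at a fraction of its maximum; the
## threshold is chosen automatically as the most classification-stable grid
## value, and per-step masks are merged by logical OR.

#' Functional EIT image
#'
#' Per-pixel sample standard deviation of delta-Z over the frames of a
#' (bandpass-filtered) image series.
#'
#' @param filteredImages an \linkS4class{ImageSeries}.
#' @return list of class \code{FEITImage}: \code{sd} (side x side matrix,
#'   NA outside the mask), \code{mask}, \code{source}.
#' @export
feitImage <- function(filteredImages) {
  if (nrow(filteredImages@frames) < 2L)
    stop("need at least 2 frames for a standard deviation")
  s <- apply(filteredImages@frames, 2L, sd)
  m <- matrix(s, filteredImages@side, filteredImages@side)
  m[!filteredImages@insideMask] <- NA_real_
  structure(
    list(sd = m, mask = filteredImages@insideMask,
         source = filteredImages@provenance$step_label %||% ""),
    class = "FEITImage"
  )
}

#' Threshold a functional EIT image into a lung ROI
#'
#' A pixel belongs to the ROI iff its standard deviation is at least
#' \code{theta} times the maximum standard deviation over valid pixels.
#'
#' @param feit a \code{\link{feitImage}} result.
#' @param theta threshold in [0, 1].
#' @return list of class \code{ROIMask}: logical \code{mask} (side x side),
#'   \code{theta}, \code{source}.
#' @export
roiFromThreshold <- function(feit, theta) {
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  mx <- max(feit$sd, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("all-zero functional EIT image")
  mask <- !is.na(feit$sd) & feit$sd >= theta * mx
  structure(list(mask = mask, theta = theta, source = feit$source),
            class = "ROIMask")
}

#' Automatic fEIT threshold selection
#'
#' For each grid value, counts the pixels classified inconsistently against
#' the ROI at theta - 0.025 and theta + 0.025 (symmetric differences) and
#' returns the most stable threshold; ties break towards the value closest
#' to 0.25, then the lower theta.
#'
#' @param feit a \code{\link{feitImage}} result.
#' @param grid candidate thresholds.
#' @return the selected theta.
#' @export
autoThreshold <- function(feit, grid = seq(0.05, 0.60, by = 0.025)) {
  if (any(grid < 0.025) || any(grid > 0.975)) stop("grid outside [0.025, 0.975]")
  roiAt <- function(th) roiFromThreshold(feit, th)$mask
  inc <- vapply(grid, function(th) {
    r0 <- roiAt(th)
    sum(xor(r0, roiAt(th - 0.025))) + sum(xor(r0, roiAt(th + 0.025)))
  }, numeric(1))
  cand <- which(inc == min(inc))
  cand <- cand[order(abs(grid[cand] - 0.25), grid[cand])]
  grid[cand[1]]
}

#' Aggregate lung ROI over protocol steps
#'
#' Pixelwise logical OR of per-step ROI masks.
#'
#' @param masks list of \code{\link{roiFromThreshold}} results.
#' @return an aggregate \code{ROIMask} with source \code{"aggregate"}.
#' @export
aggregateRoi <- function(masks) {
  if (!length(masks)) stop("need at least one mask")
  dims <- lapply(masks, function(m) dim(m$mask))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("mask geometry mismatch")
  agg <- Reduce(`|`, lapply(masks, `[[`, "mask"))
  structure(list(mask = agg, theta = NA_real_, source = "aggregate"),
            class = "ROIMask")
}
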