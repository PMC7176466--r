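#' @import methods
#' @importFrom Matrix sparseMatrix Cholesky forceSymmetric solve t crossprod
#' @importFrom stats filter fft cor.test sd quantile IQR median approx rnorm runif
#' @importFrom utils read.csv write.csv head tail
NULL

#' Two-dimensional finite-element thorax model
#'
#' Triangular mesh of the chest cross-section at the electrode plane, with 16
#' point electrodes on the boundary. Electrodes are numbered clockwise in the
#' radiological convention (ventral at image top, patient right at image
#' left): electrodes 1 and 16 flank the ventral midline, 8 and 9 the dorsal
#' midline.
#'
#' @slot nodes numeric matrix (n_nodes x 2) of vertex coordinates.
#' @slot elements integer matrix (n_elements x 3) of node indices per
#'   triangle, positively oriented.
#' @slot boundary integer vector of boundary node indices, ordered along the
#'   contour.
#' @slot electrodeNodes integer vector of 16 boundary node indices.
#' @slot refinement character, \code{"coarse"} or \code{"fine"}.
#' @slot contour numeric matrix of the generating contour polygon.
#' @export
setClass("EitMesh",
  representation(
    nodes = "matrix",
    elements = "matrix",
    boundary = "integer",
    electrodeNodes = "integer",
    refinement = "character",
    contour = "matrix"
  )
)

setValidity("EitMesh", function(object) {
  msg <- character()
  nd <- object@nodes
  el <- object@elements
  if (ncol(nd) != 2L) msg <- c(msg, "nodes must be an n x 2 matrix")
  if (ncol(el) != 3L) msg <- c(msg, "elements must be an n x 3 matrix")
  if (max(el) > nrow(nd) || min(el) < 1L)
    msg <- c(msg, "element indices out of range")
  ar <- triangleAreas(nd, el)
  if (any(ar <= 0))
    msg <- c(msg, "all triangles must be positively oriented and non-degenerate")
  if (!all(object@electrodeNodes %in% object@boundary))
    msg <- c(msg, "every electrode node must lie on the boundary")
  if (anyDuplicated(object@electrodeNodes))
    msg <- c(msg, "electrode nodes must be distinct")
  if (!object@refinement %in% c("coarse", "fine"))
    msg <- c(msg, "refinement must be 'coarse' or 'fine'")
  ## connectivity: every node reachable from node 1 through shared elements
  if (!meshConnected(nrow(nd), el))
    msg <- c(msg, "mesh must be connected")
  if (length(msg)) msg else TRUE
})

#' Adjacent stimulation/measurement pattern
#'
#' Current is driven through adjacent electrode pairs; voltages are read on
#' all adjacent pairs not involving a driving electrode, giving
#' n_M = n_electrodes * (n_electrodes - 3) retained measurements.
#'
#' @slot injections integer matrix (n_inj x 2) of driving electrode pairs.
#' @slot measChannels integer matrix (n_M x 4): injection electrodes (a, b)
#'   and measurement electrodes (m1, m2) per retained channel.
#' @slot currentAmplitude numeric, nominal drive current (mA rms); scale only.
#' @slot nMeasurements integer, total retained measurements.
#' @export
setClass("StimPattern",
  representation(
    injections = "matrix",
    measChannels = "matrix",
    currentAmplitude = "numeric",
    nMeasurements = "integer"
  )
)

setValidity("StimPattern", function(object) {
  msg <- character()
  mc <- object@measChannels
  if (nrow(mc) != object@nMeasurements)
    msg <- c(msg, "nMeasurements must match measChannels rows")
  if (any(mc[, 3] %in% c(mc[, 1], mc[, 2])) || any(mc[, 4] == mc[, 1]) ||
      any(mc[, 4] == mc[, 2])) {
    bad <- mc[, 3] == mc[, 1] | mc[, 3] == mc[, 2] |
      mc[, 4] == mc[, 1] | mc[, 4] == mc[, 2]
    if (any(bad))
      msg <- c(msg, "measurements must not involve a driving electrode")
  }
  if (length(msg)) msg else TRUE
})

#' Boundary-voltage frame series
#'
#' @slot frames numeric matrix, one row per time frame, one column per
#'   measurement channel.
#' @slot frameRate numeric, frames per second.
#' @slot metadata list (pattern hash, units, seed, ...).
#' @export
setClass("VoltageSeries",
  representation(frames = "matrix", frameRate = "numeric", metadata = "list")
)

setValidity("VoltageSeries", function(object) {
  msg <- character()
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a positive scalar")
  if (anyNA(object@frames)) msg <- c(msg, "frames must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Regional impedance-change image series
#'
#' Frames of regional impedance change (delta-Z) on a 32 x 32 raster in the
#' radiological convention. Pixels outside the thorax contour are invalid.
#'
#' @slot frames numeric matrix, time x (side^2), pixels flattened in R
#'   column-major order of the side x side raster.
#' @slot insideMask logical matrix (side x side), TRUE for pixels inside the
#'   thorax with sufficient coverage.
#' @slot side integer raster side length.
#' @slot frameRate numeric, frames per second.
#' @slot provenance list (reference description, lambda, noise figure, ...).
#' @export
setClass("ImageSeries",
  representation(
    frames = "matrix",
    insideMask = "matrix",
    side = "integer",
    frameRate = "numeric",
    provenance = "list"
  )
)

setValidity("ImageSeries", function(object) {
  msg <- character()
  if (ncol(object@frames) != object@side^2)
    msg <- c(msg, "frames columns must equal side^2")
  if (!identical(dim(object@insideMask), c(object@side, object@side)))
    msg <- c(msg, "insideMask must be side x side")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
  if (length(msg)) msg else TRUE
})

#' One-step Gauss-Newton reconstruction model
#'
#' Holds the linear reconstruction map B = (J'J + lambda^2 R)^-1 J' restricted
#' to conductivity parameters, together with the regularization that produced
#' it and the achieved noise figure.
#'
#' @slot B numeric matrix (n_elements x n_M) linear reconstruction map
#'   (movement parameters, if estimated, already discarded).
#' @slot lambda numeric regularization parameter.
#' @slot regularizer list describing the prior (blocks, movement flag).
#' @slot noiseFigure numeric, noise figure achieved at \code{lambda}.
#' @slot jacobian numeric matrix, the (normalized) Jacobian used.
#' @slot mesh the coarse \linkS4class{EitMesh} the model lives on.
#' @slot raster list with the rasterization operator for 32 x 32 output.
#' @export
setClass("ReconModel",
  representation(
    B = "matrix",
    lambda = "numeric",
    regularizer = "list",
    noiseFigure = "numeric",
    jacobian = "matrix",
    mesh = "EitMesh",
    raster = "list"
  )
)

setValidity("ReconModel", function(object) {
  if (!all(is.finite(object@B))) "B must be finite" else TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "EitMesh", function(object) {
  cat(sprintf(
    "EitMesh (%s): %d nodes, %d elements, %d boundary nodes, %d electrodes\n",
    object@refinement, nrow(object@nodes), nrow(object@elements),
    length(object@boundary), length(object@electrodeNodes)
  ))
})

setMethod("show", "StimPattern", function(object) {
  cat(sprintf(
    "StimPattern: adjacent drive, %d injections, %d measurements (%.1f mA rms)\n",
    nrow(object@injections), object@nMeasurements, object@currentAmplitude
  ))
})

setMethod("show", "VoltageSeries", function(object) {
  cat(sprintf(
    "VoltageSeries: %d frames x %d channels at %g Hz\n",
    nrow(object@frames), ncol(object@frames), object@frameRate
  ))
})

setMethod("show", "ImageSeries", function(object) {
  cat(sprintf(
    "ImageSeries: %d frames, %dx%d raster (%d valid pixels) at %g Hz\n",
    nrow(object@frames), object@side, object@side,
    sum(object@insideMask), object@frameRate
  ))
})

setMethod("show", "ReconModel", function(object) {
  cat(sprintf(
    "ReconModel: %d elements x %d channels, lambda = %.4g, noise figure = %.3f%s\n",
    nrow(object@B), ncol(object@B), object@lambda, object@noiseFigure,
    if (isTRUE(object@regularizer$movement)) " (electrode movement modeled)" else ""
  ))
})

## ---- accessors -------------------------------------------------------------

#' @rdname accessors
#' @param object an object of one of the package classes.
#' @export
setGeneric("meshNodes", function(object) standardGeneric("meshNodes"))
#' @rdname accessors
#' @export
setGeneric("meshElements", function(object) standardGeneric("meshElements"))
#' @rdname accessors
#' @export
setGeneric("electrodeNodes", function(object) standardGeneric("electrodeNodes"))
#' @rdname accessors
#' @export
setGeneric("voltageFrames", function(object) standardGeneric("voltageFrames"))
#' @rdname accessors
#' @export
setGeneric("imageFrames", function(object) standardGeneric("imageFrames"))
#' @rdname accessors
#' @export
setGeneric("insideMask", function(object) standardGeneric("insideMask"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("nMeasurements", function(object) standardGeneric("nMeasurements"))

#' Accessors for package classes
#'
#' @name accessors
#' @return the corresponding slot content.
NULL

#' @rdname accessors
#' @export
setMethod("meshNodes", "EitMesh", function(object) object@nodes)
#' @rdname accessors
#' @export
setMethod("meshElements", "EitMesh", function(object) object@elements)
#' @rdname accessors
#' @export
setMethod("electrodeNodes", "EitMesh", function(object) object@electrodeNodes)
#' @rdname accessors
#' @export
setMethod("voltageFrames", "VoltageSeries", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("imageFrames", "ImageSeries", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("insideMask", "ImageSeries", function(object) object@insideMask)
#' @rdname accessors
#' @export
setMethod("frameRate", "VoltageSeries", function(object) object@frameRate)
#' @rdname accessors
#' @export
setMethod("frameRate", "ImageSeries", function(object) object@frameRate)
#' @rdname accessors
#' @export
setMethod("nMeasurements", "StimPattern", function(object) object@nMeasurements)
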