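## Normalized-difference one-step Gauss-Newton imaging:
##   x_hat = (J'J + lambda^2 R)^-1 J' y,   y = (V - V_ref) / V_ref
## with a Laplacian smoothness prior on conductivity, an optional
## electrode-movement block, lambda calibrated to a target noise figure, and
## delta-Z = -x_hat rasterized onto a 32 x 32 grid (radiological convention).

#' Peak-expiration voltage reference
#'
#' Two-pass contract: without a breath table, the reference is the average of
#' the frames in the lowest decile of the per-frame mean voltage (provisional
#' pass); with a breath table, it is the average of the frames at detected
#' peak-expiration indices +/- 1 frame.
#'
#' @param series a \linkS4class{VoltageSeries} of raw voltages.
#' @param breathTable optional data.frame with an \code{exp_frame} column.
#' @return numeric reference vector (one entry per channel).
#' @export
peakExpirationReference <- function(series, breathTable = NULL) {
  V <- series@frames
  if (nrow(V) == 0L) stop("no frames")
  pass1 <- function() {
    ms <- rowMeans(V)
    thr <- quantile(ms, 0.10)
    colMeans(V[ms <= thr, , drop = FALSE])
  }
  if (is.null(breathTable)) return(pass1())
  if (nrow(breathTable) == 0L) {
    warning("no detected expirations; falling back to provisional reference")
    return(pass1())
  }
  if (nrow(breathTable) < 2L) stop("need at least 2 breaths for a pass-2 reference")
  idx <- unique(pmin(pmax(
    rep(breathTable$exp_frame, each = 3L) + (-1L):1L, 1L
  ), nrow(V)))
  colMeans(V[idx, , drop = FALSE])
}

#' Normalized voltage difference
#'
#' @param V numeric vector or frames matrix (rows = frames).
#' @param Vref reference vector, elementwise nonzero.
#' @return \code{(V - Vref) / Vref}, same shape as \code{V}.
#' @export
normalizedDifference <- function(V, Vref) {
  zero <- which(Vref == 0)
  if (length(zero))
    stop(sprintf("zero reference voltage in channel(s) %s",
                 paste(head(zero, 5), collapse = ", ")))
  if (is.matrix(V)) {
    sweep(sweep(V, 2L, Vref, "-"), 2L, Vref, "/")
  } else {
    (V - Vref) / Vref
  }
}

elementAdjacency <- function(mesh) {
  el <- mesh@elements
  edges <- rbind(
    cbind(el[, 1], el[, 2]), cbind(el[, 2], el[, 3]), cbind(el[, 3], el[, 1])
  )
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  owner <- rep(seq_len(nrow(el)), 3L)
  sp <- split(owner, key)
  pairs <- do.call(rbind, lapply(sp[lengths(sp) == 2L], function(z) c(z[1], z[2])))
  pairs
}

#' Regularization structure for the inverse problem
#'
#' Conductivity block: graph Laplacian over the element adjacency (smoothness
#' prior). Movement block (optional): identity over the 2 n_E electrode
#' displacement parameters. Blocks are independently scalable.
#'
#' @param meshCoarse reconstruction mesh.
#' @param includeMovement logical, add the electrode-movement block.
#' @param nElectrodes electrode count (movement block size is twice this).
#' @return list with \code{Rcond}, \code{movement}, \code{nE},
#'   \code{movementScale}.
#' @export
buildRegularizer <- function(meshCoarse, includeMovement = TRUE,
                             nElectrodes = 16L) {
  nEl <- nrow(meshCoarse@elements)
  pr <- elementAdjacency(meshCoarse)
  deg <- tabulate(c(pr[, 1], pr[, 2]), nbins = nEl)
  L <- matrix(0, nEl, nEl)
  L[cbind(pr[, 1], pr[, 2])] <- -1
  L[cbind(pr[, 2], pr[, 1])] <- -1
  diag(L) <- deg
  list(
    Rcond = L, movement = includeMovement, nE = as.integer(nElectrodes),
    movementScale = 1
  )
}

assembleR <- function(rspec, nN) {
  if (!rspec$movement) return(rspec$Rcond)
  nMv <- 2L * rspec$nE
  R <- matrix(0, nN + nMv, nN + nMv)
  R[seq_len(nN), seq_len(nN)] <- rspec$Rcond
  diag(R)[nN + seq_len(nMv)] <- rspec$movementScale
  R
}

centralElement <- function(mesh) {
  cc <- elementCentroidsNorm(mesh)
  which.min(cc$xn^2 + cc$yn^2)
}

#' Noise figure of a linear reconstruction map
#'
#' Ratio of measurement-domain to image-domain signal-to-noise for a small
#' central target: with y_t = J x_t for a one-element central target x_t and
#' channel-iid unit-variance noise n,
#' NF = (mean|B n| / mean|B y_t|) * (mean|y_t| / mean|n|), evaluated in
#' closed form through the row norms of B.
#'
#' @param B reconstruction map restricted to conductivity parameters
#'   (n_elements x n_M).
#' @param J conductivity Jacobian (n_M x n_elements) used to build \code{B}.
#' @param targetElement index of the one-element target (defaults to the
#'   most central element of \code{mesh}).
#' @param mesh optional mesh used to locate the central element.
#' @return the noise-figure value.
#' @export
noiseFigure <- function(B, J, targetElement = NULL, mesh = NULL) {
  if (is.null(targetElement)) {
    if (is.null(mesh)) stop("provide targetElement or mesh")
    targetElement <- centralElement(mesh)
  }
  yt <- J[, targetElement]
  if (all(yt == 0)) stop("zero target response")
  rowNorm <- sqrt(rowSums(B^2))
  mean(rowNorm) * mean(abs(yt)) / mean(abs(B %*% yt))
}

solveGN <- function(J, R, lambda) {
  M <- crossprod(J) + lambda^2 * R
  solve(M, t(J))
}

#' Calibrate the regularization parameter to a target noise figure
#'
#' Bisection on log(lambda); the bracket is expanded by doubling until the
#' noise figure straddles the target (the noise figure decreases
#' monotonically in lambda over the bracket).
#'
#' @param J full Jacobian (conductivity columns first, then any movement
#'   columns).
#' @param rspec regularizer from \code{\link{buildRegularizer}}.
#' @param nN number of conductivity parameters (columns of the conductivity
#'   block).
#' @param nfTarget target noise figure (0.60 in the reference protocol).
#' @param tol tolerance on the achieved noise figure.
#' @param targetElement central-target element index for the noise figure.
#' @return list with \code{lambda}, \code{nf}, \code{B} (full parameter
#'   map).
#' @export
calibrateLambda <- function(J, rspec, nN, nfTarget = 0.60, tol = 0.01,
                            targetElement) {
  R <- assembleR(rspec, nN)
  Jc <- J[, seq_len(nN), drop = FALSE]
  nf <- function(lam) {
    B <- solveGN(J, R, lam)
    Bc <- B[seq_len(nN), , drop = FALSE]
    list(nf = noiseFigure(Bc, Jc, targetElement = targetElement), B = B)
  }
  nfSafe <- function(lam) tryCatch(nf(lam), error = function(e) NULL)
  ## initial scale from the spectrum balance of J'J against R
  lam0 <- sqrt(mean(diag(crossprod(Jc))) / mean(diag(rspec$Rcond)))
  lo <- hi <- lam0
  flo <- fhi <- nf(lam0)
  for (i in seq_len(60)) {
    if (flo$nf > nfTarget) break
    cand <- nfSafe(lo / 2)
    if (is.null(cand)) break # numerically singular: bracket cannot expand
    lo <- lo / 2
    flo <- cand
  }
  for (i in seq_len(60)) {
    if (fhi$nf < nfTarget) break
    cand <- nfSafe(hi * 2)
    if (is.null(cand)) break
    hi <- hi * 2
    fhi <- cand
  }
  if (flo$nf < nfTarget || fhi$nf > nfTarget)
    stop(sprintf(
      "noise-figure target %g unreachable; attainable range about [%g, %g]",
      nfTarget, fhi$nf, flo$nf))
  best <- NULL
  for (i in seq_len(80)) {
    mid <- sqrt(lo * hi)
    fm <- nf(mid)
    best <- list(lambda = mid, nf = fm$nf, B = fm$B)
    if (abs(fm$nf - nfTarget) <= tol * 0.5) break
    if (fm$nf > nfTarget) lo <- mid else hi <- mid
  }
  if (abs(best$nf - nfTarget) > tol)
    stop("bisection failed to reach the noise-figure tolerance")
  best
}

## ---- rasterization ---------------------------------------------------------

#' Build the 32 x 32 rasterization operator for a mesh
#'
#' Pixel value = area-weighted mean of overlapping elements (by subpixel
#' sampling); pixels with < 50\% coverage by the mesh are invalid. Row 1 of
#' the raster is ventral (image top).
#'
#' @param mesh an \linkS4class{EitMesh}.
#' @param side raster side length.
#' @param subdiv subpixel sampling density per axis.
#' @return list with sparse weight matrix \code{W} (pixels x elements),
#'   \code{coverage}, logical \code{mask}, grid geometry.
#' @export
buildRaster <- function(mesh, side = 32L, subdiv = 4L) {
  nd <- mesh@nodes
  bx <- range(nd[mesh@boundary, 1])
  by <- range(nd[mesh@boundary, 2])
  half <- max(diff(bx), diff(by)) / 2 * 1.02
  cx <- mean(bx); cy <- mean(by)
  px <- 2 * half / side

  rr <- rep(seq_len(side), times = side) # row index, flat column-major
  cc <- rep(seq_len(side), each = side)
  xc <- cx - half + (cc - 0.5) * px
  yc <- cy + half - (rr - 0.5) * px

  off <- (seq_len(subdiv) - 0.5) / subdiv - 0.5
  sx <- as.vector(outer(rep(1, subdiv), off)) # subdiv^2 offsets
  sy <- as.vector(outer(off, rep(1, subdiv)))
  npx <- side * side
  nsub <- subdiv^2

  X <- rep(xc, each = nsub) + rep(sx, times = npx) * px
  Y <- rep(yc, each = nsub) + rep(sy, times = npx) * px
  elemHit <- integer(length(X))

  el <- mesh@elements
  p1 <- nd[el[, 1], , drop = FALSE]
  p2 <- nd[el[, 2], , drop = FALSE]
  p3 <- nd[el[, 3], , drop = FALSE]
  for (e in seq_len(nrow(el))) {
    ## barycentric sign test (positively oriented triangles)
    unhit <- elemHit == 0L
    if (!any(unhit)) break
    xs <- X[unhit]; ys <- Y[unhit]
    d1 <- (p2[e, 1] - p1[e, 1]) * (ys - p1[e, 2]) - (p2[e, 2] - p1[e, 2]) * (xs - p1[e, 1])
    d2 <- (p3[e, 1] - p2[e, 1]) * (ys - p2[e, 2]) - (p3[e, 2] - p2[e, 2]) * (xs - p2[e, 1])
    d3 <- (p1[e, 1] - p3[e, 1]) * (ys - p3[e, 2]) - (p1[e, 2] - p3[e, 2]) * (xs - p3[e, 1])
    inside <- d1 >= 0 & d2 >= 0 & d3 >= 0
    if (any(inside)) elemHit[which(unhit)[inside]] <- e
  }
  pix <- rep(seq_len(npx), each = nsub)
  hit <- elemHit > 0L
  W <- sparseMatrix(
    i = pix[hit], j = elemHit[hit], x = 1 / nsub,
    dims = c(npx, nrow(el))
  )
  coverage <- Matrix::rowSums(W)
  mask <- matrix(coverage >= 0.5, side, side)
  list(
    W = W, coverage = coverage, mask = mask, side = side,
    px = px, cx = cx, cy = cy, half = half, pixelArea = px^2
  )
}

#' Rasterize per-element values to the 32 x 32 grid
#'
#' @param values numeric per-element vector.
#' @param mesh mesh the values live on (ignored when \code{raster} given).
#' @param raster optional precomputed \code{\link{buildRaster}} result.
#' @return list with \code{raster} (side x side matrix, NA outside the
#'   mask), \code{mask}, \code{coverage}.
#' @export
rasterize <- function(values, mesh = NULL, raster = NULL) {
  if (is.null(raster)) raster <- buildRaster(mesh)
  num <- as.numeric(raster$W %*% values)
  val <- ifelse(raster$coverage > 0, num / pmax(raster$coverage, 1e-12), NA_real_)
  val[!as.vector(raster$mask)] <- NA_real_
  list(
    raster = matrix(val, raster$side, raster$side),
    mask = raster$mask, coverage = raster$coverage
  )
}

#' Build the full reconstruction model on a coarse mesh
#'
#' Computes the homogeneous-background Jacobian, row-normalizes it for
#' normalized-difference data, optionally appends the electrode-movement
#' block (columns scaled so the mean movement column norm matches the
#' conductivity block), calibrates lambda to the target noise figure and
#' stores the rasterization operator.
#'
#' @param meshCoarse reconstruction mesh.
#' @param pattern stimulation pattern.
#' @param nfTarget target noise figure.
#' @param includeMovement model electrode movement (estimates are discarded
#'   from images).
#' @param tol noise-figure tolerance.
#' @return a \linkS4class{ReconModel}.
#' @export
buildReconModel <- function(meshCoarse, pattern = adjacentPattern(16),
                            nfTarget = 0.60, includeMovement = TRUE,
                            tol = 0.01) {
  nN <- nrow(meshCoarse@elements)
  sigma0 <- rep(1, nN)
  V0 <- solveForward(meshCoarse, sigma0, pattern)
  Jc <- conductivityJacobian(meshCoarse, sigma0, pattern) / V0
  J <- Jc
  rspec <- buildRegularizer(meshCoarse, includeMovement = includeMovement,
                            nElectrodes = length(meshCoarse@electrodeNodes))
  if (includeMovement) {
    Jm <- movementJacobian(meshCoarse, sigma0, pattern) / V0
    s <- mean(sqrt(colSums(Jc^2))) / mean(sqrt(colSums(Jm^2)))
    Jm <- Jm * s
    ## movement prior on the same scale as the (scaled) movement columns
    rspec$movementScale <- mean(diag(rspec$Rcond))
    J <- cbind(Jc, Jm)
  }
  cal <- calibrateLambda(J, rspec, nN, nfTarget = nfTarget, tol = tol,
                         targetElement = centralElement(meshCoarse))
  new("ReconModel",
    B = cal$B[seq_len(nN), , drop = FALSE],
    lambda = cal$lambda,
    regularizer = rspec,
    noiseFigure = cal$nf,
    jacobian = J,
    mesh = meshCoarse,
    raster = buildRaster(meshCoarse)
  )
}

#' Reconstruct an image series from normalized-difference data
#'
#' Applies the one-step Gauss-Newton map frame by frame, flips the sign so
#' that inspiration (conductivity decrease) gives positive delta-Z, and
#' rasterizes onto the 32 x 32 grid.
#'
#' @param series a \linkS4class{VoltageSeries} whose frames are normalized
#'   differences y (see \code{\link{normalizedDifference}}).
#' @param recon a \linkS4class{ReconModel}.
#' @return an \linkS4class{ImageSeries}.
#' @export
reconstructSeries <- function(series, recon) {
  Y <- series@frames
  if (ncol(Y) != ncol(recon@B))
    stop("dimension mismatch between series channels and reconstruction model")
  X <- Y %*% t(recon@B) # frames x elements
  DZ <- -X
  ras <- recon@raster
  Wn <- ras$W / pmax(ras$coverage, 1e-12)
  imgs <- as.matrix(DZ %*% Matrix::t(Wn))
  imgs[, !as.vector(ras$mask)] <- NA_real_
  new("ImageSeries",
    frames = imgs, insideMask = ras$mask, side = as.integer(ras$side),
    frameRate = series@frameRate,
    provenance = list(
      lambda = recon@lambda, noiseFigure = recon@noiseFigure,
      reference = series@metadata$reference %||% "unknown"
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
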