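## Linear-triangle FEM for the 2-D conductivity equation div(sigma grad u) = 0
## with point-electrode current injection. One dorsal boundary node is held at
## zero potential as the reference; drive/measurement use adjacent electrode
## pairs, so the reference current contribution cancels in every channel.

#' Adjacent stimulation/measurement pattern
#'
#' @param nElectrodes number of electrodes (>= 4).
#' @param currentAmplitude nominal drive current in mA rms (metadata only;
#'   computations use a unit drive).
#' @return a \linkS4class{StimPattern} with
#'   \code{nElectrodes * (nElectrodes - 3)} retained measurements.
#' @examples
#' nMeasurements(adjacentPattern(16)) # 208
#' @export
adjacentPattern <- function(nElectrodes, currentAmplitude = 5) {
  n <- as.integer(nElectrodes)
  if (n < 4L) stop("adjacent pattern requires at least 4 electrodes")
  nxt <- function(i) ifelse(i == n, 1L, i + 1L)
  inj <- cbind(seq_len(n), nxt(seq_len(n)))
  chan <- vector("list", n)
  for (i in seq_len(n)) {
    a <- inj[i, 1]; b <- inj[i, 2]
    keep <- integer(0)
    for (j in seq_len(n)) {
      m1 <- j; m2 <- nxt(j)
      if (m1 %in% c(a, b) || m2 %in% c(a, b)) next
      keep <- c(keep, j)
    }
    chan[[i]] <- cbind(a, b, keep, nxt(keep))
  }
  mc <- do.call(rbind, chan)
  colnames(mc) <- c("injA", "injB", "measA", "measB")
  new("StimPattern",
    injections = inj, measChannels = mc,
    currentAmplitude = currentAmplitude, nMeasurements = nrow(mc)
  )
}

patternHash <- function(pattern) {
  sprintf("adjacent-%d-%d", nrow(pattern@injections), pattern@nMeasurements)
}

## Precompute assembly structure for a mesh: element stiffness triplets for
## unit conductivity, gradient operators, and the reduced (grounded) system.
femStructure <- function(mesh) {
  nd <- mesh@nodes
  el <- mesh@elements
  nEl <- nrow(el)
  nNd <- nrow(nd)
  A <- triangleAreas(nd, el)

  x1 <- nd[el[, 1], 1]; y1 <- nd[el[, 1], 2]
  x2 <- nd[el[, 2], 1]; y2 <- nd[el[, 2], 2]
  x3 <- nd[el[, 3], 1]; y3 <- nd[el[, 3], 2]
  ## shape-function gradients: grad N_i = (b_i, c_i)
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / (2 * A)
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / (2 * A)

  ## element stiffness S_ij = A * (b_i b_j + c_i c_j), 9 entries per element
  ti <- tj <- integer(9L * nEl)
  sv <- numeric(9L * nEl)
  k <- 0L
  for (i in 1:3) {
    for (j in 1:3) {
      idx <- k * nEl + seq_len(nEl)
      ti[idx] <- el[, i]
      tj[idx] <- el[, j]
      sv[idx] <- A * (b[, i] * b[, j] + cc[, i] * cc[, j])
      k <- k + 1L
    }
  }
  elemOf <- rep(seq_len(nEl), times = 9L)

  ## ground: most dorsal boundary node (minimum y), never an electrode
  bndNodes <- mesh@boundary
  ground <- bndNodes[which.min(nd[bndNodes, 2])]
  if (ground %in% mesh@electrodeNodes) {
    ord <- bndNodes[order(nd[bndNodes, 2])]
    ground <- ord[!(ord %in% mesh@electrodeNodes)][1]
  }
  keep <- !(ti == ground | tj == ground)
  remap <- integer(nNd)
  remap[-ground] <- seq_len(nNd - 1L)

  gx <- sparseMatrix(
    i = rep(seq_len(nEl), 3L), j = as.vector(el), x = as.vector(b),
    dims = c(nEl, nNd)
  )
  gy <- sparseMatrix(
    i = rep(seq_len(nEl), 3L), j = as.vector(el), x = as.vector(cc),
    dims = c(nEl, nNd)
  )

  list(
    nEl = nEl, nNd = nNd, areas = A,
    ti = remap[ti[keep]], tj = remap[tj[keep]],
    sv = sv[keep], elemOf = elemOf[keep],
    ground = ground, remap = remap,
    elecRows = remap[mesh@electrodeNodes],
    gx = gx, gy = gy
  )
}

assembleReduced <- function(fs, sigma) {
  vals <- fs$sv * sigma[fs$elemOf]
  sparseMatrix(
    i = fs$ti, j = fs$tj, x = vals,
    dims = c(fs$nNd - 1L, fs$nNd - 1L)
  )
}

## Solve for unit current +1 at each electrode (ground closes the circuit);
## returns full-node potential matrix (nNd x nE), zero at the ground node.
solveElectrodeFields <- function(fs, sigma, chol = NULL) {
  K <- assembleReduced(fs, sigma)
  nE <- length(fs$elecRows)
  B <- matrix(0, fs$nNd - 1L, nE)
  B[cbind(fs$elecRows, seq_len(nE))] <- 1
  Ured <- if (is.null(chol)) {
    as.matrix(Matrix::solve(Cholesky(forceSymmetric(K)), B, system = "A"))
  } else {
    as.matrix(Matrix::solve(Matrix::update(chol, forceSymmetric(K)), B, system = "A"))
  }
  U <- matrix(0, fs$nNd, nE)
  U[-fs$ground, ] <- Ured
  U
}

## Extract the retained channel voltages from electrode-field superposition.
channelVoltages <- function(Uelec, pattern) {
  mc <- pattern@measChannels
  (Uelec[cbind(mc[, 3], mc[, 1])] - Uelec[cbind(mc[, 3], mc[, 2])]) -
    (Uelec[cbind(mc[, 4], mc[, 1])] - Uelec[cbind(mc[, 4], mc[, 2])])
}

#' Solve the nonlinear EIT forward problem
#'
#' Computes the boundary voltage vector for a conductivity field on the mesh
#' under the adjacent stimulation pattern (unit drive current).
#'
#' @param mesh an \linkS4class{EitMesh}.
#' @param sigma numeric vector of per-element conductivities (strictly
#'   positive, one per element).
#' @param pattern a \linkS4class{StimPattern} for 16 electrodes.
#' @return numeric vector of length \code{nMeasurements(pattern)}.
#' @export
solveForward <- function(mesh, sigma, pattern) {
  checkSigma(mesh, sigma)
  fs <- femStructure(mesh)
  U <- solveElectrodeFields(fs, sigma)
  channelVoltages(U[mesh@electrodeNodes, , drop = FALSE], pattern)
}

checkSigma <- function(mesh, sigma) {
  if (length(sigma) != nrow(mesh@elements))
    stop("sigma must have one value per element")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be strictly positive and finite")
  invisible(TRUE)
}

#' Conductivity Jacobian (adjoint method)
#'
#' Sensitivity of every retained voltage channel to each element's
#' conductivity, evaluated at \code{sigma0}:
#' dV_m / d sigma_e = - integral over element e of grad(u_drive) . grad(u_meas).
#'
#' @inheritParams solveForward
#' @param sigma0 conductivity at which to linearize.
#' @return numeric matrix (n_M x n_elements).
#' @export
conductivityJacobian <- function(mesh, sigma0, pattern) {
  checkSigma(mesh, sigma0)
  fs <- femStructure(mesh)
  U <- solveElectrodeFields(fs, sigma0)
  gxu <- as.matrix(fs$gx %*% U) # per-element x-gradient of each electrode field
  gyu <- as.matrix(fs$gy %*% U)
  nE <- ncol(U)
  nxt <- c(seq_len(nE)[-1], 1L)
  Px <- gxu - gxu[, nxt, drop = FALSE] # adjacent-pair drive fields
  Py <- gyu - gyu[, nxt, drop = FALSE]
  mc <- pattern@measChannels
  mi <- mc[, 1] # injection pair index = first driving electrode
  mj <- mc[, 3] # measurement pair index = first measuring electrode
  integ <- (Px[, mi, drop = FALSE] * Px[, mj, drop = FALSE] +
              Py[, mi, drop = FALSE] * Py[, mj, drop = FALSE]) * fs$areas
  -t(integ)
}

boundaryDirections <- function(mesh) {
  bnd <- mesh@boundary
  nd <- mesh@nodes
  n <- length(bnd)
  pos <- match(mesh@electrodeNodes, bnd)
  prv <- bnd[ifelse(pos == 1L, n, pos - 1L)]
  nxt <- bnd[ifelse(pos == n, 1L, pos + 1L)]
  tg <- nd[nxt, , drop = FALSE] - nd[prv, , drop = FALSE]
  tg <- tg / sqrt(rowSums(tg^2))
  cen <- colMeans(nd[bnd, , drop = FALSE])
  nm <- cbind(tg[, 2], -tg[, 1]) # rotate; orient outward below
  out <- nd[mesh@electrodeNodes, , drop = FALSE] - matrix(cen, length(pos), 2, byrow = TRUE)
  flip <- rowSums(nm * out) < 0
  nm[flip, ] <- -nm[flip, ]
  list(tangent = tg, normal = nm)
}

#' Electrode-movement Jacobian (finite differences)
#'
#' Sensitivity of each channel to small displacements of each electrode node
#' along the boundary tangent and outward normal, by central finite
#' differences with mesh re-solve. Columns 1..16 are tangential, 17..32
#' normal displacements.
#'
#' @inheritParams conductivityJacobian
#' @param step displacement step as a fraction of the inter-electrode
#'   spacing.
#' @return numeric matrix (n_M x 2 * n_electrodes).
#' @export
movementJacobian <- function(mesh, sigma0, pattern, step = 1e-3) {
  checkSigma(mesh, sigma0)
  elec <- mesh@electrodeNodes
  nE <- length(elec)
  dirs <- boundaryDirections(mesh)
  spacing <- mean(sqrt(rowSums(
    (mesh@nodes[elec, ] - mesh@nodes[elec[c(2:nE, 1)], ])^2
  )))
  nM <- pattern@nMeasurements
  J <- matrix(0, nM, 2L * nE)

  perturbSolve <- function(node, delta) {
    m2 <- mesh
    m2@nodes[node, ] <- m2@nodes[node, ] + delta
    if (any(triangleAreas(m2@nodes, m2@elements) <= 0))
      return(NULL) # tangled
    solveForward(m2, sigma0, pattern)
  }
  for (e in seq_len(nE)) {
    for (d in 1:2) {
      dir <- if (d == 1L) dirs$tangent[e, ] else dirs$normal[e, ]
      h <- step * spacing
      repeat {
        vp <- perturbSolve(elec[e], h * dir)
        vm <- perturbSolve(elec[e], -h * dir)
        if (!is.null(vp) && !is.null(vm)) break
        h <- h / 2
        if (h < 1e-9 * spacing) stop("mesh tangles under any movement step")
      }
      J[, (d - 1L) * nE + e] <- (vp - vm) / (2 * h)
    }
  }
  J
}
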