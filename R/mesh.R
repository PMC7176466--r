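## Mesh construction: structured triangulation of a star-shaped contour.
## Boundary resampled at equal arc length; interior nodes are scaled copies of
## the boundary ring toward the area centroid, plus a centre node. This keeps
## electrodes exactly on boundary nodes and gives a predictable element count
## N * (2K - 1) for N boundary nodes and K rings.

triangleAreas <- function(nodes, elements) {
  p1 <- nodes[elements[, 1], , drop = FALSE]
  p2 <- nodes[elements[, 2], , drop = FALSE]
  p3 <- nodes[elements[, 3], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
           (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

meshConnected <- function(nNodes, elements) {
  ## union-find over element node triples
  parent <- seq_len(nNodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(elements))) {
    a <- find(elements[r, 1])
    b <- find(elements[r, 2])
    c <- find(elements[r, 3])
    parent[b] <- a
    parent[find(c)] <- a
  }
  length(unique(vapply(seq_len(nNodes), find, integer(1)))) == 1L
}

segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

contourIsSimple <- function(contour) {
  n <- nrow(contour)
  idx <- rbind(cbind(seq_len(n), c(seq_len(n)[-1], 1L)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ## skip adjacent edges (share a vertex)
      if (j == i || abs(j - i) == 1L || (i == 1L && j == n)) next
      if (segmentsIntersect(
        contour[idx[i, 1], ], contour[idx[i, 2], ],
        contour[idx[j, 1], ], contour[idx[j, 2], ]
      )) {
        return(FALSE)
      }
    }
  }
  TRUE
}

polygonArea <- function(p) {
  n <- nrow(p)
  j <- c(seq_len(n)[-1], 1L)
  0.5 * sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])
}

## Resample a closed polygon at n equally spaced arc-length positions,
## starting at the point where the boundary crosses the ventral midline (the
## vertical ray from the centroid towards +y) and proceeding clockwise.
resampleBoundary <- function(contour, n) {
  cen <- colMeans(contour)
  ## ensure clockwise order (negative signed area) so electrode numbering runs
  ## clockwise in the radiological image
  if (polygonArea(contour) > 0) contour <- contour[rev(seq_len(nrow(contour))), ]
  m <- nrow(contour)
  nxt <- c(seq_len(m)[-1], 1L)
  dx1 <- contour[, 1] - cen[1]
  dx2 <- contour[nxt, 1] - cen[1]
  cand <- which(dx1 < 0 & dx2 >= 0 &
                  (contour[, 2] + contour[nxt, 2]) / 2 > cen[2])
  if (!length(cand)) cand <- which(dx1 <= 0 & dx2 > 0)
  i <- cand[1]
  t0 <- (cen[1] - contour[i, 1]) / (contour[nxt[i], 1] - contour[i, 1])
  start <- contour[i, ] + t0 * (contour[nxt[i], ] - contour[i, ])
  ring <- rbind(start, contour[c(nxt[i]:m, seq_len(i))[seq_len(m)], , drop = FALSE])
  closed <- rbind(ring, start)
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  target <- seq(0, L, length.out = n + 1L)[-(n + 1L)]
  x <- approx(s, closed[, 1], xout = target)$y
  y <- approx(s, closed[, 2], xout = target)$y
  cbind(x, y)
}

#' Build a 2-D thorax mesh with 16 boundary electrodes
#'
#' Triangulates the interior of a simple, star-shaped closed contour and
#' places 16 point electrodes equidistantly (by boundary arc length) so that
#' electrodes 1/16 flank the ventral midline and 8/9 the dorsal midline,
#' numbered clockwise in the radiological convention.
#'
#' @param contour numeric matrix (>= 16 x 2), vertices of a simple closed
#'   polygon (not repeated at the end).
#' @param targetElements integer, desired element count (achieved within
#'   +/- 25\%); must be >= 50.
#' @param refinement label stored on the mesh, \code{"coarse"} or
#'   \code{"fine"}; defaults to \code{"coarse"} below 512 elements.
#' @return an \linkS4class{EitMesh}.
#' @export
buildThoraxMesh <- function(contour, targetElements,
                            refinement = if (targetElements < 512) "coarse" else "fine") {
  contour <- as.matrix(contour)
  if (nrow(contour) < 16L) stop("contour must have at least 16 vertices")
  if (targetElements < 50L) stop("targetElements must be at least 50")
  if (!contourIsSimple(contour)) stop("geometry error: contour is self-intersecting")

  ## choose N boundary nodes (multiple of 32 so electrode positions at
  ## (j - 1/2) * N/16 land on nodes) and K rings; element count is N(2K-1),
  ## N ~ sqrt(3 * target) keeps radial and tangential spacing comparable
  N <- max(32L, 32L * as.integer(round(sqrt(3 * targetElements) / 32)))
  K <- max(2L, as.integer(round((targetElements / N + 1) / 2)))
  if (abs(N * (2L * K - 1L) - targetElements) > 0.25 * targetElements)
    warning("achieved element count deviates more than 25% from target")

  bnd <- resampleBoundary(contour, N)
  cen <- colMeans(bnd)

  ## nodes: rings k = K (boundary) .. 1, then centre
  nodes <- matrix(0, nrow = N * K + 1L, ncol = 2L)
  for (k in seq_len(K)) {
    scale <- k / K
    rows <- (K - k) * N + seq_len(N)
    nodes[rows, 1] <- cen[1] + scale * (bnd[, 1] - cen[1])
    nodes[rows, 2] <- cen[2] + scale * (bnd[, 2] - cen[2])
  }
  ## ring index r = 1 is the boundary (rows 1..N); ring r has rows (r-1)*N + 1..N
  centre <- N * K + 1L
  nodes[centre, ] <- cen

  elems <- matrix(0L, nrow = N * (2L * K - 1L), ncol = 3L)
  e <- 0L
  nxt <- function(i) if (i == N) 1L else i + 1L
  for (r in seq_len(K - 1L)) { # annulus between ring r (outer) and r+1 (inner)
    o <- (r - 1L) * N
    i <- r * N
    for (j in seq_len(N)) {
      jn <- nxt(j)
      e <- e + 1L; elems[e, ] <- c(o + j, o + jn, i + j)
      e <- e + 1L; elems[e, ] <- c(o + jn, i + jn, i + j)
    }
  }
  o <- (K - 1L) * N
  for (j in seq_len(N)) { # centre fan
    e <- e + 1L; elems[e, ] <- c(o + j, o + nxt(j), centre)
  }

  ## enforce positive orientation
  ar <- triangleAreas(nodes, elems)
  flip <- ar < 0
  if (any(flip)) elems[flip, 2:3] <- elems[flip, 3:2]
  if (any(abs(triangleAreas(nodes, elems)) < .Machine$double.eps * 100))
    stop("geometry error: degenerate triangle produced (contour not star-shaped?)")

  spacing <- N / 16L
  elecIdx <- as.integer(round((seq_len(16L) - 0.5) * spacing))
  elecIdx[elecIdx == 0L] <- N

  new("EitMesh",
    nodes = nodes, elements = elems,
    boundary = seq_len(N), electrodeNodes = elecIdx,
    refinement = refinement, contour = contour
  )
}

#' Circular contour helper
#'
#' @param n number of vertices.
#' @param radius circle radius.
#' @return an n x 2 matrix of polygon vertices.
#' @export
circleContour <- function(n = 64, radius = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(radius * cos(th), radius * sin(th))
}

#' Packaged thorax contour
#'
#' A synthetic 50-vertex cross-section of a human thorax at the electrode
#' plane (ventral towards +y), shipped with the package as a JSON fixture.
#'
#' @return a 50 x 2 matrix of polygon vertices (arbitrary length units).
#' @export
thoraxContour <- function() {
  path <- system.file("extdata", "thorax_contour.json", package = "lungeit")
  stopifnot(nzchar(path))
  dat <- jsonlite::fromJSON(path)
  cbind(dat$x, dat$y)
}

#' Serialize / deserialize a mesh as JSON
#'
#' @param mesh an \linkS4class{EitMesh}.
#' @param path file path.
#' @return \code{readMeshJson} returns an \linkS4class{EitMesh};
#'   \code{writeMeshJson} returns \code{path} invisibly.
#' @export
writeMeshJson <- function(mesh, path) {
  jsonlite::write_json(
    list(
      nodes = unname(mesh@nodes), elements = unname(mesh@elements),
      boundary = mesh@boundary, electrode_nodes = mesh@electrodeNodes,
      refinement = mesh@refinement, contour = unname(mesh@contour)
    ),
    path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname writeMeshJson
#' @export
readMeshJson <- function(path) {
  d <- jsonlite::fromJSON(path)
  new("EitMesh",
    nodes = d$nodes, elements = matrix(as.integer(d$elements), ncol = 3),
    boundary = as.integer(d$boundary),
    electrodeNodes = as.integer(d$electrode_nodes),
    refinement = d$refinement, contour = d$contour
  )
}

#' Standard coarse/fine mesh pair on the packaged thorax contour
#'
#' The fine mesh (~1024 elements) is used for forward simulation, the coarse
#' mesh (~256 elements) for reconstruction, so that simulated data are never
#' inverted on the mesh that generated them.
#'
#' @return a list with components \code{fine} and \code{coarse}.
#' @export
thoraxMeshPair <- function() {
  ct <- thoraxContour()
  list(
    fine = buildThoraxMesh(ct, 1024L, refinement = "fine"),
    coarse = buildThoraxMesh(ct, 256L, refinement = "coarse")
  )
}
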