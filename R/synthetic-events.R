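# Topological surgery on shared-vertex tilings: T1 neighbor exchanges,
# divisions, T2 removals. All operations preserve the total tiled area
# exactly (T1, division) or redistribute the removed cell's area among its
# neighbors (T2), because cells always partition the same outer boundary.

edgeCellsOf <- function(tiling, p, q) {
  hasP <- vapply(tiling@cells, function(ix) p %in% ix, TRUE)
  hasQ <- vapply(tiling@cells, function(ix) q %in% ix, TRUE)
  shared <- which(hasP & hasQ)
  # edge cells: p and q consecutive in the ring
  isEdge <- vapply(shared, function(ci) {
    ix <- tiling@cells[[ci]]
    pos <- which(ix == p)
    any(ix[pos %% length(ix) + 1L] == q) ||
      any(ix[(pos - 2L) %% length(ix) + 1L] == q)
  }, TRUE)
  list(edge = shared[isEdge], pOnly = which(hasP & !hasQ),
       qOnly = which(hasQ & !hasP))
}

replaceVertexInCell <- function(vertices, ix, old, newPair) {
  pos <- which(ix == old)
  stopifnot(length(pos) == 1)
  build <- function(pair) append(ix[-pos], pair, after = pos - 1L)
  c1 <- build(newPair)
  c2 <- build(rev(newPair))
  a1 <- polySignedArea(vertices[c1, , drop = FALSE])
  a2 <- polySignedArea(vertices[c2, , drop = FALSE])
  if (a1 >= a2) c1 else c2
}

#' Interior edges of a tiling
#'
#' @param tiling a \linkS4class{Tiling}.
#' @param interiorOnly drop edges touching outermost cells or boundary
#'   vertices.
#' @return data.frame with vertex indices \code{p}, \code{q}, the two cell
#'   ids sharing the edge, and the edge length (px).
#' @export
tilingEdges <- function(tiling, interiorOnly = TRUE) {
  ta <- tilingAdjacency(tiling)
  nc <- length(tiling@cells)
  ekeys <- lapply(tiling@cells, cellEdgeKeys)
  owner <- rep.int(seq_len(nc), lengths(ekeys))
  keyvec <- unlist(ekeys, use.names = FALSE)
  byEdge <- split(owner, keyvec)
  shared <- byEdge[lengths(byEdge) == 2]
  if (!length(shared))
    return(data.frame(p = integer(), q = integer(), cell1 = integer(),
                      cell2 = integer(), length = numeric()))
  pq <- do.call(rbind, strsplit(names(shared), "_"))
  p <- as.integer(pq[, 1]); q <- as.integer(pq[, 2])
  cm <- do.call(rbind, shared)
  len <- sqrt(rowSums((tiling@vertices[p, , drop = FALSE] -
                         tiling@vertices[q, , drop = FALSE])^2))
  out <- data.frame(p = p, q = q,
                    cell1 = tiling@ids[cm[, 1]], cell2 = tiling@ids[cm[, 2]],
                    length = len)
  if (interiorOnly) {
    om <- names(ta$outermost)[ta$outermost]
    # boundary vertices: owned by a boundary (unshared) edge
    bvert <- unique(unlist(lapply(seq_len(nc), function(ci) {
      ix <- tiling@cells[[ci]]
      ek <- cellEdgeKeys(ix)
      solo <- ek[!(ek %in% names(shared)) &
                   vapply(ek, function(k) length(byEdge[[k]]) == 1, TRUE)]
      as.integer(unlist(strsplit(solo, "_")))
    })))
    keep <- !(out$cell1 %in% om) & !(out$cell2 %in% om) &
      !(out$p %in% bvert) & !(out$q %in% bvert)
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Shrink (or grow) an edge toward/away from its midpoint
#'
#' Moves the two endpoint vertices symmetrically so the edge has length
#' \code{targetLen}; used to take a junction smoothly through the near-fourfold
#' configuration around a T1 exchange.
#'
#' @param tiling a \linkS4class{Tiling}.
#' @param p,q vertex indices of the edge.
#' @param targetLen desired edge length, px.
#' @return The modified tiling.
#' @export
resizeEdge <- function(tiling, p, q, targetLen) {
  a <- tiling@vertices[p, ]; b <- tiling@vertices[q, ]
  m <- (a + b) / 2
  u <- b - a
  len <- sqrt(sum(u^2))
  if (len < .Machine$double.eps) stop("edge has zero length")
  u <- u / len
  tiling@vertices[p, ] <- m - u * targetLen / 2
  tiling@vertices[q, ] <- m + u * targetLen / 2
  tiling
}

#' T1 neighbor exchange on an interior edge
#'
#' The two cells sharing edge (p, q) lose their contact and the two cells
#' meeting the edge only at its endpoints gain a new, perpendicular edge of
#' length \code{newLen} (default: the old edge length) through the midpoint.
#' Cell count is unchanged; total area is conserved exactly.
#'
#' @param tiling a \linkS4class{Tiling}.
#' @param p,q vertex indices of the edge to swap.
#' @param newLen new edge length, px.
#' @return list(tiling, lost = c(id, id), gained = c(id, id)).
#' @export
applyT1 <- function(tiling, p, q, newLen = NULL) {
  ec <- edgeCellsOf(tiling, p, q)
  if (length(ec$edge) != 2)
    stop("T1 requires an interior edge shared by exactly two cells")
  if (length(ec$pOnly) != 1 || length(ec$qOnly) != 1)
    stop("T1 endpoints must be threefold vertices (interior edge)")
  A <- ec$edge[1]; B <- ec$edge[2]
  Cp <- ec$pOnly; Cq <- ec$qOnly
  a <- tiling@vertices[p, ]; b <- tiling@vertices[q, ]
  m <- (a + b) / 2
  u <- (b - a)
  len <- sqrt(sum(u^2))
  if (is.null(newLen)) newLen <- len
  v <- c(-u[2], u[1]) / len
  e1 <- m + v * newLen / 2
  e2 <- m - v * newLen / 2
  # A keeps vertex p at the endpoint nearest its centroid, B keeps q
  ctrA <- polyCentroid(tiling@vertices[tiling@cells[[A]], , drop = FALSE])
  if (sum((e1 - ctrA)^2) <= sum((e2 - ctrA)^2)) {
    tiling@vertices[p, ] <- e1; tiling@vertices[q, ] <- e2
  } else {
    tiling@vertices[p, ] <- e2; tiling@vertices[q, ] <- e1
  }
  dropVertex <- function(ix, vtx) ix[ix != vtx]
  tiling@cells[[A]] <- dropVertex(tiling@cells[[A]], q)
  tiling@cells[[B]] <- dropVertex(tiling@cells[[B]], p)
  tiling@cells[[Cp]] <- replaceVertexInCell(tiling@vertices,
                                            tiling@cells[[Cp]], p, c(p, q))
  tiling@cells[[Cq]] <- replaceVertexInCell(tiling@vertices,
                                            tiling@cells[[Cq]], q, c(p, q))
  methods::validObject(tiling)
  list(tiling = tiling,
       lost = c(tiling@ids[A], tiling@ids[B]),
       gained = c(tiling@ids[Cp], tiling@ids[Cq]))
}

insertBetween <- function(ix, u, v, newIdx) {
  n <- length(ix)
  pos <- which(ix == u & ix[seq_len(n) %% n + 1L] == v)
  stopifnot(length(pos) == 1)
  append(ix, newIdx, after = pos)
}

#' Divide a cell along a line through its centroid
#'
#' Splits the polygon by the line through its centroid at \code{axisAngle}
#' (radians, measured from the x axis); the two daughters share the new edge
#' and the neighbors across the crossed edges receive the new vertices, so the
#' tiling stays conformal. Total area is conserved exactly.
#'
#' @param tiling a \linkS4class{Tiling}.
#' @param cellId id of the mother cell.
#' @param axisAngle division axis, radians. \code{NULL} = perpendicular to the
#'   cell's long axis (default).
#' @param newIds length-2 integer vector of daughter ids; default
#'   \code{max(ids) + 1:2}. Callers generating long sequences should supply
#'   ids from a monotone counter so removed ids are never reissued.
#' @return list(tiling, mother, daughters = c(id, id), axis).
#' @export
applyDivision <- function(tiling, cellId, axisAngle = NULL,
                          newIds = NULL) {
  ci <- match(cellId, tiling@ids)
  if (is.na(ci)) stop("unknown cell id")
  ix <- tiling@cells[[ci]]
  P <- tiling@vertices[ix, , drop = FALSE]
  ctr <- polyCentroid(P)
  if (is.null(axisAngle)) {
    # long axis from the second moment of the vertex cloud
    cc <- sweep(P, 2, ctr)
    S <- crossprod(cc) / nrow(cc)
    ev <- eigen(S, symmetric = TRUE)
    long <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
    axisAngle <- long + pi / 2
  }
  n <- length(ix)
  found <- FALSE
  ang <- axisAngle
  for (try in 1:25) {
    w <- c(cos(ang), sin(ang))
    s <- (P[, 1] - ctr[1]) * w[2] - (P[, 2] - ctr[2]) * w[1]
    s <- -s  # signed side of the axis line
    tol <- 1e-9 * max(abs(P))
    if (all(abs(s) > tol)) {
      nxt <- c(2:n, 1L)
      crossIdx <- which(s * s[nxt] < 0)
      if (length(crossIdx) == 2) { found <- TRUE; break }
    }
    ang <- ang + 0.013  # nudge off degenerate axes
  }
  if (!found) stop("could not find a generic division axis")
  nxt <- c(2:n, 1L)
  cut <- lapply(crossIdx, function(e) {
    a <- P[e, ]; b <- P[nxt[e], ]
    t <- s[e] / (s[e] - s[nxt[e]])
    a + t * (b - a)
  })
  nv <- nrow(tiling@vertices)
  tiling@vertices <- rbind(tiling@vertices, cut[[1]], cut[[2]])
  n1 <- nv + 1L; n2 <- nv + 2L
  e1 <- crossIdx[1]; e2 <- crossIdx[2]
  # ring with the two new vertices inserted
  ring <- ix
  ring <- insertBetween(ring, ix[e2], ix[nxt[e2]], n2)
  ring <- insertBetween(ring, ix[e1], ix[nxt[e1]], n1)
  # split the ring at the two new vertices
  ring <- c(ring[which(ring == n1):length(ring)],
            ring[seq_len(which(ring == n1) - 1L)])
  posB <- which(ring == n2)
  side1 <- ring[1:posB]
  side2 <- c(ring[posB:length(ring)], n1)
  # insert the new vertices into the neighbors across the crossed edges
  for (j in 1:2) {
    e <- crossIdx[j]
    u <- ix[e]; v <- ix[nxt[e]]
    newIdx <- if (j == 1) n1 else n2
    for (oi in seq_along(tiling@cells)) {
      if (oi == ci) next
      oc <- tiling@cells[[oi]]
      no <- length(oc)
      if (any(oc == v & oc[seq_len(no) %% no + 1L] == u)) {
        tiling@cells[[oi]] <- insertBetween(oc, v, u, newIdx)
      }
    }
  }
  if (is.null(newIds)) newIds <- max(tiling@ids) + 1:2
  d1 <- as.integer(newIds[1])
  d2 <- as.integer(newIds[2])
  if (any(c(d1, d2) %in% tiling@ids)) stop("daughter ids already in use")
  tiling@cells[[ci]] <- side1
  tiling@ids[ci] <- d1
  tiling@cells[[length(tiling@cells) + 1L]] <- side2
  tiling@ids <- c(tiling@ids, d2)
  for (cc in list(side1, side2)) {
    if (polySignedArea(tiling@vertices[cc, , drop = FALSE]) <= 0)
      stop("division produced a degenerate daughter")
  }
  methods::validObject(tiling)
  list(tiling = tiling, mother = cellId, daughters = c(d1, d2),
       axis = ang %% pi)
}

#' Remove a cell (T2 / apoptosis)
#'
#' All vertices of the cell collapse to its centroid; the neighbors close the
#' vacancy around the resulting multi-cell junction, absorbing the removed
#' cell's area.
#'
#' @param tiling a \linkS4class{Tiling}.
#' @param cellId id of the cell to remove.
#' @return list(tiling, cell, neighbors) where neighbors are the ids that
#'   ringed the removed cell.
#' @export
applyT2 <- function(tiling, cellId) {
  ci <- match(cellId, tiling@ids)
  if (is.na(ci)) stop("unknown cell id")
  V <- tiling@cells[[ci]]
  ctr <- polyCentroid(tiling@vertices[V, , drop = FALSE])
  tiling@vertices <- rbind(tiling@vertices, ctr)
  nV <- nrow(tiling@vertices)
  neighbors <- integer()
  for (oi in seq_along(tiling@cells)) {
    if (oi == ci) next
    oc <- tiling@cells[[oi]]
    if (!any(oc %in% V)) next
    neighbors <- c(neighbors, tiling@ids[oi])
    oc[oc %in% V] <- nV
    keep <- oc != c(oc[-1], oc[1])
    oc <- oc[keep]
    if (length(oc) < 3) stop("T2 would degenerate a neighbor cell")
    tiling@cells[[oi]] <- oc
  }
  tiling@cells <- tiling@cells[-ci]
  tiling@ids <- tiling@ids[-ci]
  methods::validObject(tiling)
  list(tiling = tiling, cell = cellId, neighbors = neighbors)
}
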