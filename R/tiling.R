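# Operations on the shared-vertex polygonal tiling: adjacency extraction,
# per-cell geometry, conversion to the TissueFrame data model.

newTiling <- function(vertices, cells, ids = seq_along(cells)) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  cells <- lapply(cells, as.integer)
  # enforce counterclockwise orientation
  for (ci in seq_along(cells)) {
    if (polySignedArea(vertices[cells[[ci]], , drop = FALSE]) < 0)
      cells[[ci]] <- rev(cells[[ci]])
  }
  methods::new("Tiling", vertices = vertices, cells = cells,
               ids = as.integer(ids))
}

#' Per-cell polygon areas of a tiling
#' @param tiling a \linkS4class{Tiling}.
#' @return Named numeric vector (names = cell ids), px^2.
#' @export
tilingAreas <- function(tiling) {
  a <- vapply(tiling@cells, function(ix)
    polyArea(tiling@vertices[ix, , drop = FALSE]), 0)
  names(a) <- tiling@ids
  a
}

#' Per-cell polygon centroids of a tiling
#' @param tiling a \linkS4class{Tiling}.
#' @return n x 2 matrix, rownames = cell ids.
#' @export
tilingCentroids <- function(tiling) {
  ctr <- t(vapply(tiling@cells, function(ix)
    polyCentroid(tiling@vertices[ix, , drop = FALSE]), c(0, 0)))
  rownames(ctr) <- tiling@ids
  ctr
}

# Edge keys "a_b" (a < b) per cell, in cell order
cellEdgeKeys <- function(ix) {
  j <- c(ix[-1], ix[1])
  paste(pmin(ix, j), pmax(ix, j), sep = "_")
}

#' Neighbor graph and boundary flags of a tiling
#'
#' Edge contacts are pairs of cells sharing a polygon edge (two consecutive
#' shared vertices). Cells meeting only at a vertex where four or more cells
#' meet are recorded as fourfold-vertex contacts with weight 1/2. Cells owning
#' an unshared (boundary) edge are flagged outermost.
#'
#' @param tiling a \linkS4class{Tiling}.
#' @return list with \code{adjacency} (data.frame i, k, omega, contact_kind;
#'   ids, i < k) and \code{outermost} (logical named by cell id).
#' @export
tilingAdjacency <- function(tiling) {
  nc <- length(tiling@cells)
  ids <- tiling@ids
  ekeys <- lapply(tiling@cells, cellEdgeKeys)
  owner <- rep.int(seq_len(nc), lengths(ekeys))
  keyvec <- unlist(ekeys, use.names = FALSE)
  byEdge <- split(owner, keyvec)
  nOwn <- lengths(byEdge)
  if (any(nOwn > 2))
    stop("inconsistent tiling: edge shared by more than two cells")
  pairsE <- byEdge[nOwn == 2]
  outermost <- rep(FALSE, nc)
  boundaryOwners <- unlist(byEdge[nOwn == 1], use.names = FALSE)
  outermost[unique(boundaryOwners)] <- TRUE
  adj <- NULL
  if (length(pairsE)) {
    m <- do.call(rbind, pairsE)
    i <- pmin(ids[m[, 1]], ids[m[, 2]]); k <- pmax(ids[m[, 1]], ids[m[, 2]])
    key <- paste(i, k)
    keep <- !duplicated(key)
    adj <- data.frame(i = i[keep], k = k[keep],
                      omega = 1, contact_kind = "edge",
                      stringsAsFactors = FALSE)
  } else {
    adj <- data.frame(i = integer(), k = integer(), omega = numeric(),
                      contact_kind = character(), stringsAsFactors = FALSE)
  }
  # point contacts at >= fourfold vertices
  vowner <- rep.int(seq_len(nc), lengths(tiling@cells))
  vidx <- unlist(tiling@cells, use.names = FALSE)
  byVert <- split(vowner, vidx)
  multi <- byVert[lengths(byVert) >= 4]
  if (length(multi)) {
    edgeKey <- paste(pmin(adj$i, adj$k), pmax(adj$i, adj$k))
    extra <- list()
    for (cellsAt in multi) {
      cellsAt <- unique(cellsAt)
      if (length(cellsAt) < 4) next
      cmb <- utils::combn(cellsAt, 2)
      for (j in seq_len(ncol(cmb))) {
        a <- ids[cmb[1, j]]; b <- ids[cmb[2, j]]
        kk <- paste(min(a, b), max(a, b))
        if (!(kk %in% edgeKey)) {
          extra[[length(extra) + 1L]] <- c(min(a, b), max(a, b))
          edgeKey <- c(edgeKey, kk)
        }
      }
    }
    if (length(extra)) {
      em <- do.call(rbind, extra)
      adj <- rbind(adj, data.frame(i = em[, 1], k = em[, 2], omega = 0.5,
                                   contact_kind = "fourfold-vertex",
                                   stringsAsFactors = FALSE))
    }
  }
  adj <- adj[order(adj$i, adj$k), , drop = FALSE]
  rownames(adj) <- NULL
  names(outermost) <- ids
  list(adjacency = adj, outermost = outermost)
}

#' Convert a tiling to the TissueFrame data model
#'
#' Centers are polygon centroids and areas polygon areas (exact geometry, no
#' rasterization); adjacency and outermost flags come from
#' \code{\link{tilingAdjacency}}.
#'
#' @param tiling a \linkS4class{Tiling}.
#' @param frameIndex frame number.
#' @param time time in minutes.
#' @param pixelSize micrometers per pixel.
#' @return A \linkS4class{TissueFrame}.
#' @export
tilingToFrame <- function(tiling, frameIndex = 0L, time = 0,
                          pixelSize = 1) {
  ctr <- tilingCentroids(tiling)
  areas <- tilingAreas(tiling)
  ta <- tilingAdjacency(tiling)
  ord <- order(tiling@ids)
  cells <- data.frame(
    id = tiling@ids[ord],
    x = ctr[ord, 1], y = ctr[ord, 2],
    area_px = as.numeric(areas[ord]),
    outermost = as.logical(ta$outermost[ord]),
    source = "polygon",
    stringsAsFactors = FALSE
  )
  rownames(cells) <- NULL
  methods::new("TissueFrame", frameIndex = as.integer(frameIndex),
               time = as.numeric(time), cells = cells,
               adjacency = ta$adjacency, labelImage = NULL,
               pixelSize = pixelSize)
}

# Deduplicate vertex coordinates (rounded keys) and rebuild index lists.
dedupeVertices <- function(coordList, digits = 6) {
  all <- do.call(rbind, coordList)
  key <- paste(round(all[, 1], digits), round(all[, 2], digits))
  uk <- !duplicated(key)
  vertices <- all[uk, , drop = FALSE]
  lookup <- match(key, key[uk])
  sizes <- vapply(coordList, nrow, 1L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  cells <- mapply(function(s, e) lookup[s:e], starts, ends, SIMPLIFY = FALSE)
  # drop consecutive duplicates within a cell (rounding collisions)
  cells <- lapply(cells, function(ix) {
    keep <- ix != c(ix[-1], ix[1])
    ix[keep | length(ix) < 3]
  })
  list(vertices = vertices, cells = cells)
}

#' Regular hexagonal tiling
#'
#' Centers on a triangular lattice with nearest-neighbor distance \code{d};
#' every interior cell is a regular hexagon of area \eqn{(\sqrt{3}/2) d^2}
#' with exactly six edge neighbors.
#'
#' @param nRows,nCols lattice dimensions (>= 3).
#' @param d center spacing in pixels (>= 6).
#' @return A \linkS4class{Tiling}.
#' @export
hexagonalTiling <- function(nRows, nCols, d = 20) {
  stopifnot(nRows >= 3, nCols >= 3)
  if (d < 6) stop("spacing d too small to rasterize")
  R <- d / sqrt(3)
  ang <- pi / 6 + (0:5) * pi / 3
  hx <- R * cos(ang)
  hy <- R * sin(ang)
  coordList <- list()
  for (r in seq_len(nRows) - 1L) {
    for (c in seq_len(nCols) - 1L) {
      cx <- c * d + (r %% 2) * d / 2 + d
      cy <- r * d * sqrt(3) / 2 + d
      coordList[[length(coordList) + 1L]] <- cbind(cx + hx, cy + hy)
    }
  }
  dd <- dedupeVertices(coordList)
  newTiling(dd$vertices, dd$cells)
}

#' Lloyd-relaxed Voronoi tiling
#'
#' Voronoi cells of \code{nCells} random points in a rectangle after
#' \code{lloydSteps} centroidal relaxation steps, clipped to the rectangle.
#' Adjacency comes from shared Voronoi edges. Deterministic given
#' \code{(nCells, seed, lloydSteps, window)}.
#'
#' @param nCells number of seed points (>= 10).
#' @param seed RNG seed.
#' @param lloydSteps number of Lloyd relaxation steps.
#' @param window rectangle c(xmin, xmax, ymin, ymax) in pixels.
#' @return A \linkS4class{Tiling}.
#' @export
voronoiTiling <- function(nCells, seed = 1L, lloydSteps = 5,
                          window = c(0, 400, 0, 400)) {
  stopifnot(nCells >= 10)
  pts <- withSeed(seed, cbind(
    stats::runif(nCells, window[1], window[2]),
    stats::runif(nCells, window[3], window[4])
  ))
  tiles <- NULL
  for (it in seq_len(lloydSteps + 1L)) {
    dd <- deldir::deldir(pts[, 1], pts[, 2], rw = window, suppressMsge = TRUE)
    tiles <- deldir::tile.list(dd)
    if (it <= lloydSteps) {
      pts <- t(vapply(tiles, function(tl)
        polyCentroid(cbind(tl$x, tl$y)), c(0, 0)))
    }
  }
  coordList <- lapply(tiles, function(tl) cbind(tl$x, tl$y))
  ddv <- dedupeVertices(coordList, digits = 6)
  newTiling(ddv$vertices, ddv$cells)
}
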