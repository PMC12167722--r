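# TissueFrame construction from label images, half-link extraction, and
# lossless table serialization.

#' Region of interest with Lagrangian membership
#'
#' @slot roiId integer identifier.
#' @slot origin (row, col) of the originating tile in the initial-frame grid.
#' @slot members list of integer id vectors, one per frame; consecutive
#'   member sets are related only by identity, division or apoptosis.
#' @export
setClass("ROISpec", representation(
  roiId = "integer",
  origin = "integer",
  members = "list"
))

setMethod("show", "ROISpec", function(object) {
  cat(sprintf("ROISpec %d (tile %d,%d): %s cells over %d frame(s)\n",
              object@roiId, object@origin[1], object@origin[2],
              paste(range(lengths(object@members)), collapse = "-"),
              length(object@members)))
})

#' Half-links of a region of interest
#'
#' Emits the directed half-link i -> k for every ROI member i and neighbor k,
#' excluding links that touch outermost cells. Each undirected neighbor pair
#' inside the ROI therefore contributes two half-links; a pair with one
#' endpoint outside contributes one. A set with fewer than 3 non-collinear
#' half-links is flagged degenerate.
#'
#' @param frame a \linkS4class{TissueFrame}.
#' @param roiCells integer ids of the ROI member cells (must exist in frame).
#' @param roiId identifier stored in the result.
#' @return A \linkS4class{HalfLinkSet}; link vectors in pixels.
#' @export
halfLinks <- function(frame, roiCells, roiId = 0L) {
  cells <- frame@cells
  if (!all(roiCells %in% cells$id)) stop("ROI member cells missing in frame")
  adj <- frame@adjacency
  outer <- cells$id[cells$outermost]
  # directed expansion of the undirected adjacency
  dir <- rbind(
    data.frame(i = adj$i, k = adj$k, omega = adj$omega),
    data.frame(i = adj$k, k = adj$i, omega = adj$omega)
  )
  dir <- dir[dir$i %in% roiCells & !(dir$i %in% outer) &
               !(dir$k %in% outer), , drop = FALSE]
  xi <- cells$x[match(dir$i, cells$id)]
  yi <- cells$y[match(dir$i, cells$id)]
  xk <- cells$x[match(dir$k, cells$id)]
  yk <- cells$y[match(dir$k, cells$id)]
  links <- data.frame(i = dir$i, k = dir$k, omega = dir$omega,
                      lx = xk - xi, ly = yk - yi)
  links <- links[order(links$i, links$k), , drop = FALSE]
  rownames(links) <- NULL
  nH <- nrow(links)
  degenerate <- TRUE
  if (nH >= 3) {
    C <- crossprod(cbind(links$lx, links$ly))
    degenerate <- det(C) <= .Machine$double.eps * max(C)^2
  }
  methods::new("HalfLinkSet", roiId = as.integer(roiId),
               frameIndex = frame@frameIndex, links = links,
               nC = sum(roiCells %in% cells$id[!cells$outermost]),
               nH = as.integer(nH), degenerate = degenerate)
}

#' Build a TissueFrame from an integer label image
#'
#' Cells are the positive-label regions (0 = contour/background); centers are
#' pixel-coordinate means and areas pixel counts. Neighbor pairs are read off
#' the contour: a contour pixel whose 3x3 neighborhood shows exactly two
#' labels is edge evidence for that pair; at junction pixels showing four or
#' more labels, pairs with no edge evidence anywhere are recorded as
#' fourfold-vertex contacts with weight 1/2. Cells touching the image border
#' or open background are flagged outermost.
#'
#' @param label integer matrix, \code{label[y+1, x+1]} at pixel (x, y).
#' @param pixelSize micrometers per pixel.
#' @param frameIndex,time frame metadata.
#' @return A \linkS4class{TissueFrame} carrying the label image.
#' @export
buildFrameFromLabels <- function(label, pixelSize = 1, frameIndex = 0L,
                                 time = 0) {
  if (!is.matrix(label)) stop("label must be a matrix")
  if (is.double(label)) {
    if (any(label != round(label))) stop("non-integer label raster")
    storage.mode(label) <- "integer"
  }
  ids <- sort(unique(label[label > 0L]))
  if (!length(ids)) stop("no cells")
  nr <- nrow(label); nc <- ncol(label)
  pos <- which(label > 0L)
  lab <- label[pos]
  row <- (pos - 1L) %% nr + 1L
  col <- (pos - 1L) %/% nr + 1L
  xs <- tapply((col - 1L), lab, mean)
  ys <- tapply((row - 1L), lab, mean)
  areas <- tapply(lab, lab, length)
  # pad with -1 so every pixel has 8 neighbors
  pad <- matrix(-1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- label
  zp <- which(pad == 0L)
  offs <- c(-1L, 1L, -(nr + 2L), nr + 2L,
            -(nr + 2L) - 1L, -(nr + 2L) + 1L, (nr + 2L) - 1L, (nr + 2L) + 1L)
  nb <- vapply(offs, function(o) pad[zp + o], integer(length(zp)))
  labSets <- apply(nb, 1, function(r) unique(r[r > 0L]), simplify = FALSE)
  nLabs <- lengths(labSets)
  pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edgeKeys <- character()
  if (any(nLabs == 2L)) {
    two <- do.call(rbind, labSets[nLabs == 2L])
    edgeKeys <- unique(pairKey(two[, 1], two[, 2]))
  }
  if (any(nLabs == 3L)) {
    for (s in labSets[nLabs == 3L]) {
      cmb <- utils::combn(sort(s), 2)
      edgeKeys <- union(edgeKeys, paste(cmb[1, ], cmb[2, ]))
    }
  }
  # direct label-label contacts without a contour pixel between them
  dirPairs <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (!any(sel)) return(character())
    unique(pairKey(a[sel], b[sel]))
  }
  edgeKeys <- union(edgeKeys, dirPairs(label[, -nc], label[, -1]))
  edgeKeys <- union(edgeKeys, dirPairs(label[-nr, ], label[-1, ]))
  fourKeys <- character()
  if (any(nLabs >= 4L)) {
    for (s in labSets[nLabs >= 4L]) {
      cmb <- utils::combn(sort(s), 2)
      kk <- paste(cmb[1, ], cmb[2, ])
      fourKeys <- union(fourKeys, setdiff(kk, edgeKeys))
    }
  }
  fourKeys <- setdiff(fourKeys, edgeKeys)
  parse2 <- function(keys) {
    if (!length(keys)) return(matrix(integer(), 0, 2))
    m <- do.call(rbind, strsplit(keys, " "))
    matrix(as.integer(m), ncol = 2)
  }
  em <- parse2(edgeKeys)
  fm <- parse2(fourKeys)
  adjacency <- rbind(
    if (nrow(em)) data.frame(i = em[, 1], k = em[, 2], omega = 1,
                             contact_kind = "edge") else NULL,
    if (nrow(fm)) data.frame(i = fm[, 1], k = fm[, 2], omega = 0.5,
                             contact_kind = "fourfold-vertex") else NULL
  )
  if (is.null(adjacency))
    adjacency <- data.frame(i = integer(), k = integer(), omega = numeric(),
                            contact_kind = character())
  adjacency <- adjacency[order(adjacency$i, adjacency$k), , drop = FALSE]
  rownames(adjacency) <- NULL
  # outermost: touches border, or 8-adjacent to an open-background 0-pixel
  # (a 0-pixel whose neighborhood shows at most one label)
  borderIds <- unique(c(label[1, ], label[nr, ], label[, 1], label[, nc]))
  openBg <- zp[nLabs <= 1L]
  bgIds <- integer()
  if (length(openBg)) {
    bgNb <- nb[nLabs <= 1L, , drop = FALSE]
    bgIds <- unique(bgNb[bgNb > 0L])
  }
  outermostIds <- union(borderIds[borderIds > 0L], bgIds)
  cells <- data.frame(
    id = as.integer(ids),
    x = as.numeric(xs[as.character(ids)]),
    y = as.numeric(ys[as.character(ids)]),
    area_px = as.numeric(areas[as.character(ids)]),
    outermost = ids %in% outermostIds,
    source = "pixels",
    stringsAsFactors = FALSE
  )
  methods::new("TissueFrame", frameIndex = as.integer(frameIndex),
               time = as.numeric(time), cells = cells,
               adjacency = adjacency, labelImage = label,
               pixelSize = pixelSize)
}

#' Serialize a TissueFrame as CSV tables
#'
#' Writes \code{cells.csv} (id,x,y,area_px,outermost) and
#' \code{adjacency.csv} (i,k,omega,contact_kind; both directions of every
#' pair) under \code{dir}, rows in ascending id order.
#'
#' @param frame a \linkS4class{TissueFrame}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeFrameTables <- function(frame, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- frame@cells[order(frame@cells$id),
                       c("id", "x", "y", "area_px", "outermost")]
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  a <- frame@adjacency
  both <- rbind(a, data.frame(i = a$k, k = a$i, omega = a$omega,
                              contact_kind = a$contact_kind))
  both <- both[order(both$i, both$k), ]
  utils::write.csv(both, file.path(dir, "adjacency.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a TissueFrame from CSV tables
#'
#' Inverse of \code{\link{writeFrameTables}}. Adjacency rows present in only
#' one direction are accepted and symmetrized with a warning; weights outside
#' \{1, 1/2\} are a schema error.
#'
#' @param dir directory containing \code{cells.csv} and \code{adjacency.csv}.
#' @param pixelSize micrometers per pixel.
#' @param frameIndex,time frame metadata.
#' @return A \linkS4class{TissueFrame}.
#' @export
readFrameTables <- function(dir, pixelSize = 1, frameIndex = 0L, time = 0) {
  cellsPath <- file.path(dir, "cells.csv")
  adjPath <- file.path(dir, "adjacency.csv")
  cells <- utils::read.csv(cellsPath, stringsAsFactors = FALSE)
  for (col in c("id", "x", "y", "area_px", "outermost")) {
    if (!col %in% names(cells))
      stop("cells.csv lacks required column: ", col)
  }
  adj <- utils::read.csv(adjPath, stringsAsFactors = FALSE)
  for (col in c("i", "k", "omega", "contact_kind")) {
    if (!col %in% names(adj))
      stop("adjacency.csv lacks required column: ", col)
  }
  if (!all(adj$omega %in% c(1, 0.5)))
    stop("adjacency.csv: omega must be 1 or 0.5")
  keyF <- paste(adj$i, adj$k)
  keyR <- paste(adj$k, adj$i)
  if (!all(keyF %in% keyR))
    warning("one-directional adjacency rows symmetrized on load")
  und <- adj[adj$i < adj$k | !(keyF %in% keyR) & adj$i > adj$k, , drop = FALSE]
  und <- data.frame(i = pmin(und$i, und$k), k = pmax(und$i, und$k),
                    omega = und$omega, contact_kind = und$contact_kind,
                    stringsAsFactors = FALSE)
  und <- und[!duplicated(paste(und$i, und$k)), , drop = FALSE]
  und <- und[order(und$i, und$k), , drop = FALSE]
  rownames(und) <- NULL
  cells <- cells[order(cells$id), , drop = FALSE]
  cells$source <- "tables"
  rownames(cells) <- NULL
  methods::new("TissueFrame", frameIndex = as.integer(frameIndex),
               time = as.numeric(time), cells = cells, adjacency = und,
               labelImage = NULL, pixelSize = pixelSize)
}
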