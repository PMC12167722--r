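# Rasterization of tilings into integer label images with one-pixel contours.

#' Rasterize a tiling to a label image
#'
#' Pixel centers sit at integer coordinates (0-based, x rightward = columns,
#' y downward = rows). Each pixel inside a cell polygon receives that cell's
#' id; pixels on the boundary between two labels are carved out as
#' one-pixel-wide contour (value 0), matching skeletonized segmentation
#' output. Pixels outside the tiling are 0.
#'
#' @param tiling a \linkS4class{Tiling}.
#' @param width,height canvas size in pixels; defaults cover the tiling
#'   bounding box.
#' @param contour carve 1-px contours between labels (default TRUE).
#' @return Integer matrix (height x width); \code{label[y+1, x+1]} is the
#'   label at pixel (x, y).
#' @export
rasterizeTiling <- function(tiling, width = NULL, height = NULL,
                            contour = TRUE) {
  bb <- apply(tiling@vertices, 2, range)
  if (is.null(width)) width <- ceiling(bb[2, 1]) + 2L
  if (is.null(height)) height <- ceiling(bb[2, 2]) + 2L
  lab <- matrix(0L, nrow = height, ncol = width)
  areas <- tilingAreas(tiling)
  if (any(areas <= 0)) stop("degenerate polygon in tiling")
  meanDiam <- 2 * sqrt(mean(areas) / pi)
  if (meanDiam < 8) stop("mean cell diameter below 8 px; increase spacing")
  # paint larger cells first so shared-edge ties resolve to the later
  # (smaller) cell deterministically
  for (ci in order(areas, decreasing = TRUE)) {
    ix <- tiling@cells[[ci]]
    P <- tiling@vertices[ix, , drop = FALSE]
    xr <- floor(min(P[, 1])):ceiling(max(P[, 1]))
    yr <- floor(min(P[, 2])):ceiling(max(P[, 2]))
    xr <- xr[xr >= 0 & xr < width]
    yr <- yr[yr >= 0 & yr < height]
    if (!length(xr) || !length(yr)) next
    g <- expand.grid(x = xr, y = yr)
    ins <- pointsInPolygon(g$x, g$y, P)
    if (any(ins))
      lab[cbind(g$y[ins] + 1L, g$x[ins] + 1L)] <- tiling@ids[ci]
  }
  if (contour) {
    # carve the contour alternately from either side of each boundary
    # (checkerboard parity) so pixel-mean centers stay unbiased
    parity <- outer(seq_len(height), seq_len(width), `+`) %% 2L == 0L
    right <- cbind(lab[, -1], 0L)
    down <- rbind(lab[-1, ], 0L)
    mismR <- (lab > 0L) & (right > 0L) & (right != lab)
    mismD <- (lab > 0L) & (down > 0L) & (down != lab)
    cut <- matrix(FALSE, height, width)
    cut[mismR & parity] <- TRUE
    cut[cbind(row(lab)[mismR & !parity], col(lab)[mismR & !parity] + 1L)] <- TRUE
    cut[mismD & parity] <- TRUE
    cut[cbind(row(lab)[mismD & !parity] + 1L, col(lab)[mismD & !parity])] <- TRUE
    lab[cut] <- 0L
  }
  lab
}

#' Contour (skeleton) image of a label raster
#'
#' @param label integer label matrix from \code{\link{rasterizeTiling}} or a
#'   segmentation pipeline.
#' @return Numeric matrix with 1 on contour pixels (background pixels
#'   touching a labeled cell) and 0 elsewhere, including the open
#'   background; suitable as PIV texture.
#' @export
skeletonImage <- function(label) {
  nr <- nrow(label); nc <- ncol(label)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- label
  touches <- matrix(FALSE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    touches <- touches | (pad[2:(nr + 1L) + dy, 2:(nc + 1L) + dx] > 0L)
  }
  (label == 0L & touches) * 1
}

#' Read a label image from TIFF or PNG
#'
#' Integer labels; 0 is contour/background. Multi-page TIFFs return a list of
#' matrices.
#'
#' @param path file path (.tif/.tiff/.png).
#' @return Integer matrix, or list of matrices for multi-page TIFF.
#' @export
readLabelImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  toInt <- function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    mi <- round(m * ifelse(max(m) <= 1, 65535, 1))
    storage.mode(mi) <- "integer"
    mi
  }
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    pages <- lapply(pages, function(m) {
      if (length(dim(m)) == 3) m <- m[, , 1]
      storage.mode(m) <- "integer"
      m
    })
    if (length(pages) == 1) pages[[1]] else pages
  } else if (ext == "png") {
    toInt(png::readPNG(path))
  } else {
    stop("unsupported label image format: ", ext)
  }
}

#' Write a label image as 16-bit TIFF
#' @param label integer matrix.
#' @param path output path.
#' @export
writeLabelImage <- function(label, path) {
  tiff::writeTIFF(label / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
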