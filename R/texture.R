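# Texture tensors, normalization variants, pixel second moments and shape
# summaries.
#
# The unnormalized texture tensor of an ROI is
#   M0 = sum_{i in P} (1/2) sum_k omega_ik l_ik (x) l_ik
# over half-links l_ik from member cells to their neighbors (outermost cells
# excluded). M0 grows with the number of cells in the ROI; the coarse-grained
# cell-shape tensor is the half-link-normalized M1 = M0 / N_h, and M2 =
# M0 / N_c normalizes by cell count instead. Further variants can be
# registered as extension points; no formula is guessed for them.

.textureVariants <- new.env(parent = emptyenv())

#' Register a texture-tensor normalization variant
#'
#' Extension point for additional normalizations. The function receives the
#' unnormalized tensor \code{M0} (2x2), \code{nC}, \code{nH} and the link
#' table, and must return a 2x2 matrix.
#'
#' @param name variant name (e.g. "M3").
#' @param fun normalization function \code{function(M0, nC, nH, links)}.
#' @export
registerTextureVariant <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .textureVariants)
  invisible(name)
}

#' Texture tensor of a half-link set
#'
#' @param halflinks a non-degenerate \linkS4class{HalfLinkSet}.
#' @param variant \code{"M0"} (unnormalized), \code{"M1"} (per half-link;
#'   default), \code{"M2"} (per cell), or a registered variant name.
#' @return A \linkS4class{TextureTensor}, px^2.
#' @export
textureTensor <- function(halflinks, variant = c("M1", "M0", "M2", "M3", "M4")) {
  variant <- match.arg(variant[1], c("M1", "M0", "M2", "M3", "M4"))
  if (halflinks@degenerate)
    stop("degenerate half-link set: fewer than 3 non-collinear half-links")
  L <- halflinks@links
  w <- L$omega / 2
  M0 <- matrix(c(sum(w * L$lx^2), sum(w * L$lx * L$ly),
                 sum(w * L$lx * L$ly), sum(w * L$ly^2)), 2, 2)
  M <- switch(variant,
    M0 = M0,
    M1 = M0 / halflinks@nH,
    M2 = M0 / halflinks@nC,
    {
      if (!exists(variant, envir = .textureVariants))
        stop("variant not configured: ", variant)
      get(variant, envir = .textureVariants)(M0, halflinks@nC,
                                            halflinks@nH, L)
    })
  methods::new("TextureTensor", M = M, variant = variant,
               nC = halflinks@nC, nH = halflinks@nH,
               roiId = halflinks@roiId, frameIndex = halflinks@frameIndex)
}

asTensorMatrix <- function(M) {
  if (is(M, "TextureTensor")) M@M else as.matrix(M)
}

#' Cell area approximated from a shape tensor
#'
#' \eqn{A = \pi |M|^{1/2}}: the area of the ellipse whose second-moment
#' tensor is M.
#'
#' @param M a \linkS4class{TextureTensor} or 2x2 positive-definite matrix.
#' @return Area in the squared units of M.
#' @export
textureArea <- function(M) {
  m <- asTensorMatrix(M)
  d <- det(m)
  if (d <= 0) stop("degenerate tensor: non-positive determinant")
  pi * sqrt(d)
}

#' Cell number density from a shape tensor
#'
#' \eqn{\rho = 1/A = 1/(\pi |M|^{1/2})}.
#'
#' @inheritParams textureArea
#' @return Density, 1/area units of M.
#' @export
textureDensity <- function(M) 1 / textureArea(M)

#' Shape summary of a tensor: area, aspect ratio, orientation
#'
#' Eigenvalues are ordered \eqn{\lambda_1 \ge \lambda_2}; the orientation is
#' the angle of the leading eigenvector in (-pi/2, pi/2]. For isotropic
#' tensors the orientation is undefined and returned as NA with
#' \code{isotropic = TRUE}.
#'
#' @inheritParams textureArea
#' @param tol relative eigenvalue gap below which the tensor is treated as
#'   isotropic.
#' @return list(area, aspect, theta, lambda1, lambda2, isotropic).
#' @export
shapeSummary <- function(M, tol = 1e-12) {
  m <- asTensorMatrix(M)
  ev <- eigen(m, symmetric = TRUE)
  l1 <- ev$values[1]; l2 <- ev$values[2]
  if (l2 <= 0) stop("tensor not positive definite")
  iso <- (l1 - l2) <= tol * l1
  theta <- NA_real_
  if (!iso) {
    theta <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
    theta <- ((theta + pi / 2) %% pi) - pi / 2
    if (theta == -pi / 2) theta <- pi / 2
  }
  list(area = pi * sqrt(l1 * l2), aspect = sqrt(l1 / l2), theta = theta,
       lambda1 = l1, lambda2 = l2, isotropic = iso)
}

#' Orientation coherence of a set of axes
#'
#' \eqn{|\langle e^{2 i \theta} \rangle|}: 1 when all axes align, 0 for
#' orientations spread evenly over the half-circle.
#'
#' @param theta orientations in radians (axial, i.e. modulo pi). NAs dropped.
#' @return Scalar in [0, 1].
#' @export
orientationCoherence <- function(theta) {
  theta <- theta[!is.na(theta)]
  if (!length(theta)) stop("no orientations")
  Mod(mean(exp(2i * theta)))
}

#' Pixel-based second moments of cells
#'
#' Per-cell second-moment matrices from the label raster,
#' \eqn{m_{2c} = (1/A_{px}) \sum_p (p - c)(p - c)^T}, and the ROI mean
#' \eqn{m_2 = (4/N_c) \sum_c m_{2c}}. The factor 4 makes the moment of an
#' ellipse match the tensor convention (an ellipse with semi-axis a has
#' \eqn{m_{xx} = a^2/4}). Cell areas are reported in both conventions:
#' contour pixels excluded, and half (1/n-th for n-fold contacts) of the
#' adjacent contour pixels included.
#'
#' @param label integer label matrix.
#' @param cells integer ids to include (default: all); cells with fewer than
#'   4 pixels are excluded with a message.
#' @param minPixels exclusion threshold.
#' @return list(perCell = data.frame(id, mxx, mxy, myy, area_px,
#'   area_px_half), m2 = 2x2 matrix, nC, rho_px, rho_px_half).
#' @export
pixelMoments <- function(label, cells = NULL, minPixels = 4L) {
  stopifnot(is.matrix(label))
  nr <- nrow(label); nc <- ncol(label)
  pos <- which(label > 0L)
  lab <- label[pos]
  if (!is.null(cells)) {
    keep <- lab %in% cells
    pos <- pos[keep]; lab <- lab[keep]
  }
  if (!length(pos)) stop("no labeled cells selected")
  x <- (pos - 1L) %/% nr
  y <- (pos - 1L) %% nr
  ids <- sort(unique(lab))
  perCell <- do.call(rbind, lapply(ids, function(id) {
    sel <- lab == id
    n <- sum(sel)
    if (n < minPixels) return(NULL)
    xc <- mean(x[sel]); yc <- mean(y[sel])
    dx <- x[sel] - xc; dy <- y[sel] - yc
    data.frame(id = id, mxx = sum(dx^2) / n, mxy = sum(dx * dy) / n,
               myy = sum(dy^2) / n, area_px = n)
  }))
  if (is.null(perCell)) stop("all selected cells below the pixel threshold")
  excluded <- setdiff(ids, perCell$id)
  if (length(excluded))
    message("pixelMoments: excluded ", length(excluded),
            " cell(s) with < ", minPixels, " pixels")
  # half-contour-included areas: each contour pixel contributes 1/n to each
  # of the n distinct adjacent labels
  pad <- matrix(-1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- label
  zp <- which(pad == 0L)
  offs <- c(-1L, 1L, -(nr + 2L), nr + 2L,
            -(nr + 2L) - 1L, -(nr + 2L) + 1L, (nr + 2L) - 1L, (nr + 2L) + 1L)
  nb <- vapply(offs, function(o) pad[zp + o], integer(length(zp)))
  halfExtra <- numeric(length(perCell$id))
  names(halfExtra) <- perCell$id
  sets <- apply(nb, 1, function(r) unique(r[r > 0L]), simplify = FALSE)
  for (s in sets) {
    s <- s[s %in% perCell$id]
    if (length(s)) halfExtra[as.character(s)] <-
        halfExtra[as.character(s)] + 1 / length(s)
  }
  perCell$area_px_half <- perCell$area_px + as.numeric(halfExtra)
  nCc <- nrow(perCell)
  m2 <- matrix(c(sum(perCell$mxx), sum(perCell$mxy),
                 sum(perCell$mxy), sum(perCell$myy)), 2, 2) * 4 / nCc
  list(perCell = perCell, m2 = m2, nC = nCc,
       rho_px = nCc / sum(perCell$area_px),
       rho_px_half = nCc / sum(perCell$area_px_half))
}

#' Compare a texture-tensor series against pixel second moments
#'
#' Fits the scaling factor alpha as the ratio of mean texture area to mean
#' (4x) pixel-moment area, then regresses each tensor component of the
#' texture series on alpha-scaled moments. For the half-link-normalized
#' variant M1 no fitted factor is needed and alpha is fixed at 1.
#'
#' @param Mseries list of \linkS4class{TextureTensor} (one variant).
#' @param m2series list of 2x2 pixel-moment matrices (same length).
#' @param fixAlpha force alpha = 1 (default for variant M1).
#' @return list(alpha, components = data.frame per component with slope,
#'   intercept, r2, rmse).
#' @export
variantVsMoments <- function(Mseries, m2series, fixAlpha = NULL) {
  if (length(Mseries) != length(m2series)) stop("series lengths differ")
  if (length(Mseries) < 3) stop("need at least 3 paired tensors")
  variant <- Mseries[[1]]@variant
  if (is.null(fixAlpha)) fixAlpha <- identical(variant, "M1")
  Mm <- lapply(Mseries, asTensorMatrix)
  mm <- lapply(m2series, asTensorMatrix)
  if (fixAlpha) {
    alpha <- 1
  } else {
    alpha <- mean(vapply(Mm, textureArea, 0)) /
      mean(vapply(mm, textureArea, 0))
  }
  comp <- list(Mxx = c(1, 1), Mxy = c(1, 2), Myy = c(2, 2))
  components <- do.call(rbind, lapply(names(comp), function(cn) {
    ij <- comp[[cn]]
    a <- vapply(mm, function(m) alpha * m[ij[1], ij[2]], 0)
    b <- vapply(Mm, function(m) m[ij[1], ij[2]], 0)
    st <- olsStats(a, b)
    data.frame(component = cn, slope = st$slope, intercept = st$intercept,
               r2 = st$r2, rmse = st$rmse, stringsAsFactors = FALSE)
  }))
  list(alpha = alpha, components = components, variant = variant)
}
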