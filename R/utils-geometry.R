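# Small planar-geometry primitives shared by the tiling simulator and the
# tensor code. All polygons are plain n x 2 coordinate matrices, vertices in
# counterclockwise order in the image frame (x rightward, y downward,
# 0-based pixel centers at integer coordinates).

#' Signed polygon area (shoelace)
#'
#' Positive for counterclockwise vertex order in a right-handed frame.
#'
#' @param xy n x 2 coordinate matrix.
#' @return Signed area (squared length units of the input).
#' @keywords internal
#' @noRd
polySignedArea <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  j <- c(2:n, 1L)
  sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2
}

polyArea <- function(xy) abs(polySignedArea(xy))

#' Polygon centroid (area-weighted)
#' @keywords internal
#' @noRd
polyCentroid <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(colMeans(xy))
  j <- c(2:n, 1L)
  cr <- xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) return(colMeans(xy))
  c(sum((xy[, 1] + xy[j, 1]) * cr), sum((xy[, 2] + xy[j, 2]) * cr)) / (6 * a)
}

#' Even-odd point-in-polygon test, vectorized over points
#'
#' Points exactly on an edge may fall on either side; callers that rasterize
#' resolve ties by assignment order.
#'
#' @param px,py point coordinates.
#' @param xy polygon vertex matrix.
#' @return Logical vector.
#' @keywords internal
#' @noRd
pointsInPolygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' 2D rotation matrix
#' @keywords internal
#' @noRd
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Solve the symmetric 2x2 Sylvester relation  Delta = (T M + M T) * dt
#'
#' Unique for symmetric positive-definite \code{M}; used to convert measured
#' texture-tensor increments into symmetric strain-rate tensors.
#'
#' @param Delta symmetric 2x2 increment.
#' @param M symmetric positive-definite 2x2 tensor.
#' @param dt time interval (minutes).
#' @return Symmetric 2x2 rate tensor \code{T}.
#' @keywords internal
solveSylvester2 <- function(Delta, M, dt = 1) {
  stopifnot(all(dim(Delta) == c(2, 2)), all(dim(M) == c(2, 2)), dt > 0)
  m11 <- M[1, 1]; m12 <- M[1, 2]; m22 <- M[2, 2]
  A <- rbind(
    c(2 * m11, 2 * m12, 0),
    c(m12, m11 + m22, m12),
    c(0, 2 * m12, 2 * m22)
  )
  if (abs(det(A)) < .Machine$double.eps * 100 * max(1, max(abs(M)))^3) {
    stop("Sylvester system singular: tensor M is degenerate")
  }
  b <- c(Delta[1, 1], (Delta[1, 2] + Delta[2, 1]) / 2, Delta[2, 2]) / dt
  t <- solve(A, b)
  matrix(c(t[1], t[2], t[2], t[3]), 2, 2)
}

#' Frobenius norm of a matrix
#' @keywords internal
#' @noRd
frob <- function(m) sqrt(sum(m^2))

#' Run code under a fixed RNG seed, restoring the caller's RNG state
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simple per-component ordinary least squares between two numeric vectors
#' @keywords internal
#' @noRd
olsStats <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop("need at least 3 paired observations")
  va <- stats::var(a)
  if (va == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                rmse = sqrt(mean((b - mean(b))^2)), n = n,
                degenerate = TRUE))
  }
  slope <- stats::cov(a, b) / va
  intercept <- mean(b) - slope * mean(a)
  pred <- intercept + slope * a
  ssr <- sum((b - pred)^2)
  sst <- sum((b - mean(b))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  list(slope = slope, intercept = intercept, r2 = r2,
       rmse = sqrt(mean((b - pred)^2)), n = n, degenerate = FALSE)
}
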