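# Prescribed flows and advection of tilings.

#' Construct an affine flow
#'
#' Velocity v(x) = gradv . x + u, spatially uniform gradient. The ground-truth
#' deformation gradient over an interval dt is F = I + gradv * dt exactly.
#'
#' @param gradv 2x2 velocity-gradient matrix, 1/min.
#' @param translation length-2 translation velocity, px/min.
#' @return A \linkS4class{FlowSpec}.
#' @export
affineFlow <- function(gradv = matrix(0, 2, 2), translation = c(0, 0)) {
  methods::new("FlowSpec", kind = "affine", gradv = gradv,
               translation = as.numeric(translation))
}

#' Construct a smooth grid flow
#'
#' Velocity defined on a coarse regular grid, bilinearly interpolated (and
#' clamped to the grid hull) at evaluation points.
#'
#' @param origin grid origin (x, y), px.
#' @param spacing grid spacing, px.
#' @param vx,vy matrices of velocity samples (rows index y), px/min.
#' @return A \linkS4class{FlowSpec}.
#' @export
gridFlow <- function(origin, spacing, vx, vy) {
  stopifnot(all(dim(vx) == dim(vy)), spacing > 0)
  methods::new("FlowSpec", kind = "smooth-grid",
               gridOrigin = as.numeric(origin), gridSpacing = spacing,
               gridVx = vx, gridVy = vy)
}

bilinearAt <- function(z, origin, spacing, x, y) {
  gx <- (x - origin[1]) / spacing + 1
  gy <- (y - origin[2]) / spacing + 1
  gx <- pmin(pmax(gx, 1), ncol(z))
  gy <- pmin(pmax(gy, 1), nrow(z))
  x0 <- pmin(floor(gx), ncol(z) - 1L); y0 <- pmin(floor(gy), nrow(z) - 1L)
  fx <- gx - x0; fy <- gy - y0
  z[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    z[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    z[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    z[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' Evaluate a flow's velocity at points
#'
#' @param flow a \linkS4class{FlowSpec}.
#' @param xy n x 2 matrix of positions, px.
#' @return n x 2 matrix of velocities, px/min.
#' @export
flowVelocity <- function(flow, xy) {
  xy <- matrix(xy, ncol = 2)
  if (flow@kind == "affine") {
    sweep(xy %*% t(flow@gradv), 2, flow@translation, `+`)
  } else {
    cbind(
      bilinearAt(flow@gridVx, flow@gridOrigin, flow@gridSpacing,
                 xy[, 1], xy[, 2]),
      bilinearAt(flow@gridVy, flow@gridOrigin, flow@gridSpacing,
                 xy[, 1], xy[, 2])
    )
  }
}

#' Advect a tiling through a flow
#'
#' Every vertex moves by its local velocity times \code{dt}; for affine flows
#' this is the exact map x -> (I + gradv dt) x + u dt. Adjacency is unchanged.
#'
#' @param tiling a \linkS4class{Tiling}.
#' @param flow a \linkS4class{FlowSpec}.
#' @param dt interval, minutes.
#' @return The advected tiling.
#' @export
advectTiling <- function(tiling, flow, dt) {
  stopifnot(dt > 0)
  v <- flowVelocity(flow, tiling@vertices)
  tiling@vertices <- tiling@vertices + v * dt
  bad <- vapply(tiling@cells, function(ix)
    polySignedArea(tiling@vertices[ix, , drop = FALSE]) <= 0, TRUE)
  if (any(bad)) stop("flow too strong for dt: cell inversion")
  tiling
}

#' Ground-truth velocity field sampled on a grid
#'
#' @param flow a \linkS4class{FlowSpec}.
#' @param bbox c(xmin, xmax, ymin, ymax), px.
#' @param spacing sample spacing, px.
#' @return A \linkS4class{VelocityField} with source "ground-truth".
#' @export
sampleFlowField <- function(flow, bbox, spacing = 16) {
  xs <- seq(bbox[1], bbox[2], by = spacing)
  ys <- seq(bbox[3], bbox[4], by = spacing)
  g <- expand.grid(x = xs, y = ys)
  v <- flowVelocity(flow, as.matrix(g))
  vx <- matrix(v[, 1], nrow = length(ys), ncol = length(xs), byrow = TRUE)
  vy <- matrix(v[, 2], nrow = length(ys), ncol = length(xs), byrow = TRUE)
  methods::new("VelocityField", origin = c(xs[1], ys[1]), spacing = spacing,
               vx = vx, vy = vy,
               valid = matrix(TRUE, length(ys), length(xs)),
               source = "ground-truth")
}
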