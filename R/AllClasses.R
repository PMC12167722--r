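# S4 containers for the tiling data model, tracking results and strain
# tensors. Tensors are stored in px^2 / px / min; physical units enter only
# through the pixelSize slot at reporting time.

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Polygonal tiling (simulator geometry)
#'
#' A confluent two-dimensional tiling of polygonal cells with shared vertices:
#' the authoritative geometry of a synthetic tissue. Cells are stored as
#' counterclockwise runs of indices into a common vertex table, so topological
#' surgery (T1 swaps, divisions, T2 removals) and adjacency extraction are
#' exact set operations rather than image processing.
#'
#' @slot vertices numeric matrix (n x 2), vertex coordinates in pixels.
#' @slot cells list of integer vectors, counterclockwise vertex indices.
#' @slot ids integer vector of unique cell identifiers, parallel to
#'   \code{cells}.
#' @export
setClass("Tiling", representation(
  vertices = "matrix",
  cells = "list",
  ids = "integer"
), validity = function(object) {
  msg <- character()
  if (ncol(object@vertices) != 2) msg <- c(msg, "vertices must be n x 2")
  if (length(object@cells) != length(object@ids))
    msg <- c(msg, "cells and ids lengths differ")
  if (anyDuplicated(object@ids)) msg <- c(msg, "cell ids must be unique")
  if (length(object@cells)) {
    idx <- unlist(object@cells)
    if (any(idx < 1L) || any(idx > nrow(object@vertices)))
      msg <- c(msg, "cell vertex index out of range")
    if (any(vapply(object@cells, length, 1L) < 3L))
      msg <- c(msg, "every cell needs at least 3 vertices")
  }
  if (length(msg)) msg else TRUE
})

#' One time point of a segmented tissue
#'
#' Cell centers, areas, outermost flags and the weighted neighbor graph for a
#' single frame. Adjacency is undirected (one row per pair, \code{i < k}) and
#' carries the contact kind: \code{"edge"} contacts weigh
#' \eqn{\omega_{ik} = 1}, point contacts at fourfold vertices weigh
#' \eqn{\omega_{ik} = 1/2}.
#'
#' @slot frameIndex integer frame number (0-based).
#' @slot time acquisition time in minutes.
#' @slot cells data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{area_px}, \code{outermost}, \code{source}.
#' @slot adjacency data.frame with columns \code{i}, \code{k}, \code{omega},
#'   \code{contact_kind}.
#' @slot labelImage integer label raster (0 = contour/background) or NULL.
#' @slot pixelSize physical pixel size, micrometers per pixel.
#' @export
setClass("TissueFrame", representation(
  frameIndex = "integer",
  time = "numeric",
  cells = "data.frame",
  adjacency = "data.frame",
  labelImage = "matrixOrNULL",
  pixelSize = "numeric"
), prototype(labelImage = NULL, pixelSize = 1), validity = function(object) {
  msg <- character()
  need <- c("id", "x", "y", "area_px", "outermost")
  if (!all(need %in% names(object@cells)))
    msg <- c(msg, paste("cells table lacks columns:",
                        paste(setdiff(need, names(object@cells)), collapse = ", ")))
  needA <- c("i", "k", "omega", "contact_kind")
  if (!all(needA %in% names(object@adjacency)))
    msg <- c(msg, paste("adjacency table lacks columns:",
                        paste(setdiff(needA, names(object@adjacency)), collapse = ", ")))
  if (!length(msg)) {
    if (nrow(object@cells) && any(object@cells$area_px <= 0))
      msg <- c(msg, "cell areas must be strictly positive")
    if (nrow(object@adjacency)) {
      a <- object@adjacency
      if (any(a$i == a$k)) msg <- c(msg, "self-adjacency not allowed")
      if (any(a$i > a$k)) msg <- c(msg, "adjacency rows must have i < k")
      bad <- (a$contact_kind == "edge" & a$omega != 1) |
        (a$contact_kind == "fourfold-vertex" & a$omega != 0.5)
      if (any(bad)) msg <- c(msg, "omega inconsistent with contact kind")
      if (!all(c(a$i, a$k) %in% object@cells$id))
        msg <- c(msg, "adjacency references unknown cell id")
      if (anyDuplicated(paste(a$i, a$k)))
        msg <- c(msg, "duplicate adjacency pair")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Weighted directed half-links of a region of interest
#'
#' Each undirected neighbor pair (i, k) with i in the ROI contributes the
#' half-link i -> k; a pair with both endpoints in the ROI contributes both
#' directions. Links touching outermost cells are excluded. A set with fewer
#' than 3 non-collinear half-links is flagged degenerate and rejected by the
#' tensor operations.
#'
#' @slot roiId integer ROI identifier.
#' @slot frameIndex integer frame of the link vectors.
#' @slot links data.frame with columns \code{i}, \code{k}, \code{omega},
#'   \code{lx}, \code{ly} (one row per directed half-link, pixels).
#' @slot nC number of ROI member cells used.
#' @slot nH number of half-links (rows of \code{links}).
#' @slot degenerate logical.
#' @export
setClass("HalfLinkSet", representation(
  roiId = "integer",
  frameIndex = "integer",
  links = "data.frame",
  nC = "integer",
  nH = "integer",
  degenerate = "logical"
))

#' Texture tensor of a region of interest
#'
#' 2x2 symmetric tensor (squared pixels) summarizing the coarse-grained cell
#' shape of an ROI, with the normalization variant and the counts that entered
#' it. \code{M1 = M0 / nH} exactly on the same link set; \code{M2 = M0 / nC}.
#'
#' @slot M 2x2 symmetric matrix, px^2.
#' @slot variant one of \code{"M0"}, \code{"M1"}, \code{"M2"} (plus registered
#'   extension variants).
#' @slot nC,nH counts used for normalization.
#' @slot roiId,frameIndex provenance.
#' @export
setClass("TextureTensor", representation(
  M = "matrix",
  variant = "character",
  nC = "integer",
  nH = "integer",
  roiId = "integer",
  frameIndex = "integer"
), validity = function(object) {
  msg <- character()
  if (!all(dim(object@M) == c(2, 2))) msg <- c(msg, "M must be 2 x 2")
  else if (abs(object@M[1, 2] - object@M[2, 1]) >
           1e-8 * max(1, max(abs(object@M))))
    msg <- c(msg, "M must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Velocity field on a regular grid
#'
#' @slot origin grid origin (x, y) in pixels (position of sample [1,1]).
#' @slot spacing grid spacing in pixels.
#' @slot vx,vy matrices of velocity components, px/min; rows index y.
#' @slot valid logical matrix; FALSE marks masked/interpolated vectors.
#' @slot source one of \code{"PIV"}, \code{"ground-truth"}.
#' @export
setClass("VelocityField", representation(
  origin = "numeric",
  spacing = "numeric",
  vx = "matrix",
  vy = "matrix",
  valid = "matrix",
  source = "character"
), validity = function(object) {
  if (object@spacing <= 0) return("spacing must be positive")
  if (!all(dim(object@vx) == dim(object@vy)) ||
      !all(dim(object@vx) == dim(object@valid)))
    return("vx, vy and valid must share dimensions")
  TRUE
})

#' Cell lineage across one or more frame intervals
#'
#' @slot maps list (one per interval) of data.frames with columns \code{i_t},
#'   \code{i_t1}, \code{kind} in \{map, division_mother, division_daughter,
#'   apoptosis, left_field, unmatched\}.
#' @slot divisions data.frame: \code{interval}, \code{mother}, \code{daughter1},
#'   \code{daughter2}.
#' @slot apoptoses data.frame: \code{interval}, \code{cell}.
#' @export
setClass("Lineage", representation(
  maps = "list",
  divisions = "data.frame",
  apoptoses = "data.frame"
))

#' Prescribed tissue flow
#'
#' Either a spatially uniform velocity-gradient flow (\code{kind = "affine"}:
#' v(x) = gradv . x + u) or a smooth field sampled on a coarse grid with
#' bilinear interpolation (\code{kind = "smooth-grid"}).
#'
#' @slot kind "affine" or "smooth-grid".
#' @slot gradv 2x2 velocity gradient, 1/min (affine).
#' @slot translation length-2 velocity, px/min (affine).
#' @slot gridOrigin,gridSpacing,gridVx,gridVy coarse velocity grid
#'   (smooth-grid), px and px/min.
#' @export
setClass("FlowSpec", representation(
  kind = "character",
  gradv = "matrix",
  translation = "numeric",
  gridOrigin = "numeric",
  gridSpacing = "numeric",
  gridVx = "matrix",
  gridVy = "matrix"
), prototype(kind = "affine", gradv = matrix(0, 2, 2), translation = c(0, 0),
             gridOrigin = c(0, 0), gridSpacing = 1,
             gridVx = matrix(0, 1, 1), gridVy = matrix(0, 1, 1)))

#' Synthetic tissue scene with ground truth
#'
#' A simulated frame sequence together with everything needed to audit the
#' analysis stages: the exact tiling geometry per frame, the flow, the event
#' log (T1 / division / apoptosis with participating cells), exact velocity
#' samples, and per-frame label rasters.
#'
#' @slot frames list of \linkS4class{TissueFrame}.
#' @slot tilings list of \linkS4class{Tiling} (same length).
#' @slot flow \linkS4class{FlowSpec}.
#' @slot dt frame interval, minutes.
#' @slot events data.frame: \code{interval}, \code{kind}, \code{cell},
#'   \code{daughter1}, \code{daughter2}, \code{axis}, \code{lost_i},
#'   \code{lost_k}, \code{gained_i}, \code{gained_k}.
#' @slot velocity list of \linkS4class{VelocityField} (ground truth,
#'   one per interval).
#' @slot seed integer RNG seed the scene was generated from.
#' @slot pixelSize micrometers per pixel.
#' @export
setClass("SyntheticScene", representation(
  frames = "list",
  tilings = "list",
  flow = "FlowSpec",
  dt = "numeric",
  events = "data.frame",
  velocity = "list",
  seed = "integer",
  pixelSize = "numeric"
))

#' Strain-rate tensors of one ROI and frame interval
#'
#' Deformation gradient and the decomposition of the total strain rate into
#' cell shape change (S), rearrangement (R), division (D) and apoptosis (A);
#' \code{DT = R + D + A}. In \code{closure = "strict"} mode
#' \code{S = G - DT} and the residual is zero by construction; in
#' \code{"raw"} mode S is measured from the texture change and the closure
#' residual \code{G - (S + R + D + A)} is reported.
#'
#' @slot F 2x2 deformation gradient (dimensionless).
#' @slot G,S,R,D,A,DT symmetric 2x2 strain-rate tensors, 1/min.
#' @slot gradv 2x2 velocity gradient used (1/min) or NA matrix.
#' @slot Omega antisymmetric rotation-rate part of gradv (diagnostic only).
#' @slot dt interval, minutes.
#' @slot roiId,interval provenance.
#' @slot residual 2x2 closure residual, 1/min.
#' @slot rule link-assignment rule id.
#' @slot closure "raw" or "strict".
#' @export
setClass("StrainRates", representation(
  F = "matrix", G = "matrix", S = "matrix", R = "matrix", D = "matrix",
  A = "matrix", DT = "matrix", gradv = "matrix", Omega = "matrix",
  dt = "numeric", roiId = "integer", interval = "integer",
  residual = "matrix", rule = "character", closure = "character"
))
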