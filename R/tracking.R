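# Cell tracking: PIV velocity estimation, globally optimal center matching,
# division/apoptosis detection, and Lagrangian ROI bookkeeping.

# Separable Gaussian blur with replicated edges. Sharp (one-pixel) contour
# imagery has a near-delta autocorrelation, which locks the three-point
# sub-pixel peak fit onto integer displacements; a ~1 px blur restores
# sub-pixel accuracy (standard PIV pre-processing).
gaussianBlur <- function(im, sigma) {
  if (sigma <= 0) return(im)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  padv <- rbind(im[rep(1, r), , drop = FALSE], im,
                im[rep(nrow(im), r), , drop = FALSE])
  v <- stats::filter(padv, k, sides = 2)[(r + 1):(r + nrow(im)), ,
                                         drop = FALSE]
  padh <- cbind(v[, rep(1, r), drop = FALSE], v,
                v[, rep(ncol(v), r), drop = FALSE])
  h <- t(stats::filter(t(padh), k, sides = 2))[, (r + 1):(r + ncol(im)),
                                               drop = FALSE]
  unname(as.matrix(h))
}

#' Particle image velocimetry by FFT cross-correlation
#'
#' Single-pass windowed cross-correlation: for every interrogation window the
#' displacement is the correlation peak with a three-point sub-pixel fit.
#' Vectors farther than \code{sdFilterN} standard deviations from the field
#' mean are replaced by the local median and masked as interpolated; windows
#' with no texture (zero variance) are masked invalid.
#'
#' @param imageT,imageT1 numeric matrices of equal size (rows = y).
#' @param window interrogation window size, px.
#' @param step window step, px.
#' @param sdFilterN standard-deviation filter parameter.
#' @param minTexture windows whose intensity standard deviation falls below
#'   this fraction of the whole-image standard deviation are masked invalid.
#' @param preSmooth Gaussian pre-smoothing sigma in px (0 = none); sharpens
#'   sub-pixel accuracy on binary contour imagery by widening the
#'   correlation peak.
#' @param dt interval in minutes (velocities are displacement / dt).
#' @return A \linkS4class{VelocityField} with source "PIV".
#' @export
piv <- function(imageT, imageT1, window = 64, step = 16, sdFilterN = 3,
                minTexture = 0.5, preSmooth = 1, dt = 1) {
  stopifnot(all(dim(imageT) == dim(imageT1)))
  imageT <- gaussianBlur(imageT, preSmooth)
  imageT1 <- gaussianBlur(imageT1, preSmooth)
  sdAll1 <- stats::sd(imageT)
  sdAll2 <- stats::sd(imageT1)
  if (sdAll1 == 0) sdAll1 <- .Machine$double.eps
  if (sdAll2 == 0) sdAll2 <- .Machine$double.eps
  nr <- nrow(imageT); nc <- ncol(imageT)
  if (nr < 2 * window || nc < 2 * window)
    stop("images smaller than twice the interrogation window")
  ys <- seq(1, nr - window + 1, by = step)
  xs <- seq(1, nc - window + 1, by = step)
  u <- matrix(NA_real_, length(ys), length(xs))
  v <- matrix(NA_real_, length(ys), length(xs))
  valid <- matrix(FALSE, length(ys), length(xs))
  subpix <- function(cm1, c0, cp1) {
    if (cm1 > 0 && c0 > 0 && cp1 > 0 && (c0 > cm1 || c0 > cp1)) {
      den <- 2 * (log(cm1) + log(cp1) - 2 * log(c0))
      if (den < 0) return((log(cm1) - log(cp1)) / den)
    }
    den <- 2 * (cm1 + cp1 - 2 * c0)
    if (den < 0) (cm1 - cp1) / den else 0
  }
  for (iy in seq_along(ys)) {
    for (ix in seq_along(xs)) {
      w1 <- imageT[ys[iy]:(ys[iy] + window - 1), xs[ix]:(xs[ix] + window - 1)]
      w2 <- imageT1[ys[iy]:(ys[iy] + window - 1), xs[ix]:(xs[ix] + window - 1)]
      s1 <- stats::sd(w1); s2 <- stats::sd(w2)
      # a window needs texture on a substantial fraction of its area;
      # near-empty windows produce spurious peaks and are masked invalid
      if (s1 < minTexture * sdAll1 || s2 < minTexture * sdAll2) next
      f1 <- stats::fft(w1 - mean(w1))
      f2 <- stats::fft(w2 - mean(w2))
      cc <- Re(stats::fft(Conj(f1) * f2, inverse = TRUE))
      pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      wrap <- function(i) ifelse(i - 1 > window / 2, i - 1 - window, i - 1)
      dyi <- wrap(pk[1]); dxi <- wrap(pk[2])
      at <- function(dy, dx) cc[(dy %% window) + 1, (dx %% window) + 1]
      ddx <- subpix(at(dyi, dxi - 1), at(dyi, dxi), at(dyi, dxi + 1))
      ddy <- subpix(at(dyi - 1, dxi), at(dyi, dxi), at(dyi + 1, dxi))
      u[iy, ix] <- (dxi + ddx) / dt
      v[iy, ix] <- (dyi + ddy) / dt
      valid[iy, ix] <- TRUE
    }
  }
  # standard-deviation outlier filter with local-median replacement
  for (comp in 1:2) {
    z <- if (comp == 1) u else v
    mu <- mean(z[valid]); sdv <- stats::sd(z[valid])
    if (is.finite(sdv) && sdv > 0) {
      out <- valid & (abs(z - mu) > sdFilterN * sdv)
      if (any(out)) {
        idx <- which(out, arr.ind = TRUE)
        for (r in seq_len(nrow(idx))) {
          ry <- max(1, idx[r, 1] - 1):min(nrow(z), idx[r, 1] + 1)
          rx <- max(1, idx[r, 2] - 1):min(ncol(z), idx[r, 2] + 1)
          nbv <- z[ry, rx][valid[ry, rx] & !out[ry, rx]]
          z[idx[r, 1], idx[r, 2]] <-
            if (length(nbv)) stats::median(nbv) else mu
        }
        valid[out] <- FALSE  # masked as interpolated
        if (comp == 1) u <- z else v <- z
      }
    }
  }
  # window centers: top-left window spans pixels 0..window-1
  origin <- c(xs[1] - 1 + (window - 1) / 2, ys[1] - 1 + (window - 1) / 2)
  methods::new("VelocityField", origin = origin, spacing = step,
               vx = u, vy = v, valid = valid, source = "PIV")
}

#' Sample a velocity field at points
#'
#' Bilinear interpolation over valid samples; points falling on invalid or
#' missing samples fall back to the nearest valid vector.
#'
#' @param field a \linkS4class{VelocityField}.
#' @param xy n x 2 matrix of positions, px.
#' @return n x 2 matrix of velocities.
#' @export
sampleVelocity <- function(field, xy) {
  xy <- matrix(xy, ncol = 2)
  vxf <- field@vx; vyf <- field@vy
  # fill invalid entries with nearest valid for interpolation support
  if (any(!field@valid)) {
    iv <- which(!field@valid & !is.na(vxf))
    allv <- which(field@valid)
    if (length(allv)) {
      gv <- cbind((allv - 1) %% nrow(vxf), (allv - 1) %/% nrow(vxf))
      bad <- which(!field@valid | is.na(vxf))
      gb <- cbind((bad - 1) %% nrow(vxf), (bad - 1) %/% nrow(vxf))
      for (j in seq_along(bad)) {
        d2 <- (gv[, 1] - gb[j, 1])^2 + (gv[, 2] - gb[j, 2])^2
        nnear <- allv[which.min(d2)]
        vxf[bad[j]] <- vxf[nnear]; vyf[bad[j]] <- vyf[nnear]
      }
    }
  }
  cbind(bilinearAt(vxf, field@origin, field@spacing, xy[, 1], xy[, 2]),
        bilinearAt(vyf, field@origin, field@spacing, xy[, 1], xy[, 2]))
}

#' Match cells between consecutive frames
#'
#' Centers of frame t are advected by the velocity field, then matched to
#' frame t+dt centers by a globally optimal one-to-one assignment minimizing
#' total squared Euclidean distance (Jonker-Volgenant-class solver). Pairs
#' farther apart than \code{maxDist} are forbidden (infinite cost); cells
#' left without a partner are reported unmatched.
#'
#' @param frameT,frameT1 \linkS4class{TissueFrame}s.
#' @param velocity optional \linkS4class{VelocityField} used to advect
#'   frame-t centers; NULL = no advection.
#' @param maxDist gating distance, px.
#' @param dt interval, minutes.
#' @return list(map = data.frame(i_t, i_t1, dist), unmatchedT,
#'   unmatchedT1, totalCost).
#' @export
matchCells <- function(frameT, frameT1, velocity = NULL, maxDist = 400,
                       dt = 1) {
  ct <- frameT@cells; c1 <- frameT1@cells
  if (!nrow(ct) || !nrow(c1)) stop("empty frame")
  p <- cbind(ct$x, ct$y)
  if (!is.null(velocity)) p <- p + sampleVelocity(velocity, p) * dt
  d2 <- outer(p[, 1], c1$x, `-`)^2 + outer(p[, 2], c1$y, `-`)^2
  n1 <- nrow(d2); n2 <- ncol(d2)
  BIG <- max(maxDist^2 * 1e3, max(d2[d2 <= maxDist^2], 0) * 1e6 + 1)
  # augmented square problem: every cell may stay unmatched at cost
  # maxDist^2, realizing the infinite-cost gate beyond maxDist
  cm <- matrix(BIG, n1 + n2, n1 + n2)
  cm[seq_len(n1), seq_len(n2)] <- ifelse(d2 > maxDist^2, BIG, d2)
  cm[cbind(seq_len(n1), n2 + seq_len(n1))] <- maxDist^2
  cm[cbind(n1 + seq_len(n2), seq_len(n2))] <- maxDist^2
  cm[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0
  sol <- as.integer(clue::solve_LSAP(cm))
  a <- cbind(seq_len(n1), sol[seq_len(n1)])
  a <- a[a[, 2] <= n2, , drop = FALSE]
  ok <- d2[a] <= maxDist^2
  map <- data.frame(i_t = ct$id[a[ok, 1]], i_t1 = c1$id[a[ok, 2]],
                    dist = sqrt(d2[a[ok, , drop = FALSE]]))
  map <- map[order(map$i_t), , drop = FALSE]
  rownames(map) <- NULL
  list(map = map,
       unmatchedT = setdiff(ct$id, map$i_t),
       unmatchedT1 = setdiff(c1$id, map$i_t1),
       totalCost = sum(d2[a[ok, , drop = FALSE]]))
}

#' Detect divisions and apoptoses from a partial matching
#'
#' Every unmatched new cell is assigned a mother: among its matched neighbors
#' in frame t+dt, the cell with the largest area decrease over the interval
#' (ties broken by smallest center distance, then lowest id). Unmatched old
#' interior cells become apoptoses; unmatched old outermost cells are "left
#' the field".
#'
#' @param match result of \code{\link{matchCells}}.
#' @param frameT,frameT1 the frames that were matched.
#' @return A \linkS4class{Lineage} with a single interval.
#' @export
detectEvents <- function(match, frameT, frameT1) {
  ct <- frameT@cells; c1 <- frameT1@cells
  adj1 <- frameT1@adjacency
  map <- match$map
  rows <- list()
  divisions <- list()
  apoptoses <- list()
  motherOf <- character(0)
  for (newId in match$unmatchedT1) {
    nbrs <- c(adj1$k[adj1$i == newId], adj1$i[adj1$k == newId])
    cand <- map[map$i_t1 %in% nbrs, , drop = FALSE]
    if (!nrow(cand)) {
      warning("new cell ", newId, " has no matched neighbor; unresolved")
      rows[[length(rows) + 1L]] <- data.frame(i_t = NA_integer_,
                                              i_t1 = newId,
                                              kind = "unmatched")
      next
    }
    aT <- ct$area_px[match(cand$i_t, ct$id)]
    aT1 <- c1$area_px[match(cand$i_t1, c1$id)]
    drop <- aT - aT1
    dx <- c1$x[match(cand$i_t1, c1$id)] - c1$x[match(newId, c1$id)]
    dy <- c1$y[match(cand$i_t1, c1$id)] - c1$y[match(newId, c1$id)]
    ord <- order(-drop, dx^2 + dy^2, cand$i_t)
    mother <- cand$i_t[ord[1]]
    sibling <- cand$i_t1[ord[1]]
    divisions[[length(divisions) + 1L]] <-
      data.frame(mother = mother, daughter1 = sibling, daughter2 = newId)
    motherOf <- c(motherOf, as.character(mother))
  }
  div <- if (length(divisions)) do.call(rbind, divisions) else
    data.frame(mother = integer(), daughter1 = integer(),
               daughter2 = integer())
  for (oldId in match$unmatchedT) {
    if (ct$outermost[match(oldId, ct$id)]) {
      rows[[length(rows) + 1L]] <- data.frame(i_t = oldId, i_t1 = NA_integer_,
                                              kind = "left_field")
    } else {
      apoptoses[[length(apoptoses) + 1L]] <- oldId
      rows[[length(rows) + 1L]] <- data.frame(i_t = oldId, i_t1 = NA_integer_,
                                              kind = "apoptosis")
    }
  }
  for (r in seq_len(nrow(map))) {
    it <- map$i_t[r]
    if (as.character(it) %in% motherOf) {
      d <- div[div$mother == it, ]
      rows[[length(rows) + 1L]] <- data.frame(i_t = it, i_t1 = d$daughter1[1],
                                              kind = "division_mother")
      rows[[length(rows) + 1L]] <- data.frame(i_t = it, i_t1 = d$daughter2[1],
                                              kind = "division_daughter")
    } else {
      rows[[length(rows) + 1L]] <- data.frame(i_t = it, i_t1 = map$i_t1[r],
                                              kind = "map")
    }
  }
  mp <- do.call(rbind, rows)
  mp <- mp[order(mp$i_t, mp$i_t1), , drop = FALSE]
  rownames(mp) <- NULL
  apo <- if (length(apoptoses))
    data.frame(interval = 1L, cell = unlist(apoptoses)) else
      data.frame(interval = integer(), cell = integer())
  divTab <- if (nrow(div))
    data.frame(interval = 1L, mother = div$mother, daughter1 = div$daughter1,
               daughter2 = div$daughter2) else
      data.frame(interval = integer(), mother = integer(),
                 daughter1 = integer(), daughter2 = integer())
  methods::new("Lineage", maps = list(mp), divisions = divTab,
               apoptoses = apo)
}

#' Track a whole scene or frame sequence
#'
#' Runs \code{\link{matchCells}} and \code{\link{detectEvents}} over every
#' consecutive frame pair, using either the scene's ground-truth velocity or
#' PIV on the label images.
#'
#' @param frames list of \linkS4class{TissueFrame}.
#' @param velocities optional list of \linkS4class{VelocityField} (one per
#'   interval); NULL = no advection before matching.
#' @param dt interval, minutes.
#' @param maxDist gating distance, px.
#' @return A \linkS4class{Lineage} spanning all intervals.
#' @export
trackFrames <- function(frames, velocities = NULL, dt = 1, maxDist = 400) {
  n <- length(frames) - 1
  maps <- vector("list", n)
  div <- list(); apo <- list()
  for (k in seq_len(n)) {
    vel <- if (!is.null(velocities)) velocities[[k]] else NULL
    m <- matchCells(frames[[k]], frames[[k + 1]], vel, maxDist = maxDist,
                    dt = dt)
    lin <- detectEvents(m, frames[[k]], frames[[k + 1]])
    maps[[k]] <- lin@maps[[1]]
    if (nrow(lin@divisions)) {
      d <- lin@divisions; d$interval <- k
      div[[length(div) + 1L]] <- d
    }
    if (nrow(lin@apoptoses)) {
      a <- lin@apoptoses; a$interval <- k
      apo[[length(apo) + 1L]] <- a
    }
  }
  methods::new("Lineage", maps = maps,
               divisions = if (length(div)) do.call(rbind, div) else
                 data.frame(interval = integer(), mother = integer(),
                            daughter1 = integer(), daughter2 = integer()),
               apoptoses = if (length(apo)) do.call(rbind, apo) else
                 data.frame(interval = integer(), cell = integer()))
}

#' Initial-frame ROI grid
#'
#' Divides the initial frame into square tiles and assigns every cell to the
#' tile containing its center.
#'
#' @param frame the initial \linkS4class{TissueFrame}.
#' @param tile tile side, px.
#' @param interiorOnly drop outermost cells from membership.
#' @return list of \linkS4class{ROISpec} (single-frame membership).
#' @export
tileRois <- function(frame, tile = 120, interiorOnly = TRUE) {
  cells <- frame@cells
  if (interiorOnly) cells <- cells[!cells$outermost, , drop = FALSE]
  colIdx <- floor(cells$x / tile)
  rowIdx <- floor(cells$y / tile)
  keys <- paste(rowIdx, colIdx)
  out <- list()
  for (kk in unique(keys)) {
    sel <- keys == kk
    rc <- as.integer(strsplit(kk, " ")[[1]])
    out[[length(out) + 1L]] <- methods::new(
      "ROISpec", roiId = length(out) + 1L, origin = rc,
      members = list(cells$id[sel]))
  }
  out
}

#' Propagate ROI membership through a lineage
#'
#' Membership at frame k+1 is the lineage image of membership at frame k:
#' mapped cells persist, daughters replace mothers, apoptotic cells drop out.
#' Cells never transfer between ROIs. ROIs whose membership empties are
#' closed with a message.
#'
#' @param rois list of \linkS4class{ROISpec} from \code{\link{tileRois}}.
#' @param lineage a \linkS4class{Lineage} covering the frame sequence.
#' @return The ROI list with per-frame membership filled in.
#' @export
trackRois <- function(rois, lineage) {
  n <- length(lineage@maps)
  for (r in seq_along(rois)) {
    members <- rois[[r]]@members[[1]]
    for (k in seq_len(n)) {
      mp <- lineage@maps[[k]]
      nxt <- mp$i_t1[mp$i_t %in% members &
                       mp$kind %in% c("map", "division_mother",
                                      "division_daughter")]
      nxt <- sort(unique(nxt[!is.na(nxt)]))
      if (!length(nxt)) {
        message("ROI ", rois[[r]]@roiId, " emptied at interval ", k,
                "; closed")
      }
      rois[[r]]@members[[k + 1]] <- nxt
      members <- nxt
    }
  }
  rois
}
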