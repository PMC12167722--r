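# Checks of the kinematic equation for the cell-shape tensor and of the
# cell-number-density balance, plus the comparison statistics and kymograph
# summaries used to report them.

#' Per-component comparison of two tensor series
#'
#' Ordinary least squares of series b on series a for every column, plus
#' pooled statistics over all components.
#'
#' @param a,b numeric matrices or data.frames with matching dimensions
#'   (rows = observations, columns = tensor components).
#' @return list(components = data.frame(component, slope, intercept, r2,
#'   rmse), pooled = one-row data.frame).
#' @export
compareTensorSeries <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  if (nrow(a) < 3) stop("need at least 3 paired observations")
  cn <- colnames(a)
  if (is.null(cn)) cn <- paste0("c", seq_len(ncol(a)))
  components <- do.call(rbind, lapply(seq_len(ncol(a)), function(j) {
    st <- olsStats(a[, j], b[, j])
    data.frame(component = cn[j], slope = st$slope,
               intercept = st$intercept, r2 = st$r2, rmse = st$rmse,
               degenerate = st$degenerate, stringsAsFactors = FALSE)
  }))
  pooledStats <- olsStats(as.vector(a), as.vector(b))
  pooled <- data.frame(slope = pooledStats$slope,
                       intercept = pooledStats$intercept,
                       r2 = pooledStats$r2, rmse = pooledStats$rmse,
                       n = pooledStats$n)
  list(components = components, pooled = pooled)
}

#' Check the kinematic equation for the cell-shape tensor
#'
#' For every ROI interval compares the measured change of the texture tensor
#' with the transport prediction
#' \deqn{\Delta M = [(\nabla v - D_T) M + M (\nabla v - D_T)^T] \Delta t,}
#' using the frame-t tensor on the right-hand side (the neglected term is
#' \eqn{O(\Delta t^2)}). Works for any tensor columns present in the strain
#' series (\code{Mt*}/\code{Mt1*} for the half-link-normalized variant).
#'
#' @param ss strain series from \code{\link{strainSeries}}.
#' @param gradvSource \code{"texture"} (from F) or \code{"piv"} (requires
#'   \code{piv_gv*} columns).
#' @param useDT include the topological term (set FALSE to test the
#'   event-free form only).
#' @param Mcols prefix pair of the tensor columns, default
#'   \code{c("Mt", "Mt1")}.
#' @return list(table = per-interval data.frame with LHS/RHS components,
#'   residual norm and topology flag; comparison = compareTensorSeries
#'   output; eventFree subset comparison or NULL).
#' @export
kinematicCheck <- function(ss, gradvSource = c("texture", "piv"),
                           useDT = TRUE, Mcols = c("Mt", "Mt1")) {
  gradvSource <- match.arg(gradvSource)
  pick <- function(prefix) as.matrix(
    ss[, paste0(prefix, c("xx", "xy", "yy")), drop = FALSE])
  Mt <- pick(Mcols[1]); Mt1 <- pick(Mcols[2])
  if (gradvSource == "texture") {
    gv <- as.matrix(ss[, c("gvxx", "gvxy", "gvyx", "gvyy")])
  } else {
    if (!all(c("piv_gvxx", "piv_gvyy") %in% names(ss)))
      stop("strain series lacks PIV velocity-gradient columns")
    gv <- as.matrix(ss[, c("piv_gvxx", "piv_gvxy", "piv_gvyx", "piv_gvyy")])
  }
  DT <- pick("DT")
  n <- nrow(ss)
  lhs <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("xx", "xy", "yy")))
  rhs <- lhs
  for (r in seq_len(n)) {
    M <- matrix(c(Mt[r, 1], Mt[r, 2], Mt[r, 2], Mt[r, 3]), 2, 2)
    M1 <- matrix(c(Mt1[r, 1], Mt1[r, 2], Mt1[r, 2], Mt1[r, 3]), 2, 2)
    Gv <- matrix(gv[r, ], 2, 2, byrow = TRUE)
    Dt <- matrix(c(DT[r, 1], DT[r, 2], DT[r, 2], DT[r, 3]), 2, 2)
    Aop <- Gv - (if (useDT) Dt else 0)
    pred <- (Aop %*% M + M %*% t(Aop)) * ss$dt[r]
    dM <- M1 - M
    lhs[r, ] <- c(dM[1, 1], dM[1, 2], dM[2, 2])
    rhs[r, ] <- c(pred[1, 1], pred[1, 2], pred[2, 2])
  }
  resNorm <- sqrt(as.vector((lhs - rhs)^2 %*% c(1, 2, 1)))
  eventFree <- ss$divisions == 0 & ss$apoptoses == 0 & ss$r_links == 0
  tab <- data.frame(roi = ss$roi, interval = ss$interval,
                    lhs, rhs = rhs, residual = resNorm,
                    eventFree = eventFree, divisions = ss$divisions)
  cmpAll <- compareTensorSeries(rhs, lhs)
  cmpFree <- if (sum(eventFree) >= 3)
    compareTensorSeries(rhs[eventFree, , drop = FALSE],
                        lhs[eventFree, , drop = FALSE]) else NULL
  list(table = tab, comparison = cmpAll, eventFree = cmpFree)
}

movingAverage <- function(x, t, window) {
  vapply(t, function(tc)
    mean(x[abs(t - tc) <= window / 2], na.rm = TRUE), 0)
}

#' Check the cell-number-density balance
#'
#' Evaluates, per ROI interval, the Lagrangian density balance
#' \deqn{\dot\rho/\rho + \nabla\cdot v = \mathrm{Tr} D_T}
#' with the density from the half-link-normalized texture tensor and the
#' velocity divergence from either the total strain rate (Tr G) or a PIV
#' field. Also returns interval-mean time series smoothed with a centered
#' moving average.
#'
#' @param ss strain series from \code{\link{strainSeries}}.
#' @param routes divergence routes to evaluate, subset of
#'   \code{c("TrG", "PIV")}; unavailable routes are skipped with a message.
#' @param window moving-average window, minutes.
#' @return list(table, comparisons = per-route olsStats of LHS/rho vs
#'   Tr DT, routeAgreement = TrG-vs-PIV stats or NULL, series = smoothed
#'   interval means).
#' @export
densityBalance <- function(ss, routes = c("TrG", "PIV"), window = 30) {
  dlnrho <- (ss$rho_t1 - ss$rho_t) / ((ss$rho_t1 + ss$rho_t) / 2) / ss$dt
  trDT <- ss$DTxx + ss$DTyy
  divG <- ss$Gxx + ss$Gyy
  tab <- data.frame(roi = ss$roi, interval = ss$interval,
                    dlnrho = dlnrho, trDT = trDT, div_TrG = divG)
  comparisons <- list()
  if ("TrG" %in% routes) {
    comparisons$TrG <- olsStats(trDT, dlnrho + divG)
    tab$lhs_TrG <- dlnrho + divG
  }
  divP <- NULL
  if ("PIV" %in% routes) {
    if (all(c("piv_gvxx", "piv_gvyy") %in% names(ss))) {
      divP <- ss$piv_gvxx + ss$piv_gvyy
      comparisons$PIV <- olsStats(trDT, dlnrho + divP)
      tab$div_PIV <- divP
      tab$lhs_PIV <- dlnrho + divP
    } else {
      message("PIV route unavailable: no piv_gv* columns; skipped")
    }
  }
  routeAgreement <- if (!is.null(divP)) olsStats(divG, divP) else NULL
  tmid <- (ss$interval - 0.5) * ss$dt
  ts <- stats::aggregate(cbind(dlnrho, trDT, divG), list(t = tmid), mean)
  series <- data.frame(
    t = ts$t,
    lhs_TrG = movingAverage(ts$dlnrho + ts$divG, ts$t, window),
    trDT = movingAverage(ts$trDT, ts$t, window))
  list(table = tab, comparisons = comparisons,
       routeAgreement = routeAgreement, series = series)
}

#' Kymograph of shape summaries along an axis
#'
#' Moving-window averages of per-ROI (or per-cell) shape quantities along one
#' spatial axis, per frame: the space-time maps used to compare samples.
#'
#' @param summaries data.frame with columns \code{frame}, \code{x}, \code{y},
#'   \code{area}, \code{aspect}, \code{theta}.
#' @param axis \code{"x"} or \code{"y"}.
#' @param window window width, px.
#' @param step output spacing, px.
#' @return data.frame(frame, pos, n, area, aspect, coherence); windows
#'   without data yield NA, never zero.
#' @export
kymograph <- function(summaries, axis = c("x", "y"), window = 200,
                      step = 50) {
  axis <- match.arg(axis)
  pos <- summaries[[axis]]
  rng <- range(pos)
  centers <- seq(rng[1], rng[2], by = step)
  out <- list()
  for (fr in sort(unique(summaries$frame))) {
    sel <- summaries$frame == fr
    for (ct in centers) {
      inwin <- sel & abs(pos - ct) <= window / 2
      n <- sum(inwin)
      out[[length(out) + 1L]] <- data.frame(
        frame = fr, pos = ct, n = n,
        area = if (n) mean(summaries$area[inwin]) else NA_real_,
        aspect = if (n) mean(summaries$aspect[inwin]) else NA_real_,
        coherence = if (n) orientationCoherence(summaries$theta[inwin])
        else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Shape summaries of every ROI in a frame
#'
#' Convenience wrapper: M1 texture tensor and \code{\link{shapeSummary}} per
#' ROI, with the ROI mean position attached (kymograph input).
#'
#' @param frame a \linkS4class{TissueFrame}.
#' @param rois list of \linkS4class{ROISpec}.
#' @param frameIdx 1-based index into the ROI membership lists.
#' @return data.frame(frame, roi, x, y, area, aspect, theta).
#' @export
roiShapeSummaries <- function(frame, rois, frameIdx = 1L) {
  out <- list()
  for (roi in rois) {
    members <- roi@members[[frameIdx]]
    if (length(members) < 2) next
    hl <- halfLinks(frame, members, roi@roiId)
    if (hl@degenerate) next
    sm <- shapeSummary(textureTensor(hl, "M1"))
    cells <- frame@cells[frame@cells$id %in% members, ]
    out[[length(out) + 1L]] <- data.frame(
      frame = frame@frameIndex, roi = roi@roiId,
      x = mean(cells$x), y = mean(cells$y),
      area = sm$area, aspect = sm$aspect, theta = sm$theta)
  }
  if (!length(out)) stop("no usable ROIs")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
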