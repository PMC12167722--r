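# Half-link classification across a frame pair and the strain-rate
# decomposition.
#
# The total strain rate of an ROI is measured from the affine transport of
# conserved half-links (deformation gradient F, G = (F'F - I)/(2 dt)).
# Appearing and disappearing half-links are assigned to rearrangement (R),
# division (D) or apoptosis (A); each class X contributes an increment of the
# half-link-normalized texture tensor
#
#   dM_X = [sum_app (w/2) l'(x)l' - sum_dis (w/2) l(x)l]/Nh_bar
#          - (dNh_X / Nh_bar) M_mid
#
# where the second term carries the change of the normalization count N_h
# attributable to the class. The symmetric rate of class X solves the
# Sylvester relation  -dM_X = (T_X M_mid + M_mid T_X) dt , so that divisions
# (which add links and shrink the per-link texture) yield Tr D >= 0 and T2
# removals Tr A <= 0, and the decomposition is consistent with the
# cell-number-density balance d(ln rho)/dt + div v = Tr(R + D + A).

#' Classify half-links of an ROI across a frame interval
#'
#' Conserved links join lineage-matched cell pairs adjacent at both epochs.
#' Under the division-priority rule all links created or destroyed by a
#' division (mother links, daughter-daughter link, links re-pointed from the
#' mother to a daughter) are labeled D; the alternative rule labels the
#' re-pointed neighbor links R instead. Links of an apoptotic cell and the
#' new contacts closing its vacancy are labeled A (the latter configurable to
#' R); every remaining exchange between surviving cells is a rearrangement R.
#'
#' @param frameT,frameT1 consecutive \linkS4class{TissueFrame}s.
#' @param membersT integer ids of ROI members at frame t.
#' @param lineage a \linkS4class{Lineage}.
#' @param interval 1-based interval index into the lineage.
#' @param rule \code{"division-priority"} (default) or
#'   \code{"rearrangement-alternative"}.
#' @param apoptosisAppeared label for vacancy-closing links: "A" or "R".
#' @return data.frame of undirected link records: endpoint keys (frame-t ids
#'   for survivors, daughter ids for new cells), epoch vectors, weights,
#'   half-link multiplicities, status (conserved/appeared/disappeared) and
#'   event label (S/R/D/A). Attribute \code{"discarded"} counts links
#'   touching unresolved cells; attribute \code{"membersT1"} is the mapped
#'   membership.
#' @export
classifyLinks <- function(frameT, frameT1, membersT, lineage, interval = 1L,
                          rule = c("division-priority",
                                   "rearrangement-alternative"),
                          apoptosisAppeared = c("A", "R")) {
  rule <- match.arg(rule)
  apoptosisAppeared <- match.arg(apoptosisAppeared)
  mp <- lineage@maps[[interval]]
  surv <- mp[mp$kind == "map", , drop = FALSE]
  div <- lineage@divisions[lineage@divisions$interval == interval, ,
                           drop = FALSE]
  apo <- lineage@apoptoses$cell[lineage@apoptoses$interval == interval]
  unresolved <- mp$i_t[mp$kind %in% c("unmatched")]
  mothers <- div$mother
  daughters <- c(div$daughter1, div$daughter2)
  motherOfDaughter <- stats::setNames(rep(div$mother, 2), daughters)
  backmap <- stats::setNames(surv$i_t, surv$i_t1)

  # membership at t1: survivors keep ids, daughters replace mothers
  mappedT1 <- c(surv$i_t1[surv$i_t %in% membersT],
                daughters[motherOfDaughter %in% membersT])

  pairTable <- function(frame, members) {
    cells <- frame@cells
    adj <- frame@adjacency
    outer <- cells$id[cells$outermost]
    sel <- (adj$i %in% members | adj$k %in% members) &
      !(adj$i %in% outer) & !(adj$k %in% outer)
    a <- adj[sel, , drop = FALSE]
    mult <- (a$i %in% members) + (a$k %in% members)
    data.frame(i = a$i, k = a$k, omega = a$omega, mult = mult,
               lx = cells$x[match(a$k, cells$id)] - cells$x[match(a$i, cells$id)],
               ly = cells$y[match(a$k, cells$id)] - cells$y[match(a$i, cells$id)])
  }
  pt <- pairTable(frameT, membersT)
  pt1 <- pairTable(frameT1, mappedT1)

  # keys in frame-t id space
  keyOf <- function(a, b) paste(pmin(a, b), pmax(a, b))
  bm <- function(id) {
    out <- backmap[as.character(id)]
    ifelse(is.na(out), id, out)  # daughters and unknowns keep their id
  }
  pt$key <- keyOf(pt$i, pt$k)
  i0 <- bm(pt1$i); k0 <- bm(pt1$k)
  pt1$key <- keyOf(i0, k0)
  pt1$i0 <- pmin(i0, k0); pt1$k0 <- pmax(i0, k0)

  # drop links touching unresolved cells
  discarded <- 0L
  if (length(unresolved)) {
    dropT <- pt$i %in% unresolved | pt$k %in% unresolved
    discarded <- discarded + sum(dropT)
    pt <- pt[!dropT, , drop = FALSE]
  }
  survivorsT1 <- surv$i_t1
  knownT1 <- c(survivorsT1, daughters)
  dropT1 <- !(pt1$i %in% knownT1) | !(pt1$k %in% knownT1)
  discarded <- discarded + sum(dropT1)
  pt1 <- pt1[!dropT1, , drop = FALSE]

  conservedKeys <- intersect(pt$key, pt1$key)
  rows <- list()
  addRow <- function(i, k, status, label, omega_t, omega_t1, mult,
                     lxt, lyt, lxt1, lyt1) {
    rows[[length(rows) + 1L]] <<- data.frame(
      i = i, k = k, status = status, label = label,
      omega_t = omega_t, omega_t1 = omega_t1, mult = mult,
      lxt = lxt, lyt = lyt, lxt1 = lxt1, lyt1 = lyt1,
      stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(pt))) {
    key <- pt$key[r]
    if (key %in% conservedKeys) {
      r1 <- pt1[match(key, pt1$key), ]
      # orient the t1 vector as i -> k in t-id space
      sgn <- if (bm(r1$i) == pt$i[r]) 1 else -1
      addRow(pt$i[r], pt$k[r], "conserved", "S", pt$omega[r], r1$omega,
             pt$mult[r], pt$lx[r], pt$ly[r], sgn * r1$lx, sgn * r1$ly)
    } else {
      ends <- c(pt$i[r], pt$k[r])
      label <- if (any(ends %in% mothers)) "D"
      else if (any(ends %in% apo)) "A"
      else "R"
      addRow(pt$i[r], pt$k[r], "disappeared", label, pt$omega[r], NA_real_,
             pt$mult[r], pt$lx[r], pt$ly[r], NA_real_, NA_real_)
    }
  }
  # neighbor sets of apoptotic cells at t (for vacancy-closing contacts)
  adjT <- frameT@adjacency
  apoNbrs <- lapply(apo, function(a)
    c(adjT$k[adjT$i == a], adjT$i[adjT$k == a]))
  names(apoNbrs) <- as.character(apo)
  for (r in seq_len(nrow(pt1))) {
    key <- pt1$key[r]
    if (key %in% conservedKeys) next
    endsNew <- c(pt1$i[r], pt1$k[r])  # t1 ids
    ends0 <- c(pt1$i0[r], pt1$k0[r])  # t-space keys
    isDaughter <- endsNew %in% daughters
    label <- "R"
    if (any(isDaughter)) {
      if (all(isDaughter) &&
          length(unique(motherOfDaughter[as.character(endsNew)])) == 1) {
        label <- "D"  # the new daughter-daughter junction
      } else if (rule == "division-priority") {
        label <- "D"
      } else {
        label <- "R"
      }
    } else if (length(apo)) {
      closing <- any(vapply(apoNbrs, function(nb) all(ends0 %in% nb), TRUE))
      if (closing) label <- apoptosisAppeared
    }
    addRow(pt1$i0[r], pt1$k0[r], "appeared", label, NA_real_, pt1$omega[r],
           pt1$mult[r], NA_real_, NA_real_, pt1$lx[r] *
             (if (bm(pt1$i[r]) == pt1$i0[r]) 1 else -1),
           pt1$ly[r] * (if (bm(pt1$i[r]) == pt1$i0[r]) 1 else -1))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(), k = integer(), status = character(),
               label = character(), omega_t = numeric(), omega_t1 = numeric(),
               mult = numeric(), lxt = numeric(), lyt = numeric(),
               lxt1 = numeric(), lyt1 = numeric())
  attr(out, "discarded") <- discarded
  attr(out, "membersT1") <- sort(unique(mappedT1))
  attr(out, "rule") <- rule
  out
}

outerSum <- function(w, lx, ly) {
  matrix(c(sum(w * lx^2), sum(w * lx * ly),
           sum(w * lx * ly), sum(w * ly^2)), 2, 2)
}

#' Deformation gradient from conserved half-links
#'
#' Least-squares affine transport of the conserved links:
#' \eqn{F = B C^{-1}} with \eqn{C = \sum (\omega/2) l_t l_t^T} and
#' \eqn{B = \sum (\omega/2) l_{t+dt} l_t^T}; exact when the transport is
#' affine.
#'
#' @param cls classification table from \code{\link{classifyLinks}} (its
#'   conserved rows are used), or any data.frame with columns \code{lxt,
#'   lyt, lxt1, lyt1, omega_t, mult}.
#' @return 2x2 deformation gradient matrix.
#' @export
deformationGradient <- function(cls) {
  cc <- cls[cls$status == "conserved", , drop = FALSE]
  if (nrow(cc) < 3) stop("need at least 3 conserved half-links")
  w <- cc$mult * cc$omega_t / 2
  C <- outerSum(w, cc$lxt, cc$lyt)
  if (abs(det(C)) <= .Machine$double.eps * 100 * max(abs(C))^2)
    stop("collinear texture: deformation gradient undefined")
  B <- matrix(c(sum(w * cc$lxt1 * cc$lxt), sum(w * cc$lyt1 * cc$lxt),
                sum(w * cc$lxt1 * cc$lyt), sum(w * cc$lyt1 * cc$lyt)), 2, 2)
  B %*% solve(C)
}

#' Symmetric strain rate from a deformation gradient
#'
#' \eqn{G = (F^T F - I) / (2 dt)}; invariant under rotations of F.
#'
#' @param F 2x2 deformation gradient.
#' @param dt interval, minutes.
#' @return Symmetric 2x2 strain-rate tensor, 1/min.
#' @export
strainRateG <- function(F, dt) {
  stopifnot(dt > 0)
  (t(F) %*% F - diag(2)) / (2 * dt)
}

#' Strain-rate decomposition of one ROI interval
#'
#' Computes F, G and the decomposition G = S + R + D + A from a link
#' classification. In raw closure mode S is measured as the Sylvester
#' solution of the full change of the half-link-normalized texture tensor
#' (so the closure residual is reported); in strict mode S = G - (R + D + A)
#' and the residual is zero by construction.
#'
#' @param cls classification table from \code{\link{classifyLinks}}.
#' @param dt interval, minutes.
#' @param closure \code{"raw"} (default) or \code{"strict"}.
#' @param gradv optional 2x2 velocity gradient (for the rotation diagnostic
#'   and provenance); default derived from F as (F - I)/dt.
#' @param roiId,interval provenance.
#' @return A \linkS4class{StrainRates}.
#' @export
decomposeStrain <- function(cls, dt, closure = c("raw", "strict"),
                            gradv = NULL, roiId = 0L, interval = 1L) {
  closure <- match.arg(closure)
  F <- deformationGradient(cls)
  G <- strainRateG(F, dt)
  epochT <- cls$status %in% c("conserved", "disappeared")
  epochT1 <- cls$status %in% c("conserved", "appeared")
  nhT <- sum(cls$mult[epochT])
  nhT1 <- sum(cls$mult[epochT1])
  nhBar <- (nhT + nhT1) / 2
  wT <- cls$mult * cls$omega_t / 2
  wT1 <- cls$mult * cls$omega_t1 / 2
  M0t <- outerSum(wT[epochT], cls$lxt[epochT], cls$lyt[epochT])
  M0t1 <- outerSum(wT1[epochT1], cls$lxt1[epochT1], cls$lyt1[epochT1])
  M1t <- M0t / nhT
  M1t1 <- M0t1 / nhT1
  Mmid <- (M1t + M1t1) / 2
  classTensor <- function(lab) {
    app <- cls$status == "appeared" & cls$label == lab
    dis <- cls$status == "disappeared" & cls$label == lab
    raw <- outerSum(wT1[app], cls$lxt1[app], cls$lyt1[app]) -
      outerSum(wT[dis], cls$lxt[dis], cls$lyt[dis])
    dNh <- sum(cls$mult[app]) - sum(cls$mult[dis])
    dM <- raw / nhBar - (dNh / nhBar) * Mmid
    -solveSylvester2(dM, Mmid, dt)
  }
  R <- classTensor("R")
  D <- classTensor("D")
  A <- classTensor("A")
  if (closure == "raw") {
    S <- solveSylvester2(M1t1 - M1t, Mmid, dt)
  } else {
    S <- G - (R + D + A)
  }
  DT <- R + D + A
  residual <- G - (S + R + D + A)
  if (is.null(gradv)) gradv <- (F - diag(2)) / dt
  Omega <- (gradv - t(gradv)) / 2
  methods::new("StrainRates", F = F, G = G, S = S, R = R, D = D, A = A,
               DT = DT, gradv = gradv, Omega = Omega, dt = dt,
               roiId = as.integer(roiId), interval = as.integer(interval),
               residual = residual,
               rule = attr(cls, "rule") %||% "division-priority",
               closure = closure)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Velocity gradient from a velocity field over an ROI
#'
#' Least-squares plane fit of each velocity component over the valid samples
#' inside the ROI bounding box (member cell centers plus a margin).
#'
#' @param field a \linkS4class{VelocityField}.
#' @param frame the \linkS4class{TissueFrame} providing member positions.
#' @param members integer ids of ROI member cells.
#' @param margin bounding-box margin, px.
#' @return list(gradv = 2x2 matrix (1/min), v = mean velocity, n = samples).
#' @export
gradVFromField <- function(field, frame, members, margin = 20) {
  cells <- frame@cells[frame@cells$id %in% members, , drop = FALSE]
  if (!nrow(cells)) stop("no member cells in frame")
  bb <- c(min(cells$x) - margin, max(cells$x) + margin,
          min(cells$y) - margin, max(cells$y) + margin)
  nx <- ncol(field@vx); ny <- nrow(field@vx)
  gx <- field@origin[1] + (seq_len(nx) - 1) * field@spacing
  gy <- field@origin[2] + (seq_len(ny) - 1) * field@spacing
  sel <- outer(gy >= bb[3] & gy <= bb[4], gx >= bb[1] & gx <= bb[2], `&`) &
    field@valid
  if (sum(sel) < 4) stop("fewer than 4 valid velocity samples in ROI")
  X <- gx[col(field@vx)[sel]]
  Y <- gy[row(field@vx)[sel]]
  if (stats::sd(X) == 0 || stats::sd(Y) == 0)
    stop("rank-deficient velocity sample geometry")
  fitx <- stats::lm.fit(cbind(1, X, Y), field@vx[sel])
  fity <- stats::lm.fit(cbind(1, X, Y), field@vy[sel])
  gradv <- rbind(fitx$coefficients[2:3], fity$coefficients[2:3])
  dimnames(gradv) <- NULL
  list(gradv = gradv, v = c(mean(field@vx[sel]), mean(field@vy[sel])),
       n = sum(sel))
}

flattenTensor <- function(m, prefix) {
  stats::setNames(c(m[1, 1], m[1, 2], m[2, 2]),
                  paste0(prefix, c("xx", "xy", "yy")))
}

#' Per-ROI, per-interval strain decomposition of a frame sequence
#'
#' Runs link classification and strain decomposition for every ROI and
#' interval, returning one row per (roi, interval) with the tensors
#' flattened, the per-epoch texture tensors and densities (variant M1), the
#' link-count bookkeeping and the event counts inside the ROI.
#'
#' @param frames list of \linkS4class{TissueFrame}.
#' @param lineage a \linkS4class{Lineage} covering the sequence.
#' @param rois list of tracked \linkS4class{ROISpec}.
#' @param dt interval, minutes.
#' @param rule,closure,apoptosisAppeared passed to
#'   \code{\link{classifyLinks}} / \code{\link{decomposeStrain}}.
#' @param velocities optional list of \linkS4class{VelocityField}; adds
#'   PIV/ground-truth velocity-gradient columns (\code{piv_*}).
#' @return data.frame; skipped degenerate ROI intervals are dropped with a
#'   message.
#' @export
strainSeries <- function(frames, lineage, rois, dt,
                         rule = "division-priority", closure = "raw",
                         apoptosisAppeared = "A", velocities = NULL) {
  out <- list()
  for (roi in rois) {
    for (iv in seq_len(length(frames) - 1)) {
      members <- roi@members[[iv]]
      if (length(members) < 2) next
      cls <- tryCatch(
        classifyLinks(frames[[iv]], frames[[iv + 1]], members, lineage,
                      interval = iv, rule = rule,
                      apoptosisAppeared = apoptosisAppeared),
        error = function(e) NULL)
      if (is.null(cls) || sum(cls$status == "conserved") < 3) {
        message("ROI ", roi@roiId, " interval ", iv,
                ": degenerate, skipped")
        next
      }
      sr <- tryCatch(
        decomposeStrain(cls, dt, closure = closure, roiId = roi@roiId,
                        interval = iv),
        error = function(e) NULL)
      if (is.null(sr)) {
        message("ROI ", roi@roiId, " interval ", iv,
                ": decomposition failed, skipped")
        next
      }
      epochT <- cls$status %in% c("conserved", "disappeared")
      epochT1 <- cls$status %in% c("conserved", "appeared")
      nhT <- sum(cls$mult[epochT]); nhT1 <- sum(cls$mult[epochT1])
      M1t <- outerSum(cls$mult[epochT] * cls$omega_t[epochT] / 2,
                      cls$lxt[epochT], cls$lyt[epochT]) / nhT
      M1t1 <- outerSum(cls$mult[epochT1] * cls$omega_t1[epochT1] / 2,
                       cls$lxt1[epochT1], cls$lyt1[epochT1]) / nhT1
      divHere <- sum(lineage@divisions$interval == iv &
                       lineage@divisions$mother %in% members)
      apoHere <- sum(lineage@apoptoses$interval == iv &
                       lineage@apoptoses$cell %in% members)
      rLinks <- sum(cls$label == "R" & cls$status != "conserved")
      row <- c(
        roi = roi@roiId, interval = iv, dt = dt,
        flattenTensor(sr@F, "F"), flattenTensor(sr@G, "G"),
        flattenTensor(sr@S, "S"), flattenTensor(sr@R, "R"),
        flattenTensor(sr@D, "D"), flattenTensor(sr@A, "A"),
        flattenTensor(sr@DT, "DT"), flattenTensor(sr@residual, "res"),
        flattenTensor(M1t, "Mt"), flattenTensor(M1t1, "Mt1"),
        gvxx = sr@gradv[1, 1], gvxy = sr@gradv[1, 2],
        gvyx = sr@gradv[2, 1], gvyy = sr@gradv[2, 2],
        nH_t = nhT, nH_t1 = nhT1,
        nC_t = length(members),
        rho_t = 1 / (pi * sqrt(det(M1t))),
        rho_t1 = 1 / (pi * sqrt(det(M1t1))),
        divisions = divHere, apoptoses = apoHere, r_links = rLinks,
        discarded = attr(cls, "discarded"))
      if (!is.null(velocities)) {
        gv <- tryCatch(
          gradVFromField(velocities[[iv]], frames[[iv]], members),
          error = function(e) NULL)
        row <- c(row,
                 piv_gvxx = if (is.null(gv)) NA_real_ else gv$gradv[1, 1],
                 piv_gvxy = if (is.null(gv)) NA_real_ else gv$gradv[1, 2],
                 piv_gvyx = if (is.null(gv)) NA_real_ else gv$gradv[2, 1],
                 piv_gvyy = if (is.null(gv)) NA_real_ else gv$gradv[2, 2])
      }
      out[[length(out) + 1L]] <- as.data.frame(as.list(row))
    }
  }
  if (!length(out)) stop("no usable ROI intervals")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
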