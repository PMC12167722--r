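# Synthetic scene orchestrator: advects a tiling through a prescribed flow
# and applies scheduled topological events with an exact event log.
#
# T1 exchanges are taken through the physical near-fourfold route: the edge
# is shrunk to a small fraction of its length in the frame before the swap,
# the swap opens an equally small perpendicular edge, and the new edge grows
# back to the natural length one interval later. This makes the link exchange
# approximately area-neutral in the texture metric, as a neighbor exchange in
# a real epithelium is; the instantaneous variant (t1Ramp = FALSE) swaps a
# full-length edge in one step.

emptyEventLog <- function() {
  data.frame(interval = integer(), kind = character(), cell = integer(),
             daughter1 = integer(), daughter2 = integer(), axis = numeric(),
             lost_i = integer(), lost_k = integer(),
             gained_i = integer(), gained_k = integer(),
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic tissue scene
#'
#' Generates \code{nIntervals + 1} frames of a tiling advected through
#' \code{flow}, with seeded T1 exchanges, divisions and T2 removals applied
#' between frames and recorded in a ground-truth event log. Event counts per
#' interval are Poisson with the given means; participating cells are drawn
#' uniformly among eligible interior cells/edges, excluding cells involved in
#' an event during the same or previous interval (at most one event per cell
#' per interval).
#'
#' @param tiling initial \linkS4class{Tiling}.
#' @param flow a \linkS4class{FlowSpec}.
#' @param nIntervals number of frame intervals.
#' @param dt frame interval, minutes.
#' @param t1PerInterval,divisionsPerInterval,t2PerInterval mean event counts
#'   per interval.
#' @param seed RNG seed; the scene is reproducible from (arguments, seed).
#' @param t1Ramp take T1 edges through the near-fourfold configuration
#'   (shrink/swap/regrow) rather than swapping at full length.
#' @param t1Delta residual edge length fraction at the swap.
#' @param divisionAxis \code{"long-axis"} (perpendicular to the cell's long
#'   axis) or \code{"random"}.
#' @param rasterize attach label images to the frames.
#' @param canvas c(width, height) for rasterization; default fits frame 0
#'   with a margin for the flow.
#' @param velocitySpacing grid spacing of the ground-truth velocity samples.
#' @param pixelSize micrometers per pixel.
#' @return A \linkS4class{SyntheticScene}.
#' @export
simulateScene <- function(tiling, flow = affineFlow(), nIntervals = 10,
                          dt = 5, t1PerInterval = 0,
                          divisionsPerInterval = 0, t2PerInterval = 0,
                          seed = 1L, t1Ramp = TRUE, t1Delta = 0.12,
                          divisionAxis = c("long-axis", "random"),
                          rasterize = FALSE, canvas = NULL,
                          velocitySpacing = 16, pixelSize = 1) {
  divisionAxis <- match.arg(divisionAxis)
  events <- emptyEventLog()
  frames <- vector("list", nIntervals + 1)
  tilings <- vector("list", nIntervals + 1)
  velocity <- vector("list", nIntervals)
  bb0 <- apply(tiling@vertices, 2, range)
  if (is.null(canvas))
    canvas <- c(ceiling(bb0[2, 1] * 1.3) + 4L, ceiling(bb0[2, 2] * 1.3) + 4L)
  withSeed(seed, {
    state <- tiling
    idCounter <- max(tiling@ids)
    pendingGrow <- list()  # T1 edges to regrow next interval
    prevInvolved <- integer()
    for (k in 0:nIntervals) {
      involved <- integer()
      t1Plan <- list()
      divPlan <- integer()
      t2Plan <- integer()
      if (k < nIntervals) {
        fr0 <- tilingAdjacency(state)
        om <- as.integer(names(fr0$outermost)[fr0$outermost])
        blocked <- c(prevInvolved, om)
        nT1 <- stats::rpois(1, t1PerInterval)
        nDiv <- stats::rpois(1, divisionsPerInterval)
        nT2 <- stats::rpois(1, t2PerInterval)
        if (nT1 > 0) {
          ed <- tilingEdges(state, interiorOnly = TRUE)
          # a T1 proceeds from a junction near fourfold symmetry: rank
          # candidate edges by the asymmetry between the separating-pair and
          # joining-pair center distances (the exchange is texture-neutral
          # where this vanishes), preferring shorter edges
          if (nrow(ed)) {
            ctr <- tilingCentroids(state)
            # texture metric of the current frame: the exchange should be
            # neutral in this metric (Tr R = 0), not in Euclidean distance
            frNow <- tilingToFrame(state, frameIndex = k, time = k * dt)
            hlAll <- halfLinks(frNow, cellIds(frNow)[!cellTable(frNow)$outermost])
            Minv <- tryCatch(solve(textureTensor(hlAll, "M1")@M),
                             error = function(e) diag(2))
            dM2 <- function(a, b) { dd <- a - b; sum(dd * (Minv %*% dd)) }
            quads <- lapply(seq_len(nrow(ed)), function(j) {
              ec <- edgeCellsOf(state, ed$p[j], ed$q[j])
              if (length(ec$edge) != 2 || length(ec$pOnly) != 1 ||
                  length(ec$qOnly) != 1) return(NULL)
              state@ids[c(ec$edge, ec$pOnly, ec$qOnly)]
            })
            okq <- !vapply(quads, is.null, TRUE)
            ed <- ed[okq, , drop = FALSE]
            quads <- quads[okq]
            asym <- vapply(seq_along(quads), function(j) {
              q4 <- as.character(quads[[j]])
              dAB <- dM2(ctr[q4[1], ], ctr[q4[2], ])
              dCD <- dM2(ctr[q4[3], ], ctr[q4[4], ])
              abs(dCD - dAB) / (dCD + dAB)
            }, 0)
            short <- ed$length <= stats::median(ed$length)
            pre <- order(!short, asym)
            # refine the ranking on the collapsed-junction geometry: the
            # separating- and joining-pair center distances once the edge is
            # taken to the near-fourfold configuration
            eval <- utils::head(pre, max(8L * nT1, 40L))
            asym2 <- vapply(eval, function(j) {
              st2 <- resizeEdge(state, ed$p[j], ed$q[j],
                                t1Delta * ed$length[j])
              q4 <- match(quads[[j]], st2@ids)
              cc <- t(vapply(q4, function(ci)
                polyCentroid(st2@vertices[st2@cells[[ci]], , drop = FALSE]),
                c(0, 0)))
              # the separating pair is measured at t, the joining pair at
              # t + dt: advect the joining pair to its measurement epoch
              ccAdv <- cc[3:4, ] + flowVelocity(flow, cc[3:4, ]) * dt
              dAB <- dM2(cc[1, ], cc[2, ])
              dCD <- dM2(ccAdv[1, ], ccAdv[2, ])
              abs(dCD - dAB) / (dCD + dAB)
            }, 0)
            ord <- eval[order(asym2)]
            for (j in ord) {
              if (length(t1Plan) >= nT1) break
              quad <- quads[[j]]
              if (any(quad %in% c(blocked, involved, om))) next
              t1Plan[[length(t1Plan) + 1L]] <-
                list(p = ed$p[j], q = ed$q[j], len = ed$length[j])
              involved <- c(involved, quad)
            }
          }
        }
        if (nDiv > 0 || nT2 > 0) {
          interior <- setdiff(state@ids, om)
          pool <- setdiff(interior, c(blocked, involved))
          nPick <- min(length(pool), nDiv + nT2)
          picks <- if (nPick > 0) sample(pool, nPick) else integer()
          divPlan <- utils::head(picks, min(nDiv, length(picks)))
          t2Plan <- utils::tail(picks, max(0, length(picks) - min(nDiv, length(picks))))
          t2Plan <- utils::head(t2Plan, nT2)
          involved <- c(involved, divPlan, t2Plan)
        }
        # pre-shrink T1 edges so the swap frame shows a near-fourfold junction
        if (t1Ramp) {
          for (pl in t1Plan) state <- resizeEdge(state, pl$p, pl$q,
                                                 t1Delta * pl$len)
        }
      }
      frames[[k + 1]] <- tilingToFrame(state, frameIndex = k, time = k * dt,
                                       pixelSize = pixelSize)
      tilings[[k + 1]] <- state
      if (rasterize) {
        frames[[k + 1]]@labelImage <-
          rasterizeTiling(state, width = canvas[1], height = canvas[2])
      }
      if (k == nIntervals) break
      velocity[[k + 1]] <- sampleFlowField(
        flow, c(0, canvas[1] - 1, 0, canvas[2] - 1), velocitySpacing)
      state <- advectTiling(state, flow, dt)
      # regrow edges opened by the previous interval's T1s
      for (pg in pendingGrow) {
        st <- tryCatch(resizeEdge(state, pg$p, pg$q, pg$len),
                       error = function(e) NULL)
        if (!is.null(st)) state <- st
      }
      pendingGrow <- list()
      for (pl in t1Plan) {
        res <- tryCatch(applyT1(state, pl$p, pl$q,
                                newLen = if (t1Ramp) t1Delta * pl$len
                                         else pl$len),
                        error = function(e) NULL)
        if (is.null(res)) next
        state <- res$tiling
        if (t1Ramp)
          pendingGrow[[length(pendingGrow) + 1L]] <-
            list(p = pl$p, q = pl$q, len = pl$len)
        events <- rbind(events, data.frame(
          interval = k, kind = "T1", cell = NA_integer_,
          daughter1 = NA_integer_, daughter2 = NA_integer_, axis = NA_real_,
          lost_i = min(res$lost), lost_k = max(res$lost),
          gained_i = min(res$gained), gained_k = max(res$gained),
          stringsAsFactors = FALSE))
      }
      for (cid in divPlan) {
        ax <- if (divisionAxis == "random") stats::runif(1, 0, pi) else NULL
        res <- tryCatch(applyDivision(state, cid, axisAngle = ax,
                                      newIds = idCounter + 1:2),
                        error = function(e) NULL)
        if (is.null(res)) next
        idCounter <- idCounter + 2L
        state <- res$tiling
        events <- rbind(events, data.frame(
          interval = k, kind = "division", cell = cid,
          daughter1 = res$daughters[1], daughter2 = res$daughters[2],
          axis = res$axis, lost_i = NA_integer_, lost_k = NA_integer_,
          gained_i = NA_integer_, gained_k = NA_integer_,
          stringsAsFactors = FALSE))
      }
      for (cid in t2Plan) {
        res <- tryCatch(applyT2(state, cid), error = function(e) NULL)
        if (is.null(res)) next
        state <- res$tiling
        events <- rbind(events, data.frame(
          interval = k, kind = "apoptosis", cell = cid,
          daughter1 = NA_integer_, daughter2 = NA_integer_, axis = NA_real_,
          lost_i = NA_integer_, lost_k = NA_integer_,
          gained_i = NA_integer_, gained_k = NA_integer_,
          stringsAsFactors = FALSE))
      }
      prevInvolved <- involved
    }
  })
  methods::new("SyntheticScene", frames = frames, tilings = tilings,
               flow = flow, dt = dt, events = events, velocity = velocity,
               seed = as.integer(seed), pixelSize = pixelSize)
}

#' Exact lineage of a synthetic scene
#'
#' Builds the ground-truth \linkS4class{Lineage} from the scene's event log:
#' surviving cells map to themselves, division mothers map to their logged
#' daughters, T2 cells are apoptoses.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @return A \linkS4class{Lineage}.
#' @export
sceneLineage <- function(scene) {
  n <- length(scene@frames) - 1
  maps <- vector("list", n)
  div <- scene@events[scene@events$kind == "division", , drop = FALSE]
  apo <- scene@events[scene@events$kind == "apoptosis", , drop = FALSE]
  for (k in seq_len(n)) {
    idsT <- cellIds(scene@frames[[k]])
    idsT1 <- cellIds(scene@frames[[k + 1]])
    dk <- div[div$interval == k - 1, , drop = FALSE]
    ak <- apo[apo$interval == k - 1, , drop = FALSE]
    rows <- list()
    for (id in idsT) {
      if (id %in% dk$cell) {
        r <- dk[dk$cell == id, ]
        rows[[length(rows) + 1L]] <- data.frame(
          i_t = id, i_t1 = r$daughter1, kind = "division_mother")
        rows[[length(rows) + 1L]] <- data.frame(
          i_t = id, i_t1 = r$daughter2, kind = "division_daughter")
      } else if (id %in% ak$cell) {
        rows[[length(rows) + 1L]] <- data.frame(
          i_t = id, i_t1 = NA_integer_, kind = "apoptosis")
      } else if (id %in% idsT1) {
        rows[[length(rows) + 1L]] <- data.frame(
          i_t = id, i_t1 = id, kind = "map")
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          i_t = id, i_t1 = NA_integer_, kind = "left_field")
      }
    }
    maps[[k]] <- do.call(rbind, rows)
  }
  divisions <- data.frame(interval = div$interval + 1L, mother = div$cell,
                          daughter1 = div$daughter1,
                          daughter2 = div$daughter2)
  apoptoses <- data.frame(interval = apo$interval + 1L, cell = apo$cell)
  methods::new("Lineage", maps = maps, divisions = divisions,
               apoptoses = apoptoses)
}
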