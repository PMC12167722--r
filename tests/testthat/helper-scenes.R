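# Shared synthetic fixtures. Scenes are built once per test run and cached;
# every scene is deterministic given its seed, so frozen expectations are
# stable.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# pure-shear flow used throughout: area-preserving, |gradv| = 0.01/min
shearFlow <- function(eps = 0.01) {
  affineFlow(gradv = matrix(c(eps, 0, 0, -eps), 2, 2))
}

# 300-cell Voronoi tiling under pure shear with ~5 T1 exchanges per
# interval and no divisions/apoptoses (the rearrangement-only study scene)
t1Scene <- function() fixture("t1Scene", function() {
  tl <- voronoiTiling(300, seed = 2, lloydSteps = 5,
                      window = c(0, 420, 0, 420))
  simulateScene(tl, shearFlow(), nIntervals = 20, dt = 1,
                t1PerInterval = 5, seed = 42)
})

t1SceneSeries <- function() fixture("t1SceneSeries", function() {
  sc <- t1Scene()
  lin <- sceneLineage(sc)
  rois <- trackRois(tileRois(sc@frames[[1]], tile = 140), lin)
  strainSeries(sc@frames, lin, rois, dt = sc@dt)
})

# mixed scene: divisions + T1s under an irrotational affine flow, with label
# rasters for the pixel/PIV routes
mixedScene <- function() fixture("mixedScene", function() {
  tl <- voronoiTiling(250, seed = 8, lloydSteps = 5,
                      window = c(20, 400, 20, 400))
  fl <- affineFlow(gradv = matrix(c(0.012, 0.003, 0.003, -0.006), 2, 2))
  simulateScene(tl, fl, nIntervals = 8, dt = 1, t1PerInterval = 2,
                divisionsPerInterval = 2, seed = 21, rasterize = TRUE,
                canvas = c(460, 460))
})

mixedSceneSeries <- function() fixture("mixedSceneSeries", function() {
  sc <- mixedScene()
  lin <- sceneLineage(sc)
  rois <- trackRois(tileRois(sc@frames[[1]], tile = 110), lin)
  piv <- lapply(seq_len(length(sc@frames) - 1), function(k)
    piv(skeletonImage(sc@frames[[k]]@labelImage),
        skeletonImage(sc@frames[[k + 1]]@labelImage),
        window = 64, step = 16, dt = sc@dt))
  strainSeries(sc@frames, lin, rois, dt = sc@dt, velocities = piv)
})

# small event scene for tracking-recovery checks (division + apoptosis
# rates ~ 1% of cells per interval)
eventScene <- function() fixture("eventScene", function() {
  tl <- voronoiTiling(200, seed = 5, lloydSteps = 4,
                      window = c(0, 340, 0, 340))
  simulateScene(tl, affineFlow(gradv = matrix(c(0.005, 0, 0, -0.005), 2, 2)),
                nIntervals = 5, dt = 1, t1PerInterval = 2,
                divisionsPerInterval = 1.5, t2PerInterval = 1, seed = 11)
})

# single-interval affine scene whose raster fills the canvas (for PIV)
pivScene <- function() fixture("pivScene", function() {
  tl <- voronoiTiling(300, seed = 8, lloydSteps = 5,
                      window = c(0, 440, 0, 440))
  simulateScene(tl, affineFlow(gradv = matrix(c(0.01, 0.002, 0.002, -0.01),
                                              2, 2)),
                nIntervals = 1, dt = 1, seed = 21, rasterize = TRUE,
                canvas = c(444, 444))
})

# hexagonal tiling helpers
hexFrame <- function(n = 7, d = 20) tilingToFrame(hexagonalTiling(n, n, d))

# interior cells whose neighbors are all interior
deepInteriorCells <- function(frame) {
  ct <- cellTable(frame)
  adj <- adjacencyTable(frame)
  interior <- ct$id[!ct$outermost]
  nbrs <- function(id) c(adj$k[adj$i == id], adj$i[adj$k == id])
  interior[vapply(interior, function(id) all(nbrs(id) %in% interior), TRUE)]
}

# 3x3 grid of square cells with one-pixel contours
squareGridLabels <- function(cell = 9L, n = 3L) {
  sz <- n * (cell + 1L) + 1L
  lab <- matrix(0L, sz, sz)
  id <- 0L
  for (r in seq_len(n) - 1L) {
    for (c in seq_len(n) - 1L) {
      id <- id + 1L
      rows <- (r * (cell + 1L) + 2L):(r * (cell + 1L) + cell + 1L)
      cols <- (c * (cell + 1L) + 2L):(c * (cell + 1L) + cell + 1L)
      lab[rows, cols] <- id
    }
  }
  lab
}

trTensor <- function(ss, prefix) ss[[paste0(prefix, "xx")]] +
  ss[[paste0(prefix, "yy")]]

frobCols <- function(ss, prefix) sqrt(
  ss[[paste0(prefix, "xx")]]^2 + 2 * ss[[paste0(prefix, "xy")]]^2 +
    ss[[paste0(prefix, "yy")]]^2)

# ROIs whose initial members sit well inside the tissue (velocity-field
# fits at the tissue boundary are dominated by partially empty windows)
interiorRoiIds <- function(rois, frame, margin = 45) {
  ct <- cellTable(frame)
  lo <- c(min(ct$x), min(ct$y)) + margin
  hi <- c(max(ct$x), max(ct$y)) - margin
  ids <- c()
  for (r in rois) {
    cc <- ct[ct$id %in% r@members[[1]], ]
    if (all(cc$x > lo[1] & cc$x < hi[1] & cc$y > lo[2] & cc$y < hi[2]))
      ids <- c(ids, r@roiId)
  }
  ids
}
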