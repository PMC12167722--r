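# Kinematic-equation and density-balance checks, comparison statistics,
# kymographs.

test_that("comparison statistics behave on constructed series", {
  a <- matrix(local({ set.seed(2); stats::rnorm(60) }), ncol = 3)
  cmp <- compareTensorSeries(a, a)
  expect_equal(cmp$components$slope, rep(1, 3), tolerance = 1e-12)
  expect_equal(cmp$components$r2, rep(1, 3), tolerance = 1e-12)
  expect_equal(cmp$components$rmse, rep(0, 3), tolerance = 1e-12)
  cmp2 <- compareTensorSeries(a, 2 * a)
  expect_equal(cmp2$components$slope, rep(2, 3), tolerance = 1e-12)
  expect_equal(cmp2$components$r2, rep(1, 3), tolerance = 1e-12)
  # independent noise: slope and r2 near zero
  set.seed(5)
  x <- matrix(stats::rnorm(1000), ncol = 1)
  y <- matrix(stats::rnorm(1000), ncol = 1)
  cmp3 <- compareTensorSeries(x, y)
  expect_lt(abs(cmp3$components$slope), 0.1)
  expect_lt(cmp3$components$r2, 0.05)
  # zero-variance predictor flagged degenerate
  cmp4 <- compareTensorSeries(matrix(1, 10, 1),
                              matrix(stats::rnorm(10), ncol = 1))
  expect_true(cmp4$components$degenerate)
})

test_that("the event-free kinematic residual is exactly the quadratic
           transport term", {
  tl <- voronoiTiling(150, seed = 2, lloydSteps = 4,
                      window = c(0, 300, 0, 300))
  gv <- matrix(c(0.02, 0.005, -0.003, -0.01), 2, 2)
  sc <- simulateScene(tl, affineFlow(gv), nIntervals = 1, dt = 2, seed = 3)
  lin <- sceneLineage(sc)
  rois <- trackRois(tileRois(sc@frames[[1]], tile = 150), lin)
  ss <- strainSeries(sc@frames, lin, rois, dt = 2)
  kc <- kinematicCheck(ss)
  for (r in seq_len(nrow(ss))) {
    M <- matrix(c(ss$Mtxx[r], ss$Mtxy[r], ss$Mtxy[r], ss$Mtyy[r]), 2, 2)
    pred <- gv %*% M %*% t(gv) * 4  # dt^2
    got <- matrix(c(kc$table$xx[r] - kc$table$rhs.xx[r],
                    kc$table$xy[r] - kc$table$rhs.xy[r],
                    kc$table$xy[r] - kc$table$rhs.xy[r],
                    kc$table$yy[r] - kc$table$rhs.yy[r]), 2, 2)
    expect_equal(got, pred, tolerance = 1e-6)
  }
  # static scene: both sides vanish
  scS <- simulateScene(tl, affineFlow(), nIntervals = 1, dt = 1, seed = 3)
  linS <- sceneLineage(scS)
  ssS <- strainSeries(scS@frames, linS,
                      trackRois(tileRois(scS@frames[[1]], tile = 150), linS),
                      dt = 1)
  kcS <- kinematicCheck(ssS)
  expect_lt(max(kcS$table$residual), 1e-9)
  expect_lt(max(abs(c(kcS$table$xx, kcS$table$xy, kcS$table$yy))), 1e-9)
})

test_that("the kinematic residual scales as dt^2 on smooth event-free
           scenes", {
  tl <- voronoiTiling(150, seed = 2, lloydSteps = 4,
                      window = c(0, 300, 0, 300))
  gv <- matrix(c(0.02, 0.004, 0.004, -0.01), 2, 2)
  dts <- c(0.5, 1, 2, 4)
  res <- sapply(dts, function(dt) {
    sc <- simulateScene(tl, affineFlow(gv), nIntervals = 1, dt = dt,
                        seed = 3)
    lin <- sceneLineage(sc)
    rois <- trackRois(tileRois(sc@frames[[1]], tile = 150), lin)
    mean(kinematicCheck(strainSeries(sc@frames, lin, rois,
                                     dt = dt))$table$residual)
  })
  slope <- stats::coef(stats::lm(log(res) ~ log(dts)))[2]
  expect_gt(slope, 1.8)
  expect_lt(slope, 2.2)
})

test_that("the half-link-normalized tensor satisfies the kinematic equation
           where the unnormalized one fails on dividing ROIs", {
  ss <- mixedSceneSeries()
  kc1 <- kinematicCheck(ss)
  expect_gt(kc1$comparison$pooled$slope, 0.9)
  expect_lt(kc1$comparison$pooled$slope, 1.1)
  expect_gt(kc1$comparison$pooled$r2, 0.9)
  # PIV-measured velocity gradients give the same verdict on ROIs away
  # from the tissue boundary (edge windows are partially empty)
  sc <- mixedScene()
  roisAll <- trackRois(tileRois(sc@frames[[1]], tile = 110),
                       sceneLineage(sc))
  intIds <- interiorRoiIds(roisAll, sc@frames[[1]])
  ssInt <- ss[ss$roi %in% intIds, , drop = FALSE]
  kcPiv <- kinematicCheck(ssInt, gradvSource = "piv")
  expect_gt(kcPiv$comparison$pooled$slope, 0.9)
  expect_lt(kcPiv$comparison$pooled$slope, 1.1)
  expect_gt(kcPiv$comparison$pooled$r2, 0.9)
  # unnormalized variant on division-containing ROIs
  ss0 <- ss
  for (cmp in c("xx", "xy", "yy")) {
    ss0[[paste0("M0t", cmp)]] <- ss[[paste0("Mt", cmp)]] * ss$nH_t
    ss0[[paste0("M0t1", cmp)]] <- ss[[paste0("Mt1", cmp)]] * ss$nH_t1
  }
  divRows <- ss$divisions >= 1
  expect_gt(sum(divRows), 5)
  kc0 <- kinematicCheck(ss0[divRows, , drop = FALSE],
                        Mcols = c("M0t", "M0t1"))
  kc1d <- kinematicCheck(ss[divRows, , drop = FALSE])
  expect_gt(abs(kc0$comparison$pooled$slope - 1), 0.1)
  expect_lt(abs(kc1d$comparison$pooled$slope - 1), 0.1)
  # relative residual ranking: normalized < unnormalized on the same rows
  rel0 <- mean(kc0$table$residual / (ss0$M0txx + ss0$M0tyy)[divRows])
  rel1 <- mean(kc1d$table$residual / (ss$Mtxx + ss$Mtyy)[divRows])
  expect_lt(rel1, rel0)
})

test_that("the density balance closes through both divergence routes", {
  ss <- mixedSceneSeries()
  db <- densityBalance(ss)
  expect_gt(db$comparisons$TrG$slope, 0.9)
  expect_lt(db$comparisons$TrG$slope, 1.1)
  sc <- mixedScene()
  roisAll <- trackRois(tileRois(sc@frames[[1]], tile = 110),
                       sceneLineage(sc))
  intIds <- interiorRoiIds(roisAll, sc@frames[[1]])
  ssInt <- ss[ss$roi %in% intIds, , drop = FALSE]
  dbInt <- densityBalance(ssInt)
  expect_gt(dbInt$comparisons$PIV$slope, 0.9)
  expect_lt(dbInt$comparisons$PIV$slope, 1.1)
  # the two divergence routes agree within 10% RMS on interval means over
  # interior ROIs
  byIv <- stats::aggregate(cbind(divG = ssInt$Gxx + ssInt$Gyy,
                                 divP = ssInt$piv_gvxx + ssInt$piv_gvyy),
                           list(iv = ssInt$interval), mean, na.rm = TRUE)
  expect_lt(sqrt(mean((byIv$divG - byIv$divP)^2)) /
              sqrt(mean(byIv$divG^2)), 0.1)
  expect_true(all(is.finite(db$series$lhs_TrG)))
})

test_that("quiescent and uniformly dilating tissues balance trivially", {
  tl <- voronoiTiling(150, seed = 2, lloydSteps = 4,
                      window = c(0, 300, 0, 300))
  # no events, incompressible shear: every route ~ 0
  sc <- simulateScene(tl, shearFlow(0.01), nIntervals = 3, dt = 1, seed = 6)
  lin <- sceneLineage(sc)
  rois <- trackRois(tileRois(sc@frames[[1]], tile = 150), lin)
  ss <- strainSeries(sc@frames, lin, rois, dt = 1)
  db <- densityBalance(ss, routes = "TrG")
  expect_lt(max(abs(db$table$lhs_TrG)), 1e-3)
  expect_equal(db$table$trDT, rep(0, nrow(ss)))
  # uniform dilation: dln(rho)/dt ~ -2 eps, div v = 2 eps, Tr DT = 0
  eps <- 0.005
  scD <- simulateScene(tl, affineFlow(eps * diag(2)), nIntervals = 1,
                       dt = 1, seed = 6)
  linD <- sceneLineage(scD)
  ssD <- strainSeries(scD@frames, linD,
                      trackRois(tileRois(scD@frames[[1]], tile = 150), linD),
                      dt = 1)
  dbD <- densityBalance(ssD, routes = "TrG")
  expect_equal(mean(ssD$Gxx + ssD$Gyy), 2 * eps, tolerance = 0.01)
  expect_equal(mean(dbD$table$dlnrho), -2 * eps, tolerance = 0.01)
  expect_lt(max(abs(dbD$table$lhs_TrG)), 1e-4)
})

test_that("kymographs average shape summaries along an axis", {
  # spatially uniform synthetic summaries: constant kymograph
  sm <- expand.grid(x = seq(0, 600, by = 20), y = 0)
  sm$frame <- 0L
  sm$area <- 300
  sm$aspect <- 1.4
  sm$theta <- 0.2
  ky <- kymograph(sm, axis = "x", window = 200, step = 50)
  expect_true(all(abs(ky$area - 300) < 1e-12))
  expect_true(all(abs(ky$coherence - 1) < 1e-12))
  # linear gradient reproduced within windowing smoothing
  sm2 <- sm
  sm2$area <- 100 + 0.5 * sm2$x
  ky2 <- kymograph(sm2, axis = "x", window = 200, step = 50)
  mid <- ky2$pos > 100 & ky2$pos < 500
  expect_equal(ky2$area[mid], 100 + 0.5 * ky2$pos[mid], tolerance = 0.01)
  # windows without data give NA, not zero
  sm3 <- sm[sm$x < 200, ]
  ky3 <- kymograph(sm3, axis = "x", window = 50, step = 50)
  expect_true(anyNA(ky3$area) == FALSE || all(is.na(ky3$area[ky3$n == 0])))
  gap <- kymograph(data.frame(frame = 0L, x = c(0, 500), y = 0, area = 1,
                              aspect = 1, theta = 0),
                   axis = "x", window = 50, step = 50)
  expect_true(all(is.na(gap$area[gap$n == 0])))
  expect_gt(sum(gap$n == 0), 0)
})

test_that("ROI shape summaries feed the kymograph with sensible
           orientations", {
  sc <- t1Scene()
  lin <- sceneLineage(sc)
  rois <- trackRois(tileRois(sc@frames[[1]], tile = 140), lin)
  sm0 <- roiShapeSummaries(sc@frames[[1]], rois, 1L)
  smT <- roiShapeSummaries(sc@frames[[21]], rois, 21L)
  # shear at eps = 0.01/min for 20 min elongates cells along x
  expect_gt(mean(smT$aspect), mean(sm0$aspect))
  expect_gt(orientationCoherence(smT$theta), 0.8)
  expect_lt(mean(abs(smT$theta)), 0.3)  # long axis near the x direction
})
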