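# Link classification, deformation gradient, strain-rate decomposition.

test_that("an event-free interval classifies every link as conserved", {
  sc <- fixture("quietScene", function()
    simulateScene(voronoiTiling(120, seed = 4, lloydSteps = 4,
                                window = c(0, 280, 0, 280)),
                  shearFlow(0.01), nIntervals = 2, dt = 1, seed = 3))
  lin <- sceneLineage(sc)
  f <- sc@frames[[1]]
  members <- cellTable(f)$id[!cellTable(f)$outermost]
  cls <- classifyLinks(sc@frames[[1]], sc@frames[[2]], members, lin, 1L)
  expect_true(all(cls$status == "conserved"))
  expect_true(all(cls$label == "S"))
  sr <- decomposeStrain(cls, dt = 1)
  expect_equal(sr@R, matrix(0, 2, 2))
  expect_equal(sr@D, matrix(0, 2, 2))
  expect_equal(sr@A, matrix(0, 2, 2))
})

test_that("a single T1 exchanges exactly one undirected pair, labeled R", {
  sc <- t1Scene()
  ev <- sc@events[sc@events$kind == "T1", ][1, ]
  k <- ev$interval + 1L
  lin <- sceneLineage(sc)
  f <- sc@frames[[k]]
  members <- cellTable(f)$id[!cellTable(f)$outermost]
  cls <- classifyLinks(sc@frames[[k]], sc@frames[[k + 1]], members, lin, k)
  dis <- cls[cls$status == "disappeared", ]
  app <- cls[cls$status == "appeared", ]
  evsThis <- sc@events[sc@events$kind == "T1" &
                         sc@events$interval == ev$interval, ]
  expect_equal(nrow(dis), nrow(evsThis))
  expect_equal(nrow(app), nrow(evsThis))
  expect_true(all(dis$label == "R"))
  expect_true(all(app$label == "R"))
  expect_true(paste(ev$lost_i, ev$lost_k) %in% paste(dis$i, dis$k))
  expect_true(paste(ev$gained_i, ev$gained_k) %in% paste(app$i, app$k))
  # each undirected pair inside the ROI stands for two half-links
  expect_true(all(dis$mult == 2 | dis$mult == 1))
})

test_that("division links follow the assignment rule, with the alternative
           rule moving re-pointed links to R", {
  sc <- mixedScene()
  lin <- sceneLineage(sc)
  d <- lin@divisions[1, ]
  k <- d$interval
  f <- sc@frames[[k]]
  members <- cellTable(f)$id[!cellTable(f)$outermost]
  clsD <- classifyLinks(sc@frames[[k]], sc@frames[[k + 1]], members, lin, k,
                        rule = "division-priority")
  clsR <- classifyLinks(sc@frames[[k]], sc@frames[[k + 1]], members, lin, k,
                        rule = "rearrangement-alternative")
  # mother's vanished links all D
  motherRows <- clsD[clsD$status == "disappeared" &
                       (clsD$i == d$mother | clsD$k == d$mother), ]
  expect_gt(nrow(motherRows), 3)
  expect_true(all(motherRows$label == "D"))
  dd <- function(cls) cls[cls$status == "appeared" &
                            cls$i %in% c(d$daughter1, d$daughter2) &
                            cls$k %in% c(d$daughter1, d$daughter2), ]
  expect_equal(dd(clsD)$label, "D")
  expect_equal(dd(clsR)$label, "D")  # daughter-daughter junction stays D
  repointed <- function(cls) cls[cls$status == "appeared" &
                                   xor(cls$i %in% c(d$daughter1, d$daughter2),
                                       cls$k %in% c(d$daughter1, d$daughter2)), ]
  expect_true(all(repointed(clsD)$label == "D"))
  expect_true(all(repointed(clsR)$label == "R"))
})

test_that("apoptosis links are labeled A including the vacancy-closing
           contacts", {
  sc <- eventScene()
  lin <- sceneLineage(sc)
  a <- lin@apoptoses[1, ]
  k <- a$interval
  f <- sc@frames[[k]]
  members <- cellTable(f)$id[!cellTable(f)$outermost]
  cls <- classifyLinks(sc@frames[[k]], sc@frames[[k + 1]], members, lin, k)
  dying <- cls[cls$i == a$cell | cls$k == a$cell, ]
  expect_gt(nrow(dying), 3)
  expect_true(all(dying$status == "disappeared"))
  expect_true(all(dying$label == "A"))
  closing <- cls[cls$status == "appeared" & cls$label == "A", ]
  expect_gt(nrow(closing), 0)
  clsR <- classifyLinks(sc@frames[[k]], sc@frames[[k + 1]], members, lin, k,
                        apoptosisAppeared = "R")
  expect_equal(sum(clsR$status == "appeared" & clsR$label == "A"), 0)
})

test_that("the deformation gradient is exact for affine transport and
           unbiased under noise", {
  set.seed(31)
  L <- data.frame(i = 1L, k = seq_len(40), omega = 1, mult = 1,
                  lxt = stats::rnorm(40, sd = 10),
                  lyt = stats::rnorm(40, sd = 10))
  F0 <- matrix(c(1.05, 0.02, -0.03, 0.97), 2, 2)
  l1 <- as.matrix(L[, c("lxt", "lyt")]) %*% t(F0)
  cls <- cbind(L, lxt1 = l1[, 1], lyt1 = l1[, 2],
               status = "conserved", omega_t = 1)
  expect_equal(deformationGradient(cls), F0, tolerance = 1e-12)
  # identity transport
  cls2 <- cls; cls2$lxt1 <- cls$lxt; cls2$lyt1 <- cls$lyt
  expect_equal(deformationGradient(cls2), diag(2), tolerance = 1e-12)
  # isotropic noise: component-wise bias < 0.01 over 100 replicates
  Fs <- vapply(1:100, function(r) {
    noise <- matrix(stats::rnorm(80, sd = 0.05 *
                                   sqrt(L$lxt^2 + L$lyt^2)), ncol = 2)
    clsN <- cls
    clsN$lxt1 <- l1[, 1] + noise[, 1]
    clsN$lyt1 <- l1[, 2] + noise[, 2]
    deformationGradient(clsN)
  }, matrix(0, 2, 2))
  bias <- apply(Fs, c(1, 2), mean) - F0
  expect_lt(max(abs(bias)), 0.01)
  # collinear links error
  clsC <- cls; clsC$lyt <- 0; clsC$lyt1 <- 0
  expect_error(deformationGradient(clsC), "collinear")
})

test_that("G = (F'F - I)/(2 dt) with rotation invariance", {
  expect_equal(strainRateG(diag(c(1.1, 1)), 5),
               diag(c(0.021, 0)), tolerance = 1e-12)
  expect_equal(strainRateG(diag(2), 1), matrix(0, 2, 2))
  for (phi in c(0.3, -1.2, 2.9))
    expect_equal(strainRateG(rot2(phi), 1), matrix(0, 2, 2),
                 tolerance = 1e-12)
})

test_that("the Sylvester conversion inverts the symmetric transport
           relation", {
  M <- matrix(c(120, 15, 15, 90), 2, 2)
  T0 <- matrix(c(0.01, -0.004, -0.004, 0.02), 2, 2)
  Delta <- (T0 %*% M + M %*% T0) * 2.5
  expect_equal(solveSylvester2(Delta, M, 2.5), T0, tolerance = 1e-12)
  expect_error(solveSylvester2(Delta, matrix(0, 2, 2), 1), "singular")
})

test_that("decomposition closure: strict mode exact, raw residual falls
           ~4x under dt halving on irrotational flows", {
  tl <- voronoiTiling(150, seed = 2, lloydSteps = 4,
                      window = c(0, 300, 0, 300))
  fl <- affineFlow(gradv = matrix(c(0.02, 0.004, 0.004, -0.01), 2, 2))
  res <- sapply(c(1, 2), function(dt) {
    sc <- simulateScene(tl, fl, nIntervals = 1, dt = dt, seed = 3)
    lin <- sceneLineage(sc)
    rois <- trackRois(tileRois(sc@frames[[1]], tile = 150), lin)
    ss <- strainSeries(sc@frames, lin, rois, dt = dt)
    ssStrict <- strainSeries(sc@frames, lin, rois, dt = dt,
                             closure = "strict")
    expect_lt(max(frobCols(ssStrict, "res")), 1e-12)
    # raw mode: S approximates G up to the quadratic transport term
    expect_lt(max(abs(ss$Sxx - ss$Gxx)), 3e-3 * dt)
    mean(frobCols(ss, "res")) * dt
  })
  expect_gt(res[2] / res[1], 3)
})

test_that("sign contracts hold: Tr D >= 0 on division-only scenes and
           Tr A <= 0 on apoptosis-only scenes", {
  tl <- voronoiTiling(120, seed = 4, lloydSteps = 4,
                      window = c(0, 280, 0, 280))
  scD <- simulateScene(tl, affineFlow(), nIntervals = 6, dt = 1,
                       divisionsPerInterval = 1.2, seed = 9)
  linD <- sceneLineage(scD)
  roisD <- trackRois(tileRois(scD@frames[[1]], tile = 280), linD)
  ssD <- strainSeries(scD@frames, linD, roisD, dt = 1)
  expect_true(all(trTensor(ssD, "D") >= 0))
  expect_gt(sum(trTensor(ssD, "D")), 0)
  expect_equal(trTensor(ssD, "A"), rep(0, nrow(ssD)))
  # one division in an N-cell ROI raises density by ~1/N per interval
  divRows <- ssD$divisions == 1
  expect_gt(sum(divRows), 0)
  dlnrho <- log(ssD$rho_t1 / ssD$rho_t)[divRows]
  expect_equal(mean(trTensor(ssD, "DT")[divRows]) * ssD$dt[1],
               mean(dlnrho), tolerance = 0.1)
  scA <- simulateScene(tl, affineFlow(), nIntervals = 6, dt = 1,
                       t2PerInterval = 1, seed = 13)
  linA <- sceneLineage(scA)
  roisA <- trackRois(tileRois(scA@frames[[1]], tile = 280), linA)
  ssA <- strainSeries(scA@frames, linA, roisA, dt = 1)
  expect_true(all(trTensor(ssA, "A") <= 1e-12))
  expect_lt(sum(trTensor(ssA, "A")), 0)
  expect_equal(trTensor(ssA, "D"), rep(0, nrow(ssA)))
})

test_that("area-preserving T1 scenes leave Tr R near zero relative to the
           strain scale", {
  ss <- t1SceneSeries()
  trR <- trTensor(ss, "R")
  expect_gt(sum(trR != 0), 10)
  expect_lt(abs(mean(trR)) / sqrt(mean(frobCols(ss, "G")^2)), 0.01)
})

test_that("velocity gradients fit exactly on uniform and linear fields", {
  mkField <- function(fun) {
    xs <- seq(0, 160, by = 16); ys <- seq(0, 160, by = 16)
    g <- expand.grid(x = xs, y = ys)
    v <- fun(g$x, g$y)
    methods::new("VelocityField", origin = c(0, 0), spacing = 16,
                 vx = matrix(v[, 1], length(ys), length(xs), byrow = TRUE),
                 vy = matrix(v[, 2], length(ys), length(xs), byrow = TRUE),
                 valid = matrix(TRUE, length(ys), length(xs)),
                 source = "ground-truth")
  }
  f <- hexFrame(6, 25)
  members <- cellTable(f)$id
  uni <- gradVFromField(mkField(function(x, y) cbind(3, -2)), f, members)
  expect_equal(uni$gradv, matrix(0, 2, 2), tolerance = 1e-12)
  expect_equal(uni$v, c(3, -2))
  A <- matrix(c(0.01, 0.003, -0.002, 0.02), 2, 2)
  lin <- gradVFromField(mkField(function(x, y)
    cbind(A[1, 1] * x + A[1, 2] * y, A[2, 1] * x + A[2, 2] * y)),
    f, members)
  expect_equal(lin$gradv, A, tolerance = 1e-10)
  # rank-deficient geometry errors (all samples on one grid column)
  one <- mkField(function(x, y) cbind(1, 1))
  one@valid[, -4] <- FALSE
  expect_error(gradVFromField(one, f, members), "rank-deficient")
})

test_that("the alternative assignment rule degrades the density balance on
           division-rich scenes", {
  sc <- mixedScene()
  lin <- sceneLineage(sc)
  rois <- trackRois(tileRois(sc@frames[[1]], tile = 127), lin)
  ssP <- strainSeries(sc@frames, lin, rois, dt = sc@dt,
                      rule = "division-priority")
  ssA <- strainSeries(sc@frames, lin, rois, dt = sc@dt,
                      rule = "rearrangement-alternative")
  resid <- function(ss) {
    lhs <- (ss$rho_t1 - ss$rho_t) / ((ss$rho_t1 + ss$rho_t) / 2) / ss$dt +
      ss$Gxx + ss$Gyy
    sel <- ss$divisions > 0
    sqrt(mean((lhs - trTensor(ss, "DT"))[sel]^2))
  }
  expect_gt(resid(ssA), resid(ssP))
})
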