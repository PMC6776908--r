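test_that("turn centers of mass are mass-weighted and translation-equivariant", {
  # 4 unit-square corners, one atom per residue, equal masses
  sq <- makeStructure(name = "CA", resname = "GLY", resid = 1:4, chain = "A",
                      coords = matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 0),
                                      4, 3, byrow = TRUE), element = "C")
  spec <- turnSpec("A", 1L, atomClass = "calpha")
  expect_allclose(turnCOM(sq, spec), c(0.5, 0.5, 0), 1e-12)

  # masses 12 (C) and 16 (O) at x = 0 and 7: COM x = 16*7/28 = 4
  co <- makeStructure(name = c("C1", "O1", "C2", "O2"), resname = "X",
                      resid = 1:4, chain = "A",
                      coords = matrix(c(0, 0, 0, 7, 0, 0, 0, 5, 0, 7, 5, 0),
                                      4, 3, byrow = TRUE),
                      element = c("C", "O", "C", "O"))
  com <- turnCOM(co, turnSpec("A", 1L))
  expect_equal(com[1], (12.011 * 0 + 15.999 * 7 + 12.011 * 0 +
                        15.999 * 7) / (2 * 12.011 + 2 * 15.999),
               tolerance = 1e-12)

  shifted <- sq
  coords(shifted) <- sweep(coords(sq), 2, c(3, -2, 9), "+")
  expect_allclose(turnCOM(shifted, spec) - turnCOM(sq, spec), c(3, -2, 9),
                  1e-12)

  expect_error(turnCOM(sq, turnSpec("A", 3L, "calpha")), "residue 5")
})

test_that("turn-pair distances follow construction and rigid invariance", {
  toy <- makeGateToy(rep(30, 4), rep(5, 4))
  pair <- gatePairSpec("d", toy$turnA, toy$turnB)
  d <- pairDistanceSeries(toy$trajectory, pair)
  expect_allclose(d, rep(5, 4), 1e-9)

  # rotating + translating every frame leaves the series unchanged
  traj <- toy$trajectory
  set.seed(2)
  for (f in seq_len(nFrames(traj))) {
    traj@frames[, , f] <- sweep(traj@frames[, , f] %*%
                                  t(randomRotationMatrix()),
                                2, runif(3, -10, 10), "+")
  }
  expect_allclose(pairDistanceSeries(traj, pair), d, 1e-9)

  # identical turn point sets give zero distance
  dz <- pairDistanceSeries(toy$trajectory,
                           gatePairSpec("q", turnSpec("A", 1L),
                                        turnSpec("A", 1L, "backbone")))
  expect_lt(max(dz), 1e-9)  # same atoms, same COM
})

test_that("helix axis vectors recover construction, sign and equivariance", {
  h <- makeIdealHelix(20)
  spec <- helixSpec("H", "A", 1L, 20L)
  v <- helixVector(h, spec)
  expect_lt(acos(min(1, sum(v * c(0, 0, 1)))) * 180 / pi, 1)

  # reversing residue order flips the vector
  a <- atomData(h)
  rev <- makeStructure(name = a$name, resname = a$resname,
                       resid = 21L - a$resid, chain = a$chain,
                       coords = coords(h), element = a$element)
  expect_allclose(helixVector(rev, spec), -v, 1e-9)

  R <- randomRotationMatrix()
  hr <- h; coords(hr) <- coords(h) %*% t(R)
  expect_allclose(helixVector(hr, spec), as.numeric(R %*% v), 1e-9)
})

test_that("eta angle hits programmed values, is symmetric and bounded", {
  for (theta in c(0, 15, 30, 60, 90)) {
    toy <- makeGateToy(theta, 12)
    fr <- frameStructure(toy$trajectory, 1L)
    eta <- etaAngle(fr, toy$helixA, toy$helixB)
    expect_lt(abs(eta - theta), 1.5)
    expect_equal(eta, etaAngle(fr, toy$helixB, toy$helixA))
    expect_gte(eta, 0); expect_lte(eta, 180)
  }
  # cos^-1(0.8660) = 30 degrees
  toy30 <- makeGateToy(acos(0.8660) * 180 / pi, 10)
  expect_equal(etaAngle(frameStructure(toy30$trajectory, 1L),
                        toy30$helixA, toy30$helixB), 30, tolerance = 1)

  # parallel copies give 0; an exact antiparallel (reversed residue order)
  # gives 180
  hA <- makeIdealHelix(20, chain = "A")
  hPar <- makeIdealHelix(20, origin = c(9, 0, 0), chain = "B")
  par2 <- gatescope:::.bindStructures(hA, hPar)
  expect_lt(etaAngle(par2, helixSpec("a", "A", 1L, 20L),
                     helixSpec("b", "B", 1L, 20L)), 1)
  a <- atomData(hPar)
  hAnti <- makeStructure(name = a$name, resname = a$resname,
                         resid = 21L - a$resid, chain = "B",
                         coords = coords(hPar), element = a$element)
  anti <- gatescope:::.bindStructures(hA, hAnti)
  expect_gt(etaAngle(anti, helixSpec("a", "A", 1L, 20L),
                     helixSpec("b", "B", 1L, 20L)), 179)
})

test_that("helix and hairpin tilt fold into [0, 90] and reject degenerate axes", {
  hz <- makeIdealHelix(20)
  spec <- helixSpec("H", "A", 1L, 20L)
  expect_lt(helixTilt(hz, spec, c(0, 0, 1)), 1.5)
  expect_gt(helixTilt(hz, spec, c(1, 0, 0)), 88.5)

  hx <- makeIdealHelix(20, axis = c(1, 0, 0))
  expect_gt(helixTilt(hx, helixSpec("H", "A", 1L, 20L), c(0, 0, 1)), 88.5)

  # antiparallel hairpin: combined axis along the shared direction
  up <- makeIdealHelix(12, chain = "A")
  down <- makeIdealHelix(12, axis = c(0, 0, -1), origin = c(8, 0, 18),
                         chain = "B")
  hp <- gatescope:::.bindStructures(up, down)
  tilt <- helixTilt(hp, list(helixSpec("u", "A", 1L, 12L),
                             helixSpec("d", "B", 1L, 12L)), c(0, 0, 1))
  expect_lt(tilt, 1.5)

  # a parallel pair passed as a hairpin is degenerate
  par2 <- makeIdealHelix(12, origin = c(8, 0, 0), chain = "B")
  hpp <- gatescope:::.bindStructures(up, par2)
  expect_error(helixTilt(hpp, list(helixSpec("u", "A", 1L, 12L),
                                   helixSpec("p", "B", 1L, 12L)),
                         c(0, 0, 1)), "degenerate|parallel")
})

test_that("membrane normal tracks the long axis of a helix bundle", {
  bundle <- NULL
  for (i in 0:3) {
    h <- makeIdealHelix(16, origin = c(10 * cos(i * pi / 2),
                                       10 * sin(i * pi / 2), 0),
                        chain = LETTERS[i + 1])
    bundle <- if (is.null(bundle)) h else gatescope:::.bindStructures(bundle, h)
  }
  specs <- lapply(1:4, function(i) helixSpec(paste0("H", i), LETTERS[i],
                                             1L, 16L))
  n <- membraneNormal(bundle, specs)
  expect_gt(abs(n[3]), cos(3 * pi / 180))  # within 3 degrees of z
})

test_that("gateSeries pools replicas into normalized histograms with SEM", {
  # 5 identical 1-frame replicas: a single occupied bin with SEM 0
  toy <- makeGateToy(30, 10)
  reps <- lapply(1:5, function(r) {
    t <- toy$trajectory; t@replicaId <- as.integer(r); t
  })
  pair <- gatePairSpec("I", toy$turnA, toy$turnB)
  gs <- gateSeries(reps, list(pair), list(toy$helixA, toy$helixB))
  for (m in gs@measures) {
    h <- gateHistogram(gs, m)
    expect_equal(sum(h$mean > 0), 1L)
    expect_equal(max(h$sem), 0)
    expect_allclose(colSums(h$freq), rep(1, 5), 1e-9)
  }
  expect_equal(unname(gs@reference["I"]), 10, tolerance = 1e-9)

  # a step schedule shows up as a step in the series and two occupied modes
  sched <- c(rep(10, 10), rep(40, 10))
  toy2 <- makeGateToy(sched, rep(8, 20))
  gs2 <- gateSeries(list(toy2$trajectory), list(),
                    list(toy2$helixA, toy2$helixB), bins = 10)
  eta <- gateTable(gs2)$eta
  expect_lt(max(abs(eta[1:10] - 10)), 1.5)
  expect_lt(max(abs(eta[11:20] - 40)), 1.5)
  h <- gateHistogram(gs2, "eta")
  expect_equal(sum(h$mean > 0), 2L)
})

test_that("per-bin SEM respects sampling statistics on Gaussian distances", {
  ref <- makeIdealHelix(8)
  trajs <- makeHarmonicTrajectory(ref, 0.4, nFrames = 300, nReplicas = 5,
                                  seed = 31)
  pair <- gatePairSpec("d", turnSpec("A", 1L), turnSpec("A", 5L))
  gs <- gateSeries(trajs, list(pair), bins = 20)
  h <- gateHistogram(gs, "d")
  # SEM per bin can never exceed sd/sqrt(5) computed from the freq matrix
  expect_allclose(h$sem, apply(h$freq, 1, sd) / sqrt(5), 1e-12)
  expect_allclose(colSums(h$freq), rep(1, 5), 1e-9)
})
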