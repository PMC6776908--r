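test_that("a single moving atom puts all variance on PC1 along its direction", {
  s <- randomToyStructure(6, seed = 2)
  u <- c(1, 0, 0)
  nF <- 40
  frames <- array(rep(coords(s), nF), dim = c(6, 3, nF))
  amp <- seq(-1, 1, length.out = nF)
  for (f in seq_len(nF)) frames[1, , f] <- frames[1, , f] + amp[f] * u
  traj <- new("Trajectory", topology = s, frames = frames)
  # fit on the static atoms so the motion is not absorbed by superposition
  model <- fitPCA(traj, fitSelection = 2:6, analysisSelection = 1:6)
  expect_gt(model@explainedFraction[1], 0.999)
  pc1 <- matrix(model@evecs[, 1], ncol = 3, byrow = TRUE)
  expect_gt(abs(sum(pc1[1, ] * u)), 0.999)
})

test_that("two-mode Gaussian recovers programmed explained fractions and mode", {
  sys <- twoModeSystem()
  model <- fitPCA(sys$traj, analysisSelection = seq_len(nAtoms(sys$ref)))
  expect_equal(model@explainedFraction[1], 0.8, tolerance = 0.03 / 0.8)
  expect_equal(model@explainedFraction[2], 0.2, tolerance = 0.03 / 0.2)
  expect_gt(abs(sum(model@evecs[, 1] * sys$m1)), 0.99)
})

test_that("projection obeys orthonormality, and reconstruction is complete", {
  sys <- twoModeSystem(nFrames = 300, nRes = 8)
  model <- fitPCA(sys$traj, analysisSelection = seq_len(nAtoms(sys$ref)))

  # projecting the mean structure gives the origin
  meanStruct <- sys$ref
  coords(meanStruct) <- matrix(model@mean, ncol = 3, byrow = TRUE)
  p0 <- projectOnto(meanStruct, model, k = 2)
  expect_allclose(p0, matrix(0, 1, 2), 1e-8)

  # mean + c * PC1 projects to (c, 0)
  cAmp <- 1.7
  disp <- sys$ref
  coords(disp) <- matrix(model@mean + cAmp * model@evecs[, 1],
                         ncol = 3, byrow = TRUE)
  p1 <- projectOnto(disp, model, k = 2)
  expect_equal(p1[1, 1], cAmp, tolerance = 1e-6)
  expect_equal(p1[1, 2], 0, tolerance = 1e-6)

  # full-rank round trip: centered coords = evecs %*% projections
  k <- length(model@evals)
  fr <- coords(sys$traj, 17)
  pAll <- projectOnto(fr, model, k = k)
  fit <- kabschFit(fr[model@fitIndices, ], model@refCoords[model@fitIndices, ])
  centered <- as.numeric(t(applyFit(fr, fit)[model@atomIndices, ])) -
    model@mean
  expect_allclose(model@evecs %*% t(pAll), cbind(centered), 1e-8)

  expect_error(projectOnto(fr, model, k = k + 1), "exceeds")
})

test_that("eigenvalue spectrum conserves trace and matches a Jacobi oracle", {
  sys <- twoModeSystem(nFrames = 150, nRes = 8, seed = 11)
  model <- fitPCA(sys$traj, analysisSelection = 1:4)  # 12-dim system
  # trace conservation against the superposed coordinate variance
  sup <- superposeTrajectory(sys$traj,
                             reference = model@refCoords,
                             fitSelection = model@fitIndices)
  X <- t(apply(sup@frames[1:4, , , drop = FALSE], 3, function(m)
    as.numeric(t(m))))
  totVar <- sum(apply(X, 2, var))
  expect_equal(sum(model@evals), totVar, tolerance = 1e-6 * totVar)
  # independent cyclic-Jacobi eigensolver on the same covariance
  lam <- jacobiEigenvalues(cov(X))
  expect_allclose(model@evals, lam, 1e-8)
  # orthonormal columns, descending eigenvalues, fractions sum to 1
  expect_allclose(crossprod(model@evecs), diag(ncol(model@evecs)), 1e-8)
  expect_true(all(diff(model@evals) <= 1e-12))
  expect_equal(sum(model@explainedFraction), 1, tolerance = 1e-9)
})

test_that("landscape closed forms: N_max bin at 0, half occupancy at RT ln 2", {
  proj <- cbind(c(rep(-1, 100), rep(1, 50)), rep(0, 150))
  fel <- freeEnergyLandscape(proj, bins = c(2, 1), temperature = 300)
  dg <- sort(fel@deltaG[is.finite(fel@deltaG)])
  expect_identical(dg[1], 0)
  expect_equal(dg[2], 1.9872036e-3 * 300 * log(2), tolerance = 1e-12)
  expect_equal(dg[2], 0.4132, tolerance = 1e-4)
  expect_equal(sum(fel@counts), 150L)

  # 80/20 split: difference is -RT ln(0.25) = 0.8265 kcal/mol
  proj2 <- cbind(c(rep(-1, 800), rep(1, 200)), rep(0, 1000))
  fel2 <- freeEnergyLandscape(proj2, bins = c(2, 1))
  dg2 <- fel2@deltaG[is.finite(fel2@deltaG)]
  expect_equal(max(dg2) - min(dg2), -1.9872036e-3 * 300 * log(0.25),
               tolerance = 1e-9)

  # all frames in one bin: that bin 0, everything else undefined (+Inf)
  fel3 <- freeEnergyLandscape(cbind(rep(0, 10), rep(0, 10)), bins = c(5, 5))
  expect_equal(sum(is.finite(fel3@deltaG)), 1L)
  expect_identical(fel3@deltaG[is.finite(fel3@deltaG)], 0)
  expect_true(all(is.infinite(fel3@deltaG[fel3@counts == 0])))
})

test_that("uniformly adding frames to occupied bins flattens the landscape", {
  counts0 <- c(100, 50, 25)
  mk <- function(extra) {
    proj <- cbind(rep(c(-1, 0, 1), counts0 + extra), 0)
    freeEnergyLandscape(proj, bins = c(3, 1))
  }
  d0 <- sort(mk(0)@deltaG[is.finite(mk(0)@deltaG)])
  d1 <- sort(mk(40)@deltaG[is.finite(mk(40)@deltaG)])
  expect_true(all(d1[-1] < d0[-1]))  # all differences shrink toward 0
})

test_that("locateConformation reports bin dG and flags out-of-range points", {
  sys <- twoModeSystem(nFrames = 500, nRes = 8, seed = 23)
  model <- fitPCA(sys$traj, analysisSelection = seq_len(nAtoms(sys$ref)))
  proj <- projectOnto(sys$traj, model)
  fel <- freeEnergyLandscape(proj, bins = c(20, 20))

  imax <- which(fel@counts == max(fel@counts), arr.ind = TRUE)[1, ]
  inMax <- which(gatescope:::.binIndex(proj[, 1], fel@xedges) == imax[1] &
                 gatescope:::.binIndex(proj[, 2], fel@yedges) == imax[2])
  loc <- locateConformation(frameStructure(sys$traj, inMax[1]), model, fel)
  expect_identical(loc$deltaG, 0)
  expect_false(loc$beyondLandscape)

  far <- sys$ref
  coords(far) <- matrix(model@mean + 1e3 * model@evecs[, 1],
                        ncol = 3, byrow = TRUE)
  locFar <- locateConformation(far, model, fel)
  expect_true(locFar$beyondLandscape)
  expect_true(is.finite(locFar$deltaG) || is.infinite(locFar$deltaG))
})

test_that("the representative conformation sits in the major basin, deterministically", {
  ref <- makeIdealHelix(8)
  ts <- makeTwoStateTrajectory(ref, separation = 10, pMajor = 0.8,
                               noiseSigma = 0.5, nFrames = 400,
                               nReplicas = 3, seed = 17)
  model <- fitPCA(ts$trajectories,
                  analysisSelection = seq_len(nAtoms(ref)))
  proj <- do.call(rbind, lapply(ts$trajectories, projectOnto, model = model))
  fel <- freeEnergyLandscape(proj, bins = c(30, 30))
  rep1 <- representativeConformation(ts$trajectories, model, fel)
  rep2 <- representativeConformation(ts$trajectories, model, fel)
  expect_identical(rep1$replicaId, rep2$replicaId)
  expect_identical(rep1$frame, rep2$frame)
  # the chosen frame carries the true major-basin label
  expect_true(ts$labels[[rep1$replicaId]][rep1$frame])

  # a single-frame trajectory is its own representative
  single <- new("Trajectory", topology = ref,
                frames = ts$trajectories[[1]]@frames[, , 1, drop = FALSE])
  pS <- projectOnto(single, model)
  felS <- freeEnergyLandscape(rbind(pS, pS), bins = c(3, 3))
  repS <- representativeConformation(single, model, felS)
  expect_identical(repS$frame, 1L)

  # zero-variance input is rejected with a clear message
  expect_error(fitPCA(list(single, single), analysisSelection = 1:8),
               "no coordinate variance")
})

test_that("porcupine vectors scale with sqrt(eigenvalue) and honor the cutoff", {
  sys <- twoModeSystem(nFrames = 400, nRes = 8, seed = 31)
  model <- fitPCA(sys$traj, analysisSelection = seq_len(nAtoms(sys$ref)))
  topo <- sys$ref
  arrows <- pcDisplacementVectors(model, topo, component = 1, cutoff = 0)
  expect_equal(nrow(arrows), length(model@atomIndices))
  v <- matrix(model@evecs[, 1], ncol = 3, byrow = TRUE)
  expect_allclose(arrows$magnitude,
                  sqrt(rowSums(v^2)) * sqrt(model@evals[1]), 1e-9)

  big <- pcDisplacementVectors(model, topo, component = 1,
                               cutoff = max(arrows$magnitude) * 1.01)
  expect_equal(nrow(big), 0L)

  # single-mode system: the moving atom's arrow parallels the programmed axis
  s <- randomToyStructure(6, seed = 4)
  u <- c(0, 1, 0); nF <- 60
  frames <- array(rep(coords(s), nF), dim = c(6, 3, nF))
  for (f in seq_len(nF)) frames[3, , f] <- frames[3, , f] +
      rnorm(1, sd = 1) * u
  set.seed(1)
  traj <- new("Trajectory", topology = s, frames = frames)
  m1 <- fitPCA(traj, fitSelection = c(1, 2, 4, 5, 6),
               analysisSelection = 1:6)
  a1 <- pcDisplacementVectors(m1, s, component = 1, cutoff = 0)
  vec <- unlist(a1[a1$atom == 3, c("dx", "dy", "dz")])
  expect_gt(abs(sum(vec * u) / sqrt(sum(vec^2))), 0.99)
})
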