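test_that("a static particle occupies exactly one voxel at value 1", {
  s <- makeStructure(name = "P", resname = "PC", resid = 1L, chain = "L",
                     coords = matrix(c(5.2, 5.7, 5.1), 1, 3), element = "P")
  frames <- array(rep(coords(s), 10), dim = c(1, 3, 10))
  traj <- new("Trajectory", topology = s, frames = frames)
  g <- densityGrid(traj, "name P", spacing = 1,
                   extent = list(min = c(0, 0, 0), max = c(10, 10, 10)))
  expect_equal(sum(g@values > 0), 1L)
  expect_equal(max(g@values), 1)
  expect_equal(sum(g@values), 1)  # mean per-frame in-grid particle count
})

test_that("normalization is invariant under frame replication", {
  lf <- makeLipidField(200, 4, seed = 8)
  ext <- list(min = c(0, 0, 0), max = c(60, 60, 20))
  g4 <- densityGrid(lf$trajectory, "name P", spacing = 4, extent = ext)
  rep10 <- new("Trajectory", topology = lf$trajectory@topology,
               frames = lf$trajectory@frames[, , rep(1:4, 10)])
  g40 <- densityGrid(rep10, "name P", spacing = 4, extent = ext)
  expect_identical(g4@values, g40@values)
})

test_that("uniform fields are chi-square consistent with uniform expectation", {
  lf <- makeLipidField(10000, 50, seed = 12)
  g <- densityGrid(lf$trajectory, "name P", spacing = 10,
                   extent = list(min = c(0, 0, 0), max = c(60, 60, 20)))
  counts <- g@values * 50  # back to raw counts
  p <- chisq.test(as.numeric(counts))$p.value
  expect_gt(p, 0.001)
  expect_equal(sum(g@values), 10000, tolerance = 1e-9)
})

test_that("a programmed Gaussian hotspot is recovered within one sigma", {
  center <- c(30, 30, 10); sigma <- 5
  lf <- makeLipidField(2000, 200,
                       hotspot = list(center = center, sigma = sigma,
                                      fraction = 0.3), seed = 3)
  g <- densityGrid(lf$trajectory, "name P", spacing = 2,
                   extent = list(min = c(0, 0, 0), max = c(60, 60, 20)))
  peak <- which(g@values == max(g@values), arr.ind = TRUE)[1, ]
  peakPos <- g@origin + (peak - 0.5) * g@spacing
  expect_lt(sqrt(sum((peakPos - center)^2)), sigma)
})

test_that("two classes with disjoint enrichment zones give disjoint maxima", {
  cPC <- c(15, 30, 10); cPG <- c(45, 30, 10)
  set.seed(9)
  mk <- function(center, cls, seed) {
    makeLipidField(1500, 100, hotspot = list(center = center, sigma = 4,
                                             fraction = 0.4), seed = seed)
  }
  ext <- list(min = c(0, 0, 0), max = c(60, 60, 20))
  gPC <- densityGrid(mk(cPC, "PC", 21)$trajectory, "name P", spacing = 3,
                     extent = ext, classLabel = "PC headgroups")
  gPG <- densityGrid(mk(cPG, "PG", 22)$trajectory, "name P", spacing = 3,
                     extent = ext, classLabel = "PG headgroups")
  pPC <- which(gPC@values == max(gPC@values), arr.ind = TRUE)[1, ]
  pPG <- which(gPG@values == max(gPG@values), arr.ind = TRUE)[1, ]
  posPC <- gPC@origin + (pPC - 0.5) * 3
  posPG <- gPG@origin + (pPG - 0.5) * 3
  expect_lt(sqrt(sum((posPC - cPC)^2)), 4)
  expect_lt(sqrt(sum((posPG - cPG)^2)), 4)
  expect_gt(sqrt(sum((posPC - posPG)^2)), 20)
})

test_that("frames are superposed onto the protein frame before binning", {
  # protein 4 atoms + 1 particle riding 10 A above it; every frame is the
  # same configuration under a different global rigid motion
  prot <- randomToyStructure(4, seed = 5)
  part <- makeStructure(name = "P", resname = "PC", resid = 100L,
                        chain = "L",
                        coords = matrix(colMeans(coords(prot)) +
                                          c(0, 0, 10), 1, 3),
                        element = "P")
  sys <- gatescope:::.bindStructures(prot, part)
  nF <- 12
  frames <- array(0, dim = c(5, 3, nF))
  set.seed(6)
  for (f in seq_len(nF)) {
    frames[, , f] <- sweep(coords(sys) %*% t(randomRotationMatrix()), 2,
                           runif(3, -20, 20), "+")
  }
  traj <- new("Trajectory", topology = sys, frames = frames)
  g <- densityGrid(traj, "name P", fitSelection = "chain A or chain B",
                   spacing = 1)
  expect_equal(sum(g@values > 0.99), 1L)  # particle pinned to one voxel
  expect_equal(g@nOutside, 0L)
})

test_that("non-positive spacing is a config error; outside particles only log", {
  lf <- makeLipidField(50, 2, seed = 1)
  expect_error(densityGrid(lf$trajectory, "name P", spacing = 0),
               "spacing")
  expect_message(
    g <- densityGrid(lf$trajectory, "name P", spacing = 2,
                     extent = list(min = c(0, 0, 0), max = c(10, 10, 10))),
    "outside")
  expect_gt(g@nOutside, 0L)
})

test_that("OpenDX output round-trips values, origin and spacing", {
  z <- new("DensityGrid", origin = c(0, 0, 0), spacing = 1,
           values = array(0, c(2, 2, 2)), classLabel = "zeros",
           nFrames = 1L, nOutside = 0L)
  f <- withr::local_tempfile(fileext = ".dx")
  writeDX(z, f)
  txt <- readLines(f)
  dataStart <- grep("data follows", txt) + 1L
  vals <- as.numeric(unlist(strsplit(trimws(
    txt[dataStart:(dataStart + 2)]), " ")))
  expect_equal(vals[1:8], rep(0, 8))

  lf <- makeLipidField(300, 5, hotspot = list(center = c(30, 30, 10),
                                              sigma = 6, fraction = 0.5),
                       seed = 30)
  g <- densityGrid(lf$trajectory, "name P", spacing = 3.5,
                   extent = list(min = c(-1, 0, 0), max = c(61, 60, 21)))
  f2 <- withr::local_tempfile(fileext = ".dx")
  writeDX(g, f2)
  g2 <- readDX(f2)
  expect_equal(dim(g2@values), dim(g@values))
  expect_lt(max(abs(g2@values - g@values)), 1e-6)
  expect_allclose(g2@origin, g@origin, 1e-6)
  expect_equal(g2@spacing, g@spacing, tolerance = 1e-6)
  expect_equal(g2@classLabel, g@classLabel)

  # x-slowest/z-fastest ordering: vary values along x only and check layout
  vx <- array(rep(1:3, times = 4), c(3, 2, 2))  # value = x index
  gx <- new("DensityGrid", origin = c(0, 0, 0), spacing = 1, values = vx,
            classLabel = "x-ramp", nFrames = 1L, nOutside = 0L)
  f3 <- withr::local_tempfile(fileext = ".dx")
  writeDX(gx, f3)
  txt3 <- readLines(f3)
  i0 <- grep("data follows", txt3) + 1L
  flat <- as.numeric(unlist(strsplit(trimws(txt3[i0:(i0 + 3)]), " ")))
  expect_equal(flat, rep(1:3, each = 4))
})
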