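# Fixtures are built in code; nothing binary ships with the package.

# A tiny two-chain structure with known geometry: chain Y is a 13-residue
# helix, chain E a 4-atom toy residue.
toyTwoChain <- function() {
  h <- makeIdealHelix(13, chain = "Y", firstResid = 278L)
  e <- makeStructure(name = c("N", "CA", "C", "O"), resname = "GLY",
                     resid = 1L, chain = "E",
                     coords = matrix(c(0, 0, 0, 1.5, 0, 0, 2.2, 1.1, 0,
                                       2.2, 2.3, 0.4), 4, 3, byrow = TRUE))
  gatescope:::.bindStructures(h, e, label = "toy")
}

# Random toy structure for round-trip properties (coordinates on the PDB
# 0.001 A grid so write -> read is exact).
randomToyStructure <- function(n = 25, seed = 1) {
  set.seed(seed)
  makeStructure(
    name = paste0("C", seq_len(n) %% 8),
    resname = sample(c("ALA", "GLY", "LEU"), n, TRUE),
    resid = seq_len(n),
    chain = rep(c("A", "B"), times = c(ceiling(n / 2), floor(n / 2))),
    coords = round(matrix(runif(3 * n, -50, 50), n, 3), 3),
    element = "C", label = "random toy")
}

randomRotationMatrix <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Brute-force superposition oracle: best RMSD over random proper rotations,
# each with its optimal translation (centroid match).
bruteForceRmsd <- function(P, Q, nTrials = 1000, seed = 99) {
  set.seed(seed)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  best <- Inf
  for (i in seq_len(nTrials)) {
    R <- randomRotationMatrix()
    r <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
    if (r < best) best <- r
  }
  best
}

# Independent eigensolver for symmetric matrices: cyclic Jacobi rotations.
jacobiEigenvalues <- function(A, tol = 1e-12, maxSweeps = 100) {
  A <- as.matrix(A)
  n <- nrow(A)
  for (sweep in seq_len(maxSweeps)) {
    off <- 0
    for (p in seq_len(n - 1)) {
      for (q in (p + 1):n) {
        off <- off + A[p, q]^2
        if (abs(A[p, q]) > tol) {
          theta <- (A[q, q] - A[p, p]) / (2 * A[p, q])
          t <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
          if (theta == 0) t <- 1
          c <- 1 / sqrt(t^2 + 1); s <- t * c
          J <- diag(n); J[p, p] <- c; J[q, q] <- c
          J[p, q] <- s; J[q, p] <- -s
          A <- t(J) %*% A %*% J
        }
      }
    }
    if (off < tol^2) break
  }
  sort(diag(A), decreasing = TRUE)
}

expect_allclose <- function(x, y, tol = 1e-8) {
  expect_lt(max(abs(x - y)), tol)
}

# Two independent internal Gaussian modes with per-mode sd (sd1, sd2):
# ground truth for PCA explained fractions sd1^2/(sd1^2+sd2^2) and for
# PC1-mode alignment. Modes are orthogonal to the rigid-body subspace so
# superposition does not absorb programmed variance.
twoModeSystem <- function(nFrames = 3000, sd1 = 2, sd2 = 1, seed = 5,
                          nRes = 10) {
  ref <- makeIdealHelix(nRes)
  n <- nAtoms(ref)
  set.seed(seed)
  m1 <- gatescope:::.removeRigidComponent(rnorm(3 * n), coords(ref))
  m2 <- rnorm(3 * n); m2 <- m2 - sum(m2 * m1) * m1
  m2 <- gatescope:::.removeRigidComponent(m2, coords(ref))
  m2 <- m2 - sum(m2 * m1) * m1; m2 <- m2 / sqrt(sum(m2^2))
  a1 <- rnorm(nFrames, sd = sd1); a2 <- rnorm(nFrames, sd = sd2)
  base <- coords(ref)
  frames <- array(0, c(n, 3, nFrames))
  for (f in seq_len(nFrames)) {
    frames[, , f] <- base + matrix(m1, n, 3, byrow = TRUE) * a1[f] +
      matrix(m2, n, 3, byrow = TRUE) * a2[f]
  }
  list(traj = new("Trajectory", topology = ref, frames = frames),
       ref = ref, m1 = m1, m2 = m2)
}
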