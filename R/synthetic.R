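# Synthetic-trajectory generators. The defaults emulate the study regime the
# analyses were designed for: 5 independent replicas, frames saved every
# 200 ps over 1 microsecond (5,000 frames per replica at full scale), and a
# PC:PG 2:1 lipid composition. Every generator is bit-reproducible from
# (seed, parameters); replica r draws from its own sub-stream so replica
# sets are reproducible independently.

.replicaSeed <- function(seed, replica) {
  as.integer((as.numeric(seed) * 7919 + replica * 104729) %%
               .Machine$integer.max)
}

# rotation matrix taking the z axis onto 'axis' (Rodrigues)
.rotationToAxis <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * a[3] - z[3] * a[2], z[3] * a[1] - z[1] * a[3],
         z[1] * a[2] - z[2] * a[1])
  s <- sqrt(sum(v^2)); cth <- sum(z * a)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # 180 degrees about x
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

.randomRotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Build an ideal alpha-helix backbone
#'
#' Backbone pseudo-atoms (N, CA, C, O) are placed on the canonical
#' alpha-helix parameterization (rise 1.5 Angstrom/residue, twist 100
#' degrees/residue, C-alpha radius 2.3 Angstrom) along the requested axis.
#' The fixture underlying all helix-axis operators: \code{helixVector} on a
#' 20-residue ideal helix recovers the construction axis to within 1 degree.
#'
#' @param nRes number of residues (>= 8, so both terminal turns exist).
#' @param rise rise per residue, Angstrom.
#' @param twist twist per residue, degrees.
#' @param radius C-alpha helical radius, Angstrom.
#' @param axis helix axis direction (any nonzero 3-vector).
#' @param origin position of the axis start.
#' @param chain chain id.
#' @param firstResid residue id of the first residue.
#' @return a \linkS4class{Structure}
#' @export
makeIdealHelix <- function(nRes, rise = 1.5, twist = 100, radius = 2.3,
                           axis = c(0, 0, 1), origin = c(0, 0, 0),
                           chain = "A", firstResid = 1L) {
  if (nRes < 8) stop("an ideal helix fixture needs at least 8 residues",
                     call. = FALSE)
  # per-backbone-atom offsets on the helical wheel: radius, phase (deg),
  # axial offset relative to the residue's CA
  wheel <- data.frame(
    name = c("N", "CA", "C", "O"),
    r = c(1.60, radius, 1.70, 2.05),
    dphi = c(-28, 0, 26, 32),
    dz = c(-0.95, 0, 0.75, 1.25))
  res <- rep(seq_len(nRes), each = 4L)
  at <- rep(seq_len(4L), nRes)
  phi <- ((res - 1) * twist + wheel$dphi[at]) * pi / 180
  xyz <- cbind(wheel$r[at] * cos(phi), wheel$r[at] * sin(phi),
               (res - 1) * rise + wheel$dz[at])
  R <- .rotationToAxis(axis)
  xyz <- sweep(xyz %*% t(R), 2, origin, "+")
  makeStructure(name = wheel$name[at], resname = "ALA",
                resid = firstResid + res - 1L, chain = chain, coords = xyz,
                element = substr(wheel$name[at], 1, 1),
                label = sprintf("ideal helix (%d res)", nRes))
}

#' Harmonic synthetic trajectories: Gaussian fluctuation about a reference
#'
#' Each frame is the reference plus isotropic per-atom Gaussian noise
#' (standard deviation \code{sigma} per axis), optionally composed with a
#' random global rigid motion per frame to exercise superposition. Ground
#' truth: per-atom RMSF is sigma * sqrt(3).
#'
#' @param ref reference \linkS4class{Structure}.
#' @param sigma per-atom noise sd, Angstrom (scalar or length-N).
#' @param nFrames frames per replica.
#' @param nReplicas number of replicas (default 5, the study regime).
#' @param seed master seed; replica r uses a derived sub-stream.
#' @param rigidMotions inject a random rotation + translation per frame.
#' @param frameSpacing metadata, ps (default 200).
#' @return list of \linkS4class{Trajectory}, one per replica
#' @export
makeHarmonicTrajectory <- function(ref, sigma, nFrames, nReplicas = 5L,
                                   seed = 1L, rigidMotions = FALSE,
                                   frameSpacing = 200) {
  n <- nAtoms(ref)
  sigma <- rep_len(sigma, n)
  stopifnot(all(sigma >= 0))
  base <- coords(ref)
  lapply(seq_len(nReplicas), function(r) {
    set.seed(.replicaSeed(seed, r))
    frames <- array(0, dim = c(n, 3, nFrames))
    for (f in seq_len(nFrames)) {
      fr <- base + matrix(rnorm(3 * n, sd = rep(sigma, 3)), n, 3)
      if (rigidMotions) {
        fr <- sweep(fr %*% t(.randomRotation()), 2, runif(3, -20, 20), "+")
      }
      frames[, , f] <- fr
    }
    new("Trajectory", topology = ref, frames = frames,
        frameSpacing = frameSpacing, replicaId = r)
  })
}

# Project a 3N mode onto the complement of the rigid-body subspace
# (3 translations + 3 infinitesimal rotations) at the reference, so that a
# programmed collective mode is a genuine internal motion that trajectory
# superposition cannot absorb.
.removeRigidComponent <- function(mode, refCoords) {
  n <- nrow(refCoords)
  cen <- sweep(refCoords, 2, colMeans(refCoords))
  basis <- matrix(0, 3 * n, 6)
  for (k in 1:3) {
    t <- matrix(0, n, 3); t[, k] <- 1
    basis[, k] <- as.numeric(t(t))
    ek <- c(0, 0, 0); ek[k] <- 1
    rot <- t(apply(cen, 1, function(x)
      c(ek[2] * x[3] - ek[3] * x[2], ek[3] * x[1] - ek[1] * x[3],
        ek[1] * x[2] - ek[2] * x[1])))
    basis[, 3 + k] <- as.numeric(t(rot))
  }
  Q <- qr.Q(qr(basis))
  res <- mode - Q %*% crossprod(Q, mode)
  as.numeric(res / sqrt(sum(res^2)))
}

#' Two-state synthetic trajectories along a prescribed collective mode
#'
#' Each frame sits in basin A (the reference, probability \code{pMajor}) or
#' basin B (reference displaced by \code{separation} along the unit mode),
#' plus isotropic Gaussian noise. True basin labels are returned as a
#' side-channel (\code{labels}), never encoded in the coordinates. Ground
#' truth for the landscape: the basin free-energy difference is
#' -RT ln((1 - p)/p).
#'
#' @param ref reference \linkS4class{Structure}.
#' @param mode unit 3N-vector (atom-major x1,y1,z1,...); a random unit mode
#'   is drawn when NULL.
#' @param separation basin separation along the mode, Angstrom.
#' @param pMajor occupancy of basin A, in [0.5, 1).
#' @param noiseSigma isotropic noise sd per axis, Angstrom.
#' @param nFrames frames per replica.
#' @param nReplicas replicas (default 5).
#' @param seed master seed.
#' @param frameSpacing metadata, ps.
#' @return list(trajectories = list of Trajectory, labels = list of logical
#'   vectors (TRUE = basin A), mode = the 3N mode used)
#' @export
makeTwoStateTrajectory <- function(ref, mode = NULL, separation, pMajor,
                                   noiseSigma, nFrames, nReplicas = 5L,
                                   seed = 1L, frameSpacing = 200) {
  stopifnot(pMajor >= 0.5, pMajor <= 1)
  n <- nAtoms(ref)
  if (is.null(mode)) {
    set.seed(.replicaSeed(seed, 0L))
    # a random internal mode: rigid-body components are projected out so the
    # basin separation survives superposition
    mode <- .removeRigidComponent(rnorm(3 * n), coords(ref))
  }
  stopifnot(length(mode) == 3 * n)
  mode <- mode / sqrt(sum(mode^2))
  if (separation <= 4 * noiseSigma)
    warning("basin separation <= 4 * noise sigma: basins may merge")
  shift <- matrix(mode, n, 3, byrow = TRUE) * separation
  base <- coords(ref)
  trajs <- vector("list", nReplicas)
  labels <- vector("list", nReplicas)
  for (r in seq_len(nReplicas)) {
    set.seed(.replicaSeed(seed, r))
    inA <- runif(nFrames) < pMajor
    frames <- array(0, dim = c(n, 3, nFrames))
    for (f in seq_len(nFrames)) {
      fr <- base + matrix(rnorm(3 * n, sd = noiseSigma), n, 3)
      if (!inA[f]) fr <- fr + shift
      frames[, , f] <- fr
    }
    trajs[[r]] <- new("Trajectory", topology = ref, frames = frames,
                      frameSpacing = frameSpacing, replicaId = r)
    labels[[r]] <- inA
  }
  list(trajectories = trajs, labels = labels, mode = mode)
}

#' Gate toy: two ideal helices following prescribed angle/distance schedules
#'
#' Helix A (chain A) is fixed along +z; helix B (chain B) is rebuilt each
#' frame with its axis at the scheduled angle from +z (in the xz-plane) and
#' translated so that the COM of its first 4-residue turn sits exactly at
#' the scheduled distance from the COM of helix A's first turn. The true
#' series is returned alongside the trajectory, giving the gate-geometry
#' operators a construction oracle.
#'
#' @param angleSchedule per-frame inter-axis angle, degrees.
#' @param distanceSchedule per-frame first-turn COM distance, Angstrom.
#' @param nRes residues per helix (default 20).
#' @param frameSpacing metadata, ps.
#' @return list(trajectory, truth = data.frame(frame, angle, distance),
#'   helixA, helixB = HelixSpecs, turnA, turnB = TurnSpecs)
#' @export
makeGateToy <- function(angleSchedule, distanceSchedule, nRes = 20L,
                        frameSpacing = 200) {
  stopifnot(length(angleSchedule) == length(distanceSchedule))
  nF <- length(angleSchedule)
  hA <- makeIdealHelix(nRes, chain = "A")
  topoB <- makeIdealHelix(nRes, chain = "B")
  topo <- .bindStructures(hA, topoB, label = "gate toy")
  turnA <- turnSpec("A", 1L)
  turnB <- turnSpec("B", 1L)
  comA <- turnCOM(hA, turnA)
  nA <- nAtoms(hA)

  frames <- array(0, dim = c(nAtoms(topo), 3, nF))
  for (f in seq_len(nF)) {
    th <- angleSchedule[f] * pi / 180
    axis <- c(sin(th), 0, cos(th))
    hB <- makeIdealHelix(nRes, axis = axis, chain = "B")
    cB <- turnCOM(hB, turnB)
    target <- comA + c(distanceSchedule[f], 0, 0)
    xyzB <- sweep(coords(hB), 2, target - cB, "+")
    frames[, , f] <- rbind(coords(hA), xyzB)
  }
  traj <- new("Trajectory", topology = topo, frames = frames,
              frameSpacing = frameSpacing, replicaId = 1L)
  list(trajectory = traj,
       truth = data.frame(frame = seq_len(nF), angle = angleSchedule,
                          distance = distanceSchedule),
       helixA = helixSpec("helixA", "A", 1L, nRes),
       helixB = helixSpec("helixB", "B", 1L, nRes),
       turnA = turnA, turnB = turnB)
}

.bindStructures <- function(a, b, label = NA_character_) {
  atoms <- rbind(a@atoms, b@atoms)
  atoms$serial <- seq_len(nrow(atoms))
  new("Structure", atoms = atoms, coords = rbind(a@coords, b@coords),
      label = label)
}

#' Lipid pseudo-particle field with an optional Gaussian hotspot
#'
#' Per frame, particles are drawn uniformly over a rectangular slab except
#' for a programmed fraction drawn from an isotropic 3D Gaussian hotspot
#' (the enrichment-zone ground truth for density recovery). Particle
#' classes are assigned once per replica at the given ratio (default
#' PC:PG = 2:1, the bilayer composition the generators emulate) and stored
#' as residue names.
#'
#' @param nParticles particles per frame.
#' @param nFrames frames.
#' @param hotspot NULL for a uniform field, else list(center = 3-vector,
#'   sigma = Angstrom, fraction = in [0, 1]).
#' @param classRatio named numeric ratio, default c(PC = 2, PG = 1).
#' @param slabMin,slabMax slab corners, Angstrom.
#' @param seed seed.
#' @return list(trajectory, classes = per-particle class,
#'   hotspot = the hotspot used)
#' @export
makeLipidField <- function(nParticles, nFrames, hotspot = NULL,
                           classRatio = c(PC = 2, PG = 1),
                           slabMin = c(0, 0, 0), slabMax = c(60, 60, 20),
                           seed = 1L) {
  if (!is.null(hotspot))
    stopifnot(hotspot$fraction >= 0, hotspot$fraction <= 1)
  set.seed(.replicaSeed(seed, 1L))
  classes <- sample(names(classRatio), nParticles, replace = TRUE,
                    prob = classRatio / sum(classRatio))
  topo <- makeStructure(
    name = "P", resname = classes, resid = seq_len(nParticles),
    chain = "L",
    coords = matrix(0, nParticles, 3), element = "P",
    label = "lipid pseudo-particles")
  frames <- array(0, dim = c(nParticles, 3, nFrames))
  for (f in seq_len(nFrames)) {
    inHot <- if (is.null(hotspot)) rep(FALSE, nParticles)
             else runif(nParticles) < hotspot$fraction
    xyz <- cbind(runif(nParticles, slabMin[1], slabMax[1]),
                 runif(nParticles, slabMin[2], slabMax[2]),
                 runif(nParticles, slabMin[3], slabMax[3]))
    if (any(inHot)) {
      k <- sum(inHot)
      xyz[inHot, ] <- matrix(rep(hotspot$center, each = k), k, 3) +
        matrix(rnorm(3 * k, sd = hotspot$sigma), k, 3)
    }
    frames[, , f] <- xyz
  }
  list(trajectory = new("Trajectory", topology = topo, frames = frames,
                        replicaId = 1L),
       classes = classes, hotspot = hotspot)
}
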