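# Gas constant in kcal mol^-1 K^-1, the unit system of the landscape.
.GAS_CONSTANT_KCAL <- 1.9872036e-3

#' @rdname freeEnergyLandscape
#' @export
gasConstantKcal <- function() .GAS_CONSTANT_KCAL

.flatten <- function(xyz) as.numeric(t(xyz))  # x1,y1,z1,x2,... atom-major

#' Cartesian principal component analysis of pooled trajectories
#'
#' Frames of all replicas are pooled, superposed onto the converged average
#' structure over the fit selection (removing global rotation and
#' translation), and the covariance of the flattened analysis-atom
#' coordinates is eigendecomposed. Eigenvalues are sorted descending;
#' eigenvector signs are fixed so each column's largest-magnitude entry is
#' positive, making projections reproducible across runs.
#'
#' @param trajectories a Trajectory or list of Trajectories (replicas,
#'   shared topology).
#' @param fitSelection atoms to superpose on (e.g. the ten-TMH bundle).
#' @param analysisSelection atoms entering the covariance (default "calpha"
#'   when the topology has CA atoms, else all atoms).
#' @return a \linkS4class{PCAModel}
#' @export
fitPCA <- function(trajectories, fitSelection = NULL,
                   analysisSelection = NULL) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  topo <- trajectories[[1]]@topology
  frames <- do.call(abind3, lapply(trajectories, function(t) t@frames))
  nF <- dim(frames)[3]
  if (nF < 2) stop("PCA needs at least 2 pooled frames", call. = FALSE)

  fitIdx <- .asIndices(topo, fitSelection)
  if (is.null(analysisSelection)) {
    analysisSelection <- if (any(topo@atoms$name == "CA")) "calpha" else NULL
  }
  anaIdx <- .asIndices(topo, analysisSelection)

  pooled <- new("Trajectory", topology = topo, frames = frames)
  avg <- averageStructure(pooled, fitIdx)
  refXYZ <- coords(avg)

  X <- matrix(0, nF, 3 * length(anaIdx))
  for (f in seq_len(nF)) {
    fr <- frames[, , f]
    fit <- kabschFit(fr[fitIdx, , drop = FALSE],
                     refXYZ[fitIdx, , drop = FALSE])
    X[f, ] <- .flatten(applyFit(fr, fit)[anaIdx, , drop = FALSE])
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nF - 1)
  e <- eigen(C, symmetric = TRUE)
  evals <- pmax(e$values, 0)
  if (sum(evals) <= 0)
    stop("pooled frames carry no coordinate variance after superposition",
         call. = FALSE)
  evecs <- e$vectors
  for (j in seq_len(ncol(evecs))) {
    if (evecs[which.max(abs(evecs[, j])), j] < 0) evecs[, j] <- -evecs[, j]
  }
  new("PCAModel", mean = mu, evecs = evecs, evals = evals,
      explainedFraction = evals / sum(evals),
      atomIndices = as.integer(anaIdx), fitIndices = as.integer(fitIdx),
      refCoords = refXYZ)
}

#' Eigenvalue spectrum of a PCA model
#' @param model a PCAModel
#' @return data.frame component, eigenvalue, explained_fraction,
#'   cumulative_fraction
#' @export
pcaSpectrum <- function(model) {
  data.frame(component = seq_along(model@evals),
             eigenvalue = model@evals,
             explained_fraction = model@explainedFraction,
             cumulative_fraction = cumsum(model@explainedFraction))
}

#' Project frames (or a single structure) onto principal components
#'
#' Each frame is superposed onto the model's average-structure reference
#' over the model's fit atoms, centered with the model mean, and dotted with
#' the first k eigenvectors.
#'
#' @param x a Trajectory, a Structure, or an N x 3 coordinate matrix.
#' @param model a \linkS4class{PCAModel}.
#' @param k number of components (default 2).
#' @return F x k matrix of projections (a 1 x k matrix for a Structure)
#' @export
projectOnto <- function(x, model, k = 2L) {
  if (k > length(model@evals))
    stop(sprintf("k = %d exceeds the %d available components", k,
                 length(model@evals)), call. = FALSE)
  frameList <- if (is(x, "Trajectory")) {
    lapply(seq_len(nFrames(x)), function(f) coords(x, f))
  } else list(.coordsOf(x))
  if (nrow(frameList[[1]]) < max(model@atomIndices))
    stop("structure is incompatible with the model's analysis selection",
         call. = FALSE)
  V <- model@evecs[, seq_len(k), drop = FALSE]
  out <- t(vapply(frameList, function(fr) {
    fit <- kabschFit(fr[model@fitIndices, , drop = FALSE],
                     model@refCoords[model@fitIndices, , drop = FALSE])
    v <- .flatten(applyFit(fr, fit)[model@atomIndices, , drop = FALSE]) -
      model@mean
    as.numeric(v %*% V)
  }, numeric(k)))
  matrix(out, ncol = k)
}

.binEdges <- function(v, n) {
  rng <- range(v)
  pad <- if (diff(rng) > 0) 0.02 * diff(rng) else 0.5
  seq(rng[1] - pad, rng[2] + pad, length.out = n + 1L)
}

.binIndex <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE)
  i[i < 1 | i > length(edges) - 1] <- NA_integer_
  i
}

#' Configurational free-energy landscape over (PC1, PC2)
#'
#' Boltzmann inversion of the 2D histogram of projections:
#' Delta G_i = -R T ln(N_i / N_max) per occupied bin (kcal/mol), where N_i
#' is the population of bin i and N_max that of the most populated bin, so
#' the landscape minimum is exactly 0. Unoccupied bins are undefined (+Inf).
#'
#' @param projections F x 2 matrix of (PC1, PC2) values.
#' @param bins bin count per axis, length 1 or 2 (default 100 x 100 over the
#'   data range padded 2 percent), or a list(x, y) of explicit edges.
#' @param temperature kelvin (default 300).
#' @return a \linkS4class{FreeEnergyLandscape}
#' @export
freeEnergyLandscape <- function(projections, bins = c(100L, 100L),
                                temperature = 300) {
  P <- matrix(as.numeric(projections), ncol = 2)
  if (is.list(bins)) {
    xe <- bins[[1]]; ye <- bins[[2]]
  } else {
    if (length(bins) == 1) bins <- rep(bins, 2)
    xe <- .binEdges(P[, 1], bins[1])
    ye <- .binEdges(P[, 2], bins[2])
  }
  ix <- .binIndex(P[, 1], xe)
  iy <- .binIndex(P[, 2], ye)
  ok <- !is.na(ix) & !is.na(iy)
  counts <- matrix(0L, length(xe) - 1L, length(ye) - 1L)
  tab <- table(factor(ix[ok], levels = seq_len(nrow(counts))),
               factor(iy[ok], levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  nmax <- max(counts)
  dg <- matrix(Inf, nrow(counts), ncol(counts))
  occ <- counts > 0
  dg[occ] <- -.GAS_CONSTANT_KCAL * temperature * log(counts[occ] / nmax)
  new("FreeEnergyLandscape", xedges = xe, yedges = ye, counts = counts,
      deltaG = dg, temperature = temperature,
      gasConstant = .GAS_CONSTANT_KCAL)
}

#' Landscape as a long-format table
#' @param fel a FreeEnergyLandscape
#' @return data.frame pc1, pc2 (bin centers), count, delta_g (kcal/mol; Inf
#'   for unoccupied bins)
#' @export
landscapeTable <- function(fel) {
  xm <- (fel@xedges[-1] + fel@xedges[-length(fel@xedges)]) / 2
  ym <- (fel@yedges[-1] + fel@yedges[-length(fel@yedges)]) / 2
  g <- expand.grid(pc1 = xm, pc2 = ym)
  g$count <- as.integer(fel@counts)
  g$delta_g <- as.numeric(fel@deltaG)
  g
}

#' Free energy of a single conformation on a landscape
#'
#' The structure is projected onto (PC1, PC2) and the Delta G of its bin is
#' returned. A projection outside the landscape edges is reported as
#' beyond-landscape with the nearest bin's value and a flag.
#'
#' @param structure a \linkS4class{Structure} compatible with the model.
#' @param model a \linkS4class{PCAModel}.
#' @param fel a \linkS4class{FreeEnergyLandscape} built from the model's
#'   projections.
#' @return list(deltaG, projection, bin = c(ix, iy), beyondLandscape)
#' @export
locateConformation <- function(structure, model, fel) {
  p <- projectOnto(structure, model, k = 2L)[1, ]
  ix <- .binIndex(p[1], fel@xedges)
  iy <- .binIndex(p[2], fel@yedges)
  beyond <- is.na(ix) || is.na(iy)
  clamp <- function(i, edges, v) {
    if (!is.na(i)) return(i)
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    which.min(abs(mids - v))
  }
  ix <- clamp(ix, fel@xedges, p[1])
  iy <- clamp(iy, fel@yedges, p[2])
  list(deltaG = fel@deltaG[ix, iy], projection = p, bin = c(ix, iy),
       beyondLandscape = beyond)
}

#' Representative conformation: the frame nearest the landscape minimum
#'
#' Among all pooled frames, returns the one whose (PC1, PC2) projection is
#' nearest (Euclidean) to the center of the most populated (minimum Delta G)
#' bin; ties break toward the lowest (replica, frame).
#'
#' @param trajectories the Trajectory or list the landscape was built from.
#' @param model the \linkS4class{PCAModel}.
#' @param fel the \linkS4class{FreeEnergyLandscape}.
#' @return list(replicaId, frame, projection, structure)
#' @export
representativeConformation <- function(trajectories, model, fel) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  imax <- which(fel@counts == max(fel@counts), arr.ind = TRUE)
  imax <- imax[order(imax[, 1], imax[, 2])[1], ]  # deterministic on ties
  xm <- (fel@xedges[-1] + fel@xedges[-length(fel@xedges)]) / 2
  ym <- (fel@yedges[-1] + fel@yedges[-length(fel@yedges)]) / 2
  center <- c(xm[imax[1]], ym[imax[2]])

  best <- NULL
  for (traj in trajectories) {
    proj <- projectOnto(traj, model, k = 2L)
    d2 <- (proj[, 1] - center[1])^2 + (proj[, 2] - center[2])^2
    f <- which.min(d2)  # which.min takes the first = lowest frame on ties
    if (is.null(best) || d2[f] < best$d2 - 1e-15) {
      best <- list(replicaId = traj@replicaId, frame = f, d2 = d2[f],
                   projection = proj[f, ], traj = traj)
    }
  }
  list(replicaId = best$replicaId, frame = best$frame,
       projection = best$projection,
       structure = frameStructure(best$traj, best$frame))
}

#' Principal-component displacement ("porcupine") vectors
#'
#' Per analysis atom, the eigenvector segment scaled by
#' \code{scale * sqrt(eigenvalue)}; arrows shorter than \code{cutoff} are
#' omitted (the small-displacement cutoff of porcupine plots).
#'
#' @param model a \linkS4class{PCAModel}.
#' @param topology the topology Structure (for atom annotation).
#' @param component which component (default 1).
#' @param scale amplitude scale factor (default 1).
#' @param cutoff minimum arrow length in Angstrom (default 0 = keep all).
#' @return data.frame atom, chain, resid, name, x, y, z (atom position in
#'   the model's average structure), dx, dy, dz, magnitude
#' @export
pcDisplacementVectors <- function(model, topology, component = 1L,
                                  scale = 1, cutoff = 0) {
  stopifnot(component >= 1, component <= length(model@evals))
  v <- matrix(model@evecs[, component], ncol = 3, byrow = TRUE) *
    scale * sqrt(model@evals[component])
  idx <- model@atomIndices
  atoms <- topology@atoms[idx, , drop = FALSE]
  pos <- model@refCoords[idx, , drop = FALSE]
  out <- data.frame(atom = idx, chain = atoms$chain, resid = atoms$resid,
                    name = atoms$name, x = pos[, 1], y = pos[, 2],
                    z = pos[, 3], dx = v[, 1], dy = v[, 2], dz = v[, 3],
                    magnitude = sqrt(rowSums(v^2)),
                    stringsAsFactors = FALSE)
  out[out$magnitude >= cutoff | abs(out$magnitude - cutoff) < 1e-12, ,
      drop = FALSE]
}
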