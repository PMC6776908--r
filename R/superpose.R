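.coordsOf <- function(x) {
  if (is(x, "Structure")) coords(x) else as.matrix(x)
}

#' Kabsch least-squares superposition
#'
#' SVD-based rigid fit of \code{mobile} onto \code{reference} over the fit
#' atoms, constrained to proper rotations: the SVD sign correction enforces
#' det = +1 always, so reflections are never returned. The transform maps
#' mobile coordinates as \code{x \%*\% t(R) + t}.
#'
#' @param mobile,reference N x 3 coordinate matrices or
#'   \linkS4class{Structure}s with identical atom order.
#' @param fitIndices atom indices (or a \linkS4class{Selection} resolved on
#'   the mobile Structure) to fit on; NULL fits on all atoms. At least 3
#'   non-collinear points are required.
#' @return a \linkS4class{FitResult}
#' @export
kabschFit <- function(mobile, reference, fitIndices = NULL) {
  if (is(mobile, "Structure") && (is(fitIndices, "Selection") ||
                                  is.character(fitIndices))) {
    fitIndices <- .asIndices(mobile, fitIndices)
  }
  P <- .coordsOf(mobile)
  Q <- .coordsOf(reference)
  stopifnot(nrow(P) == nrow(Q))
  if (!is.null(fitIndices)) {
    P <- P[fitIndices, , drop = FALSE]
    Q <- Q[fitIndices, , drop = FALSE]
  }
  if (nrow(P) < 3) stop("need at least 3 fit atoms", call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  X <- sweep(P, 2, cp); Y <- sweep(Q, 2, cq)
  sx <- svd(X)$d
  if (sx[2] < max(sx[1], 1) * 1e-10)
    stop("degenerate geometry: fit atoms are (near-)collinear",
         call. = FALSE)
  H <- crossprod(X, Y)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cq - R %*% cp)
  fitted <- X %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  new("FitResult", rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a FitResult to coordinates
#'
#' @param coords N x 3 matrix (or Structure).
#' @param fit a \linkS4class{FitResult}.
#' @return transformed N x 3 matrix
#' @export
applyFit <- function(coords, fit) {
  xyz <- .coordsOf(coords)
  sweep(xyz %*% t(fit@rotation), 2, fit@translation, "+")
}

#' Root-mean-square deviation between two coordinate sets after optimal fit
#'
#' @param a,b N x 3 matrices or Structures.
#' @param fitIndices atoms to fit and measure on (NULL = all).
#' @return RMSD in Angstrom
#' @export
rmsdAfterFit <- function(a, b, fitIndices = NULL) {
  kabschFit(a, b, fitIndices)@rmsd
}

#' Iterative average structure of a trajectory
#'
#' Starting from frame 1, every frame is superposed onto the current average
#' over the fit selection and the mean coordinates are recomputed, until the
#' mean per-coordinate change drops below \code{tol} or \code{maxIter} is
#' reached (then the last average is returned with a warning).
#'
#' @param traj a \linkS4class{Trajectory} (or list of Trajectories, pooled).
#' @param fitSelection atoms to superpose on (Selection, expression, indices
#'   or NULL for all).
#' @param tol convergence threshold on the mean absolute coordinate change,
#'   Angstrom (default 1e-6).
#' @param maxIter maximum iterations (default 50).
#' @return a \linkS4class{Structure} holding the converged average
#' @export
averageStructure <- function(traj, fitSelection = NULL, tol = 1e-6,
                             maxIter = 50L) {
  if (is.list(traj)) {
    frames <- do.call(abind3, lapply(traj, function(t) t@frames))
    topo <- traj[[1]]@topology
  } else {
    frames <- traj@frames
    topo <- traj@topology
  }
  fitIdx <- .asIndices(topo, fitSelection)
  nF <- dim(frames)[3]
  avg <- frames[, , 1]
  if (nF == 1) {
    topo@coords <- avg
    return(topo)
  }
  for (iter in seq_len(maxIter)) {
    acc <- matrix(0, nrow(avg), 3)
    for (f in seq_len(nF)) {
      fr <- frames[, , f]
      fit <- kabschFit(fr[fitIdx, , drop = FALSE],
                       avg[fitIdx, , drop = FALSE])
      acc <- acc + applyFit(fr, fit)
    }
    newAvg <- acc / nF
    change <- mean(abs(newAvg - avg))
    avg <- newAvg
    if (change < tol) break
    if (iter == maxIter)
      warning(sprintf(
        "average structure not converged after %d iterations (change %.2e A)",
        maxIter, change))
  }
  topo@coords <- avg
  topo@label <- "average structure"
  topo
}

# bind N x 3 x F arrays along the frame axis
abind3 <- function(...) {
  parts <- list(...)
  n <- dim(parts[[1]])[1]
  array(unlist(parts), dim = c(n, 3, sum(vapply(parts, function(p)
    dim(p)[3], numeric(1)))))
}

#' Superpose every frame of a trajectory onto a reference
#'
#' @param traj a Trajectory.
#' @param reference a Structure or N x 3 matrix (default: the iterative
#'   average over \code{fitSelection}).
#' @param fitSelection atoms to fit on.
#' @return a Trajectory with superposed frames
#' @export
superposeTrajectory <- function(traj, reference = NULL, fitSelection = NULL) {
  fitIdx <- .asIndices(traj@topology, fitSelection)
  ref <- if (is.null(reference)) {
    coords(averageStructure(traj, fitIdx))
  } else .coordsOf(reference)
  out <- traj@frames
  for (f in seq_len(nFrames(traj))) {
    fr <- out[, , f]
    fit <- kabschFit(fr[fitIdx, , drop = FALSE],
                     ref[fitIdx, , drop = FALSE])
    out[, , f] <- applyFit(fr, fit)
  }
  traj@frames <- out
  traj
}

#' Per-residue C-alpha displacement field between two states
#'
#' \code{stateB} is superposed onto \code{stateA} over the fit selection
#' (resolved on stateA; fit atoms are matched into stateB by chain, residue
#' id and atom name after applying \code{chainMap}), then the C-alpha
#' displacement vector a -> b and its magnitude are reported per residue of
#' the report selection. Residues missing from either state are skipped and
#' listed in the result.
#'
#' @param stateA,stateB \linkS4class{Structure}s (e.g. two deposited models
#'   of the same protein).
#' @param fitSelection atoms of stateA to superpose on.
#' @param reportSelection atoms of stateA whose residues are reported.
#' @param chainMap named character vector mapping stateA chain ids to stateB
#'   chain ids (default: identity).
#' @return a \linkS4class{DisplacementField}
#' @export
displacementField <- function(stateA, stateB, fitSelection = NULL,
                              reportSelection = NULL, chainMap = NULL) {
  aAtoms <- stateA@atoms; bAtoms <- stateB@atoms
  mapChain <- function(ch) {
    if (is.null(chainMap)) ch
    else ifelse(ch %in% names(chainMap), chainMap[ch], ch)
  }
  bKey <- paste(bAtoms$chain, bAtoms$resid, bAtoms$name)

  fitIdxA <- .asIndices(stateA, fitSelection)
  fitKeyA <- paste(mapChain(aAtoms$chain[fitIdxA]), aAtoms$resid[fitIdxA],
                   aAtoms$name[fitIdxA])
  hit <- match(fitKeyA, bKey)
  ok <- !is.na(hit)
  if (sum(ok) < 3)
    stop("no usable atom correspondence between the two states",
         call. = FALSE)
  fit <- kabschFit(coords(stateB)[hit[ok], , drop = FALSE],
                   coords(stateA)[fitIdxA[ok], , drop = FALSE])
  bFitted <- applyFit(coords(stateB), fit)

  repIdxA <- .asIndices(stateA, reportSelection)
  caA <- repIdxA[aAtoms$name[repIdxA] == "CA"]
  if (length(caA) == 0)
    stop("report selection contains no C-alpha atoms", call. = FALSE)
  caKey <- paste(mapChain(aAtoms$chain[caA]), aAtoms$resid[caA], "CA")
  hitB <- match(caKey, bKey)
  found <- !is.na(hitB)
  if (!any(found))
    stop("no common residues between the two states", call. = FALSE)
  if (any(!found)) {
    message(sprintf("displacementField: skipping %d residue(s) missing from state B",
                    sum(!found)))
  }
  vec <- bFitted[hitB[found], , drop = FALSE] -
    coords(stateA)[caA[found], , drop = FALSE]
  field <- data.frame(
    chain = aAtoms$chain[caA[found]], resid = aAtoms$resid[caA[found]],
    dx = vec[, 1], dy = vec[, 2], dz = vec[, 3],
    magnitude = sqrt(rowSums(vec^2)), stringsAsFactors = FALSE)
  skipped <- data.frame(chain = aAtoms$chain[caA[!found]],
                        resid = aAtoms$resid[caA[!found]],
                        stringsAsFactors = FALSE)
  new("DisplacementField", field = field, skipped = skipped)
}

#' Tabular view of a displacement field
#' @param x a DisplacementField
#' @return data.frame chain, resid, dx, dy, dz, magnitude
#' @export
displacementTable <- function(x) {
  stopifnot(is(x, "DisplacementField"))
  x@field
}
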