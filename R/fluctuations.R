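#' Root-mean-square fluctuation profile of a trajectory
#'
#' Frames are superposed onto the converged iterative average structure over
#' the fit selection (single-pass fit to frame 1 available via
#' \code{reference = "first"}), then per analyzed atom
#' RMSF_i = sqrt(mean_f |r_i(f) - <r_i>|^2). Residue values are the
#' arithmetic mean over the residue's analyzed atoms (the maximum is also
#' reported for comparison).
#'
#' @param traj a \linkS4class{Trajectory} with at least 2 frames.
#' @param fitSelection atoms to superpose on (NULL = all).
#' @param analysisSelection atoms to report (NULL = all; "heavy" is the
#'   conventional all-atom choice when hydrogens are present).
#' @param reference "average" (default), "first" (single-pass fit to frame
#'   1), or "none" for frames that are already aligned — fitting frames that
#'   carry no global motion would otherwise absorb a small part of the
#'   fluctuation itself into the rigid-body fit.
#' @return an \linkS4class{RMSFProfile}
#' @export
rmsf <- function(traj, fitSelection = NULL, analysisSelection = NULL,
                 reference = c("average", "first", "none")) {
  reference <- match.arg(reference)
  if (nFrames(traj) < 2)
    stop("RMSF needs at least 2 frames", call. = FALSE)
  topo <- traj@topology
  sup <- if (reference == "none") traj else {
    ref <- if (reference == "average") NULL else frameStructure(traj, 1L)
    superposeTrajectory(traj, reference = ref, fitSelection = fitSelection)
  }
  idx <- .asIndices(topo, analysisSelection)
  sub <- sup@frames[idx, , , drop = FALSE]
  meanPos <- apply(sub, c(1, 2), mean)
  dev2 <- sweep(sub, c(1, 2), meanPos)^2
  atomRmsf <- sqrt(apply(dev2, 1, mean) * 3)  # mean over (3, F) x 3 coords

  atoms <- topo@atoms[idx, , drop = FALSE]
  atomTable <- data.frame(chain = atoms$chain, resid = atoms$resid,
                          name = atoms$name, rmsf = atomRmsf,
                          stringsAsFactors = FALSE)
  key <- paste(atomTable$chain, atomTable$resid)
  agg <- tapply(atomTable$rmsf, key, mean)
  mx <- tapply(atomTable$rmsf, key, max)
  cnt <- tapply(atomTable$rmsf, key, length)
  first <- !duplicated(key)
  ord <- match(unique(key), names(agg))
  residueTable <- data.frame(
    chain = atomTable$chain[first], resid = atomTable$resid[first],
    rmsf = as.numeric(agg[ord]), rmsf_max = as.numeric(mx[ord]),
    n_atoms = as.integer(cnt[ord]), stringsAsFactors = FALSE)
  new("RMSFProfile", atomTable = atomTable, residueTable = residueTable)
}

#' Pool RMSF profiles over replicas
#'
#' Per-residue mean and standard error of the mean (sd/sqrt(n)) over
#' independent replicas, matched by (chain, resid).
#'
#' @param profiles list of \linkS4class{RMSFProfile}s from replicas.
#' @return data.frame chain, resid, rmsf_mean, rmsf_sem, n
#' @export
poolRMSF <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  tabs <- lapply(profiles, function(p) p@residueTable)
  base <- tabs[[1]][c("chain", "resid")]
  key <- paste(base$chain, base$resid)
  vals <- vapply(tabs, function(t) {
    t$rmsf[match(key, paste(t$chain, t$resid))]
  }, numeric(nrow(base)))
  vals <- matrix(vals, nrow = nrow(base))
  n <- length(profiles)
  data.frame(
    chain = base$chain, resid = base$resid,
    rmsf_mean = rowMeans(vals),
    rmsf_sem = if (n >= 2) apply(vals, 1, sd) / sqrt(n)
               else rep(NA_real_, nrow(base)),
    n = n, stringsAsFactors = FALSE)
}

#' Atom-level RMSF table
#' @param x an RMSFProfile
#' @return data.frame chain, resid, name, rmsf
#' @export
atomRMSF <- function(x) {
  stopifnot(is(x, "RMSFProfile"))
  x@atomTable
}

#' Residue-level RMSF table
#' @param x an RMSFProfile
#' @return data.frame chain, resid, rmsf, rmsf_max, n_atoms
#' @export
residueRMSF <- function(x) {
  stopifnot(is(x, "RMSFProfile"))
  x@residueTable
}

#' Write a structure with residue RMSF in the B-factor column
#'
#' Produces a PDB whose B-factor column carries each atom's residue-level
#' RMSF, for 3D mobility coloring in molecular viewers.
#'
#' @param structure the \linkS4class{Structure} to write (e.g. the average).
#' @param profile an \linkS4class{RMSFProfile} on the same topology.
#' @param path output PDB path.
#' @return \code{path}, invisibly
#' @export
writeRMSFColoredPDB <- function(structure, profile, path) {
  rt <- profile@residueTable
  key <- paste(structure@atoms$chain, structure@atoms$resid)
  b <- rt$rmsf[match(key, paste(rt$chain, rt$resid))]
  b[is.na(b)] <- 0
  writePDB(structure, path, bfactor = b)
}
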