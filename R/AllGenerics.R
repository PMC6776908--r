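#' Number of atoms
#' @param x a Structure or Trajectory
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of frames
#' @param x a Trajectory
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Coordinates
#' @param x a Structure or Trajectory
#' @param ... further arguments (for Trajectory: \code{frame})
#' @return numeric N x 3 matrix (Angstrom)
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' Replace coordinates
#' @param x a Structure
#' @param value N x 3 matrix
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' Atom metadata table
#' @param x a Structure or Trajectory
#' @return data.frame with columns serial, name, element, resname, resid,
#'   chain, mass
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@frames)[1])

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@frames)[3])

#' @rdname coords
#' @export
setMethod("coords", "Structure", function(x, ...) x@coords)

#' @rdname coords
#' @param frame frame index (Trajectory only)
#' @export
setMethod("coords", "Trajectory", function(x, frame = 1L, ...) {
  stopifnot(frame >= 1, frame <= nFrames(x))
  m <- x@frames[, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
})

#' @rdname coords-set
#' @name coords<-
#' @aliases coords<-,Structure-method
#' @export
setMethod("coords<-", "Structure", function(x, value) {
  x@coords <- value
  validObject(x)
  x
})

#' @rdname atomData
#' @export
setMethod("atomData", "Structure", function(x) x@atoms)

#' @rdname atomData
#' @export
setMethod("atomData", "Trajectory", function(x) x@topology@atoms)

#' Topology of a trajectory
#' @param x a Trajectory
#' @return the topology \linkS4class{Structure}
#' @export
topology <- function(x) {
  stopifnot(is(x, "Trajectory"))
  x@topology
}

#' Extract one frame of a trajectory as a Structure
#' @param traj a Trajectory
#' @param frame frame index
#' @return a \linkS4class{Structure} with that frame's coordinates
#' @export
frameStructure <- function(traj, frame) {
  s <- traj@topology
  s@coords <- coords(traj, frame)
  s@label <- sprintf("%s frame %d", ifelse(is.na(s@label), "traj", s@label),
                     frame)
  s
}

#' Selection indices
#' @param sel a Selection
#' @return integer vector of atom indices
#' @export
selectionIndices <- function(sel) sel@indices

setMethod("show", "Structure", function(object) {
  cat(sprintf("Structure '%s': %d atoms, %d chains, %d residues\n",
              object@label, nAtoms(object),
              length(unique(object@atoms$chain)),
              nrow(unique(object@atoms[c("chain", "resid")]))))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory (replica %d): %d frames x %d atoms, frame spacing %g ps\n",
    object@replicaId, nFrames(object), nAtoms(object), object@frameSpacing))
})

setMethod("show", "Selection", function(object) {
  cat(sprintf("Selection '%s': %d atoms\n", object@expression,
              length(object@indices)))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: rmsd = %.4f A\n", object@rmsd))
})

setMethod("show", "PCAModel", function(object) {
  ef <- object@explainedFraction
  cat(sprintf(
    "PCAModel: %d components over %d atoms; PC1+PC2 explain %.1f%%\n",
    length(object@evals), length(object@atomIndices),
    100 * sum(ef[seq_len(min(2, length(ef)))])))
})

setMethod("show", "FreeEnergyLandscape", function(object) {
  cat(sprintf(
    "FreeEnergyLandscape: %d x %d bins, %d frames, T = %g K, max dG = %.3f kcal/mol\n",
    nrow(object@counts), ncol(object@counts), sum(object@counts),
    object@temperature, max(object@deltaG[is.finite(object@deltaG)])))
})

setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "DensityGrid '%s': %d x %d x %d voxels at %g A, %d frames (%d particles outside)\n",
    object@classLabel, d[1], d[2], d[3], object@spacing, object@nFrames,
    object@nOutside))
})

setMethod("show", "GateGeometrySeries", function(object) {
  cat(sprintf("GateGeometrySeries: measures [%s], %d replicas, %d frames each\n",
              paste(object@measures, collapse = ", "),
              length(unique(object@series$replica)),
              max(object@series$frame)))
})

setMethod("show", "RMSFProfile", function(object) {
  cat(sprintf("RMSFProfile: %d atoms, %d residues, mean residue RMSF %.3f A\n",
              nrow(object@atomTable), nrow(object@residueTable),
              mean(object@residueTable$rmsf)))
})
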