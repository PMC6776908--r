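#' @import methods
NULL

#' Structure: a single conformation with atom metadata
#'
#' Ordered atoms (serial, name, element, residue name/id, chain, mass) plus an
#' N x 3 coordinate matrix in Angstrom. The atom table and the coordinate
#' matrix are kept in lock-step; atom order is stable under read/write round
#' trips.
#'
#' @slot atoms data.frame with columns serial, name, element, resname, resid,
#'   chain, mass (one row per atom).
#' @slot coords numeric N x 3 matrix, Angstrom.
#' @slot label character scalar naming the structure.
#' @exportClass Structure
setClass("Structure",
  representation(atoms = "data.frame", coords = "matrix", label = "character"),
  prototype(atoms = data.frame(), coords = matrix(numeric(0), 0, 3),
            label = NA_character_))

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "resid", "chain", "mass")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) != nrow(object@coords))
    return("atoms and coords disagree on atom count")
  if (ncol(object@coords) != 3) return("coords must have 3 columns")
  if (nrow(a) > 0) {
    if (!all(is.finite(object@coords))) return("non-finite coordinates")
    if (!all(a$mass > 0)) return("all atom masses must be > 0")
    key <- paste(a$chain, a$resid, a$name)
    if (anyDuplicated(key))
      return(paste("duplicate (chain, resid, name) atom key:",
                   key[anyDuplicated(key)]))
  }
  TRUE
})

#' Trajectory: a topology plus F frames of coordinates
#'
#' @slot topology a \linkS4class{Structure}; its coordinates are frame 1 of
#'   the source by convention, but analyses use \code{frames} only.
#' @slot frames numeric array N x 3 x F, Angstrom.
#' @slot frameSpacing numeric, time between saved frames (ps; metadata only,
#'   default 200).
#' @slot replicaId integer replica index.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(topology = "Structure", frames = "array",
                 frameSpacing = "numeric", replicaId = "integer"),
  prototype(frameSpacing = 200, replicaId = 1L))

setValidity("Trajectory", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3 || d[2] != 3)
    return("frames must be an N x 3 x F array")
  if (d[1] != nAtoms(object@topology))
    return(sprintf("frames have %d atoms but topology has %d",
                   d[1], nAtoms(object@topology)))
  if (d[3] < 1) return("a Trajectory needs at least one frame")
  if (!all(is.finite(object@frames))) return("non-finite frame coordinates")
  TRUE
})

#' Selection: a resolved atom selection
#'
#' @slot expression the selection expression text.
#' @slot indices strictly increasing 1-based atom indices into the Structure
#'   the expression was resolved on.
#' @exportClass Selection
setClass("Selection",
  representation(expression = "character", indices = "integer"))

setValidity("Selection", function(object) {
  i <- object@indices
  if (length(i) && (any(i < 1) || is.unsorted(i, strictly = TRUE)))
    return("indices must be strictly increasing and >= 1")
  TRUE
})

#' HelixSpec: a declared transmembrane helix
#'
#' Helices are declared by chain and an inclusive residue range; the range
#' must span at least 8 residues so that both 4-residue terminal turns exist.
#'
#' @slot label helix name, e.g. "TMH7".
#' @slot chain chain identifier.
#' @slot firstResidue,lastResidue inclusive residue-id range (author
#'   numbering).
#' @exportClass HelixSpec
setClass("HelixSpec",
  representation(label = "character", chain = "character",
                 firstResidue = "integer", lastResidue = "integer"))

setValidity("HelixSpec", function(object) {
  if (object@lastResidue - object@firstResidue < 7L)
    return("a helix needs at least 8 residues (two 4-residue terminal turns)")
  TRUE
})

#' TurnSpec: one helical turn (4 consecutive residues)
#'
#' @slot chain chain identifier.
#' @slot residues exactly 4 consecutive residue ids.
#' @slot atomClass which atoms enter the center of mass: "all", "backbone"
#'   (N, CA, C, O) or "calpha".
#' @exportClass TurnSpec
setClass("TurnSpec",
  representation(chain = "character", residues = "integer",
                 atomClass = "character"),
  prototype(atomClass = "all"))

setValidity("TurnSpec", function(object) {
  r <- object@residues
  if (length(r) != 4L || any(diff(r) != 1L))
    return("a turn is exactly 4 consecutive residue ids")
  if (!object@atomClass %in% c("all", "backbone", "calpha"))
    return("atomClass must be one of all, backbone, calpha")
  TRUE
})

#' GatePairSpec: a pair of helical turns whose COM distance is tracked
#'
#' @slot label distance label (the lateral-gate set uses "I".."IV").
#' @slot turnA,turnB the two \linkS4class{TurnSpec}s.
#' @exportClass GatePairSpec
setClass("GatePairSpec",
  representation(label = "character", turnA = "TurnSpec", turnB = "TurnSpec"))

setValidity("GatePairSpec", function(object) {
  a <- object@turnA; b <- object@turnB
  if (identical(a@chain, b@chain) && identical(a@residues, b@residues) &&
      identical(a@atomClass, b@atomClass))
    return("turnA and turnB must differ")
  TRUE
})

#' FitResult: a proper rigid-body superposition
#'
#' @slot rotation 3 x 3 proper rotation (det = +1).
#' @slot translation length-3 vector, Angstrom.
#' @slot rmsd RMSD over the fitted atoms, Angstrom.
#' @exportClass FitResult
setClass("FitResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric"))

setValidity("FitResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3 x 3")
  if (abs(det(R) - 1) > 1e-6) return("rotation must be proper (det = +1)")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation must be orthonormal")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

#' DisplacementField: per-residue C-alpha displacement between two states
#'
#' @slot field data.frame with columns chain, resid, dx, dy, dz, magnitude
#'   (Angstrom), one row per matched residue.
#' @slot skipped data.frame of residues present in only one state.
#' @exportClass DisplacementField
setClass("DisplacementField",
  representation(field = "data.frame", skipped = "data.frame"))

setValidity("DisplacementField", function(object) {
  f <- object@field
  if (nrow(f)) {
    m <- sqrt(f$dx^2 + f$dy^2 + f$dz^2)
    if (max(abs(m - f$magnitude)) > 1e-9)
      return("magnitude must equal |vector| per residue")
  }
  TRUE
})

#' GateGeometrySeries: per-frame lateral-gate descriptors with histograms
#'
#' @slot series data.frame: replica, frame, time, then one column per
#'   measure (distances in Angstrom, eta in degrees).
#' @slot measures measure column names.
#' @slot reference named numeric, the starting-structure value per measure.
#' @slot histograms named list per measure: list(edges, mids, freq
#'   (bins x replicas relative frequencies), mean, sem).
#' @exportClass GateGeometrySeries
setClass("GateGeometrySeries",
  representation(series = "data.frame", measures = "character",
                 reference = "numeric", histograms = "list"))

setValidity("GateGeometrySeries", function(object) {
  for (m in object@measures) {
    h <- object@histograms[[m]]
    if (is.null(h)) return(paste("missing histogram for", m))
    s <- colSums(h$freq)
    if (any(abs(s - 1) > 1e-9))
      return("per-replica relative frequencies must sum to 1")
  }
  TRUE
})

#' RMSFProfile: atomic and residue-level root-mean-square fluctuations
#'
#' @slot atomTable data.frame: chain, resid, name, rmsf (Angstrom) per
#'   analyzed atom.
#' @slot residueTable data.frame: chain, resid, rmsf (mean over the residue's
#'   analyzed atoms), n_atoms.
#' @exportClass RMSFProfile
setClass("RMSFProfile",
  representation(atomTable = "data.frame", residueTable = "data.frame"))

setValidity("RMSFProfile", function(object) {
  if (nrow(object@atomTable) && any(object@atomTable$rmsf < 0))
    return("RMSF values must be >= 0")
  TRUE
})

#' PCAModel: Cartesian principal components of superposed coordinates
#'
#' Coordinates are flattened atom-major (x1, y1, z1, x2, ...) over the
#' analysis atoms after superposition of every frame onto the converged
#' average structure.
#'
#' @slot mean length-3n mean coordinate vector, Angstrom.
#' @slot evecs 3n x m orthonormal eigenvector matrix, descending eigenvalue
#'   order; sign fixed so each column's largest-magnitude entry is positive.
#' @slot evals eigenvalues, Angstrom^2, descending.
#' @slot explainedFraction evals / sum(evals).
#' @slot atomIndices analysis-atom indices into the topology.
#' @slot fitIndices fit-atom indices used for superposition.
#' @slot refCoords N x 3 average-structure coordinates (the superposition
#'   reference for projecting new frames).
#' @exportClass PCAModel
setClass("PCAModel",
  representation(mean = "numeric", evecs = "matrix", evals = "numeric",
                 explainedFraction = "numeric", atomIndices = "integer",
                 fitIndices = "integer", refCoords = "matrix"))

setValidity("PCAModel", function(object) {
  ev <- object@evals
  if (any(ev < -1e-8)) return("eigenvalues must be >= 0")
  if (is.unsorted(rev(ev))) return("eigenvalues must be sorted descending")
  G <- crossprod(object@evecs)
  if (max(abs(G - diag(ncol(object@evecs)))) > 1e-8)
    return("eigenvectors must be orthonormal")
  if (abs(sum(object@explainedFraction) - 1) > 1e-9)
    return("explained fractions must sum to 1")
  TRUE
})

#' FreeEnergyLandscape: Boltzmann-inverted 2D histogram over (PC1, PC2)
#'
#' Delta G per occupied bin is -R T ln(N_i / N_max) in kcal/mol, so the most
#' populated bin is exactly 0; unoccupied bins carry +Inf (undefined, never
#' 0).
#'
#' @slot xedges,yedges bin edges along PC1 and PC2.
#' @slot counts nx x ny integer bin populations.
#' @slot deltaG nx x ny free energies, kcal/mol (+Inf where counts == 0).
#' @slot temperature kelvin.
#' @slot gasConstant kcal mol^-1 K^-1.
#' @exportClass FreeEnergyLandscape
setClass("FreeEnergyLandscape",
  representation(xedges = "numeric", yedges = "numeric", counts = "matrix",
                 deltaG = "matrix", temperature = "numeric",
                 gasConstant = "numeric"))

setValidity("FreeEnergyLandscape", function(object) {
  occ <- object@counts > 0
  if (!any(occ)) return("landscape must contain at least one frame")
  dg <- object@deltaG[occ]
  if (min(dg) != 0) return("minimum over occupied bins must be exactly 0")
  if (any(dg < 0)) return("occupied-bin delta G must be >= 0")
  if (any(is.finite(object@deltaG[!occ])))
    return("unoccupied bins must be undefined (+Inf), never numeric")
  TRUE
})

#' DensityGrid: per-frame-normalized 3D occupancy of a particle class
#'
#' Voxel values are counts summed over frames divided by the number of
#' frames, so the grid sum equals the mean per-frame in-grid particle count.
#'
#' @slot origin grid origin (corner of voxel [1,1,1]), Angstrom.
#' @slot spacing voxel edge length, Angstrom.
#' @slot values nx x ny x nz array of mean occupancies.
#' @slot classLabel particle class, e.g. "PC headgroups".
#' @slot nFrames frames accumulated.
#' @slot nOutside particles that fell outside the extent (summed over
#'   frames; logged, not an error).
#' @exportClass DensityGrid
setClass("DensityGrid",
  representation(origin = "numeric", spacing = "numeric", values = "array",
                 classLabel = "character", nFrames = "integer",
                 nOutside = "integer"),
  prototype(classLabel = NA_character_, nOutside = 0L))

setValidity("DensityGrid", function(object) {
  if (length(dim(object@values)) != 3) return("values must be a 3D array")
  if (object@spacing <= 0) return("spacing must be positive")
  if (any(object@values < 0)) return("occupancies must be >= 0")
  TRUE
})
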