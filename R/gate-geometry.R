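#' Declare a helical turn
#'
#' @param chain chain id.
#' @param firstResidue first of 4 consecutive residue ids.
#' @param atomClass atoms entering the COM: "all" (default), "backbone"
#'   (N, CA, C, O) or "calpha".
#' @return a \linkS4class{TurnSpec}
#' @export
turnSpec <- function(chain, firstResidue, atomClass = "all") {
  new("TurnSpec", chain = as.character(chain),
      residues = as.integer(firstResidue) + 0:3, atomClass = atomClass)
}

#' Declare a transmembrane helix
#'
#' @param label helix name (e.g. "TMH7").
#' @param chain chain id.
#' @param firstResidue,lastResidue inclusive residue range (>= 8 residues).
#' @return a \linkS4class{HelixSpec}
#' @export
helixSpec <- function(label, chain, firstResidue, lastResidue) {
  new("HelixSpec", label = label, chain = as.character(chain),
      firstResidue = as.integer(firstResidue),
      lastResidue = as.integer(lastResidue))
}

#' Declare a turn-pair distance
#'
#' @param label distance label ("I".."IV" for the canonical lateral-gate
#'   set, or free text).
#' @param turnA,turnB the two \linkS4class{TurnSpec}s.
#' @return a \linkS4class{GatePairSpec}
#' @export
gatePairSpec <- function(label, turnA, turnB) {
  new("GatePairSpec", label = label, turnA = turnA, turnB = turnB)
}

.turnIndices <- function(atoms, spec) {
  idx <- which(atoms$chain == spec@chain & atoms$resid %in% spec@residues)
  idx <- switch(spec@atomClass,
    all = idx,
    backbone = idx[atoms$name[idx] %in% .BACKBONE_NAMES],
    calpha = idx[atoms$name[idx] == "CA"])
  present <- unique(atoms$resid[idx])
  missing <- setdiff(spec@residues, present)
  if (length(missing)) {
    stop(sprintf("turn spec (chain %s): no %s atoms for residue %d",
                 spec@chain, spec@atomClass, missing[1]), call. = FALSE)
  }
  idx
}

.comOf <- function(xyz, masses) {
  colSums(xyz * masses) / sum(masses)
}

#' Mass-weighted center of mass of a helical turn
#'
#' @param x a \linkS4class{Structure}, or an N x 3 coordinate matrix with
#'   \code{atoms} supplied.
#' @param spec a \linkS4class{TurnSpec}.
#' @param atoms atom table (only when \code{x} is a bare matrix).
#' @return length-3 COM, Angstrom
#' @export
turnCOM <- function(x, spec, atoms = NULL) {
  if (is(x, "Structure")) { atoms <- x@atoms; xyz <- coords(x) }
  else xyz <- as.matrix(x)
  idx <- .turnIndices(atoms, spec)
  .comOf(xyz[idx, , drop = FALSE], atoms$mass[idx])
}

#' Per-frame distance between two turn centers of mass
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param pair a \linkS4class{GatePairSpec}.
#' @return numeric vector, one Euclidean COM distance (Angstrom) per frame;
#'   the first value is the starting-structure reference by construction
#' @export
pairDistanceSeries <- function(traj, pair) {
  atoms <- atomData(traj)
  ia <- .turnIndices(atoms, pair@turnA)
  ib <- .turnIndices(atoms, pair@turnB)
  ma <- atoms$mass[ia]; mb <- atoms$mass[ib]
  vapply(seq_len(nFrames(traj)), function(f) {
    xyz <- coords(traj, f)
    sqrt(sum((.comOf(xyz[ia, , drop = FALSE], ma) -
              .comOf(xyz[ib, , drop = FALSE], mb))^2))
  }, numeric(1))
}

#' Helix axis unit vector from terminal-turn backbone COMs
#'
#' The axis runs from the backbone (N, CA, C, O) center of mass of the first
#' four residues to that of the last four residues, so its orientation
#' follows the residue order (N to C terminus).
#'
#' @param x a Structure, or coordinate matrix with \code{atoms}.
#' @param helix a \linkS4class{HelixSpec}.
#' @param atoms atom table (bare-matrix case).
#' @param atomClass atom class for the terminal-turn COMs ("backbone"
#'   default; "calpha" supports C-alpha-only models).
#' @return unit 3-vector
#' @export
helixVector <- function(x, helix, atoms = NULL, atomClass = "backbone") {
  if (is(x, "Structure")) { atoms <- x@atoms; xyz <- coords(x) }
  else xyz <- as.matrix(x)
  headTurn <- new("TurnSpec", chain = helix@chain,
                  residues = helix@firstResidue + 0:3, atomClass = atomClass)
  tailTurn <- new("TurnSpec", chain = helix@chain,
                  residues = helix@lastResidue - 3:0, atomClass = atomClass)
  a <- turnCOM(xyz, headTurn, atoms)
  b <- turnCOM(xyz, tailTurn, atoms)
  v <- b - a
  n <- sqrt(sum(v^2))
  if (n < 1e-9) stop("degenerate helix axis (zero length)", call. = FALSE)
  v / n
}

.angleDeg <- function(u, v) {
  c <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, c))) * 180 / pi
}

#' Inter-helix angle eta
#'
#' The angle between the axis vectors of two helices (each drawn between the
#' backbone COMs of its terminal four residues), reported in [0, 180]
#' degrees. For the SecY lateral gate this is the angle between TMH 7 and
#' TMH 8.
#'
#' @param x a Structure, or coordinate matrix with \code{atoms}.
#' @param helix7,helix8 \linkS4class{HelixSpec}s.
#' @param atoms atom table (bare-matrix case).
#' @param atomClass atom class for the axis COMs.
#' @return angle in degrees
#' @export
etaAngle <- function(x, helix7, helix8, atoms = NULL,
                     atomClass = "backbone") {
  .angleDeg(helixVector(x, helix7, atoms, atomClass),
            helixVector(x, helix8, atoms, atomClass))
}

#' Helix (or hairpin) tilt against a membrane normal
#'
#' For a single helix the tilt is the angle between its axis and the normal,
#' folded into [0, 90] degrees. For a helical hairpin (two antiparallel
#' helices, e.g. the SecE transmembrane hairpin) the shared long axis is
#' taken as (v1 - v2)/|v1 - v2|; a near-parallel pair passed as a hairpin is
#' a degenerate-axis error.
#'
#' @param structure a \linkS4class{Structure}.
#' @param helices one \linkS4class{HelixSpec} or a list of two (hairpin).
#' @param normal membrane normal (any nonzero 3-vector).
#' @param atomClass atom class for the axis COMs.
#' @return tilt angle in degrees, in [0, 90]
#' @export
helixTilt <- function(structure, helices, normal, atomClass = "backbone") {
  if (sqrt(sum(normal^2)) < 1e-12)
    stop("membrane normal must be nonzero", call. = FALSE)
  if (is(helices, "HelixSpec")) helices <- list(helices)
  if (length(helices) == 1) {
    axis <- helixVector(structure, helices[[1]], atomClass = atomClass)
  } else {
    v1 <- helixVector(structure, helices[[1]], atomClass = atomClass)
    v2 <- helixVector(structure, helices[[2]], atomClass = atomClass)
    d <- v1 - v2
    n <- sqrt(sum(d^2))
    if (n < 1e-6)
      stop("degenerate hairpin axis: the two helices are parallel",
           call. = FALSE)
    axis <- d / n
  }
  ang <- .angleDeg(axis, normal)
  if (ang > 90) ang <- 180 - ang
  ang
}

#' Membrane normal estimated from a transmembrane helix bundle
#'
#' The sign-aligned mean of the axis vectors of the declared helices: every
#' axis is flipped, if needed, onto the hemisphere of the first helix's
#' axis, and the normalized mean is returned. Membrane-spanning helices all
#' run roughly along the bilayer normal, so their consensus axis is a
#' stable estimate even for wide, flat bundles where a global inertia
#' tensor would pick an in-plane axis. The sign follows the first declared
#' helix (N-to-C); orient against a known reference residue if a signed
#' normal is needed.
#'
#' @param structure a \linkS4class{Structure}.
#' @param helices list of \linkS4class{HelixSpec}s forming the bundle.
#' @param atomClass atom class for the helix-axis COMs ("backbone" default;
#'   "calpha" supports C-alpha-only models).
#' @return unit 3-vector
#' @export
membraneNormal <- function(structure, helices, atomClass = "backbone") {
  stopifnot(length(helices) >= 1)
  axes <- vapply(helices, function(h)
    helixVector(structure, h, atomClass = atomClass), numeric(3))
  axes <- matrix(axes, nrow = 3)
  for (j in seq_len(ncol(axes))) {
    if (sum(axes[, j] * axes[, 1]) < 0) axes[, j] <- -axes[, j]
  }
  v <- rowMeans(axes)
  n <- sqrt(sum(v^2))
  if (n < 1e-6)
    stop("helix axes cancel: cannot define a bundle normal", call. = FALSE)
  v / n
}

.relFreqHist <- function(values, edges) {
  h <- hist(values, breaks = edges, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  h$counts / length(values)
}

#' Lateral-gate descriptor series over replicas, with histogram summaries
#'
#' Computes the turn-pair COM distances and (optionally) the inter-helix
#' angle eta per frame and replica, then summarizes each measure as a
#' histogram of per-replica relative frequencies with the mean and the
#' standard error of the mean (sd/sqrt(n)) per bin over replicas. The
#' starting-structure value of each measure is reported alongside (the
#' reference-line convention of the per-measure histograms).
#'
#' @param trajectories a Trajectory or list of Trajectories (replicas) with
#'   a shared topology.
#' @param pairs list of \linkS4class{GatePairSpec}s (may be empty).
#' @param helices optional list of two \linkS4class{HelixSpec}s for eta.
#' @param bins number of histogram bins (default 50, spanning the pooled
#'   min-max range padded by 2 percent).
#' @param reference optional starting \linkS4class{Structure}; defaults to
#'   frame 1 of replica 1.
#' @return a \linkS4class{GateGeometrySeries}
#' @export
gateSeries <- function(trajectories, pairs = list(), helices = NULL,
                       bins = 50L, reference = NULL) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1)
  atoms <- atomData(trajectories[[1]])
  measures <- vapply(pairs, function(p) p@label, character(1))
  if (!is.null(helices)) measures <- c(measures, "eta")

  rows <- list()
  for (r in seq_along(trajectories)) {
    traj <- trajectories[[r]]
    df <- data.frame(replica = traj@replicaId,
                     frame = seq_len(nFrames(traj)),
                     time = (seq_len(nFrames(traj)) - 1) * traj@frameSpacing)
    for (p in pairs) df[[p@label]] <- pairDistanceSeries(traj, p)
    if (!is.null(helices)) {
      df$eta <- vapply(seq_len(nFrames(traj)), function(f)
        etaAngle(coords(traj, f), helices[[1]], helices[[2]], atoms),
        numeric(1))
    }
    rows[[r]] <- df
  }
  series <- do.call(rbind, rows)

  refStruct <- if (is.null(reference))
    frameStructure(trajectories[[1]], 1L) else reference
  reference <- vapply(seq_along(measures), function(i) {
    m <- measures[i]
    if (m == "eta") {
      etaAngle(refStruct, helices[[1]], helices[[2]])
    } else {
      p <- pairs[[which(vapply(pairs, function(q) q@label,
                               character(1)) == m)]]
      sqrt(sum((turnCOM(refStruct, p@turnA) - turnCOM(refStruct, p@turnB))^2))
    }
  }, numeric(1))
  names(reference) <- measures

  nRep <- length(trajectories)
  histograms <- lapply(measures, function(m) {
    v <- series[[m]]
    rng <- range(v)
    pad <- if (diff(rng) > 0) 0.02 * diff(rng) else 0.5
    edges <- seq(rng[1] - pad, rng[2] + pad, length.out = bins + 1L)
    freq <- vapply(rows, function(df) .relFreqHist(df[[m]], edges),
                   numeric(bins))
    freq <- matrix(freq, nrow = bins)
    list(edges = edges, mids = (edges[-1] + edges[-length(edges)]) / 2,
         freq = freq, mean = rowMeans(freq),
         sem = if (nRep >= 2) apply(freq, 1, sd) / sqrt(nRep)
               else rep(NA_real_, bins))
  })
  names(histograms) <- measures

  new("GateGeometrySeries", series = series, measures = measures,
      reference = reference, histograms = histograms)
}

#' Per-frame series of a GateGeometrySeries
#' @param x a GateGeometrySeries
#' @return data.frame replica, frame, time, one column per measure
#' @export
gateTable <- function(x) {
  stopifnot(is(x, "GateGeometrySeries"))
  x@series
}

#' Histogram summary of one gate measure
#' @param x a GateGeometrySeries
#' @param measure measure name
#' @return list(edges, mids, freq, mean, sem)
#' @export
gateHistogram <- function(x, measure) {
  stopifnot(is(x, "GateGeometrySeries"))
  h <- x@histograms[[measure]]
  if (is.null(h)) stop("no such measure: ", measure, call. = FALSE)
  h
}
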