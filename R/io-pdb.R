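# Atomic masses (u) for element inference; extend as needed.
.ATOMIC_MASS <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  NA_ = 22.990, MG = 24.305, P = 30.974, S = 32.06, CL = 35.45, K = 39.098,
  CA = 40.078, MN = 54.938, FE = 55.845, CO = 58.933, NI = 58.693,
  CU = 63.546, ZN = 65.38, SE = 78.971, BR = 79.904, I = 126.904
)

.massOf <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA_"
  m <- .ATOMIC_MASS[key]
  m[is.na(m)] <- 12.011  # unknown elements fall back to carbon mass
  unname(m)
}

# Element from a PDB atom-name field when the element column is blank.
# PDB v3.3: names of one-letter elements start in column 14; a name starting
# in column 13 whose first two characters form a known element is two-letter.
.elementFromName <- function(rawName) {
  vapply(rawName, function(nm) {
    two <- toupper(substr(nm, 1, 2))
    if (substr(nm, 1, 1) != " " && two %in%
        c("FE", "ZN", "MG", "MN", "CU", "NI", "CO", "SE", "BR", "CL", "NA",
          "CA", "K ")) {
      return(trimws(two))
    }
    ch <- gsub("[^A-Za-z]", "", nm)
    if (nchar(ch) == 0) return("C")
    toupper(substr(ch, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

#' Build a Structure from atom fields
#'
#' Low-level constructor used by the readers and the synthetic generators.
#' Masses are inferred from the element via a fixed internal table.
#'
#' @param name atom names (e.g. "CA").
#' @param resname residue names.
#' @param resid integer residue ids (author numbering preserved).
#' @param chain chain ids.
#' @param coords N x 3 coordinate matrix, Angstrom.
#' @param element element symbols; inferred from \code{name} when missing.
#' @param serial atom serial numbers; defaults to 1..N.
#' @param label structure label.
#' @return a \linkS4class{Structure}
#' @export
makeStructure <- function(name, resname, resid, chain, coords,
                          element = NULL, serial = NULL,
                          label = NA_character_) {
  n <- length(name)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (is.null(element)) {
    # bare names are taken as standard biopolymer names (one-letter element
    # starting in PDB column 14), so "CA" is a C-alpha carbon, not calcium
    element <- .elementFromName(ifelse(nchar(name) <= 3,
                                       paste0(" ", name), name))
  }
  if (is.null(serial)) serial <- seq_len(n)
  atoms <- data.frame(
    serial = as.integer(serial), name = trimws(name),
    element = toupper(trimws(element)), resname = trimws(resname),
    resid = as.integer(resid), chain = as.character(chain),
    mass = .massOf(element), stringsAsFactors = FALSE)
  new("Structure", atoms = atoms, coords = coords, label = label)
}

.parsePDBModels <- function(lines, path) {
  isAtom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  modelStarts <- which(startsWith(lines, "MODEL"))
  if (length(modelStarts) == 0) {
    groups <- list(which(isAtom))
  } else {
    ends <- c(modelStarts[-1] - 1L, length(lines))
    groups <- lapply(seq_along(modelStarts), function(i) {
      idx <- modelStarts[i]:ends[i]
      idx[isAtom[idx]]
    })
    groups <- groups[lengths(groups) > 0]
  }
  lapply(groups, function(idx) .parseAtomLines(lines[idx], idx, path))
}

.parseAtomLines <- function(ln, lineNo, path) {
  sub <- function(a, b) substr(ln, a, b)
  num <- function(a, b, what) {
    txt <- sub(a, b)
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v) | !nzchar(trimws(txt)))
    if (length(bad)) {
      stop(sprintf("malformed %s field in '%s' at line %d: '%s'",
                   what, path, lineNo[bad[1]], trimws(txt[bad[1]])),
           call. = FALSE)
    }
    v
  }
  rawName <- sub(13, 16)
  element <- trimws(sub(77, 78))
  blank <- !nzchar(element)
  if (any(blank)) element[blank] <- .elementFromName(rawName[blank])
  makeStructure(
    name = trimws(rawName),
    resname = sub(18, 20),
    resid = as.integer(num(23, 26, "residue number")),
    chain = trimws(sub(22, 22)),
    coords = cbind(num(31, 38, "x coordinate"),
                   num(39, 46, "y coordinate"),
                   num(47, 54, "z coordinate")),
    element = element,
    serial = suppressWarnings(as.integer(sub(7, 11))),
    label = basename(path))
}

#' Read a PDB file
#'
#' Fixed-column PDB v3.3 ATOM/HETATM records. MODEL/ENDMDL blocks yield one
#' Structure each under \code{modelPolicy = "all"}; residue and chain
#' identifiers are preserved verbatim, coordinates to 0.001 Angstrom.
#'
#' @param path PDB file path.
#' @param modelPolicy "first" (default) returns a single
#'   \linkS4class{Structure}; "all" returns a list with one Structure per
#'   model.
#' @return a Structure or a list of Structures
#' @export
readPDB <- function(path, modelPolicy = c("first", "all")) {
  modelPolicy <- match.arg(modelPolicy)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  models <- .parsePDBModels(readLines(path, warn = FALSE), path)
  if (length(models) == 0) stop("no ATOM/HETATM records in ", path,
                                call. = FALSE)
  if (modelPolicy == "first") models[[1]] else models
}

.formatAtomName <- function(name, element) {
  # one-letter-element names of < 4 chars start in column 14
  ifelse(nchar(name) >= 4 | nchar(element) >= 2,
         formatC(name, width = -4), paste0(" ", formatC(name, width = -3)))
}

.pdbAtomLines <- function(s) {
  a <- s@atoms; xyz <- s@coords
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial %% 100000L, .formatAtomName(a$name, a$element),
          a$resname, a$chain, a$resid, xyz[, 1], xyz[, 2], xyz[, 3],
          1, 0, a$element)
}

#' Write a Structure (or list of Structures) as PDB
#'
#' A list is written as a multi-model PDB (MODEL/ENDMDL blocks), the
#' trajectory container used throughout.
#'
#' @param x a Structure or list of Structures sharing one topology.
#' @param path output path.
#' @param bfactor optional numeric per-atom values written to the B-factor
#'   column (e.g. residue RMSF for 3D coloring).
#' @return \code{path}, invisibly
#' @export
writePDB <- function(x, path, bfactor = NULL) {
  if (is(x, "Structure")) {
    lines <- .pdbAtomLines(x)
    if (!is.null(bfactor)) {
      stopifnot(length(bfactor) == nAtoms(x))
      substr(lines, 61, 66) <- sprintf("%6.2f", pmin(bfactor, 999.99))
    }
    writeLines(c(lines, "END"), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(x)) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(.pdbAtomLines(x[[i]]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Read a trajectory from multi-model PDB or plain XYZ text
#'
#' The format is chosen by extension (".xyz" for XYZ, anything else is
#' multi-model PDB). Every frame must match the topology's atom count.
#'
#' @param path trajectory file.
#' @param topology the \linkS4class{Structure} the frames belong to.
#' @param frameSpacing time between frames, ps (metadata; default 200).
#' @param replicaId replica index (metadata).
#' @return a \linkS4class{Trajectory}
#' @export
readTrajectory <- function(path, topology, frameSpacing = 200,
                           replicaId = 1L) {
  n <- nAtoms(topology)
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    frameList <- .readXYZFrames(path)
  } else {
    models <- readPDB(path, modelPolicy = "all")
    if (is(models, "Structure")) models <- list(models)
    frameList <- lapply(models, coords)
  }
  for (f in seq_along(frameList)) {
    if (nrow(frameList[[f]]) != n) {
      stop(sprintf(
        "topology mismatch in '%s': frame %d has %d atoms, topology has %d",
        path, f, nrow(frameList[[f]]), n), call. = FALSE)
    }
  }
  frames <- array(unlist(frameList), dim = c(n, 3, length(frameList)))
  new("Trajectory", topology = topology, frames = frames,
      frameSpacing = frameSpacing, replicaId = as.integer(replicaId))
}

.readXYZFrames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop(sprintf("malformed XYZ atom count in '%s' at line %d",
                               path, i), call. = FALSE)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      stop(sprintf("malformed XYZ coordinate in '%s' near line %d", path, i),
           call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  frames
}

#' Write a Trajectory
#'
#' Multi-model PDB by default; plain XYZ text when \code{path} ends in
#' ".xyz" (per frame: atom count, comment, then "element x y z" lines).
#'
#' @param traj a Trajectory.
#' @param path output path.
#' @return \code{path}, invisibly
#' @export
writeTrajectory <- function(traj, path) {
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    el <- traj@topology@atoms$element
    for (f in seq_len(nFrames(traj))) {
      xyz <- coords(traj, f)
      writeLines(as.character(nrow(xyz)), con)
      writeLines(sprintf("frame %d", f), con)
      writeLines(sprintf("%s %.6f %.6f %.6f", el, xyz[, 1], xyz[, 2],
                         xyz[, 3]), con)
    }
  } else {
    structures <- lapply(seq_len(nFrames(traj)),
                         function(f) frameStructure(traj, f))
    writePDB(structures, path)
  }
  invisible(path)
}
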