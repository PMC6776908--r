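#' Protein-frame-aligned 3D occupancy density grid
#'
#' Frames are superposed on the fit selection (the protein frame) before
#' binning; per-voxel counts of the particle selection are summed over
#' frames and divided by the frame count, so the densities are normalized to
#' the number of considered conformations. Particles outside the extent are
#' counted and logged, never errors.
#'
#' @param traj a \linkS4class{Trajectory} containing both the reference
#'   atoms and the particles.
#' @param particleSelection atoms to bin (e.g. lipid head-group class).
#' @param fitSelection atoms defining the protein frame; NULL skips
#'   superposition (the frames are used as-is).
#' @param spacing voxel edge length, Angstrom (default 1.0).
#' @param extent list(min, max) of 3-vectors; default is the bounding box of
#'   the fitted fit-selection atoms padded 15 Angstrom, or of the particles
#'   when there is no fit selection.
#' @param classLabel label stored on the grid.
#' @return a \linkS4class{DensityGrid}
#' @export
densityGrid <- function(traj, particleSelection, fitSelection = NULL,
                        spacing = 1.0, extent = NULL,
                        classLabel = NA_character_) {
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  topo <- traj@topology
  pIdx <- .asIndices(topo, particleSelection)
  if (length(pIdx) == 0) stop("empty particle selection", call. = FALSE)

  work <- if (!is.null(fitSelection)) {
    superposeTrajectory(traj, fitSelection = fitSelection)
  } else traj
  nF <- nFrames(work)

  if (is.null(extent)) {
    refIdx <- if (!is.null(fitSelection)) .asIndices(topo, fitSelection)
              else pIdx
    pad <- if (!is.null(fitSelection)) 15 else spacing
    sub <- work@frames[refIdx, , , drop = FALSE]
    extent <- list(min = apply(sub, 2, min) - pad,
                   max = apply(sub, 2, max) + pad)
  }
  lo <- as.numeric(extent$min); hi <- as.numeric(extent$max)
  shape <- pmax(1L, as.integer(ceiling((hi - lo) / spacing - 1e-9)))

  counts <- array(0, dim = shape)
  outside <- 0L
  for (f in seq_len(nF)) {
    xyz <- coords(work, f)[pIdx, , drop = FALSE]
    v <- floor(sweep(xyz, 2, lo) / spacing) + 1
    ok <- v[, 1] >= 1 & v[, 1] <= shape[1] &
          v[, 2] >= 1 & v[, 2] <= shape[2] &
          v[, 3] >= 1 & v[, 3] <= shape[3]
    outside <- outside + sum(!ok)
    if (any(ok)) {
      lin <- (v[ok, 3] - 1) * shape[1] * shape[2] +
             (v[ok, 2] - 1) * shape[1] + v[ok, 1]
      t <- table(lin)
      counts[as.integer(names(t))] <- counts[as.integer(names(t))] +
        as.integer(t)
    }
  }
  if (outside > 0) {
    message(sprintf("densityGrid: %d particle positions fell outside the extent",
                    outside))
  }
  new("DensityGrid", origin = lo, spacing = spacing, values = counts / nF,
      classLabel = classLabel, nFrames = as.integer(nF),
      nOutside = as.integer(outside))
}

#' Write a DensityGrid as an OpenDX scalar field
#'
#' Plain-text OpenDX: gridpositions counts, origin, three delta records and
#' the data array with z varying fastest and x slowest (the OpenDX
#' standard ordering). Round-trips through \code{readDX} to 1e-6.
#'
#' @param grid a \linkS4class{DensityGrid}.
#' @param path output path.
#' @return \code{path}, invisibly
#' @export
writeDX <- function(grid, path) {
  d <- dim(grid@values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    if (!is.na(grid@classLabel))
      sprintf("# OpenDX density: %s (%d frames)", grid@classLabel,
              grid@nFrames),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid@origin[1], grid@origin[2],
            grid@origin[3]),
    sprintf("delta %.6f 0 0", grid@spacing),
    sprintf("delta 0 %.6f 0", grid@spacing),
    sprintf("delta 0 0 %.6f", grid@spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2],
            d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  vals <- as.numeric(aperm(grid@values, c(3, 2, 1)))  # z fastest, x slowest
  full <- length(vals) - length(vals) %% 3L
  if (full > 0) {
    m <- matrix(vals[seq_len(full)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.6g %.6g %.6g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (full < length(vals)) {
    writeLines(paste(sprintf("%.6g", vals[(full + 1):length(vals)]),
                     collapse = " "), con)
  }
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field back into a DensityGrid
#'
#' @param path an OpenDX file written by \code{\link{writeDX}} (regular
#'   grid, diagonal deltas with one shared spacing).
#' @return a \linkS4class{DensityGrid}
#' @export
readDX <- function(path) {
  lines <- readLines(path, warn = FALSE)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  d <- as.integer(strsplit(trimws(sub(".*counts", "", gp)),
                           "[[:space:]]+")[[1]])
  og <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", og)),
                                "[[:space:]]+")[[1]])
  dl <- grep("^delta", lines, value = TRUE)
  dmat <- t(vapply(dl, function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)),
                        "[[:space:]]+")[[1]]), numeric(3)))
  spacing <- max(dmat)
  start <- grep("data follows", lines)[1] + 1L
  vals <- numeric(0)
  i <- start
  need <- prod(d)
  while (length(vals) < need && i <= length(lines)) {
    if (grepl("^(attribute|object|component)", lines[i])) break
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]),
                                        "[[:space:]]+")[[1]]))
    i <- i + 1L
  }
  if (length(vals) != need)
    stop(sprintf("OpenDX data block in '%s' has %d values, expected %d",
                 path, length(vals), need), call. = FALSE)
  arr <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  new("DensityGrid", origin = origin, spacing = spacing, values = arr,
      classLabel = {
        cm <- grep("^# OpenDX density", lines, value = TRUE)
        if (length(cm)) gsub(" \\([0-9]+ frames\\)$", "",
                             sub("^# OpenDX density: ", "", cm[1]))
        else NA_character_
      },
      nFrames = 1L, nOutside = 0L)
}
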