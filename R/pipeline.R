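# Orchestration: config-driven end-to-end runs. One config = one run = one
# output directory. Deterministic stages are byte-reproducible under a fixed
# config; stochastic stages under a fixed seed.

#' Write a data.frame as TSV with '#' provenance header lines
#'
#' @param df data.frame.
#' @param path output path.
#' @param header character vector of comment lines (written as "# ...").
#' @return \code{path}, invisibly
#' @export
writeTSV <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{writeTSV}
#' @param path file path.
#' @return data.frame (comment lines skipped)
#' @export
readTSV <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

.configHash <- function(config) {
  config$output_dir <- NULL  # hash the scientific content, not the run path
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config)), tmp)
  unname(tools::md5sum(tmp))
}

.provenance <- function(config, stage) {
  c(sprintf("gatescope %s | stage: %s",
            as.character(utils::packageVersion("gatescope")), stage),
    sprintf("config_hash: %s", .configHash(config)),
    sprintf("seed: %s", config$seed %||% "NA"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from a YAML file
#'
#' @param path YAML mapping; see \code{\link{runPipeline}} for the keys.
#' @return a named list (class "gatescope_config")
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "gatescope_config")
}

.logStage <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the analysis pipeline from a configuration
#'
#' Stages run in dependency order: \code{synth} (or trajectory input) first,
#' then any of \code{rmsf}, \code{gate}, \code{pca}, \code{density}. Every
#' output TSV carries a provenance header (package version, config hash,
#' seed) and a summary report collects the per-stage headline numbers.
#'
#' Config keys: \code{seed}; \code{output_dir}; \code{stages} (character
#' vector); either \code{trajectories} (list of list(path, topology)) or
#' \code{synth} (list with \code{mode} = harmonic | two_state | gate_toy |
#' lipid_field plus the generator's parameters); \code{fit} / \code{analyze}
#' selection expressions; \code{gate} (turns, helices, bins); \code{pca}
#' (bins, temperature); \code{density} (particles, spacing).
#'
#' @param config a named list or a \code{\link{readRunConfig}} result.
#' @return the output directory, invisibly; the summary is written to
#'   \code{summary.txt} and \code{run.log} inside it
#' @export
runPipeline <- function(config) {
  outDir <- config$output_dir %||% stop("config needs output_dir")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logCon <- file(file.path(outDir, "run.log"), "w")
  on.exit(close(logCon))
  seed <- config$seed %||% 1L
  stages <- config$stages %||% character(0)
  summary <- c(sprintf("gatescope run (seed %s)", seed))

  fail <- function(stage, code, e) {
    .logStage(logCon, "[%s] ERROR %s: %s", stage, code, conditionMessage(e))
    stop(sprintf("pipeline stage '%s' failed [%s]: %s", stage, code,
                 conditionMessage(e)), call. = FALSE)
  }

  ## --- inputs: synthetic generation or trajectory files ------------------
  trajs <- NULL
  synthExtras <- list()
  if (!is.null(config$synth)) {
    s <- config$synth
    .logStage(logCon, "[synth] mode %s", s$mode)
    trajs <- tryCatch(switch(s$mode,
      harmonic = {
        ref <- makeIdealHelix(s$n_res %||% 20L)
        makeHarmonicTrajectory(ref, s$sigma %||% 1.0,
                               s$frames %||% 500L, s$replicas %||% 5L,
                               seed = seed)
      },
      two_state = {
        ref <- makeIdealHelix(s$n_res %||% 20L)
        ts <- makeTwoStateTrajectory(ref, separation = s$separation %||% 8,
                                     pMajor = s$p_major %||% 0.8,
                                     noiseSigma = s$noise_sigma %||% 0.5,
                                     nFrames = s$frames %||% 500L,
                                     nReplicas = s$replicas %||% 5L,
                                     seed = seed)
        synthExtras$labels <- ts$labels
        ts$trajectories
      },
      gate_toy = {
        toy <- makeGateToy(s$angles, s$distances)
        synthExtras$toy <- toy
        list(toy$trajectory)
      },
      lipid_field = {
        lf <- makeLipidField(s$particles %||% 2000L, s$frames %||% 100L,
                             hotspot = s$hotspot, seed = seed)
        synthExtras$classes <- lf$classes
        list(lf$trajectory)
      },
      stop("unknown synth mode: ", s$mode)),
      error = function(e) fail("synth", "E_SYNTH", e))
    for (i in seq_along(trajs)) {
      writeTrajectory(trajs[[i]],
                      file.path(outDir, sprintf("synth_r%d.pdb", i)))
    }
    summary <- c(summary, sprintf("synth: %d replica(s) x %d frames (%s)",
                                  length(trajs), nFrames(trajs[[1]]),
                                  s$mode))
  } else if (!is.null(config$trajectories)) {
    trajs <- tryCatch(lapply(seq_along(config$trajectories), function(i) {
      t <- config$trajectories[[i]]
      topo <- readPDB(t$topology %||% t$path)
      readTrajectory(t$path, topo, replicaId = i)
    }), error = function(e) fail("input", "E_INPUT", e))
  }
  if (is.null(trajs) && length(intersect(stages,
      c("rmsf", "gate", "pca", "density")))) {
    stop("pipeline needs trajectories (synth config or trajectory paths)",
         call. = FALSE)
  }

  fitSel <- config$fit %||% NULL
  anaSel <- config$analyze %||% NULL

  ## --- rmsf --------------------------------------------------------------
  if ("rmsf" %in% stages) {
    profiles <- tryCatch(lapply(trajs, rmsf, fitSelection = fitSel,
                                analysisSelection = anaSel),
                         error = function(e) fail("rmsf", "E_RMSF", e))
    pooled <- poolRMSF(profiles)
    writeTSV(pooled, file.path(outDir, "rmsf.tsv"),
             .provenance(config, "rmsf"))
    .logStage(logCon, "[rmsf] %d residues over %d replica(s)",
              nrow(pooled), length(profiles))
    summary <- c(summary, sprintf(
      "rmsf: residue mean %.3f A (min %.3f, max %.3f)",
      mean(pooled$rmsf_mean), min(pooled$rmsf_mean), max(pooled$rmsf_mean)))
  }

  ## --- gate geometry ------------------------------------------------------
  if ("gate" %in% stages) {
    g <- config$gate %||% list()
    pairs <- lapply(g$pairs %||% list(), function(p) {
      gatePairSpec(p$label,
                   turnSpec(p$chain_a, p$first_a, p$atom_class %||% "all"),
                   turnSpec(p$chain_b, p$first_b, p$atom_class %||% "all"))
    })
    helices <- if (!is.null(g$helices)) {
      lapply(g$helices, function(h)
        helixSpec(h$label, h$chain, h$first, h$last))
    }
    gs <- tryCatch(gateSeries(trajs, pairs, helices,
                              bins = g$bins %||% 50L),
                   error = function(e) fail("gate", "E_GATE", e))
    writeTSV(gateTable(gs), file.path(outDir, "gate_series.tsv"),
             .provenance(config, "gate"))
    hrows <- do.call(rbind, lapply(gs@measures, function(m) {
      h <- gateHistogram(gs, m)
      data.frame(measure = m, mid = h$mids, mean_freq = h$mean,
                 sem = h$sem)
    }))
    writeTSV(hrows, file.path(outDir, "gate_hist.tsv"),
             .provenance(config, "gate"))
    for (m in gs@measures) {
      v <- gs@series[[m]]
      summary <- c(summary, sprintf(
        "gate %s: min %.2f, max %.2f (start %.2f)", m, min(v), max(v),
        gs@reference[m]))
    }
  }

  ## --- pca + landscape ----------------------------------------------------
  if ("pca" %in% stages) {
    p <- config$pca %||% list()
    model <- tryCatch(fitPCA(trajs, fitSelection = fitSel,
                             analysisSelection = anaSel),
                      error = function(e) fail("pca", "E_PCA", e))
    writeTSV(pcaSpectrum(model), file.path(outDir, "pca_spectrum.tsv"),
             .provenance(config, "pca"))
    proj <- do.call(rbind, lapply(trajs, function(t) {
      pr <- projectOnto(t, model, k = 2L)
      data.frame(replica = t@replicaId, frame = seq_len(nrow(pr)),
                 pc1 = pr[, 1], pc2 = pr[, 2])
    }))
    writeTSV(proj, file.path(outDir, "pca_projections.tsv"),
             .provenance(config, "pca"))
    fel <- freeEnergyLandscape(as.matrix(proj[c("pc1", "pc2")]),
                               bins = p$bins %||% c(100L, 100L),
                               temperature = p$temperature %||% 300)
    lt <- landscapeTable(fel)
    lt$delta_g <- ifelse(is.finite(lt$delta_g),
                         sprintf("%.6g", lt$delta_g), "inf")
    writeTSV(lt, file.path(outDir, "landscape.tsv"),
             .provenance(config, "pca"))
    rep <- representativeConformation(trajs, model, fel)
    writePDB(rep$structure, file.path(outDir, "representative.pdb"))
    arrows <- pcDisplacementVectors(model, trajs[[1]]@topology,
                                    component = 1L,
                                    cutoff = p$cutoff %||% 0)
    writeTSV(arrows, file.path(outDir, "pc1_arrows.tsv"),
             .provenance(config, "pca"))
    ef <- model@explainedFraction
    dgFinite <- fel@deltaG[is.finite(fel@deltaG)]
    summary <- c(summary,
      sprintf("pca: PC1+PC2 explain %.1f%%",
              100 * sum(ef[seq_len(min(2, length(ef)))])),
      sprintf("landscape: %d occupied bins, dG range 0 - %.3f kcal/mol",
              sum(fel@counts > 0), max(dgFinite)),
      sprintf("representative: replica %d frame %d", rep$replicaId,
              rep$frame))
    .logStage(logCon, "[pca] %d frames pooled", sum(fel@counts))
  }

  ## --- lipid density -------------------------------------------------------
  if ("density" %in% stages) {
    d <- config$density %||% list()
    sels <- d$particles %||% list(all = "heavy")
    for (lbl in names(sels)) {
      grid <- tryCatch(
        densityGrid(trajs[[1]], sels[[lbl]], fitSelection = d$fit %||% NULL,
                    spacing = d$spacing %||% 1.0, classLabel = lbl),
        error = function(e) fail("density", "E_DENSITY", e))
      writeDX(grid, file.path(outDir, sprintf("density_%s.dx", lbl)))
      summary <- c(summary, sprintf(
        "density %s: peak %.3f per frame, %d outside", lbl,
        max(grid@values), grid@nOutside))
    }
  }

  writeLines(summary, file.path(outDir, "summary.txt"))
  .logStage(logCon, "run complete: %s", outDir)
  invisible(outDir)
}
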