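# Configuration-driven orchestration: run the full analysis battery on an
# input ensemble and emit TSV/PDB artifacts plus a run log. All numerical
# defaults are the published analysis parameters and live in the config,
# not in the operation bodies.

#' Default analysis configuration
#'
#' Returns the default configuration as a nested list: named selections,
#' clash/hydrogen-bond thresholds, RMSD-map and clustering settings, and
#' output controls. Every value can be overridden in a user config (YAML
#' file or list) passed to [runAnalysis()].
#'
#' @return nested list of defaults.
#' @export
defaultConfig <- function() {
  list(
    input = NULL,
    outputDir = "hingeflex-out",
    seed = 1L,
    selections = list(scope = "all"),
    rmsd = list(measure = "backbone", fit = NULL, nSamples = 2000L, k = 3L),
    rg = list(sel = "scope"),
    axisAngle = list(sel = "heavy"),
    dssp = list(sel = "scope"),
    hbonds = list(scope = "scope", minSeqSep = 5, minOccupancy = 0.15,
                  angleMin = 120,
                  thresholds = list(N = 2.52, O = 2.52, P = 3.24, S = 3.15)),
    clash = NULL,          # optional: list(a = <sel>, b = <sel>)
    distancePairs = NULL,  # optional: list of list(label=, a=, b=) selections
    helixDefs = NULL       # optional: list of list(name=, chain=, first=, last=)
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

writeTSV <- function(x, path) {
  utils::write.table(format(x, trim = TRUE, digits = 6, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis battery
#'
#' Reads the input ensemble, resolves the configured selections and emits:
#' the pairwise RMSD map with k-medoid cluster labels and representative
#' structures; the per-frame radius-of-gyration series and its range; the
#' principal-axis-to-Z angle series; the secondary-structure timeline;
#' hydrogen-bond residue tracks (intra/inter scope) with the saturation
#' report; named atom-pair distance series; helix-bundle change tables (when
#' helix definitions are configured); an optional clash report; and a run
#' log recording package version, seed and parameters. Any stage failure
#' aborts with the stage name; artifacts already written are retained.
#'
#' @param config a YAML file path or a nested list overriding
#'   [defaultConfig()]. `input` (multi-model PDB path) is required unless
#'   `traj` is given.
#' @param traj optionally, an in-memory [Trajectory] (overrides
#'   `config$input`).
#' @return named list of artifact file paths, invisibly.
#' @export
runAnalysis <- function(config, traj = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultConfig(), config)
  out <- cfg$outputDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logLines <- c(
    paste("hingeflex", as.character(utils::packageVersion("hingeflex"))),
    paste("R", getRversion()),
    paste("seed", cfg$seed),
    paste("config:", paste(deparse(cfg), collapse = " ")))
  artifacts <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  traj <- stage("input", {
    if (is.null(traj)) {
      if (is.null(cfg$input)) stop("config$input is required")
      readPDB(cfg$input)
    } else traj
  })
  resolve <- function(name) {
    expr <- cfg$selections[[name]] %||% name
    selectAtoms(traj, expr)
  }
  scopeSel <- stage("selections", resolve(cfg$dssp$sel))

  artifacts <- c(artifacts, stage("rmsd-map", {
    measure <- resolve(cfg$rmsd$measure)
    fit <- if (is.null(cfg$rmsd$fit)) NULL else resolve(cfg$rmsd$fit)
    n <- min(cfg$rmsd$nSamples, nFrames(traj))
    map <- rmsdMap(traj, measure, fit, nSamples = n)
    cl <- kmedoidCluster(map, k = min(cfg$rmsd$k, length(map@frameIndices)),
                         seed = cfg$seed)
    mt <- as.data.frame(round(map@matrix, 4))
    names(mt) <- paste0("f", map@frameIndices)
    p1 <- writeTSV(cbind(frame = map@frameIndices, mt),
                   file.path(out, "rmsd_map.tsv"))
    p2 <- writeTSV(data.frame(frame = map@frameIndices,
                              cluster = cl@labels,
                              medoid = map@frameIndices[cl@medoids][cl@labels],
                              representative =
                                map@frameIndices[cl@representatives][cl@labels]),
                   file.path(out, "cluster_labels.tsv"))
    repFrames <- map@frameIndices[cl@representatives]
    reps <- makeTrajectory(atomData(traj),
                           lapply(repFrames, function(f) frameCoords(traj, f)),
                           metadata = list(kind = "representatives"))
    p3 <- writePDB(reps, file.path(out, "representatives.pdb"))
    logLines <<- c(logLines, paste("representative frames:",
                                   paste(repFrames, collapse = ", ")))
    list(rmsdMap = p1, clusterLabels = p2, representatives = p3)
  }))

  artifacts <- c(artifacts, stage("rg", {
    rg <- rgSeriesAndRange(traj, resolve(cfg$rg$sel))
    logLines <<- c(logLines, sprintf("Rg range (A): %.3f", rg$range))
    list(rg = writeTSV(
      data.frame(frame = rg$series$frame, rg_A = round(rg$series$rg, 4)),
      file.path(out, "rg_series.tsv")))
  }))

  artifacts <- c(artifacts, stage("axis-angle", {
    aa <- principalAxisZAngle(traj, resolve(cfg$axisAngle$sel))
    list(axisAngle = writeTSV(
      data.frame(frame = aa$frame, angle_deg = round(aa$angle, 3)),
      file.path(out, "axis_angle.tsv")))
  }))

  artifacts <- c(artifacts, stage("dssp", {
    tl <- dsspTimeline(traj, scopeSel)
    df <- data.frame(chain = tl@chain, resid = tl@resid,
                     as.data.frame(tl@codes))
    names(df)[-(1:2)] <- paste0("f", seq_len(ncol(tl@codes)))
    list(dssp = writeTSV(df, file.path(out, "dssp_timeline.tsv")))
  }))

  artifacts <- c(artifacts, stage("hbond-tracks", {
    params <- new("HBondParams",
                  angleMin = cfg$hbonds$angleMin,
                  thresholds = unlist(cfg$hbonds$thresholds),
                  minSeqSep = cfg$hbonds$minSeqSep,
                  minOccupancy = cfg$hbonds$minOccupancy)
    tr <- hbondResidueTracks(traj, resolve(cfg$hbonds$scope), params)
    sat <- trackSaturation(tr, nFrames(traj))
    p1 <- writeTSV(data.frame(tr$tracks,
                              occupancy = round(tr$tracks$occupancy, 4))[
                     , c("chainI", "residI", "chainJ", "residJ",
                         "occupancy", "firstFormed", "label")],
                   file.path(out, "hbond_tracks.tsv"))
    p2 <- writeTSV(data.frame(quarter = 1:4, newTracks = sat$counts,
                              saturated = sat$saturated),
                   file.path(out, "hbond_saturation.tsv"))
    list(hbondTracks = p1, hbondSaturation = p2)
  }))

  if (!is.null(cfg$distancePairs)) {
    artifacts <- c(artifacts, stage("distance-series", {
      pairs <- do.call(rbind, lapply(cfg$distancePairs, function(p) {
        ia <- selIndices(selectAtoms(traj, p$a))
        ib <- selIndices(selectAtoms(traj, p$b))
        if (length(ia) != 1 || length(ib) != 1)
          stop("distance-pair selections must match exactly one atom: ",
               p$label)
        c(ia, ib)
      }))
      labels <- vapply(cfg$distancePairs, `[[`, character(1), "label")
      ts <- distanceTimeseries(traj, pairs, labels)
      ts$distance <- round(ts$distance, 4)
      list(distances = writeTSV(ts, file.path(out, "distance_series.tsv")))
    }))
  } else logLines <- c(logLines, "distance series: skipped (no pairs)")

  if (!is.null(cfg$helixDefs)) {
    artifacts <- c(artifacts, stage("helix-tables", {
      defs <- do.call(rbind, lapply(cfg$helixDefs, as.data.frame))
      ref <- makeTrajectory(atomData(traj), list(frameCoords(traj, 1)))
      repFrames <- unique(utils::read.table(
        file.path(out, "cluster_labels.tsv"), header = TRUE,
        sep = "\t")$representative)
      # representative column holds original frame ids; map back to frames
      rep <- helixTableReport(ref, traj, repFrames, defs)
      p1 <- writeTSV(rep$helices, file.path(out, "helix_changes.tsv"))
      pd <- data.frame(helix = rownames(rep$pairDistance),
                       round(rep$pairDistance, 3), check.names = FALSE)
      p2 <- writeTSV(pd, file.path(out, "helix_pair_distance.tsv"))
      an <- data.frame(helix = rownames(rep$angle), round(rep$angle, 3),
                       check.names = FALSE)
      p3 <- writeTSV(an, file.path(out, "helix_angles.tsv"))
      list(helixChanges = p1, helixPairDistance = p2, helixAngles = p3)
    }))
  } else logLines <- c(logLines, "helix tables: skipped (no helixDefs)")

  if (!is.null(cfg$clash)) {
    artifacts <- c(artifacts, stage("clash-report", {
      cl <- findClashes(traj, resolve(cfg$clash$a), resolve(cfg$clash$b))
      logLines <<- c(logLines, sprintf(
        "clashes: %d pairs, %d atoms, %d residues (A side)",
        nrow(cl$pairs), cl$summary["nAtomsA"], cl$summary["nResiduesA"]))
      cl$pairs$distance <- round(cl$pairs$distance, 4)
      list(clashes = writeTSV(cl$pairs, file.path(out, "clash_report.tsv")))
    }))
  } else logLines <- c(logLines, "clash report: skipped (no clash config)")

  writeLines(logLines, file.path(out, "run_log.txt"))
  artifacts$log <- file.path(out, "run_log.txt")
  invisible(artifacts)
}
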