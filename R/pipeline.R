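## Stage orchestration: composable commands over on-disk artifacts, each
## stage re-readable from the previous stage's CSV/FCS output.

#' Pipeline run configuration
#'
#' @param outDir output directory; stages write into subdirectories.
#' @param seed master seed for every stochastic step.
#' @param nEventsPerUnit synthetic events per sample unit.
#' @param nAntibodies non-blank screen antibodies in the synthetic design.
#' @param batches batch ids to process (`NULL` = all).
#' @param debarcodeMethod `"topk"` or `"cluster"`.
#' @param minSeparation top-k rejection threshold.
#' @param profilingMarkers markers used for per-subset profiling.
#' @param driftMarker marker checked for acquisition drift.
#' @param driftThreshold AOF increase that flags drift.
#' @param blankAntibody name of the blank control antibody.
#' @param foldThreshold,expressionFloor fixation classification settings.
#' @param residualCutoff differential-marker cutoff.
#' @param diffPos,diffNeg profiling subsets contrasted by the
#'   differential-marker stage.
#' @param cofactor arcsinh cofactor.
#' @return a named list of settings.
#' @export
pipelineConfig <- function(outDir, seed = 1, nEventsPerUnit = 2000,
                           nAntibodies = 12, batches = NULL,
                           debarcodeMethod = "topk", minSeparation = 0.3,
                           profilingMarkers = "CD161",
                           driftMarker = "CD161", driftThreshold = 0.1,
                           blankAntibody = "Blank", foldThreshold = 2,
                           expressionFloor = 5, residualCutoff = 2,
                           diffPos = "CD8 T Cells CD161hi",
                           diffNeg = "CD8 T Cells CD161lo",
                           cofactor = 5) {
  as.list(environment())
}

stage_dir <- function(cfg, stage) {
  d <- file.path(cfg$outDir, stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

write_provenance <- function(cfg, dir, extra = list()) {
  prov <- c(list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("cytoscreen")),
    config_hash = child_seed(0L, paste(deparse(cfg), collapse = ""))
  ), extra)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
}

pipeline_batches <- function(cfg, manifest) {
  b <- cfg$batches %||% batchIds(manifest)
  intersect(b, batchIds(manifest))
}

load_batch <- function(cfg, batchId) {
  path <- file.path(cfg$outDir, "data", paste0(batchId, ".fcs"))
  if (!file.exists(path)) {
    stop_validation("missing batch file ", path, "; run 'simulate' first")
  }
  asinhTransform(readFCS(path), cofactor = cfg$cofactor)
}

stage_simulate <- function(cfg) {
  d <- stage_dir(cfg, "data")
  sim <- defaultSimulationConfig(seed = cfg$seed,
                                 nEvents = cfg$nEventsPerUnit,
                                 nAntibodies = cfg$nAntibodies)
  manifest <- defaultManifest(sim)
  writeManifest(manifest, file.path(d, "manifest.json"))
  writeExperiment(sim, manifest, d)
  write_provenance(cfg, d, list(n_batches = nBatches(manifest)))
  invisible(manifest)
}

pipeline_manifest <- function(cfg) {
  path <- file.path(cfg$outDir, "data", "manifest.json")
  if (!file.exists(path)) {
    stop_validation("no manifest at ", path, "; run 'simulate' first")
  }
  readManifest(path)
}

stage_debarcode <- function(cfg) {
  manifest <- pipeline_manifest(cfg)
  d <- stage_dir(cfg, "debarcode")
  summaries <- list()
  for (b in pipeline_batches(cfg, manifest)) {
    ev <- load_batch(cfg, b)
    asg <- twoTierDebarcode(ev, manifest, b, method = cfg$debarcodeMethod,
                            minSeparation = cfg$minSeparation)
    asg$event_index <- seq_len(nrow(asg))
    utils::write.csv(asg, file.path(d, paste0(b, "_assignment.csv")),
                     row.names = FALSE)
    summaries[[b]] <- data.frame(batch = b, n_events = nrow(asg),
                                 n_assigned = sum(asg$assigned))
  }
  smry <- do.call(rbind, c(summaries, make.row.names = FALSE))
  utils::write.csv(smry, file.path(d, "summary.csv"), row.names = FALSE)
  write_provenance(cfg, d)
  invisible(smry)
}

stage_label <- function(cfg) {
  manifest <- pipeline_manifest(cfg)
  hier <- defaultHierarchy()
  d <- stage_dir(cfg, "label")
  for (b in pipeline_batches(cfg, manifest)) {
    ev <- load_batch(cfg, b)
    asg <- utils::read.csv(file.path(cfg$outDir, "debarcode",
                                     paste0(b, "_assignment.csv")))
    out <- data.frame(event_index = asg$event_index, donor = asg$donor,
                      treatment = asg$treatment, well_id = asg$well_id,
                      antibody = asg$antibody,
                      subset = NA_character_,
                      readout = if ("PE" %in% channelNames(ev))
                        intensities(ev)[, "PE"] else NA_real_,
                      stringsAsFactors = FALSE)
    units <- unique(stats::na.omit(asg[, c("donor", "treatment", "well_id")]))
    for (i in seq_len(nrow(units))) {
      u <- units[i, ]
      idx <- which(asg$assigned & asg$donor == u$donor &
                   asg$treatment == u$treatment & asg$well_id == u$well_id)
      if (!length(idx)) next
      sub <- cytoEvents(intensities(ev)[idx, , drop = FALSE],
                        scale = "arcsinh")
      lab <- labelEvents(sub, hier, params = clusterParams(
        seed = child_seed(cfg$seed, c(b, u$donor, u$treatment, u$well_id))))
      out$subset[idx] <- labels(lab)
    }
    out$subset[is.na(out$subset)] <- UNASSIGNED
    utils::write.csv(out, file.path(d, paste0(b, "_labels.csv")),
                     row.names = FALSE)
  }
  write_provenance(cfg, d)
  invisible(NULL)
}

stage_profile <- function(cfg) {
  manifest <- pipeline_manifest(cfg)
  d <- stage_dir(cfg, "profile")
  all_clusters <- list()
  for (b in pipeline_batches(cfg, manifest)) {
    ev <- load_batch(cfg, b)
    lab <- utils::read.csv(file.path(cfg$outDir, "label",
                                     paste0(b, "_labels.csv")),
                           stringsAsFactors = FALSE)
    lab$profiling_subset <- lab$subset
    units <- unique(stats::na.omit(lab[, c("donor", "treatment", "well_id")]))
    for (i in seq_len(nrow(units))) {
      u <- units[i, ]
      idx <- which(!is.na(lab$donor) & lab$donor == u$donor &
                   lab$treatment == u$treatment & lab$well_id == u$well_id)
      if (!length(idx)) next
      sub <- cytoEvents(intensities(ev)[idx, , drop = FALSE],
                        scale = "arcsinh")
      prof <- profileSubsets(sub, lab$subset[idx], cfg$profilingMarkers,
                             seed = child_seed(cfg$seed,
                               c("prof", b, u$donor, u$treatment,
                                 u$well_id)))
      lab$profiling_subset[idx] <- prof$perEvent$profiling_subset
      if (!is.null(prof$clusters)) {
        cl <- prof$clusters
        cl$donor <- u$donor; cl$treatment <- u$treatment
        cl$well_id <- u$well_id; cl$batch <- b
        all_clusters[[length(all_clusters) + 1L]] <- cl
      }
    }
    utils::write.csv(lab, file.path(d, paste0(b, "_profiled.csv")),
                     row.names = FALSE)
  }
  if (length(all_clusters)) {
    utils::write.csv(do.call(rbind, c(all_clusters,
                                      make.row.names = FALSE)),
                     file.path(d, "profiling_subsets.csv"),
                     row.names = FALSE)
  }
  write_provenance(cfg, d)
  invisible(NULL)
}

stage_qc_aof <- function(cfg) {
  manifest <- pipeline_manifest(cfg)
  d <- stage_dir(cfg, "qc")
  markers <- hierarchyMarkers(defaultHierarchy())
  bs <- pipeline_batches(cfg, manifest)
  values <- lapply(stats::setNames(markers, markers), function(m) {
    lapply(stats::setNames(bs, bs), function(b) {
      intensities(load_batch(cfg, b))[, m]
    })
  })
  rep <- buildAofReport(values, method = "two_means")
  utils::write.csv(data.frame(marker = rownames(aofMatrix(rep)),
                              aofMatrix(rep), check.names = FALSE),
                   file.path(d, "aof.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample = names(sampleQuality(rep)),
                              quality2_aof = sampleQuality(rep)),
                   file.path(d, "quality.csv"), row.names = FALSE)
  drift <- do.call(rbind, lapply(bs, function(b) {
    ev <- load_batch(cfg, b)
    qd <- quartileDrift(ev, cfg$driftMarker,
                        driftThreshold = cfg$driftThreshold)
    data.frame(batch = b, marker = cfg$driftMarker,
               q1 = qd$aof[1], q2 = qd$aof[2], q3 = qd$aof[3],
               q4 = qd$aof[4], flag = qd$flag)
  }))
  utils::write.csv(drift, file.path(d, "drift.csv"), row.names = FALSE)
  write_provenance(cfg, d)
  invisible(rep)
}

read_profiled <- function(cfg) {
  manifest <- pipeline_manifest(cfg)
  files <- file.path(cfg$outDir, "profile",
                     paste0(pipeline_batches(cfg, manifest),
                            "_profiled.csv"))
  files <- files[file.exists(files)]
  if (!length(files)) stop_validation("no profiled batches; run 'profile'")
  do.call(rbind, c(lapply(files, utils::read.csv,
                          stringsAsFactors = FALSE),
                   make.row.names = FALSE))
}

stage_screen <- function(cfg) {
  d <- stage_dir(cfg, "screen")
  manifest <- pipeline_manifest(cfg)
  et <- read_profiled(cfg)
  et <- et[!is.na(et$donor) & et$subset != UNASSIGNED, , drop = FALSE]
  blank_well <- manifest@wells$well_id[manifest@wells$antibody ==
                                       cfg$blankAntibody][1]
  res <- summarizeScreen(et, blank_well)
  utils::write.csv(res$summary, file.path(d, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(res$thresholds, file.path(d, "thresholds.csv"),
                   row.names = FALSE)
  write_provenance(cfg, d)
  invisible(res)
}

read_screen_summary <- function(cfg) {
  path <- file.path(cfg$outDir, "screen", "summary.csv")
  if (!file.exists(path)) stop_validation("no screen summary; run 'screen'")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

stage_fixation <- function(cfg) {
  d <- stage_dir(cfg, "fixation")
  smry <- read_screen_summary(cfg)
  fx <- fixationClassify(smry[smry$treatment == "fresh", ],
                         smry[smry$treatment == "fixed", ],
                         foldThreshold = cfg$foldThreshold,
                         expressionFloor = cfg$expressionFloor,
                         cofactor = cfg$cofactor)
  utils::write.csv(fx$byAntibody, file.path(d, "by_antibody.csv"),
                   row.names = FALSE)
  utils::write.csv(fx$bySubset, file.path(d, "by_subset.csv"),
                   row.names = FALSE)
  write_provenance(cfg, d)
  invisible(fx)
}

stage_diffexp <- function(cfg) {
  d <- stage_dir(cfg, "diffexp")
  smry <- read_screen_summary(cfg)
  smry <- smry[smry$treatment == "fresh" &
               smry$antibody != cfg$blankAntibody, , drop = FALSE]
  pp <- function(subset) {
    s <- smry[smry$profiling_subset == subset, , drop = FALSE]
    tapply(s$pct_positive, list(s$antibody, s$donor), mean)
  }
  ppPos <- pp(cfg$diffPos)
  ppNeg <- pp(cfg$diffNeg)
  common <- intersect(rownames(ppPos)[stats::complete.cases(ppPos)],
                      rownames(ppNeg)[stats::complete.cases(ppNeg)])
  dm <- differentialMarkers(ppPos[common, , drop = FALSE],
                            ppNeg[common, , drop = FALSE],
                            residualCutoff = cfg$residualCutoff)
  utils::write.csv(data.frame(antibody = rownames(dm$residuals),
                              dm$residuals, check.names = FALSE),
                   file.path(d, "residuals.csv"), row.names = FALSE)
  utils::write.csv(dm$flagged, file.path(d, "flagged.csv"),
                   row.names = FALSE)
  write_provenance(cfg, d)
  invisible(dm)
}

#' Run a pipeline stage (or the whole pipeline)
#'
#' Stages read their inputs from the previous stage's on-disk artifacts
#' under `config$outDir`, so a later stage can be re-run alone:
#' `simulate` writes the synthetic batches and manifest; `debarcode` the
#' per-event sample assignments; `label` the cell-subset labels;
#' `profile` the profiling subsets; `qc-aof` the AOF, quality and drift
#' reports; `screen` the per-(subset, antibody) summary; `fixation` the
#' gain/loss classification; `diffexp` the differential-marker test;
#' `all` chains every stage.
#'
#' @param command stage name.
#' @param config a [pipelineConfig()].
#' @return the stage's main result object, invisibly.
#' @export
runPipeline <- function(command = c("all", "simulate", "debarcode", "label",
                                    "profile", "qc-aof", "screen",
                                    "fixation", "diffexp"),
                        config) {
  command <- match.arg(command)
  stages <- list(
    simulate = stage_simulate, debarcode = stage_debarcode,
    label = stage_label, profile = stage_profile,
    `qc-aof` = stage_qc_aof, screen = stage_screen,
    fixation = stage_fixation, diffexp = stage_diffexp
  )
  if (command == "all") {
    res <- NULL
    for (s in names(stages)) {
      message("[cytoscreen] stage: ", s)
      res <- stages[[s]](config)
    }
    return(invisible(res))
  }
  invisible(stages[[command]](config))
}
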