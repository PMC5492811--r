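## Pipeline orchestration: simulate -> indices -> invert-dhp -> extract ->
## fit -> compare -> discriminate, with plain-file handoff between stages
## and a JSON run manifest. Every stage is callable standalone; files are
## the only interface.

.pipelineStages <- c("simulate", "indices", "invert_dhp", "extract", "fit",
                     "compare", "discriminate")

# Scalar view of a config for hashing/manifest (drops functions/objects).
.configScalars <- function(cfg) {
  keep <- vapply(cfg, function(x) is.numeric(x) || is.character(x) || is.integer(x),
                 logical(1))
  lapply(cfg[keep], unname)
}

#' Read a simulation/pipeline configuration from YAML
#'
#' Flat keys mirroring the arguments of [simulationConfig()] plus the
#' pipeline-only keys `alaDeg`, `omegaTarget`, `nPhotos`, `cvRepeats`.
#' Unknown keys are an error.
#'
#' @param path YAML file.
#' @return A `SimulationConfig`.
#' @export
readSimulationConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c(names(formals(simulationConfig)), "alaDeg", "omegaTarget",
             "nPhotos", "cvRepeats")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  extra <- raw[intersect(names(raw), c("alaDeg", "omegaTarget", "nPhotos", "cvRepeats"))]
  raw <- raw[setdiff(names(raw), names(extra))]
  if (!is.null(raw$traitSd)) raw$traitSd <- unlist(raw$traitSd)
  cfg <- do.call(simulationConfig, raw)
  cfg[names(extra)] <- extra
  cfg
}

.cfgDefault <- function(cfg, key, default) if (is.null(cfg[[key]])) default else cfg[[key]]

#' Run the synthetic monitoring pipeline
#'
#' Executes the requested stages in dependency order with plain files as
#' the only interface between them, logging one stage-tagged line per stage
#' to stderr, and writes a JSON run manifest (config hash, seed, stage
#' list, per-stage outputs, package version). Re-running with an identical
#' config and seed reproduces identical outputs.
#'
#' Stage outputs under `outDir`: `traits.csv`, `spectra_uav.csv`,
#' `spectra_ground.csv`, `layout.csv`, `gaps/gaps_<plot>_<dap>.csv`,
#' `mosaic(.hdr)` (simulate); `vi_uav.csv`, `vi_ground.csv` (indices);
#' `canopy.csv` (invert_dhp); `plots.csv` (extract); `models.csv` (fit);
#' `intercomp.csv` (compare); `separation.csv` (discriminate);
#' `manifest.json`.
#'
#' @param cfg a [simulationConfig()] (or path to a YAML config).
#' @param outDir output directory (created if needed).
#' @param stages subset of stages to run (default: all; upstream outputs
#'   must already exist for a partial run).
#' @param lut \linkS4class{LutSpec} for the inversion stage.
#' @param verbose log stage lines to stderr.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(cfg = simulationConfig(), outDir, stages = .pipelineStages,
                        lut = lutSpec(), verbose = TRUE) {
  if (is.character(cfg)) cfg <- readSimulationConfig(cfg)
  stopifnot(inherits(cfg, "SimulationConfig"))
  bad <- setdiff(stages, .pipelineStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .pipelineStages[.pipelineStages %in% stages]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  pth <- function(...) file.path(outDir, ...)
  needs <- function(stage, files) {
    miss <- files[!file.exists(files)]
    if (length(miss))
      stop(sprintf("stage '%s' requires missing upstream output(s): %s",
                   stage, paste(miss, collapse = ", ")))
  }
  outputs <- list()
  alaDeg <- .cfgDefault(cfg, "alaDeg", 50)
  omegaTarget <- .cfgDefault(cfg, "omegaTarget", 0.85)
  nPhotos <- .cfgDefault(cfg, "nPhotos", 4)
  cvRepeats <- .cfgDefault(cfg, "cvRepeats", 100)
  soilC <- function(bs) {
    s <- cfg$soilSpectrum(bandCenters(bs))
    estimateSoilLine(s, bs)
  }

  if ("simulate" %in% stages) {
    traits <- simulateTraits(cfg)
    writeTraitTable(traits, pth("traits.csv"))
    sp <- simulateTwoSensorSpectra(traits, cfg)
    writeSpectraTable(sp$uav, pth("spectra_uav.csv"))
    writeSpectraTable(sp$ground, pth("spectra_ground.csv"))
    gapsDir <- pth("gaps")
    dir.create(gapsDir, showWarnings = FALSE)
    for (r in seq_len(nrow(traits))) {
      g <- simulateGapField(traits$lai[r], alaDeg, omegaTarget, nPhotos = nPhotos,
                            seed = .subSeed(cfg$seed, 100L + r))
      writeGapGrids(g, file.path(gapsDir, sprintf("gaps_%s_%d.csv",
                                                  traits$plot_id[r], traits$dap[r])))
    }
    layout <- defaultStripLayout(nrow(traits[traits$dap == cfg$dapSchedule[1], ]))
    utils::write.csv(layout, pth("layout.csv"), row.names = FALSE, quote = FALSE)
    mosaic <- simulateMosaic(layout, viLevels = 0.6, soilLevel = 0.1,
                             noiseSd = 0.02, seed = .subSeed(cfg$seed, 3L))
    writeCube(mosaic, pth("mosaic"))
    outputs$simulate <- c(pth("traits.csv"), pth("spectra_uav.csv"),
                          pth("spectra_ground.csv"), pth("layout.csv"),
                          pth("mosaic"), gapsDir)
    say("simulate", "%d plots x %d dates", length(unique(traits$plot_id)),
        length(cfg$dapSchedule))
  }

  if ("indices" %in% stages) {
    needs("indices", c(pth("spectra_uav.csv"), pth("spectra_ground.csv")))
    for (sensor in c("uav", "ground")) {
      bs <- if (sensor == "uav") cfg$uavBands else cfg$groundBands
      ps <- readSpectraTable(pth(sprintf("spectra_%s.csv", sensor)), bs)
      vi <- indexTable(ps, soilLine = soilC(bs))
      utils::write.csv(vi, pth(sprintf("vi_%s.csv", sensor)), row.names = FALSE,
                       quote = FALSE)
    }
    outputs$indices <- c(pth("vi_uav.csv"), pth("vi_ground.csv"))
    say("indices", "16 indices for both sensors")
  }

  if ("invert_dhp" %in% stages) {
    gapsDir <- pth("gaps")
    needs("invert_dhp", gapsDir)
    files <- list.files(gapsDir, pattern = "^gaps_.*\\.csv$", full.names = TRUE)
    if (!length(files)) stop("no gap-fraction files in ", gapsDir)
    rows <- lapply(files, function(f) {
      m <- regmatches(basename(f), regexec("^gaps_(.*)_(\\d+)\\.csv$", basename(f)))[[1]]
      cp <- invertCanopy(readGapGrids(f), lut = lut)
      data.frame(plot_id = m[2], dap = as.integer(m[3]), lai = canopyLai(cp),
                 ala = canopyAla(cp), omega_mean = mean(clumping(cp), na.rm = TRUE),
                 ground_cover = cp@groundCover, cost = cp@cost,
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), pth("canopy.csv"), row.names = FALSE,
                     quote = FALSE)
    outputs$invert_dhp <- pth("canopy.csv")
    say("invert_dhp", "%d plot-date inversions", length(files))
  }

  if ("extract" %in% stages) {
    needs("extract", c(pth("mosaic"), pth("mosaic.hdr"), pth("layout.csv")))
    mosaic <- readCube(pth("mosaic"))
    layout <- utils::read.csv(pth("layout.csv"), stringsAsFactors = FALSE)
    edges <- detectEdges(mosaic)
    refined <- edgesToPlots(edges, layout, pixelSize = mosaic@pixelSize,
                            origin = mosaic@origin)
    utils::write.csv(refined, pth("plots.csv"), row.names = FALSE, quote = FALSE)
    outputs$extract <- pth("plots.csv")
    say("extract", "%d/%d across-track sides snapped",
        sum(refined$snapped_left) + sum(refined$snapped_right), 2L * nrow(refined))
  }

  if ("fit" %in% stages) {
    needs("fit", c(pth("vi_uav.csv"), pth("vi_ground.csv"), pth("traits.csv")))
    vi <- rbind(utils::read.csv(pth("vi_uav.csv"), stringsAsFactors = FALSE),
                utils::read.csv(pth("vi_ground.csv"), stringsAsFactors = FALSE))
    traits <- readTraitTable(pth("traits.csv"))
    models <- modelMatrix(vi, traits, repeats = cvRepeats, seed = cfg$seed)
    utils::write.csv(models, pth("models.csv"), row.names = FALSE, quote = FALSE)
    outputs$fit <- pth("models.csv")
    say("fit", "%d models", nrow(models))
  }

  if ("compare" %in% stages) {
    needs("compare", c(pth("vi_uav.csv"), pth("vi_ground.csv")))
    viU <- utils::read.csv(pth("vi_uav.csv"), stringsAsFactors = FALSE)
    viG <- utils::read.csv(pth("vi_ground.csv"), stringsAsFactors = FALSE)
    rows <- lapply(intersect(indexNames(), names(viU)), function(ix) {
      r <- tryCatch(intercompare(viU, viG, ix), error = function(e) NULL)
      if (is.null(r)) return(NULL)
      as.data.frame(r, stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), pth("intercomp.csv"), row.names = FALSE,
                     quote = FALSE)
    outputs$compare <- pth("intercomp.csv")
    say("compare", "slope discrepancy for %d indices", length(rows))
  }

  if ("discriminate" %in% stages) {
    needs("discriminate", pth("vi_uav.csv"))
    lastDap <- max(cfg$dapSchedule)
    rows <- lapply(c("uav", "ground"), function(sensor) {
      f <- pth(sprintf("vi_%s.csv", sensor))
      if (!file.exists(f)) return(NULL)
      vi <- utils::read.csv(f, stringsAsFactors = FALSE)
      st <- separationTable(vi, dapFilter = lastDap)
      if (is.null(st)) return(NULL)
      st$sensor <- sensor
      st
    })
    utils::write.csv(do.call(rbind, rows), pth("separation.csv"),
                     row.names = FALSE, quote = FALSE)
    outputs$discriminate <- pth("separation.csv")
    say("discriminate", "last-date (%d DAP) treatment separability", lastDap)
  }

  cfgPath <- pth("config.yaml")
  yaml::write_yaml(.configScalars(cfg), cfgPath)
  manifest <- list(config_hash = unname(tools::md5sum(cfgPath)),
                   seed = cfg$seed, stages = stages,
                   outputs = lapply(outputs, as.character),
                   version = as.character(utils::packageVersion("canopytrait")))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
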