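#' @importFrom jsonlite fromJSON toJSON write_json
#' @importFrom utils read.csv write.csv packageVersion
#' @importFrom tools md5sum
NULL

.CONTAINER_SCHEMA <- "jmoct-container-1"

#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable of the
#' pipeline: acquisition geometry, phantom and cohort settings, contrast
#' parameters, segmentation parameters, the abnormality threshold, the
#' analysis timepoints and the mandatory seed. [readPipelineConfig()]
#' validates a JSON file against this schema (unknown keys are rejected).
#'
#' @param seed integer seed driving every stochastic stage.
#' @return nested named list.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    geometry = .geometryToList(AcquisitionGeometry()),
    phantom = list(nz = 256, nx = 256, ny = 32, includeTumor = TRUE,
                   nVessels = 3, vesselRadius = 3, snr_db = 25),
    cohort = list(n_control = 10, n_tumor = 13,
                  timepoints_dpi = c(7, 11, 15, 19, 21)),
    contrasts = list(dopu_kernel = c(5, 5, 1), octa_window = c(5, 5),
                     delta_z = 1, reliability_margin_db = 6),
    segmentation = list(closing_size = 5, min_tissue_pixels = 50,
                        segmenter = "rule"),
    quantify = list(abnormality_threshold = 0.0006, bscan_window = 30),
    angio = list(depth_pixels = 30, sigma = 1.1, min_area = 10),
    analysis_dpi = c(7, 11, 15, 19, 21),
    seed = seed,
    output_dir = "jmoct-output"
  )
}

#' Read and validate a pipeline configuration
#'
#' Loads a JSON configuration, rejects unknown keys at the top and group
#' level, fills missing entries with defaults, and requires a seed.
#'
#' @param path JSON file path.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validatePipelineConfig(cfg)
}

#' @rdname readPipelineConfig
#' @param cfg configuration list to validate/merge.
#' @export
validatePipelineConfig <- function(cfg) {
  def <- defaultPipelineConfig()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  for (grp in names(def)) {
    if (is.list(def[[grp]]) && !is.null(cfg[[grp]])) {
      badSub <- setdiff(names(cfg[[grp]]), names(def[[grp]]))
      if (length(badSub)) {
        stop(sprintf("unknown key(s) in '%s': %s", grp,
                     paste(badSub, collapse = ", ")))
      }
      def[[grp]][names(cfg[[grp]])] <- cfg[[grp]]
    } else if (!is.null(cfg[[grp]])) {
      def[[grp]] <- cfg[[grp]]
    }
  }
  if (is.null(cfg$seed)) stop("configuration must set a seed")
  def$seed <- as.integer(cfg$seed)
  def
}

#' Volume container I/O
#'
#' Writes/reads the pipeline's volume container: a single versioned RDS
#' file holding named elements (phantom, Jones volume, contrasts, masks)
#' plus a metadata list. Complex Jones data round-trip losslessly. Reading
#' verifies the schema version and fails loudly on truncated or foreign
#' files.
#'
#' @param objects named list of objects to store.
#' @param path file path (conventionally `.rds`).
#' @param meta optional metadata list stored alongside.
#' @return `writeContainer` returns `path` invisibly; `readContainer`
#'   returns the named object list with the metadata in
#'   `attr(, "meta")`.
#' @export
writeContainer <- function(objects, path, meta = list()) {
  stopifnot(is.list(objects), !is.null(names(objects)))
  payload <- list(schema = .CONTAINER_SCHEMA,
                  meta = c(meta, list(written = format(Sys.time()))),
                  objects = objects)
  saveRDS(payload, path, version = 3)
  invisible(path)
}

#' @rdname writeContainer
#' @export
readContainer <- function(path) {
  if (!file.exists(path)) stop("container not found: ", path)
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop("container integrity error (corrupt or truncated file): ",
         conditionMessage(e))
  })
  if (!is.list(payload) || !identical(payload$schema, .CONTAINER_SCHEMA)) {
    stop("not a recognized container (expected schema '",
         .CONTAINER_SCHEMA, "')")
  }
  structure(payload$objects, meta = payload$meta)
}

# Artifact path conventions of the staged pipeline.
.artifactPath <- function(dir, name) {
  file.path(dir, c(
    volume = "volume.rds", contrasts = "contrasts.rds",
    masks = "masks.rds",
    cohort_measurements = "cohort_measurements.csv",
    cohort_survival = "cohort_survival.csv",
    animal_summaries = "animal_summaries.csv",
    group_comparisons = "group_comparisons.csv",
    survival_result = "survival_result.json",
    km_curves = "km_curves.csv",
    vessel_metrics = "vessel_metrics.csv",
    report = "report.md",
    provenance = "provenance.json"
  )[[name]])
}

.requireArtifact <- function(dir, name, producedBy) {
  p <- .artifactPath(dir, name)
  if (!file.exists(p)) {
    stop(sprintf("missing artifact '%s' (%s); run stage '%s' first",
                 name, p, producedBy))
  }
  p
}

.stageLog <- function(dir, stage, inputs = character()) {
  logPath <- file.path(dir, "pipeline.log")
  hashes <- if (length(inputs)) {
    paste(sprintf("%s=%s", basename(inputs),
                  unname(tools::md5sum(inputs))), collapse = " ")
  } else ""
  cat(sprintf("[%s] stage=%s %s\n", format(Sys.time()), stage, hashes),
      file = logPath, append = TRUE)
}

#' Run one pipeline stage
#'
#' Executes a single stage of the longitudinal analysis pipeline against
#' an output directory, reading the artifacts of upstream stages and
#' failing with an actionable message when one is missing. Stages:
#' `simulate` (phantom volume + cohort tables), `contrasts`, `segment`,
#' `quantify` (animal summaries, abnormality, group comparisons),
#' `survival`, `angio`, `report`.
#'
#' @param config configuration list (see [defaultPipelineConfig()]).
#' @param stage stage name.
#' @param dir output directory (created if needed); defaults to the
#'   config's `output_dir`.
#' @return invisibly, the paths of the artifacts written.
#' @export
runStage <- function(config, stage, dir = config$output_dir) {
  config <- validatePipelineConfig(config)
  stage <- match.arg(stage, c("simulate", "contrasts", "segment",
                              "quantify", "survival", "angio", "report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  out <- character()

  if (stage == "simulate") {
    g <- .geometryFromList(config$geometry)
    ph <- config$phantom
    phantom <- buildPhantom(g, nz = ph$nz, nx = ph$nx, ny = ph$ny,
                            includeTumor = isTRUE(ph$includeTumor),
                            nVessels = ph$nVessels,
                            vesselRadius = ph$vesselRadius,
                            seed = seed)
    jn <- cumulativeJones(phantom, seed = seed + 1L)
    jones <- renderMeasurement(jn, acqGeometry(phantom),
                               snrDb = ph$snr_db,
                               flowMask = truthMask(phantom, "vessel"),
                               seed = seed + 2L)
    vp <- .artifactPath(dir, "volume")
    writeContainer(list(phantom = phantom, jones = jones), vp,
                   meta = list(seed = seed))
    ch <- config$cohort
    spec <- cohortSpec(nControl = ch$n_control, nTumor = ch$n_tumor,
                       timepoints = ch$timepoints_dpi)
    sim <- simulateCohort(spec, seed = seed + 3L)
    mp <- .artifactPath(dir, "cohort_measurements")
    sp <- .artifactPath(dir, "cohort_survival")
    utils::write.csv(sim$measurements, mp, row.names = FALSE)
    utils::write.csv(sim$survival, sp, row.names = FALSE)
    out <- c(vp, mp, sp)
  } else if (stage == "contrasts") {
    vp <- .requireArtifact(dir, "volume", "simulate")
    vol <- readContainer(vp)
    cc <- config$contrasts
    cs <- computeContrasts(vol$jones,
                           dopuKernel = as.integer(cc$dopu_kernel),
                           octaWindow = as.integer(cc$octa_window),
                           deltaZ = as.integer(cc$delta_z),
                           marginDb = cc$reliability_margin_db)
    cp <- .artifactPath(dir, "contrasts")
    writeContainer(list(contrasts = cs), cp)
    out <- cp
  } else if (stage == "segment") {
    vp <- .requireArtifact(dir, "volume", "simulate")
    cp <- .requireArtifact(dir, "contrasts", "contrasts")
    vol <- readContainer(vp)
    cs <- readContainer(cp)$contrasts
    sg <- config$segmentation
    mask <- if (identical(sg$segmenter, "truth")) {
      truthMaskVolume(vol$phantom)
    } else {
      segmentUpperMuscle(cs, closingSize = as.integer(sg$closing_size),
                         minTissuePixels = as.integer(sg$min_tissue_pixels))
    }
    acc <- segmentationAccuracy(mask, truthMask(vol$phantom,
                                                "upper_muscle"))
    mp <- .artifactPath(dir, "masks")
    writeContainer(list(mask = mask), mp, meta = acc)
    out <- mp
  } else if (stage == "quantify") {
    cp <- .requireArtifact(dir, "contrasts", "contrasts")
    mp <- .requireArtifact(dir, "masks", "segment")
    mm <- .requireArtifact(dir, "cohort_measurements", "simulate")
    cs <- readContainer(cp)$contrasts
    mask <- readContainer(mp)$mask
    qc <- config$quantify
    window <- min(qc$bscan_window, dim(intensityDb(cs))[3L])
    summ <- maskedMeans(cs, mask, bscanWindow = window,
                        animalId = "phantom", group = "phantom")
    summ$abnormality_pct <- abnormalityFraction(
      cs, mask, threshold = qc$abnormality_threshold)
    ap <- .artifactPath(dir, "animal_summaries")
    utils::write.csv(summ, ap, row.names = FALSE)
    meas <- utils::read.csv(mm, stringsAsFactors = FALSE)
    cmp <- compareGroups(meas,
                         quantities = c("mean_intensity_db",
                                        "mean_birefringence", "mean_dopu",
                                        "abnormality_pct"),
                         dpi = config$analysis_dpi)
    gp <- .artifactPath(dir, "group_comparisons")
    utils::write.csv(cmp, gp, row.names = FALSE)
    out <- c(ap, gp)
  } else if (stage == "survival") {
    sp <- .requireArtifact(dir, "cohort_survival", "simulate")
    surv <- utils::read.csv(sp, stringsAsFactors = FALSE)
    res <- logrankAndHr(
      data.frame(time = surv$time_days[surv$group == "control"],
                 event = surv$event[surv$group == "control"]),
      data.frame(time = surv$time_days[surv$group == "tumor"],
                 event = surv$event[surv$group == "tumor"]))
    rp <- .artifactPath(dir, "survival_result")
    jsonlite::write_json(survivalResultAsList(res), rp,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    km <- rbind(cbind(group = "control", res@kmControl),
                cbind(group = "tumor", res@kmTumor))
    kp <- .artifactPath(dir, "km_curves")
    utils::write.csv(km, kp, row.names = FALSE)
    out <- c(rp, kp)
  } else if (stage == "angio") {
    vp <- .requireArtifact(dir, "volume", "simulate")
    cp <- .requireArtifact(dir, "contrasts", "contrasts")
    vol <- readContainer(vp)
    cs <- readContainer(cp)$contrasts
    an <- config$angio
    # depth window at the top of the musculature
    musc <- truthMask(vol$phantom, "musculature")
    zTop <- which(apply(musc, 1, any))[1]
    g <- acqGeometry(cs)
    depthPixels <- min(an$depth_pixels, dim(octaMap(cs))[1] - zTop)
    proj <- octaEnface(cs, depthStart = zTop, depthPixels = depthPixels,
                       sigma = an$sigma)
    vm <- binarizeVessels(proj, minArea = an$min_area)
    met <- vesselMetrics(vm, lateralPixelPitch(g@fovFast, g@nFast),
                         lateralPixelPitch(g@fovSlow, g@nSlow))
    vp2 <- .artifactPath(dir, "vessel_metrics")
    utils::write.csv(
      data.frame(animal_id = "phantom", dpi = NA,
                 mean_vessel_length_mm = met$mean_vessel_length_mm,
                 vessel_density_pct = met$vessel_density_pct,
                 n_segments = met$n_segments), vp2, row.names = FALSE)
    out <- vp2
  } else if (stage == "report") {
    gp <- .requireArtifact(dir, "group_comparisons", "quantify")
    rp <- .requireArtifact(dir, "survival_result", "survival")
    cmp <- utils::read.csv(gp, stringsAsFactors = FALSE)
    sres <- jsonlite::fromJSON(rp)
    lines <- c(
      "# JM-OCT longitudinal pipeline report", "",
      sprintf("Seed: %d", config$seed), "",
      "## Group comparisons (tumor vs control, rank sum test)", "",
      "| quantity | dpi | mean control | mean tumor | p |",
      "|---|---|---|---|---|",
      sprintf("| %s | %g | %.4g | %.4g | %.3g |", cmp$quantity, cmp$dpi,
              cmp$mean_control, cmp$mean_tumor, cmp$p),
      "",
      "## Survival", "",
      sprintf("Hazard ratio (observed/expected events): %.3f, log-rank p = %.3g",
              sres$hazard_ratio, sres$logrank_p), "")
    repP <- .artifactPath(dir, "report")
    writeLines(lines, repP)
    out <- repP
  }

  .stageLog(dir, stage, out[file.exists(out)])
  invisible(out)
}

#' Run the full pipeline
#'
#' Executes every stage in order (`simulate`, `contrasts`, `segment`,
#' `quantify`, `survival`, `angio`, `report`) and writes a provenance
#' record (configuration hash, seed, package and R versions). The whole
#' run is deterministic under the configuration seed.
#'
#' @inheritParams runStage
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        dir = config$output_dir) {
  config <- validatePipelineConfig(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (stage in c("simulate", "contrasts", "segment", "quantify",
                  "survival", "angio", "report")) {
    runStage(config, stage, dir)
  }
  cfgPath <- file.path(dir, "config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  prov <- list(
    config_md5 = unname(tools::md5sum(cfgPath)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("jmoct")),
    r_version = R.version.string
  )
  jsonlite::write_json(prov, .artifactPath(dir, "provenance"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
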