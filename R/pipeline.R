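#' @include io.R synthetic.R summary.R enhance.R
NULL

.stageOrder <- c("enhance", "segment", "filter", "track", "summarize")

#' Full pipeline configuration
#'
#' Bundles the per-module configurations plus I/O options into one object,
#' mirroring the sections of the YAML configuration file.
#'
#' @param enhancement an [enhancementConfig()].
#' @param segmentation a [segmentationConfig()].
#' @param filter a [filterCriteria()].
#' @param tracking a [trackingConfig()].
#' @param summary list with element \code{measures} (NULL = defaults).
#' @param io list with elements \code{phasePattern} (regex for
#'   [readTimeLapse()]) and \code{detectionPhase} (NULL = first phase).
#' @param simulate a [sceneConfig()].
#' @return a validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(enhancement = enhancementConfig(),
                           segmentation = segmentationConfig(),
                           filter = filterCriteria(),
                           tracking = trackingConfig(),
                           summary = list(measures = NULL),
                           io = list(phasePattern = .defaultPhasePattern,
                                     detectionPhase = NULL),
                           simulate = sceneConfig()) {
  stopifnot(inherits(enhancement, "EnhancementConfig"),
            inherits(segmentation, "SegmentationConfig"),
            inherits(filter, "FilterCriteria"),
            inherits(tracking, "TrackingConfig"),
            inherits(simulate, "SceneConfig"))
  bad <- setdiff(names(summary), "measures")
  if (length(bad)) stop("unknown summary option(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(names(io), c("phasePattern", "detectionPhase"))
  if (length(bad)) stop("unknown io option(s): ",
                        paste(bad, collapse = ", "))
  structure(list(enhancement = enhancement, segmentation = segmentation,
                 filter = filter, tracking = tracking, summary = summary,
                 io = io, simulate = simulate),
            class = c("PipelineConfig", "list"))
}

# YAML key -> constructor argument maps (snake_case config surface)
.sectionBuilders <- list(
  enhancement = list(fn = enhancementConfig,
                     keys = c(saturation_fraction = "saturationFraction")),
  segmentation = list(fn = segmentationConfig,
    keys = c(tile_size = "tileSize", threshold_bounds = "thresholdBounds",
             auto_threshold_bounds = "autoThresholdBounds",
             circle_radius_range = "circleRadiusRange",
             min_component_area = "minComponentArea",
             max_component_area = "maxComponentArea",
             boundary_margin = "boundaryMargin",
             circle_sensitivity = "circleSensitivity")),
  filter = list(fn = filterCriteria,
    keys = c(area = "area", extent = "extent", eccentricity = "eccentricity",
             max_intensity = "maxIntensity", mean_intensity = "meanIntensity",
             major_axis = "majorAxis", minor_axis = "minorAxis",
             require_activity = "requireActivity",
             activation_floor = "activationFloor")),
  tracking = list(fn = trackingConfig,
    keys = c(gate_radius = "gateRadius", feature_weights = "featureWeights",
             max_missed_frames = "maxMissedFrames",
             intensity_range = "intensityRange")),
  simulate = list(fn = sceneConfig,
    keys = c(frame_shape = "frameShape", n_frames = "nFrames",
             n_cells = "nCells", radius_range = "radiusRange",
             cell_contrast = "cellContrast",
             background_level = "backgroundLevel", noise_sd = "noiseSd",
             illumination_gradient = "illuminationGradient",
             motion_sd = "motionSd", drift = "drift",
             flash_probability = "flashProbability",
             flash_gain = "flashGain", entry_exit = "entryExit",
             n_enter = "nEnter", n_exit = "nExit", bit_depth = "bitDepth",
             seed = "seed"))
)

#' Read a pipeline configuration file
#'
#' Parses a YAML file with sections \code{enhancement}, \code{segmentation},
#' \code{filter}, \code{tracking}, \code{summary}, \code{io} and
#' \code{simulate} (all optional; omitted values take the package
#' defaults). Unknown sections or keys are errors, so typos cannot silently
#' fall back to defaults.
#'
#' @param path YAML file path.
#' @return a [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read config '%s'", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c(names(.sectionBuilders), "summary", "io")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  args <- list()
  for (sec in names(.sectionBuilders)) {
    b <- .sectionBuilders[[sec]]
    given <- raw[[sec]]
    if (is.null(given)) given <- list()
    bad <- setdiff(names(given), names(b$keys))
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
    call <- list()
    for (k in names(given)) {
      v <- given[[k]]
      call[[b$keys[[k]]]] <- if (is.list(v)) unlist(v) else v
    }
    args[[if (sec == "enhancement") "enhancement" else sec]] <-
      do.call(b$fn, call)
  }
  if (!is.null(raw$summary)) {
    bad <- setdiff(names(raw$summary), "measures")
    if (length(bad))
      stop("unknown key(s) in section 'summary': ",
           paste(bad, collapse = ", "))
    args$summary <- list(measures = unlist(raw$summary$measures))
  }
  if (!is.null(raw$io)) {
    bad <- setdiff(names(raw$io), c("phase_pattern", "detection_phase"))
    if (length(bad))
      stop("unknown key(s) in section 'io': ", paste(bad, collapse = ", "))
    args$io <- list(
      phasePattern = raw$io$phase_pattern %||% .defaultPhasePattern,
      detectionPhase = raw$io$detection_phase)
  }
  do.call(pipelineConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a scene and write its artifacts
#'
#' Generates a ground-truth scene, renders it, and writes the frame TIFFs,
#' the truth table CSV, 16-bit label-mask TIFFs and a run manifest that
#' suffices to reproduce the outputs byte for byte.
#'
#' @param config a [sceneConfig()].
#' @param outDir output directory.
#' @return invisibly, a list with the scene, time-lapse, masks and paths.
#' @export
simulateScene <- function(config = sceneConfig(), outDir) {
  scene <- generateScene(config)
  rnd <- renderTimeLapse(scene)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeTimeLapse(rnd$timelapse, file.path(outDir, "images"))
  utils::write.csv(rnd$truth, file.path(outDir, "truth.csv"),
                   row.names = FALSE)
  maskDir <- file.path(outDir, "masks")
  dir.create(maskDir, showWarnings = FALSE)
  for (t in seq_along(rnd$masks))
    tiff::writeTIFF(rnd$masks[[t]] / 65535,
                    file.path(maskDir, sprintf("t%03d_labels.tif", t - 1L)),
                    bits.per.sample = 16L)
  manifest <- list(
    tool = "phasetrack", version = as.character(utils::packageVersion("phasetrack")),
    command = "simulate", simulate = unclass(config))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  message(sprintf("simulate: %d frame(s), %d cell(s) -> %s",
                  config$nFrames, config$nCells, outDir))
  invisible(list(scene = scene, timelapse = rnd$timelapse,
                 masks = rnd$masks, outDir = outDir))
}

#' Run the processing pipeline
#'
#' Executes the stage sequence enhance, segment, filter, track, summarize
#' on a time-lapse, writing each stage's artifacts under \code{outDir}:
#' enhanced TIFFs, untracked metadata CSV, cleaned (noise-erased) frame
#' TIFFs, tracked metadata CSV plus annotated PNG renders, and the summary
#' CSV. Stages must form a prefix of the pipeline order since each consumes
#' its predecessor's output.
#'
#' @param input a [TimeLapse-class], or a path readable by
#'   [readTimeLapse()].
#' @param outDir output directory.
#' @param config a [pipelineConfig()].
#' @param stages character vector of stages to run (default: all).
#' @return invisibly, a list with the stage products (enhanced time-lapse,
#'   detections, kept/discarded, tracks, summary table).
#' @export
runPipeline <- function(input, outDir, config = pipelineConfig(),
                        stages = .stageOrder) {
  stages <- match.arg(stages, .stageOrder, several.ok = TRUE)
  want <- .stageOrder %in% stages
  if (any(want) && !identical(which(want), seq_len(sum(want)))) {
    first <- .stageOrder[which(want)[1]]
    missing <- .stageOrder[which(!want & seq_along(want) < max(which(want)))][1]
    stop(sprintf("stage '%s' requires earlier stage '%s' to run",
                 .stageOrder[max(which(want))], missing))
  }
  tl <- if (methods::is(input, "TimeLapse")) input
        else readTimeLapse(input, config$io$phasePattern %||%
                                    .defaultPhasePattern)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  # enhance
  enh <- enhanceTimeLapse(tl, config$enhancement)
  writeTimeLapse(enh, file.path(outDir, "enhanced"))
  message(sprintf("enhance: %d frame(s) written", length(enh@frames)))
  out$enhanced <- enh
  phase <- config$io$detectionPhase %||% phaseLabels(enh)[1]

  if ("segment" %in% stages) {
    dets <- segmentTimeLapse(enh, config$segmentation, phase = phase)
    writeMetadata(unlist(dets, recursive = FALSE),
                  file.path(outDir, "detections.csv"))
    message(sprintf("segment: %d detection(s) over %d time point(s)",
                    sum(lengths(dets)), length(dets)))
    out$detections <- dets
  }
  if ("filter" %in% stages) {
    kept <- vector("list", length(out$detections))
    cleanedFrames <- vector("list", 0)
    nDrop <- 0L
    for (t in seq_along(out$detections)) {
      f <- getFrame(enh, t - 1L, phase)
      fl <- applyFilter(out$detections[[t]], config$filter, frame = f)
      kept[[t]] <- fl$kept
      nDrop <- nDrop + length(fl$discarded)
      cleanedFrames[[t]] <- eraseCells(f, fl$discarded)
    }
    writeTimeLapse(TimeLapse(cleanedFrames), file.path(outDir, "cleaned"))
    message(sprintf("filter: %d detection(s) discarded and erased", nDrop))
    out$kept <- kept
  }
  if ("track" %in% stages) {
    tracks <- buildTracks(out$kept, config$tracking)
    writeMetadata(tracks, file.path(outDir, "tracks.csv"))
    writeAnnotated(enh, tracks, file.path(outDir, "annotated"),
                   phase = phase)
    message(sprintf("track: %d track(s) built", length(tracks)))
    out$tracks <- tracks
  }
  if ("summarize" %in% stages) {
    tab <- summarizeFeatures(out$tracks, config$summary$measures)
    utils::write.csv(tab, file.path(outDir, "summary.csv"),
                     row.names = FALSE)
    message(sprintf("summarize: %d measure(s) written", nrow(tab)))
    out$summary <- tab
  }
  manifest <- list(
    tool = "phasetrack",
    version = as.character(utils::packageVersion("phasetrack")),
    command = "run", stages = stages,
    input = if (is.character(input)) input else "in-memory TimeLapse",
    config = lapply(unclass(config), function(x)
      if (is.list(x)) unclass(x) else x))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(out)
}
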