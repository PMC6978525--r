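# End-to-end orchestration: simulate or load tracks, segment, estimate
# diffusivities, classify states, summarize fractions / transitions / g(r),
# and optionally analyze a flow movie. Every stage's output is written as
# CSV next to a machine-readable JSON report.

#' Build a pipeline configuration
#'
#' Defaults follow the standard acquisition and analysis settings: 33 Hz
#' frames, full-frame exposure (R = 1/6), pEM exploring up to 15 states
#' with 20 reinitializations and 150 perturbations, and STICS with 8 x 8
#' pixel subregions shifted by 2, 5-frame TOIs shifted by 3, and a 20-frame
#' immobile filter.
#'
#' @param simConfig a [SimConfig-class] to simulate tracks from, or `NULL`.
#' @param tracksCsv path to a track CSV (see [readTracksCsv()]), or `NULL`.
#'   Exactly one of `simConfig` / `tracksCsv` must be given.
#' @param dt,R frame interval (s) and blur coefficient for estimation.
#' @param segLength,minFrames,maxFrames segmentation rule.
#' @param Kmax,nReinit,nPerturb,pemStopAfter pEM search parameters.
#' @param grREdges pair-correlation bin edges (um); `NULL` disables g(r).
#' @param flow optional list describing a flow-analysis stage:
#'   `fieldSpec`, `imageSize`, `nFrames`, `pixelSize`, `frameInterval`,
#'   `noiseSd` are passed to [simulateFlowStack()]; `immobileWindow`
#'   (`0` = skip), `sub`, `subShift`, `toi`, `toiShift`, `centroid`.
#' @param seed master seed; stage seeds are derived from it.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(simConfig = NULL, tracksCsv = NULL, dt = 1 / 33,
                           R = 1 / 6, segLength = 15L, minFrames = 15L,
                           maxFrames = 105L, Kmax = 15L, nReinit = 20L,
                           nPerturb = 150L, pemStopAfter = 3L,
                           grREdges = seq(0, 5, by = 0.05), flow = NULL,
                           seed = 1L) {
  if (is.null(simConfig) == is.null(tracksCsv))
    stop("give exactly one of 'simConfig' or 'tracksCsv'")
  structure(list(simConfig = simConfig, tracksCsv = tracksCsv, dt = dt,
                 R = R, segLength = as.integer(segLength),
                 minFrames = as.integer(minFrames),
                 maxFrames = as.integer(maxFrames), Kmax = as.integer(Kmax),
                 nReinit = as.integer(nReinit),
                 nPerturb = as.integer(nPerturb),
                 pemStopAfter = pemStopAfter, grREdges = grREdges,
                 flow = flow, seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> segment -> covariance diffusivity -> pEM state
#' classification -> population fractions and transitions -> pair
#' correlation of pooled states (and STICS + directional coherence when a
#' flow stage is configured), writing one CSV per stage plus `report.json`
#' into `outDir`. The report carries the config hash, seed, package
#' version, and every stage's headline numbers; identical configs and seeds
#' give byte-identical output bundles.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if missing).
#' @return the report, invisibly (a list).
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "trackStates",
                 version = as.character(utils::packageVersion("trackStates")),
                 seed = config$seed, config_hash = configHash(config),
                 parameters = list(dt = config$dt, R = config$R,
                                   segLength = config$segLength,
                                   minFrames = config$minFrames,
                                   maxFrames = config$maxFrames,
                                   Kmax = config$Kmax,
                                   nReinit = config$nReinit,
                                   nPerturb = config$nPerturb))

  # --- tracks -------------------------------------------------------------
  if (!is.null(config$simConfig)) {
    tracks <- simulateTracks(config$simConfig)
  } else {
    if (!file.exists(config$tracksCsv))
      stop("tracks stage: input not found: ", config$tracksCsv)
    tracks <- readTracksCsv(config$tracksCsv, frameInterval = config$dt)
  }
  writeTracksCsv(tracks, file.path(outDir, "tracks.csv"))
  report$tracks <- list(n_tracks = nTracks(tracks),
                        n_localizations = nrow(trackData(tracks)))

  # --- segmentation -------------------------------------------------------
  segs <- segmentTracks(tracks, segLength = config$segLength,
                        minFrames = config$minFrames,
                        maxFrames = config$maxFrames)
  if (nSegments(segs) < 2L)
    stop("segmentation stage: fewer than 2 segments survive filtering")
  writeSegmentsCsv(segs, file.path(outDir, "segments.csv"))
  report$segments <- list(n_segments = nSegments(segs))

  # --- covariance diffusivity --------------------------------------------
  cve <- cveDiffusivity(segs, dt = config$dt, R = config$R)
  write.csv(cve, file.path(outDir, "diffusivity.csv"), row.names = FALSE)
  report$diffusivity <- list(mean_D = mean(cve$D), median_D = median(cve$D),
                             mean_sigma2 = mean(cve$sigma2))

  # --- pEM classification -------------------------------------------------
  scan <- pemSearch(segs, Kmax = config$Kmax, nReinit = config$nReinit,
                    nPerturb = config$nPerturb, dt = config$dt, R = config$R,
                    stopAfter = config$pemStopAfter, seed = config$seed)
  fit <- bestModel(scan)
  m <- fit@model
  report$pem <- list(K = m@K, D = m@D, sigma2 = m@sigma2,
                     weights = m@weights, logLik = m@logLik, bic = m@bic,
                     bic_by_K = as.list(scan@bic))
  labs <- stateLabels(fit)
  write.csv(data.frame(segment_id = as.integer(names(labs)), state = labs),
            file.path(outDir, "labels.csv"), row.names = FALSE)

  # --- fractions and transitions -----------------------------------------
  sm <- segmentMatrices(segs)
  fr <- populationFractions(unname(labs), sm$meta$burst, K = m@K)
  write.csv(fr, file.path(outDir, "fractions.csv"), row.names = FALSE)
  tm <- suppressWarnings(stateTransitions(segs, fit))
  write.csv(as.data.frame(tm$counts), file.path(outDir, "transitions.csv"),
            row.names = FALSE)
  report$fractions <- stats::setNames(
    as.list(populationFractions(unname(labs), K = m@K)$fraction),
    paste0("state", seq_len(m@K)))

  # --- pair correlation ---------------------------------------------------
  mask <- if (!is.null(config$simConfig)) config$simConfig@mask else NULL
  if (!is.null(config$grREdges) && !is.null(mask)) {
    grs <- statePairCorrelation(segs, fit, mask, rEdges = config$grREdges,
                                seed = config$seed)
    if (length(grs)) {
      tab <- do.call(rbind, lapply(names(grs), function(g)
        cbind(group = g, grTable(grs[[g]]))))
      write.csv(tab, file.path(outDir, "gr.csv"), row.names = FALSE)
      report$gr <- lapply(grs, function(cur) {
        short <- cur@valid & cur@r <= 0.5
        list(mean_g_short_r = if (any(short)) mean(cur@g[short]) else NA)
      })
    }
  }

  # --- flow stage ---------------------------------------------------------
  if (!is.null(config$flow)) {
    fl <- config$flow
    sim <- simulateFlowStack(fieldSpec = fl$fieldSpec,
                             imageSize = fl$imageSize %||% c(64, 64),
                             nFrames = fl$nFrames %||% 20L,
                             pixelSize = fl$pixelSize %||% 0.1,
                             frameInterval = fl$frameInterval %||% 2,
                             noiseSd = fl$noiseSd %||% 0,
                             seed = config$seed + 1L)
    stk <- sim$stack
    if ((fl$immobileWindow %||% 0L) > 0L)
      stk <- immobileFilter(stk, fl$immobileWindow)
    vf <- sticsVelocity(stk, sub = fl$sub %||% 8L,
                        subShift = fl$subShift %||% 2L,
                        toi = fl$toi %||% 5L, toiShift = fl$toiShift %||% 3L)
    write.csv(velocityVectors(vf), file.path(outDir, "velocity.csv"),
              row.names = FALSE)
    ctr <- fl$centroid %||%
      c(dim(stk)[2] * stackPixelSize(stk) / 2,
        dim(stk)[1] * stackPixelSize(stk) / 2)
    coh <- directionalCoherence(vf, ctr)
    write.csv(data.frame(coherence = coh@values),
              file.path(outDir, "coherence.csv"), row.names = FALSE)
    v <- velocityVectors(vf)
    report$flow <- list(n_vectors = nrow(v), n_valid = sum(v$valid),
                        median_speed = median(v$speed[v$valid]),
                        inward_fraction = coh@inwardFraction,
                        outward_fraction = coh@outwardFraction)
  }

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable hash of the configuration: serialized (version 2, deterministic)
# to a temp file and md5-summed.
configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
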