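#' Named synthetic fixtures
#'
#' Pre-parameterised simulation scenarios used throughout the package's
#' validation suite:
#' \describe{
#'   \item{fig3}{single apoptotic event in the middle of a ~455-cell
#'     non-node field; wave at 4.7 um/min out to 450 um; noiseless
#'     rendering.}
#'   \item{fig1}{patterned monolayer: nodes at 399 um spacing, 80 um radius,
#'     4x denser than the surround; one frame.}
#'   \item{fig4_pma}{global-activation regime (E = 1 everywhere, dispersed
#'     uniform field), the phorbol-ester analogue.}
#'   \item{fig6_meki}{ERK-off regime with enlarged nodes (120 um radius),
#'     the MEK-inhibition analogue.}
#'   \item{piv_wave}{dense small field with one central event, for flow
#'     analysis.}
#'   \item{piv_gefitinib}{as piv_wave but with `migrationGain = 0` (no
#'     wave-directed motion), the EGFR-inhibition analogue.}
#' }
#'
#' @param name fixture name (see Details).
#' @param seed RNG seed for the simulation.
#' @param dir optional output directory; writes the stack, ground-truth CSVs
#'   and configuration there.
#' @param render logical; render the image stack (ground truth alone is much
#'   cheaper).
#' @param ... SimConfig slot overrides (e.g. `waveExtent = 447`,
#'   `noiseSd = 0.01`).
#' @return list with `config` ([SimConfig-class]), `gt`
#'   ([GroundTruth-class]), `events` (the scheduled event table) and, when
#'   `render = TRUE`, `stack` ([FrameStack-class]).
#' @export
makeFixtures <- function(name, seed = 42, dir = NULL, render = TRUE, ...) {
    presets <- list(
        fig3 = list(cfg = list(fieldSize = c(960, 960), nodeSpacingMean = 0,
                               nodeDensity = 0, nonnodeDensity = 4.95,
                               nFrames = 28, apoptosisRate = 0,
                               waveSpeed = 4.7, waveExtent = 450,
                               durationAtOrigin = 40, noiseSd = 0),
                    events = data.frame(frame = 7)),
        fig1 = list(cfg = list(fieldSize = c(2000, 2000), nFrames = 1,
                               apoptosisRate = 0),
                    events = NULL),
        fig4_pma = list(cfg = list(fieldSize = c(1200, 1200),
                                   nodeSpacingMean = 0, nodeDensity = 0,
                                   nonnodeDensity = 15, nFrames = 3,
                                   apoptosisRate = 0, globalErk = "on"),
                        events = NULL),
        fig6_meki = list(cfg = list(fieldSize = c(2000, 2000),
                                    nodeRadius = 120, nFrames = 1,
                                    apoptosisRate = 0, globalErk = "off"),
                         events = NULL),
        piv_wave = list(cfg = list(fieldSize = c(420, 420),
                                   nodeSpacingMean = 0, nodeDensity = 0,
                                   nonnodeDensity = 30, nFrames = 14,
                                   apoptosisRate = 0, waveExtent = 220,
                                   durationAtOrigin = 40,
                                   migrationGain = 1),
                        events = data.frame(frame = 3)),
        piv_gefitinib = list(cfg = list(fieldSize = c(420, 420),
                                        nodeSpacingMean = 0, nodeDensity = 0,
                                        nonnodeDensity = 30, nFrames = 14,
                                        apoptosisRate = 0, waveExtent = 220,
                                        durationAtOrigin = 40,
                                        migrationGain = 0),
                             events = data.frame(frame = 3)))
    if (!name %in% names(presets))
        stop("unknown fixture '", name, "'; valid names: ",
             paste(names(presets), collapse = ", "))
    p <- presets[[name]]
    args <- utils::modifyList(p$cfg, list(...))
    args$rngSeed <- seed
    cfg <- do.call(simConfig, args)
    gt <- simulateMonolayer(cfg, events = p$events)
    out <- list(config = cfg, gt = gt, events = p$events)
    if (render) out$stack <- renderFrameStack(gt)
    if (!is.null(dir)) {
        writeGroundTruth(gt, dir)
        if (render)
            writeFrameStack(out$stack, file.path(dir, "stack.tif"))
    }
    out
}

defaultPipelineParams <- function() list(
    segmentation = list(smoothingSigma = 0.5, minArea = 15,
                        watershedTolerance = 0.3, annulusWidth = 2),
    tracking = list(gatingRadius = 15, maxGap = 2),
    events = list(threshold = 0.5, epsUm = 20, maxFrameGap = 2),
    waves = list(binWidth = 25, baselineFrames = 6, k = 3, relFloor = 0.01,
                 minCells = 50),
    nodes = list(bandwidth = 40, gridSize = 10, minArea = 5000,
                 densityFactor = 1.5),
    piv = list(enabled = TRUE, windowPx = 32, overlap = 0.5, rMax = Inf),
    heatmap = list(enabled = FALSE, minPts = 5))

# merge user parameter blocks over defaults, rejecting unknown keys
mergePipelineParams <- function(params) {
    def <- defaultPipelineParams()
    unknown <- setdiff(names(params), names(def))
    if (length(unknown))
        stop("unknown pipeline parameter block(s): ",
             paste(unknown, collapse = ", "))
    for (blk in names(params)) {
        bad <- setdiff(names(params[[blk]]), names(def[[blk]]))
        if (length(bad))
            stop("unknown key(s) in '", blk, "': ",
                 paste(bad, collapse = ", "))
        def[[blk]] <- utils::modifyList(def[[blk]], params[[blk]])
    }
    def
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> segment -> measure -> track -> detect events ->
#' wave kinetics per event -> node detection, compartments, event
#' localization, nearest-nuclei distances -> PIV convergence. Returns a
#' report list and, when `outDir` is given, writes `report.json`,
#' `tracks.csv`, `events.csv` and `measurements.csv` there.
#'
#' @param stack a [FrameStack-class], a path to a stack written by
#'   [writeFrameStack()], or `NULL` to simulate.
#' @param sim a [SimConfig-class] used when `stack` is `NULL`.
#' @param simEvents optional explicit event schedule for the simulation.
#' @param params nested list of per-stage parameter overrides (unknown keys
#'   are rejected); see `erkwave:::defaultPipelineParams()`.
#' @param outDir optional output directory.
#' @param verbose print stage progress.
#' @return report list with elements `nCells`, `tracks`, `events`, `waves`,
#'   `nodes`, `compartments`, `nnd`, `piv`, `timing`, `provenance`.
#' @export
runPipeline <- function(stack = NULL, sim = NULL, simEvents = NULL,
                        params = list(), outDir = NULL, verbose = FALSE) {
    par <- mergePipelineParams(params)
    say <- function(...) if (verbose) message("[erkwave] ", ...)
    t0 <- proc.time()[3]
    timing <- c()
    tick <- function(stage) {
        timing[stage] <<- round(proc.time()[3] - t0 - sum(timing), 2)
    }
    prov <- list()
    if (is.null(stack)) {
        if (is.null(sim))
            stop("provide an image stack or a simulation configuration")
        say("simulating monolayer")
        gt <- simulateMonolayer(sim, events = simEvents)
        stack <- renderFrameStack(gt)
        prov$sim_seed <- sim@rngSeed
        tick("simulate")
    } else if (is.character(stack)) {
        stack <- readFrameStack(stack)
        tick("read")
    }
    stopifnot(is(stack, "FrameStack"))
    say("segmenting ", nFrames(stack), " frames")
    seg <- segmentStack(stack, widthPx = par$segmentation$annulusWidth,
                        smoothingSigma = par$segmentation$smoothingSigma,
                        minArea = par$segmentation$minArea,
                        watershedTolerance =
                            par$segmentation$watershedTolerance)
    meas <- seg$measurements
    tick("segment")
    say("linking tracks")
    tracks <- linkTracks(meas, gatingRadius = par$tracking$gatingRadius,
                         maxGap = par$tracking$maxGap)
    tick("track")
    events <- if ("CASP" %in% channelNames(stack)) {
        detectApoptosisEvents(stack, threshold = par$events$threshold,
                              epsUm = par$events$epsUm,
                              maxFrameGap = par$events$maxFrameGap)
    } else detectApoptosisEvents(tracks = tracks)
    tick("events")
    say(nrow(events), " apoptotic event(s)")
    waves <- lapply(seq_len(nrow(events)), function(i) {
        ev <- events[i, ]
        ws <- tryCatch(estimateWave(tracks, ev,
                                    frameInterval = frameInterval(stack),
                                    binWidth = par$waves$binWidth,
                                    baselineFrames = par$waves$baselineFrames,
                                    k = par$waves$k,
                                    relFloor = par$waves$relFloor,
                                    minCells = par$waves$minCells),
                       error = function(e) conditionMessage(e))
        if (is.character(ws)) return(list(event_id = ev$event_id,
                                          skipped = ws))
        list(event_id = ev$event_id, detected = ws@detected,
             speed_um_min = ws@speed,
             speed_extent_duration = ws@speedExtentDuration,
             extent_um = ws@extent, total_duration_min = ws@totalDuration,
             n_cells = ws@nCells)
    })
    tick("waves")
    f1 <- meas[meas$frame == min(meas$frame), , drop = FALSE]
    nodeSet <- if (nrow(f1)) {
        detectNodes(f1[, c("x_um", "y_um")],
                    fieldSize = c(ncol(stack@pixels[, , 1, 1]),
                                  nrow(stack@pixels[, , 1, 1])) *
                        pixelSize(stack),
                    bandwidth = par$nodes$bandwidth,
                    gridSize = par$nodes$gridSize,
                    minArea = par$nodes$minArea,
                    densityFactor = par$nodes$densityFactor)
    } else NULL
    comp <- if (!is.null(nodeSet) && nrow(f1))
        table(assignCompartments(f1, nodeSet)) else NULL
    loc <- if (!is.null(nodeSet) && nrow(events))
        localizeEvents(events, nodeSet) else NULL
    nnd <- if (nrow(f1) >= 2)
        nearestNucleiDistances(f1[, c("x_um", "y_um")]) else numeric(0)
    tick("nodes")
    pivOut <- NULL
    if (par$piv$enabled && nFrames(stack) >= 2) {
        say("particle image velocimetry")
        flow <- pivStack(stack, windowPx = par$piv$windowPx,
                         overlap = par$piv$overlap)
        conv <- vapply(seq_len(nrow(events)), function(i)
            suppressWarnings(convergenceToward(flow, events[i, ],
                                               rMax = par$piv$rMax)),
            numeric(1))
        pivOut <- list(meanSpeed = mean(sqrt(flow$u_um_min^2 +
                                             flow$v_um_min^2), na.rm = TRUE),
                       convergence_um_min = conv)
    }
    tick("piv")
    report <- list(
        nCells = as.list(table(meas$frame)),
        tracks = list(n_tracks = length(unique(tracks$track_id)),
                      n_rows = nrow(tracks)),
        events = events,
        waves = waves,
        nodes = if (!is.null(nodeSet)) list(
            n = nrow(nodeTable(nodeSet)),
            mean_spacing_um = if (length(nodeSpacing(nodeSet)))
                mean(nodeSpacing(nodeSet)) else NA,
            total_area_um2 = sum(nodeTable(nodeSet)$area_um2)) else NULL,
        compartments = if (!is.null(comp)) as.list(comp) else NULL,
        event_localization = loc,
        nnd = if (length(nnd)) list(mean_um = mean(nnd),
                                    median_um = median(nnd)) else NULL,
        piv = pivOut,
        timing_s = as.list(timing),
        provenance = prov)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        write.csv(tracks, file.path(outDir, "tracks.csv"), row.names = FALSE)
        write.csv(events, file.path(outDir, "events.csv"), row.names = FALSE)
        write.csv(meas, file.path(outDir, "measurements.csv"),
                  row.names = FALSE)
        jsonlite::write_json(report, file.path(outDir, "report.json"),
                             auto_unbox = TRUE, digits = NA, null = "null",
                             force = TRUE)
    }
    report$trackTable <- tracks
    report$measurements <- meas
    report$nodeSet <- nodeSet
    invisible(report)
}
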