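#' @import methods
#' @importFrom stats rnorm runif rpois sd median coef lm setNames
#'   binom.test fft dist cor quantile
#' @importFrom utils head tail write.csv read.csv
#' @useDynLib erkwave, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Simulation configuration for the synthetic organoid monolayer
#'
#' `SimConfig` holds every parameter of the agent-based monolayer simulator:
#' field geometry and calibration, node (crypt-like compartment) placement,
#' cell densities, apoptosis scheduling, trigger-wave kinetics, wave-directed
#' migration, and KTR rendering. All lengths are in micrometres, all times in
#' minutes, densities in cells per 100x100 um tile.
#'
#' @slot fieldSize numeric(2), field width and height (um).
#' @slot pixelSize um per pixel of the rendered stack.
#' @slot frameInterval minutes between frames.
#' @slot nFrames number of frames.
#' @slot nodeSpacingMean target mean nearest-neighbour distance between node
#'   centres (um); 0 disables node placement.
#' @slot nodeRadius node disk radius (um).
#' @slot nodeJitter placement jitter as a fraction of the spacing.
#' @slot nodeDensity,nonnodeDensity cells per 100x100 um inside / outside
#'   node disks.
#' @slot nucleusRadius nuclear radius (um); minimum seeded inter-nucleus
#'   spacing is 1.5x this value.
#' @slot apoptosisRate expected apoptotic events per frame.
#' @slot pNonnode probability that an event strikes a non-node cell.
#' @slot waveSpeed radial front speed v (um/min).
#' @slot waveExtent maximal wave radius R_max (um).
#' @slot durationAtOrigin activation duration D0 at the source (min).
#' @slot amplitudeAtOrigin activation amplitude A0 at the source, in (0, 1].
#' @slot decayDuration,decayAmplitude taper exponents: duration and amplitude
#'   scale as (1 - d/R_max)^alpha.
#' @slot recoilDistance initial outward displacement (um) of cells within
#'   `recoilRadius` of the dying cell at the event frame.
#' @slot recoilRadius radius (um) of the recoil neighbourhood.
#' @slot migrationGain drift speed toward the wave source per unit ERK
#'   activity (um/min).
#' @slot jitterSd per-axis standard deviation of the per-frame isotropic
#'   positional jitter (um).
#' @slot ktrPartition fold-change g of the cytoplasm/nucleus (C/N) KTR ratio
#'   between ERK activity 0 and 1.
#' @slot cnBaseline true C/N ratio of a fully inactive cell (< 1: reporter
#'   nuclear-enriched when ERK is off).
#' @slot noiseSd additive Gaussian intensity noise of the renderer.
#' @slot globalErk "none" for wave-driven activity, "on" forces E = 1
#'   everywhere (phorbol-ester-like regime), "off" forces E = 0 (MEK
#'   inhibition regime).
#' @slot rngSeed integer seed threaded through every stochastic step.
#' @export
setClass("SimConfig", representation(
    fieldSize = "numeric", pixelSize = "numeric", frameInterval = "numeric",
    nFrames = "numeric", nodeSpacingMean = "numeric", nodeRadius = "numeric",
    nodeJitter = "numeric", nodeDensity = "numeric", nonnodeDensity = "numeric",
    nucleusRadius = "numeric", apoptosisRate = "numeric", pNonnode = "numeric",
    waveSpeed = "numeric", waveExtent = "numeric",
    durationAtOrigin = "numeric", amplitudeAtOrigin = "numeric",
    decayDuration = "numeric", decayAmplitude = "numeric",
    recoilDistance = "numeric", recoilRadius = "numeric",
    migrationGain = "numeric", jitterSd = "numeric",
    ktrPartition = "numeric", cnBaseline = "numeric", noiseSd = "numeric",
    globalErk = "character", rngSeed = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character(0)
    pos <- c(pixelSize = object@pixelSize, frameInterval = object@frameInterval,
             nFrames = object@nFrames, nodeRadius = object@nodeRadius,
             nucleusRadius = object@nucleusRadius, waveSpeed = object@waveSpeed,
             waveExtent = object@waveExtent,
             durationAtOrigin = object@durationAtOrigin,
             ktrPartition = object@ktrPartition, cnBaseline = object@cnBaseline)
    bad <- names(pos)[!is.finite(pos) | pos <= 0]
    if (length(bad))
        msg <- c(msg, paste0("strictly positive value required for: ",
                             paste(bad, collapse = ", ")))
    if (length(object@fieldSize) != 2 || any(object@fieldSize <= 0))
        msg <- c(msg, "fieldSize must be two positive lengths (um)")
    nonneg <- c(nodeSpacingMean = object@nodeSpacingMean,
                nodeDensity = object@nodeDensity,
                nonnodeDensity = object@nonnodeDensity,
                apoptosisRate = object@apoptosisRate,
                decayDuration = object@decayDuration,
                decayAmplitude = object@decayAmplitude,
                recoilDistance = object@recoilDistance,
                recoilRadius = object@recoilRadius,
                migrationGain = object@migrationGain,
                jitterSd = object@jitterSd, noiseSd = object@noiseSd,
                nodeJitter = object@nodeJitter)
    badn <- names(nonneg)[!is.finite(nonneg) | nonneg < 0]
    if (length(badn))
        msg <- c(msg, paste0("non-negative value required for: ",
                             paste(badn, collapse = ", ")))
    if (object@pNonnode < 0 || object@pNonnode > 1)
        msg <- c(msg, "pNonnode must lie in [0, 1]")
    if (object@amplitudeAtOrigin <= 0 || object@amplitudeAtOrigin > 1)
        msg <- c(msg, "amplitudeAtOrigin must lie in (0, 1]")
    if (object@waveExtent < object@waveSpeed * object@frameInterval)
        msg <- c(msg, "waveExtent must be >= waveSpeed * frameInterval")
    if (!object@globalErk %in% c("none", "on", "off"))
        msg <- c(msg, "globalErk must be one of 'none', 'on', 'off'")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe a confluent colonic organoid monolayer: dense crypt-like
#' nodes spaced ~399 um apart in a sparser differentiated background, rare
#' apoptotic extrusions biased to non-node regions, and apoptosis-triggered
#' ERK waves travelling at 4.7 um/min out to 450 um with linearly tapering
#' duration and amplitude.
#'
#' @param fieldSize field width/height in um.
#' @param pixelSize,frameInterval stack calibration (um/px, min/frame).
#' @param nFrames number of frames to simulate.
#' @param nodeSpacingMean,nodeRadius,nodeJitter node placement parameters.
#' @param nodeDensity,nonnodeDensity cell densities per 100x100 um.
#' @param nucleusRadius nuclear radius (um).
#' @param apoptosisRate events per frame; `pNonnode` biases them to non-node
#'   cells.
#' @param pNonnode probability an event strikes a non-node cell.
#' @param waveSpeed,waveExtent,durationAtOrigin,amplitudeAtOrigin wave front
#'   kinetics (v, R_max, D0, A0).
#' @param decayDuration,decayAmplitude taper exponents for D(d) and A(d).
#' @param recoilDistance,recoilRadius initial outward recoil of cells next to
#'   the dying cell.
#' @param migrationGain wave-directed drift speed per unit activity (um/min).
#' @param jitterSd per-frame isotropic positional jitter sd (um).
#' @param ktrPartition C/N fold-change between E = 0 and E = 1.
#' @param cnBaseline C/N ratio of an inactive cell.
#' @param noiseSd additive rendering noise sd (intensity units; signal scale
#'   is ~0.35-1).
#' @param globalErk "none", "on", or "off" (see [SimConfig-class]).
#' @param rngSeed integer seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(fieldSize = c(500, 500), nFrames = 10)
#' cfg
#' @export
simConfig <- function(fieldSize = c(2000, 2000), pixelSize = 1.3,
                      frameInterval = 5, nFrames = 30,
                      nodeSpacingMean = 399, nodeRadius = 80,
                      nodeJitter = 0.05, nodeDensity = 40,
                      nonnodeDensity = 10, nucleusRadius = 6,
                      apoptosisRate = 0.02, pNonnode = 0.8,
                      waveSpeed = 4.7, waveExtent = 450,
                      durationAtOrigin = 40, amplitudeAtOrigin = 1,
                      decayDuration = 1, decayAmplitude = 1,
                      recoilDistance = 2, recoilRadius = 25,
                      migrationGain = 0.5, jitterSd = 0.15,
                      ktrPartition = 2, cnBaseline = 0.85, noiseSd = 0.01,
                      globalErk = "none", rngSeed = 1L) {
    new("SimConfig", fieldSize = as.numeric(fieldSize),
        pixelSize = pixelSize, frameInterval = frameInterval,
        nFrames = nFrames, nodeSpacingMean = nodeSpacingMean,
        nodeRadius = nodeRadius, nodeJitter = nodeJitter,
        nodeDensity = nodeDensity, nonnodeDensity = nonnodeDensity,
        nucleusRadius = nucleusRadius, apoptosisRate = apoptosisRate,
        pNonnode = pNonnode, waveSpeed = waveSpeed, waveExtent = waveExtent,
        durationAtOrigin = durationAtOrigin,
        amplitudeAtOrigin = amplitudeAtOrigin,
        decayDuration = decayDuration, decayAmplitude = decayAmplitude,
        recoilDistance = recoilDistance, recoilRadius = recoilRadius,
        migrationGain = migrationGain, jitterSd = jitterSd,
        ktrPartition = ktrPartition, cnBaseline = cnBaseline,
        noiseSd = noiseSd, globalErk = globalErk, rngSeed = rngSeed)
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@fieldSize[1], "x", object@fieldSize[2], "um,",
        object@nFrames, "frames @", object@frameInterval, "min,",
        object@pixelSize, "um/px\n")
    cat("  nodes: spacing", object@nodeSpacingMean, "um, radius",
        object@nodeRadius, "um; densities", object@nodeDensity, "/",
        object@nonnodeDensity, "per (100 um)^2\n")
    cat("  wave: v =", object@waveSpeed, "um/min, R_max =",
        object@waveExtent, "um, D0 =", object@durationAtOrigin,
        "min, A0 =", object@amplitudeAtOrigin, "\n")
    cat("  apoptosis:", object@apoptosisRate, "events/frame, P(non-node) =",
        object@pNonnode, "; seed", object@rngSeed, "\n")
})

#' Calibrated multi-channel time-lapse image stack
#'
#' Pixel data are stored as a 4-D array indexed `[row, col, channel, frame]`.
#' Row r, column c map to micrometre coordinates x = (c - 0.5) * pixelSize,
#' y = (r - 0.5) * pixelSize (pixel centres); frame f occurs at time
#' (f - 1) * frameInterval minutes.
#'
#' @slot pixels numeric 4-D array `[row, col, channel, frame]`, non-negative.
#' @slot channels channel names (e.g. "H2B", "KTR", "CASP").
#' @slot pixelSize um per pixel.
#' @slot frameInterval minutes per frame.
#' @export
setClass("FrameStack", representation(
    pixels = "array", channels = "character",
    pixelSize = "numeric", frameInterval = "numeric"))

setValidity("FrameStack", function(object) {
    d <- dim(object@pixels)
    if (length(d) != 4)
        return("pixels must be a 4-D array [row, col, channel, frame]")
    if (d[3] != length(object@channels))
        return("length(channels) must equal dim(pixels)[3]")
    if (object@pixelSize <= 0 || object@frameInterval <= 0)
        return("pixelSize and frameInterval must be strictly positive")
    if (min(object@pixels) < 0)
        return("intensities must be non-negative")
    TRUE
})

#' @describeIn FrameStack-class constructor.
#' @param pixels 4-D array `[row, col, channel, frame]`.
#' @param channels character vector of channel names.
#' @param pixelSize,frameInterval calibration.
#' @export
FrameStack <- function(pixels, channels, pixelSize, frameInterval) {
    new("FrameStack", pixels = pixels, channels = channels,
        pixelSize = pixelSize, frameInterval = frameInterval)
}

setMethod("show", "FrameStack", function(object) {
    d <- dim(object@pixels)
    cat("FrameStack:", d[1], "x", d[2], "px,", d[4], "frames,",
        d[3], "channels (", paste(object@channels, collapse = ", "), ")\n")
    cat("  calibration:", object@pixelSize, "um/px,",
        object@frameInterval, "min/frame\n")
})

#' Ground truth of a simulated monolayer
#'
#' @slot cells data.frame with one row per living cell per frame:
#'   `cell_id`, `frame`, `x_um`, `y_um`, `E` (true ERK activity in `[0, 1]`),
#'   `compartment` ("node"/"non-node").
#' @slot events data.frame of apoptotic events: `event_id`, `frame`, `x_um`,
#'   `y_um`, `cell_id`.
#' @slot nodes data.frame of planted node disks: `node_id`, `x_um`, `y_um`,
#'   `radius_um`.
#' @slot config the [SimConfig-class] that generated the object.
#' @export
setClass("GroundTruth", representation(
    cells = "data.frame", events = "data.frame", nodes = "data.frame",
    config = "SimConfig"))

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", length(unique(object@cells$cell_id)), "cells,",
        max(object@cells$frame), "frames,", nrow(object@events), "events,",
        nrow(object@nodes), "nodes\n")
})

#' @describeIn GroundTruth-class per-cell per-frame table.
#' @param object a `GroundTruth`.
#' @export
setGeneric("cellTable", function(object) standardGeneric("cellTable"))
#' @rdname GroundTruth-class
#' @export
setMethod("cellTable", "GroundTruth", function(object) object@cells)

#' @describeIn GroundTruth-class apoptotic event table.
#' @export
setGeneric("eventTable", function(object) standardGeneric("eventTable"))
#' @rdname GroundTruth-class
#' @export
setMethod("eventTable", "GroundTruth", function(object) object@events)

#' @describeIn GroundTruth-class planted node table.
#' @export
setGeneric("plantedNodes", function(object) standardGeneric("plantedNodes"))
#' @rdname GroundTruth-class
#' @export
setMethod("plantedNodes", "GroundTruth", function(object) object@nodes)

#' Detected node compartments
#'
#' Result of [detectNodes()]: connected high-density regions of the nuclear
#' centroid field, with centroids, areas, boundary polygons, the
#' nearest-neighbour spacing distribution, and the label grid used for
#' compartment lookup.
#'
#' @slot nodes data.frame: `node_id`, `x_um`, `y_um` (density-weighted
#'   centroid), `area_um2`.
#' @slot boundaries list of two-column matrices (x_um, y_um polygon vertices),
#'   one per node.
#' @slot spacing numeric vector of nearest-neighbour centroid distances (um);
#'   empty when fewer than two nodes were found.
#' @slot regionGrid integer matrix labelling grid tiles by node id (0 =
#'   non-node).
#' @slot gridSize tile edge length (um) of `regionGrid`.
#' @export
setClass("NodeSet", representation(
    nodes = "data.frame", boundaries = "list", spacing = "numeric",
    regionGrid = "matrix", gridSize = "numeric"))

setMethod("show", "NodeSet", function(object) {
    cat("NodeSet:", nrow(object@nodes), "nodes")
    if (length(object@spacing))
        cat("; mean NN spacing", round(mean(object@spacing), 1), "um")
    cat("; total area", round(sum(object@nodes$area_um2)), "um^2\n")
})

#' @describeIn NodeSet-class number of detected nodes.
#' @param x a `NodeSet`.
#' @export
setMethod("length", "NodeSet", function(x) nrow(x@nodes))

#' @describeIn NodeSet-class node centroid/area table.
#' @param object a `NodeSet`.
#' @export
setGeneric("nodeTable", function(object) standardGeneric("nodeTable"))
#' @rdname NodeSet-class
#' @export
setMethod("nodeTable", "NodeSet", function(object) object@nodes)

#' @describeIn NodeSet-class nearest-neighbour spacing distribution (um).
#' @export
setGeneric("nodeSpacing", function(object) standardGeneric("nodeSpacing"))
#' @rdname NodeSet-class
#' @export
setMethod("nodeSpacing", "NodeSet", function(object) object@spacing)

#' @describeIn NodeSet-class boundary polygons (list of x/y um matrices).
#' @export
setGeneric("nodeBoundaries", function(object) standardGeneric("nodeBoundaries"))
#' @rdname NodeSet-class
#' @export
setMethod("nodeBoundaries", "NodeSet", function(object) object@boundaries)

#' Summary of one apoptosis-referenced ERK wave
#'
#' Result of [estimateWave()]. Distances are referenced to the apoptotic
#' event; onsets are minutes after the event.
#'
#' @slot eventId event identifier.
#' @slot detected logical; `FALSE` when no distance bin crossed threshold.
#' @slot speed front speed from the least-squares regression of bin-centre
#'   distance on onset time (um/min); `NA` with fewer than 3 onset bins.
#' @slot speedExtentDuration secondary statistic extent / totalDuration
#'   (um/min), the ratio the wave's printed exemplar figures correspond to.
#' @slot extent largest bin centre with a detected onset (um).
#' @slot totalDuration last onset plus that bin's activity duration (min).
#' @slot bins per-bin table: `bin_center_um`, `n_cells`, `onset_min`,
#'   `duration_min`, `peak_cn`.
#' @slot nCells number of tracks analysed.
#' @export
setClass("WaveSummary", representation(
    eventId = "numeric", detected = "logical", speed = "numeric",
    speedExtentDuration = "numeric", extent = "numeric",
    totalDuration = "numeric", bins = "data.frame", nCells = "numeric"))

setMethod("show", "WaveSummary", function(object) {
    if (!object@detected) {
        cat("WaveSummary (event", object@eventId, "): no wave detected\n")
        return(invisible(NULL))
    }
    cat("WaveSummary (event", object@eventId, "):",
        object@nCells, "cells\n")
    cat("  speed", round(object@speed, 2), "um/min (onset regression);",
        round(object@speedExtentDuration, 2), "um/min (extent/duration)\n")
    cat("  extent", object@extent, "um; total duration",
        round(object@totalDuration, 1), "min;",
        sum(!is.na(object@bins$onset_min)), "onset bins\n")
})

#' @describeIn WaveSummary-class estimated front speed (um/min).
#' @param object a `WaveSummary`.
#' @export
setGeneric("waveSpeedEstimate",
           function(object) standardGeneric("waveSpeedEstimate"))
#' @rdname WaveSummary-class
#' @export
setMethod("waveSpeedEstimate", "WaveSummary", function(object) object@speed)

#' @describeIn WaveSummary-class estimated maximal extent (um).
#' @export
setGeneric("waveExtentEstimate",
           function(object) standardGeneric("waveExtentEstimate"))
#' @rdname WaveSummary-class
#' @export
setMethod("waveExtentEstimate", "WaveSummary", function(object) object@extent)

#' @describeIn WaveSummary-class per-distance-bin onset/duration/peak table.
#' @export
setGeneric("binTable", function(object) standardGeneric("binTable"))
#' @rdname WaveSummary-class
#' @export
setMethod("binTable", "WaveSummary", function(object) object@bins)
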