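#' Place node (crypt-like compartment) centres
#'
#' Nodes are laid out on a jittered square grid whose constant equals the
#' requested mean nearest-neighbour spacing, then clamped so every disk lies
#' fully inside the field. A field smaller than one grid cell receives a
#' single central node. Uses the caller's RNG stream.
#'
#' @param config a [SimConfig-class].
#' @return numeric matrix with columns `x_um`, `y_um` (zero rows when
#'   `nodeSpacingMean` is 0).
#' @export
placeNodes <- function(config) {
    stopifnot(is(config, "SimConfig"))
    a <- config@nodeSpacingMean
    r <- config@nodeRadius
    W <- config@fieldSize[1]; H <- config@fieldSize[2]
    empty <- matrix(numeric(0), 0, 2,
                    dimnames = list(NULL, c("x_um", "y_um")))
    if (a == 0) return(empty)
    if (W < 2 * r || H < 2 * r)
        stop("field too small to contain a single node disk")
    nx <- max(1L, floor(W / a)); ny <- max(1L, floor(H / a))
    if ((nx > 1 || ny > 1) && a < 2 * r)
        stop("node spacing smaller than node diameter")
    gx <- (W - (nx - 1) * a) / 2 + (seq_len(nx) - 1) * a
    gy <- (H - (ny - 1) * a) / 2 + (seq_len(ny) - 1) * a
    cen <- as.matrix(expand.grid(x_um = gx, y_um = gy))
    j <- config@nodeJitter * a
    for (try in seq_len(100)) {
        out <- cen
        if (j > 0)
            out <- out + matrix(runif(2 * nrow(cen), -j, j), ncol = 2)
        out[, 1] <- pmin(pmax(out[, 1], r), W - r)
        out[, 2] <- pmin(pmax(out[, 2], r), H - r)
        if (nrow(out) < 2) break
        dmin <- min(dist(out))
        if (dmin >= 2 * r) break
        if (try == 100) stop("could not place nodes >= 2 radii apart")
    }
    dimnames(out) <- list(NULL, c("x_um", "y_um"))
    out
}

# TRUE for points inside any node disk
inNodeDisk <- function(x, y, nodeCenters, radius) {
    if (nrow(nodeCenters) == 0) return(rep(FALSE, length(x)))
    inside <- rep(FALSE, length(x))
    for (k in seq_len(nrow(nodeCenters))) {
        inside <- inside |
            ((x - nodeCenters[k, 1])^2 + (y - nodeCenters[k, 2])^2 <=
                 radius^2)
    }
    inside
}

#' Seed nuclei into node and non-node compartments
#'
#' Cells are dart-thrown at the configured densities with a hard minimum
#' inter-nucleus spacing of 1.5x the nuclear radius. Uses the caller's RNG
#' stream.
#'
#' @param config a [SimConfig-class].
#' @param nodeCenters matrix from [placeNodes()].
#' @return data.frame: `cell_id`, `x_um`, `y_um`, `compartment`.
#' @export
seedCells <- function(config, nodeCenters) {
    stopifnot(is(config, "SimConfig"))
    W <- config@fieldSize[1]; H <- config@fieldSize[2]
    r <- config@nodeRadius
    minSep <- 1.5 * config@nucleusRadius
    margin <- config@nucleusRadius
    nodeArea <- nrow(nodeCenters) * pi * r^2
    nNode <- round(config@nodeDensity * nodeArea / 1e4)
    nNon <- round(config@nonnodeDensity * (W * H - nodeArea) / 1e4)
    if (nNode + nNon < 1) stop("configured densities yield zero cells")
    xs <- numeric(0); ys <- numeric(0); comp <- character(0)
    farEnough <- function(x, y) {
        if (!length(xs)) return(TRUE)
        min((xs - x)^2 + (ys - y)^2) >= minSep^2
    }
    drawInNode <- function() {
        k <- sample.int(nrow(nodeCenters), 1)
        rr <- r * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
        c(nodeCenters[k, 1] + rr * cos(th), nodeCenters[k, 2] + rr * sin(th))
    }
    place <- function(n, node) {
        placed <- 0; attempts <- 0
        while (placed < n) {
            attempts <- attempts + 1
            if (attempts > 200 * n + 1000)
                stop("densities incompatible with minimum nuclear spacing")
            p <- if (node) drawInNode() else
                c(runif(1, margin, W - margin), runif(1, margin, H - margin))
            if (p[1] < margin || p[1] > W - margin ||
                p[2] < margin || p[2] > H - margin) next
            isNode <- inNodeDisk(p[1], p[2], nodeCenters, r)
            if (isNode != node) next
            if (!farEnough(p[1], p[2])) next
            xs[length(xs) + 1] <<- p[1]
            ys[length(ys) + 1] <<- p[2]
            comp[length(comp) + 1] <<- if (node) "node" else "non-node"
            placed <- placed + 1
        }
    }
    if (nNode > 0 && nrow(nodeCenters) > 0) place(nNode, TRUE)
    if (nNon > 0) place(nNon, FALSE)
    data.frame(cell_id = seq_along(xs), x_um = xs, y_um = ys,
               compartment = comp, stringsAsFactors = FALSE)
}

#' Schedule apoptotic events
#'
#' Per frame, a Poisson(`apoptosisRate`) number of cells die; each event
#' strikes a non-node cell with probability `pNonnode` (falling back to the
#' other compartment when empty). A cell dies at most once. Uses the caller's
#' RNG stream.
#'
#' @param config a [SimConfig-class].
#' @param cells data.frame from [seedCells()].
#' @return data.frame: `event_id`, `frame`, `cell_id` (zero rows when the
#'   rate is 0).
#' @export
scheduleApoptosis <- function(config, cells) {
    stopifnot(is(config, "SimConfig"), nrow(cells) >= 1)
    out <- data.frame(event_id = integer(0), frame = integer(0),
                      cell_id = integer(0))
    if (config@apoptosisRate == 0) return(out)
    dead <- integer(0)
    eid <- 0L
    for (f in seq_len(config@nFrames)) {
        k <- rpois(1, config@apoptosisRate)
        for (i in seq_len(k)) {
            wantNon <- runif(1) < config@pNonnode
            pool <- cells$cell_id[!cells$cell_id %in% dead &
                (cells$compartment == "non-node") == wantNon]
            if (!length(pool))
                pool <- cells$cell_id[!cells$cell_id %in% dead]
            if (!length(pool)) next
            victim <- pool[sample.int(length(pool), 1)]
            eid <- eid + 1L
            out <- rbind(out, data.frame(event_id = eid, frame = f,
                                         cell_id = victim))
            dead <- c(dead, victim)
        }
    }
    out
}

#' Wave kinetics of one apoptotic event
#'
#' For a cell at distance `d` (um) from the event at its frame, the
#' activation onset is `t_a + d/v`, the duration `D0 * (1 - d/R_max)^alpha_D`
#' and the amplitude `A0 * (1 - d/R_max)^alpha_A`; cells beyond `R_max` are
#' never activated.
#'
#' @param event list or one-row data.frame with `x_um`, `y_um`, `frame`.
#' @param cellPositions data.frame with `cell_id`, `x_um`, `y_um` at the
#'   event frame.
#' @param config a [SimConfig-class].
#' @return data.frame: `cell_id`, `d_um`, `onset_min`, `duration_min`,
#'   `amplitude`.
#' @export
propagateWave <- function(event, cellPositions, config) {
    stopifnot(is(config, "SimConfig"))
    tA <- (event$frame - 1) * config@frameInterval
    d <- sqrt((cellPositions$x_um - event$x_um)^2 +
              (cellPositions$y_um - event$y_um)^2)
    frac <- pmax(0, 1 - d / config@waveExtent)
    data.frame(cell_id = cellPositions$cell_id, d_um = d,
               onset_min = tA + d / config@waveSpeed,
               duration_min = config@durationAtOrigin *
                   frac^config@decayDuration,
               amplitude = config@amplitudeAtOrigin *
                   frac^config@decayAmplitude)
}

# activity of a set of wave parameter rows at a time point (max over events)
waveActivityAt <- function(waveParams, cellIds, timeMin) {
    E <- setNames(numeric(length(cellIds)), cellIds)
    for (wp in waveParams) {
        act <- wp$amplitude > 0 & timeMin >= wp$onset_min &
            timeMin <= wp$onset_min + wp$duration_min
        if (!any(act)) next
        idx <- match(as.character(wp$cell_id[act]), names(E))
        ok <- !is.na(idx)
        E[idx[ok]] <- pmax(E[idx[ok]], wp$amplitude[act][ok])
    }
    unname(E)
}

#' Advance cell positions by one frame
#'
#' Each cell drifts `migrationGain * E * frameInterval` um toward its target
#' (typically the nearest active wave source), capped at the remaining
#' distance; isotropic Gaussian jitter is added; positions are clamped to the
#' field and pushed apart so no two nuclei end closer than one nuclear
#' radius. Uses the caller's RNG stream.
#'
#' @param positions n x 2 matrix of (x_um, y_um).
#' @param E numeric vector of ERK activities in `[0, 1]`.
#' @param targets n x 2 matrix of drift targets (NA rows = no drift).
#' @param config a [SimConfig-class].
#' @param jitter logical; set `FALSE` for deterministic drift.
#' @return n x 2 matrix of new positions.
#' @export
moveCells <- function(positions, E, targets, config, jitter = TRUE) {
    stopifnot(is(config, "SimConfig"))
    pos <- as.matrix(positions)
    n <- nrow(pos)
    if (n == 0) return(pos)
    step <- config@migrationGain * E * config@frameInterval
    if (any(step > 0)) {
        dx <- targets[, 1] - pos[, 1]
        dy <- targets[, 2] - pos[, 2]
        dd <- sqrt(dx^2 + dy^2)
        go <- which(step > 0 & is.finite(dd) & dd > 0)
        if (length(go)) {
            s <- pmin(step[go], dd[go])
            pos[go, 1] <- pos[go, 1] + s * dx[go] / dd[go]
            pos[go, 2] <- pos[go, 2] + s * dy[go] / dd[go]
        }
    }
    if (jitter && config@jitterSd > 0)
        pos <- pos + matrix(rnorm(2 * n, 0, config@jitterSd), ncol = 2)
    W <- config@fieldSize[1]; H <- config@fieldSize[2]
    m <- config@nucleusRadius
    pos[, 1] <- pmin(pmax(pos[, 1], m), W - m)
    pos[, 2] <- pmin(pmax(pos[, 2], m), H - m)
    enforceSeparation(pos, config@nucleusRadius)
}

# symmetric pushes until no pair is closer than minSep (few iterations)
enforceSeparation <- function(pos, minSep, maxIter = 5) {
    n <- nrow(pos)
    if (n < 2) return(pos)
    for (it in seq_len(maxIter)) {
        nn <- nearestNeighbour(pos)
        bad <- which(nn$dist < minSep & nn$dist > 0)
        if (!length(bad)) break
        for (i in bad) {
            j <- nn$index[i]
            v <- pos[i, ] - pos[j, ]
            dd <- sqrt(sum(v^2))
            if (dd == 0) next
            push <- (minSep - dd) / 2
            pos[i, ] <- pos[i, ] + v / dd * push
            pos[j, ] <- pos[j, ] - v / dd * push
        }
    }
    pos
}

# chunked nearest-neighbour search: list(dist, index)
nearestNeighbour <- function(pos) {
    n <- nrow(pos)
    dists <- numeric(n); idx <- integer(n)
    chunk <- max(1, floor(2e6 / n))
    for (s in seq(1, n, by = chunk)) {
        e <- min(n, s + chunk - 1)
        block <- outer(pos[s:e, 1], pos[, 1], "-")^2 +
                 outer(pos[s:e, 2], pos[, 2], "-")^2
        block[cbind(seq_len(e - s + 1), s:e)] <- Inf
        idx[s:e] <- max.col(-block, ties.method = "first")
        dists[s:e] <- sqrt(block[cbind(seq_len(e - s + 1), idx[s:e])])
    }
    list(dist = dists, index = idx)
}

#' Simulate an organoid monolayer with apoptosis-triggered ERK waves
#'
#' Runs the full agent-based model: node placement, cell seeding, apoptosis
#' scheduling, trigger-wave activation (max over overlapping events),
#' recoil-then-attraction cell motion, and extrusion of dying cells. The
#' RNG is seeded from `config@rngSeed`, so identical configurations yield
#' identical ground truth.
#'
#' @param config a [SimConfig-class].
#' @param events optional data.frame with columns `frame` and either
#'   `cell_id` or `at = "center"` (the living cell nearest the field centre
#'   dies); overrides stochastic scheduling.
#' @return a [GroundTruth-class].
#' @examples
#' cfg <- simConfig(fieldSize = c(400, 400), nodeSpacingMean = 0,
#'                  nonnodeDensity = 5, nFrames = 8, apoptosisRate = 0)
#' gt <- simulateMonolayer(cfg)
#' head(cellTable(gt))
#' @export
simulateMonolayer <- function(config, events = NULL) {
    stopifnot(is(config, "SimConfig"))
    set.seed(config@rngSeed)
    nodeCenters <- placeNodes(config)
    cells0 <- seedCells(config, nodeCenters)
    n0 <- nrow(cells0)
    if (is.null(events)) {
        sched <- scheduleApoptosis(config, cells0)
    } else {
        sched <- as.data.frame(events)
        if (!"cell_id" %in% names(sched)) sched$cell_id <- NA_integer_
        sched$event_id <- seq_len(nrow(sched))
    }
    pos <- as.matrix(cells0[, c("x_um", "y_um")])
    ids <- cells0$cell_id
    comp <- cells0$compartment
    alive <- rep(TRUE, n0)
    waveParams <- list()
    evOut <- list(); cellRows <- vector("list", config@nFrames)
    for (f in seq_len(config@nFrames)) {
        tMin <- (f - 1) * config@frameInterval
        liveIdx <- which(alive)
        E <- switch(config@globalErk,
                    on = rep(1, length(liveIdx)),
                    off = rep(0, length(liveIdx)),
                    none = waveActivityAt(waveParams, ids[liveIdx], tMin))
        cellRows[[f]] <- data.frame(
            cell_id = ids[liveIdx], frame = f,
            x_um = pos[liveIdx, 1], y_um = pos[liveIdx, 2],
            E = E, compartment = comp[liveIdx], stringsAsFactors = FALSE)
        evHere <- sched[sched$frame == f, , drop = FALSE]
        for (r in seq_len(nrow(evHere))) {
            cid <- evHere$cell_id[r]
            if (is.na(cid)) {
                live <- which(alive)
                d2c <- (pos[live, 1] - config@fieldSize[1] / 2)^2 +
                       (pos[live, 2] - config@fieldSize[2] / 2)^2
                cid <- ids[live[which.min(d2c)]]
            }
            vi <- match(cid, ids)
            if (is.na(vi) || !alive[vi]) next
            ev <- list(event_id = evHere$event_id[r], frame = f,
                       x_um = pos[vi, 1], y_um = pos[vi, 2], cell_id = cid)
            evOut[[length(evOut) + 1]] <- ev
            others <- which(alive); others <- others[others != vi]
            if (length(others) && config@globalErk == "none") {
                wp <- propagateWave(ev, data.frame(
                    cell_id = ids[others], x_um = pos[others, 1],
                    y_um = pos[others, 2]), config)
                waveParams[[length(waveParams) + 1]] <- wp
            }
            # immediate outward recoil of adjacent cells
            if (config@recoilDistance > 0 && length(others)) {
                dx <- pos[others, 1] - ev$x_um
                dy <- pos[others, 2] - ev$y_um
                dd <- sqrt(dx^2 + dy^2)
                near <- which(dd > 0 & dd <= config@recoilRadius)
                if (length(near)) {
                    o <- others[near]
                    pos[o, 1] <- pos[o, 1] +
                        config@recoilDistance * dx[near] / dd[near]
                    pos[o, 2] <- pos[o, 2] +
                        config@recoilDistance * dy[near] / dd[near]
                }
            }
            alive[vi] <- FALSE
        }
        if (f < config@nFrames) {
            liveIdx <- which(alive)
            tNext <- tMin    # drift driven by activity at the current frame
            Enow <- switch(config@globalErk,
                           on = rep(1, length(liveIdx)),
                           off = rep(0, length(liveIdx)),
                           none = waveActivityAt(waveParams, ids[liveIdx],
                                                 tNext))
            targets <- matrix(NA_real_, length(liveIdx), 2)
            if (any(Enow > 0) && length(evOut)) {
                evm <- do.call(rbind, lapply(evOut, function(e)
                    c(e$x_um, e$y_um)))
                for (ii in which(Enow > 0)) {
                    dd <- (evm[, 1] - pos[liveIdx[ii], 1])^2 +
                          (evm[, 2] - pos[liveIdx[ii], 2])^2
                    targets[ii, ] <- evm[which.min(dd), ]
                }
            }
            pos[liveIdx, ] <- moveCells(pos[liveIdx, , drop = FALSE], Enow,
                                        targets, config)
        }
    }
    cells <- do.call(rbind, cellRows)
    eventsDf <- if (length(evOut)) {
        do.call(rbind, lapply(evOut, function(e)
            data.frame(event_id = e$event_id, frame = e$frame,
                       x_um = e$x_um, y_um = e$y_um, cell_id = e$cell_id)))
    } else {
        data.frame(event_id = integer(0), frame = integer(0),
                   x_um = numeric(0), y_um = numeric(0),
                   cell_id = integer(0))
    }
    nodesDf <- data.frame(node_id = seq_len(nrow(nodeCenters)),
                          x_um = nodeCenters[, 1], y_um = nodeCenters[, 2],
                          radius_um = rep(config@nodeRadius,
                                          nrow(nodeCenters)))
    new("GroundTruth", cells = cells, events = eventsDf, nodes = nodesDf,
        config = config)
}

#' Write ground-truth tables and configuration to a directory
#'
#' @param gt a [GroundTruth-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeGroundTruth <- function(gt, dir) {
    stopifnot(is(gt, "GroundTruth"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(gt@cells, file.path(dir, "cells.csv"), row.names = FALSE)
    write.csv(gt@events, file.path(dir, "events.csv"), row.names = FALSE)
    write.csv(gt@nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
    writeSimConfig(gt@config, file.path(dir, "sim_config.yaml"))
    invisible(dir)
}

#' Serialise / restore a SimConfig as YAML
#'
#' @param config a [SimConfig-class].
#' @param path YAML file path.
#' @return `readSimConfig` returns a [SimConfig-class]; `writeSimConfig`
#'   returns `path` invisibly. Unknown keys in the file are rejected.
#' @export
writeSimConfig <- function(config, path) {
    sl <- slotNames(config)
    vals <- lapply(sl, function(s) {
        v <- slot(config, s)
        if (length(v) > 1) as.list(v) else v
    })
    yaml::write_yaml(setNames(vals, sl), path)
    invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- slotNames("SimConfig")
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop("unknown SimConfig keys: ", paste(unknown, collapse = ", "))
    cfg <- simConfig()
    for (nm in names(vals)) {
        v <- vals[[nm]]
        if (is.list(v)) v <- unlist(v)
        if (nm != "globalErk") v <- as.numeric(v)
        slot(cfg, nm) <- v
    }
    validObject(cfg)
    cfg
}
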