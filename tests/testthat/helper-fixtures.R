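# session-level fixture cache: expensive simulated/rendered fixtures are
# built once and shared across test files
fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, maker) {
    if (!exists(key, envir = fixtureCache))
        assign(key, maker(), envir = fixtureCache)
    get(key, envir = fixtureCache)
}

# run the full measurement pipeline on a stack
pipelineOn <- function(stack) {
    seg <- segmentStack(stack)
    tr <- linkTracks(seg$measurements)
    ev <- detectApoptosisEvents(stack)
    list(seg = seg, tr = tr, ev = ev)
}

# small noiseless single-wave fixture (~95 cells), fully rendered + measured
smallWaveFixture <- function() cachedFixture("smallwave", function() {
    cfg <- simConfig(fieldSize = c(420, 420), nodeSpacingMean = 0,
                     nodeDensity = 0, nonnodeDensity = 5.5, nFrames = 16,
                     apoptosisRate = 0, waveSpeed = 3, waveExtent = 150,
                     durationAtOrigin = 30, noiseSd = 0, rngSeed = 11)
    gt <- simulateMonolayer(cfg, events = data.frame(frame = 4))
    st <- renderFrameStack(gt)
    c(list(cfg = cfg, gt = gt, st = st), pipelineOn(st))
})

# dense noiseless wave fixture (~440 cells), shared by activity-call and
# flow tests
denseWaveFixture <- function() cachedFixture("densewave", function() {
    fx <- makeFixtures("piv_wave", seed = 5, noiseSd = 0)
    c(fx, pipelineOn(fx$stack))
})

# the single-event exemplar fixture at the printed wave parameters
fig3Fixture <- function() cachedFixture("fig3full", function() {
    fx <- makeFixtures("fig3", seed = 42)
    c(fx, pipelineOn(fx$stack))
})

# track table derived from simulator ground truth (no imaging)
gtTracks <- function(gt) {
    cfg <- gt@config
    ct <- cellTable(gt)
    ct$track_id <- ct$cell_id
    ct$cn_ratio <- cfg@cnBaseline * (1 + (cfg@ktrPartition - 1) * ct$E)
    ct
}

# ground-truth event as a list usable by the wave module
gtEvent <- function(gt, i = 1) {
    ev <- eventTable(gt)[i, ]
    list(event_id = ev$event_id, frame = ev$frame, x_um = ev$x_um,
         y_um = ev$y_um)
}

# brute-force annulus oracle: direct enumeration of the definition on
# pixel-centre Euclidean distances (no image-processing library)
bruteAnnulus <- function(lab, label, widthPx = 2) {
    kIdx <- which(lab == label, arr.ind = TRUE)
    oIdx <- which(lab > 0 & lab != label, arr.ind = TRUE)
    out <- integer(0)
    for (i in seq_len(nrow(lab))) for (j in seq_len(ncol(lab))) {
        if (lab[i, j] != 0) next
        dK <- sqrt(min((kIdx[, 1] - i)^2 + (kIdx[, 2] - j)^2))
        if (dK > widthPx) next
        if (nrow(oIdx)) {
            dO <- sqrt(min((oIdx[, 1] - i)^2 + (oIdx[, 2] - j)^2))
            if (dO <= 1) next
        }
        out <- c(out, (j - 1) * nrow(lab) + i)
    }
    sort(out)
}

# textbook DBSCAN oracle: core points from neighbourhood counts, clusters =
# connected components of the core-core eps graph (igraph), border points
# attached to any core neighbour
oracleDbscan <- function(pts, eps, minPts) {
    n <- nrow(pts)
    D <- as.matrix(dist(pts))
    core <- rowSums(D <= eps) >= minPts
    labels <- integer(n)
    if (any(core)) {
        A <- D[core, core, drop = FALSE] <= eps
        g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
        comp <- igraph::components(g)$membership
        labels[core] <- comp
        for (i in which(!core)) {
            nb <- which(core & D[i, ] <= eps)
            if (length(nb)) labels[i] <- labels[nb[1]]
        }
    }
    list(labels = labels, core = core)
}

# exhaustive minimum-cost perfect matching of rows to columns (n <= m)
bruteAssignmentCost <- function(cost) {
    n <- nrow(cost); m <- ncol(cost)
    best <- Inf
    rec <- function(row, used, acc) {
        if (acc >= best) return()
        if (row > n) { best <<- acc; return() }
        for (j in seq_len(m)) if (!used[j]) {
            used[j] <- TRUE
            rec(row + 1, used, acc + cost[row, j])
            used[j] <- FALSE
        }
    }
    rec(1, logical(m), 0)
    best
}

# translated texture pair for PIV: img2 content is img1 shifted by
# (dxPx, dyPx) (positive = down/right)
shiftedPair <- function(n = 160, dxPx = 3, dyPx = 5, seed = 1) {
    set.seed(seed)
    pad <- 16
    base <- matrix(rnorm((n + 2 * pad)^2), n + 2 * pad)
    base <- as.matrix(EBImage::filter2(
        base, EBImage::makeBrush(9, "gaussian", sigma = 1.5),
        boundary = "circular"))
    i1 <- pad + seq_len(n)
    list(img1 = base[i1, i1],
         img2 = base[i1 - dyPx, i1 - dxPx])
}
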