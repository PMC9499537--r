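test_that("DBSCAN separates well-spaced groups and labels sparse points noise", {
    set.seed(3)
    g1 <- cbind(rnorm(10, 100, 5), rnorm(10, 100, 5))
    g2 <- cbind(rnorm(10, 600, 5), rnorm(10, 600, 5))
    lab <- dbscanCluster(rbind(g1, g2), eps = 50, minPts = 5)
    expect_equal(length(setdiff(unique(lab), 0)), 2)
    expect_length(unique(lab[1:10]), 1)
    expect_length(unique(lab[11:20]), 1)
    # all pairwise distances beyond eps: everything is noise
    iso <- cbind(seq(0, 900, by = 100), 0)
    expect_true(all(dbscanCluster(iso, eps = 50, minPts = 2) == 0))
})

test_that("DBSCAN matches the density-reachability definition on random sets", {
    set.seed(9)
    for (rep in 1:8) {
        n <- sample(20:50, 1)
        pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
        eps <- runif(1, 8, 25)
        minPts <- sample(3:6, 1)
        mine <- dbscanCluster(pts, eps, minPts)
        orc <- oracleDbscan(pts, eps, minPts)
        # identical noise set
        expect_identical(mine == 0, orc$labels == 0)
        # identical partition of core points (up to relabelling)
        core <- orc$core
        if (any(core)) {
            tab <- table(mine[core], orc$labels[core])
            expect_true(all(rowSums(tab > 0) == 1))
            expect_true(all(colSums(tab > 0) == 1))
        }
        # border points sit in the cluster of one of their core neighbours
        D <- as.matrix(dist(pts))
        for (i in which(!core & mine != 0)) {
            nb <- which(core & D[i, ] <= eps)
            expect_true(mine[i] %in% mine[nb])
        }
    }
})

test_that("cluster regions and heat maps equal brute-force membership counts", {
    set.seed(5)
    dimPx <- c(60, 60); ps <- 2; alpha <- 8
    masks <- list()
    heatOracle <- matrix(0L, 60, 60)
    for (f in 1:6) {
        pts <- cbind(runif(5, 20, 100), runif(5, 20, 100))
        masks[[f]] <- regionMask(pts, dimPx, ps, alpha)
        # brute force: pixel centre within alpha of a member's pixel centre
        rr <- round(pts[, 2] / ps + 0.5); cc <- round(pts[, 1] / ps + 0.5)
        bf <- matrix(FALSE, 60, 60)
        for (i in 1:60) for (j in 1:60)
            bf[i, j] <- min((rr - i)^2 + (cc - j)^2) <= (alpha / ps)^2
        expect_identical(unname(masks[[f]]), unname(bf))
        heatOracle <- heatOracle + bf
    }
    heat <- accumulateHeatmap(masks)
    expect_identical(unname(heat), unname(heatOracle))
    expect_true(max(heat) <= 6)
    # one static cluster: interior counts every frame, exterior none
    still <- replicate(10, masks[[1]], simplify = FALSE)
    h <- accumulateHeatmap(still)
    expect_setequal(unique(as.vector(h)), c(0L, 10L))
})

test_that("a movie without active cells accumulates an all-zero heat map", {
    meas <- data.frame(frame = rep(1:5, each = 4),
                       x_um = runif(20, 0, 100), y_um = runif(20, 0, 100),
                       erk_active = FALSE)
    h <- erkActivityHeatmap(meas, dim = c(50, 50), pixelSize = 2)
    expect_true(all(h == 0))
})

test_that("node detection recovers lattices exactly and rejects uniform fields", {
    # 3x3 grid of dense clumps, constant 500 um
    set.seed(6)
    cen <- expand.grid(x = c(300, 800, 1300), y = c(300, 800, 1300))
    pts <- do.call(rbind, lapply(seq_len(9), function(k)
        cbind(cen$x[k] + rnorm(60, 0, 25), cen$y[k] + rnorm(60, 0, 25))))
    bg <- cbind(runif(150, 0, 1600), runif(150, 0, 1600))
    cells <- data.frame(x_um = c(pts[, 1], bg[, 1]),
                        y_um = c(pts[, 2], bg[, 2]))
    ns <- detectNodes(cells, fieldSize = c(1600, 1600))
    expect_equal(length(ns), 9)
    expect_equal(unname(nodeSpacing(ns)), rep(500, 9), tolerance = 0.02)
    # uniform field: empty NodeSet
    uni <- data.frame(x_um = runif(800, 0, 1600),
                      y_um = runif(800, 0, 1600))
    expect_equal(length(detectNodes(uni, fieldSize = c(1600, 1600))), 0)
})

test_that("node spacing is recovered within 10% across seeded monolayers", {
    errs <- vapply(1:10, function(s) {
        cfg <- simConfig(fieldSize = c(1200, 1200), rngSeed = s)
        gt <- simulateMonolayer(simConfig(fieldSize = c(1200, 1200),
                                          nFrames = 1, apoptosisRate = 0,
                                          rngSeed = s))
        ns <- detectNodes(cellTable(gt)[, c("x_um", "y_um")],
                          fieldSize = c(1200, 1200))
        abs(mean(nodeSpacing(ns)) - 399) / 399
    }, numeric(1))
    expect_lt(max(errs), 0.10)
})

test_that("compartment labels agree with simulator ground truth", {
    gt <- simulateMonolayer(simConfig(fieldSize = c(1200, 1200),
                                      nFrames = 1, apoptosisRate = 0,
                                      rngSeed = 3))
    ct <- cellTable(gt)
    ns <- detectNodes(ct[, c("x_um", "y_um")], fieldSize = c(1200, 1200))
    comp <- assignCompartments(ct, ns)
    expect_length(comp, nrow(ct))          # total
    expect_gte(mean(comp == ct$compartment), 0.95)
    # node centroids are labelled node; remote points non-node
    expect_true(all(assignCompartments(nodeTable(ns), ns) == "node"))
    far <- data.frame(x_um = 1e5, y_um = 1e5)
    expect_equal(assignCompartments(far, ns), "non-node")
})

test_that("per-cell channel quantification sums and gates correctly", {
    lab <- matrix(0L, 40, 40)
    lab[5:10, 5:10] <- 1L      # 36 px
    lab[20:29, 20:29] <- 2L    # 100 px
    lm <- new("LabelMap", labels = lab,
              table = data.frame(label = 1:2, x_px = c(7.5, 24.5),
                                 y_px = c(7.5, 24.5),
                                 area_px = c(36L, 100L), border = FALSE))
    ch <- matrix(0, 40, 40)
    ch[lab == 1L] <- 2; ch[lab == 2L] <- 10
    q <- quantifyChannelPerCell(ch, lm, mode = "sum", gate = 100)
    expect_equal(q$intensity, c(72, 1000))
    expect_equal(q$gate, c("low", "high"))
    qm <- quantifyChannelPerCell(ch, lm, mode = "mean")
    expect_equal(qm$intensity, c(2, 10))
    qz <- quantifyChannelPerCell(matrix(0, 40, 40), lm, mode = "sum",
                                 gate = 1)
    expect_true(all(qz$intensity == 0))
    expect_true(all(qz$gate == "low"))
    expect_error(quantifyChannelPerCell(matrix(0, 10, 10), lm), "shape")
})

test_that("node cells rendered brighter give the configured intensity ratio", {
    # two compartments rendered with a 5x generic-channel contrast
    cfg <- simConfig(fieldSize = c(400, 400), nFrames = 1, noiseSd = 0,
                     nodeSpacingMean = 0, nodeDensity = 0,
                     nonnodeDensity = 2)
    set.seed(8)
    cells <- data.frame(cell_id = 1:32,
                        x_um = rep(seq(40, 360, length.out = 8), 4),
                        y_um = rep(seq(60, 340, length.out = 4), each = 8),
                        E = 0, frame = 1,
                        compartment = rep(c("node", "non-node"), 16))
    gt <- new("GroundTruth", cells = cells,
              events = data.frame(event_id = integer(0), frame = integer(0),
                                  x_um = numeric(0), y_um = numeric(0),
                                  cell_id = integer(0)),
              nodes = data.frame(node_id = integer(0), x_um = numeric(0),
                                 y_um = numeric(0), radius_um = numeric(0)),
              config = cfg)
    st <- renderFrameStack(gt)
    lm <- segmentNuclei(getFrame(st, 1, "H2B"))
    # paint the generic channel from the true label geometry: node nuclei 5x
    ch <- matrix(0, nrow(labelMatrix(lm)), ncol(labelMatrix(lm)))
    tab <- labelTable(lm)
    isNode <- vapply(seq_len(nrow(tab)), function(i) {
        d2 <- (cells$x_um - (tab$x_px[i] - 0.5) * 1.3)^2 +
              (cells$y_um - (tab$y_px[i] - 0.5) * 1.3)^2
        cells$compartment[which.min(d2)] == "node"
    }, logical(1))
    for (i in seq_len(nrow(tab)))
        ch[labelMatrix(lm) == tab$label[i]] <- if (isNode[i]) 5 else 1
    q <- quantifyChannelPerCell(ch, lm, mode = "mean")
    ratio <- mean(q$intensity[isNode]) / mean(q$intensity[!isNode])
    expect_lt(abs(ratio - 5) / 5, 0.10)
})

test_that("nearest-nuclei distances match brute force and lattice geometry", {
    lat <- expand.grid(x_um = seq(0, 60, by = 12),
                       y_um = seq(0, 60, by = 12))
    expect_true(all(nearestNucleiDistances(lat) == 12))
    two <- data.frame(x_um = c(0, 7), y_um = 0)
    expect_equal(nearestNucleiDistances(two), c(7, 7))
    set.seed(10)
    pts <- data.frame(x_um = runif(100, 0, 500), y_um = runif(100, 0, 500))
    D <- as.matrix(dist(pts)); diag(D) <- Inf
    expect_equal(nearestNucleiDistances(pts), unname(apply(D, 1, min)))
    expect_error(nearestNucleiDistances(two[1, , drop = FALSE]),
                 "at least two")
})

test_that("event localization counts compartments correctly", {
    gt <- simulateMonolayer(simConfig(fieldSize = c(1200, 1200),
                                      nFrames = 1, apoptosisRate = 0,
                                      rngSeed = 3))
    ct <- cellTable(gt)
    ns <- detectNodes(ct[, c("x_um", "y_um")], fieldSize = c(1200, 1200))
    # all events on non-node ground-truth cells
    nonnode <- ct[ct$compartment == "non-node", ][1:50, ]
    loc <- localizeEvents(nonnode, ns)
    expect_gte(loc$fractionNonNode, 0.9)
    expect_equal(sum(loc$counts), 50)
    # no events
    loc0 <- localizeEvents(nonnode[0, ], ns)
    expect_equal(sum(loc0$counts), 0)
    expect_true(is.na(loc0$fractionNonNode))
})

test_that("biased apoptosis localization is recovered within binomial error", {
    cfg <- simConfig(fieldSize = c(1200, 1200), nFrames = 120,
                     apoptosisRate = 2, pNonnode = 0.8, rngSeed = 14)
    gt <- simulateMonolayer(cfg)
    ev <- eventTable(gt)
    expect_gt(nrow(ev), 150)
    ct1 <- cellTable(gt)[cellTable(gt)$frame == 1, ]
    ns <- detectNodes(ct1[, c("x_um", "y_um")], fieldSize = c(1200, 1200))
    loc <- localizeEvents(ev, ns)
    n <- sum(loc$counts)
    ci <- binom.test(round(loc$fractionNonNode * n), n)$conf.int
    expect_true(ci[1] <= 0.8 && 0.8 <= ci[2])
})
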