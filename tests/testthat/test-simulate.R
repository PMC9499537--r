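test_that("node placement reproduces the requested spacing", {
    set.seed(1)
    cfg <- simConfig(fieldSize = c(2000, 2000), nodeSpacingMean = 399)
    cen <- placeNodes(cfg)
    expect_equal(nrow(cen), 25)
    D <- as.matrix(dist(cen)); diag(D) <- Inf
    nn <- apply(D, 1, min)
    expect_lt(abs(mean(nn) - 399) / 399, 0.10)
    expect_true(min(D) >= 2 * cfg@nodeRadius)
})

test_that("degenerate node placements behave as specified", {
    set.seed(1)
    # field smaller than the spacing: a single interior centre
    cfg <- simConfig(fieldSize = c(300, 300), nodeSpacingMean = 399,
                     nodeRadius = 80)
    cen <- placeNodes(cfg)
    expect_equal(nrow(cen), 1)
    expect_true(all(cen >= 80 & cen <= 220))
    # spacing = width/2 with zero jitter: exact grid constant
    cfg2 <- simConfig(fieldSize = c(1000, 1000), nodeSpacingMean = 500,
                      nodeJitter = 0)
    cen2 <- placeNodes(cfg2)
    D <- as.matrix(dist(cen2)); diag(D) <- Inf
    expect_equal(unname(apply(D, 1, min)), rep(500, 4))
    # a field too small for one node disk errors
    cfg3 <- simConfig(fieldSize = c(100, 100), nodeSpacingMean = 399,
                      nodeRadius = 80)
    expect_error(placeNodes(cfg3), "too small")
})

test_that("seeded cell densities respect the node/non-node contrast", {
    set.seed(2)
    cfg <- simConfig(fieldSize = c(1200, 1200), nodeSpacingMean = 399,
                     nodeDensity = 40, nonnodeDensity = 10)
    cen <- placeNodes(cfg)
    cells <- seedCells(cfg, cen)
    inNode <- cells$compartment == "node"
    areaNode <- nrow(cen) * pi * cfg@nodeRadius^2
    areaNon <- prod(cfg@fieldSize) - areaNode
    ratio <- (sum(inNode) / areaNode) / (sum(!inNode) / areaNon)
    expect_gt(ratio, 3); expect_lt(ratio, 5)
    # hard minimum spacing
    nn <- nearestNucleiDistances(cells[, c("x_um", "y_um")])
    expect_true(all(nn >= 1.5 * cfg@nucleusRadius - 1e-9))
})

test_that("seeding edge cases: empty surround and node-free fields", {
    set.seed(3)
    cfg <- simConfig(fieldSize = c(900, 900), nodeSpacingMean = 399,
                     nodeDensity = 30, nonnodeDensity = 0)
    cells <- seedCells(cfg, placeNodes(cfg))
    expect_true(all(cells$compartment == "node"))
    cfg2 <- simConfig(fieldSize = c(900, 900), nodeSpacingMean = 0,
                      nonnodeDensity = 8)
    cells2 <- seedCells(cfg2, placeNodes(cfg2))
    expect_true(all(cells2$compartment == "non-node"))
    expect_equal(nrow(cells2), round(8 * 900 * 900 / 1e4))
})

test_that("apoptosis scheduling follows the compartment bias", {
    set.seed(4)
    cfg <- simConfig(fieldSize = c(1200, 1200), nFrames = 80,
                     apoptosisRate = 3, pNonnode = 0.8)
    cells <- seedCells(cfg, placeNodes(cfg))
    sched <- scheduleApoptosis(cfg, cells)
    expect_gt(nrow(sched), 150)
    expect_false(any(duplicated(sched$cell_id)))
    frac <- mean(cells$compartment[match(sched$cell_id,
                                         cells$cell_id)] == "non-node")
    ci <- binom.test(round(frac * nrow(sched)), nrow(sched))$conf.int
    expect_true(ci[1] <= 0.8 && 0.8 <= ci[2])
    # extremes
    cfg1 <- simConfig(nFrames = 40, apoptosisRate = 1, pNonnode = 1)
    s1 <- scheduleApoptosis(cfg1, cells)
    expect_true(all(cells$compartment[match(s1$cell_id,
                                            cells$cell_id)] == "non-node"))
    cfg0 <- simConfig(apoptosisRate = 0)
    expect_equal(nrow(scheduleApoptosis(cfg0, cells)), 0)
})

test_that("wave kinetics follow the onset/duration/amplitude law", {
    cfg <- simConfig(waveSpeed = 4.7, waveExtent = 450,
                     durationAtOrigin = 40, amplitudeAtOrigin = 1)
    ev <- list(frame = 7, x_um = 0, y_um = 0)   # t_a = 30 min
    cells <- data.frame(cell_id = 1:4, x_um = c(0, 450, 235, 600),
                        y_um = 0)
    wp <- propagateWave(ev, cells, cfg)
    expect_equal(wp$onset_min[1], 30)            # at the origin
    expect_equal(wp$duration_min[1], 40)
    expect_equal(wp$amplitude[1], 1)
    expect_equal(wp$duration_min[2], 0)          # at R_max: never active
    expect_equal(wp$amplitude[2], 0)
    expect_equal(wp$onset_min[3], 30 + 50)       # d/v = 235/4.7 = 50 min
    expect_equal(wp$amplitude[4], 0)             # beyond R_max
})

test_that("simulated activity obeys the activation-time law", {
    cfg <- simConfig(fieldSize = c(500, 500), nodeSpacingMean = 0,
                     nodeDensity = 0, nonnodeDensity = 6, nFrames = 20,
                     apoptosisRate = 0, waveSpeed = 4, waveExtent = 200,
                     durationAtOrigin = 30, jitterSd = 0,
                     migrationGain = 0, recoilDistance = 0, rngSeed = 9)
    gt <- simulateMonolayer(cfg, events = data.frame(frame = 4))
    ev <- eventTable(gt)
    ct <- cellTable(gt)
    atA <- ct[ct$frame == ev$frame, ]
    d <- sqrt((atA$x_um - ev$x_um)^2 + (atA$y_um - ev$y_um)^2)
    names(d) <- atA$cell_id
    for (cid in atA$cell_id) {
        tr <- ct[ct$cell_id == cid, ]
        tActive <- (tr$frame[tr$E > 0] - 1) * cfg@frameInterval
        di <- d[as.character(cid)]
        if (di > cfg@waveExtent) {
            expect_length(tActive, 0)
        } else if (length(tActive)) {
            tOn <- (ev$frame - 1) * cfg@frameInterval + di / cfg@waveSpeed
            dur <- cfg@durationAtOrigin * (1 - di / cfg@waveExtent)
            expect_true(all(tActive >= tOn - 1e-9))
            expect_true(all(tActive <= tOn + dur + 1e-9))
            # recorded onset within one frame interval of the law
            expect_lt(min(tActive) - tOn, cfg@frameInterval + 1e-9)
        }
    }
})

test_that("the simulation is deterministic and conserves cells", {
    cfg <- simConfig(fieldSize = c(600, 600), nodeSpacingMean = 0,
                     nodeDensity = 0, nonnodeDensity = 6, nFrames = 15,
                     apoptosisRate = 0.5, rngSeed = 21)
    g1 <- simulateMonolayer(cfg)
    g2 <- simulateMonolayer(cfg)
    expect_identical(cellTable(g1), cellTable(g2))
    expect_identical(eventTable(g1), eventTable(g2))
    counts <- table(cellTable(g1)$frame)
    drops <- -diff(as.integer(counts))
    deaths <- table(factor(eventTable(g1)$frame,
                           levels = seq_len(cfg@nFrames - 1)))
    expect_equal(unname(drops), as.integer(deaths))
    expect_gt(nrow(eventTable(g1)), 0)
})

test_that("zero apoptosis rate keeps every cell ERK-silent", {
    cfg <- simConfig(fieldSize = c(500, 500), nodeSpacingMean = 0,
                     nodeDensity = 0, nonnodeDensity = 5, nFrames = 12,
                     apoptosisRate = 0, rngSeed = 2)
    gt <- simulateMonolayer(cfg)
    expect_true(all(cellTable(gt)$E == 0))
    expect_equal(nrow(eventTable(gt)), 0)
})

test_that("cell motion follows drift, jitter and recoil rules", {
    cfg <- simConfig(migrationGain = 1, jitterSd = 0,
                     fieldSize = c(500, 500))
    # 1 um/min * E = 0.5 * 5 min per step: 7.5 um over three steps
    pos <- matrix(c(100, 100), 1)
    target <- matrix(c(400, 100), 1)
    for (i in 1:3)
        pos <- moveCells(pos, 0.5, target, cfg, jitter = FALSE)
    expect_equal(unname(pos[1, 1]), 107.5)
    expect_equal(unname(pos[1, 2]), 100)
    # zero activity: jitter only, zero mean
    cfgJ <- simConfig(jitterSd = 0.2, fieldSize = c(5000, 5000))
    set.seed(30)
    p0 <- as.matrix(expand.grid(seq(100, 4900, by = 280),
                                seq(100, 4900, by = 280)))
    p1 <- moveCells(p0, rep(0, nrow(p0)), p0 * NA, cfgJ)
    disp <- p1 - p0
    expect_lt(max(abs(colMeans(disp))), 0.05)
    expect_lt(max(abs(disp)), 1.5)
    # drift moves strictly closer after the recoil frame
    cfgW <- simConfig(fieldSize = c(500, 500), nodeSpacingMean = 0,
                      nodeDensity = 0, nonnodeDensity = 5, nFrames = 12,
                      apoptosisRate = 0, waveSpeed = 5, waveExtent = 200,
                      durationAtOrigin = 40, jitterSd = 0, rngSeed = 13)
    gt <- simulateMonolayer(cfgW, events = data.frame(frame = 3))
    ev <- eventTable(gt)
    ct <- cellTable(gt)
    act <- ct[ct$E > 0, ]
    cid <- act$cell_id[1]
    tr <- ct[ct$cell_id == cid, ]
    dn <- sqrt((tr$x_um - ev$x_um)^2 + (tr$y_um - ev$y_um)^2)
    af <- tr$frame >= ev$frame + 1
    expect_lt(min(dn[af]), dn[tr$frame == ev$frame])
})
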