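# build a GroundTruth with hand-placed cells for controlled rendering
manualGT <- function(cells, cfg) {
    cells$frame <- 1
    if (is.null(cells$compartment)) cells$compartment <- "non-node"
    if (is.null(cells$E)) cells$E <- 0
    new("GroundTruth", cells = cells,
        events = data.frame(event_id = integer(0), frame = integer(0),
                            x_um = numeric(0), y_um = numeric(0),
                            cell_id = integer(0)),
        nodes = data.frame(node_id = integer(0), x_um = numeric(0),
                           y_um = numeric(0), radius_um = numeric(0)),
        config = cfg)
}

test_that("well-separated nuclei are segmented one-to-one with sub-pixel centroids", {
    cfg <- simConfig(fieldSize = c(700, 700), nFrames = 1, noiseSd = 0,
                     nodeSpacingMean = 0, nodeDensity = 0,
                     nonnodeDensity = 1)
    grid <- expand.grid(x_um = seq(60, 640, length.out = 8),
                        y_um = seq(60, 640, length.out = 8))[1:50, ]
    gt <- manualGT(data.frame(cell_id = 1:50, grid), cfg)
    st <- renderFrameStack(gt)
    lm <- segmentNuclei(getFrame(st, 1, "H2B"))
    tab <- labelTable(lm)
    expect_equal(nrow(tab), 50)
    # centroid error below one pixel
    xpx <- grid$x_um / 1.3 + 0.5
    ypx <- grid$y_um / 1.3 + 0.5
    err <- vapply(seq_len(50), function(i)
        min(sqrt((tab$x_px - xpx[i])^2 + (tab$y_px - ypx[i])^2)),
        numeric(1))
    expect_lt(max(err), 1)
})

test_that("blank frames give empty label maps, not errors", {
    lm <- segmentNuclei(matrix(0, 64, 64))
    expect_equal(nrow(labelTable(lm)), 0)
    expect_true(all(labelMatrix(lm) == 0))
    m <- measureKTR(matrix(1, 64, 64), lm)
    expect_equal(nrow(m), 0)
})

test_that("touching nuclei at 1.2 nuclear diameters are split", {
    cfg <- simConfig(fieldSize = c(130, 65), nFrames = 1, noiseSd = 0,
                     nodeSpacingMean = 0, nodeDensity = 0,
                     nonnodeDensity = 1)
    sep <- 1.2 * 2 * cfg@nucleusRadius    # 14.4 um
    gt <- manualGT(data.frame(cell_id = 1:2,
                              x_um = c(65 - sep / 2, 65 + sep / 2),
                              y_um = c(32, 32)), cfg)
    st <- renderFrameStack(gt)
    lm <- segmentNuclei(getFrame(st, 1, "H2B"))
    expect_equal(nrow(labelTable(lm)), 2)
})

test_that("annulus masks equal brute-force enumeration exactly", {
    # isolated disk of radius 5 in a 31x31 image
    lab <- matrix(0L, 31, 31)
    for (i in 1:31) for (j in 1:31)
        if ((i - 16)^2 + (j - 16)^2 <= 25) lab[i, j] <- 1L
    lm <- new("LabelMap", labels = lab,
              table = data.frame(label = 1L, x_px = 16, y_px = 16,
                                 area_px = sum(lab), border = FALSE))
    ann <- makeAnnulus(lm, 1, widthPx = 2)
    expect_identical(ann, bruteAnnulus(lab, 1, 2))
    # ring of inner radius 5, outer radius 7 (pixel-centre distances)
    d <- sqrt(outer((1:31 - 16)^2, (1:31 - 16)^2, "+"))
    expect_equal(length(ann), sum(d > 5 & d <= 7))
    expect_error(makeAnnulus(lm, 99), "unknown label")
})

test_that("annuli of adjacent nuclei avoid all nuclear pixels", {
    set.seed(7)
    # crowded random disks
    lab <- matrix(0L, 80, 80)
    cen <- cbind(runif(12, 8, 72), runif(12, 8, 72))
    for (k in seq_len(12)) for (i in 1:80) for (j in 1:80)
        if ((i - cen[k, 1])^2 + (j - cen[k, 2])^2 <= 16 && lab[i, j] == 0)
            lab[i, j] <- k
    labs <- sort(unique(lab[lab > 0]))
    lm <- new("LabelMap", labels = lab,
              table = data.frame(label = labs, x_px = cen[labs, 2],
                                 y_px = cen[labs, 1],
                                 area_px = tabulate(lab)[labs],
                                 border = FALSE))
    lm@table$label <- seq_along(labs)     # relabel consecutively
    lab2 <- lab
    lab2[lab > 0] <- match(lab[lab > 0], labs)
    lm@labels <- lab2
    for (k in lm@table$label) {
        ann <- makeAnnulus(lm, k, 2)
        expect_identical(ann, bruteAnnulus(lab2, k, 2))
        expect_true(all(lab2[ann] == 0))
    }
})

test_that("nucleus filling the whole image has an empty annulus", {
    lab <- matrix(1L, 20, 20)
    lm <- new("LabelMap", labels = lab,
              table = data.frame(label = 1L, x_px = 10.5, y_px = 10.5,
                                 area_px = 400L, border = TRUE))
    expect_length(makeAnnulus(lm, 1), 0)
    m <- measureKTR(matrix(2, 20, 20), lm)
    expect_true(is.na(m$cn_ratio))
    expect_true(is.na(m$erk_active))
})

test_that("KTR measurement implements the strict cytoplasm > nucleus rule", {
    lab <- matrix(0L, 31, 31)
    for (i in 1:31) for (j in 1:31)
        if ((i - 16)^2 + (j - 16)^2 <= 25) lab[i, j] <- 1L
    lm <- new("LabelMap", labels = lab,
              table = data.frame(label = 1L, x_px = 16, y_px = 16,
                                 area_px = sum(lab), border = FALSE))
    # uniform image: ratio exactly 1, tie is inactive
    m <- measureKTR(matrix(3.5, 31, 31), lm)
    expect_equal(m$cn_ratio, 1)
    expect_false(m$erk_active)
    # nucleus 1.0, annulus 1.2: active at ratio 1.2
    ktr <- matrix(1.2, 31, 31)
    ktr[lab == 1L] <- 1.0
    m2 <- measureKTR(ktr, lm)
    expect_equal(m2$cn_ratio, 1.2)
    expect_true(m2$erk_active)
    expect_error(measureKTR(matrix(1, 10, 10), lm), "shape")
})

test_that("rendered C/N fold-change between E=0 and E=1 recovers the KTR partition", {
    cfg <- simConfig(fieldSize = c(400, 200), nFrames = 1, noiseSd = 0,
                     nodeSpacingMean = 0, nodeDensity = 0,
                     nonnodeDensity = 1, ktrPartition = 2)
    cells <- data.frame(cell_id = 1:8,
                        x_um = rep(seq(50, 350, by = 100), 2),
                        y_um = rep(c(60, 140), each = 4),
                        E = rep(c(0, 1), each = 4))
    gt <- manualGT(cells, cfg)
    st <- renderFrameStack(gt)
    lm <- segmentNuclei(getFrame(st, 1, "H2B"))
    m <- measureKTR(getFrame(st, 1, "KTR"), lm, pixelSize = 1.3)
    grp <- ifelse(m$y_um > 100, 1, 0)      # top row has E = 1
    fold <- mean(m$cn_ratio[grp == 1]) / mean(m$cn_ratio[grp == 0])
    expect_lt(abs(fold - 2) / 2, 0.05)
})

test_that("activity calls are exact on a noiseless monolayer", {
    fx <- denseWaveFixture()
    meas <- fx$seg$measurements
    ct <- cellTable(fx$gt)
    # match measurements to ground-truth cells by position per frame
    A0 <- fx$config@amplitudeAtOrigin
    nWrong <- 0; nCalls <- 0
    for (f in unique(meas$frame)) {
        mf <- meas[meas$frame == f & !meas$border & !is.na(meas$erk_active), ]
        cf <- ct[ct$frame == f, ]
        idx <- vapply(seq_len(nrow(mf)), function(i)
            which.min((cf$x_um - mf$x_um[i])^2 + (cf$y_um - mf$y_um[i])^2),
            integer(1))
        E <- cf$E[idx]
        sel <- E > A0 / 2 | E == 0
        nCalls <- nCalls + sum(sel)
        nWrong <- nWrong + sum(mf$erk_active[sel] != (E[sel] > A0 / 2))
    }
    expect_gt(nCalls, 2000)
    expect_equal(nWrong, 0)
})

test_that("a constant intensity offset pulls the C/N ratio toward one", {
    lab <- matrix(0L, 31, 31)
    for (i in 1:31) for (j in 1:31)
        if ((i - 16)^2 + (j - 16)^2 <= 25) lab[i, j] <- 1L
    lm <- new("LabelMap", labels = lab,
              table = data.frame(label = 1L, x_px = 16, y_px = 16,
                                 area_px = sum(lab), border = FALSE))
    ktr <- matrix(1.6, 31, 31)
    ktr[lab == 1L] <- 0.8                  # active cell, C/N = 2
    ratios <- vapply(c(0, 0.5, 1, 2, 4), function(off)
        measureKTR(ktr + off, lm)$cn_ratio, numeric(1))
    expect_true(all(diff(ratios) < 0))
    expect_true(all(ratios > 1))
    ktr2 <- matrix(0.8, 31, 31)
    ktr2[lab == 1L] <- 1.6                 # inactive cell, C/N = 0.5
    ratios2 <- vapply(c(0, 0.5, 1, 2, 4), function(off)
        measureKTR(ktr2 + off, lm)$cn_ratio, numeric(1))
    expect_true(all(diff(ratios2) > 0))
    expect_true(all(ratios2 < 1))
})
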