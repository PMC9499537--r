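# paint a clipped Gaussian blob (additive)
paintGaussian <- function(img, xpx, ypx, sigma, amp, cutoff = 3.5) {
    nr <- nrow(img); nc <- ncol(img)
    r <- ceiling(cutoff * sigma)
    i0 <- max(1, floor(ypx - r)); i1 <- min(nr, ceiling(ypx + r))
    j0 <- max(1, floor(xpx - r)); j1 <- min(nc, ceiling(xpx + r))
    if (i0 > i1 || j0 > j1) return(img)
    ii <- i0:i1; jj <- j0:j1
    img[ii, jj] <- img[ii, jj] +
        amp * exp(-outer((ii - ypx)^2, (jj - xpx)^2, "+") / (2 * sigma^2))
    img
}

#' Render a simulated monolayer into a calibrated image stack
#'
#' Channels: `H2B` -- per nucleus a uniform disk with a one-pixel
#' anti-aliased edge whose half-maximum radius equals the nuclear radius
#' (a sharp-edged object seen through the microscope's point-spread
#' function), so an intensity-threshold segmentation recovers the true
#' nuclear pixel set; `KTR` -- per cell a cytoplasmic disk and a
#' nuclear disk whose mean intensities encode the true C/N ratio
#' `cnBaseline * (1 + (g - 1) E)` (so the C/N fold-change between E = 0 and
#' E = 1 is exactly the configured `ktrPartition` g); `CASP` -- a bright spot
#' at each event site for the event frame and the next. A dying nucleus
#' shrinks for two frames before disappearing. Gaussian noise of sd
#' `noiseSd` is added to all channels and intensities clamped at zero.
#'
#' @param gt a [GroundTruth-class].
#' @param memoryBudget maximal stack size in bytes (default 4e9); a larger
#'   request is an error.
#' @return a [FrameStack-class] with channels H2B, KTR, CASP.
#' @export
renderFrameStack <- function(gt, memoryBudget = 4e9) {
    stopifnot(is(gt, "GroundTruth"))
    cfg <- gt@config
    ps <- cfg@pixelSize
    nr <- round(cfg@fieldSize[2] / ps)
    nc <- round(cfg@fieldSize[1] / ps)
    nf <- cfg@nFrames
    need <- as.numeric(nr) * nc * 3 * nf * 8
    if (need > memoryBudget)
        stop("requested stack (", round(need / 1e9, 2),
             " GB) exceeds the memory budget")
    set.seed(cfg@rngSeed + 7777L)    # noise stream, decoupled from the model
    px <- array(0, c(nr, nc, 3, nf))
    nucRpx <- cfg@nucleusRadius / ps
    sigma <- nucRpx / sqrt(2 * log(2))   # caspase spots / dying remnants
    cytoRpx <- nucRpx + 4
    g <- cfg@ktrPartition
    base <- 0.5
    cells <- gt@cells
    events <- gt@events
    # patch bounds for painting (in-place, no full-frame copies)
    clip <- function(xpx, ypx, r) {
        list(i0 = max(1, floor(ypx - r)), i1 = min(nr, ceiling(ypx + r)),
             j0 = max(1, floor(xpx - r)), j1 = min(nc, ceiling(xpx + r)))
    }
    for (f in seq_len(nf)) {
        sub <- cells[cells$frame == f, , drop = FALSE]
        h2b <- matrix(0, nr, nc)
        ktr <- matrix(0, nr, nc)
        casp <- matrix(0, nr, nc)
        if (nrow(sub)) {
            xpx <- umToPx(sub$x_um, ps); ypx <- umToPx(sub$y_um, ps)
            cn <- cfg@cnBaseline * (1 + (g - 1) * sub$E)
            cyto <- base * sqrt(cn); nuc <- base / sqrt(cn)
            for (i in seq_len(nrow(sub))) {
                b <- clip(xpx[i], ypx[i], nucRpx + 1)
                ii <- b$i0:b$i1; jj <- b$j0:b$j1
                r <- sqrt(outer((ii - ypx[i])^2, (jj - xpx[i])^2, "+"))
                h2b[ii, jj] <- h2b[ii, jj] +
                    pmin(pmax(nucRpx + 0.5 - r, 0), 1)
            }
            for (i in seq_len(nrow(sub))) {
                b <- clip(xpx[i], ypx[i], cytoRpx)
                ii <- b$i0:b$i1; jj <- b$j0:b$j1
                m <- outer((ii - ypx[i])^2, (jj - xpx[i])^2, "+") <=
                    cytoRpx^2
                s <- ktr[ii, jj]; s[m] <- cyto[i]; ktr[ii, jj] <- s
            }
            for (i in seq_len(nrow(sub))) {
                b <- clip(xpx[i], ypx[i], nucRpx)
                ii <- b$i0:b$i1; jj <- b$j0:b$j1
                m <- outer((ii - ypx[i])^2, (jj - xpx[i])^2, "+") <=
                    nucRpx^2
                s <- ktr[ii, jj]; s[m] <- nuc[i]; ktr[ii, jj] <- s
            }
        }
        if (nrow(events)) {
            # extrusion: shrinking remnant of the dying nucleus
            for (r in which(events$frame %in% c(f - 1, f - 2))) {
                shrink <- if (events$frame[r] == f - 1) 0.55 else 0.25
                h2b <- paintGaussian(h2b, umToPx(events$x_um[r], ps),
                                     umToPx(events$y_um[r], ps),
                                     sigma * shrink, 0.8)
            }
            for (r in which(events$frame %in% c(f, f - 1)))
                casp <- paintGaussian(casp, umToPx(events$x_um[r], ps),
                                      umToPx(events$y_um[r], ps),
                                      sigma, 1)
        }
        if (cfg@noiseSd > 0) {
            h2b <- h2b + matrix(rnorm(nr * nc, 0, cfg@noiseSd), nr, nc)
            ktr <- ktr + matrix(rnorm(nr * nc, 0, cfg@noiseSd), nr, nc)
            casp <- casp + matrix(rnorm(nr * nc, 0, cfg@noiseSd), nr, nc)
        }
        px[, , 1, f] <- pmax(h2b, 0)
        px[, , 2, f] <- pmax(ktr, 0)
        px[, , 3, f] <- pmax(casp, 0)
    }
    FrameStack(px, c("H2B", "KTR", "CASP"), ps, cfg@frameInterval)
}
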