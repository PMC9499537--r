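#' Per-frame nuclear label map
#'
#' @slot labels integer matrix; 0 = background, k > 0 = nucleus k.
#' @slot table data.frame with one row per label: `label`, `x_px`, `y_px`
#'   (centroid, pixel units), `area_px`, `border` (touches the image edge).
#' @export
setClass("LabelMap", representation(labels = "matrix", table = "data.frame"))

setValidity("LabelMap", function(object) {
    if (nrow(object@table) &&
        !all(object@table$label == seq_len(nrow(object@table))))
        return("labels must be consecutive positive integers")
    TRUE
})

setMethod("show", "LabelMap", function(object) {
    cat("LabelMap:", nrow(object@table), "nuclei on",
        nrow(object@labels), "x", ncol(object@labels), "px\n")
})

#' @describeIn LabelMap-class the integer label image.
#' @param object a `LabelMap`.
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))
#' @rdname LabelMap-class
#' @export
setMethod("labelMatrix", "LabelMap", function(object) object@labels)

#' @describeIn LabelMap-class per-label centroid/area table.
#' @export
setGeneric("labelTable", function(object) standardGeneric("labelTable"))
#' @rdname LabelMap-class
#' @export
setMethod("labelTable", "LabelMap", function(object) object@table)

#' Segment nuclei from an H2B image
#'
#' Gaussian smoothing, Otsu threshold, then a watershed on the exact
#' Euclidean distance transform to split touching nuclei. Objects below
#' `minArea` pixels are removed; objects touching the image border are kept
#' but flagged. A blank image yields an empty label map.
#'
#' @param img numeric matrix `[row, col]`, non-negative.
#' @param smoothingSigma Gaussian smoothing sd in px (0 disables).
#' @param minArea minimum object area in px.
#' @param watershedTolerance minimum distance-transform height separating two
#'   objects (px).
#' @param threshold absolute intensity threshold; `NULL` (default) uses Otsu
#'   on the smoothed image.
#' @return a [LabelMap-class].
#' @export
segmentNuclei <- function(img, smoothingSigma = 0.5, minArea = 15,
                          watershedTolerance = 0.3, threshold = NULL) {
    if (any(img < 0)) stop("image intensities must be non-negative")
    emptyMap <- function() new("LabelMap",
        labels = matrix(0L, nrow(img), ncol(img)),
        table = data.frame(label = integer(0), x_px = numeric(0),
                           y_px = numeric(0), area_px = integer(0),
                           border = logical(0)))
    if (max(img) - min(img) < 1e-12) return(emptyMap())
    sm <- if (smoothingSigma > 0) {
        ks <- 2L * ceiling(3 * smoothingSigma) + 1L
        as.matrix(EBImage::filter2(
            img, EBImage::makeBrush(ks, "gaussian", sigma = smoothingSigma),
            boundary = "replicate"))
    } else img
    if (is.null(threshold)) {
        mx <- max(sm)
        threshold <- EBImage::otsu(EBImage::Image(sm / mx),
                                   range = c(0, 1)) * mx
    }
    mask <- sm > threshold
    if (!any(mask)) return(emptyMap())
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    ws <- EBImage::watershed(dm, tolerance = watershedTolerance)
    lab <- as.matrix(EBImage::imageData(ws))
    storage.mode(lab) <- "integer"
    areas <- tabulate(lab)
    keep <- which(areas >= minArea)
    if (!length(keep)) return(emptyMap())
    remap <- integer(length(areas))
    remap[keep] <- seq_along(keep)
    nz <- lab > 0
    lab[nz] <- remap[lab[nz]]
    idx <- which(lab > 0, arr.ind = TRUE)
    lv <- lab[lab > 0]
    rowc <- tapply(idx[, 1], lv, mean)
    colc <- tapply(idx[, 2], lv, mean)
    area <- tabulate(lv, nbins = length(keep))
    brd <- tapply(idx[, 1] == 1 | idx[, 1] == nrow(lab) |
                  idx[, 2] == 1 | idx[, 2] == ncol(lab), lv, any)
    new("LabelMap", labels = lab,
        table = data.frame(label = seq_along(keep),
                           x_px = as.numeric(colc), y_px = as.numeric(rowc),
                           area_px = area, border = as.logical(brd)))
}

#' Cytoplasmic annulus mask of one nucleus
#'
#' The annulus is the set of background pixels within Euclidean distance
#' `widthPx` of the nucleus, excluding every pixel of any nucleus and every
#' pixel within distance 1 of another nucleus. Distances are measured
#' between pixel centres with the exact Euclidean distance transform, so the
#' mask matches a brute-force enumeration pixel for pixel. The mask may be
#' empty in pathological crowding.
#'
#' @param labelMap a [LabelMap-class].
#' @param label nucleus label.
#' @param widthPx annulus width in px (default 2).
#' @return sorted integer vector of linear indices into the label matrix.
#' @export
makeAnnulus <- function(labelMap, label, widthPx = 2) {
    stopifnot(is(labelMap, "LabelMap"))
    lab <- labelMap@labels
    if (!label %in% labelMap@table$label)
        stop("unknown label: ", label)
    idx <- which(lab == label, arr.ind = TRUE)
    annulusFromBBox(lab, label, min(idx[, 1]), max(idx[, 1]),
                    min(idx[, 2]), max(idx[, 2]), widthPx)
}

# annulus pixel indices given the label's bounding box (exact Euclidean
# distances via EBImage's distance transform on a small crop)
annulusFromBBox <- function(lab, label, rmin, rmax, cmin, cmax, widthPx) {
    m <- ceiling(widthPx) + 2
    i0 <- max(1, rmin - m); i1 <- min(nrow(lab), rmax + m)
    j0 <- max(1, cmin - m); j1 <- min(ncol(lab), cmax + m)
    crop <- lab[i0:i1, j0:j1, drop = FALSE]
    maskK <- crop == label
    dK <- as.matrix(EBImage::distmap(EBImage::Image((!maskK) * 1)))
    ann <- crop == 0 & dK <= widthPx
    others <- crop > 0 & !maskK
    if (any(others)) {
        dO <- as.matrix(EBImage::distmap(EBImage::Image((!others) * 1)))
        ann <- ann & dO > 1
    }
    aidx <- which(ann, arr.ind = TRUE)
    if (!nrow(aidx)) return(integer(0))
    sort((aidx[, 2] + j0 - 2) * nrow(lab) + (aidx[, 1] + i0 - 1))
}

#' Measure nuclear and cytoplasmic KTR intensity per cell
#'
#' For each nucleus: mean reporter intensity over nuclear pixels, mean over
#' the two-pixel cytoplasmic annulus ([makeAnnulus()]), their ratio
#' `cn_ratio = cyto/nuclear`, and the activity call
#' `erk_active = cyto_mean > nuclear_mean` (strict; a tie is inactive).
#' Cells with an empty annulus get `NA` ratio and activity.
#'
#' @param ktr numeric matrix, the KTR reporter channel.
#' @param labelMap a [LabelMap-class] from the matching H2B frame.
#' @param widthPx annulus width in px.
#' @param pixelSize optional um/px; adds `x_um`, `y_um` columns.
#' @return data.frame: `label`, `x_px`, `y_px`, `area_px`, `border`,
#'   `nuc_mean`, `cyto_mean`, `cn_ratio`, `erk_active` (+ `x_um`, `y_um`).
#' @export
measureKTR <- function(ktr, labelMap, widthPx = 2, pixelSize = NULL) {
    stopifnot(is(labelMap, "LabelMap"))
    lab <- labelMap@labels
    if (!identical(dim(ktr), dim(lab)))
        stop("KTR channel and label map shapes differ")
    tab <- labelMap@table
    out <- tab
    if (!nrow(tab)) {
        out$nuc_mean <- out$cyto_mean <- out$cn_ratio <- numeric(0)
        out$erk_active <- logical(0)
        return(out)
    }
    nzi <- which(lab > 0)
    lv <- lab[nzi]
    nucMean <- tapply(ktr[nzi], lv, mean)
    out$nuc_mean <- as.numeric(nucMean[as.character(tab$label)])
    # bounding boxes in one pass (avoids a full-image scan per label)
    nrL <- nrow(lab)
    rows <- ((nzi - 1L) %% nrL) + 1L
    cols <- ((nzi - 1L) %/% nrL) + 1L
    rmin <- tapply(rows, lv, min); rmax <- tapply(rows, lv, max)
    cmin <- tapply(cols, lv, min); cmax <- tapply(cols, lv, max)
    cytoMean <- vapply(tab$label, function(k) {
        kk <- as.character(k)
        a <- annulusFromBBox(lab, k, rmin[[kk]], rmax[[kk]],
                             cmin[[kk]], cmax[[kk]], widthPx)
        if (!length(a)) NA_real_ else mean(ktr[a])
    }, numeric(1))
    out$cyto_mean <- cytoMean
    out$cn_ratio <- out$cyto_mean / out$nuc_mean
    out$erk_active <- out$cyto_mean > out$nuc_mean
    if (!is.null(pixelSize)) {
        out$x_um <- pxToUm(out$x_px, pixelSize)
        out$y_um <- pxToUm(out$y_px, pixelSize)
    }
    out
}

#' Segment and measure every frame of a stack
#'
#' Runs [segmentNuclei()] on the H2B channel and [measureKTR()] on the KTR
#' channel of each frame.
#'
#' @param stack a [FrameStack-class] with H2B and KTR channels.
#' @param h2bChannel,ktrChannel channel names.
#' @param widthPx annulus width.
#' @param ... passed to [segmentNuclei()].
#' @return list with `labelMaps` (list of [LabelMap-class]) and
#'   `measurements` (data.frame with a `frame` column and um coordinates).
#' @export
segmentStack <- function(stack, h2bChannel = "H2B", ktrChannel = "KTR",
                         widthPx = 2, ...) {
    stopifnot(is(stack, "FrameStack"))
    nf <- nFrames(stack)
    maps <- vector("list", nf)
    meas <- vector("list", nf)
    for (f in seq_len(nf)) {
        lm <- segmentNuclei(getFrame(stack, f, h2bChannel), ...)
        maps[[f]] <- lm
        m <- measureKTR(getFrame(stack, f, ktrChannel), lm,
                        widthPx = widthPx, pixelSize = stack@pixelSize)
        if (nrow(m)) m$frame <- f
        meas[[f]] <- m
    }
    meas <- do.call(rbind, meas[vapply(meas, nrow, 1L) > 0])
    if (is.null(meas))
        meas <- data.frame(label = integer(0), frame = integer(0),
                           x_um = numeric(0), y_um = numeric(0))
    list(labelMaps = maps, measurements = meas)
}
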