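#' Density-based spatial clustering (DBSCAN)
#'
#' Classic DBSCAN with Euclidean distances: a point is a core point when at
#' least `minPts` points (itself included) lie within `eps`; clusters are the
#' density-connected components of core points; non-core points within `eps`
#' of a core point join its cluster (first reached wins); the rest are noise
#' (cluster 0).
#'
#' @param points n x 2 matrix or data.frame of coordinates.
#' @param eps neighbourhood radius (same units as `points`).
#' @param minPts minimum neighbourhood size of a core point (self included).
#' @return integer vector of cluster labels (0 = noise).
#' @export
dbscanCluster <- function(points, eps, minPts) {
    pts <- as.matrix(points)
    n <- nrow(pts)
    if (n == 0) return(integer(0))
    stopifnot(eps > 0, minPts >= 1)
    nbr <- vector("list", n)
    chunk <- max(1, floor(2e6 / n))
    for (s in seq(1, n, by = chunk)) {
        e <- min(n, s + chunk - 1)
        block <- outer(pts[s:e, 1], pts[, 1], "-")^2 +
                 outer(pts[s:e, 2], pts[, 2], "-")^2
        for (i in s:e)
            nbr[[i]] <- which(block[i - s + 1, ] <= eps^2)
    }
    core <- lengths(nbr) >= minPts
    labels <- integer(n)
    cl <- 0L
    for (i in seq_len(n)) {
        if (labels[i] != 0L || !core[i]) next
        cl <- cl + 1L
        labels[i] <- cl
        queue <- nbr[[i]]
        while (length(queue)) {
            j <- queue[1]; queue <- queue[-1]
            if (labels[j] == 0L) {
                labels[j] <- cl
                if (core[j]) queue <- c(queue, nbr[[j]][labels[nbr[[j]]] == 0L])
            }
        }
    }
    labels
}

#' Cluster ERK-active cells in one frame
#'
#' DBSCAN over the centroids of ERK-active cells; noise points are excluded
#' from every cluster. By default `eps` adapts to the frame as 1.5x the
#' median nearest-nuclei distance of *all* cells in the frame.
#'
#' @param measurements data.frame with `x_um`, `y_um` and logical
#'   `erk_active` (NA treated as inactive).
#' @param epsUm DBSCAN radius (um); `NULL` for the adaptive default.
#' @param minPts DBSCAN core threshold.
#' @return the active-cell subset with a `cluster` column (0 = noise), and
#'   the used `eps` in attribute `"eps"`.
#' @export
clusterErkActive <- function(measurements, epsUm = NULL, minPts = 5) {
    act <- measurements[!is.na(measurements$erk_active) &
                        measurements$erk_active, , drop = FALSE]
    if (is.null(epsUm)) {
        if (nrow(measurements) < 2)
            stop("cannot derive adaptive eps from fewer than 2 cells")
        epsUm <- 1.5 * median(nearestNucleiDistances(
            measurements[, c("x_um", "y_um")]))
    }
    if (!nrow(act)) {
        act$cluster <- integer(0)
        attr(act, "eps") <- epsUm
        return(act)
    }
    act$cluster <- dbscanCluster(act[, c("x_um", "y_um")], epsUm, minPts)
    attr(act, "eps") <- epsUm
    act
}

#' Rasterised active region of a point cluster
#'
#' The region is the union of disks of radius `alphaUm` around the member
#' points, rasterised on the pixel grid (a pixel belongs to the region when
#' its centre lies within `alphaUm` of a member point's pixel centre).
#'
#' @param points data.frame/matrix of member coordinates (um).
#' @param dim image dimensions `c(nrow, ncol)` in px.
#' @param pixelSize um per px.
#' @param alphaUm disk radius (um).
#' @return logical matrix mask.
#' @export
regionMask <- function(points, dim, pixelSize, alphaUm) {
    mask0 <- matrix(FALSE, dim[1], dim[2])
    pts <- as.matrix(points)
    if (nrow(pts)) {
        rr <- pmin(pmax(round(umToPx(pts[, 2], pixelSize)), 1), dim[1])
        cc <- pmin(pmax(round(umToPx(pts[, 1], pixelSize)), 1), dim[2])
        mask0[cbind(rr, cc)] <- TRUE
    }
    if (!any(mask0)) return(mask0)
    d <- as.matrix(EBImage::distmap(EBImage::Image((!mask0) * 1)))
    mask0 | d <= alphaUm / pixelSize
}

#' @rdname regionMask
#' @param mask logical matrix from `regionMask`.
#' @return `regionBoundary`: list of polygon matrices (x_um, y_um vertices),
#'   one per connected region.
#' @export
regionBoundary <- function(mask, pixelSize) {
    if (!any(mask)) return(list())
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    ct <- EBImage::ocontour(lab)
    lapply(ct, function(m) {
        # EBImage contours are (x, y) 0-based pixel coordinates
        cbind(x_um = pxToUm(m[, 1] + 1, pixelSize),
              y_um = pxToUm(m[, 2] + 1, pixelSize))
    })
}

#' Cumulative ERK-activity heat map
#'
#' `accumulateHeatmap` sums per-frame active-region masks: the heat value of
#' a pixel is the number of frames whose active region contained it.
#' `erkActivityHeatmap` runs the full per-frame pipeline (activity calls ->
#' DBSCAN clusters -> rasterised regions -> sum) over a measurement table.
#'
#' @param masks list of logical matrices (one per frame).
#' @return integer matrix of per-pixel frame counts.
#' @export
accumulateHeatmap <- function(masks) {
    stopifnot(length(masks) >= 1)
    out <- matrix(0L, nrow(masks[[1]]), ncol(masks[[1]]))
    for (m in masks) {
        stopifnot(identical(dim(m), dim(out)))
        out <- out + m
    }
    out
}

#' @rdname accumulateHeatmap
#' @param measurements per-cell measurement table with `frame`, `x_um`,
#'   `y_um`, `erk_active`.
#' @param dim image dimensions `c(nrow, ncol)` px.
#' @param pixelSize um/px.
#' @param frames frames to accumulate (default: all in the table).
#' @param epsUm,minPts DBSCAN parameters (see [clusterErkActive()]).
#' @param alphaUm region disk radius; defaults to the DBSCAN eps.
#' @export
erkActivityHeatmap <- function(measurements, dim, pixelSize, frames = NULL,
                               epsUm = NULL, minPts = 5, alphaUm = NULL) {
    if (is.null(frames)) frames <- sort(unique(measurements$frame))
    heat <- matrix(0L, dim[1], dim[2])
    for (f in frames) {
        sub <- measurements[measurements$frame == f, , drop = FALSE]
        if (nrow(sub) < 2) next
        cls <- clusterErkActive(sub, epsUm = epsUm, minPts = minPts)
        members <- cls[cls$cluster > 0, , drop = FALSE]
        if (!nrow(members)) next
        a <- if (is.null(alphaUm)) attr(cls, "eps") else alphaUm
        heat <- heat + regionMask(members[, c("x_um", "y_um")], dim,
                                  pixelSize, a)
    }
    heat
}

#' Detect node compartments from nuclear positions
#'
#' A binned Gaussian kernel density of nuclear centroids is thresholded and
#' connected components above `minArea` become nodes. The threshold is the
#' Otsu level of the density map, floored at `densityFactor` times the
#' background median *and* at `median + noiseZ * MAD` (the latter keeps
#' Poisson clumpiness of a sparse uniform field from producing phantom
#' nodes). A field with no tile above the floor yields an empty NodeSet.
#' Input can be a centroid table or an H2B frame (segmented internally).
#'
#' @param cells data.frame with `x_um`, `y_um`, or a numeric matrix image.
#' @param fieldSize `c(width, height)` um (required for centroid input).
#' @param pixelSize um/px (required for image input).
#' @param bandwidth KDE bandwidth (um).
#' @param gridSize density grid tile edge (um).
#' @param minArea minimal node area (um^2).
#' @param densityFactor floor on the node/background density contrast.
#' @param noiseZ robust z-score floor against density-map sampling noise.
#' @param ... passed to [segmentNuclei()] for image input.
#' @return a [NodeSet-class].
#' @export
detectNodes <- function(cells, fieldSize = NULL, pixelSize = NULL,
                        bandwidth = 40, gridSize = 10, minArea = 5000,
                        densityFactor = 1.5, noiseZ = 5, ...) {
    if (is.matrix(cells) && is.numeric(cells)) {
        if (is.null(pixelSize))
            stop("pixelSize required for image input")
        lm <- segmentNuclei(cells, ...)
        tab <- labelTable(lm)
        cells <- data.frame(x_um = pxToUm(tab$x_px, pixelSize),
                            y_um = pxToUm(tab$y_px, pixelSize))
        if (is.null(fieldSize))
            fieldSize <- c(ncol(lm@labels), nrow(lm@labels)) * pixelSize
    }
    if (is.null(fieldSize))
        stop("fieldSize required for centroid input")
    if (nrow(cells) < 1) stop("need at least one nucleus")
    nc <- max(2, ceiling(fieldSize[1] / gridSize))
    nr <- max(2, ceiling(fieldSize[2] / gridSize))
    counts <- matrix(0, nr, nc)
    rr <- pmin(pmax(ceiling(cells$y_um / gridSize), 1), nr)
    cc <- pmin(pmax(ceiling(cells$x_um / gridSize), 1), nc)
    for (i in seq_along(rr)) counts[rr[i], cc[i]] <- counts[rr[i], cc[i]] + 1
    dens <- as.matrix(EBImage::gblur(counts, sigma = bandwidth / gridSize))
    emptySet <- new("NodeSet",
        nodes = data.frame(node_id = integer(0), x_um = numeric(0),
                           y_um = numeric(0), area_um2 = numeric(0)),
        boundaries = list(), spacing = numeric(0),
        regionGrid = matrix(0L, nr, nc), gridSize = gridSize)
    # background level from the lower quartile region, which stays
    # uncontaminated even when nodes cover a large area fraction
    q <- quantile(dens, c(0.10, 0.25), names = FALSE)
    sigmaBg <- max((q[2] - q[1]) / 0.607, 0)   # N(0,1): z_.25 - z_.10
    bg <- q[2] + 0.6745 * sigmaBg              # background median
    # existence test against complete spatial randomness: a KDE tile of a
    # uniform field of the same intensity has mean lambda and sd
    # sqrt(lambda / (4 pi sigma_t^2)), so some tile must exceed that
    # clumpiness before any node is declared
    lambda <- nrow(cells) * gridSize^2 / prod(fieldSize)
    sdCSR <- sqrt(lambda / (4 * pi * (bandwidth / gridSize)^2))
    floorThr <- max(densityFactor * bg, lambda + noiseZ * sdCSR)
    if (max(dens) <= floorThr) return(emptySet)
    ot <- EBImage::otsu(EBImage::Image(dens / max(dens)),
                        range = c(0, 1)) * max(dens)
    thr <- max(ot, densityFactor * bg)
    mask <- dens > thr
    if (!any(mask)) return(emptySet)
    lab <- as.matrix(EBImage::imageData(
        EBImage::bwlabel(EBImage::Image(mask * 1))))
    storage.mode(lab) <- "integer"
    areas <- tabulate(lab) * gridSize^2
    keep <- which(areas >= minArea)
    if (!length(keep)) return(emptySet)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    nz <- lab > 0
    lab[nz] <- remap[lab[nz]]
    idx <- which(lab > 0, arr.ind = TRUE)
    lv <- lab[lab > 0]; w <- dens[lab > 0]
    xc <- tapply(idx[, 2] * w, lv, sum) / tapply(w, lv, sum)
    yc <- tapply(idx[, 1] * w, lv, sum) / tapply(w, lv, sum)
    nodes <- data.frame(node_id = seq_along(keep),
                        x_um = (as.numeric(xc) - 0.5) * gridSize,
                        y_um = (as.numeric(yc) - 0.5) * gridSize,
                        area_um2 = areas[keep])
    bnd <- lapply(EBImage::ocontour(EBImage::Image(lab)), function(m)
        cbind(x_um = (m[, 1] + 0.5) * gridSize,
              y_um = (m[, 2] + 0.5) * gridSize))
    spacing <- if (nrow(nodes) >= 2)
        nearestNucleiDistances(nodes[, c("x_um", "y_um")]) else numeric(0)
    new("NodeSet", nodes = nodes, boundaries = bnd, spacing = spacing,
        regionGrid = lab, gridSize = gridSize)
}

#' Assign cells to node / non-node compartments
#'
#' A cell is "node" when its centroid falls in a detected node region (label
#' grid lookup); assignment is deterministic and total.
#'
#' @param cells data.frame with `x_um`, `y_um`.
#' @param nodeSet a [NodeSet-class].
#' @return character vector, "node" or "non-node", one per row of `cells`.
#' @export
assignCompartments <- function(cells, nodeSet) {
    stopifnot(is(nodeSet, "NodeSet"))
    if (!nrow(cells)) return(character(0))
    g <- nodeSet@regionGrid
    gs <- nodeSet@gridSize
    rr <- ceiling(cells$y_um / gs)
    cc <- ceiling(cells$x_um / gs)
    inside <- rr >= 1 & rr <= nrow(g) & cc >= 1 & cc <= ncol(g)
    lab <- integer(nrow(cells))
    lab[inside] <- g[cbind(rr[inside], cc[inside])]
    ifelse(lab > 0, "node", "non-node")
}

#' Per-cell intensity of an arbitrary channel
#'
#' Sum or mean of a channel over each cell's nuclear pixels (optionally
#' nucleus plus cytoplasmic annulus), with an optional two-population
#' high/low gate at an absolute threshold.
#'
#' @param channel numeric matrix aligned with the label map.
#' @param labelMap a [LabelMap-class].
#' @param mode "sum" or "mean".
#' @param includeAnnulus also include the two-pixel annulus pixels.
#' @param gate optional absolute threshold; adds a `gate` column
#'   ("high"/"low").
#' @param widthPx annulus width when `includeAnnulus`.
#' @return data.frame: `label`, `intensity` (+ `gate`).
#' @export
quantifyChannelPerCell <- function(channel, labelMap,
                                   mode = c("sum", "mean"),
                                   includeAnnulus = FALSE, gate = NULL,
                                   widthPx = 2) {
    mode <- match.arg(mode)
    stopifnot(is(labelMap, "LabelMap"))
    lab <- labelMap@labels
    if (!identical(dim(channel), dim(lab)))
        stop("channel and label map shapes differ")
    tab <- labelMap@table
    f <- if (mode == "sum") sum else mean
    vals <- vapply(tab$label, function(k) {
        px <- which(lab == k)
        if (includeAnnulus) px <- c(px, makeAnnulus(labelMap, k, widthPx))
        f(channel[px])
    }, numeric(1))
    out <- data.frame(label = tab$label, intensity = vals)
    if (!is.null(gate))
        out$gate <- ifelse(out$intensity > gate, "high", "low")
    out
}

#' Nearest-neighbour distances between nuclei
#'
#' Per nucleus, the Euclidean distance to its nearest neighbour (computed
#' exactly, in memory-bounded chunks).
#'
#' @param points n x 2 matrix or data.frame of centroids.
#' @return numeric vector of length n.
#' @export
nearestNucleiDistances <- function(points) {
    pts <- as.matrix(points)
    if (nrow(pts) < 2) stop("need at least two nuclei")
    nearestNeighbour(pts)$dist
}

#' Count apoptotic events per compartment
#'
#' @param events data.frame with `x_um`, `y_um`.
#' @param nodeSet a [NodeSet-class].
#' @return list: `counts` (named vector node / non-node) and
#'   `fractionNonNode`.
#' @export
localizeEvents <- function(events, nodeSet) {
    if (!nrow(events))
        return(list(counts = c(node = 0L, `non-node` = 0L),
                    fractionNonNode = NA_real_))
    comp <- assignCompartments(events, nodeSet)
    counts <- c(node = sum(comp == "node"),
                `non-node` = sum(comp == "non-node"))
    list(counts = counts,
         fractionNonNode = unname(counts["non-node"] / sum(counts)))
}
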