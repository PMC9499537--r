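#' Optimal one-to-one assignment
#'
#' Solves the rectangular linear assignment problem (Hungarian algorithm,
#' compiled) minimising the total cost. With fewer rows than columns some
#' columns stay unassigned, and vice versa.
#'
#' @param cost numeric cost matrix (finite entries).
#' @return integer vector: for each row, the assigned column (0 = none).
#' @export
solveAssignment <- function(cost) {
    cost <- as.matrix(cost)
    if (!all(is.finite(cost))) stop("assignment costs must be finite")
    if (nrow(cost) == 0 || ncol(cost) == 0)
        return(integer(nrow(cost)))
    if (nrow(cost) <= ncol(cost))
        return(as.integer(solve_assignment_cpp(cost)))
    byCol <- solve_assignment_cpp(t(cost))
    out <- integer(nrow(cost))
    out[byCol] <- seq_len(ncol(cost))
    out
}

# union-find over integers 1..n
ufFind <- function(parent, i) {
    while (parent[i] != i) i <- parent[i]
    i
}

# gated minimum-squared-displacement matching between two point sets.
# Returns list(match = column per row (0 = unmatched), cost = total d^2).
gatedMatch <- function(prev, cur, gate) {
    np <- nrow(prev); nc <- nrow(cur)
    if (np == 0 || nc == 0)
        return(list(match = integer(np), cost = 0))
    d2 <- outer(prev[, 1], cur[, 1], "-")^2 +
          outer(prev[, 2], cur[, 2], "-")^2
    ok <- d2 <= gate^2
    match <- integer(np)
    total <- 0
    # connected components of the gating graph keep assignment problems tiny
    parent <- seq_len(np + nc)
    for (i in seq_len(np)) for (j in which(ok[i, ])) {
        ri <- ufFind(parent, i); rj <- ufFind(parent, np + j)
        if (ri != rj) parent[rj] <- ri
    }
    roots <- vapply(seq_len(np + nc), function(i) ufFind(parent, i), 1L)
    BIG <- max(gate^2, 1) * 1e8
    pen <- gate^2 + 1     # cost of leaving a point unmatched
    for (comp in unique(roots[seq_len(np)])) {
        rows <- which(roots[seq_len(np)] == comp)
        cols <- which(roots[np + seq_len(nc)] == comp)
        if (!length(cols)) next
        s <- length(rows) + length(cols)
        cm <- matrix(BIG, s, s)
        sub <- d2[rows, cols, drop = FALSE]
        sub[!ok[rows, cols, drop = FALSE]] <- BIG
        cm[seq_along(rows), seq_along(cols)] <- sub
        for (a in seq_along(rows)) cm[a, length(cols) + a] <- pen
        for (b in seq_along(cols)) cm[length(rows) + b, b] <- pen
        cm[(length(rows) + 1):s, (length(cols) + 1):s] <- 0
        asg <- solveAssignment(cm)
        for (a in seq_along(rows)) {
            j <- asg[a]
            if (j >= 1 && j <= length(cols) && sub[a, j] < BIG) {
                match[rows[a]] <- cols[j]
                total <- total + sub[a, j]
            }
        }
    }
    list(match = match, cost = total)
}

#' Link per-frame detections into single-cell tracks
#'
#' Frame-to-frame matching minimises the total squared displacement by
#' optimal one-to-one assignment, subject to a hard gating radius. Unmatched
#' detections start new tracks; a track unmatched for more than `maxGap`
#' frames terminates. Skipped frames inside a surviving track are linearly
#' interpolated and flagged `gapfilled` (their measurement columns are NA).
#'
#' @param detections data.frame with at least `frame`, `x_um`, `y_um`; all
#'   other columns are carried into the output.
#' @param gatingRadius maximal per-step displacement (um).
#' @param maxGap maximal number of consecutive missed frames.
#' @return TrackTable data.frame: `track_id`, `frame`, `x_um`, `y_um`,
#'   `gapfilled`, plus the carried columns. Empty input gives an empty table.
#' @export
linkTracks <- function(detections, gatingRadius = 15, maxGap = 2) {
    stopifnot(gatingRadius > 0)
    need <- c("frame", "x_um", "y_um")
    if (!all(need %in% names(detections)))
        stop("detections need columns: ", paste(need, collapse = ", "))
    carried <- setdiff(names(detections), need)
    emptyOut <- cbind(
        data.frame(track_id = integer(0), frame = integer(0),
                   x_um = numeric(0), y_um = numeric(0),
                   gapfilled = logical(0)),
        detections[0, carried, drop = FALSE])
    if (!nrow(detections)) return(emptyOut)
    detections <- detections[order(detections$frame), , drop = FALSE]
    frames <- seq(min(detections$frame), max(detections$frame))
    # open track state
    tid <- integer(0); lastF <- integer(0)
    lx <- numeric(0); ly <- numeric(0)
    nextId <- 1L
    # detection rows (index into detections) and interpolated gap rows
    dtTid <- integer(nrow(detections)); dtIdx <- integer(nrow(detections))
    nDt <- 0L
    gpTid <- integer(0); gpFrame <- integer(0)
    gpX <- numeric(0); gpY <- numeric(0)
    for (f in frames) {
        di <- which(detections$frame == f)
        if (length(tid) && length(di)) {
            prev <- cbind(lx, ly)
            cur <- cbind(detections$x_um[di], detections$y_um[di])
            gm <- gatedMatch(prev, cur, gatingRadius)
            matchedDet <- logical(length(di))
            for (a in seq_along(tid)) {
                j <- gm$match[a]
                if (j == 0) next
                matchedDet[j] <- TRUE
                i <- di[j]
                if (f - lastF[a] > 1) {
                    gf <- seq(lastF[a] + 1, f - 1)
                    w <- (gf - lastF[a]) / (f - lastF[a])
                    gpTid <- c(gpTid, rep(tid[a], length(gf)))
                    gpFrame <- c(gpFrame, gf)
                    gpX <- c(gpX, lx[a] + w * (detections$x_um[i] - lx[a]))
                    gpY <- c(gpY, ly[a] + w * (detections$y_um[i] - ly[a]))
                }
                nDt <- nDt + 1L
                dtTid[nDt] <- tid[a]; dtIdx[nDt] <- i
                lastF[a] <- f; lx[a] <- detections$x_um[i]
                ly[a] <- detections$y_um[i]
            }
            newDet <- di[!matchedDet]
        } else newDet <- di
        for (i in newDet) {
            nDt <- nDt + 1L
            dtTid[nDt] <- nextId; dtIdx[nDt] <- i
            tid <- c(tid, nextId); lastF <- c(lastF, f)
            lx <- c(lx, detections$x_um[i]); ly <- c(ly, detections$y_um[i])
            nextId <- nextId + 1L
        }
        stale <- which(f - lastF >= maxGap + 1)
        if (length(stale)) {
            tid <- tid[-stale]; lastF <- lastF[-stale]
            lx <- lx[-stale]; ly <- ly[-stale]
        }
    }
    dtTid <- dtTid[seq_len(nDt)]; dtIdx <- dtIdx[seq_len(nDt)]
    out <- cbind(
        data.frame(track_id = dtTid, frame = detections$frame[dtIdx],
                   x_um = detections$x_um[dtIdx],
                   y_um = detections$y_um[dtIdx], gapfilled = FALSE),
        detections[dtIdx, carried, drop = FALSE])
    if (length(gpTid)) {
        gaps <- cbind(
            data.frame(track_id = gpTid, frame = gpFrame, x_um = gpX,
                       y_um = gpY, gapfilled = TRUE),
            detections[rep(1L, length(gpTid)), carried, drop = FALSE])
        gaps[, carried] <- NA
        out <- rbind(out, gaps)
    }
    out <- out[order(out$track_id, out$frame), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Detect apoptotic events
#'
#' Image mode: per frame, connected regions of the caspase channel above
#' `threshold` become detections; detections within `epsUm` of each other and
#' at most `maxFrameGap` frames apart are merged into one event anchored at
#' the intensity-weighted centroid of its first frame. Fallback mode (no
#' caspase channel): track terminations lacking any continuing detection
#' within `contRadius` in the next frame.
#'
#' @param stack a [FrameStack-class] with a caspase channel, or `NULL`.
#' @param tracks TrackTable for fallback mode, or `NULL`.
#' @param channel caspase channel name.
#' @param threshold absolute intensity threshold for a caspase spot.
#' @param epsUm spatial merge radius (um).
#' @param maxFrameGap temporal merge window (frames).
#' @param contRadius fallback continuation radius (um).
#' @return data.frame: `event_id`, `frame`, `x_um`, `y_um`.
#' @export
detectApoptosisEvents <- function(stack = NULL, tracks = NULL,
                                  channel = "CASP", threshold = 0.5,
                                  epsUm = 20, maxFrameGap = 2,
                                  contRadius = 15) {
    empty <- data.frame(event_id = integer(0), frame = integer(0),
                        x_um = numeric(0), y_um = numeric(0))
    if (!is.null(stack)) {
        stopifnot(is(stack, "FrameStack"))
        if (!channel %in% stack@channels)
            stop("stack has no '", channel, "' channel")
        ps <- stack@pixelSize
        det <- list()
        for (f in seq_len(nFrames(stack))) {
            img <- getFrame(stack, f, channel)
            mask <- img > threshold
            if (!any(mask)) next
            lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
            lab <- as.matrix(EBImage::imageData(lab))
            idx <- which(lab > 0, arr.ind = TRUE)
            lv <- lab[lab > 0]; w <- img[lab > 0]
            xs <- tapply(idx[, 2] * w, lv, sum) / tapply(w, lv, sum)
            ys <- tapply(idx[, 1] * w, lv, sum) / tapply(w, lv, sum)
            det[[length(det) + 1]] <- data.frame(
                frame = f, x_um = pxToUm(as.numeric(xs), ps),
                y_um = pxToUm(as.numeric(ys), ps),
                intensity = as.numeric(tapply(w, lv, sum)))
        }
        if (!length(det)) return(empty)
        det <- do.call(rbind, det)
        # greedy spatiotemporal clustering in frame order
        cl <- integer(nrow(det))
        cx <- numeric(0); cy <- numeric(0); cf <- integer(0)
        for (i in seq_len(nrow(det))) {
            assigned <- 0L
            if (length(cx)) {
                dd <- sqrt((cx - det$x_um[i])^2 + (cy - det$y_um[i])^2)
                okc <- which(dd <= epsUm &
                             det$frame[i] - cf <= maxFrameGap)
                if (length(okc)) assigned <- okc[which.min(dd[okc])]
            }
            if (assigned == 0L) {
                cx <- c(cx, det$x_um[i]); cy <- c(cy, det$y_um[i])
                cf <- c(cf, det$frame[i])
                assigned <- length(cx)
            } else cf[assigned] <- det$frame[i]
            cl[i] <- assigned
        }
        out <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
            d <- det[cl == k, , drop = FALSE]
            d <- d[d$frame == min(d$frame), , drop = FALSE]
            data.frame(frame = d$frame[1],
                       x_um = sum(d$x_um * d$intensity) / sum(d$intensity),
                       y_um = sum(d$y_um * d$intensity) / sum(d$intensity))
        }))
        out <- out[order(out$frame, out$x_um), , drop = FALSE]
        out <- cbind(event_id = seq_len(nrow(out)), out)
        rownames(out) <- NULL
        return(out)
    }
    if (!is.null(tracks)) {
        if (!nrow(tracks)) return(empty)
        lastFrame <- max(tracks$frame)
        ends <- do.call(rbind, lapply(split(tracks, tracks$track_id),
                                      function(tr) tr[which.max(tr$frame), ]))
        ends <- ends[ends$frame < lastFrame, , drop = FALSE]
        if (!nrow(ends)) return(empty)
        keep <- vapply(seq_len(nrow(ends)), function(i) {
            nxt <- tracks[tracks$frame == ends$frame[i] + 1, , drop = FALSE]
            if (!nrow(nxt)) return(TRUE)
            all(sqrt((nxt$x_um - ends$x_um[i])^2 +
                     (nxt$y_um - ends$y_um[i])^2) > contRadius)
        }, logical(1))
        ends <- ends[keep, , drop = FALSE]
        if (!nrow(ends)) return(empty)
        out <- data.frame(event_id = seq_len(nrow(ends)),
                          frame = ends$frame, x_um = ends$x_um,
                          y_um = ends$y_um)
        rownames(out) <- NULL
        return(out)
    }
    stop("provide a caspase stack or a track table")
}
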