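#' Apoptosis-referenced distance of every tracked cell
#'
#' For each track row, the Euclidean distance from the nucleus to the
#' apoptotic site, `dNuc_{i,t} = sqrt((x_{i,t} - x_a)^2 + (y_{i,t} - y_a)^2)`,
#' plus the per-track reference distance at the event frame, `dNuc_{i,a}`.
#' Tracks absent at the event frame are excluded and reported in the
#' `"excluded"` attribute.
#'
#' @param tracks TrackTable data.frame (`track_id`, `frame`, `x_um`, `y_um`,
#'   ...).
#' @param event list or one-row data.frame with `x_um`, `y_um`, `frame`.
#' @return the track table restricted to tracks covering the event frame,
#'   with columns `dnuc` and `dnuc_a` added.
#' @export
computeDNuc <- function(tracks, event) {
    stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
    a <- event$frame
    atA <- tracks[tracks$frame == a, c("track_id", "x_um", "y_um")]
    keep <- tracks$track_id %in% atA$track_id
    excluded <- unique(tracks$track_id[!keep])
    out <- tracks[keep, , drop = FALSE]
    out$dnuc <- sqrt((out$x_um - event$x_um)^2 + (out$y_um - event$y_um)^2)
    dA <- sqrt((atA$x_um - event$x_um)^2 + (atA$y_um - event$y_um)^2)
    out$dnuc_a <- dA[match(out$track_id, atA$track_id)]
    attr(out, "excluded") <- excluded
    attr(out, "event_frame") <- a
    out
}

#' Movement statistics relative to the apoptotic site
#'
#' `Mov_{i,t} = dNuc_{i,a} - dNuc_{i,t}`: zero at the event frame by
#' construction, positive when the nucleus is closer to the apoptotic site
#' than it was at the time of death, negative when farther.
#' `dMov_{i,t} = Mov_{i,t} - Mov_{i,t-1}` is the frame-to-frame change
#' (positive = approaching), undefined (`NA`) at each track's first frame.
#'
#' @param movTable output of [computeDNuc()].
#' @return the table with `mov` and `dmov` columns added.
#' @export
computeMov <- function(movTable) {
    stopifnot(all(c("dnuc", "dnuc_a") %in% names(movTable)))
    out <- movTable[order(movTable$track_id, movTable$frame), , drop = FALSE]
    out$mov <- out$dnuc_a - out$dnuc
    prev <- c(NA, out$mov[-nrow(out)])
    samePrev <- c(FALSE, out$track_id[-nrow(out)] == out$track_id[-1] &
                         diff(out$frame) == 1)
    out$dmov <- ifelse(samePrev, out$mov - prev, NA)
    attr(out, "excluded") <- attr(movTable, "excluded")
    attr(out, "event_frame") <- attr(movTable, "event_frame")
    out
}

#' Distance-ordered kymographs around an apoptotic event
#'
#' Matrices with one row per track (sorted by distance from the dying cell at
#' the event frame, closest first) and one column per frame, for the C/N
#' ratio, `Mov`, and `dMov`. Row order is identical across the three
#' matrices; missing frames are `NA`.
#'
#' @param tracks TrackTable with a `cn_ratio` column.
#' @param event event with `x_um`, `y_um`, `frame`.
#' @return list of matrices `cn`, `mov`, `dmov` with rownames = track ids and
#'   attributes `distances` (um) and `times` (frame index).
#' @export
buildKymograph <- function(tracks, event) {
    mt <- computeMov(computeDNuc(tracks, event))
    if (!nrow(mt)) stop("no tracked cell spans the event frame")
    ord <- mt[!duplicated(mt$track_id), c("track_id", "dnuc_a")]
    ord <- ord[order(ord$dnuc_a), ]
    frames <- seq(min(mt$frame), max(mt$frame))
    shape <- function(col) {
        m <- matrix(NA_real_, nrow(ord), length(frames),
                    dimnames = list(ord$track_id, frames))
        m[cbind(match(mt$track_id, ord$track_id),
                match(mt$frame, frames))] <- mt[[col]]
        m
    }
    out <- list(cn = shape("cn_ratio"), mov = shape("mov"),
                dmov = shape("dmov"))
    for (nm in names(out)) {
        attr(out[[nm]], "distances") <- ord$dnuc_a
        attr(out[[nm]], "times") <- frames
    }
    out
}

#' Estimate wave speed, extent and distance-resolved kinetics
#'
#' Tracks are binned by their distance from the apoptotic site at the event
#' frame. Per bin, a frame is "crossed" when either (a) the bin's mean C/N
#' ratio exceeds its pre-event baseline by `max(k * sd, relFloor *
#' baseline)`, or (b) at least `minActiveCells` individual cells exceed
#' their own baselines by `max(kCell * sd_pooled, relFloor * baseline)`.
#' Criterion (b) matters at the far edge of a wave, where activation
#' persists for less than one frame interval so only a few staggered cells
#' are sampled while active and the bin mean barely moves. The onset is the
#' first crossed post-event frame, the duration the total crossed time and
#' the peak the maximal post-event bin mean.
#' The front speed is the least-squares slope of bin-centre distance on onset
#' time; the wave is taken as the contiguous run of onset bins growing
#' outward from the innermost one (a single-bin gap is tolerated), so an
#' isolated spurious crossing far outside the front does not inflate the
#' estimate; the extent is the largest bin centre of that run; the total
#' duration is the last onset plus that bin's activity duration.
#' `extent / totalDuration` is reported as a secondary speed statistic.
#' Nuclei flagged as border-touching in any frame are excluded (their
#' annulus measurements are truncated by the field of view). If no bin
#' crosses threshold, a "no wave detected" summary is returned (not an
#' error); with fewer than 3 onset bins the regression speed is `NA`.
#'
#' @param tracks TrackTable with `cn_ratio`.
#' @param event event with `x_um`, `y_um`, `frame`.
#' @param frameInterval minutes per frame.
#' @param binWidth distance bin width (um).
#' @param baselineFrames number of pre-event frames used as baseline.
#' @param k baseline threshold multiplier (`baseline + k * sd`).
#' @param relFloor minimal relative threshold elevation above baseline,
#'   guarding against a degenerate zero-variance baseline.
#' @param minCells minimum number of tracks spanning the event frame.
#' @param minCellsPerBin bins with fewer cells are dropped.
#' @param kCell,minActiveCells single-cell criterion: a frame is crossed
#'   when `minActiveCells` cells exceed their own baseline by
#'   `max(kCell * pooled sd, relFloor * baseline)`.
#' @param excludeBorder drop tracks whose nucleus touches the image border
#'   in any frame (requires a logical `border` column).
#' @return a [WaveSummary-class].
#' @export
estimateWave <- function(tracks, event, frameInterval, binWidth = 25,
                         baselineFrames = 6, k = 3, relFloor = 0.01,
                         minCells = 50, minCellsPerBin = 5, kCell = 3,
                         minActiveCells = 2, excludeBorder = TRUE) {
    if (excludeBorder && "border" %in% names(tracks)) {
        bad <- unique(tracks$track_id[!is.na(tracks$border) &
                                      tracks$border])
        tracks <- tracks[!tracks$track_id %in% bad, , drop = FALSE]
    }
    mt <- computeDNuc(tracks, event)
    mt <- mt[!is.na(mt$cn_ratio), , drop = FALSE]
    nCells <- length(unique(mt$track_id))
    if (nCells < minCells)
        stop("only ", nCells, " tracks span the event frame (need >= ",
             minCells, ")")
    a <- event$frame
    mt$bin <- floor(mt$dnuc_a / binWidth)
    frames <- sort(unique(mt$frame))
    noWave <- function() new("WaveSummary", eventId = as.numeric(
        if (!is.null(event$event_id)) event$event_id else NA),
        detected = FALSE, speed = NA_real_,
        speedExtentDuration = NA_real_, extent = NA_real_,
        totalDuration = NA_real_,
        bins = data.frame(bin_center_um = numeric(0), n_cells = integer(0),
                          onset_min = numeric(0), duration_min = numeric(0),
                          peak_cn = numeric(0)),
        nCells = nCells)
    binIds <- sort(unique(mt$bin))
    post <- frames >= a
    baseSel <- frames >= a - baselineFrames & frames < a
    if (!any(baseSel)) return(noWave())
    # globally pooled per-cell baseline noise: a 6-frame per-bin estimate is
    # too unstable for small bins, so the bin-mean sd is floored at
    # sigma_cell_pooled / sqrt(n_bin)
    isBaseAll <- mt$frame %in% frames[baseSel]
    cbAll <- tapply(mt$cn_ratio[isBaseAll], mt$track_id[isBaseAll], mean,
                    na.rm = TRUE)
    sCellGlobal <- sd(mt$cn_ratio[isBaseAll] -
                      cbAll[as.character(mt$track_id[isBaseAll])])
    if (is.na(sCellGlobal)) sCellGlobal <- 0
    stats <- lapply(binIds, function(b) {
        sub <- mt[mt$bin == b, , drop = FALSE]
        nb <- length(unique(sub$track_id))
        if (nb < minCellsPerBin) return(NULL)
        mu <- tapply(sub$cn_ratio, factor(sub$frame, levels = frames), mean,
                     na.rm = TRUE)
        isBase <- sub$frame %in% frames[baseSel]
        bm <- mean(sub$cn_ratio[isBase], na.rm = TRUE)
        bs <- sd(tapply(sub$cn_ratio[isBase], factor(sub$frame[isBase]),
                        mean, na.rm = TRUE))
        if (is.na(bs)) bs <- 0
        bs <- max(bs, sCellGlobal / sqrt(nb))
        thr <- bm + max(k * bs, relFloor * bm)
        # single-cell criterion: cells exceeding their own baseline.
        # Measurement noise is heavy-tailed (mask re-quantisation under
        # positional jitter), so cells already "hot" during the baseline
        # are excluded from the count.
        cellBase <- tapply(sub$cn_ratio[isBase], sub$track_id[isBase],
                           mean, na.rm = TRUE)
        resid <- sub$cn_ratio[isBase] -
            cellBase[as.character(sub$track_id[isBase])]
        sPool <- sd(resid)
        if (is.na(sPool)) sPool <- 0
        cb <- cellBase[as.character(sub$track_id)]
        cellHot <- !is.na(cb) & !is.na(sub$cn_ratio) &
            sub$cn_ratio > cb + pmax(kCell * sPool, relFloor * cb)
        spiky <- unique(sub$track_id[cellHot &
                                     sub$frame %in% frames[baseSel]])
        cellHot <- cellHot & !sub$track_id %in% spiky
        nAct <- tapply(cellHot, factor(sub$frame, levels = frames), sum)
        nAct[is.na(nAct)] <- 0
        # the single-cell criterion is informative only when cell-level
        # noise resolves a relFloor-sized activation; otherwise per-cell
        # baseline estimation error floods the counts
        useCount <- sPool <= relFloor * bm / 2
        list(bin = b, n = nb, mu = mu,
             muAbove = post & !is.na(mu) & mu > thr,
             countAbove = post & useCount & nAct >= minActiveCells)
    })
    stats <- stats[!vapply(stats, is.null, logical(1))]
    if (!length(stats)) return(noWave())
    # outward pass: a wave front reaches outer bins no earlier than inner
    # ones, so crossings before the latest accepted inner onset are
    # discarded
    lastOnset <- a
    res <- lapply(stats, function(s) {
        crossed <- (s$muAbove | s$countAbove) & frames >= lastOnset
        onset <- if (any(crossed)) frames[which(crossed)[1]] else NA
        if (!is.na(onset)) lastOnset <<- max(lastOnset, onset)
        data.frame(
            bin_center_um = (s$bin + 0.5) * binWidth, n_cells = s$n,
            onset_min = if (is.na(onset)) NA_real_ else
                (onset - a) * frameInterval,
            duration_min = sum(crossed) * frameInterval,
            peak_cn = if (any(post & !is.na(s$mu)))
                max(s$mu[post], na.rm = TRUE) else NA_real_)
    })
    bins <- do.call(rbind, res)
    if (is.null(bins) || !any(!is.na(bins$onset_min))) return(noWave())
    # contiguous run of onset bins growing outward from the innermost one;
    # tolerate a single-bin gap (sparse bins), stop at the second
    bins <- bins[order(bins$bin_center_um), , drop = FALSE]
    has <- !is.na(bins$onset_min)
    first <- which(has)[1]
    run <- first
    gaps <- 0
    i <- first + 1
    while (i <= nrow(bins)) {
        if (has[i]) {
            run <- c(run, i)
            gaps <- 0
        } else {
            gaps <- gaps + 1
            if (gaps > 1) break
        }
        i <- i + 1
    }
    det <- bins[run, , drop = FALSE]
    extent <- max(det$bin_center_um)
    lastBin <- det[which.max(det$bin_center_um), ]
    totalDuration <- lastBin$onset_min + lastBin$duration_min
    speed <- if (nrow(det) >= 3 && length(unique(det$onset_min)) >= 2)
        unname(coef(lm(bin_center_um ~ onset_min, data = det))[2])
        else NA_real_
    new("WaveSummary",
        eventId = as.numeric(if (!is.null(event$event_id)) event$event_id
                             else NA),
        detected = TRUE, speed = speed,
        speedExtentDuration = extent / totalDuration,
        extent = extent, totalDuration = totalDuration, bins = bins,
        nCells = nCells)
}

# normalised cross-correlation of two equal-length series at a given lag;
# positive lag: x leads y (x at time t aligns with y at time t + lag)
laggedCor <- function(x, y, lag) {
    n <- length(x)
    if (lag >= 0) {
        xs <- x[seq_len(n - lag)]
        ys <- y[seq_len(n - lag) + lag]
    } else {
        xs <- x[seq_len(n + lag) - lag]
        ys <- y[seq_len(n + lag)]
    }
    if (length(xs) < 3 || sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)
}

#' Lag between ERK activity and cell movement
#'
#' Per cell, the lag maximising the Pearson cross-correlation between the
#' C/N ratio series and the frame-to-frame movement series `dMov` (both
#' mean-centred and variance-normalised); positive lag means ERK activity
#' precedes movement. Ties are broken toward the smaller absolute lag.
#' Zero-variance cells are excluded and counted.
#'
#' @param tracks TrackTable with `cn_ratio`.
#' @param event event with `x_um`, `y_um`, `frame`.
#' @param maxLag maximal lag in frames; series must span at least
#'   `2 * maxLag + 1` frames.
#' @return list: `perCell` (data.frame `track_id`, `lag_frames`,
#'   `peak_cor`), `medianLag` (frames), `signTest` (binomial test of
#'   positive vs negative lags, `NULL` if no nonzero lags), `nExcluded`.
#' @export
crossCorrErkMovement <- function(tracks, event, maxLag = 6) {
    mt <- computeMov(computeDNuc(tracks, event))
    lags <- seq(-maxLag, maxLag)
    lags <- lags[order(abs(lags), lags)]    # ties -> smaller |lag|
    excluded <- 0L
    per <- lapply(split(mt, mt$track_id), function(tr) {
        tr <- tr[order(tr$frame), ]
        ok <- !is.na(tr$cn_ratio) & !is.na(tr$dmov)
        x <- tr$cn_ratio[ok]; y <- tr$dmov[ok]
        if (length(x) < 2 * maxLag + 1 || sd(x) == 0 || sd(y) == 0) {
            excluded <<- excluded + 1L
            return(NULL)
        }
        cc <- vapply(lags, function(l) laggedCor(x, y, l), numeric(1))
        if (all(is.na(cc))) {
            excluded <<- excluded + 1L
            return(NULL)
        }
        best <- which.max(cc)
        data.frame(track_id = tr$track_id[1], lag_frames = lags[best],
                   peak_cor = cc[best])
    })
    per <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
    if (is.null(per) || !nrow(per))
        return(list(perCell = data.frame(), medianLag = NA_real_,
                    signTest = NULL, nExcluded = excluded))
    nz <- per$lag_frames[per$lag_frames != 0]
    st <- if (length(nz)) binom.test(sum(nz > 0), length(nz)) else NULL
    list(perCell = per, medianLag = median(per$lag_frames),
         signTest = st, nExcluded = excluded)
}
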