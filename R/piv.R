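# zero-normalised cross-correlation (ZNCC) of two windows for every
# displacement in [-maxShift, maxShift]^2, computed over the actual overlap
# region of each displacement via zero-padded FFTs. Values lie in [-1, 1].
windowXcorr <- function(a, b, maxShift) {
    w <- nrow(a)
    N <- 2L * w
    pad <- function(x) { p <- matrix(0, N, N); p[1:w, 1:w] <- x; p }
    xc <- function(fx, fy) Re(fft(Conj(fx) * fy, inverse = TRUE)) / (N * N)
    fa <- fft(pad(a)); fa2 <- fft(pad(a * a))
    fb <- fft(pad(b)); fb2 <- fft(pad(b * b))
    fm <- fft(pad(matrix(1, w, w)))
    sh <- seq(-maxShift, maxShift)
    idx <- ((sh %% N) + 1L)
    pick <- function(m) m[idx, idx, drop = FALSE]
    n <- outer(w - abs(sh), w - abs(sh))          # overlap pixel count
    sab <- pick(xc(fa, fb))
    sa <- pick(xc(fa, fm)); sb <- pick(xc(fm, fb))
    saa <- pick(xc(fa2, fm)); sbb <- pick(xc(fm, fb2))
    va <- pmax(saa - sa^2 / n, 0)
    vb <- pmax(sbb - sb^2 / n, 0)
    den <- sqrt(va * vb)
    out <- (sab - sa * sb / n) / pmax(den, 1e-12)
    out[den < 1e-9] <- 0
    pmin(pmax(out, -1), 1)
}

# 3-point sub-pixel refinement (Gaussian when the triplet is positive,
# parabolic otherwise); returns offset in (-0.5, 0.5)
subpixelPeak <- function(cm1, c0, cp1) {
    if (is.na(cm1) || is.na(cp1)) return(0)
    if (cm1 > 0 && c0 > 0 && cp1 > 0) {
        den <- 2 * (log(cm1) + log(cp1) - 2 * log(c0))
        if (den >= 0) return(0)
        return((log(cm1) - log(cp1)) / den)
    }
    den <- 2 * (cm1 + cp1 - 2 * c0)
    if (den >= 0) return(0)
    (cm1 - cp1) / den
}

#' Particle image velocimetry between two frames
#'
#' Single-pass windowed zero-normalised cross-correlation: per interrogation
#' window, the displacement maximising the ZNCC with the next frame (search
#' up to half a window), refined to sub-pixel accuracy by a 3-point Gaussian
#' peak fit and converted to um/min. Flat windows are flagged invalid; a
#' peak correlation below `qualityMin` flags low quality.
#'
#' @param img1,img2 numeric matrices of equal shape.
#' @param windowPx interrogation window edge (px, >= 16).
#' @param overlap fractional window overlap in `[0, 1)`.
#' @param pixelSize um/px.
#' @param frameInterval minutes between the frames.
#' @param qualityMin minimal peak correlation (in `[0, 1]`) of a valid
#'   vector.
#' @return data.frame: `x_um`, `y_um` (window centre), `u_um_min`,
#'   `v_um_min`, `quality` (peak ZNCC), `valid`.
#' @export
pivPair <- function(img1, img2, windowPx = 32, overlap = 0.5,
                    pixelSize = 1, frameInterval = 1, qualityMin = 0.5) {
    stopifnot(identical(dim(img1), dim(img2)), windowPx >= 16)
    w <- as.integer(windowPx)
    maxShift <- w %/% 2L
    step <- max(1L, as.integer(round(w * (1 - overlap))))
    rows <- seq(1L, nrow(img1) - w + 1L, by = step)
    cols <- seq(1L, ncol(img1) - w + 1L, by = step)
    sh <- seq(-maxShift, maxShift)
    n <- length(rows) * length(cols)
    out <- data.frame(x_um = numeric(n), y_um = numeric(n),
                      u_um_min = NA_real_, v_um_min = NA_real_,
                      quality = NA_real_, valid = FALSE)
    k <- 0L
    for (r0 in rows) for (c0 in cols) {
        k <- k + 1L
        out$x_um[k] <- pxToUm(c0 + (w - 1) / 2, pixelSize)
        out$y_um[k] <- pxToUm(r0 + (w - 1) / 2, pixelSize)
        A <- img1[r0:(r0 + w - 1L), c0:(c0 + w - 1L)]
        B <- img2[r0:(r0 + w - 1L), c0:(c0 + w - 1L)]
        sa <- sd(A); sb <- sd(B)
        if (sa < 1e-10 || sb < 1e-10) next
        m <- windowXcorr(A, B, maxShift)
        pk <- which(m == max(m), arr.ind = TRUE)[1, ]
        c0v <- m[pk[1], pk[2]]
        quality <- c0v
        dy <- sh[pk[1]]; dx <- sh[pk[2]]
        ddy <- if (pk[1] > 1 && pk[1] < nrow(m))
            subpixelPeak(m[pk[1] - 1, pk[2]], c0v, m[pk[1] + 1, pk[2]]) else 0
        ddx <- if (pk[2] > 1 && pk[2] < ncol(m))
            subpixelPeak(m[pk[1], pk[2] - 1], c0v, m[pk[1], pk[2] + 1]) else 0
        out$u_um_min[k] <- (dx + ddx) * pixelSize / frameInterval
        out$v_um_min[k] <- (dy + ddy) * pixelSize / frameInterval
        out$quality[k] <- quality
        out$valid[k] <- quality >= qualityMin
    }
    out
}

#' PIV over a whole stack
#'
#' Runs [pivPair()] on consecutive frame pairs of the nuclear channel and
#' either time-averages the valid vectors per window or integrates them into
#' a total displacement.
#'
#' @param stack a [FrameStack-class].
#' @param channel channel name (nuclear marker by default).
#' @param frames frame indices to use (pairs are formed between consecutive
#'   entries); default all.
#' @param mode "average" (mean um/min) or "integrate" (summed displacement,
#'   um).
#' @param ... passed to [pivPair()].
#' @return data.frame: `x_um`, `y_um`, `u_um_min`/`u_um`, `v_um_min`/`v_um`,
#'   `n_valid`.
#' @export
pivStack <- function(stack, channel = "H2B", frames = NULL,
                     mode = c("average", "integrate"), ...) {
    mode <- match.arg(mode)
    stopifnot(is(stack, "FrameStack"))
    if (is.null(frames)) frames <- seq_len(nFrames(stack))
    stopifnot(length(frames) >= 2)
    acc <- NULL
    for (i in seq_len(length(frames) - 1)) {
        fl <- pivPair(getFrame(stack, frames[i], channel),
                      getFrame(stack, frames[i + 1], channel),
                      pixelSize = stack@pixelSize,
                      frameInterval = stack@frameInterval *
                          (frames[i + 1] - frames[i]), ...)
        if (is.null(acc)) {
            acc <- fl[, c("x_um", "y_um")]
            acc$u <- 0; acc$v <- 0; acc$n_valid <- 0L
        }
        ok <- fl$valid & !is.na(fl$u_um_min)
        acc$u[ok] <- acc$u[ok] + fl$u_um_min[ok]
        acc$v[ok] <- acc$v[ok] + fl$v_um_min[ok]
        acc$n_valid <- acc$n_valid + ok
    }
    if (mode == "average") {
        acc$u_um_min <- ifelse(acc$n_valid > 0, acc$u / acc$n_valid, NA)
        acc$v_um_min <- ifelse(acc$n_valid > 0, acc$v / acc$n_valid, NA)
        acc[, c("x_um", "y_um", "u_um_min", "v_um_min", "n_valid")]
    } else {
        dt <- stack@frameInterval
        acc$u_um <- acc$u * dt
        acc$v_um <- acc$v * dt
        acc[, c("x_um", "y_um", "u_um", "v_um", "n_valid")]
    }
}

#' Mean radial inflow toward an apoptotic site
#'
#' Projects each flow vector onto the unit vector pointing from its window
#' centre to the event; positive values mean motion toward the event. The
#' average is taken over valid vectors within `(rMin, rMax]` of the event.
#'
#' @param flow data.frame from [pivPair()] or [pivStack()] (um/min vectors).
#' @param event list with `x_um`, `y_um`.
#' @param rMax,rMin radial range (um) of included windows.
#' @return mean radial inflow (um/min), or `NA` (with a warning) when no
#'   valid vector lies in range.
#' @export
convergenceToward <- function(flow, event, rMax = Inf, rMin = 0) {
    u <- if ("u_um_min" %in% names(flow)) flow$u_um_min else flow$u_um
    v <- if ("v_um_min" %in% names(flow)) flow$v_um_min else flow$v_um
    ok <- !is.na(u) & !is.na(v)
    if ("valid" %in% names(flow)) ok <- ok & flow$valid
    dx <- event$x_um - flow$x_um
    dy <- event$y_um - flow$y_um
    d <- sqrt(dx^2 + dy^2)
    sel <- ok & d > rMin & d <= rMax & d > 0
    if (!any(sel)) {
        warning("no valid flow vector within range of the event")
        return(NA_real_)
    }
    mean((u[sel] * dx[sel] + v[sel] * dy[sel]) / d[sel])
}
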