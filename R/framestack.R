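#' Extract one channel of one frame
#'
#' @param stack a [FrameStack-class].
#' @param frame frame index (1-based).
#' @param channel channel name or index.
#' @return numeric matrix `[row, col]`.
#' @export
getFrame <- function(stack, frame, channel) {
    stopifnot(is(stack, "FrameStack"))
    if (is.character(channel)) {
        ch <- match(channel, stack@channels)
        if (is.na(ch)) stop("unknown channel: ", channel)
    } else ch <- channel
    if (frame < 1 || frame > dim(stack@pixels)[4])
        stop("frame out of range")
    stack@pixels[, , ch, frame]
}

#' @rdname getFrame
#' @export
nFrames <- function(stack) dim(stack@pixels)[4]

#' @rdname getFrame
#' @export
channelNames <- function(stack) stack@channels

#' @rdname getFrame
#' @export
pixelSize <- function(stack) stack@pixelSize

#' @rdname getFrame
#' @export
frameInterval <- function(stack) stack@frameInterval

#' Write / read a FrameStack as multi-plane TIFF with a YAML sidecar
#'
#' Planes are written frame-major (all channels of frame 1, then frame 2,
#' ...) as 32-bit float TIFF. Channel names, pixel size and frame interval go
#' to `<path>.yaml`.
#'
#' @param stack a [FrameStack-class].
#' @param path output TIFF path.
#' @return `writeFrameStack` returns `path` invisibly; `readFrameStack`
#'   returns a [FrameStack-class].
#' @export
writeFrameStack <- function(stack, path) {
    stopifnot(is(stack, "FrameStack"))
    d <- dim(stack@pixels)
    planes <- vector("list", d[3] * d[4])
    k <- 1
    for (f in seq_len(d[4])) for (ch in seq_len(d[3])) {
        planes[[k]] <- stack@pixels[, , ch, f]
        k <- k + 1
    }
    tiff::writeTIFF(planes, path, bits.per.sample = 32L,
                    reduce = FALSE, compression = "none")
    meta <- list(channels = as.list(stack@channels),
                 pixel_size_um = stack@pixelSize,
                 frame_interval_min = stack@frameInterval,
                 n_frames = d[4], height_px = d[1], width_px = d[2])
    yaml::write_yaml(meta, paste0(path, ".yaml"))
    invisible(path)
}

#' @rdname writeFrameStack
#' @export
readFrameStack <- function(path) {
    if (!file.exists(path)) stop("no such stack file: ", path)
    metaPath <- paste0(path, ".yaml")
    if (!file.exists(metaPath)) stop("missing stack metadata: ", metaPath)
    meta <- yaml::read_yaml(metaPath)
    planes <- tiff::readTIFF(path, all = TRUE)
    nch <- length(meta$channels)
    nf <- length(planes) / nch
    if (nf != round(nf)) stop("plane count inconsistent with channel count")
    d1 <- dim(planes[[1]])
    px <- array(0, c(d1[1], d1[2], nch, nf))
    k <- 1
    for (f in seq_len(nf)) for (ch in seq_len(nch)) {
        px[, , ch, f] <- planes[[k]]
        k <- k + 1
    }
    FrameStack(px, unlist(meta$channels), meta$pixel_size_um,
               meta$frame_interval_min)
}

# project-wide pixel <-> um conversions (pixel centres at half-integers)
pxToUm <- function(px, pixelSize) (px - 0.5) * pixelSize
umToPx <- function(um, pixelSize) um / pixelSize + 0.5
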