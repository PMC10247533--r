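#' Calibrated multi-channel voxel stack
#'
#' The universal image carrier: a fractional-intensity volume with physical
#' voxel sizes. Data are stored as a 4D array ordered (channel, z, y, x);
#' z index 1 is the distal-most slice (the embryo is mounted distal side
#' down). Intensities are fractional values in \[0, 1\]; integer bit depths
#' appear only at file I/O.
#'
#' @param data numeric array: 3D (z, y, x) for a single channel or 4D
#'   (channel, z, y, x).
#' @param voxel_size_z,voxel_size_xy voxel sizes in microns (> 0).
#' @param channels optional character vector of channel names.
#' @return an object of class `voxel_stack`.
#' @export
voxel_stack <- function(data, voxel_size_z, voxel_size_xy, channels = NULL) {
    if (length(dim(data)) == 3)
        data <- array(data, c(1L, dim(data)))
    if (length(dim(data)) != 4)
        abort("data must be a 3D (z,y,x) or 4D (channel,z,y,x) array")
    if (!is.numeric(voxel_size_z) || voxel_size_z <= 0 ||
        !is.numeric(voxel_size_xy) || voxel_size_xy <= 0)
        abort("voxel sizes must be positive numbers")
    rng <- range(data, finite = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
        abort("intensities must lie in [0, 1]")
    channels <- channels %||% paste0("ch", seq_len(dim(data)[1]))
    if (length(channels) != dim(data)[1])
        abort("channel names do not match the number of channels")
    structure(list(data = data, voxel_size_z = voxel_size_z,
                   voxel_size_xy = voxel_size_xy, channels = channels),
              class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
    d <- dim(x$data)
    cat(sprintf("<voxel_stack> %d channel(s) [%s], %d x %d x %d (z,y,x), voxels %g x %g x %g um\n",
                d[1], paste(x$channels, collapse = ", "), d[2], d[3], d[4],
                x$voxel_size_z, x$voxel_size_xy, x$voxel_size_xy))
    invisible(x)
}

#' Extract one channel of a voxel stack as a 3D array
#'
#' @param stack a [voxel_stack()].
#' @param channel channel name or index.
#' @return 3D numeric array (z, y, x).
#' @export
stack_channel <- function(stack, channel) {
    if (is.character(channel)) {
        channel <- match(channel, stack$channels)
        if (is.na(channel)) abort("unknown channel name")
    }
    d <- dim(stack$data)
    array(stack$data[channel, , , ], d[2:4])
}

dim_zyx <- function(stack) dim(stack$data)[2:4]

voxel_volume_um3 <- function(stack)
    stack$voxel_size_z * stack$voxel_size_xy^2

#' Write / read a voxel stack as multi-page TIFF
#'
#' Pages are ordered z-major, channel-minor (for z in 1..nz, for channel in
#' 1..nc). Calibration and channel names travel in a JSON sidecar
#' (`<path>.json`) because baseline TIFF has no standard multi-channel
#' voxel-size tags.
#'
#' @param stack a [voxel_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
    d <- dim(stack$data)
    pages <- vector("list", d[1] * d[2])
    p <- 0L
    for (iz in seq_len(d[2])) for (ic in seq_len(d[1])) {
        p <- p + 1L
        pages[[p]] <- matrix(stack$data[ic, iz, , ], d[3], d[4])
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    meta <- list(shape_zyx = d[2:4], n_channels = d[1],
                 channels = stack$channels,
                 voxel_size_z = stack$voxel_size_z,
                 voxel_size_xy = stack$voxel_size_xy)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
    meta_path <- paste0(path, ".json")
    if (!file.exists(meta_path))
        abort("calibration sidecar ", meta_path, " not found")
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    nc <- meta$n_channels
    nz <- meta$shape_zyx[1]
    data <- array(0, c(nc, nz, meta$shape_zyx[2], meta$shape_zyx[3]))
    p <- 0L
    for (iz in seq_len(nz)) for (ic in seq_len(nc)) {
        p <- p + 1L
        data[ic, iz, , ] <- pages[[p]]
    }
    voxel_stack(data, meta$voxel_size_z, meta$voxel_size_xy, meta$channels)
}

#' Time-lapse container
#'
#' A sequence of voxel stacks acquired at a fixed frame interval.
#'
#' @param frames list of [voxel_stack()] objects with identical geometry.
#' @param frame_interval_min acquisition interval in minutes.
#' @return an object of class `timelapse`.
#' @export
timelapse <- function(frames, frame_interval_min = 12) {
    if (length(frames) < 2) abort("a timelapse needs at least 2 frames")
    d0 <- dim(frames[[1]]$data)
    for (f in frames)
        if (!identical(dim(f$data), d0)) abort("frames differ in geometry")
    structure(list(frames = frames, frame_interval_min = frame_interval_min),
              class = "timelapse")
}

#' @export
print.timelapse <- function(x, ...) {
    cat(sprintf("<timelapse> %d frames every %g min\n",
                length(x$frames), x$frame_interval_min))
    print(x$frames[[1]])
    invisible(x)
}
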