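`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)

abort <- function(...) stop(..., call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the previous RNG state,
#' so seeded sub-streams do not disturb the caller's random sequence.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    code
}

## physical z coordinate (um) of voxel centre for 1-based slice index
z_um_of <- function(iz, voxel_size_z) (iz - 1) * voxel_size_z

## shift an array along one axis by `off` voxels, replicating edge values
shift_axis <- function(a, axis, off) {
    d <- dim(a)
    idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
    args <- rep(list(quote(expr = )), length(d))
    args[[axis]] <- idx
    do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

#' Separable Gaussian blur of a 3D volume with anisotropic voxel sizes
#'
#' @param a numeric 3D array ordered (z, y, x).
#' @param sigma_um blur standard deviation in microns (isotropic in physical
#'   space; converted per axis by the voxel sizes).
#' @param voxel_size_z,voxel_size_xy voxel sizes in microns.
#' @return blurred array of the same dimensions. Edges are handled by
#'   replication, so a constant volume is exactly preserved.
#' @export
gaussian_blur_3d <- function(a, sigma_um, voxel_size_z, voxel_size_xy) {
    if (sigma_um < 0) abort("sigma_um must be >= 0")
    if (sigma_um == 0) return(a)
    sig <- c(sigma_um / voxel_size_z, sigma_um / voxel_size_xy,
             sigma_um / voxel_size_xy)
    for (axis in 1:3) {
        s <- sig[axis]
        r <- max(1L, ceiling(3 * s))
        k <- dnorm(seq(-r, r), sd = s)
        k <- k / sum(k)
        out <- array(0, dim(a))
        for (i in seq_along(k))
            out <- out + k[i] * shift_axis(a, axis, i - r - 1L)
        a <- out
    }
    a
}

## 26-connected (or 6-connected) binary dilation by one voxel, in R;
## cheap for the small patches it is used on
dilate1 <- function(mask, connectivity = 26) {
    out <- mask
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        if (connectivity == 6 && abs(dz) + abs(dy) + abs(dx) != 1) next
        out <- out | shift_axis(shift_axis(shift_axis(mask, 1, dz), 2, dy), 3, dx)
    }
    out
}

## wrapper: 3D/2D connected components, array in, integer array out
label_components <- function(mask, connectivity = 6) {
    d <- dim(mask)
    lab <- cpp_label3d(as.logical(mask), as.integer(d), as.integer(connectivity))
    n <- attr(lab, "n_labels")
    lab <- array(lab, d)
    attr(lab, "n_labels") <- n
    lab
}

## fill enclosed holes of a 2D mask: background is 4-connected (so an
## 8-connected foreground web seals its apices), holes are background
## components not reaching the image border
fill_holes2d <- function(mask) {
    bg <- label_components(!mask, connectivity = 6)
    border_labs <- setdiff(unique(c(bg[1, ], bg[nrow(bg), ],
                                    bg[, 1], bg[, ncol(bg)])), 0L)
    hole <- bg > 0 & !matrix(bg %in% border_labs, nrow(bg), ncol(bg))
    mask | hole
}

## hole label image of a 2D mask (enclosed 4-connected background)
holes2d <- function(mask) {
    label_components(fill_holes2d(mask) & !mask, connectivity = 6)
}

## wrapper: squared EDT to nearest FALSE voxel, physical spacings
edt_sq <- function(mask, spacing) {
    d <- dim(mask)
    array(cpp_edt_sq(as.logical(mask), as.integer(d), as.numeric(spacing)), d)
}
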