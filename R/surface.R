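#' Erode a mask by a physical depth in microns
#'
#' Retains exactly the voxels whose Euclidean distance (anisotropy-aware,
#' in microns) to the mask complement exceeds `depth_um`. Voxels beyond the
#' image border are not treated as background, so a mask reaching the border
#' is not eroded from that side.
#'
#' @param mask logical 3D array (z, y, x) (a 2D matrix is also accepted).
#' @param depth_um erosion depth in microns (>= 0).
#' @param voxel_size_z,voxel_size_xy voxel sizes in microns.
#' @param per_slice if TRUE erode each z slice independently in 2D
#'   (the behaviour of slice-wise ROI erosion); default is true 3D.
#' @return logical array of the same shape.
#' @export
erode_physical <- function(mask, depth_um, voxel_size_z, voxel_size_xy,
                           per_slice = FALSE) {
    if (depth_um < 0) abort("depth_um must be >= 0")
    if (depth_um == 0) return(mask)
    d <- dim(mask)
    if (length(d) == 2) {
        dd <- edt_sq(mask, c(voxel_size_xy, voxel_size_xy))
        return(mask & dd > depth_um^2)
    }
    if (per_slice) {
        out <- mask
        for (iz in seq_len(d[1]))
            out[iz, , ] <- erode_physical(matrix(mask[iz, , ], d[2], d[3]),
                                          depth_um, voxel_size_z, voxel_size_xy)
        return(out)
    }
    dd <- edt_sq(mask, c(voxel_size_z, voxel_size_xy, voxel_size_xy))
    mask & dd > depth_um^2
}

#' Per-column surface height map of an interior mask
#'
#' For every (y, x) column, the physical z coordinate (microns, distal slice
#' = 0) of the shallowest interior voxel; NA where the column contains none.
#'
#' @param interior logical 3D array (z, y, x).
#' @param voxel_size_z z step in microns.
#' @return numeric (y, x) matrix of heights in microns.
#' @export
surface_height_map <- function(interior, voxel_size_z) {
    d <- dim(interior)
    first <- apply(interior, c(2, 3), function(col) {
        w <- which(col)
        if (length(w)) w[1] else NA_integer_
    })
    (first - 1) * voxel_size_z
}

#' Split a stack into surface and subsurface signal
#'
#' The interior indicator is Gaussian-blurred (anisotropy-aware, sigma in
#' microns) into a weight field w in \[0, 1\]. In `soft` mode the split
#' conserves signal exactly: surface = I (1 - w), subsurface = I w. In
#' `fiji_subtract` mode the clamped-subtraction arithmetic of 8-bit image
#' calculators is replicated in fractional units: surface = max(0, I - w),
#' subsurface = max(0, I - (1 - w)).
#'
#' @param stack a [voxel_stack()].
#' @param interior logical 3D array (z, y, x), the (eroded) embryo interior.
#' @param sigma_um blur standard deviation in microns (>= 0).
#' @param mode `"soft"` (default) or `"fiji_subtract"`.
#' @return an object of class `surface_split`: list with `surface` and
#'   `subsurface` voxel stacks, the weight field `w`, `mode` and
#'   `blur_sigma_um`.
#' @export
split_surface <- function(stack, interior, sigma_um = 2,
                          mode = c("soft", "fiji_subtract")) {
    mode <- match.arg(mode)
    if (sigma_um < 0) abort("sigma_um must be >= 0")
    d <- dim_zyx(stack)
    if (!identical(dim(interior), d))
        abort("interior mask and stack dimensions differ")
    w <- gaussian_blur_3d(interior * 1, sigma_um,
                          stack$voxel_size_z, stack$voxel_size_xy)
    nc <- dim(stack$data)[1]
    surf <- sub <- stack$data
    for (ic in seq_len(nc)) {
        I <- array(stack$data[ic, , , ], d)
        if (mode == "soft") {
            surf[ic, , , ] <- I * (1 - w)
            sub[ic, , , ] <- I * w
        } else {
            surf[ic, , , ] <- pmax(0, I - w)
            sub[ic, , , ] <- pmax(0, I - (1 - w))
        }
    }
    structure(list(
        surface = voxel_stack(surf, stack$voxel_size_z, stack$voxel_size_xy,
                              stack$channels),
        subsurface = voxel_stack(sub, stack$voxel_size_z, stack$voxel_size_xy,
                                 stack$channels),
        w = w, mode = mode, blur_sigma_um = sigma_um
    ), class = "surface_split")
}

#' @export
print.surface_split <- function(x, ...) {
    cat(sprintf("<surface_split> mode %s, sigma %g um\n", x$mode, x$blur_sigma_um))
    print(x$surface)
    invisible(x)
}

#' Maximum-intensity projection of a split (or raw) stack
#'
#' @param split a `surface_split` (or a [voxel_stack()], projected as-is).
#' @param which `"surface"` or `"subsurface"` (ignored for a raw stack).
#' @param channel channel name or index.
#' @return numeric (y, x) matrix.
#' @export
project_surface <- function(split, which = c("surface", "subsurface"),
                            channel = 1) {
    which <- match.arg(which)
    stk <- if (inherits(split, "voxel_stack")) split else split[[which]]
    a <- stack_channel(stk, channel)
    apply(a, c(2, 3), max)
}

#' Sequential slab projections below a reference surface
#'
#' Partitions depth below the per-column reference surface into consecutive
#' half-open bins \[k slab, (k+1) slab) and returns one maximum-intensity
#' projection per bin (slab index k is 0-based; the k-th list element is
#' slab k-1).
#'
#' @param stack a [voxel_stack()].
#' @param slab_um slab thickness in microns; must divide `total_um`.
#' @param total_um total depth range covered.
#' @param reference numeric (y, x) height map in microns (e.g. from
#'   [surface_height_map()]).
#' @param channel channel name or index.
#' @return list of `total_um / slab_um` numeric (y, x) matrices.
#' @export
slab_projections <- function(stack, slab_um, total_um, reference, channel = 1) {
    if (abs(total_um / slab_um - round(total_um / slab_um)) > 1e-9)
        abort("slab_um must divide total_um")
    nslab <- as.integer(round(total_um / slab_um))
    a <- stack_channel(stack, channel)
    d <- dim(a)
    zc <- z_um_of(seq_len(d[1]), stack$voxel_size_z)
    depth <- array(rep(zc, times = d[2] * d[3]), d) -
        array(rep(reference, each = d[1]), d)
    out <- vector("list", nslab)
    for (k in seq_len(nslab) - 1L) {
        sel <- depth >= k * slab_um & depth < (k + 1) * slab_um
        masked <- array(ifelse(sel, a, -Inf), d)
        pr <- apply(masked, c(2, 3), max)
        pr[!is.finite(pr)] <- 0
        out[[k + 1]] <- pr
    }
    names(out) <- paste0("slab_", seq_len(nslab) - 1L)
    out
}

#' Orthogonal reslice of a stack
#'
#' Produces transverse (slices along y) or sagittal (slices along x) views.
#' The new slice spacing equals the original z step and the in-plane axis
#' that was z is resampled (nearest neighbour) to the original xy pixel
#' size, so output calibration matches the input. On an isotropic stack the
#' operation is a pure axis permutation and applying it twice restores the
#' original volume.
#'
#' @param stack a [voxel_stack()].
#' @param plane `"transverse"` or `"sagittal"`.
#' @return a [voxel_stack()] of the resliced volume.
#' @export
reslice <- function(stack, plane = c("transverse", "sagittal")) {
    plane <- match.arg(plane)
    d <- dim(stack$data)
    nz <- d[2]; ny <- d[3]; nx <- d[4]
    vz <- stack$voxel_size_z; vxy <- stack$voxel_size_xy
    ## new slice axis <- old y (transverse) or old x (sagittal), sampled at vz
    n_old <- if (plane == "transverse") ny else nx
    n_newz <- as.integer(floor((n_old - 1) * vxy / vz + 1e-9)) + 1L
    src_slice <- pmin(round(seq_len(n_newz) - 1) * vz / vxy + 1, n_old)
    ## new row axis <- old z, resampled at vxy
    n_newy <- as.integer(floor((nz - 1) * vz / vxy + 1e-9)) + 1L
    src_z <- pmin(round((seq_len(n_newy) - 1) * vxy / vz) + 1, nz)
    n_newx <- if (plane == "transverse") nx else ny
    out <- array(0, c(d[1], n_newz, n_newy, n_newx))
    for (ic in seq_len(d[1])) {
        a <- array(stack$data[ic, , , ], d[2:4])
        for (s in seq_len(n_newz)) {
            pl <- if (plane == "transverse") a[, src_slice[s], ] else a[, , src_slice[s]]
            out[ic, s, , ] <- pl[src_z, , drop = FALSE]
        }
    }
    voxel_stack(out, vz, vxy, stack$channels)
}
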