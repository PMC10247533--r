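## ---- rosette renderer ------------------------------------------------------

## Renders one rosette into the mutable volume list `vol` (sig channels,
## cell_lab, ground-truth masks). Geometry: cells occupy an oblate spheroid
## (lateral radius lat_r, axial radius ax_r) around the centre; the central
## membrane-rich domain is an apical-marker shell around a cavity (lumen or
## open cup), or a solid focus; the junctional marker forms a central ball
## (early) or an equatorial ring plus radial spokes with a central gap
## (late). Tunnel lumens are capsules along y (the anterior-posterior axis).
render_rosette <- function(vol, p, i, cls, stage, has_lum, is_tube,
                           r_l, r_a, L, cz_um, cy, cx,
                           iz_a, iz_b, lat_r, ax_r, surf_lab) {
    nz <- dim(vol$cell_lab)[1]; ny <- dim(vol$cell_lab)[2]
    nx <- dim(vol$cell_lab)[3]
    vz <- p$voxel_size_z; vxy <- p$voxel_size_xy
    ncell <- p$n_cells_per_rosette
    has_cavity <- has_lum || cls == "partially_emerged"
    r_open <- max(2, if (has_cavity) 0.8 * r_l else 0)

    bz <- ceiling((max(ax_r, r_a) + 2) / vz)
    half_len <- if (is_tube) L / 2 else 0        # tunnels run along y (AP)
    by <- ceiling((lat_r + half_len + 2) / vxy)
    bx <- ceiling((lat_r + 2) / vxy)
    icz <- round(cz_um / vz) + 1L
    icy <- round(cy / vxy) + 1L; icx <- round(cx / vxy) + 1L
    zi <- max(1L, icz - bz):min(nz, icz + bz)
    yi <- max(1L, icy - by):min(ny, icy + by)
    xi <- max(1L, icx - bx):min(nx, icx + bx)
    dz <- (zi - 1) * vz - cz_um
    dy <- (yi - 1) * vxy - cy
    dx <- (xi - 1) * vxy - cx
    nzb <- length(zi); nyb <- length(yi); nxb <- length(xi)
    DZ <- array(rep(dz, times = nyb * nxb), c(nzb, nyb, nxb))
    DY <- array(rep(rep(dy, each = nzb), times = nxb), c(nzb, nyb, nxb))
    DX <- array(rep(dx, each = nzb * nyb), c(nzb, nyb, nxb))

    ## capsule distances (tunnel axis along y)
    day <- if (is_tube) pmax(abs(DY) - L / 2, 0) else DY
    rad3 <- sqrt(DZ^2 + day^2 + DX^2)
    rad_xy <- sqrt(day^2 + DX^2)
    theta <- atan2(DX, DY)
    sector_bnd <- 2 * pi * (seq_len(ncell) - 0.5) / ncell - pi
    dang <- Reduce(pmin, lapply(sector_bnd, function(b) ang_dist(theta, b)))

    cavity <- if (has_cavity) rad3 < r_l else array(FALSE, dim(rad3))
    apical_sh <- if (has_cavity) rad3 >= r_l & rad3 < r_a
                 else if (stage == "late_rosette") rad3 < r_a
                 else array(FALSE, dim(rad3))
    if (cls == "partially_emerged")   # cup: open the shell toward the surface
        apical_sh <- apical_sh & !(DZ < -0.4 * r_a & rad_xy < r_open)

    if (stage == "early_rosette") {
        junc <- rad3 < 1.5
        central <- junc
    } else {
        ring <- abs(DZ) <= 1.2 & rad_xy >= r_a & rad_xy < r_a + 1.2
        spokes <- abs(DZ) <= 1.2 & rad_xy >= r_a & rad_xy <= 0.8 * lat_r &
            dang * pmax(rad_xy, 0.5) < 0.35
        junc <- ring | spokes
        central <- apical_sh
    }

    oblate <- (rad_xy / lat_r)^2 + (DZ / ax_r)^2 <= 1
    wedge <- oblate & rad_xy > r_a & dang * pmax(rad_xy, 0.5) < 0.3
    sector <- pmin(floor((theta + pi) / (2 * pi) * ncell) + 1L, ncell)
    body <- oblate & !apical_sh & !cavity & !junc

    gidx <- function(mask) {
        w <- which(mask, arr.ind = TRUE)
        cbind(zi[w[, 1]], yi[w[, 2]], xi[w[, 3]])
    }
    ix <- gidx(apical_sh)
    vol$sig$apical[ix] <- pmax(vol$sig$apical[ix], .levels$apical)
    vol$apical[ix] <- TRUE
    vol$central[ix] <- TRUE
    ix <- gidx(junc)
    vol$sig$junction[ix] <- pmax(vol$sig$junction[ix], .levels$junction_mesoderm)
    vol$jsub[ix] <- TRUE
    if (stage == "early_rosette") vol$central[ix] <- TRUE
    ix <- gidx(wedge)
    vol$sig$membrane[ix] <- pmax(vol$sig$membrane[ix], .levels$membrane)
    w <- which(body, arr.ind = TRUE)
    vol$cell_lab[cbind(zi[w[, 1]], yi[w[, 2]], xi[w[, 3]])] <-
        10000L + i * 100L + sector[body]

    ## endoderm-contacting: a basally displaced endoderm cell process
    ## reaching from the shell down to the top of the central domain
    if (cls == "endoderm_contacting") {
        ax_pix <- outer(((yi - 1) * vxy - cy)^2, ((xi - 1) * vxy - cx)^2, `+`) <=
            1.2^2
        cen_ax <- (apical_sh | (stage == "early_rosette" & junc)) & rad_xy <= 1.6
        z_top <- if (any(cen_ax)) min(zi[which(cen_ax, arr.ind = TRUE)[, 1]])
                 else icz
        wp <- which(ax_pix, arr.ind = TRUE)
        for (k in seq_len(nrow(wp))) {
            gy <- yi[wp[k, 1]]; gx <- xi[wp[k, 2]]
            z0 <- iz_b[gy, gx] + 1L; z1 <- z_top - 1L
            if (z1 < z0) next
            zr <- z0:z1
            vol$sig$membrane[cbind(zr, gy, gx)] <-
                pmax(vol$sig$membrane[cbind(zr, gy, gx)], .levels$protrusion)
            vol$cell_lab[cbind(zr, gy, gx)] <- surf_lab[gy, gx] %% 1000L
        }
    }

    ## partially emerged: carve the overlying shell open down to the cavity
    hole <- NULL
    if (cls == "partially_emerged") {
        yy <- (seq_len(ny) - 1) * vxy; xx <- (seq_len(nx) - 1) * vxy
        hole <- outer((yy - cy)^2, (xx - cx)^2, `+`) <= r_open^2
        wp <- which(hole, arr.ind = TRUE)
        for (k in seq_len(nrow(wp))) {
            gy <- wp[k, 1]; gx <- wp[k, 2]
            zr <- iz_a[gy, gx]:icz
            idx <- cbind(zr, gy, gx)
            vol$sig$junction[idx] <- 0
            vol$sig$membrane[idx] <- 0
            vol$sig$nuclei[idx] <- 0
            vol$jsurf[idx] <- FALSE
            vol$cell_lab[idx] <- 0L
        }
    }

    ## 2D footprint of the planted junctional/apical structure, hole-filled
    proj <- matrix(FALSE, ny, nx)
    w <- which(junc | apical_sh, arr.ind = TRUE)
    proj[cbind(yi[w[, 2]], xi[w[, 3]])] <- TRUE
    proj <- fill_holes2d(proj)

    list(vol = vol, footprint = proj, lumen_voxels = sum(cavity & has_lum),
         hole = hole)
}

## ---- granules ---------------------------------------------------------------

place_granules <- function(p, rostab, nz, ny, nx, vz, vxy) {
    rows <- list()
    if (!is.null(rostab) && nrow(rostab)) {
        acc <- matrix(NA_real_, 0, 3)
        band <- p$granule_diameter_range
        for (i in seq_len(nrow(rostab))) {
            r_a <- rostab$apical_radius_um[i]
            tube_L <- if (identical(rostab$lumen_shape[i], "tunnel"))
                rostab$lumen_length_um[i] else 0
            sect <- 2 * pi / p$n_cells_per_rosette
            for (m in seq_len(p$n_cells_per_rosette)) {
                k <- rpois(1, p$granules_per_cell)
                for (g in seq_len(k)) {
                    placed <- FALSE
                    for (t in 1:20) {
                        th <- sect * (m - 0.5) - pi + runif(1, -0.3, 0.3) * sect
                        rho <- r_a + 2 + runif(1) * 2.2
                        dzg <- runif(1, -2, 2)
                        zc <- round((rostab$z_um[i] + dzg) / vz) * vz
                        zc <- min(max(zc, vz), (nz - 2) * vz)
                        yc <- rostab$y_um[i] + rho * cos(th)
                        xc <- rostab$x_um[i] + rho * sin(th)
                        if (yc < 2 || xc < 2 || yc > (ny - 5) * vxy ||
                            xc > (nx - 5) * vxy) next
                        ## keep clear of the (possibly tunnel-elongated)
                        ## apical shell: capsule distance, axis along y
                        cd <- sqrt((zc - rostab$z_um[i])^2 +
                                   (xc - rostab$x_um[i])^2 +
                                   max(abs(yc - rostab$y_um[i]) - tube_L / 2,
                                       0)^2)
                        if (cd < r_a + 2) next
                        if (nrow(acc) &&
                            min(sqrt((acc[, 1] - zc)^2 + (acc[, 2] - yc)^2 +
                                     (acc[, 3] - xc)^2)) < 5.5) next
                        placed <- TRUE
                        break
                    }
                    if (!placed) next
                    acc <- rbind(acc, c(zc, yc, xc))
                    rows[[length(rows) + 1]] <- tibble::tibble(
                        z_um = zc, y_um = yc, x_um = xc,
                        diameter_um = runif(1, band[1], band[2]),
                        apkc_positive = runif(1) < p$granule_copositive_fraction,
                        rosette = rostab$id[i])
                }
            }
        }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
        tibble::tibble(z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
                       diameter_um = numeric(0), apkc_positive = logical(0),
                       rosette = integer(0))
    list(table = tab)
}

## add a Gaussian intensity blob (diffraction-blurred granule) to a volume
add_gaussian_blob <- function(arr, row, amp, vz, vxy) {
    nz <- dim(arr)[1]; ny <- dim(arr)[2]; nx <- dim(arr)[3]
    sigma <- row$diameter_um / 2.355          # FWHM = nominal diameter
    ext <- 2.5 * sigma
    zi <- max(1, floor((row$z_um - ext) / vz) + 1):min(nz, ceiling((row$z_um + ext) / vz) + 1)
    yi <- max(1, floor((row$y_um - ext) / vxy) + 1):min(ny, ceiling((row$y_um + ext) / vxy) + 1)
    xi <- max(1, floor((row$x_um - ext) / vxy) + 1):min(nx, ceiling((row$x_um + ext) / vxy) + 1)
    dz <- (zi - 1) * vz - row$z_um
    dy <- (yi - 1) * vxy - row$y_um
    dx <- (xi - 1) * vxy - row$x_um
    r2 <- outer(dz^2, outer(dy^2, dx^2, `+`), `+`)
    blob <- amp * exp(-r2 / (2 * sigma^2))
    arr[zi, yi, xi] <- pmax(arr[zi, yi, xi], blob)
    arr
}

## ---- contour annotation surrogate ------------------------------------------

#' Generate sparse outline contours from ground truth
#'
#' Emulates hand annotation of the embryo exterior: outline polygons of the
#' true interior mask, recorded only on strided slices (a finer stride near
#' the curved surface, a coarser one in deep low-curvature regions) plus
#' the last slice, with optional Gaussian vertex jitter emulating freehand
#' drawing. With zero jitter the dense polygon of each annotated slice
#' rasterizes back to that slice's mask exactly; with jitter the polygons
#' are vertex-subsampled first (hand-drawn outlines are sparse).
#'
#' @param truth an `embryo_truth` object (or any list with
#'   `interior_mask`, `surface_height_map` and `params`).
#' @param stride_near slice stride within the curved-surface zone (>= 1).
#' @param stride_deep slice stride below it (default: `stride_near`).
#' @param jitter_um vertex jitter standard deviation in microns.
#' @param seed RNG seed for the jitter.
#' @return a [contour_set()].
#' @export
generate_contours <- function(truth, stride_near, stride_deep = stride_near,
                              jitter_um = 0, seed = 1L) {
    if (stride_near < 1 || stride_deep < 1) abort("strides must be >= 1")
    p <- truth$params
    nz <- dim(truth$interior_mask)[1]
    vz <- p$voxel_size_z; vxy <- p$voxel_size_xy
    zmax_near <- max(truth$surface_height_map) + vz
    near_last <- min(nz - 1, ceiling(zmax_near / vz))
    ann <- seq(0, near_last, by = stride_near)
    if (max(ann) < nz - 1)
        ann <- c(ann, seq(max(ann) + stride_deep, nz - 1, by = stride_deep))
    ann <- sort(unique(c(ann, nz - 1L)))
    ann <- ann[ann <= nz - 1]

    polys <- local_seed(seed, lapply(ann, function(k) {
        mask <- matrix(truth$interior_mask[k + 1, , ],
                       dim(truth$interior_mask)[2], dim(truth$interior_mask)[3])
        pl <- mask_outline_polygons(mask)
        if (jitter_um > 0) pl <- lapply(pl, function(poly) {
            n <- nrow(poly)
            if (n > 24) poly <- poly[seq(1, n, by = 4), , drop = FALSE]
            ## a freehand outline never crosses itself: redraw the jitter
            ## until the polygon stays simple
            for (t in 1:20) {
                jit <- poly + matrix(rnorm(2 * nrow(poly), sd = jitter_um / vxy),
                                     ncol = 2)
                if (!polygon_self_intersects(jit)) return(jit)
            }
            poly
        })
        pl
    }))
    names(polys) <- as.character(ann)
    contour_set(polys, dim(truth$interior_mask)[2:3])
}

## ---- stage patches -----------------------------------------------------------

#' Render a 2D junctional patch of a given maturation stage
#'
#' Produces the canonical projected appearance of the four junctional
#' categories: a compact punctum (`spot`), a short linear domain (`edge`),
#' uninterrupted central signal at a multi-cell vertex with radial spokes
#' (`early_rosette`), and a discontinuous ring-and-spokes pattern with a
#' central gap (`late_rosette`). Used by the synthetic movies and by
#' staging tests as labelled ground truth.
#'
#' @param stage one of `"spot"`, `"edge"`, `"early_rosette"`, `"late_rosette"`.
#' @param px_size_um pixel size (um).
#' @param n_cells number of converging cells (spokes) for rosette stages.
#' @param size_px odd patch edge length in pixels.
#' @return numeric matrix with attribute `"stage"`.
#' @export
simulate_stage_patch <- function(stage = c("spot", "edge", "early_rosette",
                                           "late_rosette"),
                                 px_size_um = 0.5, n_cells = 6L,
                                 size_px = 31L) {
    stage <- match.arg(stage)
    n <- size_px
    c0 <- (n + 1) / 2
    dy <- ((seq_len(n)) - c0) * px_size_um
    DY <- matrix(rep(dy, times = n), n, n)
    DX <- matrix(rep(dy, each = n), n, n)
    rad <- sqrt(DY^2 + DX^2)
    theta <- atan2(DX, DY)
    amp <- .levels$junction_mesoderm
    patch <- matrix(0, n, n)
    if (stage == "spot") {
        patch[rad < 0.5] <- amp
    } else if (stage == "edge") {
        patch[abs(DY) < 0.35 & abs(DX) < 1.5] <- amp
    } else {
        bnd <- 2 * pi * (seq_len(n_cells) - 0.5) / n_cells - pi
        dang <- Reduce(pmin, lapply(bnd, function(b) ang_dist(theta, b)))
        if (stage == "early_rosette") {
            spokes <- rad >= 1 & rad <= 5 & dang * pmax(rad, 0.5) < 0.35
            patch[rad < 1.8 | spokes] <- amp
        } else {
            ring <- rad >= 2.5 & rad < 3.5
            spokes <- rad >= 2.5 & rad <= 6 & dang * pmax(rad, 0.5) < 0.35
            patch[ring | spokes] <- amp
        }
    }
    attr(patch, "stage") <- stage
    attr(patch, "px_size_um") <- px_size_um
    patch
}
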