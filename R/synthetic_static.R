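## ---- internal helpers -----------------------------------------------------

## rejection-sample n points (um, rows y,x) with pairwise min separation and
## margins inside [m, W-m] x [m, H-m]; optional repulsors (matrix + radius).
## Fails loudly: infeasible placement must never silently truncate.
sample_separated <- function(n, extent_yx, margin, min_sep,
                             repulsors = NULL, repulse_dist = 0,
                             max_tries = 200, what = "structure",
                             radii = NULL, gap = 4, restarts = 25) {
    for (attempt in seq_len(restarts)) {
        pts <- matrix(NA_real_, 0, 2)
        failed <- FALSE
        for (i in seq_len(n)) {
            m_i <- if (is.null(radii)) margin else radii[i] + 3
            ok <- FALSE
            for (t in seq_len(max_tries)) {
                cand <- c(runif(1, m_i, extent_yx[1] - m_i),
                          runif(1, m_i, extent_yx[2] - m_i))
                if (nrow(pts)) {
                    d <- sqrt(rowSums(sweep(pts, 2, cand)^2))
                    need <- if (is.null(radii)) min_sep
                            else radii[seq_len(i - 1)] + radii[i] + gap
                    if (any(d < need)) next
                }
                if (!is.null(repulsors) && nrow(repulsors) &&
                    min(sqrt(rowSums(sweep(repulsors, 2, cand)^2))) <
                        repulse_dist) next
                ok <- TRUE
                break
            }
            if (!ok) {              # dead end; restart the configuration
                failed <- TRUE
                break
            }
            pts <- rbind(pts, cand)
        }
        if (!failed) return(pts)
    }
    abort("placement infeasible: could not place ", n, " ", what,
          "(s) without overlap")
}

## nearest-seed assignment of the pixel grid: returns list(label matrix,
## squared distance to own seed). seeds: matrix (y_um, x_um); ids: integer.
assign_nearest_seed <- function(ny, nx, vxy, seeds, ids) {
    py <- rep((seq_len(ny) - 1) * vxy, times = nx)
    px <- rep((seq_len(nx) - 1) * vxy, each = ny)
    best <- rep(Inf, ny * nx)
    lab <- integer(ny * nx)
    for (s in seq_len(nrow(seeds))) {
        d2 <- (py - seeds[s, 1])^2 + (px - seeds[s, 2])^2
        hit <- d2 < best
        best[hit] <- d2[hit]
        lab[hit] <- ids[s]
    }
    list(labels = matrix(lab, ny, nx), dist2 = matrix(best, ny, nx))
}

## boundary pixels of a label image (4-neighbour label change)
label_boundaries <- function(lab) {
    b <- matrix(FALSE, nrow(lab), ncol(lab))
    b[-1, ] <- b[-1, ] | (lab[-1, ] != lab[-nrow(lab), ])
    b[-nrow(lab), ] <- b[-nrow(lab), ] | (lab[-nrow(lab), ] != lab[-1, ])
    b[, -1] <- b[, -1] | (lab[, -1] != lab[, -ncol(lab)])
    b[, -ncol(lab)] <- b[, -ncol(lab)] | (lab[, -ncol(lab)] != lab[, -1])
    b
}

## wrapped angular distance
ang_dist <- function(a, b) {
    d <- abs(a - b) %% (2 * pi)
    pmin(d, 2 * pi - d)
}

## ---- static stack ---------------------------------------------------------

#' Generate a calibrated synthetic embryo stack with full ground truth
#'
#' Renders a five-channel volume — `membrane` (cell outlines), `junction`
#' (tight-junction marker: dim endoderm lattice, bright axial-mesoderm
#' junctions), `nuclei`, `apical` (apical-kinase marker) and `granule`
#' (apical-protein granules) — over a distally convex spherical-cap surface,
#' and returns the complete ground truth needed to validate every analysis
#' stage. Deterministic given `params$seed` (see [embryo_params()] for the
#' documented RNG sub-streams).
#'
#' @param params an [embryo_params()] object.
#' @return list with elements `stack` (a [voxel_stack()]) and `truth`
#'   (class `embryo_truth`): surface height map, interior/shell masks,
#'   emerged label mask, cluster and rosette tables with label masks,
#'   granule table, 3D cell label volume and channel ground-truth masks.
#' @export
generate_static_stack <- function(params) {
    p <- params
    nz <- p$stack_shape[1]; ny <- p$stack_shape[2]; nx <- p$stack_shape[3]
    vz <- p$voxel_size_z; vxy <- p$voxel_size_xy
    extent <- c((ny - 1) * vxy, (nx - 1) * vxy)
    h <- .cap_height_map(p)

    ## z bookkeeping (1-based indices; voxel centre z = (i-1)*vz)
    iz_a <- ceiling(h / vz - 1e-9) + 1          # first voxel at/below surface
    iz_b <- pmax(iz_a, floor((h + p$shell_thickness - 1e-9) / vz) + 1)
    z_um <- (seq_len(nz) - 1) * vz

    ## --- stream seed+0: surface layout ------------------------------------
    crad <- p$emerged_cluster_diameter / 2
    layout <- local_seed(p$seed, {
        ccent <- sample_separated(p$n_emerged_clusters, extent,
                                  margin = crad + 4,
                                  min_sep = p$emerged_cluster_diameter + 8,
                                  what = "emerged cluster")
        se <- p$endoderm_cell_diameter
        gy <- seq(se / 2, extent[1] - se / 4, by = se)
        gx <- seq(se / 2, extent[2] - se / 4, by = se)
        eseed <- cbind(rep(gy, times = length(gx)), rep(gx, each = length(gy)))
        eseed <- eseed + matrix(runif(length(eseed), -0.3 * se, 0.3 * se),
                                ncol = 2)
        sm <- p$mesoderm_cell_diameter / 2
        mseed <- NULL; mclus <- integer(0)
        for (k in seq_len(p$n_emerged_clusters)) {
            offs <- expand.grid(dy = seq(-crad, crad, by = sm),
                                dx = seq(-crad, crad, by = sm))
            offs <- offs[offs$dy^2 + offs$dx^2 <= crad^2, ]
            pts <- cbind(ccent[k, 1] + offs$dy, ccent[k, 2] + offs$dx) +
                matrix(runif(2 * nrow(offs), -0.25 * sm, 0.25 * sm), ncol = 2)
            mseed <- rbind(mseed, pts)
            mclus <- c(mclus, rep(k, nrow(pts)))
        }
        list(ccent = ccent, eseed = eseed, mseed = mseed, mclus = mclus)
    })
    ## drop endoderm seeds swallowed by clusters
    if (p$n_emerged_clusters > 0) {
        keep <- rep(TRUE, nrow(layout$eseed))
        for (k in seq_len(nrow(layout$ccent)))
            keep <- keep & sqrt((layout$eseed[, 1] - layout$ccent[k, 1])^2 +
                                (layout$eseed[, 2] - layout$ccent[k, 2])^2) > crad
        layout$eseed <- layout$eseed[keep, , drop = FALSE]
    }

    n_endo <- nrow(layout$eseed)
    seeds <- rbind(layout$eseed, layout$mseed)
    ids <- c(seq_len(n_endo), 1000L + seq_len(nrow(layout$mseed)))
    asg <- assign_nearest_seed(ny, nx, vxy, seeds, ids)
    surf_lab <- asg$labels
    meso_pix <- surf_lab >= 1000L
    ## clusters are bounded by their disk: mesoderm ownership beyond the
    ## cluster radius reverts to the surrounding endoderm, so neighbouring
    ## clusters always keep an endoderm corridor between them
    if (p$n_emerged_clusters > 0 && n_endo > 0) {
        py <- matrix(rep((seq_len(ny) - 1) * vxy, times = nx), ny, nx)
        px <- matrix(rep((seq_len(nx) - 1) * vxy, each = ny), ny, nx)
        in_disk <- matrix(FALSE, ny, nx)
        for (k in seq_len(nrow(layout$ccent)))
            in_disk <- in_disk | ((py - layout$ccent[k, 1])^2 +
                                  (px - layout$ccent[k, 2])^2) <= crad^2
        stray <- meso_pix & !in_disk
        if (any(stray)) {
            easg <- assign_nearest_seed(ny, nx, vxy, layout$eseed,
                                        seq_len(n_endo))
            surf_lab[stray] <- easg$labels[stray]
            asg$dist2[stray] <- easg$dist2[stray]
            meso_pix <- surf_lab >= 1000L
        }
    }
    bnd <- label_boundaries(surf_lab)
    ## cluster id per mesoderm pixel
    clus_of_seed <- integer(max(ids))
    clus_of_seed[1000L + seq_along(layout$mclus)] <- layout$mclus
    cluster_mask <- matrix(0L, ny, nx)
    cluster_mask[meso_pix] <- clus_of_seed[surf_lab[meso_pix]]

    ## --- stream seed+2: lumen draws (fixed draw count, replayable) ---------
    ## drawn before placement in code, but on an independent sub-stream, so
    ## tunnel extents can inform rosette spacing
    lum <- local_seed(p$seed + 2L, list(
        present = runif(p$n_rosettes) < p$lumen_probability,
        rfrac = runif(p$n_rosettes),
        tunnel = runif(p$n_rosettes) < p$tunnel_fraction,
        lfrac = runif(p$n_rosettes)))

    ## --- stream seed+1: rosette placement and classes ----------------------
    lat_r <- .rosette_lateral_radius(p)
    ax_r <- .rosette_axial_radius(p)
    tube_halflen <- ifelse(lum$present & lum$tunnel,
                           (p$tunnel_length_range[1] +
                            lum$lfrac * diff(p$tunnel_length_range)) / 2, 0)
    ## spacing is governed by the junctional/apical footprint (ring outer
    ## radius), not the full cell-body radius: rosette cell bodies may
    ## interdigitate, their central domains must stay distinct
    ## apical shell must exceed the z step so lumens stay sealed in 3D
    sh_t <- max(1.5, p$voxel_size_z + 0.25)
    r_l_all <- p$lumen_radius_range[1] + lum$rfrac * diff(p$lumen_radius_range)
    foot_r <- ifelse(lum$present, r_l_all + sh_t + 1.2, 3.7) + tube_halflen
    ros <- local_seed(p$seed + 1L, if (p$n_rosettes == 0) NULL else {
        cls <- sample(names(p$rosette_class_probs), p$n_rosettes,
                      replace = TRUE, prob = p$rosette_class_probs)
        ## rosettes live below the surface: they may share xy with an
        ## emerged cluster (different projection), but their centre axis
        ## keeps clear of cluster footprints so endoderm processes and
        ## carved openings stay in endoderm territory
        cent <- sample_separated(p$n_rosettes, extent,
                                 margin = lat_r + 3,
                                 min_sep = 2 * lat_r + 4,
                                 repulsors = layout$ccent,
                                 repulse_dist = crad + 2,
                                 what = "rosette",
                                 radii = foot_r, gap = 6)
        dfrac <- runif(p$n_rosettes)
        list(cls = cls, cent = cent, dfrac = dfrac)
    })

    ## --- stream seed+3: stages ---------------------------------------------
    stage_u <- local_seed(p$seed + 3L, runif(p$n_rosettes))

    ## --- channel arrays -----------------------------------------------------
    ch <- c("membrane", "junction", "nuclei", "apical", "granule")
    sig <- setNames(lapply(ch, function(...) array(0, c(nz, ny, nx))), ch)
    cell_lab <- array(0L, c(nz, ny, nx))
    junction_surface_mask <- array(FALSE, c(nz, ny, nx))
    junction_subsurface_mask <- array(FALSE, c(nz, ny, nx))
    apical_mask <- array(FALSE, c(nz, ny, nx))
    central_domain_mask <- array(FALSE, c(nz, ny, nx))

    ## --- render surface shell ----------------------------------------------
    interior <- array(FALSE, c(nz, ny, nx))
    for (iz in seq_len(nz))
        interior[iz, , ] <- z_um[iz] >= h - 1e-9
    shell_mask <- array(FALSE, c(nz, ny, nx))
    for (iz in seq_len(nz))
        shell_mask[iz, , ] <- iz >= iz_a & iz <= iz_b

    pix_idx <- function(mask2d, iz2d) {
        ## (z,y,x) index matrix for 2D pixel mask at per-pixel z index
        w <- which(mask2d, arr.ind = TRUE)
        cbind(iz2d[mask2d], w)
    }
    ## apical junction lattice at the surface slice
    endo_bnd <- bnd & !meso_pix
    meso_bnd <- bnd & meso_pix
    ix <- pix_idx(endo_bnd, iz_a)
    sig$junction[ix] <- .levels$junction_endoderm
    junction_surface_mask[ix] <- TRUE
    ix <- pix_idx(meso_bnd, iz_a)
    sig$junction[ix] <- .levels$junction_mesoderm
    junction_surface_mask[ix] <- TRUE
    ## membrane walls through the shell depth; cell labels extruded
    max_sh <- max(iz_b - iz_a)
    for (off in 0:max_sh) {
        sel <- (iz_a + off) <= iz_b
        ix <- pix_idx(bnd & sel, iz_a + off)
        sig$membrane[ix] <- .levels$membrane
        wl <- which(sel, arr.ind = TRUE)
        cell_lab[cbind(iz_a[sel] + off, wl)] <- surf_lab[sel]
    }
    ## nuclei: one blob per cell at mid-shell, radius scaled to cell type
    rnuc <- ifelse(meso_pix, p$mesoderm_cell_diameter * 0.18,
                   p$endoderm_cell_diameter * 0.2)
    nuc_pix <- asg$dist2 <= rnuc^2
    iz_n <- pmin(pmax(round((h + p$shell_thickness / 2) / vz) + 1, iz_a), iz_b)
    ix <- pix_idx(nuc_pix, iz_n)
    sig$nuclei[ix] <- .levels$nuclei

    ## --- rosettes ------------------------------------------------------------
    dep_lo <- max(p$rosette_depth_range[1],
                  p$shell_thickness + p$mesoderm_cell_diameter + 2)
    dep_hi <- max(p$rosette_depth_range[2], dep_lo)
    rostab <- NULL
    footprint_mask <- matrix(0L, ny, nx)
    emerged_label <- matrix(1L, ny, nx)
    emerged_label[meso_pix] <- 2L
    vol <- list(sig = sig, cell_lab = cell_lab,
                jsurf = junction_surface_mask,
                jsub = junction_subsurface_mask,
                apical = apical_mask, central = central_domain_mask)
    if (p$n_rosettes > 0) {
        recs <- vector("list", p$n_rosettes)
        for (i in seq_len(p$n_rosettes)) {
            cls <- ros$cls[i]
            has_lum <- lum$present[i] && cls != "partially_emerged"
            r_l <- p$lumen_radius_range[1] +
                lum$rfrac[i] * diff(p$lumen_radius_range)
            is_tube <- has_lum && lum$tunnel[i]
            L <- p$tunnel_length_range[1] +
                lum$lfrac[i] * diff(p$tunnel_length_range)
            if (!is_tube) L <- 0
            r_a <- if (has_lum || cls == "partially_emerged") r_l + sh_t else 2.5
            stage <- if (has_lum || cls == "partially_emerged") "late_rosette"
                     else if (stage_u[i] < 0.5) "early_rosette" else "late_rosette"
            cy <- ros$cent[i, 1]; cx <- ros$cent[i, 2]
            iy <- round(cy / vxy) + 1L; ixx <- round(cx / vxy) + 1L
            h0 <- h[iy, ixx]
            depth <- if (cls == "partially_emerged")
                p$shell_thickness + r_a else dep_lo + ros$dfrac[i] * (dep_hi - dep_lo)
            icz <- round((h0 + depth) / vz) + 1L
            icz <- min(max(icz, 2L), nz - 1L)
            cz_um <- (icz - 1) * vz
            res <- render_rosette(vol, p, i, cls, stage, has_lum, is_tube,
                                  r_l, r_a, L, cz_um, cy, cx,
                                  iz_a, iz_b, lat_r, ax_r, surf_lab)
            vol <- res$vol
            footprint_mask[res$footprint] <- i
            if (!is.null(res$hole)) {
                emerged_label[res$hole] <- 0L
                for (iz in seq_len(nz)) {
                    sel <- res$hole & iz >= iz_a & iz <= iz_b
                    shell_mask[iz, , ][sel] <- FALSE
                }
            }
            vol_analytic <- if (!has_lum) 0 else if (is_tube)
                pi * r_l^2 * L + 4 / 3 * pi * r_l^3 else 4 / 3 * pi * r_l^3
            recs[[i]] <- tibble::tibble(
                id = i, z_um = cz_um, y_um = cy, x_um = cx, depth_um = depth,
                location_class = cls, stage = stage, has_lumen = has_lum,
                lumen_shape = if (!has_lum) NA_character_
                              else if (is_tube) "tunnel" else "sphere",
                lumen_radius_um = if (has_lum) r_l else NA_real_,
                lumen_length_um = if (is_tube) L else NA_real_,
                apical_radius_um = r_a,
                lumen_volume_um3 = vol_analytic,
                lumen_voxels = res$lumen_voxels,
                n_cells = p$n_cells_per_rosette,
                footprint_area_um2 = sum(res$footprint) * vxy^2)
        }
        rostab <- do.call(rbind, recs)
    }
    sig <- vol$sig; cell_lab <- vol$cell_lab
    junction_surface_mask <- vol$jsurf
    junction_subsurface_mask <- vol$jsub
    apical_mask <- vol$apical; central_domain_mask <- vol$central
    endoderm_mask <- cell_lab > 0L & cell_lab < 1000L

    ## --- stream seed+4: granules -------------------------------------------
    gran <- local_seed(p$seed + 4L, {
        place_granules(p, rostab, nz, ny, nx, vz, vxy)
    })
    if (nrow(gran$table)) {
        for (g in seq_len(nrow(gran$table))) {
            sig$granule <- add_gaussian_blob(sig$granule, gran$table[g, ],
                                             .levels$granule, vz, vxy)
            if (gran$table$apkc_positive[g])
                sig$apical <- add_gaussian_blob(sig$apical, gran$table[g, ],
                                                .levels$apical, vz, vxy)
        }
    }

    ## --- stream seed+5: noise ------------------------------------------------
    nvox <- nz * ny * nx
    data <- array(0, c(length(ch), nz, ny, nx))
    local_seed(p$seed + 5L, {
        for (ic in seq_along(ch)) {
            S <- sig[[ch[ic]]]
            I <- p$background_level + S
            if (p$noise_sd > 0)
                I <- I + rnorm(nvox) * p$noise_sd +
                    rnorm(nvox) * p$noise_sd * sqrt(S)
            data[ic, , , ] <- clamp01(I)
        }
    })

    clusters <- NULL
    if (p$n_emerged_clusters > 0) {
        area <- tabulate(cluster_mask[cluster_mask > 0],
                         nbins = p$n_emerged_clusters) * vxy^2
        ncell <- sapply(seq_len(p$n_emerged_clusters), function(k)
            length(unique(surf_lab[cluster_mask == k])))
        clusters <- tibble::tibble(id = seq_len(p$n_emerged_clusters),
                                   area_um2 = area, n_cells = ncell,
                                   center_y_um = layout$ccent[, 1],
                                   center_x_um = layout$ccent[, 2])
    }

    truth <- structure(list(
        params = p,
        surface_height_map = h,
        interior_mask = interior,
        shell_mask = shell_mask,
        emerged_label_mask = emerged_label,
        cluster_label_mask = cluster_mask,
        clusters = clusters,
        rosettes = rostab,
        rosette_footprint_mask = footprint_mask,
        granules = gran$table,
        cell_label_volume = cell_lab,
        endoderm_mask = endoderm_mask,
        junction_surface_mask = junction_surface_mask,
        junction_subsurface_mask = junction_subsurface_mask,
        apical_mask = apical_mask,
        central_domain_mask = central_domain_mask
    ), class = "embryo_truth")

    list(stack = voxel_stack(data, vz, vxy, ch), truth = truth)
}

#' Write ground truth as a JSON document
#'
#' Serializes the scalar ground truth of a synthetic stack (parameters and
#' the cluster / rosette / granule tables) to one JSON file. Label volumes
#' and masks are arrays, not scalars: write them separately with
#' [write_stack_tiff()] if needed.
#'
#' @param truth an `embryo_truth` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
    obj <- list(params = unclass(truth$params),
                clusters = truth$clusters,
                rosettes = truth$rosettes,
                granules = truth$granules)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(path)
}

#' @export
print.embryo_truth <- function(x, ...) {
    cat(sprintf("<embryo_truth> %d emerged cluster(s), %d rosette(s), %d granule(s)\n",
                if (is.null(x$clusters)) 0L else nrow(x$clusters),
                if (is.null(x$rosettes)) 0L else nrow(x$rosettes),
                nrow(x$granules)))
    invisible(x)
}
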