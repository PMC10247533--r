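## ---- location ----------------------------------------------------------------

#' Classify a rosette's position relative to the embryo surface
#'
#' Exactly one class is returned, evaluated in precedence order
#' `partially_emerged` (the central domain is open to the external embryo
#' surface through traversable dark space, evaluated within a local
#' cylinder so distant surface gaps do not count), then
#' `endoderm_contacting` (any central-domain voxel is 26-adjacent to the
#' endoderm mask — "visibly contacted" operationalized as voxel adjacency),
#' then `basal`. The precedence mirrors the closest-to-surface rule for
#' composite morphologies.
#'
#' @param center_um rosette centre c(z, y, x) in microns.
#' @param central_mask logical 3D array: the central membrane-rich
#'   (apical/junctional) domain.
#' @param height_map numeric (y, x) surface height map in microns.
#' @param endoderm_mask logical 3D array of endoderm-occupied voxels
#'   (used for the contact test).
#' @param open_mask logical 3D array of traversable (signal-free) voxels.
#' @param voxel_size_z,voxel_size_xy voxel sizes in microns.
#' @param cell_diameter_um one axial mesoderm cell diameter: the distance
#'   rule for basal rosettes (unstated in real data; a parameter here).
#' @param patch_radius_um radius of the local cylinder used for the
#'   openness test.
#' @param tissue_mask logical 3D array of cell-occupied voxels blocking
#'   passage in the openness test; defaults to `endoderm_mask`.
#' @return one of `"partially_emerged"`, `"endoderm_contacting"`, `"basal"`.
#' @export
classify_rosette_location <- function(center_um, central_mask, height_map,
                                      endoderm_mask, open_mask,
                                      voxel_size_z, voxel_size_xy,
                                      cell_diameter_um = 10,
                                      patch_radius_um = 10,
                                      tissue_mask = endoderm_mask) {
    d <- dim(central_mask)
    icz <- round(center_um[1] / voxel_size_z) + 1
    icy <- round(center_um[2] / voxel_size_xy) + 1
    icx <- round(center_um[3] / voxel_size_xy) + 1
    if (icz < 1 || icz > d[1] || icy < 1 || icy > d[2] || icx < 1 || icx > d[3])
        abort("rosette center lies outside the stack")

    ## local cylinder (full z) around the centre axis
    bxy <- ceiling(patch_radius_um / voxel_size_xy)
    yi <- max(1, icy - bxy):min(d[2], icy + bxy)
    xi <- max(1, icx - bxy):min(d[3], icx + bxy)
    sub <- function(a) a[, yi, xi, drop = FALSE]
    cen <- sub(central_mask)
    endo <- sub(endoderm_mask)
    open <- sub(open_mask)
    tissue <- sub(tissue_mask)

    ## exterior: voxels above the local surface
    hm <- height_map[yi, xi, drop = FALSE]
    zc <- (seq_len(d[1]) - 1) * voxel_size_z
    ext <- array(rep(zc, times = length(yi) * length(xi)),
                 c(d[1], length(yi), length(xi))) <
        array(rep(hm, each = d[1]), c(d[1], length(yi), length(xi)))

    ## restrict the openness test to a true cylinder about the centre axis
    ryx <- sqrt(outer(((yi - 1) * voxel_size_xy - center_um[2])^2,
                      ((xi - 1) * voxel_size_xy - center_um[3])^2, `+`))
    cyl <- array(rep(ryx <= patch_radius_um, each = d[1]),
                 c(d[1], length(yi), length(xi)))
    traverse <- (open | ext) & !tissue & !cen & cyl
    lab <- label_components(traverse, connectivity = 6)
    ext_labs <- unique(lab[ext & lab > 0])
    touch <- dilate1(cen, 6) & !cen
    touch_labs <- unique(lab[touch & lab > 0])
    if (length(intersect(ext_labs, touch_labs)) > 0)
        return("partially_emerged")
    if (any(dilate1(cen, 26) & endo))
        return("endoderm_contacting")
    "basal"
}

## ---- lumen ---------------------------------------------------------------------

#' Detect and measure a rosette lumen
#'
#' A lumen is a low-intensity connected component enclosed by
#' apical-marker signal: dark voxels (below `dark_threshold`) that do not
#' touch the patch border (enclosure in 3D; components reaching the border
#' are treated as background-connected), are adjacent to bright apical
#' signal, and meet the minimum volume. In `"2d"` mode enclosure is
#' instead required in at least one transverse xz plane. Volume is voxel
#' count times voxel volume; the transverse area is the largest xz
#' cross-section; the lumen is flagged elongated when the ratio of longest
#' to shortest principal extents exceeds 2.
#'
#' @param patch 3D numeric array (z, y, x): apical-marker intensities
#'   around the rosette.
#' @param center_um rosette centre c(z, y, x) in microns, in patch
#'   coordinates (voxel (1,1,1) centre = 0).
#' @param voxel_size_z,voxel_size_xy voxel sizes in microns.
#' @param min_lumen_um3 minimum lumen volume.
#' @param dark_threshold "clear negative space" criterion (absolute
#'   intensity, typically background + 2 sd of noise).
#' @param apical_threshold intensity above which a voxel counts as apical
#'   signal.
#' @param mode `"3d"` (default) or `"2d"` enclosure.
#' @return list: `has_lumen`, `lumen_mask` (3D logical),
#'   `lumen_area_um2`, `lumen_volume_um3`, `elongated`.
#' @export
analyze_lumen <- function(patch, center_um, voxel_size_z, voxel_size_xy,
                          min_lumen_um3 = 5, dark_threshold = 0.1,
                          apical_threshold = 0.5, mode = c("3d", "2d")) {
    mode <- match.arg(mode)
    d <- dim(patch)
    icz <- round(center_um[1] / voxel_size_z) + 1
    icy <- round(center_um[2] / voxel_size_xy) + 1
    icx <- round(center_um[3] / voxel_size_xy) + 1
    if (icz < 1 || icz > d[1] || icy < 1 || icy > d[2] || icx < 1 || icx > d[3])
        abort("center lies outside the patch")
    none <- list(has_lumen = FALSE, lumen_mask = array(FALSE, d),
                 lumen_area_um2 = 0, lumen_volume_um3 = 0, elongated = FALSE)

    dark <- patch < dark_threshold
    bright <- patch > apical_threshold
    lab <- label_components(dark, connectivity = 6)
    n <- attr(lab, "n_labels")
    if (n == 0) return(none)
    border <- array(FALSE, d)
    border[c(1, d[1]), , ] <- TRUE
    border[, c(1, d[2]), ] <- TRUE
    border[, , c(1, d[3])] <- TRUE
    border_labs <- unique(lab[border & lab > 0])
    vv <- voxel_size_z * voxel_size_xy^2

    best <- NULL; best_d2 <- Inf
    for (k in setdiff(seq_len(n), border_labs)) {
        comp <- lab == k
        if (sum(comp) * vv < min_lumen_um3) next
        if (!any(dilate1(comp, 6) & bright)) next
        if (mode == "2d") {
            ## require enclosure within at least one transverse plane
            ok <- FALSE
            for (iy in unique(which(comp, arr.ind = TRUE)[, 2])) {
                pl <- comp[, iy, ]
                if (!any(pl[c(1, d[1]), ]) && !any(pl[, c(1, d[3])])) {
                    ok <- TRUE
                    break
                }
            }
            if (!ok) next
        }
        w <- which(comp, arr.ind = TRUE)
        cz <- mean((w[, 1] - 1) * voxel_size_z)
        cy <- mean((w[, 2] - 1) * voxel_size_xy)
        cx <- mean((w[, 3] - 1) * voxel_size_xy)
        d2 <- (cz - center_um[1])^2 + (cy - center_um[2])^2 +
            (cx - center_um[3])^2
        if (d2 < best_d2) {
            best <- comp
            best_d2 <- d2
        }
    }
    if (is.null(best)) return(none)

    w <- which(best, arr.ind = TRUE)
    vol <- nrow(w) * vv
    per_y <- tabulate(w[, 2], nbins = d[2])
    area <- max(per_y) * voxel_size_z * voxel_size_xy
    pts <- cbind((w[, 1] - 1) * voxel_size_z, (w[, 2] - 1) * voxel_size_xy,
                 (w[, 3] - 1) * voxel_size_xy)
    ext <- if (nrow(pts) > 3) {
        ev <- eigen(stats::cov(pts), symmetric = TRUE)$vectors
        pr <- pts %*% ev
        apply(pr, 2, function(v) diff(range(v))) +
            c(voxel_size_z, voxel_size_xy, voxel_size_xy)
    } else rep(1, 3)
    elong <- max(ext) / max(min(ext), 1e-9) > 2
    list(has_lumen = TRUE, lumen_mask = best, lumen_area_um2 = area,
         lumen_volume_um3 = vol, elongated = elong)
}

## ---- staging ------------------------------------------------------------------

## maximum pairwise (Feret) diameter of a pixel set, in microns
feret_um <- function(w, px) {
    if (nrow(w) < 2) return(px)
    pts <- w * px
    d <- 0
    for (i in seq_len(nrow(pts) - 1))
        d <- max(d, sqrt((pts[i, 1] - pts[-(1:i), 1])^2 +
                         (pts[i, 2] - pts[-(1:i), 2])^2))
    d + px
}

#' Stage a junctional region: spot, edge, early or late rosette
#'
#' Spots are compact puncta below `spot_max_feret_um`; edges are linear
#' segments not at a multi-cell vertex; early rosettes show uninterrupted
#' central signal at a vertex of five or more cells; late rosettes show a
#' fragmented or holed (webbed / latticed / reticular) central pattern
#' with at least one enclosed gap above `hole_min_um2`.
#'
#' @param patch 2D numeric junctional patch centred on the region.
#' @param cell_vertex_count number of cells converging on the centre
#'   (supplied from cell outlines or annotation, as counted manually in
#'   practice).
#' @param px_size_um pixel size (um).
#' @param threshold binarization threshold.
#' @param spot_max_feret_um,hole_min_um2 geometric thresholds
#'   (operationalizations; configurable).
#' @param center_rc c(row, col) of the region centre within the patch;
#'   defaults to the patch centre.
#' @return one of `"spot"`, `"edge"`, `"early_rosette"`, `"late_rosette"`.
#' @export
stage_junctional_region <- function(patch, cell_vertex_count, px_size_um,
                                    threshold = 0.5, spot_max_feret_um = 1.5,
                                    hole_min_um2 = 2, center_rc = NULL) {
    bw <- patch > threshold
    if (!any(bw)) abort("empty junctional patch")
    lab <- label_components(bw, connectivity = 26)
    ## central component: nearest to the (given or patch) centre
    center_rc <- center_rc %||% c((nrow(bw) + 1) / 2, (ncol(bw) + 1) / 2)
    cy <- center_rc[1]; cx <- center_rc[2]
    w <- which(bw, arr.ind = TRUE)
    cen_lab <- lab[w[which.min((w[, 1] - cy)^2 + (w[, 2] - cx)^2), , drop = FALSE]]
    comp <- lab == cen_lab
    hl <- holes2d(comp)
    n_holes <- 0L
    if (attr(hl, "n_labels") > 0)
        n_holes <- sum(tabulate(hl[hl > 0]) * px_size_um^2 >= hole_min_um2)
    if (n_holes >= 1) return("late_rosette")
    if (cell_vertex_count >= 5) return("early_rosette")
    fer <- feret_um(which(comp, arr.ind = TRUE), px_size_um)
    if (fer < spot_max_feret_um) "spot" else "edge"
}

## ---- granules ------------------------------------------------------------------

## in-plane (xy only) Gaussian smoothing of a (z, y, x) volume; granules
## span a single optical section at 2 um z steps, so axial smoothing would
## only dilute them
.blur_xy <- function(a, sigma_px) {
    for (axis in 2:3) {
        r <- max(1L, ceiling(3 * sigma_px))
        k <- dnorm(seq(-r, r), sd = sigma_px)
        k <- k / sum(k)
        out <- array(0, dim(a))
        for (i in seq_along(k))
            out <- out + k[i] * shift_axis(a, axis, i - r - 1L)
        a <- out
    }
    a
}

#' Detect cytoplasmic granules in a marker channel
#'
#' Matched-filter blob detection restricted to a physical diameter band.
#' The channel is smoothed in-plane with a Gaussian of `smooth_sigma_um`
#' (comparable to the smallest granule radius), and thresholded at
#' `k_sigma` robust standard deviations (MAD) above the median — a
#' scale-free criterion that adapts to the noise level. Components of at
#' least `min_voxels` voxels are sized from their largest in-plane
#' thresholded area, inverting the Gaussian-blob threshold radius
#' analytically: `r_thr^2 = (s_b^2 + s_f^2) 2 ln(amp / thr)` with the
#' filter width `s_f` removed in quadrature. Axial extent is not used for
#' sizing (1-2 um granules span a single 2-um optical section); the band
#' is applied with `band_slack_um` slack for pixel rasterization. Per
#' extra channel, a co-positivity flag marks blobs whose mean raw
#' co-channel intensity exceeds the local background by `cofactor`.
#'
#' @param channel 3D numeric array (z, y, x).
#' @param voxel_size_z,voxel_size_xy voxel sizes (um).
#' @param diameter_band_um c(lo, hi) accepted granule diameters.
#' @param smooth_sigma_um matched-filter width (um).
#' @param k_sigma detection threshold in robust sd units.
#' @param cofluor named list of co-stained 3D channels.
#' @param cofactor enrichment factor for co-positivity.
#' @param background background level used for the co-positivity call.
#' @param min_voxels minimum component size.
#' @param band_slack_um slack on the diameter band.
#' @return tibble: centre (z,y,x um, intensity-weighted, subpixel),
#'   `diameter_um`, `n_voxels`, and one `<name>_positive` column per
#'   co-channel.
#' @export
detect_granules <- function(channel, voxel_size_z, voxel_size_xy,
                            diameter_band_um = c(1, 2),
                            smooth_sigma_um = 0.5, k_sigma = 8,
                            cofluor = list(), cofactor = 2,
                            background = 0.05,
                            min_voxels = 3, band_slack_um = 0.3) {
    sf_px <- smooth_sigma_um / voxel_size_xy
    sm <- .blur_xy(channel, sf_px)
    med <- median(sm)
    thr <- med + k_sigma * max(stats::mad(sm), 1e-4)
    bw <- sm > thr
    lab <- label_components(bw, connectivity = 26)
    n <- attr(lab, "n_labels")
    rows <- list()
    for (k in seq_len(n)) {
        comp <- lab == k
        nv <- sum(comp)
        if (nv < min_voxels) next
        w <- which(comp, arr.ind = TRUE)
        amp <- max(sm[comp]) - med
        ## largest single-plane thresholded area -> blob sigma
        best_a <- max(tabulate(w[, 1]))
        r_thr_px <- sqrt(best_a / pi)
        ratio <- max(amp / (thr - med), 1.05)
        s_tot2 <- r_thr_px^2 / (2 * log(ratio))
        s_b2 <- max(s_tot2 - sf_px^2, 0.01)
        d_est <- 2.355 * sqrt(s_b2) * voxel_size_xy
        if (d_est < diameter_band_um[1] - band_slack_um ||
            d_est > diameter_band_um[2] + band_slack_um) next
        wt <- sm[comp] - med
        cz <- sum((w[, 1] - 1) * voxel_size_z * wt) / sum(wt)
        cyy <- sum((w[, 2] - 1) * voxel_size_xy * wt) / sum(wt)
        cxx <- sum((w[, 3] - 1) * voxel_size_xy * wt) / sum(wt)
        row <- tibble::tibble(z_um = cz, y_um = cyy, x_um = cxx,
                              diameter_um = d_est, n_voxels = nv)
        ## co-positivity over the blob core only, so bright neighbouring
        ## structures at the component fringe cannot contaminate the call
        core <- comp & sm >= med + 0.6 * amp
        for (nm in names(cofluor)) {
            co <- cofluor[[nm]]
            row[[paste0(nm, "_positive")]] <-
                mean(co[core]) > cofactor * background
        }
        rows[[length(rows) + 1]] <- row
    }
    if (length(rows)) do.call(rbind, rows) else {
        out <- tibble::tibble(z_um = numeric(0), y_um = numeric(0),
                              x_um = numeric(0), diameter_um = numeric(0),
                              n_voxels = integer(0))
        for (nm in names(cofluor)) out[[paste0(nm, "_positive")]] <- logical(0)
        out
    }
}

## ---- marker distribution -------------------------------------------------------

#' Classify the distribution of an apical marker in a region
#'
#' Vocabulary: `none` (no signal above background), `granular` (granules
#' only), `apical` (apical-membrane enrichment only), `transitional`
#' (granules plus membrane enrichment), and `junctional` (reserved for
#' markers that colocalize with the junctional signal rather than the
#' apical membrane).
#'
#' @param marker 3D numeric marker channel (region patch).
#' @param n_granules number of granules detected in the region.
#' @param membrane_mask logical 3D mask of the apical membrane.
#' @param junction_mask logical 3D mask of junctional signal.
#' @param background background level.
#' @param enrich_factor mean-intensity enrichment factor over background
#'   that counts as localization.
#' @return one of `"none"`, `"granular"`, `"apical"`, `"transitional"`,
#'   `"junctional"`.
#' @export
classify_marker_distribution <- function(marker, n_granules, membrane_mask,
                                         junction_mask, background = 0.05,
                                         enrich_factor = 2) {
    thr <- enrich_factor * background
    memb <- any(membrane_mask) && mean(marker[membrane_mask]) > thr
    junc <- any(junction_mask) && mean(marker[junction_mask]) > thr
    gran <- n_granules > 0
    if (!memb && !junc && !gran) return("none")
    if (gran && memb) return("transitional")
    if (gran) return("granular")
    if (memb) return("apical")
    "junctional"
}

## ---- whole-stack wrapper ---------------------------------------------------------

#' Analyze all rosettes of a stack at given centres
#'
#' Rosette centres are inputs (annotation or ground truth), mirroring
#' manual identification by junctional/actin enrichment. Central-domain,
#' endoderm and traversable-space masks are derived from the image
#' channels by thresholding unless supplied.
#'
#' @param stack a [voxel_stack()] with `junction` and `apical` channels.
#' @param centers matrix/data.frame of centres (columns z_um, y_um, x_um).
#' @param height_map surface height map (um).
#' @param endoderm_mask logical 3D endoderm occupancy.
#' @param vertex_counts per-rosette converging-cell counts (for staging).
#' @param cell_diameter_um basal-rule distance.
#' @param patch_radius_um analysis patch radius.
#' @param lumen_patch_y_um patch half-extent along y for lumen analysis
#'   (tunnel lumens are elongated along the anterior-posterior axis).
#' @param background,noise_sd intensity model for the dark / detection
#'   thresholds.
#' @param tissue_mask optional cell-occupancy mask blocking passage in the
#'   surface-openness test (defaults to `endoderm_mask`).
#' @return tibble of rosette records: location class, stage, lumen
#'   presence/area/volume and elongation.
#' @export
analyze_rosettes <- function(stack, centers, height_map, endoderm_mask,
                             vertex_counts, cell_diameter_um = 10,
                             patch_radius_um = 10, lumen_patch_y_um = 22,
                             background = 0.05, noise_sd = 0.02,
                             tissue_mask = endoderm_mask) {
    centers <- as.data.frame(centers)
    junc <- stack_channel(stack, "junction")
    apic <- stack_channel(stack, "apical")
    memb <- stack_channel(stack, "membrane")
    vz <- stack$voxel_size_z; vxy <- stack$voxel_size_xy
    d <- dim(junc)
    bright <- junc > .junction_threshold_default | apic > 0.5
    structural <- bright | memb > 0.3
    open_mask <- !structural
    dark_thr <- background + max(2 * noise_sd, 0.02)

    rows <- list()
    for (i in seq_len(nrow(centers))) {
        cz <- centers$z_um[i]; cy <- centers$y_um[i]; cx <- centers$x_um[i]
        ## central domain: bright component containing / nearest the centre,
        ## within the local patch
        icz <- round(cz / vz) + 1; icy <- round(cy / vxy) + 1
        icx <- round(cx / vxy) + 1
        bz <- ceiling(patch_radius_um / vz); bxy <- ceiling(patch_radius_um / vxy)
        zi <- max(1, icz - bz):min(d[1], icz + bz)
        yi <- max(1, icy - bxy):min(d[2], icy + bxy)
        xi <- max(1, icx - bxy):min(d[3], icx + bxy)
        cen_patch <- array(FALSE, d)
        sub_bright <- bright[zi, yi, xi, drop = FALSE]
        lab <- label_components(sub_bright, connectivity = 26)
        if (attr(lab, "n_labels") > 0) {
            w <- which(sub_bright, arr.ind = TRUE)
            pz <- (zi[w[, 1]] - 1) * vz; py <- (yi[w[, 2]] - 1) * vxy
            px <- (xi[w[, 3]] - 1) * vxy
            sel <- lab == lab[w[which.min((pz - cz)^2 + (py - cy)^2 +
                                          (px - cx)^2), , drop = FALSE]]
            wc <- which(sel, arr.ind = TRUE)
            cen_patch[cbind(zi[wc[, 1]], yi[wc[, 2]], xi[wc[, 3]])] <- TRUE
        }
        loc <- classify_rosette_location(c(cz, cy, cx), cen_patch, height_map,
                                         endoderm_mask, open_mask, vz, vxy,
                                         cell_diameter_um, patch_radius_um,
                                         tissue_mask = tissue_mask)
        ## lumen from the apical channel patch (y-extended for tunnels)
        byl <- ceiling(lumen_patch_y_um / vxy)
        yl <- max(1, icy - byl):min(d[2], icy + byl)
        lum_patch <- apic[zi, yl, xi, drop = FALSE]
        lum <- analyze_lumen(lum_patch,
                             c(cz - (zi[1] - 1) * vz, cy - (yl[1] - 1) * vxy,
                               cx - (xi[1] - 1) * vxy),
                             vz, vxy, dark_threshold = dark_thr)
        if (loc == "partially_emerged") {
            lum$has_lumen <- FALSE
            lum$lumen_volume_um3 <- 0
            lum$lumen_area_um2 <- 0
        }
        ## staging on a projected junctional patch around the centre depth
        ## (y-extended so tunnel rings are not cropped open)
        zs <- max(1, icz - 2):min(d[1], icz + 2)
        jp <- apply(junc[zs, yl, xi, drop = FALSE], c(2, 3), max)
        stg <- stage_junctional_region(jp, vertex_counts[i], vxy,
                                       threshold = .junction_threshold_default,
                                       center_rc = c(icy - yl[1] + 1,
                                                     icx - xi[1] + 1))
        rows[[i]] <- tibble::tibble(
            id = i, z_um = cz, y_um = cy, x_um = cx,
            location_class = loc, stage = stg,
            has_lumen = lum$has_lumen,
            lumen_area_um2 = lum$lumen_area_um2,
            lumen_volume_um3 = lum$lumen_volume_um3,
            elongated = lum$elongated)
    }
    do.call(rbind, rows)
}
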