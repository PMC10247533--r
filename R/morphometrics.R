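#' Crop a projection to a physical field of view
#'
#' Extracts a sub-image of the requested physical extent (e.g. the
#' 160 x 260 um analysis window centred on the ventral midline). Extents
#' are converted to whole pixels by rounding (`round(extent / px)`), and
#' the window is placed so its centre pixel is `round(center / px)`.
#'
#' @param image 2D numeric matrix (y, x).
#' @param width_um,height_um field extent in microns (width = x, height = y).
#' @param center_um c(y, x) centre in microns; default image centre.
#' @param px_size_um pixel size in microns.
#' @return cropped matrix with attribute `"offset_px"` (0-based y, x).
#' @export
crop_field_of_view <- function(image, width_um, height_um, center_um = NULL,
                               px_size_um) {
    if (missing(px_size_um) || is.null(px_size_um))
        abort("px_size_um calibration is required")
    ny <- nrow(image); nx <- ncol(image)
    center_um <- center_um %||% c((ny - 1) * px_size_um / 2,
                                  (nx - 1) * px_size_um / 2)
    hpx <- round(height_um / px_size_um)
    wpx <- round(width_um / px_size_um)
    cy <- round(center_um[1] / px_size_um) + 1
    cx <- round(center_um[2] / px_size_um) + 1
    y0 <- cy - floor(hpx / 2); x0 <- cx - floor(wpx / 2)
    y1 <- y0 + hpx - 1; x1 <- x0 + wpx - 1
    if (y0 < 1 || x0 < 1 || y1 > ny || x1 > nx)
        abort("field of view exceeds image bounds")
    out <- image[y0:y1, x0:x1, drop = FALSE]
    attr(out, "offset_px") <- c(y = y0 - 1, x = x0 - 1)
    out
}

## segment one projection into filled junctional regions; returns label
## matrix plus per-region stats
.segment_projection <- function(proj, px_size_um, threshold,
                                closing_radius_um, small_apex_threshold_um2,
                                min_region_um2, min_count_apex_um2) {
    bw0 <- proj > threshold
    bw <- bw0
    if (closing_radius_um > 0) {
        brush_d <- 2 * max(1, round(closing_radius_um / px_size_um)) + 1
        bw <- EBImage::closing(bw0 * 1, EBImage::makeBrush(brush_d, "disc")) > 0
    }
    lab <- label_components(bw, connectivity = 26)   # 8-connected in 2D
    nlab <- attr(lab, "n_labels")
    filled_lab <- matrix(0L, nrow(proj), ncol(proj))
    rows <- list()
    for (k in seq_len(nlab)) {
        comp <- lab == k
        ## closing only heals connectivity; areas are measured on the raw
        ## thresholded web, which avoids the closing's boundary fillets —
        ## unless the raw fill leaks through a healed gap, in which case
        ## the closed component is measured instead
        raw <- comp & bw0
        filled <- fill_holes2d(raw)
        base <- raw
        filled_c <- fill_holes2d(comp)
        if (sum(filled) < 0.9 * sum(filled_c)) {
            filled <- filled_c
            base <- comp
        }
        area <- sum(filled) * px_size_um^2
        if (area < min_region_um2) next
        hl <- holes2d(base)
        apex_areas <- numeric(0)
        if (attr(hl, "n_labels") > 0)
            apex_areas <- tabulate(hl[hl > 0]) * px_size_um^2
        counted <- apex_areas[apex_areas >= min_count_apex_um2]
        mesoderm <- if (length(apex_areas))
            median(apex_areas) < small_apex_threshold_um2
        else area < 4 * small_apex_threshold_um2
        w <- which(filled, arr.ind = TRUE)
        rows[[length(rows) + 1]] <- tibble::tibble(
            area_um2 = area,
            centroid_y_um = mean(w[, 1] - 1) * px_size_um,
            centroid_x_um = mean(w[, 2] - 1) * px_size_um,
            n_apices = length(apex_areas),
            n_cells = length(counted),
            median_apex_um2 = if (length(apex_areas)) median(apex_areas)
                              else NA_real_,
            mesoderm = mesoderm)
        filled_lab[filled] <- length(rows)
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
        tibble::tibble(area_um2 = numeric(0), centroid_y_um = numeric(0),
                       centroid_x_um = numeric(0), n_apices = integer(0),
                       n_cells = integer(0), median_apex_um2 = numeric(0),
                       mesoderm = logical(0))
    list(table = tab, labels = filled_lab)
}

#' Segment emerged and unemerged epithelial regions
#'
#' Binarizes the junctional signal of the surface and subsurface
#' projections, closes small gaps, labels connected lattices and fills
#' their enclosed apices. Regions found in the surface projection are
#' flagged emerged, regions from the subsurface projection unemerged. A
#' region is called axial mesoderm when the median enclosed-apex area is
#' below `small_apex_threshold_um2` (emerged axial mesoderm cells have
#' smaller apical surfaces than the squamous endoderm); solid regions
#' without apices qualify when their total area is below four times the
#' threshold. Cells are counted as apices of at least
#' `min_count_apex_um2` (highly constricted perimeter cells are excluded
#' from counts).
#'
#' @param surface_proj,subsurface_proj 2D numeric projections sharing
#'   calibration.
#' @param px_size_um pixel size in microns (required calibration).
#' @param junction_threshold binarization threshold (fractional units); the
#'   default separates bright axial-mesoderm junctions from the dim
#'   endoderm lattice.
#' @param small_apex_threshold_um2 mesoderm apex-area criterion (um^2); an
#'   operationalization of the paper-style manual call, not a measured
#'   value.
#' @param min_region_um2 regions smaller than this are dropped.
#' @param closing_radius_um morphological closing radius (um).
#' @param min_count_apex_um2 minimum apex area counted as a cell.
#' @return tibble with one row per region (`region`, `emerged`, `area_um2`,
#'   centroid, apex statistics, `mesoderm`), with label images in the
#'   `"labels"` attribute (list `emerged`, `unemerged`).
#' @export
segment_epithelial_regions <- function(surface_proj, subsurface_proj,
                                       px_size_um,
                                       junction_threshold = .junction_threshold_default,
                                       small_apex_threshold_um2 = 50,
                                       min_region_um2 = 10,
                                       closing_radius_um = 0.5,
                                       min_count_apex_um2 = 2) {
    if (missing(px_size_um) || is.null(px_size_um) || !is.numeric(px_size_um))
        abort("px_size_um calibration is required")
    se <- .segment_projection(surface_proj, px_size_um, junction_threshold,
                              closing_radius_um, small_apex_threshold_um2,
                              min_region_um2, min_count_apex_um2)
    su <- .segment_projection(subsurface_proj, px_size_um, junction_threshold,
                              closing_radius_um, small_apex_threshold_um2,
                              min_region_um2, min_count_apex_um2)
    tab <- rbind(
        if (nrow(se$table)) tibble::tibble(emerged = TRUE, se$table) else NULL,
        if (nrow(su$table)) tibble::tibble(emerged = FALSE, su$table) else NULL)
    if (is.null(tab))
        tab <- tibble::tibble(emerged = logical(0), area_um2 = numeric(0),
                              centroid_y_um = numeric(0),
                              centroid_x_um = numeric(0),
                              n_apices = integer(0), n_cells = integer(0),
                              median_apex_um2 = numeric(0),
                              mesoderm = logical(0))
    tab <- tibble::tibble(region = seq_len(nrow(tab)), tab)
    attr(tab, "labels") <- list(emerged = se$labels, unemerged = su$labels)
    tab
}

#' Summarize an epithelial region table
#'
#' @param table a region table from [segment_epithelial_regions()].
#' @param cell_counts optional externally supplied per-region cell counts
#'   (named or positional by `region`), mirroring manual counting;
#'   overrides the automatic apex counts.
#' @return list with `n_emerged_clusters`, `emerged_area_um2`,
#'   `unemerged_area_um2`, `total_area_um2`, `emerged_fraction` (emerged /
#'   (emerged + unemerged) area) and a per-region tibble with
#'   `mean_cell_area_um2` (NA where the cell count is zero — an explicit
#'   undefined marker, never a division).
#' @export
summarize_clusters <- function(table, cell_counts = NULL) {
    n_cells <- table$n_cells
    if (!is.null(cell_counts)) {
        if (any(cell_counts < 0, na.rm = TRUE))
            abort("cell counts must be >= 0")
        n_cells <- as.integer(cell_counts)
    }
    mean_cell <- ifelse(!is.na(n_cells) & n_cells >= 1,
                        table$area_um2 / n_cells, NA_real_)
    emerged_area <- sum(table$area_um2[table$emerged])
    unemerged_area <- sum(table$area_um2[!table$emerged])
    total <- emerged_area + unemerged_area
    list(n_emerged_clusters = sum(table$emerged),
         n_unemerged_regions = sum(!table$emerged),
         emerged_area_um2 = emerged_area,
         unemerged_area_um2 = unemerged_area,
         total_area_um2 = total,
         emerged_fraction = if (total > 0) emerged_area / total else NA_real_,
         regions = tibble::tibble(region = table$region,
                                  emerged = table$emerged,
                                  area_um2 = table$area_um2,
                                  n_cells = n_cells,
                                  mean_cell_area_um2 = mean_cell))
}
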