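#' Sparse per-slice embryo-outline contours
#'
#' The manual-annotation surrogate: closed polygons outlining the embryo
#' exterior on a sparse subset of slices. Vertex coordinates are 0-based
#' pixel units with the origin at the image corner, x along columns and y
#' along rows; the centre of pixel (row i, col j) (1-based) is
#' (x, y) = (j - 0.5, i - 0.5). A slice may carry zero polygons, which
#' annotates it as empty.
#'
#' @param polygons named list: names are 0-based slice indices, values are
#'   lists of n x 2 matrices (columns x, y).
#' @param shape_yx image extent c(ny, nx) in pixels.
#' @return an object of class `contour_set`.
#' @export
contour_set <- function(polygons, shape_yx) {
    slices <- as.integer(names(polygons))
    if (anyNA(slices)) abort("polygon list names must be 0-based slice indices")
    o <- order(slices)
    structure(list(slices = slices[o], polys = unname(polygons)[o],
                   shape_yx = as.integer(shape_yx)),
              class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
    cat(sprintf("<contour_set> %d annotated slice(s) on a %d x %d image: %s\n",
                length(x$slices), x$shape_yx[1], x$shape_yx[2],
                paste(x$slices, collapse = ", ")))
    invisible(x)
}

## TRUE if the closed polygon self-intersects (non-adjacent edges cross)
polygon_self_intersects <- function(p) {
    n <- nrow(p)
    if (n < 4) return(FALSE)
    a <- p
    b <- p[c(2:n, 1), , drop = FALSE]
    cross2 <- function(ox, oy, px, py, qx, qy)
        (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
    for (i in seq_len(n - 2)) {
        j <- (i + 2):n
        j <- j[!(i == 1 & j == n)]          # skip edges sharing a vertex
        if (!length(j)) next
        d1 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
        d2 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
        d3 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
        d4 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
        if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
    }
    FALSE
}

#' Rasterize the polygons of one slice to a logical mask
#'
#' A pixel is inside if its centre falls inside any polygon (even-odd rule
#' per polygon, union across polygons).
#'
#' @param polys list of n x 2 vertex matrices (x, y; 0-based corner origin).
#' @param shape_yx image extent c(ny, nx).
#' @return logical (ny, nx) matrix.
#' @export
rasterize_polygons <- function(polys, shape_yx) {
    ny <- shape_yx[1]; nx <- shape_yx[2]
    mask <- matrix(FALSE, ny, nx)
    if (!length(polys)) return(mask)
    cx <- rep(seq_len(nx) - 0.5, each = ny)
    cy <- rep(seq_len(ny) - 0.5, times = nx)
    pts <- cbind(cx, cy)
    for (p in polys) {
        p <- as.matrix(p)
        inside <- mgcv::in.out(rbind(p, p[1, , drop = FALSE]), pts)
        mask <- mask | matrix(inside, ny, nx)
    }
    mask
}

## signed distance field of a slice's polygons, evaluated at pixel centres
## in pixel units: negative inside. Computed against the polygon geometry
## itself (exact point-to-segment distances), not a raster, so linear
## blending of two fields interpolates boundaries at sub-pixel accuracy.
## Slices without polygons get a large positive constant.
sdf_polygons <- function(polys, shape_yx) {
    ny <- shape_yx[1]; nx <- shape_yx[2]
    big <- ny + nx
    if (!length(polys)) return(matrix(big, ny, nx))
    px <- rep(seq_len(nx) - 0.5, each = ny)
    py <- rep(seq_len(ny) - 0.5, times = nx)
    d2 <- rep(Inf, ny * nx)
    inside <- rep(FALSE, ny * nx)
    for (p in polys) {
        p <- as.matrix(p)
        a <- p
        b <- p[c(2:nrow(p), 1), , drop = FALSE]
        for (s in seq_len(nrow(p))) {
            ex <- b[s, 1] - a[s, 1]; ey <- b[s, 2] - a[s, 2]
            len2 <- ex^2 + ey^2
            t <- if (len2 > 0)
                pmin(pmax(((px - a[s, 1]) * ex + (py - a[s, 2]) * ey) / len2,
                          0), 1) else 0
            dx <- px - (a[s, 1] + t * ex)
            dy <- py - (a[s, 2] + t * ey)
            d2 <- pmin(d2, dx^2 + dy^2)
        }
        inside <- inside | mgcv::in.out(rbind(p, p[1, , drop = FALSE]),
                                        cbind(px, py))
    }
    matrix(ifelse(inside, -sqrt(d2), sqrt(d2)), ny, nx)
}

#' Interpolate sparse contours into a filled volume
#'
#' Annotated slices reproduce their polygons' rasterization exactly.
#' Between two annotations the mask is interpolated by linear blending of
#' per-slice signed distance fields, which reproduces the behaviour of
#' ROI-interpolation tools on convex outlines and is well defined for all
#' simple polygons. Slices outside the annotated range copy the nearest
#' annotation.
#'
#' @param contours a [contour_set()].
#' @param n_slices number of slices of the output volume (>= max annotated
#'   index + 1).
#' @return logical array (z, y, x).
#' @export
interpolate_contours <- function(contours, n_slices) {
    if (!length(contours$slices)) abort("contour set has no annotated slices")
    if (n_slices < max(contours$slices) + 1)
        abort("n_slices smaller than the last annotated slice")
    for (i in seq_along(contours$slices))
        for (p in contours$polys[[i]])
            if (polygon_self_intersects(as.matrix(p)))
                abort("self-intersecting polygon on slice ", contours$slices[i])

    ny <- contours$shape_yx[1]; nx <- contours$shape_yx[2]
    ann <- contours$slices
    masks <- lapply(contours$polys, rasterize_polygons, shape_yx = contours$shape_yx)
    sdfs <- lapply(contours$polys, sdf_polygons, shape_yx = contours$shape_yx)

    ## an empty annotation next to a non-empty one is interpolated as the
    ## neighbouring outline collapsing linearly onto its innermost point
    ## (cone collapse), rather than as an arbitrary far-away level set
    pair_sdfs <- function(i, j) {
        si <- sdfs[[i]]; sj <- sdfs[[j]]
        ei <- !length(contours$polys[[i]]); ej <- !length(contours$polys[[j]])
        if (ei && !ej) si <- sj + max(-min(sj), 1)
        if (ej && !ei) sj <- si + max(-min(si), 1)
        list(si, sj)
    }
    out <- array(FALSE, c(n_slices, ny, nx))
    for (k in seq_len(n_slices) - 1L) {
        if (k %in% ann) {
            out[k + 1, , ] <- masks[[match(k, ann)]]
        } else if (k < ann[1]) {
            out[k + 1, , ] <- masks[[1]]
        } else if (k > ann[length(ann)]) {
            out[k + 1, , ] <- masks[[length(ann)]]
        } else {
            i <- max(which(ann < k)); j <- i + 1L
            w <- (k - ann[i]) / (ann[j] - ann[i])
            ss <- pair_sdfs(i, j)
            out[k + 1, , ] <- ((1 - w) * ss[[1]] + w * ss[[2]]) < 0
        }
    }
    out
}

#' Contour JSON I/O
#'
#' Format: `{"shape_yx": [ny, nx], "slices": {"<index>": [[[x,y], ...], ...]}}`
#' with 0-based slice indices and corner-origin pixel coordinates.
#'
#' @param contours a [contour_set()].
#' @param path file path.
#' @return `path` (write) or a [contour_set()] (read).
#' @export
write_contours_json <- function(contours, path) {
    slices <- lapply(contours$polys, function(pl) lapply(pl, function(p) {
        p <- as.matrix(p)
        lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2]))
    }))
    names(slices) <- as.character(contours$slices)
    jsonlite::write_json(list(shape_yx = contours$shape_yx, slices = slices),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname write_contours_json
#' @export
read_contours_json <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    shape <- unlist(obj$shape_yx)
    polys <- lapply(obj$slices, function(pl) lapply(pl, function(p)
        do.call(rbind, lapply(p, unlist))))
    contour_set(polys, shape)
}

## extract exterior outline polygons of a 2D mask (0.5-level contour of the
## zero-padded indicator), vertices in corner-origin pixel coordinates
mask_outline_polygons <- function(mask) {
    ny <- nrow(mask); nx <- ncol(mask)
    pad <- matrix(0, ny + 2, nx + 2)
    pad[2:(ny + 1), 2:(nx + 1)] <- mask * 1
    ## grid coordinates of pixel centres after padding: centre of padded
    ## row i is y = i - 1.5 in the unpadded corner-origin frame
    cl <- grDevices::contourLines(x = seq_len(ny + 2) - 1.5,
                                  y = seq_len(nx + 2) - 1.5,
                                  z = pad, levels = 0.5)
    lapply(cl, function(cc) cbind(x = cc$y, y = cc$x))
}
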