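#' Classify a junctional region patch as pre-cluster or cluster
#'
#' Pre-clusters are solid junctional domains; clusters enclose at least
#' one background hole of `hole_min_um2` or more (cells with expanded
#' apical domains produce a discontinuous, apex-enclosing pattern).
#' Patches below `min_area_um2` are ignored (returns `NA`), not an error.
#'
#' @param patch 2D numeric (or logical) junctional patch.
#' @param px_size_um pixel size (um).
#' @param threshold binarization threshold for numeric patches.
#' @param hole_min_um2 minimum enclosed-hole area.
#' @param min_area_um2 minimum region area.
#' @return `"pre_cluster"`, `"cluster"`, or `NA_character_`.
#' @export
classify_state <- function(patch, px_size_um, threshold = 0.5,
                           hole_min_um2 = 4, min_area_um2 = 6) {
    bw <- if (is.logical(patch)) patch else patch > threshold
    if (sum(bw) * px_size_um^2 < min_area_um2) return(NA_character_)
    hl <- holes2d(bw)
    if (attr(hl, "n_labels") > 0 &&
        any(tabulate(hl[hl > 0]) * px_size_um^2 >= hole_min_um2))
        return("cluster")
    "pre_cluster"
}

#' Segment one movie frame into junctional regions
#'
#' Thresholds the total maximum-intensity projection, labels regions, and
#' attaches per-region area, state ([classify_state()]) and an emerged
#' fraction: the intensity-weighted share of the region's projected signal
#' that falls in the surface projection,
#' `sum(surface) / sum(surface + subsurface)` over region pixels.
#'
#' @param total_proj,surface_proj,subsurface_proj 2D projections.
#' @param px_size_um pixel size (um).
#' @param threshold junctional binarization threshold.
#' @param min_area_um2 regions below this are dropped.
#' @param hole_min_um2 cluster criterion, see [classify_state()].
#' @return a `region_frame`: list with `labels` (integer matrix) and
#'   `table` (tibble: region, area_um2, centroids, state,
#'   emerged_fraction).
#' @export
segment_movie_frame <- function(total_proj, surface_proj, subsurface_proj,
                                px_size_um,
                                threshold = .junction_threshold_default,
                                min_area_um2 = 6, hole_min_um2 = 4) {
    bw <- total_proj > threshold
    lab <- label_components(bw, connectivity = 26)
    n <- attr(lab, "n_labels")
    keep <- 0L
    out_lab <- matrix(0L, nrow(lab), ncol(lab))
    rows <- list()
    for (k in seq_len(n)) {
        comp <- lab == k
        area <- sum(comp) * px_size_um^2
        if (area < min_area_um2) next
        keep <- keep + 1L
        ## the label image carries the filled region (web plus enclosed
        ## apices): overlap linking of filled masks is robust to motion,
        ## where thin junctional webs would barely overlap themselves
        filled <- fill_holes2d(comp)
        out_lab[filled] <- keep
        w <- which(comp, arr.ind = TRUE)
        bb <- c(range(w[, 1]), range(w[, 2]))
        patch <- comp[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
        st <- classify_state(patch, px_size_um, hole_min_um2 = hole_min_um2,
                             min_area_um2 = min_area_um2)
        s_sum <- sum(surface_proj[comp])
        t_sum <- s_sum + sum(subsurface_proj[comp])
        rows[[keep]] <- tibble::tibble(
            region = keep, area_um2 = sum(filled) * px_size_um^2,
            centroid_y_um = mean(w[, 1] - 1) * px_size_um,
            centroid_x_um = mean(w[, 2] - 1) * px_size_um,
            state = st,
            emerged_fraction = if (t_sum > 0) s_sum / t_sum else NA_real_)
    }
    tab <- if (keep) do.call(rbind, rows) else
        tibble::tibble(region = integer(0), area_um2 = numeric(0),
                       centroid_y_um = numeric(0), centroid_x_um = numeric(0),
                       state = character(0), emerged_fraction = numeric(0))
    structure(list(labels = out_lab, table = tab, px_size_um = px_size_um),
              class = "region_frame")
}

## pixel overlaps between two label images: tibble(from, to, inter, a_from, a_to)
.label_overlaps <- function(la, lb) {
    sel <- la > 0 & lb > 0
    if (!any(sel))
        return(tibble::tibble(from = integer(0), to = integer(0),
                              inter = integer(0)))
    key <- paste(la[sel], lb[sel])
    tt <- table(key)
    parts <- do.call(rbind, strsplit(names(tt), " "))
    tibble::tibble(from = as.integer(parts[, 1]), to = as.integer(parts[, 2]),
                   inter = as.integer(tt))
}

#' Build a track graph from a sequence of region frames
#'
#' Greedy bipartite linking by mask overlap: every region links to the
#' next-frame region with the highest IoU, provided IoU >=
#' `link_min_iou`; a region left unlinked is retried against frame t+2
#' (1-frame gap closing, restricted to regions without a predecessor).
#' Successors with two or more predecessors are merge nodes; the
#' predecessor with the largest pixel overlap (tie: lowest region id)
#' continues its track, the others terminate at the merge.
#'
#' @param frames list of `region_frame` objects ([segment_movie_frame()]).
#' @param link_min_iou minimum IoU to link (default 0.25).
#' @return a `track_graph`: list with `nodes` (frame, region, track,
#'   area_um2, state, emerged_fraction, terminated_by_merge), `edges`
#'   (frame_from, region_from, frame_to, region_to, iou, gap) and `merges`
#'   (frame, region, tracks of all predecessors).
#' @export
build_tracks <- function(frames, link_min_iou = 0.25) {
    if (length(frames) < 2) abort("need at least 2 frames")
    nt <- length(frames)
    areas <- lapply(frames, function(f)
        tabulate(f$labels[f$labels > 0], nbins = max(1, max(f$labels))))
    edges <- list()
    linked_from <- lapply(frames, function(f) rep(FALSE, nrow(f$table)))
    has_pred <- lapply(frames, function(f) rep(FALSE, nrow(f$table)))

    link_pair <- function(t1, t2, only_orphans) {
        ov <- .label_overlaps(frames[[t1]]$labels, frames[[t2]]$labels)
        if (!nrow(ov)) return()
        ov$iou <- ov$inter /
            (areas[[t1]][ov$from] + areas[[t2]][ov$to] - ov$inter)
        ov <- ov[ov$iou >= link_min_iou, , drop = FALSE]
        ov <- ov[order(-ov$iou), , drop = FALSE]
        for (r in seq_len(nrow(ov))) {
            f <- ov$from[r]; s <- ov$to[r]
            if (linked_from[[t1]][f]) next           # one successor per region
            if (only_orphans && has_pred[[t2]][s]) next
            linked_from[[t1]][f] <<- TRUE
            has_pred[[t2]][s] <<- TRUE
            edges[[length(edges) + 1]] <<- tibble::tibble(
                frame_from = t1 - 1L, region_from = f,
                frame_to = t2 - 1L, region_to = s,
                iou = ov$iou[r], overlap_px = ov$inter[r], gap = t2 - t1 - 1L)
        }
    }
    for (t in seq_len(nt - 1)) link_pair(t, t + 1, only_orphans = FALSE)
    for (t in seq_len(nt - 2)) {
        un <- which(!linked_from[[t]])
        if (length(un)) link_pair(t, t + 2, only_orphans = TRUE)
    }
    edges <- if (length(edges)) do.call(rbind, edges) else
        tibble::tibble(frame_from = integer(0), region_from = integer(0),
                       frame_to = integer(0), region_to = integer(0),
                       iou = numeric(0), overlap_px = integer(0),
                       gap = integer(0))

    ## assign track ids frame by frame
    nodes <- list(); merges <- list()
    track_of <- lapply(frames, function(f) rep(NA_integer_, nrow(f$table)))
    term_merge <- lapply(frames, function(f) rep(FALSE, nrow(f$table)))
    next_track <- 0L
    for (t in seq_len(nt)) {
        ft <- frames[[t]]$table
        for (r in seq_len(nrow(ft))) {
            preds <- edges[edges$frame_to == t - 1L & edges$region_to == r, ]
            if (nrow(preds) == 0) {
                next_track <- next_track + 1L
                track_of[[t]][r] <- next_track
            } else if (nrow(preds) == 1) {
                track_of[[t]][r] <-
                    track_of[[preds$frame_from + 1L]][preds$region_from]
            } else {
                o <- order(-preds$overlap_px, preds$region_from)
                win <- preds[o[1], ]
                track_of[[t]][r] <-
                    track_of[[win$frame_from + 1L]][win$region_from]
                losers <- preds[o[-1], ]
                for (l in seq_len(nrow(losers)))
                    term_merge[[losers$frame_from[l] + 1L]][losers$region_from[l]] <- TRUE
                merges[[length(merges) + 1]] <- tibble::tibble(
                    frame = t - 1L, region = r,
                    tracks = list(sort(sapply(seq_len(nrow(preds)), function(i)
                        track_of[[preds$frame_from[i] + 1L]][preds$region_from[i]]))))
            }
        }
        if (nrow(ft))
            nodes[[t]] <- tibble::tibble(frame = t - 1L, region = ft$region,
                                         track = track_of[[t]],
                                         area_um2 = ft$area_um2,
                                         state = ft$state,
                                         emerged_fraction = ft$emerged_fraction)
    }
    nodes <- do.call(rbind, nodes)
    nodes$terminated_by_merge <- FALSE
    for (t in seq_len(nt)) {
        w <- which(term_merge[[t]])
        if (length(w))
            nodes$terminated_by_merge[nodes$frame == t - 1L &
                                      nodes$region %in% w] <- TRUE
    }
    merges <- if (length(merges)) do.call(rbind, merges) else
        tibble::tibble(frame = integer(0), region = integer(0),
                       tracks = list())
    structure(list(nodes = nodes, edges = edges, merges = merges,
                   n_frames = nt), class = "track_graph")
}

#' @export
print.track_graph <- function(x, ...) {
    cat(sprintf("<track_graph> %d node(s), %d edge(s), %d merge(s), %d track(s)\n",
                nrow(x$nodes), nrow(x$edges), nrow(x$merges),
                length(unique(x$nodes$track))))
    invisible(x)
}

#' Count coalescence events
#'
#' One event per merge node (a k-way merge counts once), recording the
#' state of each participating region at the frame before the merge.
#'
#' @param graph a [build_tracks()] result.
#' @return list: `count`, `events` tibble (frame, participating tracks,
#'   state pair at merge time).
#' @export
count_coalescence <- function(graph) {
    if (!nrow(graph$merges))
        return(list(count = 0L, events = tibble::tibble(
            frame = integer(0), tracks = list(), states = character(0))))
    evs <- lapply(seq_len(nrow(graph$merges)), function(i) {
        m <- graph$merges[i, ]
        trs <- m$tracks[[1]]
        sts <- sapply(trs, function(tr) {
            nd <- graph$nodes[graph$nodes$track == tr &
                              graph$nodes$frame < m$frame, ]
            if (nrow(nd)) nd$state[which.max(nd$frame)] else NA_character_
        })
        tibble::tibble(frame = m$frame, tracks = list(trs),
                       states = paste(sort(sts), collapse = "+"))
    })
    events <- do.call(rbind, evs)
    list(count = nrow(events), events = events)
}

#' Pre-cluster outcomes: expansion, persistence, disassembly
#'
#' Every track that begins as a pre-cluster receives exactly one outcome:
#' `expansion` at its first pre-cluster-to-cluster transition;
#' `disassembly` if the track ends before the final frame other than by
#' merging (regions cannot leave the field in synthetic data; for real
#' data use `border_touch` to suppress disassembly calls at the image
#' boundary); otherwise `persistence` (tracks terminated by a merge that
#' never expanded neither expanded nor disappeared).
#'
#' @param graph a [build_tracks()] result.
#' @param border_touch optional logical per track: TRUE suppresses a
#'   disassembly call (region touched the image border when last seen).
#' @return tibble: track, outcome, frame (transition / disappearance
#'   frame, NA for persistence).
#' @export
detect_precluster_outcomes <- function(graph, border_touch = NULL) {
    nd <- graph$nodes
    tracks <- sort(unique(nd$track))
    rows <- list()
    for (tr in tracks) {
        sub <- nd[nd$track == tr, ]
        sub <- sub[order(sub$frame), ]
        st0 <- sub$state[!is.na(sub$state)]
        if (!length(st0) || st0[1] != "pre_cluster") next
        out <- "persistence"; frame <- NA_integer_
        trans <- which(sub$state == "cluster")
        if (length(trans)) {
            out <- "expansion"
            frame <- sub$frame[trans[1]]
        } else {
            last <- sub[nrow(sub), ]
            ended_early <- last$frame < graph$n_frames - 1L
            merged_away <- any(sub$terminated_by_merge)
            suppressed <- !is.null(border_touch) && isTRUE(border_touch[[as.character(tr)]])
            if (ended_early && !merged_away && !suppressed) {
                out <- "disassembly"
                frame <- last$frame + 1L
            }
        }
        rows[[length(rows) + 1]] <- tibble::tibble(track = tr, outcome = out,
                                                   frame = frame)
    }
    if (length(rows)) do.call(rbind, rows) else
        tibble::tibble(track = integer(0), outcome = character(0),
                       frame = integer(0))
}

#' Classify emergence of each track over an observation window
#'
#' Endpoint rule on the emerged fraction at first detection (or window
#' start) and window end: emerged at both endpoints = `remains_emerged`;
#' below at both = `does_not_emerge`; below-to-emerged = `emerges`.
#' Partially emerged endpoints score `emerges` only with increasing
#' emergence (by at least `delta`); partial and stable scores
#' `remains_emerged`; regression (including emerged-to-submerged, the
#' documented time-reversal asymmetry) scores `does_not_emerge`.
#'
#' @param graph a [build_tracks()] result.
#' @param window_frames c(start, end) frame window (default whole movie;
#'   tracks first detected mid-movie use their first detection).
#' @param emerged_hi,unemerged_lo emerged-fraction thresholds for
#'   "on the surface" / "below the surface".
#' @param delta minimum emergence increase scored as progress.
#' @return tibble: track, class, fraction_start, fraction_end.
#' @export
classify_emergence <- function(graph, window_frames = NULL,
                               emerged_hi = 0.7, unemerged_lo = 0.3,
                               delta = 0.2) {
    nd <- graph$nodes
    w0 <- if (is.null(window_frames)) 0L else window_frames[1]
    w1 <- if (is.null(window_frames)) graph$n_frames - 1L else window_frames[2]
    rows <- list()
    for (tr in sort(unique(nd$track))) {
        sub <- nd[nd$track == tr & nd$frame >= w0 & nd$frame <= w1, ]
        if (!nrow(sub)) next
        sub <- sub[order(sub$frame), ]
        e0 <- sub$emerged_fraction[1]
        e1 <- sub$emerged_fraction[nrow(sub)]
        cls <- if (e0 < emerged_hi && e1 >= emerged_hi) "emerges"
        else if (e0 >= emerged_hi && e1 >= emerged_hi) "remains_emerged"
        else if (e1 > unemerged_lo && e1 >= e0 + delta) "emerges"
        else if (e0 > unemerged_lo && e1 > unemerged_lo) "remains_emerged"
        else "does_not_emerge"
        rows[[length(rows) + 1]] <- tibble::tibble(
            track = tr, class = cls, fraction_start = e0, fraction_end = e1)
    }
    do.call(rbind, rows)
}

#' Apical-area time series after emergence
#'
#' Per cell, the apical area at the requested times since first
#' visibility; t = 12 min is the first frame at which the apical domain is
#' discernible (the frame before is t = 0).
#'
#' @param cells tibble with columns `cell`, `frame` (0-based) and
#'   `area_um2` (calibrated outline areas per frame).
#' @param frame_interval_min acquisition interval.
#' @param sample_times_min sampling times (minutes since first
#'   visibility); must be multiples of the frame interval.
#' @return tibble: cell, time_min, area_um2, missing (TRUE where the
#'   requested time falls beyond the track's life).
#' @export
apical_area_series <- function(cells, frame_interval_min = 12,
                               sample_times_min = c(12, 36, 180)) {
    if (any(sample_times_min %% frame_interval_min != 0))
        abort("sample times must be multiples of the frame interval")
    if (any(sample_times_min < 0)) abort("sample times must be >= 0")
    rows <- list()
    for (cl in unique(cells$cell)) {
        sub <- cells[cells$cell == cl, ]
        sub <- sub[order(sub$frame), ]
        f0 <- sub$frame[1]          # first visibility = t = one interval
        for (tm in sample_times_min) {
            f <- f0 + tm / frame_interval_min - 1L
            hit <- sub$area_um2[sub$frame == f]
            rows[[length(rows) + 1]] <- tibble::tibble(
                cell = cl, time_min = tm,
                area_um2 = if (length(hit)) hit[1] else NA_real_,
                missing = !length(hit))
        }
    }
    do.call(rbind, rows)
}

#' Full time-lapse analysis of a synthetic or real movie
#'
#' Computes the surface/subsurface weight field once from the interior
#' mask (the surface is static over a movie), projects and segments every
#' frame, links regions into tracks and derives the event taxonomy.
#'
#' @param movie a [timelapse()].
#' @param interior_mask logical 3D interior mask (from contours or ground
#'   truth).
#' @param erode_um,sigma_um surface-extraction parameters.
#' @param threshold junctional binarization threshold.
#' @param link_min_iou tracker linking threshold.
#' @param min_area_um2,hole_min_um2 segmentation parameters.
#' @return list: `frames` (region frames), `graph`, `coalescence`,
#'   `outcomes`, `emergence`.
#' @export
analyze_timelapse <- function(movie, interior_mask, erode_um = 10,
                              sigma_um = 2,
                              threshold = .junction_threshold_default,
                              link_min_iou = 0.25, min_area_um2 = 6,
                              hole_min_um2 = 4) {
    f1 <- movie$frames[[1]]
    vz <- f1$voxel_size_z; vxy <- f1$voxel_size_xy
    eroded <- erode_physical(interior_mask, erode_um, vz, vxy)
    w <- gaussian_blur_3d(eroded * 1, sigma_um, vz, vxy)
    rfs <- lapply(movie$frames, function(fr) {
        I <- stack_channel(fr, 1)
        total <- apply(I, c(2, 3), max)
        surf <- apply(I * (1 - w), c(2, 3), max)
        sub <- apply(I * w, c(2, 3), max)
        segment_movie_frame(total, surf, sub, vxy, threshold = threshold,
                            min_area_um2 = min_area_um2,
                            hole_min_um2 = hole_min_um2)
    })
    graph <- build_tracks(rfs, link_min_iou = link_min_iou)
    list(frames = rfs, graph = graph,
         coalescence = count_coalescence(graph),
         outcomes = detect_precluster_outcomes(graph),
         emergence = classify_emergence(graph))
}
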