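## ---- event schedule ---------------------------------------------------------

#' Random event schedule for a synthetic movie
#'
#' Lays out junctional regions on a jittered grid and assigns each a
#' behaviour: pre-clusters (solid domains) that persist, expand into
#' clusters, or disassemble; clusters that coalesce pairwise; regions that
#' emerge onto the surface (depth transit completing within the movie) or
#' remain emerged throughout. Drawn under sub-stream `seed + 6`.
#'
#' Conventions mirrored by the tracker: when regions merge, the larger
#' partner's track continues; a pre-cluster terminated by a merge scores
#' `persistence` (it neither expanded nor disappeared). Merge participants
#' stay deep, so their emergence class is `does_not_emerge`.
#'
#' @param params an [embryo_params()] object.
#' @param n_persistence,n_expansion,n_disassembly,n_coalescence,n_emergence
#'   event counts; `NULL` draws each from its default range.
#' @return list of class `event_schedule` with `regions` and `events`
#'   tibbles.
#' @export
make_event_schedule <- function(params, n_persistence = NULL,
                                n_expansion = NULL, n_disassembly = NULL,
                                n_coalescence = NULL, n_emergence = NULL) {
    p <- params
    nf <- p$n_frames
    if (nf < 12) abort("schedules need n_frames >= 12")
    local_seed(p$seed + 6L, {
        n_pers <- n_persistence %||% sample(2:3, 1)
        n_exp <- n_expansion %||% sample(1:2, 1)
        n_dis <- n_disassembly %||% 1L
        n_coal <- n_coalescence %||% sample(1:2, 1)
        n_emg <- n_emergence %||% sample(1:2, 1)
        n_slots <- n_pers + n_exp + n_dis + 2L * n_coal + n_emg + 1L

        extent <- c((p$stack_shape[2] - 1) * p$voxel_size_xy,
                    (p$stack_shape[3] - 1) * p$voxel_size_xy)
        ncol_g <- max(2L, ceiling(sqrt(n_slots)))
        nrow_g <- ceiling(n_slots / ncol_g)
        slot_y <- (rep(seq_len(nrow_g), each = ncol_g) - 0.5) * extent[1] / nrow_g
        slot_x <- (rep(seq_len(ncol_g), times = nrow_g) - 0.5) * extent[2] / ncol_g
        ngrid <- nrow_g * ncol_g
        jit <- matrix(runif(2 * ngrid, -2, 2), ncol = 2)
        slots_all <- cbind(slot_y, slot_x) + jit
        used <- rep(FALSE, ngrid)
        take_slot <- function() {
            k <- which(!used)[1]
            used[k] <<- TRUE
            slots_all[k, ]
        }
        take_pair <- function() {
            ## two x-adjacent free slots in the same row (pairs keep their
            ## own jitter-free axis so the initial separation is the grid
            ## spacing)
            for (k in seq_len(ngrid - 1)) {
                if (used[k] || used[k + 1]) next
                if ((k %% ncol_g) == 0) next      # row wrap
                used[c(k, k + 1)] <<- TRUE
                return(rbind(slots_all[k, ], slots_all[k + 1, ]))
            }
            abort("no adjacent slot pair free for a coalescence event")
        }

        deep <- 16; surf <- 1
        regions <- list(); events <- list(); id <- 0L
        add_region <- function(y, x, state0, depth0, outcome, oframe,
                               emergence, e0, e1, radius, death, merge_to) {
            id <<- id + 1L
            regions[[id]] <<- tibble::tibble(
                id = id, y_um = unname(y), x_um = unname(x), state0 = state0,
                depth0 = depth0, outcome = outcome,
                outcome_frame = oframe, emergence = emergence,
                emerge_start = e0, emerge_end = e1, radius_um = radius,
                death_frame = death, merge_to = merge_to)
            id
        }
        merged_id0 <- 100L
        for (k in seq_len(n_coal)) {
            sp <- take_pair()
            f <- sample(10:(nf - 6), 1)
            mid <- merged_id0 + k
            a <- add_region(sp[1, 1], sp[1, 2], "cluster", deep, NA, NA,
                            "does_not_emerge", NA, NA, 4.5, f, mid)
            b <- add_region(sp[2, 1], sp[2, 2], "cluster", deep, NA, NA,
                            "does_not_emerge", NA, NA, 4.0, f, mid)
            events[[length(events) + 1]] <- tibble::tibble(
                kind = "coalescence", frame = f, region_ids = list(c(a, b)))
        }
        for (k in seq_len(n_pers)) {
            s <- take_slot()
            add_region(s[1], s[2], "pre_cluster", deep, "persistence", NA,
                       "does_not_emerge", NA, NA, 2.5, NA, NA)
        }
        for (k in seq_len(n_exp)) {
            s <- take_slot()
            f <- sample(4:min(15, nf - 4), 1)
            rid <- add_region(s[1], s[2], "pre_cluster", deep, "expansion",
                              f, "does_not_emerge", NA, NA, 4, NA, NA)
            events[[length(events) + 1]] <- tibble::tibble(
                kind = "expansion", frame = f, region_ids = list(rid))
        }
        for (k in seq_len(n_dis)) {
            s <- take_slot()
            f <- sample(6:(nf - 6), 1)
            rid <- add_region(s[1], s[2], "pre_cluster", deep, "disassembly",
                              f, "does_not_emerge", NA, NA, 2.5, f, NA)
            events[[length(events) + 1]] <- tibble::tibble(
                kind = "disassembly", frame = f, region_ids = list(rid))
        }
        for (k in seq_len(n_emg)) {
            s <- take_slot()
            e0 <- sample(4:8, 1)
            e1 <- e0 + sample(10:min(18, nf - e0 - 3), 1)
            rid <- add_region(s[1], s[2], "cluster", deep, NA, NA,
                              "emerges", e0, e1, 4, NA, NA)
            events[[length(events) + 1]] <- tibble::tibble(
                kind = "emergence", frame = e1, region_ids = list(rid))
        }
        s <- take_slot()
        add_region(s[1], s[2], "cluster", surf, NA, NA,
                   "remains_emerged", NA, NA, 4, NA, NA)

        structure(list(regions = do.call(rbind, regions),
                       events = do.call(rbind, events),
                       merged_id0 = merged_id0),
                  class = "event_schedule")
    })
}

## stamp pixel mask (logical, ny x nx) of one region at a given centre/state
.region_stamp <- function(state, radius, cy, cx, ny, nx, vxy) {
    b <- ceiling((radius + 1) / vxy)
    icy <- round(cy / vxy) + 1L; icx <- round(cx / vxy) + 1L
    yi <- max(1L, icy - b):min(ny, icy + b)
    xi <- max(1L, icx - b):min(nx, icx + b)
    dy <- (yi - 1) * vxy - cy
    dx <- (xi - 1) * vxy - cx
    rad <- sqrt(outer(dy^2, dx^2, `+`))
    theta <- atan2(matrix(dx, length(yi), length(xi), byrow = TRUE),
                   matrix(dy, length(yi), length(xi)))
    m <- matrix(FALSE, ny, nx)
    if (state == "pre_cluster") {
        m[yi, xi] <- rad < radius
    } else {
        bnd <- 2 * pi * (seq_len(6) - 0.5) / 6 - pi
        dang <- Reduce(pmin, lapply(bnd, function(b) ang_dist(theta, b)))
        ring <- rad >= radius - 1.2 & rad < radius
        spokes <- rad >= 1.2 & rad < radius & dang * pmax(rad, 0.5) < 0.35
        m[yi, xi] <- ring | spokes
    }
    m
}

## per-frame centre and depth of a region under the schedule. Coalescing
## partners approach along their joining axis: from their initial
## separation down to (r1 + r2 + 1.5) um at the frame before the merge
## (still two distinct regions), then to (r1 + r2 - 2) um (overlapping) at
## the merge frame itself, where the fused region is rendered.
.region_pose <- function(reg, frame, sched) {
    y <- reg$y_um; x <- reg$x_um; d <- reg$depth0
    if (!is.na(reg$merge_to)) {
        f <- reg$death_frame
        ev <- sched$events[sched$events$kind == "coalescence", ]
        for (r in seq_len(nrow(ev))) {
            if (!(reg$id %in% ev$region_ids[[r]])) next
            partners <- sched$regions[sched$regions$id %in% ev$region_ids[[r]], ]
            mid_y <- mean(partners$y_um); mid_x <- mean(partners$x_um)
            sep0 <- 2 * sqrt((y - mid_y)^2 + (x - mid_x)^2)
            fs1 <- sum(partners$radius_um) + 1.5
            fs0 <- sum(partners$radius_um) - 2
            s <- if (frame >= f) fs0
                 else if (frame <= f - 6) sep0
                 else sep0 + (fs1 - sep0) * (frame - (f - 6)) / 5
            y <- mid_y + (y - mid_y) * s / sep0
            x <- mid_x + (x - mid_x) * s / sep0
        }
    }
    if (identical(reg$emergence, "emerges") && !is.na(reg$emerge_start)) {
        if (frame >= reg$emerge_end) d <- 1
        else if (frame > reg$emerge_start)
            d <- reg$depth0 + (1 - reg$depth0) *
                (frame - reg$emerge_start) / (reg$emerge_end - reg$emerge_start)
    }
    c(y = unname(y), x = unname(x), depth = unname(d))
}

#' Generate a synthetic time-lapse movie with scheduled events
#'
#' Renders a single-channel (junctional marker) movie over the same curved
#' surface model as [generate_static_stack()]: a dim static endoderm
#' lattice plus bright axial-mesoderm regions that persist, expand,
#' disassemble, approach and coalesce, and translocate surfaceward to
#' emerge, following the event schedule. Frame metadata records the
#' acquisition interval.
#'
#' @param params an [embryo_params()] object (`n_frames >= 2`).
#' @param schedule an [make_event_schedule()] result, or `NULL` to draw one.
#' @return list with `movie` (a [timelapse()]) and `truth` (class
#'   `movie_truth`: schedule, surface height map, interior mask, params).
#' @export
generate_timelapse <- function(params, schedule = NULL) {
    p <- params
    if (p$n_frames < 2) abort("n_frames must be >= 2")
    schedule <- schedule %||% make_event_schedule(p)
    fr <- unlist(lapply(seq_len(nrow(schedule$events)), function(r)
        schedule$events$frame[r]))
    if (length(fr) && any(fr >= p$n_frames))
        abort("schedule references frames >= n_frames")

    nz <- p$stack_shape[1]; ny <- p$stack_shape[2]; nx <- p$stack_shape[3]
    vz <- p$voxel_size_z; vxy <- p$voxel_size_xy
    h <- .cap_height_map(p)
    iz_a <- ceiling(h / vz - 1e-9) + 1
    z_um <- (seq_len(nz) - 1) * vz
    interior <- array(FALSE, c(nz, ny, nx))
    for (iz in seq_len(nz)) interior[iz, , ] <- z_um[iz] >= h - 1e-9

    ## static endoderm lattice (layout stream seed+0)
    base <- local_seed(p$seed, {
        se <- p$endoderm_cell_diameter
        extent <- c((ny - 1) * vxy, (nx - 1) * vxy)
        gy <- seq(se / 2, extent[1] - se / 4, by = se)
        gx <- seq(se / 2, extent[2] - se / 4, by = se)
        eseed <- cbind(rep(gy, times = length(gx)), rep(gx, each = length(gy)))
        eseed <- eseed + matrix(runif(length(eseed), -0.3 * se, 0.3 * se),
                                ncol = 2)
        asg <- assign_nearest_seed(ny, nx, vxy, eseed, seq_len(nrow(eseed)))
        label_boundaries(asg$labels)
    })
    base_sig <- array(0, c(nz, ny, nx))
    w2 <- which(base, arr.ind = TRUE)
    base_sig[cbind(iz_a[base], w2)] <- .levels$junction_endoderm

    ## region aliveness helper
    regions <- schedule$regions
    merged <- list()
    ev_coal <- schedule$events[schedule$events$kind == "coalescence", ]
    frames <- vector("list", p$n_frames)
    nvox <- nz * ny * nx
    local_seed(p$seed + 5L, {
        for (f in seq_len(p$n_frames) - 1L) {
            S <- base_sig
            stamp2d <- matrix(FALSE, ny, nx)
            add_at_depth <- function(stamp, depth) {
                ## place the stamp one slice thick at the given depth below
                ## the local surface
                w <- which(stamp, arr.ind = TRUE)
                if (!nrow(w)) return(invisible())
                izd <- round((h[w] + depth) / vz) + 1L
                izd <- pmin(pmax(izd, iz_a[w]), nz)
                S[cbind(izd, w)] <<- .levels$junction_mesoderm
                invisible()
            }
            for (r in seq_len(nrow(regions))) {
                reg <- regions[r, ]
                if (!is.na(reg$death_frame) && f >= reg$death_frame) next
                pose <- .region_pose(reg, f, schedule)
                st <- if (reg$state0 == "cluster" ||
                          (!is.na(reg$outcome_frame) &&
                           identical(reg$outcome, "expansion") &&
                           f >= reg$outcome_frame)) "cluster" else "pre_cluster"
                stamp <- .region_stamp(st, reg$radius_um, pose["y"], pose["x"],
                                       ny, nx, vxy)
                add_at_depth(stamp, pose["depth"])
            }
            ## merged regions: union of partner stamps at their final poses
            if (nrow(ev_coal)) for (r in seq_len(nrow(ev_coal))) {
                if (f < ev_coal$frame[r]) next
                ids <- ev_coal$region_ids[[r]]
                un <- matrix(FALSE, ny, nx)
                for (idp in ids) {
                    reg <- regions[regions$id == idp, ]
                    pose <- .region_pose(reg, reg$death_frame, schedule)
                    un <- un | .region_stamp("cluster", reg$radius_um,
                                             pose["y"], pose["x"], ny, nx, vxy)
                }
                un <- EBImage::dilate(un * 1, EBImage::makeBrush(3, "box")) > 0
                add_at_depth(un, 16)
            }
            I <- p$background_level + S
            if (p$noise_sd > 0)
                I <- I + rnorm(nvox) * p$noise_sd +
                    rnorm(nvox) * p$noise_sd * sqrt(S)
            frames[[f + 1]] <- voxel_stack(array(clamp01(I), c(1, nz, ny, nx)),
                                           vz, vxy, "junction")
        }
    })

    truth <- structure(list(params = p, schedule = schedule,
                            surface_height_map = h, interior_mask = interior),
                       class = "movie_truth")
    list(movie = timelapse(frames, p$frame_interval_min), truth = truth)
}

#' @export
print.movie_truth <- function(x, ...) {
    cat(sprintf("<movie_truth> %d region(s), %d scheduled event(s)\n",
                nrow(x$schedule$regions), nrow(x$schedule$events)))
    invisible(x)
}
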