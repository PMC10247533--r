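## build a region_frame from a list of logical masks
frame_of <- function(masks, px = 0.5, states = NULL, emerged = NULL) {
    ny <- nrow(masks[[1]]); nx <- ncol(masks[[1]])
    lab <- matrix(0L, ny, nx)
    rows <- list()
    for (i in seq_along(masks)) {
        lab[masks[[i]]] <- i
        w <- which(masks[[i]], arr.ind = TRUE)
        rows[[i]] <- tibble::tibble(
            region = i, area_um2 = sum(masks[[i]]) * px^2,
            centroid_y_um = mean(w[, 1] - 1) * px,
            centroid_x_um = mean(w[, 2] - 1) * px,
            state = if (is.null(states)) "pre_cluster" else states[i],
            emerged_fraction = if (is.null(emerged)) 0 else emerged[i])
    }
    structure(list(labels = lab, table = do.call(rbind, rows),
                   px_size_um = px), class = "region_frame")
}

disk <- function(cy, cx, r, n = 60) {
    outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`) <= r^2
}

test_that("a static region yields one track with one edge per frame", {
    f <- frame_of(list(disk(20, 20, 6)))
    g <- build_tracks(rep(list(f), 5))
    expect_equal(length(unique(g$nodes$track)), 1)
    expect_equal(nrow(g$edges), 4)
    expect_equal(nrow(g$merges), 0)
})

test_that("one-frame gaps are closed", {
    a <- frame_of(list(disk(20, 20, 6)))
    empty <- structure(list(labels = matrix(0L, 60, 60),
                            table = a$table[0, ], px_size_um = 0.5),
                       class = "region_frame")
    g <- build_tracks(list(a, empty, a))
    expect_equal(length(unique(g$nodes$track)), 1)
    expect_equal(g$edges$gap, 1L)
})

test_that("converging regions produce a single merge node", {
    ## merge bookkeeping at a permissive linking threshold: partner-to-fused
    ## IoU is inherently < 0.5 (each partner covers a fraction of the union)
    f1 <- frame_of(list(disk(20, 14, 6), disk(20, 34, 6)))
    f2 <- frame_of(list(disk(20, 19, 6), disk(20, 29, 6)))
    f3 <- frame_of(list(disk(20, 24, 9)))    # fused
    g <- build_tracks(list(f1, f1, f2, f3, f3), link_min_iou = 0.15)
    expect_equal(nrow(g$merges), 1)
    expect_equal(g$merges$frame, 3L)         # 0-based frame of fusion
    co <- count_coalescence(g)
    expect_equal(co$count, 1)
})

test_that("a simultaneous 3-way merge counts once with 3 participants", {
    f1 <- frame_of(list(disk(14, 14, 5), disk(14, 28, 5), disk(26, 21, 5)))
    fused <- disk(14, 14, 5) | disk(14, 28, 5) | disk(26, 21, 5) |
        disk(18, 21, 7)
    f2 <- frame_of(list(fused))
    g <- build_tracks(list(f1, f1, f2), link_min_iou = 0.1)
    co <- count_coalescence(g)
    expect_equal(co$count, 1)
    expect_length(co$events$tracks[[1]], 3)
})

test_that("solid and apex-enclosing patches classify as pre-cluster/cluster", {
    solid <- disk(15, 15, 8)
    expect_equal(classify_state(solid, 0.5), "pre_cluster")
    ann <- disk(15, 15, 10) & !disk(15, 15, 7)   # hole ~38 um2 at 0.5 um/px
    expect_equal(classify_state(ann, 0.5), "cluster")
    expect_true(is.na(classify_state(disk(15, 15, 2), 0.5)))
})

test_that("pre-cluster outcomes partition tracks exclusively", {
    mk <- function(state_by_frame, end_frame = 5) {
        lapply(seq_len(end_frame), function(t) {
            if (t > length(state_by_frame) || is.na(state_by_frame[t]))
                return(NULL)
            state_by_frame[t]
        })
    }
    d <- disk(20, 20, 6)
    frames <- list()
    for (t in 1:6) {
        st_a <- "pre_cluster"                       # persists
        st_b <- if (t >= 4) "cluster" else "pre_cluster"  # expands at frame 3
        masks <- list(d, disk(40, 40, 6))
        states <- c(st_a, st_b)
        if (t <= 3) {                               # c disassembles after frame 2
            masks <- c(masks, list(disk(40, 12, 5)))
            states <- c(states, "pre_cluster")
        }
        frames[[t]] <- frame_of(masks, states = states)
    }
    g <- build_tracks(frames)
    out <- detect_precluster_outcomes(g)
    expect_equal(sort(out$outcome),
                 c("disassembly", "expansion", "persistence"))
    expect_equal(out$frame[out$outcome == "expansion"], 3L)
    expect_equal(out$frame[out$outcome == "disassembly"], 3L)
    ## exactly one outcome per pre-cluster track
    expect_equal(nrow(out), 3)
})

test_that("emergence classes follow the endpoint rule with its asymmetry", {
    mk_graph <- function(f0, f1) {
        d <- disk(20, 20, 6)
        frames <- list(frame_of(list(d), emerged = f0),
                       frame_of(list(d), emerged = (f0 + f1) / 2),
                       frame_of(list(d), emerged = f1))
        build_tracks(frames)
    }
    expect_equal(classify_emergence(mk_graph(0.95, 0.95))$class,
                 "remains_emerged")
    expect_equal(classify_emergence(mk_graph(0.05, 0.05))$class,
                 "does_not_emerge")
    expect_equal(classify_emergence(mk_graph(0.05, 0.95))$class, "emerges")
    ## unemerged -> partially emerged: increasingly emerged, scores emerges
    expect_equal(classify_emergence(mk_graph(0.05, 0.5))$class, "emerges")
    ## stable partial emergence: remains emerged
    expect_equal(classify_emergence(mk_graph(0.5, 0.52))$class,
                 "remains_emerged")
    ## time reversal of an emergence is NOT scored as emerging
    expect_equal(classify_emergence(mk_graph(0.95, 0.05))$class,
                 "does_not_emerge")
})

test_that("apical-area series sample at the stated times", {
    cells <- tibble::tibble(cell = 1, frame = 4:12,
                            area_um2 = 10 + (0:8) * 1)   # 1 um2 per frame
    ser <- apical_area_series(cells)
    expect_equal(ser$time_min, c(12, 36, 180))
    expect_equal(ser$area_um2[1], 10)        # first visibility = 12 min
    expect_equal(ser$area_um2[2], 12)
    expect_true(ser$missing[3])              # 180 min beyond track life
    ## flat series stays flat
    flat <- tibble::tibble(cell = "a", frame = 0:20, area_um2 = 30)
    expect_true(all(apical_area_series(flat)$area_um2 == 30))
    ## planted linear expansion: fitted slope within 10 %
    lin <- tibble::tibble(cell = "b", frame = 0:30, area_um2 = 5 + 2 * (0:30))
    s3 <- apical_area_series(lin, sample_times_min = c(12, 36, 180))
    fit <- stats::lm(area_um2 ~ time_min, data = s3)
    slope_per_frame <- unname(stats::coef(fit)[2]) * 12
    expect_lt(abs(slope_per_frame - 2) / 2, 0.1)
    expect_error(apical_area_series(lin, sample_times_min = c(10)),
                 "multiples")
})

test_that("every region observation belongs to exactly one track node", {
    p <- movie_params(seed = 3)
    mv <- generate_timelapse(p)
    res <- analyze_timelapse(mv$movie, mv$truth$interior_mask)
    nd <- res$graph$nodes
    obs <- sum(sapply(res$frames, function(f) nrow(f$table)))
    expect_equal(nrow(nd), obs)
    expect_false(any(is.na(nd$track)))
    expect_false(any(duplicated(nd[, c("frame", "region")])))
})

test_that("scheduled movie events are recovered end to end", {
    p <- movie_params(seed = 5)
    mv <- generate_timelapse(p)
    sch <- mv$truth$schedule
    res <- analyze_timelapse(mv$movie, mv$truth$interior_mask)
    expect_equal(res$coalescence$count, sum(sch$events$kind == "coalescence"))
    gt_out <- table(sch$regions$outcome[sch$regions$state0 == "pre_cluster"])
    me_out <- table(res$outcomes$outcome)
    expect_equal(as.list(me_out)[names(gt_out)], as.list(gt_out))
    gt_em <- table(sch$regions$emergence)
    me_em <- table(res$emergence$class)
    expect_equal(as.list(me_em)[names(gt_em)], as.list(gt_em))
})

test_that("movies respect their metadata and schedule validation", {
    p <- movie_params(seed = 2, n_frames = 1L)
    expect_error(generate_timelapse(p), "n_frames")
    p2 <- movie_params(seed = 2)
    sch <- make_event_schedule(p2)
    sch$events$frame[1] <- 99L
    expect_error(generate_timelapse(p2, sch), "frames")
    expect_equal(eval(formals(embryo_params)$frame_interval_min), 12)
})
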