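test_that("generation is bit-identical for identical params and seed", {
    p <- small_params(seed = 6)
    a <- generate_static_stack(p)
    b <- generate_static_stack(p)
    expect_identical(a$stack$data, b$stack$data)
    expect_identical(a$truth$rosettes, b$truth$rosettes)
    expect_identical(a$truth$granules, b$truth$granules)
})

test_that("an embryo without rosettes has a quiet subsurface", {
    p <- small_params(seed = 1, n_rosettes = 0, noise_sd = 0)
    res <- generate_static_stack(p)
    expect_null(res$truth$rosettes)
    J <- stack_channel(res$stack, "junction")
    below <- res$truth$interior_mask & !res$truth$shell_mask
    expect_true(all(J[below] <= p$background_level + 1e-12))
    ## at default noise the subsurface stays within the noise band
    p2 <- small_params(seed = 1, n_rosettes = 0)
    res2 <- generate_static_stack(p2)
    J2 <- stack_channel(res2$stack, "junction")
    below2 <- res2$truth$interior_mask & !res2$truth$shell_mask
    expect_lt(quantile(J2[below2], 0.999),
              p2$background_level + 5 * p2$noise_sd)
})

test_that("lumen draws replay from the documented sub-stream", {
    p <- embryo_params(n_rosettes = 8, lumen_probability = 0.5, seed = 31)
    truth <- generate_static_stack(p)$truth
    expect_equal(nrow(truth$rosettes), 8)
    ## independent replay of the documented draw order: stream seed+2,
    ## first n_rosettes uniforms are the lumen presence Bernoullis
    set.seed(p$seed + 2)
    draws <- runif(p$n_rosettes) < p$lumen_probability
    expected <- draws & truth$rosettes$location_class != "partially_emerged"
    expect_identical(truth$rosettes$has_lumen, expected)
})

test_that("rosette members stay within the configured depth band", {
    p <- small_params(seed = 8)
    truth <- generate_static_stack(p)$truth
    sub <- truth$rosettes[truth$rosettes$location_class != "partially_emerged", ]
    ax_r <- p$mesoderm_cell_diameter / 2
    expect_true(all(sub$depth_um >= p$rosette_depth_range[1] - 1e-9))
    expect_true(all(sub$depth_um <= p$rosette_depth_range[2] + 1e-9))
    ## rendered central domains live within depth band +- axial extent
    w <- which(truth$central_domain_mask, arr.ind = TRUE)
    depth <- (w[, 1] - 1) * p$voxel_size_z -
        truth$surface_height_map[w[, 2:3]]
    expect_true(all(depth >= p$rosette_depth_range[1] - ax_r - 2))
    expect_true(all(depth <= p$rosette_depth_range[2] + ax_r + 2))
})

test_that("planted lumen voxel volumes track the analytic values", {
    found <- FALSE
    for (sd_ in c(3, 5, 8)) {
        p <- embryo_params(seed = sd_)
        truth <- generate_static_stack(p)$truth
        lum <- truth$rosettes[truth$rosettes$has_lumen, ]
        if (!nrow(lum)) next
        found <- TRUE
        vv <- p$voxel_size_z * p$voxel_size_xy^2
        err <- abs(lum$lumen_voxels * vv - lum$lumen_volume_um3) /
            lum$lumen_volume_um3
        expect_true(all(err < 0.1))
    }
    expect_true(found)
})

test_that("planted junctional structures are detectable above noise", {
    p <- small_params(seed = 4)
    res <- generate_static_stack(p)
    J <- stack_channel(res$stack, "junction")
    sub <- J[res$truth$junction_subsurface_mask]
    expect_gte(mean(sub), p$background_level + 5 * p$noise_sd)
})

test_that("infeasible placement fails loudly, never truncates", {
    p <- small_params(seed = 1, n_emerged_clusters = 60L)
    expect_error(generate_static_stack(p), "placement infeasible")
})

test_that("generated contours follow the stride arithmetic", {
    p <- small_params(seed = 2)
    truth <- generate_static_stack(p)$truth
    nz <- dim(truth$interior_mask)[1]
    cs <- generate_contours(truth, stride_near = 3, jitter_um = 0)
    expect_identical(cs$slices,
                     sort(unique(c(seq(0L, nz - 1L, by = 3L), nz - 1L))))
})

test_that("parameter validation enforces the documented invariants", {
    expect_error(embryo_params(n_cells_per_rosette = 4), "five or more")
    expect_error(embryo_params(lumen_probability = 1.2), "probabilities")
    expect_error(embryo_params(shell_thickness = -1), "lengths")
    expect_error(embryo_params(rosette_depth_range = c(10, 2000)),
                 "stack depth")
})

test_that("ground truth serializes to JSON", {
    p <- small_params(seed = 2, n_rosettes = 2)
    truth <- generate_static_stack(p)$truth
    path <- tempfile(fileext = ".json")
    write_truth_json(truth, path)
    back <- jsonlite::read_json(path, simplifyVector = TRUE)
    expect_equal(nrow(back$rosettes), 2)
    expect_equal(back$params$seed, 2)
})

test_that("stage patches carry their own labels", {
    for (stg in c("spot", "edge", "early_rosette", "late_rosette")) {
        patch <- simulate_stage_patch(stg)
        expect_equal(attr(patch, "stage"), stg)
        expect_true(any(patch > 0))
    }
})
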