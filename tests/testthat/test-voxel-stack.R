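test_that("voxel stacks validate their invariants", {
    expect_error(voxel_stack(array(0.5, c(2, 2, 2)), 0, 1), "positive")
    expect_error(voxel_stack(array(2, c(2, 2, 2)), 1, 1), "0, 1")
    st <- voxel_stack(array(0.5, c(2, 3, 4, 5)), 2, 0.5, c("a", "b"))
    expect_equal(st$channels, c("a", "b"))
    expect_equal(dim(stack_channel(st, "b")), c(3, 4, 5))
    expect_error(stack_channel(st, "zzz"), "unknown")
})

test_that("stacks round-trip through 16-bit TIFF with metadata sidecar", {
    set.seed(4)
    st <- voxel_stack(array(runif(2 * 4 * 6 * 5), c(2, 4, 6, 5)), 2, 0.5,
                      c("junction", "membrane"))
    path <- tempfile(fileext = ".tif")
    write_stack_tiff(st, path)
    back <- read_stack_tiff(path)
    expect_equal(back$voxel_size_z, 2)
    expect_equal(back$channels, st$channels)
    expect_equal(back$data, st$data, tolerance = 1 / 65535)
    file.remove(paste0(path, ".json"))
    expect_error(read_stack_tiff(path), "sidecar")
})

test_that("timelapse containers check geometry and length", {
    f <- voxel_stack(array(0.1, c(1, 2, 3, 3)), 2, 0.5)
    g <- voxel_stack(array(0.1, c(1, 2, 4, 3)), 2, 0.5)
    expect_error(timelapse(list(f)), "2 frames")
    expect_error(timelapse(list(f, g)), "geometry")
    tl <- timelapse(list(f, f), frame_interval_min = 12)
    expect_equal(tl$frame_interval_min, 12)
})
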