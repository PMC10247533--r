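test_that("soft-mode splitting conserves signal voxelwise", {
    set.seed(11)
    for (t in 1:5) {
        d <- c(sample(4:10, 1), sample(8:24, 1), sample(8:24, 1))
        st <- voxel_stack(array(runif(2 * prod(d)), c(2, d)), 2, 0.5)
        interior <- array(runif(prod(d)) > 0.5, d)
        sp <- split_surface(st, interior, sigma_um = runif(1, 0.5, 3))
        expect_equal(sp$surface$data + sp$subsurface$data, st$data,
                     tolerance = 1e-12)
    }
})

test_that("fiji_subtract with sigma 0 partitions nonzero voxels exactly once", {
    set.seed(12)
    d <- c(6, 16, 16)
    I <- array(runif(prod(d)), d)
    I[I < 0.3] <- 0
    st <- voxel_stack(I, 2, 0.5)
    interior <- array(FALSE, d)
    interior[3:6, , ] <- TRUE
    sp <- split_surface(st, interior, sigma_um = 0, mode = "fiji_subtract")
    s <- array(sp$surface$data, d); b <- array(sp$subsurface$data, d)
    nz <- I > 0
    expect_true(all(xor(s[nz] > 0, b[nz] > 0)))
    expect_true(all(s[!nz] == 0 & b[!nz] == 0))
})

test_that("an all-interior mask routes everything subsurface in soft mode", {
    d <- c(4, 8, 8)
    st <- voxel_stack(array(runif(prod(d)), d), 1, 1)
    sp <- split_surface(st, array(TRUE, d), sigma_um = 2)
    expect_equal(max(abs(sp$surface$data)), 0, tolerance = 1e-12)
    expect_equal(sp$subsurface$data, st$data, tolerance = 1e-12)
})

test_that("projections reduce trivially for single-slice and zero stacks", {
    m <- matrix(runif(64), 8, 8)
    st1 <- voxel_stack(array(m, c(1, 8, 8)), 1, 1)
    expect_equal(project_surface(st1, channel = 1), m)
    st0 <- voxel_stack(array(0, c(5, 8, 8)), 1, 1)
    expect_true(all(project_surface(st0, channel = 1) == 0))
})

test_that("slab projections honour half-open depth bins below the surface", {
    h <- matrix(0, 10, 10)
    a <- array(0, c(48, 10, 10))
    a[24, 5, 5] <- 1                       # z = 23 um
    a[11, 2, 2] <- 1                       # z = 10 um: bin edge, slab 2
    st <- voxel_stack(a, 1, 1)
    sl <- slab_projections(st, 5, 50, h)
    expect_length(sl, 10)
    expect_true(sl[[5]][5, 5] == 1)        # slab index 4 (0-based)
    expect_true(all(sapply(sl[-5], function(m) m[5, 5]) == 0))
    expect_true(sl[[3]][2, 2] == 1)        # depth 10 lands in [10, 15)
    expect_error(slab_projections(st, 7, 50, h), "divide")
    one <- slab_projections(st, 50, 50, h)
    expect_length(one, 1)
    expect_equal(one[[1]], apply(array(a, c(48, 10, 10)), c(2, 3), max))
})

test_that("double reslicing restores an isotropic stack up to permutation", {
    set.seed(3)
    b <- array(runif(6 * 7 * 8), c(6, 7, 8))
    st <- voxel_stack(b, 1, 1)
    tt <- reslice(reslice(st, "transverse"), "transverse")
    expect_equal(stack_channel(tt, 1), b)    # transverse is an involution
    ss <- reslice(reslice(st, "sagittal"), "sagittal")
    expect_equal(stack_channel(ss, 1), aperm(b, c(2, 3, 1)))
})

test_that("resliced ellipsoid sections have the planted semi-axes", {
    nz <- 32; ny <- 80; nx <- 80; vz <- 2; vxy <- 0.5
    a <- array(0, c(nz, ny, nx))
    cz <- 30; cy <- 20; cx <- 20          # semi-axes az 8, ay 12, ax 6 um
    for (iz in seq_len(nz)) {
        z <- (iz - 1) * vz
        yy <- outer((((1:ny) - 1) * vxy - cy)^2 / 144,
                    (((1:nx) - 1) * vxy - cx)^2 / 36, `+`)
        a[iz, , ] <- (((z - cz)^2 / 64) + yy) <= 1
    }
    tv <- reslice(voxel_stack(a * 0.8, vz, vxy), "transverse")
    expect_equal(tv$voxel_size_z, vz)
    s <- stack_channel(tv, 1)[round(cy / vz) + 1, , ]
    wz <- range(which(apply(s > 0, 1, any)))
    wx <- range(which(apply(s > 0, 2, any)))
    expect_lte(abs(diff(wz) * vxy / 2 - 8), 1)
    expect_lte(abs(diff(wx) * vxy / 2 - 6), 1)
})

test_that("constant stacks reslice to constant stacks", {
    st <- voxel_stack(array(0.3, c(5, 9, 11)), 2, 0.5)
    out <- reslice(st, "sagittal")
    expect_true(all(out$data == 0.3))
})

test_that("surface height maps report the shallowest interior voxel", {
    m <- array(FALSE, c(6, 3, 3))
    m[3:6, 1, 1] <- TRUE
    m[5:6, 2, 2] <- TRUE
    h <- surface_height_map(m, 2)
    expect_equal(h[1, 1], 4)
    expect_equal(h[2, 2], 8)
    expect_true(is.na(h[3, 3]))
})
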