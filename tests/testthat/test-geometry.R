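test_that("physical erosion handles identity and annihilation limits", {
    m <- array(TRUE, c(8, 10, 10))
    m[, c(1, 10), ] <- FALSE
    m[, , c(1, 10)] <- FALSE
    m[c(1, 8), , ] <- FALSE
    expect_identical(erode_physical(m, 0, 2, 1), m)
    expect_false(any(erode_physical(m, 100, 2, 1)))
})

test_that("eroding a sphere matches the analytic shrunken volume", {
    ## solid sphere r = 30 um on a 1 um isotropic grid, depth 10 um
    n <- 64
    co <- ((seq_len(n)) - (n + 1) / 2)
    r2 <- outer(co^2, outer(co^2, co^2, `+`), `+`)
    sph <- array(r2 <= 30^2, c(n, n, n))
    er <- erode_physical(sph, 10, 1, 1)
    ratio <- sum(er) / sum(sph)
    expect_lt(abs(ratio - (20 / 30)^3), 0.05 * (20 / 30)^3)
    ## surviving boundary voxels sit ~10 um inside the original boundary
    dd <- sqrt(embryomorph:::edt_sq(sph, c(1, 1, 1)))
    surf_er <- er & !erode_physical(er, 1.8, 1, 1)
    rng <- range(dd[surf_er])
    expect_gte(rng[1], 10 - sqrt(3))
    expect_lte(rng[2], 10 + 2 * sqrt(3))
})

test_that("erosion agrees exactly with a brute-force distance oracle", {
    set.seed(42)
    for (t in 1:8) {
        dims <- c(sample(4:12, 1), sample(4:16, 1), sample(4:16, 1))
        m <- array(runif(prod(dims)) > 0.4, dims)
        vz <- runif(1, 0.5, 3); vxy <- runif(1, 0.2, 1.5)
        depth <- runif(1, 0, 6)
        expect_identical(erode_physical(m, depth, vz, vxy),
                         brute_force_erode(m, depth, vz, vxy))
    }
})

test_that("erosion is monotone in depth", {
    set.seed(7)
    m <- array(runif(16 * 20 * 20) > 0.3, c(16, 20, 20))
    prev <- m
    for (d in c(1, 2, 4, 8)) {
        cur <- erode_physical(m, d, 2, 0.5)
        expect_true(all(prev | !cur))      # cur subset of prev
        prev <- cur
    }
})

test_that("per-slice erosion ignores the z dimension", {
    m <- array(FALSE, c(4, 20, 20))
    m[, 5:16, 5:16] <- TRUE
    e2 <- erode_physical(m, 3, 2, 1, per_slice = TRUE)
    for (iz in 1:4)
        expect_identical(e2[iz, , ],
                         erode_physical(matrix(m[iz, , ], 20, 20), 3, 2, 1))
})

test_that("Gaussian blur preserves constants and never sharpens", {
    a <- array(0.4, c(8, 12, 12))
    expect_equal(gaussian_blur_3d(a, 2, 2, 0.5), a, tolerance = 1e-12)
    set.seed(1)
    b <- array(runif(10 * 16 * 16), c(10, 16, 16))
    grad_max <- function(x) {
        gz <- abs(diff(x))
        max(gz)
    }
    prev <- Inf
    for (s in c(0.5, 1, 2, 4)) {
        g <- gaussian_blur_3d(b, s, 1, 1)
        cur <- grad_max(g)
        expect_lte(cur, prev + 1e-12)
        prev <- cur
    }
})

test_that("3D component labeling respects connectivity", {
    m <- array(FALSE, c(3, 5, 5))
    m[2, 1, 1] <- TRUE
    m[2, 2, 2] <- TRUE                      # diagonal neighbour
    l6 <- embryomorph:::label_components(m, 6)
    l26 <- embryomorph:::label_components(m, 26)
    expect_equal(attr(l6, "n_labels"), 2L)
    expect_equal(attr(l26, "n_labels"), 1L)
})
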