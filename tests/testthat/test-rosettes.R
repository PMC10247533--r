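## build a minimal scene for location tests: flat surface at 4 um, an
## endoderm slab 4-10 um, and a hollow apical ball at the given depth
location_scene <- function(depth_um, open_channel = FALSE,
                           protrusion = FALSE) {
    nz <- 30; ny <- 60; nx <- 60; vz <- 2; vxy <- 1
    h <- matrix(4, ny, nx)
    endo <- array(FALSE, c(nz, ny, nx))
    endo[3:5, , ] <- TRUE                   # z = 4..8 um
    cen <- array(FALSE, c(nz, ny, nx))
    icz <- round(depth_um / vz) + 1 + 2     # depth below surface at 4 um
    co_z <- ((1:nz) - icz) * vz
    co <- ((1:ny) - 30) * vxy
    r2 <- outer(co_z^2, outer(co^2, co^2, `+`), `+`)
    shell <- r2 >= 4^2 & r2 <= 6.5^2
    cen[shell] <- TRUE
    if (protrusion) {
        ztop <- min(which(apply(cen, 1, any)))
        endo[6:(ztop - 1), 29:31, 29:31] <- TRUE
    }
    if (open_channel) {
        ztop <- min(which(apply(cen, 1, any)))
        for (iz in 1:ztop) endo[iz, 28:32, 28:32] <- FALSE
        cen[1:ztop, 29:31, 29:31] <- FALSE  # open the shell cap
    }
    open <- !cen & !endo
    list(center = c((icz - 1) * vz, 29, 29), cen = cen, h = h,
         endo = endo, open = open, vz = vz, vxy = vxy)
}

test_that("deep rosettes with no contact are basal", {
    sc <- location_scene(depth_um = 30)
    cls <- classify_rosette_location(sc$center, sc$cen, sc$h, sc$endo,
                                     sc$open, sc$vz, sc$vxy)
    expect_equal(cls, "basal")
})

test_that("an endoderm process touching the central domain means contact", {
    sc <- location_scene(depth_um = 24, protrusion = TRUE)
    cls <- classify_rosette_location(sc$center, sc$cen, sc$h, sc$endo,
                                     sc$open, sc$vz, sc$vxy)
    expect_equal(cls, "endoderm_contacting")
})

test_that("a central domain open to the exterior is partially emerged", {
    sc <- location_scene(depth_um = 16, open_channel = TRUE)
    cls <- classify_rosette_location(sc$center, sc$cen, sc$h, sc$endo,
                                     sc$open, sc$vz, sc$vxy)
    expect_equal(cls, "partially_emerged")
})

test_that("centers outside the stack are rejected", {
    sc <- location_scene(depth_um = 20)
    expect_error(classify_rosette_location(c(500, 29, 29), sc$cen, sc$h,
                                           sc$endo, sc$open, sc$vz, sc$vxy),
                 "outside")
})

## apical patches with analytic cavities for lumen tests
apical_patch <- function(kind = c("sphere", "tube", "solid"), r = 4,
                         L = 20) {
    kind <- match.arg(kind)
    nz <- 17; ny <- 90; nx <- 50; vz <- 2; vxy <- 0.5
    cz <- 16; cy <- 22; cx <- 12
    zz <- ((1:nz) - 1) * vz - cz
    yy <- ((1:ny) - 1) * vxy - cy
    xx <- ((1:nx) - 1) * vxy - cx
    DZ <- array(rep(zz, ny * nx), c(nz, ny, nx))
    DY <- array(rep(rep(yy, each = nz), nx), c(nz, ny, nx))
    DX <- array(rep(xx, each = nz * ny), c(nz, ny, nx))
    day <- if (kind == "tube") pmax(abs(DY) - L / 2, 0) else DY
    rad <- sqrt(DZ^2 + day^2 + DX^2)
    a <- array(0.05, c(nz, ny, nx))
    if (kind == "solid") {
        a[rad < r + 2.5] <- 0.85
    } else {
        a[rad >= r & rad < r + 2.5] <- 0.85
    }
    list(patch = a, center = c(cz, cy, cx), vz = vz, vxy = vxy)
}

test_that("a solid apical focus has no lumen", {
    ap <- apical_patch("solid")
    lum <- analyze_lumen(ap$patch, ap$center, ap$vz, ap$vxy)
    expect_false(lum$has_lumen)
    expect_equal(lum$lumen_volume_um3, 0)
})

test_that("a spherical lumen of r = 4 um measures (4/3) pi r^3", {
    ap <- apical_patch("sphere", r = 4)
    lum <- analyze_lumen(ap$patch, ap$center, ap$vz, ap$vxy)
    expect_true(lum$has_lumen)
    expect_lt(abs(lum$lumen_volume_um3 - 268.1) / 268.1, 0.1)
    expect_false(lum$elongated)
})

test_that("a tube lumen r = 3, L = 20 measures pi r^2 L + caps, elongated", {
    ap <- apical_patch("tube", r = 3, L = 20)
    lum <- analyze_lumen(ap$patch, ap$center, ap$vz, ap$vxy)
    expect_true(lum$has_lumen)
    analytic <- pi * 9 * 20 + 4 / 3 * pi * 27     # capsule: tube + end caps
    expect_lt(abs(lum$lumen_volume_um3 - analytic) / analytic, 0.1)
    expect_true(lum$elongated)
})

test_that("junctional staging recognises all four categories", {
    for (stg in c("spot", "edge", "early_rosette", "late_rosette")) {
        patch <- simulate_stage_patch(stg, n_cells = 6)
        vc <- if (grepl("rosette", stg)) 6 else 2
        expect_equal(stage_junctional_region(patch, vc, 0.5), stg)
    }
    ## a 6-cell vertex with continuous centre is early even when large
    patch <- simulate_stage_patch("early_rosette", n_cells = 7)
    expect_equal(stage_junctional_region(patch, 7, 0.5), "early_rosette")
    expect_error(stage_junctional_region(matrix(0, 10, 10), 2, 0.5), "empty")
})

test_that("granule detection is empty on an empty channel", {
    ch <- array(0.05, c(10, 40, 40)) +
        array(rnorm(16000, sd = 0.02), c(10, 40, 40))
    det <- detect_granules(ch, 2, 0.5)
    expect_equal(nrow(det), 0)
})

test_that("granules are recovered perfectly at SNR 10", {
    f <- plant_granule_field(seed = 3)
    det <- detect_granules(f$channel, 2, 0.5)
    expect_equal(nrow(det), 12)
    expect_equal(match_centers(det, f$centers, tol = 1), 12L)
    expect_true(all(det$diameter_um > 0.7 & det$diameter_um < 2.3))
})

test_that("the default granule band is 1-2 um", {
    expect_equal(formals(detect_granules)$diameter_band_um, quote(c(1, 2)))
    expect_equal(eval(formals(embryo_params)$granule_diameter_range), c(1, 2))
})

test_that("marker distributions use the five-category vocabulary", {
    d <- c(6, 20, 20)
    memb <- array(FALSE, d); memb[3, 8:12, 8:12] <- TRUE
    junc <- array(FALSE, d); junc[4, 15:18, 15:18] <- TRUE
    zero <- array(0.02, d)
    bright_m <- zero; bright_m[memb] <- 0.8
    bright_j <- zero; bright_j[junc] <- 0.8
    expect_equal(classify_marker_distribution(zero, 0, memb, junc), "none")
    expect_equal(classify_marker_distribution(zero, 3, memb, junc), "granular")
    expect_equal(classify_marker_distribution(bright_m, 0, memb, junc), "apical")
    expect_equal(classify_marker_distribution(bright_m, 2, memb, junc),
                 "transitional")
    expect_equal(classify_marker_distribution(bright_j, 0, memb, junc),
                 "junctional")
})
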