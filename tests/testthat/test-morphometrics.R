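test_that("field-of-view crops honour physical units", {
    img <- matrix(runif(520 * 400), 520, 400)    # 260 x 200 um at 0.5 um/px
    full <- crop_field_of_view(img, 200, 260, px_size_um = 0.5)
    expect_equal(dim(full), c(520, 400))
    fov <- crop_field_of_view(img, 160, 260, px_size_um = 0.5)
    expect_equal(dim(fov), c(520, 320))
    expect_error(crop_field_of_view(img, 500, 100, px_size_um = 0.5),
                 "exceeds")
    expect_error(crop_field_of_view(img, 10, 10), "calibration")
})

test_that("cropping does not change the area of an enclosed region", {
    proj <- matrix(0, 200, 200)
    proj[90:110, 90:110] <- 0.9             # solid block well inside
    blank <- matrix(0, 200, 200)
    t_full <- segment_epithelial_regions(proj, blank, px_size_um = 0.5)
    cfov <- list(w = 80, h = 80)
    pc <- crop_field_of_view(proj, cfov$w, cfov$h, px_size_um = 0.5)
    bc <- crop_field_of_view(blank, cfov$w, cfov$h, px_size_um = 0.5)
    t_crop <- segment_epithelial_regions(pc, bc, px_size_um = 0.5)
    expect_equal(t_crop$area_um2, t_full$area_um2)
})

test_that("blank projections give an empty region table", {
    blank <- matrix(0, 50, 50)
    tab <- segment_epithelial_regions(blank, blank, px_size_um = 0.5)
    expect_equal(nrow(tab), 0)
})

test_that("a planted 10x10 px solid region measures 25 um2", {
    proj <- matrix(0, 60, 60)
    proj[20:29, 30:39] <- 0.9
    blank <- matrix(0, 60, 60)
    tab <- segment_epithelial_regions(proj, blank, px_size_um = 0.5,
                                      closing_radius_um = 0)
    expect_equal(nrow(tab), 1)
    expect_true(tab$emerged[1])
    expect_equal(tab$area_um2[1], 25)
    expect_true(tab$mesoderm[1])
})

test_that("cluster summaries follow the stated arithmetic", {
    tab <- tibble::tibble(region = 1:2, emerged = c(TRUE, TRUE),
                          area_um2 = c(100, 60),
                          centroid_y_um = c(0, 0), centroid_x_um = c(0, 0),
                          n_apices = c(4L, 0L), n_cells = c(4L, 0L),
                          median_apex_um2 = c(10, NA), mesoderm = TRUE)
    s <- summarize_clusters(tab)
    expect_equal(s$emerged_fraction, 1)
    expect_equal(s$regions$mean_cell_area_um2[1], 25)
    expect_true(is.na(s$regions$mean_cell_area_um2[2]))   # 0 cells: undefined
    s2 <- summarize_clusters(tab, cell_counts = c(5, 3))
    expect_equal(s2$regions$mean_cell_area_um2, c(20, 20))
    expect_error(summarize_clusters(tab, cell_counts = c(-1, 2)), ">= 0")
})

test_that("emerged and unemerged areas partition the total exactly", {
    p <- small_params(seed = 5)
    res <- generate_static_stack(p)
    sp <- extract_default(res)
    tab <- segment_epithelial_regions(
        project_surface(sp, "surface", "junction"),
        project_surface(sp, "subsurface", "junction"),
        px_size_um = res$stack$voxel_size_xy)
    s <- summarize_clusters(tab)
    expect_equal(s$emerged_area_um2 + s$unemerged_area_um2, s$total_area_um2)
    expect_gte(s$emerged_fraction, 0)
    expect_lte(s$emerged_fraction, 1)
})

test_that("measurements in um2 are stable under pixel-size rescaling", {
    ## same physical scene rasterized at 0.5 and 1.0 um/px
    mk <- function(px) {
        n <- round(60 / px)
        proj <- matrix(0, n, n)
        ring <- function(cy, cx, r, w) {
            yy <- outer((seq_len(n) - 1) * px - cy, rep(0, n), `+`)
            xx <- outer(rep(0, n), (seq_len(n) - 1) * px - cx, `+`)
            d <- sqrt(yy^2 + xx^2)
            d >= r - w & d <= r
        }
        proj[ring(30, 30, 10, 1.6)] <- 0.9
        proj
    }
    blank1 <- matrix(0, 120, 120); blank2 <- matrix(0, 60, 60)
    a1 <- segment_epithelial_regions(mk(0.5), blank1, px_size_um = 0.5,
                                     small_apex_threshold_um2 = 500)
    a2 <- segment_epithelial_regions(mk(1.0), blank2, px_size_um = 1.0,
                                     small_apex_threshold_um2 = 500)
    expect_equal(nrow(a1), 1)
    expect_equal(nrow(a2), 1)
    expect_lt(abs(a1$area_um2 - a2$area_um2) / a1$area_um2, 0.02)
})

test_that("regions are classified mesoderm by their median apex area", {
    ## fine lattice (small apices) vs a single big enclosed apex
    proj <- matrix(0, 120, 120)
    proj[20:60, 20] <- proj[20:60, 60] <- proj[20, 20:60] <- proj[60, 20:60] <- 0.9
    for (k in seq(28, 52, by = 8)) proj[20:60, k] <- proj[k, 20:60] <- 0.9
    big <- matrix(0, 120, 120)
    big[70:115, 70:115] <- 0.9
    big[72:113, 72:113] <- 0
    both <- pmax(proj, big)
    blank <- matrix(0, 120, 120)
    tab <- segment_epithelial_regions(both, blank, px_size_um = 0.5,
                                      closing_radius_um = 0)
    expect_equal(nrow(tab), 2)
    fine <- tab[which.min(tab$centroid_y_um), ]
    coarse <- tab[which.max(tab$centroid_y_um), ]
    expect_true(fine$mesoderm)
    expect_false(coarse$mesoderm)
})
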