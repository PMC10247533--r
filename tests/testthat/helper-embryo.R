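## reduced embryo for fast unit tests: 3 clusters, 4 rosettes, 28 slices
small_params <- function(...) {
    args <- utils::modifyList(list(stack_shape = c(28L, 200L, 144L),
                                   n_emerged_clusters = 3L,
                                   n_rosettes = 4L), list(...))
    do.call(embryo_params, args)
}

## movie preset used by tracking tests
movie_params <- function(...) {
    args <- utils::modifyList(list(stack_shape = c(24L, 128L, 128L),
                                   n_frames = 36L), list(...))
    do.call(embryo_params, args)
}

## standard surface extraction of a generated stack
extract_default <- function(res, erode_um = 10, sigma_um = 2) {
    st <- res$stack
    er <- erode_physical(res$truth$interior_mask, erode_um,
                         st$voxel_size_z, st$voxel_size_xy)
    split_surface(st, er, sigma_um, "soft")
}

## greedy matching of detected centres to planted centres within tol (um);
## returns number matched
match_centers <- function(det, planted, tol = 1) {
    if (!nrow(det) || !nrow(planted)) return(0L)
    used <- rep(FALSE, nrow(det))
    n <- 0L
    for (i in seq_len(nrow(planted))) {
        d <- sqrt((det$z_um - planted$z_um[i])^2 +
                  (det$y_um - planted$y_um[i])^2 +
                  (det$x_um - planted$x_um[i])^2)
        d[used] <- Inf
        j <- which.min(d)
        if (length(j) && d[j] <= tol) {
            used[j] <- TRUE
            n <- n + 1L
        }
    }
    n
}

## plant an isolated granule field: n Gaussian blobs of diameter d_um at
## SNR = amp / noise_sd, on a calibrated (z, y, x) grid
plant_granule_field <- function(seed, n = 12, d_um = 1.5, noise_sd = 0.05,
                                background = 0.05, snr = 10,
                                dims = c(20L, 120L, 120L)) {
    set.seed(seed)
    vz <- 2; vxy <- 0.5
    amp <- snr * noise_sd
    a <- array(0, dims)
    cents <- matrix(NA_real_, 0, 3)
    while (nrow(cents) < n) {
        cand <- c(round(runif(1, 3, dims[1] - 3)) * vz,
                  runif(1, 6, (dims[2] - 12) * vxy),
                  runif(1, 6, (dims[3] - 12) * vxy))
        if (nrow(cents) &&
            min(sqrt(rowSums(sweep(cents, 2, cand)^2))) < 5) next
        cents <- rbind(cents, cand)
    }
    for (i in seq_len(n))
        a <- embryomorph:::add_gaussian_blob(
            a, list(z_um = cents[i, 1], y_um = cents[i, 2],
                    x_um = cents[i, 3], diameter_um = d_um), amp, vz, vxy)
    ch <- background + a + array(rnorm(prod(dims), sd = noise_sd), dims)
    list(channel = ch, centers = tibble::tibble(z_um = cents[, 1],
                                                y_um = cents[, 2],
                                                x_um = cents[, 3]))
}

## brute-force anisotropic erosion oracle: per-voxel minimum distance to
## the mask complement, chunked to stay in memory
brute_force_erode <- function(mask, depth_um, vz, vxy) {
    d <- dim(mask)
    out <- mask
    bg <- which(!mask, arr.ind = TRUE)
    fg <- which(mask, arr.ind = TRUE)
    if (!nrow(bg) || !nrow(fg)) return(out)
    bz <- (bg[, 1] - 1) * vz; by <- (bg[, 2] - 1) * vxy
    bx <- (bg[, 3] - 1) * vxy
    for (start in seq(1, nrow(fg), by = 1000)) {
        idx <- start:min(start + 999, nrow(fg))
        fz <- (fg[idx, 1] - 1) * vz; fy <- (fg[idx, 2] - 1) * vxy
        fx <- (fg[idx, 3] - 1) * vxy
        d2 <- outer(fz, bz, `-`)^2 + outer(fy, by, `-`)^2 +
            outer(fx, bx, `-`)^2
        keep <- apply(d2, 1, min) > depth_um^2
        out[fg[idx, , drop = FALSE]] <- keep
    }
    out
}
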