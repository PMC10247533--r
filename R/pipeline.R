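#' Pipeline configuration
#'
#' Builds and validates the single configuration object driving the full
#' pipeline (simulate or load, extract surface, quantify, rosettes, track,
#' report). Defaults mirror stated acquisition/processing values where they
#' exist (erosion 10 um, the midpoint of the 9-12 um range; 5 um slabs
#' over the distal 50 um; 12-min frame interval) and operational choices
#' elsewhere; the emitted summary marks each parameter's provenance.
#'
#' @param config named list or path to a YAML file. Recognised fields:
#'   `simulate` (list of [embryo_params()] arguments; used when no
#'   `input_stack` is given), `input_stack` (TIFF path), `contours` (JSON
#'   path), `erode_um`, `sigma_um`, `split_mode`, `fov` (list width_um,
#'   height_um), `junction_threshold`, `small_apex_threshold_um2`,
#'   `hole_min_um2`, `granule_band_um`, `link_min_iou`, `timelapse`
#'   (logical), `seed`, `out_dir`.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    defaults <- list(simulate = list(), input_stack = NULL, contours = NULL,
                     erode_um = 10, sigma_um = 2, split_mode = "soft",
                     fov = NULL, junction_threshold = .junction_threshold_default,
                     small_apex_threshold_um2 = 50, hole_min_um2 = 4,
                     granule_band_um = c(1, 2), link_min_iou = 0.25,
                     timelapse = FALSE, seed = 1L, out_dir = "embryomorph_out")
    cfg <- utils::modifyList(defaults, config)
    if (!is.null(cfg$input_stack)) {
        meta <- paste0(cfg$input_stack, ".json")
        if (!file.exists(meta))
            abort("input stack has no calibration metadata (", meta, ")")
    }
    thr <- c(cfg$erode_um, cfg$sigma_um, cfg$junction_threshold,
             cfg$small_apex_threshold_um2, cfg$hole_min_um2,
             cfg$granule_band_um, cfg$link_min_iou)
    if (any(thr < 0)) abort("all thresholds must be >= 0")
    if (!cfg$split_mode %in% c("soft", "fiji_subtract"))
        abort("split_mode must be soft or fiji_subtract")
    class(cfg) <- "pipeline_config"
    cfg
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> surface extraction -> morphometrics -> rosettes ->
#' (optional) tracking -> report. Deterministic given the configuration and
#' its seeds: the JSON summary is byte-identical across runs; timings and
#' versions go to a separate log file. Any stage failure aborts with the
#' stage name.
#'
#' @param config a [pipeline_config()] (or list / YAML path coerced by it).
#' @param write_images also write split stacks and projections as TIFF.
#' @return the summary list, invisibly; artifacts are written to
#'   `config$out_dir` (per-stage CSV tables, `summary.json`, `run.log`).
#' @export
run_pipeline <- function(config, write_images = FALSE) {
    cfg <- if (inherits(config, "pipeline_config")) config
           else pipeline_config(config)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    logf <- file.path(cfg$out_dir, "run.log")
    cat(sprintf("embryomorph %s | R %s\n",
                as.character(utils::packageVersion("embryomorph")),
                paste(R.version$major, R.version$minor, sep = ".")),
        file = logf)
    t_all <- Sys.time()
    stage <- function(name, expr) {
        t0 <- Sys.time()
        res <- tryCatch(expr, error = function(e)
            abort("stage '", name, "' failed: ", conditionMessage(e)))
        cat(sprintf("%-10s %6.2f s\n", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            file = logf, append = TRUE)
        res
    }

    ## --- input -------------------------------------------------------------
    truth <- NULL
    sim <- stage("input", {
        if (is.null(cfg$input_stack)) {
            prm <- do.call(embryo_params, utils::modifyList(
                list(seed = cfg$seed), cfg$simulate))
            generate_static_stack(prm)
        } else list(stack = read_stack_tiff(cfg$input_stack), truth = NULL)
    })
    stack <- sim$stack
    truth <- sim$truth

    ## --- surface extraction --------------------------------------------------
    ext <- stage("extract", {
        interior <- if (!is.null(cfg$contours)) {
            cs <- read_contours_json(cfg$contours)
            interpolate_contours(cs, dim_zyx(stack)[1])
        } else if (!is.null(truth)) truth$interior_mask
        else abort("no contours given and no ground truth available")
        eroded <- erode_physical(interior, cfg$erode_um,
                                 stack$voxel_size_z, stack$voxel_size_xy)
        split <- split_surface(stack, eroded, cfg$sigma_um, cfg$split_mode)
        hmap <- surface_height_map(interior, stack$voxel_size_z)
        list(split = split, height_map = hmap)
    })
    jc <- if ("junction" %in% stack$channels) "junction" else 1
    surf_proj <- project_surface(ext$split, "surface", jc)
    sub_proj <- project_surface(ext$split, "subsurface", jc)
    if (write_images) {
        write_stack_tiff(ext$split$surface,
                         file.path(cfg$out_dir, "surface.tif"))
        write_stack_tiff(ext$split$subsurface,
                         file.path(cfg$out_dir, "subsurface.tif"))
    }

    ## --- morphometrics -------------------------------------------------------
    quant <- stage("quantify", {
        sp <- surf_proj; up <- sub_proj
        if (!is.null(cfg$fov)) {
            sp <- crop_field_of_view(sp, cfg$fov$width_um, cfg$fov$height_um,
                                     px_size_um = stack$voxel_size_xy)
            up <- crop_field_of_view(up, cfg$fov$width_um, cfg$fov$height_um,
                                     px_size_um = stack$voxel_size_xy)
        }
        tab <- segment_epithelial_regions(
            sp, up, px_size_um = stack$voxel_size_xy,
            junction_threshold = cfg$junction_threshold,
            small_apex_threshold_um2 = cfg$small_apex_threshold_um2)
        list(table = tab, summary = summarize_clusters(tab))
    })
    write.csv(quant$table, file.path(cfg$out_dir, "regions.csv"),
              row.names = FALSE)

    ## --- rosettes ------------------------------------------------------------
    ros <- NULL
    if (!is.null(truth) && !is.null(truth$rosettes)) {
        ros <- stage("rosettes", analyze_rosettes(
            stack, truth$rosettes[, c("z_um", "y_um", "x_um")],
            ext$height_map, truth$endoderm_mask,
            vertex_counts = truth$rosettes$n_cells,
            cell_diameter_um = truth$params$mesoderm_cell_diameter,
            background = truth$params$background_level,
            noise_sd = truth$params$noise_sd,
            tissue_mask = truth$cell_label_volume > 0))
        write.csv(ros, file.path(cfg$out_dir, "rosettes.csv"),
                  row.names = FALSE)
    }

    ## --- tracking ------------------------------------------------------------
    trk <- NULL
    if (isTRUE(cfg$timelapse)) {
        trk <- stage("track", {
            prm <- do.call(embryo_params, utils::modifyList(
                list(seed = cfg$seed), cfg$simulate))
            mv <- generate_timelapse(prm)
            res <- analyze_timelapse(mv$movie, mv$truth$interior_mask,
                                     erode_um = cfg$erode_um,
                                     sigma_um = cfg$sigma_um,
                                     threshold = cfg$junction_threshold,
                                     link_min_iou = cfg$link_min_iou,
                                     hole_min_um2 = cfg$hole_min_um2)
            list(truth = mv$truth, res = res)
        })
        write.csv(trk$res$graph$nodes, file.path(cfg$out_dir, "tracks.csv"),
                  row.names = FALSE)
    }

    ## --- report ---------------------------------------------------------------
    summary <- stage("report", {
        s <- quant$summary
        out <- list(
            parameters = list(
                erode_um = list(value = cfg$erode_um, provenance = "paper (9-12 um range midpoint)"),
                sigma_um = list(value = cfg$sigma_um, provenance = "operational"),
                split_mode = list(value = cfg$split_mode, provenance = "operational"),
                junction_threshold = list(value = cfg$junction_threshold, provenance = "operational"),
                small_apex_threshold_um2 = list(value = cfg$small_apex_threshold_um2, provenance = "operational"),
                frame_interval_min = list(value = 12, provenance = "paper"),
                seed = list(value = cfg$seed, provenance = "operational")),
            morphometrics = list(
                n_emerged_clusters = s$n_emerged_clusters,
                n_unemerged_regions = s$n_unemerged_regions,
                emerged_area_um2 = s$emerged_area_um2,
                unemerged_area_um2 = s$unemerged_area_um2,
                emerged_fraction = s$emerged_fraction))
        if (!is.null(ros))
            out$rosettes <- list(
                n = nrow(ros),
                by_class = as.list(table(ros$location_class)),
                by_stage = as.list(table(ros$stage)),
                lumen_fraction = mean(ros$has_lumen))
        if (!is.null(trk))
            out$events <- list(
                n_tracks = length(unique(trk$res$graph$nodes$track)),
                coalescence = trk$res$coalescence$count,
                outcomes = as.list(table(trk$res$outcomes$outcome)),
                emergence = as.list(table(trk$res$emergence$class)))
        out
    })
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cat(sprintf("%-10s %6.2f s total\n", "done",
                as.numeric(difftime(Sys.time(), t_all, units = "secs"))),
        file = logf, append = TRUE)
    invisible(summary)
}
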