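#' Parameters of the synthetic embryo generator
#'
#' Defines the geometry, optics and biology of a simulated distal mouse
#' egg-cylinder: a distally convex squamous endoderm shell carrying
#' polygonal cell outlines, emerged axial-mesoderm clusters with smaller
#' apices, subsurface multicellular rosettes (optionally with spherical or
#' tunnel-like lumens elongated along the anterior-posterior axis, here the
#' y axis), 1-2 um apical-protein granules, and movie frames at a fixed
#' acquisition interval. Defaults emulate a late-streak (~E7.0) embryo
#' imaged with a 20x objective (2 um z steps, 0.5 um pixels).
#'
#' Randomness is organised in documented sub-streams so that draw sequences
#' can be replayed independently: `seed + 0` surface layout (cluster
#' centres, cell seed points), `seed + 1` rosette placement and location
#' classes, `seed + 2` lumen draws (`runif(n_rosettes)` presence
#' Bernoullis, then radius, tunnel and length fractions, always
#' `n_rosettes` draws each), `seed + 3` stage draws, `seed + 4` granules,
#' `seed + 5` noise (per channel: one `rnorm` field for additive noise,
#' one for intensity-scaled noise), `seed + 6` movie schedule.
#'
#' @param stack_shape integer c(z, y, x) voxel counts.
#' @param voxel_size_z,voxel_size_xy voxel sizes in microns.
#' @param surface_cap_radius radius of curvature of the distal surface (um).
#' @param shell_thickness endoderm shell thickness (um).
#' @param endoderm_cell_diameter,mesoderm_cell_diameter cell diameters (um);
#'   the mesoderm value also sets the basal-rosette distance rule and is a
#'   free simulation parameter, not a measured value.
#' @param n_emerged_clusters,emerged_cluster_diameter emerged axial-mesoderm
#'   clusters on the surface (count; diameter um).
#' @param n_rosettes number of subsurface rosettes.
#' @param rosette_depth_range c(lo, hi) um: depth band below the surface for
#'   subsurface (basal / endoderm-contacting) rosette centres.
#' @param rosette_class_probs named numeric: sampling weights for
#'   basal / endoderm_contacting / partially_emerged.
#' @param n_cells_per_rosette cells per rosette (>= 5).
#' @param lumen_probability fraction of rosettes developing a lumen.
#' @param lumen_radius_range c(lo, hi) um lumen radius.
#' @param tunnel_fraction fraction of lumens that are elongated tunnels.
#' @param tunnel_length_range c(lo, hi) um tunnel axis length.
#' @param granule_diameter_range c(lo, hi) um cytoplasmic granule diameter.
#' @param granules_per_cell expected granules per rosette cell (Poisson rate).
#' @param granule_copositive_fraction fraction of granules also carrying the
#'   apical-kinase marker.
#' @param noise_sd additive Gaussian noise standard deviation (fractional
#'   intensity units).
#' @param background_level baseline intensity.
#' @param frame_interval_min movie acquisition interval (minutes).
#' @param n_frames movie length in frames.
#' @param seed integer RNG seed.
#' @return validated list of class `embryo_params`.
#' @export
embryo_params <- function(stack_shape = c(32L, 288L, 192L),
                          voxel_size_z = 2, voxel_size_xy = 0.5,
                          surface_cap_radius = 150,
                          shell_thickness = 6,
                          endoderm_cell_diameter = 15,
                          mesoderm_cell_diameter = 10,
                          n_emerged_clusters = 7,
                          emerged_cluster_diameter = 24,
                          n_rosettes = 8,
                          rosette_depth_range = c(18, 28),
                          rosette_class_probs = c(basal = 0.6,
                                                  endoderm_contacting = 0.4,
                                                  partially_emerged = 0),
                          n_cells_per_rosette = 6L,
                          lumen_probability = 0.5,
                          lumen_radius_range = c(3, 4.5),
                          tunnel_fraction = 0.25,
                          tunnel_length_range = c(12, 18),
                          granule_diameter_range = c(1, 2),
                          granules_per_cell = 1,
                          granule_copositive_fraction = 0.35,
                          noise_sd = 0.02,
                          background_level = 0.05,
                          frame_interval_min = 12,
                          n_frames = 36L,
                          seed = 1L) {
    p <- list(stack_shape = as.integer(stack_shape),
              voxel_size_z = voxel_size_z, voxel_size_xy = voxel_size_xy,
              surface_cap_radius = surface_cap_radius,
              shell_thickness = shell_thickness,
              endoderm_cell_diameter = endoderm_cell_diameter,
              mesoderm_cell_diameter = mesoderm_cell_diameter,
              n_emerged_clusters = as.integer(n_emerged_clusters),
              emerged_cluster_diameter = emerged_cluster_diameter,
              n_rosettes = as.integer(n_rosettes),
              rosette_depth_range = rosette_depth_range,
              rosette_class_probs = rosette_class_probs,
              n_cells_per_rosette = as.integer(n_cells_per_rosette),
              lumen_probability = lumen_probability,
              lumen_radius_range = lumen_radius_range,
              tunnel_fraction = tunnel_fraction,
              tunnel_length_range = tunnel_length_range,
              granule_diameter_range = granule_diameter_range,
              granules_per_cell = granules_per_cell,
              granule_copositive_fraction = granule_copositive_fraction,
              noise_sd = noise_sd, background_level = background_level,
              frame_interval_min = frame_interval_min,
              n_frames = as.integer(n_frames), seed = as.integer(seed))
    lens <- c(p$voxel_size_z, p$voxel_size_xy, p$surface_cap_radius,
              p$shell_thickness, p$endoderm_cell_diameter,
              p$mesoderm_cell_diameter, p$emerged_cluster_diameter,
              p$lumen_radius_range, p$tunnel_length_range,
              p$granule_diameter_range, p$frame_interval_min)
    if (any(lens <= 0)) abort("all lengths must be > 0")
    probs <- c(p$lumen_probability, p$tunnel_fraction,
               p$granule_copositive_fraction, p$rosette_class_probs)
    if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
    if (p$n_cells_per_rosette < 5)
        abort("n_cells_per_rosette must be >= 5 (a rosette is a vertex of five or more cells)")
    if (p$noise_sd < 0 || p$background_level < 0)
        abort("noise_sd and background_level must be >= 0")
    max_depth <- (p$stack_shape[1] - 1) * p$voxel_size_z
    if (p$rosette_depth_range[1] < 0 || p$rosette_depth_range[2] > max_depth)
        abort("rosette_depth_range must lie within the stack depth")
    if (p$rosette_depth_range[1] > p$rosette_depth_range[2])
        abort("rosette_depth_range must be increasing")
    class(p) <- "embryo_params"
    p
}

## rendered intensity levels (fractional units, before background and noise)
.levels <- list(junction_endoderm = 0.30, junction_mesoderm = 0.85,
                membrane = 0.55, nuclei = 0.65, apical = 0.80,
                granule = 0.85, protrusion = 0.45)

## analysis-side default threshold separating the bright (axial mesoderm)
## junctional signal from the dim squamous-endoderm lattice
.junction_threshold_default <- 0.55

## geometric derivations shared by the renderers
.rosette_lateral_radius <- function(p) p$mesoderm_cell_diameter
.rosette_axial_radius <- function(p) p$mesoderm_cell_diameter / 2
.surface_clearance <- 4   # um of medium above the cap apex

## spherical-cap height map (um) over the pixel grid
.cap_height_map <- function(p) {
    ny <- p$stack_shape[2]; nx <- p$stack_shape[3]
    vxy <- p$voxel_size_xy; R <- p$surface_cap_radius
    yy <- (seq_len(ny) - 1) * vxy; xx <- (seq_len(nx) - 1) * vxy
    cy <- (ny - 1) * vxy / 2; cx <- (nx - 1) * vxy / 2
    r2 <- outer((yy - cy)^2, (xx - cx)^2, `+`)
    r2 <- pmin(r2, (0.99 * R)^2)
    .surface_clearance + R - sqrt(R^2 - r2)
}
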