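#' Benchmark presets
#'
#' Named configuration bundles reproducing the standard benchmark
#' geometries:
#'
#' * `tube1d`: 6 mm x 60 um x 60 um straight tube (100 voxels) containing
#'   one capillary of radius 4 um; the feeding point is the first voxel.
#'   The boundary pressures are chosen to drive the target tube flow
#'   (default 1e4 um^3/s, i.e. a bolus transit of ~30 s over the tube).
#' * `grid2d`: 100 x 100 voxel plane (6 x 6 mm), central feeding artery,
#'   four corner venous roots, vascularized tumor (radius 900 um, necrotic
#'   core 450 um) off-centre; 1e4 voxel fits.
#' * `quasi3d`: the same plane treated as a 60 um thick slab with
#'   interstitial diffusion, default permeability 0.1 um/s.
#' * `block3d`: 6 x 3 x 3 mm block (100 x 50 x 50 = 2.5e5 voxels), feeding
#'   artery on the left face, central spherical tumor.
#' * `coarse3d`: `block3d` read out at 300 x 300 x 3000 um resolution
#'   (5 x 5 x 50 voxel block ROIs, 20 x 10 x 1 = 200 ROIs).
#'
#' @param name Preset name.
#' @param overrides Named list merged over the preset (nested lists merged
#'   recursively).
#' @return A `run_config` list with elements `lattice` (dims, l), `roots`,
#'   `regions` (tumor geometry), `remodeling` ([remodeling_params()]
#'   arguments), `bcs`, `transport` ([transport_params()] arguments),
#'   `acquisition` (`dt`), `inference` (`model`, `rescale`), `tube`
#'   (1d-only geometry), `seed`.
#' @export
benchmark_preset <- function(name = c("tube1d", "grid2d", "quasi3d",
                                      "block3d", "coarse3d"),
                             overrides = list()) {
  name <- match.arg(name)
  base <- list(
    preset = name,
    lattice = list(dims = c(100L, 100L, 1L), l = 60),
    roots = list(arterial = matrix(c(50L, 50L, 0L), 1),
                 venous = rbind(c(0L, 0L, 0L), c(99L, 0L, 0L),
                                c(0L, 99L, 0L), c(99L, 99L, 0L))),
    regions = list(tumor_center_voxel = c(30L, 70L, 0L),
                   tumor_radius = 900, core_radius = 450),
    remodeling = list(iterations = 30, target_fraction = 0.4),
    bcs = list(p_arterial = 3000, p_venous = 2000, mu = 4e-3),
    transport = list(P = 0, D_I = 1e3, T_total = 300, store_dt = 1),
    acquisition = list(dt = 1),
    inference = list(model = "brix2", rescale = TRUE),
    tube = NULL,
    rois = NULL,
    seed = 1L)
  cfg <- switch(name,
    tube1d = modifyList(base, list(
      lattice = list(dims = c(100L, 1L, 1L), l = 60),
      roots = NULL, regions = NULL, remodeling = NULL,
      tube = list(n_voxels = 100L, r = 4, target_flow = 1e4))),
    grid2d = base,
    quasi3d = modifyList(base, list(transport = list(P = 0.1))),
    block3d = modifyList(base, list(
      lattice = list(dims = c(100L, 50L, 50L), l = 60),
      roots = list(arterial = matrix(c(0L, 25L, 25L), 1),
                   venous = rbind(c(99L, 0L, 0L), c(99L, 49L, 0L),
                                  c(99L, 0L, 49L), c(99L, 49L, 49L))),
      regions = list(tumor_center_voxel = c(50L, 25L, 25L),
                     tumor_radius = 900, core_radius = 450))),
    coarse3d = {
      b <- modifyList(base, list(
        lattice = list(dims = c(100L, 50L, 50L), l = 60),
        roots = list(arterial = matrix(c(0L, 25L, 25L), 1),
                     venous = rbind(c(99L, 0L, 0L), c(99L, 49L, 0L),
                                    c(99L, 0L, 49L), c(99L, 49L, 49L))),
        regions = list(tumor_center_voxel = c(50L, 25L, 25L),
                       tumor_radius = 900, core_radius = 450)))
      b$rois <- list(block_dims = c(5L, 5L, 50L))
      b
    })
  cfg <- merge_config(cfg, overrides)
  class(cfg) <- "run_config"
  cfg
}

merge_config <- function(base, over) {
  for (k in names(over)) {
    if (is.list(base[[k]]) && is.list(over[[k]]) &&
        !is.null(names(over[[k]]))) {
      base[[k]] <- merge_config(base[[k]], over[[k]])
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

#' Geometric counts implied by a preset
#'
#' The number of voxelwise inverse problems (`fit_count`), of coarse block
#' ROIs (`roi_count`, coarse presets only), and of voxels in the standard
#' circular measurement ROI (`circular_roi_voxels`, radius 15 voxels in
#' 2d).
#' @param config A `run_config` from [benchmark_preset()].
#' @return Named list of counts.
#' @export
preset_counts <- function(config) {
  dims <- config$lattice$dims
  n_vox <- prod(dims)
  roi_count <- if (!is.null(config$rois)) {
    bd <- config$rois$block_dims
    if (any(dims %% bd != 0))
      stop_invalid("coarse ROI blocks do not tile the domain")
    prod(dims %/% bd)
  } else NA_integer_
  lat <- lattice_spec(dims, config$lattice$l)
  circ <- if (dims[1] >= 31 && dims[2] >= 31) {
    length(make_circular_roi(c(dims[1] %/% 2, dims[2] %/% 2, 0), 15, lat))
  } else NA_integer_
  list(fit_count = n_vox, roi_count = roi_count,
       circular_roi_voxels = circ)
}
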