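#' Run a full benchmark: generate, flow, transport, synthesize, fit
#'
#' Executes the pipeline stages of a preset configuration: network
#' generation (stochastic growth + shear-stress remodeling, or the analytic
#' 1d tube), Poiseuille flow solve, ground-truth parameter maps,
#' contrast-agent transport, DCE series synthesis, and optionally the
#' inverse tracer-kinetic procedure with flow rescaling. All randomness
#' derives from `seed`; the run manifest records the configuration and
#' per-stage seeds.
#'
#' @param preset Preset name (see [benchmark_preset()]) or a `run_config`.
#' @param overrides Config overrides (named nested list).
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param aif An [aif_model()]; default is the raw population AIF
#'   (peak about 6 mM), matching the reported ROI peak scale.
#' @param fit `"none"`, `"voxels"` (per-voxel fits, optionally restricted
#'   via `fit_voxels`), or `"rois"` (fit the curves of `rois`).
#' @param fit_voxels Optional integer voxel subset for `fit = "voxels"`.
#' @param rois Optional list of `roi` objects (required for
#'   `fit = "rois"` unless the preset defines coarse blocks).
#' @param out_dir Optional output directory; when given, the graph
#'   (GraphML), maps and series (NIfTI), ROI curves and fits (CSV) and a
#'   JSON manifest are written there.
#' @return List with `config`, `graph`, `flow`, `maps` (ground truth),
#'   `field`, `series`, and when fitted `recovered` (+ `comparison` for
#'   ROI fits).
#' @export
run_benchmark <- function(preset = "tube1d", overrides = list(), seed = 1,
                          aif = aif_population(),
                          fit = c("none", "voxels", "rois"),
                          fit_voxels = NULL, rois = NULL, out_dir = NULL) {
  fit <- match.arg(fit)
  cfg <- if (inherits(preset, "run_config")) merge_config(preset, overrides)
         else benchmark_preset(preset, overrides)
  cfg$seed <- as.integer(seed)
  lat <- lattice_spec(cfg$lattice$dims, cfg$lattice$l)
  stage_seed <- function(k) (as.integer(seed) * 101L + k) %% .Machine$integer.max

  if (!is.null(cfg$tube)) {
    graph <- tube_network(cfg$tube$n_voxels, cfg$lattice$l, cfg$tube$r)
    g_edge <- pi * cfg$tube$r^4 / (8 * cfg$bcs$mu * cfg$lattice$l)
    dP <- cfg$tube$target_flow * (cfg$tube$n_voxels - 1) / g_edge
    bcs <- boundary_conditions(cfg$bcs$p_venous + dP, cfg$bcs$p_venous,
                               cfg$bcs$mu)
    regions <- NULL
  } else {
    bcs <- do.call(boundary_conditions, cfg$bcs)
    regions <- if (!is.null(cfg$regions)) {
      ctr <- idx_to_pos(lat, matrix(cfg$regions$tumor_center_voxel, ncol = 3))
      build_region_map(lat, ctr, cfg$regions$tumor_radius,
                       cfg$regions$core_radius)
    }
    rp_args <- cfg$remodeling
    tf <- rp_args$target_fraction %||% 0.4
    rp_args$target_fraction <- NULL
    rp <- do.call(remodeling_params, rp_args)
    graph <- grow_trees(lat, cfg$roots$arterial, cfg$roots$venous,
                        seed = stage_seed(1L), target_fraction = tf)
    graph <- remodel_network(graph, regions, rp, bcs, seed = stage_seed(2L))
  }
  flow <- solve_flow(graph, bcs)
  tp <- do.call(transport_params, cfg$transport)
  maps <- ground_truth_maps(graph, flow, tp$P, regions)
  maps$F <- flow_map(graph, flow)
  field <- simulate_transport(graph, flow, maps, tp, aif)
  feed <- idx_to_pos(lat, site_to_idx(lat, site_index(
    lat, matrix(feeding_voxel(cfg), ncol = 3))))
  series <- total_concentration_series(field, maps, cfg$acquisition$dt,
                                       feeding_point = as.numeric(feed))
  out <- list(config = cfg, graph = graph, flow = flow, maps = maps,
              field = field, series = series, aif = aif)

  if (fit == "voxels") {
    out$recovered <- fit_parameter_maps(series, aif, cfg$inference$model,
                                        voxels = fit_voxels,
                                        rescale = cfg$inference$rescale)
  } else if (fit == "rois") {
    if (is.null(rois) && !is.null(cfg$rois)) rois <- tile_block_rois(lat, cfg)
    if (is.null(rois)) stop_invalid("fit = 'rois' needs ROI definitions")
    out$recovered <- fit_rois(series, aif, rois, maps, graph, flow,
                              model = cfg$inference$model,
                              rescale = cfg$inference$rescale)
  }
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

feeding_voxel <- function(cfg) {
  if (!is.null(cfg$tube)) c(0L, 0L, 0L) else cfg$roots$arterial[1, ]
}

tile_block_rois <- function(lat, cfg) {
  bd <- cfg$rois$block_dims
  nb <- lat$dims %/% bd
  g <- expand.grid(i = 0:(nb[1] - 1), j = 0:(nb[2] - 1), k = 0:(nb[3] - 1))
  lapply(seq_len(nrow(g)), function(r)
    make_block_roi(c(g$i[r], g$j[r], g$k[r]) * bd, bd, lat,
                   label = sprintf("block_%d_%d_%d", g$i[r], g$j[r], g$k[r])))
}

#' Fit TK models to ROI-averaged curves and compare with ROI ground truth
#'
#' Implements the multi-voxel ROI protocol: the measurement is the mean
#' total concentration over the ROI, the ROI volume is `n_voxels * V_i`,
#' the recovered flow is rescaled by the ROI-centre distance to the
#' feeding point, and ground truth follows [roi_ground_truth()].
#'
#' @param series A `dce_series` with `feeding_point`.
#' @param aif Feeding [aif_model()].
#' @param rois List of `roi` objects.
#' @param maps,graph,flow Ground-truth inputs.
#' @param model,rescale,config As in [fit_tk()] / [rescale_flow()].
#' @return List with `table` (per-ROI truth, fit and relative errors) and
#'   `fits` (the raw `fit_result`s).
#' @export
fit_rois <- function(series, aif, rois, maps, graph, flow,
                     model = "brix2", rescale = TRUE, config = list()) {
  lat <- series$lattice
  rows <- list(); fits <- list()
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    curve <- roi_curve(series, roi)
    V <- length(roi) * lat$voxel_volume
    ft <- fit_tk(model, series$times, curve, aif, V, config)
    truth <- roi_ground_truth(roi, maps, graph, flow)
    ctr <- colMeans(idx_to_pos(lat, site_to_idx(lat, as.integer(roi))))
    Fres <- if (rescale && !is.null(series$feeding_point) &&
                !is.na(ft$F_recov)) {
      as.numeric(rescale_flow(ft$F_recov, ctr, series$feeding_point, lat$l))
    } else ft$F_recov
    K_rec <- if (model == "brix2") unname(ft$par[3]) else unname(ft$par[2])
    rows[[i]] <- data.frame(
      roi = attr(roi, "label") %||% as.character(i),
      n_voxels = length(roi),
      phi_P_true = truth$phi_P, phi_P_rec = unname(ft$par[1]),
      F_true = truth$F, F_recov = ft$F_recov, F_rescaled = Fres,
      K_PS_true = truth$K_PS, K_PS_rec = K_rec,
      phi_P_rel_err = (truth$phi_P - ft$par[1]) / truth$phi_P,
      F_rel_err = if (truth$F > 0) (truth$F - Fres) / truth$F else NA_real_,
      S = ft$S, converged = ft$converged)
    fits[[i]] <- ft
  }
  tab <- do.call(rbind, rows)
  list(table = tab, fits = fits,
       ranking_phi_ok = identical(order(tab$phi_P_true),
                                  order(tab$phi_P_rec)),
       ranking_F_ok = identical(order(tab$F_true), order(tab$F_rescaled)))
}

#' Parameter sweep over a config entry
#'
#' Runs the benchmark once per value of a configuration entry (same seeds
#' throughout) and collates per-run error summaries into one table. The
#' parameter is addressed by its path in the config, e.g.
#' `c("transport", "P")`.
#'
#' @param param_path Character vector path into the config.
#' @param values Values to sweep (empty vector: no runs, empty table).
#' @param preset Base preset name or `run_config`.
#' @param seed Master seed shared by all runs.
#' @param fit_voxels Voxel subset used for the error summary.
#' @param ... Passed to [run_benchmark()].
#' @return Data frame with one row per value: median absolute relative
#'   errors of `phi_P` and rescaled `F` over the fitted voxels with
#'   positive ground truth.
#' @export
sweep_benchmark <- function(param_path, values, preset = "tube1d", seed = 1,
                            fit_voxels = NULL, ...) {
  cfg0 <- if (inherits(preset, "run_config")) preset
          else benchmark_preset(preset)
  path_ok <- tryCatch(!is.null(cfg0[[param_path[1]]]) ||
                        param_path[1] %in% names(cfg0),
                      error = function(e) FALSE)
  if (!path_ok)
    stop_invalid("unknown config entry '%s'", paste(param_path,
                                                    collapse = "$"))
  rows <- lapply(values, function(v) {
    ov <- value_at_path(param_path, v)
    res <- run_benchmark(cfg0, overrides = ov, seed = seed, fit = "voxels",
                         fit_voxels = fit_voxels, ...)
    summarize_voxel_errors(res, value = v)
  })
  if (length(rows) == 0) {
    return(data.frame(value = numeric(0), median_phi_err = numeric(0),
                      median_F_err = numeric(0), n_fitted = integer(0)))
  }
  do.call(rbind, rows)
}

value_at_path <- function(path, value) {
  out <- value
  for (k in rev(path)) out <- setNames(list(out), k)
  out
}

summarize_voxel_errors <- function(res, value = NA) {
  truth <- res$maps
  rec <- res$recovered
  fitted <- rec$fits$voxel[rec$fits$flag == ""]
  phi_t <- as.numeric(truth$phi_P)[fitted]
  keep <- phi_t > 0
  phi_err <- abs((phi_t - as.numeric(rec$phi_P)[fitted]) / phi_t)[keep]
  F_t <- as.numeric(truth$F)[fitted]
  keepF <- F_t > 0
  F_err <- abs((F_t - as.numeric(rec$F_rescaled)[fitted]) / F_t)[keepF]
  data.frame(value = value,
             median_phi_err = median(phi_err),
             median_F_err = median(F_err),
             n_fitted = length(fitted))
}

write_run_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_graphml(out$graph, file.path(out_dir, "network.graphml"))
  write_vtk_polydata(out$graph, file.path(out_dir, "network.vtk"), out$flow)
  write_flow_csv(out$graph, out$flow, file.path(out_dir, "flow"))
  write_map_nifti(out$maps$phi_P, file.path(out_dir, "phi_P.nii.gz"),
                  out$maps$lattice)
  write_map_nifti(out$maps$F, file.path(out_dir, "F.nii.gz"),
                  out$maps$lattice)
  write_map_nifti(out$maps$K_PS, file.path(out_dir, "K_PS.nii.gz"),
                  out$maps$lattice)
  write_series_nifti(out$series, file.path(out_dir, "dce.nii.gz"))
  if (!is.null(out$recovered$table))
    write.csv(out$recovered$table, file.path(out_dir, "roi_fits.csv"),
              row.names = FALSE)
  if (!is.null(out$recovered$fits) && is.data.frame(out$recovered$fits))
    write.csv(out$recovered$fits, file.path(out_dir, "voxel_fits.csv"),
              row.names = FALSE)
  manifest <- list(config = out$config,
                   package_version = as.character(utils::packageVersion(
                     "dcephantom")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(out_dir)
}
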