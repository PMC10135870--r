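#' Sample the total-concentration DCE series from a simulation
#'
#' The image signal surrogate per voxel is the total concentration
#' `c_i(t) = phi_P,i c_P,i(t) + phi_I,i c_I,i(t)` (mM), sampled every `dt`
#' seconds on the stored frames. Since `phi_P + phi_I = 1`, a uniform
#' concentration field maps to itself.
#'
#' @param field A `concentration_field` from [simulate_transport()].
#' @param maps `parameter_maps` with `phi_P` / `phi_I`.
#' @param dt Frame interval in s; must be a multiple of the stored frame
#'   interval and lie within the simulated horizon.
#' @param feeding_point Position (um, length 3) of the contrast feeding
#'   artery, carried along for distance-based flow rescaling.
#' @return A `dce_series`: matrix `c` (voxels x frames, mM), `times`,
#'   lattice, feeding point.
#' @export
total_concentration_series <- function(field, maps, dt = 1,
                                       feeding_point = NULL) {
  tms <- field$times
  want <- seq(0, max(tms), by = dt)
  ok <- vapply(want, function(w) any(abs(tms - w) < 1e-9), logical(1))
  if (!all(ok))
    stop_invalid("requested stamps not all available in the stored frames")
  sel <- vapply(want, function(w) which.min(abs(tms - w)), integer(1))
  cc <- as.numeric(maps$phi_P) * field$c_P[, sel, drop = FALSE] +
    as.numeric(maps$phi_I) * field$c_I[, sel, drop = FALSE]
  structure(list(c = cc, times = want, lattice = field$lattice,
                 feeding_point = feeding_point),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  cat(sprintf("<dce_series> %d voxels x %d frames, dt = %g s, max c = %.3g mM\n",
              nrow(x$c), ncol(x$c), diff(x$times[1:2]), max(x$c)))
  invisible(x)
}

#' Circular / spherical region of interest on the lattice
#'
#' All voxels whose centre lies within `radius_voxels * l` (Euclidean) of
#' the centre voxel's centre: a disk in 2d, a ball in 3d. Radius 15 in 2d
#' gives the standard 709-voxel (about 2 mm diameter) measurement region.
#'
#' @param center_voxel 0-based index triple of the centre voxel.
#' @param radius_voxels Radius in voxel widths (>= 0).
#' @param lattice A [lattice_spec()].
#' @param label Optional ROI label.
#' @return An object of class `roi`: integer voxel (site) indices plus
#'   geometry attributes.
#' @export
make_circular_roi <- function(center_voxel, radius_voxels, lattice,
                              label = "roi") {
  if (radius_voxels < 0) stop_invalid("roi radius must be >= 0")
  ctr_site <- site_index(lattice, matrix(as.integer(center_voxel), ncol = 3))
  idx <- site_to_idx(lattice, seq_len(lattice$n_voxels))
  dd <- sweep(idx, 2, as.integer(center_voxel))
  sel <- which(rowSums(dd^2) <= radius_voxels^2 + 1e-12)
  structure(sel, class = "roi", label = label,
            center_voxel = as.integer(center_voxel),
            radius_voxels = radius_voxels, lattice = lattice)
}

#' Block-shaped ROI (coarse imaging voxel)
#'
#' Rectangular block of `block_dims` lattice voxels with 0-based corner
#' `corner`; used to emulate coarse acquisition resolutions such as
#' 300 x 300 x 3000 um on a 60 um lattice (5 x 5 x 50 voxels).
#' @param corner 0-based index triple of the lowest corner.
#' @param block_dims Block extent in voxels per axis.
#' @inheritParams make_circular_roi
#' @export
make_block_roi <- function(corner, block_dims, lattice, label = "roi") {
  corner <- as.integer(corner); block_dims <- as.integer(block_dims)
  if (any(block_dims < 1)) stop_invalid("block dims must be >= 1")
  if (any(corner < 0) || any(corner + block_dims > lattice$dims))
    stop_invalid("block ROI exceeds the domain")
  g <- expand.grid(ix = corner[1] + seq_len(block_dims[1]) - 1L,
                   iy = corner[2] + seq_len(block_dims[2]) - 1L,
                   iz = corner[3] + seq_len(block_dims[3]) - 1L)
  structure(site_index(lattice, as.matrix(g)), class = "roi", label = label,
            lattice = lattice)
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> '%s', %d voxels\n", attr(x, "label"), length(x)))
  invisible(x)
}

#' Ground-truth parameters aggregated over an ROI
#'
#' * `phi_P_roi`: volume-weighted mean plasma fraction (total vessel volume
#'   over total ROI volume), so a uniform map gives the same value at every
#'   ROI size;
#' * `K_PS_roi`: plain sum (the exchange rate is extensive);
#' * `F_roi`: sum of the positive fluxes entering the ROI across its
#'   boundary -- interior fluxes cancel and are excluded.
#'
#' @param roi An `roi`.
#' @param maps `parameter_maps` with `phi_P` and `K_PS`.
#' @param graph,flow The vascular graph and its flow state.
#' @return List with `phi_P`, `K_PS`, `F` (um^3/s), `n_voxels`.
#' @export
roi_ground_truth <- function(roi, maps, graph, flow) {
  if (length(roi) == 0) stop_invalid("empty ROI")
  sel <- as.integer(roi)
  phi <- mean(as.numeric(maps$phi_P)[sel])
  K <- if (is.null(maps$K_PS)) 0 else sum(as.numeric(maps$K_PS)[sel])
  inroi <- logical(graph$lattice$n_voxels)
  inroi[sel] <- TRUE
  e <- graph$edges
  nf <- inroi[graph$nodes$site[e$from]]
  nt <- inroi[graph$nodes$site[e$to]]
  # boundary-crossing fluxes, counted when directed into the ROI
  Fin <- sum(pmax(flow$flux[!nf & nt], 0)) +
    sum(pmax(-flow$flux[nf & !nt], 0))
  # arterial roots inside the ROI feed it from outside the domain
  art_in <- which(graph$nodes$root & graph$nodes$kind == "arterial" &
                    inroi[graph$nodes$site])
  if (length(art_in)) {
    net <- node_net_outflux(graph, flow)
    Fin <- Fin + sum(pmax(net[art_in], 0))
  }
  list(phi_P = phi, K_PS = K, F = Fin, n_voxels = length(sel))
}

#' Mean ROI concentration curve
#'
#' Unweighted voxel mean of the total concentration per frame (all voxels
#' have the same volume by construction).
#' @param series A `dce_series`.
#' @param roi An `roi`.
#' @return Numeric vector, one value per frame (mM).
#' @export
roi_curve <- function(series, roi) {
  if (length(roi) == 0) stop_invalid("empty ROI")
  colMeans(series$c[as.integer(roi), , drop = FALSE])
}

#' Add measurement noise to a DCE series
#'
#' Multiplicative Gaussian noise `c * (1 + sigma * eta)` with standard
#' normal `eta`, clipped at zero (the default, matching relative
#' noise-level phrasing), or additive `c + sigma * eta` in mM.
#' @param series A `dce_series` (or plain numeric curve).
#' @param sigma Relative (or absolute, for `mode = "additive"`) noise level.
#' @param seed RNG seed.
#' @param mode `"multiplicative"` or `"additive"`.
#' @return Same shape as the input.
#' @export
add_noise <- function(series, sigma, seed = 1,
                      mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  if (sigma < 0) stop_invalid("noise level must be >= 0")
  vals <- if (inherits(series, "dce_series")) series$c else series
  noisy <- with_seed(seed, {
    eta <- rnorm(length(vals))
    if (mode == "multiplicative") vals * (1 + sigma * eta)
    else vals + sigma * eta
  })
  noisy <- pmax(noisy, 0)
  if (inherits(series, "dce_series")) {
    series$c <- matrix(noisy, nrow(series$c), ncol(series$c))
    series
  } else noisy
}
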