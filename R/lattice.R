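#' Regular lattice specification
#'
#' The simulation domain is a regular lattice of cubic voxels of side
#' `l` micrometres. Vessel nodes sit at voxel centres, so a voxel with index
#' `(i, j, k)` (0-based) has its centre at `(i + 0.5, j + 0.5, k + 0.5) * l`.
#' The voxel volume is `l^3` and the cross-section side `L` equals `l`.
#'
#' @param dims Integer vector `c(nx, ny, nz)`; use `nz = 1` for a 2d slab and
#'   `ny = nz = 1` for a 1d tube.
#' @param l Lattice spacing in um (default 60).
#' @return An object of class `lattice_spec` with fields `dims`, `l`,
#'   `voxel_volume` (um^3) and `n_voxels`.
#' @examples
#' lat <- lattice_spec(c(100, 100, 1))
#' lat$voxel_volume  # 216000 um^3
#' @export
lattice_spec <- function(dims, l = 60) {
  dims <- as.integer(dims)
  if (length(dims) == 1) dims <- c(dims, 1L, 1L)
  if (length(dims) == 2) dims <- c(dims, 1L)
  if (length(dims) != 3 || any(dims < 1))
    stop_invalid("dims must be three integers >= 1")
  if (!is.numeric(l) || l <= 0) stop_invalid("lattice spacing l must be > 0")
  structure(list(dims = dims, l = l, voxel_volume = l^3,
                 n_voxels = prod(dims)),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %d x %d x %d voxels, l = %g um (V = %g um^3)\n",
              x$dims[1], x$dims[2], x$dims[3], x$l, x$voxel_volume))
  invisible(x)
}

#' Voxel addressing helpers
#'
#' Voxels are addressed either by 0-based index triples `(ix, iy, iz)` or
#' by the 1-based linear site index `1 + ix + nx (iy + ny iz)`.
#' `site_index` / `site_to_idx` convert between the two, `idx_to_pos`
#' returns voxel-centre positions in um, and `axis_neighbors` lists the
#' in-domain axis-aligned neighbour indices of one voxel.
#'
#' @param lattice A [lattice_spec()].
#' @param idx Matrix (or vector) of 0-based index triples.
#' @param site Vector of 1-based linear site indices.
#' @return Linear indices, an index matrix, or a position matrix (um).
#' @export
site_index <- function(lattice, idx) {
  idx <- matrix(as.integer(idx), ncol = 3)
  d <- lattice$dims
  if (any(idx < 0) || any(idx[, 1] >= d[1] | idx[, 2] >= d[2] | idx[, 3] >= d[3]))
    stop_invalid("lattice index out of range")
  1L + idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3])
}

#' @rdname site_index
#' @export
site_to_idx <- function(lattice, site) {
  d <- lattice$dims
  s <- as.integer(site) - 1L
  cbind(ix = s %% d[1], iy = (s %/% d[1]) %% d[2], iz = s %/% (d[1] * d[2]))
}

#' @rdname site_index
#' @export
idx_to_pos <- function(lattice, idx) {
  (matrix(as.numeric(idx), ncol = 3) + 0.5) * lattice$l
}

#' @rdname site_index
#' @export
axis_neighbors <- function(lattice, idx) {
  idx <- as.integer(idx)
  d <- lattice$dims
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nb <- sweep(steps, 2, idx, "+")
  keep <- nb[, 1] >= 0 & nb[, 1] < d[1] & nb[, 2] >= 0 & nb[, 2] < d[2] &
    nb[, 3] >= 0 & nb[, 3] < d[3]
  nb[keep, , drop = FALSE]
}

#' Label voxels as normal tissue, tumor rim or necrotic core
#'
#' A spherical tumor of radius `tumor_radius` around `tumor_center` is placed
#' in the domain; voxels whose centre lies within `core_radius` of the centre
#' are labelled necrotic, voxels within `tumor_radius` but outside the core
#' are tumor, all others are normal tissue. Vessel remodeling rules
#' (sprouting probability, degeneration probability, microvascular density)
#' are region specific.
#'
#' @param lattice A [lattice_spec()].
#' @param tumor_center Position in um (length 3); defaults to the domain
#'   centre.
#' @param tumor_radius,core_radius Radii in um, `0 <= core_radius <=
#'   tumor_radius`. A zero tumor radius yields an all-normal map.
#' @return A `region_map`: integer array over the lattice with values
#'   1 = normal, 2 = tumor, 3 = necrotic, plus geometry attributes.
#' @export
build_region_map <- function(lattice, tumor_center = NULL,
                             tumor_radius = 0, core_radius = 0) {
  if (tumor_radius < 0 || core_radius < 0)
    stop_invalid("region radii must be non-negative")
  if (core_radius > tumor_radius)
    stop_invalid("core_radius must not exceed tumor_radius")
  if (is.null(tumor_center)) tumor_center <- lattice$dims * lattice$l / 2
  d <- lattice$dims
  ctr <- matrix(tumor_center, nrow = lattice$n_voxels, ncol = 3, byrow = TRUE)
  pos <- idx_to_pos(lattice, site_to_idx(lattice, seq_len(lattice$n_voxels)))
  dist <- sqrt(rowSums((pos - ctr)^2))
  lab <- rep(1L, lattice$n_voxels)
  lab[dist <= tumor_radius] <- 2L
  lab[dist <= core_radius] <- 3L
  structure(array(lab, dim = d),
            class = "region_map", lattice = lattice,
            tumor_center = tumor_center, tumor_radius = tumor_radius,
            core_radius = core_radius,
            labels = c("normal", "tumor", "necrotic"))
}

#' @export
print.region_map <- function(x, ...) {
  tab <- tabulate(as.integer(x), nbins = 3)
  cat(sprintf("<region_map> normal %d | tumor %d | necrotic %d voxels\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

# Region label (integer) at given site indices; a NULL map means all normal.
region_at <- function(regions, site) {
  if (is.null(regions)) return(rep(1L, length(site)))
  as.integer(regions)[site]
}
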