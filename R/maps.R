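#' Ground-truth voxel parameter maps
#'
#' Per-voxel maps derived from the vascular graph and its flow solution.
#' Each edge contributes half of its cylinder volume and half of its lateral
#' surface to each endpoint voxel; multiplicity-`n` edges count `n` times.
#'
#' * plasma volume fraction
#'   `phi_P,i = pi / (2 l^2) * sum_j n_ij r_ij^2`, and `phi_I = 1 - phi_P`;
#' * flow `F_i = sum_j max(f_ji, 0)`, the sum of fluxes entering voxel `i`;
#' * exchange rate
#'   `K_PS,i = sum_j n_ij P_i pi l r_ij` (um^3/s), i.e. permeability times
#'   half the lateral surface `2 pi r l` of each incident vessel, with the
#'   voxel's regional permeability; the volumetric rate is
#'   `k_PS = K_PS / V_i` (1/s).
#'
#' @param graph A `vascular_graph` with radii assigned.
#' @param flow A `flow_state` (for `flow_map`).
#' @param P Permeability in um/s: a scalar, or a named vector
#'   `c(normal=, tumor=, necrotic=)` resolved through `regions`.
#' @param regions Optional `region_map` when `P` is region specific.
#' @return `plasma_fraction_map` returns an object of class
#'   `parameter_maps` holding arrays `phi_P` and `phi_I` over the lattice;
#'   `flow_map` and `exchange_map` return arrays (um^3/s).
#' @examples
#' tube <- tube_network(10)
#' m <- plasma_fraction_map(tube)
#' m$phi_P[5, 1, 1]  # interior voxel: pi * 16 / 3600 ~ 0.014
#' @export
plasma_fraction_map <- function(graph) {
  e <- graph$edges
  if (anyNA(e$radius_um)) stop_invalid("radii not assigned")
  lat <- graph$lattice
  contrib <- e$multiplicity * e$radius_um^2
  per_node <- numeric(nrow(graph$nodes))
  agg <- tapply(c(contrib, contrib), c(e$from, e$to), sum)
  per_node[as.integer(names(agg))] <- agg
  phi <- numeric(lat$n_voxels)
  phi[graph$nodes$site] <- pi / (2 * lat$l^2) * per_node
  over <- which(phi > 1 + 1e-12)
  if (length(over))
    stop_invalid("plasma volume fraction exceeds 1 in voxel(s) %s",
                 paste(head(over, 5), collapse = ", "))
  structure(list(phi_P = array(phi, lat$dims),
                 phi_I = array(1 - phi, lat$dims),
                 lattice = lat),
            class = "parameter_maps")
}

#' @rdname plasma_fraction_map
#' @export
flow_map <- function(graph, flow) {
  lat <- graph$lattice
  e <- graph$edges
  entering <- c(pmax(flow$flux, 0), pmax(-flow$flux, 0))
  at <- c(e$to, e$from)
  per_node <- numeric(nrow(graph$nodes))
  agg <- tapply(entering, at, sum)
  per_node[as.integer(names(agg))] <- agg
  Fv <- numeric(lat$n_voxels)
  Fv[graph$nodes$site] <- per_node
  array(Fv, lat$dims)
}

#' @rdname plasma_fraction_map
#' @export
exchange_map <- function(graph, P, regions = NULL) {
  lat <- graph$lattice
  e <- graph$edges
  if (any(P < 0)) stop_invalid("permeability must be >= 0")
  if (length(P) > 1) {
    if (is.null(names(P))) stop_invalid("region-specific P must be named")
    P_vox <- unname(P[c("normal", "tumor", "necrotic")][
      region_at(regions, graph$nodes$site)])
  } else {
    P_vox <- rep(P, nrow(graph$nodes))
  }
  half_surface <- e$multiplicity * pi * lat$l * e$radius_um
  per_node <- numeric(nrow(graph$nodes))
  agg <- tapply(c(half_surface, half_surface), c(e$from, e$to), sum)
  per_node[as.integer(names(agg))] <- agg
  K <- numeric(lat$n_voxels)
  K[graph$nodes$site] <- per_node * P_vox
  array(K, lat$dims)
}

#' Assemble the full ground-truth map set
#'
#' Convenience wrapper returning `phi_P`, `phi_I`, `F` and `K_PS` arrays in
#' one `parameter_maps` object.
#' @inheritParams plasma_fraction_map
#' @export
ground_truth_maps <- function(graph, flow, P = 0, regions = NULL) {
  m <- plasma_fraction_map(graph)
  m$F <- flow_map(graph, flow)
  m$K_PS <- exchange_map(graph, P, regions)
  m
}

#' @export
print.parameter_maps <- function(x, ...) {
  d <- x$lattice$dims
  cat(sprintf("<parameter_maps> %d x %d x %d; phi_P in [%.3g, %.3g]",
              d[1], d[2], d[3], min(x$phi_P), max(x$phi_P)))
  if (!is.null(x$F)) cat(sprintf("; F max %.3g um^3/s", max(x$F)))
  if (!is.null(x$K_PS)) cat(sprintf("; K_PS max %.3g um^3/s", max(x$K_PS)))
  cat("\n")
  invisible(x)
}
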