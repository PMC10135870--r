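#' Lattice-embedded vascular graphs
#'
#' A `vascular_graph` holds the vessel network: one node per occupied lattice
#' site (at the voxel centre) and cylindrical edges of length `l` between
#' axis-aligned neighbour sites. Tree edges form the arterial and venous
#' hierarchies; capillary edges connect the two trees and carry a
#' multiplicity `n` standing for `n` parallel vessels of the same radius
#' (contributing `n` times the conductance, lateral surface and
#' cross-section volume).
#'
#' @section Structure:
#' * `nodes`: data frame with 0-based lattice indices `ix, iy, iz`, linear
#'   `site`, `kind` (`"arterial"`, `"venous"`, `"junction"`) and `root` flag.
#' * `edges`: data frame with node ids `from, to`, `radius_um`,
#'   `multiplicity`, `kind` (`"tree"` or `"capillary"`).
#'
#' @name vascular_graph
NULL

new_vascular_graph <- function(lattice, nodes, edges) {
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(lattice = lattice, nodes = nodes, edges = edges),
            class = "vascular_graph")
}

empty_nodes <- function() {
  data.frame(ix = integer(), iy = integer(), iz = integer(),
             site = integer(), kind = character(), root = logical())
}

empty_edges <- function() {
  data.frame(from = integer(), to = integer(), radius_um = numeric(),
             multiplicity = integer(), kind = character())
}

#' @export
print.vascular_graph <- function(x, ...) {
  cat(sprintf(paste0("<vascular_graph> %d nodes (%d arterial, %d venous, ",
                     "%d junction), %d edges (%d tree, %d capillary)\n"),
              nrow(x$nodes), sum(x$nodes$kind == "arterial"),
              sum(x$nodes$kind == "venous"), sum(x$nodes$kind == "junction"),
              nrow(x$edges), sum(x$edges$kind == "tree"),
              sum(x$edges$kind == "capillary")))
  invisible(x)
}

# Node positions in um (n x 3 matrix).
node_positions <- function(graph) {
  idx_to_pos(graph$lattice, as.matrix(graph$nodes[, c("ix", "iy", "iz")]))
}

# Node degree counting every incident edge once (multiplicity ignored).
node_degree <- function(graph) {
  tabulate(c(graph$edges$from, graph$edges$to), nbins = nrow(graph$nodes))
}

# Nodes eligible for capillary sprouting: terminal or pass-through tree
# segments (tree-degree <= 2, i.e. not a branch hub), non-root, without an
# incident capillary yet. A node becomes eligible again when its capillary
# degenerates.
tree_tips <- function(graph) {
  tree_e <- graph$edges[graph$edges$kind == "tree", , drop = FALSE]
  cap_e <- graph$edges[graph$edges$kind == "capillary", , drop = FALSE]
  nb <- nrow(graph$nodes)
  tdeg <- tabulate(c(tree_e$from, tree_e$to), nbins = nb)
  has_cap <- logical(nb)
  has_cap[c(cap_e$from, cap_e$to)] <- TRUE
  which(tdeg >= 1 & tdeg <= 2 & !has_cap & !graph$nodes$root &
          graph$nodes$kind %in% c("arterial", "venous"))
}

#' Build the 1d tube benchmark network
#'
#' A straight chain of `n` voxels along x containing a single cylindrical
#' capillary of constant radius `r` um: the analytic traveling-wave
#' benchmark. The first node is the arterial root (feeding point), the last
#' the venous root. The interior plasma volume fraction is
#' `pi * r^2 / l^2` (about 0.014 for the defaults r = 4, l = 60).
#'
#' @param n_voxels Number of voxels along the tube (default 100, i.e. 6 mm).
#' @param l Lattice spacing um.
#' @param r Capillary radius um.
#' @return A `vascular_graph`.
#' @export
tube_network <- function(n_voxels = 100, l = 60, r = 4) {
  if (n_voxels < 2) stop_invalid("tube needs >= 2 voxels")
  lat <- lattice_spec(c(n_voxels, 1, 1), l)
  nodes <- data.frame(ix = 0:(n_voxels - 1), iy = 0L, iz = 0L,
                      site = seq_len(n_voxels),
                      kind = c("arterial",
                               rep("junction", n_voxels - 2), "venous"),
                      root = c(TRUE, rep(FALSE, n_voxels - 2), TRUE))
  edges <- data.frame(from = 1:(n_voxels - 1), to = 2:n_voxels,
                      radius_um = r, multiplicity = 1L, kind = "capillary")
  new_vascular_graph(lat, nodes, edges)
}

#' Convert between vascular graphs and igraph objects
#'
#' The igraph form carries all node and edge attributes and is used for
#' GraphML round trips and path queries.
#' @param graph A `vascular_graph`.
#' @return `as_igraph` returns an [igraph::graph_from_data_frame()] object.
#' @export
as_igraph <- function(graph) {
  v <- cbind(name = as.character(seq_len(nrow(graph$nodes))), graph$nodes)
  igraph::graph_from_data_frame(graph$edges, directed = FALSE, vertices = v)
}

#' Write / read a vascular graph as GraphML
#'
#' Node attributes: lattice indices, kind, root flag; edge attributes:
#' radius_um, multiplicity, kind. The lattice spacing and dims are stored as
#' graph attributes so the round trip is complete.
#' @param graph A `vascular_graph`.
#' @param path Output file.
#' @export
write_graphml <- function(graph, path) {
  g <- as_igraph(graph)
  g <- igraph::set_graph_attr(g, "lattice_l", graph$lattice$l)
  g <- igraph::set_graph_attr(g, "lattice_dims",
                              paste(graph$lattice$dims, collapse = " "))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  dims <- as.integer(strsplit(igraph::graph_attr(g, "lattice_dims"), " ")[[1]])
  lat <- lattice_spec(dims, igraph::graph_attr(g, "lattice_l"))
  vd <- igraph::as_data_frame(g, "vertices")
  ord <- order(as.integer(vd$name))
  vd <- vd[ord, ]
  remap <- match(seq_len(nrow(vd)), as.integer(vd$name))  # identity after sort
  nodes <- data.frame(ix = as.integer(vd$ix), iy = as.integer(vd$iy),
                      iz = as.integer(vd$iz), site = as.integer(vd$site),
                      kind = vd$kind, root = as.logical(vd$root))
  ed <- igraph::as_data_frame(g, "edges")
  edges <- data.frame(from = as.integer(ed$from), to = as.integer(ed$to),
                      radius_um = as.numeric(ed$radius_um),
                      multiplicity = as.integer(ed$multiplicity),
                      kind = ed$kind)
  new_vascular_graph(lat, nodes, edges)
}

#' Export a vascular graph as VTK legacy polydata
#'
#' Writes an ASCII VTK file with one polyline per edge and point/cell data
#' (radius, multiplicity) for visualization in ParaView and friends.
#' @param graph A `vascular_graph`.
#' @param path Output `.vtk` file.
#' @param flow Optional `flow_state`; if given, per-edge flux and wall shear
#'   stress are added as cell data.
#' @export
write_vtk_polydata <- function(graph, path, flow = NULL) {
  pos <- node_positions(graph)
  e <- graph$edges
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vascular network", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nrow(pos))),
             con)
  writeLines(apply(pos, 1, paste, collapse = " "), con)
  writeLines(sprintf("LINES %d %d", nrow(e), 3 * nrow(e)), con)
  writeLines(sprintf("2 %d %d", e$from - 1L, e$to - 1L), con)
  writeLines(sprintf("CELL_DATA %d", nrow(e)), con)
  writeLines(c("SCALARS radius_um float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(e$radius_um), con)
  writeLines(c("SCALARS multiplicity float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.numeric(e$multiplicity)), con)
  if (!is.null(flow)) {
    writeLines(c("SCALARS flux_um3_s float 1", "LOOKUP_TABLE default"), con)
    writeLines(format(flow$flux), con)
    writeLines(c("SCALARS wss_Pa float 1", "LOOKUP_TABLE default"), con)
    writeLines(format(flow$wss), con)
  }
  invisible(path)
}
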