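#' Pressure boundary conditions for the network flow solve
#'
#' Fixed pressures at the arterial and venous roots and a constant effective
#' blood viscosity. Defaults are physiological for the arteriolar/venular
#' scale: 60 mmHg (7999 Pa) inlet, 15 mmHg (2000 Pa) outlet, and
#' `mu = 4e-3` Pa s; only the pressure drop matters for the linear solve.
#'
#' @param p_arterial,p_venous Root pressures in Pa (`p_arterial > p_venous`).
#' @param mu Effective dynamic viscosity in Pa s.
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(p_arterial = 7999, p_venous = 2000,
                                mu = 4e-3) {
  if (p_arterial <= p_venous)
    stop_invalid("arterial pressure must exceed venous pressure")
  if (mu <= 0) stop_invalid("viscosity must be > 0")
  structure(list(p_arterial = p_arterial, p_venous = p_venous, mu = mu),
            class = "boundary_conditions")
}

#' Solve steady Poiseuille flow on a vascular graph
#'
#' Each edge of radius `r`, length `l` and multiplicity `n` is a Poiseuille
#' resistor of conductance `g = n * pi * r^4 / (8 * mu * l)` (um^3 / (Pa s)).
#' Node pressures solve the sparse Kirchhoff system `G p = b` with Dirichlet
#' pressures at the roots; edge fluxes are `f_ij = g_ij (p_i - p_j)`
#' (um^3/s, positive from `from` to `to`). Per parallel vessel, velocity is
#' `|f| / (n pi r^2)` and wall shear stress `4 mu |f| / (n pi r^3)`.
#'
#' @param graph A `vascular_graph` with radii assigned; every connected
#'   component must contain at least one root.
#' @param bcs A [boundary_conditions()].
#' @return A `flow_state`: list with `pressure` (Pa per node), `flux`
#'   (um^3/s per edge, signed from->to), `velocity` (um/s), `wss` (Pa) and
#'   `mu`; attribute `root_inflow` holds the total inflow at arterial roots.
#' @export
solve_flow <- function(graph, bcs = boundary_conditions()) {
  e <- graph$edges
  nds <- graph$nodes
  nn <- nrow(nds)
  if (nrow(e) == 0) stop_invalid("graph has no edges")
  if (anyNA(e$radius_um)) stop_invalid("radii not assigned; call assign_radii()")
  if (any(e$radius_um <= 0)) stop_invalid("edge radii must be > 0")
  l <- graph$lattice$l
  g <- e$multiplicity * pi * e$radius_um^4 / (8 * bcs$mu * l)

  fixed <- nds$root
  p_fix <- ifelse(nds$kind == "arterial", bcs$p_arterial, bcs$p_venous)
  if (!any(fixed)) stop_invalid("no pressure-fixed root nodes")

  # check every component touches a root
  comp <- igraph::components(as_igraph(graph))$membership
  root_comps <- unique(comp[fixed])
  floating <- which(!(comp %in% root_comps))
  if (length(floating))
    stop_invalid("component without root contains nodes: %s",
                 paste(head(floating, 10), collapse = ", "))

  ii <- c(e$from, e$to, e$from, e$to)
  jj <- c(e$to, e$from, e$from, e$to)
  xx <- c(-g, -g, g, g)
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))
  free <- which(!fixed)
  p <- p_fix
  if (length(free)) {
    rhs <- -L[free, fixed, drop = FALSE] %*% p_fix[fixed]
    p[free] <- as.numeric(Matrix::solve(L[free, free], rhs))
  }
  flux <- g * (p[e$from] - p[e$to])
  vel <- abs(flux) / (e$multiplicity * pi * e$radius_um^2)
  wss <- 4 * bcs$mu * abs(flux) / (e$multiplicity * pi * e$radius_um^3)

  fs <- structure(list(pressure = p, flux = flux, velocity = vel, wss = wss,
                       mu = bcs$mu),
                  class = "flow_state")
  art <- which(nds$root & nds$kind == "arterial")
  net_out <- node_net_outflux(graph, fs)
  attr(fs, "root_inflow") <- sum(pmax(net_out[art], 0))
  fs
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state> %d node pressures, %d edge fluxes; max |f| = %.3g um^3/s, root inflow = %.3g um^3/s\n",
              length(x$pressure), length(x$flux), max(abs(x$flux)),
              attr(x, "root_inflow")))
  invisible(x)
}

# Net outward flux per node (positive = node exports into the network).
node_net_outflux <- function(graph, flow) {
  e <- graph$edges
  out <- numeric(nrow(graph$nodes))
  agg <- tapply(c(flow$flux, -flow$flux), c(e$from, e$to), sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' Maximum Kirchhoff residual over interior nodes
#'
#' Returns `max_i |sum_j f_ji|` over all non-root nodes: the mass-defect of
#' the linear solve, in um^3/s.
#' @param flow A `flow_state`.
#' @param graph The matching `vascular_graph`.
#' @export
kirchhoff_residual <- function(flow, graph) {
  net <- node_net_outflux(graph, flow)
  interior <- !graph$nodes$root
  if (!any(interior)) return(0)
  max(abs(net[interior]))
}

#' Recompute per-vessel velocity and wall shear stress
#'
#' For an edge of multiplicity `n` the flux splits over `n` identical
#' parallel vessels, so per vessel `v = |f| / (n pi r^2)` and
#' `tau = 4 mu |f| / (n pi r^3)`.
#' @param flow A `flow_state` with fluxes.
#' @param graph The matching graph.
#' @param mu Viscosity in Pa s (defaults to the one used in the solve).
#' @return The `flow_state` with `velocity` and `wss` replaced.
#' @export
edge_velocity_wss <- function(flow, graph, mu = flow$mu) {
  e <- graph$edges
  if (any(e$radius_um <= 0)) stop_invalid("edge radii must be > 0")
  flow$velocity <- abs(flow$flux) / (e$multiplicity * pi * e$radius_um^2)
  flow$wss <- 4 * mu * abs(flow$flux) / (e$multiplicity * pi * e$radius_um^3)
  flow$mu <- mu
  flow
}

#' Per-edge morphometry table
#'
#' One row per edge with diameter (um), per-vessel wall shear stress (Pa),
#' per-vessel flow (um^3/s), velocity (um/s), midpoint pressure (Pa, mean of
#' the endpoint pressures) and the tree side (`arterial`, `venous`,
#' `capillary`). Suitable for log-log regression of flow against diameter,
#' which on hierarchical trees recovers the radius power-law exponent.
#'
#' @param graph A `vascular_graph`.
#' @param flow The matching `flow_state`.
#' @return A data frame.
#' @export
morphometry_table <- function(graph, flow) {
  e <- graph$edges
  side <- ifelse(e$kind == "capillary", "capillary",
                 graph$nodes$kind[e$from])
  data.frame(diameter_um = 2 * e$radius_um,
             wss_Pa = flow$wss,
             flow_um3_s = abs(flow$flux) / e$multiplicity,
             velocity_um_s = flow$velocity,
             pressure_Pa = (flow$pressure[e$from] + flow$pressure[e$to]) / 2,
             multiplicity = e$multiplicity,
             side = side)
}

#' Export flow results as CSV
#'
#' Writes `<stem>_edges.csv` (i, j, radius_um, multiplicity, flux_um3_s,
#' velocity_um_s, wss_Pa) and `<stem>_nodes.csv` (index, pressure_Pa).
#' @param graph A `vascular_graph`; `flow` the matching `flow_state`.
#' @param stem Path stem without extension.
#' @export
write_flow_csv <- function(graph, flow, stem) {
  e <- graph$edges
  write.csv(data.frame(i = e$from, j = e$to, radius_um = e$radius_um,
                       multiplicity = e$multiplicity,
                       flux_um3_s = flow$flux,
                       velocity_um_s = flow$velocity, wss_Pa = flow$wss),
            paste0(stem, "_edges.csv"), row.names = FALSE)
  write.csv(data.frame(index = seq_along(flow$pressure),
                       pressure_Pa = flow$pressure),
            paste0(stem, "_nodes.csv"), row.names = FALSE)
  invisible(stem)
}
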