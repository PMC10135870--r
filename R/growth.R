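#' Remodeling parameters for network construction
#'
#' Region-specific rules controlling capillary sprouting, shear-stress
#' driven degeneration and microvascular density (MVD) during iterative
#' network remodeling:
#'
#' * sprouting probability `p_spr`: normal 0.5, tumor 1, necrotic 0.1;
#' * degeneration probability of a capillary with wall shear stress `tau`:
#'   normal `(tau_max - tau) / (tau_max - tau_min)` clamped to `[0, 1]`,
#'   tumor = normal / 10, necrotic = normal * 10 (clamped);
#' * MVD multiplicity `n` of new capillaries: normal 1, tumor 10,
#'   necrotic 10.
#'
#' The shear-stress bounds `tau_min`/`tau_max` may be fixed (Pa); by default
#' (`NULL`) they adapt each remodeling iteration to the 10th/90th
#' percentiles of the current flowing-capillary wall shear stress, which
#' keeps the degeneration ramp informative at any pressure scale.
#'
#' @param p_spr Named sprouting probabilities per region.
#' @param n_mvd Named capillary multiplicities per region.
#' @param deg_factor Named multipliers applied to the normal degeneration
#'   ramp per region.
#' @param tau_min,tau_max Fixed wall-shear-stress bounds in Pa or `NULL` for
#'   the adaptive percentile rule.
#' @param tau_quantiles Percentiles used by the adaptive rule.
#' @param alpha_art,alpha_ven Radius power-law exponents of the arterial and
#'   venous trees (defaults 3 and 2.7).
#' @param r_cap Capillary radius in um (default 4).
#' @param iterations Remodeling iteration count (default 30).
#' @return An object of class `remodeling_params`.
#' @export
remodeling_params <- function(p_spr = c(normal = 0.5, tumor = 1, necrotic = 0.1),
                              n_mvd = c(normal = 1, tumor = 10, necrotic = 10),
                              deg_factor = c(normal = 1, tumor = 0.1,
                                             necrotic = 10),
                              tau_min = NULL, tau_max = NULL,
                              tau_quantiles = c(0.1, 0.9),
                              alpha_art = 3, alpha_ven = 2.7,
                              r_cap = 4, iterations = 30) {
  if (any(p_spr < 0 | p_spr > 1)) stop_invalid("p_spr must lie in [0, 1]")
  if (any(n_mvd < 1)) stop_invalid("multiplicities must be >= 1")
  if (!is.null(tau_min) && !is.null(tau_max) && tau_max <= tau_min)
    stop_invalid("tau_max must exceed tau_min")
  if (alpha_art < 2 || alpha_art > 3.5 || alpha_ven < 2 || alpha_ven > 3.5)
    stop_invalid("radius exponents must lie in [2, 3.5]")
  if (r_cap <= 0) stop_invalid("r_cap must be > 0")
  if (iterations < 0) stop_invalid("iterations must be >= 0")
  structure(list(p_spr = p_spr,
                 n_mvd = setNames(as.integer(n_mvd), names(n_mvd)),
                 deg_factor = deg_factor,
                 tau_min = tau_min, tau_max = tau_max,
                 tau_quantiles = tau_quantiles,
                 alpha_art = alpha_art, alpha_ven = alpha_ven,
                 r_cap = r_cap, iterations = as.integer(iterations)),
            class = "remodeling_params")
}

#' Grow interpenetrating arterial and venous trees
#'
#' Seeded stochastic dendritic growth by directed branching walkers: each
#' tree maintains a set of active tips that advance one lattice step per
#' sweep in a persistent direction (turning when blocked) and branch
#' sideways with probability `p_branch`. Sweeps alternate between the
#' arterial and venous tree until each reaches its target occupancy
#' fraction or can no longer grow; when a tree stalls below target, fresh
#' walkers are re-seeded on random tree nodes with free neighbours. The
#' thin persistent branches of the two trees interdigitate -- unlike
#' compact cluster growth, which segregates the trees into disjoint
#' territories -- so that many arterial/venous tip pairs end up within
#' capillary-connection range. The two trees are vertex-disjoint and
#' acyclic by construction; capillary connections are added later by
#' [connect_tips()] / [remodel_network()].
#'
#' @param lattice A [lattice_spec()].
#' @param arterial_roots,venous_roots Matrices (or vectors) of 0-based
#'   lattice index triples; all root sites must be distinct.
#' @param seed RNG seed; fixed seed gives a bit-identical graph.
#' @param target_fraction Fraction of lattice sites each tree may occupy
#'   (default 0.4).
#' @param p_branch Per-step probability that an advancing tip spawns a
#'   perpendicular side branch (default 0.1); long persistent branches interdigitate best.
#' @return A `vascular_graph` with tree edges only.
#' @export
grow_trees <- function(lattice, arterial_roots, venous_roots, seed = 1,
                       target_fraction = 0.4, p_branch = 0.1) {
  ar <- matrix(as.integer(arterial_roots), ncol = 3)
  vr <- matrix(as.integer(venous_roots), ncol = 3)
  roots <- rbind(ar, vr)
  sites <- site_index(lattice, roots)
  if (anyDuplicated(sites)) stop_invalid("root sites collide")
  if (lattice$n_voxels < nrow(roots))
    stop_invalid("lattice too small for the requested roots")

  occ <- integer(lattice$n_voxels)          # 0 free, 1 arterial, 2 venous
  kind <- c(rep(1L, nrow(ar)), rep(2L, nrow(vr)))
  occ[sites] <- kind

  nmax <- lattice$n_voxels
  n_ix <- integer(nmax); n_iy <- integer(nmax); n_iz <- integer(nmax)
  n_site <- integer(nmax); n_kind <- integer(nmax); n_root <- logical(nmax)
  nn <- nrow(roots)
  n_ix[1:nn] <- roots[, 1]; n_iy[1:nn] <- roots[, 2]; n_iz[1:nn] <- roots[, 3]
  n_site[1:nn] <- sites; n_kind[1:nn] <- kind; n_root[1:nn] <- TRUE
  from_l <- integer(nmax); to_l <- integer(nmax); ne <- 0L

  target <- max(1, floor(target_fraction * lattice$n_voxels))
  dirs <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  ndim <- sum(lattice$dims > 1)
  usable_dirs <- which(dirs[, 1] * (lattice$dims[1] > 1) +
                         dirs[, 2] * (lattice$dims[2] > 1) +
                         dirs[, 3] * (lattice$dims[3] > 1) != 0)
  perp <- lapply(1:6, function(d)
    setdiff(usable_dirs, c(d, d + c(1L, -1L)[1 + (d %% 2 == 0)])))

  in_domain <- function(ix, iy, iz) {
    ix >= 0 && ix < lattice$dims[1] && iy >= 0 && iy < lattice$dims[2] &&
      iz >= 0 && iz < lattice$dims[3]
  }
  site_of <- function(ix, iy, iz) 1L + ix + lattice$dims[1] *
    (iy + lattice$dims[2] * iz)

  count <- c(sum(kind == 1L), sum(kind == 2L))
  # walkers: per tree, matrix cols (node, dir)
  walkers <- list(NULL, NULL)
  with_seed(seed, {
    for (tr in 1:2) {
      ids <- which(kind == tr)
      walkers[[tr]] <- cbind(node = rep(ids, each = min(ndim * 2, 4)),
                             dir = rep_len(usable_dirs,
                                           length(ids) * min(ndim * 2, 4)))
    }
    advance <- function(tr) {
      w <- walkers[[tr]]
      if (is.null(w) || nrow(w) == 0) return(FALSE)
      keep <- logical(nrow(w)); spawned <- list()
      ord <- sample.int(nrow(w))
      grew_any <- FALSE
      for (q in ord) {
        if (count[tr] >= target) break
        nid <- w[q, 1]; d <- w[q, 2]
        # try persistent direction, then perpendicular turns
        cand_dirs <- c(d, perp[[d]][sample.int(length(perp[[d]]))])
        moved <- FALSE
        for (dd in cand_dirs) {
          ix <- n_ix[nid] + dirs[dd, 1]; iy <- n_iy[nid] + dirs[dd, 2]
          iz <- n_iz[nid] + dirs[dd, 3]
          if (!in_domain(ix, iy, iz)) next
          s <- site_of(ix, iy, iz)
          if (occ[s] != 0L) next
          nn <<- nn + 1L
          n_ix[nn] <<- ix; n_iy[nn] <<- iy; n_iz[nn] <<- iz
          n_site[nn] <<- s; n_kind[nn] <<- tr; n_root[nn] <<- FALSE
          occ[s] <<- tr
          ne <<- ne + 1L
          from_l[ne] <<- nid; to_l[ne] <<- nn
          count[tr] <<- count[tr] + 1L
          w[q, 1] <- nn; w[q, 2] <- dd
          keep[q] <- TRUE; moved <- TRUE; grew_any <- TRUE
          # side branch from the old node
          if (runif(1) < p_branch && length(perp[[dd]]))
            spawned[[length(spawned) + 1L]] <-
              c(nid, perp[[dd]][sample.int(length(perp[[dd]]), 1)])
          break
        }
      }
      walkers[[tr]] <<- rbind(w[keep, , drop = FALSE],
                              do.call(rbind, spawned))
      grew_any
    }
    reseed <- function(tr) {
      ids <- which(n_kind[1:nn] == tr)
      if (length(ids) == 0) return(FALSE)
      pick <- ids[sample.int(length(ids), min(20, length(ids)))]
      ok <- pick[vapply(pick, function(nid) {
        nb <- axis_neighbors(lattice, c(n_ix[nid], n_iy[nid], n_iz[nid]))
        any(occ[site_index(lattice, nb)] == 0L)
      }, logical(1))]
      if (length(ok) == 0) return(FALSE)
      walkers[[tr]] <<- rbind(walkers[[tr]],
                              cbind(ok, sample(usable_dirs, length(ok),
                                               replace = TRUE)))
      TRUE
    }
    stalls <- c(0L, 0L)
    repeat {
      grew <- FALSE
      for (tr in 1:2) {
        if (count[tr] >= target) next
        g1 <- advance(tr)
        if (!g1) {
          stalls[tr] <- stalls[tr] + 1L
          reseed(tr)
        } else {
          grew <- TRUE
          stalls[tr] <- 0L
        }
      }
      if (all(count >= target | stalls > 10L)) break
    }
  })
  nodes <- data.frame(ix = n_ix[1:nn], iy = n_iy[1:nn], iz = n_iz[1:nn],
                      site = n_site[1:nn],
                      kind = c("arterial", "venous")[n_kind[1:nn]],
                      root = n_root[1:nn])
  edges <- if (ne > 0) {
    data.frame(from = from_l[1:ne], to = to_l[1:ne], radius_um = NA_real_,
               multiplicity = 1L, kind = "tree")
  } else empty_edges()
  new_vascular_graph(lattice, nodes, edges)
}

#' Shear-stress dependent capillary degeneration probability
#'
#' Normal tissue follows the linear ramp
#' `(tau_max - tau) / (tau_max - tau_min)` clamped to `[0, 1]`: capillaries
#' with low wall shear stress are likely to collapse, well-perfused ones are
#' kept. In tumor tissue the probability is divided by 10 (PDGF-mediated
#' vessel stabilization), in the necrotic core multiplied by 10 (vessel
#' destruction), each clamped to `[0, 1]`.
#'
#' @param tau Wall shear stress in Pa (vector).
#' @param region Region labels (integer 1/2/3 or names).
#' @param params A [remodeling_params()] with resolved `tau_min`/`tau_max`.
#' @param tau_min,tau_max Override bounds in Pa.
#' @return Probabilities in `[0, 1]`.
#' @export
degeneration_probability <- function(tau, region, params,
                                     tau_min = params$tau_min,
                                     tau_max = params$tau_max) {
  if (is.null(tau_min) || is.null(tau_max))
    stop_invalid("tau_min/tau_max must be given (or resolved adaptively)")
  if (tau_max <= tau_min) stop_invalid("tau_max must exceed tau_min")
  if (is.character(region))
    region <- match(region, c("normal", "tumor", "necrotic"))
  base <- pmin(1, pmax(0, (tau_max - tau) / (tau_max - tau_min)))
  fac <- unname(params$deg_factor[c("normal", "tumor", "necrotic")][region])
  pmin(1, pmax(0, base * fac))
}

#' Connect opposite-tree tips by capillaries
#'
#' Every pair of an arterial and a venous tip (leaf nodes without a
#' capillary yet) that are direct axis neighbours is connected by one
#' capillary edge with the sprouting probability of the local region; tip
#' pairs two lattice steps apart with a free intermediate site axis-adjacent
#' to both are connected through a new junction node at that site. New
#' capillaries get radius `r_cap` and the multiplicity `n` of the region.
#'
#' @param graph A `vascular_graph` containing both trees.
#' @param regions A `region_map` or `NULL` (all normal).
#' @param params A [remodeling_params()].
#' @param seed RNG seed.
#' @return The graph with capillary edges (and junction nodes) added.
#' @export
connect_tips <- function(graph, regions = NULL, params = remodeling_params(),
                         seed = 1) {
  tips <- tree_tips(graph)
  a_tips <- tips[graph$nodes$kind[tips] == "arterial"]
  v_tips <- tips[graph$nodes$kind[tips] == "venous"]
  if (length(a_tips) == 0 || length(v_tips) == 0) return(graph)
  lat <- graph$lattice
  occ <- integer(lat$n_voxels)
  occ[graph$nodes$site] <- 1L
  v_site <- integer(lat$n_voxels)           # venous tip lookup by site
  v_site[graph$nodes$site[v_tips]] <- v_tips
  reg_of <- function(sites) region_at(regions, sites)
  lab <- c("normal", "tumor", "necrotic")

  nodes <- graph$nodes
  e_from <- integer(0); e_to <- integer(0); e_n <- integer(0)
  used_v <- logical(nrow(nodes))            # one new capillary per tip pair pass

  with_seed(seed, {
    for (a in a_tips[order(runif(length(a_tips)))]) {
      aidx <- c(nodes$ix[a], nodes$iy[a], nodes$iz[a])
      nb <- axis_neighbors(lat, aidx)
      nbs <- site_index(lat, nb)
      # direct neighbours first
      direct <- nbs[v_site[nbs] > 0 & !used_v[pmax(v_site[nbs], 1)]]
      connected <- FALSE
      for (sdir in direct) {
        v <- v_site[sdir]
        reg <- reg_of(nodes$site[a])
        if (runif(1) <= params$p_spr[lab[reg]]) {
          e_from <- c(e_from, a); e_to <- c(e_to, v)
          e_n <- c(e_n, params$n_mvd[lab[reg]])
          used_v[v] <- TRUE
          connected <- TRUE
          break
        }
      }
      if (connected) next
      # a free intermediate site axis-adjacent to this tip and a venous tip
      free_nb <- nb[occ[nbs] == 0L, , drop = FALSE]
      if (nrow(free_nb) == 0) next
      for (wi in sample.int(nrow(free_nb))) {
        w <- free_nb[wi, ]
        wnb <- axis_neighbors(lat, w)
        wnbs <- site_index(lat, wnb)
        cand <- wnbs[v_site[wnbs] > 0 & !used_v[pmax(v_site[wnbs], 1)]]
        if (length(cand) == 0) next
        v <- v_site[if (length(cand) == 1) cand else
                      cand[sample.int(length(cand), 1)]]
        ws <- site_index(lat, matrix(w, ncol = 3))
        reg <- reg_of(ws)
        if (runif(1) <= params$p_spr[lab[reg]]) {
          nodes[nrow(nodes) + 1L, ] <- list(w[1], w[2], w[3], ws,
                                            "junction", FALSE)
          j <- nrow(nodes)
          occ[ws] <- 1L
          v_site[nodes$site[v]] <- 0L       # consumed
          nmv <- params$n_mvd[lab[reg]]
          e_from <- c(e_from, a, j); e_to <- c(e_to, j, v)
          e_n <- c(e_n, nmv, nmv)
          used_v[v] <- TRUE
        }
        break                               # one sprouting attempt per tip
      }
    }
  })
  if (length(e_from)) {
    new_e <- data.frame(from = e_from, to = e_to, radius_um = params$r_cap,
                        multiplicity = as.integer(e_n), kind = "capillary")
    graph$edges <- rbind(graph$edges, new_e)
  }
  graph$nodes <- nodes
  graph
}

#' Assign vessel radii by the branching power law
#'
#' Capillary edges keep radius `r_cap`. Tree edges are assigned recursively
#' from the capillaries up to the roots: at every branch point the parent
#' radius satisfies `r_p^alpha = sum_children n_c * r_c^alpha`, with the
#' arterial exponent for the arterial tree and the venous exponent for the
#' venous tree; a multiplicity-`n` capillary counts as `n` identical
#' children. Dead-end tree edges with no downstream capillary get `r_cap`.
#' Radii are capped at `l/2`: on a lattice model the vessel diameter is
#' bounded by the lattice constant, and uncapped power-law radii at the
#' roots would overfill their voxel.
#'
#' @inheritParams connect_tips
#' @param alpha_art,alpha_ven,r_cap Override the values in `params`.
#' @return The graph with `radius_um` filled in on all edges.
#' @export
assign_radii <- function(graph, params = remodeling_params(),
                         alpha_art = params$alpha_art,
                         alpha_ven = params$alpha_ven,
                         r_cap = params$r_cap) {
  e <- graph$edges
  e$radius_um[e$kind == "capillary"] <- r_cap
  nn <- nrow(graph$nodes)

  # capillary load at each node: sum n * r_cap^alpha, evaluated per tree alpha
  cap <- e[e$kind == "capillary", , drop = FALSE]
  tree <- e$kind == "tree"
  for (side in c("arterial", "venous")) {
    alpha <- if (side == "arterial") alpha_art else alpha_ven
    roots <- which(graph$nodes$root & graph$nodes$kind == side)
    if (length(roots) == 0) next
    sel <- which(tree & graph$nodes$kind[e$from] == side)
    if (length(sel) == 0) next
    # adjacency over this tree's edges
    adj <- split(c(sel, sel), c(e$from[sel], e$to[sel]))
    parent_edge <- rep(NA_integer_, nn)
    order_nodes <- integer(0)
    visited <- logical(nn)
    queue <- roots
    visited[roots] <- TRUE
    qh <- 1L
    while (qh <= length(queue)) {            # BFS orientation away from root
      cur <- queue[qh]; qh <- qh + 1L
      order_nodes <- c(order_nodes, cur)
      for (ei in adj[[as.character(cur)]]) {
        other <- if (e$from[ei] == cur) e$to[ei] else e$from[ei]
        if (!visited[other]) {
          visited[other] <- TRUE
          parent_edge[other] <- ei
          queue <- c(queue, other)
        }
      }
    }
    # acyclicity: every tree edge must be the BFS parent edge of one endpoint
    if (sum(!is.na(parent_edge)) != length(sel))
      stop_invalid("cycle detected within the %s tree", side)
    cap_load <- numeric(nn)
    if (nrow(cap)) {
      at <- c(cap$from, cap$to)
      w <- rep(cap$multiplicity * r_cap^alpha, 2)
      keep <- graph$nodes$kind[at] == side
      cl <- tapply(w[keep], at[keep], sum)
      cap_load[as.integer(names(cl))] <- cl
    }
    # accumulate r^alpha from deepest nodes upward
    ralpha <- rep(NA_real_, nrow(e))
    for (nd in rev(order_nodes)) {
      pe <- parent_edge[nd]
      if (is.na(pe)) next
      child_edges <- setdiff(adj[[as.character(nd)]], pe)
      s <- cap_load[nd]
      if (length(child_edges)) s <- s + sum(ralpha[child_edges])
      if (s <= 0) s <- r_cap^alpha          # dead-end branch
      ralpha[pe] <- s
    }
    # the lattice constant bounds the vessel diameter: cap radii at l/2
    e$radius_um[sel] <- pmin(ralpha[sel]^(1 / alpha), graph$lattice$l / 2)
  }
  graph$edges <- e
  graph
}

#' Iterative shear-stress remodeling of the network
#'
#' Repeats for `params$iterations` rounds: sprout capillaries between
#' opposite-tree tips ([connect_tips()]), assign radii ([assign_radii()]),
#' solve flow ([solve_flow()]), then visit all capillary edges in seeded
#' random order and remove each with its [degeneration_probability()]
#' (adaptive percentile shear bounds unless fixed in `params`). After the
#' final round, capillaries carrying no flow (not on any root-to-root
#' pressure path) are pruned, orphan junction nodes removed and radii
#' reassigned, so that every retained capillary is functional.
#'
#' @inheritParams connect_tips
#' @param bcs A [boundary_conditions()] used for the flow solves.
#' @return The remodeled `vascular_graph`; attribute `flow_history` records
#'   total root inflow per iteration. If the trees end up disconnected the
#'   result carries attribute `disconnected = TRUE` (with a warning) rather
#'   than failing silently.
#' @export
remodel_network <- function(graph, regions = NULL,
                            params = remodeling_params(),
                            bcs = boundary_conditions(), seed = 1) {
  if (params$iterations == 0) return(graph)
  lab <- c("normal", "tumor", "necrotic")
  flow_hist <- numeric(0)
  with_seed(seed, {
    for (it in seq_len(params$iterations)) {
      graph <- connect_tips(graph, regions, params,
                            seed = NULL)       # inherits this RNG stream
      graph <- assign_radii(graph, params)
      fs <- solve_flow(graph, bcs)
      flow_hist <- c(flow_hist, attr(fs, "root_inflow"))
      is_cap <- graph$edges$kind == "capillary"
      if (!any(is_cap)) next
      tau <- fs$wss[is_cap]
      flowing <- abs(fs$flux[is_cap]) > 1e-12 * max(abs(fs$flux), 1e-300)
      tmin <- params$tau_min; tmax <- params$tau_max
      if (is.null(tmin) || is.null(tmax)) {
        tq <- if (any(flowing)) quantile(tau[flowing], params$tau_quantiles)
              else c(0, 1)
        tmin <- tq[1]; tmax <- tq[2]
        if (tmax <= tmin) tmax <- tmin + 1e-12
      }
      cap_idx <- which(is_cap)
      cap_idx <- cap_idx[sample.int(length(cap_idx))]
      mids <- (node_positions(graph)[graph$edges$from[cap_idx], , drop = FALSE] +
               node_positions(graph)[graph$edges$to[cap_idx], , drop = FALSE]) / 2
      reg <- if (is.null(regions)) rep(1L, length(cap_idx)) else {
        midx <- pmin(pmax(floor(mids / graph$lattice$l), 0),
                     matrix(graph$lattice$dims - 1L, nrow(mids), 3, byrow = TRUE))
        region_at(regions, site_index(graph$lattice, midx))
      }
      p <- degeneration_probability(fs$wss[cap_idx], reg, params,
                                    tau_min = tmin, tau_max = tmax)
      drop <- cap_idx[runif(length(cap_idx)) < p]
      if (length(drop)) graph <- drop_edges(graph, drop)
    }
  })
  graph <- prune_nonfunctional(graph, bcs, params)
  attr(graph, "flow_history") <- flow_hist
  graph
}

# Remove edges by index, then non-root nodes left without edges.
drop_edges <- function(graph, idx) {
  graph$edges <- graph$edges[-idx, , drop = FALSE]
  deg <- node_degree(graph)
  orphan <- which(deg == 0 & !graph$nodes$root)
  if (length(orphan)) {
    keep <- setdiff(seq_len(nrow(graph$nodes)), orphan)
    remap <- match(seq_len(nrow(graph$nodes)), keep)
    graph$nodes <- graph$nodes[keep, , drop = FALSE]
    graph$edges$from <- remap[graph$edges$from]
    graph$edges$to <- remap[graph$edges$to]
    rownames(graph$nodes) <- NULL
  }
  rownames(graph$edges) <- NULL
  graph
}

# Prune vessels that carry (numerically) no flow: in a resistive network
# an edge lies on an arterial-to-venous pressure path iff its flux is
# nonzero, so zero-flow edges (dead-end capillaries AND dead tree
# branches) are exactly the non-functional parts. The final network is
# fully functional: every retained vessel is perfused, and voxels whose
# vessels all died carry zero plasma volume.
prune_nonfunctional <- function(graph, bcs, params) {
  if (!nrow(graph$edges)) return(graph)
  graph <- assign_radii(graph, params)
  fs <- solve_flow(graph, bcs)
  fmax <- max(abs(fs$flux), 1e-300)
  dead <- which(abs(fs$flux) <= 1e-10 * fmax)
  if (length(dead) == nrow(graph$edges)) {
    warning("arterial and venous roots are no longer connected by flow")
    attr(graph, "disconnected") <- TRUE
    return(graph)
  }
  if (length(dead)) graph <- drop_edges(graph, dead)
  graph <- assign_radii(graph, params)
  fs2 <- solve_flow(graph, bcs)
  if (attr(fs2, "root_inflow") <= 0) {
    warning("arterial and venous roots are no longer connected by flow")
    attr(graph, "disconnected") <- TRUE
  }
  graph
}
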