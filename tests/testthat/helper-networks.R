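# Shared fixtures, built in code and cached for the session. The heavier
# networks (the 100x100 benchmark realization) are computed once and reused
# across test files.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# raw population AIF shared by all fitting tests
fixture_aif <- function() cached("aif", function() aif_population())

# 1d tube + solved flow at the benchmark conditions (r = 4 um, l = 60 um,
# F = 1e4 um^3/s)
fixture_tube <- function(n = 100, F_target = 1e4, l = 60, r = 4) {
  key <- sprintf("tube_%d_%g_%g_%g", n, F_target, l, r)
  cached(key, function() {
    graph <- tube_network(n, l = l, r = r)
    g_edge <- pi * r^4 / (8 * 4e-3 * l)
    dP <- F_target * (n - 1) / g_edge
    bcs <- boundary_conditions(2000 + dP, 2000, 4e-3)
    flow <- solve_flow(graph, bcs)
    list(graph = graph, bcs = bcs, flow = flow, F_target = F_target,
         phi = pi * r^2 / l^2)
  })
}

# tube DCE series for given permeability (simulation + sampling)
fixture_tube_series <- function(P = 0, T_total = 300) {
  key <- sprintf("tube_series_%g_%g", P, T_total)
  cached(key, function() {
    tb <- fixture_tube()
    maps <- ground_truth_maps(tb$graph, tb$flow, P)
    field <- simulate_transport(tb$graph, tb$flow, maps,
                                transport_params(P = P, T_total = T_total),
                                fixture_aif())
    series <- total_concentration_series(field, maps, 1,
                                         feeding_point = c(30, 30, 30))
    list(tube = tb, maps = maps, field = field, series = series)
  })
}

# Hierarchical comb network: an arterial trunk feeding n_teeth parallel
# terminal branches, each ending in one capillary to a mirrored venous
# collector. Tooth fluxes are near-equal, so flow follows diameter^alpha
# along the trunks by construction of the radius power law.
fixture_comb <- function(n_teeth = 16, tooth_len = 9) {
  key <- sprintf("comb_%d_%d", n_teeth, tooth_len)
  cached(key, function() {
    nx <- tooth_len + 2L
    ny <- 2L * n_teeth
    lat <- lattice_spec(c(nx, ny, 1))
    idmap <- new.env(parent = emptyenv())
    nl <- list(); nid <- 0L
    addn <- function(ix, iy, kind, root = FALSE) {
      nid <<- nid + 1L
      nl[[nid]] <<- data.frame(ix = ix, iy = iy, iz = 0L,
                               site = 1L + ix + nx * iy,
                               kind = kind, root = root)
      assign(paste(ix, iy), nid, idmap)
      nid
    }
    getn <- function(ix, iy) get(paste(ix, iy), idmap)
    for (y in 0:(ny - 1L)) addn(0L, y, "arterial", y == 0L)
    for (y in 0:(ny - 1L)) addn(nx - 1L, y, "venous", y == ny - 1L)
    el <- list(); ne <- 0L
    adde <- function(a, b, kind) {
      ne <<- ne + 1L
      el[[ne]] <<- data.frame(from = a, to = b, radius_um = NA_real_,
                              multiplicity = 1L, kind = kind)
    }
    for (y in 0:(ny - 2L)) {
      adde(getn(0L, y), getn(0L, y + 1L), "tree")
      adde(getn(nx - 1L, y), getn(nx - 1L, y + 1L), "tree")
    }
    for (k in 0:(n_teeth - 1L)) {
      ya <- 2L * k; yv <- 2L * k + 1L
      prev <- getn(0L, ya)
      for (xx in 1:(nx - 2L)) {
        cur <- addn(xx, ya, "arterial")
        adde(prev, cur, "tree")
        prev <- cur
      }
      cur <- addn(nx - 2L, yv, "venous")
      adde(getn(nx - 1L, yv), cur, "tree")
      adde(getn(nx - 2L, ya), cur, "capillary")
    }
    graph <- dcephantom:::new_vascular_graph(lat, do.call(rbind, nl),
                                             do.call(rbind, el))
    graph <- assign_radii(graph, remodeling_params())
    bcs <- boundary_conditions()
    list(graph = graph, bcs = bcs, flow = solve_flow(graph, bcs))
  })
}

# small remodeled 2d network for structural tests
fixture_small_grid <- function(seed = 7) {
  key <- sprintf("grid40_%d", seed)
  cached(key, function() {
    lat <- lattice_spec(c(40, 40, 1))
    regions <- build_region_map(lat, c(1800, 1800, 30), 600, 300)
    g <- grow_trees(lat, matrix(c(20L, 20L, 0L), 1),
                    rbind(c(0L, 0L, 0L), c(39L, 39L, 0L)), seed = seed)
    bcs <- boundary_conditions(3000, 2000)
    gr <- remodel_network(g, regions, remodeling_params(iterations = 15),
                          bcs, seed = seed)
    list(lattice = lat, regions = regions, raw = g, graph = gr, bcs = bcs,
         flow = solve_flow(gr, bcs))
  })
}

# the frozen 2d benchmark realization (seed 11) used for the multi-voxel
# ROI protocol and the map-range checks; heavy, built once
fixture_grid2d <- function() {
  cached("grid2d_seed11", function() {
    lat <- lattice_spec(c(100, 100, 1))
    regions <- build_region_map(lat, c(30.5, 70.5, 0.5) * 60, 900, 450)
    g <- grow_trees(lat, matrix(c(50L, 50L, 0L), 1),
                    rbind(c(0L, 0L, 0L), c(99L, 0L, 0L),
                          c(0L, 99L, 0L), c(99L, 99L, 0L)), seed = 11)
    bcs <- boundary_conditions(3000, 2000)
    graph <- remodel_network(g, regions, remodeling_params(iterations = 30),
                             bcs, seed = 11)
    flow <- solve_flow(graph, bcs)
    maps <- ground_truth_maps(graph, flow, P = 0, regions)
    field <- simulate_transport(graph, flow, maps,
                                transport_params(P = 0, T_total = 300),
                                fixture_aif())
    series <- total_concentration_series(field, maps, 1,
                                         feeding_point = c(50.5, 50.5, 0.5) * 60)
    rois <- list(make_circular_roi(c(30, 70, 0), 15, lat, "I"),
                 make_circular_roi(c(71, 59, 0), 15, lat, "II"),
                 make_circular_roi(c(29, 29, 0), 15, lat, "III"),
                 make_circular_roi(c(83, 17, 0), 15, lat, "IV"))
    list(lattice = lat, regions = regions, graph = graph, flow = flow,
         maps = maps, field = field, series = series, rois = rois)
  })
}
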