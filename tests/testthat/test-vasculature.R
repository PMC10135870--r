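test_that("tree growth is seeded, axis-aligned, vertex-disjoint and acyclic", {
  lat <- lattice_spec(c(20, 20, 1))
  ar <- matrix(c(10L, 10L, 0L), 1)
  vr <- rbind(c(0L, 0L, 0L), c(19L, 19L, 0L))
  g1 <- grow_trees(lat, ar, vr, seed = 3)
  g2 <- grow_trees(lat, ar, vr, seed = 3)
  expect_identical(g1, g2)                   # bit-identical for fixed seed
  g3 <- grow_trees(lat, ar, vr, seed = 4)
  expect_false(identical(g1$nodes, g3$nodes))

  # arterial and venous node sets occupy disjoint sites
  a_sites <- g1$nodes$site[g1$nodes$kind == "arterial"]
  v_sites <- g1$nodes$site[g1$nodes$kind == "venous"]
  expect_length(intersect(a_sites, v_sites), 0)

  # every edge connects axis neighbours one lattice step apart
  di <- abs(g1$nodes$ix[g1$edges$from] - g1$nodes$ix[g1$edges$to])
  dj <- abs(g1$nodes$iy[g1$edges$from] - g1$nodes$iy[g1$edges$to])
  dk <- abs(g1$nodes$iz[g1$edges$from] - g1$nodes$iz[g1$edges$to])
  expect_true(all(di + dj + dk == 1))

  # exhaustive cycle check: each tree is a forest
  ig <- as_igraph(g1)
  expect_equal(igraph::gsize(ig), igraph::gorder(ig) -
                 igraph::components(ig)$no)  # |E| = |V| - #components
  expect_error(grow_trees(lat, ar, ar, seed = 1), "collide")
})

test_that("a single-root one-voxel lattice yields one node and no edges", {
  g <- grow_trees(lattice_spec(c(1, 1, 1)), matrix(c(0L, 0L, 0L), 1),
                  matrix(integer(0), ncol = 3), seed = 1)
  expect_equal(nrow(g$nodes), 1)
  expect_equal(nrow(g$edges), 0)
})

test_that("degeneration probability follows the clamped regional ramp", {
  rp <- remodeling_params(tau_min = 1, tau_max = 3)
  expect_equal(degeneration_probability(3, "normal", rp), 0)
  expect_equal(degeneration_probability(1, "normal", rp), 1)
  expect_equal(degeneration_probability(1, "tumor", rp), 0.1)
  expect_equal(degeneration_probability(2, "necrotic", rp), 1)  # 0.5*10 clamped
  # clamping property over random shear values and all regions
  set.seed(42)
  tau <- runif(200, -1, 6)
  for (reg in c("normal", "tumor", "necrotic")) {
    p <- degeneration_probability(tau, rep(reg, 200), rp)
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_error(degeneration_probability(1, "normal",
                                        remodeling_params(), tau_min = 2,
                                        tau_max = 2), "exceed")
})

test_that("tip connection respects sprouting probability, radius and MVD", {
  rp0 <- remodeling_params(p_spr = c(normal = 0, tumor = 0, necrotic = 0))
  sg <- fixture_small_grid()
  g0 <- connect_tips(sg$raw, sg$regions, rp0, seed = 1)
  expect_identical(g0$edges, sg$raw$edges)   # p_spr = 0: unchanged

  rp1 <- remodeling_params(p_spr = c(normal = 1, tumor = 1, necrotic = 1))
  g1 <- connect_tips(sg$raw, sg$regions, rp1, seed = 1)
  caps <- g1$edges[g1$edges$kind == "capillary", ]
  expect_gt(nrow(caps), 0)
  expect_true(all(caps$radius_um == 4))
  # capillaries sprouted in the tumor rim carry the tumor multiplicity
  rim_sites <- which(as.integer(sg$regions) == 2L)
  from_rim <- g1$nodes$site[caps$from] %in% rim_sites
  expect_true(all(caps$multiplicity[from_rim] == 10))
  expect_true(all(caps$multiplicity %in% c(1L, 10L)))
})

test_that("radius power law holds at branch points and radii stay monotone", {
  rp <- remodeling_params()
  # single capillary child: parent radius equals r_cap
  # two capillary children (n = 1, alpha = 3): parent r = 4 * 2^(1/3)
  lat <- lattice_spec(c(3, 3, 1))
  nodes <- data.frame(ix = c(1L, 1L, 0L, 2L, 0L, 2L),
                      iy = c(0L, 1L, 1L, 1L, 2L, 2L),
                      iz = 0L,
                      site = c(2L, 5L, 4L, 6L, 7L, 9L),
                      kind = c("arterial", "arterial", "arterial",
                               "arterial", "venous", "venous"),
                      root = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  edges <- data.frame(from = c(1L, 2L, 2L, 3L, 4L),
                      to = c(2L, 3L, 4L, 5L, 6L),
                      radius_um = NA_real_, multiplicity = 1L,
                      kind = c("tree", "tree", "tree", "capillary",
                               "capillary"))
  g <- dcephantom:::new_vascular_graph(lat, nodes, edges)
  g <- assign_radii(g, rp)
  expect_equal(g$edges$radius_um[2], 4)               # single capillary child
  expect_equal(g$edges$radius_um[3], 4)
  expect_equal(g$edges$radius_um[1], 4 * 2^(1 / 3), tolerance = 1e-12)

  # arterial (alpha = 3) and venous (alpha = 2.7) defaults differ on the
  # mirrored comb topology
  comb <- fixture_comb()
  e <- comb$graph$edges
  art_trunk <- sort(e$radius_um[e$kind == "tree" &
                                  comb$graph$nodes$kind[e$from] == "arterial"],
                    decreasing = TRUE)
  ven_trunk <- sort(e$radius_um[e$kind == "tree" &
                                  comb$graph$nodes$kind[e$from] == "venous"],
                    decreasing = TRUE)
  expect_false(isTRUE(all.equal(art_trunk[1], ven_trunk[1])))

  # branch-point law on the generated network: at every interior tree node
  # (away from the l/2 radius cap) the largest incident tree radius is the
  # parent and satisfies r_p^alpha >= sum of the children's n r^alpha
  sg <- fixture_small_grid()
  ge <- sg$graph$edges
  alpha <- c(arterial = 3, venous = 2.7)
  for (side in c("arterial", "venous")) {
    sel <- which(ge$kind == "tree" &
                   sg$graph$nodes$kind[ge$from] == side)
    nds <- unique(c(ge$from[sel], ge$to[sel]))
    checked <- 0
    for (nd in nds) {
      inc <- sel[ge$from[sel] == nd | ge$to[sel] == nd]
      if (length(inc) < 2 || any(ge$radius_um[inc] >= 30)) next
      rr <- ge$radius_um[inc]^alpha[side]
      expect_gte(max(rr) + 1e-6, sum(rr) - max(rr))
      checked <- checked + 1
    }
    expect_gt(checked, 3)
  }
})

test_that("remodeling strengthens root-to-root flow and shapes the tumor", {
  sg <- fixture_small_grid()
  # zero iterations leave the graph untouched
  g0 <- remodel_network(sg$raw, sg$regions,
                        remodeling_params(iterations = 0), sg$bcs, seed = 1)
  expect_identical(g0, sg$raw)

  fh <- attr(sg$graph, "flow_history")
  expect_gte(fh[length(fh)], fh[1])          # overall flow grows with iterations

  # every retained edge carries flow (functional network)
  expect_true(all(abs(sg$flow$flux) >
                    1e-10 * max(abs(sg$flow$flux))))

  # capillary density: tumor rim exceeds necrotic core
  caps <- sg$graph$edges[sg$graph$edges$kind == "capillary", ]
  cap_sites <- sg$graph$nodes$site[caps$from]
  reg <- as.integer(sg$regions)
  rim_density <- sum(reg[cap_sites] == 2L) / sum(reg == 2L)
  core_density <- sum(reg[cap_sites] == 3L) / sum(reg == 3L)
  expect_gt(rim_density, core_density)

  # tumor MVD: mean per-voxel sum(n r^2) in the rim exceeds normal tissue
  m <- plasma_fraction_map(sg$graph)
  expect_gt(mean(m$phi_P[reg == 2L]), mean(m$phi_P[reg == 1L]))
})
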