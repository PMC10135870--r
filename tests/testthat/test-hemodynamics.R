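test_that("single-edge flow matches the Poiseuille closed form", {
  tube <- tube_network(2)
  # equal root pressures: zero flux
  fs0 <- solve_flow(tube, boundary_conditions(2000 + 1e-9, 2000))
  expect_lt(abs(fs0$flux[1]), 1e-6)
  # unit pressure drop: f = pi r^4 dP / (8 mu l)
  fs <- solve_flow(tube, boundary_conditions(2001, 2000))
  f_expect <- pi * 4^4 / (8 * 4e-3 * 60)
  expect_equal(fs$flux[1], f_expect, tolerance = 1e-12)
  # wall shear stress: two independent closed forms agree
  # tau = 4 mu |f| / (pi r^3) and tau = r dP / (2 l)
  expect_equal(fs$wss[1], 4 * 4e-3 * f_expect / (pi * 4^3), tolerance = 1e-12)
  expect_equal(fs$wss[1], 4 * 1 / (2 * 60), tolerance = 1e-12)
  expect_equal(fs$velocity[1], f_expect / (pi * 16), tolerance = 1e-12)
})

test_that("multiplicity splits flux over parallel vessels", {
  t1 <- tube_network(2)
  t10 <- tube_network(2)
  t10$edges$multiplicity <- 10L
  bcs <- boundary_conditions(2001, 2000)
  f1 <- solve_flow(t1, bcs)
  f10 <- solve_flow(t10, bcs)
  expect_equal(f10$flux[1], 10 * f1$flux[1])          # 10x conductance
  # per-vessel velocity and wss at the SAME total flux are 1/10
  f10b <- f10; f10b$flux <- f1$flux
  f10b <- edge_velocity_wss(f10b, t10)
  expect_equal(f10b$velocity[1], f1$velocity[1] / 10)
  expect_equal(f10b$wss[1], f1$wss[1] / 10)
})

test_that("Kirchhoff balance holds at junctions and across the network", {
  comb <- fixture_comb()
  fs <- comb$flow
  # residual small relative to the largest flux
  expect_lt(kirchhoff_residual(fs, comb$graph),
            1e-8 * max(abs(fs$flux)))
  # global conservation: arterial inflow equals venous outflow
  net <- dcephantom:::node_net_outflux(comb$graph, fs)
  art <- comb$graph$nodes$root & comb$graph$nodes$kind == "arterial"
  ven <- comb$graph$nodes$root & comb$graph$nodes$kind == "venous"
  expect_equal(sum(net[art]), -sum(net[ven]),
               tolerance = 1e-9)
  # perturbing one flux breaks the balance at its endpoints
  fs2 <- fs
  fs2$flux[5] <- fs2$flux[5] + 1
  expect_gte(kirchhoff_residual(fs2, comb$graph), 1 - 1e-9)
})

test_that("the flow solve is linear in the applied pressure drop", {
  sg <- fixture_small_grid()
  f1 <- solve_flow(sg$graph, boundary_conditions(3000, 2000))
  f2 <- solve_flow(sg$graph, boundary_conditions(5000, 2000))
  expect_equal(f2$flux, 3 * f1$flux, tolerance = 1e-9)
})

test_that("floating root-free components are rejected", {
  tube <- tube_network(4)
  # detach the last two nodes from any root
  tube$nodes$root[4] <- FALSE
  tube$edges <- tube$edges[-2, ]
  expect_error(solve_flow(tube, boundary_conditions()), "without root")
})

test_that("hierarchical trees reproduce the diameter power laws", {
  comb <- fixture_comb()
  mt <- morphometry_table(comb$graph, comb$flow)
  expect_equal(nrow(mt), nrow(comb$graph$edges))
  # single-edge sanity: velocity = flux / (pi r^2)
  expect_equal(mt$velocity_um_s,
               mt$flow_um3_s / (pi * (mt$diameter_um / 2)^2),
               tolerance = 1e-9)
  # log-log slope of flow vs diameter recovers alpha per tree side
  for (side in c("arterial", "venous")) {
    alpha <- if (side == "arterial") 3 else 2.7
    sub <- mt[mt$side == side & mt$flow_um3_s > 1e-9, ]
    slope <- coef(lm(log(flow_um3_s) ~ log(diameter_um), sub))[2]
    expect_lt(abs(slope - alpha), 0.3)
  }
  # velocity increases with diameter on the hierarchy (v ~ d^(alpha-2))
  expect_gt(cor(mt$diameter_um, mt$velocity_um_s, method = "spearman"), 0.5)
})

test_that("wss and velocity rise with diameter on remodeled networks", {
  # in stochastic networks the large vessels carry disproportionately more
  # flow than the idealized power law, so wall shear stress and velocity
  # increase with diameter as observed in vivo
  gd <- fixture_grid2d()
  mt <- morphometry_table(gd$graph, gd$flow)
  mt <- mt[mt$flow_um3_s > 1e-9 * max(mt$flow_um3_s), ]
  expect_gt(cor(mt$diameter_um, mt$wss_Pa, method = "spearman"), 0.3)
  expect_gt(cor(mt$diameter_um, mt$velocity_um_s, method = "spearman"), 0.5)
})

test_that("pressure decreases monotonically from arterial to venous root", {
  comb <- fixture_comb()
  g <- comb$graph; fs <- comb$flow
  # follow the directed flux from the arterial root to a venous root;
  # pressure must not increase along the path
  ig <- as_igraph(g)
  art <- which(g$nodes$root & g$nodes$kind == "arterial")
  ven <- which(g$nodes$root & g$nodes$kind == "venous")
  path <- igraph::shortest_paths(ig, art[1], ven[1])$vpath[[1]]
  p_seq <- fs$pressure[as.integer(igraph::as_ids(path))]
  expect_true(all(diff(p_seq) <= 1e-9))
})
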