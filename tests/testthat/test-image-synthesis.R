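test_that("plasma fraction map matches the cross-section formula", {
  tb <- fixture_tube(10)
  m <- plasma_fraction_map(tb$graph)
  # vessel-free voxel of an empty corner: build a 2-node tube in a 3-wide
  # lattice is not possible here, so check an interior and an end voxel
  expect_equal(m$phi_P[5, 1, 1], pi * 16 / 3600, tolerance = 1e-12)
  expect_equal(m$phi_P[1, 1, 1], pi * 16 / 7200, tolerance = 1e-12)  # half edge
  expect_true(all(m$phi_P + m$phi_I == 1))
  # multiplicity 10 scales the fraction tenfold
  t10 <- tb$graph
  t10$edges$multiplicity <- 10L
  m10 <- plasma_fraction_map(t10)
  expect_equal(m10$phi_P[5, 1, 1], 10 * pi * 16 / 3600, tolerance = 1e-12)
  # overpacked voxel is an error naming the voxel
  t200 <- tb$graph
  t200$edges$multiplicity <- 200L
  expect_error(plasma_fraction_map(t200), "exceeds 1")
})

test_that("flow map sums entering fluxes and respects Kirchhoff", {
  tb <- fixture_tube(10)
  Fm <- flow_map(tb$graph, tb$flow)
  expect_equal(Fm[5, 1, 1], 1e4, tolerance = 1e-6)   # through-tube voxel
  # converging junction: entering flux sum equals leaving flux
  comb <- fixture_comb()
  Fmap <- flow_map(comb$graph, comb$flow)
  net <- dcephantom:::node_net_outflux(comb$graph, comb$flow)
  art <- comb$graph$nodes$root & comb$graph$nodes$kind == "arterial"
  # whole-domain ROI inflow equals total root inflow
  lat <- comb$graph$lattice
  all_roi <- structure(seq_len(lat$n_voxels), class = "roi", label = "all",
                       lattice = lat)
  maps <- ground_truth_maps(comb$graph, comb$flow, 0.1)
  gt <- roi_ground_truth(all_roi, maps, comb$graph, comb$flow)
  # whole-domain ROI inflow equals the total arterial root inflow
  expect_equal(gt$F, attr(comb$flow, "root_inflow"), tolerance = 1e-9)
  expect_equal(sum(pmax(net[art], 0)), attr(comb$flow, "root_inflow"))
})

test_that("total concentration series applies the volume-fraction mix", {
  ts <- fixture_tube_series(P = 0)
  # uniform field maps to itself since phi_P + phi_I = 1
  fld <- ts$field
  fld$c_P[] <- 0.7
  fld$c_I[] <- 0.7
  ser_u <- total_concentration_series(fld, ts$maps, 1)
  expect_true(all(abs(ser_u$c - 0.7) < 1e-12))
  # direct arithmetic: phi_P 0.2, c_P 1, c_I 0.5 -> 0.6
  maps2 <- ts$maps
  maps2$phi_P[] <- 0.2
  maps2$phi_I[] <- 0.8
  fld$c_P[] <- 1
  fld$c_I[] <- 0.5
  ser2 <- total_concentration_series(fld, maps2, 1)
  expect_true(all(abs(ser2$c - 0.6) < 1e-12))
  # frame count: T = 300 s at dt = 1 s
  expect_equal(ncol(ts$series$c), 301)
  expect_error(total_concentration_series(ts$field, ts$maps, 0.25), "stamps")
})

test_that("circular ROIs enumerate the right lattice voxels", {
  lat <- lattice_spec(c(40, 40, 1))
  expect_length(make_circular_roi(c(20, 20, 0), 0, lat), 1)
  expect_length(make_circular_roi(c(20, 20, 0), 1, lat), 5)
  expect_length(make_circular_roi(c(20, 20, 0), 15, lat), 709)
  # oracle: exhaustive integer-point count inside the disk
  count <- sum(outer(-20:19, -20:19,
                     function(dx, dy) dx^2 + dy^2 <= 15^2))
  expect_equal(length(make_circular_roi(c(20, 20, 0), 15, lat)), count)
  expect_error(make_circular_roi(c(50, 20, 0), 3, lat), "range")
})

test_that("ROI ground truth counts boundary fluxes and sums exchange", {
  ts <- fixture_tube_series(P = 0.1)
  tb <- ts$tube
  lat <- tb$graph$lattice
  # single-voxel ROI reduces to the voxel definitions
  roi1 <- make_circular_roi(c(5, 0, 0), 0, lat)
  gt1 <- roi_ground_truth(roi1, ts$maps, tb$graph, tb$flow)
  expect_equal(gt1$phi_P, as.numeric(ts$maps$phi_P[6, 1, 1]))
  expect_equal(gt1$K_PS, as.numeric(ts$maps$K_PS[6, 1, 1]))
  expect_equal(gt1$F, 1e4, tolerance = 1e-6)
  # k-voxel tube segment: interior fluxes are excluded, one flux enters
  roi5 <- make_circular_roi(c(50, 0, 0), 2, lat)
  gt5 <- roi_ground_truth(roi5, ts$maps, tb$graph, tb$flow)
  expect_equal(gt5$F, 1e4, tolerance = 1e-6)
  # exchange rate is extensive: union of disjoint ROIs sums
  roiA <- make_circular_roi(c(20, 0, 0), 1, lat)
  roiB <- make_circular_roi(c(70, 0, 0), 1, lat)
  gtA <- roi_ground_truth(roiA, ts$maps, tb$graph, tb$flow)
  gtB <- roi_ground_truth(roiB, ts$maps, tb$graph, tb$flow)
  roiAB <- structure(c(as.integer(roiA), as.integer(roiB)), class = "roi",
                     label = "AB", lattice = lat)
  gtAB <- roi_ground_truth(roiAB, ts$maps, tb$graph, tb$flow)
  expect_equal(gtAB$K_PS, gtA$K_PS + gtB$K_PS, tolerance = 1e-12)
  expect_error(roi_ground_truth(structure(integer(0), class = "roi"),
                                ts$maps, tb$graph, tb$flow), "empty")
})

test_that("ROI averaging broadens the bolus peak", {
  ts <- fixture_tube_series(P = 0)
  ser <- ts$series
  lat <- ts$tube$graph$lattice
  single <- ser$c[51, ]
  roi <- make_circular_roi(c(50, 0, 0), 10, lat)   # 21 voxels along the tube
  avg <- roi_curve(ser, roi)
  expect_equal(avg, colMeans(ser$c[as.integer(roi), ]))
  width <- function(y) {
    above <- which(y >= max(y) / 2)
    diff(range(ser$times[above]))
  }
  expect_gte(width(avg), width(single))      # averaging delayed waves disperses
  # two-voxel mean sanity
  roi2 <- structure(c(3L, 4L), class = "roi", lattice = lat)
  expect_equal(roi_curve(ser, roi2), (ser$c[3, ] + ser$c[4, ]) / 2)
})

test_that("measurement noise is seeded, multiplicative and calibrated", {
  ts <- fixture_tube_series(P = 0)
  ser <- ts$series
  expect_identical(add_noise(ser, 0, seed = 1)$c, ser$c)
  n1 <- add_noise(ser, 0.2, seed = 9)
  n2 <- add_noise(ser, 0.2, seed = 9)
  expect_identical(n1$c, n2$c)
  expect_false(identical(add_noise(ser, 0.2, seed = 10)$c, n1$c))
  # empirical relative standard deviation over a large constant sample
  flat <- rep(1, 2e5)
  noisy <- add_noise(flat, 0.2, seed = 3)
  expect_equal(sd(noisy / flat), 0.2, tolerance = 0.02)
  expect_true(all(noisy >= 0))
})
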