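test_that("noiseless curves from each forward model are recovered exactly", {
  aif <- fixture_aif()
  V <- 216000
  times <- 0:300
  truth_b <- c(0.1, 2000, 150)
  crv <- brix2_forward(truth_b[1], truth_b[2], truth_b[3], aif, V, times, 8)
  ft <- fit_tk("brix2", times, crv, aif, V, config = list(n_substeps = 8))
  expect_true(all(abs(ft$par - truth_b) / truth_b < 0.01))
  expect_true(ft$converged)
  expect_lt(ft$S, 1e-10)
  expect_equal(ft$F_recov, unname(ft$par[2]))

  truth_t <- c(0.08, 300, 7.5)
  crv_t <- detofts_forward(truth_t[1], truth_t[2], truth_t[3], aif, V,
                           times, 8)
  ft2 <- fit_tk("detofts", times, crv_t, aif, V,
                config = list(n_substeps = 8))
  expect_true(all(abs(ft2$par - truth_t) / truth_t < 0.01))
  expect_equal(ft2$F_recov, unname(ft2$par[1] * V / ft2$par[3]))
})

test_that("degenerate curves are flagged rather than fitted", {
  aif <- fixture_aif()
  z <- fit_tk("brix2", 0:60, rep(0, 61), aif, 216000)
  expect_equal(unname(z$par[1]), 0)
  expect_match(z$flag, "all-zero")
  expect_error(fit_tk("brix2", 0:2, c(0, NA, 1), aif, 216000), "non-finite")
  expect_error(fit_tk("brix2", numeric(0), numeric(0), aif, 216000),
               "length")
})

test_that("a 1d intravascular voxel yields the advective delay and flow", {
  ts <- fixture_tube_series(P = 0)
  ser <- ts$series
  aif <- fixture_aif()
  phi <- ts$tube$phi
  V <- 216000
  # DE-Tofts delay at voxel N equals t0 = N phi_P V / F
  for (N in c(10, 50)) {
    ft <- fit_tk("detofts", ser$times, ser$c[N + 1, ], aif, V)
    expect_equal(unname(ft$par[3]), N * phi * V / 1e4, tolerance = 0.05)
  }
})

test_that("rescaled 1d flow recovers the true flow up to 50 voxels out", {
  ts <- fixture_tube_series(P = 0)
  ser <- ts$series
  aif <- fixture_aif()
  V <- 216000
  ratios <- vapply(c(2, 5, 10, 20, 35, 50), function(N) {
    ft <- fit_tk("detofts", ser$times, ser$c[N + 1, ], aif, V)
    Fr <- rescale_flow(ft$F_recov, c((N + 0.5) * 60, 30, 30),
                       c(30, 30, 30), 60)
    as.numeric(Fr) / 1e4
  }, numeric(1))
  expect_true(all(ratios > 0.9 & ratios < 1.1))
  # without rescaling the error grows with N: F_recov * N stays ~constant,
  # so F_recov itself falls roughly like 1/N
  raw <- ratios / c(2, 5, 10, 20, 35, 50)
  expect_gt(raw[1] / raw[6], 10)
})

test_that("voxelwise map fitting is order-insensitive and flags failures", {
  ts <- fixture_tube_series(P = 0)
  ser <- ts$series
  aif <- fixture_aif()
  vox <- c(11L, 31L, 51L)
  r1 <- fit_parameter_maps(ser, aif, "brix2", voxels = vox)
  r2 <- fit_parameter_maps(ser, aif, "brix2", voxels = rev(vox))
  expect_equal(r1$phi_P, r2$phi_P)           # independent, order-free fits
  expect_equal(r1$F_rescaled, r2$F_rescaled)
  expect_true(all(abs(r1$phi_P[vox] - ts$tube$phi) / ts$tube$phi < 0.2))
  # an all-zero series yields zero maps with flags
  ser0 <- ser
  ser0$c[] <- 0
  r0 <- fit_parameter_maps(ser0, aif, "brix2", voxels = vox)
  expect_true(all(r0$phi_P == 0))
  expect_true(all(r0$fits$flag == "all-zero curve"))
})

test_that("map comparison reports relative errors and rank concordance", {
  lat <- lattice_spec(c(10, 10, 1))
  truth <- list(phi_P = array(runif(100, 0.01, 0.2), c(10, 10, 1)),
                F = array(runif(100, 1e3, 1e5), c(10, 10, 1)),
                K_PS = array(0, c(10, 10, 1)))
  rois <- list(make_circular_roi(c(2, 2, 0), 2, lat, "A"),
               make_circular_roi(c(7, 7, 0), 2, lat, "B"))
  same <- compare_maps(truth, truth, rois)
  expect_true(all(same$table$phi_P_rel_err == 0))
  expect_true(same$ranking_phi_ok && same$ranking_F_ok)
  # uniform 1.27x overestimate: relative error -0.27 everywhere
  rec <- truth
  rec$phi_P <- truth$phi_P * 1.27
  rec$F <- truth$F * 1.27
  cmp <- compare_maps(rec, truth, rois)
  expect_equal(cmp$table$phi_P_rel_err, rep(-0.27, 2), tolerance = 1e-12)
  expect_true(cmp$ranking_phi_ok)
  # zero ground truth: no relative error can be reported
  expect_true(all(is.na(cmp$table$K_PS_rel_err)))
})
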