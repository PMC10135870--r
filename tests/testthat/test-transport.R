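test_that("zero input gives zero concentrations everywhere", {
  tb <- fixture_tube(20)
  maps <- ground_truth_maps(tb$graph, tb$flow, P = 0.1)
  zero_aif <- aif_from_samples(c(0, 300), c(0, 0))
  fld <- simulate_transport(tb$graph, tb$flow, maps,
                            transport_params(P = 0.1, T_total = 30),
                            zero_aif)
  expect_true(all(fld$c_P == 0))
  expect_true(all(fld$c_I == 0))
})

test_that("exchange map evaluates permeability times half surface", {
  tb <- fixture_tube(10)
  # P = 0: strictly intravascular
  expect_true(all(exchange_map(tb$graph, 0) == 0))
  # interior voxel, two edges r = 4, l = 60, n = 1, P = 0.1:
  # K_PS = 2 * 0.1 * pi * 60 * 4
  K <- exchange_map(tb$graph, 0.1)
  expect_equal(K[5, 1, 1], 2 * 0.1 * pi * 60 * 4, tolerance = 1e-12)
  expect_equal(K[5, 1, 1] / 216000, 6.98e-4, tolerance = 1e-2)
})

test_that("1d transport converges first order to the traveling wave", {
  aif <- fixture_aif()
  err <- vapply(c(60, 30), function(l) {
    n <- round(6000 / l)
    tb <- fixture_tube(n, 1e4, l = l)
    maps <- ground_truth_maps(tb$graph, tb$flow, P = 0)
    fld <- simulate_transport(tb$graph, tb$flow, maps,
                              transport_params(P = 0, T_total = 60,
                                               cfl = 0.8, max_dt = 10), aif)
    phi <- pi * 16 / l^2
    vx <- round(3000 / l) + 1
    ana <- tube_analytic((vx - 1) * l, fld$times, 1e4, phi, l, aif) * phi
    num <- fld$c_P[vx, ] * phi
    max(abs(num - ana)) / max(ana)
  }, numeric(1))
  expect_lt(err[1], 0.15)
  expect_gt(err[1] / err[2], 1.5)            # halving the step ~halves the error
  expect_lt(err[1] / err[2], 2.6)
})

test_that("tracer mass is conserved with full in/outflow accounting", {
  aif <- fixture_aif()
  tb <- fixture_tube(50)
  maps <- ground_truth_maps(tb$graph, tb$flow, P = 0.1)
  for (blocked in c(FALSE, TRUE)) {
    fld <- simulate_transport(tb$graph, tb$flow, maps,
                              transport_params(P = 0.1, T_total = 120),
                              aif, block_outflow = blocked)
    mb <- fld$mass[nrow(fld$mass), ]
    residual <- abs(mb$injected - mb$backflow - mb$outflowed - mb$stored) /
      mb$injected
    expect_lt(residual, 0.005)               # < 0.5 % of injected tracer
    if (blocked) expect_equal(mb$outflowed, 0)
  }
})

test_that("concentrations stay within [0, max AIF]", {
  aif <- fixture_aif()
  ts <- fixture_tube_series(P = 0.1, T_total = 120)
  cmax <- max(aif_value(seq(0, 120, by = 0.05), aif))
  expect_gte(min(ts$field$c_P), 0)
  expect_gte(min(ts$field$c_I), 0)
  expect_lte(max(ts$field$c_P), cmax * (1 + 1e-9))
  expect_lte(max(ts$field$c_I), cmax * (1 + 1e-9))
})

test_that("the analytic tube solution shifts and scales as advection demands", {
  aif <- fixture_aif()
  phi <- pi * 16 / 3600
  # x = 0 reproduces the input
  expect_equal(tube_analytic(0, c(5, 20, 60), 1e4, phi, 60, aif),
               aif_value(c(5, 20, 60), aif))
  # the delay at x is t0 = x phi L^2 / F; doubling F halves it
  t0 <- 1200 * phi * 3600 / 1e4
  expect_equal(tube_analytic(1200, 10 + t0, 1e4, phi, 60, aif),
               aif_value(10, aif), tolerance = 1e-12)
  expect_equal(tube_analytic(1200, 10 + t0 / 2, 2e4, phi, 60, aif),
               aif_value(10, aif), tolerance = 1e-12)
  expect_error(tube_analytic(0, 1, -1, phi, 60, aif), "F must be")
})

test_that("an impossible CFL step is an error, not a silent crawl", {
  tb <- fixture_tube(5, F_target = 1e9)     # absurdly fast flow
  maps <- ground_truth_maps(tb$graph, tb$flow, P = 0)
  expect_error(simulate_transport(tb$graph, tb$flow, maps,
                                  transport_params(T_total = 10,
                                                   dt_floor = 1e-3),
                                  fixture_aif()),
               "CFL")
})
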