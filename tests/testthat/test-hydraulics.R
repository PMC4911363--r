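p0 <- leaf_params()

test_that("irradiance component of hydraulic conductance saturates", {
  expect_equal(kx_radiation(0), 0.0259)
  expect_equal(kx_radiation(500), 0.0259 + 0.2268 / 2)
  expect_equal(kx_radiation(1000), 0.2527)
  expect_equal(kx_radiation(1500), 0.2527)  # saturated above ppfd_lim
  expect_error(kx_radiation(-1), "non-negative")
})

test_that("oscillation component follows the circadian cosine", {
  # cos(-pi t/60 + 5 pi/2) is 0 at t = 0 and 1 at t = 30 min
  expect_equal(kx_oscillation(0, p0), 0, tolerance = 1e-12)
  expect_equal(kx_oscillation(30 * 60, p0),
               (0.324 / 15) * (-0.08 - (-0.9)))
  expect_equal(kx_oscillation(30 * 60, p0), 0.017712, tolerance = 1e-6)
  expect_equal(kx_oscillation(123, leaf_params(tau_c = 0)), 0)
  # 120-minute cycle in the default minutes unit
  t <- c(0, 17, 1800, 3999)
  expect_equal(kx_oscillation(t + 120 * 60, p0), kx_oscillation(t, p0))
  # hours mode stretches the cycle to 120 h
  ph <- leaf_params(osc_time_unit = "hours")
  expect_equal(kx_oscillation(t + 120 * 3600, ph), kx_oscillation(t, ph))
  expect_false(isTRUE(all.equal(kx_oscillation(1800, ph),
                                kx_oscillation(1800, p0))))
})

test_that("total hydraulic conductance is molar and floored at zero", {
  # at t = 0 the oscillation term vanishes: cv_f1 * a
  expect_equal(hydraulic_conductance(0, 0), 0.05556 * 0.0259)
  # a strongly negative oscillation cannot drive the total negative
  pneg <- leaf_params(tau_c = 10, a = 0, b = 0)
  t <- seq(0, 7200, by = 60)
  expect_true(all(hydraulic_conductance(t, 0, pneg) >= 0))
})

test_that("osmotic potential is the van 't Hoff term", {
  expect_equal(osmotic_potential(0, 16, 295.15), 0)
  expect_equal(osmotic_potential(0.121, 16, 295.15),
               -55.56 * 8.3145e-3 * 295.15 * 0.121 / 16)
  expect_equal(osmotic_potential(0.121, 16, 295.15), -1.031,
               tolerance = 1e-3)
  expect_equal(osmotic_potential(0.242, 16, 295.15),
               2 * osmotic_potential(0.121, 16, 295.15))
  expect_error(osmotic_potential(0.1, 0, 295.15), "positive")
})

test_that("turgor pressure rises exponentially to full turgor", {
  expect_equal(turgor_pressure(16), 2.4)
  wm_half <- 16 * (1 - log(2) / 10.6)
  expect_equal(turgor_pressure(wm_half), 1.2)
  wm <- seq(8, 16, by = 0.25)
  expect_true(all(diff(turgor_pressure(wm)) > 0))
  expect_error(turgor_pressure(16.5), "wm_max")
})

test_that("mesophyll potential composes its parts and responds to state", {
  pot <- mesophyll_potential(0, 16, 295.15)
  expect_equal(pot$psi_m, 2.4)
  pot2 <- mesophyll_potential(0.121, 14, 295.15)
  expect_equal(pot2$psi_m, pot2$psi_s + pot2$psi_p)
  # more solutes at fixed water content lower the total potential
  expect_lt(mesophyll_potential(0.2, 14, 295.15)$psi_m, pot2$psi_m)
})

test_that("water influx and state derivatives follow their balances", {
  expect_equal(water_influx(1.44e-3, -0.08), 0)  # equilibrium with xylem
  expect_gt(water_influx(1.44e-3, -1.0), 0)
  expect_equal(water_influx(1.44e-3, -1.08), 1.44e-3, tolerance = 1e-12)
  d <- water_state_derivatives(1e-3, 1e-3)
  expect_equal(d$dwm, 0)
  expect_equal(water_state_derivatives(0, 5e-4)$dnm, 0)
  expect_equal(water_state_derivatives(1e-3, 0)$dnm, 2 * 3e-4 * 1e-3)
})

test_that("with no efflux the water state relaxes to xylem potential", {
  # forward-integrate dWm/dt = kx (psi_x - psi_m) with Fo = 0; the fixed
  # point is psi_m = psi_x
  p <- leaf_params()
  wm <- 16; nm <- 0.121; tl <- 295.15
  kx <- hydraulic_conductance(0, 500, p)
  for (i in 1:30000) {
    psi_m <- mesophyll_potential(nm, wm, tl, p)$psi_m
    fi <- water_influx(kx, psi_m, p)
    wm <- min(wm + fi, p$wm_max)
    nm <- nm + p$c_i * p$n_xy * fi
  }
  expect_equal(mesophyll_potential(nm, wm, tl, p)$psi_m, p$psi_x,
               tolerance = 1e-4)
})

test_that("potential components are monotone over random states", {
  set.seed(7)
  for (i in 1:50) {
    wm <- runif(2, 4, 16); wm <- sort(wm)
    nm <- runif(1, 0.01, 0.5); tl <- runif(1, 280, 310)
    expect_gt(turgor_pressure(wm[2]), turgor_pressure(wm[1]))
    # osmotic potential rises (towards 0) with water content
    expect_gt(osmotic_potential(nm, wm[2], tl), osmotic_potential(nm, wm[1], tl))
  }
})
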