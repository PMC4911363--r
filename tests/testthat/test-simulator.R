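test_that("trace has the expected shape and is deterministic", {
  day <- ideal_day_params("cloudy", period = 3600)
  sim <- simulate_leaf(day, dt = 30, t_start = 8 * 3600, t_end = 10 * 3600)
  expect_s3_class(sim, "leaf_simulation")
  expect_equal(nrow(sim$trace), 2 * 3600 / 30 + 1)
  sim2 <- simulate_leaf(day, dt = 30, t_start = 8 * 3600, t_end = 10 * 3600)
  expect_identical(sim$trace, sim2$trace)
})

test_that("every trace row is internally consistent with the sub-models", {
  day <- ideal_day_params("sunny", period = 1800)
  sim <- simulate_leaf(day, dt = 10, t_start = 7 * 3600, t_end = 9 * 3600)
  tr <- sim$trace
  p <- sim$params
  expect_equal(tr$psi_m, tr$psi_s + tr$psi_p)
  expect_equal(tr$gsc, tr$gsw / 1.6)
  idx <- round(seq(1, nrow(tr) - 1, length.out = 25))
  for (i in idx) {
    st <- steady_state_photosynthesis(tr$de[i], tr$psi_m[i], tr$ppfd[i], p)
    expect_equal(tr$a_target[i], st$a, tolerance = 1e-10)
    expect_equal(tr$g_target[i], st$g, tolerance = 1e-10)
    inst <- instantaneous_assimilation(tr$gsc[i], tr$ppfd[i], p)
    expect_equal(tr$a_now[i], inst$a, tolerance = 1e-10)
    expect_equal(tr$gtw[i], total_conductance(tr$gsw[i], p),
                 tolerance = 1e-12)
    expect_equal(tr$tl[i], leaf_temperature(tr$ta[i], tr$de[i], tr$s[i],
                                            tr$gtw[i], tr$rn[i], p),
                 tolerance = 1e-12)
    expect_equal(tr$fo[i], transpiration(tr$tl[i], tr$ta[i], tr$de[i],
                                         tr$s[i], tr$gtw[i], p),
                 tolerance = 1e-12)
    expect_equal(tr$kx[i], hydraulic_conductance(tr$t[i], tr$ppfd[i], p),
                 tolerance = 1e-12)
    expect_equal(tr$fi[i], water_influx(tr$kx[i], tr$psi_m[i], p),
                 tolerance = 1e-12)
  }
})

test_that("a dark saturated night relaxes to the dark steady state", {
  night <- constant_climate(0, 4 * 3600, ppfd = 0, ta = 293.15, hr = 100)
  sim <- simulate_leaf(night, dt = 5, t_start = 0, t_end = 4 * 3600)
  tr <- sim$trace
  expect_true(all(tr$a_now == 0))
  expect_true(all(abs(tr$fo) < 1e-12))        # no deficit, no transpiration
  expect_equal(tail(tr$gsw, 1), 1.6 * 0.009, tolerance = 1e-3)
  expect_equal(tail(tr$tl, 1), 293.15)        # no radiation, leaf at Ta
})

test_that("water and solute balances close over a short run", {
  day <- ideal_day_params("cloudy", period = 1800)
  sim <- simulate_leaf(day, dt = 1, t_start = 7 * 3600, t_end = 9 * 3600)
  cl <- closure_balance(sim)
  expect_equal(sim$counters$wm_clipped, 0)
  expect_lt(cl$water_rel_err, 1e-6)
  expect_lt(cl$solute_rel_err, 1e-6)
  # solutes only accumulate while influx is positive
  tr <- sim$trace
  gain <- diff(tr$nm)
  expect_true(all(gain[tr$fi[-nrow(tr)] >= 0] >= 0))
})

test_that("halving the step barely changes the trajectory", {
  day <- ideal_day_params("sunny", period = 3600)
  s1 <- simulate_leaf(day, dt = 5, t_start = 6 * 3600, t_end = 12 * 3600)
  s2 <- simulate_leaf(day, dt = 2.5, t_start = 6 * 3600, t_end = 12 * 3600)
  wm1 <- s1$trace$wm
  wm2 <- s2$trace$wm[seq(1, nrow(s2$trace), by = 2)]
  expect_lt(max(abs(wm1 - wm2) / wm2), 1e-3)
  w1 <- daily_wue(s1, c(7, 11) * 3600)$wue
  w2 <- daily_wue(s2, c(7, 11) * 3600)$wue
  expect_lt(abs(w1 / w2 - 1), 1e-3)
})

test_that("stomatal conductance stays within its physical corridor", {
  day <- ideal_day_params("cloudy", period = 900)
  sim <- simulate_leaf(day, dt = 5)
  tr <- sim$trace
  p <- sim$params
  expect_true(all(tr$gsw >= p$r0 + 1e-6 - 1e-15))
  expect_lt(max(tr$gsw), 1.6 * max(tr$g_target) + 1e-9)
})

test_that("daily WUE is the ratio of the window integrals", {
  # hand-built constant trace: A = 10 umol, E = 2e-3 mol -> 5 mmol/mol
  t <- seq(6 * 3600, 21 * 3600, by = 60)
  fake <- structure(list(
    trace = data.frame(t = t, a_now = 10, fo = 2e-3),
    dt = 60, t_start = t[1], t_end = t[length(t)]),
    class = "leaf_simulation")
  w <- daily_wue(fake)
  expect_equal(w$wue, 5)
  # ratio invariance under window narrowing for a constant trace
  expect_equal(daily_wue(fake, c(8, 10) * 3600)$wue, 5)
  # all-dark trace has undefined WUE
  dark <- fake
  dark$trace$a_now <- 0
  dark$trace$fo <- 0
  expect_error(daily_wue(dark), "undefined")
  expect_error(daily_wue(fake, c(5, 20) * 3600), "within")
})

test_that("simulation spans outside the forcing are rejected", {
  clim <- constant_climate(8 * 3600, 10 * 3600, ppfd = 100, ta = 295,
                           hr = 80)
  expect_error(simulate_leaf(clim, dt = 60, t_start = 7 * 3600,
                             t_end = 9 * 3600), "span")
  expect_error(simulate_leaf(clim, dt = 0), "positive")
})
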