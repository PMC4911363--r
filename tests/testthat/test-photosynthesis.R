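p0 <- leaf_params()

test_that("electron transport is the smaller hyperbola root", {
  expect_equal(electron_transport(0), 0)
  expect_equal(electron_transport(1e9), 140, tolerance = 1e-5)
  # cross-check against the quadratic's roots computed independently
  for (iinc in c(50, 200, 500, 1200)) {
    x <- 0.425 * iinc
    roots <- sort(Re(polyroot(c(x * 140, -(x + 140), 0.75))))
    expect_equal(electron_transport(iinc), roots[1], tolerance = 1e-9)
  }
  expect_equal(electron_transport(500), 110.3, tolerance = 1e-3)
  expect_error(leaf_params(theta = 1.2), "theta")
})

test_that("CO2 drawdown through the two conductances", {
  expect_equal(cc_from_a(0, 0.1), 380)
  expect_equal(cc_from_a(10, 0.1), 380 - 10 * 0.4 / 0.03)
  expect_equal(cc_from_a(5, 1e6, leaf_params(gm = 1e6)), 380,
               tolerance = 1e-3)
})

test_that("branch cubics vanish at the implicit-system root", {
  # the cubic coefficients must be an exact polynomial form of the
  # demand/supply/target system: evaluate each cubic at the root found by
  # bisecting the implicit system itself
  set.seed(17)
  for (i in 1:20) {
    p <- draw_physio_params()
    gscb <- target_coefficient(runif(1, 0.3, 2.5), runif(1, -1, 0), p)
    j <- electron_transport(runif(1, 30, 1500), p)
    scale_c <- function(co, a) sum(co * a^(3:0)) / max(abs(co * a^(3:0)))
    a_c <- oracle_branch_root("rubisco", gscb, j, p)
    expect_lt(abs(scale_c(cubic_rubisco(gscb, p), a_c)), 1e-9)
    a_j <- oracle_branch_root("rubp", gscb, j, p)
    expect_lt(abs(scale_c(cubic_rubp(gscb, j, p), a_j)), 1e-9)
    # printed structural identity between the branches
    expect_equal(cubic_rubp(gscb, j, p)[1], 4 * cubic_rubisco(gscb, p)[1])
  }
})

test_that("admissible-root selection handles degenerate cases", {
  # J = 0 makes A = 0 a root of the light-limited cubic, and it is the
  # admissible one
  expect_equal(solve_admissible_root(cubic_rubp(0.0119, 0, p0), 0.0119, p0),
               0)
  # gscb = 0 degenerates to a quadratic with a closed-form solution
  co <- cubic_rubisco(0, p0)
  expect_equal(co[1], 0)
  a_quad <- solve_admissible_root(co, 0, p0)
  disc <- co[3]^2 - 4 * co[2] * co[4]
  roots <- (-co[3] + c(-1, 1) * sqrt(disc)) / (2 * co[2])
  expect_true(any(abs(roots - a_quad) < 1e-9))
  # impossible coefficients raise with diagnostics rather than guessing
  expect_error(solve_admissible_root(c(0, 0, 1, 100), 1, p0), "admissible")
})

test_that("steady state solves both branches and reports the minimum", {
  st <- steady_state_photosynthesis(1, -0.1, 500)
  expect_equal(st$a, min(st$ac, st$aj))
  expect_lt(steady_state_residual(st, p0), 1e-9)
  expect_gt(st$cc, 0)
  expect_lt(st$cc, 380)
  expect_gte(st$g, p0$g0)
  dark <- steady_state_photosynthesis(1, -0.1, 0)
  expect_equal(dark$a, 0)
  expect_equal(dark$g, p0$g0)
  # assimilation never decreases with mesophyll conductance
  a_gm <- vapply(seq(0.1, 1.5, by = 0.2), function(gm)
    steady_state_photosynthesis(1, -0.1, 800, leaf_params(gm = gm))$a, 0)
  expect_true(all(diff(a_gm) >= 0))
  # nor with light
  a_i <- vapply(c(0, 50, 150, 400, 900, 1500), function(i)
    steady_state_photosynthesis(1, -0.1, i)$a, 0)
  expect_true(all(diff(a_i) >= 0))
})

test_that("instantaneous assimilation has the right limits", {
  # infinite conductances put the chloroplast at ambient CO2
  p_inf <- leaf_params(gm = 1e9)
  inst <- instantaneous_assimilation(1e9, 1e9, p_inf)
  expect_equal(inst$ac, 102 * (380 - 43.02) / (380 + 711), tolerance = 1e-6)
  expect_equal(inst$ac, 31.50, tolerance = 1e-3)
  expect_equal(instantaneous_assimilation(0.1, 0)$a, 0)
  expect_error(instantaneous_assimilation(0, 500), "positive")
  # respiration subtraction is a pure offset on the reported rate
  p_rd <- leaf_params(subtract_rd = TRUE)
  expect_equal(instantaneous_assimilation(0.1, 500, p_rd)$a,
               instantaneous_assimilation(0.1, 500, p0)$a - 1.08)
})

test_that("instantaneous and steady-state solutions agree at the target", {
  # when the current conductance happens to equal the steady-state target,
  # both solution paths describe the same physical state
  set.seed(19)
  for (i in 1:10) {
    p <- draw_physio_params()
    iinc <- runif(1, 100, 1200)
    st <- steady_state_photosynthesis(runif(1, 0.3, 2), runif(1, -1, 0),
                                      iinc, p)
    inst <- instantaneous_assimilation(st$g, iinc, p)
    expect_equal(inst$a, st$a, tolerance = 1e-8)
  }
})
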