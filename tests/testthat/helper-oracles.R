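# Independent numerical oracles used to cross-check the analytical solvers.
# These deliberately avoid the code paths they verify: the steady-state
# assimilation oracle brackets and bisects the implicit demand/supply
# balance, and the leaf-temperature oracle solves the raw energy-balance
# residual, instead of the closed forms used by the package.

# Bisection solve of the implicit steady state of one demand branch:
#   A = demand(Cc(A)),  Cc(A) = Ca - A (1/G + 1/gm),  G = g0 + gscb A.
oracle_branch_root <- function(branch, gscb, j, p) {
  demand <- function(cc) {
    if (branch == "rubisco")
      p$vcmax * (cc - p$gamma_star) / (cc + p$km)
    else
      j * (cc - p$gamma_star) / (4 * cc + 8 * p$gamma_star)
  }
  f <- function(a) {
    g <- p$g0 + gscb * a
    cc <- p$ca - a * (g + p$gm) / (g * p$gm)
    a - demand(cc)
  }
  hi <- 1e-6
  while (f(hi) < 0) hi <- hi * 1.5
  stats::uniroot(f, c(0, hi), tol = 1e-13)$root
}

# Root of the leaf energy balance Rn - Gi = H + lambda E, solved on the
# residual directly (sensible heat through g_aH = gbw / 1.15, latent heat
# through the package's transpiration formula).
oracle_leaf_temperature <- function(ta, de, s, gtw, rn, p) {
  f <- function(x) {
    (rn - p$g_i) - p$rho_a * p$cp * (p$gbw / 1.15) * (x - ta) -
      p$lam * transpiration(x, ta, de, s, gtw, p)
  }
  stats::uniroot(f, c(ta - 60, ta + 60), tol = 1e-13)$root
}

# Random physiological parameter draw for solver cross-checks.
draw_physio_params <- function() {
  leaf_params(vcmax = stats::runif(1, 40, 150),
              jmax = stats::runif(1, 80, 250),
              gm = stats::runif(1, 0.1, 1.5),
              g0 = stats::runif(1, 0.001, 0.05))
}

# Implicit-equation residual of a steady-state solution, relative scale.
steady_state_residual <- function(st, p) {
  g <- p$g0 + st$gscb * st$a
  cc <- cc_from_a(st$a, g, p)
  dem <- if (st$limitation == "rubisco")
    p$vcmax * (cc - p$gamma_star) / (cc + p$km)
  else
    st$j * (cc - p$gamma_star) / (4 * cc + 8 * p$gamma_star)
  abs(st$a - dem) / max(1, abs(st$a))
}

# A tiny constant climate table covering [t0, t1].
constant_climate <- function(t0, t1, ppfd = 0, ta = 295.15, hr = 100,
                             ca = 380, dt = 60) {
  t <- seq(t0, t1, by = dt)
  data.frame(time = t, ppfd = ppfd, ta = ta, hr = hr, ca = ca)
}
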