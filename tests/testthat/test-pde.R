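test_that("dissolution source term follows the Noyes-Whitney form", {
  p <- dimensionless_params(1 / 2, 1, 0)
  # exhausted solid cannot dissolve; saturated solution stops dissolving
  expect_equal(dissolution_source(0.2, 0, p), 0)
  expect_equal(dissolution_source(p$K, 0.3, p), 0)
  expect_equal(dissolution_source(0, 1 / 2, p), 0.5)
  # shape factor scales the source through the remaining-area power law
  p23 <- dimensionless_params(1 / 2, 2, 2 / 3)
  phia <- c(0.5, 0.25, 0.1)
  expect_equal(dissolution_source(0.1, phia, p23),
               2 * (phia / 0.5)^(2 / 3) * (0.5 - 0.1))
})

test_that("solution starts from the saturated initial state", {
  sol <- solve_quick(1 / 2, 1, 0)
  expect_equal(sol$tau[1], 0)
  N <- sol$mesh$n_points
  # the sink node carries the only released mass at tau = 0: one half-cell
  # of the quadrature, 3*K*h/2
  expect_lt(sol$curve$fraction_released[1], 3 * 0.5 / (N - 1))
  expect_equal(sol$curve$eta_star[1], 1)
  expect_equal(unname(sol$phi[1, -N]), rep(1 / 2, N - 1))
  expect_equal(unname(sol$phi[1, N]), 0)   # sink node
  expect_equal(unname(sol$phi_a[1, ]), rep(1 / 2, N))
})

test_that("released fraction integrates the concentration complement", {
  # piecewise profile: full load on the inner half-radius, empty outside
  # -> F = 1 - (1/2)^3 = 0.875
  eta <- seq(0, 1, length.out = 2000)
  K <- 0.3
  st <- structure(list(tau = 0, eta = eta,
                       phi = ifelse(eta <= 0.5, K, 0),
                       phi_a = ifelse(eta <= 0.5, 1 - K, 0)),
                  class = "state_profile")
  expect_equal(release_fraction(st), 0.875, tolerance = 1e-3)
  # empty matrix -> 1; untouched matrix -> 0
  st$phi <- rep(0, length(eta)); st$phi_a <- rep(0, length(eta))
  expect_equal(release_fraction(st), 1, tolerance = 1e-9)
  st$phi <- rep(K, length(eta)); st$phi_a <- rep(1 - K, length(eta))
  expect_equal(release_fraction(st), 0, tolerance = 1e-9)
})

test_that("depletion front tracks the outermost un-depleted node", {
  eta <- seq(0, 1, length.out = 101)
  mk <- function(phia) structure(list(tau = 0, eta = eta,
                                      phi = 0 * eta, phi_a = phia),
                                 class = "state_profile")
  expect_equal(depletion_front(mk(rep(0.5, 101))), 1)
  expect_equal(depletion_front(mk(rep(0, 101))), 0)
  expect_equal(depletion_front(mk(ifelse(eta <= 0.37, 0.5, 0))), 0.37)
})

test_that("finite-difference rate is exact for linear release", {
  tau <- exp(seq(log(0.01), log(10), length.out = 40))
  expect_equal(release_rate(tau, 0.05 * tau), rep(0.05, 40))
  expect_error(release_rate(c(1, 1, 2), c(0, 0, 0)), "increasing")
  expect_error(release_rate(c(1, 2), c(0, 0)), "3 time points")
})

test_that("surface solid trajectory reproduces the closed form exactly", {
  # at the surface the sink condition makes the solid balance an ODE with
  # the closed-form solution of surface_undissolved()
  for (case in list(c(1 / 2, 1, 0), c(1 / 101, 1, 0), c(1 / 2, 1, 2 / 3))) {
    p <- dimensionless_params(case[1], case[2], case[3])
    tc <- critical_time(p)
    opts <- solver_options(output_tau = seq(tc / 20, tc, length.out = 20))
    sol <- solve_release(p, release_mesh(300), opts)
    surf <- sol$phi_a[, 300]
    expect_lt(max(abs(surf - surface_undissolved(sol$tau, p))), 1e-3)
  }
})

test_that("depletion onset brackets the critical time within one step", {
  for (case in list(c(1 / 2, 1, 0), c(1 / 101, 10, 0), c(1 / 2, 1, 2 / 3))) {
    p <- dimensionless_params(case[1], case[2], case[3])
    tc <- critical_time(p)
    sol <- solve_release(p, release_mesh(300),
                         quick_opts(p, n_out = 200, span = c(1e-3, 3)))
    i <- which(sol$curve$eta_star < 1)[1]
    expect_true(sol$tau[i - 1] <= tc && tc <= sol$tau[i] * (1 + 1e-10))
  }
})

test_that("release curves conserve mass and are monotone", {
  for (case in list(c(1 / 2, 0.1, 0), c(1 / 2, 1, 1 / 2),
                    c(1 / 101, 1, 2 / 3), c(1 / 2, 100, 2 / 3))) {
    sol <- solve_quick(case[1], case[2], case[3], mesh_n = 300,
                       span = c(1e-4, 20))
    curve <- sol$curve
    # mass balance via an independent trapezoidal quadrature of what
    # remains in the matrix
    eta <- sol$mesh$eta
    retained <- vapply(seq_along(sol$tau), function(i) {
      g <- (sol$phi[i, ] + sol$phi_a[i, ]) * 3 * eta^2
      sum(diff(eta) * (head(g, -1) + tail(g, -1)) / 2)
    }, numeric(1))
    expect_lt(max(abs(curve$fraction_released + retained - 1)), 2e-3)
    expect_true(all(curve$fraction_released >= -1e-6))
    expect_true(all(curve$fraction_released <= 1 + 1e-3))
    expect_true(all(diff(curve$fraction_released) >= -1e-6))
    expect_true(all(diff(curve$eta_star) <= 1e-12))
    # solid is consumed, never produced (small tolerance for the
    # regularized switch-off at depletion)
    expect_true(all(apply(sol$phi_a, 2, function(col) all(diff(col) <= 1e-4))))
    expect_true(min(sol$phi_a) > -1e-3)
  }
})

test_that("release slows with the particle shape factor", {
  for (K in c(1 / 2, 1 / 101)) for (G in c(0.1, 1)) {
    p0 <- dimensionless_params(K, G, 0)
    grid <- default_output_grid(p0, n_out = 60, span = c(1e-3, 20))
    Fs <- lapply(c(0, 1 / 2, 2 / 3), function(n) {
      p <- dimensionless_params(K, G, n)
      solve_release(p, release_mesh(300),
                    solver_options(output_tau = grid))$curve$fraction_released
    })
    expect_true(all(Fs[[1]] >= Fs[[2]] - 1e-3))
    expect_true(all(Fs[[2]] >= Fs[[3]] - 1e-3))
  }
})

test_that("released fraction is mesh-converged at the critical time", {
  p <- dimensionless_params(1 / 2, 10, 2 / 3)
  tc <- critical_time(p)
  F_at_tc <- vapply(c(1000L, 2000L), function(nm) {
    opts <- solver_options(output_tau = c(tc / 2, tc))
    sol <- solve_release(p, release_mesh(nm), opts)
    sol$curve$fraction_released[sol$curve$tau == tc]
  }, numeric(1))
  expect_lt(abs(F_at_tc[2] - F_at_tc[1]), 1e-3)
})

test_that("approach to the diffusion-controlled (Higuchi) limit", {
  # the gap to the instantaneous-dissolution reference shrinks as G grows
  K <- 1 / 101
  gaps <- vapply(c(1, 1e2, 1e5), function(G) {
    p <- dimensionless_params(K, G, 2 / 3)
    dv <- deviation_analysis(p, mesh = release_mesh(300), n_grid = 200)
    abs(dv$max_deviation)
  }, numeric(1))
  expect_false(is.unsorted(rev(gaps), strictly = TRUE))
})
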