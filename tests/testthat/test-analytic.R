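test_that("critical depletion time matches its closed form", {
  expect_equal(critical_time(dimensionless_params(1 / 2, 0.1, 0)), 10)
  expect_equal(critical_time(dimensionless_params(1 / 101, 1, 0)), 100)
  expect_equal(critical_time(dimensionless_params(1 / 101, 0.1, 0)), 1000)

  # the shape factor multiplies the planar value by 1/(1-n): x2 and x3
  for (K in c(1 / 2, 1 / 11)) for (G in c(0.3, 2)) {
    t0 <- critical_time(dimensionless_params(K, G, 0))
    expect_equal(critical_time(dimensionless_params(K, G, 1 / 2)), 2 * t0)
    expect_equal(critical_time(dimensionless_params(K, G, 2 / 3)), 3 * t0)
  }

  # inverse proportionality to G over several decades
  Gs <- 10^seq(-2, 4, by = 1)
  tcs <- vapply(Gs, function(G)
    critical_time(dimensionless_params(1 / 11, G, 1 / 2)), numeric(1))
  expect_equal(tcs * Gs, rep(tcs[1] * Gs[1], length(Gs)))
})

test_that("surface solid concentration decays to zero at the critical time", {
  for (K in c(1 / 2, 1 / 101)) for (G in c(0.1, 1, 10)) {
    for (n in c(0, 1 / 2, 2 / 3)) {
      p <- dimensionless_params(K, G, n)
      tc <- critical_time(p)
      expect_equal(surface_undissolved(0, p), 1 - K)
      expect_equal(surface_undissolved(tc, p), 0)
      expect_equal(surface_undissolved(2 * tc, p), 0)
      taus <- seq(0, 1.5 * tc, length.out = 50)
      vals <- surface_undissolved(taus, p)
      expect_true(all(vals >= 0))
      expect_true(all(diff(vals) <= 1e-14))
    }
  }
  # the planar case is exactly linear in tau: (1-K) - G K tau
  p <- dimensionless_params(1 / 2, 1, 0)
  expect_equal(surface_undissolved(0.5, p), 0.25)
  taus <- seq(0, critical_time(p), length.out = 20)
  expect_equal(surface_undissolved(taus, p), (1 - p$K) - p$G * p$K * taus)
})

test_that("series solution honors its boundary and initial conditions", {
  p <- dimensionless_params(1 / 2, 10, 0)
  # sink condition: every sine term vanishes at the surface
  st <- series_state(0.01, 1, p)
  expect_equal(st$phi, 0)
  # initial condition recovered in the interior (alternating-series tail
  # bounded by the term tolerance)
  st0 <- series_state(0, c(0.3, 0.5, 0.8), p)
  expect_equal(st0$phi, rep(p$K, 3), tolerance = 1e-3)
  expect_equal(st0$phi_a, rep(1 - p$K, 3), tolerance = 1e-12)
  # center limit well-defined
  stc <- series_state(0.02, 0, p)
  expect_true(is.finite(stc$phi) && is.finite(stc$phi_a))

  # surface solid concentration from the series bracket reduces to the
  # closed form (1-K) - G K tau
  for (tau in c(0.02, 0.05, 0.09)) {
    expect_equal(series_state(tau, 1, p)$phi_a,
                 surface_undissolved(tau, p), tolerance = 1e-10)
  }

  expect_error(series_state(0.1, 0.5, dimensionless_params(1 / 2, 10, 2 / 3)),
               "planar")
  expect_error(series_state(2 * critical_time(p), 0.5, p), "critical time")
})

test_that("series released fraction starts at zero and grows", {
  p <- dimensionless_params(1 / 101, 10, 0)
  taus <- seq(0, critical_time(p), length.out = 9)
  Fs <- series_release_fraction(taus, p)
  expect_equal(Fs[1], 0, tolerance = 1e-6)
  expect_false(is.unsorted(Fs))
})

test_that("series and PDE solver agree before depletion (planar oracle)", {
  # profile agreement within 5e-3 and released fraction within 1e-3
  for (K in c(1 / 2, 1 / 101)) for (G in c(1, 10, 100)) {
    p <- dimensionless_params(K, G, 0)
    tc <- critical_time(p)
    opts <- solver_options(output_tau = c(tc / 4, tc / 2))
    sol <- solve_release(p, release_mesh(500), opts)
    st <- state_profile(sol, tc / 2)
    ss <- series_state(tc / 2, st$eta, p)
    expect_lt(max(abs(ss$phi - st$phi)), 5e-3)
    expect_lt(max(abs(ss$phi_a - st$phi_a)), 5e-3)
    F_pde <- sol$curve$fraction_released[sol$curve$tau == tc / 2]
    F_series <- series_release_fraction(tc / 2, p)
    expect_lt(abs(F_pde - F_series), 1e-3)
  }
})
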