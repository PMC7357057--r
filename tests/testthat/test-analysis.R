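test_that("window detection on an exactly linear release curve", {
  # F = c*tau: every point is at the constant rate, so the window starts
  # at the first grid time and the coverage is the rate times the window
  K <- 1 / 2; G <- 1; c0 <- 0.4
  p <- dimensionless_params(K, G, 0)
  tau_c <- critical_time(p)                 # 1
  tau <- seq(0.01, 2 * tau_c, length.out = 300)
  curve <- data.frame(tau = tau, fraction_released = c0 * tau,
                      rate = release_rate(tau, c0 * tau),
                      eta_star = rep(1, length(tau)))
  reg <- constant_rate_region(curve, p)
  expect_false(reg$negligible)
  expect_equal(reg$tau_s, tau[1])
  expect_equal(reg$tau_c, tau_c)
  expect_equal(reg$rate_middle, c0, tolerance = 1e-10)
  expect_equal(reg$coverage_percent, 100 * c0 * (tau_c - tau[1]),
               tolerance = 1e-8)
})

test_that("zero-order window matches the definitional 1% criterion", {
  # detected on a real planar curve: the rate over [tau_s, tau_c] stays
  # within 1% (relative) of the end rate
  p <- dimensionless_params(1 / 101, 1, 0)
  reg <- constant_rate_analysis(p, mesh = release_mesh(300), n_out = 200)
  expect_false(reg$negligible)
  curve <- attr(reg, "curves")$planar
  inside <- curve$tau >= reg$tau_s & curve$tau <= 0.99 * reg$tau_c
  expect_true(all(abs(curve$rate[inside] - reg$rate_end) <=
                    0.011 * reg$rate_end))
  expect_equal(reg$coverage_percent,
               100 * (matrixrelease:::interp_curve(curve, reg$tau_c,
                                                   "fraction_released") -
                        matrixrelease:::interp_curve(curve, reg$tau_s,
                                                     "fraction_released")))
  # coverage shrinks from planar to cylindrical to spherical particles
  reg12 <- constant_rate_analysis(dimensionless_params(1 / 101, 1, 1 / 2),
                                  mesh = release_mesh(300), n_out = 200)
  reg23 <- constant_rate_analysis(dimensionless_params(1 / 101, 1, 2 / 3),
                                  mesh = release_mesh(300), n_out = 200)
  expect_gt(reg$coverage_percent, reg12$coverage_percent)
  expect_gt(reg12$coverage_percent, reg23$coverage_percent)
})

test_that("burst-dominated systems are flagged as having no usable window", {
  # fast dissolution at high solubility: depletion starts before the rate
  # ever settles, the nominal window covers almost nothing
  reg <- constant_rate_analysis(dimensionless_params(1 / 2, 10, 0),
                                mesh = release_mesh(300), n_out = 200)
  expect_true(reg$negligible)
})

test_that("deviation analysis is signed and flags short grids", {
  p <- dimensionless_params(1 / 2, 1, 2 / 3)
  dv <- deviation_analysis(p, mesh = release_mesh(300), n_grid = 300)
  expect_length(dv$flags, 0)
  expect_equal(dv$deviation, dv$fraction_higuchi - dv$fraction_present)
  expect_gte(abs(dv$max_deviation),
             max(abs(dv$deviation)) - 1e-12)  # refinement only grows it
  # instantaneous dissolution can only be ahead early on
  expect_gte(dv$deviation[1], 0)
  # a grid truncated mid-release is flagged
  dv_short <- deviation_analysis(p, tau_grid = 10^seq(-3, -0.5, length.out = 50),
                                 mesh = release_mesh(300))
  expect_true(length(dv_short$flags) > 0)
})

test_that("sweep covers the parameter grid and captures per-row errors", {
  mesh <- release_mesh(150)
  tab <- release_sweep(1 / 2, c(1, 10), c(0, 1 / 2, 2 / 3),
                       what = "constant_rate", mesh = mesh, n_out = 150)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$status == "ok"))
  expect_true(all(is.na(tab$max_deviation_percent)))

  tab2 <- release_sweep(c(1 / 2, 1 / 11), 100, 2 / 3,
                        what = "deviation", mesh = mesh)
  expect_equal(nrow(tab2), 2)
  expect_true(all(is.finite(tab2$max_deviation_percent)))

  # invalid K is reported in-row, not thrown
  tab3 <- release_sweep(c(1 / 2, 2), 1, 0, what = "constant_rate",
                        mesh = mesh, n_out = 100)
  expect_equal(nrow(tab3), 2)
  expect_equal(tab3$status[1], "ok")
  expect_match(tab3$status[2], "'K'")
})
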