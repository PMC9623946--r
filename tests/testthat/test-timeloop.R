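test_that("dV_out bookkeeping equals the cumulative spinal flux quadrature", {
  h <- run_model("standard")$history
  cum <- cumsum(h$fluxes[, "spinal_outlet"]) * h$dt
  expect_equal(h$dV_out, cum, tolerance = 1e-10)
  # final-cycle oscillation amplitude of dV_out = spinal stroke volume
  idx <- icpulse:::cycle_index(h)
  base <- h$dV_out[idx[1] - 1]
  expect_equal(max(h$dV_out[idx] - base),
               run_model("standard")$qoi$spinal_stroke_volume,
               tolerance = 1e-10)
})

test_that("cycle-to-cycle periodicity decreases and is small", {
  h <- run_model("standard")$history
  expect_lt(periodic_state_check(h), 0.05)
  expect_error(periodic_state_check(
    run_transient(run_config(mini_domain(), material_params(),
                             synthetic_net_inflow(Q_peak = 0, V_in = 0),
                             n_cycles = 1, steps_per_cycle = 8))),
    "2 full cycles")
})

test_that("temporal refinement converges the peak probe pressure at O(dt)", {
  # miniature production domain with an O(1) waveform; the lagged outlet
  # linearization and interface backward differences are all first order
  dom <- mini_domain()
  pr <- vparams()
  Vp <- measure(dom, "PARENCHYMA")
  w <- synthetic_net_inflow(T = 1, t_rev = 0.38, V_in = 0.05 * Vp,
                            Q_peak = 0.3 * Vp, t_peak = 0.1)
  peaks <- vapply(c(8, 16, 32, 64), function(ns) {
    h <- run_transient(run_config(dom, pr, w, n_cycles = 1,
                                  steps_per_cycle = ns))
    max(h$probes[, "LV"])
  }, 0)
  err <- abs(peaks - peaks[4])[1:3]
  rate <- stats::coef(stats::lm(log(err) ~ log(1 / c(8, 16, 32))))[2]
  # at least first order (superconvergence of the peak value is fine)
  expect_gt(rate, 0.7)
  expect_true(all(diff(err) < 0))
})

test_that("solver aborts cleanly on non-finite states", {
  dom <- mini_domain()
  # vanishing spinal PVI: the exponential outlet law overflows as soon as
  # any volume leaves, driving the step solve non-finite
  pr <- material_params(E = 2.5, nu = 0.25, alpha = 0.9, c = 0.8, kappa = 0.7,
                        mu_f = 0.6, rho_f = 1, rho_s = 1, gamma = 1,
                        PVI = 1e-15, PVI_unit = "m3", p0 = 1, p0_unit = "Pa")
  Vp <- measure(dom, "PARENCHYMA")
  w <- synthetic_net_inflow(T = 1, t_rev = 0.38, V_in = 0.05 * Vp,
                            Q_peak = 0.3 * Vp, t_peak = 0.1)
  cfg <- run_config(dom, pr, w, n_cycles = 1, steps_per_cycle = 8)
  expect_error(run_transient(cfg), "non-finite|underflow|pressure")
})
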