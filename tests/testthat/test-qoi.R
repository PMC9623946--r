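test_that("stroke volume of analytic flux series", {
  T <- 1; dt <- 1e-4
  t <- seq(dt, T, by = dt)
  expect_equal(stroke_volume(rep(0, length(t)), dt), 0)
  Q0 <- 3.2e-6
  # max of cumulative integral of Q0 sin(2 pi t / T) is Q0 T / pi
  expect_equal(stroke_volume(Q0 * sin(2 * pi * t / T), dt), Q0 * T / pi,
               tolerance = 1e-4)
  # sign-convention consistency: reversed orientation of the mirrored cycle
  q <- Q0 * (sin(2 * pi * t / T) + 0.3 * sin(4 * pi * t / T))
  q_mirror <- -rev(q)
  expect_equal(stroke_volume(q, dt), stroke_volume(q_mirror, dt),
               tolerance = 1e-3 * Q0)
  expect_error(stroke_volume(numeric(0), dt), "empty")
})

test_that("pressure amplitude and transmantle gradient arithmetic", {
  expect_equal(pressure_amplitude(rep(3.3, 10)), 0)
  t <- seq(0, 1, by = 1e-3)
  expect_equal(pressure_amplitude(2.5 * sin(2 * pi * t)), 5, tolerance = 1e-4)
  p1 <- data.frame(t = t, p = 1 + 0 * t)
  p2 <- data.frame(t = t, p = 1 - 0.0108 * 133.322 + 0 * t)
  g <- transmantle_gradient(p1, p2, 0.06)
  expect_equal(mmHg(attr(g, "peak_abs")), 0.18, tolerance = 1e-3)
  g2 <- transmantle_gradient(p1, p2, 0.03)
  expect_equal(attr(g2, "peak_abs"), 2 * attr(g, "peak_abs"))
  expect_equal(transmantle_gradient(p1, p1, 0.05)$grad, rep(0, length(t)))
  expect_error(transmantle_gradient(p1, p2[1:5, ], 0.05), "mismatched")
  expect_error(transmantle_gradient(p1, p2, 0), "positive")
})

test_that("flux functional is exact for interpolated fields", {
  dom <- test_domain()
  sp_u <- icpulse:::fe_space(dom, "CSF", 2L)
  # uniform downward flow: flux through the aqueduct = w * area (positive
  # along the stored ventricle->SAS orientation, which points down)
  w <- 2.3e-3
  uvals <- icpulse:::interp_space(sp_u, function(x)
    cbind(0 * x[, 1], 0 * x[, 1], rep(-w, nrow(x))), vec = TRUE)
  b_aq <- icpulse:::asm_facet_normal_load(dom, sp_u, dom$surfaces$aqueduct)
  expect_equal(sum(b_aq * uvals), w * measure(dom, "aqueduct"),
               tolerance = 1e-12)
  # divergence-free linear field through the closed skull+outlet boundary
  uvals2 <- icpulse:::interp_space(sp_u, function(x)
    cbind(x[, 1], x[, 2], -2 * x[, 3]), vec = TRUE)
  b_closed <- numeric(length(uvals2))
  for (nm in c("SKULL", "SPINAL_SAS")) {
    fs <- dom$facets[[nm]]
    b_closed <- b_closed + icpulse:::asm_facet_normal_load(dom, sp_u, fs)
  }
  # exterior CSF boundary is closed by the interface; total div u integral
  # over CSF equals the sum of both boundary contributions
  b_ifc <- icpulse:::asm_facet_normal_load(dom, sp_u, dom$facets$INTERFACE)
  expect_equal(sum((b_closed + b_ifc) * uvals2), 0 * measure(dom, "CSF"),
               tolerance = 1e-10)
})

test_that("probe and displacement extrema behave on a rest history", {
  dom <- mini_domain()
  pr <- material_params()
  w0 <- synthetic_net_inflow(Q_peak = 0, V_in = 0)
  cfg <- run_config(dom, pr, w0, n_cycles = 2, steps_per_cycle = 8)
  h <- run_transient(cfg)
  expect_equal(max(abs(h$probes[, "LV"] - pr$p0)) / pr$p0, 0, tolerance = 1e-9)
  expect_lt(periodic_state_check(h), 0.01)
  pk <- peak_displacement(h)
  expect_lt(pk$value, 1e-12)
  expect_equal(max(abs(h$dV_out)), 0, tolerance = 1e-15)
  expect_error(probe_pressure(h, "NOPE"), "unknown probe")
  expect_error(flux_across(h, "NOPE"), "unknown surface")
})
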