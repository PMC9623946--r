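test_that("zero inflow keeps the lumped state at rest", {
  pr <- material_params()
  w0 <- synthetic_net_inflow(Q_peak = 0, V_in = 0)
  lump <- solve_lumped(pr, 1.37e-3, w0, n_cycles = 1, n_out = 50)
  expect_equal(lump$p, rep(pr$p0, length(lump$p)), tolerance = 1e-12)
  expect_equal(max(abs(lump$V_sp)), 0)
  expect_equal(max(abs(lump$V_store)), 0)
})

test_that("near-constant-compliance limit matches the linear closed form", {
  # tiny added volume => p barely moves => C_sp ~ const = PVI/(p0 ln 10)
  pr <- material_params(PVI = 3, p0 = 4.5)
  Vp <- 1.36954e-3
  w <- synthetic_net_inflow(V_in = 1.54e-12, Q_peak = 9e-12)
  lump <- solve_lumped(pr, Vp, w, n_cycles = 1, n_out = 200)
  Cb <- pr$c * Vp
  Csp <- pr$PVI / (pr$p0 * log(10))
  p_lin <- pr$p0 + lump$V_added / (Cb + Csp)
  expect_equal(lump$p, p_lin, tolerance = 1e-8)
})

test_that("adaptive RK45 trace matches the exact separable-ODE inversion", {
  pr <- material_params()
  Vp <- 1.36954e-3
  lump <- solve_lumped(pr, Vp, test_waveform(), n_cycles = 1, n_out = 100)
  p_exact <- lumped_pressure_exact(pr, Vp, lump$V_added)
  expect_equal(lump$p, p_exact, tolerance = 1e-7)
  # conservation: V_sp + V_store = V_added along the whole trace
  expect_lt(max(abs(lump$V_sp + lump$V_store - lump$V_added)),
            1e-8 * test_waveform()$V_in)
})

test_that("lumped model reproduces the global pressure and partition scales", {
  pr <- material_params()
  Vp <- 1.36954e-3
  lump <- solve_lumped(pr, Vp, test_waveform(), n_cycles = 1)
  expect_equal(mmHg(max(lump$p)), 8.4, tolerance = 0.05)
  expect_equal(compliance_partition(lump), 0.54, tolerance = 0.05)
  # Model D: high storage coefficient -> spinal share collapses to ~13%
  prD <- material_params(c = 1e-5)
  lumpD <- solve_lumped(prD, Vp, test_waveform(), n_cycles = 1)
  expect_equal(compliance_partition(lumpD), 0.13, tolerance = 0.10)
  # zero parenchymal storage -> everything spinal
  pr0 <- material_params(c = 0)
  lump0 <- solve_lumped(pr0, Vp, test_waveform(), n_cycles = 1)
  expect_equal(compliance_partition(lump0), 1, tolerance = 1e-9)
})
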