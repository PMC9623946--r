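test_that("BJS coefficient and spinal outlet pressure", {
  pr <- material_params()
  expect_equal(bjs_coefficient(pr), 0.8e-3 / sqrt(1e-16))
  expect_equal(bjs_coefficient(pr), 8.0e4)
  pr0 <- material_params(gamma = 1e-12)
  expect_equal(bjs_coefficient(material_params(gamma = 2)),
               2 * bjs_coefficient(pr))
  expect_equal(spinal_outlet_pressure(0, pr), pr$p0)
  expect_equal(spinal_outlet_pressure(0, pr), 599.949, tolerance = 1e-6)
  expect_equal(spinal_outlet_pressure(pr$PVI, pr), 10 * pr$p0)
  expect_equal(pressure_convert(spinal_outlet_pressure(0.8e-6, pr), "Pa", "mmHg"),
               4.5 * 10^(0.8 / 3), tolerance = 1e-12)
  expect_equal(pressure_convert(spinal_outlet_pressure(0.8e-6, pr), "Pa", "mmHg"),
               8.31, tolerance = 1e-3)
})

test_that("rest state is reproduced exactly with zero source", {
  dom <- mini_domain()
  pr <- material_params()
  sys <- build_system(dom, pr, dt = 0.01)
  sys <- icpulse:::factorize_system(sys)
  st <- rest_state(sys)
  for (k in 1:3) {
    res <- icpulse:::step_state(sys, st, g_val = 0, p_out = pr$p0)
    sys <- res$sys
    st <- res$state
  }
  expect_lt(max(abs(st$d)), 1e-10)
  expect_lt(max(abs(st$u)), 1e-10)
  expect_lt(max(abs(st$pp - pr$p0)) / pr$p0, 1e-10)
  expect_lt(max(abs(st$pf - pr$p0)) / pr$p0, 1e-10)
  expect_lt(max(abs(st$phi - pr$alpha * pr$p0)) / pr$p0, 1e-10)
  expect_lt(abs(st$dV_out), 1e-16)
})

test_that("scaled step matrix is symmetric and interface blocks pair up", {
  dom <- mini_domain()
  sys <- build_system(dom, material_params(), dt = 0.02)
  rs <- icpulse:::symmetric_row_scale(sys)
  As <- Matrix::Diagonal(x = rs) %*% sys$A
  expect_lt(max(abs(As - Matrix::t(As))) / max(abs(As)), 1e-14)
  # adjoint pairing of the BJS cross blocks
  sp_d <- sys$spaces$d; sp_u <- sys$spaces$u
  fs <- dom$facets$INTERFACE
  S_du <- icpulse:::asm_facet_bjs(dom, sp_d, sp_u, fs)
  S_ud <- icpulse:::asm_facet_bjs(dom, sp_u, sp_d, fs)
  expect_lt(max(abs(S_du - Matrix::t(S_ud))), 1e-14)
})

test_that("BJS projector formulation equals explicit tangents on a flat interface", {
  dom <- mini_domain()
  sp_u <- icpulse:::fe_space(dom, "CSF", 2L)
  sp_d <- icpulse:::fe_space(dom, "PARENCHYMA", 2L)
  fs <- dom$facets$INTERFACE
  for (pair in list(list(sp_u, sp_u), list(sp_d, sp_u), list(sp_d, sp_d))) {
    Sp <- icpulse:::asm_facet_bjs(dom, pair[[1]], pair[[2]], fs, "projector")
    Se <- icpulse:::asm_facet_bjs(dom, pair[[1]], pair[[2]], fs, "explicit")
    expect_lt(max(abs(Sp - Se)), 1e-12 * max(abs(Sp)))
  }
})

test_that("assembly guards reject bad inputs", {
  dom <- mini_domain()
  pr <- material_params()
  expect_error(build_system(dom, pr, dt = 0), "dt > 0")
  expect_error(build_system(dom, material_params(nu = 0.4999999) , dt = 0.1),
               NA) # admissible
  expect_error(assemble_step(build_system(dom, pr, dt = 0.1),
                             rest_state(build_system(dom, pr, dt = 0.1)),
                             0, -5), "non-negative")
  dom_noout <- two_box_domain(2, "verification")
  expect_error(build_system(dom_noout, pr, dt = 0.1), "outlet")
})
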