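test_that("Lame constants follow the closed-form conversion", {
  # frozen oracle values: evaluate the printed formulas directly
  l <- lame_from_elastic(1500, 0.479)
  expect_equal(l$lam, 0.479 * 1500 / ((1 - 2 * 0.479) * (1 + 0.479)))
  expect_equal(l$lam, 1.1566e4, tolerance = 1e-3)
  expect_equal(l$mu_s, 507.1, tolerance = 1e-3)
  # degenerate nu = 0
  l0 <- lame_from_elastic(123, 0)
  expect_equal(l0$lam, 0)
  expect_equal(l0$mu_s, 123 / 2)
  # linearity in E
  l2 <- lame_from_elastic(3000, 0.479)
  expect_equal(l2$lam, 2 * l$lam)
  expect_equal(l2$mu_s, 2 * l$mu_s)
  expect_error(lame_from_elastic(1500, 0.5), "incompressible")
  expect_error(lame_from_elastic(-1, 0.3), "positive")
})

test_that("pressure conversion and round trips", {
  expect_equal(pressure_convert(0, "mmHg", "Pa"), 0)
  expect_equal(pressure_convert(4.5, "mmHg", "Pa"), 599.949)
  x <- c(0.3, 11, 1234.5)
  expect_equal(pressure_convert(pressure_convert(x, "Pa", "mmHg"),
                                "mmHg", "Pa"), x, tolerance = 1e-15)
  expect_error(match.arg("bar", c("Pa", "mmHg")))
})

test_that("material_params stores SI and re-derives elastic constants", {
  pr <- material_params()
  expect_equal(pr$p0, 4.5 * 133.322)
  expect_equal(pr$PVI, 3e-6)
  # invert (lam, mu_s) -> (E, nu) and recover inputs to 1e-10 relative
  E_back <- pr$mu_s * (3 * pr$lam + 2 * pr$mu_s) / (pr$lam + pr$mu_s)
  nu_back <- pr$lam / (2 * (pr$lam + pr$mu_s))
  expect_equal(E_back, pr$E, tolerance = 1e-10)
  expect_equal(nu_back, pr$nu, tolerance = 1e-10)
  expect_error(material_params(alpha = 0), "alpha")
  expect_error(material_params(c = -1), "storage")
  expect_error(material_params(kappa = 0), "permeability")
  expect_error(material_params(p0 = -2), "p0")
})
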