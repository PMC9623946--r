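test_that("synthetic default waveform satisfies the printed constraints", {
  w <- test_waveform()
  # positive-lobe volume 1.54 ml (kink-aware quadrature)
  vpos <- waveform_volume(w, 0, w$t_rev)
  expect_equal(vpos, 1.54e-6, tolerance = 1e-10)
  # zero net cycle volume to 1e-10 * V_in
  vnet <- waveform_volume(w, 0, w$T)
  expect_lt(abs(vnet), 1e-10 * w$V_in)
  # peak 9 ml/s at t_peak, zero crossing at t_rev
  tg <- seq(0, 1, by = 1e-3)
  expect_equal(max(w$Q(tg)), 9e-6, tolerance = 1e-6)
  expect_equal(w$Q(0.10), 9e-6, tolerance = 1e-6)
  expect_lt(max(abs(w$Q(c(0, 0.38, 1)))), 1e-20)
  expect_true(all(w$Q(seq(0.01, 0.37, by = 0.01)) > 0))
  expect_true(all(w$Q(seq(0.40, 0.99, by = 0.01)) < 0))
  # periodicity to machine precision
  expect_equal(w$Q(tg + 3), w$Q(tg), tolerance = 1e-14)
})

test_that("degenerate and infeasible waveforms", {
  w0 <- synthetic_net_inflow(Q_peak = 0, V_in = 0)
  expect_true(all(w0$Q(seq(0, 2, by = 0.1)) == 0))
  expect_error(synthetic_net_inflow(V_in = 5e-6, Q_peak = 9e-6, t_rev = 0.38),
               "infeasible")
})

test_that("from_samples interpolates, zero-means and round-trips CSV", {
  T <- 0.8
  ts <- seq(0, T, length.out = 65)[-65]
  A <- 2.5e-6
  # pure sinusoid: already zero-mean, interpolant follows it
  w <- from_samples(ts, A * sin(2 * pi * ts / T), T)
  tg <- seq(0, T, length.out = 101)
  expect_lt(max(abs(w$Q(tg) - A * sin(2 * pi * tg / T))), 1e-3 * A)
  # constant samples collapse to zero
  wc <- from_samples(ts, rep(3e-6, length(ts)), T)
  expect_lt(max(abs(wc$Q(tg))), 1e-18)
  # mean m removed exactly at sample points
  m <- 1.1e-6
  wm <- from_samples(ts, A * sin(2 * pi * ts / T) + m, T)
  expect_equal(wm$Q(ts), A * sin(2 * pi * ts / T), tolerance = 1e-12)
  expect_error(from_samples(c(0, 0, 0.1, 0.2), rep(1, 4), T),
               "duplicate|increasing")
  expect_error(from_samples(numeric(0), numeric(0), T), "empty")
  expect_error(from_samples(c(0, 0.1), c(1, 2), T), "4 samples")
  # CSV round trip
  path <- file.path(tempdir(), "wave.csv")
  waveform_to_csv(test_waveform(), path, n = 256)
  w2 <- waveform_from_csv(path, T = 1.0)
  expect_equal(w2$Q(0.1), test_waveform()$Q(0.1), tolerance = 1e-3)
})

test_that("source density is the volume-normalized inflow", {
  w <- test_waveform()
  g <- source_density(w, 1.36954e-3)
  expect_equal(g(0.1), 9e-6 / 1.36954e-3, tolerance = 1e-6)
  expect_equal(g(0.1), 6.57e-3, tolerance = 1e-3)
  gz <- source_density(synthetic_net_inflow(Q_peak = 0, V_in = 0), 1)
  expect_equal(gz(0.2), 0)
  expect_error(source_density(w, 0), "positive")
  # uniformity: integral of g over the mesh equals Q(t)
  dom <- test_domain()
  Vp <- measure(dom, "PARENCHYMA")
  gd <- source_density(w, Vp)
  spp <- icpulse:::fe_space(dom, "PARENCHYMA", 1L)
  int1 <- icpulse:::asm_load_p1(dom, spp)
  expect_equal(sum(int1) * gd(0.15), w$Q(0.15), tolerance = 1e-12)
})
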