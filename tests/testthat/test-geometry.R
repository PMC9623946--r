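test_that("idealized domain matches its volume and cross-section targets", {
  dom <- test_domain()
  expect_equal(measure(dom, "PARENCHYMA") * 1e6, 1369.54, tolerance = 0.02)
  # SAS = CSF minus ventricular cavity and channel
  sas <- dom$meta$L^3 - measure(dom, "PARENCHYMA") -
    30.30e-6 - dom$meta$s_aq^2 * (dom$meta$z_vb - dom$meta$t)
  expect_equal(sas * 1e6, 292.08, tolerance = 0.05)
  expect_equal(measure(dom, "aqueduct"), pi * (2.88e-3 / 2)^2, tolerance = 1e-10)
  expect_equal(measure(dom, "spinal_outlet"),
               pi * (6e-3)^2 - pi * (3.5e-3)^2, tolerance = 1e-10)
  expect_equal(measure(dom, "SPINAL_CORD"), pi * (3.5e-3)^2, tolerance = 1e-10)
  # partition: subdomain volumes sum to the full box volume
  expect_equal(measure(dom, "PARENCHYMA") + measure(dom, "CSF"),
               dom$meta$L^3, tolerance = 1e-12)
  expect_error(measure(dom, "NOWHERE"), "unknown region")
})

test_that("infeasible geometric specs are rejected with a diagnosis", {
  # channel at least as wide as the ventricular cavity
  expect_error(build_idealized(V_ventricle = 1e-8, d_aqueduct = 5e-3),
               "channel wider")
  expect_error(build_idealized(d_cord = 13e-3), "cord wider")
  expect_error(build_idealized(V_sas = -1), "V_sas > 0")
})

test_that("interface orientation and adjacency invariants hold", {
  for (dom in list(mini_domain(), test_domain())) {
    fs <- dom$facets$INTERFACE
    t_csf <- dom$cell_tag[fs$cell]
    t_par <- dom$cell_tag[fs$cell2]
    expect_true(all(t_csf == icpulse:::TAG_CELLS[["CSF"]]))
    expect_true(all(t_par == icpulse:::TAG_CELLS[["PARENCHYMA"]]))
    # stored normal points out of the CSF cell, i.e. from CSF into parenchyma
    ctf <- (dom$vert[fs$tri[, 1], ] + dom$vert[fs$tri[, 2], ] +
            dom$vert[fs$tri[, 3], ]) / 3
    tc <- dom$tet[fs$cell, , drop = FALSE]
    ctc <- (dom$vert[tc[, 1], ] + dom$vert[tc[, 2], ] + dom$vert[tc[, 3], ] +
            dom$vert[tc[, 4], ]) / 4
    expect_true(all(rowSums(fs$normal * (ctf - ctc)) > 0))
  }
})

test_that("probes sit strictly inside their intended subdomains", {
  dom <- test_domain()
  for (nm in names(dom$probes)) {
    loc <- icpulse:::locate_point(dom, dom$probes[[nm]]$point)
    expect_false(is.null(loc))
    expect_equal(unname(dom$cell_tag[loc$cell]),
                 unname(icpulse:::TAG_CELLS[dom$probes[[nm]]$subdomain]))
  }
})

test_that("empty facet sets measure zero", {
  dom <- two_box_domain(2, "verification")
  expect_equal(measure(dom, "SPINAL_SAS"), 0)
})
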