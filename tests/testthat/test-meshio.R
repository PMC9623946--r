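test_that("write/load round trip preserves coordinates, tags and probes", {
  dom <- mini_domain()
  path <- file.path(tempdir(), "mini_mesh")
  write_mesh(dom, path)
  dom2 <- load_mesh(path)
  expect_equal(measure(dom2, "PARENCHYMA"), measure(dom, "PARENCHYMA"),
               tolerance = 1e-12)
  expect_equal(measure(dom2, "CSF"), measure(dom, "CSF"), tolerance = 1e-12)
  expect_identical(sort(as.vector(dom2$tet)), sort(as.vector(dom$tet)))
  for (nm in names(dom$facets)) {
    expect_equal(sum(dom2$facets[[nm]]$area), sum(dom$facets[[nm]]$area),
                 tolerance = 1e-12, label = nm)
  }
  expect_equal(dom2$probes$LV$point, dom$probes$LV$point)
  expect_equal(measure(dom2, "spinal_outlet"), measure(dom, "spinal_outlet"),
               tolerance = 1e-12)
})

test_that("single-subdomain unit cube with all-SKULL boundary loads", {
  raw <- icpulse:::mesh_rectilinear(0:2 / 2, 0:2 / 2, 0:2 / 2)
  ct <- rep(icpulse:::TAG_CELLS[["PARENCHYMA"]], nrow(raw$tet))
  fx <- icpulse:::extract_facets(raw, ct)
  dom <- icpulse:::make_domain(raw$vert, raw$tet, ct,
                               list(SKULL = list(tri = fx$exterior$tri,
                                                 cell = fx$exterior$cell1)))
  expect_equal(measure(dom, "PARENCHYMA"), 1, tolerance = 1e-14)
  path <- file.path(tempdir(), "cube_mesh")
  write_mesh(dom, path)
  expect_equal(measure(load_mesh(path), "PARENCHYMA"), 1, tolerance = 1e-14)
})

test_that("corrupt meshes are rejected", {
  dom <- mini_domain()
  path <- file.path(tempdir(), "bad_mesh")
  write_mesh(dom, path)
  # drop one SKULL facet line -> untagged exterior facet
  lines <- readLines(paste0(path, ".msh"))
  drop <- grep("^\\d+ 2 2 1 1 ", lines)[1]
  ne_line <- which(lines == "$Elements") + 1
  lines[ne_line] <- as.character(as.integer(lines[ne_line]) - 1L)
  writeLines(lines[-drop], paste0(path, ".msh"))
  expect_error(load_mesh(path), "not fully tagged")
  # missing sidecar
  write_mesh(dom, path)
  file.remove(paste0(path, ".json"))
  expect_error(load_mesh(path), "sidecar")
})
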