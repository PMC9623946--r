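test_that("named scenarios differ from standard in exactly one parameter", {
  std <- resolve_scenario("standard")
  expect_equal(std$params$E, 1500)
  expect_equal(std$params$nu, 0.479)
  expect_equal(std$params$c, 1e-6)
  expect_equal(std$params$PVI, 3e-6)
  expect_equal(mmHg(std$params$p0), 4.5)
  diffs <- function(a, b) {
    nm <- names(unclass(a$params))
    nm[vapply(nm, function(k) !isTRUE(all.equal(a$params[[k]], b$params[[k]])),
              TRUE)]
  }
  expect_setequal(diffs(resolve_scenario("A"), std), "PVI")
  expect_equal(resolve_scenario("A")$params$PVI, 10e-6)
  expect_setequal(diffs(resolve_scenario("B"), std), c("E", "lam", "mu_s"))
  expect_equal(resolve_scenario("B")$params$E, 3000)
  expect_setequal(diffs(resolve_scenario("C"), std), c("nu", "lam", "mu_s"))
  expect_equal(resolve_scenario("C")$params$nu, 0.4)
  expect_setequal(diffs(resolve_scenario("D"), std), "c")
  expect_equal(resolve_scenario("D")$params$c, 1e-5)
  expect_error(resolve_scenario("X"), "unknown scenario")
  expect_error(resolve_scenario("A", overrides = list(E = 2000)), "conflict")
  cust <- resolve_scenario("custom", overrides = list(E = 2000))
  expect_equal(cust$params$E, 2000)
})

test_that("config file round trip with unit tags", {
  cfgf <- file.path(tempdir(), "scn.json")
  writeLines('{"scenario": "custom",
    "params": {"E": 2100, "PVI": {"value": 5, "unit": "ml"},
               "p0": {"value": 10, "unit": "mmHg"}},
    "tier": "acceptance", "n_cycles": 2, "steps_per_cycle": 64}', cfgf)
  scn <- read_scenario_config(cfgf)
  expect_equal(scn$params$E, 2100)
  expect_equal(scn$params$PVI, 5e-6)
  expect_equal(scn$params$p0, 10 * 133.322)
  expect_equal(scn$n_cycles, 2L)
})

test_that("run_scenario writes a complete, deterministic artifact bundle", {
  res <- run_model("standard")
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  qoi_export(res$qoi, res$history, d1)
  qoi_export(res$qoi, res$history, d2)
  expect_identical(readLines(file.path(d1, "qoi.csv")),
                   readLines(file.path(d2, "qoi.csv")))
  qcsv <- utils::read.csv(file.path(d1, "qoi.csv"))
  needed <- c("lv_peak", "lv_amplitude", "peak_aqueduct_flow",
              "aqueduct_stroke_volume", "spinal_stroke_volume",
              "peak_displacement", "peak_transmantle_gradient_abs",
              "compliance_partition")
  expect_true(all(needed %in% qcsv$quantity))
  # VTK snapshot of the final state parses structurally
  vf <- file.path(d1, "final.vtk")
  vtk_export(res$domain, res$history$final_state, vf)
  vl <- readLines(vf)
  expect_true(any(grepl("DATASET UNSTRUCTURED_GRID", vl)))
  expect_true(any(grepl("VECTORS displacement", vl)))
})
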