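# Shared fixtures, built once per test run and cached.
#
# Scenario runs use a scaled-down resolution tier (hmax = 0.06 m mesh,
# 2 cycles x 64 steps) so the whole suite stays within its time budget;
# the dt-convergence property test is what justifies this scaling.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

# O(1) verification parameters (not the physiological set): alpha < 1 so the
# steady pressure level is pinned by the interface coupling alone.
vparams <- function() {
  material_params(E = 2.5, nu = 0.25, alpha = 0.9, c = 0.8, kappa = 0.7,
                  mu_f = 0.6, rho_f = 1, rho_s = 1, gamma = 1,
                  PVI = 1, PVI_unit = "m3", p0 = 1, p0_unit = "Pa")
}

test_domain <- function() fixture("dom_test", function() build_idealized(hmax = 0.06))
test_waveform <- function() fixture("wave", function() synthetic_net_inflow())

# miniature production domain (all boundary types, tiny system)
mini_domain <- function() fixture("dom_mini", function() {
  two_box_domain(2, "production", L = 0.05)
})

run_model <- function(name) {
  fixture(paste0("run_", name), function() {
    scn <- resolve_scenario(name, hmax = 0.06, n_cycles = 2,
                            steps_per_cycle = 64)
    run_scenario(scn, domain = test_domain(), waveform = test_waveform())
  })
}

mmHg <- function(pa) pressure_convert(pa, "Pa", "mmHg")
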