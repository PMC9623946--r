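# Scenario-driven end-to-end runs: the standard parameterization and the
# four single-parameter model variations.
#
#   A: PVI = 10 ml        (greater spinal compliance)
#   B: E = 3000 Pa        (stiffer parenchyma)
#   C: nu = 0.4           (greater tissue compressibility)
#   D: c = 1e-5 1/Pa      (greater cranial storage compliance)

SCENARIO_MODS <- list(
  standard = list(),
  A = list(PVI = 10),
  B = list(E = 3000),
  C = list(nu = 0.4),
  D = list(c = 1e-5)
)

#' Resolve a named scenario
#'
#' @param name one of `"standard"`, `"A"`..`"D"`, `"custom"`.
#' @param overrides named list of [material_params()] arguments; only
#'   allowed with `"custom"` (a named scenario deviates from standard in
#'   exactly its one defining parameter).
#' @param tier resolution tier: `"acceptance"` (coarse mesh, 100 steps per
#'   cycle, 3 cycles) or `"fine"` (finer mesh, 320 steps per cycle).
#' @param hmax,n_cycles,steps_per_cycle optional explicit run controls
#'   overriding the tier defaults.
#' @return an `icp_scenario` list with resolved `params`, geometry and run
#'   controls.
#' @export
resolve_scenario <- function(name, overrides = NULL,
                             tier = c("acceptance", "fine"),
                             hmax = NULL, n_cycles = NULL,
                             steps_per_cycle = NULL) {
  tier <- match.arg(tier)
  if (!name %in% c(names(SCENARIO_MODS), "custom")) {
    stop("unknown scenario: ", name)
  }
  mods <- if (name == "custom") list() else SCENARIO_MODS[[name]]
  if (!is.null(overrides) && length(overrides)) {
    if (name != "custom") {
      stop(sprintf("parameter overrides conflict with named scenario '%s'; use name = \"custom\"", name))
    }
    mods <- overrides
  }
  params <- do.call(material_params, mods)
  ctrl <- if (tier == "acceptance") {
    list(hmax = 0.05, n_cycles = 3L, steps_per_cycle = 100L)
  } else {
    list(hmax = 0.02, n_cycles = 3L, steps_per_cycle = 320L)
  }
  if (!is.null(hmax)) ctrl$hmax <- hmax
  if (!is.null(n_cycles)) ctrl$n_cycles <- as.integer(n_cycles)
  if (!is.null(steps_per_cycle)) ctrl$steps_per_cycle <- as.integer(steps_per_cycle)
  structure(list(name = name, params = params, mods = mods, tier = tier,
                 hmax = ctrl$hmax, n_cycles = ctrl$n_cycles,
                 steps_per_cycle = ctrl$steps_per_cycle),
            class = "icp_scenario")
}

#' Run a scenario end to end
#'
#' Builds (or reuses) the idealized geometry and the synthetic net-inflow
#' waveform, marches the coupled system, computes the quantity-of-interest
#' table and the lumped-oracle cross-check, and optionally writes an
#' artifact bundle (QoI CSV/JSON, time-series CSV, waveform echo, lumped
#' trace, VTK snapshot of the final state, and a reproducibility manifest).
#' Identical inputs give bit-identical QoI output (direct solves, no
#' randomness).
#'
#' @param scn an `icp_scenario` from [resolve_scenario()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param domain optional pre-built `icp_domain` (reused across scenarios).
#' @param waveform optional pre-built `icp_waveform`.
#' @param verbose print progress.
#' @return list `history`, `qoi`, `lumped`, `lumped_qoi`, `domain`.
#' @export
run_scenario <- function(scn, out_dir = NULL, domain = NULL, waveform = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(scn, "icp_scenario"))
  if (is.null(domain)) domain <- build_idealized(hmax = scn$hmax)
  if (is.null(waveform)) waveform <- synthetic_net_inflow()
  cfg <- run_config(domain, scn$params, waveform, n_cycles = scn$n_cycles,
                    steps_per_cycle = scn$steps_per_cycle, verbose = verbose)
  h <- run_transient(cfg)
  qoi <- qoi_table(h)
  Vp <- measure(domain, "PARENCHYMA")
  lump <- solve_lumped(scn$params, Vp, waveform, n_cycles = 1)
  lumped_qoi <- list(
    peak_p = max(lump$p),
    amplitude = max(lump$p) - min(lump$p),
    spinal_stroke_volume = max(lump$V_sp),
    compliance_partition = compliance_partition(lump)
  )
  out <- list(history = h, qoi = qoi, lumped = lump, lumped_qoi = lumped_qoi,
              domain = domain, scenario = scn)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    qoi_export(qoi, h, out_dir)
    waveform_to_csv(waveform, file.path(out_dir, "waveform.csv"))
    lumped_to_csv(lump, file.path(out_dir, "lumped.csv"))
    vtk_export(domain, h$final_state, file.path(out_dir, "final_state.vtk"))
    manifest <- list(
      scenario = scn$name, tier = scn$tier, modifications = scn$mods,
      params_si = unclass(scn$params),
      mesh = list(vertices = nrow(domain$vert), tetrahedra = nrow(domain$tet),
                  parenchyma_ml = measure(domain, "PARENCHYMA") * 1e6,
                  csf_ml = measure(domain, "CSF") * 1e6,
                  hmax = scn$hmax),
      run = list(n_cycles = scn$n_cycles,
                 steps_per_cycle = scn$steps_per_cycle, dt = h$dt),
      lumped_crosscheck = lumped_qoi,
      software = list(R = as.character(getRversion()),
                      Matrix = as.character(utils::packageVersion("Matrix")))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Export fields to legacy VTK (ASCII)
#'
#' Unstructured-grid snapshot with point data: displacement, velocity and
#' the three pressures (fields of the subdomain a vertex belongs to; zero
#' elsewhere).
#'
#' @param dom an `icp_domain`.
#' @param st an `icp_state`.
#' @param path output `.vtk` path.
#' @export
vtk_export <- function(dom, st, path) {
  nv <- nrow(dom$vert)
  sp_d <- fe_space(dom, "PARENCHYMA", 2L)
  sp_u <- fe_space(dom, "CSF", 2L)
  sp_pp <- fe_space(dom, "PARENCHYMA", 1L)
  sp_pf <- fe_space(dom, "CSF", 1L)
  pick_vec <- function(sp, vals) {
    out <- matrix(0, nv, 3)
    has <- which(!is.na(sp$vert_dof))
    for (a in 1:3) out[has, a] <- vals[3L * (sp$vert_dof[has] - 1L) + a]
    out
  }
  pick_sca <- function(sp, vals) {
    out <- numeric(nv)
    has <- which(!is.na(sp$vert_dof))
    out[has] <- vals[sp$vert_dof[has]]
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "icpulse fields", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nv)), con)
  writeLines(sprintf("%.9g %.9g %.9g", dom$vert[, 1], dom$vert[, 2],
                     dom$vert[, 3]), con)
  nt <- nrow(dom$tet)
  writeLines(sprintf("CELLS %d %d", nt, 5 * nt), con)
  writeLines(sprintf("4 %d %d %d %d", dom$tet[, 1] - 1L, dom$tet[, 2] - 1L,
                     dom$tet[, 3] - 1L, dom$tet[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(as.character(rep(10L, nt)), con)
  writeLines(sprintf("CELL_DATA %d", nt), con)
  writeLines(c("SCALARS subdomain int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(dom$cell_tag), con)
  writeLines(sprintf("POINT_DATA %d", nv), con)
  d <- pick_vec(sp_d, st$d); u <- pick_vec(sp_u, st$u)
  writeLines("VECTORS displacement double", con)
  writeLines(sprintf("%.9g %.9g %.9g", d[, 1], d[, 2], d[, 3]), con)
  writeLines("VECTORS velocity double", con)
  writeLines(sprintf("%.9g %.9g %.9g", u[, 1], u[, 2], u[, 3]), con)
  for (nm in c("pp", "phi", "pf")) {
    sp <- if (nm == "pf") sp_pf else sp_pp
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", pick_sca(sp, st[[nm]])), con)
  }
  invisible(path)
}

#' Read a scenario configuration file
#'
#' JSON with unit-tagged quantities, e.g.
#' `{"scenario": "custom", "params": {"E": 1500,
#'   "PVI": {"value": 3, "unit": "ml"}, "p0": {"value": 4.5, "unit": "mmHg"}},
#'  "tier": "acceptance", "n_cycles": 3}`.
#'
#' @param path JSON config path.
#' @return an `icp_scenario`.
#' @export
read_scenario_config <- function(path) {
  cfg <- jsonlite::read_json(path)
  name <- cfg$scenario %||% "standard"
  ov <- NULL
  if (!is.null(cfg$params)) {
    ov <- list()
    for (nm in names(cfg$params)) {
      v <- cfg$params[[nm]]
      if (is.list(v)) {
        ov[[nm]] <- v$value
        unit_arg <- paste0(nm, "_unit")
        if (!is.null(v$unit)) ov[[unit_arg]] <- v$unit
      } else ov[[nm]] <- v
    }
  }
  resolve_scenario(name, overrides = ov,
                   tier = cfg$tier %||% "acceptance",
                   hmax = cfg$hmax, n_cycles = cfg$n_cycles,
                   steps_per_cycle = cfg$steps_per_cycle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Invoked by `inst/cli/icsim.R`:
#' `Rscript icsim.R --scenario standard --out runs/standard [--tier acceptance]
#'  [--config cfg.json] [--waveform-csv w.csv] [--cycles 3] [--steps 100]`
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, the [run_scenario()] result.
#' @export
icpulse_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  take <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i)) args[i[1] + 1] else default
  }
  if ("--help" %in% args || length(args) == 0) {
    cat("usage: icsim.R [--scenario standard|A|B|C|D|custom] [--config cfg.json]\n",
        "               [--tier acceptance|paper] [--out DIR] [--cycles N]\n",
        "               [--steps N] [--hmax H] [--waveform-csv FILE] [--mesh PATH]\n")
    return(invisible(NULL))
  }
  scn <- if (!is.null(take("--config"))) {
    read_scenario_config(take("--config"))
  } else {
    resolve_scenario(take("--scenario", "standard"),
                     tier = take("--tier", "acceptance"),
                     hmax = as.numeric(take("--hmax", NA)) %|NA|% NULL,
                     n_cycles = as.numeric(take("--cycles", NA)) %|NA|% NULL,
                     steps_per_cycle = as.numeric(take("--steps", NA)) %|NA|% NULL)
  }
  domain <- if (!is.null(take("--mesh"))) load_mesh(take("--mesh")) else NULL
  waveform <- if (!is.null(take("--waveform-csv"))) {
    waveform_from_csv(take("--waveform-csv"), T = 1.0)
  } else NULL
  out_dir <- take("--out", file.path("runs", scn$name))
  message(sprintf("scenario %s (tier %s) -> %s", scn$name, scn$tier, out_dir))
  res <- run_scenario(scn, out_dir = out_dir, domain = domain,
                      waveform = waveform, verbose = TRUE)
  print(res$qoi)
  invisible(res)
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
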