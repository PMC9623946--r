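# Quantities of interest from a state history.
#
# Intracranial pressure (ICP) is identified with the fluid pressure p_f at
# CSF probe points and with the total pressure phi at parenchyma points.
# All cycle-scoped scalars are evaluated on the final simulated cycle.

#' Probe pressure series
#'
#' For CSF probes the recorded p_f trace is returned; for a parenchyma
#' point, phi snapshots would be required, so arbitrary points are supported
#' by evaluating a given state. Named probes are read from the history.
#'
#' @param h an `icp_history`.
#' @param probe probe name present in the domain.
#' @return data.frame `t`, `p` (Pa).
#' @export
probe_pressure <- function(h, probe) {
  stopifnot(inherits(h, "icp_history"))
  if (!probe %in% colnames(h$probes)) stop("unknown probe: ", probe)
  data.frame(t = h$times, p = h$probes[, probe])
}

#' Evaluate the ICP field of a single state at a point
#'
#' Uses `p_f` if the point lies in the CSF and `phi` in the parenchyma.
#' @param sys an `icp_system`.
#' @param st an `icp_state`.
#' @param point length-3 coordinates (m).
#' @return ICP (Pa).
#' @export
icp_at_point <- function(sys, st, point) {
  loc <- locate_point(sys$dom, point)
  if (is.null(loc)) stop("point outside mesh")
  if (sys$dom$cell_tag[loc$cell] == TAG_CELLS[["CSF"]]) {
    eval_field(sys$dom, sys$spaces$pf, st$pf, loc)
  } else {
    eval_field(sys$dom, sys$spaces$phi, st$phi, loc)
  }
}

#' Nadir-to-peak amplitude over the final cycle
#'
#' @param series numeric pressure series covering the final cycle (or a
#'   data.frame from [probe_pressure()]).
#' @return `max - min` (same unit as input).
#' @export
pressure_amplitude <- function(series) {
  if (is.data.frame(series)) series <- series$p
  if (length(series) == 0) stop("empty series")
  max(series) - min(series)
}

#' Flux series across a named surface
#'
#' @param h an `icp_history`.
#' @param surface surface name (`"aqueduct"`, `"spinal_outlet"`, ...).
#' @return data.frame `t`, `q` (m^3/s, positive along the surface's stored
#'   orientation: out of the cranium for the spinal outlet, ventricle to
#'   SAS for the aqueduct).
#' @export
flux_across <- function(h, surface) {
  stopifnot(inherits(h, "icp_history"))
  if (!surface %in% colnames(h$fluxes)) stop("unknown surface: ", surface)
  data.frame(t = h$times, q = h$fluxes[, surface])
}

#' Stroke volume of a flux series
#'
#' Maximum over the cycle of the cumulative flow volume
#' `max_t int_0^t q dt'` (trapezoidal in time, volume zero at cycle start).
#'
#' @param flux numeric flux series over one cycle (m^3/s) or a data.frame
#'   from [flux_across()].
#' @param dt time step (s); taken from the data.frame spacing if omitted.
#' @return stroke volume (m^3), non-negative.
#' @export
stroke_volume <- function(flux, dt = NULL) {
  if (is.data.frame(flux)) {
    if (is.null(dt)) dt <- stats::median(diff(flux$t))
    flux <- flux$q
  }
  if (length(flux) == 0) stop("empty series")
  if (is.null(dt)) stop("dt required for a bare series")
  q <- c(0, flux)   # volume starts at 0 at cycle start
  cumvol <- cumsum((q[-1] + q[-length(q)]) / 2) * dt
  max(0, max(cumvol))
}

#' Transmantle pressure gradient series
#'
#' `(p_lv - p_sas) / distance` per time point.
#'
#' @param p_lv,p_sas time-aligned pressure series (Pa) or data.frames.
#' @param distance probe separation (m), positive.
#' @return data.frame `t` (if available), `grad` (Pa/m); attributes
#'   `peak_signed` and `peak_abs` over the series.
#' @export
transmantle_gradient <- function(p_lv, p_sas, distance) {
  t <- NULL
  if (is.data.frame(p_lv)) { t <- p_lv$t; p_lv <- p_lv$p }
  if (is.data.frame(p_sas)) {
    if (!is.null(t) && (length(p_sas$t) != length(t) ||
                        max(abs(p_sas$t - t)) > 1e-12)) {
      stop("mismatched time grids")
    }
    p_sas <- p_sas$p
  }
  if (length(p_lv) != length(p_sas)) stop("mismatched time grids")
  if (!is.numeric(distance) || distance <= 0) stop("distance must be positive")
  g <- (p_lv - p_sas) / distance
  out <- if (is.null(t)) data.frame(grad = g) else data.frame(t = t, grad = g)
  attr(out, "peak_signed") <- g[which.max(abs(g))]
  attr(out, "peak_abs") <- max(abs(g))
  out
}

#' Peak tissue displacement over the final cycle
#'
#' Maximum over final-cycle time steps and parenchyma nodes of |d|, with
#' the time of occurrence.
#'
#' @param h an `icp_history`.
#' @return list `value` (m), `time` (s).
#' @export
peak_displacement <- function(h) {
  stopifnot(inherits(h, "icp_history"))
  idx <- cycle_index(h)
  k <- idx[which.max(h$max_disp[idx])]
  list(value = h$max_disp[k], time = h$times[k])
}

#' Summarize the clinical quantities of interest of a run
#'
#' Final-cycle scalars: peak and amplitude of the lateral-ventricle ICP,
#' peak aqueduct flow and aqueduct stroke volume, spinal peak flow and
#' stroke volume, peak displacement, peak transmantle gradient (signed and
#' absolute), the compliance partition (spinal share of the added volume at
#' the end of the net-inflow phase), and the stored parenchymal volume.
#'
#' @param h an `icp_history`.
#' @return object of class `qoi_table` (a list of scalars; see print method
#'   for units).
#' @export
qoi_table <- function(h) {
  stopifnot(inherits(h, "icp_history"))
  idx <- cycle_index(h)
  lv <- h$probes[idx, "LV"]
  sas <- h$probes[idx, "SAS"]
  q_aq <- h$fluxes[idx, "aqueduct"]
  q_sp <- h$fluxes[idx, "spinal_outlet"]
  # cumulative spinal volume relative to cycle start (same quadrature as
  # the dV_out bookkeeping: rectangle rule)
  cum_sp <- h$dV_out[idx] - if (idx[1] == 1) 0 else h$dV_out[idx[1] - 1]
  # end of net-inflow phase within the final cycle
  t_local <- h$times[idx] - (h$n_cycles - 1) * h$waveform$T
  i_rev <- which.min(abs(t_local - h$waveform$t_rev))
  V_added_cyc <- h$V_added[idx] - if (idx[1] == 1) 0 else h$V_added[idx[1] - 1]
  pk <- peak_displacement(h)
  dist <- sqrt(sum((h$domain$probes$LV$point - h$domain$probes$SAS$point)^2))
  tg <- transmantle_gradient(lv, sas, dist)
  structure(list(
    lv_peak = max(lv),
    lv_amplitude = max(lv) - min(lv),
    peak_aqueduct_flow = max(abs(q_aq)),
    aqueduct_stroke_volume = stroke_volume(q_aq, h$dt),
    peak_spinal_flow = max(abs(q_sp)),
    spinal_stroke_volume = max(0, max(cum_sp)),
    spinal_outflow_at_trev = cum_sp[i_rev],
    stored_at_trev = V_added_cyc[i_rev] - cum_sp[i_rev],
    compliance_partition = cum_sp[i_rev] / V_added_cyc[i_rev],
    peak_displacement = pk$value,
    peak_displacement_time = pk$time,
    probe_distance = dist,
    peak_transmantle_gradient_signed = attr(tg, "peak_signed"),
    peak_transmantle_gradient_abs = attr(tg, "peak_abs"),
    periodicity = if (h$n_cycles >= 2) periodic_state_check(h) else NA_real_
  ), class = "qoi_table")
}

#' @export
print.qoi_table <- function(x, ...) {
  mm <- function(p) pressure_convert(p, "Pa", "mmHg")
  cat("Quantities of interest (final cycle):\n")
  cat(sprintf("  LV peak ICP              %8.3f mmHg\n", mm(x$lv_peak)))
  cat(sprintf("  LV nadir-to-peak         %8.3f mmHg\n", mm(x$lv_amplitude)))
  cat(sprintf("  peak aqueduct flow       %8.4f ml/s\n", x$peak_aqueduct_flow * 1e6))
  cat(sprintf("  aqueduct stroke volume   %8.4f ml\n", x$aqueduct_stroke_volume * 1e6))
  cat(sprintf("  peak spinal flow         %8.3f ml/s\n", x$peak_spinal_flow * 1e6))
  cat(sprintf("  spinal stroke volume     %8.3f ml\n", x$spinal_stroke_volume * 1e6))
  cat(sprintf("  spinal share at t_rev    %8.1f %%\n", x$compliance_partition * 100))
  cat(sprintf("  stored volume at t_rev   %8.3f ml\n", x$stored_at_trev * 1e6))
  cat(sprintf("  peak displacement        %8.4f mm at t = %.3f s\n",
              x$peak_displacement * 1e3, x$peak_displacement_time))
  cat(sprintf("  peak transmantle grad    %8.4f mmHg/m (|.|, probe distance %.3f m)\n",
              mm(x$peak_transmantle_gradient_abs), x$probe_distance))
  if (is.finite(x$periodicity))
    cat(sprintf("  cycle periodicity        %8.4f (rel. L2, last two cycles)\n",
                x$periodicity))
  invisible(x)
}

#' Write a QoI table and series to CSV / JSON
#'
#' @param qoi a `qoi_table`.
#' @param h the `icp_history` it came from.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
qoi_export <- function(qoi, h, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scal <- qoi[vapply(qoi, function(v) is.numeric(v) && length(v) == 1, TRUE)]
  utils::write.csv(data.frame(quantity = names(scal),
                              value = unlist(scal)),
                   file.path(dir, "qoi.csv"), row.names = FALSE)
  jsonlite::write_json(scal, file.path(dir, "qoi.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(data.frame(t = h$times, h$probes, h$fluxes,
                              dV_out = h$dV_out),
                   file.path(dir, "series.csv"), row.names = FALSE)
  invisible(dir)
}
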