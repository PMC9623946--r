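# Lumped two-compartment compliance model.
#
# Independent oracle for the global balance quantities of the full
# simulation. A single intracranial pressure p(t) drives two compliances in
# parallel: the parenchymal storage compartment C_b = c * V_p (constant) and
# the spinal compartment with differential compliance
# C_sp(p) = PVI / (p ln 10), i.e. the derivative of the inverse of the
# exponential pressure-volume law p = p0 * 10^(dV/PVI). The prescribed net
# blood inflow Q(t) splits between the two:
#
#   dp/dt      = Q(t) / (C_b + C_sp(p))
#   dV_sp/dt   = C_sp(p) dp/dt
#   dV_store/dt= C_b     dp/dt
#
# The oracle ignores CSF inertia and viscous losses (negligible at these
# pressures) and any spatial pressure variation.

#' Integrate the lumped compliance model
#'
#' Adaptive embedded Runge-Kutta (Cash-Karp 4/5) integration to a relative
#' tolerance of 1e-8, sampled on a uniform grid.
#'
#' @param params an `icp_params`.
#' @param V_p parenchyma volume (m^3).
#' @param waveform an `icp_waveform`.
#' @param n_cycles number of cardiac cycles.
#' @param n_out output samples per cycle.
#' @return an `icp_lumped` list of traces `t`, `p` (Pa), `V_sp`, `V_store`,
#'   `V_added` (m^3).
#' @export
solve_lumped <- function(params, V_p, waveform, n_cycles = 3, n_out = 400,
                         rel_tol = 1e-9) {
  stopifnot(inherits(params, "icp_params"), V_p > 0,
            inherits(waveform, "icp_waveform"))
  Cb <- params$c * V_p
  Csp <- function(p) params$PVI / (p * log(10))
  rhs <- function(t, y) {
    p <- y[1]
    if (p <= 1e-12 * params$p0) {
      stop("lumped model pressure underflow: spinal compliance unbounded")
    }
    waveform$Q(t) / (Cb + Csp(p))
  }
  t_end <- n_cycles * waveform$T
  t_out <- seq(0, t_end, length.out = n_cycles * n_out + 1)
  y <- params$p0
  out <- matrix(NA_real_, length(t_out), 3)
  p_tr <- numeric(length(t_out))
  p_tr[1] <- y
  t <- 0
  h <- waveform$T / 200
  for (k in 2:length(t_out)) {
    tk <- t_out[k]
    while (t < tk - 1e-14) {
      h <- min(h, tk - t)
      st <- rk45_step(rhs, t, y, h, rel_tol = rel_tol,
                      abs_tol = rel_tol * params$p0)
      t <- st$t; y <- st$y; h <- st$h_next
    }
    p_tr[k] <- y
  }
  # both compartment volumes are functions of p alone (exact quadrature of
  # dV_sp = C_sp dp and dV_store = C_b dp along the pressure path)
  out[, 1] <- p_tr
  out[, 2] <- params$PVI * log10(p_tr / params$p0)
  out[, 3] <- Cb * (p_tr - params$p0)
  V_added <- vapply(t_out, function(tt) {
    rem <- tt - floor(tt / waveform$T + 1e-12) * waveform$T
    # per-cycle integral is 0; integrate the remainder (kink-aware)
    if (rem < 1e-14) 0 else waveform_volume(waveform, 0, rem)
  }, 0)
  structure(list(t = t_out, p = out[, 1], V_sp = out[, 2], V_store = out[, 3],
                 V_added = V_added, params = params, V_p = V_p,
                 waveform = waveform),
            class = "icp_lumped")
}

# One adaptive Cash-Karp 4(5) step with step-size control.
rk45_step <- function(f, t, y, h, rel_tol, abs_tol) {
  a <- c(0, 1/5, 3/10, 3/5, 1, 7/8)
  b <- list(c(), c(1/5), c(3/40, 9/40), c(3/10, -9/10, 6/5),
            c(-11/54, 5/2, -70/27, 35/27),
            c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096))
  c5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)
  c4 <- c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4)
  repeat {
    ks <- list(f(t, y))
    for (s in 2:6) {
      yi <- y
      for (m in seq_len(s - 1)) yi <- yi + h * b[[s]][m] * ks[[m]]
      ks[[s]] <- f(t + a[s] * h, yi)
    }
    y5 <- y; y4 <- y
    for (s in 1:6) {
      y5 <- y5 + h * c5[s] * ks[[s]]
      y4 <- y4 + h * c4[s] * ks[[s]]
    }
    err <- max(abs(y5 - y4) / (abs_tol + rel_tol * pmax(abs(y), abs(y5))))
    if (err <= 1 || h < 1e-12) {
      h_next <- h * min(5, max(0.2, 0.9 * (1 / max(err, 1e-10))^0.2))
      return(list(t = t + h, y = y5, h_next = h_next))
    }
    h <- h * max(0.2, 0.9 * (1 / err)^0.25)
  }
}

#' Exact lumped pressure by inversion of the separable ODE
#'
#' The lumped model is separable: the cumulative added volume satisfies
#' `V(p) = C_b (p - p0) + PVI log10(p / p0)`, so `p(t)` is the inverse of a
#' monotone function evaluated at `V_added(t)`. Used as the independent
#' oracle route for [solve_lumped()].
#'
#' @param params an `icp_params`.
#' @param V_p parenchyma volume (m^3).
#' @param V_added cumulative added volume(s) (m^3).
#' @return pressure(s) (Pa).
#' @export
lumped_pressure_exact <- function(params, V_p, V_added) {
  Cb <- params$c * V_p
  vapply(V_added, function(V) {
    fn <- function(p) Cb * (p - params$p0) + params$PVI * log10(p / params$p0) - V
    lo <- params$p0 * 1e-3
    hi <- params$p0
    while (fn(hi) < 0) hi <- hi * 2
    stats::uniroot(fn, c(lo, hi), tol = 1e-14)$root
  }, 0)
}

#' Spinal share of the accommodated volume
#'
#' `V_sp / (V_sp + V_store)` evaluated at the end of the net-inflow phase
#' (`t_rev` of the driving waveform, within the last cycle covered).
#'
#' @param lump an `icp_lumped`.
#' @return fraction in `[0, 1]`.
#' @export
compliance_partition <- function(lump) {
  stopifnot(inherits(lump, "icp_lumped"))
  if (max(lump$t) < lump$waveform$t_rev) stop("history does not cover the net-inflow phase")
  # V_sp and V_store are functions of p alone, so any cycle's t_rev works
  i <- which.min(abs(lump$t - lump$waveform$t_rev))
  num <- lump$V_sp[i]
  den <- lump$V_sp[i] + lump$V_store[i]
  if (den == 0) stop("zero accommodated volume: partition undefined")
  num / den
}

#' CSV export of a lumped trace
#' @param lump an `icp_lumped`.
#' @param path output CSV path.
#' @export
lumped_to_csv <- function(lump, path) {
  utils::write.csv(data.frame(t = lump$t, p_Pa = lump$p, V_sp_m3 = lump$V_sp,
                              V_store_m3 = lump$V_store), path,
                   row.names = FALSE)
  invisible(path)
}
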