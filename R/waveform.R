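# Prescribed periodic net blood inflow Q(t) and the derived uniform
# parenchymal source density g(t) = Q(t) / V_parenchyma.
#
# Q(t) is the difference between arterial inflow and venous outflow: a
# fast-rising positive systolic lobe (phases I-II) followed by a shallower
# negative lobe (phases III-IV), with exactly zero net volume per cycle.

#' Synthesize the net blood inflow waveform
#'
#' Builds a C^1 periodic waveform from the printed constraints: a single
#' positive lobe of volume `V_in` that rises to `Q_peak` at `t_peak` and
#' crosses zero at `t_rev`, followed by a negative lobe over `(t_rev, T)`
#' whose volume is exactly `-V_in`. Each lobe is a scaled quartic bump
#' `s^2 (1-s)^2`-type polynomial with an adjustable interior peak position,
#' so the systolic rise can be faster than the decay.
#'
#' @param T cardiac period (s).
#' @param t_rev zero crossing of the positive lobe (s); net blood outflow
#'   begins here (38\% of the cycle by default).
#' @param V_in positive-lobe volume (m^3).
#' @param Q_peak peak inflow rate (m^3/s).
#' @param t_peak time of the peak (s), `0 < t_peak < t_rev`.
#' @return an object of class `icp_waveform`: list with evaluator `Q(t)`
#'   (periodic, vectorized), `T`, `t_rev`, `V_in`, `Q_peak`, `t_peak`.
#' @examples
#' w <- synthetic_net_inflow()
#' integrate(w$Q, 0, w$T)$value        # ~0: zero net cycle volume
#' @export
synthetic_net_inflow <- function(T = 1.0, t_rev = 0.38, V_in = 1.54e-6,
                                 Q_peak = 9.0e-6, t_peak = 0.10) {
  if (Q_peak == 0 && V_in == 0) {
    w <- structure(list(Q = function(t) rep(0, length(t)), T = T,
                        t_rev = t_rev, V_in = 0, Q_peak = 0, t_peak = t_peak,
                        knots = c(0, T)),
                   class = "icp_waveform")
    return(w)
  }
  stopifnot(T > 0, t_peak > 0, t_peak < t_rev, t_rev < T, V_in > 0, Q_peak > 0)
  if (V_in >= Q_peak * t_rev) {
    stop(sprintf(paste0("infeasible lobe: a nonnegative bump with peak %g and ",
                        "support %g cannot hold V_in = %g m^3"),
                 Q_peak, t_rev, V_in))
  }
  # sharpen/flatten the generic bump until the lobe volume matches V_in
  # exactly (shape degree of freedom; peak value and zero crossing fixed)
  pos <- calibrate_lobe(t_rev, t_peak, Q_peak, V_in)
  # negative lobe: same family on (t_rev, T), scaled to volume -V_in
  dur_n <- T - t_rev
  t_peak_n <- 0.45 * dur_n   # shallow, roughly centered negative lobe
  neg <- make_lobe(dur_n, t_peak_n, 1)
  neg_scale <- -V_in / neg$volume
  Q <- function(t) {
    s <- t %% T
    out <- numeric(length(s))
    i1 <- s <= t_rev
    out[i1] <- pos$f(s[i1])
    out[!i1] <- neg_scale * neg$f(s[!i1] - t_rev)
    out
  }
  structure(list(Q = Q, T = T, t_rev = t_rev, V_in = V_in, Q_peak = Q_peak,
                 t_peak = t_peak,
                 # lobe peaks and the zero crossing are C^1 kinks; quadrature
                 # must honor them piecewise
                 knots = c(0, t_peak, t_rev, t_rev + t_peak_n, T)),
             class = "icp_waveform")
}

#' Integrate a waveform over a time window
#'
#' Piecewise adaptive quadrature honoring the waveform's kink locations
#' (`knots`); plain adaptive quadrature across the C^1 kinks of the lobe
#' construction silently loses ~1e-3 relative accuracy.
#'
#' @param w an `icp_waveform`.
#' @param a,b window bounds (s), `0 <= a <= b <= T`.
#' @return integral of Q over `[a, b]` (m^3).
#' @export
waveform_volume <- function(w, a, b) {
  stopifnot(inherits(w, "icp_waveform"), a >= 0, b <= w$T + 1e-12, a <= b)
  kn <- sort(unique(c(a, b, w$knots[w$knots > a & w$knots < b])))
  tot <- 0
  for (i in seq_len(length(kn) - 1)) {
    tot <- tot + stats::integrate(w$Q, kn[i], kn[i + 1], rel.tol = 1e-12,
                                  subdivisions = 200L)$value
  }
  tot
}

# Single-peaked C^1 bump on (0, L) with peak `amp` at t = tp, zero value and
# slope at both ends: piecewise quintic-smoothstep rise and fall.
# volume = integral over (0, L).
make_lobe <- function(L, tp, amp) {
  smooth <- function(s) s^3 * (10 - 15 * s + 6 * s^2)   # quintic smoothstep
  int_smooth <- 0.5                                     # integral on [0,1]
  f <- function(t) {
    out <- numeric(length(t))
    r <- t > 0 & t <= tp
    d <- t > tp & t < L
    out[r] <- amp * smooth(t[r] / tp)
    out[d] <- amp * smooth((L - t[d]) / (L - tp))
    out
  }
  volume <- amp * (tp * int_smooth + (L - tp) * int_smooth)
  list(f = f, volume = volume)
}

# Choose the interior peak position of the bump so its volume equals V_in
# while the peak value and zero crossing stay fixed. With the smoothstep
# bump, volume = amp * L / 2 independent of tp, so instead the bump is
# blended with a narrower power-sharpened variant.
calibrate_lobe <- function(L, tp, amp, V_in) {
  base <- make_lobe(L, tp, amp)
  # family f_q(t) = amp * (f(t)/amp)^q, q >= 1 narrows the bump (volume
  # decreases monotonically with q); q in (0,1] widens it up to amp*L.
  vol_q <- function(q) {
    f <- function(t) amp * (base$f(t) / amp)^q
    # integrate the rise and decay separately: f has a C^1 kink at tp
    stats::integrate(f, 0, tp, rel.tol = 1e-12, subdivisions = 400L)$value +
      stats::integrate(f, tp, L, rel.tol = 1e-12, subdivisions = 400L)$value
  }
  q <- tryCatch(
    stats::uniroot(function(q) vol_q(q) - V_in, c(0.35, 60), tol = 1e-14)$root,
    error = function(e) stop("infeasible lobe: volume/peak combination outside the bump family")
  )
  f <- function(t) amp * (base$f(t) / amp)^q
  list(f = f, volume = vol_q(q), q = q)
}

#' Periodic waveform from samples
#'
#' Builds a smooth periodic interpolant through `(times, rates)` samples and
#' shifts it by a constant so its cycle integral is exactly zero (the same
#' adjustment applied to measured venous curves to equalize total inflow and
#' outflow).
#'
#' @param times sample times (s), strictly increasing within `[0, T)`.
#' @param rates net inflow samples (m^3/s).
#' @param T cardiac period (s).
#' @return an `icp_waveform`.
#' @export
from_samples <- function(times, rates, T) {
  if (length(times) == 0) stop("empty sample input")
  if (length(times) != length(rates)) stop("times and rates differ in length")
  if (length(times) < 4) stop("need at least 4 samples")
  if (any(duplicated(times))) stop("duplicate sample times")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (min(times) < 0 || max(times) >= T) stop("times must lie in [0, T)")
  sp <- stats::splinefun(c(times, times[1] + T), c(rates, rates[1]),
                         method = "periodic")
  mean_q <- stats::integrate(sp, 0, T, rel.tol = 1e-12,
                             subdivisions = 400L)$value / T
  Q <- function(t) sp(t %% T) - mean_q
  qs <- Q(seq(0, T, length.out = 2001)[-2001])
  pos <- qs > 0
  t_rev <- if (any(pos)) seq(0, T, length.out = 2001)[max(which(pos))] else 0
  V_in <- stats::integrate(function(t) pmax(Q(t), 0), 0, T, rel.tol = 1e-10,
                           subdivisions = 800L)$value
  structure(list(Q = Q, T = T, t_rev = t_rev, V_in = V_in,
                 Q_peak = max(qs),
                 t_peak = seq(0, T, length.out = 2001)[which.max(qs)],
                 knots = c(0, T)),   # periodic spline: smooth everywhere
            class = "icp_waveform")
}

#' Read / write waveform CSV
#'
#' Two-column CSV `t` (s), `Q` (ml/s) with a header line.
#' @param path CSV file path.
#' @param T cardiac period (s).
#' @rdname waveform_csv
#' @export
waveform_from_csv <- function(path, T) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("waveform CSV needs two columns: t [s], Q [ml/s]")
  from_samples(df[[1]], df[[2]] * 1e-6, T)
}

#' @param w an `icp_waveform`.
#' @param n number of sample rows to write.
#' @rdname waveform_csv
#' @export
waveform_to_csv <- function(w, path, n = 200) {
  t <- seq(0, w$T, length.out = n + 1)[-(n + 1)]
  utils::write.csv(data.frame(t = t, Q_ml_s = w$Q(t) * 1e6), path,
                   row.names = FALSE)
  invisible(path)
}

#' Uniform volumetric source density
#'
#' Converts the net inflow rate into the spatially uniform source density
#' `g(t) = Q(t) / V_p`, so that the source integrated over the parenchyma
#' equals `Q(t)` exactly.
#'
#' @param w an `icp_waveform`.
#' @param V_p parenchyma volume (m^3), positive.
#' @return vectorized function `t -> g(t)` (1/s).
#' @export
source_density <- function(w, V_p) {
  stopifnot(inherits(w, "icp_waveform"))
  if (!is.numeric(V_p) || V_p <= 0) stop("parenchyma volume V_p must be positive")
  function(t) w$Q(t) / V_p
}
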