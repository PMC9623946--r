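#' Unit conversion constants
#'
#' 1 mmHg in pascal. All internal computation in icpulse is SI
#' (m, s, Pa, m^3); clinical units (mmHg, ml, ml/s) appear only at the
#' input/output boundary.
#' @keywords internal
MMHG_PA <- 133.322

#' Convert pressures between pascal and mmHg
#'
#' @param value numeric vector of pressures.
#' @param from,to unit labels, one of `"Pa"` or `"mmHg"`.
#' @return numeric vector in the target unit.
#' @examples
#' pressure_convert(4.5, "mmHg", "Pa")   # ~599.95
#' pressure_convert(599.949, "Pa", "mmHg")
#' @export
pressure_convert <- function(value, from = c("Pa", "mmHg"), to = c("Pa", "mmHg")) {
  from <- match.arg(from)
  to <- match.arg(to)
  stopifnot(is.numeric(value))
  if (from == to) return(value)
  if (from == "mmHg") value * MMHG_PA else value / MMHG_PA
}

#' Derive Lame parameters from engineering elastic constants
#'
#' \eqn{\lambda = \nu E /((1-2\nu)(1+\nu))}, \eqn{\mu_s = E/(2(1+\nu))}.
#'
#' @param E Young modulus (Pa), positive.
#' @param nu Poisson ratio, in `[0, 0.5)`.
#' @return list with `lam` and `mu_s` (Pa).
#' @export
lame_from_elastic <- function(E, nu) {
  if (!is.numeric(E) || any(E <= 0)) stop("Young modulus E must be positive")
  if (!is.numeric(nu) || any(nu < 0)) stop("Poisson ratio nu must be >= 0")
  if (any(nu >= 0.5)) {
    stop("nu >= 0.5: incompressible limit, first Lame parameter undefined")
  }
  list(lam = nu * E / ((1 - 2 * nu) * (1 + nu)), mu_s = E / (2 * (1 + nu)))
}

#' Material parameters of the intracranial model
#'
#' Constructs the full physical parameter set, stored in SI units. Defaults
#' are the standard parameterization of the model: soft, nearly
#' incompressible parenchyma, unit Biot-Willis coefficient, low
#' permeability, a 3 ml spinal pressure-volume index and a 4.5 mmHg
#' baseline intracranial pressure. The Lame constants `lam` and `mu_s` are
#' always derived from `(E, nu)` and kept consistent.
#'
#' @param E Young modulus (Pa).
#' @param nu Poisson ratio (dimensionless, `0 <= nu < 0.5`).
#' @param alpha Biot-Willis coefficient (dimensionless, `0 < alpha <= 1`).
#' @param c storage coefficient (1/Pa, `>= 0`).
#' @param kappa permeability (m^2, positive).
#' @param mu_f CSF/ISF dynamic viscosity (Pa s).
#' @param rho_f CSF density (kg/m^3).
#' @param rho_s brain tissue density (kg/m^3). Recorded for completeness;
#'   the quasi-static solid momentum balance carries no inertia term, so
#'   this value is never used by the solver.
#' @param gamma Beavers-Joseph-Saffman slip-rate coefficient (dimensionless).
#' @param PVI spinal pressure-volume index; value in `PVI_unit`.
#' @param PVI_unit `"ml"` or `"m3"`.
#' @param p0 initial intracranial pressure; value in `p0_unit`.
#' @param p0_unit `"mmHg"` or `"Pa"`.
#' @return object of class `icp_params`: a list of SI scalars including the
#'   derived `lam` and `mu_s`.
#' @examples
#' pr <- material_params()
#' pr$lam / pr$mu_s   # nearly incompressible: lambda >> mu_s
#' @export
material_params <- function(E = 1500, nu = 0.479, alpha = 1.0, c = 1e-6,
                            kappa = 1e-16, mu_f = 0.8e-3,
                            rho_f = 1007, rho_s = 1081, gamma = 1,
                            PVI = 3, PVI_unit = c("ml", "m3"),
                            p0 = 4.5, p0_unit = c("mmHg", "Pa")) {
  PVI_unit <- match.arg(PVI_unit)
  p0_unit <- match.arg(p0_unit)
  PVI_si <- if (PVI_unit == "ml") PVI * 1e-6 else PVI
  p0_si <- if (p0_unit == "mmHg") pressure_convert(p0, "mmHg", "Pa") else p0
  stopifnot(
    is.numeric(E), length(E) == 1L,
    is.numeric(nu), length(nu) == 1L
  )
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must satisfy 0 < alpha <= 1")
  if (c < 0) stop("storage coefficient c must be >= 0")
  if (kappa <= 0) stop("permeability kappa must be positive")
  if (mu_f <= 0) stop("viscosity mu_f must be positive")
  if (PVI_si <= 0) stop("PVI must be positive")
  if (p0_si <= 0) stop("p0 must be positive")
  lame <- lame_from_elastic(E, nu)
  structure(list(
    E = E, nu = nu, lam = lame$lam, mu_s = lame$mu_s,
    alpha = alpha, c = c, kappa = kappa, mu_f = mu_f,
    rho_f = rho_f, rho_s = rho_s, gamma = gamma,
    PVI = PVI_si, p0 = p0_si
  ), class = "icp_params")
}

#' @export
print.icp_params <- function(x, ...) {
  cat("Intracranial material parameters (SI):\n")
  cat(sprintf("  E      = %g Pa, nu = %g  ->  lam = %g Pa, mu_s = %g Pa\n",
              x$E, x$nu, x$lam, x$mu_s))
  cat(sprintf("  alpha  = %g, c = %g 1/Pa, kappa = %g m^2\n",
              x$alpha, x$c, x$kappa))
  cat(sprintf("  mu_f   = %g Pa s, rho_f = %g, rho_s = %g kg/m^3, gamma = %g\n",
              x$mu_f, x$rho_f, x$rho_s, x$gamma))
  cat(sprintf("  PVI    = %g ml, p0 = %g mmHg (%g Pa)\n",
              x$PVI * 1e6, pressure_convert(x$p0, "Pa", "mmHg"), x$p0))
  invisible(x)
}
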