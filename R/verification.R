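# Manufactured-solution verification harness.
#
# Fixture: two stacked boxes sharing the flat interface z = 0 — parenchyma
# below (z in [-1, 0]), CSF above (z in [0, 1]) — the simplest geometry on
# which the transmission conditions can be satisfied exactly with explicit
# tangents. Exterior boundaries carry Dirichlet data of the exact fields
# (d and p_p on the parenchyma side, u on the CSF side); p_f is pinned
# through the interface coupling and needs no boundary condition.

#' Two-box verification fixture
#'
#' @param n cells per unit length (the full fixture is 1 x 1 x 2).
#' @param tagging `"verification"` (whole CSF exterior tagged SKULL and
#'   whole parenchyma exterior tagged SPINAL_CORD, used as Dirichlet
#'   carriers for manufactured data; no outlet) or `"production"` (CSF
#'   exterior = SKULL except the top face = SPINAL_SAS outlet; parenchyma
#'   exterior = SPINAL_CORD), the latter a miniature domain with the full
#'   physiological boundary-condition set, probes and flux surfaces.
#' @param L edge length scale (m).
#' @return an `icp_domain`.
#' @export
two_box_domain <- function(n = 2, tagging = c("verification", "production"),
                           L = 1) {
  tagging <- match.arg(tagging)
  ticks1 <- seq(0, L, length.out = n + 1)
  ticksz <- seq(-L, L, length.out = 2 * n + 1)
  raw <- mesh_rectilinear(ticks1, ticks1, ticksz)
  ctr <- raw$box_center[raw$box_of_tet, , drop = FALSE]
  cell_tag <- ifelse(ctr[, 3] < 0, TAG_CELLS[["PARENCHYMA"]], TAG_CELLS[["CSF"]])
  fx <- extract_facets(raw, cell_tag)
  ext <- fx$exterior
  fc <- (raw$vert[ext$tri[, 1], , drop = FALSE] + raw$vert[ext$tri[, 2], , drop = FALSE] +
         raw$vert[ext$tri[, 3], , drop = FALSE]) / 3
  par_side <- fc[, 3] < 0
  top <- fc[, 3] > L - 1e-12 * max(1, L)
  pick <- function(sel) list(tri = ext$tri[sel, , drop = FALSE],
                             cell = ext$cell1[sel])
  ifc_csf <- ifelse(cell_tag[fx$interface$cell1] == TAG_CELLS[["CSF"]],
                    fx$interface$cell1, fx$interface$cell2)
  ifc_par <- ifelse(cell_tag[fx$interface$cell1] == TAG_CELLS[["CSF"]],
                    fx$interface$cell2, fx$interface$cell1)
  iface <- list(tri = fx$interface$tri, cell = ifc_csf, cell2 = ifc_par)
  if (tagging == "production") {
    facet_sets <- list(SKULL = pick(!par_side & !top),
                       SPINAL_CORD = pick(par_side),
                       SPINAL_SAS = pick(top),
                       INTERFACE = iface)
    probes <- list(
      LV = list(point = c(L / 2 + L * 0.01, L / 2, L / 2), subdomain = "CSF"),
      SAS = list(point = c(L / 2 + L * 0.01, L / 2, 0.9 * L), subdomain = "CSF"),
      V4 = list(point = c(L / 2 + L * 0.01, L / 2, 0.1 * L), subdomain = "CSF"))
    surfaces <- list(
      aqueduct = list(tri = iface$tri, cell = iface$cell,
                      direction = c(0, 0, -1)),
      spinal_outlet = list(tri = facet_sets$SPINAL_SAS$tri,
                           cell = facet_sets$SPINAL_SAS$cell,
                           direction = c(0, 0, 1)))
    return(make_domain(raw$vert, raw$tet, cell_tag, facet_sets, probes,
                       surfaces,
                       meta = list(kind = "two-box-production", n = n, L = L)))
  } else {
    facet_sets <- list(SKULL = pick(!par_side),       # CSF exterior
                       SPINAL_CORD = pick(par_side),  # parenchyma exterior
                       SPINAL_SAS = list(tri = ext$tri[0, , drop = FALSE],
                                         cell = integer(0)),
                       INTERFACE = iface)
  }
  make_domain(raw$vert, raw$tet, cell_tag, facet_sets,
              meta = list(kind = paste0("two-box-", tagging), n = n, L = L))
}

#' Build a manufactured solution case
#'
#' Closed-form fields on the two-box fixture satisfying the interface
#' conditions exactly. Two families:
#'
#' * `"trig"` (steady): trigonometric fields for spatial convergence.
#'   With wavenumber k, streamfunction `psi = f0 cos(k z) sin(k x)` gives a
#'   divergence-free `u`; `d` mixes a divergence-free part `b0` and a
#'   compressible part `e0 z^2 cos(k x)`; pressures vanish on the interface
#'   so the normal-stress balance holds for any Biot-Willis coefficient.
#' * `"poly"` (transient): fields quadratic/linear in space (inside the
#'   P2/P1 spaces, so spatial error vanishes) with smooth time factors,
#'   isolating the O(dt) implicit-Euler error.
#'
#' The constructor verifies the interface conditions numerically at random
#' interface points and stops if the ansatz violates them.
#'
#' @param params an `icp_params` (use O(1) verification parameters, not the
#'   physiological set, and `alpha < 1` so the steady pressure level is
#'   controlled by the interface coupling).
#' @param family `"trig"` or `"poly"`.
#' @param k wavenumber (trig family).
#' @param omega angular frequency (poly family).
#' @return a `manufactured_case`: closures for all fields, forcing terms
#'   and time factors.
#' @export
build_case <- function(params, family = c("trig", "trig0", "poly", "patch"), k = pi,
                       omega = 2 * pi) {
  family <- match.arg(family)
  mu_f <- params$mu_f; mu_s <- params$mu_s; lam <- params$lam
  alpha <- params$alpha; kap <- params$kappa; cst <- params$c
  rho_f <- params$rho_f
  if (family == "trig") {
    f0 <- 1; b0 <- 1; e0 <- 0.5
    P1 <- f0 * mu_f / kap          # from the normal-flux condition (3a)
    pf0 <- 1
    case <- list(
      family = "trig", params = params,
      u = function(x, t = 0) cbind(-f0 * k * sin(k * x[, 3]) * sin(k * x[, 1]),
                                   0 * x[, 1],
                                   -f0 * k * cos(k * x[, 3]) * cos(k * x[, 1])),
      pf = function(x, t = 0) pf0 * cos(k * x[, 1]) * sin(k * x[, 3]),
      d = function(x, t = 0) cbind(b0 * sin(k * x[, 1]) * sin(k * x[, 3]),
                                   0 * x[, 1],
                                   cos(k * x[, 1]) * (b0 * cos(k * x[, 3]) +
                                                        e0 * x[, 3]^2)),
      pp = function(x, t = 0) P1 * sin(k * x[, 3]) * cos(k * x[, 1]),
      phi = function(x, t = 0) alpha * P1 * sin(k * x[, 3]) * cos(k * x[, 1]) -
        2 * lam * e0 * x[, 3] * cos(k * x[, 1]),
      # forcing: f_u = -div(2 mu_f eps(u)) + grad pf ; f_d likewise with phi;
      # g_m = -div(kappa/mu_f grad pp)
      f_u = function(x, t = 0) {
        s1 <- sin(k * x[, 1]); c1 <- cos(k * x[, 1])
        s3 <- sin(k * x[, 3]); c3 <- cos(k * x[, 3])
        cbind(2 * mu_f * k^2 * (-f0 * k * s3 * s1) - pf0 * k * s1 * s3,
              0 * s1,
              2 * mu_f * k^2 * (-f0 * k * c3 * c1) + pf0 * k * c1 * c3)
      },
      f_d = function(x, t = 0) {
        s1 <- sin(k * x[, 1]); c1 <- cos(k * x[, 1])
        s3 <- sin(k * x[, 3]); c3 <- cos(k * x[, 3])
        z <- x[, 3]
        lap_d1 <- -2 * k^2 * b0 * s1 * s3
        lap_d3 <- -2 * k^2 * b0 * c1 * c3 - k^2 * e0 * z^2 * c1 + 2 * e0 * c1
        grad_div1 <- -2 * e0 * k * z * s1
        grad_div3 <- 2 * e0 * c1
        gphi1 <- -k * (alpha * P1 * s3 - 2 * lam * e0 * z) * s1
        gphi3 <- (alpha * P1 * k * c3 - 2 * lam * e0) * c1
        cbind(-mu_s * (lap_d1 + grad_div1) + gphi1,
              0 * s1,
              -mu_s * (lap_d3 + grad_div3) + gphi3)
      },
      g_m = function(x, t = 0) (kap / mu_f) * 2 * k^2 * P1 *
        sin(k * x[, 3]) * cos(k * x[, 1])
    )
  } else if (family == "trig0") {
    # steady trigonometric case with identically zero pore pressure and
    # zero interface velocity trace (streamfunction ~ z^3): the quadratic
    # fields d and u converge at their own element order, free of the
    # lower-order pressure-trace pollution of the fully coupled "trig"
    # case.
    f0 <- 1; b0 <- 1; e0 <- 0.5; pf0 <- 1
    case <- list(
      family = "trig0", params = params,
      u = function(x, t = 0) cbind(3 * f0 * x[, 3]^2 * sin(k * x[, 1]),
                                   0 * x[, 1],
                                   -k * f0 * x[, 3]^3 * cos(k * x[, 1])),
      pf = function(x, t = 0) pf0 * cos(k * x[, 1]) * sin(k * x[, 3]),
      d = function(x, t = 0) cbind(b0 * sin(k * x[, 1]) * sin(k * x[, 3]),
                                   0 * x[, 1],
                                   cos(k * x[, 1]) * (b0 * cos(k * x[, 3]) +
                                                        e0 * x[, 3]^2)),
      pp = function(x, t = 0) rep(0, nrow(x)),
      phi = function(x, t = 0) -2 * lam * e0 * x[, 3] * cos(k * x[, 1]),
      f_u = function(x, t = 0) {
        s1 <- sin(k * x[, 1]); c1 <- cos(k * x[, 1])
        z <- x[, 3]
        cbind(-mu_f * f0 * (6 - 3 * k^2 * z^2) * s1 -
                pf0 * k * s1 * sin(k * z),
              0 * s1,
              mu_f * k * f0 * (6 * z - k^2 * z^3) * c1 +
                pf0 * k * c1 * cos(k * z))
      },
      f_d = function(x, t = 0) {
        s1 <- sin(k * x[, 1]); c1 <- cos(k * x[, 1])
        s3 <- sin(k * x[, 3]); c3 <- cos(k * x[, 3])
        z <- x[, 3]
        lap_d1 <- -2 * k^2 * b0 * s1 * s3
        lap_d3 <- -2 * k^2 * b0 * c1 * c3 - k^2 * e0 * z^2 * c1 + 2 * e0 * c1
        grad_div1 <- -2 * e0 * k * z * s1
        grad_div3 <- 2 * e0 * c1
        gphi1 <- 2 * lam * e0 * k * z * s1
        gphi3 <- -2 * lam * e0 * c1
        cbind(-mu_s * (lap_d1 + grad_div1) + gphi1,
              0 * s1,
              -mu_s * (lap_d3 + grad_div3) + gphi3)
      },
      g_m = function(x, t = 0) rep(0, nrow(x))
    )
  } else if (family == "patch") {
    # steady, spatially polynomial (patch test): fields lie inside the
    # P2/P1 spaces, so the discrete solution reproduces them to solver
    # tolerance on any mesh.
    Ppz <- 1.2; Pfz <- 0.7; b2 <- 0.4
    w0 <- -(kap / mu_f) * Ppz          # normal-flux condition (3a), steady
    case <- list(
      family = "patch", params = params,
      u = function(x, t = 0) cbind(0 * x[, 1], 0 * x[, 1], rep(w0, nrow(x))),
      pf = function(x, t = 0) Pfz * x[, 3],
      d = function(x, t = 0) cbind(0 * x[, 1], 0 * x[, 1], b2 * x[, 3]^2),
      pp = function(x, t = 0) Ppz * x[, 3],
      phi = function(x, t = 0) alpha * Ppz * x[, 3] - 2 * lam * b2 * x[, 3],
      f_u = function(x, t = 0) cbind(0 * x[, 1], 0 * x[, 1], rep(Pfz, nrow(x))),
      f_d = function(x, t = 0) cbind(0 * x[, 1], 0 * x[, 1],
                                     rep(-4 * mu_s * b2 + alpha * Ppz -
                                           2 * lam * b2, nrow(x))),
      g_m = function(x, t = 0) rep(0, nrow(x))
    )
  } else {
    # spatially polynomial transient case: u constant in space, d quadratic
    # in z, pressures linear in z; theta(t) = cos(omega t) drives u and the
    # pressures, theta_d(t) = sin(omega t)/omega drives d so that
    # d/dt theta_d = theta and the flux condition (3a) holds at all times.
    w0 <- 0.3; b00 <- 1; b2 <- 0.4
    Ppz <- 2         # pp = theta * Ppz * z
    Pfz <- 1.5
    # (3a) at z = 0 (n = -e3): -w0 = -b00 + (kappa/mu_f) Ppz
    b00 <- w0 + (kap / mu_f) * Ppz
    th <- function(t) cos(omega * t)
    thd <- function(t) sin(omega * t) / omega
    case <- list(
      family = "poly", params = params, omega = omega,
      theta = th, theta_d = thd,
      u = function(x, t = 0) cbind(0 * x[, 1], 0 * x[, 1],
                                   rep(w0 * th(t), nrow(x))),
      pf = function(x, t = 0) th(t) * Pfz * x[, 3],
      d = function(x, t = 0) cbind(0 * x[, 1], 0 * x[, 1],
                                   thd(t) * (b00 + b2 * x[, 3]^2)),
      pp = function(x, t = 0) th(t) * Ppz * x[, 3],
      phi = function(x, t = 0) alpha * th(t) * Ppz * x[, 3] -
        lam * thd(t) * 2 * b2 * x[, 3],
      f_u = function(x, t = 0) {
        dth <- -omega * sin(omega * t)
        cbind(0 * x[, 1], 0 * x[, 1],
              rho_f * w0 * dth + th(t) * Pfz)
      },
      f_d = function(x, t = 0) {
        # -div(2 mu_s eps(d) - phi I) = -mu_s(lap d + grad div d) + grad phi
        cbind(0 * x[, 1], 0 * x[, 1],
              -mu_s * (thd(t) * 2 * b2 + thd(t) * 2 * b2) +
                alpha * th(t) * Ppz - lam * thd(t) * 2 * b2)
      },
      g_m = function(x, t = 0) {
        dth <- -omega * sin(omega * t)
        # (c + a^2/l) dpp/dt - (a/l) dphi/dt - div(k/mu grad pp)
        (cst + alpha^2 / lam) * dth * Ppz * x[, 3] -
          (alpha / lam) * (alpha * dth * Ppz * x[, 3] -
                             lam * th(t) * 2 * b2 * x[, 3])
      }
    )
  }
  class(case) <- "manufactured_case"
  check_case_interface(case)
  case
}

# Numerical check of the transmission conditions of a manufactured case on
# the flat interface z = 0 (normal n = -e3 pointing CSF -> parenchyma).
check_case_interface <- function(case, nx = 7, tt = 0.21) {
  p <- case$params
  x <- cbind(seq(0.05, 0.95, length.out = nx), rep(0.4, nx), rep(0, nx))
  hh <- 1e-6
  num_dz <- function(f, comp) (f(x + cbind(0, 0, rep(hh, nx)), tt)[, comp] -
                                 f(x - cbind(0, 0, rep(hh, nx)), tt)[, comp]) / (2 * hh)
  num_dz_s <- function(f) (f(x + cbind(0, 0, rep(hh, nx)), tt) -
                             f(x - cbind(0, 0, rep(hh, nx)), tt)) / (2 * hh)
  num_dx_s <- function(f) (f(x + cbind(rep(hh, nx), 0, 0), tt) -
                             f(x - cbind(rep(hh, nx), 0, 0), tt)) / (2 * hh)
  dt_d <- if (case$family == "poly") {
    function(x_, t_) {
      e <- 1e-6
      (case$d(x_, t_ + e) - case$d(x_, t_ - e)) / (2 * e)
    }
  } else function(x_, t_) 0 * case$d(x_, t_)
  u <- case$u(x, tt); d_t <- dt_d(x, tt)
  tol <- 1e-5
  # (3a): -u3 = -dt_d3 + (kappa/mu_f) d_z pp
  r3a <- -u[, 3] - (-d_t[, 3] + (p$kappa / p$mu_f) * num_dz_s(function(x_, t_)
    case$pp(x_, t_)))
  # (3c): sigma_f33 = -pp  with sigma_f33 = 2 mu_f dz u3 - pf
  s_f33 <- 2 * p$mu_f * num_dz(case$u, 3) - case$pf(x, tt)
  r3c <- s_f33 + case$pp(x, tt)
  # (3b) normal: sigma_p33 = sigma_f33
  s_p33 <- 2 * p$mu_s * num_dz(case$d, 3) - case$phi(x, tt)
  r3b <- s_p33 - s_f33
  # (3d)/(3b) tangential: fluid and solid shear vanish, and slip is zero
  shear_f <- p$mu_f * (num_dz(case$u, 1) + num_dx_s(function(x_, t_) case$u(x_, t_)[, 3]))
  shear_s <- p$mu_s * (num_dz(case$d, 1) + num_dx_s(function(x_, t_) case$d(x_, t_)[, 3]))
  slip <- (u - d_t)[, c(1, 2)]
  worst <- max(abs(r3a), abs(r3c), abs(r3b), abs(shear_f), abs(shear_s), abs(slip))
  if (worst > tol) {
    stop(sprintf("manufactured ansatz violates the interface conditions (residual %.3g)", worst))
  }
  invisible(TRUE)
}

#' Solve a manufactured case on a fixture
#'
#' Steady (trig) cases assemble the steady operator with the case forcing
#' and exact Dirichlet data; transient (poly) cases start from the exact
#' initial state and march `n_steps` implicit-Euler steps to `t_end`.
#'
#' @param case a `manufactured_case`.
#' @param dom a two-box `icp_domain` (verification tagging).
#' @param n_steps steps for the transient family.
#' @param t_end final time for the transient family (s).
#' @return list with the system, solution vector/state, and L2 errors per
#'   field (`d`, `pp`, `phi`, `u`, `pf`).
#' @export
solve_case <- function(case, dom, n_steps = 8, t_end = 0.5) {
  p <- case$params
  if (case$family %in% c("trig", "trig0", "patch")) {
    bc <- list(d = list(facets = "SPINAL_CORD", fn = function(x) case$d(x)),
               pp = list(facets = "SPINAL_CORD", fn = function(x) case$pp(x)),
               u = list(facets = "SKULL", fn = function(x) case$u(x)))
    sys <- build_system(dom, p, mode = "steady", dirichlet = bc)
    b <- case_rhs(sys, case, t = 0)
    x <- solve_steady(sys, b)
    st <- vec_to_state(sys, x)
    t_err <- 0
  } else {
    dt <- t_end / n_steps
    # time-dependent Dirichlet data: rebuild constraint values per step
    sys <- build_system(dom, p, dt = dt, mode = "transient",
                        dirichlet = list(
                          d = list(facets = "SPINAL_CORD", fn = function(x) case$d(x, 0)),
                          pp = list(facets = "SPINAL_CORD", fn = function(x) case$pp(x, 0)),
                          u = list(facets = "SKULL", fn = function(x) case$u(x, 0))))
    sys <- factorize_system(sys)
    st <- exact_state(sys, case, t = 0)
    for (nstep in seq_len(n_steps)) {
      tn1 <- nstep * dt
      sys$cvals <- dirichlet_values(sys, case, tn1)
      b <- case_rhs(sys, case, t = tn1) +
        as.numeric(sys$C %*% state_to_vec(sys, st))
      x <- solve_system(sys, b)
      st <- vec_to_state(sys, x, t = tn1)
    }
    t_err <- t_end
  }
  errs <- c(
    d = l2_error(dom, sys$spaces$d, st$d, function(x) case$d(x, t_err), vec = TRUE),
    pp = l2_error(dom, sys$spaces$pp, st$pp, function(x) case$pp(x, t_err)),
    phi = l2_error(dom, sys$spaces$phi, st$phi, function(x) case$phi(x, t_err)),
    u = l2_error(dom, sys$spaces$u, st$u, function(x) case$u(x, t_err), vec = TRUE),
    pf = l2_error(dom, sys$spaces$pf, st$pf, function(x) case$pf(x, t_err))
  )
  list(sys = sys, state = st, errors = errs)
}

# Forcing right-hand side of a case at time t (unscaled equation rows).
case_rhs <- function(sys, case, t) {
  b <- numeric(sys$N)
  bd <- asm_load_closure(sys$dom, sys$spaces$d, function(x) case$f_d(x, t), vec = TRUE)
  bu <- asm_load_closure(sys$dom, sys$spaces$u, function(x) case$f_u(x, t), vec = TRUE)
  bp <- asm_load_closure(sys$dom, sys$spaces$pp, function(x) case$g_m(x, t))
  b[sys$off$d + seq_along(bd)] <- bd
  b[sys$off$u + seq_along(bu)] <- bu
  b[sys$off$pp + seq_along(bp)] <- bp
  b
}

# Interpolate the exact fields of a case into a state at time t.
exact_state <- function(sys, case, t) {
  structure(list(
    d = interp_space(sys$spaces$d, function(x) case$d(x, t), vec = TRUE),
    pp = interp_space(sys$spaces$pp, function(x) case$pp(x, t)),
    phi = interp_space(sys$spaces$phi, function(x) case$phi(x, t)),
    u = interp_space(sys$spaces$u, function(x) case$u(x, t), vec = TRUE),
    pf = interp_space(sys$spaces$pf, function(x) case$pf(x, t)),
    dV_out = 0, t = t
  ), class = "icp_state")
}

# Recompute the Dirichlet value vector of a system at time t.
dirichlet_values <- function(sys, case, t) {
  off <- sys$off
  vals <- numeric(length(sys$cdofs))
  for (i in seq_along(sys$cdofs)) {
    g <- sys$cdofs[i]
    if (g > off$u && g <= off$u + 3L * sys$spaces$u$ndof) {
      s <- g - off$u; sd <- (s - 1) %/% 3 + 1; comp <- (s - 1) %% 3 + 1
      vals[i] <- case$u(sys$spaces$u$coords[sd, , drop = FALSE], t)[, comp]
    } else if (g <= 3L * sys$spaces$d$ndof) {
      sd <- (g - 1) %/% 3 + 1; comp <- (g - 1) %% 3 + 1
      vals[i] <- case$d(sys$spaces$d$coords[sd, , drop = FALSE], t)[, comp]
    } else if (g > off$pp && g <= off$pp + sys$spaces$pp$ndof) {
      vals[i] <- case$pp(sys$spaces$pp$coords[g - off$pp, , drop = FALSE], t)
    }
  }
  vals
}

#' Convergence study
#'
#' Solves a case on a sequence of refinements and reports least-squares
#' slopes of log error against log h (or log dt).
#'
#' @param params verification parameters (`icp_params`).
#' @param family `"trig"` (spatial) or `"poly"` (temporal).
#' @param levels mesh sizes n (trig) or step counts (poly).
#' @param n_fixed fixed mesh size for the temporal study.
#' @return list with `errors` (matrix levels x fields), `rates` (named
#'   vector), `h` and a `monotone` flag per field.
#' @export
convergence_study <- function(params, family = c("trig", "trig0", "poly"),
                              levels = if (family[1] == "poly") c(32, 64, 128)
                              else c(2, 4, 8),
                              n_fixed = 2) {
  family <- match.arg(family)
  if (length(levels) < 3) stop("need at least 3 refinement levels")
  errs <- NULL
  hs <- numeric(0)
  for (lv in levels) {
    if (family != "poly") {
      dom <- two_box_domain(lv, "verification")
      case <- build_case(params, family)
      res <- solve_case(case, dom)
      hs <- c(hs, 1 / lv)
    } else {
      dom <- two_box_domain(n_fixed, "verification")
      case <- build_case(params, "poly")
      res <- solve_case(case, dom, n_steps = lv, t_end = 0.5)
      hs <- c(hs, 0.5 / lv)
    }
    errs <- rbind(errs, res$errors)
  }
  rates <- apply(errs, 2, function(e) {
    if (any(e <= 0)) return(NA_real_)
    as.numeric(stats::coef(stats::lm(log(e) ~ log(hs)))[2])
  })
  nl <- nrow(errs)
  rates_finest <- log(errs[nl - 1, ] / errs[nl, ]) /
    log(hs[nl - 1] / hs[nl])
  monotone <- apply(errs, 2, function(e) all(diff(e) < 0))
  if (any(!monotone)) {
    warning("non-monotone error sequence for: ",
            paste(colnames(errs)[!monotone], collapse = ", "))
  }
  list(errors = errs, rates = rates, rates_finest = rates_finest, h = hs,
       monotone = monotone)
}
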