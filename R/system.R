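# Monolithic discrete system for one implicit-Euler step of the coupled
# three-field Biot / Stokes problem with Beavers-Joseph-Saffman (BJS)
# transmission conditions.
#
# Unknown ordering: x = [ d (3 nd) | p_p (np) | phi (np) | u (3 nu) | p_f (nf) ].
# With tau = dt, beta = gamma mu_f / sqrt(kappa), interface normal n pointing
# from the CSF into the parenchyma, and backward differences for all time
# derivatives (including the interface trace of dd/dt), the weak form reads:
#
#  d rows:   mu_s K2 d + (beta/tau) S dd - B^T phi - G^T p_p - beta S du u
#            = (beta/tau) S dd^n
#  phi rows: M phi - alpha M p_p + lambda B d = 0
#  p_p rows: ((c + a^2/l)/tau) M p_p - (a/l)/tau M phi + (k/mu_f) K p_p
#            + (1/tau) G d - G u  =  g M 1 + (prev terms)
#  u rows:   (rho_f/tau) M2 u + mu_f K2 u + beta S uu - (beta/tau) S ud
#            - B_u^T p_f + G_u^T p_p = (prev terms) - p_out b_out
#  p_f rows: B_u u = 0
#
# The nonlinear spinal outlet traction is linearized by time lag: p_out at
# step n+1 uses the outflow volume accumulated through step n, keeping every
# step a single linear solve with a constant matrix (factorized once).

#' BJS slip coefficient
#'
#' Returns \eqn{\gamma \mu_f / \sqrt{\kappa}} (Pa s/m).
#' @param params an `icp_params`.
#' @export
bjs_coefficient <- function(params) {
  if (params$kappa <= 0) stop("kappa must be positive")
  params$gamma * params$mu_f / sqrt(params$kappa)
}

#' Spinal outlet pressure from accumulated outflow volume
#'
#' Exponential craniospinal compliance law `p = p0 * 10^(dV_out / PVI)`.
#' @param dV_out accumulated outflow volume (m^3); any real value.
#' @param params an `icp_params`.
#' @return outlet pressure (Pa).
#' @export
spinal_outlet_pressure <- function(dV_out, params) {
  if (params$PVI <= 0 || params$p0 <= 0) stop("PVI and p0 must be positive")
  params$p0 * 10^(dV_out / params$PVI)
}

#' Build the monolithic coupled system
#'
#' Assembles all operator blocks once. In `"transient"` mode the system
#' matrix corresponds to one implicit-Euler step of size `dt` and a
#' companion matrix `C` maps the previous state to its right-hand-side
#' contribution. In `"steady"` mode all time-derivative terms are dropped
#' (used by the manufactured-solution verification harness).
#'
#' @param dom an `icp_domain`.
#' @param params an `icp_params`.
#' @param dt time step (s); required and positive in transient mode.
#' @param mode `"transient"` or `"steady"`.
#' @param dirichlet named list describing Dirichlet data per field
#'   (`d`, `u`, `pp`); each entry is `list(facets = <facet set names>,
#'   fn = NULL | closure(coords))`, `fn = NULL` meaning zero. Default is the
#'   physiological set: no-slip `u` on SKULL, clamped `d` on SPINAL_CORD.
#' @return an `icp_system` (operators, offsets, constraint data).
#' @export
build_system <- function(dom, params, dt = NULL,
                         mode = c("transient", "steady"),
                         dirichlet = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(dom, "icp_domain"), inherits(params, "icp_params"))
  if (mode == "transient") {
    if (is.null(dt) || dt <= 0) stop("transient mode requires dt > 0")
    # with the physiological boundary conditions the outlet traction is the
    # only condition pinning the pressure level
    if (is.null(dirichlet) &&
        (is.null(dom$facets$SPINAL_SAS) || sum(dom$facets$SPINAL_SAS$area) <= 0)) {
      stop("spinal SAS outlet must have positive area (pressure level would be undetermined)")
    }
  }
  if (params$nu >= 0.5) stop("nu >= 0.5: singular parameter combination")
  if (is.null(dirichlet)) {
    dirichlet <- list(d = list(facets = "SPINAL_CORD", fn = NULL),
                      u = list(facets = "SKULL", fn = NULL))
  }

  sp_d <- fe_space(dom, "PARENCHYMA", 2L)
  sp_pp <- fe_space(dom, "PARENCHYMA", 1L)
  sp_u <- fe_space(dom, "CSF", 2L)
  sp_pf <- fe_space(dom, "CSF", 1L)
  nd <- 3L * sp_d$ndof; np <- sp_pp$ndof; nu <- 3L * sp_u$ndof; nf <- sp_pf$ndof
  off <- list(d = 0L, pp = nd, phi = nd + np, u = nd + 2L * np,
              pf = nd + 2L * np + nu)
  N <- nd + 2L * np + nu + nf

  beta <- bjs_coefficient(params)
  lam <- params$lam; alpha <- params$alpha
  fsI <- dom$facets$INTERFACE

  K_d <- asm_stiff_vec_p2(dom, sp_d)
  M_p <- asm_mass_scalar(dom, sp_pp)
  K_pp <- asm_stiff_p1(dom, sp_pp)
  B_d <- asm_div_p2_p1(dom, sp_d, sp_pp)
  M_u <- if (mode == "transient") asm_mass_vec_p2(dom, sp_u) else NULL
  K_u <- asm_stiff_vec_p2(dom, sp_u)
  B_u <- asm_div_p2_p1(dom, sp_u, sp_pf)
  S_dd <- asm_facet_bjs(dom, sp_d, sp_d, fsI)
  S_du <- asm_facet_bjs(dom, sp_d, sp_u, fsI)
  S_uu <- asm_facet_bjs(dom, sp_u, sp_u, fsI)
  G_d <- asm_facet_un_p1(dom, sp_d, sp_pp, fsI)
  G_u <- asm_facet_un_p1(dom, sp_u, sp_pp, fsI)
  b_out_u <- if (!is.null(dom$facets$SPINAL_SAS) && nrow(dom$facets$SPINAL_SAS$tri) > 0) {
    asm_facet_normal_load(dom, sp_u, dom$facets$SPINAL_SAS)
  } else numeric(nu)
  b_g_pp <- asm_load_p1(dom, sp_pp)

  blocks <- list()
  add <- function(scale, M, ro, co) {
    Mt <- as(as(M, "generalMatrix"), "TsparseMatrix")
    blocks[[length(blocks) + 1L]] <<- list(i = Mt@i + 1L + ro, j = Mt@j + 1L + co,
                                           x = scale * Mt@x)
  }
  tr <- mode == "transient"
  # d rows
  add(params$mu_s, K_d, off$d, off$d)
  if (tr) add(beta / dt, S_dd, off$d, off$d)
  add(-1, Matrix::t(B_d), off$d, off$phi)
  add(-1, Matrix::t(G_d), off$d, off$pp)
  add(-beta, S_du, off$d, off$u)
  # phi rows
  add(1, M_p, off$phi, off$phi)
  add(-alpha, M_p, off$phi, off$pp)
  add(lam, B_d, off$phi, off$d)
  # p_p rows
  if (tr) {
    add((params$c + alpha^2 / lam) / dt, M_p, off$pp, off$pp)
    add(-(alpha / lam) / dt, M_p, off$pp, off$phi)
    add(1 / dt, G_d, off$pp, off$d)
  }
  add(params$kappa / params$mu_f, K_pp, off$pp, off$pp)
  add(-1, G_u, off$pp, off$u)
  # u rows
  if (tr) {
    add(params$rho_f / dt, M_u, off$u, off$u)
    add(-beta / dt, Matrix::t(S_du), off$u, off$d)
  }
  add(params$mu_f, K_u, off$u, off$u)
  add(beta, S_uu, off$u, off$u)
  add(-1, Matrix::t(B_u), off$u, off$pf)
  add(1, Matrix::t(G_u), off$u, off$pp)
  # p_f rows
  add(1, B_u, off$pf, off$u)

  A <- Matrix::sparseMatrix(i = unlist(lapply(blocks, `[[`, "i")),
                            j = unlist(lapply(blocks, `[[`, "j")),
                            x = unlist(lapply(blocks, `[[`, "x")),
                            dims = c(N, N))
  Cm <- NULL
  if (tr) {
    blocks <- list()
    add(beta / dt, S_dd, off$d, off$d)
    add((params$c + alpha^2 / lam) / dt, M_p, off$pp, off$pp)
    add(-(alpha / lam) / dt, M_p, off$pp, off$phi)
    add(1 / dt, G_d, off$pp, off$d)
    add(params$rho_f / dt, M_u, off$u, off$u)
    add(-beta / dt, Matrix::t(S_du), off$u, off$d)
    Cm <- Matrix::sparseMatrix(i = unlist(lapply(blocks, `[[`, "i")),
                               j = unlist(lapply(blocks, `[[`, "j")),
                               x = unlist(lapply(blocks, `[[`, "x")),
                               dims = c(N, N))
  }

  # Dirichlet constraints
  spaces <- list(d = sp_d, u = sp_u, pp = sp_pp)
  cdofs <- integer(0); cvals <- numeric(0)
  for (fld in names(dirichlet)) {
    bc <- dirichlet[[fld]]
    sp <- spaces[[fld]]
    if (is.null(sp)) stop("unknown Dirichlet field: ", fld)
    sdofs <- integer(0)
    for (fsn in bc$facets) {
      fs <- if (fsn %in% names(dom$facets)) dom$facets[[fsn]] else
        stop("unknown facet set in Dirichlet spec: ", fsn)
      if (nrow(fs$tri) > 0) sdofs <- union(sdofs, facet_space_dofs(dom, sp, fs))
    }
    if (length(sdofs) == 0) next
    vecfld <- fld %in% c("d", "u")
    if (vecfld) {
      gdofs <- as.vector(t(outer(3L * (sdofs - 1L), 1:3, `+`))) + off[[fld]]
      vals <- if (is.null(bc$fn)) numeric(length(gdofs)) else
        as.numeric(t(bc$fn(sp$coords[sdofs, , drop = FALSE])))
    } else {
      gdofs <- sdofs + off[[fld]]
      vals <- if (is.null(bc$fn)) numeric(length(gdofs)) else
        as.numeric(bc$fn(sp$coords[sdofs, , drop = FALSE]))
    }
    cdofs <- c(cdofs, gdofs); cvals <- c(cvals, vals)
  }
  keep <- !duplicated(cdofs)
  cdofs <- cdofs[keep]; cvals <- cvals[keep]
  free <- setdiff(seq_len(N), cdofs)

  structure(list(
    dom = dom, params = params, dt = dt, mode = mode,
    spaces = list(d = sp_d, pp = sp_pp, phi = sp_pp, u = sp_u, pf = sp_pf),
    off = off, N = N, A = A, C = Cm,
    b_g = {v <- numeric(N); v[off$pp + seq_len(np)] <- b_g_pp; v},
    b_out = {v <- numeric(N); v[off$u + seq_len(nu)] <- b_out_u; v},
    flux_out_fun = {v <- numeric(nu); v <- b_out_u; v},
    cdofs = cdofs, cvals = cvals, free = free,
    factor = NULL
  ), class = "icp_system")
}

# ---- linear solver -----------------------------------------------------
#
# The transient step matrix can be row-scaled to a symmetric quasi-definite
# (SQD) form: rows d x1, phi x(-1/lambda), p_p x(-dt), u x(dt), p_f x(-dt)
# give a symmetric matrix with positive (d, u) and negative (phi, p_p)
# diagonal blocks; the p_f (incompressibility) block has zero diagonal and
# receives a tiny negative shift so CHOLMOD's no-pivoting LDL' applies.
# The shift is removed by iterative refinement against the unshifted matrix,
# so solutions are exact to machine precision. This gives MUMPS-class direct
# solves using only the Matrix package.

# Row scaling turning the transient matrix into its symmetric form.
symmetric_row_scale <- function(sys) {
  s <- numeric(sys$N)
  off <- sys$off
  np <- sys$spaces$pp$ndof
  s[off$d + seq_len(3L * sys$spaces$d$ndof)] <- 1
  s[off$phi + seq_len(np)] <- -1 / sys$params$lam
  if (sys$mode == "transient") {
    s[off$pp + seq_len(np)] <- -sys$dt
    s[off$u + seq_len(3L * sys$spaces$u$ndof)] <- sys$dt
    s[off$pf + seq_len(sys$spaces$pf$ndof)] <- -sys$dt
  } else {
    # steady mode: the (u, p_f, p_p) block is symmetric with p_p, p_f x(-1);
    # the (d, phi) block couples one-way to it and is handled separately.
    s[off$pp + seq_len(np)] <- -1
    s[off$u + seq_len(3L * sys$spaces$u$ndof)] <- 1
    s[off$pf + seq_len(sys$spaces$pf$ndof)] <- -1
  }
  s
}

# LDL' factorization of a (shifted) SQD matrix with equilibration.
# zero_diag: indices (within the matrix) whose diagonal is structurally
# zero and receives the negative shift.
sqd_factor <- function(As, zero_diag, shift = 1e-10) {
  n <- nrow(As)
  rm1 <- as.numeric(abs(As) %*% rep(1, n))
  dS <- 1 / sqrt(pmax(rm1, 1e-300))
  Aeq <- Matrix::Diagonal(x = dS) %*% As %*% Matrix::Diagonal(x = dS)
  ch <- NULL
  for (sh in shift * c(1, 1e2, 1e4, 1e6)) {
    shiftv <- numeric(n)
    shiftv[zero_diag] <- -sh
    P <- Matrix::forceSymmetric(Aeq + Matrix::Diagonal(x = shiftv), "U")
    ch <- tryCatch(Matrix::Cholesky(P, LDL = TRUE, super = FALSE, perm = TRUE),
                   error = function(e) NULL)
    if (!is.null(ch)) break
  }
  if (is.null(ch)) stop("SQD LDL factorization failed")
  list(ch = ch, dS = dS, Aeq = Aeq)
}

# Solve As y = r with the shifted factor plus iterative refinement until
# the relative residual stalls or drops below ~1e2 machine epsilon.
sqd_solve <- function(f, r, rel_tol = 1e-13, max_refine = 20L) {
  rs <- f$dS * r
  nr0 <- max(sqrt(sum(rs^2)), 1e-300)
  y <- as.numeric(Matrix::solve(f$ch, rs))
  prev <- Inf
  for (k in seq_len(max_refine)) {
    res <- rs - as.numeric(f$Aeq %*% y)
    nr <- sqrt(sum(res^2)) / nr0
    if (nr < rel_tol || nr > 0.5 * prev) break
    prev <- nr
    y <- y + as.numeric(Matrix::solve(f$ch, res))
  }
  f$dS * y
}

# Factorize the constrained transient system; cached in the object.
factorize_system <- function(sys) {
  stopifnot(sys$mode == "transient")
  rsym <- symmetric_row_scale(sys)
  As_full <- Matrix::Diagonal(x = rsym) %*% sys$A
  Aff <- As_full[sys$free, sys$free, drop = FALSE]
  pf_rows <- sys$off$pf + seq_len(sys$spaces$pf$ndof)
  zero_diag <- match(pf_rows, sys$free)
  zero_diag <- zero_diag[!is.na(zero_diag)]
  f <- sqd_factor(Aff, zero_diag)
  f$rsym <- rsym
  f$Afc <- As_full[sys$free, sys$cdofs, drop = FALSE]
  sys$factor <- f
  sys
}

# Solve A x = b with the cached factorization, imposing Dirichlet values.
solve_system <- function(sys, b) {
  if (is.null(sys$factor)) stop("system not factorized")
  f <- sys$factor
  rhs <- (f$rsym * b)[sys$free]
  if (length(sys$cdofs)) rhs <- rhs - as.numeric(f$Afc %*% sys$cvals)
  x <- numeric(sys$N)
  x[sys$free] <- sqd_solve(f, rhs)
  x[sys$cdofs] <- sys$cvals
  x
}

#' Solve the steady coupled system
#'
#' The steady problem is one-way coupled: (u, p_f, p_p) solve a symmetric
#' Stokes-Darcy saddle problem, after which (d, phi) solve a symmetric
#' elasticity saddle problem driven by the interface tractions. Both stages
#' use the SQD LDL' solver.
#'
#' @param sys an `icp_system` built with `mode = "steady"`.
#' @param b right-hand side (length `sys$N`, unscaled equation rows).
#' @return solution vector of length `sys$N` with Dirichlet values imposed.
#' @keywords internal
solve_steady <- function(sys, b) {
  stopifnot(sys$mode == "steady")
  rsym <- symmetric_row_scale(sys)
  As <- Matrix::Diagonal(x = rsym) %*% sys$A
  bs <- rsym * b
  off <- sys$off
  idx_f <- c(off$u + seq_len(3L * sys$spaces$u$ndof),
             off$pf + seq_len(sys$spaces$pf$ndof),
             off$pp + seq_len(sys$spaces$pp$ndof))
  idx_s <- c(off$d + seq_len(3L * sys$spaces$d$ndof),
             off$phi + seq_len(sys$spaces$pp$ndof))
  x <- numeric(sys$N)
  x[sys$cdofs] <- sys$cvals
  # stage 1: fluid/pore block
  free_f <- setdiff(idx_f, sys$cdofs)
  A1 <- As[free_f, free_f, drop = FALSE]
  r1 <- bs[free_f] - as.numeric(As[free_f, sys$cdofs, drop = FALSE] %*% sys$cvals)
  pf_rows <- off$pf + seq_len(sys$spaces$pf$ndof)
  zd <- match(intersect(pf_rows, free_f), free_f)
  f1 <- sqd_factor(A1, zd)
  x[free_f] <- sqd_solve(f1, r1)
  # stage 2: solid block, driven by the fluid solution
  free_s <- setdiff(idx_s, sys$cdofs)
  known <- sort(union(idx_f, sys$cdofs))
  A2 <- As[free_s, free_s, drop = FALSE]
  r2 <- bs[free_s] - as.numeric(As[free_s, known, drop = FALSE] %*% x[known])
  f2 <- sqd_factor(A2, integer(0))
  x[free_s] <- sqd_solve(f2, r2)
  x
}

# ---- field states ------------------------------------------------------

#' Rest state of the coupled system
#'
#' Zero displacement and velocity, uniform pore and fluid pressure `p0`,
#' total pressure `alpha * p0`, zero accumulated outflow.
#' @param sys an `icp_system`.
#' @return an `icp_state`.
#' @export
rest_state <- function(sys) {
  p0 <- sys$params$p0
  structure(list(
    d = numeric(3L * sys$spaces$d$ndof),
    pp = rep(p0, sys$spaces$pp$ndof),
    phi = rep(sys$params$alpha * p0, sys$spaces$pp$ndof),
    u = numeric(3L * sys$spaces$u$ndof),
    pf = rep(p0, sys$spaces$pf$ndof),
    dV_out = 0, t = 0
  ), class = "icp_state")
}

state_to_vec <- function(sys, st) {
  x <- numeric(sys$N)
  x[sys$off$d + seq_along(st$d)] <- st$d
  x[sys$off$pp + seq_along(st$pp)] <- st$pp
  x[sys$off$phi + seq_along(st$phi)] <- st$phi
  x[sys$off$u + seq_along(st$u)] <- st$u
  x[sys$off$pf + seq_along(st$pf)] <- st$pf
  x
}

vec_to_state <- function(sys, x, dV_out = 0, t = 0) {
  structure(list(
    d = x[sys$off$d + seq_len(3L * sys$spaces$d$ndof)],
    pp = x[sys$off$pp + seq_len(sys$spaces$pp$ndof)],
    phi = x[sys$off$phi + seq_len(sys$spaces$pp$ndof)],
    u = x[sys$off$u + seq_len(3L * sys$spaces$u$ndof)],
    pf = x[sys$off$pf + seq_len(sys$spaces$pf$ndof)],
    dV_out = dV_out, t = t
  ), class = "icp_state")
}

#' Interface mass-conservation residual
#'
#' Facet integral over the interface of
#' `(u - dd/dt + kappa/mu_f grad p_p) . n` evaluated from the discrete
#' fields (backward-difference `dd/dt`, parenchyma-side cell gradient of
#' the piecewise-linear pore pressure). The normal-flux transmission
#' condition is enforced weakly, so this measures how well the discrete
#' solution honors it in an integral sense.
#'
#' @param sys an `icp_system` (transient).
#' @param st current `icp_state`.
#' @param prev previous `icp_state`.
#' @return signed residual (m^3/s).
#' @export
interface_mass_residual <- function(sys, st, prev) {
  f <- interface_residual_functionals(sys)
  sum(f$b_nu * st$u) - sum(f$b_nd * (st$d - prev$d)) / sys$dt +
    sum(f$w_darcy * st$pp)
}

# Linear functionals entering the interface mass residual:
# b_nu . u  -  b_nd . dd/dt  +  w_darcy . p_p
interface_residual_functionals <- function(sys) {
  dom <- sys$dom
  fs <- dom$facets$INTERFACE
  b_nu <- asm_facet_normal_load(dom, sys$spaces$u, fs)
  b_nd <- asm_facet_normal_load(dom, sys$spaces$d, fs)
  spp <- sys$spaces$pp
  ci <- match(fs$cell2, spp$cells)
  gp <- phys_grads(dom$geo, spp$cells[ci], p1_tet_grads())
  w <- numeric(spp$ndof)
  coef <- sys$params$kappa / sys$params$mu_f
  for (i in 1:4) {
    contrib <- coef * fs$area * (fs$normal[, 1] * gp[[i]][, 1] +
                                   fs$normal[, 2] * gp[[i]][, 2] +
                                   fs$normal[, 3] * gp[[i]][, 3])
    idx <- spp$dofmap[i, ci]
    add <- tapply(contrib, idx, sum)
    w[as.integer(names(add))] <- w[as.integer(names(add))] + add
  }
  list(b_nu = b_nu, b_nd = b_nd, w_darcy = w)
}

#' Assemble one implicit-Euler step
#'
#' Returns the (factorized, cached) discrete operator together with the
#' right-hand side for source value `g_val` and outlet traction `p_out`,
#' with all previous-state contributions folded in.
#'
#' @param sys an `icp_system` from [build_system()] in transient mode.
#' @param prev previous `icp_state`.
#' @param g_val source density g(t^(n+1)) (1/s).
#' @param p_out outlet normal traction magnitude (Pa), non-negative.
#' @return list `sys` (with factorization) and `rhs`.
#' @export
assemble_step <- function(sys, prev, g_val, p_out) {
  stopifnot(sys$mode == "transient")
  if (!is.finite(p_out)) {
    stop("non-finite outlet pressure (exponential compliance law overflow)")
  }
  if (p_out < 0) stop("p_out must be non-negative")
  if (is.null(sys$factor)) sys <- factorize_system(sys)
  rhs <- as.numeric(sys$C %*% state_to_vec(sys, prev)) +
    g_val * sys$b_g - p_out * sys$b_out
  list(sys = sys, rhs = rhs)
}

#' Advance one step
#' @keywords internal
step_state <- function(sys, prev, g_val, p_out) {
  as_ <- assemble_step(sys, prev, g_val, p_out)
  x <- solve_system(as_$sys, as_$rhs)
  st <- vec_to_state(as_$sys, x)
  # outward spinal flux of the new velocity; rectangle rule in time
  q_out <- sum(sys$b_out[sys$off$u + seq_along(st$u)] * st$u)
  st$dV_out <- prev$dV_out + sys$dt * q_out
  st$t <- prev$t + sys$dt
  list(sys = as_$sys, state = st, q_out = q_out)
}
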