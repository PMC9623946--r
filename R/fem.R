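# Finite element spaces and assembly on tagged tetrahedral meshes.
#
# Continuous Lagrange P1 (vertex dofs) and P2 (vertex + edge dofs) spaces
# restricted to a cell subdomain. Vector fields use interleaved component
# numbering: vector dof of scalar dof s, component a (1..3) is 3*(s-1)+a.
# All element integrals are exact for the polynomial integrands they carry
# (degree-2 rule for stiffness/divergence products, degree-4 for masses).

#' Scalar finite element space on a subdomain
#'
#' @param dom an `icp_domain`.
#' @param subdomain `"PARENCHYMA"` or `"CSF"`.
#' @param degree 1 or 2.
#' @return list with the cell set, local-to-global `dofmap` (nloc x ncell),
#'   dof count and dof coordinates.
#' @keywords internal
fe_space <- function(dom, subdomain, degree) {
  cells <- which(dom$cell_tag == TAG_CELLS[[subdomain]])
  tet <- dom$tet[cells, , drop = FALSE]
  nv <- nrow(dom$vert)
  vids <- sort(unique(as.vector(tet)))
  vert_dof <- rep(NA_integer_, nv)
  vert_dof[vids] <- seq_along(vids)
  if (degree == 1) {
    dofmap <- matrix(vert_dof[t(tet)], nrow = 4)
    return(list(degree = 1L, subdomain = subdomain, cells = cells,
                dofmap = dofmap, ndof = length(vids),
                coords = dom$vert[vids, , drop = FALSE],
                vert_dof = vert_dof, edge_dof = NULL))
  }
  t2e <- dom$tet2edge[cells, , drop = FALSE]
  eids <- sort(unique(as.vector(t2e)))
  edge_dof <- rep(NA_integer_, nrow(dom$edges))
  edge_dof[eids] <- length(vids) + seq_along(eids)
  dofmap <- rbind(matrix(vert_dof[t(tet)], nrow = 4),
                  matrix(edge_dof[t(t2e)], nrow = 6))
  mid <- (dom$vert[dom$edges[eids, 1], , drop = FALSE] +
          dom$vert[dom$edges[eids, 2], , drop = FALSE]) / 2
  list(degree = 2L, subdomain = subdomain, cells = cells, dofmap = dofmap,
       ndof = length(vids) + length(eids),
       coords = rbind(dom$vert[vids, , drop = FALSE], mid),
       vert_dof = vert_dof, edge_dof = edge_dof)
}

# Interpolate a closure onto a space: fn(x) for scalar (returns vector) or
# fn(x) -> n x 3 for vector fields (returns interleaved vector).
interp_space <- function(sp, fn, vec = FALSE) {
  vals <- fn(sp$coords)
  if (!vec) return(as.numeric(vals))
  as.numeric(t(vals))
}

# Physical gradients of reference basis at one quadrature point:
# list over basis index of (ncell x 3) matrices.
phys_grads <- function(geo, cells, gref_q) {
  invJt <- geo$invJt[cells, , , drop = FALSE]
  nb <- nrow(gref_q)
  lapply(seq_len(nb), function(i) {
    g <- matrix(0, length(cells), 3)
    for (k in 1:3) {
      g[, k] <- invJt[, k, 1] * gref_q[i, 1] + invJt[, k, 2] * gref_q[i, 2] +
        invJt[, k, 3] * gref_q[i, 3]
    }
    g
  })
}

# triplets -> dgCMatrix
make_sparse <- function(i, j, x, nr, nc) {
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nr, nc))
}

#' Scalar mass matrix (P1 or P2)
#' @keywords internal
asm_mass_scalar <- function(dom, sp) {
  q <- quad_tet(4)
  vals <- if (sp$degree == 1) p1_tet_values(q$p) else p2_tet_values(q$p)
  mref <- t(vals) %*% (vals * q$w)
  det <- dom$geo$det[sp$cells]
  nloc <- nrow(sp$dofmap)
  x <- as.vector(mref) %o% det
  i <- sp$dofmap[rep(seq_len(nloc), times = nloc), ]
  j <- sp$dofmap[rep(seq_len(nloc), each = nloc), ]
  make_sparse(as.vector(i), as.vector(j), as.vector(x), sp$ndof, sp$ndof)
}

#' P1 scalar stiffness matrix: int grad p . grad q
#' @keywords internal
asm_stiff_p1 <- function(dom, sp) {
  stopifnot(sp$degree == 1)
  gp <- phys_grads(dom$geo, sp$cells, p1_tet_grads())
  vol <- dom$geo$vol[sp$cells]
  ne <- length(sp$cells)
  acc <- array(0, c(4, 4, ne))
  for (i in 1:4) for (j in 1:4) {
    acc[i, j, ] <- vol * rowSums(gp[[i]] * gp[[j]])
  }
  i <- sp$dofmap[rep(1:4, times = 4), ]
  j <- sp$dofmap[rep(1:4, each = 4), ]
  make_sparse(as.vector(i), as.vector(j), as.vector(acc), sp$ndof, sp$ndof)
}

# Vector dof index matrix (3*nloc x ncell) from a scalar dofmap.
vec_dofmap <- function(dofmap) {
  nloc <- nrow(dofmap)
  out <- matrix(0L, 3L * nloc, ncol(dofmap))
  for (i in seq_len(nloc)) for (a in 1:3) {
    out[(i - 1L) * 3L + a, ] <- 3L * (dofmap[i, ] - 1L) + a
  }
  out
}

#' Vector P2 mass matrix: int u . v
#' @keywords internal
asm_mass_vec_p2 <- function(dom, sp) {
  q <- quad_tet(4)
  vals <- p2_tet_values(q$p)
  mref <- t(vals) %*% (vals * q$w)
  det <- dom$geo$det[sp$cells]
  ne <- length(sp$cells)
  R <- vec_dofmap(sp$dofmap)
  nl3 <- 30L
  acc <- array(0, c(nl3, nl3, ne))
  for (i in 1:10) for (j in 1:10) {
    v <- mref[i, j] * det
    for (a in 1:3) acc[(i - 1) * 3 + a, (j - 1) * 3 + a, ] <- v
  }
  i <- R[rep(seq_len(nl3), times = nl3), ]
  j <- R[rep(seq_len(nl3), each = nl3), ]
  make_sparse(as.vector(i), as.vector(j), as.vector(acc), 3L * sp$ndof, 3L * sp$ndof)
}

#' Vector P2 strain stiffness: int 2 eps(u) : eps(v)
#' @keywords internal
asm_stiff_vec_p2 <- function(dom, sp) {
  q <- quad_tet(2)
  gref <- p2_tet_grads(q$p)
  ne <- length(sp$cells)
  det <- dom$geo$det[sp$cells]
  acc <- array(0, c(30L, 30L, ne))
  for (qq in seq_along(q$w)) {
    gp <- phys_grads(dom$geo, sp$cells, gref[qq, , ])
    wdet <- q$w[qq] * det
    for (i in 1:10) for (j in 1:10) {
      dot_ij <- rowSums(gp[[i]] * gp[[j]])
      for (a in 1:3) for (b in 1:3) {
        v <- gp[[i]][, b] * gp[[j]][, a]
        if (a == b) v <- v + dot_ij
        acc[(i - 1) * 3 + a, (j - 1) * 3 + b, ] <-
          acc[(i - 1) * 3 + a, (j - 1) * 3 + b, ] + wdet * v
      }
    }
  }
  R <- vec_dofmap(sp$dofmap)
  i <- R[rep(1:30, times = 30), ]
  j <- R[rep(1:30, each = 30), ]
  make_sparse(as.vector(i), as.vector(j), as.vector(acc), 3L * sp$ndof, 3L * sp$ndof)
}

#' Mixed divergence operator: B[j,(i,a)] = int (d_a phi_i) lambda_j
#' rows: P1 space on the same cells; cols: vector P2 space.
#' @keywords internal
asm_div_p2_p1 <- function(dom, sp2, sp1) {
  stopifnot(identical(sp2$cells, sp1$cells))
  q <- quad_tet(2)
  gref <- p2_tet_grads(q$p)
  l1 <- p1_tet_values(q$p)
  ne <- length(sp2$cells)
  det <- dom$geo$det[sp2$cells]
  acc <- array(0, c(4L, 30L, ne))
  for (qq in seq_along(q$w)) {
    gp <- phys_grads(dom$geo, sp2$cells, gref[qq, , ])
    wdet <- q$w[qq] * det
    for (j in 1:4) {
      wl <- wdet * l1[qq, j]
      for (i in 1:10) for (a in 1:3) {
        acc[j, (i - 1) * 3 + a, ] <- acc[j, (i - 1) * 3 + a, ] + wl * gp[[i]][, a]
      }
    }
  }
  R2 <- vec_dofmap(sp2$dofmap)
  i <- sp1$dofmap[rep(1:4, times = 30), ]
  j <- R2[rep(1:30, each = 4), ]
  make_sparse(as.vector(i), as.vector(j), as.vector(acc), sp1$ndof, 3L * sp2$ndof)
}

#' Load vector of a P1 space: b[j] = int lambda_j dV
#' @keywords internal
asm_load_p1 <- function(dom, sp) {
  det <- dom$geo$det[sp$cells]
  b <- numeric(sp$ndof)
  for (j in 1:4) {
    contrib <- det / 24
    b_add <- tapply(contrib, sp$dofmap[j, ], sum)
    b[as.integer(names(b_add))] <- b[as.integer(names(b_add))] + b_add
  }
  b
}

# Volumetric load from a closure: scalar P1 or vector P2 right-hand side.
asm_load_closure <- function(dom, sp, fn, vec = FALSE, deg = 5) {
  q <- quad_tet(deg)
  det <- dom$geo$det[sp$cells]
  v1 <- dom$geo$v1[sp$cells, , drop = FALSE]
  J <- dom$geo$J[sp$cells, , , drop = FALSE]
  nq <- length(q$w)
  vals <- if (sp$degree == 1) p1_tet_values(q$p) else p2_tet_values(q$p)
  nloc <- ncol(vals)
  if (vec) {
    b <- numeric(3L * sp$ndof)
    R <- vec_dofmap(sp$dofmap)
  } else b <- numeric(sp$ndof)
  for (qq in seq_len(nq)) {
    x <- v1 + J[, , 1] * q$p[qq, 1] + J[, , 2] * q$p[qq, 2] + J[, , 3] * q$p[qq, 3]
    f <- fn(x)
    w <- q$w[qq] * det
    if (vec) {
      for (i in seq_len(nloc)) for (a in 1:3) {
        contrib <- w * vals[qq, i] * f[, a]
        idx <- R[(i - 1) * 3 + a, ]
        add <- tapply(contrib, idx, sum)
        b[as.integer(names(add))] <- b[as.integer(names(add))] + add
      }
    } else {
      for (i in seq_len(nloc)) {
        contrib <- w * vals[qq, i] * f
        idx <- sp$dofmap[i, ]
        add <- tapply(contrib, idx, sum)
        b[as.integer(names(add))] <- b[as.integer(names(add))] + add
      }
    }
  }
  b
}

# ---- facet machinery ---------------------------------------------------

# P2 facet scalar dofs (6 per facet: 3 vertices + 3 edges in TRI_EDGES
# order) and P1 facet dofs (3 vertices), in a given space's numbering.
facet_dofs <- function(dom, sp, fs) {
  tri <- fs$tri
  nv <- nrow(dom$vert)
  vd <- matrix(sp$vert_dof[tri], ncol = 3)
  if (sp$degree == 1) {
    if (anyNA(vd)) stop("facet set touches dofs outside the space's subdomain")
    return(t(vd))
  }
  ekey <- function(a, b) (pmin(a, b) - 1) * as.double(nv) + pmax(a, b)
  all_ekey <- ekey(dom$edges[, 1], dom$edges[, 2])
  ed <- matrix(NA_integer_, nrow(tri), 3)
  for (e in 1:3) {
    a <- tri[, TRI_EDGES[e, 1]]; b <- tri[, TRI_EDGES[e, 2]]
    eid <- match(ekey(a, b), all_ekey)
    ed[, e] <- sp$edge_dof[eid]
  }
  out <- t(cbind(vd, ed))
  if (anyNA(out)) stop("facet set touches dofs outside the space's subdomain")
  out
}

# Reference P2/P1 triangle matrices (exact).
tri_ref_matrices <- function() {
  q <- quad_tri(4)
  v2 <- p2_tri_values(q$p)
  v1 <- p1_tri_values(q$p)
  list(m22 = t(v2) %*% (v2 * q$w),
       m21 = t(v2) %*% (v1 * q$w),
       int2 = colSums(v2 * q$w))
}

#' Facet Beavers-Joseph-Saffman coupling matrix
#'
#' `S[(iA,a),(jB,b)] = int_F (P phiA_i e_a) . (P phiB_j e_b) dS` with
#' `P` the tangential projector. `tangent = "projector"` uses
#' `P = I - n n^T`; `tangent = "explicit"` uses `P = tau1 tau1^T +
#' tau2 tau2^T` with tangents constructed per facet. Both are
#' mathematically identical; the pair exists as a cross-check.
#' @keywords internal
asm_facet_bjs <- function(dom, spA, spB, fs, tangent = c("projector", "explicit")) {
  tangent <- match.arg(tangent)
  ref <- tri_ref_matrices()
  dA <- facet_dofs(dom, spA, fs)
  dB <- facet_dofs(dom, spB, fs)
  nf <- nrow(fs$tri)
  Tm <- array(0, c(nf, 3, 3))
  if (tangent == "projector") {
    for (a in 1:3) for (b in 1:3) {
      Tm[, a, b] <- (a == b) - fs$normal[, a] * fs$normal[, b]
    }
  } else {
    e1 <- dom$vert[fs$tri[, 2], , drop = FALSE] - dom$vert[fs$tri[, 1], , drop = FALSE]
    e1 <- e1 - fs$normal * rowSums(e1 * fs$normal)
    tau1 <- e1 / sqrt(rowSums(e1^2))
    tau2 <- cbind(fs$normal[, 2] * tau1[, 3] - fs$normal[, 3] * tau1[, 2],
                  fs$normal[, 3] * tau1[, 1] - fs$normal[, 1] * tau1[, 3],
                  fs$normal[, 1] * tau1[, 2] - fs$normal[, 2] * tau1[, 1])
    for (a in 1:3) for (b in 1:3) {
      Tm[, a, b] <- tau1[, a] * tau1[, b] + tau2[, a] * tau2[, b]
    }
  }
  acc <- array(0, c(18L, 18L, nf))
  twoA <- 2 * fs$area
  for (i in 1:6) for (j in 1:6) {
    m <- ref$m22[i, j] * twoA
    for (a in 1:3) for (b in 1:3) {
      acc[(i - 1) * 3 + a, (j - 1) * 3 + b, ] <- m * Tm[, a, b]
    }
  }
  RA <- vec_dofmap(dA)
  RB <- vec_dofmap(dB)
  i <- RA[rep(1:18, times = 18), ]
  j <- RB[rep(1:18, each = 18), ]
  make_sparse(as.vector(i), as.vector(j), as.vector(acc), 3L * spA$ndof, 3L * spB$ndof)
}

#' Facet normal-velocity / P1-pressure coupling
#'
#' `G[j,(i,a)] = int_F (phi2_i e_a . n) lambda_j dS` using the oriented
#' facet normals of the set.
#' @keywords internal
asm_facet_un_p1 <- function(dom, sp2, sp1, fs) {
  ref <- tri_ref_matrices()
  d2 <- facet_dofs(dom, sp2, fs)
  d1 <- facet_dofs(dom, sp1, fs)
  nf <- nrow(fs$tri)
  acc <- array(0, c(3L, 18L, nf))
  twoA <- 2 * fs$area
  for (j in 1:3) for (i in 1:6) {
    m <- ref$m21[i, j] * twoA
    for (a in 1:3) acc[j, (i - 1) * 3 + a, ] <- m * fs$normal[, a]
  }
  R2 <- vec_dofmap(d2)
  i <- d1[rep(1:3, times = 18), ]
  j <- R2[rep(1:18, each = 3), ]
  make_sparse(as.vector(i), as.vector(j), as.vector(acc), sp1$ndof, 3L * sp2$ndof)
}

#' Facet normal load: b[(i,a)] = int_F phi2_i n_a dS
#'
#' Doubles as the exact flux functional: `sum(b * u) = int_F u . n dS` for a
#' P2 vector field u.
#' @keywords internal
asm_facet_normal_load <- function(dom, sp2, fs) {
  ref <- tri_ref_matrices()
  d2 <- facet_dofs(dom, sp2, fs)
  b <- numeric(3L * sp2$ndof)
  twoA <- 2 * fs$area
  R2 <- vec_dofmap(d2)
  for (i in 1:6) for (a in 1:3) {
    contrib <- ref$int2[i] * twoA * fs$normal[, a]
    idx <- R2[(i - 1) * 3 + a, ]
    add <- tapply(contrib, idx, sum)
    b[as.integer(names(add))] <- b[as.integer(names(add))] + add
  }
  b
}

# Scalar dofs of a space lying on a facet set (unique).
facet_space_dofs <- function(dom, sp, fs) {
  sort(unique(as.vector(facet_dofs(dom, sp, fs))))
}

# ---- evaluation and errors ---------------------------------------------

# Evaluate a FE field at one located point. values: scalar dof vector or
# interleaved vector dof vector (vec = TRUE).
eval_field <- function(dom, sp, values, loc, vec = FALSE) {
  cell_idx <- match(loc$cell, sp$cells)
  if (is.na(cell_idx)) stop("evaluation point outside the space's subdomain")
  p <- matrix(loc$ref, 1, 3)
  phi <- if (sp$degree == 1) p1_tet_values(p) else p2_tet_values(p)
  dofs <- sp$dofmap[, cell_idx]
  if (!vec) return(sum(phi[1, ] * values[dofs]))
  out <- numeric(3)
  for (a in 1:3) out[a] <- sum(phi[1, ] * values[3L * (dofs - 1L) + a])
  out
}

# L2 norm of (field - exact closure) over the space's cells.
l2_error <- function(dom, sp, values, exact_fn, vec = FALSE, deg = 5) {
  q <- quad_tet(deg)
  det <- dom$geo$det[sp$cells]
  v1 <- dom$geo$v1[sp$cells, , drop = FALSE]
  J <- dom$geo$J[sp$cells, , , drop = FALSE]
  vals <- if (sp$degree == 1) p1_tet_values(q$p) else p2_tet_values(q$p)
  nloc <- ncol(vals)
  err2 <- 0
  for (qq in seq_along(q$w)) {
    x <- v1 + J[, , 1] * q$p[qq, 1] + J[, , 2] * q$p[qq, 2] + J[, , 3] * q$p[qq, 3]
    ex <- exact_fn(x)
    if (vec) {
      uh <- matrix(0, length(sp$cells), 3)
      for (i in seq_len(nloc)) for (a in 1:3) {
        uh[, a] <- uh[, a] + vals[qq, i] * values[3L * (sp$dofmap[i, ] - 1L) + a]
      }
      err2 <- err2 + sum(q$w[qq] * det * rowSums((uh - ex)^2))
    } else {
      uh <- numeric(length(sp$cells))
      for (i in seq_len(nloc)) uh <- uh + vals[qq, i] * values[sp$dofmap[i, ]]
      err2 <- err2 + sum(q$w[qq] * det * (uh - ex)^2)
    }
  }
  sqrt(err2)
}
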