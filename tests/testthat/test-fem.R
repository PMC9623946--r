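# FE infrastructure: quadrature exactness, elements, operator identities.

# closed-form monomial integral over the reference tetrahedron:
# int x^a y^b z^c = a! b! c! / (a+b+c+3)!
tet_monomial <- function(a, b, c) {
  factorial(a) * factorial(b) * factorial(c) / factorial(a + b + c + 3)
}
tri_monomial <- function(a, b) factorial(a) * factorial(b) / factorial(a + b + 2)

test_that("simplex quadrature rules are exact to their stated degree", {
  for (deg in c(2, 4, 5)) {
    q <- icpulse:::quad_tet(deg)
    for (a in 0:deg) for (b in 0:(deg - a)) for (c in 0:(deg - a - b)) {
      got <- sum(q$w * q$p[, 1]^a * q$p[, 2]^b * q$p[, 3]^c)
      expect_equal(got, tet_monomial(a, b, c), tolerance = 1e-13,
                   label = sprintf("tet deg %d monomial %d%d%d", deg, a, b, c))
    }
  }
  for (deg in c(4, 6)) {
    q <- icpulse:::quad_tri(deg)
    for (a in 0:deg) for (b in 0:(deg - a)) {
      expect_equal(sum(q$w * q$p[, 1]^a * q$p[, 2]^b), tri_monomial(a, b),
                   tolerance = 1e-13)
    }
  }
})

test_that("P2 basis has the Lagrange nodal property and partition of unity", {
  # nodes: 4 vertices + 6 edge midpoints
  vv <- rbind(diag(3) * 0, diag(3))[c(1, 4, 5, 6), ]
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mids <- (verts[icpulse:::TET_EDGES[, 1], ] + verts[icpulse:::TET_EDGES[, 2], ]) / 2
  nodes <- rbind(verts, mids)
  V <- icpulse:::p2_tet_values(nodes)
  expect_equal(V, diag(10), tolerance = 1e-14, ignore_attr = TRUE)
  pts <- matrix(stats::runif(30), 10, 3) / 3
  expect_equal(rowSums(icpulse:::p2_tet_values(pts)), rep(1, 10),
               tolerance = 1e-13)
  # gradients consistent with finite differences
  g <- icpulse:::p2_tet_grads(pts)
  h <- 1e-6
  for (k in 1:3) {
    dp <- pts; dp[, k] <- dp[, k] + h
    dm <- pts; dm[, k] <- dm[, k] - h
    fd <- (icpulse:::p2_tet_values(dp) - icpulse:::p2_tet_values(dm)) / (2 * h)
    expect_equal(g[, , k], fd, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("mass, stiffness and divergence operators satisfy exact identities", {
  dom <- two_box_domain(2, "verification")
  for (sub in c("PARENCHYMA", "CSF")) {
    sp1 <- icpulse:::fe_space(dom, sub, 1L)
    sp2 <- icpulse:::fe_space(dom, sub, 2L)
    vol <- measure(dom, sub)
    M1 <- icpulse:::asm_mass_scalar(dom, sp1)
    expect_equal(sum(M1), vol, tolerance = 1e-12)
    K1 <- icpulse:::asm_stiff_p1(dom, sp1)
    expect_lt(max(abs(K1 %*% rep(1, sp1$ndof))), 1e-12)
    # stiffness against a linear field: int |grad(a.x)|^2 = |a|^2 vol
    a <- c(0.3, -1.2, 0.7)
    lin <- as.numeric(sp1$coords %*% a)
    expect_equal(as.numeric(lin %*% (K1 %*% lin)), sum(a^2) * vol,
                 tolerance = 1e-12)
    # vector P2 strain stiffness annihilates rigid motions
    K2 <- icpulse:::asm_stiff_vec_p2(dom, sp2)
    rigid <- icpulse:::interp_space(sp2, function(x)
      cbind(1 + x[, 2] - x[, 3], 2 - x[, 1] + x[, 3], x[, 1] - x[, 2]),
      vec = TRUE)
    expect_lt(max(abs(K2 %*% rigid)), 1e-10)
    # divergence of a linear field: int div(d) q for d = (x, 2y, 3z)
    B <- icpulse:::asm_div_p2_p1(dom, sp2, sp1)
    dlin <- icpulse:::interp_space(sp2, function(x)
      cbind(x[, 1], 2 * x[, 2], 3 * x[, 3]), vec = TRUE)
    expect_equal(sum(B %*% dlin), 6 * vol, tolerance = 1e-12)
  }
})

test_that("facet operators integrate exactly on the flat interface", {
  dom <- two_box_domain(2, "verification")
  fs <- dom$facets$INTERFACE
  expect_equal(sum(fs$area), 1, tolerance = 1e-13)
  # interface normals point from CSF (above) into parenchyma (below)
  expect_true(all(abs(fs$normal[, 3] + 1) < 1e-13))
  sp_u <- icpulse:::fe_space(dom, "CSF", 2L)
  b <- icpulse:::asm_facet_normal_load(dom, sp_u, fs)
  uq <- icpulse:::interp_space(sp_u, function(x)
    cbind(x[, 2], x[, 1], x[, 1]^2 + 0.5 * x[, 2]), vec = TRUE)
  # int u.n over z=0 with n = -e3: -int (x^2 + y/2) dx dy = -(1/3 + 1/4)
  expect_equal(sum(b * uq), -(1 / 3 + 1 / 4), tolerance = 1e-12)
})

test_that("point evaluation and L2 errors are exact for in-space fields", {
  dom <- two_box_domain(2, "verification")
  sp2 <- icpulse:::fe_space(dom, "CSF", 2L)
  f <- function(x) x[, 1]^2 - 2 * x[, 2] * x[, 3] + 0.3
  vals <- icpulse:::interp_space(sp2, f)
  expect_lt(icpulse:::l2_error(dom, sp2, vals, f), 1e-13)
  loc <- icpulse:::locate_point(dom, c(0.31, 0.42, 0.57))
  expect_equal(icpulse:::eval_field(dom, sp2, vals, loc),
               f(matrix(c(0.31, 0.42, 0.57), 1)), tolerance = 1e-12)
})
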