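# Quadrature rules on reference simplices.
#
# Reference tetrahedron: vertices (0,0,0),(1,0,0),(0,1,0),(0,0,1), volume 1/6.
# Reference triangle: vertices (0,0),(1,0),(0,1), area 1/2.
# Rules are either classical symmetric rules (low degree) or collapsed
# (Duffy-type) tensor Gauss-Legendre rules whose exactness is asserted in the
# test suite against closed-form monomial integrals.

# Gauss-Legendre nodes/weights on [0,1] via Golub-Welsch.
gauss_legendre01 <- function(n) {
  if (n == 1) return(list(x = 0.5, w = 1))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
}

# Collapsed tensor rule on the reference tetrahedron, n points per direction.
# Exact for total polynomial degree <= 2n - 3 (Jacobian inflates degrees).
quad_tet_duffy <- function(n) {
  g <- gauss_legendre01(n)
  grid <- expand.grid(a = seq_len(n), b = seq_len(n), c = seq_len(n))
  xi1 <- g$x[grid$a]; xi2 <- g$x[grid$b]; xi3 <- g$x[grid$c]
  w <- g$w[grid$a] * g$w[grid$b] * g$w[grid$c]
  z <- xi3
  y <- xi2 * (1 - xi3)
  x <- xi1 * (1 - xi2) * (1 - xi3)
  jac <- (1 - xi2) * (1 - xi3)^2
  list(p = cbind(x, y, z), w = w * jac)
}

# Classical 4-point degree-2 symmetric rule on the tetrahedron.
quad_tet_deg2 <- function() {
  a <- 0.5854101966249685
  b <- 0.1381966011250105
  p <- rbind(c(a, b, b), c(b, a, b), c(b, b, a), c(b, b, b))
  list(p = p, w = rep(1 / 24, 4))
}

# Quadrature on the reference tetrahedron exact for total degree <= deg.
quad_tet <- function(deg) {
  if (deg <= 2) return(quad_tet_deg2())
  n <- ceiling((deg + 3) / 2)
  quad_tet_duffy(n)
}

# Collapsed tensor rule on the reference triangle, exact for degree <= 2n - 2.
quad_tri <- function(deg) {
  n <- max(2L, ceiling((deg + 2) / 2))
  g <- gauss_legendre01(n)
  grid <- expand.grid(a = seq_len(n), b = seq_len(n))
  xi1 <- g$x[grid$a]; xi2 <- g$x[grid$b]
  w <- g$w[grid$a] * g$w[grid$b]
  y <- xi2
  x <- xi1 * (1 - xi2)
  jac <- (1 - xi2)
  list(p = cbind(x, y), w = w * jac)
}
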