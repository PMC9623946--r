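# Lagrange reference elements on simplices.
#
# Tetrahedron node order: 4 vertices, then 6 edge midpoints in edge order
# (1,2), (1,3), (1,4), (2,3), (2,4), (3,4).
# Triangle node order: 3 vertices, then 3 edge midpoints (1,2), (1,3), (2,3).

TET_EDGES <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                   c(2L, 3L), c(2L, 4L), c(3L, 4L))
TRI_EDGES <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))

# Barycentric coordinates (npt x 4) at reference points (npt x 3).
tet_bary <- function(p) {
  cbind(1 - p[, 1] - p[, 2] - p[, 3], p[, 1], p[, 2], p[, 3])
}

# P1 tetrahedron: values npt x 4; gradients constant, 4 x 3.
p1_tet_values <- function(p) tet_bary(p)
p1_tet_grads <- function() {
  rbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
}

# P2 tetrahedron values: npt x 10.
p2_tet_values <- function(p) {
  l <- tet_bary(p)
  v <- matrix(0, nrow(p), 10)
  for (i in 1:4) v[, i] <- l[, i] * (2 * l[, i] - 1)
  for (e in 1:6) {
    a <- TET_EDGES[e, 1]; b <- TET_EDGES[e, 2]
    v[, 4 + e] <- 4 * l[, a] * l[, b]
  }
  v
}

# P2 tetrahedron reference gradients: npt x 10 x 3.
p2_tet_grads <- function(p) {
  l <- tet_bary(p)
  gl <- p1_tet_grads()
  g <- array(0, c(nrow(p), 10, 3))
  for (i in 1:4) {
    for (k in 1:3) g[, i, k] <- (4 * l[, i] - 1) * gl[i, k]
  }
  for (e in 1:6) {
    a <- TET_EDGES[e, 1]; b <- TET_EDGES[e, 2]
    for (k in 1:3) g[, 4 + e, k] <- 4 * (l[, a] * gl[b, k] + l[, b] * gl[a, k])
  }
  g
}

# P1/P2 triangle values at reference points (npt x 2).
p1_tri_values <- function(p) cbind(1 - p[, 1] - p[, 2], p[, 1], p[, 2])
p2_tri_values <- function(p) {
  l <- p1_tri_values(p)
  v <- matrix(0, nrow(p), 6)
  for (i in 1:3) v[, i] <- l[, i] * (2 * l[, i] - 1)
  for (e in 1:3) {
    a <- TRI_EDGES[e, 1]; b <- TRI_EDGES[e, 2]
    v[, 3 + e] <- 4 * l[, a] * l[, b]
  }
  v
}
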