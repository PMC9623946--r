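# Tetrahedral mesh construction on non-uniform rectilinear grids.
#
# Each grid box is split into 6 tetrahedra by the uniform Freudenthal (Kuhn)
# decomposition along the main diagonal, which yields a conforming
# triangulation across neighbouring boxes. All region boundaries of the
# idealized geometry lie exactly on grid planes, so subdomain tagging by box
# membership is exact and every tagged facet is axis-aligned.

# The six Kuhn tetrahedra of the unit cube, as vertex index offsets.
# Cube corners are numbered 1..8 by bit pattern (ix, iy, iz) ->
# 1 + ix + 2*iy + 4*iz; each tet is (v0, path via one axis at a time, v7).
kuhn_tets <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  bit <- c(1L, 2L, 4L)
  t(apply(perms, 1, function(pr) {
    v <- integer(4)
    v[1] <- 1L
    acc <- 0L
    for (k in 1:3) {
      acc <- acc + bit[pr[k]]
      v[k + 1] <- 1L + acc
    }
    v
  }))
}

#' Build a tetrahedral mesh of a rectilinear grid
#'
#' @param xs,ys,zs strictly increasing coordinate tick vectors (m).
#' @return a raw mesh: list with `vert` (n x 3), `tet` (nt x 4, positively
#'   oriented), `box_of_tet`, and box center coordinates for tagging.
#' @keywords internal
mesh_rectilinear <- function(xs, ys, zs) {
  stopifnot(all(diff(xs) > 0), all(diff(ys) > 0), all(diff(zs) > 0))
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  vert <- cbind(rep(xs, times = ny * nz),
                rep(rep(ys, each = nx), times = nz),
                rep(zs, each = nx * ny))
  vid <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  ex <- nx - 1L; ey <- ny - 1L; ez <- nz - 1L
  ii <- rep(seq_len(ex), times = ey * ez)
  jj <- rep(rep(seq_len(ey), each = ex), times = ez)
  kk <- rep(seq_len(ez), each = ex * ey)
  # cube corner global ids in bit order (n boxes x 8)
  corners <- cbind(vid(ii, jj, kk), vid(ii + 1L, jj, kk),
                   vid(ii, jj + 1L, kk), vid(ii + 1L, jj + 1L, kk),
                   vid(ii, jj, kk + 1L), vid(ii + 1L, jj, kk + 1L),
                   vid(ii, jj + 1L, kk + 1L), vid(ii + 1L, jj + 1L, kk + 1L))
  kt <- kuhn_tets()
  nbox <- length(ii)
  tet <- matrix(0L, nbox * 6L, 4L)
  box_of_tet <- integer(nbox * 6L)
  for (s in 1:6) {
    idx <- seq.int(s, by = 6L, length.out = nbox)
    tet[idx, ] <- corners[, kt[s, ], drop = FALSE]
    box_of_tet[idx] <- seq_len(nbox)
  }
  # enforce positive orientation
  v1 <- vert[tet[, 1], , drop = FALSE]
  a <- vert[tet[, 2], , drop = FALSE] - v1
  b <- vert[tet[, 3], , drop = FALSE] - v1
  cc <- vert[tet[, 4], , drop = FALSE] - v1
  det6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  flip <- det6 < 0
  if (any(flip)) tet[flip, c(3, 4)] <- tet[flip, c(4, 3)]
  bc <- cbind((xs[ii] + xs[ii + 1L]) / 2,
              (ys[jj] + ys[jj + 1L]) / 2,
              (zs[kk] + zs[kk + 1L]) / 2)
  list(vert = vert, tet = tet, box_of_tet = box_of_tet, box_center = bc,
       dims = c(nx, ny, nz))
}

# Global edge table. Returns `edges` (ne x 2, sorted pairs) and
# `tet2edge` (nt x 6) following TET_EDGES local order.
build_edges <- function(mesh) {
  tet <- mesh$tet
  nv <- nrow(mesh$vert)
  pairs <- NULL
  loc <- matrix(0, nrow(tet), 6)
  allpairs <- matrix(0L, nrow(tet) * 6L, 2L)
  for (e in 1:6) {
    a <- tet[, TET_EDGES[e, 1]]
    b <- tet[, TET_EDGES[e, 2]]
    allpairs[seq.int(e, by = 6L, length.out = nrow(tet)), ] <-
      cbind(pmin(a, b), pmax(a, b))
  }
  key <- (allpairs[, 1] - 1) * as.double(nv) + allpairs[, 2]
  ukey <- sort(unique(key))
  eid <- match(key, ukey)
  edges <- cbind(((ukey - 1) %/% nv) + 1, ((ukey - 1) %% nv) + 1)
  storage.mode(edges) <- "integer"
  tet2edge <- matrix(0L, nrow(tet), 6L)
  for (e in 1:6) {
    tet2edge[, e] <- eid[seq.int(e, by = 6L, length.out = nrow(tet))]
  }
  list(edges = edges, tet2edge = tet2edge)
}

# Facets of interest: exterior facets and facets between cells of different
# tags. Returns data frame-like list with triangle vertex ids, adjacent
# cells (cell2 = NA for exterior), and for interior facets cell1 is chosen
# so facets can later be oriented.
extract_facets <- function(mesh, cell_tag) {
  tet <- mesh$tet
  nv <- as.double(nrow(mesh$vert))
  faces_local <- rbind(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))
  nt <- nrow(tet)
  tri <- matrix(0L, nt * 4L, 3L)
  owner <- integer(nt * 4L)
  for (f in 1:4) {
    idx <- seq.int(f, by = 4L, length.out = nt)
    tri[idx, ] <- tet[, faces_local[f, ], drop = FALSE]
    owner[idx] <- seq_len(nt)
  }
  s <- t(apply(tri, 1, sort))
  key <- (s[, 1] - 1) * nv * nv + (s[, 2] - 1) * nv + s[, 3]
  ord <- order(key)
  key_s <- key[ord]
  dup_next <- c(key_s[-1] == key_s[-length(key_s)], FALSE)
  dup_prev <- c(FALSE, dup_next[-length(dup_next)])
  first_of_pair <- which(dup_next)
  single <- which(!dup_next & !dup_prev)
  # exterior facets
  ext <- list(tri = s[ord[single], , drop = FALSE],
              cell1 = owner[ord[single]], cell2 = rep(NA_integer_, length(single)))
  # interior facets between differing tags
  c1 <- owner[ord[first_of_pair]]
  c2 <- owner[ord[first_of_pair + 1L]]
  diffs <- which(cell_tag[c1] != cell_tag[c2])
  int <- list(tri = s[ord[first_of_pair[diffs]], , drop = FALSE],
              cell1 = c1[diffs], cell2 = c2[diffs])
  list(exterior = ext, interface = int)
}

# Per-cell affine geometry: detJ (6*vol) and inverse-transpose Jacobians.
tet_geometry <- function(vert, tet) {
  v1 <- vert[tet[, 1], , drop = FALSE]
  A <- array(0, c(nrow(tet), 3, 3))  # columns of J: edge vectors
  for (k in 2:4) A[, , k - 1] <- vert[tet[, k], , drop = FALSE] - v1
  a <- A[, , 1]; b <- A[, , 2]; cc <- A[, , 3]
  det <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  # inverse of J (J[:, m] = edge m); invJ (3 x 3) rows: grad of ref coords
  inv <- array(0, c(nrow(tet), 3, 3))
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  inv[, 1, ] <- cross(b, cc) / det
  inv[, 2, ] <- cross(cc, a) / det
  inv[, 3, ] <- cross(a, b) / det
  # physical gradient of ref basis: grad_phys = t(invJ) %*% grad_ref, i.e.
  # gphys[k] = sum_m invJ[m, k] * gref[m]; store invJt[e, k, m] = invJ[e, m, k]
  invJt <- aperm(inv, c(1, 3, 2))
  list(det = det, invJt = invJt, vol = det / 6, v1 = v1, J = A)
}

# Triangle facet geometry: areas and (unoriented) unit normals.
tri_geometry <- function(vert, tri) {
  a <- vert[tri[, 2], , drop = FALSE] - vert[tri[, 1], , drop = FALSE]
  b <- vert[tri[, 3], , drop = FALSE] - vert[tri[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(nrm^2))
  list(area = len / 2, normal = nrm / len)
}
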