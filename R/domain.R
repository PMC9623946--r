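# Tagged computational domain: mesh + subdomain/boundary/interface tags,
# probe points and named measurement surfaces.

#' Cell and facet tag ids
#'
#' Integer tag conventions used throughout: cells are `PARENCHYMA` (1) or
#' `CSF` (2); facets are `SKULL` (1), `SPINAL_CORD` (2), `SPINAL_SAS` (3),
#' `INTERFACE` (4), and internal measurement surfaces use ids >= 10.
#' @keywords internal
TAG_CELLS <- c(PARENCHYMA = 1L, CSF = 2L)
TAG_FACETS <- c(SKULL = 1L, SPINAL_CORD = 2L, SPINAL_SAS = 3L, INTERFACE = 4L)

# Assemble an icp_domain from a raw mesh, cell tags, a list of tagged facet
# sets and probe/surface metadata. Facet sets are lists with elements
# tri (nf x 3), cell (adjacent cell used for orientation; for INTERFACE the
# CSF-side cell so the stored normal points from CSF into parenchyma).
make_domain <- function(vert, tet, cell_tag, facet_sets, probes = list(),
                        surfaces = list(), meta = list()) {
  ed <- build_edges(list(vert = vert, tet = tet))
  geo <- tet_geometry(vert, tet)
  if (any(geo$det <= 0)) stop("mesh contains inverted tetrahedra")
  dom <- structure(list(
    vert = vert, tet = tet, edges = ed$edges, tet2edge = ed$tet2edge,
    cell_tag = cell_tag, facets = facet_sets, probes = probes,
    surfaces = surfaces, geo = geo, meta = meta
  ), class = "icp_domain")
  for (nm in names(dom$facets)) {
    dom$facets[[nm]] <- orient_facet_set(dom, dom$facets[[nm]])
  }
  for (nm in names(dom$surfaces)) {
    dom$surfaces[[nm]] <- orient_facet_set(dom, dom$surfaces[[nm]],
                                           dom$surfaces[[nm]]$direction)
  }
  validate_domain(dom)
  dom
}

# Attach areas and oriented unit normals to a facet set. Default orientation
# is outward from the adjacent cell `cell`; if `direction` is given, normals
# are flipped to have positive dot product with it instead.
orient_facet_set <- function(dom, fs, direction = NULL) {
  if (nrow(fs$tri) == 0) {
    fs$area <- numeric(0); fs$normal <- matrix(0, 0, 3); return(fs)
  }
  tg <- tri_geometry(dom$vert, fs$tri)
  centroid_f <- (dom$vert[fs$tri[, 1], , drop = FALSE] +
                 dom$vert[fs$tri[, 2], , drop = FALSE] +
                 dom$vert[fs$tri[, 3], , drop = FALSE]) / 3
  ct <- dom$tet[fs$cell, , drop = FALSE]
  centroid_c <- (dom$vert[ct[, 1], , drop = FALSE] + dom$vert[ct[, 2], , drop = FALSE] +
                 dom$vert[ct[, 3], , drop = FALSE] + dom$vert[ct[, 4], , drop = FALSE]) / 4
  outward <- rowSums(tg$normal * (centroid_f - centroid_c)) > 0
  nrm <- tg$normal * ifelse(outward, 1, -1)
  if (!is.null(direction)) {
    flip <- as.vector(nrm %*% direction) < 0
    nrm <- nrm * ifelse(flip, -1, 1)
  }
  fs$area <- tg$area
  fs$normal <- nrm
  fs
}

#' Validate domain invariants
#'
#' Checks the tag partition of the exterior boundary, interface adjacency
#' (each interface facet shared by exactly one parenchyma and one CSF cell),
#' probe placement, and positivity of subdomain volumes.
#' @param dom an `icp_domain`.
#' @return `dom`, invisibly; stops with a descriptive error on violation.
#' @keywords internal
validate_domain <- function(dom) {
  fx <- extract_facets(dom, dom$cell_tag)
  n_ext <- nrow(fx$exterior$tri)
  tagged_ext <- sum(vapply(c("SKULL", "SPINAL_CORD", "SPINAL_SAS"),
                           function(nm) if (is.null(dom$facets[[nm]])) 0L
                           else nrow(dom$facets[[nm]]$tri), 0L))
  if (tagged_ext != n_ext) {
    stop(sprintf("exterior boundary not fully tagged: %d facets, %d tagged",
                 n_ext, tagged_ext))
  }
  ifc <- dom$facets[["INTERFACE"]]
  n_int <- nrow(fx$interface$tri)
  if (is.null(ifc) && n_int == 0) ifc <- list(tri = fx$interface$tri)
  if (is.null(ifc) || nrow(ifc$tri) != n_int) {
    stop(sprintf("interface tagging inconsistent: %d facets between subdomains, %d tagged",
                 n_int, if (is.null(ifc)) 0L else nrow(ifc$tri)))
  }
  if (n_int > 0 && !is.null(ifc$cell)) {
    t1 <- dom$cell_tag[ifc$cell]
    t2 <- dom$cell_tag[ifc$cell2]
    if (!all(t1 == TAG_CELLS["CSF"]) || !all(t2 == TAG_CELLS["PARENCHYMA"])) {
      stop("interface facets must have a CSF cell on the orientation side and a parenchyma cell opposite")
    }
  }
  vols <- c(measure(dom, "PARENCHYMA"), measure(dom, "CSF"))
  if (all(vols <= 0)) stop("subdomain volumes must be positive")
  if (n_int > 0 && any(vols <= 0)) stop("subdomain volumes must be positive")
  for (nm in names(dom$probes)) {
    loc <- locate_point(dom, dom$probes[[nm]]$point)
    if (is.null(loc)) stop(sprintf("probe '%s' lies outside the mesh", nm))
    want <- TAG_CELLS[dom$probes[[nm]]$subdomain]
    if (dom$cell_tag[loc$cell] != want) {
      stop(sprintf("probe '%s' not inside its intended subdomain", nm))
    }
  }
  invisible(dom)
}

#' Measure a tagged region
#'
#' Exact mesh-level integral of 1 over a named cell region (volume, m^3) or
#' facet region (area, m^2). Surfaces registered for flux measurement can be
#' measured as well.
#'
#' @param dom an `icp_domain`.
#' @param region region name: `"PARENCHYMA"`, `"CSF"`, a facet tag name, or
#'   a named measurement surface.
#' @return scalar volume or area.
#' @export
measure <- function(dom, region) {
  stopifnot(inherits(dom, "icp_domain"))
  if (region %in% names(TAG_CELLS)) {
    return(sum(dom$geo$vol[dom$cell_tag == TAG_CELLS[region]]))
  }
  if (region %in% names(dom$facets)) return(sum(dom$facets[[region]]$area))
  if (region %in% names(dom$surfaces)) return(sum(dom$surfaces[[region]]$area))
  stop(sprintf("unknown region '%s'", region))
}

#' Locate the cell containing a point
#'
#' @param dom an `icp_domain`.
#' @param p length-3 numeric point (m).
#' @param tol barycentric tolerance.
#' @return list with `cell` and reference coordinates `ref`, or `NULL` if
#'   the point is outside the mesh.
#' @keywords internal
locate_point <- function(dom, p, tol = 1e-10) {
  d <- sweep(dom$geo$v1, 2, p, function(a, b) b - a)  # p - v1
  ref <- matrix(0, nrow(dom$tet), 3)
  for (k in 1:3) {
    # ref_m = sum_k invJ[m,k] d[k]; invJt[e,k,m] = invJ[e,m,k]
    ref[, k] <- dom$geo$invJt[, 1, k] * d[, 1] +
      dom$geo$invJt[, 2, k] * d[, 2] + dom$geo$invJt[, 3, k] * d[, 3]
  }
  lam0 <- 1 - rowSums(ref)
  ok <- which(ref[, 1] >= -tol & ref[, 2] >= -tol & ref[, 3] >= -tol &
                lam0 >= -tol)
  if (length(ok) == 0) return(NULL)
  list(cell = ok[1], ref = ref[ok[1], ])
}

#' @export
print.icp_domain <- function(x, ...) {
  cat("icp_domain:", nrow(x$vert), "vertices,", nrow(x$tet), "tetrahedra\n")
  cat(sprintf("  parenchyma %.2f ml, CSF %.2f ml\n",
              measure(x, "PARENCHYMA") * 1e6, measure(x, "CSF") * 1e6))
  for (nm in names(x$facets)) {
    cat(sprintf("  facets %-12s %6d  (%.2f cm^2)\n", nm, nrow(x$facets[[nm]]$tri),
                sum(x$facets[[nm]]$area) * 1e4))
  }
  if (length(x$probes)) cat("  probes:", paste(names(x$probes), collapse = ", "), "\n")
  invisible(x)
}
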