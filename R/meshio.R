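# Tagged-mesh exchange: Gmsh MSH 2.2 ASCII plus a JSON sidecar naming the
# integer tags and carrying probe points and surface orientations.

SURFACE_TAG_BASE <- 10L

#' Write a tagged domain to disk
#'
#' Writes `<path>.msh` (Gmsh 2.2 ASCII; tetrahedra carry the cell tag,
#' triangles the facet/surface tag as physical group) and `<path>.json`
#' (tag-name map, probes, measurement-surface directions).
#'
#' @param dom an `icp_domain`.
#' @param path file path without extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(dom, path) {
  stopifnot(inherits(dom, "icp_domain"))
  msh <- paste0(path, ".msh")
  con <- file(msh, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(dom$vert))), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(dom$vert)),
                     dom$vert[, 1], dom$vert[, 2], dom$vert[, 3]), con)
  writeLines(c("$EndNodes", "$Elements"), con)
  tri_lines <- character(0)
  tag_of_surface <- integer(0)
  k <- 0L
  for (nm in names(dom$facets)) {
    fs <- dom$facets[[nm]]
    tag <- TAG_FACETS[[nm]]
    if (nrow(fs$tri) > 0) {
      tri_lines <- c(tri_lines, sprintf("2 2 %d %d %d %d %d", tag, tag,
                                        fs$tri[, 1], fs$tri[, 2], fs$tri[, 3]))
    }
  }
  for (nm in names(dom$surfaces)) {
    k <- k + 1L
    fs <- dom$surfaces[[nm]]
    tag <- SURFACE_TAG_BASE + k - 1L
    tag_of_surface[nm] <- tag
    if (nrow(fs$tri) > 0) {
      tri_lines <- c(tri_lines, sprintf("2 2 %d %d %d %d %d", tag, tag,
                                        fs$tri[, 1], fs$tri[, 2], fs$tri[, 3]))
    }
  }
  tet_lines <- sprintf("4 2 %d %d %d %d %d %d", dom$cell_tag, dom$cell_tag,
                       dom$tet[, 1], dom$tet[, 2], dom$tet[, 3], dom$tet[, 4])
  writeLines(as.character(length(tri_lines) + length(tet_lines)), con)
  n_tri <- length(tri_lines)
  writeLines(sprintf("%d %s", seq_len(n_tri), tri_lines), con)
  writeLines(sprintf("%d %s", n_tri + seq_along(tet_lines), tet_lines), con)
  writeLines("$EndElements", con)

  sidecar <- list(
    format = "icpulse-tagged-mesh-1",
    cell_tags = as.list(TAG_CELLS),
    facet_tags = as.list(TAG_FACETS),
    surface_tags = as.list(tag_of_surface),
    surface_directions = lapply(dom$surfaces, function(s) s$direction),
    probes = lapply(dom$probes, function(p) list(point = p$point,
                                                 subdomain = p$subdomain)),
    meta = dom$meta[!vapply(dom$meta, is.function, TRUE)]
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a tagged domain from disk
#'
#' Inverse of [write_mesh()]: reads `<path>.msh` and `<path>.json`, rebuilds
#' facet adjacency and orientations, and validates all domain invariants
#' (full boundary tagging, interface adjacency, probe placement).
#'
#' @param path file path without extension.
#' @return an `icp_domain`.
#' @export
load_mesh <- function(path) {
  msh <- paste0(path, ".msh")
  side <- paste0(path, ".json")
  if (!file.exists(msh)) stop("mesh file not found: ", msh)
  if (!file.exists(side)) stop("sidecar naming map not found: ", side)
  sc <- jsonlite::read_json(side, simplifyVector = TRUE)
  lines <- readLines(msh)
  ni <- which(lines == "$Nodes")
  nn <- as.integer(lines[ni + 1])
  node_rows <- do.call(rbind, strsplit(lines[(ni + 2):(ni + 1 + nn)], " ", fixed = TRUE))
  vert <- matrix(as.numeric(node_rows[, 2:4]), ncol = 3)
  vert <- vert[order(as.integer(node_rows[, 1])), , drop = FALSE]
  ei <- which(lines == "$Elements")
  ne <- as.integer(lines[ei + 1])
  el_lines <- lines[(ei + 2):(ei + 1 + ne)]
  parts <- strsplit(el_lines, " ", fixed = TRUE)
  etype <- vapply(parts, function(p) as.integer(p[2]), 0L)
  tris <- parts[etype == 2L]
  tets <- parts[etype == 4L]
  if (length(tets) == 0) stop("mesh contains no tetrahedra")
  tet_tab <- do.call(rbind, lapply(tets, function(p) as.integer(p[c(4, 6:9)])))
  tet <- tet_tab[, 2:5, drop = FALSE]
  cell_tag <- tet_tab[, 1]
  if (!all(cell_tag %in% unlist(sc$cell_tags))) {
    stop("mesh carries a cell tag id with no name in the sidecar")
  }
  tri_tab <- if (length(tris)) {
    do.call(rbind, lapply(tris, function(p) as.integer(p[c(4, 6:8)])))
  } else matrix(0L, 0, 4)

  # adjacency: match each triangle to the cells owning that face
  fx <- extract_facets(list(vert = vert, tet = tet), cell_tag)
  keyf <- function(tri3) {
    if (nrow(tri3) == 0) return(numeric(0))
    s <- t(apply(tri3, 1, sort))
    nv <- as.double(nrow(vert))
    (s[, 1] - 1) * nv * nv + (s[, 2] - 1) * nv + s[, 3]
  }
  ext_key <- keyf(fx$exterior$tri)
  int_key <- keyf(fx$interface$tri)
  facet_names <- names(sc$facet_tags)
  facet_sets <- list()
  for (nm in facet_names) {
    tag <- sc$facet_tags[[nm]]
    sel <- tri_tab[, 1] == tag
    tri3 <- tri_tab[sel, 2:4, drop = FALSE]
    if (nm == "INTERFACE") {
      m <- match(keyf(tri3), int_key)
      if (nrow(tri3) > 0 && anyNA(m)) {
        stop("dangling INTERFACE facet: not shared by one parenchyma and one CSF cell")
      }
      c1 <- fx$interface$cell1[m]; c2 <- fx$interface$cell2[m]
      csf_first <- ifelse(cell_tag[c1] == sc$cell_tags$CSF, c1, c2)
      par_side <- ifelse(cell_tag[c1] == sc$cell_tags$CSF, c2, c1)
      facet_sets[[nm]] <- list(tri = tri3, cell = csf_first, cell2 = par_side)
    } else {
      m <- match(keyf(tri3), ext_key)
      if (nrow(tri3) > 0 && anyNA(m)) stop(sprintf("facet tagged %s is not an exterior facet", nm))
      facet_sets[[nm]] <- list(tri = tri3, cell = fx$exterior$cell1[m])
    }
  }
  used_tags <- unique(tri_tab[, 1])
  known <- c(unlist(sc$facet_tags), unlist(sc$surface_tags))
  if (!all(used_tags %in% known)) {
    stop("mesh carries facet tag id(s) with no name in the sidecar: ",
         paste(setdiff(used_tags, known), collapse = ", "))
  }
  surfaces <- list()
  for (nm in names(sc$surface_tags)) {
    tag <- sc$surface_tags[[nm]]
    sel <- tri_tab[, 1] == tag
    tri3 <- tri_tab[sel, 2:4, drop = FALSE]
    allf <- faces_of_tets(vert, tet)
    m <- match(keyf(tri3), allf$key)
    if (nrow(tri3) > 0 && anyNA(m)) stop(sprintf("surface %s facet not found in mesh", nm))
    surfaces[[nm]] <- list(tri = tri3, cell = allf$owner[m],
                           direction = as.numeric(sc$surface_directions[[nm]]))
  }
  probes <- lapply(sc$probes, function(p) list(point = as.numeric(p$point),
                                               subdomain = p$subdomain))
  meta <- sc$meta
  make_domain(vert, tet, cell_tag, facet_sets, probes, surfaces, meta)
}

# All faces of all tets with sort-key and one owning cell.
faces_of_tets <- function(vert, tet) {
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
  nv <- as.double(nrow(vert))
  key <- (s[, 1] - 1) * nv * nv + (s[, 2] - 1) * nv + s[, 3]
  first <- !duplicated(key)
  list(key = key[first], owner = owner[first])
}
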