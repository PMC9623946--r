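# Idealized intracranial geometry.
#
# Desk-scale twin of a segmented intracranial space, built on a non-uniform
# rectilinear grid so that every region boundary coincides exactly with grid
# planes. Topology (cranio-caudal z axis, outlet at z = 0):
#   * rigid outer box (SKULL boundary) enclosing everything;
#   * CSF gap of thickness t on all sides (subarachnoid space analog);
#   * poroelastic cube of side a (parenchyma) centered in the box;
#   * CSF cube cavity (ventricular system analog) at the parenchyma center;
#   * square CSF channel (aqueduct analog) from the cavity floor straight
#     down through the parenchyma into the caudal gap;
#   * square parenchymal cord column continuing from the parenchyma floor
#     through the gap to the bottom boundary (spinal cord analog); its end
#     face is the clamped SPINAL_CORD patch, and the surrounding spinal
#     canal annulus on the bottom boundary is the open SPINAL_SAS outlet.
# Circular cross sections (aqueduct, cord, canal) are represented by squares
# of equal area.

# Insert evenly spaced interior points so no interval exceeds h.
refine_ticks <- function(forced, h) {
  forced <- sort(unique(forced))
  out <- numeric(0)
  for (i in seq_len(length(forced) - 1)) {
    n <- max(1L, ceiling((forced[i + 1] - forced[i]) / h - 1e-9))
    out <- c(out, seq(forced[i], forced[i + 1], length.out = n + 1L)[-(n + 1L)])
  }
  c(out, forced[length(forced)])
}

# side of the square with the same area as a disc of diameter d
square_side <- function(d) d * sqrt(pi) / 2

#' Build the idealized tagged intracranial domain
#'
#' Solves for the parenchyma cube side and gap thickness so that parenchyma
#' and SAS volumes match their targets exactly (up to floating point), then
#' meshes, tags and validates the domain.
#'
#' @param V_parenchyma target parenchyma volume (m^3).
#' @param V_sas target subarachnoid (gap) CSF volume (m^3).
#' @param V_ventricle ventricular cavity volume (m^3); default is the sum of
#'   lateral (24.01 ml), third (3.60 ml) and fourth (2.69 ml) ventricle
#'   volumes of a healthy adult head model.
#' @param d_aqueduct,d_canal,d_cord diameters (m) of the aqueduct channel,
#'   spinal canal and spinal cord; converted to equal-area squares.
#' @param hmax target bulk mesh spacing (m). Region boundaries force
#'   additional grid planes, so the actual local spacing can be finer.
#' @return an `icp_domain` with probes `LV`, `SAS`, `V4` and measurement
#'   surfaces `aqueduct` and `spinal_outlet`.
#' @examples
#' \donttest{
#' dom <- build_idealized(hmax = 0.03)
#' measure(dom, "PARENCHYMA") * 1e6   # ml, matches the 1369.54 target
#' }
#' @export
build_idealized <- function(V_parenchyma = 1369.54e-6,
                            V_sas = 292.08e-6,
                            V_ventricle = 30.30e-6,
                            d_aqueduct = 2.88e-3,
                            d_canal = 12e-3,
                            d_cord = 7e-3,
                            hmax = 0.02) {
  stopifnot(V_parenchyma > 0, V_sas > 0, V_ventricle > 0, hmax > 0)
  s_aq <- square_side(d_aqueduct)
  s_cord <- square_side(d_cord)
  s_canal <- square_side(d_canal)
  v <- V_ventricle^(1 / 3)
  if (s_aq >= v) stop("infeasible geometry: channel wider than the ventricular cavity")
  if (s_cord >= s_canal) stop("infeasible geometry: spinal cord wider than the spinal canal")

  # Solve for parenchyma side a and gap thickness t:
  #   a^3 - v^3 - s_aq^2 (a - v)/2 + s_cord^2 t = V_parenchyma
  #   (a + 2t)^3 - a^3 - s_cord^2 t              = V_sas
  a <- (V_parenchyma + V_ventricle)^(1 / 3)
  t <- 4e-3
  for (it in 1:40) {
    fa <- function(a_) a_^3 - v^3 - s_aq^2 * (a_ - v) / 2 + s_cord^2 * t - V_parenchyma
    a_new <- tryCatch(stats::uniroot(fa, c(v * 1.01, 1), tol = 1e-14)$root,
                      error = function(e) stop("infeasible geometry: parenchyma volume target unreachable (",
                                               conditionMessage(e), ")"))
    ft <- function(t_) (a_new + 2 * t_)^3 - a_new^3 - s_cord^2 * t_ - V_sas
    t_new <- tryCatch(stats::uniroot(ft, c(1e-5, 0.2), tol = 1e-15)$root,
                      error = function(e) stop("infeasible geometry: SAS volume target unreachable (",
                                               conditionMessage(e), ")"))
    done <- abs(a_new - a) < 1e-14 && abs(t_new - t) < 1e-14
    a <- a_new; t <- t_new
    if (done) break
  }
  L <- a + 2 * t
  if (s_canal >= a) stop("infeasible geometry: spinal canal wider than the parenchyma block")
  cx <- L / 2
  z_vb <- t + (a - v) / 2        # ventricular cavity floor
  z_vt <- z_vb + v               # cavity ceiling
  zmid <- (t + z_vb) / 2         # aqueduct measurement plane

  xt <- refine_ticks(c(0, t, cx - v / 2, cx - s_canal / 2, cx - s_cord / 2,
                       cx - s_aq / 2, cx + s_aq / 2, cx + s_cord / 2,
                       cx + s_canal / 2, cx + v / 2, L - t, L), hmax)
  zt <- refine_ticks(c(0, t, zmid, z_vb, z_vt, L - t, L), hmax)
  raw <- mesh_rectilinear(xt, xt, zt)

  ctr <- raw$box_center[raw$box_of_tet, , drop = FALSE]
  in_sq <- function(p, half) abs(p[, 1] - cx) < half & abs(p[, 2] - cx) < half
  in_block <- ctr[, 1] > t & ctr[, 1] < L - t & ctr[, 2] > t & ctr[, 2] < L - t &
    ctr[, 3] > t & ctr[, 3] < L - t
  in_vent <- in_sq(ctr, v / 2) & ctr[, 3] > z_vb & ctr[, 3] < z_vt
  in_chan <- in_sq(ctr, s_aq / 2) & ctr[, 3] > t & ctr[, 3] < z_vb
  in_cord <- in_sq(ctr, s_cord / 2) & ctr[, 3] < t
  cell_tag <- rep(TAG_CELLS[["CSF"]], nrow(raw$tet))
  cell_tag[in_block] <- TAG_CELLS[["PARENCHYMA"]]
  cell_tag[in_vent | in_chan] <- TAG_CELLS[["CSF"]]
  cell_tag[in_cord] <- TAG_CELLS[["PARENCHYMA"]]

  fx <- extract_facets(raw, cell_tag)
  ext <- fx$exterior
  fc <- (raw$vert[ext$tri[, 1], , drop = FALSE] +
         raw$vert[ext$tri[, 2], , drop = FALSE] +
         raw$vert[ext$tri[, 3], , drop = FALSE]) / 3
  eps <- 1e-12 * L
  on_bottom <- fc[, 3] < eps
  cord_face <- on_bottom & in_sq(fc, s_cord / 2)
  sas_face <- on_bottom & !cord_face & in_sq(fc, s_canal / 2)
  pick <- function(sel, cells, tris) list(tri = tris[sel, , drop = FALSE],
                                          cell = cells[sel])
  ifc_csf_first <- ifelse(cell_tag[fx$interface$cell1] == TAG_CELLS[["CSF"]],
                          fx$interface$cell1, fx$interface$cell2)
  ifc_par <- ifelse(cell_tag[fx$interface$cell1] == TAG_CELLS[["CSF"]],
                    fx$interface$cell2, fx$interface$cell1)
  facet_sets <- list(
    SKULL = pick(!(cord_face | sas_face), ext$cell1, ext$tri),
    SPINAL_CORD = pick(cord_face, ext$cell1, ext$tri),
    SPINAL_SAS = pick(sas_face, ext$cell1, ext$tri),
    INTERFACE = list(tri = fx$interface$tri, cell = ifc_csf_first,
                     cell2 = ifc_par)
  )

  aq <- faces_on_plane(raw, zmid, function(p) in_sq(p, s_aq / 2))
  surfaces <- list(
    aqueduct = list(tri = aq$tri, cell = aq$cell, direction = c(0, 0, -1)),
    spinal_outlet = list(tri = facet_sets$SPINAL_SAS$tri,
                         cell = facet_sets$SPINAL_SAS$cell,
                         direction = c(0, 0, -1))
  )

  dx <- s_aq / 5
  probes <- list(
    LV = list(point = c(cx + dx, cx, z_vb + v / 2), subdomain = "CSF"),
    SAS = list(point = c(cx + dx, cx, L - t / 2), subdomain = "CSF"),
    V4 = list(point = c(cx + dx, cx, t + 0.1 * (zmid - t)), subdomain = "CSF")
  )

  meta <- list(a = a, t = t, L = L, v = v, z_vb = z_vb, z_vt = z_vt,
               zmid = zmid, s_aq = s_aq, s_cord = s_cord, s_canal = s_canal,
               hmax = hmax, kind = "idealized-nested-box")
  make_domain(raw$vert, raw$tet, cell_tag, facet_sets, probes, surfaces, meta)
}

# Interior mesh faces lying on the grid plane z = z0 whose centroid passes
# region_test; each face reported once with one adjacent cell.
faces_on_plane <- function(raw, z0, region_test) {
  tet <- raw$tet
  vert <- raw$vert
  faces_local <- rbind(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))
  nt <- nrow(tet)
  tri <- matrix(0L, nt * 4L, 3L)
  owner <- integer(nt * 4L)
  for (f in 1:4) {
    idx <- seq.int(f, by = 4L, length.out = nt)
    tri[idx, ] <- tet[, faces_local[f, ], drop = FALSE]
    owner[idx] <- seq_len(nt)
  }
  eps <- 1e-12 + 1e-12 * abs(z0)
  onz <- abs(vert[tri[, 1], 3] - z0) < eps & abs(vert[tri[, 2], 3] - z0) < eps &
    abs(vert[tri[, 3], 3] - z0) < eps
  tri <- tri[onz, , drop = FALSE]
  owner <- owner[onz]
  fc <- (vert[tri[, 1], , drop = FALSE] + vert[tri[, 2], , drop = FALSE] +
         vert[tri[, 3], , drop = FALSE]) / 3
  keep <- region_test(fc)
  tri <- tri[keep, , drop = FALSE]
  owner <- owner[keep]
  s <- t(apply(tri, 1, sort))
  nv <- as.double(nrow(vert))
  key <- (s[, 1] - 1) * nv * nv + (s[, 2] - 1) * nv + s[, 3]
  first <- !duplicated(key)
  list(tri = s[first, , drop = FALSE], cell = owner[first])
}
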