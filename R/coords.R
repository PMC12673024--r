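#' Compute universal ventricular coordinates
#'
#' Harmonic (Laplace) interpolation of the normalized ventricular coordinate
#' fields on a biventricular tetrahedral mesh:
#' \describe{
#'   \item{transmural}{0 on the endocardium, 1 on the epicardium. The septal
#'     surface facing the RV cavity counts as the outer (value 1) boundary of
#'     the septum, while the RV free-wall endocardium counts as inner
#'     (value 0); at the insertion lines, where the two meet, the epicardial
#'     value takes precedence.}
#'   \item{apicobasal}{0 at the apex, 1 on the base, harmonic in between.}
#'   \item{rotational}{geometric angle about the long axis in \[-pi, pi),
#'     origin at the anterior LV-RV junction, increasing through the septum.}
#'   \item{ventricle}{`"lv"` (including the septum) or `"rv"`.}
#' }
#'
#' @param mesh a `bv_mesh` with tagged boundary faces.
#' @return a `ventricular_coordinates` object: data.frame with one row per
#'   node plus the assembled stiffness matrix and element geometry cached as
#'   attributes (reused by fiber assignment).
#' @export
compute_ventricular_coordinates <- function(mesh) {
  stopifnot(inherits(mesh, "bv_mesh"))
  if (is.null(mesh$face_tag) || !length(mesh$face_tag))
    stop("mesh has no surface tags; cannot set boundary conditions")
  need <- c("lv_endo", "rv_endo", "epi", "base")
  if (!all(need %in% mesh$face_tag))
    stop("missing surface tags: ",
         paste(setdiff(need, mesh$face_tag), collapse = ", "))
  geom <- tet_geometry(mesh$nodes, mesh$elems)
  K <- assemble_stiffness(mesh$nodes, mesh$elems, geom = geom)

  face_nodes <- function(tag, elem_sel = NULL) {
    sel <- mesh$face_tag == tag
    if (!is.null(elem_sel)) sel <- sel & elem_sel[mesh$face_elem]
    unique(as.vector(mesh$faces[sel, , drop = FALSE]))
  }
  septal <- mesh$region == "septum"
  rv_wall <- mesh$region == "rv"
  inner <- union(face_nodes("lv_endo"), face_nodes("rv_endo", rv_wall))
  outer <- union(face_nodes("epi"), face_nodes("rv_endo", septal))
  inner <- setdiff(inner, outer)  # epicardial value wins at insertion lines
  transmural <- solve_laplace(K, c(inner, outer),
                              c(rep(0, length(inner)), rep(1, length(outer))))
  transmural <- pmin(1, pmax(0, transmural))

  # apicobasal: normalized geodesic position between the apex and the base,
  # ab = d_apex / (d_apex + d_base) computed through the wall volume. (A pure
  # Laplace solve is ill-suited here: the apex boundary set is point-like in
  # 3-D, so the harmonic field hugs 1 almost everywhere.)
  base_nodes <- face_nodes("base")
  # apex set: the full transmural column on the long axis (distance-to-axis
  # criterion), so endo and epi apex both carry ab = 0
  zmin <- min(mesh$nodes[, 3])
  rho <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2)
  apex_nodes <- setdiff(which(rho < 2.5 * mesh$params$edge_length &
                              mesh$nodes[, 3] < zmin / 2), base_nodes)
  if (!length(apex_nodes)) stop("could not locate the apex region")
  ed <- mesh_edges(mesh$elems)
  len <- sqrt(rowSums((mesh$nodes[ed[, 1], ] - mesh$nodes[ed[, 2], ])^2))
  n <- nrow(mesh$nodes)
  # two super-source vertices (n+1: apex set, n+2: base set) make the
  # min-over-set distances a single shortest-path run each
  ed_all <- rbind(ed, cbind(rep(n + 1L, length(apex_nodes)), apex_nodes),
                  cbind(rep(n + 2L, length(base_nodes)), base_nodes))
  g <- igraph::graph_from_edgelist(ed_all, directed = FALSE)
  igraph::E(g)$weight <- c(len, rep(0, length(apex_nodes) + length(base_nodes)))
  da <- as.numeric(igraph::distances(g, v = n + 1L))[seq_len(n)]
  db <- as.numeric(igraph::distances(g, v = n + 2L))[seq_len(n)]
  apicobasal <- pmin(1, pmax(0, da / (da + db)))

  rot_raw <- atan2(mesh$nodes[, 2], mesh$nodes[, 1]) - mesh$params$phi1
  rotational <- ((rot_raw + pi) %% (2 * pi)) - pi

  elem_rv <- mesh$region == "rv"
  nv <- rep("lv", nrow(mesh$nodes))
  nv[unique(as.vector(mesh$elems[elem_rv, ]))] <- "rv"
  # nodes shared with the LV (insertion lines) stay labelled LV
  nv[unique(as.vector(mesh$elems[!elem_rv, ]))[
       unique(as.vector(mesh$elems[!elem_rv, ])) %in%
       unique(as.vector(mesh$elems[elem_rv, ]))]] <- "lv"

  out <- data.frame(apicobasal = apicobasal, transmural = transmural,
                    rotational = rotational, ventricle = nv,
                    stringsAsFactors = FALSE)
  attr(out, "geom") <- geom
  attr(out, "stiffness") <- K
  class(out) <- c("ventricular_coordinates", "data.frame")
  out
}

#' Assign rule-based myocardial fibers
#'
#' Rule-based fiber architecture: within each element the helix angle
#' interpolates linearly in the transmural coordinate from `alpha_endo` on
#' the endocardium to `alpha_epi` on the epicardium, and the fiber direction
#' is rotated by that angle from the local circumferential direction towards
#' the local longitudinal direction. The local frame is built from the
#' gradients of the transmural and apicobasal Laplace fields.
#'
#' @param mesh a `bv_mesh`.
#' @param coords output of [compute_ventricular_coordinates()].
#' @param alpha_endo,alpha_epi helix angles (degrees) on endo/epicardium.
#' @return the mesh with per-element unit `fibers` replaced.
#' @export
assign_fibers <- function(mesh, coords, alpha_endo = 60, alpha_epi = -60) {
  stopifnot(inherits(mesh, "bv_mesh"),
            inherits(coords, "ventricular_coordinates"))
  geom <- attr(coords, "geom")
  if (is.null(geom)) geom <- tet_geometry(mesh$nodes, mesh$elems)
  gt <- field_gradient(coords$transmural, mesh$elems, geom)
  gab <- field_gradient(coords$apicobasal, mesh$elems, geom)
  nt <- sqrt(rowSums(gt^2)); nt[nt < 1e-12] <- 1
  e_t <- gt / nt
  # longitudinal: apicobasal gradient orthogonalized against transmural
  gl <- gab - rowSums(gab * e_t) * e_t
  nl <- sqrt(rowSums(gl^2))
  # degenerate frames (flat gradients at junction lines): fall back to the
  # global long axis
  bad <- nl < 1e-9
  if (any(bad)) {
    up <- cbind(0, 0, 1)[rep(1, sum(bad)), , drop = FALSE]
    gl[bad, ] <- up - rowSums(up * e_t[bad, , drop = FALSE]) * e_t[bad, , drop = FALSE]
    nl[bad] <- sqrt(rowSums(gl[bad, , drop = FALSE]^2))
    nl[nl < 1e-9] <- 1
  }
  e_l <- gl / nl
  e_c <- cbind(e_l[, 2] * e_t[, 3] - e_l[, 3] * e_t[, 2],
               e_l[, 3] * e_t[, 1] - e_l[, 1] * e_t[, 3],
               e_l[, 1] * e_t[, 2] - e_l[, 2] * e_t[, 1])
  tfrac <- rowMeans(matrix(coords$transmural[mesh$elems], ncol = 4))
  alpha <- (alpha_endo + (alpha_epi - alpha_endo) * tfrac) * pi / 180
  f <- cos(alpha) * e_c + sin(alpha) * e_l
  nf <- sqrt(rowSums(f^2))
  # fully degenerate frames (a handful of junction-line elements where the
  # Laplace gradient vanishes): fall back to the parametric geometric frame
  deg <- nf < 1e-6
  if (any(deg)) {
    cent <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
             mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
    f[deg, ] <- .fibers_from_frame(cent[deg, , drop = FALSE], tfrac[deg],
                                   alpha_endo, alpha_epi)
    nf[deg] <- sqrt(rowSums(f[deg, , drop = FALSE]^2))
  }
  mesh$fibers <- f / nf
  attr(mesh$fibers, "helix_deg") <- alpha * 180 / pi
  mesh
}
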