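#' Build an idealized biventricular tetrahedral mesh
#'
#' Constructs a desk-scale stand-in for image-derived biventricular anatomy:
#' a thick-walled truncated ellipsoidal LV shell with a thin-walled RV
#' crescent wrapped around part of its epicardium. The wall midsurface is
#' triangulated with rings graded so that all edges stay close to the target
#' edge length (including near the apex pole), then extruded transmurally
#' into prisms that are split into tetrahedra with a consistent
#' (minimum-vertex) diagonal rule, which guarantees a conforming mesh. The RV
#' free wall is extruded outward from the septal sector of the LV epicardium,
#' leaving the RV cavity as an unmeshed gap that pinches out at the insertion
#' lines and at the RV apex, where the free wall attaches to the septum.
#'
#' The construction is fully deterministic: the same parameters always
#' produce identical node and element arrays (the `seed` argument is accepted
#' for interface uniformity and recorded, but no randomness is used).
#'
#' @param lv_radius LV endocardial equatorial semi-axis (mm).
#' @param lv_length LV endocardial long semi-axis, apex to equator plane (mm).
#' @param lv_wall LV/septal wall thickness (mm): a positive scalar or a
#'   function of the apicobasal position (0 apex, 1 base) returning mm.
#' @param rv_wall RV free-wall thickness (mm).
#' @param rv_gap maximal RV cavity width (mm).
#' @param rv_phi_deg rotational extent (degrees, length 2) of the RV sector.
#' @param rv_apex_frac apicobasal position where the RV begins (fraction of
#'   the truncated meridian, from the apex).
#' @param theta_base_deg polar truncation angle of the base (degrees; 90 is
#'   the equator).
#' @param edge_length target edge length (mm); must not exceed half the
#'   thinnest requested wall.
#' @param seed recorded for provenance; the construction is deterministic.
#' @return an object of class `bv_mesh` with fields `nodes` (mm), `elems`
#'   (1-based tetrahedra), `region` (per element: `"lv"`, `"rv"`,
#'   `"septum"`), `fibers` (per-element unit vectors, rule-based default),
#'   `faces`/`face_tag`/`face_elem` (boundary faces tagged `"lv_endo"`,
#'   `"rv_endo"`, `"epi"`, `"base"`), and `node_meta` (construction
#'   provenance per node).
#' @examples
#' mesh <- build_idealized_biventricle(lv_radius = 15, lv_length = 28,
#'                                     lv_wall = 6, rv_wall = 3,
#'                                     edge_length = 2.5)
#' table(mesh$region)
#' @export
build_idealized_biventricle <- function(lv_radius = 24, lv_length = 48,
                                        lv_wall = 10, rv_wall = 3.5,
                                        rv_gap = 5,
                                        rv_phi_deg = c(60, 200),
                                        rv_apex_frac = 0.16,
                                        theta_base_deg = 100,
                                        edge_length = 1.5, seed = 1L) {
  wall_fun <- if (is.function(lv_wall)) lv_wall else function(ab) rep(lv_wall, length(ab))
  wt_probe <- wall_fun(seq(0, 1, length.out = 21))
  if (any(!is.finite(wt_probe)) || any(wt_probe <= 0))
    stop("lv_wall must be positive everywhere")
  if (rv_wall <= 0 || rv_gap < 0) stop("rv_wall must be > 0 and rv_gap >= 0")
  if (edge_length > min(wt_probe) / 2)
    stop(sprintf(paste0("target edge length %.2f mm exceeds half the thinnest",
                        " LV wall (%.2f mm); refine the mesh or thicken the wall"),
                 edge_length, min(wt_probe)))
  if (max(wt_probe) >= lv_radius)
    stop("infeasible geometry: wall thicker than the LV radius")
  a <- lv_radius; cc <- lv_length
  theta_max <- theta_base_deg * pi / 180
  phi1 <- rv_phi_deg[1] * pi / 180; phi2 <- rv_phi_deg[2] * pi / 180
  if (phi2 <= phi1) stop("rv_phi_deg must be increasing")

  ## ---- graded rings along the meridian -------------------------------------
  # grade on the outer surface so the longest (epicardial) edges stay at the
  # target; inner layers are proportionally shorter
  mid <- max(wt_probe)
  m_of <- function(th) sqrt((a + mid)^2 * cos(th)^2 + (cc + mid)^2 * sin(th)^2)
  he <- 0.9 * edge_length   # grading margin keeps worst prism diagonals in band
  thetas <- 0
  while (tail(thetas, 1) < theta_max) {
    th <- tail(thetas, 1)
    thetas <- c(thetas, th + he / m_of(th))
  }
  if (length(thetas) < 4) stop("geometry too small for the target edge length")
  # rescale the ladder so the last ring lands exactly on the truncation angle
  thetas <- thetas * (theta_max / tail(thetas, 1))
  nring <- length(thetas)
  ring_n <- pmax(6L, as.integer(round(2 * pi * (a + mid) * sin(thetas) / he)))
  ring_n[1] <- 1L  # pole

  ## ---- midsurface triangulation (pole fan + ring stitching) ----------------
  ring_off <- cumsum(c(0L, ring_n))        # 0-based offsets
  n_surf <- ring_off[nring + 1]
  surf_theta <- numeric(n_surf); surf_phi <- numeric(n_surf)
  surf_ring <- integer(n_surf)
  for (k in seq_len(nring)) {
    idx <- ring_off[k] + seq_len(ring_n[k])
    surf_theta[idx] <- thetas[k]
    surf_phi[idx] <- 2 * pi * (seq_len(ring_n[k]) - 1) / ring_n[k]
    surf_ring[idx] <- k
  }
  stitch <- function(idsA, phiA, idsB, phiB) {
    # conforming triangulation of the annulus between two rings (any counts);
    # walks both rings in angle order, always advancing the pointer whose next
    # vertex comes first.
    nA <- length(idsA); nB <- length(idsB)
    tris <- matrix(0L, nA + nB, 3)
    i <- 1L; j <- 1L; t <- 0L
    nextA <- function(i) phiA[1L + (i %% nA)] + 2 * pi * ((i %% nA) == 0)
    nextB <- function(j) phiB[1L + (j %% nB)] + 2 * pi * ((j %% nB) == 0)
    while (i <= nA || j <= nB) {
      advA <- if (i > nA) FALSE else if (j > nB) TRUE else nextA(i) <= nextB(j)
      t <- t + 1L
      if (advA) {
        tris[t, ] <- c(idsA[1L + ((i - 1L) %% nA)], idsA[1L + (i %% nA)],
                       idsB[1L + ((j - 1L) %% nB)])
        i <- i + 1L
      } else {
        tris[t, ] <- c(idsB[1L + (j %% nB)], idsB[1L + ((j - 1L) %% nB)],
                       idsA[1L + ((i - 1L) %% nA)])
        j <- j + 1L
      }
    }
    tris[seq_len(t), , drop = FALSE]
  }
  tri_list <- vector("list", nring - 1)
  for (k in seq_len(nring - 1)) {
    idsA <- ring_off[k] + seq_len(ring_n[k])
    idsB <- ring_off[k + 1] + seq_len(ring_n[k + 1])
    if (ring_n[k] == 1L) {
      nB <- ring_n[k + 1]
      tri_list[[k]] <- cbind(idsA, idsB[1L + (seq_len(nB) %% nB)], idsB)
    } else {
      tri_list[[k]] <- stitch(idsA, surf_phi[idsA], idsB, surf_phi[idsB])
    }
  }
  tris <- do.call(rbind, tri_list)

  ## ---- transmural extrusion ------------------------------------------------
  ab_of <- function(th) th / theta_max
  wt_surf <- wall_fun(ab_of(surf_theta))
  n_t <- max(2L, as.integer(ceiling(max(wt_probe) / edge_length)))
  pos_of <- function(theta, phi, d)
    cbind((a + d) * sin(theta) * cos(phi),
          (a + d) * sin(theta) * sin(phi),
          -(cc + d) * cos(theta))
  n_lv_nodes <- n_surf * (n_t + 1L)
  lv_id <- function(s, l) s + n_surf * l       # l = 0..n_t
  nodes <- matrix(0, n_lv_nodes, 3)
  meta_l <- integer(n_lv_nodes)
  for (l in 0:n_t) {
    idx <- lv_id(seq_len(n_surf), l)
    nodes[idx, ] <- pos_of(surf_theta, surf_phi, (l / n_t) * wt_surf)
    meta_l[idx] <- l
  }
  meta_family <- rep("lv", n_lv_nodes)
  meta_surf <- rep(seq_len(n_surf), n_t + 1L)

  ## ---- RV sector -----------------------------------------------------------
  # snap the RV start to an existing ring so the most apical free-wall ring
  # is exactly attached to the septum (gap 0); the cavity gap profile is
  # rescaled per ring so the first and last in-sector columns are attached
  # too (sealed cavity, conducting insertion lines)
  theta_rv0_nom <- rv_apex_frac * theta_max
  theta_rv0 <- min(thetas[thetas >= theta_rv0_nom - 1e-12])
  in_sector <- surf_phi >= phi1 - 1e-9 & surf_phi <= phi2 + 1e-9 &
    surf_theta >= theta_rv0 - 1e-9
  ramp_rad <- max(4 * edge_length, 9) / m_of(theta_rv0)
  gap_ramp <- pmin(1, pmax(0, (surf_theta - theta_rv0) / ramp_rad))
  gap <- numeric(n_surf)
  for (k in which(thetas >= theta_rv0 - 1e-12)) {
    ring_idx <- which(surf_ring == k & in_sector)
    if (length(ring_idx) < 3) { in_sector[ring_idx] <- FALSE; next }
    ph <- surf_phi[ring_idx]
    s <- (ph - min(ph)) / max(max(ph) - min(ph), 1e-12)
    gap[ring_idx] <- rv_gap * sin(pi * s) * gap_ramp[ring_idx]
  }
  sector_tri <- in_sector[tris[, 1]] & in_sector[tris[, 2]] & in_sector[tris[, 3]]
  n_trv <- max(2L, as.integer(ceiling(rv_wall / edge_length)))
  rv_cols <- which(in_sector)                      # surface columns carrying RV nodes
  rv_id_map <- matrix(NA_integer_, n_surf, n_trv + 1L)
  if (length(rv_cols)) {
    grid <- expand.grid(s = rv_cols, l = 0:n_trv)
    attach_row <- grid$l == 0L & gap[grid$s] <= 1e-9
    rv_id_map[cbind(grid$s[attach_row], 1L)] <- lv_id(grid$s[attach_row], n_t)
    new <- grid[!attach_row, , drop = FALSE]
    if (nrow(new)) {
      ids <- n_lv_nodes + seq_len(nrow(new))
      rv_id_map[cbind(new$s, new$l + 1L)] <- ids
      d <- wt_surf[new$s] + gap[new$s] + (new$l / n_trv) * rv_wall
      nodes <- rbind(nodes, pos_of(surf_theta[new$s], surf_phi[new$s], d))
      meta_l <- c(meta_l, new$l)
      meta_family <- c(meta_family, rep("rv", nrow(new)))
      meta_surf <- c(meta_surf, new$s)
    }
  }

  ## ---- prisms -> tetrahedra (minimum-vertex diagonal rule) -----------------
  prism_split <- function(bot, top) {
    # bot/top: n x 3 node ids, column i of top above column i of bot.
    # Rotate/mirror each prism so its smallest global id sits at bottom
    # vertex 1; that vertex anchors two quad diagonals, the third quad splits
    # by the min rule. Identical face diagonals on shared quads make the
    # split conforming.
    v <- cbind(bot, top)
    imin <- max.col(-v, ties.method = "first")
    rots <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2),
                 c(1, 3, 2), c(2, 1, 3), c(3, 2, 1))
    b <- matrix(0L, nrow(v), 3); tt <- matrix(0L, nrow(v), 3)
    for (case in 1:6) {
      sel <- imin == case
      if (!any(sel)) next
      rot <- rots[[case]]
      if (case <= 3) {
        b[sel, ] <- v[sel, rot, drop = FALSE]
        tt[sel, ] <- v[sel, rot + 3, drop = FALSE]
      } else {  # mirrored: the smallest id is on the top triangle
        b[sel, ] <- v[sel, rot + 3, drop = FALSE]
        tt[sel, ] <- v[sel, rot, drop = FALSE]
      }
    }
    caseA <- pmin(b[, 2], tt[, 3]) < pmin(b[, 3], tt[, 2])
    t1 <- cbind(b[, 1], b[, 2], b[, 3], ifelse(caseA, tt[, 3], tt[, 2]))
    t2 <- ifelse(rep(caseA, 4),
                 cbind(b[, 1], b[, 2], tt[, 3], tt[, 2]),
                 cbind(b[, 1], tt[, 2], b[, 3], tt[, 3]))
    dim(t2) <- c(nrow(b), 4)
    t3 <- cbind(b[, 1], tt[, 2], tt[, 3], tt[, 1])
    out <- matrix(0L, 3L * nrow(b), 4L)
    out[seq(1, by = 3, length.out = nrow(b)), ] <- t1
    out[seq(2, by = 3, length.out = nrow(b)), ] <- t2
    out[seq(3, by = 3, length.out = nrow(b)), ] <- t3
    out
  }
  lv_elems <- vector("list", n_t)
  for (l in seq_len(n_t)) {
    bot <- matrix(lv_id(as.vector(tris), l - 1L), ncol = 3)
    top <- matrix(lv_id(as.vector(tris), l), ncol = 3)
    lv_elems[[l]] <- prism_split(bot, top)
  }
  lv_elems <- do.call(rbind, lv_elems)
  lv_region <- rep(rep(ifelse(sector_tri, 3L, 1L), each = 3L), n_t)

  rv_elems <- NULL
  if (any(sector_tri)) {
    st <- tris[sector_tri, , drop = FALSE]
    rv_el <- vector("list", n_trv)
    for (l in seq_len(n_trv)) {
      bot <- matrix(rv_id_map[cbind(as.vector(st), l)], ncol = 3)
      top <- matrix(rv_id_map[cbind(as.vector(st), l + 1L)], ncol = 3)
      rv_el[[l]] <- prism_split(bot, top)
    }
    rv_elems <- do.call(rbind, rv_el)
  }
  elems <- rbind(lv_elems, rv_elems)
  region <- c(lv_region, rep(2L, if (is.null(rv_elems)) 0 else nrow(rv_elems)))

  # drop degenerate tetrahedra (collapsed at the pole / insertion pinch) and
  # orient positively
  geom <- tet_geometry(nodes, elems)
  keep <- abs(geom$volume_mm3) > 1e-9
  elems <- elems[keep, , drop = FALSE]
  region <- region[keep]
  vol <- geom$volume_mm3[keep]
  flip <- vol < 0
  if (any(flip)) elems[flip, c(3, 4)] <- elems[flip, c(4, 3)]

  # drop unreferenced nodes (aliased RV layer-0 slots never materialized)
  used <- sort(unique(as.vector(elems)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  elems <- matrix(remap[elems], ncol = 4)
  meta <- data.frame(family = meta_family[used], surf = meta_surf[used],
                     layer = meta_l[used],
                     theta = surf_theta[meta_surf[used]],
                     phi = surf_phi[meta_surf[used]],
                     stringsAsFactors = FALSE)

  ## ---- boundary faces ------------------------------------------------------
  fc <- boundary_faces(elems)
  fam <- matrix(meta$family[fc$faces] == "rv", ncol = 3)
  lay <- matrix(meta$layer[fc$faces], ncol = 3)
  reg <- region[fc$elem]
  lay_rv <- ifelse(fam, lay, 0L)           # attached nodes sit at the RV endo
  face_tag <- rep("base", nrow(fc$faces))
  is_rv <- reg == 2L
  face_tag[is_rv] <- ifelse(rowSums(lay_rv[is_rv, , drop = FALSE] == 0L) == 3L,
                            "rv_endo", "epi")
  lv_endo_f <- !is_rv & rowSums(!fam & lay == 0L) == 3L
  lv_outer_f <- !is_rv & rowSums(!fam & lay == n_t) == 3L
  face_tag[lv_endo_f] <- "lv_endo"
  face_tag[lv_outer_f] <- ifelse(reg[lv_outer_f] == 3L, "rv_endo", "epi")

  mesh <- structure(list(
    nodes = nodes, elems = elems,
    region = factor(c("lv", "rv", "septum")[region],
                    levels = c("lv", "rv", "septum")),
    fibers = NULL,
    faces = fc$faces, face_tag = face_tag, face_elem = fc$elem,
    node_meta = meta,
    params = list(lv_radius = lv_radius, lv_length = lv_length,
                  lv_wall = if (is.function(lv_wall)) "function" else lv_wall,
                  rv_wall = rv_wall, rv_gap = rv_gap,
                  rv_phi_deg = rv_phi_deg, rv_apex_frac = rv_apex_frac,
                  theta_base_deg = theta_base_deg,
                  edge_length = edge_length, seed = seed,
                  n_t = n_t, n_trv = n_trv, theta_max = theta_max,
                  phi1 = phi1, phi2 = phi2)),
    class = "bv_mesh")
  mesh$fibers <- .parametric_fibers(mesh)
  mesh
}

# boundary faces of a tet mesh: faces referenced by exactly one element
boundary_faces <- function(elems) {
  m <- nrow(elems)
  combs <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  faces <- matrix(0L, 4L * m, 3L)
  for (q in 1:4) faces[(q - 1L) * m + seq_len(m), ] <- elems[, combs[q, ]]
  elem_of <- rep(seq_len(m), times = 4)
  s1 <- pmin(faces[, 1], faces[, 2], faces[, 3])
  s3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  s2 <- faces[, 1] + faces[, 2] + faces[, 3] - s1 - s3
  o <- order(s1, s2, s3)
  d1 <- s1[o]; d2 <- s2[o]; d3 <- s3[o]
  same_prev <- c(FALSE, d1[-1] == d1[-length(d1)] & d2[-1] == d2[-length(d2)] &
                        d3[-1] == d3[-length(d3)])
  same_next <- c(same_prev[-1], FALSE)
  solo <- !(same_prev | same_next)
  sel <- o[solo]
  list(faces = faces[sel, , drop = FALSE], elem = elem_of[sel])
}

# default rule-based fibers from the parametric construction (the Laplace
# route lives in assign_fibers)
.parametric_fibers <- function(mesh, alpha_endo = 60, alpha_epi = -60) {
  cent <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
           mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
  lay <- matrix(mesh$node_meta$layer[mesh$elems], ncol = 4)
  fam_rv <- matrix(mesh$node_meta$family[mesh$elems] == "rv", ncol = 4)
  n_t <- mesh$params$n_t; n_trv <- mesh$params$n_trv
  depth <- ifelse(fam_rv, lay / n_trv, lay / n_t)
  tfrac <- rowMeans(depth)
  .fibers_from_frame(cent, tfrac, alpha_endo, alpha_epi)
}

.fibers_from_frame <- function(cent, tfrac, alpha_endo, alpha_epi) {
  # transmural direction ~ outward normal of the ellipsoidal level surface;
  # circumferential = horizontal tangent; longitudinal completes the frame
  up <- cbind(0, 0, 1)
  e_c <- cbind(-cent[, 2], cent[, 1], 0)
  nc <- sqrt(rowSums(e_c^2)); nc[nc < 1e-9] <- 1
  e_c <- e_c / nc
  radial <- cbind(cent[, 1], cent[, 2], cent[, 3])
  e_t <- radial / pmax(sqrt(rowSums(radial^2)), 1e-9)
  e_l <- cbind(e_t[, 2] * e_c[, 3] - e_t[, 3] * e_c[, 2],
               e_t[, 3] * e_c[, 1] - e_t[, 1] * e_c[, 3],
               e_t[, 1] * e_c[, 2] - e_t[, 2] * e_c[, 1])
  nl <- sqrt(rowSums(e_l^2)); nl[nl < 1e-9] <- 1
  e_l <- e_l / nl
  alpha <- (alpha_endo + (alpha_epi - alpha_endo) * tfrac) * pi / 180
  f <- cos(alpha) * e_c + sin(alpha) * e_l
  f / sqrt(rowSums(f^2))
}

#' Mesh sanity checks
#'
#' Verifies the structural invariants of a biventricular mesh: valid element
#' indices, unit fibers, positive element volumes, a single connected
#' component, and edge lengths within a factor-2 band of the target.
#'
#' @param mesh a `bv_mesh`.
#' @return invisibly, a list of diagnostics; problems raise errors.
#' @export
check_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "bv_mesh"))
  n <- nrow(mesh$nodes)
  if (any(mesh$elems < 1L) || any(mesh$elems > n))
    stop("element references an invalid node")
  geom <- tet_geometry(mesh$nodes, mesh$elems)
  if (any(geom$volume_mm3 <= 0))
    stop("mesh contains inverted (non-positive volume) tetrahedra")
  if (!is.null(mesh$fibers)) {
    nrm <- sqrt(rowSums(mesh$fibers^2))
    if (any(abs(nrm - 1) > 1e-9)) stop("fibers are not unit vectors")
  }
  ed <- mesh_edges(mesh$elems)
  len <- sqrt(rowSums((mesh$nodes[ed[, 1], ] - mesh$nodes[ed[, 2], ])^2))
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  comp <- igraph::components(g)$no
  if (comp != 1L) stop(sprintf("mesh has %d connected components", comp))
  invisible(list(n_nodes = n, n_elems = nrow(mesh$elems),
                 volume_mm3 = sum(geom$volume_mm3),
                 edge_range_mm = range(len), components = comp))
}

# unique undirected edges of a tet mesh
mesh_edges <- function(elems) {
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  ed <- do.call(rbind, lapply(seq_len(6), function(q)
    cbind(elems[, pairs[q, 1]], elems[, pairs[q, 2]])))
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  unique(ed)
}

#' @export
print.bv_mesh <- function(x, ...) {
  cat(sprintf("Biventricular tetrahedral mesh: %d nodes, %d elements\n",
              nrow(x$nodes), nrow(x$elems)))
  cat("  regions:", paste(sprintf("%s=%d", levels(x$region), table(x$region)),
                          collapse = ", "), "\n")
  cat("  boundary faces:",
      paste(sprintf("%s=%d", names(table(x$face_tag)), table(x$face_tag)),
            collapse = ", "), "\n")
  invisible(x)
}
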