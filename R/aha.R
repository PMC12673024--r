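#' AHA 17-segment segmentation of the left ventricle
#'
#' Assigns every LV element (free wall and septum) to one of the standard 17
#' AHA segments using the ventricular coordinates: the apex cap (segment 17)
#' below an apicobasal cutoff, then apical (13-16, four 90-degree sectors),
#' mid (7-12) and basal (1-6, six 60-degree sectors) rings. The rotational
#' origin sits at the anterior LV-RV junction, so the septal segments (2, 3,
#' 8, 9, 14) face the RV.
#'
#' @param mesh a `bv_mesh`.
#' @param coords [compute_ventricular_coordinates()].
#' @param apex_cut,apical_cut,mid_cut apicobasal boundaries of the apex cap,
#'   apical and mid rings.
#' @return an `aha_segmentation`: integer vector (1-17) per element, `NA` for
#'   RV elements.
#' @export
aha_segmentation <- function(mesh, coords, apex_cut = 0.12,
                             apical_cut = 0.41, mid_cut = 0.70) {
  stopifnot(inherits(mesh, "bv_mesh"),
            inherits(coords, "ventricular_coordinates"))
  ab <- rowMeans(matrix(coords$apicobasal[mesh$elems], ncol = 4))
  # rotational mean must respect wrap-around: average unit vectors
  rc <- rowMeans(matrix(cos(coords$rotational[mesh$elems]), ncol = 4))
  rs <- rowMeans(matrix(sin(coords$rotational[mesh$elems]), ncol = 4))
  rot <- atan2(rs, rc) %% (2 * pi)           # [0, 2pi), 0 = anterior junction
  deg <- rot * 180 / pi
  seg <- rep(NA_integer_, nrow(mesh$elems))
  lv <- mesh$region != "rv"
  ring6 <- function(d) {
    # 2 anteroseptal, 3 inferoseptal, 4 inferior, 5 inferolateral,
    # 6 anterolateral, 1 anterior
    c(2L, 3L, 4L, 5L, 6L, 1L)[pmin(6L, 1L + (d %/% 60))]
  }
  ring4 <- function(d) {
    # 14 septal, 15 inferior, 16 lateral, 13 anterior (origin at the anterior
    # septal junction)
    dd <- (d + 45) %% 360
    c(14L, 15L, 16L, 13L)[pmin(4L, 1L + (dd %/% 90))]
  }
  basal <- lv & ab >= mid_cut
  midr <- lv & ab >= apical_cut & ab < mid_cut
  apical <- lv & ab >= apex_cut & ab < apical_cut
  apexc <- lv & ab < apex_cut
  seg[basal] <- ring6(deg[basal])
  seg[midr] <- ring6(deg[midr]) + 6L
  seg[apical] <- ring4(deg[apical])
  seg[apexc] <- 17L
  structure(seg, class = "aha_segmentation",
            cuts = c(apex = apex_cut, apical = apical_cut, mid = mid_cut))
}

#' Measure LV wall thickness per AHA segment
#'
#' For every endocardial surface node the local wall thickness is the
#' distance to the nearest point of the outer LV surface (epicardium, or the
#' RV-facing septal surface for septal segments). Segment thickness is the
#' area-weighted mean over the segment's endocardial nodes, and the LV
#' average is the area-weighted mean of the segment values, so the identity
#' `lv_average == weighted.mean(per_segment, weights)` holds exactly.
#'
#' @param mesh a `bv_mesh`.
#' @param coords [compute_ventricular_coordinates()].
#' @param segmentation [aha_segmentation()].
#' @return a `wall_thickness_map`: data.frame (segment, thickness_mm,
#'   weight), with attributes `lv_average_mm` and the weight vector; empty
#'   segments carry `NA` thickness.
#' @export
measure_wall_thickness <- function(mesh, coords, segmentation) {
  stopifnot(inherits(mesh, "bv_mesh"))
  lv_sel <- mesh$region != "rv"
  endo_faces <- which(mesh$face_tag == "lv_endo")
  septal <- mesh$region == "septum"
  outer_faces <- which((mesh$face_tag == "epi" & lv_sel[mesh$face_elem]) |
                       (mesh$face_tag == "rv_endo" & septal[mesh$face_elem]))
  if (!length(endo_faces) || !length(outer_faces))
    stop("mesh lacks tagged endocardial/epicardial surfaces")
  endo_nodes <- unique(as.vector(mesh$faces[endo_faces, , drop = FALSE]))
  outer_nodes <- unique(as.vector(mesh$faces[outer_faces, , drop = FALSE]))
  # area weight per endo node: 1/3 of each incident endo face
  fa <- .face_areas(mesh$nodes, mesh$faces[endo_faces, , drop = FALSE])
  w <- numeric(nrow(mesh$nodes))
  for (q in 1:3) {
    acc <- tapply(fa / 3, mesh$faces[endo_faces, q], sum)
    idx <- as.integer(names(acc))
    w[idx] <- w[idx] + as.numeric(acc)
  }
  # nearest outer-surface point per endo node (chunked brute force)
  ep <- mesh$nodes[endo_nodes, , drop = FALSE]
  op <- mesh$nodes[outer_nodes, , drop = FALSE]
  thick <- numeric(nrow(ep))
  chunk <- 512L
  for (s in seq(1, nrow(ep), by = chunk)) {
    e <- min(nrow(ep), s + chunk - 1L)
    d2 <- outer(rowSums(ep[s:e, , drop = FALSE]^2), rep(1, nrow(op))) +
      outer(rep(1, e - s + 1L), rowSums(op^2)) -
      2 * ep[s:e, , drop = FALSE] %*% t(op)
    thick[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  # segment of an endo node: from any incident LV element
  node_seg <- rep(NA_integer_, nrow(mesh$nodes))
  el_lv <- which(lv_sel)
  for (a in 1:4) {
    idx <- mesh$elems[el_lv, a]
    fill <- is.na(node_seg[idx])
    node_seg[idx[fill]] <- unclass(segmentation)[el_lv][fill]
  }
  seg_of <- node_seg[endo_nodes]
  wts <- w[endo_nodes]
  res <- data.frame(segment = 1:17, thickness_mm = NA_real_, weight = 0)
  for (s in 1:17) {
    sel <- !is.na(seg_of) & seg_of == s
    if (any(sel)) {
      res$thickness_mm[s] <- sum(thick[sel] * wts[sel]) / sum(wts[sel])
      res$weight[s] <- sum(wts[sel])
    }
  }
  ok <- !is.na(res$thickness_mm)
  lv_avg <- sum(res$thickness_mm[ok] * res$weight[ok]) / sum(res$weight[ok])
  structure(res, class = c("wall_thickness_map", "data.frame"),
            lv_average_mm = lv_avg)
}

.face_areas <- function(nodes, faces) {
  a <- nodes[faces[, 2], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  b <- nodes[faces[, 3], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  cx <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * sqrt(rowSums(cx^2))
}

#' @export
print.wall_thickness_map <- function(x, ...) {
  cat("LV wall thickness per AHA segment (mm):\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  cat(sprintf("LV average: %.2f mm\n", attr(x, "lv_average_mm")))
  invisible(x)
}
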