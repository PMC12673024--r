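#' Place stimulation landmarks on a biventricular mesh
#'
#' Defines the five early activation sites (EAS) whose simultaneous pacing
#' mimics a physiological pattern of ventricular depolarization, the RV
#' apical pacing site, and the pair of conduction-velocity probes on the RV
#' septal endocardium placed approximately 2 cm apart along the apicobasal
#' axis.
#'
#' Default EAS (all endocardial, onset 0 ms): two LV septal sites (mid and
#' basal), an LV anterior paraseptal site, an LV inferior free-wall site, and
#' an RV septal site. Positions are specified in ventricular coordinates and
#' are configurable through `eas_spec`, a data.frame with columns `name`,
#' `surface` (`"lv_endo"` or `"rv_septal"`), `apicobasal`, `rotational_deg`
#' and `onset_ms`; exactly five sites are required. If a requested position
#' is not spanned by the mesh the nearest surface node is used and a warning
#' is issued.
#'
#' @param mesh a `bv_mesh`.
#' @param coords [compute_ventricular_coordinates()].
#' @param eas_spec optional EAS table; `NULL` for the defaults.
#' @param probe_sep_mm target geodesic separation of the CV probes (mm).
#' @param site_radius_mm stimulus site radius: surface nodes within this
#'   distance of the landmark node join the stimulated node set.
#' @return a `landmark_set`: list with `eas` (list of node sets + onsets),
#'   `rv_apex` (node set), `cv_probes` (two node indices with geodesic
#'   separation in mm).
#' @export
place_landmarks <- function(mesh, coords, eas_spec = NULL,
                            probe_sep_mm = 20, site_radius_mm = 2.5) {
  stopifnot(inherits(mesh, "bv_mesh"),
            inherits(coords, "ventricular_coordinates"))
  if (is.null(eas_spec)) eas_spec <- default_eas_spec()
  need <- c("name", "surface", "apicobasal", "rotational_deg", "onset_ms")
  if (!all(need %in% names(eas_spec)))
    stop("eas_spec must have columns: ", paste(need, collapse = ", "))
  if (nrow(eas_spec) != 5L)
    stop(sprintf("exactly 5 early activation sites are required, got %d",
                 nrow(eas_spec)))

  septal <- mesh$region == "septum"
  rv_wall <- mesh$region == "rv"
  surf_nodes <- function(kind) {
    sel <- switch(kind,
      lv_endo = mesh$face_tag == "lv_endo",
      rv_septal = mesh$face_tag == "rv_endo" & septal[mesh$face_elem],
      rv_endo = mesh$face_tag == "rv_endo" & rv_wall[mesh$face_elem],
      stop("unknown surface kind: ", kind))
    unique(as.vector(mesh$faces[sel, , drop = FALSE]))
  }
  pick_site <- function(kind, ab, rot_deg) {
    cand <- surf_nodes(kind)
    rot <- rot_deg * pi / 180
    drot <- atan2(sin(coords$rotational[cand] - rot),
                  cos(coords$rotational[cand] - rot))
    # distances in normalized coordinate space; rotation scaled to be
    # commensurate with apicobasal extent
    d2 <- (coords$apicobasal[cand] - ab)^2 + (drot / pi)^2
    best <- cand[which.min(d2)]
    if (min(d2) > 0.15^2)
      warning(sprintf("requested site (ab=%.2f, rot=%.0f deg) outside mesh support; using nearest surface node",
                      ab, rot_deg))
    ball <- cand[sqrt(rowSums(sweep(mesh$nodes[cand, , drop = FALSE], 2,
                                    mesh$nodes[best, ])^2)) <= site_radius_mm]
    list(center = best, nodes = sort(unique(c(best, ball))))
  }

  eas <- vector("list", nrow(eas_spec))
  for (i in seq_len(nrow(eas_spec))) {
    s <- pick_site(eas_spec$surface[i], eas_spec$apicobasal[i],
                   eas_spec$rotational_deg[i])
    eas[[i]] <- list(name = eas_spec$name[i], center = s$center,
                     nodes = s$nodes, onset_ms = eas_spec$onset_ms[i])
  }

  # RV apical pacing site: RV free-wall endocardium at minimal apicobasal,
  # restricted to the middle of the cavity sector (away from the insertion
  # lines) so the paced wave enters the septum at its apical end
  rv_endo <- surf_nodes("rv_endo")
  rot_mid_rv <- stats::median(coords$rotational[rv_endo])
  drot_rv <- atan2(sin(coords$rotational[rv_endo] - rot_mid_rv),
                   cos(coords$rotational[rv_endo] - rot_mid_rv))
  mid_band <- abs(drot_rv) < pi / 6
  if (!any(mid_band)) mid_band <- rep(TRUE, length(rv_endo))
  ab_rv <- ifelse(mid_band, coords$apicobasal[rv_endo], Inf)
  apex_center <- rv_endo[which.min(ab_rv)]
  if (coords$apicobasal[apex_center] > 0.35)
    warning("RV apical site sits unusually high on the apicobasal axis")
  ball <- rv_endo[sqrt(rowSums(sweep(mesh$nodes[rv_endo, , drop = FALSE], 2,
                                     mesh$nodes[apex_center, ])^2)) <= site_radius_mm]
  rv_apex <- list(center = apex_center, nodes = sort(unique(c(apex_center, ball))))

  # CV probes on the RV-facing septal endocardium, ~probe_sep_mm apart along
  # the apicobasal axis (geodesic along the septal surface)
  sept_nodes <- surf_nodes("rv_septal")
  sept_faces <- mesh$faces[mesh$face_tag == "rv_endo" & septal[mesh$face_elem], ,
                           drop = FALSE]
  rot_mid <- median(coords$rotational[sept_nodes])
  drot <- atan2(sin(coords$rotational[sept_nodes] - rot_mid),
                cos(coords$rotational[sept_nodes] - rot_mid))
  pa <- sept_nodes[which.min((coords$apicobasal[sept_nodes] - 0.30)^2 +
                             (drot / pi)^2)]
  gd <- .surface_geodesics(mesh$nodes, sept_faces, pa)
  ab_s <- coords$apicobasal[sept_nodes]
  upward <- ab_s > coords$apicobasal[pa]
  score <- abs(gd[sept_nodes] - probe_sep_mm) + 10 * abs(drot) + 1e3 * !upward
  pb <- sept_nodes[which.min(score)]
  sep <- gd[pb]
  if (!is.finite(sep) || abs(sep - probe_sep_mm) > 0.15 * probe_sep_mm)
    warning(sprintf("CV probe separation %.1f mm deviates from the %.0f mm target",
                    sep, probe_sep_mm))

  structure(list(eas = eas, rv_apex = rv_apex,
                 cv_probes = list(a = pa, b = pb, separation_mm = sep)),
            class = "landmark_set")
}

#' Default early-activation-site table
#' @return data.frame accepted by [place_landmarks()].
#' @export
default_eas_spec <- function() {
  data.frame(
    name = c("lv_septal_mid", "lv_septal_basal", "lv_anterior_paraseptal",
             "lv_inferior_freewall", "rv_anterior_freewall"),
    surface = c("lv_endo", "lv_endo", "lv_endo", "lv_endo", "rv_endo"),
    apicobasal = c(0.45, 0.70, 0.50, 0.40, 0.45),
    rotational_deg = c(70, 70, -25, 200, 70),
    onset_ms = c(0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
}

# geodesic distances (mm) from a source node along a triangulated surface
.surface_geodesics <- function(nodes, faces, from) {
  ed <- rbind(faces[, c(1, 2)], faces[, c(1, 3)], faces[, c(2, 3)])
  ed <- unique(cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2])))
  len <- sqrt(rowSums((nodes[ed[, 1], , drop = FALSE] -
                       nodes[ed[, 2], , drop = FALSE])^2))
  vids <- sort(unique(as.vector(ed)))
  remap <- integer(nrow(nodes)); remap[vids] <- seq_along(vids)
  g <- igraph::graph_from_edgelist(cbind(remap[ed[, 1]], remap[ed[, 2]]),
                                   directed = FALSE)
  igraph::E(g)$weight <- len
  if (!(from %in% vids)) stop("geodesic source not on the surface")
  d <- igraph::distances(g, v = remap[from])[1, ]
  out <- rep(NA_real_, nrow(nodes))
  out[vids] <- d
  out
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Landmarks:\n  EAS:\n")
  for (s in x$eas)
    cat(sprintf("    %-24s node %d (%d stimulated), onset %.1f ms\n",
                s$name, s$center, length(s$nodes), s$onset_ms))
  cat(sprintf("  RV apex: node %d (%d stimulated)\n",
              x$rv_apex$center, length(x$rv_apex$nodes)))
  cat(sprintf("  CV probes: %d -> %d, separation %.1f mm\n",
              x$cv_probes$a, x$cv_probes$b, x$cv_probes$separation_mm))
  invisible(x)
}
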