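test_that("idealized biventricle satisfies its structural invariants", {
  mesh <- test_mesh()
  d <- check_mesh(mesh)   # errors on inverted tets / disconnection / bad fibers
  expect_identical(d$components, 1)
  el <- mesh$params$edge_length
  expect_gte(d$edge_range_mm[1], 0.5 * el)
  expect_lte(d$edge_range_mm[2], 2 * el)
  expect_setequal(unique(mesh$face_tag), c("lv_endo", "rv_endo", "epi", "base"))
  expect_true(all(c("lv", "rv", "septum") %in% as.character(unique(mesh$region))))
})

test_that("mesh construction is deterministic", {
  m1 <- build_idealized_biventricle(lv_radius = 12, lv_length = 24,
                                    lv_wall = 6, rv_wall = 3, rv_gap = 3,
                                    edge_length = 2.4, seed = 5)
  m2 <- build_idealized_biventricle(lv_radius = 12, lv_length = 24,
                                    lv_wall = 6, rv_wall = 3, rv_gap = 3,
                                    edge_length = 2.4, seed = 5)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elems, m2$elems)
})

test_that("requested uniform wall thickness is recovered by measurement", {
  twin <- test_twin()
  seg <- aha_segmentation(twin$mesh, twin$coords)
  wt <- measure_wall_thickness(twin$mesh, twin$coords, seg)
  # construction used a 7 mm wall; agreement within half an edge length
  expect_lt(abs(attr(wt, "lv_average_mm") - 7), twin$mesh$params$edge_length / 2)
  ok <- !is.na(wt$thickness_mm)
  expect_true(all(wt$thickness_mm[ok] > 0))
  # the LV average is exactly the weight-averaged segment table
  expect_equal(attr(wt, "lv_average_mm"),
               sum(wt$thickness_mm[ok] * wt$weight[ok]) / sum(wt$weight[ok]),
               tolerance = 1e-9)
})

test_that("a basal-thick wall yields thicker basal than apical segments", {
  mesh <- build_idealized_biventricle(
    lv_radius = 15, lv_length = 30,
    lv_wall = function(ab) 8 + 4 * ab,   # 8 mm apex -> 12 mm base
    rv_wall = 3, rv_gap = 4, edge_length = 2.2)
  co <- compute_ventricular_coordinates(mesh)
  seg <- aha_segmentation(mesh, co)
  wt <- measure_wall_thickness(mesh, co, seg)
  basal <- mean(wt$thickness_mm[1:6], na.rm = TRUE)
  apical <- mean(wt$thickness_mm[13:16], na.rm = TRUE)
  expect_gt(basal, apical + 1.5)
})

test_that("wall thickness of a hollow-sphere octant matches the radii difference", {
  # analytically constructed shell: r in [14, 20] -> thickness 6 mm
  r1 <- 14; r2 <- 20; h <- 1.5
  th <- seq(0.35, pi / 2 - 0.35, length.out = 12)
  ph <- seq(0.2, pi / 2 - 0.2, length.out = 12)
  rr <- seq(r1, r2, length.out = 5)
  idx <- function(i, j, k) i + 12L * (j - 1L) + 144L * (k - 1L)
  g <- expand.grid(i = 1:12, j = 1:12, k = 1:5)
  nodes <- cbind(rr[g$k] * sin(th[g$i]) * cos(ph[g$j]),
                 rr[g$k] * sin(th[g$i]) * sin(ph[g$j]),
                 rr[g$k] * cos(th[g$i]))
  cell <- expand.grid(i = 1:11, j = 1:11, k = 1:4)
  hexes <- cbind(idx(cell$i, cell$j, cell$k), idx(cell$i + 1, cell$j, cell$k),
                 idx(cell$i, cell$j + 1, cell$k), idx(cell$i + 1, cell$j + 1, cell$k),
                 idx(cell$i, cell$j, cell$k + 1), idx(cell$i + 1, cell$j, cell$k + 1),
                 idx(cell$i, cell$j + 1, cell$k + 1), idx(cell$i + 1, cell$j + 1, cell$k + 1))
  tets <- do.call(rbind, apply(hexes, 1, function(v) {
    rbind(v[c(1, 2, 3, 5)], v[c(2, 4, 3, 8)], v[c(2, 6, 8, 5)],
          v[c(3, 8, 7, 5)], v[c(2, 8, 3, 5)])
  }, simplify = FALSE))
  vol <- cardiotwin:::tet_geometry(nodes, tets)$volume_mm3
  tets[vol < 0, c(3, 4)] <- tets[vol < 0, c(4, 3)]
  fc <- cardiotwin:::boundary_faces(tets)
  rad <- sqrt(rowSums(nodes^2))
  frad <- matrix(rad[fc$faces], ncol = 3)
  tag <- rep("base", nrow(fc$faces))
  tag[rowSums(abs(frad - r1) < 1e-6) == 3] <- "lv_endo"
  tag[rowSums(abs(frad - r2) < 1e-6) == 3] <- "epi"
  shell <- structure(list(nodes = nodes, elems = tets,
                          region = factor(rep("lv", nrow(tets)),
                                          levels = c("lv", "rv", "septum")),
                          faces = fc$faces, face_tag = tag,
                          face_elem = fc$elem), class = "bv_mesh")
  seg <- structure(rep(1L, nrow(tets)), class = "aha_segmentation")
  wt <- measure_wall_thickness(shell, NULL, seg)
  expect_lt(abs(wt$thickness_mm[1] - (r2 - r1)), 1.0)
  expect_true(all(is.na(wt$thickness_mm[2:17])))
})

test_that("AHA segmentation partitions the LV", {
  twin <- test_twin()
  seg <- aha_segmentation(twin$mesh, twin$coords)
  lv_count <- sum(twin$mesh$region != "rv")
  expect_identical(sum(!is.na(unclass(seg))), lv_count)
  expect_true(all(is.na(unclass(seg)[twin$mesh$region == "rv"])))
  expect_setequal(sort(unique(unclass(seg)[!is.na(unclass(seg))])), 1:17)
})

test_that("infeasible geometry requests fail loudly", {
  expect_error(build_idealized_biventricle(lv_radius = 10, lv_wall = 12,
                                           edge_length = 1.5),
               "infeasible|thicker")
  expect_error(build_idealized_biventricle(lv_wall = 6, edge_length = 4),
               "edge length")
  expect_error(build_idealized_biventricle(lv_wall = -2, edge_length = 1.5),
               "positive")
})
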