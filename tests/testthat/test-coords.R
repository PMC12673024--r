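test_that("transmural coordinate honours its boundary conditions and range", {
  mesh <- test_mesh(); co <- test_coords()
  expect_true(all(co$transmural >= 0 & co$transmural <= 1))
  lv_endo <- unique(as.vector(mesh$faces[mesh$face_tag == "lv_endo", ]))
  epi <- unique(as.vector(mesh$faces[mesh$face_tag == "epi", ]))
  expect_equal(max(abs(co$transmural[lv_endo])), 0, tolerance = 1e-12)
  expect_equal(min(co$transmural[epi]), 1, tolerance = 1e-12)
})

test_that("transmural field increases monotonically along transmural columns", {
  mesh <- test_mesh(); co <- test_coords()
  meta <- mesh$node_meta
  lv <- which(meta$family == "lv")
  # within each construction column the Laplace solution must increase with
  # the layer index
  cols <- split(lv, meta$surf[lv])
  viol <- vapply(cols[1:500], function(ix) {
    t <- co$transmural[ix][order(meta$layer[ix])]
    any(diff(t) < -1e-9)
  }, logical(1))
  expect_false(any(viol))
})

test_that("the harmonic interpolation solves the 1-D Laplace problem on a slab wall", {
  # flat slab: the analytic transmural solution is linear, so the mid-plane
  # must sit at 0.5
  slab <- cardiotwin:::.slab_mesh(10, 10, 4, h_mm = 1)
  K <- cardiotwin:::assemble_stiffness(slab$nodes, slab$elems)
  bottom <- which(slab$nodes[, 3] == 0)
  top <- which(slab$nodes[, 3] == 4)
  u <- cardiotwin:::solve_laplace(K, c(bottom, top),
                                  c(rep(0, length(bottom)),
                                    rep(1, length(top))))
  mid <- which(slab$nodes[, 3] == 2)
  expect_lt(max(abs(u[mid] - 0.5)), 0.05)
  quarter <- which(slab$nodes[, 3] == 1)
  expect_lt(max(abs(u[quarter] - 0.25)), 0.05)
})

test_that("apicobasal coordinate runs 0 at the apex to 1 at the base, monotone along the meridian", {
  mesh <- test_mesh(); co <- test_coords()
  expect_true(all(co$apicobasal >= 0 & co$apicobasal <= 1))
  base_nodes <- unique(as.vector(mesh$faces[mesh$face_tag == "base", ]))
  expect_equal(min(co$apicobasal[base_nodes]), 1, tolerance = 1e-9)
  expect_equal(min(co$apicobasal), 0, tolerance = 1e-9)
  lv <- mesh$node_meta$family == "lv"
  expect_gt(cor(co$apicobasal[lv], mesh$node_meta$theta[lv]), 0.99)
})

test_that("rotational coordinate and ventricle labels are well formed", {
  mesh <- test_mesh(); co <- test_coords()
  expect_true(all(co$rotational >= -pi & co$rotational < pi))
  expect_setequal(unique(co$ventricle), c("lv", "rv"))
  rv_only <- setdiff(unique(as.vector(mesh$elems[mesh$region == "rv", ])),
                     unique(as.vector(mesh$elems[mesh$region != "rv", ])))
  expect_true(all(co$ventricle[rv_only] == "rv"))
})

test_that("coordinates require surface tags", {
  mesh <- test_mesh()
  mesh$face_tag <- NULL
  expect_error(compute_ventricular_coordinates(mesh), "surface tags")
})

test_that("fiber helix angle interpolates linearly from endo to epi", {
  twin <- test_twin()
  mesh <- assign_fibers(twin$mesh, twin$coords, alpha_endo = 60,
                        alpha_epi = -60)
  expect_equal(max(abs(sqrt(rowSums(mesh$fibers^2)) - 1)), 0,
               tolerance = 1e-9)
  helix <- attr(mesh$fibers, "helix_deg")
  tfrac <- rowMeans(matrix(twin$coords$transmural[mesh$elems], ncol = 4))
  fit <- stats::lm(helix ~ tfrac)
  expect_lt(abs(coef(fit)[1] - 60), 2)
  expect_lt(abs(coef(fit)[2] + 120), 2)
  # innermost/outermost elements sit within 2 degrees of the rule ends
  expect_lt(abs(max(helix) - 60), 2 + 120 * min(tfrac))
  expect_lt(abs(min(helix) + 60), 2 + 120 * (1 - max(tfrac)))
})

test_that("zero helix angles give circumferential fibers", {
  twin <- test_twin()
  mesh <- assign_fibers(twin$mesh, twin$coords, alpha_endo = 0, alpha_epi = 0)
  ab_el <- rowMeans(matrix(twin$coords$apicobasal[mesh$elems], ncol = 4))
  sel <- mesh$region != "rv" & ab_el > 0.25 & ab_el < 0.7
  # circumferential = horizontal over the mid-ventricular wall
  expect_lt(stats::quantile(abs(mesh$fibers[sel, 3]), 0.95), 0.08)
  # and in every case orthogonal to the transmural direction by construction
  expect_equal(max(abs(rowSums(mesh$fibers^2) - 1)), 0, tolerance = 1e-9)
})
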