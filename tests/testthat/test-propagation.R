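test_that("strand conduction velocity is physiological and mesh-converged", {
  bl <- ref_baseline()
  cv <- as.numeric(calibrate_cv(tissue_parameters(), bl, "fiber",
                                h_cm = 0.005, adapt_h = FALSE))
  expect_gt(cv, 40); expect_lt(cv, 90)
  cv_half <- as.numeric(calibrate_cv(tissue_parameters(), bl, "fiber",
                                     h_cm = 0.0025, adapt_h = FALSE))
  expect_lt(abs(cv - cv_half) / cv_half, 0.02)
})

test_that("an uncoupled strand activates only at the stimulus", {
  sm <- strand_mesh(length_cm = 1, h_cm = 0.01)
  expect_warning(
    map <- run_monodomain(sm, 0, protocol = stimulus_protocol(n_beats = 1)),
    "no capture")
  act <- which(!is.na(map))
  expect_true(all(act <= round(0.1 / 0.01)))   # within the stimulated 1 mm
  expect_gt(sum(is.na(map)), 0.8 * sm$n)
})

test_that("calibration caches and repeats deterministically", {
  p <- tissue_parameters(12.3, 0.27, 0.05, strict = FALSE)
  a <- calibrate_cv(p, ref_baseline(), "fiber")
  b <- calibrate_cv(p, ref_baseline(), "fiber")
  expect_identical(as.numeric(a), as.numeric(b))
  expect_gt(as.numeric(calibrate_cv(p, ref_baseline(), "fiber")),
            as.numeric(calibrate_cv(p, ref_baseline(), "transverse")))
})

test_that("eikonal arrival on a uniform cube equals Euclidean distance over speed", {
  m <- cube_mesh(15, 1.4)   # ~20 mm cube
  v <- 55  # cm/s
  map <- run_eikonal(m, list(fiber = v, transverse = v), sites = 1L,
                     method = "factored")
  d <- sqrt(rowSums(m$nodes^2))
  exact <- d / (v / 100)
  sel <- d > 0.25 * max(d)
  expect_lt(max(abs(map[sel] - exact[sel]) / exact[sel]), 0.02)
})

test_that("multi-source first arrival is the pointwise minimum of single-source maps", {
  m <- cube_mesh(11, 1.5)
  cv <- list(fiber = 60, transverse = 25)
  n <- nrow(m$nodes)
  s1 <- 1L; s2 <- as.integer(n)
  m1 <- run_eikonal(m, cv, sites = s1)
  m2 <- run_eikonal(m, cv, sites = s2)
  m12 <- run_eikonal(m, cv, sites = c(s1, s2))
  lower <- pmin(as.numeric(m1), as.numeric(m2))
  # the default solver never exceeds the single-source envelope, and only
  # undershoots it by the first-order seam error where the two fronts collide
  expect_true(all(as.numeric(m12) <= lower + 1e-6))
  expect_lt(max((lower - as.numeric(m12)) / pmax(lower, 1)), 0.05)
  expect_lt(mean((lower - as.numeric(m12)) / pmax(lower, 1)), 0.005)
  # factored route is exactly the minimum by construction
  f1 <- run_eikonal(m, cv, sites = s1, method = "factored")
  f2 <- run_eikonal(m, cv, sites = s2, method = "factored")
  f12 <- run_eikonal(m, cv, sites = c(s1, s2), method = "factored")
  expect_equal(as.numeric(f12), pmin(as.numeric(f1), as.numeric(f2)),
               tolerance = 1e-12)
})

test_that("total activation time follows its definition and is shift invariant", {
  map <- structure(c(0, 12, 44, 88), onsets_ms = 0, class = "activation_map")
  expect_equal(total_activation_time(map), 88)
  shifted <- structure(c(10, 22, 54, 98), onsets_ms = 10,
                       class = "activation_map")
  expect_equal(total_activation_time(shifted), 88)
  holey <- structure(c(0, NA, NA, 44), onsets_ms = 0, class = "activation_map")
  expect_error(total_activation_time(holey), "activated")
})

test_that("CV measurement arithmetic, orientation handling, and self-consistency", {
  fake_lm <- structure(list(cv_probes = list(a = 1L, b = 2L,
                                             separation_mm = 20)),
                       class = "landmark_set")
  map <- structure(c(5, 35), onsets_ms = 0, class = "activation_map")
  cv <- measure_cv(map, fake_lm)
  expect_equal(cv$cv_cm_s, 2 / 0.030, tolerance = 1e-12)  # 66.67 cm/s
  expect_true(cv$valid)
  # swapped probes: same magnitude, flagged invalid
  swapped <- structure(list(cv_probes = list(a = 2L, b = 1L,
                                             separation_mm = 20)),
                       class = "landmark_set")
  expect_warning(cv2 <- measure_cv(map, swapped), "wrong side")
  expect_false(cv2$valid)
  expect_equal(cv2$cv_cm_s, cv$cv_cm_s)
  # uniform-speed medium: measured CV equals the imposed speed (probes on the
  # straight characteristic from the source)
  m <- cube_mesh(11, 1.5)
  v <- 60
  map3 <- run_eikonal(m, list(fiber = v, transverse = v), sites = 1L,
                      method = "factored")
  along <- which(m$nodes[, 2] == 0 & m$nodes[, 3] == 0)
  pa <- along[4]; pb <- along[11]
  lm3 <- structure(list(cv_probes = list(
    a = pa, b = pb,
    separation_mm = m$nodes[pb, 1] - m$nodes[pa, 1])), class = "landmark_set")
  cv3 <- measure_cv(map3, lm3)
  expect_lt(abs(cv3$cv_cm_s - v) / v, 0.03)
})

test_that("monodomain rejects meshes too coarse for full-ionic accuracy", {
  m <- cube_mesh(8, 2.5)
  cond <- effective_conductivity(tissue_parameters(), ref_baseline())
  expect_error(run_monodomain(m, cond, sites = 1L), "too coarse")
})
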