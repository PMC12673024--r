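test_that("default landmarks: five simultaneous EAS, RV apex, calibrated probe pair", {
  lm <- test_twin()$landmarks
  expect_length(lm$eas, 5)
  expect_true(all(vapply(lm$eas, function(s) s$onset_ms, numeric(1)) == 0))
  expect_true(all(vapply(lm$eas, function(s) length(s$nodes) >= 1, logical(1))))
  expect_gte(lm$cv_probes$separation_mm, 18)
  expect_lte(lm$cv_probes$separation_mm, 22)
  co <- test_coords()
  expect_lt(co$apicobasal[lm$rv_apex$center], 0.35)
  # both probes on the RV-facing septal surface
  mesh <- test_mesh()
  septal_faces <- mesh$face_tag == "rv_endo" &
    (mesh$region == "septum")[mesh$face_elem]
  sept_nodes <- unique(as.vector(mesh$faces[septal_faces, ]))
  expect_true(all(c(lm$cv_probes$a, lm$cv_probes$b) %in% sept_nodes))
  # probe B is basal to probe A (apicobasal ordering for apical pacing)
  expect_gt(co$apicobasal[lm$cv_probes$b], co$apicobasal[lm$cv_probes$a])
})

test_that("an EAS table without exactly five sites is rejected", {
  spec4 <- default_eas_spec()[1:4, ]
  expect_error(place_landmarks(test_mesh(), test_coords(), eas_spec = spec4),
               "exactly 5")
  expect_error(place_landmarks(test_mesh(), test_coords(),
                               eas_spec = data.frame(name = "x")),
               "columns")
})

test_that("out-of-support site requests fall back to the nearest node with a warning", {
  spec <- default_eas_spec()
  # the RV-facing septal surface does not extend to the apex, nor to the
  # far free wall rotationally
  spec$surface[1] <- "rv_septal"
  spec$apicobasal[1] <- 0.02
  spec$rotational_deg[1] <- -90
  expect_warning(place_landmarks(test_mesh(), test_coords(), eas_spec = spec),
                 "nearest")
})
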