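test_that("relative radius change follows the myocyte-volume conservation rule", {
  expect_equal(relative_radius_change(11, 11, 0.25, 0.25), 1)
  # thinner wall and higher ECV after surgery both shrink the implied radius
  expect_lt(relative_radius_change(11.6, 11.6, 0.242, 0.280), 1)
  expect_lt(relative_radius_change(11.6, 9.5, 0.242, 0.242), 1)
  # cohort-median inputs, value frozen from a hand evaluation of the formula
  expect_equal(relative_radius_change(11.6, 9.5, 0.242, 0.280), 0.88199,
               tolerance = 1e-4)
  expect_error(relative_radius_change(-1, 9, 0.2, 0.2), "positive")
  expect_error(relative_radius_change(10, 9, 0.2, 1.2), "ECV")
})

test_that("ECF fitting recovers a grid-valued truth and is locally optimal", {
  twin <- test_twin()
  ecv <- 0.27
  truth_ecf <- 0.10
  target <- as.numeric(model_qrs(twin, tissue_parameters(13, ecv, truth_ecf,
                                                         strict = FALSE)))
  fit <- fit_ecf(twin, 13, target, ecv)
  expect_equal(fit$ecf, truth_ecf)
  expect_false(fit$skipped)
  # local optimality against the neighbouring grid values
  for (nb in c(truth_ecf - 0.05, truth_ecf + 0.05)) {
    q <- as.numeric(model_qrs(twin, tissue_parameters(13, ecv, nb,
                                                      strict = FALSE)))
    expect_lte(abs(fit$qrs_ms - target), abs(q - target) + 1e-9)
  }
  # a target already exceeded at ECF = 0 skips the stage by contract
  q0 <- as.numeric(model_qrs(twin, tissue_parameters(13, ecv, 0,
                                                     strict = FALSE)))
  f2 <- fit_ecf(twin, 13, q0 - 5, ecv)
  expect_true(f2$skipped)
  expect_equal(f2$ecf, 0)
  expect_gt(f2$error_ms, 0)
})

test_that("radius fitting: symmetric pair equals single-model logic; infeasible targets flag the bound", {
  twin <- test_twin()
  ecv <- 0.26
  target <- as.numeric(model_qrs(twin, tissue_parameters(14, ecv, 0,
                                                         strict = FALSE)))
  fr <- fit_radius(twin, twin, target, target, rho = 1, ecv, ecv)
  expect_equal(fr$r_post_um, fr$r_pre_um)
  expect_lte(fr$r_pre_um, 14 + fit_settings()$r_tol_um)
  expect_gte(fr$r_pre_um, 14 - 1e-9)
  # unreachably short target QRS -> upper bound, flagged
  q_fastest <- as.numeric(model_qrs(twin, tissue_parameters(17.8, ecv, 0,
                                                            strict = FALSE)))
  fr2 <- fit_radius(twin, twin, q_fastest - 5, q_fastest - 5, 1, ecv, ecv)
  expect_true(fr2$at_upper)
  expect_equal(fr2$r_pre_um, 17.8)
})

test_that("noise-free personalization inverts the forward model exactly on the grids", {
  coh <- recovery_cohort(n = 2, seed = 11)
  for (i in 1:2) {
    res <- personalize_patient(coh, i)
    expect_lt(abs(res$r_pre_um - coh$truth$r_pre_um[i]),
              fit_settings()$r_tol_um + 1e-9)
    expect_equal(res$ecf_pre, coh$truth$ecf_pre[i])
    expect_equal(res$ecf_post, coh$truth$ecf_post[i])
    # the ratio constraint holds to machine precision
    expect_equal(res$r_post_um, res$rho * res$r_pre_um, tolerance = 1e-15)
    expect_true(res$cv_pre_cm_s > 30 && res$cv_pre_cm_s < 110)
  }
})

test_that("re-running the forward model at the fitted parameters reproduces the stored QRS", {
  coh <- recovery_cohort(n = 2, seed = 11)
  res <- personalize_patient(coh, 1)
  rec <- coh$records
  pre <- as.list(rec[rec$patient_id == 1 & rec$timepoint == "pre", ])
  q <- as.numeric(model_qrs(coh$models[["p1_pre"]],
                            tissue_parameters(res$r_pre_um, pre$ecv,
                                              res$ecf_pre, strict = FALSE)))
  expect_identical(q, res$qrs_model_pre_ms)
})

test_that("the QRS inclusion criterion is enforced on patient records", {
  coh <- recovery_cohort(n = 2, seed = 11)
  rec <- coh$records
  bad <- as.list(rec[rec$patient_id == 1 & rec$timepoint == "pre", ])
  bad$qrs_ms <- 120
  expect_error(
    personalize_pair(bad,
                     as.list(rec[rec$patient_id == 1 & rec$timepoint == "post", ]),
                     coh$models[["p1_pre"]], coh$models[["p1_post"]]),
    "inclusion criterion")
})

test_that("model QRS is strictly decreasing in R and increasing in ECF", {
  twin <- test_twin()
  ecv <- 0.258
  qs <- vapply(c(10, 12, 14, 16, 17.8), function(r)
    as.numeric(model_qrs(twin, tissue_parameters(r, ecv, 0, strict = FALSE))),
    numeric(1))
  expect_true(all(diff(qs) < 0))
  qe <- vapply(c(0, 0.15, 0.3, 0.45), function(e)
    as.numeric(model_qrs(twin, tissue_parameters(14, ecv, e, strict = FALSE))),
    numeric(1))
  expect_true(all(diff(qe) > 0))
})
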