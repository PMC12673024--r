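test_that("cohort generation is deterministic for fixed spec and seed", {
  a <- generate_cohort(cohort_spec(n = 8), seed = 3, build_models = FALSE)
  b <- generate_cohort(cohort_spec(n = 8), seed = 3, build_models = FALSE)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cohort_spec(n = 8), seed = 4, build_models = FALSE)
  expect_false(identical(a$records$ecv, c$records$ecv))
})

test_that("generated cohorts show the paired remodeling structure", {
  coh <- generate_cohort(cohort_spec(n = 200), seed = 9, build_models = FALSE)
  rec <- coh$records
  pre <- rec[rec$timepoint == "pre", ]; post <- rec[rec$timepoint == "post", ]
  expect_gte(mean(post$ecv > pre$ecv), 0.9)        # ECV rises after surgery
  expect_true(all(post$wt_mm <= pre$wt_mm + 1e-12)) # walls shrink
  red <- 1 - post$wt_mm / pre$wt_mm
  expect_gt(mean(red[pre$sex == "female"]), mean(red[pre$sex == "male"]))
  expect_true(all(coh$truth$rho > 0 & coh$truth$rho <= 1.05))
  rb <- r_bounds_um()
  expect_true(all(coh$truth$r_pre_um >= rb[1] & coh$truth$r_pre_um <= rb[2]))
  expect_true(all(coh$truth$r_post_um >= rb[1] & coh$truth$r_post_um <= rb[2]))
  expect_true(all(abs(coh$truth$ecf_pre / 0.05 -
                      round(coh$truth$ecf_pre / 0.05)) < 1e-9))
  # the binding timepoint carries no fibrosis (canonical identifiable form)
  expect_true(all(ifelse(coh$truth$binding == "pre", coh$truth$ecf_pre,
                         coh$truth$ecf_post) == 0))
})

test_that("ground-truth radius ratio closes the loop with the inverse method's formula", {
  coh <- generate_cohort(cohort_spec(n = 30), seed = 5, build_models = FALSE)
  rec <- coh$records
  pre <- rec[rec$timepoint == "pre", ]; post <- rec[rec$timepoint == "post", ]
  rho <- mapply(relative_radius_change, pre$wt_mm, post$wt_mm, pre$ecv,
                post$ecv)
  expect_equal(unname(rho), coh$truth$rho, tolerance = 1e-12)
  expect_equal(coh$truth$r_post_um, coh$truth$rho * coh$truth$r_pre_um,
               tolerance = 1e-15)
})

test_that("derived volumes obey their defining identities", {
  dv <- derived_volumes(100, 0.25, 2)
  expect_equal(dv$matrix_ml_m2, 12.5)
  expect_equal(dv$cell_ml_m2, 37.5)
  expect_equal(dv$mass_g_m2, 52.5)
  set.seed(1)
  v <- runif(50, 50, 250); e <- runif(50, 0.1, 0.5); b <- runif(50, 1.4, 2.3)
  dv <- derived_volumes(v, e, b)
  expect_equal(dv$matrix_ml + dv$cell_ml, v, tolerance = 1e-12)
  expect_equal(dv$mass_g, 1.05 * v, tolerance = 1e-12)
  expect_equal(derived_volumes(100, 1e-9, 2)$matrix_ml, 1e-7, tolerance = 1e-12)
  expect_error(derived_volumes(-1, 0.2, 2))
})

test_that("median/IQR summaries use linear order-statistic interpolation", {
  s <- summarize_iqr(c(1, 2, 3, 4, 5))
  expect_equal(unname(s[c("median", "q25", "q75")]), c(3, 2, 4))
  set.seed(2)
  x <- rnorm(37)
  s2 <- summarize_iqr(x)
  # independent brute-force oracle: type-7 quantile by direct interpolation
  xs <- sort(x)
  q_oracle <- function(p) {
    hh <- (length(xs) - 1) * p
    lo <- floor(hh)
    xs[lo + 1] + (hh - lo) * (xs[min(lo + 2, length(xs))] - xs[lo + 1])
  }
  expect_equal(unname(s2["q25"]), q_oracle(0.25), tolerance = 1e-12)
  expect_equal(unname(s2["q75"]), q_oracle(0.75), tolerance = 1e-12)
  expect_equal(unname(s2["median"]), q_oracle(0.5), tolerance = 1e-12)
})

test_that("bull's-eye difference panel is exactly post minus pre, NAs propagate", {
  mk <- function(th) structure(
    data.frame(segment = 1:17, thickness_mm = th, weight = 1),
    class = c("wall_thickness_map", "data.frame"), lv_average_mm = mean(th, na.rm = TRUE))
  pre <- mk(c(rep(11, 16), NA))
  post <- mk(c(rep(9, 16), NA))
  be <- bulls_eye(pre, post)
  expect_equal(be$diff_mm[1:16], rep(-2, 16))
  expect_true(is.na(be$diff_mm[17]))
  expect_identical(nrow(be), 17L)
})
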