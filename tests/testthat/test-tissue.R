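test_that("reference tissue state reproduces the baseline conductivities exactly", {
  bl <- ref_baseline()
  cond <- effective_conductivity(tissue_parameters(), bl)
  harmonic <- bl$sigma_i * bl$sigma_e / (bl$sigma_i + bl$sigma_e)
  expect_equal(unname(cond$sigma_mono_S_m), unname(harmonic), tolerance = 1e-12)
  expect_equal(cond$beta_per_cm, 2 / (15.45e-4), tolerance = 1e-12)
  # D = sigma / (beta * Cm), computed independently in plain units
  d_indep <- (harmonic / 100) / (cond$beta_per_cm * 1e-6) / 1000
  expect_equal(unname(cond$diffusivity_cm2_ms), unname(d_indep),
               tolerance = 1e-12)
  expect_true(cond$propagating)
})

test_that("a fully fibrotic extracellular space (ECF = 1) yields zero conductivity, not an error", {
  cond <- effective_conductivity(tissue_parameters(ecf = 1), ref_baseline())
  expect_equal(unname(cond$sigma_mono_S_m), c(0, 0, 0))
  expect_equal(unname(cond$diffusivity_cm2_ms), c(0, 0, 0))
  expect_false(cond$propagating)
})

test_that("cell radius enters only through the surface-to-volume ratio: doubling R doubles D", {
  bl <- ref_baseline()
  c1 <- effective_conductivity(tissue_parameters(8, 0.3, 0.1, strict = FALSE), bl)
  c2 <- effective_conductivity(tissue_parameters(16, 0.3, 0.1, strict = FALSE), bl)
  expect_equal(unname(c2$diffusivity_cm2_ms),
               unname(2 * c1$diffusivity_cm2_ms), tolerance = 1e-12)
  expect_equal(unname(c2$sigma_mono_S_m), unname(c1$sigma_mono_S_m),
               tolerance = 1e-12)
})

test_that("monodomain conductivity is bounded by both spaces and scales as stated in ECV/ECF", {
  bl <- ref_baseline()
  for (ecv in c(0.18, 0.258, 0.34)) for (ecf in c(0, 0.25, 0.6)) {
    cond <- effective_conductivity(
      tissue_parameters(13, ecv, ecf, strict = FALSE), bl)
    sig_e <- bl$sigma_e * (ecv / bl$ecv_ref) * (1 - ecf)
    expect_true(all(cond$sigma_mono_S_m <= pmin(bl$sigma_i, sig_e) + 1e-12))
    expect_equal(unname(cond$sigma_e_eff_S_m), unname(sig_e), tolerance = 1e-12)
  }
})

test_that("tissue parameter validation rejects nonsense and warns outside the histological range", {
  expect_error(tissue_parameters(ecv = 1.2))
  expect_error(tissue_parameters(ecf = -0.1))
  expect_error(tissue_parameters(r_um = -3))
  expect_warning(tissue_parameters(r_um = 25), "outside the personalization range")
  expect_silent(tissue_parameters(r_um = 25, strict = FALSE))
})

test_that("baseline parameter file round-trips and is validated", {
  bl <- ref_baseline()
  expect_equal(bl$r_ref_um, 15.45)
  expect_equal(bl$ecv_ref, 0.258)
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(sigma_i = list(fiber = 1)), bad)
  expect_error(baseline_conductivities(bad), "missing fields")
})
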