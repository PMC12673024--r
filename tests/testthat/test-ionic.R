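test_that("the resting membrane stays put without stimulation", {
  run <- cardiotwin:::ttp06_cell_run_cpp(myocyte_state(), 1000, 0.02,
                                         numeric(0), 1, 0, 1, 0L)
  expect_lt(max(abs(run$vm - run$vm[1])), 1)
  expect_gt(run$vm[1], -90); expect_lt(run$vm[1], -80)
})

test_that("a suprathreshold stimulus elicits an action potential, a weak one does not", {
  sup <- run_single_cell(n_beats = 1, quiescent_ms = 200, stim_amp_pApF = 40)
  expect_true(sup$captured)
  expect_gt(sup$peak_mV, 20)
  expect_warning(
    sub <- run_single_cell(n_beats = 1, quiescent_ms = 200,
                           stim_amp_pApF = 4),
    "non-capture")
  expect_false(sub$captured)
})

test_that("paced single cell reaches steady state with a plausible epicardial APD90", {
  run <- run_single_cell(pacing_cl_ms = 600, n_beats = 6)
  expect_true(run$steady)
  expect_gt(tail(run$apd90_ms, 1), 250)
  expect_lt(tail(run$apd90_ms, 1), 350)
  expect_gt(run$resting_mV, -90); expect_lt(run$resting_mV, -80)
  # determinism
  run2 <- run_single_cell(pacing_cl_ms = 600, n_beats = 6)
  expect_identical(run$vm, run2$vm)
})

test_that("halving the time step changes APD90 by less than 1%", {
  a <- run_single_cell(n_beats = 2, dt = 0.02, quiescent_ms = 200)
  b <- run_single_cell(n_beats = 2, dt = 0.01, quiescent_ms = 200)
  expect_lt(abs(tail(a$apd90_ms, 1) - tail(b$apd90_ms, 1)) /
              tail(b$apd90_ms, 1), 0.01)
})

test_that("gating variables remain in [0,1] through aggressive pacing", {
  s <- myocyte_state()
  for (k in 1:4000) {
    stim <- if (k %% 1000 < 100) 45 else 0
    s <- step_membrane(s, stim, 0.02)
  }
  gates <- s[7:19]
  expect_true(all(gates >= 0 & gates <= 1))
  expect_true(all(s[c("Nai", "Ki", "Cai", "CaSS", "CaSR")] > 0))
})

test_that("cell variants use their published repolarization differences", {
  epi <- run_single_cell("epicardial", n_beats = 2, quiescent_ms = 200)
  mid <- run_single_cell("mid", n_beats = 2, quiescent_ms = 200)
  endo <- run_single_cell("endocardial", n_beats = 2, quiescent_ms = 200)
  # mid-myocardial cells (low IKs) have the longest APD
  expect_gt(tail(mid$apd90_ms, 1), tail(epi$apd90_ms, 1))
  expect_gt(tail(mid$apd90_ms, 1), tail(endo$apd90_ms, 1))
})

test_that("membrane stepping validates its inputs", {
  expect_error(step_membrane(myocyte_state(), 0, dt = 0))
  expect_warning(step_membrane(myocyte_state(), 0, dt = 0.1), "full-accuracy")
  bad <- myocyte_state(); bad[1] <- NaN
  expect_error(step_membrane(bad, 0, 0.02), "non-finite")
})
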