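test_that("preparation modules transform Mz as specified", {
  sq <- default_seq()
  ts <- tissue_params(0.7, 0.040)
  expect_equal(apply_prep(0.8, "IR", ts, sq), -0.8)
  expect_equal(apply_prep(1.0, "T1RHO", ts, sq), exp(-1), tolerance = 1e-12)
  expect_equal(apply_prep(0.37, "NONE", ts, sq), 0.37)
  sq2 <- sequence_params(inversion_efficiency = 0.9)
  expect_equal(apply_prep(1, "IR", ts, sq2), -0.9)
  expect_error(apply_prep(1, "SAT", ts, sq), "unknown preparation")
})

test_that("spoiled pulse train matches closed forms and a scalar recursion", {
  ts <- tissue_params(t1 = 0.7, t1rho = 0.056, m0 = 1)
  ## 90 degree pulse nulls Mz, then one TR of relaxation from zero
  r <- rf_spoiled_train(0.5, fa = 90, tr = 0.01, n = 1, ts)
  expect_equal(r$mz_final, 1 - exp(-0.01 / 0.7), tolerance = 1e-12)
  expect_equal(r$mz_at_pulses, 0.5)
  ## zero flip angle: pure relaxation over n TRs
  r0 <- rf_spoiled_train(-0.3, fa = 0, tr = 0.009, n = 7, ts)
  expect_equal(r0$mz_final, 1 + (-0.3 - 1) * exp(-7 * 0.009 / 0.7),
               tolerance = 1e-12)
  ## independent step-by-step recursion at the imaging settings
  mz <- 0.42
  for (i in 1:16) mz <- 1 + (mz * cos(8 * pi / 180) - 1) * exp(-0.00971 / 0.7)
  r16 <- rf_spoiled_train(0.42, fa = 8, tr = 0.00971, n = 16, ts)
  expect_equal(r16$mz_final, mz, tolerance = 1e-12)
  expect_length(r16$mz_at_pulses, 16)
  expect_error(rf_spoiled_train(1, 8, -0.01, 4, ts), "negative TR")
})

test_that("signal evolution degenerates correctly at limit parameters", {
  tm <- hr60()
  sq0 <- sequence_params(fa_imaging = 0)
  expect_equal(simulate_signals(sq0, tm, tissue_params(0.7, 0.056))$signals,
               rep(0, 4))
  ## zero spin-lock makes the T1rho prep the identity; volumes 2..4 then
  ## share the same prep, and with T1 << RR (full inter-beat recovery) the
  ## same starting magnetisation, hence identical signals
  sq_tsl0 <- sequence_params(tsl = 0)
  s <- simulate_signals(sq_tsl0, tm, tissue_params(0.1, 0.056),
                        tol = 1e-12, max_blocks = 400)$signals
  expect_equal(s[2], s[3], tolerance = 1e-3)
  expect_equal(s[3], s[4], tolerance = 1e-3)
  ## at physiological T1 the incomplete recovery keeps volumes distinct --
  ## the reason mapping needs a numerical dictionary at all
  sl <- simulate_signals(sq_tsl0, tm, tissue_params(0.7, 0.056))$signals
  expect_gt(abs(sl[3] - sl[2]), 1e-3)
})

test_that("steady-state signals match the independent event-list oracle", {
  sq <- default_seq(); tm <- hr60()
  for (pars in list(c(0.7, 0.056), c(0.3, 0.02), c(1.8, 0.12))) {
    got <- simulate_signals(sq, tm, tissue_params(pars[1], pars[2]),
                            tol = 1e-13, max_blocks = 500)
    want <- oracle_signals(sq, tm, pars[1], pars[2], n_blocks = 120)
    expect_equal(got$signals, want, tolerance = 1e-10)
  }
  ## HR 100: different block timing
  tm100 <- cardiac_timing(hr = 100)
  got <- simulate_signals(sq, tm100, tissue_params(0.7, 0.056),
                          tol = 1e-13, max_blocks = 500)
  expect_equal(got$signals, oracle_signals(sq, tm100, 0.7, 0.056,
                                           n_blocks = 120),
               tolerance = 1e-10)
})

test_that("steady state is a fixed point and signals are homogeneous in m0", {
  sq <- default_seq(); tm <- hr60()
  s1 <- bloch_signals(sq, tm, 0.9, 0.07, m0 = 1)
  ## doubling m0 doubles every signal
  s2 <- bloch_signals(sq, tm, 0.9, 0.07, m0 = 2)
  expect_equal(s2$signals, 2 * s1$signals, tolerance = 1e-9)
  ## restarting from the converged state reproduces the signals
  expect_true(s1$converged)
  again <- bloch_signals(sq, tm, 0.9, 0.07, m0 = 1)
  expect_equal(again$signals, s1$signals, tolerance = 1e-8)
})

test_that("inversion makes volume 1 darker than volume 2 across T1", {
  sq <- default_seq(); tm <- hr60()
  t1s <- seq(0.1, 3.0, length.out = 15)
  s <- bloch_signals(sq, tm, t1s, 0.056)$signals
  expect_true(all(s[, 1] < s[, 2]))
})

test_that("volume 4 approaches volume 3 as the spin-lock duration vanishes", {
  ## with full inter-beat recovery (short T1) the tsl -> 0 limit of the
  ## volume-4 signal is the volume-3 signal; the gap shrinks continuously
  tm <- hr60(); ts <- tissue_params(0.12, 0.056)
  gaps <- vapply(c(0.020, 0.005, 0.001), function(tsl) {
    s <- simulate_signals(sequence_params(tsl = tsl), tm, ts,
                          tol = 1e-12, max_blocks = 400)$signals
    abs(s[4] - s[3])
  }, 0)
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-3)
})

test_that("infeasible timing is rejected", {
  sq <- default_seq()
  expect_error(bloch_signals(sq, cardiac_timing(hr = 200), 0.7, 0.056),
               "does not fit")
  expect_error(bloch_signals(sq, cardiac_timing(hr = 60, trigger_delay = 0.2),
                             0.7, 0.056), "trigger delay")
})
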