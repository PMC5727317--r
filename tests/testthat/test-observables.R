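test_that("amplitude is a robust peak-to-trough measure", {
  t <- seq(0, 1000, by = 0.1)
  expect_equal(amplitude(rep(0.4, length(t)), sample_every = 0.1), 0)
  x <- 0.5 + 0.3 * sin(2 * pi * t / 24)
  expect_equal(amplitude(x, sample_every = 0.1),
               2 * 0.3 * sin(0.475 * pi), tolerance = 1e-3)
  expect_error(amplitude(x[1:100], sample_every = 0.1), "200 h")
  # invariance under constant offset and time shift
  expect_equal(amplitude(x + 3, sample_every = 0.1),
               amplitude(x, sample_every = 0.1))
  expect_equal(amplitude(x[1001:10001], sample_every = 0.1),
               amplitude(x[1:9001], sample_every = 0.1), tolerance = 1e-6)
})

test_that("FFT period estimation recovers a circadian signal", {
  t <- seq(0, 1500, by = 0.1)
  x <- sin(2 * pi * t / 24)
  pk <- period_fft(x, sample_every = 0.1)
  expect_true(pk$peak_ok)
  expect_equal(pk$tau, 24, tolerance = 0.1 / 24)
  # with additive white noise the estimate stays within 0.3 h
  taus <- vapply(1:5, function(s) {
    set.seed(s)
    period_fft(x + rnorm(length(x), sd = 0.1), sample_every = 0.1)$tau
  }, numeric(1))
  expect_true(all(abs(taus - 24) < 0.3))
  # constant series has no spectral peak
  expect_false(period_fft(rep(1, length(t)), sample_every = 0.1)$peak_ok)
  # invariance under offset and shift
  pk2 <- period_fft(x + 5, sample_every = 0.1)
  expect_equal(pk2$tau, pk$tau)
  pk3 <- period_fft(x, sample_every = 0.1, transient = 100)
  expect_equal(pk3$tau, 24, tolerance = 0.1 / 24)
})

test_that("ATPase activity is defined for the free-KaiC condition only", {
  expect_error(atpase_activity(kai_params()), "A_T = B_T = 0")
  p0 <- rescale_ensemble(kai_params(A_T = 0, B_T = 0, f0 = 0), 20)
  ctl <- sim_control(t_end = 300, dt = 0.01, transient = 50, seed = 1)
  expect_equal(atpase_activity(p0, ctl), 0)
})

test_that("sweep drivers return tidy per-seed points with summaries", {
  p <- quick_params()
  ctl <- sim_control(t_end = 260, dt = 0.005, transient = 50, seed = 1)
  sw <- sweep_amplitude_period(p, "f0", c(0, 2.4), seeds = 1:2,
                               control = ctl)
  expect_equal(nrow(sw$points), 4L)
  expect_equal(nrow(sw$summary), 2L)
  expect_lt(sw$summary$amplitude[sw$summary$value == 0], 0.05)
  expect_gt(sw$summary$amplitude[sw$summary$value == 2.4], 0.15)
})

test_that("fixtures regenerate deterministically with their documented behavior", {
  f1 <- make_fixture("stationary_free_kaic")
  expect_lt(max(abs(f1$Dbar[f1$times >= 50])), 1e-3)
  f2 <- make_fixture("nonoscillating_noA")
  expect_lt(amplitude(f2), 0.05)
  f3 <- make_fixture("oscillating_small")
  expect_gt(amplitude(f3), 0.15)
  f3b <- make_fixture("oscillating_small")
  expect_identical(f3$Dbar, f3b$Dbar)
  expect_error(make_fixture("bogus"), "unknown fixture")
})
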