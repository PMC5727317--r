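test_that("simulation controls enforce their invariants", {
  expect_error(sim_control(dt = 0.2, sample_every = 0.1), "dt")
  expect_error(sim_control(t_end = 100, transient = 100), "transient")
  expect_error(sim_control(dt = 0.003, sample_every = 0.1), "multiple")
  expect_silent(sim_control(t_end = 10, dt = 0.01, transient = 0))
})

test_that("initial ensembles are free, desynchronized, and seed-reproducible", {
  p <- quick_params()
  s1 <- initialize_ensemble(p, seed = 4)
  expect_equal(colSums(s1$P), rep(1, p$N))
  expect_equal(s1$A_free, p$A_T)
  expect_equal(s1$B_free, p$B_T)
  expect_gt(stats::sd(s1$D), 0.15)          # uniform draw, not a point mass
  expect_true(all(s1$X > 0 & s1$X < 1))
  s2 <- initialize_ensemble(p, seed = 4)
  expect_identical(s1, s2)
  s3 <- initialize_ensemble(p, seed = 4, D_init = 0.25)
  expect_equal(s3$D, rep(0.25, p$N))
})

test_that("compiled engine agrees with the pure-R reference stepper", {
  p <- rescale_ensemble(kai_params(), 4)
  ctl <- sim_control(t_end = 2, dt = 0.01, sample_every = 0.1,
                     transient = 0, seed = 9, record_hexamers = 1:2)
  ta <- simulate_ensemble(p, ctl, engine = "cpp")
  tb <- simulate_ensemble(p, ctl, engine = "R")
  expect_equal(ta$times, tb$times)
  expect_lt(max(abs(ta$Dbar - tb$Dbar)), 1e-10)
  expect_lt(max(abs(ta$Xbar - tb$Xbar)), 1e-10)
  expect_lt(max(abs(ta$P_CA - tb$P_CA)), 1e-10)
  expect_lt(max(abs(ta$P_CBA - tb$P_CBA)), 1e-10)
  expect_equal(ta$releases, tb$releases)    # identical event sequences
  expect_lt(max(abs(ta$Dk - tb$Dk)), 1e-10)
  expect_lt(max(abs(ta$state$P - tb$state$P)), 1e-10)
  expect_equal(ta$state$release_count, tb$state$release_count)
})

test_that("identical seeds give identical trajectories", {
  p <- quick_params()
  ctl <- sim_control(t_end = 20, dt = 0.01, transient = 0, seed = 3)
  ta <- simulate_ensemble(p, ctl)
  tb <- simulate_ensemble(p, ctl)
  expect_identical(ta$Dbar, tb$Dbar)
  expect_identical(ta$releases, tb$releases)
  ctl2 <- ctl; ctl2$seed <- 4L
  expect_false(identical(simulate_ensemble(p, ctl2)$Dbar, ta$Dbar))
})

test_that("free KaiC with no hydrolysis sits at its fixed point", {
  p <- rescale_ensemble(kai_params(A_T = 0, B_T = 0, f0 = 0), 20)
  ctl <- sim_control(t_end = 50, dt = 0.01, transient = 0, seed = 1)
  traj <- simulate_ensemble(p, ctl, D_init = 0)
  expect_lt(max(abs(traj$Dbar)), 1e-9)
  X_star <- 0.5 * tanh(10) + 0.5
  expect_lt(max(abs(traj$Xbar - X_star)), 1e-9)
  expect_equal(traj$state$P[2, ], rep(1, p$N))   # all mass still on free C6
  expect_equal(sum(traj$releases), 0)
})

test_that("accounting and normalization stay exact along a stochastic run", {
  p <- quick_params()
  ctl <- sim_control(t_end = 50, dt = 0.005, transient = 0, seed = 2)
  traj <- simulate_ensemble(p, ctl)
  expect_true(all(traj$A_free >= 0))
  expect_true(all(traj$B_free >= 0))
  expect_lt(traj$diagnostics$max_renorm_correction, 1e-6)
  expect_equal(colSums(traj$state$P), rep(1, p$N), tolerance = 1e-12)
  # free concentrations recomputed from the final state match the engine
  fc <- free_concentrations(traj$state$P, p)
  expect_equal(fc$A, traj$state$A_free)
  expect_equal(fc$B, traj$state$B_free)
  expect_equal(length(traj$times), ctl$t_end / ctl$sample_every + 1)
})

test_that("halving the step leaves the deterministic dynamics unchanged", {
  # with hydrolysis off the scheme is deterministic; step-halving bounds
  # the Euler error (with f0 > 0 resampling noise dominates instead)
  p <- rescale_ensemble(kai_params(f0 = 0), 50)
  D100 <- vapply(c(0.004, 0.002, 0.001), function(dt) {
    ctl <- sim_control(t_end = 100, dt = dt, transient = 0, seed = 6)
    traj <- simulate_ensemble(p, ctl)
    traj$Dbar[length(traj$Dbar)]
  }, numeric(1))
  expect_lt(abs(D100[1] - D100[2]), 1e-3)
  expect_lt(abs(D100[2] - D100[3]), 1e-3)
  expect_lt(abs(D100[2] - D100[3]), abs(D100[1] - D100[2]) + 1e-12)
})

test_that("per-hexamer levels stay heterogeneous while the ensemble mean is coherent", {
  p <- quick_params()
  ctl <- sim_control(t_end = 260, dt = 0.005, transient = 50, seed = 8,
                     record_hexamers = 1:5)
  traj <- simulate_ensemble(p, ctl)
  keep <- traj$times >= 50
  spread <- apply(traj$Dk[keep, ], 1, stats::sd)
  expect_gt(median(spread), 0.02)           # stochastic desynchronization
  expect_gt(amplitude(traj), 0.15)          # yet a coherent mean rhythm
})
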