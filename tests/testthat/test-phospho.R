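test_that("soft-spin gradient matches its potential and pins the half-way point", {
  a <- 1.6
  expect_equal(soft_spin_gradient(0.5, a), 0)
  expect_equal(soft_spin_gradient(0, a), -a / 4)
  expect_equal(soft_spin_gradient(1, a), a / 4)
  # analytic derivative agrees with numerical differentiation of g
  g <- function(D) a * D * (D - 0.5)^2 * (D - 1)
  h <- 1e-6
  for (D in seq(-0.4, 1.4, by = 0.1)) {
    expect_equal(soft_spin_gradient(D, a), (g(D + h) - g(D - h)) / (2 * h),
                 tolerance = 1e-8)
  }
})

test_that("phosphorylation has exact stable fixed points at D = 0 and 1", {
  p <- kai_params()   # k_p = k_dp = a/4
  expect_identical(phospho_rhs(0, 0, p), 0)
  expect_identical(phospho_rhs(1, 1, p), 0)
  expect_equal(phospho_rhs(0.5, 0.5, p), 0)
  # stability: restoring flow on either side of each fixed point
  eps <- 1e-3
  expect_gt(phospho_rhs(-eps, 0, p), 0)
  expect_lt(phospho_rhs(eps, 0, p), 0)
  expect_gt(phospho_rhs(1 - eps, 1, p), 0)
  expect_lt(phospho_rhs(1 + eps, 1, p), 0)
  expect_error(phospho_rhs(0.5, 1.2, p), "p_CA")
})

test_that("KaiB-binding extent saturates per the tanh weighting", {
  expect_equal(kaiB_extent(dist_point(0, 0), 1), 0)
  expect_equal(kaiB_extent(dist_point(6, 0), 1), tanh(6))
  expect_equal(kaiB_extent(dist_point(1, 1), 1), tanh(1))
  mix <- 0.5 * dist_point(2, 1) + 0.5 * dist_point(4, 0)
  expect_equal(kaiB_extent(mix, 1), 0.5 * tanh(2) + 0.5 * tanh(4))
  expect_error(kaiB_extent(dist_point(1, 0), 0), "n_B")
})

test_that("structural order parameter follows the mean field with correct monotonicity", {
  p <- kai_params()
  expect_equal(structure_X(0, 0, 0, 0, kai_params(c0 = 0)), 0.5)
  expect_equal(structure_X(1, 0, 0, 0, p), 0.5 * tanh(4) + 0.5)
  # full KaiB binding plus full ADP load flips the structure to cs
  expect_equal(structure_X(1, 0, tanh(6), 4.8, p),
               0.5 * tanh(10 - 6 - 3 * tanh(6) - 4.8) + 0.5,
               tolerance = 1e-12)
  expect_equal(structure_X(1, 0, tanh(6), 4.8, p), 0.000500,
               tolerance = 1e-3)
  # monotonicity by finite differences (c2 > 0 so the pA term is live)
  p2 <- kai_params(c2 = 1)
  base <- structure_X(0.5, 0.5, 0.5, 2, p2)
  eps <- 1e-4
  expect_lt(structure_X(0.5 + eps, 0.5, 0.5, 2, p2), base)
  expect_gt(structure_X(0.5, 0.5 + eps, 0.5, 2, p2), base)
  expect_lt(structure_X(0.5, 0.5, 0.5 + eps, 2, p2), base)
  expect_lt(structure_X(0.5, 0.5, 0.5, 2 + eps, p2), base)
})

test_that("exact 6-ring Ising enumeration reproduces the limits behind the mean field", {
  expect_equal(ising_ring_mean(0, 10), 0)
  # J = 0: independent spins, each in field h/6
  expect_equal(ising_ring_mean(1, 0), tanh(1 / 6), tolerance = 1e-12)
  # strong coupling locks the ring into a single collective spin
  expect_equal(ising_ring_mean(4, 10), tanh(4), tolerance = 1e-4)
  for (h in c(-6, -2, -0.5, 0.5, 2, 6)) {
    expect_equal(ising_ring_mean(h, 20), tanh(h), tolerance = 1e-3)
  }
})
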