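test_that("state enumeration has 29 states in the canonical order", {
  st <- binding_states()
  expect_equal(nrow(st), 29L)
  expect_equal(st$state[1:3], c("C6A2", "C6B0A0", "C6B1A0"))
  expect_true(all(st$j[-1] <= st$i[-1]))
  expect_error(dist_point(2, 3), "0 <= j <= i")
})

test_that("structure modulates binding rates linearly with the gs/cs limits", {
  p <- kai_params()
  gs <- rates_from_structure(1, p)
  expect_equal(unlist(gs[c("h_A", "f_A", "h_B", "f_B")]),
               c(h_A = p$h_A0, f_A = 0, h_B = 0, f_B = p$f_B0))
  cs <- rates_from_structure(0, p)
  expect_equal(unlist(cs[c("h_A", "f_A", "h_B", "f_B")]),
               c(h_A = 0, f_A = p$f_A0, h_B = p$h_B0, f_B = 0))
  mid <- rates_from_structure(0.5, p)
  expect_equal(mid$h_A, p$h_A0 / 2)
  expect_equal(mid$f_B, p$f_B0 / 2)
  expect_equal(mid$h_BA, p$h_BA)
  expect_error(rates_from_structure(1.1, p), "0, 1")
})

test_that("binding master equation conserves probability and positivity", {
  p <- kai_params()
  rates <- rates_from_structure(0.4, p)
  expect_equal(binding_rhs(dist_point(0, 0), 0, 0, rates), rep(0, 29))
  set.seed(42)
  for (rep in 1:20) {
    d <- random_binding_dist()
    A <- runif(1, 0, 2000); B <- runif(1, 0, 20000)
    r <- rates_from_structure(runif(1), p)
    dp <- binding_rhs(d, A, B, r)
    expect_lt(abs(sum(dp)), 1e-12)
    # any state with zero mass can only gain probability
    d0 <- d
    d0[sample(29, 5)] <- 0
    dp0 <- binding_rhs(d0 / sum(d0), A, B, r)
    expect_true(all(dp0[d0 == 0] >= 0))
  }
})

test_that("frozen-rate chain relaxes to the detailed-balance stationary state", {
  skip_if_not_installed("deSolve")
  p <- kai_params()
  rates <- rates_from_structure(0.3, p)
  A <- 500; B <- 10000
  # route 1: long-time integration of the master equation
  sol <- deSolve::ode(
    y = as.numeric(dist_point(0, 0)), times = c(0, 500),
    func = function(t, y, parms) list(binding_rhs(y, A, B, rates)),
    method = "lsoda", rtol = 1e-12, atol = 1e-14
  )
  p_int <- sol[2, -1]
  # route 2: null space of the generator matrix
  M <- binding_rate_matrix(A, B, rates)
  ns <- svd(M)$v[, 29]
  p_null <- ns / sum(ns)
  # route 3: closed product form from detailed balance
  p_prod <- product_form_stationary(A, B, rates)
  expect_lt(max(abs(p_int - p_null)), 1e-8)
  expect_lt(max(abs(p_int - p_prod)), 1e-8)
  expect_lt(max(abs(binding_rhs(p_prod, A, B, rates))), 1e-12)
})

test_that("stationary KaiB occupancy increases with free KaiB", {
  p <- kai_params()
  rates <- rates_from_structure(0.3, p)
  st <- binding_states()
  wB <- c(0, st$i[-1])
  mean_i <- vapply(c(2000, 10000, 20000, 40000), function(B) {
    sum(wB * product_form_stationary(500, B, rates))
  }, numeric(1))
  expect_true(all(diff(mean_i) > 0))
})

test_that("conservation laws give the free concentrations and flag infeasible states", {
  p <- kai_params()
  P_free <- matrix(dist_point(0, 0), 29L, p$N)
  fc <- free_concentrations(P_free, p)
  expect_equal(fc$A, p$A_T)
  expect_equal(fc$B, p$B_T)
  P_CA <- matrix(dist_CA(), 29L, p$N)
  expect_equal(free_concentrations(P_CA, p)$A, 0)  # A_T - 2 N/V exactly
  # every hexamer fully loaded would need 12 N/V KaiA monomers > A_T
  P_full <- matrix(dist_point(6, 6), 29L, p$N)
  expect_error(free_concentrations(P_full, p), "deficit")
})
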