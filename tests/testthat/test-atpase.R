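test_that("ADP lifetime shortens in the gs state", {
  p <- kai_params()
  expect_equal(adp_lifetime(1, p), 1.25)
  expect_equal(adp_lifetime(0, p), 3.75)
  expect_equal(adp_lifetime(1, kai_params(gamma = 1)), 0)
  expect_error(adp_lifetime(1.2, p), "0, 1")
})

test_that("ATPase perturbation counts ADP-bound subunits", {
  p <- kai_params()
  expect_equal(q_of(rep(-Inf, 6), p), 0)
  expect_equal(q_of(rep(0, 6), p), 4.8)
  expect_equal(q_of(c(0, 1, rep(-Inf, 4)), p), 1.6)
})

test_that("subunit stepping is refractory, seeded, and silent at f0 = 0", {
  p <- kai_params(f0 = 0)
  set.seed(1)
  st <- step_subunits(rep(-Inf, 6), 0.9, 0, 0.01, p)
  expect_equal(st$releases, 0L)
  expect_true(all(!is.finite(st$adp_since)))
  p <- kai_params()
  expect_error(step_subunits(rep(-Inf, 6), 1, 0, 0.1, p), "0.1")
  # bound subunits never fire again before their ADP leaves
  set.seed(2)
  st <- list(adp_since = rep(0, 6))
  res <- step_subunits(st$adp_since, 1, 0.5, 0.01, p)  # age 0.5 < 1.25
  expect_equal(res$releases, 0L)
  expect_equal(res$adp_since, rep(0, 6))
  # at age >= lifetime the ADP leaves (and the subunit may fire anew)
  set.seed(3)
  res <- step_subunits(rep(0, 6), 1, 1.25, 0.001, p)
  expect_true(all(res$adp_since[res$adp_since < 0] == -Inf))
  # same seed, same draws
  set.seed(7); a <- step_subunits(rep(-Inf, 6), 0.5, 0, 0.04, p)
  set.seed(7); b <- step_subunits(rep(-Inf, 6), 0.5, 0, 0.04, p)
  expect_identical(a, b)
})

test_that("frozen-structure release process matches the renewal rate and law", {
  # direct renewal oracle: alternating Exp(f0) waits and deterministic
  # delta-long bound periods; simulate many subunits with the package's
  # per-step rule and compare
  p <- kai_params(f0 = 2.4)
  X <- 1                      # delta = 1.25 h
  dt <- 0.002
  n_sub <- 300L
  T_end <- 250
  set.seed(11)
  since <- rep(-Inf, n_sub)
  p_rel <- 1 - exp(-p$f0 * dt)
  life <- adp_lifetime(X, p)
  cap <- 100000L
  rel_t <- numeric(cap)
  sub_of <- integer(cap)
  n_rel <- 0L
  for (step in seq_len(T_end / dt)) {
    t <- (step - 1) * dt
    expired <- is.finite(since) & (t - since >= life)
    since[expired] <- -Inf
    free <- !is.finite(since)
    fire <- free & (runif(n_sub) < p_rel) # one draw per subunit, fixed order
    k <- sum(fire)
    if (k > 0) {
      since[fire] <- t
      rel_t[n_rel + seq_len(k)] <- t
      sub_of[n_rel + seq_len(k)] <- which(fire)
      n_rel <- n_rel + k
    }
  }
  expect_gt(n_rel, 1e4)
  rate <- n_rel / n_sub / T_end
  expect_equal(rate, 1 / (1 / p$f0 + life), tolerance = 0.02)
  # inter-event gaps per subunit: delta-shifted exponential(f0)
  rel_t <- rel_t[seq_len(n_rel)]; sub_of <- sub_of[seq_len(n_rel)]
  gaps <- unlist(lapply(split(rel_t, sub_of), function(ts) diff(sort(ts))))
  waits <- gaps - life
  expect_gt(min(waits), -1e-9)
  waits <- waits[seq_len(10000)]
  ks <- suppressWarnings(stats::ks.test(waits + dt * runif(length(waits)),
                                        "pexp", rate = p$f0))
  expect_gt(ks$p.value, 0.01)
})
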