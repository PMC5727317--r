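# closed-form stationary distribution of the frozen-rate binding chain:
# the chain satisfies detailed balance (Kolmogorov cycle condition on
# every (i, j) square), so pi(i, j) ~ C(6, i) rB^i * C(i, j) rBA^j with
# rB = h_B B / f_B and rBA = h_BA A^2 / f_BA, and
# pi(C6A2) / pi(0, 0) = h_A A^2 / f_A
product_form_stationary <- function(A, B, rates) {
  rB <- rates$h_B * B / rates$f_B
  rBA <- rates$h_BA * A^2 / rates$f_BA
  st <- binding_states()
  w <- numeric(29L)
  for (r in 2:29) {
    i <- st$i[r]; j <- st$j[r]
    w[r] <- choose(6, i) * rB^i * choose(i, j) * rBA^j
  }
  w[1] <- w[2] * rates$h_A * A^2 / rates$f_A   # relative to free C6
  w / sum(w)
}

# random valid binding distribution (Dirichlet-ish via normalized gamma)
random_binding_dist <- function() {
  p <- stats::rgamma(29L, shape = 0.5)
  p / sum(p)
}

# a small, quick oscillatory setup shared by several tests
quick_params <- function(...) rescale_ensemble(kai_params(...), 50)
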