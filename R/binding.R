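#' Enumeration of the 29 binding states of one KaiC hexamer
#'
#' A hexamer is either in the C6A2 complex (a KaiA dimer on the CII ring)
#' or in a C6BiA2j complex with `i` KaiB monomers on the CI ring
#' (0 <= i <= 6) and `j` of them carrying a KaiA dimer (0 <= j <= i);
#' `(i = 0, j = 0)` is free C6. This fixed ordering — C6A2 first, then
#' `(i, j)` in lexicographic order — defines the layout of every
#' probability vector in the package and of serialized trajectories.
#'
#' @return A data frame with columns `state` (label), `i`, `j` (`NA` for
#'   the C6A2 state), in the canonical order of the 29 states.
#' @examples
#' binding_states()
#' @export
binding_states <- function() {
  i <- unlist(lapply(0:6, function(k) rep(k, k + 1L)))
  j <- unlist(lapply(0:6, function(k) 0:k))
  data.frame(
    state = c("C6A2", sprintf("C6B%dA%d", i, 2L * j)),
    i = c(NA_integer_, i),
    j = c(NA_integer_, j)
  )
}

# 1-based index of state (i, j) in the canonical 29-vector
state_index <- function(i, j) 2L + (i * (i + 1L)) %/% 2L + j

#' Create and validate a binding-state probability vector
#'
#' @param p numeric vector of length 29 in the canonical order of
#'   [binding_states()]; entries in \[0, 1\] summing to 1 within `1e-6`.
#' @return The validated vector, named by state label.
#' @export
binding_dist <- function(p) {
  if (length(p) != 29L) stop("a binding distribution has 29 entries")
  if (any(!is.finite(p)) || any(p < -1e-9) || any(p > 1 + 1e-9)) {
    stop("binding probabilities must lie in [0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-6) {
    stop("binding probabilities must sum to 1 (within 1e-6)")
  }
  setNames(as.numeric(p), binding_states()$state)
}

#' Point-mass binding distributions
#'
#' `dist_point(i, j)` puts all mass on the C6BiA2j state;
#' `dist_CA()` puts all mass on C6A2. Handy for tests and initial states.
#'
#' @param i,j KaiB count and KaiA-on-KaiB count, `0 <= j <= i <= 6`.
#' @return A binding distribution (length-29 named vector).
#' @export
dist_point <- function(i, j) {
  if (i < 0 || i > 6 || j < 0 || j > i) {
    stop("require 0 <= j <= i <= 6 (KaiA on KaiB binds only to bound KaiB)")
  }
  p <- numeric(29L)
  p[state_index(i, j)] <- 1
  binding_dist(p)
}

#' @rdname dist_point
#' @export
dist_CA <- function() {
  p <- numeric(29L)
  p[1L] <- 1
  binding_dist(p)
}

#' Structure-dependent binding and unbinding rates
#'
#' The structural order parameter X modulates the affinities: KaiA binds
#' the CII ring strongly in the gs state (X near 1) and KaiB binds the CI
#' ring strongly in the cs state (X near 0):
#' `h_A = h_A0 * X`, `f_A = f_A0 * (1 - X)`,
#' `h_B = h_B0 * (1 - X)`, `f_B = f_B0 * X`.
#' The KaiA-on-KaiB rates `h_BA`, `f_BA` do not depend on the KaiC
#' structure (that KaiA contacts KaiB, not KaiC) and are passed through.
#'
#' @param X structural order parameter in \[0, 1\].
#' @param params a [kai_params()] object.
#' @return A list with elements `h_A`, `f_A`, `h_B`, `f_B`, `h_BA`, `f_BA`.
#' @export
rates_from_structure <- function(X, params) {
  if (!is.finite(X) || X < -1e-9 || X > 1 + 1e-9) {
    stop("X must lie in [0, 1]")
  }
  X <- min(max(X, 0), 1)
  list(
    h_A = params$h_A0 * X,
    f_A = params$f_A0 * (1 - X),
    h_B = params$h_B0 * (1 - X),
    f_B = params$f_B0 * X,
    h_BA = params$h_BA,
    f_BA = params$f_BA
  )
}

# Transition list of the 29-state binding chain: rows (from, to, rate).
# Rates are per unit time given free concentrations A, B and a RateSet.
# Reactions: C6 <-> C6A2 at h_A*A^2 / f_A; KaiB on at (6-i)*h_B*B,
# off at (i-j)*f_B (only KaiA-free KaiB can leave); KaiA-on-KaiB on at
# (i-j)*h_BA*A^2, off at j*f_BA.
binding_transitions <- function(A, B, rates) {
  from <- integer(0); to <- integer(0); rate <- numeric(0)
  add <- function(f, t, r) {
    from <<- c(from, f); to <<- c(to, t); rate <<- c(rate, r)
  }
  A2 <- A * A
  add(state_index(0L, 0L), 1L, rates$h_A * A2)
  add(1L, state_index(0L, 0L), rates$f_A)
  for (i in 0:6) {
    for (j in 0:i) {
      s <- state_index(i, j)
      if (i < 6) add(s, state_index(i + 1L, j), (6 - i) * rates$h_B * B)
      if (i - j > 0) add(s, state_index(i - 1L, j), (i - j) * rates$f_B)
      if (j < i) add(s, state_index(i, j + 1L), (i - j) * rates$h_BA * A2)
      if (j > 0) add(s, state_index(i, j - 1L), j * rates$f_BA)
    }
  }
  data.frame(from = from, to = to, rate = rate)
}

#' Generator matrix of the binding master equation at frozen rates
#'
#' Builds the 29 x 29 rate matrix `M` such that `dp/dt = M p` for one
#' hexamer with frozen structure (fixed rates) and fixed free
#' concentrations. Columns sum to zero (probability conservation).
#'
#' @param A,B free KaiA and KaiB concentrations (>= 0).
#' @param rates a rate set from [rates_from_structure()].
#' @return A 29 x 29 numeric matrix.
#' @export
binding_rate_matrix <- function(A, B, rates) {
  stopifnot(A >= 0, B >= 0)
  tr <- binding_transitions(A, B, rates)
  M <- matrix(0, 29L, 29L)
  for (r in seq_len(nrow(tr))) {
    M[tr$to[r], tr$from[r]] <- M[tr$to[r], tr$from[r]] + tr$rate[r]
    M[tr$from[r], tr$from[r]] <- M[tr$from[r], tr$from[r]] - tr$rate[r]
  }
  M
}

#' Time derivative of one hexamer's binding distribution
#'
#' Right-hand side of the master-equation ODEs for the 29 binding states,
#' at given free KaiA/KaiB concentrations and structure-modulated rates.
#' The components always sum to zero.
#'
#' @param p binding distribution (length-29 vector, canonical order).
#' @param A,B free KaiA and KaiB concentrations (>= 0).
#' @param rates a rate set from [rates_from_structure()].
#' @return The derivative vector, length 29.
#' @export
binding_rhs <- function(p, A, B, rates) {
  if (length(p) != 29L) stop("p must have 29 entries")
  stopifnot(A >= 0, B >= 0)
  drop(binding_rate_matrix(A, B, rates) %*% as.numeric(p))
}

# Per-state counts of sequestered KaiA monomers (2 per dimer) and bound
# KaiB monomers, in canonical order; used for the conservation laws.
bound_weights <- function() {
  st <- binding_states()
  wA <- c(2, 2 * st$j[-1])
  wB <- c(0, st$i[-1])
  list(A = wA, B = wB)
}

#' Free KaiA and KaiB concentrations from the ensemble binding state
#'
#' Applies the conservation laws: free KaiA is total KaiA minus two
#' monomers per bound KaiA dimer (one dimer in each C6A2, `j` dimers in
#' each C6BiA2j), and free KaiB is total KaiB minus `i` monomers per
#' C6BiA2j, summed over hexamers and divided by the volume.
#'
#' @param P a 29 x N matrix of binding distributions (one column per
#'   hexamer), or a single length-29 vector.
#' @param params a [kai_params()] object.
#' @return A list with elements `A` and `B` (free concentrations, >= 0).
#'   Tiny negative values (integrator roundoff, deficit <= 1e-6 scale)
#'   are clamped to zero with a warning; a deficit exceeding
#'   `1e-3 * A_T` (or `1e-3 * B_T`) is an error, signalling an
#'   integration-step failure.
#' @export
free_concentrations <- function(P, params) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 29L)
  if (nrow(P) != 29L) stop("P must have 29 rows (canonical state order)")
  w <- bound_weights()
  A <- params$A_T - sum(crossprod(w$A, P)) / params$V
  B <- params$B_T - sum(crossprod(w$B, P)) / params$V
  for (nm in c("A", "B")) {
    tot <- if (nm == "A") params$A_T else params$B_T
    val <- get(nm)
    if (val < -1e-3 * max(tot, 1)) {
      stop("free Kai", nm, " deficit exceeds 1e-3 of the total (", val,
           "); integration step too large or infeasible binding state")
    }
    if (val < -1e-6) {
      warning("free Kai", nm, " slightly negative (", signif(val, 3),
              "); clamped to 0")
    }
    assign(nm, max(val, 0))
  }
  list(A = A, B = B)
}
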