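#' Simulation controls
#'
#' @param t_end run length (h). The reference analyses use 2000 h.
#' @param dt explicit-Euler step (h). The default 0.002 h keeps
#'   `dt` times the fastest default rate (KaiA binding at
#'   `h_A0 * A_T^2` of order 64 per hour) near 0.13; accuracy is
#'   certified by step-halving tests rather than scheme order.
#' @param sample_every recording interval (h); must be a multiple of `dt`.
#' @param transient initial span (h) excluded from trajectory analyses.
#' @param seed integer seed for the run's random stream.
#' @param record_hexamers indices of hexamers whose individual D_k is
#'   recorded at each sample time (default: none).
#' @return An object of class `kai_control`.
#' @export
sim_control <- function(t_end = 2000, dt = 0.002, sample_every = 0.1,
                        transient = 500, seed = 1L,
                        record_hexamers = integer(0)) {
  if (!(dt > 0 && dt <= sample_every && sample_every <= t_end)) {
    stop("require 0 < dt <= sample_every <= t_end")
  }
  if (transient >= t_end) stop("transient must be < t_end")
  stride <- sample_every / dt
  if (abs(stride - round(stride)) > 1e-8) {
    stop("sample_every must be an integer multiple of dt")
  }
  structure(
    list(t_end = t_end, dt = dt, sample_every = sample_every,
         transient = transient, seed = as.integer(seed),
         record_hexamers = as.integer(record_hexamers)),
    class = "kai_control"
  )
}

#' Initial ensemble state
#'
#' All hexamers start free (binding mass on C6 with nothing bound), with
#' no ADP-bound subunit and phosphorylation levels drawn independently
#' and uniformly on \[0, 1\] — a deliberately desynchronized start, so
#' any coherent ensemble rhythm that develops is emergent. X is set
#' consistently from the mean-field relation and the free concentrations
#' from the conservation laws.
#'
#' @param params a [kai_params()] object.
#' @param seed optional seed; if `NULL` the current random stream is
#'   used (as when called from [simulate_ensemble()]).
#' @param D_init optional fixed initial phosphorylation level(s),
#'   recycled to N; overrides the uniform draw.
#' @return An object of class `kai_ensemble`: fields `t`, `P` (29 x N),
#'   `D`, `X`, `adp_since` (6 x N; `-Inf` = subunit not ADP-bound),
#'   `release_count`, `A_free`, `B_free`.
#' @export
initialize_ensemble <- function(params, seed = NULL, D_init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- params$N
  P <- matrix(0, 29L, N)
  P[state_index(0L, 0L), ] <- 1
  D <- if (is.null(D_init)) runif(N) else rep_len(D_init, N)
  adp_since <- matrix(-Inf, 6L, N)
  X <- structure_X(D, pA = 0, pB = 0, q = 0, params)
  structure(
    list(t = 0, P = P, D = D, X = X, adp_since = adp_since,
         release_count = integer(N),
         A_free = params$A_T, B_free = params$B_T),
    class = "kai_ensemble"
  )
}

#' One hybrid step of the full ensemble (reference implementation)
#'
#' Pure-R reference for the splitting scheme; the production path is the
#' compiled engine inside [simulate_ensemble()], and tests assert the
#' two agree. Operator order per step: (1) recompute free A and B from
#' the conservation laws; (2) advance every hexamer's binding
#' distribution by one explicit-Euler step with rates from its current
#' X, clipping negatives and renormalizing; (3) advance D by one Euler
#' step; (4) ADP releases (age reaching the current structure-dependent
#' lifetime) and stochastic Pi-release events on each subunit;
#' (5) recompute q and X (structure treated as infinitely fast), then
#' advance t.
#'
#' @param state a `kai_ensemble` state.
#' @param params a [kai_params()] object.
#' @param dt step size (h).
#' @return The updated `kai_ensemble` state.
#' @export
step_ensemble <- function(state, params, dt) {
  N <- params$N
  fc <- free_concentrations(state$P, params)
  A <- fc$A; B <- fc$B
  p_rel <- 1 - exp(-params$f0 * dt)
  life <- adp_lifetime(state$X, params)
  for (k in seq_len(N)) {
    rates <- rates_from_structure(state$X[k], params)
    p <- state$P[, k] + dt * binding_rhs(state$P[, k], A, B, rates)
    p[p < 0] <- 0
    s <- sum(p)
    if (abs(1 - s) > 1e-3) stop("binding renormalization correction > 1e-3; reduce dt")
    state$P[, k] <- p / s
  }
  state$D <- state$D + dt * phospho_rhs(state$D, state$P[1L, ], params)
  # ADP releases at the current structure-dependent lifetime, then
  # Pi-release draws in column-major order (subunit fastest within
  # hexamer), for non-ADP-bound subunits only
  lifemat <- matrix(rep(life, each = 6L), 6L, N)
  expire <- is.finite(state$adp_since) &
    (state$t - state$adp_since >= lifemat)
  state$adp_since[expire] <- -Inf
  unbound <- !is.finite(state$adp_since)
  n_try <- sum(unbound)
  if (n_try > 0 && params$f0 > 0) {
    fire <- matrix(FALSE, 6L, N)
    fire[unbound] <- runif(n_try) < p_rel
    state$adp_since[fire] <- state$t
    state$release_count <- state$release_count + colSums(fire)
  }
  state$t <- state$t + dt
  q <- params$q0 * colSums(is.finite(state$adp_since))
  st <- binding_states()
  wpB <- c(0, tanh(st$i[-1] / params$n_B))
  pB <- drop(crossprod(wpB, state$P))
  state$X <- structure_X(state$D, pA = state$P[1L, ], pB = pB, q = q, params)
  fc <- free_concentrations(state$P, params)
  state$A_free <- fc$A; state$B_free <- fc$B
  state
}

#' Simulate the KaiABC ensemble
#'
#' Runs the hybrid scheme — deterministic binding and phosphorylation
#' ODEs, algebraic structure, stochastic per-subunit ATPase events —
#' from a desynchronized initial state, recording ensemble averages at
#' each sample time: mean phosphorylation `Dbar`, mean structure `Xbar`,
#' mean C6A2 probability `P_CA`, mean total KaiB-complex-with-KaiA
#' probability `P_CBA` (all states with `i >= 1` and `j >= 1`), and the
#' number of Pi-release events in each sampling interval.
#'
#' @param params a [kai_params()] object.
#' @param control a [sim_control()] object.
#' @param engine `"cpp"` (compiled, default) or `"R"` (slow reference,
#'   identical random stream and near-identical arithmetic).
#' @param D_init optional fixed initial phosphorylation level(s); by
#'   default D starts uniform on \[0, 1\].
#' @return An object of class `kai_trajectory`: a list with `times`,
#'   `Dbar`, `Xbar`, `P_CA`, `P_CBA`, `releases`, a matrix `Dk` of
#'   recorded per-hexamer levels (possibly 0 columns), the final
#'   `state`, the `params` and `control` used, and integrator
#'   `diagnostics` (max renormalization correction, counts of clamped
#'   concentrations).
#' @examples
#' \donttest{
#' p <- rescale_ensemble(kai_params(), 50)
#' traj <- simulate_ensemble(p, sim_control(t_end = 120, transient = 48,
#'                                          seed = 7))
#' oscillation_summary(traj)
#' }
#' @export
simulate_ensemble <- function(params, control = sim_control(),
                              engine = c("cpp", "R"), D_init = NULL) {
  stopifnot(inherits(params, "kai_params"), inherits(control, "kai_control"))
  engine <- match.arg(engine)
  if (control$dt * params$f0 > 0.1) {
    stop("dt * f0 must be <= 0.1 for the per-step Bernoulli event model")
  }
  if (length(control$record_hexamers) &&
      (min(control$record_hexamers) < 1 ||
       max(control$record_hexamers) > params$N)) {
    stop("record_hexamers out of range 1..N")
  }
  set.seed(control$seed)
  state <- initialize_ensemble(params, seed = NULL, D_init = D_init)
  n_steps <- round(control$t_end / control$dt)
  stride <- round(control$sample_every / control$dt)
  if (engine == "cpp") {
    res <- engine_run(state$P, state$D, state$adp_since, state$t,
                      state$release_count, unclass(params),
                      n_steps, control$dt, stride,
                      control$record_hexamers)
  } else {
    res <- r_engine_run(state, params, control, n_steps, stride)
  }
  traj <- list(
    times = res$times, Dbar = res$Dbar, Xbar = res$Xbar,
    P_CA = res$P_CA, P_CBA = res$P_CBA, releases = res$releases,
    A_free = res$A_free, B_free = res$B_free,
    Dk = res$Dk, state = res$state, params = params, control = control,
    diagnostics = res$diagnostics
  )
  class(traj) <- "kai_trajectory"
  traj
}

# slow pure-R engine: repeated step_ensemble with identical sampling
r_engine_run <- function(state, params, control, n_steps, stride) {
  n_samp <- n_steps %/% stride + 1L
  rec <- control$record_hexamers
  out <- list(
    times = numeric(n_samp), Dbar = numeric(n_samp), Xbar = numeric(n_samp),
    P_CA = numeric(n_samp), P_CBA = numeric(n_samp),
    releases = numeric(n_samp),
    A_free = numeric(n_samp), B_free = numeric(n_samp),
    Dk = matrix(NA_real_, n_samp, length(rec))
  )
  st <- binding_states()
  cba <- which(!is.na(st$i) & st$i >= 1L & st$j >= 1L)
  record <- function(row, state, rel) {
    out$times[row] <<- state$t
    out$Dbar[row] <<- mean(state$D)
    out$Xbar[row] <<- mean(state$X)
    out$P_CA[row] <<- mean(state$P[1L, ])
    out$P_CBA[row] <<- mean(colSums(state$P[cba, , drop = FALSE]))
    out$releases[row] <<- rel
    fc <- free_concentrations(state$P, params)
    out$A_free[row] <<- fc$A
    out$B_free[row] <<- fc$B
    if (length(rec)) out$Dk[row, ] <<- state$D[rec]
  }
  record(1L, state, 0)
  rel_prev <- sum(state$release_count)
  for (step in seq_len(n_steps)) {
    state <- step_ensemble(state, params, control$dt)
    state$t <- step * control$dt   # avoid accumulation drift
    if (step %% stride == 0L) {
      rel_now <- sum(state$release_count)
      record(step %/% stride + 1L, state, rel_now - rel_prev)
      rel_prev <- rel_now
    }
  }
  out$state <- state
  out$diagnostics <- list(max_renorm_correction = NA_real_,
                          n_renorm_warn = NA_integer_,
                          n_clamped_conc = NA_integer_)
  out
}

#' @export
print.kai_trajectory <- function(x, ...) {
  cat(sprintf("KaiABC trajectory: N = %d hexamers, %g h (dt = %g h, seed %d)\n",
              x$params$N, x$control$t_end, x$control$dt, x$control$seed))
  s <- try(oscillation_summary(x), silent = TRUE)
  if (!inherits(s, "try-error")) {
    if (s$oscillating) {
      cat(sprintf("  oscillating: amplitude dDbar = %.3f, period tau = %.2f h\n",
                  s$amplitude, s$tau))
    } else {
      cat(sprintf("  not oscillating (amplitude dDbar = %.3f)\n", s$amplitude))
    }
  }
  invisible(x)
}

#' Plot ensemble observables of a trajectory
#'
#' @param x a `kai_trajectory`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.kai_trajectory <- function(x, ...) {
  graphics::matplot(x$times, cbind(x$Dbar, x$Xbar, x$P_CA, x$P_CBA),
                    type = "l", lty = 1, xlab = "time (h)", ylab = "",
                    col = c("red", "black", "darkgreen", "magenta"), ...)
  graphics::legend("topright",
                   legend = c("Dbar", "Xbar", "P(C6A2)", "P(CBA)"),
                   col = c("red", "black", "darkgreen", "magenta"),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
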