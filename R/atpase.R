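#' Structure-dependent ADP-bound lifetime
#'
#' After a Pi-release event the CI of a subunit stays ADP-bound for a
#' duration `delta = delta0 * (gamma - X)`. The lifetime tracks the
#' hexamer's current structure: the ADP leaves when the age of the
#' bound state first exceeds `delta0 * (gamma - X(t))`. The lifetime is
#' shorter in the gs state (X near 1), so ATP is turned over more
#' frequently during the phosphorylation phase; conversely, a drop in X
#' lengthens the residence of already-bound ADP, which reinforces the
#' structural transition it helped cause.
#'
#' @param X structural order parameter in \[0, 1\].
#' @param params a [kai_params()] object (uses `delta0`, `gamma`).
#' @return Lifetime in hours (>= 0 since `gamma >= 1`).
#' @export
adp_lifetime <- function(X, params) {
  if (any(!is.finite(X) | X < -1e-9 | X > 1 + 1e-9)) {
    stop("X must lie in [0, 1]")
  }
  params$delta0 * (params$gamma - pmin(pmax(X, 0), 1))
}

#' ATPase structural perturbation of one hexamer
#'
#' Each ADP-bound subunit contributes `q0` to the field pushing the
#' structure toward the cs state; subunits with ATP, ADP + Pi, or no
#' nucleotide bound contribute nothing. `adp_since` holds, per subunit,
#' the clock time of the Pi release that made it ADP-bound, or `-Inf`
#' when no ADP is bound.
#'
#' @param adp_since length-6 vector of Pi-release times (h; `-Inf` for
#'   unbound subunits).
#' @param params a [kai_params()] object (uses `q0`).
#' @return `q = q0 * #` of ADP-bound subunits, in `[0, 6 * q0]`.
#' @export
q_of <- function(adp_since, params) {
  if (length(adp_since) != 6L) stop("adp_since must have 6 entries")
  params$q0 * sum(is.finite(adp_since))
}

#' One stochastic ATPase step for the six subunits of a hexamer
#'
#' Over a step `dt` at current structure `X`: (1) every ADP-bound
#' subunit whose age `t - adp_since` has reached the current lifetime
#' `delta0 * (gamma - X)` releases its ADP; (2) every subunit not
#' ADP-bound releases Pi with probability `1 - exp(-f0 * dt)` and
#' becomes ADP-bound from time `t`. ADP-bound subunits are refractory:
#' no new Pi release can occur until the ADP leaves. Draws come from
#' the R random stream, one uniform per non-bound subunit, in subunit
#' order 1..6.
#'
#' @param adp_since length-6 vector of Pi-release times (`-Inf` when
#'   not bound).
#' @param X current structural order parameter of the hexamer.
#' @param t current clock time (h).
#' @param dt step size (h); requires `dt * f0 <= 0.1` so the per-step
#'   Bernoulli approximation of the exponential waiting time is valid.
#' @param params a [kai_params()] object.
#' @return A list with `adp_since` (updated) and `releases` (Pi-release
#'   events in this step, 0..6).
#' @export
step_subunits <- function(adp_since, X, t, dt, params) {
  if (length(adp_since) != 6L) stop("adp_since must have 6 entries")
  if (dt <= 0) stop("dt must be > 0")
  if (dt * params$f0 > 0.1) {
    stop("dt * f0 must be <= 0.1 for the per-step Bernoulli approximation")
  }
  p_rel <- 1 - exp(-params$f0 * dt)
  life <- adp_lifetime(X, params)
  releases <- 0L
  for (s in 1:6) {
    if (is.finite(adp_since[s]) && t - adp_since[s] >= life) {
      adp_since[s] <- -Inf
    }
    if (!is.finite(adp_since[s]) && params$f0 > 0) {
      if (runif(1) < p_rel) {
        adp_since[s] <- t
        releases <- releases + 1L
      }
    }
  }
  list(adp_since = adp_since, releases = releases)
}
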