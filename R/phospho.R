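#' Gradient of the soft-spin confinement potential
#'
#' The phosphorylation level D of a hexamer is a continuous variable
#' confined near its fully dephosphorylated (D = 0) and fully
#' phosphorylated (D = 1) states by the quartic potential
#' `g(D) = a * D * (D - 1/2)^2 * (D - 1)`. This returns the analytic
#' derivative `dg/dD = a * (4 u^3 - u / 2)` with `u = D - 1/2`.
#'
#' @param D phosphorylation level.
#' @param a constraint strength (1/h).
#' @return `dg/dD`, same length as `D`.
#' @export
soft_spin_gradient <- function(D, a) {
  u <- D - 0.5
  a * (4 * u^3 - 0.5 * u)
}

#' Time derivative of the phosphorylation level
#'
#' A hexamer phosphorylates at rate `k_p` while the KaiA dimer is bound
#' to its CII ring (probability `p_CA`) and dephosphorylates at rate
#' `k_dp` otherwise, with the soft-spin force confining D:
#' `dD/dt = k_p * p_CA - k_dp * (1 - p_CA) - dg/dD`.
#' At the default rates (`k_p = k_dp = a/4`) the points D = 0 under pure
#' dephosphorylation drive (`p_CA = 0`) and D = 1 under full KaiA drive
#' (`p_CA = 1`) are exact fixed points.
#'
#' @param D phosphorylation level.
#' @param p_CA probability of the C6A2 complex, in \[0, 1\].
#' @param params a [kai_params()] object.
#' @return `dD/dt`.
#' @export
phospho_rhs <- function(D, p_CA, params) {
  if (any(p_CA < -1e-9 | p_CA > 1 + 1e-9)) stop("p_CA must lie in [0, 1]")
  params$k_p * p_CA - params$k_dp * (1 - p_CA) -
    soft_spin_gradient(D, params$a)
}

#' Saturating extent of KaiB binding felt by the structure
#'
#' The structural field responds to KaiB binding through a saturating
#' weight: `pB = sum_i tanh(i / n_B) * sum_j p[i, j]`, so each
#' additional bound KaiB beyond roughly `n_B` contributes less.
#'
#' @param p binding distribution (length-29 vector, canonical order).
#' @param n_B saturation level (> 0).
#' @return `pB`, in `[0, tanh(6 / n_B)]`.
#' @export
kaiB_extent <- function(p, n_B) {
  if (length(p) != 29L) stop("p must have 29 entries")
  if (n_B <= 0) stop("n_B must be > 0")
  st <- binding_states()
  w <- c(0, tanh(st$i[-1] / n_B))
  sum(w * p)
}

#' Quasi-equilibrium structural order parameter
#'
#' The hexamer structure relaxes much faster than binding, P/dP, and
#' ATPase events, so X is an algebraic (not integrated) quantity: the
#' mean-field average of a cooperative two-state (gs/cs) transition
#' under the field `h = c0 - c1*D + c2*pA - c3*pB - q`,
#' `X = tanh(beta * h) / 2 + 1/2`, strictly inside (0, 1).
#' High phosphorylation, KaiB binding, and ADP-bound subunits (q) all
#' push the hexamer toward the cs state (X near 0); KaiA binding on the
#' CII (pA, weighted by c2) pushes toward gs.
#'
#' @param D phosphorylation level.
#' @param pA C6A2 probability, in \[0, 1\].
#' @param pB KaiB-binding extent from [kaiB_extent()].
#' @param q ATPase structural perturbation, in `[0, 6 * q0]`.
#' @param params a [kai_params()] object.
#' @return X in (0, 1).
#' @export
structure_X <- function(D, pA, pB, q, params) {
  h <- params$c0 - params$c1 * D + params$c2 * pA - params$c3 * pB - q
  0.5 * tanh(params$beta * h) + 0.5
}

#' Exact ring-Ising average of the subunit structure
#'
#' Independent oracle for the mean-field limit behind [structure_X()].
#' The six subunits carry Ising variables `x_i = +/-1` (gs/cs) with
#' energy `G = -(h/6) * sum_i x_i - J * sum_ring x_i x_{i+1}` (nearest
#' neighbours on the 6-ring). This enumerates all 2^6 configurations
#' and returns the exact Boltzmann average of `(1/6) * sum_i x_i`.
#' For `J >> k_B T` the subunits lock together and the average tends to
#' `tanh(beta * h)`, the mean-field form used in the simulator.
#'
#' @param h uniform field (k_B T units).
#' @param J nearest-neighbour coupling (k_B T units).
#' @param beta inverse temperature.
#' @return The exact mean spin, in (-1, 1).
#' @export
ising_ring_mean <- function(h, J, beta = 1) {
  stopifnot(is.finite(h), is.finite(J), is.finite(beta))
  configs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6L)))
  m <- rowMeans(configs)
  ring <- configs[, c(2:6, 1L)]
  E <- -h * m - J * rowSums(configs * ring)
  w <- exp(-beta * (E - min(E)))
  sum(m * w) / sum(w)
}
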