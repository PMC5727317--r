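#' Model parameter set for the KaiABC oscillator
#'
#' Creates the full parameter set of the multifold-feedback model. The
#' defaults are the reference set used throughout: an ensemble of
#' `N = 1000` KaiC hexamers in volume `V = 1` (so the hexamer
#' concentration is `C6T = N/V = 1000`), total KaiA at `A_T/C6T = 2`
#' and total KaiB at `B_T/C6T = 20`, with thermal energy `k_B T = 1`
#' (`beta = 1`).
#'
#' Fields (units use hours and the `V = 1`, `k_B T = 1` convention):
#' \describe{
#'   \item{N}{number of KaiC hexamers in the ensemble}
#'   \item{V}{system volume; concentration = copy number / V}
#'   \item{A_T, B_T}{total KaiA-monomer and KaiB-monomer concentrations}
#'   \item{h_A0, f_A0}{KaiA-dimer on/off rate constants on the CII ring;
#'     binding is mass-action in the square of free KaiA}
#'   \item{h_B0, f_B0}{KaiB on/off rate constants on the CI ring}
#'   \item{h_BA, f_BA}{KaiA-dimer on/off rate constants on bound KaiB
#'     (structure independent)}
#'   \item{k_p, k_dp}{phosphorylation / dephosphorylation rates (1/h)}
#'   \item{a}{strength of the quartic soft-spin constraint on D (1/h)}
#'   \item{c0, c1, c2, c3}{couplings of the structural mean field to a
#'     constant offset, D, KaiA binding, and KaiB binding (k_B T units)}
#'   \item{beta}{inverse temperature 1/k_B T}
#'   \item{n_B}{saturation level of the KaiB-binding effect on structure}
#'   \item{f0}{Pi-release frequency per CI subunit (1/h)}
#'   \item{q0}{structural impact of one ADP-bound subunit (k_B T)}
#'   \item{delta0, gamma}{ADP-bound lifetime `delta = delta0 * (gamma - X)`;
#'     `gamma >= 1` keeps the lifetime non-negative for `X` in \[0, 1\]}
#' }
#'
#' @param ... named overrides of any field listed above.
#' @return An object of class `kai_params` (a validated named list).
#' @examples
#' p <- kai_params()
#' p$A_T / (p$N / p$V)   # total KaiA to KaiC-hexamer ratio, 2
#' kai_params(f0 = 3.6, q0 = 1.0)
#' @export
kai_params <- function(...) {
  defaults <- list(
    N = 1000L, V = 1,
    A_T = 2000, B_T = 20000,
    h_A0 = 1.6e-5, h_B0 = 7.2e-6, h_BA = 1.0e-6,
    f_A0 = 0.8, f_B0 = 0.32, f_BA = 0.2,
    k_p = 0.4, k_dp = 0.4, a = 1.6,
    c0 = 10, c1 = 6, c2 = 0, c3 = 3,
    beta = 1, n_B = 1,
    f0 = 2.4, q0 = 0.8, delta0 = 2.5, gamma = 1.5
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides)[1])) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  }
  p <- modifyList(defaults, overrides)
  p$N <- as.integer(p$N)
  validate_params(p)
  structure(p, class = "kai_params")
}

#' @export
print.kai_params <- function(x, ...) {
  cat("KaiABC model parameters\n")
  c6t <- x$N / x$V
  cat(sprintf("  ensemble: N = %d hexamers, V = %g (C6T = %g)\n",
              x$N, x$V, c6t))
  cat(sprintf("  totals:   A_T = %g (A_T/C6T = %g), B_T = %g (B_T/C6T = %g)\n",
              x$A_T, x$A_T / c6t, x$B_T, x$B_T / c6t))
  cat(sprintf("  binding:  h_A0 = %g, f_A0 = %g, h_B0 = %g, f_B0 = %g, h_BA = %g, f_BA = %g\n",
              x$h_A0, x$f_A0, x$h_B0, x$f_B0, x$h_BA, x$f_BA))
  cat(sprintf("  P/dP:     k_p = %g, k_dp = %g, a = %g\n", x$k_p, x$k_dp, x$a))
  cat(sprintf("  structure: c0 = %g, c1 = %g, c2 = %g, c3 = %g, beta = %g, n_B = %g\n",
              x$c0, x$c1, x$c2, x$c3, x$beta, x$n_B))
  cat(sprintf("  ATPase:   f0 = %g /h, q0 = %g, delta0 = %g h, gamma = %g\n",
              x$f0, x$q0, x$delta0, x$gamma))
  invisible(x)
}

validate_params <- function(p) {
  nonneg <- c("A_T", "B_T", "h_A0", "h_B0", "h_BA", "f_A0", "f_B0", "f_BA",
              "k_p", "k_dp", "a", "n_B", "f0", "q0", "delta0")
  for (f in nonneg) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]) ||
        p[[f]] < 0) {
      stop("parameter '", f, "' must be a single non-negative number")
    }
  }
  if (p$N < 1L) stop("N must be >= 1")
  if (p$V <= 0) stop("V must be > 0")
  if (p$beta <= 0) stop("beta must be > 0")
  if (p$gamma < 1) {
    stop("gamma must be >= 1 (ADP lifetime delta0*(gamma - X) must stay ",
         ">= 0 for X in [0, 1])")
  }
  invisible(p)
}

#' Rescale the ensemble size at fixed concentrations
#'
#' Changes the number of simulated hexamers while scaling the volume so
#' that all concentrations (`C6T = N/V`, `A_T`, `B_T`) are unchanged.
#' The per-hexamer dynamics are statistically identical; only the noise
#' of ensemble averages grows as the ensemble shrinks. Useful for
#' desk-scale runs and parameter sweeps.
#'
#' @param params a [kai_params()] object.
#' @param N_new new ensemble size (>= 1).
#' @return A `kai_params` object with `N = N_new` and `V` rescaled.
#' @examples
#' p <- rescale_ensemble(kai_params(), 200)
#' p$N / p$V   # still 1000
#' @export
rescale_ensemble <- function(params, N_new) {
  stopifnot(inherits(params, "kai_params"))
  N_new <- as.integer(N_new)
  if (is.na(N_new) || N_new < 1L) stop("N_new must be >= 1")
  params$V <- params$V * N_new / params$N
  params$N <- N_new
  validate_params(params)
  params
}

#' Read or write a parameter set as a flat config file
#'
#' Parameter sets serialize to a flat key-value file, YAML (`.yaml`/`.yml`)
#' or JSON (`.json`), with keys named exactly as the `kai_params` fields.
#' Unknown keys in a file are rejected.
#'
#' @param params a `kai_params` object.
#' @param path file path; the extension selects the format.
#' @return `write_params` returns `path` invisibly; `read_params` returns
#'   a `kai_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "kai_params"))
  x <- unclass(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(kai_params, fix_yaml_bool_keys(as.list(x)))
}

# YAML 1.1 parses a bare `N:` key as the boolean FALSE ("Norway
# problem"); map it back to the ensemble-size field
fix_yaml_bool_keys <- function(x) {
  if (!is.null(names(x))) names(x)[names(x) == "FALSE"] <- "N"
  x
}
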