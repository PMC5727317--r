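#' Write or read a trajectory as CSV
#'
#' Columns: `t`, `Dbar`, `Xbar`, `P_CA`, `P_CBA`, `releases`, then one
#' `D_k<i>` column per recorded hexamer. The 29-state ordering of
#' serialized binding vectors elsewhere follows [binding_states()].
#'
#' @param traj a `kai_trajectory`.
#' @param path output CSV path.
#' @return `write_trajectory` returns `path` invisibly;
#'   `read_trajectory` returns a data frame.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = traj$times, Dbar = traj$Dbar, Xbar = traj$Xbar,
                   P_CA = traj$P_CA, P_CBA = traj$P_CBA,
                   releases = traj$releases)
  if (!is.null(traj$Dk) && ncol(traj$Dk) > 0) {
    dk <- as.data.frame(traj$Dk)
    names(dk) <- paste0("D_k", traj$control$record_hexamers)
    df <- cbind(df, dk)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) read.csv(path)

#' Write a run manifest
#'
#' Records the fully resolved parameter set, simulation control, seed,
#' and package version as JSON so any output file can be regenerated
#' bit-identically from its manifest alone.
#'
#' @param params a [kai_params()] object.
#' @param control a [sim_control()] object.
#' @param path output JSON path.
#' @param extra optional named list appended to the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, control, path, extra = list()) {
  manifest <- c(
    list(package = "kaiabc",
         version = as.character(utils::packageVersion("kaiabc")),
         params = unclass(params), control = unclass(control)),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a run configuration file
#'
#' A config file (YAML or JSON) may carry a `params` block (fields of
#' [kai_params()]), a `control` block (fields of [sim_control()]), and
#' sweep-specific keys (`kind`, `axis`, `values`, `AT_ratios`,
#' `BT_ratios`, `f0_values`, `seeds`). Unknown keys are rejected.
#'
#' @param path config file path; `NULL` gives an empty config.
#' @param overrides named list merged over the file contents
#'   (e.g. command-line flags).
#' @return A list with resolved `params` and `control` objects plus any
#'   sweep keys.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else {
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }
  known <- c("params", "control", "kind", "axis", "values", "AT_ratios",
             "BT_ratios", "f0_values", "seeds", "out")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(cfg, overrides)
  cfg$params <- do.call(kai_params, fix_yaml_bool_keys(as.list(cfg$params)))
  cfg$control <- do.call(sim_control, as.list(cfg$control))
  cfg
}

#' Run one simulation and write its outputs
#'
#' Writes `trajectory.csv` and `manifest.json` into `out`. Determinism
#' contract: the same config and seed reproduce the files bit for bit.
#'
#' @param config a list from [load_run_config()], or a config file path.
#' @param out output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
cmd_simulate <- function(config = list(), out = ".") {
  if (is.character(config)) config <- load_run_config(config)
  if (is.null(config$params)) config$params <- kai_params()
  if (is.null(config$control)) config$control <- sim_control()
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  traj <- simulate_ensemble(config$params, config$control)
  paths <- c(trajectory = file.path(out, "trajectory.csv"),
             manifest = file.path(out, "manifest.json"))
  write_trajectory(traj, paths[["trajectory"]])
  write_manifest(config$params, config$control, paths[["manifest"]],
                 extra = list(command = "simulate"))
  invisible(paths)
}

#' Run a parameter sweep and write its outputs
#'
#' Sweep kinds: `"phase"` (amplitude over the KaiA/KaiB concentration
#' plane), `"q0"`, `"delta0"`, `"f0"` (amplitude and period along one
#' parameter), `"activity"` (ATPase activity vs rhythm frequency and
#' the fitted slope), `"compensation"` (period spread with `f0 * delta0`
#' held fixed vs `delta0` fixed). Writes a tidy `sweep.csv`, a
#' `summary.json`, and `manifest.json` into `out`.
#'
#' @param config a list from [load_run_config()] (needs `kind` and the
#'   kind's inputs), or a config file path.
#' @param out output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
cmd_sweep <- function(config = list(), out = ".") {
  if (is.character(config)) config <- load_run_config(config)
  if (is.null(config$params)) config$params <- kai_params()
  if (is.null(config$control)) config$control <- sim_control()
  if (is.null(config$kind)) stop("sweep config needs a 'kind'")
  kind <- match.arg(config$kind,
                    c("phase", "q0", "delta0", "f0", "activity",
                      "compensation"))
  seeds <- if (is.null(config$seeds)) 1:3 else as.integer(config$seeds)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sweep = file.path(out, "sweep.csv"),
             summary = file.path(out, "summary.json"),
             manifest = file.path(out, "manifest.json"))

  if (kind == "phase") {
    if (is.null(config$AT_ratios)) stop("phase sweep needs AT_ratios")
    bt <- if (is.null(config$BT_ratios)) 20 else config$BT_ratios
    pd <- phase_diagram(config$params, config$AT_ratios, bt, seeds,
                        config$control)
    write.csv(pd$grid, paths[["sweep"]], row.names = FALSE)
    jsonlite::write_json(
      list(kind = kind, reference_amplitude = pd$reference_amplitude,
           threshold = pd$threshold),
      paths[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (kind %in% c("q0", "delta0", "f0")) {
    if (is.null(config$values) || !length(config$values)) {
      stop("sweep needs a non-empty 'values' list")
    }
    sw <- sweep_amplitude_period(config$params, kind, config$values,
                                 seeds, config$control)
    write.csv(sw$points, paths[["sweep"]], row.names = FALSE)
    jsonlite::write_json(list(kind = kind, summary = sw$summary),
                         paths[["summary"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else if (kind == "activity") {
    f0v <- if (is.null(config$f0_values)) c(1.2, 1.8, 2.4, 3.0, 3.6)
           else config$f0_values
    res <- activity_frequency_slope(config$params, f0v, seeds,
                                    config$control)
    write.csv(res$points, paths[["sweep"]], row.names = FALSE)
    jsonlite::write_json(list(kind = kind, slope = res$slope,
                              points = res$points),
                         paths[["summary"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else { # compensation
    f0v <- if (is.null(config$f0_values)) c(1.6, 2.4, 3.2)
           else config$f0_values
    fixed_prod <- config$params$f0 * config$params$delta0
    run_tau <- function(f0, delta0) {
      sw <- sweep_amplitude_period(
        kai_params(modifyList(unclass(config$params),
                              list(delta0 = delta0))),
        "f0", f0, seeds, config$control)
      sw$summary$tau
    }
    tau_fixed_delta <- vapply(f0v, function(f)
      run_tau(f, config$params$delta0), numeric(1))
    tau_fixed_prod <- vapply(f0v, function(f)
      run_tau(f, fixed_prod / f), numeric(1))
    pts <- data.frame(f0 = f0v, tau_fixed_delta0 = tau_fixed_delta,
                      tau_fixed_product = tau_fixed_prod)
    write.csv(pts, paths[["sweep"]], row.names = FALSE)
    jsonlite::write_json(
      list(kind = kind, f0_delta0 = fixed_prod,
           spread_fixed_delta0 = diff(range(tau_fixed_delta)),
           spread_fixed_product = diff(range(tau_fixed_prod))),
      paths[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_manifest(config$params, config$control, paths[["manifest"]],
                 extra = list(command = "sweep", kind = kind,
                              seeds = seeds))
  invisible(paths)
}

#' Deterministic miniature runs for testing
#'
#' Small seeded simulations used as regenerable fixtures:
#' `"stationary_free_kaic"` (no KaiA/KaiB, no hydrolysis, D started at
#' 0 — the free-KaiC fixed point), `"nonoscillating_noA"` (KaiA absent,
#' rhythm dies), and `"oscillating_small"` (a 50-hexamer ensemble at
#' reference concentrations, sustained rhythm).
#'
#' @param name fixture name (above).
#' @param seed seed for the run.
#' @return A `kai_trajectory`.
#' @export
make_fixture <- function(name, seed = 1L) {
  spec <- switch(
    name,
    stationary_free_kaic = list(
      params = rescale_ensemble(kai_params(A_T = 0, B_T = 0, f0 = 0), 20),
      control = sim_control(t_end = 100, dt = 0.01, transient = 50,
                            seed = seed),
      D_init = 0
    ),
    nonoscillating_noA = list(
      params = rescale_ensemble(kai_params(A_T = 0), 50),
      control = sim_control(t_end = 300, dt = 0.005, transient = 50,
                            seed = seed),
      D_init = NULL
    ),
    oscillating_small = list(
      params = rescale_ensemble(kai_params(), 50),
      control = sim_control(t_end = 300, dt = 0.005, transient = 50,
                            seed = seed),
      D_init = NULL
    ),
    stop("unknown fixture name: ", name)
  )
  simulate_ensemble(spec$params, spec$control, D_init = spec$D_init)
}
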