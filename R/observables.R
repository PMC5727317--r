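#' Oscillation amplitude of an ensemble series
#'
#' The amplitude of the ensemble-mean phosphorylation rhythm is defined
#' as the difference between the 97.5th and 2.5th percentiles of the
#' series over the post-transient window — a peak-to-trough measure that
#' is robust to the stochastic jitter of small ensembles.
#'
#' @param x a `kai_trajectory`, or a numeric series.
#' @param transient span (h) discarded from the start; defaults to the
#'   trajectory's control value.
#' @param sample_every sampling interval (h) of a bare numeric series.
#' @param ... unused.
#' @return The amplitude (>= 0). Requires at least 200 h of
#'   post-transient data.
#' @export
amplitude <- function(x, ...) UseMethod("amplitude")

#' @rdname amplitude
#' @export
amplitude.kai_trajectory <- function(x, transient = x$control$transient, ...) {
  keep <- x$times >= transient
  amplitude.numeric(x$Dbar[keep], sample_every = x$control$sample_every,
                    transient = 0)
}

#' @rdname amplitude
#' @export
amplitude.numeric <- function(x, sample_every, transient = 0, ...) {
  n_skip <- floor(transient / sample_every)
  if (n_skip > 0) x <- x[-seq_len(n_skip)]
  span <- (length(x) - 1) * sample_every
  if (span < 200) stop("need >= 200 h of post-transient data")
  qs <- quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  qs[2] - qs[1]
}

#' Period and peak frequency from the Fourier spectrum
#'
#' The rhythm's frequency `f_p` is the location of the peak of the
#' power spectrum of the mean-removed, Hann-windowed post-transient
#' series (zero-frequency bin excluded), refined by quadratic
#' interpolation of the three bins around the maximum; the period is
#' `tau = 1/f_p`. When the maximum power does not exceed five times the
#' median spectral power the series is flagged as having no peak and
#' `f_p`/`tau` are `NA`.
#'
#' @param x a `kai_trajectory` or a numeric series.
#' @param sample_every sampling interval (h) of a bare numeric series.
#' @param transient span (h) discarded from the start.
#' @param ... unused.
#' @return A list with `f_p` (1/h), `tau` (h), and `peak_ok` (logical).
#' @export
period_fft <- function(x, ...) UseMethod("period_fft")

#' @rdname period_fft
#' @export
period_fft.kai_trajectory <- function(x, transient = x$control$transient, ...) {
  keep <- x$times >= transient
  period_fft.numeric(x$Dbar[keep], sample_every = x$control$sample_every,
                     transient = 0)
}

#' @rdname period_fft
#' @export
period_fft.numeric <- function(x, sample_every, transient = 0, ...) {
  n_skip <- floor(transient / sample_every)
  if (n_skip > 0) x <- x[-seq_len(n_skip)]
  L <- length(x)
  span <- (L - 1) * sample_every
  if (span < 200) stop("need >= 200 h of post-transient data")
  y <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))  # Hann
  pw <- Mod(fft(y * w))^2
  half <- pw[2:floor(L / 2)]            # positive frequencies, no DC
  m <- which.max(half)
  if (max(half) <= 5 * median(half)) {
    return(list(f_p = NA_real_, tau = NA_real_, peak_ok = FALSE))
  }
  # quadratic interpolation around the peak bin (bins 1..len in `half`)
  delta <- 0
  if (m > 1 && m < length(half)) {
    p0 <- half[m - 1]; p1 <- half[m]; p2 <- half[m + 1]
    den <- p0 - 2 * p1 + p2
    if (den != 0) delta <- 0.5 * (p0 - p2) / den
  }
  f_p <- (m + delta) / (L * sample_every)
  list(f_p = f_p, tau = 1 / f_p, peak_ok = TRUE)
}

#' Summarize a trajectory's oscillation
#'
#' @param traj a `kai_trajectory`.
#' @param transient span (h) discarded from the start.
#' @param threshold amplitude above which the run is classified as
#'   oscillating (default 0.1, about a sixth of the full-scale rhythm).
#' @return A list with `amplitude`, `f_p`, `tau`, `oscillating`.
#' @export
oscillation_summary <- function(traj, transient = traj$control$transient,
                                threshold = 0.1) {
  amp <- amplitude(traj, transient = transient)
  pk <- period_fft(traj, transient = transient)
  list(amplitude = amp, f_p = pk$f_p, tau = pk$tau,
       oscillating = amp > threshold)
}

#' ATPase activity in the free-KaiC condition
#'
#' Runs the model with total KaiA and KaiB both zero (the
#' non-oscillatory condition used to characterize intrinsic hydrolysis)
#' and reports the mean number of ADP molecules released per CI subunit
#' per 24 h over the post-transient window.
#'
#' @param params a [kai_params()] object with `A_T = B_T = 0`.
#' @param control a [sim_control()] object.
#' @return Activity in ADP per CI subunit per day.
#' @export
atpase_activity <- function(params, control = sim_control(t_end = 300,
                                                          transient = 50)) {
  if (params$A_T != 0 || params$B_T != 0) {
    stop("atpase_activity is defined for the A_T = B_T = 0 condition")
  }
  traj <- simulate_ensemble(params, control)
  keep <- traj$times > control$transient
  window <- control$t_end - control$transient
  sum(traj$releases[keep]) / (6 * params$N) / (window / 24)
}

#' Amplitude and period along a one-parameter sweep
#'
#' Repeats the simulation over a grid of values of one model parameter
#' (with fresh seeds per replicate) and summarizes the oscillation
#' amplitude and FFT period at each grid point.
#'
#' @param params baseline [kai_params()].
#' @param axis one of `"q0"`, `"delta0"`, `"f0"`, `"A_T"`, `"B_T"`.
#' @param values numeric grid for the swept parameter.
#' @param seeds integer vector of seeds (replicates per grid point).
#' @param control a [sim_control()] object.
#' @return An object of class `kai_sweep`: `$points` has one row per
#'   (value, seed) with `amplitude`, `tau`, `oscillating`; `$summary`
#'   has per-value means and standard errors.
#' @export
sweep_amplitude_period <- function(params, axis, values, seeds = 1:3,
                                   control = sim_control()) {
  axis <- match.arg(axis, c("q0", "delta0", "f0", "A_T", "B_T"))
  rows <- list()
  for (v in values) {
    p <- params
    p[[axis]] <- v
    p <- validate_params(p)
    for (s in seeds) {
      ctl <- control
      ctl$seed <- as.integer(s)
      traj <- simulate_ensemble(p, ctl)
      sm <- oscillation_summary(traj)
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axis, value = v, seed = s, amplitude = sm$amplitude,
        tau = if (is.na(sm$tau)) NA_real_ else sm$tau,
        oscillating = sm$oscillating
      )
    }
  }
  points <- do.call(rbind, rows)
  se <- function(x) if (sum(!is.na(x)) > 1) sd(x, na.rm = TRUE) /
    sqrt(sum(!is.na(x))) else NA_real_
  summary <- do.call(rbind, lapply(split(points, points$value), function(d) {
    data.frame(value = d$value[1],
               amplitude = mean(d$amplitude), amplitude_se = se(d$amplitude),
               tau = mean(d$tau, na.rm = TRUE), tau_se = se(d$tau),
               n_oscillating = sum(d$oscillating))
  }))
  summary <- summary[order(summary$value), ]
  rownames(summary) <- NULL
  structure(list(points = points, summary = summary, axis = axis),
            class = "kai_sweep")
}

#' @export
print.kai_sweep <- function(x, ...) {
  cat("KaiABC parameter sweep over", x$axis, "\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Oscillation amplitude over the KaiA/KaiB concentration plane
#'
#' Scans total KaiA and KaiB (as ratios to the KaiC-hexamer
#' concentration `C6T = N/V`) and maps the oscillation amplitude.
#' Also estimates the KaiA onset threshold at each KaiB level: the
#' smallest scanned KaiA ratio whose mean amplitude exceeds half the
#' reference amplitude at ratios (A, B) = (2, 20).
#'
#' @param params baseline [kai_params()].
#' @param AT_ratios,BT_ratios scanned ratios `A_T/C6T`, `B_T/C6T`.
#' @param seeds seeds (replicates per grid point).
#' @param control a [sim_control()] object.
#' @return A list with `grid` (rows: AT_ratio, BT_ratio, seed,
#'   amplitude), `reference_amplitude`, and `threshold` (one row per
#'   BT_ratio: the estimated KaiA onset ratio, `NA` if never reached).
#' @export
phase_diagram <- function(params, AT_ratios, BT_ratios = 20, seeds = 1:3,
                          control = sim_control()) {
  c6t <- params$N / params$V
  run_point <- function(atr, btr, s) {
    p <- params
    p$A_T <- atr * c6t
    p$B_T <- btr * c6t
    p <- validate_params(p)
    ctl <- control
    ctl$seed <- as.integer(s)
    amplitude(simulate_ensemble(p, ctl))
  }
  grid <- expand.grid(AT_ratio = AT_ratios, BT_ratio = BT_ratios,
                      seed = seeds)
  grid$amplitude <- mapply(run_point, grid$AT_ratio, grid$BT_ratio,
                           grid$seed)
  in_grid <- grid$AT_ratio == 2 & grid$BT_ratio == 20
  ref <- if (any(in_grid)) mean(grid$amplitude[in_grid]) else
    mean(vapply(seeds, function(s) run_point(2, 20, s), numeric(1)))
  threshold <- do.call(rbind, lapply(BT_ratios, function(btr) {
    d <- grid[grid$BT_ratio == btr, ]
    m <- vapply(split(d, d$AT_ratio), function(g) mean(g$amplitude),
                numeric(1))
    ratios <- as.numeric(names(m))
    hit <- ratios[m > ref / 2]
    data.frame(BT_ratio = btr,
               AT_threshold = if (length(hit)) min(hit) else NA_real_)
  }))
  list(grid = grid, reference_amplitude = ref, threshold = threshold)
}

#' Correlation between ATPase activity and rhythm frequency
#'
#' For each intrinsic hydrolysis frequency `f0`, measures (a) the
#' ATPase activity in the free-KaiC condition (`A_T = B_T = 0`) and
#' (b) the phosphorylation-rhythm peak frequency in the oscillatory
#' condition (baseline KaiA/KaiB totals), converted to cycles per day,
#' then fits an ordinary least-squares line of frequency against
#' activity. Grid points that fail to oscillate are dropped with a
#' warning.
#'
#' @param params baseline [kai_params()] (oscillatory condition).
#' @param f0_values grid of Pi-release frequencies (1/h), >= 4 values.
#' @param seeds seeds for the oscillatory-condition replicates.
#' @param control control for the oscillatory runs.
#' @param control_activity control for the free-KaiC activity runs.
#' @return A list with `points` (f0, activity, f_p_day per row),
#'   `slope` (day^-1 per ADP per CI per day), and the `fit` object.
#' @export
activity_frequency_slope <- function(params, f0_values, seeds = 1:3,
                                     control = sim_control(),
                                     control_activity =
                                       sim_control(t_end = 300,
                                                   transient = 50)) {
  if (length(f0_values) < 4) stop("need >= 4 f0 values")
  rows <- lapply(f0_values, function(f0) {
    p_act <- params
    p_act$f0 <- f0
    p_act$A_T <- 0
    p_act$B_T <- 0
    p_act <- validate_params(p_act)
    act <- atpase_activity(p_act, control_activity)
    p_osc <- params
    p_osc$f0 <- f0
    p_osc <- validate_params(p_osc)
    fps <- vapply(seeds, function(s) {
      ctl <- control
      ctl$seed <- as.integer(s)
      traj <- simulate_ensemble(p_osc, ctl)
      sm <- oscillation_summary(traj)
      if (!sm$oscillating || is.na(sm$f_p)) NA_real_ else sm$f_p
    }, numeric(1))
    data.frame(f0 = f0, activity = act,
               f_p_day = mean(fps, na.rm = TRUE) * 24,
               n_oscillating = sum(!is.na(fps)))
  })
  points <- do.call(rbind, rows)
  drop <- is.na(points$f_p_day) | points$n_oscillating == 0
  if (any(drop)) {
    warning("dropping non-oscillating point(s) at f0 = ",
            paste(points$f0[drop], collapse = ", "))
  }
  pts <- points[!drop, ]
  if (nrow(pts) < 2) stop("fewer than 2 oscillating points; cannot fit")
  fit <- lm(f_p_day ~ activity, data = pts)
  list(points = points, slope = unname(coef(fit)[2]), fit = fit)
}
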