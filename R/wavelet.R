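#' Morlet wavelet analysis configuration
#'
#' The complex Morlet mother wavelet
#' `psi(t) = omega^(-1/2) * exp(i*omega*t) * exp(-t^2/2)` with centre angular
#' frequency `omega = 2*pi` is applied over a logarithmic grid of periods
#' (scales) covering the 2-5 min oscillation band; phase is analysed inside
#' the window `[t_min, t_max]`.
#'
#' @param omega centre angular frequency (default `2*pi`).
#' @param t_min,t_max analysis window bounds in seconds (defaults 60 and 330).
#' @param scales periods probed in seconds; default 40 log-spaced values
#'   spanning 60-600 s.
#' @param amp_guard_frac nodes whose ridge amplitude falls below this fraction
#'   of the cell median are treated as phase-undefined (default 0.1).
#' @return A `wavelet_config` object.
#' @export
wavelet_config <- function(omega = 2 * pi, t_min = 60, t_max = 330,
                           scales = NULL, amp_guard_frac = 0.1) {
  if (t_min >= t_max) stop("t_min must be below t_max")
  if (is.null(scales)) scales <- exp(seq(log(60), log(600), length.out = 40))
  scales <- sort(scales, decreasing = TRUE)  # ties resolve to lower frequency
  structure(list(omega = omega, t_min = t_min, t_max = t_max,
                 scales = scales, amp_guard_frac = amp_guard_frac),
            class = "wavelet_config")
}

morlet_mother <- function(t, omega) {
  omega^(-0.5) * exp(1i * omega * t) * exp(-t^2 / 2)
}

#' Continuous Morlet wavelet transform of one series
#'
#' Convolves the mean-subtracted series with scaled and translated copies of
#' the Morlet wavelet (`L2` normalisation `1/sqrt(s)`); for `omega = 2*pi`
#' the scale `s` equals the probed period in seconds. The mean is removed
#' because the kernels truncated at the record boundaries are not exactly
#' zero-mean, so a baseline would otherwise leak into the largest scales.
#' Coefficients inside the cone of influence of the record boundaries
#' (within `sqrt(2)*s` of either end) are flagged.
#'
#' @param series numeric time series.
#' @param dt sampling interval in seconds.
#' @param config a [wavelet_config()].
#' @return list with complex matrix `coef` (scale x time), `scales`, `time`,
#'   logical `coi` (same shape; `TRUE` where boundary-affected).
#' @export
morlet_transform <- function(series, dt, config = wavelet_config()) {
  n <- length(series)
  series <- series - mean(series)
  tt <- (seq_len(n) - 1) * dt
  ns <- length(config$scales)
  co <- matrix(0i, ns, n)
  coi <- matrix(FALSE, ns, n)
  for (k in seq_len(ns)) {
    co[k, ] <- matrix(series, 1) %*% morlet_kernel(tt, dt, config, k)
    s <- scale_seconds(config, k)
    coi[k, ] <- tt < sqrt(2) * s | tt > max(tt) - sqrt(2) * s
  }
  list(coef = co, scales = config$scales, time = tt, coi = coi)
}

# seconds-unit dilation for scale k (equals the probed period for omega = 2*pi)
scale_seconds <- function(config, k) config$scales[k] * config$omega / (2 * pi)

# (time x time) kernel of the conjugated, scaled wavelet centred at every t0
morlet_kernel <- function(tt, dt, config, k) {
  s <- scale_seconds(config, k)
  lag <- outer(tt, tt, "-") / s            # (t - t0)/s
  Conj(morlet_mother(lag, config$omega)) / sqrt(s) * dt
}

#' Ridge extraction: instantaneous phase and dominant period
#'
#' For every time point the scale with maximal coefficient amplitude is the
#' ridge; the dominant period is that scale and the phase is the argument of
#' the ridge coefficient, stored in `(0, 2*pi]` so that the intensity peak
#' maps to `2*pi` (the wave front). Amplitude ties resolve to the
#' lower-frequency scale. No temporal unwrapping is applied.
#'
#' @param transform output of [morlet_transform()].
#' @param config the [wavelet_config()] used.
#' @return list with `phase`, `period`, `amplitude`, `coi` per time point.
#' @export
ridge_phase <- function(transform, config = wavelet_config()) {
  amp <- Mod(transform$coef)
  ridge <- apply(amp, 2, which.max)  # scales sorted by decreasing period
  nt <- ncol(amp)
  sel <- cbind(ridge, seq_len(nt))
  a <- amp[sel]
  ph <- Arg(transform$coef[sel])
  phase <- 2 * pi - ((-ph) %% (2 * pi))  # peak (Arg = 0) -> 2*pi
  undef <- a < 1e-12
  phase[undef] <- NA
  list(phase = phase, period = transform$scales[ridge], amplitude = a,
       coi = transform$coi[sel], time = transform$time)
}

#' Entire-membrane phase map
#'
#' Applies the Morlet transform and ridge extraction to every node series and
#' restricts the output to the analysis window `[t_min, t_max]`. Nodes whose
#' ridge amplitude stays below `amp_guard_frac` of the cell-median amplitude
#' are flagged low-confidence; their phase is retained but excluded from
#' singularity detection.
#'
#' @param signal a [signal_field()].
#' @param mesh the matching [cell_mesh()].
#' @param config a [wavelet_config()].
#' @return A `phase_map`: list with matrices `phase`, `period`, `amplitude`
#'   (node x time within the window), `time`, logical `low_amp` per node,
#'   `config`.
#' @export
phase_map <- function(signal, mesh, config = wavelet_config()) {
  V <- signal$values - rowMeans(signal$values)
  n <- nrow(V)
  nt <- ncol(V)
  tt <- signal_times(signal)
  if (min(tt) > config$t_min || max(tt) < config$t_max) {
    stop("series does not cover the analysis window [",
         config$t_min, ", ", config$t_max, "] s")
  }
  ns <- length(config$scales)
  win <- which(tt >= config$t_min & tt <= config$t_max)
  # stream over scales (largest period first), keeping the running ridge;
  # strict improvement means amplitude ties resolve to the lower frequency
  best_amp <- matrix(-1, n, length(win))
  best_arg <- best_per <- matrix(0, n, length(win))
  best_coi <- matrix(TRUE, n, length(win))
  for (k in seq_len(ns)) {
    CO <- (V %*% morlet_kernel(tt, signal$dt, config, k))[, win, drop = FALSE]
    A <- Mod(CO)
    upd <- A > best_amp
    s <- scale_seconds(config, k)
    coi_k <- tt[win] < sqrt(2) * s | tt[win] > max(tt) - sqrt(2) * s
    best_coi[upd] <- matrix(coi_k, n, length(win), byrow = TRUE)[upd]
    best_amp[upd] <- A[upd]
    best_arg[upd] <- Arg(CO)[upd]
    best_per[upd] <- config$scales[k]
  }
  phase <- 2 * pi - ((-best_arg) %% (2 * pi))
  period <- best_per
  ampl <- best_amp
  phase[ampl < 1e-12] <- NA
  med <- stats::median(ampl, na.rm = TRUE)
  low <- apply(ampl, 1, stats::median) < config$amp_guard_frac * med
  structure(list(phase = phase, period = period, amplitude = ampl,
                 time = tt[win], low_amp = low, coi = best_coi,
                 config = config),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf(
    "phase_map: %d nodes x %d times (%g-%g s), %d low-amplitude node(s)\n",
    nrow(x$phase), ncol(x$phase), min(x$time), max(x$time), sum(x$low_amp)))
  invisible(x)
}
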