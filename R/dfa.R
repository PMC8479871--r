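#' Configuration for detrended fluctuation analysis
#'
#' First-order DFA quantifies the self-affinity of a membrane time series by
#' the scaling of the detrended fluctuation `F(tau) ~ tau^alpha` over window
#' lengths up to `T_max`. On white noise `alpha` is near 0.5, on a random
#' walk near 1.5, and a smooth noise-free oscillation probed well below its
#' period approaches 2.
#'
#' @param dt sampling interval (seconds).
#' @param T_max largest window length in seconds (default 180).
#' @param order polynomial detrending order (default 1).
#' @param tau_set window lengths in samples; default all integers from
#'   `order + 3` (at least 4) to `floor(T_max/dt)`.
#' @return A `dfa_config` object.
#' @export
dfa_config <- function(dt = 10, T_max = 180, order = 1, tau_set = NULL) {
  if (is.null(tau_set)) {
    tau_set <- seq(max(4, order + 3), floor(T_max / dt))
  }
  if (any(tau_set < order + 2)) stop("all tau must be >= order + 2")
  if (max(tau_set) * dt > T_max + 1e-9) stop("max tau exceeds T_max")
  structure(list(dt = dt, T_max = T_max, order = as.integer(order),
                 tau_set = as.integer(tau_set)),
            class = "dfa_config")
}

#' Mean-subtracted cumulative sum of a series
#'
#' `S_i = sum_{k<=i} (s_k - mean(s))`; the final element vanishes by
#' construction.
#'
#' @param series numeric vector (length >= 4).
#' @return numeric vector of the same length.
#' @export
cumulate <- function(series) {
  if (length(series) < 4) stop("series too short")
  cumsum(series - mean(series))
}

#' Detrended fluctuation at one window length
#'
#' The cumulated series is split into `floor(N/tau)` non-overlapping segments
#' from the start (the shorter tail is discarded); in every segment the best
#' least-squares polynomial of the given order is removed, and `F(tau)` is the
#' root mean squared residual over all covered samples.
#'
#' @param S cumulated series from [cumulate()].
#' @param tau window length in samples (`order + 2 <= tau <= length(S)`).
#' @param order polynomial detrending order (default 1).
#' @return The fluctuation `F(tau) >= 0`.
#' @export
fluctuation_function <- function(S, tau, order = 1) {
  N <- length(S)
  if (tau > N) stop("tau exceeds series length")
  if (tau < order + 2) stop("tau must be >= order + 2")
  nseg <- N %/% tau
  X <- stats::poly(seq_len(tau), degree = order, raw = TRUE)
  X <- cbind(1, X)
  H <- X %*% solve(crossprod(X), t(X))
  ss <- 0
  for (s in seq_len(nseg)) {
    seg <- S[((s - 1) * tau + 1):(s * tau)]
    res <- seg - H %*% seg
    ss <- ss + sum(res^2)
  }
  sqrt(ss / (nseg * tau))
}

#' DFA scaling exponent of one time series
#'
#' Computes `F(tau)` over the configured window set and returns the
#' least-squares slope of `log F` versus `log tau` together with the r^2 of
#' that fit.
#'
#' @param series numeric time series.
#' @param dt sampling interval in seconds (used for the default window set).
#' @param config a [dfa_config()].
#' @return list with `alpha`, `r_squared`, `tau` (samples), `F`.
#' @export
dfa_alpha <- function(series, dt = 10, config = dfa_config(dt = dt)) {
  S <- cumulate(series)
  taus <- config$tau_set
  if (length(series) < max(taus)) stop("series shorter than largest tau")
  Fv <- vapply(taus, function(tau) fluctuation_function(S, tau, config$order),
               numeric(1))
  if (any(Fv <= 0)) {
    stop("undefined alpha: fluctuation vanishes (constant series?)")
  }
  lt <- log(taus)
  lF <- log(Fv)
  fit <- stats::lm.fit(cbind(1, lt), lF)
  r2 <- 1 - sum(fit$residuals^2) / sum((lF - mean(lF))^2)
  list(alpha = unname(fit$coefficients[2]), r_squared = r2,
       tau = taus, F = Fv)
}

#' Per-node DFA exponent map
#'
#' Applies first-order DFA independently to every node series of a signal
#' field. Nodes where the fluctuation vanishes (constant signal) are flagged
#' `NA` rather than aborting the map. The computation is vectorised across
#' nodes: for each window length the per-segment polynomial projection is a
#' single matrix product shared by all nodes.
#'
#' @param signal a [signal_field()].
#' @param mesh the matching [cell_mesh()] (used for bookkeeping only).
#' @param config a [dfa_config()]; defaults to windows of 4..18 samples at the
#'   signal's `dt`.
#' @return An `alpha_map`: list with `alpha` (per node, `NA` where undefined),
#'   `r_squared`, `config`.
#' @export
alpha_map <- function(signal, mesh = NULL, config = dfa_config(dt = signal$dt)) {
  V <- signal$values
  if (!is.null(mesh) && nrow(V) != nrow(mesh$nodes)) {
    stop("signal and mesh disagree on node count")
  }
  n <- nrow(V)
  N <- ncol(V)
  taus <- config$tau_set
  if (N < max(taus)) stop("series shorter than largest tau")
  S <- t(apply(V - rowMeans(V), 1, cumsum))
  logF <- matrix(NA_real_, n, length(taus))
  for (k in seq_along(taus)) {
    tau <- taus[k]
    nseg <- N %/% tau
    X <- cbind(1, stats::poly(seq_len(tau), degree = config$order, raw = TRUE))
    H <- X %*% solve(crossprod(X), t(X))
    ss <- numeric(n)
    for (s in seq_len(nseg)) {
      B <- S[, ((s - 1) * tau + 1):(s * tau), drop = FALSE]
      Rr <- B - B %*% H
      ss <- ss + rowSums(Rr^2)
    }
    Fk <- sqrt(ss / (nseg * tau))
    logF[, k] <- ifelse(Fk > 0, log(Fk), NA)
  }
  lt <- log(taus)
  ltc <- lt - mean(lt)
  denom <- sum(ltc^2)
  ok <- !apply(logF, 1, anyNA)
  alpha <- rep(NA_real_, n)
  r2 <- rep(NA_real_, n)
  if (any(ok)) {
    Fo <- logF[ok, , drop = FALSE]
    Fc <- Fo - rowMeans(Fo)
    slope <- as.numeric(Fc %*% ltc) / denom
    ssr <- rowSums((Fc - outer(slope, ltc))^2)
    sst <- rowSums(Fc^2)
    alpha[ok] <- slope
    r2[ok] <- 1 - ssr / pmax(sst, 1e-300)
  }
  structure(list(alpha = alpha, r_squared = r2, config = config),
            class = "alpha_map")
}

#' Polar profile of the DFA exponent and the Delta-alpha summary
#'
#' Bins the per-node exponents by polar angle `theta` (node areas as
#' weights), fits a weighted polynomial (default order 4, weights = bin
#' occupancy area) to the bin medians, and evaluates it at the ventral centre
#' `theta_min = -pi/2` (`alpha_min`) and at the contact perimeter `theta_adh`
#' (`alpha_adh`). The scaling contrast `delta_alpha = alpha_adh - alpha_min`
#' is negative for oscillation-dominated and positive for noise-dominated
#' ventral membranes. On a cell without an adhered patch `alpha_adh` and
#' `delta_alpha` are `NA`.
#'
#' @param amap an [alpha_map()].
#' @param mesh the matching [cell_mesh()].
#' @param poly_order polynomial order of the profile fit (default 4).
#' @param n_bins number of theta bins (default 24; at least 10 must be
#'   populated).
#' @return An `alpha_profile`: list with `theta` (bin centres), `median_alpha`,
#'   `weight`, `coefficients`, `alpha_min`, `alpha_adh`, `delta_alpha`,
#'   `fit` (function of theta).
#' @export
alpha_profile <- function(amap, mesh, poly_order = 4, n_bins = 24) {
  ok <- !is.na(amap$alpha)
  th <- mesh$theta[ok]
  al <- amap$alpha[ok]
  w <- mesh$node_area[ok]
  breaks <- seq(-pi / 2, pi / 2, length.out = n_bins + 1)
  bin <- cut(th, breaks, labels = FALSE, include.lowest = TRUE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  med <- tapply(seq_along(al), bin, function(i) weighted_median(al[i], w[i]))
  wt <- tapply(w, bin, sum)
  used <- as.integer(names(med))
  if (length(used) < 10) stop("fewer than 10 populated theta bins")
  xc <- centers[used]
  X <- stats::poly(xc, degree = poly_order, raw = TRUE)
  fit <- stats::lm.wfit(cbind(1, X), as.numeric(med), as.numeric(wt))
  cf <- fit$coefficients
  fit_fun <- function(theta) {
    drop(cbind(1, stats::poly(theta, degree = poly_order, raw = TRUE)) %*% cf)
  }
  alpha_min <- fit_fun(-pi / 2)
  alpha_adh <- if (is.na(mesh$theta_adh)) NA_real_ else fit_fun(mesh$theta_adh)
  structure(list(theta = xc, median_alpha = as.numeric(med),
                 weight = as.numeric(wt), coefficients = cf,
                 alpha_min = alpha_min, alpha_adh = alpha_adh,
                 delta_alpha = alpha_adh - alpha_min, fit = fit_fun),
            class = "alpha_profile")
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' @export
print.alpha_profile <- function(x, ...) {
  cat(sprintf(
    "alpha_profile: alpha_min = %.3f, alpha_adh = %s, delta_alpha = %s\n",
    x$alpha_min,
    if (is.na(x$alpha_adh)) "NA" else sprintf("%.3f", x$alpha_adh),
    if (is.na(x$delta_alpha)) "NA" else sprintf("%.3f", x$delta_alpha)))
  invisible(x)
}
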