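#' Extra-column (system) dispersion model
#'
#' Plug-flow dead volume followed by a tanks-in-series cascade — the standard
#' reduced description of HPLC plant hold-up and mixing. Its residence-time
#' moments at flow rate F are `mu = (V_delay + n * V_mix) / F` and
#' `sigma2 = n * (V_mix / F)^2`, which is all the extra-column correction
#' (moment subtraction) uses.
#'
#' @param V_delay_ml plug-flow dead volume (mL).
#' @param V_mix_ml volume of each mixing tank (mL).
#' @param n_tanks number of tanks (integer >= 1); ignored if `V_mix_ml = 0`.
#' @return object of class `system_model`.
#' @export
system_model <- function(V_delay_ml = 0, V_mix_ml = 0, n_tanks = 1L) {
  stopifnot(V_delay_ml >= 0, V_mix_ml >= 0, n_tanks >= 1)
  structure(list(V_delay_ml = V_delay_ml, V_mix_ml = V_mix_ml,
                 n_tanks = as.integer(n_tanks)),
            class = "system_model")
}

#' Moments of a system model at a flow rate
#' @param model a [system_model()].
#' @param F_ml_min flow rate (mL/min).
#' @return `peak_moments` (area 1).
#' @export
system_moments <- function(model, F_ml_min) {
  stopifnot(inherits(model, "system_model"), F_ml_min > 0)
  Fs <- F_ml_min / 60  # mL/s
  mu <- (model$V_delay_ml + model$n_tanks * model$V_mix_ml) / Fs
  s2 <- model$n_tanks * (model$V_mix_ml / Fs)^2
  as_peak_moments(mu = mu, sigma2 = s2, area = 1)
}

#' Fit a system model to column-bypass moments
#'
#' Moment matching: given the extra-column first moment and variance measured
#' in a bypass run, choose the number of tanks as the largest integer
#' `n <= mu^2 / sigma2` (so the residual mean is a non-negative plug-flow
#' delay), then `V_mix = F * sqrt(sigma2 / n)` and
#' `V_delay = F * mu - n * V_mix`. `sigma2 = 0` yields a pure delay.
#'
#' @param mu_s extra-column first moment (s).
#' @param sigma2_s2 extra-column variance (s^2).
#' @param F_ml_min flow rate (mL/min).
#' @param n_max cap on the tank count (default 50).
#' @return a [system_model()] whose moments reproduce the inputs (exactly for
#'   `n <= n_max`).
#' @export
fit_system <- function(mu_s, sigma2_s2, F_ml_min, n_max = 50L) {
  stopifnot(mu_s >= 0, sigma2_s2 >= 0, F_ml_min > 0)
  Fs <- F_ml_min / 60
  if (mu_s == 0 && sigma2_s2 == 0) return(system_model(0, 0, 1L))
  if (sigma2_s2 == 0) return(system_model(V_delay_ml = Fs * mu_s, V_mix_ml = 0))
  ratio <- mu_s^2 / sigma2_s2
  if (ratio < 1)
    stop("sigma2 too large for any tanks-in-series model with n >= 1 and non-negative delay")
  n <- as.integer(min(floor(ratio), n_max))
  V_mix <- Fs * sqrt(sigma2_s2 / n)
  V_delay <- Fs * mu_s - n * V_mix
  system_model(V_delay_ml = V_delay, V_mix_ml = V_mix, n_tanks = n)
}

#' Split a system model into inlet and outlet halves
#'
#' The plant volume sits both upstream (injector to column) and downstream
#' (column to detector) of the bed. The delay is halved; the tanks are split
#' `floor(n/2)` upstream and the rest downstream with unchanged per-tank
#' volume, so the summed mean and variance equal the full model exactly.
#'
#' @param model a [system_model()].
#' @return list with `inlet` and `outlet` system models.
#' @export
split_system <- function(model) {
  stopifnot(inherits(model, "system_model"))
  n_in <- model$n_tanks %/% 2L
  n_out <- model$n_tanks - n_in
  mk <- function(n) {
    if (model$V_mix_ml == 0 || n == 0)
      system_model(model$V_delay_ml / 2, 0, 1L)
    else
      system_model(model$V_delay_ml / 2, model$V_mix_ml, n)
  }
  list(inlet = mk(n_in), outlet = mk(n_out))
}

#' Pass a signal through the system-dispersion model
#'
#' Applies the plug-flow delay as a time shift, then each mixing tank as the
#' exact exponential-integrator solution of `tau * dy/dt = u - y` with
#' piecewise-linear input (area preserving, unconditionally stable).
#'
#' @param time numeric time grid (s), uniform.
#' @param signal numeric vector (one species) or matrix (species in columns).
#' @param model a [system_model()].
#' @param F_ml_min flow rate (mL/min).
#' @param init pre-run steady composition the plant volume is filled with at
#'   t = 0 (scalar, or one value per signal column). Defaults to the first
#'   signal value — correct for detector peaks starting at baseline; pass the
#'   equilibration-buffer composition when dispersing an inlet program whose
#'   first segment is an injection.
#' @return signal object of the same shape on the same time grid.
#' @export
convolve_system <- function(time, signal, model, F_ml_min, init = NULL) {
  stopifnot(inherits(model, "system_model"), F_ml_min > 0)
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-8 * dt[1]))
    stop("convolve_system requires a uniform time grid")
  dt <- dt[1]
  one <- function(y, y0val) {
    Fs <- F_ml_min / 60
    t_delay <- model$V_delay_ml / Fs
    if (t_delay > 0) {
      shift <- t_delay / dt
      k <- floor(shift); fr <- shift - k
      y0 <- c(rep(y0val, k), y[seq_len(length(y) - k)])
      if (fr > 0) {
        y1 <- c(rep(y0val, min(k + 1, length(y))), y[seq_len(max(0, length(y) - k - 1))])
        y0 <- (1 - fr) * y0 + fr * y1
      }
      y <- y0
    }
    if (model$V_mix_ml > 0) {
      tau <- model$V_mix_ml / Fs
      e <- exp(-dt / tau)
      # exact update for linear-in-time input over each step
      c1 <- tau / dt * (1 - e) - e
      c0 <- 1 - tau / dt * (1 - e)
      for (j in seq_len(model$n_tanks)) {
        z <- c1 * y[-length(y)] + c0 * y[-1]
        y <- c(y0val, as.numeric(stats::filter(z, e, method = "recursive", init = y0val)))
      }
    }
    y
  }
  if (is.matrix(signal)) {
    if (is.null(init)) init <- signal[1, ]
    init <- rep_len(init, ncol(signal))
    out <- signal
    for (j in seq_len(ncol(signal))) out[, j] <- one(signal[, j], init[j])
    out
  } else {
    one(signal, if (is.null(init)) signal[1] else init[1])
  }
}
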