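#' Fiber-bed column geometry and porosity set
#'
#' @param L_cm bed length (cm).
#' @param d_col_cm column inner diameter (cm).
#' @param eps_T total (liquid-accessible) voidage.
#' @param eps_b interstitial (between-fiber) voidage carrying convective flow.
#' @param alpha_cm dispersivity (cm), `D_ax = alpha * v`.
#' @param r_F_um fiber radius (micrometers).
#' @param V_ml optional measured column volume; must agree with the cylinder
#'   volume from `d_col_cm`/`L_cm` within 0.5%.
#' @return object of class `bed_geometry` with derived `V_ml` (mL), `A_col_cm2`
#'   (cross section, cm^2) and `eps_p` (stationary-phase porosity, Eq. of
#'   [porosity_from_voidages()]).
#' @export
bed_geometry <- function(L_cm = 3, d_col_cm = 1, eps_T = 0.76, eps_b = 0.54,
                         alpha_cm = 0.051, r_F_um = 7.5, V_ml = NULL) {
  stopifnot(L_cm > 0, d_col_cm > 0, alpha_cm >= 0, r_F_um > 0)
  if (!(eps_b > 0 && eps_b < eps_T && eps_T < 1))
    stop("porosity ordering violated: need 0 < eps_b < eps_T < 1")
  A_col <- pi * (d_col_cm / 2)^2
  V_geom <- A_col * L_cm
  if (!is.null(V_ml) && abs(V_ml - V_geom) / V_geom > 0.005)
    stop(sprintf("declared V = %g mL disagrees with geometry (%0.3f mL) by > 0.5%%",
                 V_ml, V_geom))
  structure(list(L_cm = L_cm, d_col_cm = d_col_cm, A_col_cm2 = A_col,
                 V_ml = V_geom, eps_T = eps_T, eps_b = eps_b,
                 eps_p = porosity_from_voidages(eps_T, eps_b),
                 alpha_cm = alpha_cm, r_F_um = r_F_um),
            class = "bed_geometry")
}

#' Interstitial velocity for a flow rate
#'
#' `v = F / (A_col * eps_b)` — the convective velocity of the transport model.
#' The superficial velocity `u = F / A_col` is only used inside correlation
#' Reynolds numbers.
#'
#' @param bed a [bed_geometry()].
#' @param F_ml_min volumetric flow rate (mL/min).
#' @return interstitial velocity in cm/s.
#' @export
interstitial_velocity <- function(bed, F_ml_min) {
  (F_ml_min / 60) / (bed$A_col_cm2 * bed$eps_b)
}

#' Statistical moments of a chromatographic peak
#'
#' Zeroth moment (area), first moment (mean residence time) and second central
#' moment (variance) by trapezoidal quadrature. An optional linear baseline is
#' estimated from leading/trailing windows and subtracted; integration is
#' restricted to the contiguous region around the peak maximum where the
#' corrected signal exceeds `frac` of the peak maximum (moments are sensitive
#' to tails, so the support rule is explicit and configurable).
#'
#' @param time numeric vector of times (s), strictly increasing.
#' @param signal numeric signal vector, same length.
#' @param baseline `"linear"` (default) or `"none"`.
#' @param window_frac fraction of points at each end used to estimate the
#'   baseline (default 0.05).
#' @param frac integration-support threshold as a fraction of peak maximum
#'   (default 1e-3).
#' @return object of class `peak_moments`: list with `area`, `mu`, `sigma2`.
#' @export
peak_moments <- function(time, signal, baseline = c("linear", "none"),
                         window_frac = 0.05, frac = 1e-3) {
  baseline <- match.arg(baseline)
  stopifnot(length(time) == length(signal), length(time) >= 4)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  y <- signal
  if (baseline == "linear") {
    k <- max(2L, floor(window_frac * length(time)))
    idx <- c(seq_len(k), seq(length(time) - k + 1, length(time)))
    bl <- stats::lm(y[idx] ~ time[idx])
    y <- y - (stats::coef(bl)[1] + stats::coef(bl)[2] * time)
  }
  y[y < 0] <- 0  # tail noise after baseline correction
  if (all(y == 0)) stop("signal is identically zero after baseline correction")
  ipk <- which.max(y)
  thr <- frac * y[ipk]
  lo <- ipk; while (lo > 1 && y[lo - 1] > thr) lo <- lo - 1
  hi <- ipk; while (hi < length(y) && y[hi + 1] > thr) hi <- hi + 1
  lo <- max(1, lo - 1); hi <- min(length(y), hi + 1)  # include the crossings
  tt <- time[lo:hi]; yy <- y[lo:hi]
  area <- pracma::trapz(tt, yy)
  if (area <= 0) stop("peak area is non-positive")
  mu <- pracma::trapz(tt, yy * tt) / area
  sigma2 <- pracma::trapz(tt, yy * (tt - mu)^2) / area
  structure(list(area = area, mu = mu, sigma2 = sigma2), class = "peak_moments")
}

#' Construct a peak_moments object from known values
#' @param mu first moment (s).
#' @param sigma2 second central moment (s^2).
#' @param area zeroth moment (signal * s).
#' @export
as_peak_moments <- function(mu, sigma2, area = 1) {
  stopifnot(area > 0 || (mu == 0 && sigma2 == 0), sigma2 >= 0)
  structure(list(area = area, mu = mu, sigma2 = sigma2), class = "peak_moments")
}

#' Correct observed moments for extra-column contributions
#'
#' Moment additivity under convolution: the column-only moments are the
#' observed (whole-system) moments minus those of the extra-column (HPLC)
#' system, measured in a column-bypass run.
#'
#' @param obs observed [peak_moments()] (column + system).
#' @param hplc extra-column [peak_moments()] (system only).
#' @return corrected `peak_moments` (area taken from `obs`).
#' @export
correct_extra_column <- function(obs, hplc) {
  stopifnot(inherits(obs, "peak_moments"), inherits(hplc, "peak_moments"))
  mu <- obs$mu - hplc$mu
  s2 <- obs$sigma2 - hplc$sigma2
  if (mu < 0 || s2 < 0)
    stop("column signal narrower/earlier than system signal: corrected moment negative")
  structure(list(area = obs$area, mu = mu, sigma2 = s2), class = "peak_moments")
}

#' Accessible volume fraction from a tracer first moment
#'
#' `eps = F * mu_p / V`: the fraction of the column volume a (non-binding)
#' tracer can access, the iSEC readout. A fully accessing tracer
#' (`mu_p = V/F`) gives 1.
#'
#' @param mu_p_s extra-column-corrected first moment (s).
#' @param F_ml_min flow rate (mL/min).
#' @param V_ml column volume (mL).
#' @return accessible volume fraction; values in (1, 1.05] are kept with a
#'   warning, values > 1.05 raise an error.
#' @export
accessible_fraction <- function(mu_p_s, F_ml_min, V_ml) {
  stopifnot(mu_p_s > 0, F_ml_min > 0, V_ml > 0)
  eps <- (F_ml_min / 60) * mu_p_s / V_ml
  if (eps > 1.05) stop(sprintf("accessible fraction %.3f > 1.05: check inputs", eps))
  if (eps > 1) warning(sprintf("accessible fraction %.3f slightly exceeds 1", eps))
  eps
}

#' Stationary-phase porosity from total and interstitial voidage
#'
#' `eps_p = (eps_T - eps_b) / (1 - eps_b)`: the hydrogel fraction of the
#' stationary-phase volume, from the two iSEC plateau voidages.
#'
#' @param eps_T total voidage (small-tracer iSEC plateau).
#' @param eps_b interstitial voidage (large-tracer iSEC plateau).
#' @export
porosity_from_voidages <- function(eps_T, eps_b) {
  if (!(eps_b >= 0 && eps_b <= eps_T && eps_T <= 1))
    stop("need 0 <= eps_b <= eps_T <= 1")
  if (eps_b == 1) return(1)
  (eps_T - eps_b) / (1 - eps_b)
}

#' Axial dispersion coefficient from the second moment
#'
#' `D_ax = sigma2 * v^3 / (2 L)` — exact for a non-retained, pore-excluded
#' tracer in the large-Peclet limit. For pore-accessing tracers the variance
#' carries a hold-up factor; see the methods vignette.
#'
#' @param sigma2 extra-column-corrected peak variance (s^2).
#' @param v interstitial velocity (cm/s).
#' @param L bed length (cm).
#' @return axial dispersion coefficient (cm^2/s).
#' @export
dax_from_moments <- function(sigma2, v, L) {
  stopifnot(sigma2 >= 0, v > 0, L > 0)
  sigma2 * v^3 / (2 * L)
}

#' Dispersivity from (velocity, dispersion) pairs
#'
#' Least-squares slope through the origin of `D_ax = alpha * v`. A
#' free-intercept fit is reported as a diagnostic but not used.
#'
#' @param v interstitial velocities (cm/s), length >= 2.
#' @param Dax axial dispersion coefficients (cm^2/s).
#' @return list with `alpha_cm`, `r_squared` (of the through-origin fit) and
#'   `diagnostic` (free-intercept lm).
#' @export
fit_dispersivity <- function(v, Dax) {
  stopifnot(length(v) == length(Dax))
  if (length(v) < 2) stop("need at least 2 velocities")
  fit0 <- stats::lm(Dax ~ v - 1)
  alpha <- unname(stats::coef(fit0)[1])
  ss_res <- sum(stats::resid(fit0)^2)
  ss_tot <- sum(Dax^2)  # through-origin R^2 convention
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(alpha_cm = alpha, r_squared = r2,
       diagnostic = stats::lm(Dax ~ v))
}

#' Fit the two iSEC plateaus and the partition transition
#'
#' Fits `eps(r_H) = eps_b + (eps_T - eps_b) / (1 + exp((log r - log r0)/w))`
#' — a logistic partition function in log hydrodynamic radius — to an iSEC
#' accessible-fraction curve. The small-radius plateau estimates the total
#' voidage, the large-radius plateau the interstitial voidage; Eq. of
#' [porosity_from_voidages()] then yields the stationary-phase porosity.
#'
#' @param records data.frame with columns `r_h_nm` and `eps`.
#' @return list with `eps_T`, `eps_b`, `eps_p`, `r_cutoff_nm`, `width`, `fit`.
#' @export
fit_isec <- function(records) {
  stopifnot(is.data.frame(records), all(c("r_h_nm", "eps") %in% names(records)))
  if (nrow(records) < 5) stop("need at least 5 iSEC points")
  if (any(records$eps < -0.05 | records$eps > 1.05))
    stop("accessible fractions must lie in [0, 1]")
  lr <- log(records$r_h_nm)
  fit <- minpack.lm::nlsLM(
    eps ~ eb + (et - eb) / (1 + exp((log(r_h_nm) - lr0) / w)),
    data = records,
    start = list(et = max(records$eps), eb = min(records$eps),
                 lr0 = stats::median(lr), w = 0.3),
    lower = c(0, 0, min(lr) - 2, 0.01),
    upper = c(1, 1, max(lr) + 2, 5))
  co <- stats::coef(fit)
  eps_T <- unname(co["et"]); eps_b <- unname(co["eb"])
  list(eps_T = eps_T, eps_b = eps_b,
       eps_p = porosity_from_voidages(eps_T, eps_b),
       r_cutoff_nm = exp(unname(co["lr0"])), width = unname(co["w"]),
       fit = fit)
}
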