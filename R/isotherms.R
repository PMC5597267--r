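#' Langmuir parameter set for one or more components
#'
#' Container for the multi-component Langmuir isotherm
#' \deqn{q_i = \frac{K_{eq,i}\, q_{max,i}\, C_i}{1 + \sum_j K_{eq,j} C_j}}
#' with `q_max` the maximum binding capacity (mg per mL stationary phase) and
#' `K_eq` the equilibrium binding constant (mL/mg). With a single component
#' the expression reduces to the textbook Langmuir isotherm.
#'
#' @param q_max numeric vector of maximum binding capacities (mg/mL
#'   stationary phase), one per component.
#' @param K_eq numeric vector of equilibrium binding constants (mL/mg).
#' @param names optional component names.
#' @return an object of class `langmuir_params`.
#' @export
langmuir_params <- function(q_max, K_eq, names = NULL) {
  if (length(q_max) != length(K_eq))
    stop("q_max and K_eq must have the same length")
  if (any(!is.finite(q_max)) || any(!is.finite(K_eq)))
    stop("Langmuir parameters must be finite")
  if (any(q_max < 0) || any(K_eq < 0))
    stop("Langmuir parameters must be non-negative")
  out <- list(q_max = as.numeric(q_max), K_eq = as.numeric(K_eq))
  if (!is.null(names)) {
    names(out$q_max) <- names(out$K_eq) <- names
  }
  class(out) <- "langmuir_params"
  out
}

#' Salt dependence of Langmuir parameters
#'
#' Encodes the modifier (NaCl) dependence used for ion-exchange binding:
#' a linear capacity law `q_max(c) = a1 * c + a2` and an exponential decay of
#' the binding constant `K_eq(c) = b1 * exp(-b2 * c)`, with `c` the salt
#' concentration in mM.
#'
#' The capacity law is validated, not clipped: `q_max` must be non-negative
#' over the declared `salt_range`. During column simulation salt may transiently
#' exceed the calibrated range (e.g. a 500 mM elution step); there the solver
#' evaluates with an explicit floor at zero (see [eval_salt_dependence()] with
#' `clip = TRUE`), which is the physical high-salt limit where binding
#' vanishes.
#'
#' @param a1 slope of `q_max` vs salt (mg mL^-1 mM^-1), usually negative.
#' @param a2 `q_max` at zero salt (mg/mL).
#' @param b1 `K_eq` at zero salt (mL/mg); must be >= 0.
#' @param b2 exponential decay rate (1/mM); must be >= 0.
#' @param salt_range declared validity range in mM (length 2).
#' @return an object of class `salt_dependence`.
#' @export
salt_dependence <- function(a1, a2, b1, b2, salt_range = c(0, 150)) {
  stopifnot(length(salt_range) == 2, salt_range[1] <= salt_range[2])
  if (!all(is.finite(c(a1, a2, b1, b2)))) stop("salt-dependence parameters must be finite")
  if (b1 < 0) stop("b1 must be non-negative")
  if (b2 < 0) stop("b2 must be non-negative")
  # linear law: checking the endpoints of the declared range suffices
  qm <- a1 * salt_range + a2
  if (any(qm < 0)) {
    bad <- salt_range[which(qm < 0)[1]]
    stop(sprintf("q_max = a1*c + a2 is negative at declared salt level %g mM", bad))
  }
  structure(list(a1 = a1, a2 = a2, b1 = b1, b2 = b2,
                 salt_range = as.numeric(salt_range)),
            class = "salt_dependence")
}

#' Evaluate the multi-component Langmuir isotherm
#'
#' @param params a [langmuir_params()] object.
#' @param C_f numeric vector of stagnant-phase concentrations (mg/mL), one per
#'   component.
#' @return numeric vector of bound amounts `q_f` (mg/mL stationary phase).
#' @export
eval_langmuir <- function(params, C_f) {
  stopifnot(inherits(params, "langmuir_params"))
  if (length(C_f) != length(params$q_max))
    stop("C_f must have one entry per component")
  if (any(C_f < 0)) stop("concentrations must be non-negative")
  denom <- 1 + sum(params$K_eq * C_f)
  params$K_eq * params$q_max * C_f / denom
}

#' Evaluate Langmuir parameters at a salt concentration
#'
#' @param sd a [salt_dependence()] object.
#' @param c_mod salt concentration (mM), scalar.
#' @param clip if `TRUE`, floor a negative evaluated `q_max` at zero (used by
#'   the column solver outside the calibrated salt range); if `FALSE`
#'   (default), a negative `q_max` raises an error naming the salt level.
#' @return a [langmuir_params()] object for one component.
#' @export
eval_salt_dependence <- function(sd, c_mod, clip = FALSE) {
  stopifnot(inherits(sd, "salt_dependence"), length(c_mod) == 1)
  if (c_mod < 0) stop("salt concentration must be non-negative")
  q_max <- sd$a1 * c_mod + sd$a2
  if (q_max < 0) {
    if (!clip)
      stop(sprintf("q_max evaluates negative (%.4g) at salt level %g mM", q_max, c_mod))
    q_max <- 0
  }
  K_eq <- sd$b1 * exp(-sd$b2 * c_mod)
  langmuir_params(q_max = q_max, K_eq = K_eq)
}

#' Fit a single-component Langmuir isotherm to batch-adsorption data
#'
#' Nonlinear least squares of `q = K_eq * q_max * C / (1 + K_eq * C)` against
#' equilibrium points from a static batch adsorption experiment at one salt
#' level. Starting values come from the Hanes linearization `C/q ~ C`.
#'
#' @param data a data.frame with columns `c_eq_mg_ml` and `q_mg_ml` (a
#'   `BatchAdsorptionDataset` restricted to one component and salt level).
#' @return a list with elements `params` ([langmuir_params()]), `r_squared`,
#'   `non_binding` flag and the `fit` object (NULL for degenerate data).
#' @export
fit_langmuir <- function(data) {
  stopifnot(is.data.frame(data), all(c("c_eq_mg_ml", "q_mg_ml") %in% names(data)))
  C <- data$c_eq_mg_ml
  q <- data$q_mg_ml
  if (any(C < 0) || any(q < 0)) stop("batch data must be non-negative")
  keep <- C > 0
  if (sum(keep) < 3) stop("need at least 3 points with C_eq > 0")
  if (length(unique(C[keep])) < 2) stop("C_eq values must not all be identical")
  if (all(q == 0)) {
    p0 <- structure(list(q_max = NA_real_, K_eq = 0), class = "langmuir_params")
    return(list(params = p0, r_squared = NA_real_, non_binding = TRUE, fit = NULL))
  }
  Cp <- C[keep]; qp <- q[keep]
  # Hanes: C/q = C/qmax + 1/(K*qmax)
  h <- stats::lm(I(Cp / qp) ~ Cp)
  qmax0 <- 1 / max(stats::coef(h)[2], 1e-8)
  K0 <- max(1 / (stats::coef(h)[1] * qmax0), 1e-6)
  fit <- minpack.lm::nlsLM(
    qp ~ K * qmax * Cp / (1 + K * Cp),
    start = list(qmax = qmax0, K = K0),
    lower = c(0, 0), control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((qp - mean(qp))^2)
  list(params = langmuir_params(q_max = unname(co["qmax"]), K_eq = unname(co["K"])),
       r_squared = 1 - ss_res / ss_tot,
       non_binding = FALSE, fit = fit)
}

#' Regress Langmuir parameters against salt concentration
#'
#' Linear least squares of `q_max` vs `c_mod` and a log-linear fit of `K_eq`
#' vs `c_mod` (falling back to nonlinear least squares if any `K_eq <= 0`),
#' yielding the salt-dependence parameters (a1, a2, b1, b2). A positive
#' log-slope (K_eq increasing with salt) is clamped to b2 = 0 with a warning,
#' keeping the exponential-decay form.
#'
#' @param fits a data.frame with columns `salt_mM`, `q_max`, `K_eq` — one row
#'   per salt level, e.g. assembled from [fit_langmuir()] results.
#' @param salt_range declared validity range passed to [salt_dependence()];
#'   defaults to the span of the fitted salt levels.
#' @return a list with `sd` ([salt_dependence()]), `r_squared_qmax`,
#'   `r_squared_keq`.
#' @export
fit_salt_dependence <- function(fits, salt_range = NULL) {
  stopifnot(is.data.frame(fits), all(c("salt_mM", "q_max", "K_eq") %in% names(fits)))
  if (length(unique(fits$salt_mM)) < 3)
    stop("need at least 3 distinct salt levels (the reference workflow used 4)")
  if (is.null(salt_range)) salt_range <- range(fits$salt_mM)
  r2 <- function(fit, y) 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  lmq <- stats::lm(q_max ~ salt_mM, data = fits)
  a1 <- unname(stats::coef(lmq)[2]); a2 <- unname(stats::coef(lmq)[1])
  r2q <- r2(lmq, fits$q_max)
  if (all(fits$K_eq > 0)) {
    lmk <- stats::lm(log(K_eq) ~ salt_mM, data = fits)
    b1 <- exp(unname(stats::coef(lmk)[1])); b2 <- -unname(stats::coef(lmk)[2])
    r2k <- r2(lmk, log(fits$K_eq))
  } else {
    fitk <- minpack.lm::nlsLM(K_eq ~ b1 * exp(-b2 * salt_mM), data = fits,
                              start = list(b1 = max(fits$K_eq), b2 = 0.01),
                              lower = c(0, 0))
    co <- stats::coef(fitk)
    b1 <- unname(co["b1"]); b2 <- unname(co["b2"])
    r2k <- 1 - sum(stats::resid(fitk)^2) / sum((fits$K_eq - mean(fits$K_eq))^2)
  }
  if (b2 < 0) {
    if (b2 < -1e-10)
      warning("fitted K_eq increases with salt; clamping b2 to 0")
    b2 <- 0
    b1 <- exp(mean(log(fits$K_eq)))
  }
  list(sd = salt_dependence(a1, a2, b1, b2, salt_range = salt_range),
       r_squared_qmax = r2q, r_squared_keq = r2k)
}

#' Default composite-assay weight matrix for a three-class broth
#'
#' Rows are assays, columns the true classes (monomer, aggregate, lowMW).
#' Protein A reads total mAb (monomer + aggregate); SEC resolves all three
#' classes in IgG-equivalent pseudo-concentrations.
#'
#' @return a 4 x 3 numeric matrix with dimnames.
#' @export
composite_weights <- function() {
  w <- rbind(total_mab = c(1, 1, 0),
             monomer   = c(1, 0, 0),
             aggregate = c(0, 1, 0),
             lowmw     = c(0, 0, 1))
  colnames(w) <- c("monomer", "aggregate", "lowmw")
  w
}

#' Invert composite assay measurements to class concentrations
#'
#' Least-squares inversion of linear composite measurements (e.g. Protein A
#' total-mAb and SEC monomer/aggregate/lowMW readouts) to the three broth
#' classes, with a consistency check that the Protein A total agrees with the
#' SEC monomer + aggregate sum.
#'
#' @param measurements data.frame with columns `assay` and `value` (mg/mL,
#'   IgG-equivalent pseudo-concentrations).
#' @param weights assay-by-class weight matrix; rownames must cover the
#'   assays present. Defaults to [composite_weights()].
#' @param tol consistency tolerance (mg/mL) for the Protein A vs SEC check.
#' @return named numeric vector of class concentrations, with attributes
#'   `inconsistency` (Protein A total minus SEC monomer+aggregate, NA if not
#'   both measured) and `consistent` (logical against `tol`).
#' @export
invert_composite <- function(measurements, weights = composite_weights(), tol = 0.3) {
  stopifnot(is.data.frame(measurements), all(c("assay", "value") %in% names(measurements)))
  miss <- setdiff(measurements$assay, rownames(weights))
  if (length(miss) > 0) stop("unknown assay(s): ", paste(miss, collapse = ", "))
  W <- weights[measurements$assay, , drop = FALSE]
  if (qr(W)$rank < ncol(W))
    stop("assay weight matrix is rank deficient over the component classes")
  y <- measurements$value
  est <- qr.solve(qr(W), y)
  names(est) <- colnames(weights)
  inc <- NA_real_
  if (all(c("total_mab", "monomer", "aggregate") %in% measurements$assay)) {
    v <- function(a) measurements$value[match(a, measurements$assay)]
    inc <- v("total_mab") - (v("monomer") + v("aggregate"))
  }
  attr(est, "inconsistency") <- inc
  attr(est, "consistent") <- is.na(inc) || abs(inc) <= tol
  est
}
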