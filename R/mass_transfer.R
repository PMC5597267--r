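#' Sherwood number from the Wilson packed-bed correlation
#'
#' `Sh = (1.09 / eps_b) * Sc^0.33 * Re^0.33`, valid for 0.0015 < Re < 55.
#' Outside the validity range the value is still computed but flagged with a
#' warning.
#'
#' @param eps_b interstitial voidage.
#' @param Sc Schmidt number `mu / (rho * D_m)`.
#' @param Re Reynolds number `rho * u * d_F / mu` (superficial velocity,
#'   fiber diameter).
#' @export
sherwood_wilson <- function(eps_b, Sc, Re) {
  stopifnot(eps_b > 0, Sc > 0, Re > 0)
  if (Re <= 0.0015 || Re >= 55)
    warning(sprintf("Re = %g outside correlation validity range (0.0015, 55)", Re))
  (1.09 / eps_b) * Sc^0.33 * Re^0.33
}

#' External film mass-transfer coefficient from a Sherwood number
#'
#' `k_ext = Sh * D_m / d_F`.
#'
#' @param Sh Sherwood number.
#' @param D_m molecular diffusivity (m^2/s).
#' @param d_F fiber diameter (m).
#' @return k_ext in m/s.
#' @export
k_ext_from_sherwood <- function(Sh, D_m, d_F) {
  stopifnot(Sh > 0, D_m > 0, d_F > 0)
  Sh * D_m / d_F
}

#' Effective diffusivity in the stagnant (hydrogel) phase
#'
#' Default is the Mackie–Meares obstruction factor
#' `D_eff = D_m * (eps_p / (2 - eps_p))^2`; a plain porosity/tortuosity form
#' `D_eff = D_m * eps_p / tau` is available as an alternative strategy.
#'
#' @param D_m molecular diffusivity (m^2/s).
#' @param eps_p stationary-phase porosity, in (0, 1].
#' @param method `"mackie-meares"` (default) or `"porosity-tortuosity"`.
#' @param tau tortuosity for the porosity/tortuosity form.
#' @return D_eff in m^2/s.
#' @export
effective_diffusivity <- function(D_m, eps_p,
                                  method = c("mackie-meares", "porosity-tortuosity"),
                                  tau = 2) {
  method <- match.arg(method)
  stopifnot(D_m > 0, eps_p > 0, eps_p <= 1)
  switch(method,
         "mackie-meares" = D_m * (eps_p / (2 - eps_p))^2,
         "porosity-tortuosity" = D_m * eps_p / tau)
}

#' Internal mass-transfer coefficient of the hydrogel layer
#'
#' Fiber geometry (default): the mean diffusive path into the hydrogel-filled
#' winged channels is `r_F / 2`, giving `k_int = 2 * D_eff / r_F`. The
#' Glueckauf sphere form `k_int = 5 * D_eff / R_p` is available for
#' comparison with bead-based media.
#'
#' @param D_eff effective diffusivity (m^2/s).
#' @param r effective radius (m): fiber radius for `"fiber"`, particle radius
#'   for `"sphere"`.
#' @param geometry `"fiber"` (default) or `"sphere"`.
#' @return k_int in m/s.
#' @export
k_int_fiber <- function(D_eff, r, geometry = c("fiber", "sphere")) {
  geometry <- match.arg(geometry)
  stopifnot(D_eff > 0, r > 0)
  switch(geometry, fiber = 2 * D_eff / r, sphere = 5 * D_eff / r)
}

#' Specific exchange area of a cylindrical fiber
#'
#' Lateral area over volume of a cylinder: `A = 2 / r_F`, per stationary-phase
#' volume. The BET-derived specific surface area is only a theoretical upper
#' bound (hydrogel swelling and fiber contact in the packed bed reduce the
#' effective area) and can be reported via `A_bet_upper_bound()`.
#'
#' @param r_F fiber radius (m).
#' @return A in 1/m.
#' @export
exchange_area_fiber <- function(r_F) {
  stopifnot(r_F > 0)
  2 / r_F
}

#' BET-based theoretical upper bound for the exchange area
#'
#' `A_BET = s_BET * rho_pack / (1 - eps_b)` converts a specific surface area
#' per fiber mass into an area per stationary-phase volume. Reported as a
#' labelled upper limit only; the cylinder value of [exchange_area_fiber()]
#' is used in the model.
#'
#' @param s_bet_m2_g specific surface area (m^2/g fiber).
#' @param rho_pack_g_ml fiber packing density (g fiber per mL column volume).
#' @param eps_b interstitial voidage.
#' @return upper-bound A in 1/m.
#' @export
A_bet_upper_bound <- function(s_bet_m2_g, rho_pack_g_ml, eps_b) {
  stopifnot(s_bet_m2_g > 0, rho_pack_g_ml > 0, eps_b > 0, eps_b < 1)
  # g/mL -> kg/m^3 is *1000; m^2/g -> m^2/kg is *1000
  s_bet_m2_g * 1000 * rho_pack_g_ml * 1000 / (1 - eps_b)
}

#' Lump film and internal resistances into the volumetric rate coefficient
#'
#' `1/k_eff = 1/k_ext + 1/k_int` (resistances in series), then
#' `k_eff_A = (1 - eps_b) * A * k_eff`. In `"internal"` mode (default) the
#' film resistance is ignored and `k_eff = k_int` — the regime where internal
#' hydrogel diffusion dominates, which is the operative case for this bed.
#'
#' @param eps_b interstitial voidage.
#' @param A specific exchange area (1/m).
#' @param k_int internal coefficient (m/s).
#' @param k_ext external film coefficient (m/s); required for `"series"` mode.
#' @param mode `"internal"` (default) or `"series"`.
#' @return list with `k_eff` (m/s) and `k_eff_A` (1/s).
#' @export
lump_keff_A <- function(eps_b, A, k_int, k_ext = NULL,
                        mode = c("internal", "series")) {
  mode <- match.arg(mode)
  stopifnot(eps_b > 0, eps_b < 1, A > 0, k_int >= 0)
  if (mode == "series") {
    if (is.null(k_ext)) stop("series mode requires k_ext")
    if (k_ext <= 0 && k_int <= 0) stop("both mass-transfer coefficients are zero")
    k_eff <- 1 / (1 / k_ext + 1 / k_int)
  } else {
    if (k_int <= 0) stop("internal mass-transfer coefficient is zero")
    k_eff <- k_int
  }
  list(k_eff = k_eff, k_eff_A = (1 - eps_b) * A * k_eff)
}

#' Full mass-transfer chain for a solute on a fiber bed
#'
#' Convenience wrapper: Mackie–Meares effective diffusivity, fiber internal
#' coefficient, cylinder exchange area, and the lumped volumetric rate
#' coefficient, from the bed porosities and a molecular diffusivity. This is
#' the chain that produces the per-component rate coefficients of the column
#' model.
#'
#' @param D_m molecular diffusivity (m^2/s).
#' @param bed a [bed_geometry()].
#' @param mode passed to [lump_keff_A()].
#' @param F_ml_min flow rate (mL/min), only needed for `"series"` mode (Wilson
#'   film coefficient); water properties assumed (rho = 1000 kg/m^3,
#'   mu = 1e-3 Pa s).
#' @return list with `D_eff`, `k_int`, `k_ext` (NA in internal mode), `A`,
#'   `k_eff`, `k_eff_A`.
#' @export
transport_chain <- function(D_m, bed, mode = c("internal", "series"),
                            F_ml_min = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(bed, "bed_geometry"))
  r_F <- bed$r_F_um * 1e-6
  D_eff <- effective_diffusivity(D_m, bed$eps_p)
  k_int <- k_int_fiber(D_eff, r_F)
  A <- exchange_area_fiber(r_F)
  k_ext <- NA_real_
  if (mode == "series") {
    rho <- 1000; mu <- 1e-3
    u <- (F_ml_min * 1e-6 / 60) / (bed$A_col_cm2 * 1e-4)  # m/s superficial
    Re <- rho * u * (2 * r_F) / mu
    Sc <- mu / (rho * D_m)
    Sh <- sherwood_wilson(bed$eps_b, Sc, Re)
    k_ext <- k_ext_from_sherwood(Sh, D_m, 2 * r_F)
  }
  lk <- lump_keff_A(bed$eps_b, A, k_int,
                    k_ext = if (mode == "series") k_ext else NULL, mode = mode)
  list(D_eff = D_eff, k_int = k_int, k_ext = k_ext, A = A,
       k_eff = lk$k_eff, k_eff_A = lk$k_eff_A)
}

#' Table of transport parameters for a set of solutes
#'
#' @param D_m named numeric vector of molecular diffusivities (m^2/s).
#' @param bed a [bed_geometry()].
#' @param ... passed to [transport_chain()].
#' @return data.frame with one row per solute: `D_m_m2_s`, `D_eff_m2_s`,
#'   `k_int_m_s`, `k_eff_A_1_s`.
#' @export
transport_table <- function(D_m, bed, ...) {
  rows <- lapply(seq_along(D_m), function(i) {
    ch <- transport_chain(D_m[i], bed, ...)
    data.frame(solute = names(D_m)[i] %||% paste0("solute", i),
               D_m_m2_s = unname(D_m[i]), D_eff_m2_s = ch$D_eff,
               k_int_m_s = ch$k_int, k_eff_A_1_s = ch$k_eff_A)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
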