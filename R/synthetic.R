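#' Ground truth for the synthetic-data generators
#'
#' Bundles the bed geometry, molecular diffusivities, salt-dependent binding
#' parameters and noise settings that every generator draws from. Bed and
#' diffusivity defaults are the characterized values of the fiber bed this
#' package models (total voidage 0.76, interstitial voidage 0.54,
#' dispersivity 0.051 cm, fiber radius 7.5 um, 3 cm x 1 cm column; NaCl
#' 1.99e-9, acetone 1.14e-9, mAb 4.00e-11 m^2/s). The binding ground truth is
#' a fixture chosen once to be realistic for a grafted cation-exchange fiber
#' bed (capacities of tens of mg/mL decaying linearly with salt, binding
#' constants of a few mL/mg decaying exponentially); see the methods
#' vignette.
#'
#' @param bed a [bed_geometry()].
#' @param detector_sd additive detector noise (signal units).
#' @param batch_rel_sd multiplicative (relative) noise on batch bound
#'   amounts.
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(bed = bed_geometry(), detector_sd = 0.002,
                         batch_rel_sd = 0.02) {
  stopifnot(detector_sd >= 0, batch_rel_sd >= 0)
  structure(list(
    bed = bed,
    D_m = c(salt = 1.99e-9, acetone = 1.14e-9, mab = 4.00e-11,
            monomer = 4.00e-11, aggregate = 3.0e-11, lowmw = 1.0e-10),
    binding = list(
      mab       = salt_dependence(-0.10, 60, 5.0, 0.020, salt_range = c(0, 500)),
      monomer   = salt_dependence(-0.10, 60, 5.0, 0.020, salt_range = c(0, 500)),
      aggregate = salt_dependence(-0.10, 59, 5.1, 0.020, salt_range = c(0, 500)),
      lowmw     = salt_dependence(-0.02, 25, 4.0, 0.010, salt_range = c(0, 500))),
    broth_load = c(monomer = 2.0, aggregate = 0.2, lowmw = 1.0),
    detector_sd = detector_sd, batch_rel_sd = batch_rel_sd),
    class = "ground_truth")
}

#' Generate a batch-adsorption dataset
#'
#' Bound amounts from the salt-dependent Langmuir ground truth at each
#' (C_eq, salt) point, with multiplicative Gaussian noise — emulating a
#' static batch adsorption series (>= 5 protein concentrations at >= 4 salt
#' levels).
#'
#' @param truth a [ground_truth()].
#' @param component component name in `truth$binding`.
#' @param salt_levels salt concentrations (mM).
#' @param conc_grid equilibrium liquid concentrations (mg/mL).
#' @param replicates replicate points per (C_eq, salt).
#' @param seed RNG seed (fixed seed gives identical output).
#' @return data.frame with columns `component`, `c_eq_mg_ml`, `q_mg_ml`,
#'   `salt_mM` (a `BatchAdsorptionDataset`).
#' @export
gen_batch_dataset <- function(truth = ground_truth(), component = "mab",
                              salt_levels = c(20, 60, 100, 140),
                              conc_grid = c(0.1, 0.5, 1, 2.5, 5),
                              replicates = 1, seed = 1) {
  stopifnot(length(salt_levels) >= 1, length(conc_grid) >= 1, replicates >= 1)
  sd_b <- truth$binding[[component]]
  if (is.null(sd_b)) stop("no binding ground truth for component ", component)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(rep = seq_len(replicates), c_eq_mg_ml = conc_grid,
                      salt_mM = salt_levels)
  q <- mapply(function(C, c_mod) {
    eval_langmuir(eval_salt_dependence(sd_b, c_mod), C)
  }, grid$c_eq_mg_ml, grid$salt_mM)
  q <- q * (1 + stats::rnorm(length(q), 0, truth$batch_rel_sd))
  q[q < 0] <- 0
  data.frame(component = component, c_eq_mg_ml = grid$c_eq_mg_ml,
             q_mg_ml = q, salt_mM = grid$salt_mM)
}

#' Generate a non-binding tracer pulse chromatogram
#'
#' Runs the full forward model (column solver, optionally extra-column
#' dispersion) for a 100 uL tracer injection and adds detector noise — the
#' generator *is* the solver, so moment-recovery tests are internally
#' consistent. `"acetone"` accesses the hydrogel (total-voidage hold-up);
#' `"excluded"` emulates a large pullulan tracer that never enters the
#' stagnant phase (k_eff,A = 0, interstitial hold-up only).
#'
#' @param truth a [ground_truth()].
#' @param species `"acetone"` or `"excluded"`.
#' @param F_ml_min flow rate (mL/min).
#' @param system optional [system_model()].
#' @param settings [solver_settings()].
#' @param seed RNG seed for the detector noise (`NULL`: no noise).
#' @return a `chromatogram` data.frame (`time_s`, tracer column, `salt`) with
#'   attribute `sim` (the underlying `column_sim`).
#' @export
gen_tracer_peak <- function(truth = ground_truth(), species = c("acetone", "excluded"),
                            F_ml_min = 3, system = NULL,
                            settings = solver_settings(), seed = 1) {
  species <- match.arg(species)
  bed <- truth$bed
  keffA <- if (species == "excluded") 0 else
    transport_chain(truth$D_m[["acetone"]], bed)$k_eff_A
  sp <- list(
    species_def("salt", transport_chain(truth$D_m[["salt"]], bed)$k_eff_A, is_salt = TRUE),
    species_def(species, keffA))
  prog <- tracer_program(bed, species = species, F_ml_min = F_ml_min,
                         V_inj_ml = 0.1, conc = 1, salt_mM = 20, total_cv = 3)
  sim <- simulate_column(bed, sp, prog, settings = settings, system = system)
  chrom <- sim$chrom
  if (!is.null(seed)) {
    set.seed(seed)
    chrom[[species]] <- chrom[[species]] +
      stats::rnorm(nrow(chrom), 0, truth$detector_sd)
  }
  attr(chrom, "sim") <- sim
  chrom
}

#' Generate an inverse-SEC accessible-fraction curve
#'
#' `eps(r_H) = eps_b + (eps_T - eps_b) * phi(r_H)` with a logistic partition
#' function `phi` in log hydrodynamic radius: small tracers see the total
#' voidage, tracers larger than the hydrogel cutoff only the interstitial
#' voidage — the two-plateau shape of a fiber-bed iSEC experiment.
#'
#' @param truth a [ground_truth()].
#' @param r_h_nm tracer hydrodynamic radii (nm); default spans 0.5-20 nm.
#' @param cutoff_nm partition cutoff radius (nm).
#' @param width logistic width in log-radius units.
#' @param noise_sd additive noise on the fractions.
#' @param seed RNG seed (`NULL`: no noise).
#' @return data.frame with columns `r_h_nm`, `eps`.
#' @export
gen_isec_curve <- function(truth = ground_truth(),
                           r_h_nm = exp(seq(log(0.5), log(20), length.out = 16)),
                           cutoff_nm = 4, width = 0.25, noise_sd = 0.004,
                           seed = 1) {
  stopifnot(all(r_h_nm > 0), cutoff_nm > 0, width > 0)
  bed <- truth$bed
  phi <- 1 / (1 + exp((log(r_h_nm) - log(cutoff_nm)) / width))
  eps <- bed$eps_b + (bed$eps_T - bed$eps_b) * phi
  if (!is.null(seed) && noise_sd > 0) {
    set.seed(seed)
    eps <- eps + stats::rnorm(length(eps), 0, noise_sd)
  }
  data.frame(r_h_nm = r_h_nm, eps = pmin(pmax(eps, 0), 1))
}

#' Generate a three-class broth gradient elution with fraction table
#'
#' Forward-simulates a bind-wash-gradient cycle of the synthetic clarified
#' broth (mAb monomer, aggregates, low-molecular-weight contaminants in
#' IgG-equivalent pseudo-concentrations), integrates the outlet into
#' fixed-volume fractions, and emits composite Protein-A/SEC-style assay
#' readouts per fraction via the [composite_weights()] matrix.
#'
#' @param truth a [ground_truth()].
#' @param grad_cv gradient length (CV).
#' @param F_ml_min flow rate (mL/min).
#' @param frac_ml fraction volume (mL; default 0.4 = 400 uL).
#' @param settings [solver_settings()].
#' @param seed RNG seed for detector noise on the chromatogram (`NULL`: none).
#' @return list with `sim` (`column_sim`), `chrom`, `fractions` (data.frame:
#'   fraction, t_start_s, t_end_s, per-class mass mg and mean conc), and
#'   `composites` (per-fraction assay pseudo-concentrations).
#' @export
gen_broth_elution <- function(truth = ground_truth(), grad_cv = 10, F_ml_min = 3,
                              frac_ml = 0.4, settings = solver_settings(),
                              seed = 1) {
  bed <- truth$bed
  classes <- c("monomer", "aggregate", "lowmw")
  sp <- c(list(species_def("salt", transport_chain(truth$D_m[["salt"]], bed)$k_eff_A,
                           is_salt = TRUE)),
          lapply(classes, function(cl)
            species_def(cl, transport_chain(truth$D_m[[cl]], bed)$k_eff_A,
                        isotherm = truth$binding[[cl]])))
  prog <- bind_elute_program(bed, load = truth$broth_load, F_ml_min = F_ml_min,
                             grad_cv = grad_cv)
  sim <- simulate_column(bed, sp, prog, settings = settings)
  tt <- sim$time_s
  Fs <- F_ml_min / 60
  # fractionate the outlet from the start of the gradient
  wash_end <- sum(vapply(prog$segments[1:2], `[[`, numeric(1), "duration_s"))
  dt_frac <- frac_ml / Fs
  starts <- seq(wash_end, max(tt) - dt_frac, by = dt_frac)
  # window masses from the exact cumulative eluted mass (window edges need
  # not align with the output grid)
  cum <- lapply(classes, function(cl) pracma::cumtrapz(tt, Fs * sim$outlet[, cl]))
  names(cum) <- classes
  frac <- do.call(rbind, lapply(seq_along(starts), function(i) {
    masses <- vapply(classes, function(cl) {
      ce <- stats::approx(tt, cum[[cl]], xout = c(starts[i], starts[i] + dt_frac))$y
      ce[2] - ce[1]
    }, numeric(1))
    conc <- masses / frac_ml
    out <- data.frame(fraction = i, t_start_s = starts[i],
                      t_end_s = starts[i] + dt_frac)
    out[paste0("mass_", classes)] <- as.list(masses)
    out[paste0("conc_", classes)] <- as.list(conc)
    out
  }))
  W <- composite_weights()
  conc_mat <- as.matrix(frac[, paste0("conc_", classes)])
  composites <- data.frame(fraction = frac$fraction,
                           t(W %*% t(conc_mat)))
  names(composites) <- c("fraction", rownames(W))
  chrom <- sim$chrom
  if (!is.null(seed)) {
    set.seed(seed)
    for (cl in classes)
      chrom[[cl]] <- chrom[[cl]] + stats::rnorm(nrow(chrom), 0, truth$detector_sd)
  }
  list(sim = sim, chrom = chrom, fractions = frac, composites = composites)
}
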