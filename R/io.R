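#' Read / write chromatogram CSV files
#'
#' Dialect: comma-separated, UTF-8, '.' decimal, mandatory header. First
#' column `time_s` (strictly increasing, uniform or irregular), remaining
#' columns one species each. Round trip is lossless to ~1e-12 relative.
#'
#' @param path file path.
#' @return `read_chromatogram`: a `chromatogram` data.frame.
#' @export
read_chromatogram <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s")
    stop("chromatogram header must start with 'time_s' (got '", names(df)[1], "')")
  if (ncol(df) < 2) stop("chromatogram needs at least one species column")
  if (any(diff(df$time_s) <= 0)) stop("time_s must be strictly increasing")
  class(df) <- c("chromatogram", "data.frame")
  df
}

#' @rdname read_chromatogram
#' @param chrom a `chromatogram` data.frame (`time_s` + species columns).
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(is.data.frame(chrom), names(chrom)[1] == "time_s")
  utils::write.csv(as.data.frame(chrom), path, row.names = FALSE)
  invisible(path)
}

#' Read a batch-adsorption dataset CSV
#'
#' Columns: `component`, `c_eq_mg_ml`, `q_mg_ml`, `salt_mM`. Bound amounts in
#' mg per gram fiber can be converted to the internal per-mL-stationary-phase
#' basis via a declared packing density.
#'
#' @param path file path.
#' @param per_gram if TRUE, `q_mg_ml` is interpreted as mg/g fiber and
#'   converted using `packing_g_ml` and the interstitial voidage `eps_b`
#'   (stationary-phase volume fraction `1 - eps_b`).
#' @param packing_g_ml fiber packing density (g fiber per mL column).
#' @param eps_b interstitial voidage for the conversion.
#' @export
read_batch_csv <- function(path, per_gram = FALSE, packing_g_ml = 0.35,
                           eps_b = 0.54) {
  df <- utils::read.csv(path)
  need <- c("component", "c_eq_mg_ml", "q_mg_ml", "salt_mM")
  if (!all(need %in% names(df)))
    stop("batch CSV must have columns: ", paste(need, collapse = ", "))
  if (any(df$c_eq_mg_ml < 0) || any(df$q_mg_ml < 0))
    stop("batch data must be non-negative")
  if (per_gram) {
    # mg/g fiber -> mg per mL stationary phase
    df$q_mg_ml <- df$q_mg_ml * packing_g_ml / (1 - eps_b)
  }
  df
}

# block -> allowed keys; unknown keys are rejected with the offending name
.config_schema <- list(
  bed = c("L_cm", "d_col_cm", "eps_T", "eps_b", "alpha_cm", "r_F_um", "V_ml"),
  components = c("name", "D_m_m2_s", "keffA_1_s", "is_salt", "langmuir",
                 "salt_dependence"),
  program = c("duration_s", "duration_cv", "F_ml_min", "inlet"),
  system = c("V_delay_ml", "V_mix_ml", "n_tanks"),
  solver = c("N", "rtol", "atol", "dt_out_s", "correct_numerical_dispersion"),
  seed = character(0))

#' Load and validate a run configuration (YAML)
#'
#' Blocks: `bed` (geometry; bed defaults are the characterized fiber-bed
#' values), `components` (list; each with `name`, and either `keffA_1_s` or
#' `D_m_m2_s` from which the rate coefficient is derived via
#' [transport_chain()]; optional `langmuir: {q_max, K_eq}` or
#' `salt_dependence: {a1, a2, b1, b2, salt_range}`; `is_salt` flag), optional
#' `program` (list of segments), `system`, `solver`, `seed`. Unknown keys are
#' rejected by name.
#'
#' @param path YAML file.
#' @return list of class `run_config` with `bed` ([bed_geometry()]),
#'   `species` (list of [species_def()]), `program` (or NULL), `system`,
#'   `settings`, `seed`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(.config_schema))
  if (length(unknown)) stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$bed)) stop("missing config block 'bed'")
  for (blk in c("bed", "system", "solver")) {
    bad <- setdiff(names(raw[[blk]]), .config_schema[[blk]])
    if (length(bad)) stop(sprintf("unknown key(s) in '%s': %s", blk, paste(bad, collapse = ", ")))
  }
  for (k in c("eps_T", "eps_b")) {
    if (is.null(raw$bed[[k]])) stop("missing required key 'bed.", k, "' (dimensionless)")
  }
  bed <- do.call(bed_geometry, raw$bed)
  if (is.null(raw$components) || !length(raw$components))
    stop("missing config block 'components'")
  species <- lapply(raw$components, function(cmp) {
    bad <- setdiff(names(cmp), .config_schema$components)
    if (length(bad)) stop("unknown key(s) in component: ", paste(bad, collapse = ", "))
    if (is.null(cmp$name)) stop("each component needs a 'name'")
    keffA <- cmp$keffA_1_s
    if (is.null(keffA)) {
      if (is.null(cmp$D_m_m2_s))
        stop("component '", cmp$name, "' needs keffA_1_s or D_m_m2_s (m^2/s)")
      keffA <- transport_chain(cmp$D_m_m2_s, bed)$k_eff_A
      message("derived k_eff,A = ", signif(keffA, 3), " 1/s for ", cmp$name)
    } else {
      message("using precomputed k_eff,A for ", cmp$name, " (mass-transfer chain bypassed)")
    }
    iso <- NULL
    if (!is.null(cmp$langmuir))
      iso <- langmuir_params(cmp$langmuir$q_max, cmp$langmuir$K_eq)
    if (!is.null(cmp$salt_dependence)) {
      sdc <- cmp$salt_dependence
      iso <- salt_dependence(sdc$a1, sdc$a2, sdc$b1, sdc$b2,
                             salt_range = sdc$salt_range %||% c(0, 150))
    }
    species_def(cmp$name, keffA, isotherm = iso, is_salt = isTRUE(cmp$is_salt))
  })
  nms <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("component defined more than once: ",
                               nms[duplicated(nms)][1])
  program <- NULL
  if (!is.null(raw$program)) program <- flow_program(raw$program, bed)
  system <- NULL
  if (!is.null(raw$system)) system <- do.call(system_model, raw$system)
  settings <- do.call(solver_settings, raw$solver %||% list())
  structure(list(bed = bed, species = species, program = program,
                 system = system, settings = settings, seed = raw$seed %||% 1L),
            class = "run_config")
}

#' Compare a simulated and a reference chromatogram
#'
#' Resamples the reference onto the simulation grid over the overlapping time
#' range and reports the coefficient of determination, the offset of the peak
#' maxima, the FWHM ratio and the area (mass) ratio for one species.
#'
#' @param sim,ref `chromatogram` data.frames.
#' @param species species column to compare (default: first shared species).
#' @return list with `r_squared`, `peak_offset_s`, `width_ratio`,
#'   `mass_ratio`, `n` (points compared).
#' @export
compare_runs <- function(sim, ref, species = NULL) {
  stopifnot(is.data.frame(sim), is.data.frame(ref))
  shared <- setdiff(intersect(names(sim), names(ref)), "time_s")
  if (is.null(species)) species <- shared[1]
  if (!species %in% shared) stop("species '", species, "' not present in both runs")
  lo <- max(min(sim$time_s), min(ref$time_s))
  hi <- min(max(sim$time_s), max(ref$time_s))
  if (hi <= lo) stop("chromatograms have no overlapping time range")
  keep <- sim$time_s >= lo & sim$time_s <= hi
  tt <- sim$time_s[keep]
  ys <- sim[[species]][keep]
  yr <- stats::approx(ref$time_s, ref[[species]], xout = tt)$y
  r2 <- 1 - sum((ys - yr)^2) / sum((yr - mean(yr))^2)
  ps <- peak_stats(tt, ys); pr <- peak_stats(tt, yr)
  list(r_squared = r2,
       peak_offset_s = ps$t_max - pr$t_max,
       width_ratio = ps$fwhm_s / pr$fwhm_s,
       mass_ratio = pracma::trapz(tt, ys) / pracma::trapz(tt, yr),
       n = length(tt))
}
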