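#' Define a transported species for the column model
#'
#' @param name species name (column header in chromatograms).
#' @param keffA_1_s lumped volumetric mass-transfer rate coefficient (1/s),
#'   usually from [transport_chain()]. `0` models a pore-excluded tracer.
#' @param isotherm `NULL` (non-binding), a [langmuir_params()] (fixed
#'   parameters) or a [salt_dependence()] (salt-dependent parameters).
#' @param is_salt `TRUE` for the modifier (NaCl) species; its stagnant-phase
#'   concentration drives the salt-dependent isotherms of the other species.
#'   The salt itself never binds.
#' @return object of class `species_def`.
#' @export
species_def <- function(name, keffA_1_s, isotherm = NULL, is_salt = FALSE) {
  stopifnot(is.character(name), keffA_1_s >= 0)
  if (is_salt && !is.null(isotherm)) stop("the salt species must be non-binding")
  if (!is.null(isotherm) &&
      !inherits(isotherm, "langmuir_params") && !inherits(isotherm, "salt_dependence"))
    stop("isotherm must be NULL, langmuir_params or salt_dependence")
  structure(list(name = name, keffA = keffA_1_s, isotherm = isotherm,
                 is_salt = is_salt), class = "species_def")
}

#' Numerical settings for the column solver
#'
#' @param N number of axial finite-volume cells (>= 20; default 400).
#' @param rtol,atol relative/absolute tolerances for the stiff integrator.
#' @param dt_out_s output sampling interval (s); default picks
#'   `min(max(T/2000, 0.05), 1)`.
#' @param correct_numerical_dispersion subtract the upwind scheme's numerical
#'   dispersion `v*dz/2` from the applied axial dispersion (default TRUE; see
#'   the methods vignette).
#' @export
solver_settings <- function(N = 400L, rtol = 1e-6, atol = 1e-8, dt_out_s = NULL,
                            correct_numerical_dispersion = TRUE) {
  stopifnot(N >= 20, rtol > 0, atol > 0)
  structure(list(N = as.integer(N), rtol = rtol, atol = atol,
                 dt_out_s = dt_out_s,
                 correct_numerical_dispersion = correct_numerical_dispersion),
            class = "solver_settings")
}

#' Piecewise flow/gradient program
#'
#' Each segment has a duration (seconds or column volumes), a flow rate, and
#' per-species inlet concentrations given either as a scalar (constant over
#' the segment) or length-2 vector (linear ramp from start to end, e.g. a
#' salt gradient). Species not named in a segment default to 0.
#'
#' @param segments list of segments; each a list with `duration_s` or
#'   `duration_cv`, `F_ml_min`, and `inlet` (named list of scalars or
#'   length-2 numeric vectors).
#' @param bed a [bed_geometry()] used to convert CV durations.
#' @return object of class `flow_program`.
#' @export
flow_program <- function(segments, bed) {
  stopifnot(is.list(segments), length(segments) >= 1, inherits(bed, "bed_geometry"))
  segs <- lapply(segments, function(s) {
    if (is.null(s$F_ml_min) || s$F_ml_min <= 0) stop("each segment needs F_ml_min > 0")
    if (!is.null(s$duration_s)) {
      dur <- s$duration_s
    } else if (!is.null(s$duration_cv)) {
      dur <- s$duration_cv * bed$V_ml / (s$F_ml_min / 60)
    } else stop("each segment needs duration_s or duration_cv")
    if (dur <= 0) stop("segment durations must be positive")
    inlet <- lapply(s$inlet %||% list(), function(x) {
      if (!length(x) %in% c(1, 2) || any(x < 0)) stop("inlet entries must be non-negative scalars or length-2 ramps")
      if (length(x) == 1) c(x, x) else as.numeric(x)
    })
    list(duration_s = dur, F_ml_min = s$F_ml_min, inlet = inlet)
  })
  structure(list(segments = segs, bed_V_ml = bed$V_ml), class = "flow_program")
}

#' Standard tracer-pulse program
#'
#' Rectangular injection of `V_inj_ml` at concentration `conc`, then buffer
#' for `total_cv` column volumes, at constant salt.
#'
#' @param bed a [bed_geometry()].
#' @param species tracer species name.
#' @param F_ml_min flow rate (mL/min).
#' @param V_inj_ml injection volume (mL; default 0.1 = 100 uL).
#' @param conc injected concentration (signal units).
#' @param salt_mM buffer salt concentration.
#' @param total_cv run length after injection in CV.
#' @export
tracer_program <- function(bed, species = "tracer", F_ml_min = 3,
                           V_inj_ml = 0.1, conc = 1, salt_mM = 20, total_cv = 3) {
  inj <- list(duration_s = V_inj_ml / (F_ml_min / 60), F_ml_min = F_ml_min,
              inlet = stats::setNames(list(conc, salt_mM), c(species, "salt")))
  hold <- list(duration_cv = total_cv, F_ml_min = F_ml_min,
               inlet = list(salt = salt_mM))
  flow_program(list(inj, hold), bed)
}

#' Standard bind-wash-gradient-hold elution program
#'
#' @param bed a [bed_geometry()].
#' @param load named vector of protein feed concentrations (mg/mL).
#' @param F_ml_min flow rate (mL/min).
#' @param V_inj_ml injection volume (mL).
#' @param wash_cv wash length (CV) at `salt_low_mM`.
#' @param grad_cv linear gradient length (CV) from `salt_low_mM` to
#'   `salt_high_mM`.
#' @param hold_cv high-salt hold after the gradient (CV).
#' @param salt_low_mM,salt_high_mM gradient endpoints (mM).
#' @export
bind_elute_program <- function(bed, load, F_ml_min = 3, V_inj_ml = 0.1,
                               wash_cv = 5, grad_cv = 7.5, hold_cv = 3,
                               salt_low_mM = 20, salt_high_mM = 500) {
  inj <- list(duration_s = V_inj_ml / (F_ml_min / 60), F_ml_min = F_ml_min,
              inlet = c(as.list(load), list(salt = salt_low_mM)))
  wash <- list(duration_cv = wash_cv, F_ml_min = F_ml_min,
               inlet = list(salt = salt_low_mM))
  grad <- list(duration_cv = grad_cv, F_ml_min = F_ml_min,
               inlet = list(salt = c(salt_low_mM, salt_high_mM)))
  hold <- list(duration_cv = hold_cv, F_ml_min = F_ml_min,
               inlet = list(salt = salt_high_mM))
  flow_program(list(inj, wash, grad, hold), bed)
}

# Build the piecewise-linear inlet table (times x species) for a program,
# with tiny double points at segment boundaries so steps stay sharp.
build_inlet_table <- function(program, species_names) {
  segs <- program$segments
  n <- length(species_names)
  t0 <- 0; times <- numeric(0); vals <- NULL
  for (s in segs) {
    v0 <- v1 <- stats::setNames(numeric(n), species_names)
    for (nm in names(s$inlet)) {
      if (!nm %in% species_names) stop("program references unknown species: ", nm)
      v0[nm] <- s$inlet[[nm]][1]; v1[nm] <- s$inlet[[nm]][2]
    }
    eps <- 1e-9
    times <- c(times, t0 + eps, t0 + s$duration_s)
    vals <- rbind(vals, v0, v1)
    t0 <- t0 + s$duration_s
  }
  list(t = times, C = unname(as.matrix(vals)), T_total = t0)
}

#' Simulate the lumped-pore column model
#'
#' Method-of-lines solution of the coupled mobile/stagnant transport
#' equations with Danckwerts boundary conditions, local-equilibrium
#' multi-component Langmuir binding (optionally salt dependent) and
#' piecewise flow/gradient programs. Integration uses a stiff-capable
#' adaptive solver (deSolve::lsoda) with a banded Jacobian.
#'
#' @param bed a [bed_geometry()].
#' @param species list of [species_def()]s; include exactly one with
#'   `is_salt = TRUE` if any isotherm is salt dependent.
#' @param program a [flow_program()].
#' @param settings a [solver_settings()].
#' @param system optional [system_model()]; split over inlet and outlet via
#'   [split_system()] so detector signals are comparable to measured ones.
#' @param init named vector of initial (equilibration buffer) concentrations;
#'   defaults to the first segment's inlet salt and zero for everything else.
#' @return object of class `column_sim`: `chrom` (data.frame `time_s` +
#'   species columns, detector-plane signal), `outlet` (column-plane matrix),
#'   `balance` (per-species injected/eluted/held-up masses, mg or mM*mL),
#'   final fields, and the inputs.
#' @export
simulate_column <- function(bed, species, program, settings = solver_settings(),
                            system = NULL, init = NULL) {
  stopifnot(inherits(bed, "bed_geometry"), inherits(program, "flow_program"),
            inherits(settings, "solver_settings"))
  if (!all(vapply(species, inherits, logical(1), "species_def")))
    stop("species must be a list of species_def objects")
  nms <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate species names")
  n <- length(species)
  salt_idx <- which(vapply(species, `[[`, logical(1), "is_salt"))
  if (length(salt_idx) > 1) stop("at most one salt species")
  has_saltdep <- any(vapply(species, function(s) inherits(s$isotherm, "salt_dependence"), logical(1)))
  if (has_saltdep && length(salt_idx) == 0)
    stop("salt-dependent isotherms require a species with is_salt = TRUE")

  N <- settings$N
  dz <- bed$L_cm / N
  segs <- program$segments
  seg_dur <- vapply(segs, `[[`, numeric(1), "duration_s")
  seg_t <- cumsum(c(0, seg_dur[-length(seg_dur)]))
  seg_F <- vapply(segs, `[[`, numeric(1), "F_ml_min")
  seg_v <- vapply(seg_F, function(f) interstitial_velocity(bed, f), numeric(1))
  T_total <- sum(seg_dur)

  # applied dispersion: alpha*v minus the upwind scheme's numerical dispersion
  seg_dax <- matrix(0, nrow = length(segs), ncol = n)
  for (k in seq_along(segs)) {
    D <- bed$alpha_cm * seg_v[k]
    if (settings$correct_numerical_dispersion) {
      Dn <- seg_v[k] * dz / 2
      if (Dn > D)
        warning("numerical dispersion exceeds physical dispersion; increase N")
      D <- max(D - Dn, 0)
    }
    seg_dax[k, ] <- D
  }

  inlet <- build_inlet_table(program, nms)
  # initial (equilibration buffer) composition; also the pre-run content of
  # the extra-column plant volume
  if (is.null(init)) {
    init <- stats::setNames(numeric(n), nms)
    if (length(salt_idx)) init[salt_idx] <- inlet$C[1, salt_idx]
  } else {
    full <- stats::setNames(numeric(n), nms)
    full[names(init)] <- init
    init <- full
  }
  sys_halves <- NULL
  if (!is.null(system)) {
    stopifnot(inherits(system, "system_model"))
    sys_halves <- split_system(system)
    # densify the inlet on a uniform grid, then disperse it through the
    # upstream plant half (constant-F programs only)
    if (length(unique(seg_F)) > 1)
      stop("system dispersion with varying flow rate is not supported")
    dt_in <- max(min(0.05, min(seg_dur) / 20), 1e-3)
    tg <- seq(0, T_total, by = dt_in)
    # area-preserving resampling of the piecewise-linear program onto the
    # uniform grid (cell averages via the exact cumulative integral)
    tu <- sort(unique(c(tg, pmin(pmax(inlet$t, 0), T_total))))
    Cg <- sapply(seq_len(n), function(i) {
      yu <- stats::approx(inlet$t, inlet$C[, i], xout = tu, rule = 2)$y
      cum <- pracma::cumtrapz(tu, yu)
      cg <- stats::approx(tu, cum, xout = tg)$y
      c(diff(cg) / diff(tg), yu[length(yu)])
    })
    Cg <- convolve_system(tg, Cg, sys_halves$inlet, seg_F[1], init = init)
    inlet <- list(t = tg, C = as.matrix(Cg), T_total = T_total)
  }

  iso_type <- integer(n); qmax_fix <- Keq_fix <- a1 <- a2 <- b1 <- b2 <- numeric(n)
  for (i in seq_len(n)) {
    iso <- species[[i]]$isotherm
    if (is.null(iso)) next
    if (inherits(iso, "langmuir_params")) {
      iso_type[i] <- 1L; qmax_fix[i] <- iso$q_max; Keq_fix[i] <- iso$K_eq
    } else {
      iso_type[i] <- 2L; a1[i] <- iso$a1; a2[i] <- iso$a2; b1[i] <- iso$b1; b2[i] <- iso$b2
    }
  }

  parms <- list(N = N, n = n, dz = dz, eps_b = bed$eps_b, eps_p = bed$eps_p,
                keffA = vapply(species, `[[`, numeric(1), "keffA"),
                iso_type = iso_type, qmax_fix = qmax_fix, Keq_fix = Keq_fix,
                a1 = a1, a2 = a2, b1 = b1, b2 = b2,
                salt_idx = if (length(salt_idx)) as.integer(salt_idx) else 0L,
                seg_t = seg_t, seg_v = seg_v, seg_dax = seg_dax,
                inlet_t = inlet$t, inlet_C = inlet$C)

  y0 <- rep(c(init, init), times = N)  # C then Cf per cell, buffer-equilibrated

  dt_out <- settings$dt_out_s %||% min(max(T_total / 2000, 0.05), 1)
  times <- seq(0, T_total, by = dt_out)
  rhs <- function(t, y, p) list(column_rhs_cpp(t, y, p))
  sol <- deSolve::lsoda(y = y0, times = times, func = rhs, parms = parms,
                        rtol = settings$rtol, atol = settings$atol,
                        jactype = "bandint", bandup = 2L * n, banddown = 2L * n)
  if (attr(sol, "istate")[1] < 0)
    stop("column integrator failed at t = ", max(sol[, 1]))
  tt <- sol[, 1]
  # outlet-plane mobile concentrations (last cell)
  out_cols <- 1 + (N - 1) * 2 * n + seq_len(n)
  outlet <- sol[, out_cols, drop = FALSE]
  colnames(outlet) <- nms
  neg <- min(outlet)
  if (neg < -50 * max(settings$atol, 1e-10) - 1e-6 * max(abs(outlet)))
    warning(sprintf("outlet undershoot %.3g; consider a finer grid", neg))

  detector <- outlet
  if (!is.null(sys_halves))
    detector <- convolve_system(tt, outlet, sys_halves$outlet, seg_F[1])

  # mass balance over the column proper (plant halves preserve area)
  inj_mass <- stats::setNames(numeric(n), nms)
  for (s in segs) {
    for (nm in names(s$inlet))
      inj_mass[nm] <- inj_mass[nm] +
        (s$F_ml_min / 60) * s$duration_s * mean(s$inlet[[nm]])
  }
  Fout <- vapply(tt, function(t) seg_F[max(which(seg_t <= t + 1e-12))] / 60, numeric(1))
  out_mass <- vapply(seq_len(n), function(i) pracma::trapz(tt, Fout * outlet[, i]), numeric(1))
  yT <- sol[nrow(sol), -1]
  hold <- numeric(n)
  csalt_vec <- if (length(salt_idx)) pmax(yT[(0:(N - 1)) * 2 * n + n + salt_idx], 0) else rep(0, N)
  for (i in seq_len(n)) {
    C <- yT[(0:(N - 1)) * 2 * n + i]
    Cf <- yT[(0:(N - 1)) * 2 * n + n + i]
    q <- numeric(N)
    if (iso_type[i] != 0) {
      for (k in seq_len(N)) {
        csalt <- csalt_vec[k]
        if (iso_type[i] == 1) { qm <- qmax_fix[i]; Ke <- Keq_fix[i] }
        else { qm <- max(a1[i] * csalt + a2[i], 0); Ke <- b1[i] * exp(-b2[i] * csalt) }
        S <- 1
        for (j in seq_len(n)) if (iso_type[j] != 0) {
          if (iso_type[j] == 1) Kj <- Keq_fix[j]
          else Kj <- b1[j] * exp(-b2[j] * csalt)
          S <- S + Kj * max(yT[(k - 1) * 2 * n + n + j], 0)
        }
        q[k] <- Ke * qm * max(Cf[k], 0) / S
      }
    }
    hold[i] <- dz * bed$A_col_cm2 *
      sum(bed$eps_b * C + (1 - bed$eps_b) * (bed$eps_p * Cf + (1 - bed$eps_p) * q))
  }
  # initial column inventory (buffer-equilibrated, q consistent with init salt)
  init_inv <- numeric(n)
  for (i in seq_len(n)) {
    c0 <- init[i]
    q0 <- 0
    if (iso_type[i] != 0 && c0 > 0) {
      cs0 <- if (length(salt_idx)) init[salt_idx] else 0
      if (iso_type[i] == 1) { qm <- qmax_fix[i]; Ke <- Keq_fix[i] }
      else { qm <- max(a1[i] * cs0 + a2[i], 0); Ke <- b1[i] * exp(-b2[i] * cs0) }
      q0 <- Ke * qm * c0 / (1 + Ke * c0)
    }
    init_inv[i] <- bed$V_ml *
      (bed$eps_b * c0 + (1 - bed$eps_b) * (bed$eps_p * c0 + (1 - bed$eps_p) * q0))
  }
  total_in <- unname(inj_mass) + init_inv
  balance <- data.frame(species = nms, injected = unname(inj_mass),
                        initial = init_inv, eluted = out_mass, held_up = hold,
                        closure = (out_mass + hold) / ifelse(total_in > 0, total_in, NA))

  chrom <- data.frame(time_s = tt, detector, check.names = FALSE)
  class(chrom) <- c("chromatogram", "data.frame")
  structure(list(chrom = chrom, outlet = outlet, time_s = tt, balance = balance,
                 bed = bed, species = species, program = program,
                 settings = settings, system = system, state_final = yT),
            class = "column_sim")
}

#' Summary statistics of a single-species peak
#'
#' @param time time vector (s).
#' @param conc concentration vector.
#' @param t_min optional lower bound restricting the analysis window (e.g. to
#'   the elution phase).
#' @return list with `t_max` (retention of peak maximum, s), `height`,
#'   `fwhm_s` (interpolated full width at half maximum), and the peak
#'   [peak_moments()].
#' @export
peak_stats <- function(time, conc, t_min = 0) {
  keep <- time >= t_min
  tt <- time[keep]; y <- conc[keep]
  if (max(y) <= 0) stop("no peak in the analysis window")
  i <- which.max(y)
  half <- y[i] / 2
  li <- max(which(y[1:i] <= half), 0)
  t_lo <- if (li == 0) tt[1] else
    tt[li] + (half - y[li]) / (y[li + 1] - y[li]) * (tt[li + 1] - tt[li])
  ri_rel <- which(y[i:length(y)] <= half)
  if (length(ri_rel) == 0) {
    t_hi <- tt[length(tt)]
  } else {
    ri <- i + ri_rel[1] - 1
    t_hi <- tt[ri - 1] + (half - y[ri - 1]) / (y[ri] - y[ri - 1]) * (tt[ri] - tt[ri - 1])
  }
  list(t_max = tt[i], height = y[i], fwhm_s = t_hi - t_lo,
       moments = peak_moments(tt, y, baseline = "none"))
}

#' Scan a solver parameter over a set of values
#'
#' Re-simulates the same bed/program for each value of the scanned parameter
#' and summarizes retention and peak width of one species. Currently
#' scannable: `"keffA"` (of a named species), `"grad_cv"` (gradient length of
#' a rebuilt bind-elute program) and `"F_ml_min"`.
#'
#' @param bed,species,program,settings,system as in [simulate_column()].
#' @param parameter one of `"keffA"`, `"grad_cv"`, `"F_ml_min"`.
#' @param values numeric vector of parameter values (non-empty).
#' @param target species name summarized (default: first binding species).
#' @param t_min analysis window start for [peak_stats()] (default: end of the
#'   wash, 0 if unknown).
#' @param ... for `"grad_cv"`: arguments forwarded to [bind_elute_program()].
#' @return list with `summary` (data.frame value, t_max, fwhm_s, sigma2) and
#'   `sims` (the column_sim objects).
#' @export
sensitivity_scan <- function(bed, species, program, parameter = "keffA", values,
                             target = NULL, settings = solver_settings(),
                             system = NULL, t_min = 0, ...) {
  if (length(values) == 0) stop("empty value list")
  if (is.null(target)) {
    bind <- vapply(species, function(s) !is.null(s$isotherm), logical(1))
    target <- vapply(species, `[[`, character(1), "name")[which(bind)[1]]
    if (is.na(target)) target <- species[[1]]$name
  }
  sims <- lapply(values, function(val) {
    sp <- species; pr <- program
    if (parameter == "keffA") {
      idx <- which(vapply(sp, `[[`, character(1), "name") == target)
      sp[[idx]]$keffA <- val
    } else if (parameter == "grad_cv") {
      pr <- bind_elute_program(bed, grad_cv = val, ...)
    } else if (parameter == "F_ml_min") {
      segs <- lapply(pr$segments, function(s) { s$F_ml_min <- val; s })
      pr <- structure(list(segments = segs, bed_V_ml = pr$bed_V_ml),
                      class = "flow_program")
    } else stop("parameter not scannable: ", parameter)
    simulate_column(bed, sp, pr, settings = settings, system = system)
  })
  summary <- do.call(rbind, lapply(seq_along(values), function(i) {
    st <- peak_stats(sims[[i]]$time_s, sims[[i]]$chrom[[target]], t_min = t_min)
    data.frame(value = values[i], t_max = st$t_max, fwhm_s = st$fwhm_s,
               sigma2 = st$moments$sigma2)
  }))
  list(summary = summary, sims = sims, target = target)
}

#' Analytic hold-up time of the lumped-pore model
#'
#' First moment of a non-binding pulse (injection excluded):
#' `t0 = (L/v) * (1 + ((1-eps_b)/eps_b) * (eps_p + (1-eps_p)*K))`, where `K`
#' is the linear-range slope `dq/dC` (0 for an inert tracer). A fully
#' pore-excluded tracer has `t0 = L/v`.
#'
#' @param bed a [bed_geometry()].
#' @param F_ml_min flow rate (mL/min).
#' @param K linear isotherm slope (default 0).
#' @param excluded if TRUE, the tracer does not enter the stagnant phase.
#' @export
holdup_time <- function(bed, F_ml_min, K = 0, excluded = FALSE) {
  v <- interstitial_velocity(bed, F_ml_min)
  if (excluded) return(bed$L_cm / v)
  phi <- (1 - bed$eps_b) / bed$eps_b
  (bed$L_cm / v) * (1 + phi * (bed$eps_p + (1 - bed$eps_p) * K))
}
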