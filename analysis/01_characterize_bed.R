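#!/usr/bin/env Rscript
# Step 1 — bed characterization from tracer and iSEC data.
#
# Generates synthetic iSEC accessible-fraction data and non-binding tracer
# pulses with the forward model, then runs the estimation workflow the other
# way: plateau fit -> (eps_T, eps_b, eps_p); moment analysis over several
# flow rates -> dispersivity alpha. Writes results/bed_characterization.csv
# and results/isec_curve.csv.

suppressPackageStartupMessages(library(porfiber))
seed <- 101
set.seed(seed)
dir.create("results", showWarnings = FALSE)

truth <- ground_truth()
bed <- truth$bed

## -- inverse SEC: two-plateau accessible-fraction curve ---------------------
isec <- gen_isec_curve(truth, seed = seed)
fit <- fit_isec(isec)
write.csv(isec, "results/isec_curve.csv", row.names = FALSE)
cat(sprintf("iSEC plateaus: eps_T = %.3f, eps_b = %.3f -> eps_p = %.3f (truth 0.760 / 0.540 / 0.478)\n",
            fit$eps_T, fit$eps_b, fit$eps_p))

## -- moment analysis of excluded tracer pulses at several flow rates --------
flows <- c(1, 2, 3, 5, 7)  # mL/min
pairs <- do.call(rbind, lapply(flows, function(Fm) {
  chrom <- gen_tracer_peak(truth, "excluded", F_ml_min = Fm, seed = seed + Fm,
                           settings = solver_settings(N = 400))
  pm <- peak_moments(chrom$time_s, chrom$excluded, baseline = "none")
  t_inj <- 0.1 / (Fm / 60)
  pmc <- correct_extra_column(pm, as_peak_moments(t_inj / 2, t_inj^2 / 12))
  v <- interstitial_velocity(bed, Fm)
  data.frame(F_ml_min = Fm, v_cm_s = v,
             mu_s = pmc$mu, sigma2_s2 = pmc$sigma2,
             Dax_cm2_s = dax_from_moments(pmc$sigma2, v, bed$L_cm))
}))
disp <- fit_dispersivity(pairs$v_cm_s, pairs$Dax_cm2_s)
cat(sprintf("dispersivity alpha = %.4f cm (configured %.3f cm), R^2 = %.4f\n",
            disp$alpha_cm, bed$alpha_cm, disp$r_squared))

out <- data.frame(parameter = c("eps_T", "eps_b", "eps_p", "alpha_cm"),
                  estimate = c(fit$eps_T, fit$eps_b, fit$eps_p, disp$alpha_cm),
                  truth = c(bed$eps_T, bed$eps_b, bed$eps_p, bed$alpha_cm),
                  method = c("iSEC plateau fit", "iSEC plateau fit",
                             "porosity identity", "moment analysis"))
write.csv(out, "results/bed_characterization.csv", row.names = FALSE)
write.csv(pairs, "results/dispersion_vs_velocity.csv", row.names = FALSE)
jsonlite::write_json(list(step = "01_characterize_bed", seed = seed,
                          package_version = as.character(packageVersion("porfiber"))),
                     "results/manifest_01.json", auto_unbox = TRUE)
cat("wrote results/bed_characterization.csv\n")
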