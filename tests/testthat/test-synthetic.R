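test_that("generators are deterministic under a fixed seed", {
  truth <- ref_truth()
  b1 <- gen_batch_dataset(truth, seed = 42)
  b2 <- gen_batch_dataset(truth, seed = 42)
  expect_identical(b1, b2)
  expect_false(identical(b1, gen_batch_dataset(truth, seed = 43)))

  i1 <- gen_isec_curve(truth, seed = 9)
  i2 <- gen_isec_curve(truth, seed = 9)
  expect_identical(i1, i2)

  t1 <- gen_tracer_peak(truth, seed = 5, settings = fast_settings(N = 60))
  t2 <- gen_tracer_peak(truth, seed = 5, settings = fast_settings(N = 60))
  expect_identical(t1$acetone, t2$acetone)
})

test_that("noise-free batch data lie exactly on the Langmuir surface", {
  truth <- ref_truth()
  truth$batch_rel_sd <- 0
  d <- gen_batch_dataset(truth, component = "mab", seed = 1)
  for (s in unique(d$salt_mM)) {
    sub <- d[d$salt_mM == s, ]
    fit <- fit_langmuir(sub)
    expect_gt(fit$r_squared, 1 - 1e-9)
    p_true <- eval_salt_dependence(truth$binding$mab, s)
    expect_rel(fit$params$q_max, p_true$q_max, 1e-3)
    expect_rel(fit$params$K_eq, p_true$K_eq, 1e-3)
  }
})

test_that("full recovery loop returns the salt-dependence truth within 10% at 2% noise", {
  truth <- ref_truth()
  sd_true <- truth$binding$mab
  est <- sapply(1:20, function(seed) {
    d <- gen_batch_dataset(truth, component = "mab", seed = seed)
    per_salt <- do.call(rbind, lapply(unique(d$salt_mM), function(s) {
      f <- fit_langmuir(d[d$salt_mM == s, ])
      data.frame(salt_mM = s, q_max = f$params$q_max, K_eq = f$params$K_eq)
    }))
    out <- fit_salt_dependence(per_salt)$sd
    c(out$a1, out$a2, out$b1, out$b2)
  })
  mean_est <- rowMeans(est)
  truth_vec <- c(sd_true$a1, sd_true$a2, sd_true$b1, sd_true$b2)
  expect_true(all(abs(mean_est - truth_vec) / abs(truth_vec) < 0.10))
})

test_that("the synthetic iSEC curve has the constructed plateaus", {
  truth <- ref_truth()
  rec <- gen_isec_curve(truth, seed = NULL, noise_sd = 0)
  expect_rel(rec$eps[which.min(rec$r_h_nm)], 0.76, 1e-3)
  expect_rel(rec$eps[which.max(rec$r_h_nm)], 0.54, 1e-3)
  expect_true(all(diff(rec$eps[order(rec$r_h_nm)]) <= 1e-9))
  # degenerate partition: cutoff far above the grid -> constant eps_T
  flat <- gen_isec_curve(truth, cutoff_nm = 1e6, seed = NULL, noise_sd = 0)
  expect_lt(max(abs(flat$eps - 0.76)), 1e-6)
})

test_that("broth elution conserves mass and orders the classes as constructed", {
  truth <- ref_truth()
  out <- gen_broth_elution(truth, grad_cv = 10, seed = NULL,
                           settings = fast_settings(N = 150))
  bal <- out$sim$balance
  for (cl in c("monomer", "aggregate", "lowmw"))
    expect_rel(bal$closure[bal$species == cl], 1, 1e-3)
  # fraction masses sum to the injected masses (fractions span the elution)
  fr <- out$fractions
  for (cl in c("monomer", "aggregate")) {
    injected <- bal$injected[bal$species == cl]
    expect_rel(sum(fr[[paste0("mass_", cl)]]), injected, 0.05)
  }
  # monomer and aggregate co-elute (centroids within a quarter peak width)
  st_m <- peak_stats(out$sim$time_s, out$sim$outlet[, "monomer"], t_min = 250)
  st_a <- peak_stats(out$sim$time_s, out$sim$outlet[, "aggregate"], t_min = 250)
  expect_lt(abs(st_m$t_max - st_a$t_max), st_m$fwhm_s / 4)
  # lowMW contaminants elute at higher salt than the mAb classes
  t_mono <- peak_stats(out$sim$time_s, out$sim$outlet[, "monomer"], t_min = 250)$t_max
  t_low <- peak_stats(out$sim$time_s, out$sim$outlet[, "lowmw"], t_min = 250)$t_max
  expect_gt(t_low, t_mono)
  # composite readouts are the weighted class concentrations
  expect_equal(out$composites$total_mab,
               out$composites$monomer + out$composites$aggregate, tolerance = 1e-12)
})

test_that("near-identical species elute at a nearly constant fraction ratio", {
  # the constant-ratio property requires matched transport as well as
  # near-identical binding: give the aggregate the monomer diffusivity
  truth <- ref_truth()
  truth$D_m["aggregate"] <- truth$D_m["monomer"]
  out <- gen_broth_elution(truth, grad_cv = 10, seed = NULL,
                           settings = fast_settings(N = 150))
  fr <- out$fractions
  main <- fr[fr$mass_monomer > 0.05 * max(fr$mass_monomer), ]
  ratio <- main$mass_monomer / main$mass_aggregate
  expect_lt(diff(range(ratio)) / mean(ratio), 0.15)
  # and the ratio reflects the injected composition
  expect_rel(mean(ratio), 2.0 / 0.2, 0.10)
})
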