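test_that("peak moments match closed forms for uniform, Gaussian and EMG peaks", {
  # rectangular pulse on [10, 20]: mu = 15, sigma2 = 100/12
  tt <- seq(0, 30, by = 5e-4)
  y <- as.numeric(tt >= 10 & tt <= 20)
  pm <- peak_moments(tt, y, baseline = "none", frac = 0)
  expect_rel(pm$mu, 15, 1e-6)
  # edge handling of the sampled discontinuity limits the rectangle to O(dt)
  expect_rel(pm$sigma2, 100 / 12, 3e-4)
  expect_rel(pm$area, 10, 1e-4)

  # Gaussian: mu = t0, sigma2 = s^2
  t0 <- 60; s <- 4
  tg <- seq(t0 - 10 * s, t0 + 10 * s, by = s / 200)
  g <- exp(-(tg - t0)^2 / (2 * s^2))
  pg <- peak_moments(tg, g, baseline = "none", frac = 0)
  expect_rel(pg$mu, t0, 1e-8)
  expect_rel(pg$sigma2, s^2, 1e-6)

  # translation invariance
  pg2 <- peak_moments(tg + 7, g, baseline = "none", frac = 0)
  expect_rel(pg2$mu, t0 + 7, 1e-8)
  expect_rel(pg2$sigma2, s^2, 1e-6)

  # exponentially modified Gaussian: mu = t0 + tau, sigma2 = s^2 + tau^2
  tau <- 6; lam <- 1 / tau
  te <- seq(0, 250, by = 0.01)
  emg <- lam / 2 * exp(lam / 2 * (2 * t0 + lam * s^2 - 2 * te)) *
    pracma::erfc((t0 + lam * s^2 - te) / (sqrt(2) * s))
  pe <- peak_moments(te, emg, baseline = "none", frac = 0)
  expect_rel(pe$mu, t0 + tau, 1e-6)
  expect_rel(pe$sigma2, s^2 + tau^2, 1e-4)

  expect_error(peak_moments(tt, rep(0, length(tt)), baseline = "none"),
               "identically zero")
})

test_that("a sloping baseline is removed before integration", {
  tt <- seq(0, 100, by = 0.02)
  peak <- 5 * exp(-(tt - 40)^2 / (2 * 3^2))
  drift <- 0.2 + 0.001 * tt
  pm <- peak_moments(tt, peak + drift, baseline = "linear")
  expect_rel(pm$mu, 40, 1e-3)
  expect_rel(pm$sigma2, 9, 0.02)
})

test_that("moment additivity under convolution justifies the extra-column correction", {
  # Gaussian convolved with a single mixing tank (CSTR): moments add
  t0 <- 50; s <- 3
  tt <- seq(0, 300, by = 0.02)
  g <- exp(-(tt - t0)^2 / (2 * s^2))
  model <- system_model(V_delay_ml = 0.2, V_mix_ml = 0.35, n_tanks = 2L)
  Fr <- 3
  out <- convolve_system(tt, g, model, Fr)
  pin <- peak_moments(tt, g, baseline = "none", frac = 0)
  pout <- peak_moments(tt, out, baseline = "none", frac = 0)
  sysm <- system_moments(model, Fr)
  expect_rel(pout$mu, pin$mu + sysm$mu, 1e-4)
  expect_rel(pout$sigma2, pin$sigma2 + sysm$sigma2, 5e-3)
  expect_rel(pout$area, pin$area, 1e-3)  # mass preserved

  # and correct_extra_column inverts the addition
  corr <- correct_extra_column(pout, sysm)
  expect_rel(corr$mu, pin$mu, 1e-4)
  expect_rel(corr$sigma2, pin$sigma2, 2e-2)
})

test_that("extra-column moment subtraction handles boundary cases", {
  obs <- as_peak_moments(60, 25); hplc <- as_peak_moments(10, 4)
  corr <- correct_extra_column(obs, hplc)
  expect_equal(c(corr$mu, corr$sigma2), c(50, 21))
  ident <- correct_extra_column(obs, as_peak_moments(0, 0))
  expect_equal(c(ident$mu, ident$sigma2), c(60, 25))
  zero <- correct_extra_column(obs, obs)
  expect_equal(c(zero$mu, zero$sigma2), c(0, 0))
  expect_error(correct_extra_column(hplc, obs), "negative")
})

test_that("accessible fraction and porosity identities hold", {
  # F = 1 mL/min, mu_p = 1.2 min, V = 2.36 mL -> eps ~ 0.508
  expect_rel(accessible_fraction(72, 1, 2.36), 1.2 / 2.36, 1e-12)
  # full access: mu_p = V/F -> eps = 1
  expect_equal(accessible_fraction(2.36 * 60, 1, 2.36), 1)
  expect_error(accessible_fraction(2.36 * 60 * 1.1, 1, 2.36), "1.05")

  expect_rel(porosity_from_voidages(0.76, 0.54), 0.22 / 0.46, 1e-12)
  expect_equal(round(porosity_from_voidages(0.76, 0.54), 2), 0.48)
  expect_equal(porosity_from_voidages(0.6, 0.6), 0)
  expect_equal(porosity_from_voidages(1, 0.5), 1)
  expect_error(porosity_from_voidages(0.5, 0.76), "eps_b <= eps_T")
})

test_that("axial dispersion and dispersivity estimators are consistent", {
  expect_rel(dax_from_moments(2, 0.1, 3), 2 * 0.001 / 6, 1e-12)
  expect_equal(dax_from_moments(4, 0.1, 3), 2 * dax_from_moments(2, 0.1, 3))

  v <- seq(0.05, 0.3, length.out = 6)
  fd <- fit_dispersivity(v, 0.051 * v)
  expect_rel(fd$alpha_cm, 0.051, 1e-12)
  expect_gt(fd$r_squared, 1 - 1e-12)
  expect_equal(fit_dispersivity(v, rep(0, 6))$alpha_cm, 0)
  expect_error(fit_dispersivity(0.1, 0.005), "2 velocities")

  # noisy line: slope recovered within 10% over 10 velocities
  set.seed(11)
  v10 <- seq(0.03, 0.3, length.out = 10)
  d10 <- 0.051 * v10 * (1 + rnorm(10, 0, 0.05))
  expect_rel(fit_dispersivity(v10, d10)$alpha_cm, 0.051, 0.10)
})

test_that("bed geometry validates volume and porosity ordering", {
  bed <- bed_geometry()
  expect_rel(bed$V_ml, 2.356, 1e-3)
  expect_rel(bed$eps_p, 0.4783, 1e-3)
  expect_error(bed_geometry(eps_T = 0.5, eps_b = 0.6), "ordering")
  expect_error(bed_geometry(V_ml = 2.5), "disagrees")
  expect_silent(bed_geometry(V_ml = 2.36))
})

test_that("iSEC plateau fit recovers the generator voidages", {
  truth <- ref_truth()
  rec <- gen_isec_curve(truth, seed = NULL, noise_sd = 0)
  fit <- fit_isec(rec)
  expect_rel(fit$eps_T, 0.76, 1e-4)
  expect_rel(fit$eps_b, 0.54, 1e-4)
  expect_rel(fit$eps_p, 0.22 / 0.46, 1e-3)

  noisy <- gen_isec_curve(truth, seed = 3)
  fitn <- fit_isec(noisy)
  expect_rel(fitn$eps_T, 0.76, 0.02)
  expect_rel(fitn$eps_b, 0.54, 0.02)
  expect_rel(fitn$eps_p, 0.478, 0.05)
})
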