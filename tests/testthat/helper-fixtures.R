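# Shared fixtures: the characterized fiber bed and generator ground truth.
ref_bed <- function() bed_geometry()
ref_truth <- function() ground_truth()

# Fast solver settings for unit tests; acceptance tests use the default N.
fast_settings <- function(N = 200L, ...) solver_settings(N = N, ...)

# Moments of a simulated tracer after removing the rectangular-injection
# contribution (mu = t_inj/2, sigma2 = t_inj^2/12).
tracer_moments_corrected <- function(chrom, species, F_ml_min = 3, V_inj_ml = 0.1) {
  pm <- peak_moments(chrom$time_s, chrom[[species]], baseline = "none")
  t_inj <- V_inj_ml / (F_ml_min / 60)
  correct_extra_column(pm, as_peak_moments(mu = t_inj / 2, sigma2 = t_inj^2 / 12))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
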