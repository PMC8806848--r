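test_that("profile evaluation matches the closed-form lineshapes", {
  g <- peak_profile("gaussian", 2, 960, 5)
  expect_equal(eval_profile(g, 960), 2)
  expect_equal(eval_profile(g, 965), 2 * exp(-0.5))
  l <- peak_profile("lorentzian", 2, 960, 5)
  expect_equal(eval_profile(l, 960), 2)
  # half maximum at x +/- sigma/2: sigma is the Lorentzian FWHM
  expect_equal(eval_profile(l, 962.5), 1)
  expect_equal(eval_profile(l, 957.5), 1)
})

test_that("analytic areas agree with numerical quadrature", {
  for (p in list(peak_profile("gaussian", 1, 0, 5),
                 peak_profile("lorentzian", 1, 0, 5),
                 peak_profile("gaussian", 2.7, 960, 3.1),
                 peak_profile("lorentzian", 0.4, 974, 8))) {
    # split at the apex so the quadrature never misses a narrow peak
    quad <- stats::integrate(function(v) eval_profile(p, v), -Inf, p$center,
                             rel.tol = 1e-10, subdivisions = 1000L)$value +
      stats::integrate(function(v) eval_profile(p, v), p$center, Inf,
                       rel.tol = 1e-10, subdivisions = 1000L)$value
    expect_equal(profile_area(p), quad, tolerance = 1e-6)
  }
  expect_equal(profile_area(peak_profile("gaussian", 1, 0, 5)),
               5 * sqrt(2 * pi))
  expect_equal(profile_area(peak_profile("lorentzian", 1, 0, 5)),
               5 * pi / 2)
  expect_equal(profile_area(peak_profile("gaussian", 0, 0, 5)), 0)
  expect_equal(profile_area(peak_profile("lorentzian", 0, 0, 5)), 0)
})

test_that("profile invariants are enforced", {
  expect_error(peak_profile("gaussian", -1, 960, 5), "amplitude")
  expect_error(peak_profile("gaussian", 1, 960, 0), "width")
})

test_that("a noiseless single Gaussian is recovered to high precision", {
  x <- seq(930, 990, by = 1)
  s <- raman_spectrum(x, eval_profile(peak_profile("gaussian", 1.5, 960, 6), x))
  fit <- fit_profiles(s, region(930, 990), n = 1, shape = "gaussian")
  p <- fit$profiles[[1]]
  expect_true(fit$converged)
  expect_equal(p$amplitude, 1.5, tolerance = 1e-4)
  expect_equal(p$center, 960, tolerance = 1e-4)
  expect_equal(p$width, 6, tolerance = 1e-4)
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("the overlapped anomeric doublet is resolved to sub-wavenumber accuracy", {
  s <- synth_spectrum(anomeric_cfg())
  fit <- fit_profiles(s, anomeric_region(), n = 2, shape = "gaussian")
  centers <- vapply(fit$profiles, `[[`, numeric(1), "center")
  expect_equal(centers[1], 960, tolerance = 0.5 / 960)
  expect_equal(centers[2], 974, tolerance = 0.5 / 974)
  expect_false(fit$close_centers)
  # evaluating the fitted model reproduces the generated input
  recon <- Reduce(`+`, lapply(fit$profiles, eval_profile,
                              grid = crop(s, anomeric_region())$wavenumbers))
  expect_lt(sqrt(mean((recon - crop(s, anomeric_region())$intensities)^2)),
            1e-6)
})

test_that("a mismatched lineshape fits Gaussian data worse", {
  s <- synth_spectrum(anomeric_cfg())
  fg <- fit_profiles(s, anomeric_region(), n = 2, shape = "gaussian")
  fl <- fit_profiles(s, anomeric_region(), n = 2, shape = "lorentzian")
  expect_gt(fl$residual_rms, fg$residual_rms)
})

test_that("fitting demands enough points for the parameter count", {
  s <- raman_spectrum(1:5, rep(1, 5))
  expect_error(fit_profiles(s, region(1, 5), n = 2), "at least 7")
})

test_that("model selection returns the smallest sufficient component count", {
  one <- generator_config(bands = single_band(960, "m"),
                          populations = c(alpha = 0.5, beta = 0.5),
                          baseline_coeffs = 0, noise_sd = 0)
  sel1 <- select_n_profiles(synth_spectrum(one), anomeric_region(),
                            "gaussian", n_max = 3, rel_tol = 0.01)
  expect_true(sel1$selected)
  expect_equal(sel1$n_selected, 1)

  sel2 <- select_n_profiles(synth_spectrum(anomeric_cfg()), anomeric_region(),
                            "gaussian", n_max = 4, rel_tol = 0.01)
  expect_true(sel2$selected)
  expect_equal(sel2$n_selected, 2)
})

test_that("pure noise is flagged as never satisfactorily fitted", {
  x <- seq(941, 992, by = 1)
  noise <- ramanomer:::with_local_seed(11, abs(rnorm(length(x), 0, 1)) + 0.5)
  sel <- select_n_profiles(raman_spectrum(x, noise), region(941, 992),
                           "gaussian", n_max = 3, rel_tol = 0.01)
  expect_false(sel$selected)
})

test_that("the fit is translation-equivariant", {
  delta <- 500
  x <- seq(930, 990, by = 1)
  y <- eval_profile(peak_profile("gaussian", 1, 955, 5), x) +
    eval_profile(peak_profile("gaussian", 0.5, 970, 5), x)
  f1 <- fit_profiles(raman_spectrum(x, y), region(930, 990), n = 2)
  f2 <- fit_profiles(raman_spectrum(x + delta, y),
                     region(930 + delta, 990 + delta), n = 2)
  c1 <- vapply(f1$profiles, `[[`, numeric(1), "center")
  c2 <- vapply(f2$profiles, `[[`, numeric(1), "center")
  expect_equal(c2, c1 + delta, tolerance = 1e-6)
})

test_that("centers stay within 1 cm^-1 under 1% apex noise across replicates", {
  worst <- 0
  for (seed in 1:100) {
    cfg <- anomeric_cfg(noise_sd = 0.01 * 0.5 * 0.655, seed = seed)
    s <- crop(synth_spectrum(cfg), anomeric_region())
    fit <- fit_profiles(s, anomeric_region(), n = 2, shape = "gaussian")
    centers <- vapply(fit$profiles, `[[`, numeric(1), "center")
    worst <- max(worst, abs(centers[1] - 960), abs(centers[2] - 974))
  }
  expect_lt(worst, 1)
})

test_that("fit tables expose one row per profile with analytic areas", {
  s <- synth_spectrum(anomeric_cfg())
  tab <- fit_table(fit_profiles(s, anomeric_region(), n = 2))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$area, tab$amplitude * tab$width * sqrt(2 * pi))
})
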