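test_that("the invariant bracket weights isotropic and anisotropic parts 45:7", {
  cfg <- excitation_config()
  base <- (cfg$omega_0 - 1000)^4 / (2 * 1000)
  expect_equal(cross_section(1000, alpha2 = 1, gamma2 = 0, cfg = cfg), base)
  expect_equal(cross_section(1000, alpha2 = 0, gamma2 = 1, cfg = cfg),
               base * 7 / 45)
})

test_that("cross-section scales with the fourth power of the Stokes shift", {
  # two excitation energies with (omega_0 - omega_v) in ratio 2 at fixed mode
  cfg1 <- excitation_config(omega_0 = 1000 + 5000)
  cfg2 <- excitation_config(omega_0 = 1000 + 10000)
  r <- cross_section(1000, 1, 1, cfg = cfg2) /
    cross_section(1000, 1, 1, cfg = cfg1)
  expect_equal(r, 16)
})

test_that("cross-section is linear in degeneracy and homogeneous in invariants", {
  expect_equal(cross_section(1000, 1, 2, g_v = 2) /
                 cross_section(1000, 1, 2, g_v = 1), 2)
  expect_equal(cross_section(1000, 3 * 1, 3 * 2),
               3 * cross_section(1000, 1, 2), tolerance = 1e-12)
})

test_that("anti-Stokes requests are rejected", {
  expect_error(cross_section(13000, 1, 1, cfg = excitation_config()),
               "omega_0")
})

test_that("absolute and proportional prefactors give proportional spectra", {
  m <- mode_table(c(960, 974), 1, c(1, 0.5), c(2, 1))
  prop <- cross_section(m$omega_v, m$alpha2, m$gamma2, m$g_v,
                        excitation_config())
  abso <- cross_section(m$omega_v, m$alpha2, m$gamma2, m$g_v,
                        excitation_config(prefactor = "absolute"))
  expect_equal(abso / prop, rep(abso[1] / prop[1], 2), tolerance = 1e-12)
})

test_that("broadening places a single mode's band at its frequency", {
  m <- mode_table(960, 1, 1, 0, label = "one")
  s <- broaden(m, width = 6, grid_lo = 900, grid_hi = 1020)
  expect_equal(s$wavenumbers[which.max(s$intensities)], 960)
})

test_that("broadening conserves total cross-section as area", {
  m <- mode_table(c(950, 960, 980), 1, c(1, 2, 0.5), c(0.5, 0, 3))
  sticks <- cross_section(m$omega_v, m$alpha2, m$gamma2, m$g_v)
  s <- broaden(m, width = 4, grid_lo = 700, grid_hi = 1300, grid_step = 0.5)
  expect_equal(ramanomer:::trapz_area(s$wavenumbers, s$intensities),
               sum(sticks), tolerance = 1e-3)
})

test_that("coincident identical modes double the intensity", {
  m1 <- mode_table(960, 1, 1, 1)
  m2 <- mode_table(c(960, 960), 1, c(1, 1), c(1, 1))
  s1 <- broaden(m1, grid_lo = 900, grid_hi = 1020)
  s2 <- broaden(m2, grid_lo = 900, grid_hi = 1020)
  expect_equal(s2$intensities, 2 * s1$intensities, tolerance = 1e-12)
})

test_that("mode tables round-trip through delimited text", {
  m <- mode_table(c(956, 971, 984), c(1L, 2L, 1L), c(0.1, 0.2, 0.3),
                  c(1, 0, 0.5), label = "synthetic_alpha")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  r <- read_mode_table(path, label = "synthetic_alpha")
  expect_equal(r$omega_v, m$omega_v)
  expect_equal(r$gamma2, m$gamma2)
  expect_error(read_mode_table(withr::local_tempfile(lines = "a,b\n1,2")),
               "lacks columns")
})

test_that("anomer weighting is a convex combination of the two spectra", {
  ma <- mode_table(960, 1, 1, 0)
  mb <- mode_table(974, 1, 1, 0)
  sa <- broaden(ma, grid_lo = 900, grid_hi = 1020)
  sb <- broaden(mb, grid_lo = 900, grid_hi = 1020)
  expect_equal(combine_anomers(sa, sb, c(alpha = 1, beta = 0))$intensities,
               sa$intensities)
  expect_equal(combine_anomers(sa, sa, c(alpha = 0.5, beta = 0.5))$intensities,
               sa$intensities)
  mix <- combine_anomers(sa, sb, anomer_fractions(0.655, 0.345))
  area <- function(s) ramanomer:::trapz_area(s$wavenumbers, s$intensities)
  expect_equal(area(mix), 0.655 * area(sa) + 0.345 * area(sb),
               tolerance = 1e-9)
})

test_that("summed cross-section ratios pass through anomer weighting exactly", {
  # alpha and beta structures whose mode-for-mode invariants are in ratio
  # r: the summed cross-sections, and hence the computed intensity ratio,
  # must be in ratio r exactly
  r <- 61.1 / 38.9
  mb <- mode_table(c(956, 971), 1, c(0.3, 0.7), c(0.2, 0.1))
  ma <- mode_table(c(956, 971), 1, r * c(0.3, 0.7), r * c(0.2, 0.1))
  cs <- function(m) sum(cross_section(m$omega_v, m$alpha2, m$gamma2, m$g_v))
  expect_equal(cs(ma) / cs(mb), r, tolerance = 1e-12)
  sa <- broaden(ma, grid_lo = 900, grid_hi = 1020)
  sb <- broaden(mb, grid_lo = 900, grid_hi = 1020)
  expect_equal(max(sa$intensities) / max(sb$intensities), r,
               tolerance = 1e-12)
})

test_that("hydration stoichiometry matches round-number expectations", {
  expect_identical(waters_for_dm(0.30), 23L)
  expect_identical(waters_for_dm(1.0), 0L)
  expect_identical(waters_for_dm(0.5), 10L)
  expect_error(waters_for_dm(0), "dm")
  expect_error(waters_for_dm(1.2), "dm")
  # monotone non-increasing in dm
  counts <- vapply(seq(0.05, 1, by = 0.05), waters_for_dm, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the 3n-6 mode count is enforced for nonlinear molecules", {
  expect_identical(count_normal_modes(3), 3L)
  expect_identical(count_normal_modes(24), 66L)
  expect_identical(count_normal_modes(93), 273L)
  expect_error(count_normal_modes(2), "n >= 3")
})

test_that("band matching is greedy, tolerance-bounded and single-use", {
  m <- match_bands(computed_frequencies("mannose_alpha"), 960, tol = 10)
  expect_equal(m$computed, 956)
  expect_equal(m$delta, 4)

  self <- match_bands(c(941, 960, 974), c(941, 960, 974), tol = 0.1)
  expect_equal(self$computed, self$experimental)
  expect_true(all(self$delta == 0))

  far <- match_bands(computed_frequencies("glucose"), 960, tol = 5)
  expect_true(is.na(far$computed))

  # two bands competing for one computed frequency: only the closer wins
  comp <- match_bands(c(961), c(960, 962.5), tol = 5)
  expect_equal(comp$computed, c(961, NA))
})

test_that("region filtering keeps closed-interval frequencies in order", {
  expect_equal(region_filter(computed_frequencies("glucose"),
                             region(941, 992)),
               c(969, 986))
  expect_length(region_filter(993, region(941, 992)), 0)
  expect_length(region_filter(numeric(0), region(941, 992)), 0)
  expect_equal(region_filter(computed_frequencies("mannose_beta"),
                             region(941, 992)),
               c(941, 950, 965, 968, 978, 988, 991))
})
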