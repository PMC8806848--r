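# Fixture builders shared across the suite. All synthetic: nothing is read
# from disk except files the tests themselves write.

# config with only the two D-mannose anomeric marker bands (960 alpha /
# 974 beta), flat zero baseline unless asked otherwise
anomeric_cfg <- function(populations = c(alpha = 0.655, beta = 0.345),
                         noise_sd = 0, baseline_coeffs = 0, seed = 1L,
                         widths = 6, shape = "gaussian",
                         grid_lo = 100, grid_hi = 3000, grid_step = 1) {
  generator_config(bands = anomeric_bands(), populations = populations,
                   widths = widths, shape = shape,
                   baseline_coeffs = baseline_coeffs, noise_sd = noise_sd,
                   grid_lo = grid_lo, grid_hi = grid_hi,
                   grid_step = grid_step, seed = seed)
}

# a single-band table for one-component fixtures
single_band <- function(center = 960, strength = "s") {
  data.frame(center = center, strength = strength, assignment = "nu(CO)",
             species = "mannose", anomer = "none")
}

anomeric_region <- function() region(941, 992)
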