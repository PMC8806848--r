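#' Synthetic-spectrum generator configuration
#'
#' Describes a pure aqueous solution of one solute the way the analysis
#' assumes the measurement behaves: a sum of Gaussian or Lorentzian bands
#' at the reference band-table positions, with each band's amplitude equal
#' to its strength weight times the population of its anomer tag, sitting
#' on a smooth polynomial baseline, with additive i.i.d. Gaussian noise.
#'
#' Defaults encode the study conditions: the aqueous D-mannose anomeric
#' equilibrium (alpha 65.5%, beta 34.5%, from NMR), strength weights
#' s/m/w = 1.0/0.5/0.2, band width sigma = 6 cm^-1, a 100-3000 cm^-1 grid
#' at 1 cm^-1 steps, and a gentle quadratic baseline.
#'
#' @param bands A band table (see [band_table()]).
#' @param populations Named fractions `c(alpha=, beta=)` summing to 1;
#'   bands tagged `"none"` get weight 1.
#' @param widths Band width sigma in cm^-1 (Gaussian standard deviation, or
#'   Lorentzian FWHM); scalar or one per band.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @param strength_weights Named amplitudes for the s/m/w labels.
#' @param baseline_coeffs Polynomial coefficients (constant first) in the
#'   scaled coordinate `u = (v - lo)/(hi - lo)` over the grid, so the
#'   baseline amplitude is grid-independent.
#' @param noise_sd Standard deviation of additive Gaussian noise (a.u.).
#' @param grid_lo,grid_hi,grid_step Wavenumber grid in cm^-1.
#' @param seed Integer seed; identical configs give bit-identical spectra.
#' @param label Free-form label stored in spectrum metadata.
#' @return A `generator_config` list.
#' @export
generator_config <- function(bands = band_table("mannose"),
                             populations = c(alpha = 0.655, beta = 0.345),
                             widths = 6,
                             shape = c("gaussian", "lorentzian"),
                             strength_weights = c(s = 1.0, m = 0.5, w = 0.2),
                             baseline_coeffs = c(0.05, 0.04, -0.03),
                             noise_sd = 0,
                             grid_lo = 100, grid_hi = 3000, grid_step = 1,
                             seed = 1L,
                             label = NULL) {
  shape <- match.arg(shape)
  bands <- validate_band_table(bands)
  if (!all(c("alpha", "beta") %in% names(populations))) {
    stop("populations must be named with 'alpha' and 'beta'")
  }
  if (abs(sum(populations) - 1) > 1e-12) {
    stop("populations must sum to 1")
  }
  if (any(populations < 0)) stop("populations must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (grid_step <= 0) stop("grid_step must be > 0")
  if (grid_lo >= grid_hi) stop("grid_lo must be < grid_hi")
  if (length(widths) == 1L) widths <- rep(widths, nrow(bands))
  if (length(widths) != nrow(bands)) {
    stop("widths must be scalar or one per band")
  }
  if (any(widths <= 0)) stop("widths must be > 0")
  if (!all(c("s", "m", "w") %in% names(strength_weights))) {
    stop("strength_weights must name 's', 'm', 'w'")
  }
  structure(
    list(bands = bands, populations = populations, widths = widths,
         shape = shape, strength_weights = strength_weights,
         baseline_coeffs = as.numeric(baseline_coeffs),
         noise_sd = noise_sd,
         grid_lo = grid_lo, grid_hi = grid_hi, grid_step = grid_step,
         seed = as.integer(seed), label = label),
    class = "generator_config"
  )
}

config_grid <- function(cfg) {
  seq(cfg$grid_lo, cfg$grid_hi, by = cfg$grid_step)
}

# one row per band kept on the grid: amplitude, center, width, shape
config_profiles <- function(cfg, warn_skipped = TRUE) {
  bands <- cfg$bands
  keep <- bands$center >= cfg$grid_lo & bands$center <= cfg$grid_hi
  if (warn_skipped && any(!keep)) {
    warning(sprintf("%d band(s) outside the grid were skipped", sum(!keep)))
  }
  bands <- bands[keep, , drop = FALSE]
  widths <- cfg$widths[keep]
  pop <- ifelse(bands$anomer == "none", 1,
                unname(cfg$populations[bands$anomer]))
  amp <- unname(cfg$strength_weights[bands$strength]) * pop
  data.frame(shape = cfg$shape, amplitude = amp, center = bands$center,
             width = widths, species = bands$species,
             stringsAsFactors = FALSE)
}

sum_profiles <- function(profiles, grid) {
  total <- numeric(length(grid))
  for (i in seq_len(nrow(profiles))) {
    total <- total + eval_profile(
      peak_profile(profiles$shape[i], profiles$amplitude[i],
                   profiles$center[i], profiles$width[i]),
      grid)
  }
  total
}

baseline_values <- function(cfg, grid) {
  u <- (grid - cfg$grid_lo) / (cfg$grid_hi - cfg$grid_lo)
  drop(outer(u, seq_along(cfg$baseline_coeffs) - 1, `^`) %*%
         cfg$baseline_coeffs)
}

# evaluate expr with a local RNG stream; global .Random.seed untouched
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic pure-solution spectrum
#'
#' Intensities are the sum over bands of the configured lineshape with
#' amplitude = strength weight x anomer population, plus the polynomial
#' baseline, plus seeded zero-mean Gaussian noise. The same config yields
#' bit-identical spectra.
#'
#' @param cfg A [generator_config()].
#' @return A [raman_spectrum] with generator provenance in `meta`.
#' @export
synth_spectrum <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  grid <- config_grid(cfg)
  profiles <- config_profiles(cfg)
  signal <- sum_profiles(profiles, grid) + baseline_values(cfg, grid)
  if (cfg$noise_sd > 0) {
    signal <- signal + with_local_seed(cfg$seed,
                                       rnorm(length(grid), 0, cfg$noise_sd))
  }
  raman_spectrum(grid, signal,
                 meta = list(generator = "synth_spectrum", seed = cfg$seed,
                             label = cfg$label))
}

#' Generate a synthetic two-solute mixture spectrum
#'
#' Emulates a two-sugar aqueous mixture at fixed dry matter: each solute's
#' band amplitudes are scaled by its mass fraction of the dry matter times
#' `dm`; solvent (species `"water"`) bands are taken once, from `cfg_a`,
#' scaled by `1 - dm`; the baseline and seeded noise of `cfg_a` are added
#' once. Both configs must share the same grid.
#'
#' @param cfg_a,cfg_b [generator_config()]s for the two solutes.
#' @param frac_a Mass fraction of solute A in the dry matter, in `[0, 1]`.
#' @param dm Dry-matter mass fraction of the solution (default 0.30).
#' @return A [raman_spectrum].
#' @export
synth_mixture <- function(cfg_a, cfg_b, frac_a, dm = 0.30) {
  stopifnot(inherits(cfg_a, "generator_config"),
            inherits(cfg_b, "generator_config"))
  if (frac_a < 0 || frac_a > 1) stop("frac_a must be in [0, 1]")
  if (dm <= 0 || dm > 1) stop("dm must be in (0, 1]")
  if (cfg_a$grid_lo != cfg_b$grid_lo || cfg_a$grid_hi != cfg_b$grid_hi ||
      cfg_a$grid_step != cfg_b$grid_step) {
    stop("mismatched grids between mixture components")
  }
  grid <- config_grid(cfg_a)
  pa <- config_profiles(cfg_a)
  pb <- config_profiles(cfg_b)
  water_a <- pa$species == "water"
  pa$amplitude[!water_a] <- pa$amplitude[!water_a] * frac_a * dm
  pa$amplitude[water_a] <- pa$amplitude[water_a] * (1 - dm)
  pb <- pb[pb$species != "water", , drop = FALSE]
  pb$amplitude <- pb$amplitude * (1 - frac_a) * dm
  signal <- sum_profiles(pa, grid) + sum_profiles(pb, grid) +
    baseline_values(cfg_a, grid)
  if (cfg_a$noise_sd > 0) {
    signal <- signal + with_local_seed(cfg_a$seed,
                                       rnorm(length(grid), 0, cfg_a$noise_sd))
  }
  raman_spectrum(grid, signal,
                 meta = list(generator = "synth_mixture", frac_a = frac_a,
                             dm = dm, seed = cfg_a$seed))
}

#' Generate a calibration series of mixture spectra
#'
#' One mixture spectrum per solute-A fraction, with per-spectrum noise
#' seeds derived deterministically as `cfg_a$seed + index - 1`.
#'
#' @param fracs Fractions of solute A in the dry matter, each in `[0, 1]`.
#' @param cfg_a,cfg_b Component configs, as in [synth_mixture()].
#' @param dm Dry-matter fraction.
#' @return A list with one element per fraction, each a list
#'   `(frac, spectrum)`.
#' @export
synth_calibration_series <- function(fracs, cfg_a, cfg_b, dm = 0.30) {
  if (length(fracs) == 0L) stop("fracs must be non-empty")
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  lapply(seq_along(fracs), function(i) {
    cfg_i <- cfg_a
    cfg_i$seed <- cfg_a$seed + i - 1L
    list(frac = fracs[i],
         spectrum = synth_mixture(cfg_i, cfg_b, frac_a = fracs[i], dm = dm))
  })
}
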