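#' Construct a computed vibrational mode table
#'
#' One row per normal mode of a (hydrated) structure: harmonic frequency
#' `omega_v` (cm^-1), degeneracy `g_v`, and the rotational invariants of
#' the polarizability derivative along the mode — the isotropic part
#' `alpha2` (alpha'^2) and the anisotropy `gamma2` (gamma'^2) — which
#' together determine the Raman scattering strength.
#'
#' @param omega_v Mode frequencies in cm^-1, > 0.
#' @param g_v Integer degeneracies >= 1 (default 1).
#' @param alpha2,gamma2 Non-negative polarizability-derivative invariants.
#' @param label Structure name, e.g. `"mannose_alpha"`.
#' @return A data.frame of class `mode_table` with attribute `label`.
#' @export
mode_table <- function(omega_v, g_v = 1L, alpha2, gamma2, label = "") {
  n <- length(omega_v)
  if (n == 0L) stop("mode table must contain at least one mode")
  g_v <- rep_len(as.integer(g_v), n)
  if (any(omega_v <= 0)) stop("omega_v must be > 0")
  if (any(g_v < 1L)) stop("g_v must be >= 1")
  if (any(alpha2 < 0) || any(gamma2 < 0)) {
    stop("polarizability invariants must be >= 0")
  }
  out <- data.frame(omega_v = as.numeric(omega_v), g_v = g_v,
                    alpha2 = as.numeric(alpha2),
                    gamma2 = as.numeric(gamma2))
  attr(out, "label") <- label
  class(out) <- c("mode_table", "data.frame")
  out
}

#' Read a mode table from delimited text
#'
#' Expects a header with columns `omega_v`, `g_v`, `alpha2`, `gamma2`
#' (comma- or tab-separated, auto-detected).
#'
#' @param path File path.
#' @param label Structure label; defaults to the file name.
#' @return A [mode_table()].
#' @export
read_mode_table <- function(path, label = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  needed <- c("omega_v", "g_v", "alpha2", "gamma2")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("mode table file lacks columns: ", paste(missing, collapse = ", "))
  }
  mode_table(df$omega_v, df$g_v, df$alpha2, df$gamma2,
             label = label %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Excitation configuration for cross-section conversion
#'
#' @param omega_0 Excitation wavenumber in cm^-1. The default corresponds
#'   to a 785 nm probe laser (1e7 / 785 ~ 12739 cm^-1).
#' @param prefactor `"proportional"` (default) sets the physical constant
#'   in front of the cross-section to 1: relative spectra, normalized
#'   spectra and intensity ratios — everything the analysis uses — are
#'   unchanged. `"absolute"` multiplies by the standard
#'   `h / (8 pi^2 c omega_v)`-type prefactor with SI constants
#'   (wavenumbers converted to m^-1), giving values on a physical
#'   cross-section scale.
#' @return An `excitation_config` list.
#' @export
excitation_config <- function(omega_0 = 1e7 / 785,
                              prefactor = c("proportional", "absolute")) {
  prefactor <- match.arg(prefactor)
  if (omega_0 <= 0) stop("omega_0 must be > 0")
  structure(list(omega_0 = omega_0, prefactor = prefactor),
            class = "excitation_config")
}

#' Raman backscattering cross-section of a vibrational mode
#'
#' Differential cross-section for unpolarized 180-degree collection,
#' proportional to
#' \deqn{(\omega_0 - \omega_v)^4 \; \frac{g_v}{2\,\omega_v} \;
#'       \frac{45\,\alpha'^2 + 7\,\gamma'^2}{45}}
#' Only Stokes scattering is modeled, so the excitation must lie above
#' the mode frequency. Homogeneous of degree 1 in `(alpha2, gamma2)`
#' jointly and exactly linear in the degeneracy.
#'
#' @param omega_v Mode frequency (cm^-1); vectorized.
#' @param alpha2,gamma2 Polarizability-derivative invariants.
#' @param g_v Degeneracy (default 1).
#' @param cfg An [excitation_config()].
#' @return Cross-section values (a.u. in proportional mode, m^2/sr-scale
#'   in absolute mode).
#' @export
cross_section <- function(omega_v, alpha2, gamma2, g_v = 1L,
                          cfg = excitation_config()) {
  if (any(cfg$omega_0 <= omega_v)) {
    stop("excitation omega_0 must exceed every mode frequency (Stokes only)")
  }
  val <- (cfg$omega_0 - omega_v)^4 * g_v / (2 * omega_v) *
    (45 * alpha2 + 7 * gamma2) / 45
  if (cfg$prefactor == "absolute") {
    h <- 6.62607015e-34   # J s
    c0 <- 2.99792458e8    # m/s
    # wavenumbers enter in m^-1; the (omega_0-omega_v)^4 factor above is
    # in cm^-4, so rescale by 100^4 for the quartic and 100 for omega_v
    val <- val * 100^4 / 100 * h / (8 * pi^2 * c0)
  }
  val
}

#' Broaden a mode table into a continuous spectrum
#'
#' Places each mode's cross-section as a stick at `omega_v` and convolves
#' with a unit-area Gaussian or Lorentzian of the given width, so each
#' mode contributes a band whose integrated area equals its cross-section.
#' Optionally normalizes the result the same way experimental spectra
#' are normalized.
#'
#' @param modes A [mode_table()].
#' @param cfg An [excitation_config()].
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @param width Band width sigma in cm^-1 (Gaussian sd / Lorentzian FWHM).
#' @param grid_lo,grid_hi,grid_step Output wavenumber grid.
#' @param normalize `"none"` (default), `"max"` or `"area"`, applied over
#'   the full output grid via [normalize_spectrum()].
#' @return A [raman_spectrum] of the broadened computed intensities.
#' @export
broaden <- function(modes, cfg = excitation_config(),
                    shape = c("gaussian", "lorentzian"), width = 6,
                    grid_lo = 100, grid_hi = 3000, grid_step = 1,
                    normalize = c("none", "max", "area")) {
  shape <- match.arg(shape)
  normalize <- match.arg(normalize)
  if (!inherits(modes, "mode_table") || nrow(modes) == 0L) {
    stop("modes must be a non-empty mode_table")
  }
  if (width <= 0) stop("width must be > 0")
  grid <- seq(grid_lo, grid_hi, by = grid_step)
  sticks <- cross_section(modes$omega_v, modes$alpha2, modes$gamma2,
                          modes$g_v, cfg)
  unit_area <- if (shape == "gaussian") width * sqrt(2 * pi) else width * pi / 2
  total <- numeric(length(grid))
  for (i in seq_len(nrow(modes))) {
    p <- peak_profile(shape, amplitude = sticks[i] / unit_area,
                      center = modes$omega_v[i], width = width)
    total <- total + eval_profile(p, grid)
  }
  out <- raman_spectrum(grid, total,
                        meta = list(kind = "computed",
                                    label = attr(modes, "label"),
                                    omega_0 = cfg$omega_0))
  if (normalize != "none") out <- normalize_spectrum(out, mode = normalize)
  out
}

#' Population-weighted combination of anomer spectra
#'
#' Weights the computed spectrum of each anomeric structure by its
#' solution population (e.g. the NMR-determined alpha/beta pyranose
#' fractions) and sums.
#'
#' @param spec_alpha,spec_beta [raman_spectrum]s on identical grids.
#' @param pops An `anomer_composition` (see [anomer_fractions()]) or a
#'   named vector `c(alpha=, beta=)`.
#' @return The weighted-sum [raman_spectrum].
#' @export
combine_anomers <- function(spec_alpha, spec_beta, pops) {
  stop_grid_mismatch(spec_alpha, spec_beta)
  if (inherits(pops, "anomer_composition")) pops <- unlist(pops)
  if (!all(c("alpha", "beta") %in% names(pops))) {
    stop("pops must provide 'alpha' and 'beta' weights")
  }
  raman_spectrum(spec_alpha$wavenumbers,
                 pops[["alpha"]] * spec_alpha$intensities +
                   pops[["beta"]] * spec_beta$intensities,
                 meta = list(kind = "anomer_weighted",
                             alpha = pops[["alpha"]], beta = pops[["beta"]]))
}

#' Hydration-shell size at a given dry-matter fraction
#'
#' Number of water molecules accompanying one solute molecule when the
#' solution is at dry-matter mass fraction `dm`:
#' `round(m_solute (1 - dm) / dm / m_water)`. At 30% DM a hexose
#' (180.16 g/mol) carries 23 waters.
#'
#' @param dm Dry-matter mass fraction, in (0, 1].
#' @param m_solute Solute molar mass (g/mol); default a hexose.
#' @param m_water Water molar mass (g/mol).
#' @return Integer water count.
#' @export
waters_for_dm <- function(dm, m_solute = 180.16, m_water = 18.015) {
  if (dm <= 0 || dm > 1) stop("dm must be in (0, 1]")
  as.integer(round(m_solute * (1 - dm) / dm / m_water))
}

#' Number of vibrational normal modes of a nonlinear molecule
#'
#' The 3n - 6 rule.
#'
#' @param n_atoms Atom count, >= 3.
#' @return Integer mode count.
#' @export
count_normal_modes <- function(n_atoms) {
  if (any(n_atoms < 3)) stop("3n - 6 applies to nonlinear molecules (n >= 3)")
  as.integer(3 * n_atoms - 6)
}

#' Match computed frequencies to experimental bands
#'
#' Greedy nearest-distance assignment: pairs are considered in ascending
#' absolute difference, each computed frequency is used at most once, and
#' a band is matched only if the difference is within `tol` (default
#' 10 cm^-1, the typical harmonic-DFT error scale). Unmatched bands get
#' `NA`.
#'
#' @param computed Numeric computed frequencies (cm^-1).
#' @param experimental A band table (see [band_table()]) or numeric
#'   centers.
#' @param tol Match tolerance in cm^-1, > 0.
#' @return A data.frame: `experimental` (band center), `computed`
#'   (matched frequency or NA), `delta` (absolute difference or NA).
#' @export
match_bands <- function(computed, experimental, tol = 10) {
  if (tol <= 0) stop("tol must be > 0")
  centers <- if (is.data.frame(experimental)) experimental$center
             else as.numeric(experimental)
  out <- data.frame(experimental = centers,
                    computed = NA_real_, delta = NA_real_)
  if (length(computed) == 0L || length(centers) == 0L) return(out)
  pairs <- expand.grid(e = seq_along(centers), c = seq_along(computed))
  pairs$delta <- abs(centers[pairs$e] - computed[pairs$c])
  pairs <- pairs[pairs$delta <= tol, , drop = FALSE]
  pairs <- pairs[order(pairs$delta), , drop = FALSE]
  used_e <- logical(length(centers))
  used_c <- logical(length(computed))
  for (k in seq_len(nrow(pairs))) {
    e <- pairs$e[k]; cc <- pairs$c[k]
    if (used_e[e] || used_c[cc]) next
    used_e[e] <- TRUE; used_c[cc] <- TRUE
    out$computed[e] <- computed[cc]
    out$delta[e] <- pairs$delta[k]
  }
  out
}

#' Keep frequencies inside a wavenumber region
#'
#' Closed-interval filter, order preserved.
#'
#' @param frequencies Numeric cm^-1 values.
#' @param reg A [region] (or `c(lo, hi)`).
#' @return The retained frequencies.
#' @export
region_filter <- function(frequencies, reg) {
  reg <- as_region(reg)
  frequencies[frequencies >= reg[["lo"]] & frequencies <= reg[["hi"]]]
}

#' Computed anomeric-region frequencies for hydrated sugar structures
#'
#' Harmonic frequencies near the 900-1000 cm^-1 anomeric window from
#' DFT vibrational analysis of hydrated (23-water shell, 30% DM)
#' pyranose structures: alpha-D-mannose shows four modes, beta-D-mannose
#' seven, and D-glucose only two weak modes in the 941-992 cm^-1 window
#' (one per anomer) — the basis for attributing the 960/974 cm^-1 pair
#' to D-mannose alone.
#'
#' @param structure One of `"mannose_alpha"`, `"mannose_beta"`,
#'   `"glucose"`.
#' @return Numeric frequencies in cm^-1.
#' @export
computed_frequencies <- function(structure = c("mannose_alpha",
                                               "mannose_beta", "glucose")) {
  structure <- match.arg(structure)
  switch(structure,
    mannose_alpha = c(956, 971, 984, 993),
    mannose_beta = c(941, 950, 965, 968, 978, 988, 991),
    glucose = c(969, 986))
}
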