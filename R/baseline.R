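#' Baseline-estimation parameters
#'
#' Controls the asymmetric penalized least-squares (Whittaker-type)
#' baseline estimator: the smoother minimizes
#' `sum w_i (y_i - z_i)^2 + smoothness * sum (diff(z, 2))^2`, with weights
#' updated so points above the current baseline (peaks) get weight
#' `asymmetry` and points at or below it get `1 - asymmetry`.
#'
#' @param smoothness Second-difference penalty weight (> 0). Larger values
#'   give stiffer baselines; 1e5 suits cm^-1-gridded Raman spectra.
#' @param asymmetry Weight given to points above the baseline, in (0, 1).
#'   Small values (0.01) let peaks float above the estimate.
#' @param max_iter Maximum reweighting iterations.
#' @param tol Convergence threshold on the mean absolute weight change.
#' @return A `baseline_params` list.
#' @export
baseline_params <- function(smoothness = 1e5, asymmetry = 0.01,
                            max_iter = 10L, tol = 1e-3) {
  if (smoothness <= 0) stop("smoothness must be > 0")
  if (asymmetry <= 0 || asymmetry >= 1) stop("asymmetry must be in (0, 1)")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(smoothness = smoothness, asymmetry = asymmetry,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "baseline_params")
}

#' Estimate a smooth baseline by asymmetric penalized least squares
#'
#' Iteratively reweighted Whittaker smoothing with a second-difference
#' penalty: solve `(W + lambda D'D) z = W y` for the baseline `z`, then
#' reassign weights asymmetrically so that peak points barely pull on the
#' fit, until the weights stabilize. Returns the baseline on the same grid;
#' `meta$converged` records whether the weight updates settled within
#' `max_iter`.
#'
#' @param spec A [raman_spectrum] of length >= 10.
#' @param params A [baseline_params()].
#' @return A [raman_spectrum] holding the baseline, with fit diagnostics
#'   in `meta` (`converged`, `iterations`, echoed parameters).
#' @export
estimate_baseline <- function(spec, params = baseline_params()) {
  stopifnot(inherits(params, "baseline_params"))
  y <- spec$intensities
  m <- length(y)
  if (m < 10L) stop("baseline estimation needs a spectrum of length >= 10")
  D <- Matrix::bandSparse(m - 2L, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  P <- params$smoothness * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  converged <- FALSE
  it <- 0L
  # dead-band so points numerically on the baseline (flat segments) are
  # classified as below it, not flipped by float noise
  eps <- 1e-10 * max(abs(y), 1)
  for (it in seq_len(params$max_iter)) {
    W <- Matrix::Diagonal(x = w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    w_new <- ifelse(y - z > eps, params$asymmetry, 1 - params$asymmetry)
    delta <- mean(abs(w_new - w))
    w <- w_new
    if (delta < params$tol) {
      converged <- TRUE
      break
    }
  }
  # non-convergence is recorded in metadata; the last iterate is returned
  raman_spectrum(spec$wavenumbers, z,
                 meta = list(kind = "baseline", converged = converged,
                             iterations = it,
                             smoothness = params$smoothness,
                             asymmetry = params$asymmetry))
}

#' Subtract a baseline from a spectrum
#'
#' Pointwise difference on a shared grid. The baseline's parameters are
#' recorded in the result's metadata.
#'
#' @param spec,baseline [raman_spectrum]s on identical grids.
#' @return The corrected [raman_spectrum].
#' @export
subtract_baseline <- function(spec, baseline) {
  stop_grid_mismatch(spec, baseline)
  meta <- spec$meta
  meta$baseline <- baseline$meta[c("converged", "smoothness", "asymmetry")]
  raman_spectrum(spec$wavenumbers, spec$intensities - baseline$intensities,
                 meta = meta)
}

#' Correct a spectrum's baseline in one step
#'
#' Convenience wrapper: [estimate_baseline()] then [subtract_baseline()].
#'
#' @inheritParams estimate_baseline
#' @return The baseline-corrected [raman_spectrum].
#' @export
correct_baseline <- function(spec, params = baseline_params()) {
  subtract_baseline(spec, estimate_baseline(spec, params))
}

#' Normalize a spectrum over a region
#'
#' Divides the whole spectrum by either the maximum intensity (`"max"`)
#' or the trapezoidal area (`"area"`) within `reg`. Idempotent and
#' scale-equivariant.
#'
#' @param spec A [raman_spectrum].
#' @param mode `"max"` or `"area"`.
#' @param reg Region over which the norm is taken; defaults to the full
#'   grid.
#' @return The normalized [raman_spectrum].
#' @export
normalize_spectrum <- function(spec, mode = c("max", "area"), reg = NULL) {
  mode <- match.arg(mode)
  if (is.null(reg)) {
    reg <- region(min(spec$wavenumbers), max(spec$wavenumbers))
  }
  sub <- crop(spec, reg)
  norm <- switch(mode,
    max = max(sub$intensities),
    area = trapz_area(sub$wavenumbers, sub$intensities))
  if (!is.finite(norm) || norm <= 0) {
    stop(sprintf("cannot normalize: %s over region is %g (must be > 0)",
                 mode, norm))
  }
  raman_spectrum(spec$wavenumbers, spec$intensities / norm, meta = spec$meta)
}
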