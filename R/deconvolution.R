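#' A single Gaussian or Lorentzian line profile
#'
#' The two lineshapes used for deconvolution are
#' \deqn{I_G(v) = A \exp(-\tfrac12 ((v - x)/\sigma)^2)}
#' \deqn{I_L(v) = A / (1 + 4((v - x)/\sigma)^2)}
#' Note the asymmetric width convention, kept deliberately: for the
#' Gaussian, sigma is the standard deviation (FWHM = 2 sqrt(2 ln 2) sigma
#' ~ 2.355 sigma); for the Lorentzian the factor 4 makes sigma the FWHM
#' itself (half maximum at v = x +/- sigma/2).
#'
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @param amplitude Apex intensity A >= 0 (a.u.).
#' @param center Apex position x in cm^-1.
#' @param width Width sigma > 0 in cm^-1 (see convention above).
#' @return A `peak_profile` list.
#' @export
peak_profile <- function(shape = c("gaussian", "lorentzian"),
                         amplitude, center, width) {
  shape <- match.arg(shape)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (width <= 0) stop("width must be > 0")
  structure(list(shape = shape, amplitude = amplitude,
                 center = center, width = width),
            class = "peak_profile")
}

#' Evaluate a profile on a wavenumber grid
#'
#' @param p A [peak_profile()].
#' @param grid Numeric wavenumbers (cm^-1).
#' @return Intensities at each grid point.
#' @export
eval_profile <- function(p, grid) {
  d <- (grid - p$center) / p$width
  switch(p$shape,
    gaussian = p$amplitude * exp(-0.5 * d^2),
    lorentzian = p$amplitude / (1 + 4 * d^2))
}

#' Analytic area under a profile
#'
#' Integral over the real line: `A sigma sqrt(2 pi)` for a Gaussian,
#' `A sigma pi / 2` for a Lorentzian (with sigma the FWHM).
#'
#' @param p A [peak_profile()].
#' @return Area in a.u. x cm^-1.
#' @export
profile_area <- function(p) {
  switch(p$shape,
    gaussian = p$amplitude * p$width * sqrt(2 * pi),
    lorentzian = p$amplitude * p$width * pi / 2)
}

# local maxima with a minimum prominence, used to initialize centers
pick_peaks <- function(x, y, min_prominence) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  idx <- which(y[2:(n - 1L)] > y[1:(n - 2L)] &
               y[2:(n - 1L)] >= y[3:n]) + 1L
  # prominence approximated as height above the higher of the two
  # flanking minima between neighbouring maxima
  keep <- logical(length(idx))
  bounds <- c(1L, idx, n)
  for (j in seq_along(idx)) {
    left_min <- min(y[bounds[j]:idx[j]])
    right_min <- min(y[idx[j]:bounds[j + 2L]])
    keep[j] <- (y[idx[j]] - max(left_min, right_min)) >= min_prominence
  }
  idx[keep][order(y[idx[keep]], decreasing = TRUE)]
}

init_profiles <- function(x, y, n, width0) {
  lo <- min(x); hi <- max(x)
  peaks <- pick_peaks(x, y, min_prominence = 0.05 * max(y))
  centers <- x[peaks]
  if (length(centers) >= n) {
    centers <- centers[seq_len(n)]
  } else {
    extra <- n - length(centers)
    centers <- c(centers,
                 seq(lo, hi, length.out = extra + 2L)[2:(extra + 1L)])
  }
  centers <- sort(centers)
  amps <- vapply(centers, function(ci) max(y[which.min(abs(x - ci))], 1e-6),
                 numeric(1))
  data.frame(amplitude = amps, center = centers, width = width0)
}

#' Fit a sum of line profiles to a spectral region
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nls.lm]) over the amplitudes, centers and widths of `n`
#' profiles of a common shape. Centers are constrained inside the region,
#' widths to `[grid step, region width]`, amplitudes to be non-negative.
#' Initialization, when not supplied, picks local maxima with prominence
#' at least 5% of the region maximum and spreads any remaining centers
#' uniformly.
#'
#' @param spec A [raman_spectrum] (typically baseline-corrected).
#' @param reg [region] to fit over; must contain at least `3n + 1` points.
#' @param n Number of profiles, >= 1.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @param init Optional list of [peak_profile()]s used as the start.
#' @param width0 Initial width when `init` is absent (cm^-1).
#' @return A `fit_result` list: `profiles` (sorted by center),
#'   `residual_rms`, `region`, `n_evaluations`, `converged`, and
#'   `close_centers` flagging any pair of fitted centers closer than
#'   1 cm^-1.
#' @export
fit_profiles <- function(spec, reg, n, shape = c("gaussian", "lorentzian"),
                         init = NULL, width0 = 6) {
  shape <- match.arg(shape)
  reg <- as_region(reg)
  if (n < 1) stop("n must be >= 1")
  sub <- crop(spec, reg)
  x <- sub$wavenumbers
  y <- sub$intensities
  if (length(x) < 3 * n + 1) {
    stop(sprintf("region has %d points; need at least %d for n = %d profiles",
                 length(x), 3 * n + 1, n))
  }
  step <- min(diff(x))
  lo <- reg[["lo"]]; hi <- reg[["hi"]]
  if (is.null(init)) {
    start <- init_profiles(x, y, n, width0 = min(width0, hi - lo))
  } else {
    if (length(init) != n) stop("init must supply exactly n profiles")
    start <- data.frame(
      amplitude = vapply(init, `[[`, numeric(1), "amplitude"),
      center = vapply(init, `[[`, numeric(1), "center"),
      width = vapply(init, `[[`, numeric(1), "width"))
  }
  # parameter layout: (A_1..A_n, x_1..x_n, s_1..s_n)
  par0 <- c(start$amplitude, start$center, start$width)
  lower <- c(rep(0, n), rep(lo, n), rep(step, n))
  upper <- c(rep(Inf, n), rep(hi, n), rep(hi - lo, n))
  par0 <- pmin(pmax(par0, lower), upper)
  model <- function(par) {
    total <- numeric(length(x))
    for (i in seq_len(n)) {
      d <- (x - par[n + i]) / par[2 * n + i]
      total <- total + if (shape == "gaussian") {
        par[i] * exp(-0.5 * d^2)
      } else {
        par[i] / (1 + 4 * d^2)
      }
    }
    total
  }
  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(par) model(par) - y,
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-10, ptol = 1e-10, maxiter = 500, maxfev = 10000))
  par <- fit$par
  ord <- order(par[(n + 1):(2 * n)])
  profiles <- lapply(ord, function(i) {
    peak_profile(shape, amplitude = par[i], center = par[n + i],
                 width = par[2 * n + i])
  })
  centers <- par[n + ord]
  resid <- model(par) - y
  structure(
    list(profiles = profiles,
         residual_rms = sqrt(mean(resid^2)),
         region = reg,
         n_evaluations = fit$niter,
         converged = fit$info %in% 1:4,
         close_centers = n > 1 && any(diff(centers) < 1),
         shape = shape),
    class = "fit_result")
}

#' @export
#' @method print fit_result
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d %s profile(s) over [%g, %g] cm^-1, rms %.4g%s\n",
              length(x$profiles), x$shape, x$region[["lo"]], x$region[["hi"]],
              x$residual_rms, if (x$converged) "" else " (not converged)"))
  for (p in x$profiles) {
    cat(sprintf("  A = %.5g  x = %.4f cm^-1  sigma = %.4f cm^-1  area = %.5g\n",
                p$amplitude, p$center, p$width, profile_area(p)))
  }
  invisible(x)
}

#' Fit-result parameter table
#'
#' @param fit A `fit_result`.
#' @return A data.frame with one row per profile: shape, amplitude,
#'   center, width, analytic area.
#' @export
fit_table <- function(fit) {
  data.frame(
    shape = vapply(fit$profiles, `[[`, character(1), "shape"),
    amplitude = vapply(fit$profiles, `[[`, numeric(1), "amplitude"),
    center = vapply(fit$profiles, `[[`, numeric(1), "center"),
    width = vapply(fit$profiles, `[[`, numeric(1), "width"),
    area = vapply(fit$profiles, profile_area, numeric(1)))
}

#' Choose the number of profiles by residual threshold
#'
#' Fits `n = 1..n_max` and returns the smallest `n` whose residual RMS,
#' relative to the maximum intensity in the region, falls below `rel_tol`
#' (the "profiles sufficient for a satisfactory fit" judgment, made
#' quantitative). If no `n` qualifies, the best fit is returned with
#' `selected = FALSE`.
#'
#' @inheritParams fit_profiles
#' @param n_max Largest number of components tried.
#' @param rel_tol Relative residual threshold (default 1%).
#' @return A `fit_result` with extra fields `n_selected` and `selected`.
#' @export
select_n_profiles <- function(spec, reg, shape = c("gaussian", "lorentzian"),
                              n_max = 4, rel_tol = 0.01, width0 = 6) {
  shape <- match.arg(shape)
  reg <- as_region(reg)
  peak <- max(crop(spec, reg)$intensities)
  if (peak <= 0) stop("region maximum must be positive for model selection")
  best <- NULL
  for (n in seq_len(n_max)) {
    fit <- fit_profiles(spec, reg, n = n, shape = shape, width0 = width0)
    if (is.null(best) || fit$residual_rms < best$residual_rms) best <- fit
    if (fit$residual_rms / peak < rel_tol) {
      fit$n_selected <- n
      fit$selected <- TRUE
      return(fit)
    }
  }
  best$n_selected <- length(best$profiles)
  best$selected <- FALSE
  best
}
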