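#' Anomer fractions from the 960/974 cm^-1 intensity ratio
#'
#' The anomeric proportions of D-mannopyranose follow directly from the
#' deconvoluted intensities of the two nu(CO) marker bands:
#' \deqn{\alpha\% = I_{960} / (I_{960} + I_{974})}
#' \deqn{\beta\% = I_{974} / (I_{960} + I_{974})}
#' The statistic is invariant under common scaling of both intensities,
#' which is what makes it concentration-independent.
#'
#' @param i_960,i_974 Non-negative deconvoluted intensities (apex
#'   amplitudes or band areas) at the two marker positions; their sum must
#'   be positive.
#' @return An `anomer_composition`: list with `alpha` and `beta` summing
#'   to exactly 1.
#' @export
anomer_fractions <- function(i_960, i_974) {
  if (i_960 < 0 || i_974 < 0) stop("intensities must be >= 0")
  total <- i_960 + i_974
  if (total <= 0) stop("no anomeric signal: intensity sum is zero")
  alpha <- i_960 / total
  structure(list(alpha = alpha, beta = 1 - alpha),
            class = "anomer_composition")
}

#' @export
#' @method print anomer_composition
print.anomer_composition <- function(x, ...) {
  cat(sprintf("<anomer_composition> alpha %.1f%%, beta %.1f%%\n",
              100 * x$alpha, 100 * x$beta))
  invisible(x)
}

#' Anomer composition from a deconvolution fit
#'
#' Associates fitted profiles to the alpha and beta marker bands by
#' nearest center (within `tol`), extracts either the apex amplitude or
#' the analytic area of each, and applies [anomer_fractions()]. The
#' band-to-anomer mapping is an explicit argument: by default 960 cm^-1 is
#' read as the alpha band and 974 cm^-1 as the beta band, matching the
#' reference assignment for aqueous D-mannose.
#'
#' @param fit A `fit_result` from [fit_profiles()].
#' @param alpha_center,beta_center Marker band positions (cm^-1).
#' @param measure `"apex"` (amplitude ratio; the statistic's native form)
#'   or `"area"` (analytic band areas; equivalent at equal widths).
#' @param tol Maximum center-to-band distance for association (cm^-1);
#'   the default 8 is below half the 960-974 separation, so profiles
#'   cannot cross-assign.
#' @return An `anomer_composition`.
#' @export
anomer_from_fit <- function(fit, alpha_center = 960, beta_center = 974,
                            measure = c("apex", "area"), tol = 8) {
  measure <- match.arg(measure)
  centers <- vapply(fit$profiles, `[[`, numeric(1), "center")
  pick <- function(target, label) {
    d <- abs(centers - target)
    i <- which.min(d)
    if (d[i] > tol) {
      stop(sprintf("no fitted profile within %g cm^-1 of the %s band at %g cm^-1",
                   tol, label, target))
    }
    i
  }
  ia <- pick(alpha_center, "alpha")
  ib <- pick(beta_center, "beta")
  if (ia == ib) {
    stop("a single profile is nearest to both marker bands; fit more components")
  }
  value <- function(i) {
    if (measure == "apex") fit$profiles[[i]]$amplitude
    else profile_area(fit$profiles[[i]])
  }
  anomer_fractions(value(ia), value(ib))
}

#' Linear calibration of sugar content against band area
#'
#' Ordinary least squares of the anomeric-region area on the known
#' D-mannose dry-matter fraction; the linear trend between content and
#' area under the deconvoluted curve is the basis of concentration
#' estimation.
#'
#' @param fracs Known contents (mass fraction of the dry matter), >= 3
#'   points with >= 2 distinct values.
#' @param areas Corresponding band areas (a.u. x cm^-1).
#' @return A `calibration_model`: `slope`, `intercept`, `r_squared`, and
#'   the underlying [stats::lm] fit.
#' @export
fit_calibration <- function(fracs, areas) {
  if (length(fracs) != length(areas)) stop("fracs and areas lengths differ")
  if (length(fracs) < 3) stop("calibration needs at least 3 points")
  if (length(unique(fracs)) < 2) {
    stop("degenerate abscissa: need at least 2 distinct content values")
  }
  fit <- stats::lm(areas ~ fracs)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((areas - mean(areas))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, lm = fit),
            class = "calibration_model")
}

#' @export
#' @method print calibration_model
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> area = %.5g x content + %.5g, R^2 = %.6f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Invert a calibration model to estimate content
#'
#' @param model A `calibration_model`.
#' @param area Measured band area.
#' @return Estimated content `(area - intercept)/slope`. Values outside
#'   `[0, 1]` are returned as-is with attribute `extrapolated = TRUE`.
#' @export
estimate_content <- function(model, area) {
  if (model$slope == 0) stop("zero slope: calibration cannot be inverted")
  est <- (area - model$intercept) / model$slope
  if (est < 0 || est > 1) attr(est, "extrapolated") <- TRUE
  est
}

#' Full quantification pipeline for one spectrum
#'
#' Baseline-correct the spectrum, deconvolute the anomeric window with
#' two profiles, and report the anomer composition and the total area
#' under the fitted profiles (the quantity calibrated against content).
#'
#' @param spec A raw [raman_spectrum].
#' @param reg Analysis region (default the 941-992 cm^-1 anomeric window).
#' @param shape Profile shape for the fit.
#' @param n Number of profiles (default 2, one per anomer band).
#' @param baseline A [baseline_params()].
#' @param measure Passed to [anomer_from_fit()].
#' @param alpha_center,beta_center Marker band map, as in
#'   [anomer_from_fit()].
#' @return A list: `composition` (anomer fractions), `fit` (the
#'   deconvolution result), `total_area` (sum of analytic profile areas),
#'   `corrected` (the baseline-corrected spectrum).
#' @export
quantify_anomers <- function(spec, reg = region(941, 992),
                             shape = c("gaussian", "lorentzian"), n = 2,
                             baseline = baseline_params(),
                             measure = c("apex", "area"),
                             alpha_center = 960, beta_center = 974) {
  shape <- match.arg(shape)
  measure <- match.arg(measure)
  corrected <- correct_baseline(spec, baseline)
  fit <- fit_profiles(corrected, reg, n = n, shape = shape)
  comp <- anomer_from_fit(fit, alpha_center = alpha_center,
                          beta_center = beta_center, measure = measure)
  list(composition = comp, fit = fit,
       total_area = sum(vapply(fit$profiles, profile_area, numeric(1))),
       corrected = corrected)
}
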