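#' Construct a Raman spectrum
#'
#' A spectrum pairs a strictly increasing wavenumber grid (cm^-1) with
#' intensities in arbitrary units (detector counts, or dimensionless after
#' normalization), plus free-form metadata.
#'
#' @param wavenumbers Numeric vector of Raman shifts in cm^-1, strictly
#'   increasing, length >= 2.
#' @param intensities Numeric vector of the same length. Negative values are
#'   permitted (baseline-subtracted spectra routinely dip below zero).
#' @param meta Named list of free-form metadata (exposure, label, provenance).
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumbers`, `intensities`, `meta`.
#' @export
raman_spectrum <- function(wavenumbers, intensities, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have equal length")
  }
  if (length(wavenumbers) < 2L) {
    stop("degenerate input: a spectrum needs at least 2 points")
  }
  if (anyNA(wavenumbers) || anyNA(intensities)) {
    stop("spectrum values must be finite (NA found)")
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be strictly increasing (duplicates not allowed)")
  }
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         meta = as.list(meta)),
    class = "raman_spectrum"
  )
}

#' @export
#' @method print raman_spectrum
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.6g-%.6g cm^-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumbers)

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumbers, intensity = x$intensities)
}

#' Spectral region
#'
#' A closed wavenumber interval `[lo, hi]`, e.g. the 941-992 cm^-1 anomeric
#' window used for D-mannose quantification.
#'
#' @param lo,hi Interval bounds in cm^-1, `lo < hi`.
#' @return Numeric vector `c(lo, hi)` of class `raman_region`.
#' @export
region <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(length(lo) == 1L, length(hi) == 1L, is.finite(lo), is.finite(hi))
  if (lo >= hi) stop("region requires lo < hi")
  structure(c(lo = lo, hi = hi), class = "raman_region")
}

as_region <- function(x) {
  if (inherits(x, "raman_region")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(region(x[1], x[2]))
  stop("expected a region (see region())")
}

#' Read a two-column spectrum file
#'
#' The interchange format is delimited text: wavenumber (cm^-1) then
#' intensity, comma- or tab-separated (auto-detected from the first line),
#' with an optional header row (detected by a non-numeric first field).
#' Rows are sorted ascending by wavenumber; duplicate wavenumbers are
#' rejected.
#'
#' @param path File path.
#' @param dialect `"auto"` (default), `"csv"` or `"tsv"`.
#' @param warn_negative Warn if any intensity is negative. Raw detector
#'   reads should not be negative; baseline-subtracted spectra may be, so
#'   downstream readers pass `FALSE`.
#' @return A [raman_spectrum], with `meta$source` recording the path.
#' @export
read_spectrum <- function(path, dialect = c("auto", "csv", "tsv"),
                          warn_negative = TRUE) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("degenerate input: empty spectrum file")
  sep <- switch(dialect,
    csv = ",", tsv = "\t",
    auto = if (grepl("\t", lines[[1]])) "\t" else ",")
  first_fields <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(trimws(first_fields[[1]]))))
  data_lines <- if (has_header) lines[-1L] else lines
  line_no <- seq_along(lines)[if (has_header) -1L else TRUE]
  if (length(data_lines) < 2L) {
    stop("degenerate input: a spectrum needs at least 2 points")
  }
  parts <- strsplit(data_lines, sep, fixed = TRUE)
  wn <- numeric(length(parts)); it <- numeric(length(parts))
  for (i in seq_along(parts)) {
    f <- trimws(parts[[i]])
    if (length(f) < 2L) {
      stop(sprintf("parse error at line %d: fewer than 2 columns", line_no[i]))
    }
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (anyNA(v)) {
      stop(sprintf("parse error at line %d: non-numeric value '%s'",
                   line_no[i], f[which(is.na(v))[1]]))
    }
    wn[i] <- v[1]; it[i] <- v[2]
  }
  if (anyDuplicated(wn)) {
    stop("duplicate wavenumbers in spectrum file")
  }
  ord <- order(wn)
  if (warn_negative && any(it < 0)) {
    warning("negative intensities in raw spectrum read")
  }
  raman_spectrum(wn[ord], it[ord], meta = list(source = path))
}

#' Write a spectrum as delimited text
#'
#' Values are written at full double precision so that
#' `read_spectrum(write_spectrum(s))` round-trips exactly.
#'
#' @param spec A [raman_spectrum].
#' @param path Output path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @param header Write a `wavenumber,intensity` header row (default TRUE).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, dialect = c("csv", "tsv"),
                           header = TRUE) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  lines <- paste(format(spec$wavenumbers, digits = 17, trim = TRUE,
                        scientific = FALSE),
                 format(spec$intensities, digits = 17, trim = TRUE),
                 sep = sep)
  if (header) lines <- c(paste("wavenumber", "intensity", sep = sep), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Crop a spectrum to a region
#'
#' Keeps grid points with `lo <= wavenumber <= hi` (closed interval, since
#' printed band ranges like 941-992 cm^-1 read as inclusive). Metadata is
#' preserved. Idempotent.
#'
#' @param spec A [raman_spectrum].
#' @param reg A [region] (or `c(lo, hi)`).
#' @return The cropped [raman_spectrum].
#' @export
crop <- function(spec, reg) {
  reg <- as_region(reg)
  keep <- spec$wavenumbers >= reg[["lo"]] & spec$wavenumbers <= reg[["hi"]]
  if (sum(keep) < 2L) {
    stop(sprintf("degenerate input: region [%g, %g] overlaps fewer than 2 grid points",
                 reg[["lo"]], reg[["hi"]]))
  }
  raman_spectrum(spec$wavenumbers[keep], spec$intensities[keep],
                 meta = spec$meta)
}

# trapezoidal area over a (sub)grid; the quadrature used everywhere areas
# of sampled spectra are needed
trapz_area <- function(x, y) {
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

stop_grid_mismatch <- function(a, b) {
  if (length(a$wavenumbers) != length(b$wavenumbers) ||
      any(a$wavenumbers != b$wavenumbers)) {
    stop("spectra are on different wavenumber grids")
  }
  invisible(NULL)
}
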