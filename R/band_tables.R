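#' Reference Raman band tables for aqueous monosaccharide solutions
#'
#' Band positions, qualitative strengths (s/m/w) and vibrational
#' assignments for 30% dry-matter aqueous solutions of D-glucose and
#' D-mannose, as observed with a 785 nm probe. The D-mannose table carries
#' the anomeric marker pair used throughout: the nu(CO) ring modes at
#' 960 cm^-1 (tagged alpha) and 974 cm^-1 (tagged beta), whose intensity
#' ratio tracks the alpha/beta pyranose equilibrium. Bands shared with the
#' solvent (the 3400 cm^-1 OH envelope, the 1645 cm^-1 HOH bend) are
#' tagged species `"water"`.
#'
#' @param species `"mannose"` or `"glucose"`.
#' @return A data.frame with columns `center` (cm^-1), `strength`
#'   (`"s"`, `"m"`, `"w"`), `assignment`, `species`, `anomer`
#'   (`"alpha"`, `"beta"` or `"none"`).
#' @export
band_table <- function(species = c("mannose", "glucose")) {
  species <- match.arg(species)
  if (species == "mannose") {
    bands <- data.frame(
      center = c(3400, 2942, 2909, 2737, 1645, 1462, 1368, 1336, 1264,
                 1138, 1103, 1063, 1010, 960, 974, 910, 878, 831, 749,
                 681, 665, 577, 520, 488, 454, 417, 398, 341),
      strength = c("s", "s", "s", "w", "m", "w", "w", "m", "w",
                   "m", "m", "m", "w", "m", "m", "w", "w", "m", "w",
                   "m", "m", "w", "m", "m", "w", "w", "w", "w"),
      assignment = c("nu(OH)", "nu_as(CH2)", "nu_ss(CH2)", "nu(CH)",
                     "delta(OH)", "delta(CH2)", "delta(CH2)", "delta(CH)",
                     "wag(CH2)", "delta(COH)", "delta(COH)", "wag(CH2)",
                     "delta(COH)", "nu(CO)", "nu(CO)", "delta(COH)",
                     "delta(COH)", "delta(COH)", "delta(CCH)", "nu(CCH)",
                     "delta(CH)", "ring", "ring", "ring", "delta(CCO)",
                     "delta(CCO)", "delta(CCC)", "delta(CCC)"),
      anomer = "none",
      stringsAsFactors = FALSE
    )
    bands$anomer[bands$center == 960] <- "alpha"
    bands$anomer[bands$center == 974] <- "beta"
  } else {
    bands <- data.frame(
      center = c(3400, 2945, 2898, 2721, 1645, 1462, 1367, 1336, 1264,
                 1126, 1061, 1017, 899, 910, 846, 774, 749, 709, 644,
                 590, 577, 540, 518, 497, 447, 417, 407, 350),
      strength = c("s", "s", "s", "s", "m", "s", "s", "m", "m",
                   "m", "m", "s", "m", "m", "m", "w", "w", "w", "w",
                   "w", "w", "m", "m", "m", "m", "s", "w", "w"),
      assignment = c("nu(OH)", "nu_as(CH2)", "nu_ss(CH2)", "nu(CH)",
                     "delta(OH)", "delta(CH2)", "delta(CH2)", "delta(CH)",
                     "wag(CH2)", "delta(COH)", "wag(CH2)", "delta(COH)",
                     "delta(COH)", "delta(COH)", "delta(COH)", "delta(COH)",
                     "delta(CCH)", "nu(CCH)", "delta(CH)", "ring", "ring",
                     "ring", "ring", "ring", "delta(CCO)", "delta(CCO)",
                     "delta(CCC)", "delta(CCC)"),
      anomer = "none",
      stringsAsFactors = FALSE
    )
  }
  bands$species <- species
  bands$species[bands$center %in% c(3400, 1645)] <- "water"
  validate_band_table(bands)
}

validate_band_table <- function(bands) {
  bands <- as.data.frame(bands, stringsAsFactors = FALSE)
  needed <- c("center", "strength", "anomer")
  missing <- setdiff(needed, names(bands))
  if (length(missing)) {
    stop("band table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (is.null(bands$species)) bands$species <- "unknown"
  if (is.null(bands$assignment)) bands$assignment <- ""
  if (any(bands$center <= 0)) stop("band centers must be positive")
  if (!all(bands$strength %in% c("s", "m", "w"))) {
    stop("band strength labels must be 's', 'm' or 'w'")
  }
  if (!all(bands$anomer %in% c("alpha", "beta", "none"))) {
    stop("band anomer tags must be 'alpha', 'beta' or 'none'")
  }
  bands[c("center", "strength", "assignment", "species", "anomer")]
}

#' Anomeric-region band table for D-mannose
#'
#' Just the two nu(CO) anomeric marker bands (960 cm^-1 alpha, 974 cm^-1
#' beta), for fixtures that isolate the 941-992 cm^-1 window.
#'
#' @return A two-row band table (see [band_table()]).
#' @export
anomeric_bands <- function() {
  b <- band_table("mannose")
  validate_band_table(b[b$anomer != "none", ])
}
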