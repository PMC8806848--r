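#!/usr/bin/env Rscript
# Stage 3 — the statistics: anomer fractions of D-mannose from the
# 960/974 cm^-1 deconvoluted intensities, and the linear calibration of
# mannose content against anomeric-region area across the mixture series.
# Requires stage 01 outputs.

suppressPackageStartupMessages(library(ramanomer))

anomeric <- region(941, 992)

## anomer fractions from the pure-mannose spectrum
spec <- read_spectrum("results/spectra/mannose_pure.csv")
q <- quantify_anomers(spec, reg = anomeric, measure = "apex")
cat(sprintf("D-mannose anomer fractions (apex ratio): alpha %.1f%%, beta %.1f%%\n",
            100 * q$composition$alpha, 100 * q$composition$beta))
q_area <- anomer_from_fit(q$fit, measure = "area")
cat(sprintf("                          (area ratio): alpha %.1f%%, beta %.1f%%\n",
            100 * q_area$alpha, 100 * q_area$beta))

## calibration: total fitted area vs known mannose fraction, on the
## 30% DM mixture series
fracs <- c(0.25, 0.50, 0.75, 1.00)
areas <- vapply(fracs, function(f) {
  s <- read_spectrum(sprintf("results/spectra/mixture_mannose_%02d.csv",
                             round(100 * f)),
                     warn_negative = FALSE)
  quantify_anomers(s, reg = anomeric)$total_area
}, numeric(1))

model <- fit_calibration(fracs, areas)
print(model)
utils::write.csv(data.frame(frac = fracs, area = areas),
                 "results/calibration.csv", row.names = FALSE)
cat("wrote results/calibration.csv\n")

## invert the model on each measured area: content round-trip
for (i in seq_along(fracs)) {
  est <- estimate_content(model, areas[i])
  cat(sprintf("  true mannose fraction %.2f -> estimated %.3f\n",
              fracs[i], est))
}
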