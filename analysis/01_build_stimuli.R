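#!/usr/bin/env Rscript
# Build the illuminant stimuli: the D67 target metamer on the 13-channel LED
# basis and the four directional comparison series (blue/yellow along the
# Planckian locus, red/green along the iso-CCT line), 51 members each at
# nominal CIELUV colour differences 0..50.
#
# Run from the repository root:  Rscript analysis/01_build_stimuli.R
# Outputs: results/series_<direction>.csv, results/stimulus_summary.csv,
#          results/target_spectrum.csv

library(illumdisc)

dir.create("results", showWarnings = FALSE)

basis <- make_led_basis()
target_fit <- fit_weights(daylight_spectrum(6700), basis)
write_spectrum_csv(target_fit$fitted, "results/target_spectrum.csv")

directions <- c("blue", "yellow", "red", "green")
summary_rows <- lapply(directions, function(d) {
  se <- generate_series(d, basis)
  utils::write.csv(se$table, sprintf("results/series_%s.csv", d),
                   row.names = FALSE)
  data.frame(direction = d,
             n_comparisons = length(se$comparisons),
             de_at_0 = se$achieved_de[1],
             de_at_50 = se$achieved_de[51],
             mean_abs_deviation = se$mean_abs_deviation,
             cct_min = min(se$table$cct),
             cct_max = max(se$table$cct))
})
summary_tab <- do.call(rbind, summary_rows)
summary_tab$target_chromaticity_error_uv <- target_fit$chromaticity_error_uv
utils::write.csv(summary_tab, "results/stimulus_summary.csv",
                 row.names = FALSE)
print(summary_tab)
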