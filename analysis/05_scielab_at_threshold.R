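#!/usr/bin/env Rscript
# Image-difference analysis: for each chromatic direction, compute the mean
# S-CIELAB difference between the scene under the target illumination and
# under the comparison at that direction's group threshold, interpolated from
# the bracketing series members. A small max/min dispersion across directions
# indicates thresholds correspond to a roughly constant image difference.
#
# Requires results/experiment/group_summary.csv from
# analysis/03_run_experiment.R.
#
# Run from the repository root:  Rscript analysis/05_scielab_at_threshold.R
# Outputs: results/scielab_at_threshold.csv

library(illumdisc)

root_seed <- 20240702  # same pipeline seed as the experiment run

grp_path <- "results/experiment/group_summary.csv"
if (!file.exists(grp_path)) {
  stop("run analysis/03_run_experiment.R first (missing ", grp_path, ")")
}
grp <- utils::read.csv(grp_path)
thresholds <- stats::setNames(grp$mean, grp$direction)

basis <- make_led_basis()
directions <- c("blue", "yellow", "red", "green")
series_list <- stats::setNames(
  lapply(directions, function(d) generate_series(d, basis)), directions)
cfg <- experiment_config(seed = root_seed, dialect = "simulated")
scene <- make_scene(cfg, series_list[[1]]$target)

tab <- threshold_image_difference(series_list, thresholds, scene,
                                  scielab_config(ppd = 17))
utils::write.csv(tab, "results/scielab_at_threshold.csv", row.names = FALSE)
print(tab)
cat(sprintf("max/min dispersion of the metric across directions: %.3f\n",
            attr(tab, "dispersion")))
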