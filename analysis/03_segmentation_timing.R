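#!/usr/bin/env Rscript
# Segmentation support and cardiac timing: PC-MRA threshold segmentation
# against the generator's lumen (Dice), wall-surface extraction sanity
# (area versus the analytic lateral area), and peak-systole detection
# against the waveform truth for every simulated subject.

library(hemoflow4d)

config <- analysis_config(seed = 1)
cohorts <- readRDS("results/sim/cohorts.rds")

rows <- list()
for (g in names(cohorts)) {
  for (s in cohorts[[g]]$subjects) {
    ph <- s$segments$aorta
    pp <- preprocess_field(ph$field, config,
                           static_mask = ph$masks$static_tissue)
    pc <- compute_pcmra(ph$magnitude, pp$field)
    seg <- segment_threshold(pc, config$pcmra_threshold_frac)
    dice <- 2 * sum(seg & ph$masks$lumen) /
      (sum(seg) + sum(ph$masks$lumen))
    surf <- extract_wall_surface(ph$masks$aorta, ph$field$spacing,
                                 flow_mask = ph$masks$lumen,
                                 smooth_sigma = config$wss_smooth_sigma)
    lateral <- 2 * pi * ph$spec$radius * ph$spec$length
    pk <- find_peak_systole(pp$field, ph$masks$lv)
    rows[[length(rows) + 1]] <- data.frame(
      group = g, subject = s$id, dice_threshold_vs_lumen = dice,
      surface_points = nrow(surf$points),
      area_ratio = sum(surf$area_weights) / lateral,
      peak_frame = pk,
      peak_frame_true = ph$truth$peak_systole_frame_true)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/segmentation_timing.csv", row.names = FALSE)
print(tab, digits = 3)
message(sprintf("peak frame recovered for %d/%d subjects; area within %.1f%%",
                sum(tab$peak_frame == tab$peak_frame_true), nrow(tab),
                100 * max(abs(tab$area_ratio - 1))))
message("note: half-max threshold segmentation tracks an iso-velocity ",
        "contour for non-blunt profiles (Dice well below 1); the ",
        "supplied masks are what the cohort analyses use")
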