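# End-to-end cohort recovery: generate a calibrated synthetic cohort for
# one group, run the full measurement pipeline on every subject, and
# average one metric across subjects. This is the quantity the package's
# validation compares with the published group means.

#' Pipeline group mean for one metric on a calibrated synthetic cohort
#'
#' Generates `n_subjects` phantoms calibrated to the requested group of
#' [reference_group_targets()], runs preprocessing, segmentation support,
#' peak-systole detection and the metric computation on each subject, and
#' returns the across-subject mean of the requested metric.
#'
#' @param metric One of `"wss_aorta"`, `"peak_velocity_lvot"`, `"ke_lvot"`,
#'   `"ke_aorta"`, `"av_forward"`, `"mv_forward"`.
#' @param group A group label of [reference_group_targets()].
#' @param seed Integer seed for the cohort draw and noise.
#' @param config An [analysis_config()].
#' @param n_subjects Number of subjects (3 matches the study arms).
#' @param noise_frac Velocity noise SD as a fraction of venc.
#' @return List with `value` (group mean of the pipeline measurement),
#'   `n` (number of subjects), `per_subject`, and `truth_mean` (group mean
#'   of the analytic truths).
#' @export
cohort_group_mean <- function(metric, group, seed,
                              config = analysis_config(),
                              n_subjects = 3, noise_frac = 0.02) {
  segment <- switch(metric,
                    wss_aorta = , ke_aorta = , av_forward = "aorta",
                    peak_velocity_lvot = , ke_lvot = , mv_forward = "lvot",
                    stop("unknown metric: ", metric, call. = FALSE))
  tg <- reference_group_targets()
  row <- tg[tg$group == group, ]
  if (nrow(row) != 1) stop("unknown group: ", group, call. = FALSE)
  coh <- make_cohort(row, n_subjects = n_subjects, config = config,
                     seed = seed, noise_frac = noise_frac,
                     segments = segment)
  per <- vapply(coh$subjects,
                function(s) analyze_subject(s, config)[[metric]],
                numeric(1))
  truth_col <- switch(metric,
                      wss_aorta = "wss_aorta", ke_aorta = "ke_aorta",
                      av_forward = "av_forward",
                      peak_velocity_lvot = "vpeak_lvot",
                      ke_lvot = "ke_lvot", mv_forward = "mv_forward")
  list(value = mean(per), n = n_subjects, per_subject = per,
       truth_mean = mean(coh$target_table[[truth_col]]))
}
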