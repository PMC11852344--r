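# Group-level summaries: mean, SD, Student-t confidence intervals and
# percent differences against the isolated-myectomy reference group.
# Descriptive only, matching the study design (no hypothesis tests).

#' Summarise one metric within a group
#'
#' Sample mean, sample SD (n-1 denominator; 0 when n = 1) and a Student-t
#' confidence interval `mean +/- t_{(1+level)/2, n-1} sd / sqrt(n)`;
#' degenerate at the mean when n = 1.
#'
#' @param values Numeric vector of per-subject values (NAs dropped).
#' @param ci_level Confidence level in (0, 1).
#' @return List with `n`, `mean`, `sd`, `ci_low`, `ci_high`.
#' @export
summarize_group <- function(values, ci_level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) stop("no values to summarise", call. = FALSE)
  m <- mean(values)
  s <- if (n > 1) stats::sd(values) else 0
  half <- if (n > 1) stats::qt((1 + ci_level) / 2, n - 1) * s / sqrt(n) else 0
  list(n = n, mean = m, sd = s, ci_low = m - half, ci_high = m + half)
}

#' Percent difference of a comparison value against a reference
#'
#' `(comparison - reference) / |reference| * 100`.
#'
#' @param reference Reference value, non-zero.
#' @param comparison Comparison value.
#' @return Percent difference.
#' @export
percent_difference <- function(reference, comparison) {
  if (!is.finite(reference) || reference == 0) {
    stop("undefined percentage: reference is zero", call. = FALSE)
  }
  (comparison - reference) / abs(reference) * 100
}

#' Build the cohort table from per-subject results
#'
#' One row per metric and group with n, mean, SD and CI; when the
#' isolated-myectomy group is present, each other group also gets its
#' percent difference from that reference (recomputed from group means).
#' Output ordering is deterministic and independent of subject order.
#'
#' @param results Data.frame of [analyze_subject()] rows (needs a `group`
#'   column).
#' @param config An [analysis_config()]; uses `ci_level`.
#' @param out_dir Optional directory; writes `cohort_table.csv` and
#'   `cohort_table.md` when given.
#' @param reference_group Group label used for percent differences.
#' @return Object of class `cohort_table` (a data.frame).
#' @export
build_report <- function(results, config = analysis_config(), out_dir = NULL,
                         reference_group = "isolated_myectomy") {
  if (!"group" %in% names(results)) stop("results need a 'group' column",
                                         call. = FALSE)
  known <- reference_group_targets()$group
  bad <- setdiff(unique(results$group), known)
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  metrics <- c("wss_aorta", "peak_velocity_lvot", "ke_lvot", "ke_aorta",
               "av_forward", "av_backward", "mv_forward", "mv_backward",
               "dp_mean", "dp_max", "strain_lvot")
  metrics <- intersect(metrics, names(results))
  groups <- intersect(known, unique(results$group))   # canonical order
  rows <- list()
  for (met in metrics) {
    for (g in groups) {
      vals <- results[results$group == g, met]
      if (all(is.na(vals))) next
      s <- summarize_group(vals, config$ci_level)
      pd <- NA_real_
      if (reference_group %in% groups && g != reference_group &&
          length(groups) > 1) {
        ref <- summarize_group(results[results$group == reference_group, met],
                               config$ci_level)$mean
        pd <- percent_difference(ref, s$mean)
      }
      rows[[length(rows) + 1]] <- data.frame(
        metric = met, group = g, n = s$n, mean = s$mean, sd = s$sd,
        ci_low = s$ci_low, ci_high = s$ci_high, pct_diff_vs_reference = pd)
    }
  }
  tab <- do.call(rbind, rows)
  if (length(groups) < 2 || !reference_group %in% groups) {
    tab$pct_diff_vs_reference <- NULL
  }
  class(tab) <- c("cohort_table", "data.frame")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "cohort_table.csv"),
                     row.names = FALSE)
    writeLines(render_cohort_md(tab), file.path(out_dir, "cohort_table.md"))
  }
  tab
}

render_cohort_md <- function(tab) {
  has_pd <- "pct_diff_vs_reference" %in% names(tab)
  hdr <- c("| metric | group | n | mean ± SD | 95% CI |",
           "|---|---|---|---|---|")
  if (has_pd) {
    hdr <- c("| metric | group | n | mean ± SD | 95% CI | % diff |",
             "|---|---|---|---|---|---|")
  }
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    base <- sprintf("| %s | %s | %d | %.3g ± %.2g | [%.3g, %.3g] |",
                    r$metric, r$group, r$n, r$mean, r$sd, r$ci_low, r$ci_high)
    if (has_pd) {
      base <- paste0(base, if (is.na(r$pct_diff_vs_reference)) " – |"
                     else sprintf(" %+.1f%% |", r$pct_diff_vs_reference))
    }
    base
  }, character(1))
  c(hdr, rows)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(paste(render_cohort_md(x), collapse = "\n"), "\n")
  invisible(x)
}
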