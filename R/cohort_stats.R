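#' Paired ischemic-vs-control cohort
#'
#' One subject contributes a control and an ischemic [morphometry_result()]
#' on the same contrast; pairing removes between-subject variation (size,
#' age) as a confounder.
#'
#' @param subject_id character or integer vector of unique subject ids.
#' @param control,ischemic lists of [morphometry_result()] (or named numeric
#'   vectors over [MORPHOMETRY_METRICS]), one per subject.
#' @param contrast_label one of [CONTRASTS].
#' @return An object of class `paired_cohort`.
#' @export
paired_cohort <- function(subject_id, control, ischemic, contrast_label) {
  n <- length(subject_id)
  if (n < 2L) stop("a paired cohort needs at least 2 subjects", call. = FALSE)
  if (anyDuplicated(subject_id))
    stop("subject ids must be unique", call. = FALSE)
  if (length(control) != n || length(ischemic) != n)
    stop("control and ischemic lists must match subject_id length",
         call. = FALSE)
  contrast_label <- match.arg(contrast_label, CONTRASTS)
  as_metrics <- function(x) {
    if (inherits(x, "morphometry_result")) {
      if (x$contrast_label != contrast_label)
        stop("member contrast does not match the cohort contrast",
             call. = FALSE)
      unlist(x[MORPHOMETRY_METRICS])
    } else {
      v <- unlist(x)
      if (is.null(names(v)) || !any(names(v) %in% MORPHOMETRY_METRICS))
        stop("metric vector must use names from: ",
             paste(MORPHOMETRY_METRICS, collapse = ", "), call. = FALSE)
      out <- stats::setNames(rep(NA_real_, length(MORPHOMETRY_METRICS)),
                             MORPHOMETRY_METRICS)
      out[intersect(names(v), MORPHOMETRY_METRICS)] <-
        v[intersect(names(v), MORPHOMETRY_METRICS)]
      out
    }
  }
  structure(list(
    subject_id = as.character(subject_id),
    control = t(vapply(control, as_metrics, numeric(length(MORPHOMETRY_METRICS)))),
    ischemic = t(vapply(ischemic, as_metrics, numeric(length(MORPHOMETRY_METRICS)))),
    contrast_label = contrast_label), class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort> %s, n = %d subjects\n",
              x$contrast_label, length(x$subject_id)))
  invisible(x)
}

#' Paired t-test, effect size and percent change for one metric
#'
#' Textbook paired analysis of `ischemic - control` differences:
#' `t = mean_diff / (sd_diff / sqrt(n))` on `n - 1` degrees of freedom,
#' two-sided p, 95 percent CI `mean_diff +/- t[0.975, n-1] * sd_diff/sqrt(n)`,
#' paired Cohen's d `|mean_diff| / sd_diff`, and percent change computed per
#' subject (`100 * (ischemic - control) / control`) then summarized by its
#' mean and SD — the definition under which a percent change carries its own
#' SD.
#'
#' @param cohort a [paired_cohort()].
#' @param metric one of [MORPHOMETRY_METRICS].
#' @return An object of class `paired_stats` (also a one-row list of the
#'   summary quantities).
#' @export
paired_analysis <- function(cohort, metric) {
  stopifnot(inherits(cohort, "paired_cohort"))
  metric <- match.arg(metric, MORPHOMETRY_METRICS)
  ctrl <- cohort$control[, metric]
  isch <- cohort$ischemic[, metric]
  bad <- !is.finite(ctrl) | !is.finite(isch)
  if (any(bad))
    stop("non-finite ", metric, " for subject(s): ",
         paste(cohort$subject_id[bad], collapse = ", "), call. = FALSE)
  n <- length(ctrl)
  diffs <- isch - ctrl
  mean_diff <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  if (sd_diff == 0)
    stop("degenerate variance: all paired differences identical for ",
         metric, call. = FALSE)
  se <- sd_diff / sqrt(n)
  t_stat <- mean_diff / se
  p_value <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  tcrit <- stats::qt(0.975, df = n - 1)
  pct <- 100 * diffs / ctrl
  structure(list(
    metric = metric, contrast = cohort$contrast_label, n = n,
    mean_control = mean(ctrl), mean_ischemic = mean(isch),
    mean_diff = mean_diff, sd_diff = sd_diff,
    ci95_low = mean_diff - tcrit * se, ci95_high = mean_diff + tcrit * se,
    t_stat = t_stat, p_value = p_value,
    cohens_d = abs(mean_diff) / sd_diff,
    pct_change_mean = mean(pct), pct_change_sd = stats::sd(pct)),
    class = "paired_stats")
}

#' @export
print.paired_stats <- function(x, ...) {
  cat(sprintf(
    "<paired_stats> %s %s (n=%d): diff %.3g +/- %.3g, t=%.2f, p=%.3g, d=%.2f\n",
    x$contrast, x$metric, x$n, x$mean_diff, x$sd_diff, x$t_stat, x$p_value,
    x$cohens_d))
  invisible(x)
}

#' Summarize paired statistics over contrasts and metrics
#'
#' Runs [paired_analysis()] for every cohort and metric and returns a
#' long-format table (one row per contrast x metric) with a significance
#' flag at p < 0.05. No multiple-testing correction is applied; the number
#' of tests performed is attached as attribute `n_tests`. Missing cells are
#' reported in an error rather than skipped.
#'
#' @param cohorts list of [paired_cohort()], at most one per contrast.
#' @param metrics metric names to analyze; default all six.
#' @return A `data.frame` with the paired summary per row, significance flag,
#'   and `mean/sd` columns for both arms.
#' @export
summarize_cohort <- function(cohorts, metrics = MORPHOMETRY_METRICS) {
  if (inherits(cohorts, "paired_cohort")) cohorts <- list(cohorts)
  labels <- vapply(cohorts, function(x) x$contrast_label, character(1))
  if (anyDuplicated(labels))
    stop("multiple cohorts share a contrast label", call. = FALSE)
  rows <- list()
  missing_cells <- character(0)
  for (co in cohorts) {
    for (m in metrics) {
      st <- tryCatch(paired_analysis(co, m), error = function(e) e)
      if (inherits(st, "error")) {
        missing_cells <- c(missing_cells,
                           sprintf("%s/%s (%s)", co$contrast_label, m,
                                   conditionMessage(st)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = st$contrast, metric = st$metric, n = st$n,
        mean_control = st$mean_control,
        sd_control = stats::sd(co$control[, m]),
        mean_ischemic = st$mean_ischemic,
        sd_ischemic = stats::sd(co$ischemic[, m]),
        mean_diff = st$mean_diff, sd_diff = st$sd_diff,
        ci95_low = st$ci95_low, ci95_high = st$ci95_high,
        t_stat = st$t_stat, p_value = st$p_value, cohens_d = st$cohens_d,
        pct_change_mean = st$pct_change_mean,
        pct_change_sd = st$pct_change_sd,
        significant = st$p_value < 0.05)
    }
  }
  if (length(missing_cells))
    stop("missing or degenerate cells:\n  ",
         paste(missing_cells, collapse = "\n  "), call. = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "n_tests") <- nrow(out)
  out
}

#' Round a summary table the way the reporting tables print
#'
#' Relaxation times (ms) and Cohen's d to one decimal, thicknesses (mm) to
#' two decimals, percent changes to whole percent.
#'
#' @param summary a table from [summarize_cohort()].
#' @return A data.frame of formatted character columns.
#' @export
format_summary_table <- function(summary) {
  thick <- grepl("thickness", summary$metric)
  dg <- ifelse(thick, 2L, 1L)
  fmt <- function(x, k) sprintf(paste0("%.", k, "f"), x)
  data.frame(
    contrast = summary$contrast, metric = summary$metric,
    control = paste0(fmt(summary$mean_control, dg), " ± ",
                     fmt(summary$sd_control, dg)),
    ischemic = paste0(fmt(summary$mean_ischemic, dg), " ± ",
                      fmt(summary$sd_ischemic, dg)),
    paired_difference = paste0(fmt(summary$mean_diff, dg), " ± ",
                               fmt(summary$sd_diff, dg)),
    ci95 = sprintf("[%s, %s]", fmt(summary$ci95_low, dg),
                   fmt(summary$ci95_high, dg)),
    t = sprintf("%.1f", abs(summary$t_stat)),
    p_value = ifelse(summary$p_value < 0.001, "<0.001",
                     sprintf("%.3f", summary$p_value)),
    cohens_d = sprintf("%.1f", summary$cohens_d),
    pct_change = paste0(sprintf("%.0f", summary$pct_change_mean), " ± ",
                        sprintf("%.0f", summary$pct_change_sd)),
    significant = ifelse(summary$significant, "*", ""))
}
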