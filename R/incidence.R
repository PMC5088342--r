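# Adverse-event incidence statistics.
#
# Incidence within a stratum is the micro-average (pooled proportion):
# total affected participants over total at-risk participants across the
# stratum's arms. Groups are contrasted against a reference group (by
# default the 20-29 group, the lowest-incidence group in registry data)
# with risk differences, rate ratios and Welch t-tests on per-arm rates.

#' Incidence of an event or arm: affected / at risk
#'
#' @param affected Non-negative integer vector.
#' @param at_risk Positive integer vector.
#' @return Numeric proportion(s) in `[0, 1]`.
#' @examples
#' arm_incidence(10, 100)
#' @export
arm_incidence <- function(affected, at_risk) {
  if (any(is.na(affected)) || any(is.na(at_risk))) {
    stop("affected and at_risk must be non-missing")
  }
  if (any(at_risk <= 0)) stop("at_risk must be positive")
  if (any(affected < 0) || any(affected > at_risk)) {
    stop("affected must satisfy 0 <= affected <= at_risk")
  }
  affected / at_risk
}

#' Micro-average incidence of a group of arms
#'
#' Pools affected and at-risk totals over the group's arms: micro-average
#' = sum(affected) / sum(enrolled), with each arm's affected total taken
#' from [effective_overall_affected()]. A 95% normal-approximation CI on
#' the pooled proportion uses se = sqrt(p (1 - p) / N).
#'
#' @param entries List of `list(trial_id, arm)` pairs (one group of an
#'   [partition_arms()] result), or a list of `arm_record`s.
#' @param group Optional group label carried into the summary.
#' @param level Confidence level (default 0.95).
#' @return A `group_incidence_summary`: group, n_arms, total_at_risk,
#'   total_affected, micro_average, arm_rates, se, ci_low, ci_high,
#'   n_lower_bound (arms whose affected total is the flagged lower bound),
#'   empty flag.
#' @export
group_micro_average <- function(entries, group = NA_character_,
                                level = 0.95) {
  arms <- lapply(entries, function(e) if (inherits(e, "arm_record")) e else e$arm)
  if (!length(arms)) {
    return(structure(list(group = group, n_arms = 0L, empty = TRUE,
                          total_at_risk = 0L, total_affected = 0L,
                          micro_average = NA_real_, arm_rates = numeric(0),
                          se = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, n_lower_bound = 0L),
                     class = "group_incidence_summary"))
  }
  eff <- lapply(arms, effective_overall_affected)
  affected <- vapply(eff, function(x) as.numeric(x$count), numeric(1))
  enrolled <- vapply(arms, function(a) as.numeric(a$enrolled), numeric(1))
  total_affected <- sum(affected)
  total_at_risk <- sum(enrolled)
  p <- total_affected / total_at_risk
  se <- sqrt(p * (1 - p) / total_at_risk)
  ci <- wald_ci(p, se, level)
  structure(list(group = group, n_arms = length(arms), empty = FALSE,
                 total_at_risk = total_at_risk,
                 total_affected = total_affected,
                 micro_average = p,
                 arm_rates = affected / enrolled,
                 se = se, ci_low = ci[["low"]], ci_high = ci[["high"]],
                 n_lower_bound = sum(vapply(eff, function(x)
                   x$provenance == "lower_bound", logical(1)))),
            class = "group_incidence_summary")
}

#' @export
print.group_incidence_summary <- function(x, ...) {
  if (x$empty) {
    cat("<group_incidence_summary> ", x$group, ": empty\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "<group_incidence_summary> %s: %d arms, %.0f/%.0f affected (%.2f%%, 95%% CI %.2f-%.2f)\n",
    x$group, x$n_arms, x$total_affected, x$total_at_risk,
    100 * x$micro_average, 100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

new_comparison_result <- function(group_a, group_b, estimate, se, t_stat,
                                  df, p_value, flagged = FALSE,
                                  flag_reason = NA_character_) {
  structure(list(group_a = group_a, group_b = group_b, estimate = estimate,
                 se = se, t_stat = t_stat, df = df, p_value = p_value,
                 flagged = flagged, flag_reason = flag_reason),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s vs %s: estimate %.4g (se %.3g)",
              x$group_a, x$group_b, x$estimate, x$se))
  if (x$flagged) {
    cat(" [flagged: ", x$flag_reason, "]\n", sep = "")
  } else {
    cat(sprintf(", t = %.3g, df = %.3g, p = %.3g\n", x$t_stat, x$df,
                x$p_value))
  }
  invisible(x)
}

#' Risk difference between two group micro-averages
#'
#' estimate = p_a - p_b with the two-proportion standard error
#' sqrt(p_a (1-p_a)/n_a + p_b (1-p_b)/n_b), n being each group's total
#' at-risk count. The z statistic estimate/se is reported with a two-sided
#' normal p-value (df = Inf).
#'
#' @param summary_a,summary_b Non-empty `group_incidence_summary` objects.
#' @return A `comparison_result`. Antisymmetric in its arguments
#'   (`estimate(a, b) == -estimate(b, a)`); the se is symmetric.
#' @export
risk_difference <- function(summary_a, summary_b) {
  if (summary_a$empty || summary_b$empty) {
    stop("risk_difference requires two non-empty groups")
  }
  pa <- summary_a$micro_average
  pb <- summary_b$micro_average
  se <- sqrt(pa * (1 - pa) / summary_a$total_at_risk +
             pb * (1 - pb) / summary_b$total_at_risk)
  est <- pa - pb
  z <- if (se > 0) est / se else if (est == 0) 0 else sign(est) * Inf
  new_comparison_result(summary_a$group, summary_b$group, est, se,
                        t_stat = z, df = Inf,
                        p_value = 2 * stats::pnorm(-abs(z)))
}

#' Ratio of two incidence rates (or diversity means)
#'
#' @param p_a,p_b Non-negative values on the same scale; `p_b` must be
#'   positive for a defined ratio.
#' @return `p_a / p_b`; `NA` with a warning when `p_b == 0`.
#' @examples
#' rate_ratio(31.41, 20.76)  # ~1.51
#' @export
rate_ratio <- function(p_a, p_b) {
  if (any(p_b == 0)) {
    warning("undefined ratio: denominator is zero")
    return(ifelse(p_b == 0, NA_real_, p_a / p_b))
  }
  p_a / p_b
}

#' Welch two-sample t-test on per-arm (or per-trial) values
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom. Degenerate inputs — fewer than two values on a side, or zero
#' variance in both samples combined — return a flagged result with no
#' p-value rather than an error.
#'
#' @param sample_a,sample_b Numeric vectors.
#' @param label_a,label_b Labels carried into the result.
#' @return A `comparison_result` with `estimate = mean(a) - mean(b)`.
#' @export
welch_t_test <- function(sample_a, sample_b, label_a = "a", label_b = "b") {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    return(new_comparison_result(label_a, label_b,
                                 mean(sample_a) - mean(sample_b),
                                 NA_real_, NA_real_, NA_real_, NA_real_,
                                 flagged = TRUE,
                                 flag_reason = "fewer than 2 values per side"))
  }
  va <- stats::var(sample_a)
  vb <- stats::var(sample_b)
  if (va + vb == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(new_comparison_result(label_a, label_b, 0, 0, 0, NA_real_, 1))
    }
    return(new_comparison_result(label_a, label_b,
                                 mean(sample_a) - mean(sample_b), 0,
                                 NA_real_, NA_real_, NA_real_,
                                 flagged = TRUE,
                                 flag_reason = "zero variance in both samples"))
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  new_comparison_result(label_a, label_b,
                        estimate = mean(sample_a) - mean(sample_b),
                        se = unname(tt$stderr),
                        t_stat = unname(tt$statistic),
                        df = unname(tt$parameter),
                        p_value = unname(tt$p.value))
}

#' Normal-approximation (Wald) confidence interval
#'
#' mean +/- z * se. For the conventional 95% level z is fixed at 1.96;
#' other levels use the exact normal quantile.
#'
#' @param mean,se Point estimate and its standard error (`se >= 0`).
#' @param level Confidence level in (0, 1).
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' wald_ci(55.55, 2.867)  # c(49.93, 61.17) at 2 d.p.
#' @export
wald_ci <- function(mean, se, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (any(se < 0)) stop("se must be non-negative")
  z <- if (identical(level, 0.95)) 1.96 else
    stats::qnorm(1 - (1 - level) / 2)
  c(low = mean - z * se, high = mean + z * se)
}

#' Per-group incidence table for a partitioned cohort
#'
#' @param partition An `arm_partition`.
#' @param level Confidence level for the pooled-proportion CI.
#' @return Data frame, one row per age group: group, n_arms,
#'   total_at_risk, total_affected, micro_average_pct, ci_low_pct,
#'   ci_high_pct, n_lower_bound.
#' @export
incidence_by_group <- function(partition, level = 0.95) {
  rows <- lapply(names(partition$groups), function(g) {
    s <- group_micro_average(partition$groups[[g]], group = g, level = level)
    data.frame(group = g, n_arms = s$n_arms,
               total_at_risk = s$total_at_risk,
               total_affected = s$total_affected,
               micro_average_pct = 100 * s$micro_average,
               ci_low_pct = 100 * s$ci_low,
               ci_high_pct = 100 * s$ci_high,
               n_lower_bound = s$n_lower_bound,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-vs-reference incidence comparisons
#'
#' For every non-empty, non-reference group: the risk difference on the
#' micro-averages (percentage points), its two-proportion se, a Welch
#' t-test on the per-arm incidence rates (or on per-trial means when
#' `aggregate = "trial"`), and the rate ratio versus the reference group.
#'
#' @param partition An `arm_partition`.
#' @param reference Reference group label (default `"20-29"`).
#' @param aggregate `"arm"` (default) tests per-arm rates; `"trial"`
#'   averages a trial's arms within the group first.
#' @return Data frame, one row per compared group.
#' @export
compare_groups_to_reference <- function(partition, reference = "20-29",
                                        aggregate = c("arm", "trial")) {
  aggregate <- match.arg(aggregate)
  if (!reference %in% names(partition$groups)) {
    stop("unknown reference group '", reference, "'")
  }
  rates_of <- function(entries) {
    r <- vapply(entries, function(e) {
      effective_overall_affected(e$arm)$count / e$arm$enrolled
    }, numeric(1))
    if (aggregate == "trial") {
      ids <- vapply(entries, function(e) e$trial_id, character(1))
      r <- as.numeric(tapply(r, ids, mean))
    }
    r
  }
  ref_sum <- group_micro_average(partition$groups[[reference]],
                                 group = reference)
  if (ref_sum$empty) stop("reference group '", reference, "' is empty")
  ref_rates <- rates_of(partition$groups[[reference]])
  rows <- list()
  for (g in setdiff(names(partition$groups), reference)) {
    s <- group_micro_average(partition$groups[[g]], group = g)
    if (s$empty) next
    rd <- risk_difference(s, ref_sum)
    wt <- welch_t_test(rates_of(partition$groups[[g]]), ref_rates,
                       label_a = g, label_b = reference)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, reference = reference,
      diff_pp = 100 * rd$estimate, se = rd$se,
      t = if (wt$flagged) NA_real_ else wt$t_stat,
      df = if (wt$flagged) NA_real_ else wt$df,
      p = if (wt$flagged) NA_real_ else wt$p_value,
      ratio_vs_reference = rate_ratio(s$micro_average,
                                      ref_sum$micro_average),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(group = character(0), reference = character(0),
                      diff_pp = numeric(0), se = numeric(0), t = numeric(0),
                      df = numeric(0), p = numeric(0),
                      ratio_vs_reference = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
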