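# Per-event cross-group comparison.
#
# For an (event, age group) pair, the target sample holds per-trial mean
# incidences of the event over the trial's arms in the group; the
# comparison sample holds per-trial incidences from trials reporting the
# same event only outside the group. A trial with arms on both sides
# contributes its in-group arms to the target and is excluded from the
# comparison, keeping the two samples disjoint for a valid two-sample
# test.

# per-arm incidence of one canonical event within an arm: max affected/at_risk
# over the arm's event rows whose canonical term matches (raw variants of
# the same canonical term collapse to the best-supported row)
arm_event_incidence <- function(arm, canonical) {
  key <- normalize_term(arm$events$term)
  hit <- key == canonical
  if (!any(hit)) return(NA_real_)
  max(arm$events$subjects_affected[hit] / arm$events$subjects_at_risk[hit])
}

#' Build the target/comparison trial samples for one event and group
#'
#' Per-trial incidence is the mean over the trial's relevant arms (arms in
#' the target group for the target side; arms outside it for the
#' comparison side) of the event's affected/at-risk rate. Trials
#' contributing to the target are excluded from the comparison, so the
#' two trial sets are always disjoint.
#'
#' @param event Event term (canonicalized internally).
#' @param group Age-group label.
#' @param partition An `arm_partition`.
#' @return An `event_cohort_pair`: event, group, `target` and `comparison`
#'   data frames (trial_id, incidence), and a `flagged`/`flag_reason`
#'   pair when either side is empty.
#' @export
build_event_cohorts <- function(event, group, partition) {
  canonical <- normalize_term(event)
  if (!group %in% names(partition$groups)) {
    stop("unknown age group '", group, "'")
  }
  per_trial <- function(entries) {
    inc <- vapply(entries, function(e) arm_event_incidence(e$arm, canonical),
                  numeric(1))
    ids <- vapply(entries, function(e) e$trial_id, character(1))
    keep <- !is.na(inc)
    if (!any(keep)) {
      return(data.frame(trial_id = character(0), incidence = numeric(0),
                        stringsAsFactors = FALSE))
    }
    agg <- tapply(inc[keep], ids[keep], mean)
    data.frame(trial_id = names(agg), incidence = as.numeric(agg),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  target <- per_trial(partition$groups[[group]])
  other <- unlist(partition$groups[setdiff(names(partition$groups), group)],
                  recursive = FALSE)
  comparison <- per_trial(other)
  comparison <- comparison[!comparison$trial_id %in% target$trial_id, ,
                           drop = FALSE]
  flagged <- !nrow(target) || !nrow(comparison)
  structure(list(event = canonical, group = group,
                 target = target, comparison = comparison,
                 flagged = flagged,
                 flag_reason = if (!nrow(target)) {
                   "event not reported in target group"
                 } else if (!nrow(comparison)) {
                   "no comparison trials outside target group"
                 } else NA_character_),
            class = "event_cohort_pair")
}

#' @export
print.event_cohort_pair <- function(x, ...) {
  cat(sprintf("<event_cohort_pair> '%s' in %s: %d target vs %d comparison trials%s\n",
              x$event, x$group, nrow(x$target), nrow(x$comparison),
              if (x$flagged) paste0(" [", x$flag_reason, "]") else ""))
  invisible(x)
}

#' Welch t-test of an event's incidence inside vs outside a group
#'
#' Delegates to [welch_t_test()] on the pair's two per-trial incidence
#' samples. Pairs with fewer than two trials on either side are flagged
#' with no p-value.
#'
#' @param pair An `event_cohort_pair`.
#' @return A `comparison_result` labelled `<group>` vs `other groups`.
#' @export
compare_event_across_groups <- function(pair) {
  welch_t_test(pair$target$incidence, pair$comparison$incidence,
               label_a = pair$group, label_b = "other groups")
}

#' Candidate event-by-group comparison table for a cohort
#'
#' Enumerates every canonical event term in the cohort against every age
#' group, builds the disjoint target/comparison samples, and tests each
#' pair with at least `min_trials` trials per side.
#'
#' @param partition An `arm_partition`.
#' @param map A `term_map` used to annotate each event's SOC.
#' @param min_trials Minimum trials per side for a testable pair.
#' @return Data frame: event, group, soc, n_target, mean_target,
#'   n_comparison, mean_comparison, t, df, p_value. Untestable pairs are
#'   omitted.
#' @export
event_comparison_table <- function(partition, map = default_term_map(),
                                   min_trials = 2L) {
  # flatten once: one row per (arm, canonical event) with the arm-level
  # incidence; semantics identical to build_event_cohorts, which remains
  # the reference path (equivalence is property-tested)
  flat <- list()
  for (g in names(partition$groups)) {
    for (e in partition$groups[[g]]) {
      ev <- e$arm$events
      if (!nrow(ev)) next
      key <- normalize_term(ev$term)
      inc <- ev$subjects_affected / ev$subjects_at_risk
      best <- tapply(inc, key, max)
      flat[[length(flat) + 1L]] <- data.frame(
        key = names(best), group = g, trial_id = e$trial_id,
        inc = as.numeric(best), stringsAsFactors = FALSE)
    }
  }
  if (!length(flat)) flat <- list(data.frame(key = character(0),
                                             group = character(0),
                                             trial_id = character(0),
                                             inc = numeric(0)))
  flat <- do.call(rbind, flat)
  rows <- list()
  for (ev in unique(flat$key)) {
    sub <- flat[flat$key == ev, , drop = FALSE]
    for (g in names(partition$groups)) {
      tgt <- sub[sub$group == g, , drop = FALSE]
      if (!nrow(tgt)) next
      t_inc <- tapply(tgt$inc, tgt$trial_id, mean)
      cmp <- sub[sub$group != g &
                   !(sub$trial_id %in% names(t_inc)), , drop = FALSE]
      if (!nrow(cmp)) next
      c_inc <- tapply(cmp$inc, cmp$trial_id, mean)
      if (length(t_inc) < min_trials || length(c_inc) < min_trials) next
      res <- welch_t_test(as.numeric(t_inc), as.numeric(c_inc),
                          label_a = g, label_b = "other groups")
      if (res$flagged) next
      rows[[length(rows) + 1L]] <- data.frame(
        event = ev, group = g,
        soc = map_to_soc(ev, map),
        n_target = length(t_inc),
        mean_target = mean(t_inc),
        n_comparison = length(c_inc),
        mean_comparison = mean(c_inc),
        t = res$t_stat, df = res$df, p_value = res$p_value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(event = character(0), group = character(0),
                      soc = character(0), n_target = integer(0),
                      mean_target = numeric(0), n_comparison = integer(0),
                      mean_comparison = numeric(0), t = numeric(0),
                      df = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Select and rank significantly elevated events per group
#'
#' Drops events on the nonserious filter list, keeps comparisons with
#' `p_value < alpha`, and ranks within each group by ascending p-value,
#' ties broken by descending target-group mean incidence. An optional
#' Benjamini-Hochberg correction (off by default, matching the raw
#' selection convention) replaces p-values by adjusted ones before the
#' threshold is applied.
#'
#' @param results Data frame from [event_comparison_table()].
#' @param alpha Significance threshold (default 0.01).
#' @param filter_list Character vector of canonical terms to drop (e.g.
#'   [load_filter_list()]).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return The filtered, ranked data frame with a `rank_in_group` column.
#' @export
top_events <- function(results, alpha = 0.01, filter_list = character(0),
                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  out <- results[!results$event %in% normalize_term(filter_list), ,
                 drop = FALSE]
  if (adjust == "BH" && nrow(out)) {
    out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  }
  out <- out[!is.na(out$p_value) & out$p_value < alpha, , drop = FALSE]
  if (!nrow(out)) {
    out$rank_in_group <- integer(0)
    return(out)
  }
  out <- out[order(out$group, out$p_value, -out$mean_target), , drop = FALSE]
  out$rank_in_group <- stats::ave(out$p_value, out$group,
                                  FUN = seq_along)
  rownames(out) <- NULL
  out
}
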