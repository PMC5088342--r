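# Adverse-event diversity: distinct event types per trial arm.
#
# Diversity is a species-richness style count at the arm level — the
# registry does not report which events co-occur in a patient, so
# patient-level diversity is out of reach. Terms are deduplicated on their
# canonical (normalized) strings; group diversity is the arm-level mean.

#' Adverse-event diversity of one arm
#'
#' The number of distinct event types reported for the arm, deduplicating
#' on canonical term strings ([normalize_term()]): "Nausea" and "nausea "
#' count once. An arm reporting heart failure, dizziness and nausea has
#' diversity 3. The SOC map does not enter the count (deduplication is at
#' term level, below SOC).
#'
#' @param arm An `arm_record`.
#' @return Integer count (0 for an arm with no events).
#' @export
arm_diversity <- function(arm) {
  if (!nrow(arm$events)) return(0L)
  length(unique(normalize_term(arm$events$term)))
}

#' Mean adverse-event diversity of a group of arms
#'
#' Mean of the per-arm diversities; se is the sample standard deviation
#' over sqrt(n_arms); 95% CI via [wald_ci()]. With a single arm the se and
#' CI are flagged unavailable.
#'
#' @param entries List of `list(trial_id, arm)` pairs or `arm_record`s.
#' @param group Optional label carried into the summary.
#' @param level Confidence level.
#' @return A `group_diversity_summary`: group, n_arms,
#'   mean_events_per_arm, se, ci_low, ci_high, diversities, empty flag.
#' @export
group_diversity_summary <- function(entries, group = NA_character_,
                                    level = 0.95) {
  arms <- lapply(entries, function(e) if (inherits(e, "arm_record")) e else e$arm)
  if (!length(arms)) {
    return(structure(list(group = group, n_arms = 0L, empty = TRUE,
                          mean_events_per_arm = NA_real_, se = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          diversities = integer(0)),
                     class = "group_diversity_summary"))
  }
  d <- vapply(arms, arm_diversity, integer(1))
  m <- mean(d)
  if (length(d) >= 2) {
    se <- stats::sd(d) / sqrt(length(d))
    ci <- wald_ci(m, se, level)
    ci_low <- ci[["low"]]; ci_high <- ci[["high"]]
  } else {
    se <- NA_real_; ci_low <- NA_real_; ci_high <- NA_real_
  }
  structure(list(group = group, n_arms = length(d), empty = FALSE,
                 mean_events_per_arm = m, se = se,
                 ci_low = ci_low, ci_high = ci_high, diversities = d),
            class = "group_diversity_summary")
}

#' @export
print.group_diversity_summary <- function(x, ...) {
  if (x$empty) {
    cat("<group_diversity_summary> ", x$group, ": empty\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "<group_diversity_summary> %s: %d arms, %.2f events/arm (se %.3g)\n",
    x$group, x$n_arms, x$mean_events_per_arm, x$se))
  invisible(x)
}

#' Per-group diversity table for a partitioned cohort
#'
#' @param partition An `arm_partition`.
#' @return Data frame, one row per age group: group, n_arms,
#'   mean_events_per_arm, se, ci_low, ci_high.
#' @export
diversity_by_group <- function(partition) {
  rows <- lapply(names(partition$groups), function(g) {
    s <- group_diversity_summary(partition$groups[[g]], group = g)
    data.frame(group = g, n_arms = s$n_arms,
               mean_events_per_arm = s$mean_events_per_arm,
               se = s$se, ci_low = s$ci_low, ci_high = s$ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# distinct canonical terms per SOC for one arm; returns a named integer
# vector over soc_classes() plus "UNCLASSIFIED"
arm_soc_counts <- function(arm, map) {
  socs <- c(soc_classes(), unclassifiedLabel())
  counts <- stats::setNames(integer(length(socs)), socs)
  if (!nrow(arm$events)) return(counts)
  key <- normalize_term(arm$events$term)
  soc <- map_to_soc(arm$events$term, map, arm$events$soc_hint)
  dedup <- !duplicated(paste(soc, key, sep = "\r"))
  tab <- table(soc[dedup])
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' SOC-by-age-group diversity matrix
#'
#' Cell (SOC, group) is the mean, over the group's arms, of the number of
#' distinct event types in the arm mapping to that SOC (zero for arms with
#' none). `support` counts the distinct trials in the group with at least
#' one event in the SOC; cells backed by fewer than `low_support` trials
#' are flagged in `low_support_mask` (registry practice treats such cells
#' as weakly supported). Events resolving to no SOC are tracked in a
#' diagnostic `unclassified` row kept out of the 26-row matrix.
#'
#' @param partition An `arm_partition`.
#' @param map A `term_map` (default [default_term_map()]).
#' @param low_support Support threshold in distinct trials (default 30).
#' @return A `soc_diversity_matrix`: list with `values` (26 x 8),
#'   `support` (26 x 8 integer), `low_support_mask` (logical),
#'   `unclassified` (values + support vectors over groups), `n_arms`
#'   (arms per group). Empty groups hold `NA` values and zero support.
#' @export
soc_diversity_matrix <- function(partition, map = default_term_map(),
                                 low_support = 30L) {
  socs <- soc_classes()
  lv <- names(partition$groups)
  values <- matrix(NA_real_, length(socs), length(lv),
                   dimnames = list(socs, lv))
  support <- matrix(0L, length(socs), length(lv),
                    dimnames = list(socs, lv))
  uncls_val <- stats::setNames(rep(NA_real_, length(lv)), lv)
  uncls_sup <- stats::setNames(integer(length(lv)), lv)
  n_arms <- stats::setNames(integer(length(lv)), lv)
  for (g in lv) {
    entries <- partition$groups[[g]]
    n_arms[g] <- length(entries)
    if (!length(entries)) next
    counts <- vapply(entries, function(e) arm_soc_counts(e$arm, map),
                     integer(length(socs) + 1L))
    # counts: (26 + 1) x n_arms
    means <- rowMeans(counts)
    values[, g] <- means[socs]
    uncls_val[g] <- means[unclassifiedLabel()]
    ids <- vapply(entries, function(e) e$trial_id, character(1))
    for (s in socs) {
      support[s, g] <- length(unique(ids[counts[s, ] > 0L]))
    }
    uncls_sup[g] <- length(unique(ids[counts[unclassifiedLabel(), ] > 0L]))
  }
  structure(list(values = values, support = support,
                 low_support_mask = support < low_support,
                 low_support = as.integer(low_support),
                 unclassified = list(values = uncls_val,
                                     support = uncls_sup),
                 n_arms = n_arms),
            class = "soc_diversity_matrix")
}

#' @export
print.soc_diversity_matrix <- function(x, ...) {
  cat("<soc_diversity_matrix> ", nrow(x$values), " SOCs x ",
      ncol(x$values), " age groups; low-support (< ", x$low_support,
      " trials) cells: ", sum(x$low_support_mask), "\n", sep = "")
  invisible(x)
}

# competition (min) rank by descending value; NA cells stay NA
competition_rank_desc <- function(v) {
  r <- rep(NA_integer_, length(v))
  ok <- !is.na(v)
  r[ok] <- as.integer(rank(-v[ok], ties.method = "min"))
  r
}

#' Rank SOCs by diversity within each age group
#'
#' Within each group (column), SOCs are ranked by descending mean
#' diversity with competition ranking: rank 1 is the most diverse; tied
#' values share the minimum applicable rank and are flagged. `total_rank`
#' ranks the 26 SOCs by the unweighted mean of their group values.
#'
#' @param matrix A `soc_diversity_matrix`.
#' @return A `rank_table`: `per_group_ranks` (26 x 8 integer),
#'   `total_rank` (named integer), `total_mean` (named numeric),
#'   `tie_flags` (logical matrix), `total_tie_flags` (logical).
#' @export
rank_soc_diversity <- function(matrix) {
  v <- matrix$values
  ranks <- apply(v, 2, competition_rank_desc)
  dimnames(ranks) <- dimnames(v)
  tie_flags <- apply(v, 2, function(col) {
    !is.na(col) & col %in% col[duplicated(col[!is.na(col)])]
  })
  dimnames(tie_flags) <- dimnames(v)
  total_mean <- rowMeans(v, na.rm = TRUE)
  total_rank <- competition_rank_desc(total_mean)
  names(total_rank) <- rownames(v)
  total_ties <- !is.na(total_mean) &
    total_mean %in% total_mean[duplicated(total_mean[!is.na(total_mean)])]
  structure(list(per_group_ranks = ranks, total_rank = total_rank,
                 total_mean = total_mean, tie_flags = tie_flags,
                 total_tie_flags = total_ties),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  top <- names(sort(x$total_rank))[seq_len(min(3, length(x$total_rank)))]
  cat("<rank_table> 26 SOCs x ", ncol(x$per_group_ranks),
      " groups; top overall: ", paste(top, collapse = ", "), "\n", sep = "")
  invisible(x)
}
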