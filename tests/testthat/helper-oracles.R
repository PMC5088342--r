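# Independent oracles and small fixture builders shared across the suite.
# The oracles deliberately use direct textbook arithmetic on raw fields,
# never the package's own aggregation paths.

# Welch two-sample t-test from the textbook formulas
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# competition rank by counting strictly larger values
rank_oracle_desc <- function(v) {
  v <- unname(v)
  vapply(v, function(x) 1L + sum(v > x), integer(1))
}

# distinct-term count by an independent normalization path
diversity_oracle <- function(terms) {
  k <- trimws(gsub("[[:space:]]+", " ",
                   gsub("[[:punct:]]", " ", tolower(terms))))
  length(unique(k))
}

make_arm <- function(arm_id = "A1", enrolled = 100L, mean_age = 45,
                     overall_affected = NA_integer_, terms = character(0),
                     affected = integer(0), at_risk = NULL,
                     serious = FALSE, soc_hint = NA_character_) {
  events <- if (length(terms)) {
    data.frame(term = terms,
               soc_hint = rep_len(soc_hint, length(terms)),
               serious = rep_len(serious, length(terms)),
               subjects_affected = as.integer(affected),
               subjects_at_risk = as.integer(
                 if (is.null(at_risk)) rep(enrolled, length(terms)) else at_risk),
               stringsAsFactors = FALSE)
  } else NULL
  arm_record(arm_id, enrolled, mean_age = mean_age,
             overall_affected = overall_affected, events = events)
}

# a small seeded synthetic cohort for property loops
small_cohort <- function(seed, n_trials = 5L) {
  generate_cohort(simulation_config(
    n_trials = n_trials, arms_per_trial = c(1L, 2L),
    enrollment = c(20L, 60L),
    event_pool = default_event_pool(per_soc = 1L, max_prob = 0.12),
    seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
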