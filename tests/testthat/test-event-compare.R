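# A tiny cohort with known trial membership: three 40-49 trials and two
# 20-29 trials all reporting pharyngitis.
fixed_event_cohort <- function() {
  mk <- function(id, age, rate_num) {
    trial_record(id, list(
      make_arm("A1", enrolled = 100L, mean_age = age,
               terms = "Pharyngitis", affected = rate_num)))
  }
  list(mk("T1", 45, 10L), mk("T2", 44, 12L), mk("T3", 46, 14L),
       mk("T4", 25, 5L), mk("T5", 26, 6L))
}

test_that("target and comparison samples have the constructed sizes", {
  p <- partition_arms(fixed_event_cohort())
  pair <- build_event_cohorts("Pharyngitis", "40-49", p)
  expect_equal(nrow(pair$target), 3)
  expect_equal(nrow(pair$comparison), 2)
  expect_false(pair$flagged)
  expect_equal(sort(pair$target$incidence), c(0.10, 0.12, 0.14))
  expect_equal(sort(pair$comparison$incidence), c(0.05, 0.06))
})

test_that("an event reported only inside the target group is flagged untestable", {
  p <- partition_arms(fixed_event_cohort())
  # pharyngitis appears in 40-49 and 20-29; from 20-29's view the event
  # exists both sides, but an event unique to one group flags the other way
  only_in <- list(trial_record("S1", list(
    make_arm("A1", enrolled = 50L, mean_age = 33, terms = "Vertigo",
             affected = 3L))))
  pp <- partition_arms(only_in)
  pair <- build_event_cohorts("Vertigo", "30-39", pp)
  expect_true(pair$flagged)
  expect_equal(nrow(pair$comparison), 0)
  absent <- build_event_cohorts("Vertigo", "50-59", pp)
  expect_true(absent$flagged)
  expect_match(absent$flag_reason, "not reported")
})

test_that("a trial spanning both sides goes to target only, keeping samples disjoint", {
  spanning <- trial_record("TX", list(
    make_arm("A1", enrolled = 100L, mean_age = 45, terms = "Pharyngitis",
             affected = 20L),
    make_arm("A2", enrolled = 100L, mean_age = 25, terms = "Pharyngitis",
             affected = 2L)))
  p <- partition_arms(c(fixed_event_cohort(), list(spanning)))
  pair <- build_event_cohorts("Pharyngitis", "40-49", p)
  expect_true("TX" %in% pair$target$trial_id)
  expect_false("TX" %in% pair$comparison$trial_id)
  # only the in-group arm contributes to TX's target incidence
  expect_equal(pair$target$incidence[pair$target$trial_id == "TX"], 0.20)
})

test_that("target and comparison trial sets are disjoint for every event and group", {
  sim <- small_cohort(55, n_trials = 15L)
  p <- partition_arms(sim$records)
  terms <- unique(unlist(lapply(sim$records, function(tr) {
    unlist(lapply(tr$arms, function(a) normalize_term(a$events$term)))
  })))
  for (ev in terms) {
    for (g in age_group_levels()) {
      pair <- build_event_cohorts(ev, g, p)
      expect_length(intersect(pair$target$trial_id,
                              pair$comparison$trial_id), 0)
    }
  }
})

test_that("compare_event_across_groups delegates to the Welch test", {
  p <- partition_arms(fixed_event_cohort())
  pair <- build_event_cohorts("Pharyngitis", "40-49", p)
  res <- compare_event_across_groups(pair)
  direct <- welch_t_test(pair$target$incidence, pair$comparison$incidence)
  expect_equal(res$p_value, direct$p_value)
  expect_equal(res$t_stat, direct$t_stat)
  same <- pair
  same$comparison <- same$target
  expect_equal(compare_event_across_groups(same)$t_stat, 0)
  expect_equal(compare_event_across_groups(same)$p_value, 1)
})

test_that("a spiked event is recovered in its spiked group with p < .01", {
  pool <- data.frame(
    term = c("Pharyngitis", "Nausea", "Headache", "Rash", "Cough",
             "Fatigue", "Dizziness", "Arthralgia", "Insomnia", "Anaemia"),
    soc = c("Infections and infestations", "Gastrointestinal disorders",
            "Nervous system disorders",
            "Skin and subcutaneous tissue disorders",
            "Respiratory, thoracic and mediastinal disorders",
            "General disorders and administration site conditions",
            "Nervous system disorders",
            "Musculoskeletal and connective tissue disorders",
            "Psychiatric disorders",
            "Blood and lymphatic system disorders"),
    base_prob = c(0.15, 0.12, 0.12, 0.10, 0.10, 0.08, 0.08, 0.06, 0.05,
                  0.04),
    serious = FALSE, stringsAsFactors = FALSE)
  hits <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(
      n_trials = 100L, arms_per_trial = 1L, enrollment = c(60L, 150L),
      age_group_weights = rep(1 / 8, 8),
      event_pool = pool,
      group_effect = data.frame(term = "Pharyngitis", group = "0-9",
                                multiplier = 2, stringsAsFactors = FALSE),
      seed = 1000L + r)
    sim <- generate_cohort(cfg)
    p <- partition_arms(sim$records)
    pair <- build_event_cohorts("Pharyngitis", "0-9", p)
    res <- compare_event_across_groups(pair)
    if (!res$flagged && !is.na(res$p_value) && res$p_value < 0.01) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("the comparison table matches the pairwise reference path", {
  sim <- small_cohort(66, n_trials = 12L)
  p <- partition_arms(sim$records)
  tab <- event_comparison_table(p, min_trials = 2L)
  expect_gt(nrow(tab), 0)
  for (k in seq_len(min(nrow(tab), 40L))) {
    pair <- build_event_cohorts(tab$event[k], tab$group[k], p)
    res <- compare_event_across_groups(pair)
    expect_equal(tab$n_target[k], nrow(pair$target))
    expect_equal(tab$n_comparison[k], nrow(pair$comparison))
    expect_equal(tab$p_value[k], res$p_value, tolerance = 1e-12)
    expect_equal(tab$mean_target[k], mean(pair$target$incidence),
                 tolerance = 1e-12)
  }
})

test_that("top_events filters, thresholds and ranks", {
  results <- data.frame(
    event = c("pharyngitis", "headache", "rash", "cough", "vertigo"),
    group = c("0-9", "0-9", "0-9", "40-49", "40-49"),
    soc = "x", n_target = 5L, mean_target = c(0.3, 0.9, 0.2, 0.4, 0.1),
    n_comparison = 5L, mean_comparison = 0.1, t = 3, df = 8,
    p_value = c(0.001, 1e-9, 0.001, 0.5, 0.004),
    stringsAsFactors = FALSE)
  out <- top_events(results, alpha = 0.01, filter_list = c("Headache"))
  expect_false("headache" %in% out$event)
  expect_true(all(out$p_value < 0.01))
  expect_false("cough" %in% out$event)
  zero_nine <- out[out$group == "0-9", ]
  # tie on p broken by descending target mean
  expect_equal(zero_nine$event, c("pharyngitis", "rash"))
  expect_equal(zero_nine$rank_in_group, c(1, 2))
  bh <- top_events(results, alpha = 0.01, adjust = "BH")
  expect_true(all(bh$p_value >= results$p_value[match(bh$event,
                                                      results$event)]))
})
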