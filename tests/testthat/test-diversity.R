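test_that("arm diversity counts distinct normalized event types", {
  arm <- make_arm(terms = c("heart failure", "dizziness", "nausea"),
                  affected = c(1L, 2L, 3L))
  expect_equal(arm_diversity(arm), 3)
  expect_equal(arm_diversity(make_arm()), 0)
  dup <- make_arm(terms = c("Nausea", "nausea  "), affected = c(1L, 2L))
  expect_equal(arm_diversity(dup), 1)
})

test_that("enlarging an arm's event set never decreases diversity", {
  set.seed(13)
  vocab <- names(default_term_map())
  for (i in 1:25) {
    t1 <- sample(vocab, sample(1:10, 1))
    extra <- sample(vocab, sample(1:5, 1))
    a1 <- make_arm(terms = t1, affected = rep(1L, length(t1)))
    a2 <- make_arm(terms = c(t1, extra),
                   affected = rep(1L, length(t1) + length(extra)))
    expect_gte(arm_diversity(a2), arm_diversity(a1))
  }
})

test_that("group diversity summary averages arm diversities with sd/sqrt(n) se", {
  arms <- list(make_arm("A1", terms = c("Nausea", "Rash"),
                        affected = c(1L, 1L)),
               make_arm("A2", terms = c("Nausea", "Rash", "Cough", "Fall"),
                        affected = rep(1L, 4)))
  s <- group_diversity_summary(arms, group = "demo")
  expect_equal(s$mean_events_per_arm, 3)
  one <- group_diversity_summary(arms[1])
  expect_equal(one$mean_events_per_arm, 2)
  expect_true(is.na(one$se) && is.na(one$ci_low))
  expect_true(group_diversity_summary(list())$empty)
})

test_that("group diversity matches a brute-force oracle on a 50-arm synthetic group", {
  sim <- generate_cohort(simulation_config(
    n_trials = 50L, arms_per_trial = 1L, enrollment = c(30L, 80L),
    age_group_weights = c(0, 0, 1, 0, 0, 0, 0, 0), seed = 31L))
  p <- partition_arms(sim$records)
  entries <- p$groups[["20-29"]]
  expect_length(entries, 50)
  s <- group_diversity_summary(entries, group = "20-29")
  d <- vapply(entries, function(e) diversity_oracle(e$arm$events$term),
              numeric(1))
  expect_equal(s$mean_events_per_arm, mean(d), tolerance = 1e-10)
  expect_equal(s$se, stats::sd(d) / sqrt(length(d)), tolerance = 1e-10)
  expect_equal(unname(wald_ci(mean(d), stats::sd(d) / sqrt(length(d)))),
               c(s$ci_low, s$ci_high), tolerance = 1e-10)
})

test_that("a single-SOC cohort fills one matrix row and zeroes the rest", {
  arms <- list(make_arm("A1", mean_age = 25,
                        terms = c("Nausea", "Vomiting"),
                        affected = c(1L, 1L)),
               make_arm("A2", mean_age = 25, terms = "Dyspepsia",
                        affected = 1L))
  p <- partition_arms(list(trial_record("T1", arms[1]),
                           trial_record("T2", arms[2])))
  m <- soc_diversity_matrix(p)
  expect_equal(m$values["Gastrointestinal disorders", "20-29"], 1.5)
  other <- m$values[rownames(m$values) != "Gastrointestinal disorders",
                    "20-29"]
  expect_true(all(other == 0))
  expect_equal(m$support["Gastrointestinal disorders", "20-29"], 2L)
  expect_true(m$low_support_mask["Gastrointestinal disorders", "20-29"])
})

test_that("per-arm SOC diversities plus unclassified conserve total diversity", {
  map <- default_term_map()
  for (seed in c(8, 80)) {
    sim <- small_cohort(seed, n_trials = 10L)
    p <- partition_arms(sim$records)
    m <- soc_diversity_matrix(p, map)
    for (g in age_group_levels()) {
      entries <- p$groups[[g]]
      if (!length(entries)) next
      total <- mean(vapply(entries, function(e) arm_diversity(e$arm),
                           integer(1)))
      expect_equal(sum(m$values[, g]) + m$unclassified$values[g],
                   c(total), tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})

test_that("support counts distinct trials and drives the low-support mask", {
  # 29 single-arm trials sharing one SOC in one group -> masked cell
  trials <- lapply(1:29, function(i) {
    trial_record(paste0("T", i),
                 list(make_arm("A1", mean_age = 45, terms = "Pharyngitis",
                               affected = 1L)))
  })
  p <- partition_arms(trials)
  m <- soc_diversity_matrix(p)
  expect_equal(m$support["Infections and infestations", "40-49"], 29L)
  expect_true(m$low_support_mask["Infections and infestations", "40-49"])
  trials30 <- c(trials, list(trial_record("T30",
    list(make_arm("A1", mean_age = 45, terms = "Pharyngitis",
                  affected = 1L)))))
  m30 <- soc_diversity_matrix(partition_arms(trials30))
  expect_false(m30$low_support_mask["Infections and infestations", "40-49"])
})

test_that("competition ranking matches a sort-based oracle and flags ties", {
  sim <- small_cohort(40, n_trials = 20L)
  p <- partition_arms(sim$records)
  m <- soc_diversity_matrix(p)
  rk <- rank_soc_diversity(m)
  for (g in colnames(m$values)) {
    v <- m$values[, g]
    if (all(is.na(v))) next
    expect_equal(unname(rk$per_group_ranks[, g]), rank_oracle_desc(v))
  }
  # strictly decreasing column ranks 1..26 in order; ties share the min rank
  mm <- m
  mm$values[, 1] <- seq(26, 1)
  mm$values[, 2] <- c(30, 30, seq(24, 1) + 0.5)
  rk2 <- rank_soc_diversity(mm)
  expect_equal(unname(rk2$per_group_ranks[, 1]), 1:26)
  expect_equal(unname(rk2$per_group_ranks[1:3, 2]), c(1L, 1L, 3L))
  expect_true(all(rk2$tie_flags[1:2, 2]))
  expect_false(any(rk2$tie_flags[3:26, 2]))
  # total rank orders by the unweighted cross-group mean
  expect_equal(unname(rk$total_rank),
               rank_oracle_desc(rowMeans(m$values, na.rm = TRUE)))
})
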