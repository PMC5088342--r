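test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulation_config(n_trials = 15L, seed = 123L)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  p1 <- withr::local_tempfile(fileext = ".xml")
  p2 <- withr::local_tempfile(fileext = ".xml")
  write_trial_records(s1$records, p1)
  write_trial_records(s2$records, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  s3 <- generate_cohort(simulation_config(n_trials = 15L, seed = 124L))
  expect_false(identical(lapply(s1$records, unclass),
                         lapply(s3$records, unclass)))
})

test_that("trial and arm counts follow the config", {
  sim <- generate_cohort(simulation_config(n_trials = 10L,
                                           arms_per_trial = 2L, seed = 2L))
  expect_length(sim$records, 10)
  expect_equal(sum(vapply(sim$records, function(tr) length(tr$arms),
                          integer(1))), 20)
  expect_equal(nrow(sim$truth$arms), 20)
})

test_that("invalid configurations fail before any output", {
  expect_error(simulation_config(n_trials = 0), "n_trials")
  expect_error(simulation_config(age_group_weights = rep(0.2, 8)),
               "summing to 1")
  expect_error(simulation_config(group_incidence = c(rep(0.2, 7), 1.5)),
               "group_incidence")
  expect_error(simulation_config(enrollment = c(50L, 10L)), "enrollment")
  pool <- default_event_pool()
  pool$base_prob[1] <- 0
  expect_error(simulation_config(event_pool = pool), "event_pool")
  expect_error(simulation_config(group_effect = data.frame(
    term = "x", group = "nope", multiplier = 1)), "group_effect")
})

test_that("generated cohorts satisfy the registry invariants for varied configs", {
  for (seed in c(1, 2)) {
    sim <- generate_cohort(simulation_config(
      n_trials = 8L, arms_per_trial = c(1L, 4L), enrollment = c(10L, 30L),
      seed = seed))
    for (tr in sim$records) {
      expect_length(aecohort:::validate_trial(tr), 0)
      for (a in tr$arms) {
        expect_lte(a$overall_affected, a$enrolled)
        if (nrow(a$events)) {
          expect_true(all(a$events$subjects_affected >= 1L))
          expect_gte(a$overall_affected, max(a$events$subjects_affected))
        }
      }
    }
  }
})

test_that("per-group probabilities reproduce the configured overall incidence", {
  cfg <- simulation_config(seed = 3L)
  sim <- generate_cohort(cfg)
  expect_equal(unname(sim$truth$achieved_incidence),
               unname(cfg$group_incidence), tolerance = 1e-8)
})

test_that("the reporting threshold removes exactly sub-threshold nonserious events", {
  arm_a <- make_arm("A1", enrolled = 100L, mean_age = 50,
                    terms = c("Nausea", "Rash", "Sepsis"),
                    affected = c(4L, 10L, 1L),
                    serious = c(FALSE, FALSE, TRUE))
  arm_b <- make_arm("A2", enrolled = 100L, mean_age = 52,
                    terms = c("Nausea", "Rash"),
                    affected = c(3L, 2L), serious = c(FALSE, FALSE))
  cohort <- aecohort:::new_trial_cohort(
    list(trial_record("T1", list(arm_a, arm_b))))

  same <- apply_reporting_threshold(cohort, 0)
  expect_identical(lapply(same, unclass), lapply(cohort, unclass))

  thr <- apply_reporting_threshold(cohort, 0.05)
  ev_a <- thr[[1]]$arms[[1]]$events
  ev_b <- thr[[1]]$arms[[2]]$events
  # nausea at 4% and 3% in the two arms: below threshold everywhere -> gone
  expect_false("Nausea" %in% ev_a$term)
  expect_false("Nausea" %in% ev_b$term)
  # rash exceeds 5% in one arm -> kept in every arm of the trial
  expect_true("Rash" %in% ev_a$term)
  expect_true("Rash" %in% ev_b$term)
  # serious events exempt even at 1%
  expect_true("Sepsis" %in% ev_a$term)
  # overall_affected untouched, counts never increase
  expect_equal(thr[[1]]$arms[[1]]$overall_affected,
               cohort[[1]]$arms[[1]]$overall_affected)
  expect_lte(nrow(ev_a), nrow(cohort[[1]]$arms[[1]]$events))
})

test_that("thresholding only ever drops nonserious sub-threshold rows", {
  sim <- generate_cohort(simulation_config(n_trials = 12L,
                                           enrollment = c(30L, 60L),
                                           seed = 9L))
  thr <- apply_reporting_threshold(sim$records, 0.05)
  for (i in seq_along(sim$records)) {
    for (j in seq_along(sim$records[[i]]$arms)) {
      before <- sim$records[[i]]$arms[[j]]$events
      after <- thr[[i]]$arms[[j]]$events
      expect_true(all(after$term %in% before$term))
      dropped <- setdiff(before$term, after$term)
      drows <- before[before$term %in% dropped, , drop = FALSE]
      expect_true(all(!drows$serious))
    }
  }
})

test_that("a larger event pool yields higher expected and observed diversity", {
  narrow <- simulation_config(
    n_trials = 40L, arms_per_trial = 1L, enrollment = c(80L, 120L),
    event_pool = default_event_pool(per_soc = 1L), seed = 17L)
  wide <- simulation_config(
    n_trials = 40L, arms_per_trial = 1L, enrollment = c(80L, 120L),
    event_pool = default_event_pool(per_soc = 4L), seed = 17L)
  s_narrow <- generate_cohort(narrow)
  s_wide <- generate_cohort(wide)
  expect_true(all(s_wide$truth$expected_diversity >
                    s_narrow$truth$expected_diversity))
  mean_div <- function(sim) {
    mean(unlist(lapply(sim$records, function(tr) {
      vapply(tr$arms, arm_diversity, integer(1))
    })))
  }
  expect_gt(mean_div(s_wide), mean_div(s_narrow))
})

test_that("ground truth serializes to JSON with the recovery quantities", {
  sim <- generate_cohort(simulation_config(n_trials = 5L, seed = 4L))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$seed, 4L)
  expect_length(back$expected_diversity, 8)
  expect_equal(back$achieved_incidence[["20-29"]],
               unname(sim$truth$achieved_incidence["20-29"]),
               tolerance = 1e-12)
  expect_equal(length(back$arms$trial_id), nrow(sim$truth$arms))
})
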