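# Synthetic registry cohorts with known ground truth.
#
# The generator emulates the structure the analyses consume: trials with
# one or more arms, per-arm enrollment and mean age, per-event
# affected/at-risk counts, serious vs nonserious events, age-group-
# dependent event probabilities, and (optionally) the registry convention
# of omitting nonserious events under a 5% within-arm frequency. Events
# are independent across participants and terms; affected counts and the
# deduplicated overall-affected total come from one participant-level
# simulation, so they are mutually consistent.

#' Default synthetic event pool
#'
#' Up to `per_soc` terms per SOC drawn from the shipped term map, with
#' geometrically declining base probabilities (most common term
#' `max_prob`); the rarest `serious_fraction` of terms are marked serious,
#' mirroring the registry pattern that serious events are the rarer ones.
#'
#' @param per_soc Terms kept per SOC (default 2).
#' @param max_prob Base probability of the most common term.
#' @param decay Geometric decay of base probabilities down the pool.
#' @param serious_fraction Fraction of terms flagged serious.
#' @return Data frame: term, soc, base_prob, serious.
#' @export
default_event_pool <- function(per_soc = 2L, max_prob = 0.08, decay = 0.94,
                               serious_fraction = 0.1) {
  map <- default_term_map()
  terms <- names(map)
  socs <- unname(unclass(map))
  keep <- unlist(lapply(unique(socs), function(s) {
    utils::head(which(socs == s), per_soc)
  }))
  keep <- sort(keep)
  n <- length(keep)
  pool <- data.frame(term = terms[keep], soc = socs[keep],
                     base_prob = max_prob * decay^(seq_len(n) - 1),
                     serious = FALSE, stringsAsFactors = FALSE)
  n_serious <- ceiling(serious_fraction * n)
  if (n_serious > 0) {
    pool$serious[order(pool$base_prob)[seq_len(n_serious)]] <- TRUE
  }
  pool
}

#' Simulation configuration for [generate_cohort()]
#'
#' The defaults describe an illustrative registry-like cohort: 200 trials
#' of 1-3 arms, 40-200 participants per arm, age-group weights skewed
#' toward older groups, and per-group overall incidence peaking in the
#' youngest (0-9) and the 50-59 groups with a trough at 20-29 — the
#' qualitative pattern seen in registry data. Per-term probabilities are
#' rescaled per group (see [generate_cohort()]) so each group's expected
#' overall incidence equals `group_incidence`.
#'
#' @param n_trials Number of trials.
#' @param arms_per_trial Integer range `c(min, max)` (or single value).
#' @param enrollment Integer range of participants per arm.
#' @param age_group_weights Eight probabilities summing to 1, in
#'   [age_group_levels()] order.
#' @param group_incidence Eight per-group overall incidence targets in
#'   (0, 1).
#' @param event_pool Data frame (term, soc, base_prob, serious); default
#'   [default_event_pool()].
#' @param group_effect Optional data frame (term, group, multiplier)
#'   scaling a term's probability in one group (applied after the
#'   incidence calibration, clipped to `[0, 0.99]` with a warning).
#' @param soc_hint_fraction Fraction of event rows carrying the
#'   registry-style SOC annotation.
#' @param reporting_threshold Nonserious reporting threshold applied by
#'   [generate_cohort()] before returning (0 = report everything; 0.05 =
#'   registry convention).
#' @param seed Integer seed; the cohort is a deterministic function of
#'   the config.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_trials = 200L,
                              arms_per_trial = c(1L, 3L),
                              enrollment = c(40L, 200L),
                              age_group_weights = c(0.08, 0.07, 0.10, 0.12,
                                                    0.15, 0.18, 0.17, 0.13),
                              group_incidence = c(0.31, 0.24, 0.21, 0.24,
                                                  0.27, 0.30, 0.28, 0.27),
                              event_pool = default_event_pool(),
                              group_effect = NULL,
                              soc_hint_fraction = 0.5,
                              reporting_threshold = 0,
                              seed = 1L) {
  if (length(arms_per_trial) == 1L) arms_per_trial <- rep(arms_per_trial, 2)
  if (length(enrollment) == 1L) enrollment <- rep(enrollment, 2)
  cfg <- list(n_trials = as.integer(n_trials),
              arms_per_trial = as.integer(arms_per_trial),
              enrollment = as.integer(enrollment),
              age_group_weights = stats::setNames(age_group_weights,
                                                  age_group_levels()),
              group_incidence = stats::setNames(group_incidence,
                                                age_group_levels()),
              event_pool = event_pool,
              group_effect = group_effect,
              soc_hint_fraction = soc_hint_fraction,
              reporting_threshold = reporting_threshold,
              seed = as.integer(seed))
  problems <- character(0)
  if (is.na(cfg$n_trials) || cfg$n_trials < 1L) {
    problems <- c(problems, "n_trials must be a positive integer")
  }
  if (any(is.na(cfg$arms_per_trial)) || cfg$arms_per_trial[1] < 1L ||
      cfg$arms_per_trial[2] < cfg$arms_per_trial[1]) {
    problems <- c(problems, "arms_per_trial must be a positive range")
  }
  if (any(is.na(cfg$enrollment)) || cfg$enrollment[1] < 1L ||
      cfg$enrollment[2] < cfg$enrollment[1]) {
    problems <- c(problems, "enrollment must be a positive range")
  }
  if (length(cfg$age_group_weights) != 8L ||
      any(cfg$age_group_weights < 0) ||
      abs(sum(cfg$age_group_weights) - 1) > 1e-8) {
    problems <- c(problems, "age_group_weights must be 8 values summing to 1")
  }
  if (length(cfg$group_incidence) != 8L ||
      any(cfg$group_incidence <= 0 | cfg$group_incidence >= 1)) {
    problems <- c(problems, "group_incidence must be 8 values in (0, 1)")
  }
  ep <- cfg$event_pool
  if (!is.data.frame(ep) || !all(c("term", "soc", "base_prob",
                                   "serious") %in% names(ep)) ||
      !nrow(ep) || any(ep$base_prob <= 0 | ep$base_prob > 1) ||
      anyDuplicated(normalize_term(ep$term))) {
    problems <- c(problems,
                  "event_pool must have unique terms and base_prob in (0, 1]")
  } else if (!all(ep$soc %in% soc_classes())) {
    problems <- c(problems, "event_pool soc values must be valid SOC names")
  }
  if (!is.null(cfg$group_effect)) {
    ge <- cfg$group_effect
    if (!is.data.frame(ge) || !all(c("term", "group",
                                     "multiplier") %in% names(ge)) ||
        any(ge$multiplier < 0) ||
        !all(ge$group %in% age_group_levels())) {
      problems <- c(problems,
                    "group_effect must map (term, group) to multiplier >= 0")
    }
  }
  if (cfg$soc_hint_fraction < 0 || cfg$soc_hint_fraction > 1) {
    problems <- c(problems, "soc_hint_fraction must be in [0, 1]")
  }
  if (cfg$reporting_threshold < 0 || cfg$reporting_threshold > 1) {
    problems <- c(problems, "reporting_threshold must be in [0, 1]")
  }
  if (length(problems)) {
    stop("invalid simulation config: ", paste(problems, collapse = "; "))
  }
  structure(cfg, class = "simulation_config")
}

# uniform draw from an integer range; safe when min == max (sample() would
# otherwise treat the scalar as 1:x)
sample_range <- function(range) {
  if (range[1] == range[2]) return(range[1])
  sample(range[1]:range[2], 1L)
}

# solve s so that 1 - prod(1 - min(s * p, cap)) == target; monotone in s
solve_incidence_scale <- function(p, target, cap = 0.99) {
  f <- function(s) 1 - prod(1 - pmin(s * p, cap)) - target
  hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (f(hi) < 0) {
    warning("incidence target ", target,
            " unreachable with this event pool; using saturated pool")
    return(hi)
  }
  stats::uniroot(f, c(0, hi), tol = 1e-12)$root
}

# per-group per-term probability matrix (terms x 8), calibrated so that
# without multipliers each group's overall incidence is the target
group_term_probs <- function(cfg) {
  p <- cfg$event_pool$base_prob
  lv <- age_group_levels()
  probs <- matrix(NA_real_, length(p), length(lv),
                  dimnames = list(normalize_term(cfg$event_pool$term), lv))
  clipped <- FALSE
  for (g in lv) {
    s <- solve_incidence_scale(p, cfg$group_incidence[[g]])
    pg <- pmin(s * p, 0.99)
    if (!is.null(cfg$group_effect)) {
      ge <- cfg$group_effect[cfg$group_effect$group == g, , drop = FALSE]
      if (nrow(ge)) {
        idx <- match(normalize_term(ge$term), rownames(probs))
        raw <- pg[idx] * ge$multiplier
        if (any(raw > 0.99)) clipped <- TRUE
        pg[idx] <- pmin(raw, 0.99)
      }
    }
    probs[, g] <- pg
  }
  if (clipped) {
    warning("group_effect multipliers pushed probabilities above 0.99; clipped")
  }
  probs
}

#' Generate a synthetic trial cohort with ground truth
#'
#' For each arm: an age group is drawn by `age_group_weights`, the mean
#' age uniformly inside the group's bin, and enrollment uniformly in the
#' `enrollment` range. Each participant experiences each pool term
#' independently with the group's calibrated probability;
#' `subjects_affected` is the resulting per-term count,
#' `overall_affected` the number of participants with at least one event,
#' and terms with zero affected are omitted (the registry never reports
#' them). A nonzero `reporting_threshold` additionally drops sub-threshold
#' nonserious events via [apply_reporting_threshold()]. Deterministic
#' under the config seed.
#'
#' @param config A [simulation_config()].
#' @return List with `records` (a `trial_cohort`) and `truth` (a
#'   `ground_truth` list: per-arm assignments, per-group term
#'   probabilities, achieved overall incidence, and the analytic expected
#'   diversity per arm).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  set.seed(config$seed)
  probs <- group_term_probs(config)
  lv <- age_group_levels()
  bounds <- age_group_bounds()
  pool <- config$event_pool
  pool_terms <- pool$term
  n_terms <- nrow(pool)
  trials <- vector("list", config$n_trials)
  arm_rows <- list()
  id_width <- max(4L, nchar(as.character(config$n_trials)))
  for (i in seq_len(config$n_trials)) {
    trial_id <- sprintf(paste0("T%0", id_width, "d"), i)
    n_arms <- sample_range(config$arms_per_trial)
    arms <- vector("list", n_arms)
    for (j in seq_len(n_arms)) {
      g_idx <- sample.int(8L, 1L, prob = config$age_group_weights)
      g <- lv[g_idx]
      mean_age <- stats::runif(1, bounds$lower[g_idx], bounds$upper[g_idx])
      n <- sample_range(config$enrollment)
      # participant x term independent Bernoulli draws
      hit <- matrix(stats::runif(n * n_terms) <
                      rep(probs[, g], each = n), n, n_terms)
      affected <- colSums(hit)
      overall <- sum(rowSums(hit) > 0L)
      present <- which(affected > 0L)
      events <- if (length(present)) {
        hinted <- stats::runif(length(present)) < config$soc_hint_fraction
        data.frame(term = pool_terms[present],
                   soc_hint = ifelse(hinted, pool$soc[present],
                                     NA_character_),
                   serious = pool$serious[present],
                   subjects_affected = as.integer(affected[present]),
                   subjects_at_risk = rep(as.integer(n), length(present)),
                   stringsAsFactors = FALSE)
      } else empty_events()
      arms[[j]] <- arm_record(arm_id = paste0("A", j), enrolled = n,
                              mean_age = mean_age,
                              overall_affected = as.integer(overall),
                              events = events)
      arm_rows[[length(arm_rows) + 1L]] <-
        data.frame(trial_id = trial_id, arm_id = paste0("A", j),
                   group = g, mean_age = mean_age, enrolled = n,
                   stringsAsFactors = FALSE)
    }
    trials[[i]] <- trial_record(trial_id, arms)
  }
  records <- new_trial_cohort(trials)
  if (config$reporting_threshold > 0) {
    records <- apply_reporting_threshold(records,
                                         config$reporting_threshold)
  }
  enr_grid <- config$enrollment[1]:config$enrollment[2]
  expected_diversity <- vapply(lv, function(g) {
    mean(vapply(enr_grid,
                function(n) sum(1 - (1 - probs[, g])^n), numeric(1)))
  }, numeric(1))
  achieved_incidence <- vapply(lv, function(g) {
    1 - prod(1 - probs[, g])
  }, numeric(1))
  truth <- structure(list(
    seed = config$seed,
    arms = do.call(rbind, arm_rows),
    group_term_probs = probs,
    target_incidence = config$group_incidence,
    achieved_incidence = achieved_incidence,
    expected_diversity = expected_diversity,
    reporting_threshold = config$reporting_threshold),
    class = "ground_truth")
  list(records = records, truth = truth)
}

#' Apply the registry's nonserious reporting threshold
#'
#' Within each trial, a nonserious event (keyed by canonical term) is kept
#' only if its frequency (affected/at-risk) exceeds `threshold` in at
#' least one arm of that trial; serious events are always kept and
#' `overall_affected` is left unchanged. With `threshold = 0` this is the
#' identity.
#'
#' @param records A `trial_cohort`.
#' @param threshold Proportion in `[0, 1]` (registry convention: 0.05).
#' @return The filtered `trial_cohort`.
#' @export
apply_reporting_threshold <- function(records, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (threshold == 0) return(records)
  out <- lapply(records, function(tr) {
    # per canonical term, the best within-arm frequency among nonserious rows
    freq <- new.env(parent = emptyenv())
    for (a in tr$arms) {
      ev <- a$events
      if (!nrow(ev)) next
      key <- normalize_term(ev$term)
      f <- ev$subjects_affected / ev$subjects_at_risk
      for (k in which(!ev$serious)) {
        cur <- mget(key[k], envir = freq, ifnotfound = -1)[[1]]
        if (f[k] > cur) assign(key[k], f[k], envir = freq)
      }
    }
    arms <- lapply(tr$arms, function(a) {
      ev <- a$events
      if (!nrow(ev)) return(a)
      key <- normalize_term(ev$term)
      keep <- ev$serious | vapply(key, function(k) {
        mget(k, envir = freq, ifnotfound = -1)[[1]] > threshold
      }, logical(1))
      a$events <- ev[keep, , drop = FALSE]
      rownames(a$events) <- NULL
      a
    })
    tr$arms <- arms
    tr
  })
  new_trial_cohort(out, attr(records, "rejected"))
}

#' Serialize ground truth as JSON
#'
#' @param truth A `ground_truth` from [generate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(seed = truth$seed,
              arms = truth$arms,
              group_term_probs = cbind(
                data.frame(term = rownames(truth$group_term_probs),
                           stringsAsFactors = FALSE),
                as.data.frame(truth$group_term_probs)),
              target_incidence = as.list(truth$target_incidence),
              achieved_incidence = as.list(truth$achieved_incidence),
              expected_diversity = as.list(truth$expected_diversity),
              reporting_threshold = truth$reporting_threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
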