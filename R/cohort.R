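# Age-group binning of trial arms.
#
# Arms are binned by reported mean participant age into eight groups in
# 10-year increments, except the terminal group which spans 70-100. The
# first seven bins are half-open [L, L+10); the last is closed [70, 100],
# so the bins tile [0, 100] without overlap. Arms with missing or
# out-of-range mean age are excluded from group analyses with a diagnostic,
# never silently.

#' Age-group labels, youngest to oldest
#' @return Character vector of the eight labels.
#' @export
age_group_levels <- function() {
  c("0-9", "10-19", "20-29", "30-39", "40-49", "50-59", "60-69", "70-100")
}

#' Age-group bin boundaries
#' @return Data frame with `label`, `lower`, `upper`. The first seven bins
#'   are half-open on the right; the last is closed.
#' @export
age_group_bounds <- function() {
  data.frame(label = age_group_levels(),
             lower = c(0, 10, 20, 30, 40, 50, 60, 70),
             upper = c(10, 20, 30, 40, 50, 60, 70, 100),
             stringsAsFactors = FALSE)
}

#' Assign mean ages to age groups
#'
#' @param mean_age Numeric vector of mean ages in years; `NA` allowed.
#' @return Factor with levels [age_group_levels()]; `NA` for missing ages
#'   or ages outside `[0, 100]` (callers report these as exclusions).
#' @examples
#' assign_age_group(c(9.99, 10, 70, 100, 100.5, NA))
#' @export
assign_age_group <- function(mean_age) {
  lv <- age_group_levels()
  idx <- ifelse(is.na(mean_age) | mean_age < 0 | mean_age > 100,
                NA_integer_,
                pmin(floor(mean_age / 10) + 1, 8L))
  factor(lv[idx], levels = lv)
}

#' Partition a cohort's arms into age groups
#'
#' Every arm with an in-range mean age lands in exactly one group; arms
#' with missing or out-of-range mean age are collected in an exclusions
#' table with a reason. Group membership plus exclusions always account
#' for every arm in the input.
#'
#' @param records A `trial_cohort` or list of `trial_record`s.
#' @return An `arm_partition`: list with `groups` (named list, one entry
#'   per age group, each a list of `list(trial_id, arm)` pairs) and
#'   `exclusions` (data frame: trial_id, arm_id, reason).
#' @export
partition_arms <- function(records) {
  lv <- age_group_levels()
  groups <- stats::setNames(vector("list", length(lv)), lv)
  for (g in lv) groups[[g]] <- list()
  excl <- list()
  for (tr in records) {
    for (a in tr$arms) {
      if (is.na(a$mean_age)) {
        excl[[length(excl) + 1L]] <-
          data.frame(trial_id = tr$trial_id, arm_id = a$arm_id,
                     reason = "missing mean_age", stringsAsFactors = FALSE)
        next
      }
      g <- as.character(assign_age_group(a$mean_age))
      if (is.na(g)) {
        excl[[length(excl) + 1L]] <-
          data.frame(trial_id = tr$trial_id, arm_id = a$arm_id,
                     reason = "mean_age outside [0, 100]",
                     stringsAsFactors = FALSE)
        next
      }
      groups[[g]][[length(groups[[g]]) + 1L]] <-
        list(trial_id = tr$trial_id, arm = a)
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(trial_id = character(0), arm_id = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  structure(list(groups = groups, exclusions = exclusions),
            class = "arm_partition")
}

#' @export
print.arm_partition <- function(x, ...) {
  cat("<arm_partition>\n")
  for (g in names(x$groups)) {
    cat(sprintf("  %-7s %d arms\n", g, length(x$groups[[g]])))
  }
  if (nrow(x$exclusions)) {
    cat("  excluded:", nrow(x$exclusions), "arm(s)\n")
  }
  invisible(x)
}
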