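#' Fixed experimental reversal schedule
#'
#' The 160-trial probabilistic reversal-learning block used in the behavioral
#' experiment: reward contingencies are stable for the first 55 trials
#' (pre-reversal phase), then reverse four times after intervals of 15 or 20
#' trials (reversal phase, 70 trials in total), and remain stable for the
#' final 35 trials (post-reversal phase). The ordering of the four mid-block
#' intervals is configurable; any permutation of two 15s and two 20s is
#' admissible.
#'
#' @param interval_pattern Integer vector of the four mid-block intervals;
#'   must consist of 15s and 20s summing to 70. Default `c(20, 15, 20, 15)`.
#' @param p_high Reward probability of the currently better option.
#' @return A `task_schedule` object; see [make_schedule()].
#' @export
#' @examples
#' sched <- experimental_schedule()
#' sched$reversal_trials  # 56 76 91 111 126
experimental_schedule <- function(interval_pattern = c(20L, 15L, 20L, 15L),
                                  p_high = 0.8) {
  if (length(interval_pattern) != 4L || !all(interval_pattern %in% c(15L, 20L)) ||
      sum(interval_pattern) != 70L) {
    stop("`interval_pattern` must be four intervals of 15 or 20 trials summing to 70")
  }
  intervals <- c(55L, as.integer(interval_pattern), 35L)
  make_schedule(intervals, n_trials = 160L, p_high = p_high)
}

#' Build a task schedule from a sequence of dwell intervals
#'
#' @param intervals Integer vector of between-reversal intervals; the
#'   environment starts in the non-reversal state and flips after each
#'   interval elapses.
#' @param n_trials Total number of trials; intervals are truncated or an
#'   error raised if they do not cover the block.
#' @param p_high Reward probability of the better option (the worse option
#'   wins with `1 - p_high`; the two options are anti-correlated).
#' @return An object of class `task_schedule` with fields `n_trials`,
#'   `states` (per-trial, `"NR"`/`"R"`), `reversal_trials` (1-based trial
#'   indices at which the state differs from the previous trial), `p_high`
#'   and `p_low`.
#' @export
make_schedule <- function(intervals, n_trials = sum(intervals), p_high = 0.8) {
  stopifnot(p_high >= 0, p_high <= 1, all(intervals >= 1), n_trials >= 1)
  if (sum(intervals) < n_trials) {
    stop("intervals cover only ", sum(intervals), " of ", n_trials, " trials")
  }
  states_full <- rep(rep(c("NR", "R"), length.out = length(intervals)),
                     times = intervals)
  states <- states_full[seq_len(n_trials)]
  reversal_trials <- which(states[-1L] != states[-n_trials]) + 1L
  structure(
    list(n_trials = as.integer(n_trials), states = states,
         reversal_trials = as.integer(reversal_trials),
         p_high = p_high, p_low = 1 - p_high),
    class = "task_schedule"
  )
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("Task schedule: %d trials, %d reversals (p_high = %.2f)\n",
              x$n_trials, length(x$reversal_trials), x$p_high))
  if (length(x$reversal_trials)) {
    cat("  reversals at trials:", paste(x$reversal_trials, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sample a reversal schedule from a duration prior
#'
#' Draws between-reversal intervals i.i.d. from a [duration_prior()] until the
#' block is covered, truncating the final interval. Used to build the
#' "irregular" (geometric, mu = 20) and "semi-regular" (negative binomial,
#' mu = 20, sigma = 20) simulation environments.
#'
#' @param interval_prior A [duration_prior()] over interval lengths.
#' @param n_trials Number of trials in the block.
#' @param p_high Reward probability of the better option.
#' @return A `task_schedule`. Uses the current RNG state; call `set.seed()`
#'   beforehand for reproducibility.
#' @export
sample_schedule <- function(interval_prior, n_trials = 160L, p_high = 0.8) {
  stopifnot(inherits(interval_prior, "duration_prior"))
  n_trials <- as.integer(n_trials)
  intervals <- integer(0)
  total <- 0L
  while (total < n_trials) {
    d <- sample.int(interval_prior$d_max, 1L, prob = interval_prior$pmf)
    intervals <- c(intervals, d)
    total <- total + d
  }
  make_schedule(intervals, n_trials = n_trials, p_high = p_high)
}

#' Correct (high-reward-probability) option at a trial
#'
#' Option `"A"` is, by convention, the better option in the non-reversal
#' state; in the reversal state the contingencies are swapped.
#'
#' @param schedule A `task_schedule`.
#' @param trial Trial index (vectorized).
#' @return Character vector of `"A"`/`"B"`.
#' @export
correct_choice <- function(schedule, trial = seq_len(schedule$n_trials)) {
  ifelse(schedule$states[trial] == "NR", "A", "B")
}

#' Sample a trial outcome
#'
#' The chosen option wins (`+1`) with probability `p_high` when it is the
#' currently better option, and with `p_low = 1 - p_high` otherwise; losses
#' are coded `-1`. Win probabilities of the two options are anti-correlated.
#'
#' @param schedule A `task_schedule`.
#' @param trial Trial index.
#' @param choice `"A"` or `"B"`.
#' @return `+1` or `-1`. Uses the current RNG state.
#' @export
sample_outcome <- function(schedule, trial, choice) {
  if (trial > schedule$n_trials) stop("`trial` exceeds the schedule length")
  p_win <- if (choice == correct_choice(schedule, trial)) schedule$p_high else schedule$p_low
  if (stats::runif(1L) < p_win) 1 else -1
}

#' Assemble a behavioral dataset
#'
#' Tidy per-trial record of one subject's choices and outcomes, optionally
#' annotated with the generating schedule's latent state and correctness.
#'
#' @param subject Subject identifier.
#' @param choice Character vector of `"A"`/`"B"`.
#' @param outcome Numeric vector of `-1`/`+1`.
#' @param schedule Optional `task_schedule` that generated the block; adds
#'   `state` and `correct` columns.
#' @return A `data.frame` with columns `subject`, `trial`, `choice`,
#'   `outcome` and, when a schedule is given, `state` and `correct`.
#' @export
behavioral_dataset <- function(subject, choice, outcome, schedule = NULL) {
  n <- length(choice)
  if (length(outcome) != n) stop("`choice` and `outcome` lengths differ")
  if (!all(choice %in% c("A", "B"))) stop("choices must be \"A\" or \"B\"")
  if (!all(outcome %in% c(-1, 1))) stop("outcomes must be -1 or +1")
  d <- data.frame(subject = subject, trial = seq_len(n), choice = choice,
                  outcome = as.integer(outcome), stringsAsFactors = FALSE)
  if (!is.null(schedule)) {
    if (schedule$n_trials != n) stop("schedule length does not match the data")
    d$state <- schedule$states
    d$correct <- as.integer(choice == correct_choice(schedule))
  }
  d
}

#' Validate a behavioral dataset data frame
#'
#' Checks the CSV schema contract: required columns `subject`, `trial`,
#' `choice` (`"A"`/`"B"`), `outcome` (`-1`/`1`), consecutive trials within
#' subject.
#'
#' @param data A data frame.
#' @return `data` invisibly; errors describe the first violated constraint.
#' @export
validate_behavior <- function(data) {
  req <- c("subject", "trial", "choice", "outcome")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(data$choice %in% c("A", "B"))) stop("choices must be \"A\" or \"B\"")
  if (!all(data$outcome %in% c(-1, 1))) stop("outcomes must be -1 or +1")
  bad <- vapply(split(data$trial, data$subject),
                function(tr) any(tr != seq_along(tr)), logical(1))
  if (any(bad)) {
    stop("trials must be consecutive from 1 within subject: ",
         paste(names(bad)[bad], collapse = ", "))
  }
  invisible(data)
}

#' Read / write behavioral CSV files
#'
#' @param path File path.
#' @return `read_behavior_csv` returns a validated data frame;
#'   `write_behavior_csv` returns `path` invisibly.
#' @export
read_behavior_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_behavior(d)
  d
}

#' @param data A behavioral data frame (see [behavioral_dataset()]).
#' @rdname read_behavior_csv
#' @export
write_behavior_csv <- function(data, path) {
  validate_behavior(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a task schedule to JSON
#'
#' @param schedule A `task_schedule`.
#' @param path Optional output file.
#' @return JSON string, invisibly when written to file.
#' @export
schedule_to_json <- function(schedule, path = NULL) {
  js <- jsonlite::toJSON(
    list(n_trials = schedule$n_trials, states = schedule$states,
         reversal_trials = schedule$reversal_trials,
         p_high = schedule$p_high),
    auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a task schedule from JSON
#'
#' @param x JSON string or file path.
#' @return A `task_schedule`.
#' @export
schedule_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  n <- obj$n_trials
  structure(
    list(n_trials = as.integer(n), states = obj$states,
         reversal_trials = as.integer(obj$reversal_trials),
         p_high = obj$p_high, p_low = 1 - obj$p_high),
    class = "task_schedule"
  )
}
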