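## Choice-performance summaries and the t-test / effect-size battery used to
## compare performance against chance (50%) and between trial groupings.

#' Percent correct choices
#'
#' Percentage of correct choices among countable trials
#' (`100 * correct / (correct + error)`), optionally restricted to a trial
#' type and/or stimulus class. Aborted and no-choice trials never count.
#'
#' @param sessions A session, list of sessions, or list of `peck_trial`s.
#' @param trial_type Optional `"known"` or `"transfer"`.
#' @param class Optional `"X"` or `"Y"`; `NULL` pools both classes.
#' @return An object of class `performance_summary` with fields `grouping`,
#'   `n_trials` and `percent_correct`.
#' @export
percent_correct <- function(sessions, trial_type = NULL, class = NULL) {
  trials <- as_trial_list(sessions)
  if (!is.null(trial_type)) {
    check_enum(trial_type, TRIAL_TYPES, "trial_type")
    trials <- Filter(function(t) t$trial_type %in% trial_type, trials)
  }
  if (!is.null(class)) {
    check_enum(class, CLASSES, "class")
    trials <- Filter(function(t) t$stimulus_class %in% class, trials)
  }
  outcomes <- vapply(trials, `[[`, "", "outcome")
  countable <- outcomes %in% c("correct", "error")
  if (!any(countable))
    stop("no countable (correct/error) trials in this grouping", call. = FALSE)
  n <- sum(countable)
  pc <- 100 * sum(outcomes[countable] == "correct") / n
  structure(
    list(grouping = list(trial_type = trial_type, class = class),
         n_trials = n, percent_correct = pc),
    class = "performance_summary"
  )
}

as_trial_list <- function(x) {
  if (inherits(x, "peck_session")) return(x$trials)
  if (inherits(x, "peck_trial")) return(list(x))
  stopifnot(is.list(x))
  unlist(lapply(x, as_trial_list), recursive = FALSE)
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("Percent correct: %.2f%% over %d trials [trial_type=%s, class=%s]\n",
              x$percent_correct, x$n_trials,
              if (is.null(x$grouping$trial_type)) "any" else x$grouping$trial_type,
              if (is.null(x$grouping$class)) "pooled" else x$grouping$class))
  invisible(x)
}

#' One-sample Cohen's d from summary statistics
#'
#' `d = (mean - mu0) / sd`, the effect size of a one-sample t test against a
#' reference value (50% for a binary choice). The companion identity
#' `t = d * sqrt(n)` links it to the t statistic.
#'
#' @param mean,sd Sample mean and standard deviation.
#' @param mu0 Reference value.
#' @return Cohen's d.
#' @examples
#' cohens_d(91.81, 3.26)  # 12.83 to 2 d.p.
#' @export
cohens_d <- function(mean, sd, mu0 = 50) {
  stopifnot(sd > 0)
  (mean - mu0) / sd
}

#' One-sample t test against a reference value
#'
#' Tests whether per-subject percentages differ from a reference (chance =
#' 50% for a binary choice). Two-sided; `cohen_d = (mean - mu0) / sd`.
#'
#' @param values Numeric vector (one value per subject), length `>= 2`.
#' @param mu0 Reference value.
#' @return An object of class `t_test_result` with `kind`, `t`, `df`, `p`,
#'   `cohen_d`, `mu0`, `n`, `mean` and `sd`.
#' @export
one_sample_t <- function(values, mu0 = 50) {
  stopifnot(is.numeric(values), length(values) >= 2)
  s <- stats::sd(values)
  if (s == 0)
    stop("zero variance: all values identical; one-sample t is undefined",
         call. = FALSE)
  tt <- stats::t.test(values, mu = mu0)
  structure(
    list(kind = "one_sample", t = unname(tt$statistic),
         df = as.integer(unname(tt$parameter)), p = tt$p.value,
         cohen_d = cohens_d(mean(values), s, mu0), mu0 = mu0,
         n = length(values), mean = mean(values), sd = s),
    class = "t_test_result"
  )
}

#' Paired t test
#'
#' Standard paired t on `a - b` (e.g. per-subject transfer vs known-stimulus
#' performance), two-sided, with `cohen_d = mean(diff) / sd(diff)`.
#'
#' @param a,b Numeric vectors of equal length `>= 2`.
#' @return An object of class `t_test_result`.
#' @export
paired_t <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b))
    stop(sprintf("length mismatch: %d vs %d", length(a), length(b)),
         call. = FALSE)
  stopifnot(length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0)
    stop(if (all(d == 0)) "no difference: a and b are identical pairwise"
         else "zero variance of differences; paired t is undefined",
         call. = FALSE)
  tt <- stats::t.test(a, b, paired = TRUE)
  structure(
    list(kind = "paired", t = unname(tt$statistic),
         df = as.integer(unname(tt$parameter)), p = tt$p.value,
         cohen_d = mean(d) / stats::sd(d), mu0 = NA_real_,
         n = length(a), mean = mean(d), sd = stats::sd(d)),
    class = "t_test_result"
  )
}

#' @export
print.t_test_result <- function(x, ...) {
  lab <- if (x$kind == "one_sample")
    sprintf("One-sample t vs %.4g", x$mu0) else "Paired t"
  cat(sprintf("%s: t(%d) = %.2f, p = %.4g, Cohen's d = %.2f\n",
              lab, x$df, x$t, x$p, x$cohen_d))
  invisible(x)
}
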