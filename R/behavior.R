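#' Signal-detection sensitivity d-prime
#'
#' `d' = qnorm(hit_rate) - qnorm(false_alarm_rate)`, with extreme rates
#' clamped to `[1 / (2N), 1 - 1 / (2N)]` (N = trials of that class) so the
#' result is always finite.
#'
#' @param hit_rate proportion of targets with a press.
#' @param false_alarm_rate proportion of non-targets with a press.
#' @param n_target,n_nontarget trial counts used for clamping; `Inf`
#'   disables the correction.
#' @return d-prime, finite whenever the counts are finite.
#' @export
d_prime <- function(hit_rate, false_alarm_rate, n_target = Inf,
                    n_nontarget = Inf) {
  clamp <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clamp(hit_rate, n_target)) -
    stats::qnorm(clamp(false_alarm_rate, n_nontarget))
}

#' Score one go/no-go session
#'
#' Percent correct is the average of the hit rate on targets and the
#' correct-rejection rate on non-targets (unweighted, even when trial
#' counts are unbalanced). d-prime uses the 1/(2N) extreme-rate correction.
#'
#' @param trials data.frame of one session's trials with logical columns
#'   `is_target` and `pressed`.
#' @return object of class `"session_score"`: `hit_rate`,
#'   `false_alarm_rate`, `correct_rejection_rate`, `percent_correct`,
#'   `d_prime`, `n_target_trials`, `n_nontarget_trials`.
#' @export
score_session <- function(trials) {
  nt <- sum(trials$is_target)
  nn <- sum(!trials$is_target)
  if (nt == 0L || nn == 0L)
    stop("session needs at least one target and one non-target trial")
  hit <- sum(trials$pressed & trials$is_target) / nt
  fa <- sum(trials$pressed & !trials$is_target) / nn
  structure(list(
    hit_rate = hit, false_alarm_rate = fa,
    correct_rejection_rate = 1 - fa,
    percent_correct = 100 * (hit + (1 - fa)) / 2,
    d_prime = d_prime(hit, fa, nt, nn),
    n_target_trials = nt, n_nontarget_trials = nn),
    class = "session_score")
}

#' @export
print.session_score <- function(x, ...) {
  cat(sprintf(
    "session: %.1f%% correct, d' = %.2f (hit %.2f, fa %.2f; %d + %d trials)\n",
    x$percent_correct, x$d_prime, x$hit_rate, x$false_alarm_rate,
    x$n_target_trials, x$n_nontarget_trials))
  invisible(x)
}

#' Training-stage advancement rule
#'
#' Two rule kinds mirror the staged go/no-go protocol: `"press_count"`
#' (e.g. 100 independent presses in a session, for 2 sessions) and
#' `"dprime"` (e.g. d' >= 1.5 for 10 sessions). For the d-prime rule the
#' qualifying sessions are consecutive by default; `consecutive = FALSE`
#' gives the cumulative reading.
#'
#' @param type `"press_count"` or `"dprime"`.
#' @param threshold presses per session, or the d-prime criterion.
#' @param n_sessions number of qualifying sessions required.
#' @param consecutive must the qualifying sessions be consecutive?
#' @return object of class `"stage_criteria"`.
#' @export
stage_criteria <- function(type = c("dprime", "press_count"), threshold,
                           n_sessions, consecutive = TRUE) {
  type <- match.arg(type)
  structure(list(type = type, threshold = threshold,
                 n_sessions = as.integer(n_sessions),
                 consecutive = isTRUE(consecutive)),
            class = "stage_criteria")
}

#' Evaluate a stage-advancement rule over a session sequence
#'
#' @param session_values numeric vector in chronological order: per-session
#'   d-prime for a `"dprime"` rule, or per-session press counts for a
#'   `"press_count"` rule.
#' @param criteria a [stage_criteria()].
#' @return list with `advanced` (logical) and `session_index` (the first
#'   session at which the running condition is satisfied, `NA` if not yet).
#' @export
evaluate_stage <- function(session_values, criteria) {
  ok <- session_values >= criteria$threshold
  k <- criteria$n_sessions
  if (!length(ok) || length(ok) < k)
    return(list(advanced = FALSE, session_index = NA_integer_))
  if (criteria$consecutive) {
    run <- 0L
    for (i in seq_along(ok)) {
      run <- if (ok[i]) run + 1L else 0L
      if (run >= k) return(list(advanced = TRUE, session_index = i))
    }
  } else {
    cum <- cumsum(ok)
    i <- which(cum >= k)
    if (length(i)) return(list(advanced = TRUE, session_index = i[1]))
  }
  list(advanced = FALSE, session_index = NA_integer_)
}

#' Across-subject learning curve
#'
#' Scores every session, aligns subjects by session index, and returns the
#' across-subject mean and s.e.m. of percent correct at each index.
#' Subjects missing a session are excluded from that index's denominator.
#'
#' @param trials data.frame of trials with columns `subject_id`,
#'   `session_index`, `is_target`, `pressed` (plus anything else).
#' @param max_sessions truncate the curve at this many sessions (default 15,
#'   three 5-day training weeks).
#' @return data.frame with `session_index`, `mean_percent_correct`, `sem`,
#'   `n_subjects`.
#' @export
learning_curve <- function(trials, max_sessions = 15) {
  key <- interaction(trials$subject_id, trials$session_index, drop = TRUE)
  per <- lapply(split(trials, key), function(d) {
    sc <- score_session(d)
    data.frame(subject_id = d$subject_id[1],
               session_index = d$session_index[1],
               percent_correct = sc$percent_correct,
               d_prime = sc$d_prime)
  })
  per <- do.call(rbind, per)
  per <- per[per$session_index <= max_sessions, ]
  idx <- sort(unique(per$session_index))
  out <- lapply(idx, function(i) {
    v <- per$percent_correct[per$session_index == i]
    data.frame(session_index = i, mean_percent_correct = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               n_subjects = length(v))
  })
  do.call(rbind, out)
}
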