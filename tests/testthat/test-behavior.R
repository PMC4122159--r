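mk_trials <- function(n_target, n_hit, n_nontarget, n_cr) {
  data.frame(
    is_target = c(rep(TRUE, n_target), rep(FALSE, n_nontarget)),
    pressed = c(rep(TRUE, n_hit), rep(FALSE, n_target - n_hit),
                rep(TRUE, n_nontarget - n_cr), rep(FALSE, n_cr)))
}

test_that("session scoring implements the unweighted percent-correct average", {
  # 8/10 targets pressed, 6/10 non-targets rejected -> 70%
  sc <- score_session(mk_trials(10, 8, 10, 6))
  expect_equal(sc$percent_correct, 70)
  expect_equal(sc$hit_rate, 0.8)
  expect_equal(sc$correct_rejection_rate, 0.6)
  # hit = false alarm = 0.5: d' = 0, percent correct 50
  sc2 <- score_session(mk_trials(10, 5, 10, 5))
  expect_equal(sc2$d_prime, 0)
  expect_equal(sc2$percent_correct, 50)
  # unweighted even when classes are unbalanced
  sc3 <- score_session(mk_trials(40, 40, 10, 5))
  expect_equal(sc3$percent_correct, 75)
  # order invariance within a session
  tr <- mk_trials(10, 8, 10, 6)
  expect_equal(score_session(tr[sample(nrow(tr)), ])$percent_correct, 70)
  expect_error(score_session(mk_trials(5, 3, 0, 0)), "non-target")
})

test_that("d-prime reproduces standard-normal quantile arithmetic", {
  # z(0.7734) = 0.75, so hit 0.7734 / fa 0.2266 -> d' = 1.50
  expect_equal(d_prime(0.7734, 0.2266), 1.5, tolerance = 1e-3)
  # extreme rates are clamped to 1/(2N), keeping d' finite
  expect_true(is.finite(d_prime(1, 0, 20, 20)))
  expect_equal(d_prime(1, 0, 20, 20),
               qnorm(1 - 1 / 40) - qnorm(1 / 40))
  sc <- score_session(mk_trials(10, 10, 10, 10))
  expect_true(is.finite(sc$d_prime))
})

test_that("stage rules advance at the first qualifying run", {
  crit <- stage_criteria("dprime", 1.5, 10)
  # ten consecutive sessions at d' = 2 advance at session 10
  expect_equal(evaluate_stage(rep(2, 10), crit),
               list(advanced = TRUE, session_index = 10L))
  # nine at 2 then one at 1: not yet under the consecutive rule
  expect_false(evaluate_stage(c(rep(2, 9), 1), crit)$advanced)
  # but the cumulative reading advances
  crit_cum <- stage_criteria("dprime", 1.5, 10, consecutive = FALSE)
  expect_equal(evaluate_stage(c(rep(2, 9), 1, 2), crit_cum)$session_index,
               11L)
  # lever-shaping rule: 100 presses for two sessions
  press <- stage_criteria("press_count", 100, 2)
  expect_equal(evaluate_stage(c(80, 120, 130), press)$session_index, 3L)
  expect_false(evaluate_stage(numeric(0), crit)$advanced)
})

test_that("a rising learner advances where a brute-force scan says it should", {
  set.seed(7)
  d <- cummax(runif(40, 0, 2.5))  # monotone-ish learning trajectory
  crit <- stage_criteria("dprime", 1.5, 10)
  got <- evaluate_stage(d, crit)
  # oracle: scan every window of 10 consecutive sessions
  ok <- d >= 1.5
  idx <- NA_integer_
  for (i in 10:length(ok)) if (all(ok[(i - 9):i])) { idx <- i; break }
  expect_equal(got$session_index, idx)
})

test_that("programmed d-prime is recovered from simulated sessions", {
  log <- simulate_go_nogo_sessions(rep(1.5, 2), 2500, seed = 77)
  for (sid in unique(log$session_id)) {
    sc <- score_session(log[log$session_id == sid, ])
    expect_lt(abs(sc$d_prime - 1.5), 0.1)
  }
})

test_that("learning curves aggregate subjects by session index", {
  one <- simulate_go_nogo_sessions(c(0.3, 0.8, 1.4), 80, seed = 5,
                                   subject_id = "r1")
  lc1 <- learning_curve(one)
  expect_equal(nrow(lc1), 3L)
  expect_equal(lc1$n_subjects, rep(1L, 3))
  sc2 <- score_session(one[one$session_index == 2, ])
  expect_equal(lc1$mean_percent_correct[2], sc2$percent_correct)
  # identical subjects: s.e.m. exactly 0
  two <- rbind(one, transform(one, subject_id = "r2"))
  lc2 <- learning_curve(two)
  expect_equal(lc2$sem, rep(0, 3))
  expect_equal(lc2$n_subjects, rep(2L, 3))
})

test_that("consonant-task presets separate the groups, vowel presets do not", {
  p <- vpa_presets()
  cons_v <- generate_behavior_sessions(p$vpa_untrained, "consonant",
                                       n_subjects = 8, seed = 3)
  cons_s <- generate_behavior_sessions(p$saline_untrained, "consonant",
                                       n_subjects = 8, seed = 4)
  lv <- learning_curve(cons_v); ls <- learning_curve(cons_s)
  late <- lv$session_index >= 10
  expect_lt(mean(lv$mean_percent_correct[late]),
            mean(ls$mean_percent_correct[late]))
  # both rise over sessions
  expect_gt(mean(lv$mean_percent_correct[late]),
            lv$mean_percent_correct[1])
  vow_v <- generate_behavior_sessions(p$vpa_untrained, "vowel",
                                      n_subjects = 8, seed = 5)
  vow_s <- generate_behavior_sessions(p$saline_untrained, "vowel",
                                      n_subjects = 8, seed = 6)
  dv <- learning_curve(vow_v); dsal <- learning_curve(vow_s)
  expect_lt(abs(mean(dv$mean_percent_correct[late]) -
                  mean(dsal$mean_percent_correct[late])), 4)
})
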