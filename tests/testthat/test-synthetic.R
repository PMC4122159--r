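test_that("generators are bit-reproducible under a fixed seed", {
  m <- onset_response_model(10, 120, 18, 5)
  st <- stimulus_spec("dad", "speech")
  a <- generate_poisson_sweeps(m, st, 10, seed = 42)
  b <- generate_poisson_sweeps(m, st, 10, seed = 42)
  expect_identical(a, b)
  expect_false(identical(
    a, generate_poisson_sweeps(m, st, 10, seed = 43)))
  tm <- train_locking_model(3, 7.7)
  expect_identical(generate_train_response(tm, 5, seed = 1),
                   generate_train_response(tm, 5, seed = 1))
  rf <- receptive_field_model(4000, 20, 2)
  g1 <- generate_tuning_counts(rf, n_sweeps = 5, seed = 9)
  g2 <- generate_tuning_counts(rf, n_sweeps = 5, seed = 9)
  expect_identical(g1$mean_count, g2$mean_count)
})

test_that("hierarchical seeding makes sweep subsets reproducible", {
  m <- onset_response_model(10, 120, 18, 5)
  st <- stimulus_spec("dad", "speech")
  a <- generate_poisson_sweeps(m, st, 10, seed = 42)
  b <- generate_poisson_sweeps(m, st, 4, seed = 42)
  expect_identical(a$sweeps[1:4], b$sweeps)
})

test_that("Poisson sweep counts match the closed-form rate integral", {
  st <- stimulus_spec("dad", "speech", onset_ms = 0)
  # pure baseline: 10 Hz over 200 ms -> 2 spikes per sweep
  m0 <- onset_response_model(10, 0, 18, 6)
  ss <- generate_poisson_sweeps(m0, st, 4000, seed = 1,
                                sweep_window_ms = c(0, 200))
  mu <- mean(lengths(ss$sweeps))
  expect_lt(abs(mu - 2), 3 * sqrt(2 / 4000))
  # pure bump: peak 153 Hz, center 18 ms, sigma 6 ms -> 2.298 in [0, 40)
  m1 <- onset_response_model(0, 153, 18, 6)
  expect_equal(expected_driven_spikes(m1), 2.2977, tolerance = 1e-4)
  ss1 <- generate_poisson_sweeps(m1, st, 2000, seed = 2,
                                 sweep_window_ms = c(0, 200))
  cnt <- mean(vapply(ss1$sweeps, function(t) sum(t >= 0 & t < 40),
                     numeric(1)))
  expect_lt(abs(cnt - 2.2977), 3 * sqrt(2.3 / 2000))
  # property: random models, window mean within 3 standard errors
  set.seed(11)
  for (k in 1:4) {
    spont <- runif(1, 0, 30); peak <- runif(1, 40, 250)
    ctr <- runif(1, 10, 30); sig <- runif(1, 2, 8)
    m <- onset_response_model(spont, peak, ctr, sig)
    ss <- generate_poisson_sweeps(m, st, 1200, seed = 100 + k,
                                  sweep_window_ms = c(0, 100))
    expect_mu <- spont * 0.1 + expected_driven_spikes(m, c(0, 100))
    got <- mean(lengths(ss$sweeps))
    expect_lt(abs(got - expect_mu), 3 * sqrt(expect_mu / 1200))
  }
  expect_error(onset_response_model(-1, 10, 18, 5), "rates")
})

test_that("train generator realizes the programmed phase-locking", {
  # zero jitter: every spike exactly at a burst onset, VS = 1
  tm0 <- train_locking_model(3, 0)
  ss0 <- generate_train_response(tm0, 20, seed = 5)
  ph <- (unlist(ss0$sweeps) - 100) %% 100
  expect_true(all(abs(ph) < 1e-9 | abs(ph - 100) < 1e-9))
  s0 <- site_train_summary(ss0, stimulus_spec("tr", "noise_train",
                                              n_bursts = 6, period_ms = 100))
  expect_equal(s0$vs$vs, 1)
  expect_error(train_locking_model(3, -1), "jitter")
})

test_that("empirical VS converges to the wrapped-normal closed form", {
  stim <- stimulus_spec("tr", "noise_train", n_bursts = 6, period_ms = 100)
  for (sig in c(7.7, 11.5)) {
    tm <- train_locking_model(3, sig)
    ss <- generate_train_response(tm, 200, seed = 17)
    vs <- site_train_summary(ss, stim)$vs$vs
    expect_lt(abs(vs - expected_vector_strength(sig, 100)), 0.01)
  }
  # property over sigma/T <= 0.15
  for (sig in c(4, 10, 15)) {
    tm <- train_locking_model(4, sig)
    ss <- generate_train_response(tm, 200, seed = 23)
    vs <- site_train_summary(ss, stim)$vs$vs
    expect_lt(abs(vs - expected_vector_strength(sig, 100)), 0.01)
  }
})

test_that("noiseless receptive fields expose the programmed geometry", {
  rf <- receptive_field_model(4000, 20, 2, spont_rate_hz = 0)
  grid <- tuning_grid_from_model(rf)
  mask <- responsive_mask(grid)
  # responses only at intensities >= 20 dB at CF
  fc <- which(grid$freqs_hz == 4000)
  expect_equal(grid$intensities_db[min(which(mask[, fc]))], 20)
  expect_false(any(mask[grid$intensities_db < 20, fc]))
  # programmed 2-octave support at threshold + 40 dB
  s <- tuning_summary(grid)
  expect_equal(s$cf_hz, 4000)
  expect_equal(s$threshold_db, 20)
  expect_equal(s$bw40_octaves, 2)
  expect_error(generate_tuning_sweeps(rf, freqs_hz = c(500, 1000)),
               "model domain")
})

test_that("tone sweeps and fast counts agree with the field model", {
  rf <- receptive_field_model(4000, 30, 2, spont_rate_hz = 10)
  freqs <- 1000 * 2^seq(1.5, 2.5, by = 0.25)
  ints <- seq(20, 60, by = 10)
  sw <- generate_tuning_sweeps(rf, freqs, ints, n_sweeps = 40, seed = 3)
  grid <- tuning_grid_from_sweeps(sw, freqs, ints)
  mu_expect <- outer(ints, freqs, function(i, f) driven_spikes_at(rf, f, i)) +
    10 * 0.04
  expect_lt(max(abs(grid$mean_count - mu_expect)), 3 * sqrt(3 / 40) + 0.3)
  expect_equal(grid$spont_mean_count, 0.4, tolerance = 0.15)
})

test_that("go/no-go simulator hits its programmed operating points", {
  # d' = 0: percent correct ~ 50 each session
  log0 <- simulate_go_nogo_sessions(rep(0, 3), 400, seed = 21)
  for (sid in unique(log0$session_id)) {
    sc <- score_session(log0[log0$session_id == sid, ])
    expect_lt(abs(sc$percent_correct - 50), 3 * 50 / sqrt(400))
  }
  # very large d': percent correct -> 100
  log_hi <- simulate_go_nogo_sessions(6, 400, seed = 22)
  expect_gt(score_session(log_hi)$percent_correct, 99)
  # programmed d' = 1.5 recovered from >= 2000 trials
  log15 <- simulate_go_nogo_sessions(1.5, 4000, seed = 23)
  expect_lt(abs(score_session(log15)$d_prime - 1.5), 0.1)
  expect_error(simulate_go_nogo_sessions(1, 1), "trials_per_session")
})
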