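test_that("PSTH bins are half-open, conserve counts, and sum over sweeps", {
  ss <- toy_sweeps(c(0.5, 1.5), window = c(0, 10), onset = 0)
  p <- compute_psth(ss, 1, window = c(0, 3))
  expect_equal(p$counts, c(1L, 1L, 0L))
  # spike on the right window edge is excluded, on a bin edge goes right
  ss2 <- toy_sweeps(c(1, 3), window = c(0, 10), onset = 0)
  expect_equal(compute_psth(ss2, 1, window = c(0, 3))$counts, c(0L, 1L, 0L))
  # 20 identical sweeps scale counts 20x
  sweeps <- rep(list(c(0.5, 1.5)), 20)
  ss20 <- sweep_set("s", "d", sweeps, c(0, 10), 0)
  expect_equal(compute_psth(ss20, 1, window = c(0, 3))$counts,
               20L * c(1L, 1L, 0L))
  expect_equal(psth_rate(compute_psth(ss20, 1, c(0, 3)))[1], 1000)
  # conservation against a direct counting oracle on random data
  for (seed in c(2, 9)) {
    ss_r <- random_dataset(1, 1, 8, seed)[[1]]
    p_r <- compute_psth(ss_r, 2, window = c(0, 200))
    t_all <- unlist(ss_r$sweeps)
    expect_equal(sum(p_r$counts), sum(t_all >= 0 & t_all < 200))
  }
  expect_error(compute_psth(ss, 1, window = c(-5, 3)), "window")
})

test_that("driven spike count is the baseline-subtracted onset-window mean", {
  # spont 0: 4 spikes in the 40-ms window, one sweep -> 4.0
  ss <- toy_sweeps(100 + c(5, 10, 20, 39.9), onset = 100)
  expect_equal(driven_spike_count(ss, spont_rate_hz = 0), 4)
  # spont 25 Hz: 3 - 25 * 0.04 = 2.0
  ss3 <- toy_sweeps(100 + c(5, 10, 20), onset = 100)
  expect_equal(driven_spike_count(ss3, spont_rate_hz = 25), 2)
  expect_equal(driven_spike_count(ss3, subtract_baseline = FALSE), 3)
  # no baseline available and no rate supplied -> error
  ss_nb <- sweep_set("s", "d", list(c(5, 10)), c(0, 100), 0)
  expect_error(driven_spike_count(ss_nb), "baseline")
})

test_that("driven count is invariant to pure baseline shifts", {
  st <- stimulus_spec("dad", "speech")
  vals <- vapply(c(0, 5, 25), function(spont) {
    m <- onset_response_model(spont, 153, 18, 6)
    ss <- generate_poisson_sweeps(m, st, 1500, seed = 31)
    driven_spike_count(ss)
  }, numeric(1))
  expect_lt(max(vals) - min(vals), 4 * sqrt(3 / 1500) + 0.05)
})

test_that("measured driven spikes rise with the programmed peak rate", {
  st <- stimulus_spec("dad", "speech")
  vals <- vapply(c(60, 120, 240), function(pk) {
    m <- onset_response_model(10, pk, 18, 6)
    driven_spike_count(generate_poisson_sweeps(m, st, 2000, seed = 37))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("onset latency is the first 3-SD threshold crossing", {
  # silent baseline (sd 0, mean 0): first nonzero bin starts 12 ms post-onset
  sweeps <- rep(list(c(112.2, 113.5)), 5)
  ss <- sweep_set("s", "d", sweeps, c(0, 200), 100)
  sp <- spontaneous_stats(ss)
  expect_equal(sp$mean_hz, 0)
  p <- compute_psth(ss, 1, window = c(100, 200))
  expect_equal(onset_latency(p, 100, sp$mean_hz, sp$sd_hz), 12)
  # no crossing -> NA
  expect_equal(onset_latency(p, 100, 1e6, 1), NA_real_)
  expect_error(onset_latency(p, 100, 0, -1), "spont_sd")
})

test_that("latency estimator recovers programmed step change-points", {
  # high SNR: 50 random latencies, recovered within one 1-ms bin except for
  # rare baseline excursions above the 3-SD threshold; 1000 sweeps put the
  # integer count threshold deep in the Poisson baseline tail
  set.seed(53)
  lat <- runif(50, 4, 12)
  err <- vapply(seq_along(lat), function(i) {
    ss <- step_sweeps(25, 300, lat[i], n_sweeps = 1000, seed = 6000 + i)
    sp <- spontaneous_stats(ss)
    p <- compute_psth(ss, 1, window = c(100, 200))
    onset_latency(p, 100, sp$mean_hz, sp$sd_hz) - lat[i]
  }, numeric(1))
  expect_gte(sum(abs(err) <= 1), 45)
  expect_lte(stats::median(abs(err)), 1)
  # zero spontaneous rate: recovery is exact within one bin for every case
  err0 <- vapply(1:10, function(i) {
    ss <- step_sweeps(0, 400, lat[i], n_sweeps = 20, seed = 7000 + i)
    sp <- spontaneous_stats(ss)
    p <- compute_psth(ss, 1, window = c(100, 200))
    onset_latency(p, 100, sp$mean_hz, sp$sd_hz) - lat[i]
  }, numeric(1))
  expect_true(all(abs(err0) <= 1))
})

test_that("peak latency takes the earliest maximal bin center", {
  sweeps <- list(100 + c(17.2, 17.8, 25), 100 + c(17.5, 30))
  ss <- sweep_set("s", "d", sweeps, c(0, 200), 100)
  p <- compute_psth(ss, 1, window = c(100, 200))
  expect_equal(peak_latency(p, 100), 17.5)
  # flat PSTH: tie broken toward the earliest bin
  ss_flat <- sweep_set("s", "d", list(c(100.5, 101.5, 102.5)), c(0, 200), 100)
  p_flat <- compute_psth(ss_flat, 1, window = c(100, 200))
  expect_equal(peak_latency(p_flat, 100), 0.5)
  # Gaussian-bump simulations recover the programmed center within one bin
  st <- stimulus_spec("dad", "speech")
  for (ctr in c(15, 22)) {
    m <- onset_response_model(5, 300, ctr, 3)
    ss_b <- generate_poisson_sweeps(m, st, 3000, seed = 61)
    p_b <- compute_psth(ss_b, 1, window = c(100, 200))
    expect_lt(abs(peak_latency(p_b, 100) - ctr), 1.01)
  }
})

test_that("peak firing rate converts max bin counts to Hz", {
  sweeps <- c(rep(list(c(117.2)), 16), rep(list(numeric(0)), 4))
  ss <- sweep_set("s", "d", sweeps, c(0, 200), 100)
  p <- compute_psth(ss, 1, window = c(100, 200))
  expect_equal(max(p$counts), 16L)
  expect_equal(peak_firing_rate(p), 800)
  ss0 <- sweep_set("s", "d", rep(list(numeric(0)), 5), c(0, 200), 100)
  expect_equal(peak_firing_rate(compute_psth(ss0, 1, c(100, 200))), 0)
})

test_that("response_metrics keeps onset at or before peak on clean bumps", {
  st <- stimulus_spec("dad", "speech")
  m <- onset_response_model(10, 250, 20, 4)
  ss <- generate_poisson_sweeps(m, st, 100, seed = 71)
  r <- response_metrics(ss)
  expect_lte(r$onset_latency_ms, r$peak_latency_ms)
  expect_gt(r$driven_spikes, 0)
  expect_equal(r$spontaneous_rate_hz, 10, tolerance = 0.5)
})
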