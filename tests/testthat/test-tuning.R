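# definitional oracle: build the expected mask and summary for a V-shaped
# field directly from its threshold line, with plain loops
oracle_tuning <- function(cf_hz, thr_db, bw40, freqs, ints) {
  slope <- 80 / bw40
  thr_line <- thr_db + slope * abs(log2(freqs / cf_hz))
  mask <- matrix(FALSE, length(ints), length(freqs))
  for (ii in seq_along(ints)) for (fi in seq_along(freqs))
    mask[ii, fi] <- ints[ii] >= thr_line[fi] - 1e-9
  rows <- which(rowSums(mask) > 0)
  r <- rows[1]
  cand <- which(mask[r, ])
  # lowest responsive row; tie -> largest response = smallest octave
  # distance from cf, then lower frequency
  dist <- abs(log2(freqs[cand] / cf_hz))
  cand <- cand[dist == min(dist)]
  cf_exp <- freqs[min(cand)]
  fc <- which(freqs == cf_exp)
  thr_exp <- ints[min(which(mask[, fc]))]
  target <- thr_exp + 40
  if (target > max(ints)) return(list(cf = cf_exp, thr = thr_exp, bw = NA))
  rr <- which.min(abs(ints - target))
  lo <- fc; while (lo > 1 && mask[rr, lo - 1]) lo <- lo - 1
  hi <- fc; while (hi < length(freqs) && mask[rr, hi + 1]) hi <- hi + 1
  list(cf = cf_exp, thr = thr_exp, bw = log2(freqs[hi] / freqs[lo]))
}

test_that("noiseless fields are recovered grid-exactly across random parameters", {
  freqs <- tone_grid_freqs(); ints <- tone_grid_intensities()
  set.seed(91)
  for (k in 1:20) {
    bw <- sample(seq(0.5, 3, by = 0.25), 1)
    kc <- sample(ceiling(4 * bw):(40 - ceiling(4 * bw)), 1)
    cf <- freqs[kc + 1]
    thr <- sample(seq(0, 35, by = 5), 1)
    rf <- receptive_field_model(cf, thr, bw, spont_rate_hz = 0)
    s <- tuning_summary(tuning_grid_from_model(rf))
    expect_equal(s$cf_hz, cf)
    expect_equal(s$threshold_db, thr)
    expect_equal(s$bw40_octaves, bw)
  }
  # off-grid CF and threshold: agree with the definitional oracle
  for (k in 1:5) {
    cf <- runif(1, 3000, 9000); thr <- runif(1, 4, 28); bw <- runif(1, 1, 3)
    rf <- receptive_field_model(cf, thr, bw, spont_rate_hz = 0)
    s <- tuning_summary(tuning_grid_from_model(rf))
    o <- oracle_tuning(cf, thr, bw, freqs, ints)
    expect_equal(s$cf_hz, o$cf)
    expect_equal(s$threshold_db, o$thr)
    expect_equal(s$bw40_octaves, o$bw)
  }
})

test_that("an all-spontaneous grid has an empty mask and flagged summary", {
  freqs <- tone_grid_freqs(); ints <- tone_grid_intensities()
  grid <- tuning_grid(freqs, ints,
                      matrix(0.8, length(ints), length(freqs)),
                      spont_mean_count = 0.8, spont_sd_count = 0.9,
                      n_sweeps = 20)
  s <- tuning_summary(grid)
  expect_false(any(s$mask))
  expect_true(is.na(s$cf_hz))
  expect_true(is.na(s$threshold_db))
})

test_that("raising the criterion never grows the mask, threshold, or BW40", {
  rf <- receptive_field_model(4000, 20, 2, spont_rate_hz = 20)
  grid <- generate_tuning_counts(rf, n_sweeps = 20, seed = 15)
  m1 <- responsive_mask(grid, 1); m2 <- responsive_mask(grid, 2)
  m4 <- responsive_mask(grid, 4)
  expect_true(all(m2 <= m1))
  expect_true(all(m4 <= m2))
  thr <- vapply(c(1, 2, 4), function(cs) {
    m <- responsive_mask(grid, cs)
    tone_threshold(grid, m, characteristic_frequency(grid, m))
  }, numeric(1))
  expect_true(all(diff(thr) >= 0))
  bw <- vapply(c(1, 2, 4), function(cs) {
    m <- responsive_mask(grid, cs)
    cf <- characteristic_frequency(grid, m)
    bandwidth40(grid, m, cf, tone_threshold(grid, m, cf))
  }, numeric(1))
  expect_true(all(diff(bw[!is.na(bw)]) <= 0))
})

test_that("shifting the programmed field up 10 dB shifts threshold by 10", {
  for (thr in c(10, 20)) {
    rf_lo <- receptive_field_model(4000, thr, 2, spont_rate_hz = 0)
    rf_hi <- receptive_field_model(4000, thr + 10, 2, spont_rate_hz = 0)
    s_lo <- tuning_summary(tuning_grid_from_model(rf_lo))
    s_hi <- tuning_summary(tuning_grid_from_model(rf_hi))
    expect_equal(s_hi$threshold_db - s_lo$threshold_db, 10)
  }
})

test_that("CF ties resolve by driven count then lower frequency", {
  freqs <- c(2000, 4000, 8000); ints <- c(10, 20)
  mc <- matrix(0, 2, 3)
  mc[1, ] <- c(2, 3, 0)   # two responsive points at the lowest row
  mc[2, ] <- c(2, 3, 1)
  grid <- tuning_grid(freqs, ints, mc, spont_mean_count = 0,
                      spont_sd_count = 0, n_sweeps = 20)
  mask <- responsive_mask(grid)
  expect_equal(characteristic_frequency(grid, mask), 4000)  # larger count
  mc[1, ] <- c(3, 3, 0)   # exact count tie -> lower frequency
  grid2 <- tuning_grid(freqs, ints, mc, 0, 0, 20)
  expect_equal(characteristic_frequency(grid2, responsive_mask(grid2)), 2000)
})

test_that("bandwidth span rules handle holes and single points", {
  freqs <- tone_grid_freqs()[1:17]  # 1-4 kHz
  ints <- seq(0, 75, by = 5)
  mc <- matrix(0, length(ints), length(freqs))
  mc[1, 9] <- 1                          # threshold at 0 dB at 2 kHz
  mc[9, c(5:13, 16)] <- 1                # 40 dB row: run around CF + island
  grid <- tuning_grid(freqs, ints, mc, 0, 0, 20)
  mask <- responsive_mask(grid)
  cf <- characteristic_frequency(grid, mask)
  thr <- tone_threshold(grid, mask, cf)
  expect_equal(bandwidth40(grid, mask, cf, thr), 1)          # contiguous run
  expect_equal(bandwidth40(grid, mask, cf, thr, span_rule = "loose"),
               log2(freqs[16] / freqs[5]))
  # single responsive point at the 40-dB row -> 0 octaves
  mc2 <- matrix(0, length(ints), length(freqs))
  mc2[1, 9] <- 1; mc2[9, 9] <- 1
  grid2 <- tuning_grid(freqs, ints, mc2, 0, 0, 20)
  m2 <- responsive_mask(grid2)
  expect_equal(bandwidth40(grid2, m2, 2000, 0), 0)
  # threshold + 40 above the grid top -> flagged
  mc3 <- matrix(0, length(ints), length(freqs))
  mc3[16, 9] <- 1
  grid3 <- tuning_grid(freqs, ints, mc3, 0, 0, 20)
  m3 <- responsive_mask(grid3)
  expect_true(is.na(bandwidth40(grid3, m3, 2000, 75)))
})

test_that("rate-intensity functions average the +/- 1 octave band", {
  freqs <- tone_grid_freqs(); ints <- tone_grid_intensities()
  # flat field: flat function, one value per intensity row
  grid <- tuning_grid(freqs, ints,
                      matrix(1.5, length(ints), length(freqs)),
                      spont_mean_count = 0.5, spont_sd_count = 0,
                      n_sweeps = 20)
  ri <- rate_intensity_function(grid, 4000)
  expect_equal(nrow(ri), 16L)
  expect_true(all(ri$driven_spikes == 1))
  # sigmoid-in-intensity field recovers the programmed values exactly
  prog <- 2 / (1 + exp(-(ints - 40) / 8))
  grid2 <- tuning_grid(freqs, ints,
                       matrix(rep(prog, length(freqs)), length(ints)),
                       spont_mean_count = 0, spont_sd_count = 0,
                       n_sweeps = 20)
  expect_equal(rate_intensity_function(grid2, 4000)$driven_spikes, prog)
})
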