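# Synthetic multiunit auditory-cortex data: inhomogeneous-Poisson onset
# responses, jittered phase-locking to noise-burst trains, V-shaped
# frequency-intensity receptive fields, and staged go/no-go sessions.

#' Derive a reproducible sub-seed from a master seed and indices
#'
#' A single integer seed governs a hierarchical stream (site -> stimulus ->
#' sweep) so that any subset of the data can be regenerated identically.
#' Folding uses the MINSTD multiplier modulo 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param ... integer indices, folded in order.
#' @return an integer sub-seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in ks) s <- (s * 48271 + as.double(k)) %% 2147483647
  as.integer(s)
}

#' Integer index of a character label, for seed derivation
#'
#' Hashes a label (a site id, word, group name) to a stable integer so it
#' can be folded into the hierarchical seed stream with [derive_seed()].
#' @param label character scalar.
#' @return integer in `[0, 99999]`.
#' @export
label_index <- function(label) sum(utf8ToInt(label)) %% 100000L

# Sample one realization of an inhomogeneous Poisson process on `window`
# by thinning: draw Poisson(rate_max * duration) candidate times uniformly,
# accept each with probability rate(t) / rate_max. Uses the current RNG
# state. rate_fn must be vectorized and bounded by rate_max on the window.
sample_inhomogeneous <- function(rate_fn, rate_max, window) {
  dur_s <- (window[2] - window[1]) / 1000
  if (rate_max <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, rate_max * dur_s)
  if (n_cand == 0L) return(numeric(0))
  t <- stats::runif(n_cand, window[1], window[2])
  keep <- stats::runif(n_cand) < rate_fn(t) / rate_max
  sort(t[keep])
}

#' Onset-response rate model: constant baseline plus a Gaussian rate bump
#'
#' The driven response to a speech-sound onset is modeled as a Gaussian
#' bump of peak `peak_rate_hz` (above baseline) centered `center_ms` after
#' stimulus onset with width `sigma_ms`, added to a constant spontaneous
#' rate. This is the simplest form whose strength, latency and width are
#' independently controllable. Optional per-stimulus perturbations
#' (`stim_mods`) give each speech token a distinct template: a named list
#' of numeric vectors with elements `dpeak`, `dcenter`, `dsigma`, added to
#' the base parameters when generating that label.
#'
#' @param spont_rate_hz spontaneous rate, Hz (>= 0).
#' @param peak_rate_hz driven peak above baseline, Hz (>= 0).
#' @param center_ms bump center after stimulus onset, ms.
#' @param sigma_ms bump SD, ms (> 0).
#' @param stim_mods optional named list of per-label perturbations.
#' @return object of class `"onset_response_model"`.
#' @export
onset_response_model <- function(spont_rate_hz, peak_rate_hz, center_ms,
                                 sigma_ms, stim_mods = NULL) {
  if (spont_rate_hz < 0 || peak_rate_hz < 0) stop("rates must be >= 0")
  if (sigma_ms <= 0) stop("sigma_ms must be > 0")
  structure(list(spont_rate_hz = spont_rate_hz, peak_rate_hz = peak_rate_hz,
                 center_ms = center_ms, sigma_ms = sigma_ms,
                 stim_mods = stim_mods),
            class = "onset_response_model")
}

# resolve per-stimulus perturbations into effective (peak, center, sigma)
effective_bump <- function(model, label) {
  p <- model$peak_rate_hz; c <- model$center_ms; s <- model$sigma_ms
  m <- model$stim_mods[[label]]
  if (!is.null(m)) {
    p <- max(0, p + (m[["dpeak"]] %||% 0))
    c <- c + (m[["dcenter"]] %||% 0)
    s <- max(0.1, s + (m[["dsigma"]] %||% 0))
  }
  list(peak = p, center = c, sigma = s)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Expected driven spikes of a Gaussian-bump model in a window
#'
#' Closed form: `peak * sigma * sqrt(2*pi) * coverage / 1000`, where
#' coverage is the Gaussian probability mass of the bump falling inside the
#' onset-relative window.
#'
#' @param model an [onset_response_model()].
#' @param window onset-relative window `(a, b)` in ms, default `c(0, 40)`.
#' @param label optional stimulus label, to apply `stim_mods`.
#' @return expected driven spikes per sweep (baseline excluded).
#' @export
expected_driven_spikes <- function(model, window = c(0, 40), label = NULL) {
  b <- if (is.null(label)) list(peak = model$peak_rate_hz,
                                center = model$center_ms,
                                sigma = model$sigma_ms)
       else effective_bump(model, label)
  cov <- stats::pnorm((window[2] - b$center) / b$sigma) -
    stats::pnorm((window[1] - b$center) / b$sigma)
  b$peak * b$sigma * sqrt(2 * pi) * cov / 1000
}

#' Generate spike sweeps from an inhomogeneous Poisson onset response
#'
#' Each sweep is an independent realization of a Poisson process with rate
#' `spont + peak * exp(-(t - onset - center)^2 / (2 * sigma^2))`, sampled by
#' thinning. Identical seeds give identical spikes; the mean count in any
#' window converges to the rate integral.
#'
#' @param model an [onset_response_model()].
#' @param stim a [stimulus_spec()] (its `onset_ms` anchors the bump; its
#'   `label` selects any per-stimulus perturbation).
#' @param n_sweeps number of sweeps (>= 1).
#' @param seed integer seed.
#' @param sweep_window_ms recording epoch, ms.
#' @param site_id,group passed through to the [sweep_set()].
#' @return a [sweep_set()].
#' @export
generate_poisson_sweeps <- function(model, stim, n_sweeps, seed,
                                    sweep_window_ms = c(0, 250),
                                    site_id = "site1", group = NA_character_) {
  stopifnot(inherits(model, "onset_response_model"), n_sweeps >= 1)
  b <- effective_bump(model, stim$label)
  c_abs <- stim$onset_ms + b$center
  rate_fn <- function(t) model$spont_rate_hz +
    b$peak * exp(-(t - c_abs)^2 / (2 * b$sigma^2))
  rate_max <- model$spont_rate_hz + b$peak
  sweeps <- vector("list", n_sweeps)
  for (j in seq_len(n_sweeps)) {
    set.seed(derive_seed(seed, j))
    sweeps[[j]] <- sample_inhomogeneous(rate_fn, rate_max, sweep_window_ms)
  }
  sweep_set(site_id, stim$stim_id, sweeps, sweep_window_ms,
            stimulus_onset_ms = stim$onset_ms, group = group)
}

#' Phase-locking model for periodic noise-burst trains
#'
#' Per burst, a Poisson(`spikes_per_burst`) number of spikes is placed at
#' the burst onset plus Gaussian jitter of SD `jitter_sigma_ms`. Under this
#' model the expected vector strength is the wrapped-normal closed form
#' `exp(-2 * pi^2 * sigma^2 / T^2)` (see [expected_vector_strength()]).
#'
#' @param spikes_per_burst expected spike count per burst (>= 0).
#' @param jitter_sigma_ms Gaussian timing jitter SD, ms (>= 0).
#' @param period_ms interburst interval T, ms (> 0).
#' @param n_bursts number of bursts (>= 1).
#' @return object of class `"train_locking_model"`.
#' @export
train_locking_model <- function(spikes_per_burst, jitter_sigma_ms,
                                period_ms = 100, n_bursts = 6) {
  if (jitter_sigma_ms < 0) stop("jitter_sigma_ms must be >= 0")
  if (spikes_per_burst < 0) stop("spikes_per_burst must be >= 0")
  if (period_ms <= 0 || n_bursts < 1) stop("invalid train geometry")
  structure(list(spikes_per_burst = spikes_per_burst,
                 jitter_sigma_ms = jitter_sigma_ms,
                 period_ms = period_ms, n_bursts = as.integer(n_bursts)),
            class = "train_locking_model")
}

#' Generate spike sweeps phase-locked to a noise-burst train
#'
#' @param model a [train_locking_model()].
#' @param n_sweeps number of sweeps.
#' @param seed integer seed.
#' @param onset_ms first burst onset within the sweep, ms.
#' @param sweep_window_ms recording epoch; defaults wide enough to hold the
#'   whole train plus jitter.
#' @param site_id,group passed through to the [sweep_set()].
#' @return a [sweep_set()]; spikes jittered outside the sweep window are
#'   dropped (negligible for `jitter_sigma_ms` well under `onset_ms`).
#' @export
generate_train_response <- function(model, n_sweeps, seed, onset_ms = 100,
                                    sweep_window_ms = NULL,
                                    site_id = "site1",
                                    group = NA_character_) {
  stopifnot(inherits(model, "train_locking_model"), n_sweeps >= 1)
  if (is.null(sweep_window_ms))
    sweep_window_ms <- c(0, onset_ms + model$n_bursts * model$period_ms + 100)
  onsets <- onset_ms + model$period_ms * (seq_len(model$n_bursts) - 1)
  sweeps <- vector("list", n_sweeps)
  for (j in seq_len(n_sweeps)) {
    set.seed(derive_seed(seed, j))
    t <- unlist(lapply(onsets, function(o) {
      k <- stats::rpois(1, model$spikes_per_burst)
      if (k == 0L) return(numeric(0))
      o + stats::rnorm(k, 0, model$jitter_sigma_ms)
    }))
    t <- t[t >= sweep_window_ms[1] & t <= sweep_window_ms[2]]
    sweeps[[j]] <- sort(t)
  }
  sweep_set(site_id, "train10hz", sweeps, sweep_window_ms,
            stimulus_onset_ms = onset_ms, group = group)
}

#' V-shaped frequency-intensity receptive field model
#'
#' A site responds to a tone of frequency `f` and intensity `i` when
#' `i >= threshold_db + slope * |log2(f / cf_hz)|`, i.e. the field is a V
#' opening upward from (`cf_hz`, `threshold_db`) with flank slope
#' `slope_db_per_octave = 80 / bw40_octaves` (so that the responsive span
#' 40 dB above threshold is `bw40_octaves` wide). Inside the field the
#' driven response grows linearly with the level above the local threshold.
#'
#' @param cf_hz characteristic frequency, Hz.
#' @param threshold_db minimum responsive intensity at CF, dB SPL.
#' @param bw40_octaves programmed bandwidth 40 dB above threshold, octaves.
#' @param base_spikes driven spikes per tone at the local threshold.
#' @param gain_per_db additional driven spikes per dB above local threshold.
#' @param spont_rate_hz spontaneous rate, Hz.
#' @return object of class `"receptive_field_model"`.
#' @export
receptive_field_model <- function(cf_hz, threshold_db, bw40_octaves,
                                  base_spikes = 2.5, gain_per_db = 0.05,
                                  spont_rate_hz = 20) {
  if (bw40_octaves <= 0) stop("bw40_octaves must be > 0")
  if (threshold_db < 0) stop("threshold_db must be >= 0")
  structure(list(cf_hz = cf_hz, threshold_db = threshold_db,
                 bw40_octaves = bw40_octaves,
                 slope_db_per_octave = 80 / bw40_octaves,
                 base_spikes = base_spikes, gain_per_db = gain_per_db,
                 spont_rate_hz = spont_rate_hz),
            class = "receptive_field_model")
}

#' Expected driven spikes per tone at a lattice point
#' @param model a [receptive_field_model()].
#' @param freq_hz,intensity_db lattice coordinates (vectorized).
#' @return expected driven spikes per tone presentation (0 outside the
#'   field).
#' @export
driven_spikes_at <- function(model, freq_hz, intensity_db) {
  thr <- model$threshold_db +
    model$slope_db_per_octave * abs(log2(freq_hz / model$cf_hz))
  # tolerance keeps lattice points that sit exactly on the V flank inside
  # the field despite floating-point rounding of the octave distance
  ifelse(intensity_db >= thr - 1e-9,
         model$base_spikes + model$gain_per_db *
           pmax(0, intensity_db - thr), 0)
}

#' The standard tone lattice: 1-32 kHz in 0.125-octave steps
#' @return numeric vector of 41 frequencies, Hz.
#' @export
tone_grid_freqs <- function() 1000 * 2^seq(0, 5, by = 0.125)

#' The standard intensity lattice: 0-75 dB SPL in 5-dB steps
#' @return numeric vector of 16 intensities, dB.
#' @export
tone_grid_intensities <- function() seq(0, 75, by = 5)

#' Generate tone-evoked sweeps over the frequency x intensity lattice
#'
#' Per lattice point and sweep, the spontaneous background is homogeneous
#' Poisson over the sweep and the driven spikes are a Poisson count (mean
#' from [driven_spikes_at()]) placed uniformly in the early onset window.
#'
#' @param model a [receptive_field_model()].
#' @param freqs_hz,intensities_db lattice (defaults: the standard grids).
#' @param n_sweeps sweeps per lattice point.
#' @param seed integer seed.
#' @param onset_ms tone onset within the sweep.
#' @param sweep_window_ms recording epoch per tone sweep.
#' @param site_id,group passed through.
#' @return named list of [sweep_set()], one per lattice point, names
#'   `"tone_<freq>_<db>"`; attach to a grid with [tuning_grid()].
#' @export
generate_tuning_sweeps <- function(model, freqs_hz = tone_grid_freqs(),
                                   intensities_db = tone_grid_intensities(),
                                   n_sweeps = 20, seed = 1, onset_ms = 100,
                                   sweep_window_ms = c(0, 150),
                                   site_id = "site1",
                                   group = NA_character_) {
  if (min(freqs_hz) < 1000 || max(freqs_hz) > 32000)
    stop("frequency grid outside the 1-32 kHz model domain")
  out <- list()
  for (fi in seq_along(freqs_hz)) for (ii in seq_along(intensities_db)) {
    f <- freqs_hz[fi]; db <- intensities_db[ii]
    mu <- driven_spikes_at(model, f, db)
    sweeps <- vector("list", n_sweeps)
    for (j in seq_len(n_sweeps)) {
      set.seed(derive_seed(seed, fi, ii, j))
      n_sp <- stats::rpois(1, model$spont_rate_hz *
                             diff(sweep_window_ms) / 1000)
      t_sp <- stats::runif(n_sp, sweep_window_ms[1], sweep_window_ms[2])
      n_dr <- stats::rpois(1, mu)
      t_dr <- stats::runif(n_dr, onset_ms + 2, onset_ms + 38)
      sweeps[[j]] <- sort(c(t_sp, t_dr))
    }
    key <- sprintf("tone_%g_%g", f, db)
    out[[key]] <- sweep_set(site_id, key, sweeps, sweep_window_ms,
                            stimulus_onset_ms = onset_ms, group = group)
  }
  out
}

#' Fast per-point tone response counts over the lattice
#'
#' Same count distribution as [generate_tuning_sweeps()] analyzed with a
#' 40-ms count window, skipping spike-time construction: per point, per
#' sweep, `count ~ Poisson(driven + spont * 0.04)`; baseline counts are
#' Poisson(`spont * 0.04`) draws pooled across the lattice. Used for
#' lattice-scale simulations where only counts matter.
#'
#' @inheritParams generate_tuning_sweeps
#' @param count_window_ms window over which tone spikes are counted, ms.
#' @return a `"tuning_grid"` (see [tuning_grid()]).
#' @export
generate_tuning_counts <- function(model, freqs_hz = tone_grid_freqs(),
                                   intensities_db = tone_grid_intensities(),
                                   n_sweeps = 20, seed = 1,
                                   count_window_ms = 40) {
  win_s <- count_window_ms / 1000
  spont_mu <- model$spont_rate_hz * win_s
  mu <- outer(intensities_db, freqs_hz,
              function(i, f) driven_spikes_at(model, f, i)) + spont_mu
  set.seed(derive_seed(seed, 7L))
  counts <- matrix(stats::rpois(length(mu) * n_sweeps, rep(mu, n_sweeps)),
                   nrow = length(mu))
  mean_count <- matrix(rowMeans(counts), nrow = length(intensities_db),
                       dimnames = list(intensities_db, signif(freqs_hz, 6)))
  base <- stats::rpois(length(mu) * n_sweeps, spont_mu)
  tuning_grid(freqs_hz, intensities_db, mean_count,
              spont_mean_count = mean(base), spont_sd_count = stats::sd(base),
              n_sweeps = n_sweeps)
}

#' Noiseless tuning grid computed directly from a receptive-field model
#'
#' The exact expected counts on the lattice with zero spontaneous
#' variability: the high-SNR reference for exact-recovery checks of CF,
#' threshold and BW40.
#'
#' @inheritParams generate_tuning_counts
#' @return a `"tuning_grid"` with `spont_sd_count = 0`.
#' @export
tuning_grid_from_model <- function(model, freqs_hz = tone_grid_freqs(),
                                   intensities_db = tone_grid_intensities(),
                                   count_window_ms = 40, n_sweeps = 20) {
  spont_mu <- model$spont_rate_hz * count_window_ms / 1000
  mu <- outer(intensities_db, freqs_hz,
              function(i, f) driven_spikes_at(model, f, i)) + spont_mu
  dimnames(mu) <- list(intensities_db, signif(freqs_hz, 6))
  tuning_grid(freqs_hz, intensities_db, mu, spont_mean_count = spont_mu,
              spont_sd_count = 0, n_sweeps = n_sweeps)
}

#' Simulate staged go/no-go sessions from a discriminability trajectory
#'
#' Each trial's press decision is drawn from an equal-variance
#' signal-detection model: for session sensitivity `d` and criterion `c`,
#' `P(press | target) = pnorm(d / 2 - c)` and
#' `P(press | non-target) = pnorm(-d / 2 - c)`. The response window follows
#' the staged schedule, starting at 8 s and decreasing to 3 s.
#'
#' @param dprimes numeric vector, programmed d-prime per session (the
#'   learning trajectory).
#' @param trials_per_session trials per session (>= 2).
#' @param seed integer seed.
#' @param subject_id subject label for the log.
#' @param p_target probability a trial is a target (default 0.5).
#' @param criterion decision criterion (0 = neutral).
#' @return data.frame in the behavior-log dialect (one row per trial), with
#'   an extra `subject_id` column.
#' @export
simulate_go_nogo_sessions <- function(dprimes, trials_per_session = 100,
                                      seed = 1, subject_id = "s1",
                                      p_target = 0.5, criterion = 0) {
  if (trials_per_session < 2) stop("trials_per_session must be >= 2")
  out <- vector("list", length(dprimes))
  for (s in seq_along(dprimes)) {
    set.seed(derive_seed(seed, s))
    d <- dprimes[s]
    n <- trials_per_session
    is_target <- stats::runif(n) < p_target
    # guarantee both trial classes so every session is scoreable
    if (!any(is_target)) is_target[1] <- TRUE
    if (all(is_target)) is_target[1] <- FALSE
    p_hit <- stats::pnorm(d / 2 - criterion)
    p_fa <- stats::pnorm(-d / 2 - criterion)
    pressed <- stats::runif(n) < ifelse(is_target, p_hit, p_fa)
    out[[s]] <- data.frame(
      session_id = sprintf("%s_s%02d", subject_id, s),
      trial_index = seq_len(n),
      stim_label = ifelse(is_target, "dad", "bad"),
      is_target = is_target, pressed = pressed,
      response_window_s = max(3, 8 - (s - 1)),
      subject_id = subject_id, session_index = s,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
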