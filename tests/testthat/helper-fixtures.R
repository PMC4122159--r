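# shared fixture builders; everything is generated in code

# a minimal sweep_set with given per-sweep spike times (sweep time, ms)
toy_sweeps <- function(..., window = c(0, 200), onset = 100,
                       site = "s1", stim = "dad") {
  sweep_set(site, stim, list(...), sweep_window_ms = window,
            stimulus_onset_ms = onset)
}

# random sweep_set collection for round-trip property tests
random_dataset <- function(n_sites, n_stims, n_sweeps, seed) {
  set.seed(seed)
  out <- list()
  for (s in seq_len(n_sites)) for (k in seq_len(n_stims)) {
    sweeps <- lapply(seq_len(n_sweeps), function(j) {
      n <- rpois(1, 3)                      # empty sweeps occur naturally
      sort(round(runif(n, 0, 200), 4))
    })
    out[[length(out) + 1L]] <- sweep_set(
      sprintf("site%02d", s), sprintf("stim%02d", k), sweeps,
      sweep_window_ms = c(0, 200), stimulus_onset_ms = 100,
      group = sample(group_labels(), 1))
  }
  out
}

# homogeneous-Poisson sweep_set with a rate step at `latency_ms` post-onset
step_sweeps <- function(spont_hz, step_hz, latency_ms, n_sweeps, seed,
                        onset = 100, window = c(0, 200)) {
  set.seed(seed)
  t_step <- onset + latency_ms
  sweeps <- lapply(seq_len(n_sweeps), function(j) {
    base <- runif(rpois(1, spont_hz * diff(window) / 1000),
                  window[1], window[2])
    drv <- runif(rpois(1, step_hz * (window[2] - t_step) / 1000),
                 t_step, window[2])
    sort(c(base, drv))
  })
  sweep_set("s1", "step", sweeps, window, stimulus_onset_ms = onset)
}
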