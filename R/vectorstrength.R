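#' Vector strength of spike phase locking to a periodic stimulus
#'
#' For spike times `t_i` (ms, referenced to the first burst onset) and
#' interstimulus interval `T`, each spike is assigned the phase
#' `theta_i = 2 * pi * t_i / T` and
#' `VS = sqrt(x^2 + y^2) / n` with `x = sum(cos(theta_i))`,
#' `y = sum(sin(theta_i))`. VS is 0 for no synchronization and 1 for
#' perfect synchronization. With no spikes the result is undefined
#' (`vs = NA`, `defined = FALSE`) rather than 0, since 0 would fabricate
#' asynchrony.
#'
#' @param spike_times_ms numeric vector of spike times, ms, relative to the
#'   first burst onset.
#' @param period_ms interstimulus interval T, ms (> 0).
#' @param window optional `(start, end)` analysis span; spikes outside are
#'   dropped before the phases are computed.
#' @return object of class `"vector_strength"`: `vs`, `n`, `x`, `y`,
#'   `period_ms`, `window`, `defined`.
#' @export
vector_strength <- function(spike_times_ms, period_ms, window = NULL) {
  if (period_ms <= 0) stop("period_ms must be > 0")
  t <- as.numeric(spike_times_ms)
  if (!is.null(window)) t <- t[t >= window[1] & t < window[2]]
  n <- length(t)
  if (n == 0L) {
    return(structure(list(vs = NA_real_, n = 0L, x = NA_real_, y = NA_real_,
                          period_ms = period_ms, window = window,
                          defined = FALSE),
                     class = "vector_strength"))
  }
  theta <- 2 * pi * (t %% period_ms) / period_ms
  x <- sum(cos(theta)); y <- sum(sin(theta))
  structure(list(vs = sqrt(x^2 + y^2) / n, n = n, x = x, y = y,
                 period_ms = period_ms, window = window, defined = TRUE),
            class = "vector_strength")
}

#' @export
print.vector_strength <- function(x, ...) {
  if (x$defined)
    cat(sprintf("vector strength %.4f (n = %d spikes, T = %g ms)\n",
                x$vs, x$n, x$period_ms))
  else cat("vector strength undefined (no spikes)\n")
  invisible(x)
}

#' Expected vector strength under Gaussian spike-timing jitter
#'
#' For spikes locked to burst onsets with Gaussian timing jitter of SD
#' `sigma_ms`, the phase distribution is wrapped normal and the expected
#' vector strength is `exp(-2 * pi^2 * sigma^2 / T^2)`.
#'
#' @param sigma_ms jitter SD, ms.
#' @param period_ms interburst interval T, ms.
#' @return expected VS in (0, 1].
#' @export
expected_vector_strength <- function(sigma_ms, period_ms) {
  exp(-2 * pi^2 * sigma_ms^2 / period_ms^2)
}

#' Site-level synchronization summary for a noise-burst train
#'
#' Pools spikes across all sweeps of a periodic noise-burst train and
#' computes one vector strength per site, plus the mean over bursts of the
#' per-burst PSTH peak firing rate. The analysis window spans the first
#' burst onset to the last burst onset plus one period; spikes before the
#' first burst are excluded. Spike times are referenced to the first burst
#' onset before phases are computed.
#'
#' @param sweeps a [sweep_set()] recorded in response to the train.
#' @param train the train's [stimulus_spec()] (kind `"noise_train"`).
#' @param binwidth_ms PSTH bin width for per-burst peak rates, ms.
#' @return list with `vs` (a `"vector_strength"`), `peak_rate_hz_mean`
#'   (mean over bursts of per-burst peak rates), `per_burst_peak_hz`.
#' @export
site_train_summary <- function(sweeps, train, binwidth_ms = 1) {
  if (is.null(train) || train$kind != "noise_train")
    stop("train stimulus (kind 'noise_train') required")
  t0 <- train$onset_ms
  T_ms <- train$period_ms
  nb <- train$n_bursts
  w_end <- t0 + nb * T_ms
  t <- unlist(sweeps$sweeps, use.names = FALSE)
  vs <- vector_strength(t - t0, T_ms, window = c(0, nb * T_ms))
  p <- compute_psth(sweeps, binwidth_ms,
                    window = c(t0, min(w_end, sweeps$sweep_window_ms[2])))
  rate <- psth_rate(p)
  starts <- p$bin_edges_ms[-length(p$bin_edges_ms)]
  burst_of <- pmin(floor((starts - t0) / T_ms) + 1, nb)
  per_burst <- vapply(seq_len(nb),
                      function(b) if (any(burst_of == b)) max(rate[burst_of == b]) else NA_real_,
                      numeric(1))
  list(vs = vs, peak_rate_hz_mean = mean(per_burst, na.rm = TRUE),
       per_burst_peak_hz = per_burst)
}
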