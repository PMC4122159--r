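#' Peristimulus time histogram
#'
#' Bins the spikes of all sweeps into uniform half-open bins
#' `[t, t + binwidth)` over `window`; a spike exactly on the right window
#' edge is excluded. Counts are summed over sweeps; the per-bin firing rate
#' is `counts / (n_sweeps * binwidth)`.
#'
#' @param sweeps a [sweep_set()].
#' @param binwidth_ms bin width in ms (default 1 ms, the classifier's
#'   precision).
#' @param window length-2 numeric `(start, end)` in sweep time, ms; defaults
#'   to the full sweep window.
#' @return object of class `"psth"` with fields `bin_edges_ms` (length
#'   nbins + 1), `counts`, `n_sweeps`, `binwidth_ms`.
#' @export
compute_psth <- function(sweeps, binwidth_ms = 1,
                         window = sweeps$sweep_window_ms) {
  stopifnot(inherits(sweeps, "sweep_set"), binwidth_ms > 0)
  w <- sweeps$sweep_window_ms
  if (window[1] < w[1] || window[2] > w[2] || window[2] <= window[1])
    stop("PSTH window outside sweep bounds")
  nbins <- ceiling((window[2] - window[1]) / binwidth_ms - 1e-9)
  edges <- window[1] + binwidth_ms * (0:nbins)
  t <- unlist(sweeps$sweeps, use.names = FALSE)
  t <- t[t >= window[1] & t < window[1] + nbins * binwidth_ms]
  idx <- floor((t - window[1]) / binwidth_ms) + 1L
  idx[idx > nbins] <- nbins  # guard against floating-point edge round-up
  counts <- tabulate(idx, nbins)
  structure(list(bin_edges_ms = edges, counts = counts,
                 n_sweeps = length(sweeps$sweeps),
                 binwidth_ms = binwidth_ms),
            class = "psth")
}

#' Per-bin firing rate of a PSTH, in Hz
#' @param psth a `"psth"` object.
#' @return numeric vector, one rate per bin.
#' @export
psth_rate <- function(psth) {
  psth$counts / (psth$n_sweeps * psth$binwidth_ms / 1000)
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("psth: %d bins of %g ms over [%g, %g] ms, %d sweeps, %d spikes\n",
              length(x$counts), x$binwidth_ms, x$bin_edges_ms[1],
              x$bin_edges_ms[length(x$bin_edges_ms)], x$n_sweeps,
              sum(x$counts)))
  invisible(x)
}

#' Spontaneous firing statistics from the pre-onset baseline
#'
#' Mean and SD of the trial-summed PSTH over the baseline bins immediately
#' preceding stimulus onset, returned both in counts per bin and in Hz.
#' These are the reference statistics for the 3-SD onset-latency threshold
#' and for baseline subtraction of driven counts.
#'
#' @param sweeps a [sweep_set()].
#' @param baseline_ms baseline span immediately pre-onset, ms (default 100).
#' @param binwidth_ms bin width, ms.
#' @return list with `mean_hz`, `sd_hz`, `mean_count`, `sd_count`,
#'   `n_bins`, `n_sweeps`.
#' @export
spontaneous_stats <- function(sweeps, baseline_ms = 100, binwidth_ms = 1) {
  onset <- sweeps$stimulus_onset_ms
  start <- onset - baseline_ms
  if (start < sweeps$sweep_window_ms[1])
    stop("no pre-onset baseline of ", baseline_ms, " ms available")
  p <- compute_psth(sweeps, binwidth_ms, window = c(start, onset))
  k <- p$n_sweeps * binwidth_ms / 1000
  m <- mean(p$counts)
  s <- stats::sd(p$counts)
  list(mean_hz = m / k, sd_hz = s / k, mean_count = m, sd_count = s,
       n_bins = length(p$counts), n_sweeps = p$n_sweeps)
}

#' Driven (baseline-subtracted) spike count in the onset window
#'
#' Mean spikes per sweep in the `window_ms` post-onset window minus the
#' spontaneous expectation for a window of that length. Subtraction makes
#' the metric invariant to the spontaneous rate; the raw evoked count is
#' available via `subtract_baseline = FALSE`.
#'
#' @param sweeps a [sweep_set()].
#' @param onset_ms stimulus onset; defaults to the sweep_set's onset.
#' @param window_ms onset analysis window length, ms (default 40).
#' @param spont_rate_hz spontaneous rate; if `NULL`, estimated from the
#'   pre-onset baseline with [spontaneous_stats()] (error if no baseline).
#' @param baseline_ms baseline span used when estimating the rate.
#' @param subtract_baseline subtract the spontaneous expectation?
#' @return spikes per sweep (may be negative under suppression).
#' @export
driven_spike_count <- function(sweeps, onset_ms = sweeps$stimulus_onset_ms,
                               window_ms = 40, spont_rate_hz = NULL,
                               baseline_ms = 100, subtract_baseline = TRUE) {
  t <- unlist(sweeps$sweeps, use.names = FALSE)
  raw <- sum(t >= onset_ms & t < onset_ms + window_ms) / length(sweeps$sweeps)
  if (!subtract_baseline) return(raw)
  if (is.null(spont_rate_hz)) {
    if (onset_ms - baseline_ms < sweeps$sweep_window_ms[1])
      stop("no pre-onset baseline available and no spont_rate_hz supplied")
    spont_rate_hz <- spontaneous_stats(sweeps, baseline_ms)$mean_hz
  }
  raw - spont_rate_hz * window_ms / 1000
}

#' Onset latency by the 3-SD-above-spontaneous threshold
#'
#' Scans post-onset PSTH bins and returns the start time (onset-relative) of
#' the first bin whose firing rate strictly exceeds
#' `spont_mean_hz + n_sd * spont_sd_hz`. When the baseline SD is zero the
#' threshold degenerates to "any strictly positive excess over the
#' spontaneous mean". Returns `NA` when no bin crosses inside the search
#' window (latency undefined; excluded from group means).
#'
#' @param psth a `"psth"` object covering the post-onset epoch.
#' @param onset_ms stimulus onset in sweep time, ms.
#' @param spont_mean_hz,spont_sd_hz baseline statistics (see
#'   [spontaneous_stats()]).
#' @param search_ms search window length post-onset, ms (default 100).
#' @param n_sd threshold in baseline SDs (default 3).
#' @return latency in ms relative to onset, or `NA_real_`.
#' @export
onset_latency <- function(psth, onset_ms, spont_mean_hz, spont_sd_hz,
                          search_ms = 100, n_sd = 3) {
  if (spont_sd_hz < 0) stop("spont_sd_hz must be >= 0")
  starts <- psth$bin_edges_ms[-length(psth$bin_edges_ms)]
  rate <- psth_rate(psth)
  sel <- starts >= onset_ms & starts < onset_ms + search_ms
  thr <- spont_mean_hz + n_sd * spont_sd_hz
  hit <- which(sel & rate > thr)
  if (!length(hit)) return(NA_real_)
  starts[hit[1]] - onset_ms
}

#' Peak latency (time of maximum firing)
#'
#' Center of the maximal post-onset PSTH bin, relative to stimulus onset;
#' ties are broken toward the earliest bin.
#'
#' @inheritParams onset_latency
#' @return latency in ms relative to onset, or `NA_real_` for an empty PSTH.
#' @export
peak_latency <- function(psth, onset_ms, search_ms = 100) {
  starts <- psth$bin_edges_ms[-length(psth$bin_edges_ms)]
  sel <- which(starts >= onset_ms & starts < onset_ms + search_ms)
  if (!length(sel)) return(NA_real_)
  counts <- psth$counts[sel]
  i <- sel[which.max(counts)]  # which.max takes the earliest maximum
  starts[i] + psth$binwidth_ms / 2 - onset_ms
}

#' Peak firing rate of a PSTH, in Hz
#' @param psth a `"psth"` object.
#' @return maximum over bins of `counts / (n_sweeps * binwidth)`, Hz.
#' @export
peak_firing_rate <- function(psth) {
  if (!length(psth$counts)) return(0)
  max(psth_rate(psth))
}

#' All speech-response metrics for one site and stimulus
#'
#' Convenience wrapper computing the PSTH, baseline statistics, driven
#' spike count, onset latency, peak latency and peak rate with the
#' package defaults (1-ms bins, 40-ms onset window, 100-ms baseline,
#' 100-ms latency search window).
#'
#' @param sweeps a [sweep_set()].
#' @param window_ms onset window length, ms.
#' @param binwidth_ms PSTH bin width, ms.
#' @param baseline_ms baseline span, ms.
#' @param search_ms latency search window, ms.
#' @return list with `driven_spikes`, `raw_spikes`, `onset_latency_ms`,
#'   `peak_latency_ms`, `peak_rate_hz`, `spontaneous_rate_hz`, `spont_sd_hz`.
#' @export
response_metrics <- function(sweeps, window_ms = 40, binwidth_ms = 1,
                             baseline_ms = 100, search_ms = 100) {
  sp <- spontaneous_stats(sweeps, baseline_ms, binwidth_ms)
  onset <- sweeps$stimulus_onset_ms
  end <- min(onset + search_ms, sweeps$sweep_window_ms[2])
  p <- compute_psth(sweeps, binwidth_ms, window = c(onset, end))
  list(
    driven_spikes = driven_spike_count(sweeps, onset, window_ms,
                                       spont_rate_hz = sp$mean_hz),
    raw_spikes = driven_spike_count(sweeps, onset, window_ms,
                                    subtract_baseline = FALSE),
    onset_latency_ms = onset_latency(p, onset, sp$mean_hz, sp$sd_hz,
                                     search_ms),
    peak_latency_ms = peak_latency(p, onset, search_ms),
    peak_rate_hz = peak_firing_rate(p),
    spontaneous_rate_hz = sp$mean_hz,
    spont_sd_hz = sp$sd_hz
  )
}
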