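#' Frequency-intensity tuning grid
#'
#' Spike counts on the tone lattice for one site: mean spikes per sweep in
#' the tone count window at every (intensity, frequency) point, plus the
#' spontaneous count statistics of the same window length used by the
#' response criterion.
#'
#' @param freqs_hz frequency lattice, Hz (ascending).
#' @param intensities_db intensity lattice, dB (ascending).
#' @param mean_count matrix `length(intensities_db) x length(freqs_hz)` of
#'   mean raw counts per sweep (spontaneous included).
#' @param spont_mean_count mean spontaneous count for the window.
#' @param spont_sd_count SD of per-sweep spontaneous counts.
#' @param n_sweeps sweeps per lattice point.
#' @return object of class `"tuning_grid"`.
#' @export
tuning_grid <- function(freqs_hz, intensities_db, mean_count,
                        spont_mean_count, spont_sd_count, n_sweeps) {
  if (!all(dim(mean_count) == c(length(intensities_db), length(freqs_hz))))
    stop("mean_count must be intensities x frequencies")
  if (any(!is.finite(mean_count))) stop("non-finite counts in grid")
  structure(list(freqs_hz = as.numeric(freqs_hz),
                 intensities_db = as.numeric(intensities_db),
                 mean_count = mean_count,
                 spont_mean_count = spont_mean_count,
                 spont_sd_count = spont_sd_count,
                 n_sweeps = n_sweeps),
            class = "tuning_grid")
}

#' Build a tuning grid from tone-evoked sweep sets
#'
#' Counts spikes in the `count_window_ms` post-onset window per sweep and
#' lattice point; spontaneous statistics come from a pre-onset window of
#' the same length, pooled over all tone sweeps.
#'
#' @param tone_sweeps named list of [sweep_set()]s from
#'   [generate_tuning_sweeps()] (names `"tone_<freq>_<db>"`).
#' @param freqs_hz,intensities_db the lattice.
#' @param count_window_ms counting window, ms.
#' @return a `"tuning_grid"`.
#' @export
tuning_grid_from_sweeps <- function(tone_sweeps, freqs_hz, intensities_db,
                                    count_window_ms = 40) {
  nint <- length(intensities_db); nfrq <- length(freqs_hz)
  mc <- matrix(NA_real_, nint, nfrq,
               dimnames = list(intensities_db, signif(freqs_hz, 6)))
  base <- numeric(0)
  n_sweeps <- NA_integer_
  for (fi in seq_len(nfrq)) for (ii in seq_len(nint)) {
    key <- sprintf("tone_%g_%g", freqs_hz[fi], intensities_db[ii])
    ss <- tone_sweeps[[key]]
    if (is.null(ss)) stop("missing lattice point: ", key)
    on <- ss$stimulus_onset_ms
    cnt <- vapply(ss$sweeps, function(t)
      sum(t >= on & t < on + count_window_ms), numeric(1))
    mc[ii, fi] <- mean(cnt)
    base <- c(base, vapply(ss$sweeps, function(t)
      sum(t >= on - count_window_ms & t < on), numeric(1)))
    n_sweeps <- length(ss$sweeps)
  }
  tuning_grid(freqs_hz, intensities_db, mc,
              spont_mean_count = mean(base),
              spont_sd_count = stats::sd(base), n_sweeps = n_sweeps)
}

#' Responsive mask over the tone lattice
#'
#' The analysis definition of "evoked a response": a lattice point is
#' responsive when its mean count exceeds the spontaneous mean by
#' `criterion_sd` per-sweep spontaneous SDs. The per-sweep SD (rather than
#' the standard error of the point's mean) keeps the criterion stringent
#' across the ~650-point lattice, where a per-mean criterion would flood
#' the mask with false positives. With zero spontaneous variability
#' (noiseless grids) the rule reduces to any strictly positive driven
#' count.
#'
#' @param grid a `"tuning_grid"`.
#' @param criterion_sd response criterion in baseline per-sweep SDs
#'   (default 2).
#' @return logical matrix, same shape as `grid$mean_count`.
#' @export
responsive_mask <- function(grid, criterion_sd = 2) {
  if (is.null(grid$spont_mean_count) || is.na(grid$spont_mean_count))
    stop("spontaneous statistics missing from grid")
  grid$mean_count > grid$spont_mean_count +
    criterion_sd * grid$spont_sd_count
}

#' Characteristic frequency of a site
#'
#' The frequency of the responsive lattice point at the lowest responsive
#' intensity. Ties at that intensity are resolved by the larger driven
#' count, then by the lower frequency.
#'
#' @param grid a `"tuning_grid"`.
#' @param mask logical matrix from [responsive_mask()].
#' @return CF in Hz, or `NA_real_` when the mask is empty (untuned site).
#' @export
characteristic_frequency <- function(grid, mask) {
  rows <- which(apply(mask, 1, any))
  if (!length(rows)) return(NA_real_)
  r <- rows[1]
  cols <- which(mask[r, ])
  if (length(cols) > 1L) {
    cnt <- grid$mean_count[r, cols]
    cols <- cols[cnt == max(cnt)]
  }
  grid$freqs_hz[min(cols)]
}

#' Tone response threshold at the characteristic frequency
#'
#' The lowest intensity that evoked a response at CF.
#'
#' @param grid a `"tuning_grid"`.
#' @param mask logical matrix from [responsive_mask()].
#' @param cf_hz characteristic frequency (a grid frequency).
#' @return threshold in dB on the intensity grid, or `NA_real_` if no
#'   responsive point exists at CF.
#' @export
tone_threshold <- function(grid, mask, cf_hz) {
  if (is.na(cf_hz)) return(NA_real_)
  fc <- which.min(abs(log2(grid$freqs_hz / cf_hz)))
  rows <- which(mask[, fc])
  if (!length(rows)) return(NA_real_)
  grid$intensities_db[rows[1]]
}

#' Bandwidth 40 dB above threshold, in octaves
#'
#' `log2(f_max / f_min)` over the responsive frequency span at the
#' intensity row nearest `threshold + 40` dB. By default the span is the
#' contiguous responsive run containing CF (holes terminate it); the
#' `"loose"` rule takes the min-max responsive frequencies of the row.
#'
#' @param grid a `"tuning_grid"`.
#' @param mask logical matrix from [responsive_mask()].
#' @param cf_hz characteristic frequency.
#' @param threshold_db tone threshold from [tone_threshold()].
#' @param span_rule `"contiguous"` (default) or `"loose"`.
#' @return bandwidth in octaves (0 for a single responsive point), or
#'   `NA_real_` when `threshold + 40` exceeds the grid or the row has no
#'   responsive point at CF.
#' @export
bandwidth40 <- function(grid, mask, cf_hz, threshold_db,
                        span_rule = c("contiguous", "loose")) {
  span_rule <- match.arg(span_rule)
  if (is.na(cf_hz) || is.na(threshold_db)) return(NA_real_)
  target <- threshold_db + 40
  if (target > max(grid$intensities_db)) return(NA_real_)
  r <- which.min(abs(grid$intensities_db - target))
  row <- mask[r, ]
  if (!any(row)) return(NA_real_)
  fc <- which.min(abs(log2(grid$freqs_hz / cf_hz)))
  if (span_rule == "loose") {
    cols <- which(row)
  } else {
    if (!row[fc]) return(NA_real_)
    lo <- fc; while (lo > 1L && row[lo - 1L]) lo <- lo - 1L
    hi <- fc; while (hi < length(row) && row[hi + 1L]) hi <- hi + 1L
    cols <- lo:hi
  }
  log2(grid$freqs_hz[max(cols)] / grid$freqs_hz[min(cols)])
}

#' Rate-intensity function near the characteristic frequency
#'
#' Mean driven count per tone at each intensity, averaged over frequencies
#' within one octave of CF (band clipped, not wrapped, at the grid edges).
#'
#' @param grid a `"tuning_grid"`.
#' @param cf_hz characteristic frequency.
#' @return data.frame with `intensity_db` and `driven_spikes` (one row per
#'   intensity on the grid).
#' @export
rate_intensity_function <- function(grid, cf_hz) {
  if (is.na(cf_hz)) stop("cf_hz undefined")
  band <- abs(log2(grid$freqs_hz / cf_hz)) <= 1 + 1e-9
  driven <- grid$mean_count - grid$spont_mean_count
  data.frame(intensity_db = grid$intensities_db,
             driven_spikes = rowMeans(driven[, band, drop = FALSE]))
}

#' Full tuning characterization of one site
#'
#' @param grid a `"tuning_grid"`.
#' @param criterion_sd response criterion (see [responsive_mask()]).
#' @param span_rule bandwidth span rule (see [bandwidth40()]).
#' @return list with `cf_hz`, `threshold_db`, `bw40_octaves`, `mask`,
#'   `rate_intensity` (NULL for untuned sites).
#' @export
tuning_summary <- function(grid, criterion_sd = 2,
                           span_rule = "contiguous") {
  mask <- responsive_mask(grid, criterion_sd)
  cf <- characteristic_frequency(grid, mask)
  thr <- tone_threshold(grid, mask, cf)
  bw <- bandwidth40(grid, mask, cf, thr, span_rule)
  list(cf_hz = cf, threshold_db = thr, bw40_octaves = bw, mask = mask,
       rate_intensity = if (is.na(cf)) NULL else
         rate_intensity_function(grid, cf))
}
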