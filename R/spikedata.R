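#' Spike-sweep container for one (site, stimulus) pair
#'
#' A `sweep_set` holds the spike times recorded at one multiunit site over
#' repeated presentations (sweeps) of one stimulus. All times are in
#' milliseconds, floating point, 0-based relative to sweep start; the
#' stimulus onset within the sweep is carried explicitly so that every
#' downstream metric can be expressed onset-relative.
#'
#' @param site_id character scalar, unique site identifier.
#' @param stim_id character scalar, stimulus identifier.
#' @param sweeps list of numeric vectors, one per sweep, each a sorted vector
#'   of spike times in ms relative to sweep start. Empty sweeps are
#'   first-class: a silent sweep is `numeric(0)`, never dropped, so PSTH
#'   denominators stay unbiased.
#' @param sweep_window_ms length-2 numeric, recording epoch `(start, end)`.
#' @param stimulus_onset_ms stimulus onset within the sweep, ms.
#' @param group group label, one of [group_labels()] or `NA`.
#' @return An object of class `"sweep_set"`.
#' @export
sweep_set <- function(site_id, stim_id, sweeps,
                      sweep_window_ms = c(0, 500),
                      stimulus_onset_ms = 100,
                      group = NA_character_) {
  x <- structure(
    list(
      site_id = as.character(site_id),
      stim_id = as.character(stim_id),
      sweeps = lapply(sweeps, as.numeric),
      sweep_window_ms = as.numeric(sweep_window_ms),
      stimulus_onset_ms = as.numeric(stimulus_onset_ms),
      group = as.character(group)
    ),
    class = "sweep_set"
  )
  validate_sweep_set(x)
  x
}

#' Closed set of experimental group labels
#' @return Character vector of the four group labels.
#' @export
group_labels <- function() {
  c("vpa_untrained", "vpa_trained", "saline_untrained", "saline_trained")
}

#' Validate a sweep_set
#'
#' Checks the container invariants: sorted, non-negative spike times lying
#' within the sweep window, a well-formed window, and a known group label.
#'
#' @param x a `sweep_set`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_sweep_set <- function(x) {
  stopifnot(inherits(x, "sweep_set"))
  w <- x$sweep_window_ms
  if (length(w) != 2L || !all(is.finite(w)) || w[2] <= w[1] || w[1] < 0)
    stop("sweep_window_ms must be (start, end) with 0 <= start < end")
  if (!is.na(x$group) && !(x$group %in% group_labels()))
    stop("unknown group label: ", x$group)
  for (i in seq_along(x$sweeps)) {
    t <- x$sweeps[[i]]
    if (length(t) == 0L) next
    if (any(!is.finite(t))) stop("non-finite spike time in sweep ", i)
    if (is.unsorted(t)) stop("unsorted spike times in sweep ", i)
    if (any(t < w[1]) || any(t > w[2]))
      stop("spike time outside sweep window in sweep ", i)
  }
  invisible(x)
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf(
    "sweep_set: site %s, stim %s, %d sweeps, %d spikes, window [%g, %g] ms, onset %g ms\n",
    x$site_id, x$stim_id, length(x$sweeps),
    sum(lengths(x$sweeps)), x$sweep_window_ms[1], x$sweep_window_ms[2],
    x$stimulus_onset_ms))
  invisible(x)
}

#' Total number of spikes in a sweep_set
#' @param x a `sweep_set`.
#' @return integer count.
#' @export
n_spikes <- function(x) sum(lengths(x$sweeps))

#' Stimulus description
#'
#' Describes one stimulus: a vocoded CVC speech token, a periodic
#' noise-burst train, or a pure tone from the frequency-intensity grid.
#'
#' @param stim_id character scalar identifier.
#' @param kind one of `"speech"`, `"noise_train"`, `"tone"`.
#' @param label stimulus label (e.g. the word `"dad"`); defaults to `stim_id`.
#' @param onset_ms stimulus onset within the sweep, ms.
#' @param n_bursts integer, number of bursts (noise trains only).
#' @param period_ms interburst interval T in ms (noise trains only).
#' @param freq_hz tone frequency in Hz (tones only).
#' @param intensity_db tone level in dB SPL (tones only).
#' @return An object of class `"stimulus_spec"`.
#' @export
stimulus_spec <- function(stim_id, kind = c("speech", "noise_train", "tone"),
                          label = stim_id, onset_ms = 100,
                          n_bursts = NULL, period_ms = NULL,
                          freq_hz = NULL, intensity_db = NULL) {
  kind <- match.arg(kind)
  if (kind == "noise_train") {
    if (is.null(n_bursts) || n_bursts < 1) stop("noise_train needs n_bursts >= 1")
    if (is.null(period_ms) || period_ms <= 0) stop("noise_train needs period_ms > 0")
  }
  if (kind == "tone") {
    if (is.null(freq_hz) || is.null(intensity_db))
      stop("tone needs freq_hz and intensity_db")
    if (freq_hz < 1000 || freq_hz > 32000)
      stop("tone frequency outside the 1-32 kHz grid")
    if (intensity_db < 0 || intensity_db > 75)
      stop("tone intensity outside the 0-75 dB grid")
  }
  structure(
    list(stim_id = as.character(stim_id), kind = kind,
         label = as.character(label), onset_ms = as.numeric(onset_ms),
         n_bursts = if (is.null(n_bursts)) NULL else as.integer(n_bursts),
         period_ms = if (is.null(period_ms)) NULL else as.numeric(period_ms),
         freq_hz = if (is.null(freq_hz)) NULL else as.numeric(freq_hz),
         intensity_db = if (is.null(intensity_db)) NULL else as.numeric(intensity_db)),
    class = "stimulus_spec")
}

#' The 11 CVC speech tokens used in training and recording
#' @return character vector of word labels.
#' @export
speech_labels <- function() {
  c("bad", "chad", "dad", "dead", "deed", "dood",
    "dud", "gad", "sad", "shad", "tad")
}

#' Speech tokens differing by initial consonant (shared vowel)
#'
#' The subset of words that contrast the initial consonant against the same
#' "a" vowel; pairwise neural discrimination of consonants is evaluated over
#' unordered pairs of these labels.
#' @return character vector.
#' @export
consonant_labels <- function() {
  c("bad", "chad", "dad", "gad", "sad", "shad", "tad")
}

# ---- tabular I/O -----------------------------------------------------------
# Dialect: comma-separated text, one row per spike, columns
#   site_id, group, stim_id, sweep_index, spike_time_ms,
#   sweep_start_ms, sweep_end_ms, stimulus_onset_ms
# A sweep with zero spikes is kept as one row with spike_time_ms = NA so the
# sweep count (the PSTH denominator) survives the round trip.

#' Write a collection of sweep_sets to a delimited text table
#'
#' Rows are ordered deterministically by (site, stimulus, sweep, time) so two
#' writes of the same data are byte-identical.
#'
#' @param data list of `sweep_set` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(data, path) {
  rows <- lapply(data, function(ss) {
    validate_sweep_set(ss)
    per_sweep <- lapply(seq_along(ss$sweeps), function(i) {
      t <- ss$sweeps[[i]]
      if (length(t) == 0L) t <- NA_real_
      data.frame(site_id = ss$site_id, group = ss$group,
                 stim_id = ss$stim_id, sweep_index = i,
                 spike_time_ms = t,
                 sweep_start_ms = ss$sweep_window_ms[1],
                 sweep_end_ms = ss$sweep_window_ms[2],
                 stimulus_onset_ms = ss$stimulus_onset_ms,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_sweep)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(site_id = character(), group = character(),
                     stim_id = character(), sweep_index = integer(),
                     spike_time_ms = numeric(), sweep_start_ms = numeric(),
                     sweep_end_ms = numeric(), stimulus_onset_ms = numeric())
  } else {
    df <- df[order(df$site_id, df$stim_id, df$sweep_index, df$spike_time_ms), ]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a spike table into a collection of sweep_sets
#'
#' Inverse of [write_spike_table()]: returns one `sweep_set` per
#' (site, stimulus) pair, with empty sweeps preserved.
#'
#' @param path input file path.
#' @return named list of `sweep_set` (names `"<site_id>|<stim_id>"`).
#' @export
read_spike_table <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(site_id = "character", group = "character",
                                   stim_id = "character")),
    error = function(e) stop("malformed spike table '", path, "': ",
                             conditionMessage(e)))
  need <- c("site_id", "group", "stim_id", "sweep_index", "spike_time_ms",
            "sweep_start_ms", "sweep_end_ms", "stimulus_onset_ms")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("spike table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(structure(list(), names = character()))
  bad <- which(!is.na(df$spike_time_ms) & df$spike_time_ms < 0)
  if (length(bad)) stop("negative spike time at data row ", bad[1])
  key <- paste(df$site_id, df$stim_id, sep = "|")
  out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    d <- df[idx, ]
    n_sw <- max(d$sweep_index)
    sweeps <- rep(list(numeric(0)), n_sw)
    for (i in seq_len(n_sw)) {
      t <- d$spike_time_ms[d$sweep_index == i]
      t <- t[!is.na(t)]
      if (length(t) && is.unsorted(t)) stop(
        "unsorted spike times for site ", d$site_id[1], " stim ",
        d$stim_id[1], " sweep ", i)
      sweeps[[i]] <- t
    }
    grp <- d$group[1]
    if (!is.na(grp) && grp == "") grp <- NA_character_
    sweep_set(d$site_id[1], d$stim_id[1], sweeps,
              sweep_window_ms = c(d$sweep_start_ms[1], d$sweep_end_ms[1]),
              stimulus_onset_ms = d$stimulus_onset_ms[1],
              group = grp)
  })
  out
}

# ---- behavior logs ---------------------------------------------------------

#' Write go/no-go behavioral trials to a delimited text log
#'
#' @param trials data.frame with columns `session_id`, `trial_index`,
#'   `stim_label`, `is_target`, `pressed`, `response_window_s`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_behavior_log <- function(trials, path) {
  need <- c("session_id", "trial_index", "stim_label", "is_target",
            "pressed", "response_window_s")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("behavior log missing column(s): ",
                         paste(miss, collapse = ", "))
  trials <- trials[order(trials$session_id, trials$trial_index), need]
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a go/no-go behavioral trial log
#'
#' Trials are returned in session order with `is_target` and `pressed`
#' parsed as logicals. Unknown stimulus labels trigger a warning but the
#' trials are kept (labels do not affect scoring, which uses `is_target`).
#'
#' @param path input file path.
#' @param known_labels labels considered known; defaults to
#'   [speech_labels()].
#' @return data.frame of trials ordered by (session_id, trial_index), with a
#'   `session_id` column to group on.
#' @export
read_behavior_log <- function(path, known_labels = speech_labels()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("session_id", "trial_index", "stim_label", "is_target",
            "pressed", "response_window_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("behavior log missing column(s): ",
                         paste(miss, collapse = ", "))
  df$session_id <- as.character(df$session_id)
  df$stim_label <- as.character(df$stim_label)
  df$is_target <- as.logical(df$is_target)
  df$pressed <- as.logical(df$pressed)
  bad <- !(df$response_window_s >= 3 & df$response_window_s <= 8)
  if (any(bad)) stop("response_window_s outside [3, 8] at data row ",
                     which(bad)[1])
  unk <- setdiff(unique(df$stim_label), known_labels)
  if (length(unk)) warning("unknown stimulus label(s): ",
                           paste(unk, collapse = ", "))
  df[order(df$session_id, df$trial_index), need]
}

# ---- stimulus catalogs -----------------------------------------------------

#' Write a stimulus catalog as a structured config file
#'
#' @param stims list of `stimulus_spec` objects.
#' @param path output YAML file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_catalog <- function(stims, path) {
  lst <- lapply(stims, function(s) Filter(Negate(is.null), unclass(s)))
  names(lst) <- vapply(stims, function(s) s$stim_id, character(1))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a stimulus catalog config file
#' @param path YAML file written by [write_stimulus_catalog()].
#' @return named list of `stimulus_spec`.
#' @export
read_stimulus_catalog <- function(path) {
  lst <- yaml::read_yaml(path)
  lapply(lst, function(s)
    stimulus_spec(s$stim_id, s$kind, label = s$label, onset_ms = s$onset_ms,
                  n_bursts = s$n_bursts, period_ms = s$period_ms,
                  freq_hz = s$freq_hz, intensity_db = s$intensity_db))
}
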