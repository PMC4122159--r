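#' Bin one sweep into the classifier's onset-window count vector
#'
#' Counts spikes of a single sweep in uniform 1-ms bins over the 40-ms
#' window anchored at stimulus onset (half-open bins, right window edge
#' excluded).
#'
#' @param spike_times_ms numeric vector of spike times for one sweep, ms in
#'   sweep time.
#' @param onset_ms stimulus onset, ms.
#' @param window_ms window length, ms (default 40).
#' @param binwidth_ms bin width, ms (default 1).
#' @return integer vector of length `window_ms / binwidth_ms`.
#' @export
bin_sweep <- function(spike_times_ms, onset_ms, window_ms = 40,
                      binwidth_ms = 1) {
  nbins <- as.integer(round(window_ms / binwidth_ms))
  t <- spike_times_ms[spike_times_ms >= onset_ms &
                        spike_times_ms < onset_ms + window_ms]
  idx <- floor((t - onset_ms) / binwidth_ms) + 1L
  idx[idx > nbins] <- nbins
  tabulate(idx, nbins)
}

# binned matrix (sweeps x bins) for a sweep_set
sweep_matrix <- function(sweeps, window_ms = 40, binwidth_ms = 1) {
  onset <- sweeps$stimulus_onset_ms
  m <- vapply(sweeps$sweeps,
              function(t) bin_sweep(t, onset, window_ms, binwidth_ms),
              integer(round(window_ms / binwidth_ms)))
  t(m)
}

#' PSTH template: mean binned onset response across sweeps
#'
#' Element k is the mean spike count in bin k across the included sweeps.
#' With `exclude_sweep`, that sweep is left out (leave-one-out template for
#' classifying it without optimistic bias).
#'
#' @param sweeps a [sweep_set()] with at least 2 sweeps.
#' @param window_ms onset window, ms.
#' @param binwidth_ms bin width, ms.
#' @param exclude_sweep optional index of the sweep to leave out.
#' @return numeric vector of per-bin mean counts.
#' @export
build_template <- function(sweeps, window_ms = 40, binwidth_ms = 1,
                           exclude_sweep = NULL) {
  m <- sweep_matrix(sweeps, window_ms, binwidth_ms)
  if (!is.null(exclude_sweep)) {
    if (nrow(m) <= 1L) stop("cannot exclude the only sweep")
    m <- m[-exclude_sweep, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need >= 2 sweeps to build a template")
  colMeans(m)
}

#' Assign a single sweep to the nearer of two PSTH templates
#'
#' Euclidean distance between the sweep's binned count vector and each
#' template; the sweep is assigned to the template it most closely
#' resembles. Exact ties go to label A (deterministic; ties have measure
#' zero on real-valued templates but occur on integer toy data).
#'
#' @param sweep_binned binned count vector for the sweep.
#' @param template_a,template_b templates from [build_template()].
#' @param labels length-2 character, names of A and B.
#' @return list with `label`, `d_a`, `d_b`.
#' @export
classify_sweep <- function(sweep_binned, template_a, template_b,
                           labels = c("A", "B")) {
  if (length(sweep_binned) != length(template_a) ||
      length(template_a) != length(template_b))
    stop("sweep and template lengths differ")
  d_a <- sqrt(sum((sweep_binned - template_a)^2))
  d_b <- sqrt(sum((sweep_binned - template_b)^2))
  list(label = if (d_a <= d_b) labels[1] else labels[2], d_a = d_a, d_b = d_b)
}

#' Pairwise single-sweep neural discrimination of two stimuli
#'
#' Every sweep of both stimuli is classified against the two mean-PSTH
#' templates; with `loo = TRUE` (default) the sweep under test is excluded
#' from its own stimulus's template. Percent correct is
#' `100 * correct / total` over all sweeps of both stimuli.
#'
#' @param ss_a,ss_b [sweep_set()] objects for stimuli A and B at one site.
#' @param loo leave-one-out template construction (default TRUE); `FALSE`
#'   reproduces the literal resubstitution reading.
#' @param window_ms,binwidth_ms classifier window and precision.
#' @return object of class `"classifier_result"`: `stim_pair`,
#'   `percent_correct`, `confusion` (2x2 matrix, rows = true),
#'   `assignments`, `n_sweeps_per_stim`.
#' @export
pairwise_discrimination <- function(ss_a, ss_b, loo = TRUE, window_ms = 40,
                                    binwidth_ms = 1) {
  if (is.null(ss_a) || is.null(ss_b)) stop("both stimuli must be present")
  la <- ss_a$stim_id; lb <- ss_b$stim_id
  ma <- sweep_matrix(ss_a, window_ms, binwidth_ms)
  mb <- sweep_matrix(ss_b, window_ms, binwidth_ms)
  if (nrow(ma) < 2L || nrow(mb) < 2L) stop("need >= 2 sweeps per stimulus")
  tmpl_a <- colMeans(ma); tmpl_b <- colMeans(mb)
  na <- nrow(ma); nb <- nrow(mb)
  confusion <- matrix(0L, 2, 2, dimnames = list(true = c(la, lb),
                                                assigned = c(la, lb)))
  assign_one <- function(v, ta, tb) {
    if (sum((v - ta)^2) <= sum((v - tb)^2)) 1L else 2L
  }
  labs_a <- integer(na); labs_b <- integer(nb)
  for (i in seq_len(na)) {
    ta <- if (loo) (tmpl_a * na - ma[i, ]) / (na - 1) else tmpl_a
    labs_a[i] <- assign_one(ma[i, ], ta, tmpl_b)
  }
  for (i in seq_len(nb)) {
    tb <- if (loo) (tmpl_b * nb - mb[i, ]) / (nb - 1) else tmpl_b
    labs_b[i] <- assign_one(mb[i, ], tmpl_a, tb)
  }
  confusion[1, ] <- tabulate(labs_a, 2)
  confusion[2, ] <- tabulate(labs_b, 2)
  correct <- confusion[1, 1] + confusion[2, 2]
  structure(list(
    stim_pair = c(la, lb),
    percent_correct = 100 * correct / (na + nb),
    confusion = confusion,
    assignments = list(c(la, lb)[labs_a], c(la, lb)[labs_b]),
    n_sweeps_per_stim = c(na, nb)),
    class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("classifier: %s vs %s, %.1f%% correct (%d + %d sweeps)\n",
              x$stim_pair[1], x$stim_pair[2], x$percent_correct,
              x$n_sweeps_per_stim[1], x$n_sweeps_per_stim[2]))
  invisible(x)
}

#' Mean pairwise classifier accuracy over all stimulus pairs at one site
#'
#' Runs [pairwise_discrimination()] for every unordered pair of the given
#' labels and returns the unweighted mean percent correct, the per-site
#' summary the group comparisons average.
#'
#' @param site_data named list of [sweep_set()]s for one site, keyed by
#'   stimulus label.
#' @param labels stimulus labels to pair (>= 2); defaults to
#'   [consonant_labels()].
#' @param loo,window_ms,binwidth_ms passed to [pairwise_discrimination()].
#' @return list with `mean_percent_correct` and `pairs` (data.frame of
#'   per-pair results).
#' @export
all_pairs_summary <- function(site_data, labels = consonant_labels(),
                              loo = TRUE, window_ms = 40, binwidth_ms = 1) {
  if (length(labels) < 2L) stop("need >= 2 labels")
  cmb <- utils::combn(sort(labels), 2)
  pc <- numeric(ncol(cmb))
  for (j in seq_len(ncol(cmb))) {
    a <- cmb[1, j]; b <- cmb[2, j]
    if (is.null(site_data[[a]]) || is.null(site_data[[b]]))
      stop("missing stimulus: ", if (is.null(site_data[[a]])) a else b)
    pc[j] <- pairwise_discrimination(site_data[[a]], site_data[[b]], loo,
                                     window_ms, binwidth_ms)$percent_correct
  }
  list(mean_percent_correct = mean(pc),
       pairs = data.frame(label_a = cmb[1, ], label_b = cmb[2, ],
                          percent_correct = pc))
}
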