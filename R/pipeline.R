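# End-to-end orchestration: generate -> per-site metrics -> group report.

#' Per-site analysis of one group's dataset
#'
#' Computes, for every site: the speech-response metrics averaged over the
#' 11 words (driven spikes, onset latency over defined words, peak
#' latency), the mean pairwise consonant classifier accuracy, the
#' noise-train vector strength and mean per-burst peak rate, and the tone
#' tuning summary (CF, threshold, BW40).
#'
#' @param dataset output of [generate_group_dataset()] (or an equivalently
#'   shaped list built from recorded data).
#' @param classifier_labels labels paired by the classifier.
#' @param loo leave-one-out classifier templates?
#' @param criterion_sd tone response criterion.
#' @return data.frame, one row per site.
#' @export
analyze_sites <- function(dataset, classifier_labels = consonant_labels(),
                          loo = TRUE, criterion_sd = 2) {
  n <- length(dataset$site_ids)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    row <- list(site_id = dataset$site_ids[i], group = dataset$group,
                driven_spikes = NA_real_, onset_latency_ms = NA_real_,
                peak_latency_ms = NA_real_, classifier_pc = NA_real_,
                vs = NA_real_, peak_rate_hz = NA_real_,
                cf_hz = NA_real_, threshold_db = NA_real_,
                bw40_octaves = NA_real_)
    sp <- dataset$speech[[i]]
    if (!is.null(sp)) {
      m <- lapply(sp, response_metrics)
      row$driven_spikes <- mean(vapply(m, `[[`, 0, "driven_spikes"))
      ol <- vapply(m, `[[`, 0, "onset_latency_ms")
      row$onset_latency_ms <- if (all(is.na(ol))) NA_real_ else
        mean(ol, na.rm = TRUE)
      row$peak_latency_ms <- mean(vapply(m, `[[`, 0, "peak_latency_ms"),
                                  na.rm = TRUE)
      row$classifier_pc <- all_pairs_summary(sp, classifier_labels,
                                             loo = loo)$mean_percent_correct
    }
    tr <- dataset$train[[i]]
    if (!is.null(tr)) {
      s <- site_train_summary(tr, dataset$train_stim)
      row$vs <- if (s$vs$defined) s$vs$vs else NA_real_
      row$peak_rate_hz <- s$peak_rate_hz_mean
    }
    tg <- dataset$tuning[[i]]
    if (!is.null(tg)) {
      ts <- tuning_summary(tg, criterion_sd)
      row$cf_hz <- ts$cf_hz
      row$threshold_db <- ts$threshold_db
      row$bw40_octaves <- ts$bw40_octaves
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Group report: across-site means with s.e.m.
#'
#' @param site_table data.frame from [analyze_sites()] (rows may pool
#'   several groups).
#' @param metrics metric columns to summarize.
#' @return data.frame with one row per (group, metric): `mean`, `sem`
#'   (`sd / sqrt(n)`), `n` (sites with a defined value).
#' @export
group_report <- function(site_table,
                         metrics = c("driven_spikes", "onset_latency_ms",
                                     "peak_latency_ms", "classifier_pc",
                                     "vs", "peak_rate_hz", "threshold_db",
                                     "bw40_octaves")) {
  out <- list()
  for (g in unique(site_table$group)) for (m in metrics) {
    v <- site_table[site_table$group == g, m]
    v <- v[!is.na(v)]
    out[[length(out) + 1L]] <- data.frame(
      group = g, metric = m,
      mean = if (length(v)) mean(v) else NA_real_,
      sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
      n = length(v))
  }
  do.call(rbind, out)
}

#' Welch two-sample comparison of a site metric between groups
#'
#' Group inference is delegated to the standard Welch t-test; when the
#' comparison belongs to the 16-intensity family of the rate-intensity
#' analysis, a Bonferroni factor of 16 gives the corrected significance
#' threshold 0.05 / 16 = 0.003125.
#'
#' @param site_table data.frame with `group` and metric columns.
#' @param metric metric column name.
#' @param group_a,group_b group labels to compare.
#' @param bonferroni_factor number of tests in the family (1 = none).
#' @return list with `difference` (mean A - mean B), `p_value`,
#'   `p_threshold` (0.05 / factor), `significant`, `n`.
#' @export
compare_groups <- function(site_table, metric, group_a, group_b,
                           bonferroni_factor = 1) {
  va <- site_table[site_table$group == group_a, metric]
  vb <- site_table[site_table$group == group_b, metric]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(va) < 2 || length(vb) < 2) stop("need >= 2 sites per group")
  diff <- mean(va) - mean(vb)
  if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
    return(list(difference = diff, p_value = NA_real_,
                p_threshold = 0.05 / bonferroni_factor,
                significant = NA, n = c(length(va), length(vb)),
                degenerate_variance = TRUE))
  }
  tt <- stats::t.test(va, vb)
  thr <- 0.05 / bonferroni_factor
  list(difference = diff, p_value = tt$p.value, p_threshold = thr,
       significant = tt$p.value < thr, n = c(length(va), length(vb)),
       degenerate_variance = FALSE)
}

#' Default run configuration
#'
#' @param n_sites sites per group.
#' @param n_sweeps sweeps per stimulus.
#' @param seed master seed.
#' @param groups group labels to run.
#' @param components data components to generate and analyze.
#' @param n_subjects,n_sessions,trials_per_session behavioral scale.
#' @param loo,criterion_sd analysis parameters.
#' @param out_dir optional output directory for tables and the manifest.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(n_sites = 100, n_sweeps = 20, seed = 1,
                       groups = group_labels(),
                       components = c("speech", "train", "tuning"),
                       n_subjects = 10, n_sessions = 15,
                       trials_per_session = 100, loo = TRUE,
                       criterion_sd = 2, out_dir = NULL) {
  structure(list(n_sites = n_sites, n_sweeps = n_sweeps, seed = seed,
                 groups = groups, components = components,
                 n_subjects = n_subjects, n_sessions = n_sessions,
                 trials_per_session = trials_per_session, loo = loo,
                 criterion_sd = criterion_sd, out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline: generate, analyze, report
#'
#' Generates each configured group with the shipped presets, analyzes every
#' site, scores behavior, and assembles the group report plus the standard
#' pairwise comparisons against the VPA-trained group. With `out_dir` set,
#' writes `sites.csv`, `report.csv`, `behavior_curve.csv` and a
#' `manifest.json` (config, seed, package version, md5 checksums of every
#' output file). Identical config + seed reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @return list of class `"pipeline_result"`: `sites`, `report`,
#'   `comparisons`, `behavior` (learning curves per group and task, when
#'   behavior is configured), `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  presets <- vpa_presets()[config$groups]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tabs <- list()
  for (g in names(presets)) {
    ds <- stage(paste0("generate:", g),
                generate_group_dataset(presets[[g]], config$n_sites,
                                       config$n_sweeps,
                                       seed = derive_seed(config$seed,
                                                          label_index(g)),
                                       components = config$components))
    tabs[[g]] <- stage(paste0("analyze:", g),
                       analyze_sites(ds, loo = config$loo,
                                     criterion_sd = config$criterion_sd))
  }
  sites <- do.call(rbind, tabs)
  rownames(sites) <- NULL
  report <- stage("report", group_report(sites))
  comparisons <- NULL
  if (all(c("vpa_untrained", "vpa_trained") %in% config$groups)) {
    cmp_metrics <- Filter(function(m) {
      all(vapply(c("vpa_untrained", "vpa_trained"), function(g)
        sum(!is.na(sites[sites$group == g, m])) >= 2, logical(1)))
    }, c("driven_spikes", "onset_latency_ms", "classifier_pc", "vs"))
    comparisons <- do.call(rbind, lapply(cmp_metrics, function(m) {
      r <- compare_groups(sites, m, "vpa_untrained", "vpa_trained")
      data.frame(metric = m, group_a = "vpa_untrained",
                 group_b = "vpa_trained", difference = r$difference,
                 p_value = r$p_value)
    }))
  }
  behavior <- NULL
  if ("behavior" %in% config$components) {
    behavior <- stage("behavior", {
      curves <- list()
      for (g in names(presets)) for (task in c("consonant", "vowel")) {
        tr <- generate_behavior_sessions(
          presets[[g]], task, config$n_subjects, config$n_sessions,
          config$trials_per_session,
          seed = derive_seed(config$seed, label_index(g), label_index(task)))
        cv <- learning_curve(tr, config$n_sessions)
        cv$group <- g; cv$task <- task
        curves[[paste(g, task, sep = "_")]] <- cv
      }
      do.call(rbind, curves)
    })
  }
  res <- structure(list(sites = sites, report = report,
                        comparisons = comparisons, behavior = behavior,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(res$sites, "sites.csv")
  wr(res$report, "report.csv")
  if (!is.null(res$comparisons)) wr(res$comparisons, "comparisons.csv")
  if (!is.null(res$behavior)) wr(res$behavior, "behavior_curve.csv")
  manifest <- list(
    config = unclass(res$config),
    package_version = as.character(utils::packageVersion("aafdiscrim")),
    r_version = R.version.string,
    files = lapply(stats::setNames(files, basename(files)),
                   function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(files)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result:", nrow(x$sites), "sites,",
      length(unique(x$sites$group)), "groups\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
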