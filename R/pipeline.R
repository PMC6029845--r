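#' Configuration of an end-to-end run
#'
#' Bundles every parameter of the simulate -> prep -> decode -> fuse ->
#' infer -> report chain. The global `seed` is mandatory; per-stage seeds
#' are derived from it by a fixed counter scheme so that stages are
#' individually reproducible.
#'
#' @param synth A [synth_spec()] describing the simulated cohort (its own
#'   seed is overridden by a stage seed derived from `seed`).
#' @param decoding A [decoding_params()] (its seed is likewise derived per
#'   subject).
#' @param prep List with `threshold` (peak-to-peak, default 6000) and
#'   `cutoff` (low-pass Hz, default 20).
#' @param fusion List of ROI descriptions, each a list with `name`,
#'   `latency_ms` (the ground-truth geometry time the fMRI patterns
#'   realize), `n_voxels`, `noise_sd` and `n_subjects`. May be empty.
#' @param stats List with `n_boot`, `n_perm`, `cdt`, `alpha`, `q` and
#'   `window` (`c(start, end)` ms, `NULL` for 0..end of epoch).
#' @param behavior Optional list with `dprime` (named vector, one entry per
#'   speed condition), `criterion`, `n_signal`, `n_noise`; behavioral trials
#'   are generated per subject and condition.
#' @param generalize Also compute temporal generalization maps? (default
#'   `FALSE`).
#' @param out_dir Output directory (created if missing).
#' @param seed Global integer seed (mandatory).
#' @return An object of class `run_config`.
#' @export
run_config <- function(synth = synth_spec(),
                       decoding = decoding_params(),
                       prep = list(threshold = 6000, cutoff = 20),
                       fusion = list(),
                       stats = list(n_boot = 1000, n_perm = 1000, cdt = 0.05,
                                    alpha = 0.05, q = 0.05, window = NULL),
                       behavior = NULL,
                       generalize = FALSE,
                       out_dir = tempfile("megfusion_run_"),
                       seed) {
  if (missing(seed) || is.null(seed)) stop("a global seed is mandatory")
  cfg <- structure(list(synth = synth, decoding = decoding, prep = prep,
                        fusion = fusion, stats = stats, behavior = behavior,
                        generalize = isTRUE(generalize), out_dir = out_dir,
                        seed = as.integer(seed)),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param cfg A [run_config()].
#' @return `cfg`, invisibly; errors describe the first violated constraint.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!inherits(cfg$synth, "synth_spec")) stop("synth must be a synth_spec")
  if (!inherits(cfg$decoding, "decoding_params"))
    stop("decoding must be decoding_params")
  if (is.null(cfg$prep$threshold) || cfg$prep$threshold <= 0)
    stop("prep$threshold must be > 0")
  if (is.null(cfg$prep$cutoff) || cfg$prep$cutoff <= 0)
    stop("prep$cutoff must be > 0")
  for (roi in cfg$fusion) {
    if (is.null(roi$name) || is.null(roi$latency_ms) ||
        is.null(roi$n_voxels) || is.null(roi$n_subjects))
      stop("each fusion ROI needs name, latency_ms, n_voxels, n_subjects")
  }
  st <- cfg$stats
  for (f in c("n_boot", "n_perm", "cdt", "alpha", "q"))
    if (is.null(st[[f]])) stop(sprintf("stats$%s is required", f))
  if (!is.null(cfg$behavior)) {
    b <- cfg$behavior
    if (is.null(b$dprime) || is.null(b$n_signal) || is.null(b$n_noise))
      stop("behavior needs dprime, n_signal, n_noise")
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Reads a YAML file mirroring the [run_config()] fields. Envelopes are
#' given as mappings with `onset`, `peak`, `fwhm`, `amplitude`.
#'
#' @param path YAML file path.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  env_from <- function(e, default) {
    if (is.null(e)) return(default)
    envelope(e$onset, e$peak, e$fwhm,
             amplitude = if (is.null(e$amplitude)) 1 else e$amplitude)
  }
  sy <- y$synth
  def <- synth_spec()
  synth <- synth_spec(
    n_subjects = sy$n_subjects %||% def$n_subjects,
    n_conditions = sy$n_conditions %||% def$n_conditions,
    categories = unlist(sy$categories) %||% def$categories,
    n_trials_per_condition = sy$n_trials_per_condition %||%
      def$n_trials_per_condition,
    n_channels = sy$n_channels %||% def$n_channels,
    time_lim = unlist(sy$time_lim) %||% def$time_lim,
    time_step = sy$time_step %||% def$time_step,
    identity_envelope = env_from(sy$identity_envelope, def$identity_envelope),
    category_envelope = env_from(sy$category_envelope, def$category_envelope),
    noise_sd = sy$noise_sd %||% def$noise_sd,
    seed = sy$seed %||% 1
  )
  dc <- y$decoding %||% list()
  decoding <- decoding_params(
    group_size = dc$group_size %||% 3,
    n_repetitions = dc$n_repetitions %||% 100,
    svm_cost = dc$svm_cost %||% 1,
    seed = dc$seed %||% 1,
    stride = dc$stride %||% 1
  )
  st_def <- list(n_boot = 1000, n_perm = 1000, cdt = 0.05, alpha = 0.05,
                 q = 0.05, window = NULL)
  st <- utils::modifyList(st_def, y$stats %||% list())
  run_config(synth = synth, decoding = decoding,
             prep = utils::modifyList(list(threshold = 6000, cutoff = 20),
                                      y$prep %||% list()),
             fusion = y$fusion %||% list(),
             stats = st, behavior = y$behavior,
             generalize = y$generalize %||% FALSE,
             out_dir = y$out_dir %||% tempfile("megfusion_run_"),
             seed = y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_record <- function(name, seed, files, t0) {
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- basename(files)
  list(name = name, seed = seed, outputs = hashes,
       elapsed_s = round(as.numeric(Sys.time()) - t0, 3))
}

# subjects x time matrices of the four partition series from per-subject RDMs
partition_series_matrix <- function(rdms, what, part) {
  do.call(rbind, lapply(rdms, function(r) {
    switch(what,
           grand_total = partition_mean(r, "all"),
           within_A = partition_mean(r, part$within_A),
           within_B = partition_mean(r, part$within_B),
           between = partition_mean(r, part$between),
           division = categorical_division(r, part))
  }))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> prep -> decode (-> generalize) -> fuse -> stats ->
#' report in order, persisting every intermediate container and returning a
#' manifest with per-stage seeds, output hashes and wall-clock times.
#' Re-running with the same configuration and seed reproduces all numeric
#' outputs bit-identically.
#'
#' @param config A [run_config()].
#' @return The run manifest (also written to `run_manifest.json` in the
#'   output directory), invisibly.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(f) file.path(config$out_dir, f)
  stages <- list()

  ## -- simulate ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  spec <- config$synth
  spec$seed <- derive_seed(config$seed, 1)
  cohort <- generate_meg_subjects(spec)
  files <- od("cohort.rds")
  write_container(cohort, files)
  if (!is.null(config$behavior)) {
    b <- config$behavior
    rows <- list()
    for (s in seq_len(spec$n_subjects))
      for (ci in seq_along(b$dprime)) {
        cond <- names(b$dprime)[ci] %||% sprintf("speed%d", ci)
        beh <- generate_behavior(b$dprime[[ci]], b$criterion %||% 0,
                                 b$n_signal, b$n_noise,
                                 seed = derive_seed(config$seed,
                                                    100 + s * 10 + ci),
                                 condition_speed = cond)
        beh$subject <- s
        rows[[length(rows) + 1]] <- beh
      }
    behavior <- do.call(rbind, rows)
    export_csv(behavior, od("behavior.csv"))
    files <- c(files, od("behavior.csv"))
  } else behavior <- NULL
  stages$simulate <- stage_record("simulate", spec$seed, files, t0)

  ## -- prep ----------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  prepped <- lapply(cohort$subjects, preprocess_epochs,
                    threshold = config$prep$threshold,
                    cutoff = config$prep$cutoff)
  subjects <- lapply(prepped, `[[`, "epochs")
  rejections <- lapply(prepped, `[[`, "rejected")
  write_container(subjects, od("prepped.rds"))
  write_rejection_report(do.call(rbind, Map(function(r, s) {
    if (nrow(r)) r$subject <- s
    r
  }, rejections, seq_along(rejections))),
    config$prep$threshold, od("rejection_report.json"))
  stages$prep <- stage_record("prep", NA,
                              od(c("prepped.rds", "rejection_report.json")), t0)

  ## -- decode --------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  rdms <- lapply(seq_along(subjects), function(s) {
    p <- config$decoding
    p$seed <- derive_seed(config$seed, 1000 + s)
    pairwise_decoding_timecourse(subjects[[s]], p)
  })
  avg_rdm <- average_rdms(rdms)
  write_container(rdms, od("rdms.rds"))
  part <- pair_partition(avg_rdm$conditions, avg_rdm$category_of)
  series <- list(
    grand_total = partition_series_matrix(rdms, "grand_total", part),
    within_A = partition_series_matrix(rdms, "within_A", part),
    within_B = partition_series_matrix(rdms, "within_B", part),
    division = partition_series_matrix(rdms, "division", part)
  )
  pm <- data.frame(time_ms = avg_rdm$time,
                   grand_total = colMeans(series$grand_total),
                   within_A = colMeans(series$within_A),
                   within_B = colMeans(series$within_B),
                   categorical_division = colMeans(series$division))
  export_csv(pm, od("partition_means.csv"))
  files <- od(c("rdms.rds", "partition_means.csv"))
  stages$decode <- stage_record("decode", derive_seed(config$seed, 1000),
                                files, t0)

  ## -- generalize (optional) -----------------------------------------------
  if (config$generalize) {
    t0 <- as.numeric(Sys.time())
    tgs <- lapply(seq_along(subjects), function(s) {
      p <- config$decoding
      p$seed <- derive_seed(config$seed, 1000 + s)  # shared folds with decode
      temporal_generalization(subjects[[s]], p)
    })
    tg_grand <- Reduce(`+`, lapply(tgs, `[[`, "accuracy")) / length(tgs)
    write_container(list(per_subject = tgs, grand = tg_grand), od("tgm.rds"))
    stages$generalize <- stage_record("generalize",
                                      derive_seed(config$seed, 1000),
                                      od("tgm.rds"), t0)
  }

  ## -- fuse ----------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  fusion_all <- NULL
  if (length(config$fusion)) {
    rows <- lapply(seq_along(config$fusion), function(ri) {
      roi <- config$fusion[[ri]]
      ti <- which.min(abs(cohort$truth$time - roi$latency_ms))
      geom <- cohort$truth$geometry[, , ti]
      # map Euclidean geometry onto the 1 - Pearson scale preserving ranks
      g <- geom / max(geom, .Machine$double.eps) * 1.5
      fr <- lapply(seq_len(roi$n_subjects), function(fs) {
        correlation_rdm(generate_fmri_patterns(
          g, n_voxels = roi$n_voxels,
          noise_sd = roi$noise_sd %||% 0,
          seed = derive_seed(config$seed, 2000 + ri * 100 + fs),
          roi_id = roi$name))
      })
      fusion_timecourse(avg_rdm, fr, roi_id = roi$name)
    })
    fusion_all <- do.call(rbind, rows)
    export_csv(fusion_all, od("fusion.csv"))
    stages$fuse <- stage_record("fuse", derive_seed(config$seed, 2000),
                                od("fusion.csv"), t0)
  } else {
    stages$fuse <- stage_record("fuse", NA, character(), t0)
  }

  ## -- stats ---------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  st <- config$stats
  win <- st$window %||% c(max(0, min(avg_rdm$time)), max(avg_rdm$time))
  chance <- list(grand_total = 50, within_A = 50, within_B = 50, division = 0)
  latencies <- list()
  clusters <- list()
  for (nm in names(series)) {
    m <- series[[nm]]
    sseed <- derive_seed(config$seed, 3000 + match(nm, names(series)))
    pk <- bootstrap_latency(m, avg_rdm$time, "peak", window = win,
                            n_boot = st$n_boot, seed = sseed)
    on <- bootstrap_latency(m, avg_rdm$time, "onset", window = win,
                            n_boot = st$n_boot, seed = sseed,
                            null_value = chance[[nm]], cdt = st$cdt,
                            n_perm = st$n_perm)
    cl <- sign_permutation_clusters(m - chance[[nm]], n_perm = st$n_perm,
                                    cdt = st$cdt, alpha = st$alpha,
                                    seed = sseed)
    latencies[[nm]] <- list(
      peak_ms = pk$point_ms, peak_ci = c(pk$ci_low_ms, pk$ci_high_ms),
      onset_ms = on$point_ms, onset_ci = c(on$ci_low_ms, on$ci_high_ms))
    clusters[[nm]] <- clusters_summary(cl, avg_rdm$time)
  }
  fusion_stats <- list()
  if (!is.null(fusion_all)) {
    for (roi in unique(fusion_all$roi)) {
      fs <- fusion_all[fusion_all$roi == roi, ]
      m <- do.call(rbind, lapply(split(fs$rho, fs$subject), as.numeric))
      sseed <- derive_seed(config$seed, 4000 + match(roi,
                                                     unique(fusion_all$roi)))
      pk <- bootstrap_latency(m, avg_rdm$time, "peak", window = win,
                              n_boot = st$n_boot, seed = sseed)
      cl <- sign_permutation_clusters(m, n_perm = st$n_perm, cdt = st$cdt,
                                      alpha = st$alpha, seed = sseed)
      fusion_stats[[roi]] <- list(
        peak_ms = pk$point_ms, peak_ci = c(pk$ci_low_ms, pk$ci_high_ms),
        clusters = clusters_summary(cl, avg_rdm$time))
    }
  }
  behavior_stats <- NULL
  if (!is.null(behavior)) {
    dp <- do.call(rbind, lapply(split(behavior,
                                      list(behavior$subject,
                                           behavior$condition_speed),
                                      drop = TRUE), function(df) {
      cts <- behavior_counts(df)
      data.frame(subject = df$subject[1], condition_speed = df$condition_speed[1],
                 dprime = dprime(cts["n_hits"], cts["n_misses"],
                                 cts["n_fas"], cts["n_crs"]))
    }))
    behavior_stats <- list(per_subject = dp)
    conds <- unique(dp$condition_speed)
    if (length(conds) == 2 && nrow(dp[dp$condition_speed == conds[1], ]) >= 5) {
      a <- dp$dprime[dp$condition_speed == conds[1]]
      b <- dp$dprime[dp$condition_speed == conds[2]]
      behavior_stats$signed_rank_p <- signed_rank_test(a, b)
    }
    behavior_stats$mean_dprime <- stats::aggregate(dprime ~ condition_speed,
                                                   dp, mean)
  }
  # MDS of the subject-averaged RDM at the categorical-division peak
  mds_file <- character()
  div_peak <- latencies$division$peak_ms
  if (!is.na(div_peak)) {
    ti <- which.min(abs(avg_rdm$time - div_peak))
    sl <- avg_rdm$accuracy[, , ti]
    diag(sl) <- 0
    export_mds(mds_embed(sl), od("mds_coordinates.csv"))
    mds_file <- od("mds_coordinates.csv")
  }
  stats_results <- list(window_ms = win, latencies = latencies,
                        clusters = clusters, fusion = fusion_stats,
                        behavior = if (!is.null(behavior_stats))
                          list(per_subject = behavior_stats$per_subject,
                               mean_dprime = behavior_stats$mean_dprime,
                               signed_rank_p = behavior_stats$signed_rank_p)
                        else NULL)
  jsonlite::write_json(stats_results, od("stats_results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  stages$stats <- stage_record("stats", derive_seed(config$seed, 3000),
                               c(od("stats_results.json"), mds_file), t0)

  ## -- report --------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  manifest <- list(config = config_echo(config),
                   version = as.character(packageVersion("megfusion")),
                   stages = stages)
  jsonlite::write_json(manifest, od("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  make_report(config$out_dir)
  manifest$stages$report <- stage_record("report", NA, od("report.md"), t0)
  jsonlite::write_json(manifest, od("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(manifest)
}

config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$synth <- lapply(unclass(cfg$synth), function(x)
    if (inherits(x, "envelope")) unclass(x) else x)
  cfg$decoding <- unclass(cfg$decoding)
  cfg
}

clusters_summary <- function(cl, time) {
  if (nrow(cl$clusters) == 0)
    return(list(n_significant = 0L, clusters = list()))
  lab <- as.vector(cl$labels)
  rows <- lapply(seq_len(nrow(cl$clusters)), function(k) {
    cells <- which(lab == k)
    list(size = cl$clusters$size[k], p = cl$clusters$p[k],
         significant = cl$clusters$significant[k],
         start_ms = if (length(cl$sig_mask) == length(time))
           time[min(cells)] else NA,
         end_ms = if (length(cl$sig_mask) == length(time))
           time[max(cells)] else NA)
  })
  list(n_significant = sum(cl$clusters$significant), clusters = rows)
}

fmt_ms <- function(x) {
  if (is.null(x) || length(x) == 0 || all(is.na(x))) "undefined"
  else paste0(format(round(as.numeric(x), 1), trim = TRUE), collapse = ", ")
}

#' Generate the summary report for a completed run
#'
#' Renders `report.md` in the run directory from the persisted stage
#' outputs: peak/onset latency tables with confidence intervals per
#' partition series, fusion peaks per ROI, behavioral d-prime, and cluster
#' listings. Regeneration from the same persisted outputs is byte-identical
#' (the report carries no timestamps).
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return Path of the written report, invisibly.
#' @export
make_report <- function(run_dir) {
  sr_path <- file.path(run_dir, "stats_results.json")
  if (!file.exists(sr_path)) stop("stats_results.json missing; run the stats stage first")
  sr <- jsonlite::read_json(sr_path, simplifyVector = TRUE)
  L <- c("# megfusion run report", "",
         sprintf("Search window: %s ms", fmt_ms(sr$window_ms)), "",
         "## Decoding latencies", "",
         "| series | peak (ms) | peak 95% CI | onset (ms) | onset 95% CI |",
         "|---|---|---|---|---|")
  for (nm in names(sr$latencies)) {
    la <- sr$latencies[[nm]]
    L <- c(L, sprintf("| %s | %s | [%s] | %s | [%s] |", nm,
                      fmt_ms(la$peak_ms), fmt_ms(la$peak_ci),
                      fmt_ms(la$onset_ms), fmt_ms(la$onset_ci)))
  }
  L <- c(L, "", "## Cluster inference", "")
  any_sig <- FALSE
  for (nm in names(sr$clusters)) {
    cl <- sr$clusters[[nm]]
    n_sig <- if (is.null(cl$n_significant)) 0L else as.integer(cl$n_significant)
    any_sig <- any_sig || n_sig > 0
    L <- c(L, sprintf("- %s: %d significant cluster(s)", nm, n_sig))
  }
  if (!any_sig) L <- c(L, "", "No significant clusters in any series.")
  if (!is.null(sr$fusion) && length(sr$fusion)) {
    L <- c(L, "", "## MEG-fMRI fusion peaks", "",
           "| ROI | peak (ms) | 95% CI |", "|---|---|---|")
    for (roi in names(sr$fusion)) {
      fu <- sr$fusion[[roi]]
      L <- c(L, sprintf("| %s | %s | [%s] |", roi, fmt_ms(fu$peak_ms),
                        fmt_ms(fu$peak_ci)))
    }
  }
  if (!is.null(sr$behavior)) {
    L <- c(L, "", "## Behavior (d-prime)", "",
           "| condition | mean d' |", "|---|---|")
    md <- sr$behavior$mean_dprime
    for (i in seq_len(nrow(md)))
      L <- c(L, sprintf("| %s | %.3f |", md$condition_speed[i], md$dprime[i]))
    if (!is.null(sr$behavior$signed_rank_p))
      L <- c(L, "", sprintf("Two-sided signed-rank test between conditions: p = %.4g",
                            sr$behavior$signed_rank_p))
  }
  out <- file.path(run_dir, "report.md")
  writeLines(L, out)
  invisible(out)
}
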