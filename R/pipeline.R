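## End-to-end orchestration: configuration, archetype log simulation, the
## per-subject analysis pipeline and its JSON report.

#' Analysis configuration
#'
#' Bundles everything the pipeline needs; all defaults equal the standard
#' protocol, so an empty override reproduces the reference analysis
#' settings. The significance threshold is Bonferroni-corrected for the
#' number of individually tested subjects:
#' `alpha_adjusted = alpha_family / n_subjects_for_bonferroni`
#' (0.05 / 8 = 0.00625 by default).
#'
#' @param seed Integer master seed.
#' @param geometry A [display_geometry()].
#' @param classifier A [classifier_config()]; its `alpha_adjusted` is
#'   overridden by the Bonferroni-derived threshold.
#' @param alpha_family Family-wise alpha.
#' @param n_subjects_for_bonferroni Number of subjects tested individually.
#' @return An object of class `analysis_config` (includes the derived
#'   `alpha_adjusted`).
#' @export
analysis_config <- function(seed = 1L, geometry = display_geometry(),
                            classifier = classifier_config(),
                            alpha_family = 0.05,
                            n_subjects_for_bonferroni = 8L) {
  stopifnot(alpha_family > 0, alpha_family < 1,
            n_subjects_for_bonferroni >= 1)
  alpha_adjusted <- alpha_family / n_subjects_for_bonferroni
  classifier$alpha_adjusted <- alpha_adjusted
  structure(
    list(seed = as.integer(seed), geometry = geometry,
         classifier = classifier, alpha_family = alpha_family,
         n_subjects_for_bonferroni = as.integer(n_subjects_for_bonferroni),
         alpha_adjusted = alpha_adjusted),
    class = "analysis_config"
  )
}

# Stable FNV-1a fingerprint of a configuration, for report traceability.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- ((h - low + bitwXor(as.integer(low), as.integer(b %% 256))) * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Simulate archetype sessions and write peck logs
#'
#' Generates one session per requested strategy archetype (subject id =
#' archetype name) and writes each to a CSV peck log. Seeds are derived
#' deterministically from `seed`, so outputs are byte-identical across runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param archetypes Archetype names (see [make_archetype()]).
#' @param seed Master seed.
#' @param ... Profile overrides forwarded to [make_archetype()].
#' @return Named character vector of written file paths.
#' @export
simulate_archetype_logs <- function(out_dir,
                                    archetypes = ARCHETYPES,
                                    seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(archetypes), function(i) {
    name <- archetypes[i]
    profile <- make_archetype(name, ...)
    session <- generate_session(profile, generator_config(seed = seed + i),
                                subject_id = name, session_id = "sim1")
    path <- file.path(out_dir, sprintf("%s.csv", name))
    write_peck_log(session, path)
    path
  }, character(1))
  names(paths) <- archetypes
  paths
}

pipeline_decoder <- function(train_pool, test_pool, mode, cfg) {
  n_tr <- pool_size(train_pool)
  n_te <- pool_size(test_pool)
  if (n_tr < cfg$n_train + (if (mode == "CE") 0 else cfg$n_test) ||
      n_te < cfg$n_test)
    return(structure(list(mode = mode,
                          reason = sprintf("insufficient events: train pool %d, test pool %d",
                                           n_tr, n_te),
                          available = min(n_tr, n_te), required = cfg$n_train + cfg$n_test),
                     class = "decoder_insufficient"))
  run_decoding(train_pool, test_pool, mode = mode, config = cfg)
}

#' Run the full analysis pipeline for one subject
#'
#' Mirrors the standard analysis order on one subject's sessions:
#' performance summaries (pooled and per class, known and transfer trials),
#' relative heatmaps per class and outcome with class difference maps, the
#' cumulative-concentration KS comparison of correct vs error pecking
#' (pooled and per class), CC decoding for known and transfer trials, CE and
#' EE decoding (gated on `min_error_events`), and CC decoding by peck order.
#' Event counts after every filter are recorded so the sufficiency gates are
#' auditable.
#'
#' @param sessions Session or list of sessions of a single subject.
#' @param config An [analysis_config()].
#' @return An object of class `pipeline_report`.
#' @export
analyze_sessions <- function(sessions, config = analysis_config()) {
  if (inherits(sessions, "peck_session")) sessions <- list(sessions)
  subjects <- unique(vapply(sessions, `[[`, "", "subject_id"))
  if (length(subjects) != 1)
    stop(sprintf("analyze_sessions expects one subject, got: %s (use run_pipeline)",
                 paste(subjects, collapse = ", ")), call. = FALSE)
  cfg <- config$classifier
  cfg$seed <- config$seed

  performance <- list()
  for (tt in c(list(NULL), as.list(TRIAL_TYPES)))
    for (cl in c(list(NULL), as.list(CLASSES))) {
      key <- paste0(if (is.null(tt)) "all" else tt, ".",
                    if (is.null(cl)) "pooled" else cl)
      performance[[key]] <- tryCatch(
        percent_correct(sessions, trial_type = tt, class = cl),
        error = function(e) NULL)
    }

  pools <- list()
  for (oc in c("correct", "error"))
    for (cl in CLASSES)
      pools[[paste0(oc, ".", cl)]] <-
        select_pool(sessions, outcomes = oc, classes = cl)
  pool_correct <- select_pool(sessions, outcomes = "correct")
  pool_error <- select_pool(sessions, outcomes = "error")

  heatmaps <- lapply(pools, function(p) {
    if (pool_size(p) == 0)  # empty pools yield an all-zero map, silently
      suppressWarnings(relative_heatmap(bin_pecks(p), p$geometry))
    else relative_heatmap(bin_pecks(p), p$geometry)
  })
  nonzero <- vapply(pools, function(p) pool_size(p) > 0, logical(1))

  diff_maps <- list()
  if (nonzero[["correct.X"]] && nonzero[["correct.Y"]])
    diff_maps$correct_X_minus_Y <-
      difference_map(heatmaps[["correct.X"]], heatmaps[["correct.Y"]])
  if (nonzero[["error.X"]] && nonzero[["error.Y"]])
    diff_maps$error_X_minus_Y <-
      difference_map(heatmaps[["error.X"]], heatmaps[["error.Y"]])
  for (cl in CLASSES)
    if (nonzero[[paste0("correct.", cl)]] && nonzero[[paste0("error.", cl)]])
      diff_maps[[paste0("correct_minus_error.", cl)]] <-
        difference_map(heatmaps[[paste0("correct.", cl)]],
                       heatmaps[[paste0("error.", cl)]])

  ks <- list()
  if (pool_size(pool_error) > 0) {
    ks$pooled <- compare_correct_error(pool_correct, pool_error,
                                       config$alpha_adjusted)
    for (cl in CLASSES)
      if (nonzero[[paste0("correct.", cl)]] && nonzero[[paste0("error.", cl)]])
        ks[[cl]] <- compare_correct_error(pools[[paste0("correct.", cl)]],
                                          pools[[paste0("error.", cl)]],
                                          config$alpha_adjusted)
  }

  decoders <- list()
  for (tt in TRIAL_TYPES_FOR_DECODING(sessions)) {
    pc <- select_pool(sessions, trial_type = tt, outcomes = "correct")
    decoders[[paste0("CC.", tt)]] <- pipeline_decoder(pc, pc, "CC", cfg)
  }
  decoders$CE.known <- {
    pc <- select_pool(sessions, trial_type = "known", outcomes = "correct")
    pe <- select_pool(sessions, trial_type = "known", outcomes = "error")
    run_decoding(pc, pe, mode = "CE", config = cfg)
  }
  decoders$EE.known <- {
    pe <- select_pool(sessions, trial_type = "known", outcomes = "error")
    run_decoding(pe, pe, mode = "EE", config = cfg)
  }

  peck_order <- peck_order_decoding(
    select_pool(sessions, trial_type = "known", outcomes = "correct"), cfg)

  counts <- list(
    trials = sum(vapply(sessions, function(s) length(s$trials), integer(1))),
    pecks_in_bounds = pool_size(select_pool(sessions)),
    correct_pecks = pool_size(pool_correct),
    error_pecks = pool_size(pool_error))

  structure(
    list(subject_id = subjects, config = config,
         config_hash = config_hash(config), counts = counts,
         performance = performance, heatmaps = heatmaps,
         difference_maps = diff_maps, ks = ks, decoders = decoders,
         peck_order = peck_order),
    class = "pipeline_report"
  )
}

TRIAL_TYPES_FOR_DECODING <- function(sessions) {
  present <- unique(unlist(lapply(sessions, function(s)
    vapply(s$trials, `[[`, "", "trial_type"))))
  intersect(TRIAL_TYPES, present)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report for subject %s (config %s)\n", x$subject_id,
              x$config_hash))
  cat(sprintf("  %d trials, %d in-bounds pecks (%d correct / %d error)\n",
              x$counts$trials, x$counts$pecks_in_bounds,
              x$counts$correct_pecks, x$counts$error_pecks))
  if (!is.null(x$performance$all.pooled))
    cat(sprintf("  percent correct (pooled): %.2f%%\n",
                x$performance$all.pooled$percent_correct))
  if (!is.null(x$ks$pooled))
    cat(sprintf("  KS correct vs error: D = %.4f, p = %.4g\n",
                x$ks$pooled$D, x$ks$pooled$p))
  for (nm in names(x$decoders)) {
    d <- x$decoders[[nm]]
    if (inherits(d, "decoder_report"))
      cat(sprintf("  %s: %.2f%% (shuffled %.2f%%), %s\n", nm,
                  d$mean_accuracy, d$mean_shuffled, d$verdict))
    else cat(sprintf("  %s: skipped (%s)\n", nm, d$reason))
  }
  invisible(x)
}

#' Analyze a peck log end to end
#'
#' Reads a CSV peck log, groups sessions by subject, and runs
#' [analyze_sessions()] on each subject. Optionally writes the JSON report
#' and per-heatmap CSV matrices.
#'
#' @param path Peck-log CSV path.
#' @param config An [analysis_config()].
#' @param out_dir Optional output directory for the JSON report and CSVs.
#' @return Named list of `pipeline_report`s, one per subject (invisibly if
#'   `out_dir` is given).
#' @export
analyze_peck_log <- function(path, config = analysis_config(),
                             out_dir = NULL) {
  sessions <- read_peck_log(path, geometry = config$geometry)
  by_subject <- split(sessions,
                      vapply(sessions, `[[`, "", "subject_id"))
  reports <- lapply(by_subject, analyze_sessions, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (subj in names(reports)) {
      write_pipeline_report(reports[[subj]],
                            file.path(out_dir, sprintf("report_%s.json", subj)))
      for (nm in names(reports[[subj]]$heatmaps)) {
        hm <- reports[[subj]]$heatmaps[[nm]]
        utils::write.csv(hm$values,
                         file.path(out_dir, sprintf("heatmap_%s_%s.csv", subj, nm)),
                         row.names = FALSE)
      }
    }
    return(invisible(reports))
  }
  reports
}

report_to_list <- function(x) {
  decoder_list <- function(d) {
    if (inherits(d, "decoder_insufficient"))
      return(list(skipped = TRUE, reason = d$reason))
    list(mode = d$mode, mean_accuracy = d$mean_accuracy,
         mean_shuffled = d$mean_shuffled, t = d$t, df = d$df, p = d$p,
         cohen_d = d$cohen_d, verdict = d$verdict,
         iterations = d$iterations)
  }
  list(
    subject_id = x$subject_id,
    config_hash = x$config_hash,
    seed = x$config$seed,
    alpha_adjusted = x$config$alpha_adjusted,
    counts = x$counts,
    performance = lapply(Filter(Negate(is.null), x$performance), function(p)
      list(n_trials = p$n_trials, percent_correct = p$percent_correct)),
    heatmaps = lapply(x$heatmaps, function(h)
      list(total_pecks = h$total_pecks, values = h$values)),
    difference_maps = x$difference_maps,
    ks = lapply(x$ks, function(k)
      list(D = k$D, p = k$p, significant = k$significant,
           alpha_adjusted = k$alpha_adjusted)),
    decoders = lapply(x$decoders, decoder_list),
    peck_order = lapply(x$peck_order$results, function(r) {
      if (isTRUE(r$skipped)) list(rank = r$rank, skipped = TRUE,
                                  reason = r$reason)
      else list(rank = r$rank, mean_accuracy = r$mean_accuracy,
                mean_shuffled = r$mean_shuffled, reduced = isTRUE(r$reduced))
    }))
}

#' Write a pipeline report as JSON
#'
#' @param report A `pipeline_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_pipeline_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
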