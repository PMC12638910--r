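#' Pipeline configuration
#'
#' Central configuration for the end-to-end pipeline. Every default mirrors
#' the analysis procedure's stated value where one exists (k = 3 outlier
#' multiplier, 150 uV amplitude limit, 30 s discard, 10 s segments, top 10
#' links in the \[0.5, 0.7\] PLI window, alpha = 0.05); the rest are the
#' package's documented assumptions. Round-trips losslessly through YAML.
#'
#' @param ... overrides for any top-level section (`synth`, `qc`,
#'   `spectral`, `connectivity`, `stats`, `classify`), each a named list
#'   merged over the defaults.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(..., seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    synth = list(n_subjects = 2L, sessions_per_stage = c(3L, 3L, 5L),
                 effect_size = 1, task = "lab", duration = 230,
                 noise_sd = 10, amp_jitter = 0.15),
    qc = list(discard = 30, seg_len = 10, k = 3, amp_limit = 150,
              scope = "segment"),
    spectral = list(total_range = c(1, 45)),
    connectivity = list(band = c(1, 45), m = 3L, tau = 4L, bins = 16L,
                        top_k = 10L, value_range = c(0.5, 0.7),
                        long_range_rule = "distance"),
    stats = list(alpha = 0.05, measures = c("alpha", "low_beta", "high_beta"),
                 regions = c("whole", "left", "right"), adjust = "none"),
    classify = list(models = c("svm", "knn", "decision_tree", "qda",
                               "neural_network"),
                    test_frac = 0.2, folds = 10L, mrmr_k = 20L))
  over <- list(...)
  for (nm in names(over)) {
    stop_if_not(nm %in% names(cfg), paste("unknown config section:", nm))
    cfg[[nm]] <- if (is.list(cfg[[nm]])) utils::modifyList(cfg[[nm]], over[[nm]])
                 else over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns the config; `write_pipeline_config`
#'   returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, c(raw[setdiff(names(raw), "seed")],
                             seed = raw$seed))
}

#' @keywords internal
require_artifact <- function(path, step) {
  if (!file.exists(path))
    stop("missing artifact ", basename(path),
         ": run the '", step, "' step first", call. = FALSE)
  path
}

#' Run one pipeline step
#'
#' Orchestrates the analysis end to end over a run directory. Steps:
#' `simulate` (synthetic sessions as Emotiv-style CSVs), `preprocess`
#' (filter + slice + QC, kept segments cached, QC report JSON), `features`
#' (tidy feature CSV), `connectivity` (mean PLI and MI matrices per stage as
#' TSV, efficiency table, BrainNet export of top links), `components`
#' (gTRCA per stage, JSON), `stats` (comparison table CSV), `classify`
#' (classifier reports JSON + CSV, MRMR ranking CSV) and `report` (collated
#' summary JSON). Each step records the config hash in a manifest so every
#' artifact is traceable; a missing upstream artifact raises an error naming
#' the required prior step.
#'
#' @param step subcommand name.
#' @param config a [pipeline_config()].
#' @param run_dir run directory (created if needed).
#' @return the step's main result, invisibly.
#' @export
run_pipeline <- function(step = c("simulate", "preprocess", "features",
                                  "connectivity", "components", "stats",
                                  "classify", "report"),
                         config = pipeline_config(), run_dir = "eeg_run") {
  step <- match.arg(step)
  stop_if_not(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- rlang::hash(unclass(config))
  manifest_path <- file.path(run_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list(config_hash = hash, steps = list())
  if (!identical(manifest$config_hash, hash))
    manifest <- list(config_hash = hash, steps = list())

  result <- switch(step,
    simulate = {
      rec_dir <- file.path(run_dir, "recordings")
      dir.create(rec_dir, showWarnings = FALSE)
      sy <- config$synth
      recs <- make_stage_dataset(sy$n_subjects, sy$sessions_per_stage,
                                 sy$effect_size, config$seed, sy$task,
                                 sy$duration, sy$noise_sd, sy$amp_jitter)
      for (r in recs)
        write_emotiv_csv(r, file.path(rec_dir,
          sprintf("%s_s%02d_%s.csv", r$meta$subject, r$meta$session,
                  r$meta$task)))
      length(recs)
    },
    preprocess = {
      rec_dir <- require_artifact(file.path(run_dir, "recordings"), "simulate")
      files <- list.files(rec_dir, pattern = "\\.csv$", full.names = TRUE)
      stop_if_not(length(files) > 0, "no recordings found; run 'simulate' first")
      qc <- config$qc
      all_segments <- list()
      reports <- list()
      for (f in files) {
        rec <- read_emotiv_csv(f)
        pp <- preprocess_recording(rec, qc$discard, qc$seg_len, qc$k,
                                   qc$amp_limit, qc$scope)
        all_segments <- c(all_segments, pp$kept)
        reports[[basename(f)]] <- as.list(setNames(pp$report$n,
                                                   pp$report$status))
      }
      jsonlite::write_json(reports, file.path(run_dir, "qc_report.json"),
                           auto_unbox = TRUE)
      saveRDS(all_segments, file.path(run_dir, "segments.rds"))
      length(all_segments)
    },
    features = {
      segs <- readRDS(require_artifact(file.path(run_dir, "segments.rds"),
                                       "preprocess"))
      feats <- extract_features(segs)
      utils::write.csv(feats, file.path(run_dir, "features.csv"),
                       row.names = FALSE)
      feats
    },
    connectivity = {
      segs <- readRDS(require_artifact(file.path(run_dir, "segments.rds"),
                                       "preprocess"))
      cn <- config$connectivity
      stages <- vapply(segs, function(s) s$meta$stage, numeric(1))
      eff_rows <- list()
      for (st in sort(unique(stages))) {
        sub <- segs[stages == st]
        plis <- lapply(sub, pli_matrix, band = cn$band)
        mean_pli <- Reduce(`+`, lapply(plis, unclass)) / length(plis)
        write_matrix_tsv(mean_pli,
                         file.path(run_dir, sprintf("pli_stage%d.tsv", st)))
        write_brainnet(mean_pli,
                       file.path(run_dir, sprintf("net_stage%d", st)))
        mis <- lapply(sub, mi_matrix, m = cn$m, tau = cn$tau, bins = cn$bins)
        mean_mi <- Reduce(`+`, lapply(mis, unclass)) / length(mis)
        write_matrix_tsv(mean_mi,
                         file.path(run_dir, sprintf("mi_stage%d.tsv", st)))
        effs <- vapply(plis, function(p) unlist(efficiency(p)), numeric(2))
        eff_rows[[length(eff_rows) + 1L]] <- tibble::tibble(
          stage = st,
          global_efficiency = mean(effs["global_efficiency", ]),
          local_efficiency = mean(effs["local_efficiency", ]))
      }
      eff <- do.call(rbind, eff_rows)
      utils::write.csv(eff, file.path(run_dir, "efficiency.csv"),
                       row.names = FALSE)
      eff
    },
    components = {
      segs <- readRDS(require_artifact(file.path(run_dir, "segments.rds"),
                                       "preprocess"))
      stages <- vapply(segs, function(s) s$meta$stage, numeric(1))
      out <- list()
      for (st in sort(unique(stages))) {
        sub <- segs[stages == st]
        ts <- trial_set(lapply(sub, `[[`, "data"),
                        subjects = vapply(sub, function(s) s$meta$subject,
                                          character(1)),
                        condition = list(stage = st))
        comp <- fit_gtrca(ts)
        write_gtrca_json(comp,
                         file.path(run_dir, sprintf("gtrca_stage%d.json", st)))
        out[[as.character(st)]] <- comp
      }
      out
    },
    stats = {
      feats <- utils::read.csv(require_artifact(
        file.path(run_dir, "features.csv"), "features"), check.names = FALSE)
      st <- config$stats
      plan <- comparison_plan("stages_within_task", st$measures, st$regions,
                              st$alpha, st$adjust)
      res <- run_comparisons(tibble::as_tibble(feats), plan)
      utils::write.csv(res, file.path(run_dir, "comparisons.csv"),
                       row.names = FALSE)
      res
    },
    classify = {
      feats <- utils::read.csv(require_artifact(
        file.path(run_dir, "features.csv"), "features"), check.names = FALSE)
      ds <- assemble_dataset(tibble::as_tibble(feats))
      cl <- config$classify
      reports <- lapply(cl$models, function(m)
        train_eval(ds, m, split_seed = config$seed,
                   test_frac = cl$test_frac, folds = cl$folds))
      names(reports) <- cl$models
      acc <- tibble::tibble(
        model = cl$models,
        validation_accuracy = vapply(reports, `[[`, numeric(1),
                                     "validation_accuracy"),
        test_accuracy = vapply(reports, `[[`, numeric(1), "test_accuracy"))
      utils::write.csv(acc, file.path(run_dir, "accuracy.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        lapply(reports, function(r) list(
          model = r$model,
          validation_accuracy = r$validation_accuracy,
          test_accuracy = r$test_accuracy,
          confusion_test = as.data.frame.matrix(r$confusion_test))),
        file.path(run_dir, "classifier_reports.json"), digits = NA)
      rk <- mrmr_rank(ds, k = cl$mrmr_k)
      utils::write.csv(rk, file.path(run_dir, "mrmr.csv"), row.names = FALSE)
      for (r in reports)
        utils::write.csv(as.data.frame.matrix(r$confusion_test),
                         file.path(run_dir,
                                   paste0("confusion_", r$model, ".csv")))
      reports
    },
    report = {
      acc_p <- require_artifact(file.path(run_dir, "accuracy.csv"), "classify")
      cmp_p <- require_artifact(file.path(run_dir, "comparisons.csv"), "stats")
      eff_p <- require_artifact(file.path(run_dir, "efficiency.csv"),
                                "connectivity")
      summary <- list(config_hash = hash,
                      accuracy = utils::read.csv(acc_p),
                      comparisons_significant =
                        sum(utils::read.csv(cmp_p)$p < config$stats$alpha),
                      efficiency = utils::read.csv(eff_p))
      jsonlite::write_json(summary, file.path(run_dir, "summary.json"),
                           digits = NA, dataframe = "rows")
      summary
    })
  manifest$steps[[step]] <- list(completed = TRUE, time = format(Sys.time()))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(result)
}
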