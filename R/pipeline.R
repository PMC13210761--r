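# End-to-end pipeline: simulate -> segment -> features -> biomarkers ->
# train/evaluate -> report, with a YAML config, provenance snapshots and a
# per-stage log. Stage seeds derive from the global seed with fixed offsets
# so every stage is independently reproducible.

PIPELINE_DEFAULTS <- list(
  seed = 1L,
  out = "strokesense_run",
  stages = c("simulate", "segment", "features", "biomarkers", "evaluate",
             "report"),
  simulation = list(n_elite = 3L, n_amateur = 5L, noise_sd = 0.5,
                    elite_peak_gain = 1.125),
  segmentation = list(threshold_g = 20, fallback_threshold_g = 12,
                      pre_samples = 40L, post_samples = 59L, skip_first = 3L,
                      min_detections_before_fallback = 4L,
                      refractory_samples = 100L, butter_order = 2L,
                      butter_cutoff_hz = 10),
  features = list(k_select = 50L),
  model = list(variant = "cnn_bilstm", temporal_filters = 8L,
               spatial_filters = 16L, bilstm_units = 16L, dropout = 0.5,
               epochs = 10L, lr = 1e-3, batch_size = 64L,
               weight_decay = 5e-3),
  evaluation = list(k_folds = 5L, mode = "stroke_level")
)

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills in defaults for every missing
#' stage (with a warning naming the stage), rejects unknown keys, and
#' validates stage parameters (positive thresholds, the 40 + 1 + 59 = 100
#' window identity, and so on).
#'
#' @param config Path to a YAML file, or a (possibly partial) config list.
#' @return The fully resolved configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("Config file not found: ", config),
            class = "strokesense_io_error")
    }
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "strokesense_config_error")
  }
  allowed <- list(
    simulation = setdiff(names(formals(simulation_config)), "seed"),
    segmentation = names(formals(segmentation_config)),
    features = names(PIPELINE_DEFAULTS$features),
    model = names(PIPELINE_DEFAULTS$model),
    evaluation = names(PIPELINE_DEFAULTS$evaluation)
  )
  for (stage in c("simulation", "segmentation", "features", "model",
                  "evaluation")) {
    if (stage %in% names(config)) {
      bad <- setdiff(names(config[[stage]]), allowed[[stage]])
      if (length(bad)) {
        abort(paste0("Unknown key(s) in `", stage, "`: ",
                     paste(bad, collapse = ", ")),
              class = "strokesense_config_error")
      }
    } else if (length(config)) {
      warn(paste0("Config section `", stage, "` missing; defaults applied."))
    }
  }
  out <- utils::modifyList(PIPELINE_DEFAULTS, config)
  # surface invalid values early via the constructors
  do.call(segmentation_config, out$segmentation)
  do.call(simulation_config, c(out$simulation, list(seed = out$seed)))
  architecture_config(variant = out$model$variant,
                      temporal_filters = out$model$temporal_filters,
                      spatial_filters = out$model$spatial_filters,
                      bilstm_units = out$model$bilstm_units,
                      dropout = out$model$dropout)
  out
}

#' @noRd
pipe_log <- function(log_path, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(line)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full pipeline
#'
#' Executes the requested stages in order, writing all artifacts (dataset,
#' window tensor, feature matrix, biomarker report, evaluation metrics and a
#' markdown report) plus the exact resolved configuration and a timing log
#' under the output directory.
#'
#' @param config A YAML path or config list (see [validate_config()]).
#' @param out_dir Output directory (overrides the config's `out`).
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- validate_config(config)
  out <- out_dir %||% cfg$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "pipeline.log")
  jsonlite::write_json(cfg, file.path(out, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  t0 <- Sys.time()
  tensor <- NULL

  if ("simulate" %in% cfg$stages) {
    sim_cfg <- do.call(simulation_config,
                       c(cfg$simulation, list(seed = cfg$seed)))
    simulate_dataset(sim_cfg, file.path(out, "dataset"), overwrite = TRUE)
    pipe_log(log_path, "simulate: dataset written to ", file.path(out, "dataset"))
  }

  if ("segment" %in% cfg$stages) {
    ds <- file.path(out, "dataset")
    if (!file.exists(file.path(ds, "ground_truth.csv"))) {
      abort("Missing upstream artifact: dataset/ground_truth.csv",
            class = "strokesense_missing_artifact")
    }
    truth <- readr::read_csv(file.path(ds, "ground_truth.csv"),
                             show_col_types = FALSE)
    seg_cfg <- do.call(segmentation_config, cfg$segmentation)
    csvs <- list.files(ds, pattern = "sens[12]\\.csv$", recursive = TRUE,
                       full.names = TRUE)
    pairs <- pair_recordings(csvs)$pairs
    windows <- list(); metas <- list()
    for (i in seq_len(nrow(pairs))) {
      dom <- read_recording(pairs$dominant[i])
      nd <- read_recording(pairs$non_dominant[i])
      stroke <- sub(".*_(\\w+)_sens1\\.csv$", "\\1",
                    basename(pairs$dominant[i]))
      skill <- truth$skill[match(paste0("P", pairs$participant_id[i]),
                                 truth$participant_id)]
      bil <- synchronize(dom, nd, stroke_type = stroke, skill_label = skill)
      seg <- segment_recording(bil, seg_cfg)
      pipe_log(log_path, sprintf(
        "segment: %s %s - %d windows (threshold %g g, %d rejected)",
        bil$participant_id, stroke, length(seg$windows), seg$threshold_used,
        nrow(seg$rejections)))
      windows <- c(windows, seg$windows)
      metas[[length(metas) + 1L]] <- seg$meta
    }
    tensor <- assemble_tensor(windows, dplyr::bind_rows(metas))
    save_tensor(tensor, file.path(out, "windows.rds"))
    pipe_log(log_path, "segment: ", dim(tensor$windows)[1], " windows total")
  }

  need_tensor <- function() {
    if (!is.null(tensor)) return(tensor)
    p <- file.path(out, "windows.rds")
    if (!file.exists(p)) {
      abort("Missing upstream artifact: windows.rds",
            class = "strokesense_missing_artifact")
    }
    load_tensor(p)
  }

  feats <- NULL
  if ("features" %in% cfg$stages) {
    tensor <- need_tensor()
    feats <- extract_all(tensor)
    readr::write_csv(dplyr::bind_cols(tensor$meta, feats),
                     file.path(out, "features.csv"), progress = FALSE)
    pipe_log(log_path, "features: ", ncol(feats), " features x ",
             nrow(feats), " windows")
  }

  if ("biomarkers" %in% cfg$stages) {
    tensor <- need_tensor()
    asin_tbl <- asymmetry_index(tensor)
    gs <- group_summary(tensor)
    peaks <- vapply(seq_len(dim(tensor$windows)[1]), function(i) {
      max(magnitude(tensor_window(tensor, i)[, 1:3]))
    }, numeric(1))
    anova_tbl <- two_way_anova(peaks, tensor$meta$stroke_type,
                               tensor$meta$skill)
    d_by_stroke <- asin_tbl |>
      dplyr::group_by(.data$stroke_type) |>
      dplyr::group_modify(function(d, key) {
        el <- peaks[tensor$meta$stroke_type == key$stroke_type &
                      tensor$meta$skill == "elite"]
        am <- peaks[tensor$meta$stroke_type == key$stroke_type &
                      tensor$meta$skill == "amateur"]
        tibble::tibble(cohens_d = if (length(el) > 1 && length(am) > 1)
          cohens_d(el, am) else NA_real_)
      }) |> dplyr::ungroup()
    med <- asin_tbl |>
      dplyr::group_by(.data$skill) |>
      dplyr::summarise(median_asin = median(.data$asin),
                       iqr_asin = stats::IQR(.data$asin), .groups = "drop")
    jsonlite::write_json(
      list(asin_by_group = med, group_summary = gs,
           anova = tidy(anova_tbl), cohens_d = d_by_stroke),
      file.path(out, "biomarkers.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA, dataframe = "rows")
    pipe_log(log_path, "biomarkers: median AsIn ",
             paste(sprintf("%s=%.3f", med$skill, med$median_asin),
                   collapse = " "))
  }

  if ("evaluate" %in% cfg$stages) {
    tensor <- need_tensor()
    folds <- make_folds(tensor$meta$skill, k = cfg$evaluation$k_folds,
                        mode = cfg$evaluation$mode, seed = cfg$seed + 1L,
                        participants = tensor$meta$participant_id)
    arch <- architecture_config(
      variant = cfg$model$variant,
      temporal_filters = cfg$model$temporal_filters,
      spatial_filters = cfg$model$spatial_filters,
      bilstm_units = cfg$model$bilstm_units, dropout = cfg$model$dropout)
    tc <- train_config(lr = cfg$model$lr, epochs = cfg$model$epochs,
                       batch_size = min(cfg$model$batch_size,
                                        sum(folds$fold != 1L)),
                       weight_decay = cfg$model$weight_decay,
                       seed = cfg$seed + 2L)
    cv <- cross_validate(tensor, folds, arch, tc)
    jsonlite::write_json(
      list(mean_accuracy = cv$mean_accuracy, sd_accuracy = cv$sd_accuracy,
           pam = cv$pam$pam, pam_metrics = as.list(cv$pam$metrics),
           per_stroke = cv$per_stroke, fold_metrics = cv$fold_metrics),
      file.path(out, "metrics.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA, dataframe = "rows")
    if (!is.null(feats)) {
      readr::write_csv(mi_ranking(feats, tensor$meta$skill),
                       file.path(out, "mi_ranking.csv"), progress = FALSE)
    }
    pipe_log(log_path, sprintf("evaluate: CV accuracy %.4f (+/- %.4f), PAM %.4f",
                               cv$mean_accuracy, cv$sd_accuracy, cv$pam$pam))
  }

  if ("report" %in% cfg$stages) {
    report(out)
    pipe_log(log_path, "report: written")
  }
  pipe_log(log_path, sprintf("done in %.1f s",
                             as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(out)
}

#' Summarize a pipeline run as markdown
#'
#' Collects the evaluation metrics, PAM, asymmetry medians and top
#' mutual-information features from a run directory into a human-readable
#' `report.md`. Missing artifacts are listed as absent rather than raising.
#'
#' @param artifacts_dir A [run_pipeline()] output directory.
#' @return The markdown string, invisibly; also written to
#'   `artifacts_dir/report.md`.
#' @export
report <- function(artifacts_dir) {
  lines <- c("# Stroke expertise analysis report", "")
  mp <- file.path(artifacts_dir, "metrics.json")
  if (file.exists(mp)) {
    m <- jsonlite::read_json(mp, simplifyVector = TRUE)
    lines <- c(lines,
               sprintf("Cross-validated accuracy: **%.2f%%** (+/- %.2f)",
                       100 * m$mean_accuracy, 100 * m$sd_accuracy),
               sprintf("Polygon Area Metric: **%.3f**", m$pam), "")
    ps <- tibble::as_tibble(m$per_stroke)
    for (st in unique(ps$stroke_type)) {
      d <- ps[ps$stroke_type == st, ]
      lines <- c(lines, paste0("## ", st), "",
                 "| class | precision | recall | F1 | accuracy |",
                 "|---|---|---|---|---|",
                 sprintf("| %s | %.2f | %.2f | %.2f | %.2f |",
                         d$class, d$precision, d$recall, d$f1, d$accuracy),
                 "")
    }
  } else {
    lines <- c(lines, "Evaluation metrics: not available.", "")
  }
  bp <- file.path(artifacts_dir, "biomarkers.json")
  if (file.exists(bp)) {
    b <- jsonlite::read_json(bp, simplifyVector = TRUE)
    med <- tibble::as_tibble(b$asin_by_group)
    lines <- c(lines, "## Bilateral asymmetry", "",
               sprintf("- %s: median AsIn %.3f (IQR %.3f)",
                       med$skill, med$median_asin, med$iqr_asin), "")
  } else {
    lines <- c(lines, "Biomarker summary: not available.", "")
  }
  rp <- file.path(artifacts_dir, "mi_ranking.csv")
  if (file.exists(rp)) {
    mi <- readr::read_csv(rp, show_col_types = FALSE, n_max = 10)
    lines <- c(lines, "## Top mutual-information features", "",
               sprintf("%d. `%s` (MI %.3f)", seq_len(nrow(mi)), mi$feature,
                       mi$mi), "")
  }
  txt <- paste(lines, collapse = "\n")
  writeLines(txt, file.path(artifacts_dir, "report.md"))
  invisible(txt)
}
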