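#' Pipeline configuration
#'
#' All tunable constants of the analysis in one JSON-serializable list:
#' preprocessing options, the three threshold grids, quality-control limits
#' and statistics options. Defaults are the package's standard analysis
#' settings (absolute thresholds 0.15-0.75 step 0.05, costs 0.10-0.85 step
#' 0.05, per-edge significance 0.05, CV limit 7.5% in more than 80% of
#' channels, 5th-order low-pass at 0.4 Hz, DPF 6.0).
#'
#' @param seed Integer seed for every stochastic stage (simulation, Dunnett
#'   Monte-Carlo).
#' @param ... Named overrides of individual entries (partial lists are merged).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    preprocess = list(
      wavelet = list(enabled = TRUE, iqr_factor = 1.5),
      filter = list(enabled = TRUE, order = 5, fc_hz = 0.4),
      beer_lambert = list(dpf = c(6, 6)),
      cbsi = TRUE
    ),
    qc = list(cv_threshold = 0.075, channel_fraction_threshold = 0.80),
    thresholds = list(
      absolute = seq(0.15, 0.75, by = 0.05),
      cost = seq(0.10, 0.85, by = 0.05),
      surrogate_alpha = 0.05
    ),
    stats = list(log_epsilon = 1e-6, dunnett_mc = 1e5)
  )
  dots <- list(...)
  merge_lists <- function(base, new) {
    for (nm in names(new)) {
      if (is.list(new[[nm]]) && is.list(base[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], new[[nm]])
      } else {
        base[[nm]] <- new[[nm]]
      }
    }
    base
  }
  cfg <- merge_lists(cfg, dots)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Network metrics of one preprocessed session
#'
#' Epochs the total-hemoglobin series, builds the Pearson connection matrix of
#' each of the seven states, applies the three thresholding schemes over their
#' grids, and returns global metrics in long form plus the local weighted
#' densities of the surrogate-thresholded network.
#'
#' Metric names: `D` = binary global density, `WD` = weighted global density,
#' `C` = binary clustering coefficient, `E` = binary global efficiency.
#' Cost-grid `C`, `E` and `D` are also summed across the grid (scheme
#' `"cost_integrated"`).
#'
#' @param hemo A `hemo_signals` object.
#' @param config A `pipeline_config`.
#' @return List with `global` and `local` tibbles.
#' @export
session_networks <- function(hemo, config = pipeline_config()) {
  segs <- extract_segments(hemo)
  th <- config$thresholds
  global <- purrr::map_dfr(seq_len(nrow(segs)), function(i) {
    cm <- pearson_matrix(segs$data[[i]])
    rows <- list()
    for (tau in th$absolute) {
      net_w <- threshold_absolute(cm, tau)
      rows[[length(rows) + 1]] <- tibble(
        scheme = "absolute", parameter = tau,
        metric = c("WD", "D"),
        value = c(global_density(net_w), global_density(binarize(net_w)))
      )
    }
    net_s <- threshold_surrogate(cm, th$surrogate_alpha)
    rows[[length(rows) + 1]] <- tibble(
      scheme = "surrogate", parameter = th$surrogate_alpha,
      metric = c("WD", "D"),
      value = c(global_density(net_s), global_density(binarize(net_s)))
    )
    ci <- cost_integrated_metrics(cm, th$cost)
    per <- ci$per_cost[[1]]
    rows[[length(rows) + 1]] <- tibble(
      scheme = "cost", parameter = rep(per$cost, 3),
      metric = rep(c("D", "C", "E"), each = nrow(per)),
      value = c(per$D, per$C, per$E)
    )
    rows[[length(rows) + 1]] <- tibble(
      scheme = "cost_integrated", parameter = NA_real_,
      metric = c("D", "C", "E"), value = c(ci$D, ci$C, ci$E)
    )
    out <- dplyr::bind_rows(rows)
    out$task_state <- as.character(segs$label[i])
    out
  })
  local <- purrr::map_dfr(seq_len(nrow(segs)), function(i) {
    cm <- pearson_matrix(segs$data[[i]])
    net_s <- threshold_surrogate(cm, th$surrogate_alpha)
    tibble(
      task_state = as.character(segs$label[i]),
      channel = seq_len(nrow(net_s$weights)),
      value = local_density(net_s)
    )
  })
  meta <- function(df) {
    df$subject <- hemo$subject_id
    df$sleep_state <- hemo$sleep_state
    df
  }
  list(global = meta(global), local = meta(local))
}

#' Run the full analysis pipeline
#'
#' Executes quality control, preprocessing, connectivity, network metrics and
#' the statistical analysis on a cohort, and (optionally) writes all result
#' tables to an output directory.
#'
#' Stages: (1) per-recording coefficient-of-variation QC and subject
#' exclusion; (2) wavelet artifact suppression, low-pass filtering, modified
#' Beer-Lambert conversion, CBSI; (3) state epoching and Pearson connection
#' matrices; (4) absolute/cost/surrogate thresholding and binary/weighted
#' metrics; (5) log-transformed repeated-measures ANOVAs (sleep x task, with
#' threshold as a third within factor for the absolute scheme), Dunnett-style
#' comparisons against rest, the sleep-deprivation connectivity change and its
#' correlation with cognitive-score changes, between-subject concordance
#' (Kendall's W) and channel-wise FDR-corrected contrast maps.
#'
#' @param config A `pipeline_config`.
#' @param cohort A `synthetic_cohort` or a list with `recordings` (and
#'   optionally `cognitive_scores`). If `NULL`, `input_dir` is read; if that
#'   is also `NULL`, a default cohort is simulated from `config$seed`.
#' @param input_dir Directory of SNIRF files + `scores.csv` to analyze.
#' @param out_dir Output directory for result files (optional).
#' @return (Invisibly) a list with `qc`, `excluded_subjects`, `metrics`,
#'   `local`, `anova`, `dunnett`, `delta_wd`, `correlations`, `kendalls_w`,
#'   `contrast_maps` and `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         input_dir = NULL, out_dir = NULL) {
  t_start <- proc.time()[["elapsed"]]
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  lap <- function(name, t0) timings[[name]] <<- round(tic() - t0, 2)

  t0 <- tic()
  if (is.null(cohort)) {
    if (!is.null(input_dir)) {
      cohort <- read_cohort(input_dir)
    } else {
      cohort <- generate_cohort(simulation_spec(seed = config$seed))
    }
  }
  recordings <- cohort$recordings
  scores <- cohort$cognitive_scores
  lap("load", t0)

  # --- quality control ---------------------------------------------------
  t0 <- tic()
  qc <- purrr::map_dfr(recordings, function(rec) {
    rep <- subject_qc(rec, config$qc$cv_threshold,
                      config$qc$channel_fraction_threshold)
    tibble(subject = rec$subject_id, sleep_state = rec$sleep_state,
           fraction_bad = rep$fraction_bad, excluded = rep$excluded)
  })
  excluded_subjects <- sort(unique(qc$subject[qc$excluded]))
  retained <- purrr::keep(recordings,
                          ~ !(.x$subject_id %in% excluded_subjects))
  if (length(retained) == 0) abort("quality control excluded every subject")
  lap("qc", t0)

  # --- preprocessing + connectivity + metrics ----------------------------
  t0 <- tic()
  per_session <- purrr::map(retained, function(rec) {
    hemo <- preprocess_recording(rec, config)
    session_networks(hemo, config)
  })
  metrics <- dplyr::bind_rows(purrr::map(per_session, "global"))
  local <- dplyr::bind_rows(purrr::map(per_session, "local"))
  lap("metrics", t0)

  # --- statistics --------------------------------------------------------
  t0 <- tic()
  eps <- config$stats$log_epsilon
  slice <- function(df, sch, met) {
    df[df$scheme == sch & df$metric == met, ]
  }
  anova <- list()
  n_subj <- length(unique(metrics$subject))
  if (n_subj >= 2) {
    abs_d <- slice(metrics, "absolute", "D")
    abs_d$threshold <- abs_d$parameter
    anova$absolute_binary_D <- rm_anova(
      log_transform(abs_d, eps),
      within = c("sleep_state", "task_state", "threshold")
    )
    anova$surrogate_binary_D <- rm_anova(
      log_transform(slice(metrics, "surrogate", "D"), eps)
    )
    anova$surrogate_weighted_WD <- rm_anova(
      log_transform(slice(metrics, "surrogate", "WD"), eps)
    )
    anova$cost_integrated_C <- rm_anova(
      log_transform(slice(metrics, "cost_integrated", "C"), eps)
    )
    anova$cost_integrated_E <- rm_anova(
      log_transform(slice(metrics, "cost_integrated", "E"), eps)
    )
  }

  surrogate_d <- slice(metrics, "surrogate", "D")
  dunnett <- if (n_subj >= 2) {
    dplyr::bind_rows(
      dunnett_vs_rest(surrogate_d, "before_SD", n_mc = config$stats$dunnett_mc),
      dunnett_vs_rest(surrogate_d, "after_SD", n_mc = config$stats$dunnett_mc)
    )
  } else {
    NULL
  }

  dwd <- delta_wd(slice(metrics, "surrogate", "WD"))
  correlations <- if (!is.null(scores) && nrow(dwd) >= 3) {
    brain_behavior_correlation(dwd, scores)
  } else {
    NULL
  }

  # concordance of subjects on the channel ranking of the SD effect
  kw <- NA_real_
  contrast_maps <- NULL
  if (n_subj >= 2) {
    tmr <- local |>
      dplyr::group_by(.data$subject, .data$sleep_state, .data$channel) |>
      dplyr::summarise(
        tmr = mean(.data$value[.data$task_state != "Rest"]) -
          .data$value[.data$task_state == "Rest"][1],
        .groups = "drop"
      ) |>
      tidyr::pivot_wider(names_from = "sleep_state", values_from = "tmr") |>
      dplyr::mutate(effect = .data$after_SD - .data$before_SD)
    effect_mat <- tmr |>
      dplyr::select("subject", "channel", "effect") |>
      tidyr::pivot_wider(names_from = "channel", values_from = "effect") |>
      dplyr::select(-"subject") |>
      as.matrix()
    kw <- kendalls_w(effect_mat)
    contrast_maps <- list(
      task_minus_rest_before = channelwise_contrast_map(local, "task_minus_rest_before"),
      task_minus_rest_after = channelwise_contrast_map(local, "task_minus_rest_after"),
      sd_effect = channelwise_contrast_map(local, "sd_effect")
    )
  }
  lap("stats", t0)

  result <- list(
    qc = qc, excluded_subjects = excluded_subjects,
    metrics = metrics, local = local,
    anova = anova, dunnett = dunnett, delta_wd = dwd,
    correlations = correlations, kendalls_w = kw,
    contrast_maps = contrast_maps, config = config,
    timings = timings, paths = NULL
  )

  if (!is.null(out_dir)) {
    t0 <- tic()
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(results = file.path(out_dir, "results.tsv"))
    write_results_table(metrics, paths$results)
    paths$local <- file.path(out_dir, "local_density.tsv")
    write_tsv_deterministic(
      dplyr::arrange(local, .data$subject, .data$sleep_state,
                     .data$task_state, .data$channel),
      paths$local
    )
    paths$anova <- file.path(out_dir, "anova.json")
    jsonlite::write_json(purrr::map(anova, ~ as.data.frame(.x$table)),
                         paths$anova, auto_unbox = TRUE, digits = NA)
    paths$delta_wd <- file.path(out_dir, "delta_wd.tsv")
    write_tsv_deterministic(dwd, paths$delta_wd)
    if (!is.null(dunnett)) {
      paths$dunnett <- file.path(out_dir, "dunnett.tsv")
      write_tsv_deterministic(dunnett, paths$dunnett)
    }
    if (!is.null(correlations)) {
      paths$correlations <- file.path(out_dir, "correlations.tsv")
      write_tsv_deterministic(correlations, paths$correlations)
    }
    if (!is.null(contrast_maps)) {
      for (nm in names(contrast_maps)) {
        paths[[paste0("map_", nm)]] <-
          file.path(out_dir, paste0("channel_map_", nm, ".tsv"))
        write_tsv_deterministic(contrast_maps[[nm]],
                                paths[[paste0("map_", nm)]])
      }
    }
    paths$config <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                         digits = NA)
    lap("write", t0)
    log_lines <- c(
      sprintf("excluded subjects: %s",
              if (length(excluded_subjects) == 0) "none"
              else paste(excluded_subjects, collapse = ", ")),
      sprintf("stage %s: %.2f s", names(timings), unlist(timings)),
      sprintf("total: %.2f s", tic() - t_start)
    )
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
    result$paths <- paths
  }
  invisible(result)
}

# Locale-independent, fully deterministic TSV writer.
write_tsv_deterministic <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.10g", df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Write the network-metric results table
#'
#' Tab-separated, one row per subject x sleep state x task state x scheme x
#' threshold parameter, with the metrics as columns (`D` binary density, `WD`
#' weighted density, `C` clustering, `E` efficiency; absent metrics are
#' blank). Row order is deterministic, so re-running on the same input yields
#' a byte-identical file.
#'
#' @param cohort_results Long metrics tibble as produced by [run_pipeline()]
#'   (columns `subject`, `sleep_state`, `task_state`, `scheme`, `parameter`,
#'   `metric`, `value`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(cohort_results, path) {
  cols <- c("subject", "sleep_state", "task_state", "scheme", "parameter")
  if (nrow(cohort_results) == 0) {
    header <- c(cols, "D", "WD", "C", "E")
    writeLines(paste(header, collapse = "\t"), path)
    return(invisible(path))
  }
  wide <- cohort_results |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(cols),
                       names_from = "metric", values_from = "value") |>
    dplyr::arrange(.data$subject, .data$sleep_state, .data$task_state,
                   .data$scheme, .data$parameter)
  for (m in c("D", "WD", "C", "E")) {
    if (!m %in% names(wide)) wide[[m]] <- NA_real_
  }
  wide <- wide[, c(cols, "D", "WD", "C", "E")]
  write_tsv_deterministic(wide, path)
}
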